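#' Sliding-window quality trimming
#'
#' Scans each read 5' to 3' with a window of `window` bases, one base per
#' step. At the first window whose mean Phred quality falls below
#' `threshold`, the read is truncated so that nothing at or beyond that
#' window's start position remains. Reads with no failing window, and reads
#' shorter than the window, are returned unchanged. The mean comparison is
#' exact (`sum(quals) < threshold * window` on integers), so no floating
#' point ties can occur.
#'
#' @param reads Reads tibble as returned by [read_fastq()].
#' @param window Window width in bases (default 10).
#' @param threshold Minimum mean Phred quality per window (default 20).
#' @return Reads tibble with `bases`/`quals` truncated where a window
#'   failed. Reads trimmed to length zero are kept as empty rows (the
#'   length filter removes them downstream).
#' @export
trim_sliding_window <- function(reads, window = 10L, threshold = 20) {
  stopifnot(window >= 1)
  cut_at <- vapply(reads$quals, first_failing_window, integer(1),
                   window = as.integer(window), threshold = threshold)
  needs_trim <- !is.na(cut_at)
  if (any(needs_trim)) {
    keep_len <- cut_at[needs_trim] - 1L
    reads$bases[needs_trim] <- substr(reads$bases[needs_trim], 1L, keep_len)
    reads$quals[needs_trim] <- Map(
      function(q, k) q[seq_len(k)], reads$quals[needs_trim], keep_len
    )
  }
  reads
}

# Start position of the first window with mean quality < threshold, or NA.
first_failing_window <- function(quals, window, threshold) {
  n <- length(quals)
  if (n < window) return(NA_integer_)
  sums <- cumsum(as.numeric(quals))
  win_sums <- sums[window:n] - c(0, sums)[seq_len(n - window + 1L)]
  bad <- which(win_sums < threshold * window)
  if (length(bad) == 0L) NA_integer_ else bad[1L]
}

#' Mask low-quality bases with N
#'
#' Every base whose Phred score is strictly below `threshold` is replaced
#' with `N`. Qualities and read length are unchanged.
#'
#' @inheritParams trim_sliding_window
#' @param threshold Phred score below which a base is masked (default 20).
#' @return Reads tibble with low-quality bases masked.
#' @export
mask_low_quality <- function(reads, threshold = 20) {
  if (nrow(reads) == 0L) return(reads)
  reads$bases <- mapply(
    function(b, q) {
      low <- which(q < threshold)
      if (length(low) == 0L) return(b)
      chars <- strsplit(b, "", fixed = TRUE)[[1]]
      chars[low] <- "N"
      paste(chars, collapse = "")
    },
    reads$bases, reads$quals,
    USE.NAMES = FALSE
  )
  reads
}

#' Read-level N-count and length filter
#'
#' A read is discarded iff it contains more than `max_n` masked (`N`) bases
#' or is shorter than `min_len` bases; both boundaries keep the read.
#'
#' @inheritParams trim_sliding_window
#' @param max_n Maximum tolerated number of `N` bases (default 10).
#' @param min_len Minimum read length in bases (default 100).
#' @return Logical vector, `TRUE` where the read is kept.
#' @export
filter_read <- function(reads, max_n = 10L, min_len = 100L) {
  n_count <- nchar(reads$bases) - nchar(gsub("N", "", reads$bases,
                                             fixed = TRUE))
  n_count <= max_n & nchar(reads$bases) >= min_len
}

#' Read quality-control pipeline
#'
#' Applies, in order: sliding-window trimming, low-quality masking, and the
#' N-count/length filter. The pipeline is deterministic and idempotent:
#' re-running it on its own output changes nothing.
#'
#' @inheritParams trim_sliding_window
#' @param mask_threshold Phred score below which bases are masked
#'   (default 20).
#' @param max_n,min_len Filter parameters, see [filter_read()].
#' @return A list with `reads` (the kept reads tibble, post trim and mask)
#'   and `summary`, a list of counters: `input`, `trimmed` (reads shortened
#'   by the window trim), `masked_bases` (total bases replaced with N),
#'   `discarded`, and `kept`.
#' @export
qc_pipeline <- function(reads, window = 10L, threshold = 20,
                        mask_threshold = 20, max_n = 10L, min_len = 100L) {
  n_in <- nrow(reads)
  trimmed <- trim_sliding_window(reads, window = window,
                                 threshold = threshold)
  n_trimmed <- sum(nchar(trimmed$bases) < nchar(reads$bases))
  n_before_mask <- count_n(trimmed$bases)
  masked <- mask_low_quality(trimmed, threshold = mask_threshold)
  n_masked <- count_n(masked$bases) - n_before_mask
  keep <- filter_read(masked, max_n = max_n, min_len = min_len)
  list(
    reads = masked[keep, , drop = FALSE],
    summary = list(
      input = n_in,
      trimmed = n_trimmed,
      masked_bases = n_masked,
      discarded = sum(!keep),
      kept = sum(keep)
    )
  )
}

count_n <- function(bases) {
  sum(nchar(bases) - nchar(gsub("N", "", bases, fixed = TRUE)))
}
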