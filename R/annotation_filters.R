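#' V-gene germline identity filter
#'
#' Discards sequences whose V-segment germline identity is strictly below
#' `min_identity` (default 60%); a sequence exactly at the threshold is
#' kept.
#'
#' @param v_identity Numeric vector of germline identity fractions in
#'   \[0, 1\].
#' @param min_identity Minimum identity to keep (default 0.60).
#' @return Logical vector, `TRUE` where the sequence is kept.
#' @export
filter_v_identity <- function(v_identity, min_identity = 0.60) {
  if (anyNA(v_identity)) {
    stop("v_identity is missing for some sequences", call. = FALSE)
  }
  v_identity >= min_identity
}

#' Trim IMGT-aligned sequences to position 150
#'
#' FR1 primers overlap the 5' end of the V segment, so the first 150 IMGT
#' positions are removed before any mutation-bearing analysis: each
#' sequence (and its germline alignment, when present) is kept from IMGT
#' position 151 onward. A sequence whose alignment begins strictly after
#' position 150 is discarded; one beginning exactly at 150 is kept.
#'
#' Alignment convention: string position i of `sequence` is IMGT position
#' i, with leading `.` or `-` characters marking positions before the
#' sequence starts.
#'
#' @param rearrs Rearrangement tibble (see [read_airr()]) whose `sequence`
#'   column is IMGT-aligned from position 1.
#' @param at IMGT position through which to trim (default 150).
#' @return The tibble with late-starting sequences removed and `sequence` /
#'   `germline` truncated to positions `at + 1` onward.
#' @export
trim_to_imgt_150 <- function(rearrs, at = 150L) {
  if (!"sequence" %in% names(rearrs) || anyNA(rearrs$sequence)) {
    stop("sequences lack an IMGT positional alignment", call. = FALSE)
  }
  first_pos <- imgt_start(rearrs$sequence)
  keep <- first_pos <= at
  out <- rearrs[keep, , drop = FALSE]
  out$sequence <- substring(out$sequence, at + 1L)
  if ("germline" %in% names(out)) {
    out$germline <- ifelse(is.na(out$germline), out$germline,
                           substring(out$germline, at + 1L))
  }
  out
}

# 1-based IMGT position at which each aligned sequence starts (first
# character that is not a gap/pad).
imgt_start <- function(sequence) {
  pos <- regexpr("[^.\\-]", sequence)
  pos <- as.integer(pos)
  pos[pos < 0] <- nchar(sequence)[pos < 0] + 1L  # all-gap: starts past end
  pos
}

#' Extract the IMGT family from V/J gene names
#'
#' The family is the gene-name prefix up to (not including) the first
#' hyphen or asterisk, e.g. `IGHV3-23*01` belongs to family `IGHV3`.
#'
#' @param genes Character vector of gene names.
#' @return Character vector of family names.
#' @export
gene_family <- function(genes) {
  sub("[-*].*$", "", genes)
}

#' Cross-family V-call filter
#'
#' A sequence annotated with V genes from two or more different IMGT
#' families likely derives from a hybrid PCR product and is discarded.
#' Same-family V ties are kept, and cross-family J ties are never a reason
#' for discarding (this filter only inspects V calls).
#'
#' @param v_call Character vector of (possibly tied, comma-separated)
#'   V-gene calls.
#' @return Logical vector, `TRUE` where the sequence is kept.
#' @export
filter_cross_family_v <- function(v_call) {
  vapply(
    gene_call_sets(v_call),
    function(genes) length(unique(gene_family(genes))) <= 1L,
    logical(1)
  )
}

#' Flag replicates with strongly imbalanced valid-read yield
#'
#' Within a subject, a replicate whose valid-read count is five or more
#' times lower than the best other replicate is flagged for
#' re-amplification and re-sequencing. With a single replicate nothing can
#' be compared, so nothing is flagged.
#'
#' @param stats Tibble of per-library statistics with columns
#'   `replicate_id`, `total_reads` and `valid_reads` (one subject).
#' @return Character vector of flagged `replicate_id`s.
#' @export
replicate_imbalance <- function(stats) {
  stopifnot(all(c("replicate_id", "total_reads", "valid_reads")
                %in% names(stats)),
            all(stats$valid_reads <= stats$total_reads))
  n <- nrow(stats)
  if (n < 2L) return(character())
  flagged <- vapply(seq_len(n), function(i) {
    best_other <- max(stats$valid_reads[-i])
    stats$valid_reads[i] <= best_other / 5
  }, logical(1))
  stats$replicate_id[flagged]
}

#' Per-replicate valid-read fractions
#'
#' @param stats Tibble with `replicate_id`, `total_reads`, `valid_reads`.
#' @return The tibble with an added `valid_fraction` column.
#' @export
valid_fractions <- function(stats) {
  stats$valid_fraction <- stats$valid_reads / stats$total_reads
  stats
}
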