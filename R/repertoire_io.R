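#' Read a FASTQ file of quality-scored reads
#'
#' Parses a FASTQ file with Sanger-encoded (Phred+33) base qualities into a
#' tibble of reads, one row per record, preserving input order. Sequence case
#' is preserved and `N` characters are kept as-is.
#'
#' @param path Path to a FASTQ file.
#' @return A tibble with columns `read_id` (character), `bases` (character,
#'   over `A`,`C`,`G`,`T`,`N`) and `quals` (list of integer Phred scores, one
#'   per base).
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGTN", "+", "IIII#"), fq)
#' read_fastq(fq)
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) {
    stop("FASTQ file not found: ", path, call. = FALSE)
  }
  if (file.size(path) == 0) {
    return(tibble::tibble(
      read_id = character(), bases = character(), quals = list()
    ))
  }
  validate_fastq(path)
  parsed <- tryCatch({
    xs <- suppressWarnings(
      Biostrings::readQualityScaledDNAStringSet(path,
                                                quality.scoring = "phred"))
    # the quality conversion is lazy, so force it here to surface
    # malformed records inside the tryCatch
    list(ids = names(xs), bases = unname(as.character(xs)),
         quals = lapply(as(Biostrings::quality(xs), "IntegerList"),
                        unname))
  }, error = function(e) diagnose_fastq(path, conditionMessage(e)))
  tibble::tibble(
    read_id = parsed$ids,
    bases = parsed$bases,
    quals = parsed$quals
  )
}

# Structural check of the 4-line records: a base/quality length mismatch is
# reported by record name. (The backing parser does not reliably detect
# short quality strings, so this runs before parsing.)
validate_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ file (truncated record at end): ", path,
         call. = FALSE)
  }
  n_rec <- length(lines) %/% 4L
  seqlen <- nchar(lines[4L * seq_len(n_rec) - 2L])
  qlen <- nchar(lines[4L * seq_len(n_rec)])
  bad <- which(seqlen != qlen)
  if (length(bad) > 0L) {
    hdr <- sub("^@", "", lines[4L * bad[1L] - 3L])
    stop("malformed FASTQ record ", hdr, ": ", seqlen[bad[1L]],
         " bases but ", qlen[bad[1L]], " quality scores", call. = FALSE)
  }
  invisible(path)
}

diagnose_fastq <- function(path, parent_msg) {
  stop("failed to parse FASTQ file ", path, ": ", parent_msg, call. = FALSE)
}

#' Write reads to a FASTQ file
#'
#' Inverse of [read_fastq()]: writes a reads tibble using Sanger Phred+33
#' quality encoding.
#'
#' @param reads Tibble as returned by [read_fastq()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "bases", "quals") %in% names(reads)))
  seqs <- Biostrings::DNAStringSet(reads$bases)
  names(seqs) <- reads$read_id
  qual_chr <- vapply(
    reads$quals,
    function(q) rawToChar(as.raw(as.integer(q) + 33L)),
    character(1)
  )
  qs <- Biostrings::QualityScaledDNAStringSet(
    seqs, Biostrings::PhredQuality(qual_chr)
  )
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

# Canonical internal column set for annotated rearrangements.
airr_internal_cols <- c(
  "sequence_id", "subject_id", "replicate_id", "v_call", "j_call",
  "sequence", "germline", "cdr3_nt", "cdr3_aa", "v_identity", "copies"
)

#' Read an AIRR Rearrangement TSV of annotated sequences
#'
#' Reads a tab-separated file following the AIRR Rearrangement schema (v1
#' column names) into the package's canonical rearrangement tibble. Gene
#' calls with ties are kept as comma-separated strings (e.g.
#' `"IGHV1-2,IGHV1-69"`). The `duplicate_count` column is optional and
#' defaults to 1 copy per row; the replicate label is read from
#' `repertoire_id` by default.
#'
#' @param path Path to a TSV file with AIRR v1 headers.
#' @param replicate_col Column holding the replicate/library label
#'   (default `"repertoire_id"`).
#' @param subject_col Column holding the subject label; if absent the single
#'   subject `"subject1"` is assumed.
#' @return A tibble with columns `sequence_id`, `subject_id`, `replicate_id`,
#'   `v_call`, `j_call`, `sequence` (the IMGT-aligned `sequence_alignment`),
#'   `germline` (`germline_alignment`, `NA` if absent), `cdr3_nt` (the
#'   `junction`), `cdr3_aa` (`junction_aa`), `v_identity` and `copies`.
#' @export
read_airr <- function(path, replicate_col = "repertoire_id",
                      subject_col = "subject_id") {
  raw <- utils::read.delim(path, sep = "\t", colClasses = "character",
                           check.names = FALSE, na.strings = NULL, quote = "")
  required <- c("sequence_id", "v_call", "j_call", "sequence_alignment",
                "junction", "junction_aa", replicate_col)
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("AIRR file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  tibble::tibble(
    sequence_id = raw$sequence_id,
    subject_id = if (subject_col %in% names(raw)) raw[[subject_col]]
                 else rep("subject1", n),
    replicate_id = raw[[replicate_col]],
    v_call = raw$v_call,
    j_call = raw$j_call,
    sequence = raw$sequence_alignment,
    germline = if ("germline_alignment" %in% names(raw))
                 raw$germline_alignment else rep(NA_character_, n),
    cdr3_nt = raw$junction,
    cdr3_aa = raw$junction_aa,
    v_identity = if ("v_identity" %in% names(raw))
                   as.numeric(raw$v_identity) else rep(NA_real_, n),
    copies = if ("duplicate_count" %in% names(raw))
               as.integer(raw$duplicate_count) else rep(1L, n)
  )
}

#' Write annotated rearrangements to an AIRR Rearrangement TSV
#'
#' Inverse of [read_airr()]: the canonical tibble is written back under AIRR
#' v1 column names, so that `read_airr(write_airr(x))` round-trips every
#' field.
#'
#' @param rearrs Rearrangement tibble as returned by [read_airr()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(rearrs, path) {
  stopifnot(all(airr_internal_cols %in% names(rearrs)))
  out <- data.frame(
    sequence_id = rearrs$sequence_id,
    subject_id = rearrs$subject_id,
    repertoire_id = rearrs$replicate_id,
    v_call = rearrs$v_call,
    j_call = rearrs$j_call,
    sequence_alignment = rearrs$sequence,
    germline_alignment = rearrs$germline,
    junction = rearrs$cdr3_nt,
    junction_aa = rearrs$cdr3_aa,
    v_identity = rearrs$v_identity,
    duplicate_count = rearrs$copies,
    check.names = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Split comma-separated gene calls into sets
#'
#' @param calls Character vector of (possibly tied) gene calls, comma
#'   separated.
#' @return List of character vectors, one per input call.
#' @export
gene_call_sets <- function(calls) {
  strsplit(calls, ",", fixed = TRUE)
}

#' Sequencing-run quality check
#'
#' Applies run-level pass criteria: the percentage of clusters passing the
#' instrument filter must be at least 90 and the percentage of bases at or
#' above Phred Q30 must be at least 70. Both boundaries are inclusive.
#'
#' @param pct_pass_filter Percentage of clusters passing filter, in
#'   \[0, 100\].
#' @param pct_q30 Percentage of bases with quality >= Q30, in \[0, 100\].
#' @return A list with `pass` (logical) and `reasons` (character vector of
#'   violated thresholds, empty when passing).
#' @examples
#' check_run_quality(95, 75)$pass
#' check_run_quality(89.9, 75)$reasons
#' @export
check_run_quality <- function(pct_pass_filter, pct_q30) {
  stopifnot(
    pct_pass_filter >= 0, pct_pass_filter <= 100,
    pct_q30 >= 0, pct_q30 <= 100
  )
  reasons <- character()
  if (pct_pass_filter < 90) {
    reasons <- c(reasons, sprintf(
      "%%PF %.4g below required 90", pct_pass_filter))
  }
  if (pct_q30 < 70) {
    reasons <- c(reasons, sprintf(
      "%%>=Q30 %.4g below required 70", pct_q30))
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}
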