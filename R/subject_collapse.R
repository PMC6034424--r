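#' N-tolerant sequence equality
#'
#' Two sequences are considered the same if they have equal length and
#' differ only at positions where either sequence has an `N`. Note the
#' relation is not transitive (`"ANG"` matches both `"AAG"` and `"ACG"`,
#' which do not match each other); [collapse_subject()] resolves this with
#' a deterministic greedy grouping.
#'
#' @param a,b Nucleotide strings over `A`,`C`,`G`,`T`,`N`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' sequences_equal_n("ANGT", "ACGT")
#' sequences_equal_n("AAGT", "ACGT")
#' @export
sequences_equal_n <- function(a, b) {
  if (nchar(a) != nchar(b)) return(FALSE)
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  n <- charToRaw("N")
  all(ra == rb | ra == n | rb == n)
}

#' Collapse identical sequences across a subject's replicates
#'
#' Groups a subject's annotated rearrangements into unique sequences under
#' N-tolerant equality ([sequences_equal_n()]), pooling copies across all
#' replicates. Exact duplicates are merged first; the remaining distinct
#' strings are then clustered greedily in descending total-copy order
#' (lexicographically smallest sequence first on ties), each string joining
#' the first established group whose founding sequence it matches. This
#' makes the grouping deterministic and independent of input record order
#' despite the non-transitive matching relation.
#'
#' Each group is reported as one unique sequence whose representative is
#' the member with the fewest `N`s (ties: highest copies, then
#' lexicographically smallest), so downstream CDR3 translation is maximally
#' informative. Total input copies are conserved.
#'
#' @param rearrs Rearrangement tibble (see [read_airr()]); all rows must
#'   share one `subject_id`.
#' @return A tibble of unique sequences with columns `useq_id`,
#'   `subject_id`, `sequence`, `v_call`, `j_call`, `cdr3_nt`, `cdr3_aa`,
#'   `germline`, `sequence_ids` (list of the input record ids collapsed
#'   into each row), `copies_by_replicate` (list of named integer
#'   vectors), `total_copies` and `instances` (number of replicates with
#'   nonzero copies).
#' @export
collapse_subject <- function(rearrs) {
  stopifnot(nrow(rearrs) > 0)
  if (length(unique(rearrs$subject_id)) != 1L) {
    stop("collapse_subject() requires records from a single subject",
         call. = FALSE)
  }

  # merge exact duplicates, keeping per-replicate copy tallies
  agg <- rearrs |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(
      v_call = .data$v_call[which.max(.data$copies)],
      j_call = .data$j_call[which.max(.data$copies)],
      cdr3_nt = .data$cdr3_nt[which.max(.data$copies)],
      cdr3_aa = .data$cdr3_aa[which.max(.data$copies)],
      germline = .data$germline[which.max(.data$copies)],
      sequence_ids = list(.data$sequence_id),
      copies_by_replicate = list(tapply(.data$copies, .data$replicate_id,
                                        sum)),
      total_copies = sum(.data$copies),
      .groups = "drop"
    )
  ord <- order(-agg$total_copies, agg$sequence)
  agg <- agg[ord, , drop = FALSE]

  has_n <- grepl("N", agg$sequence, fixed = TRUE)
  lens <- nchar(agg$sequence)
  k <- nrow(agg)
  group_of <- integer(k)
  seed_idx <- integer(0)  # indices into agg of group founders
  for (i in seq_len(k)) {
    assigned <- 0L
    # a string can only match a non-identical seed if one side carries an N
    if (length(seed_idx) > 0L) {
      cand <- seed_idx[lens[seed_idx] == lens[i] &
                         (has_n[seed_idx] | has_n[i])]
      for (s in cand) {
        if (sequences_equal_n(agg$sequence[i], agg$sequence[s])) {
          assigned <- group_of[s]
          break
        }
      }
    }
    if (assigned == 0L) {
      seed_idx <- c(seed_idx, i)
      assigned <- length(seed_idx)
    }
    group_of[i] <- assigned
  }

  groups <- split(seq_len(k), group_of)
  rows <- lapply(groups, function(idx) {
    members <- agg[idx, , drop = FALSE]
    n_counts <- nchar(members$sequence) -
      nchar(gsub("N", "", members$sequence, fixed = TRUE))
    rep_ord <- order(n_counts, -members$total_copies, members$sequence)
    rep_row <- members[rep_ord[1L], , drop = FALSE]
    cbr_all <- unlist(members$copies_by_replicate)
    cbr <- tapply(as.integer(cbr_all), names(cbr_all), sum)
    cbr <- cbr[order(names(cbr))]
    tibble::tibble(
      sequence = rep_row$sequence,
      v_call = rep_row$v_call,
      j_call = rep_row$j_call,
      cdr3_nt = rep_row$cdr3_nt,
      cdr3_aa = rep_row$cdr3_aa,
      germline = rep_row$germline,
      sequence_ids = list(unlist(members$sequence_ids)),
      copies_by_replicate = list(cbr),
      total_copies = sum(members$total_copies),
      instances = sum(cbr > 0)
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(-out$total_copies, out$sequence), , drop = FALSE]
  tibble::tibble(
    useq_id = sprintf("U%05d", seq_len(nrow(out))),
    subject_id = rearrs$subject_id[1L],
    out
  )
}

#' Count sequences rescued by subject-wide copy pooling
#'
#' A sequence observed once in each of two or more replicates reaches the
#' copy >= 2 eligibility threshold only because copies are pooled across
#' the subject before filtering. This reports how many unique sequences
#' were rescued that way: total copies of at least 2 but no single
#' replicate contributing more than 1.
#'
#' @param useqs Unique-sequence tibble from [collapse_subject()].
#' @return Integer count of rescued unique sequences.
#' @export
rescue_low_copy <- function(useqs) {
  sum(vapply(
    useqs$copies_by_replicate,
    function(cbr) sum(cbr) >= 2L && max(cbr) == 1L,
    logical(1)
  ))
}
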