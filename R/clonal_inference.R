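#' Clone-assignment eligibility of unique sequences
#'
#' To prevent spurious clones, a unique sequence is excluded from clonal
#' assignment when any of the following holds, reported with the first
#' matching reason:
#' * `low_copy` — total copies across the subject below 2;
#' * `cdr3_stop` — a stop codon (`*`) in the CDR3 amino-acid sequence;
#' * `indel_window` — some 30-nt window of the germline-aligned sequence
#'   falls below 60% germline identity, the signature of an uncorrected
#'   insertion/deletion. Positions where either strand carries an `N` (or
#'   an alignment gap) are excluded from both the numerator and the
#'   denominator of the window identity; a window is only judged when at
#'   least half of its positions remain comparable, since identity
#'   estimated from a handful of positions is too noisy to call an indel.
#'
#' When no germline alignment is available the indel-window check is
#' skipped with a warning.
#'
#' @param useqs Unique-sequence tibble from [collapse_subject()].
#' @param min_copies Minimum subject-wide copy number (default 2).
#' @param window Indel-scan window width in nucleotides (default 30).
#' @param min_window_identity Minimum germline identity per window
#'   (default 0.60).
#' @return The tibble with an added `excluded_reason` column, one of
#'   `"low_copy"`, `"cdr3_stop"`, `"indel_window"` or `"none"`.
#' @export
eligible <- function(useqs, min_copies = 2L, window = 30L,
                     min_window_identity = 0.60) {
  reason <- rep("none", nrow(useqs))
  reason[grepl("*", useqs$cdr3_aa, fixed = TRUE)] <- "cdr3_stop"
  no_germ <- is.na(useqs$germline)
  if (any(no_germ)) {
    warning("no germline alignment for ", sum(no_germ),
            " unique sequence(s); indel-window check skipped for those",
            call. = FALSE)
  }
  check <- which(reason == "none" & !no_germ)
  bad_window <- vapply(check, function(i) {
    has_low_identity_window(useqs$sequence[i], useqs$germline[i],
                            window, min_window_identity)
  }, logical(1))
  reason[check[bad_window]] <- "indel_window"
  reason[useqs$total_copies < min_copies] <- "low_copy"
  useqs$excluded_reason <- reason
  useqs
}

# TRUE if any width-`window` window of the alignment has germline identity
# below `min_identity`, ignoring positions where either string is N or a gap.
has_low_identity_window <- function(sequence, germline, window,
                                    min_identity) {
  L <- min(nchar(sequence), nchar(germline))
  if (L < window) return(FALSE)
  rs <- charToRaw(substr(sequence, 1L, L))
  rg <- charToRaw(substr(germline, 1L, L))
  excluded <- rs %in% charToRaw("N.-") | rg %in% charToRaw("N.-")
  match <- as.integer(rs == rg & !excluded)
  comparable <- as.integer(!excluded)
  cm <- cumsum(match)
  cc <- cumsum(comparable)
  starts <- seq_len(L - window + 1L)
  wm <- cm[starts + window - 1L] - c(0, cm)[starts]
  wc <- cc[starts + window - 1L] - c(0, cc)[starts]
  # windows dominated by excluded positions give unstable identity
  # estimates; judge a window only when at least half of it is comparable
  any(wc >= window / 2 & wm < min_identity * wc)
}

#' CDR3 amino-acid similarity
#'
#' One minus the normalized Hamming distance between two equal-length CDR3
#' amino-acid strings. A position where either symbol is `X` (ambiguous,
#' e.g. from an N-containing codon) counts as a match, mirroring the
#' N-tolerance applied at the nucleotide level.
#'
#' @param a,b Amino-acid strings of equal, positive length.
#' @return Similarity fraction in \[0, 1\].
#' @examples
#' cdr3_similarity("CARDYYGMDVW", "CARDYYGMDVW")
#' cdr3_similarity("CARDYFGMDVW", "CARDYYGMDVW")
#' @export
cdr3_similarity <- function(a, b) {
  if (nchar(a) != nchar(b) || nchar(a) == 0L) {
    stop("CDR3 similarity requires equal, positive lengths (got ",
         nchar(a), " and ", nchar(b), ")", call. = FALSE)
  }
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  x <- charToRaw("X")
  1 - sum(ra != rb & ra != x & rb != x) / nchar(a)
}

#' Group eligible unique sequences into clones
#'
#' Members of a clone must share the V gene, the J gene and the CDR3
#' nucleotide length, and every pair of members must have CDR3 amino-acid
#' similarity of at least `min_sim` (complete linkage). Since gene calls
#' may carry ties, two sequences are gene-compatible when their call sets
#' intersect; a clone's gene set is the running intersection of its
#' members' sets, which preserves the shared-gene requirement.
#'
#' Clustering is greedy in descending total-copy order (lexicographically
#' smallest sequence first on ties): a sequence joins the first existing
#' clone whose gene sets it intersects and whose every current member it
#' matches at `min_sim` or better, otherwise it founds a new clone. Clone
#' ids are assigned in discovery order. The procedure is deterministic and
#' independent of input row order.
#'
#' @param useqs Unique-sequence tibble; if an `excluded_reason` column is
#'   present (from [eligible()]) only rows with reason `"none"` are
#'   clustered.
#' @param min_sim Minimum pairwise CDR3 amino-acid similarity
#'   (default 0.85).
#' @return A tibble of clones with columns `clone_id`, `subject_id`,
#'   `v_gene`, `j_gene`, `cdr3_len_nt`, `cdr3_aa` (highest-copy member's),
#'   `copies`, `instances`, `uniques`, `members` (list of `useq_id`),
#'   `copies_by_replicate` (list of named integer vectors) and
#'   `replicate_presence` (list of replicate ids).
#' @export
assign_clones <- function(useqs, min_sim = 0.85) {
  if ("excluded_reason" %in% names(useqs)) {
    useqs <- useqs[useqs$excluded_reason == "none", , drop = FALSE]
  }
  if (nrow(useqs) == 0L) {
    return(empty_clone_table())
  }
  ord <- order(-useqs$total_copies, useqs$sequence)
  useqs <- useqs[ord, , drop = FALSE]
  v_sets <- gene_call_sets(useqs$v_call)
  j_sets <- gene_call_sets(useqs$j_call)
  len_nt <- nchar(useqs$cdr3_nt)
  len_aa <- nchar(useqs$cdr3_aa)

  clone_v <- list(); clone_j <- list()
  clone_len <- integer(0); clone_len_aa <- integer(0)
  clone_members <- list()
  for (i in seq_len(nrow(useqs))) {
    assigned <- 0L
    cand <- which(clone_len == len_nt[i] & clone_len_aa == len_aa[i])
    for (cl in cand) {
      if (length(intersect(clone_v[[cl]], v_sets[[i]])) == 0L) next
      if (length(intersect(clone_j[[cl]], j_sets[[i]])) == 0L) next
      sims <- vapply(clone_members[[cl]], function(m) {
        cdr3_similarity(useqs$cdr3_aa[i], useqs$cdr3_aa[m])
      }, numeric(1))
      if (all(sims >= min_sim)) {
        assigned <- cl
        break
      }
    }
    if (assigned == 0L) {
      clone_v <- c(clone_v, list(v_sets[[i]]))
      clone_j <- c(clone_j, list(j_sets[[i]]))
      clone_len <- c(clone_len, len_nt[i])
      clone_len_aa <- c(clone_len_aa, len_aa[i])
      clone_members <- c(clone_members, list(i))
    } else {
      clone_v[[assigned]] <- intersect(clone_v[[assigned]], v_sets[[i]])
      clone_j[[assigned]] <- intersect(clone_j[[assigned]], j_sets[[i]])
      clone_members[[assigned]] <- c(clone_members[[assigned]], i)
    }
  }

  rows <- lapply(seq_along(clone_members), function(cl) {
    idx <- clone_members[[cl]]
    cbr_all <- unlist(useqs$copies_by_replicate[idx])
    cbr <- tapply(as.integer(cbr_all), names(cbr_all), sum)
    cbr <- cbr[order(names(cbr))]
    tibble::tibble(
      clone_id = cl,
      subject_id = useqs$subject_id[idx[1L]],
      v_gene = paste(sort(clone_v[[cl]]), collapse = ","),
      j_gene = paste(sort(clone_j[[cl]]), collapse = ","),
      cdr3_len_nt = clone_len[cl],
      cdr3_aa = useqs$cdr3_aa[idx[1L]],  # highest-copy member (greedy order)
      copies = sum(useqs$total_copies[idx]),
      instances = sum(useqs$instances[idx]),
      uniques = length(idx),
      members = list(useqs$useq_id[idx]),
      copies_by_replicate = list(cbr),
      replicate_presence = list(names(cbr)[cbr > 0])
    )
  })
  dplyr::bind_rows(rows)
}

empty_clone_table <- function() {
  tibble::tibble(
    clone_id = integer(), subject_id = character(), v_gene = character(),
    j_gene = character(), cdr3_len_nt = integer(), cdr3_aa = character(),
    copies = integer(), instances = integer(), uniques = integer(),
    members = list(), copies_by_replicate = list(),
    replicate_presence = list()
  )
}
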