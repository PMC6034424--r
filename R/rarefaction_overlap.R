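#' Individual-based rarefaction
#'
#' Expected clone richness in a random subsample of n individuals (copies)
#' drawn without replacement from the pooled sample:
#' `E[S(n)] = sum_i (1 - C(N - N_i, n) / C(N, n))`, where N_i is clone i's
#' count and N their sum. Binomial coefficients are evaluated in log space
#' for numerical stability.
#'
#' @param counts Positive integer copy counts, one per clone.
#' @param n Subsample size, between 0 and `sum(counts)`.
#' @return Expected number of clones observed.
#' @examples
#' individual_rarefaction(c(2, 2), 2)
#' @export
individual_rarefaction <- function(counts, n) {
  stopifnot(all(counts >= 1))
  N <- sum(counts)
  if (n < 0 || n > N) {
    stop("subsample size n must be between 0 and ", N, call. = FALSE)
  }
  if (n == 0) return(0)
  sum(1 - exp(lchoose(N - counts, n) - lchoose(N, n)))
}

#' Boolean clone-by-replicate presence matrix
#'
#' Rows are clones, columns replicates; an entry is `TRUE` when the clone
#' was observed in that replicate. Row sums (the number of replicates
#' containing each clone) drive sample-based rarefaction and clone
#' tracking.
#'
#' @param clones Clone tibble from [assign_clones()] (uses the
#'   `replicate_presence` list column).
#' @param replicates Optional character vector fixing the column set and
#'   order; defaults to all replicates observed.
#' @return Logical matrix with clone ids as row names and replicate ids as
#'   column names.
#' @export
presence_matrix <- function(clones, replicates = NULL) {
  if (is.null(replicates)) {
    replicates <- sort(unique(unlist(clones$replicate_presence)))
  }
  m <- t(vapply(
    clones$replicate_presence,
    function(pres) replicates %in% pres,
    logical(length(replicates))
  ))
  dimnames(m) <- list(clones$clone_id, replicates)
  m
}

#' Sample-based rarefaction
#'
#' Expected clone richness when t of the T replicate libraries are drawn
#' at random without replacement:
#' `E[S(t)] = sum_i (1 - C(T - T_i, t) / C(T, t))`, with T_i the number of
#' replicates containing clone i.
#'
#' @param m Presence matrix from [presence_matrix()].
#' @param t Number of replicates drawn, between 1 and `ncol(m)`.
#' @return Expected number of clones observed.
#' @export
sample_rarefaction <- function(m, t) {
  T_total <- ncol(m)
  if (t < 1 || t > T_total) {
    stop("t must be between 1 and ", T_total, call. = FALSE)
  }
  T_i <- rowSums(m)
  sum(1 - exp(lchoose(T_total - T_i, t) - lchoose(T_total, t)))
}

#' Sample-based rarefaction curves stratified by clone size
#'
#' For each instance cut-off k, restricts the presence matrix to clones
#' found in at least k replicates and computes the expected-richness curve
#' over t = 1..T. A curve that levels off before t = T indicates that
#' clones of that size are sampled sufficiently for overlap analysis.
#'
#' @param m Presence matrix from [presence_matrix()].
#' @param cutoffs Integer replicate-presence cut-offs (each >= 1).
#' @return Tibble `cutoff`, `t`, `expected_richness`.
#' @export
stratified_sample_rarefaction <- function(m,
                                          cutoffs = c(1L, 2L, 3L, 4L, 5L,
                                                      6L, 10L)) {
  stopifnot(all(cutoffs >= 1))
  T_total <- ncol(m)
  T_i <- rowSums(m)
  purrr::map_dfr(cutoffs, function(k) {
    sub <- m[T_i >= k, , drop = FALSE]
    vals <- if (nrow(sub) == 0L) {
      rep(0, T_total)
    } else {
      vapply(seq_len(T_total), function(t) sample_rarefaction(sub, t),
             numeric(1))
    }
    tibble::tibble(cutoff = as.integer(k), t = seq_len(T_total),
                   expected_richness = vals)
  })
}

#' Smallest clone-size cut-off whose rarefaction curve levels off
#'
#' The visual "levels off" judgement is made reproducible: a curve is
#' considered plateaued when the relative increment of expected richness
#' over the final step, `(S(T) - S(T-1)) / S(T)`, is below `epsilon`
#' (default 1%). Returns the smallest such cut-off, or `NA` if no curve
#' plateaus. Empty strata (all-zero curves) are never reported.
#'
#' @param curves Tibble from [stratified_sample_rarefaction()].
#' @param epsilon Maximum relative final-step increment (default 0.01).
#' @return The smallest plateauing cut-off (integer) or `NA`.
#' @export
plateau_cutoff <- function(curves, epsilon = 0.01) {
  T_total <- max(curves$t)
  stopifnot(T_total >= 3)
  for (k in sort(unique(curves$cutoff))) {
    v <- curves$expected_richness[curves$cutoff == k][order(
      curves$t[curves$cutoff == k])]
    if (v[T_total] <= 0) next
    if ((v[T_total] - v[T_total - 1L]) / v[T_total] < epsilon) {
      return(as.integer(k))
    }
  }
  NA_integer_
}

#' Cosine similarity of clonal abundance between two samples
#'
#' `sum_i A_i B_i / (sqrt(sum_i A_i^2) sqrt(sum_i B_i^2))` over vectors
#' aligned on the union of clones of the two samples (a clone absent from
#' a sample contributes 0). With non-negative abundances the value lies in
#' \[0, 1\]: 1 for identical relative abundances, 0 for disjoint clone
#' sets. Scale invariant, so any of the three size metrics can be used.
#'
#' @param a,b Numeric abundance vectors of equal length (aligned on the
#'   clone union), non-negative, each with at least one positive entry. If
#'   both are named, they are aligned by name on the union of their names
#'   first.
#' @return Cosine similarity in \[0, 1\].
#' @examples
#' cosine_similarity(c(1, 2), c(2, 1))
#' @export
cosine_similarity <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    ids <- union(names(a), names(b))
    a <- ifelse(ids %in% names(a), a[ids], 0)
    b <- ifelse(ids %in% names(b), b[ids], 0)
  }
  stopifnot(length(a) == length(b), all(a >= 0), all(b >= 0))
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("cosine similarity is undefined for an all-zero abundance vector",
         call. = FALSE)
  }
  sum(a * b) / (na * nb)
}

#' Pairwise cosine overlap between replicates
#'
#' Builds per-replicate clone abundance vectors from the clone table and
#' computes the cosine similarity for every replicate pair.
#'
#' @param clones Clone tibble from [assign_clones()].
#' @param metric Clone-size metric for the abundances: `"copies"` uses the
#'   per-replicate copy counts; `"presence"` uses Boolean presence.
#' @return Tibble `replicate_a`, `replicate_b`, `cosine`.
#' @export
replicate_overlap <- function(clones, metric = c("copies", "presence")) {
  metric <- match.arg(metric)
  reps <- sort(unique(unlist(clones$replicate_presence)))
  if (length(reps) < 2L) {
    stop("at least two replicates are required for overlap analysis",
         call. = FALSE)
  }
  abund <- vapply(clones$copies_by_replicate, function(cbr) {
    out <- stats::setNames(numeric(length(reps)), reps)
    out[names(cbr)] <- cbr
    out
  }, numeric(length(reps)))
  abund <- matrix(abund, nrow = length(reps),
                  dimnames = list(reps, clones$clone_id))
  if (metric == "presence") abund <- (abund > 0) * 1
  pairs <- utils::combn(reps, 2)
  tibble::tibble(
    replicate_a = pairs[1, ],
    replicate_b = pairs[2, ],
    cosine = apply(pairs, 2, function(pr) {
      cosine_similarity(abund[pr[1], ], abund[pr[2], ])
    })
  )
}

#' Clonal overlap counts across samples
#'
#' Venn-style summary over per-sample clone sets: for each k, the number
#' of clones present in exactly k and in at least k samples, plus the list
#' of shared clones (present in 2 or more) ordered by breadth of presence.
#'
#' @param clone_sets Named list of per-sample clone-id vectors.
#' @return A list with `counts` (tibble `k`, `exactly_k`, `at_least_k`)
#'   and `shared` (tibble `clone_id`, `n_samples`, sorted by decreasing
#'   presence then id).
#' @export
overlap_counts <- function(clone_sets) {
  stopifnot(length(clone_sets) >= 1)
  presence <- table(unlist(lapply(clone_sets, unique)))
  ks <- seq_len(length(clone_sets))
  counts <- tibble::tibble(
    k = ks,
    exactly_k = vapply(ks, function(k) sum(presence == k), integer(1)),
    at_least_k = vapply(ks, function(k) sum(presence >= k), integer(1))
  )
  shared_tab <- presence[presence >= 2]
  shared <- tibble::tibble(
    clone_id = names(shared_tab),
    n_samples = as.integer(shared_tab)
  )
  shared <- shared[order(-shared$n_samples, shared$clone_id), ,
                   drop = FALSE]
  list(counts = counts, shared = shared)
}
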