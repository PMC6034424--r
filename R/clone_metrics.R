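#' Sampling constants for bulk gDNA antibody amplification
#'
#' Defaults: 1000 pg per ng, 1.4 heavy-chain rearrangements per B cell (some
#' cells carry more than one), and 6.7 pg of genomic DNA per cell.
#'
#' @param pg_per_ng Picograms per nanogram (default 1000).
#' @param rearr_per_cell Mean rearrangements per cell (default 1.4).
#' @param pg_per_cell Genomic DNA mass per cell in pg (default 6.7).
#' @return A list of the three constants.
#' @export
sampling_constants <- function(pg_per_ng = 1000, rearr_per_cell = 1.4,
                               pg_per_cell = 6.7) {
  stopifnot(pg_per_ng > 0, rearr_per_cell > 0, pg_per_cell > 0)
  list(pg_per_ng = pg_per_ng, rearr_per_cell = rearr_per_cell,
       pg_per_cell = pg_per_cell)
}

#' Maximum number of rearrangements from an input DNA mass
#'
#' Upper bound on the number of distinct heavy-chain rearrangements a
#' sample of B-cell genomic DNA can contain, assuming maximal diversity:
#' `ng x pg_per_ng x rearr_per_cell / pg_per_cell`, rounded down to an
#' integer.
#'
#' @param ng_dna Input B-cell-equivalent DNA in nanograms (total across
#'   replicates).
#' @param consts Constants from [sampling_constants()].
#' @return Integer number of rearrangements.
#' @examples
#' max_rearrangements(100) # two replicates of 50 ng each
#' @export
max_rearrangements <- function(ng_dna, consts = sampling_constants()) {
  stopifnot(ng_dna >= 0)
  floor(ng_dna * consts$pg_per_ng * consts$rearr_per_cell /
          consts$pg_per_cell)
}

#' Approximate B cells per nanogram of B-cell DNA
#'
#' `pg_per_ng / pg_per_cell`, rounded to the nearest ten cells (1 ng of
#' B-cell genomic DNA corresponds to roughly 150 cells at the defaults).
#'
#' @param consts Constants from [sampling_constants()].
#' @param round_to_ten Round to the nearest ten (default `TRUE`); set
#'   `FALSE` for the exact quotient.
#' @return Cells per nanogram.
#' @export
cells_per_ng <- function(consts = sampling_constants(),
                         round_to_ten = TRUE) {
  x <- consts$pg_per_ng / consts$pg_per_cell
  if (round_to_ten) round(x / 10) * 10 else x
}

#' Input DNA needed to amplify a target mass of B-cell DNA
#'
#' For a sample whose B-cell fraction is below one, the input genomic DNA
#' must be scaled up: `target / b_fraction`. The headline value is
#' truncated (not rounded) to one decimal place; the exact quotient is
#' attached as attribute `"exact"`.
#'
#' @param target_ng_b_dna Desired B-cell-equivalent DNA mass in ng.
#' @param b_fraction B-cell fraction of the sample, in (0, 1\].
#' @return Input DNA in ng, truncated to one decimal.
#' @examples
#' input_dna_for_b_cells(50, 0.35)
#' @export
input_dna_for_b_cells <- function(target_ng_b_dna, b_fraction) {
  stopifnot(b_fraction > 0, b_fraction <= 1, target_ng_b_dna >= 0)
  exact <- target_ng_b_dna / b_fraction
  out <- trunc(exact * 10) / 10
  attr(out, "exact") <- exact
  out
}

#' Clone-size table
#'
#' Collects the three clone-size metrics into a plain table with totals,
#' the substrate for ranking, cut-off and diversity analyses.
#'
#' @param clones Clone tibble from [assign_clones()].
#' @return A list with `rows` (tibble `clone_id`, `copies`, `instances`,
#'   `uniques`) and `totals` (named numeric: summed copies `T`, instances,
#'   uniques, and the clone count).
#' @export
clone_size_table <- function(clones) {
  rows <- tibble::tibble(
    clone_id = clones$clone_id,
    copies = clones$copies,
    instances = clones$instances,
    uniques = clones$uniques
  )
  list(
    rows = rows,
    totals = c(
      copies = sum(rows$copies),
      instances = sum(rows$instances),
      uniques = sum(rows$uniques),
      clones = nrow(rows)
    )
  )
}

#' Fraction of copies in the largest clones (D20)
#'
#' The summed copy count of the `n` highest-copy clones divided by the
#' total copy count `T`. With fewer than `n` clones the sum runs over all
#' of them (giving 1). The same statistic can be computed on instances or
#' unique sequences.
#'
#' @param table Clone-size table from [clone_size_table()].
#' @param n Number of top clones (default 20).
#' @param metric One of `"copies"`, `"instances"`, `"uniques"`.
#' @return Fraction in (0, 1\].
#' @export
d20 <- function(table, n = 20L, metric = c("copies", "instances",
                                           "uniques")) {
  metric <- match.arg(metric)
  x <- table$rows[[metric]]
  total <- sum(x)
  stopifnot(total > 0)
  sum(sort(x, decreasing = TRUE)[seq_len(min(n, length(x)))]) / total
}

#' Top-n clones under a size metric
#'
#' Orders clones descending by the chosen metric, breaking ties by the
#' remaining metrics in the fixed order copies, instances, uniques, and
#' finally by `clone_id`. Reported fractions are of the metric's total and
#' therefore sum to at most 1.
#'
#' @inheritParams d20
#' @return Tibble `clone_id`, `value`, `fraction`, at most `n` rows.
#' @export
rank_top_n <- function(table, metric = c("copies", "instances", "uniques"),
                       n = 20L) {
  metric <- match.arg(metric)
  rows <- table$rows
  total <- sum(rows[[metric]])
  stopifnot(total > 0)
  ord <- order(-rows[[metric]], -rows$copies, -rows$instances,
               -rows$uniques, rows$clone_id)
  top <- rows[ord[seq_len(min(n, nrow(rows)))], , drop = FALSE]
  tibble::tibble(
    clone_id = top$clone_id,
    value = top[[metric]],
    fraction = top[[metric]] / total
  )
}

#' Clone counts at size cut-offs
#'
#' For each cut-off k, the number of clones whose metric value is at least
#' k. At k = 1 this is the richness.
#'
#' @inheritParams d20
#' @param cutoffs Integer cut-offs, each at least 1.
#' @return Tibble `cutoff`, `clones`.
#' @export
cutoff_counts <- function(table, metric = c("copies", "instances",
                                            "uniques"),
                          cutoffs = c(1L, 2L, 3L, 4L, 5L, 10L)) {
  metric <- match.arg(metric)
  stopifnot(all(cutoffs >= 1))
  x <- table$rows[[metric]]
  tibble::tibble(
    cutoff = as.integer(cutoffs),
    clones = vapply(cutoffs, function(k) sum(x >= k), integer(1))
  )
}

#' Fraction of total copies retained at copy-number cut-offs
#'
#' For each cut-off k, the copies belonging to clones with at least k
#' copies, as a fraction of total copies. Non-increasing in k and equal to
#' 1 at k = 1.
#'
#' @param table Clone-size table from [clone_size_table()].
#' @param cutoffs Integer cut-offs, each at least 1.
#' @return Tibble `cutoff`, `fraction`.
#' @export
copies_retained_fraction <- function(table,
                                     cutoffs = c(1L, 2L, 3L, 4L, 5L, 10L)) {
  total <- sum(table$rows$copies)
  stopifnot(total > 0, all(cutoffs >= 1))
  tibble::tibble(
    cutoff = as.integer(cutoffs),
    fraction = vapply(cutoffs, function(k) {
      sum(table$rows$copies[table$rows$copies >= k]) / total
    }, numeric(1))
  )
}
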