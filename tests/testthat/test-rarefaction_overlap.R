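# Exhaustive oracle: mean richness over every possible subsample of n
# individuals from the labeled population (feasible for N <= 8).
enumerate_individual <- function(counts, n) {
  pop <- rep(seq_along(counts), counts)
  if (n == 0) return(0)
  subs <- utils::combn(length(pop), n)
  mean(apply(subs, 2, function(idx) length(unique(pop[idx]))))
}

# Exhaustive oracle over replicate subsets for sample-based rarefaction.
enumerate_sample <- function(m, t) {
  subs <- utils::combn(ncol(m), t)
  mean(apply(subs, 2, function(cols) {
    sum(rowSums(m[, cols, drop = FALSE]) > 0)
  }))
}

mc_individual <- function(counts, n, draws) {
  pop <- rep(seq_along(counts), counts)
  reps <- vapply(seq_len(draws), function(i) {
    length(unique(sample(pop, n)))
  }, numeric(1))
  c(mean = mean(reps), se = stats::sd(reps) / sqrt(draws))
}

mc_sample <- function(m, t, draws) {
  reps <- vapply(seq_len(draws), function(i) {
    cols <- sample(ncol(m), t)
    sum(rowSums(m[, cols, drop = FALSE]) > 0)
  }, numeric(1))
  c(mean = mean(reps), se = stats::sd(reps) / sqrt(draws))
}

test_that("individual rarefaction matches exhaustive enumeration", {
  expect_equal(individual_rarefaction(c(2, 2), 2), 5 / 3)
  expect_equal(individual_rarefaction(c(2, 2), 0), 0)
  expect_equal(individual_rarefaction(c(3, 2, 1), 6), 3)  # n = N
  expect_error(individual_rarefaction(c(2, 2), 5), "between 0 and")

  set.seed(41)
  for (i in 1:10) {
    counts <- sample(1:4, sample(2:4, 1), replace = TRUE)
    n <- sample(0:sum(counts), 1)
    expect_equal(individual_rarefaction(counts, n),
                 enumerate_individual(counts, n),
                 tolerance = 1e-10)
  }
})

test_that("sample rarefaction matches exhaustive enumeration over replicates", {
  m <- matrix(c(TRUE, TRUE, TRUE, FALSE), nrow = 2,
              dimnames = list(1:2, c("R1", "R2")))
  expect_equal(sample_rarefaction(m, 1), 1.5)
  expect_equal(sample_rarefaction(m, 2), 2)
  expect_error(sample_rarefaction(m, 3), "between 1 and")

  set.seed(43)
  for (i in 1:10) {
    T_total <- sample(3:6, 1)
    rows <- sample(2:8, 1)
    m <- matrix(stats::runif(rows * T_total) < 0.5, nrow = rows)
    m <- m[rowSums(m) > 0, , drop = FALSE]
    if (nrow(m) == 0) next
    t <- sample(T_total, 1)
    expect_equal(sample_rarefaction(m, t), enumerate_sample(m, t),
                 tolerance = 1e-10)
  }
})

test_that("analytic expectations agree with Monte-Carlo resampling within 3 SE", {
  set.seed(47)
  draws <- 2e4
  for (i in 1:5) {
    counts <- sample(1:20, sample(3:8, 1), replace = TRUE)
    n <- sample(seq_len(sum(counts)), 1)
    mc <- mc_individual(counts, n, draws)
    expect_lt(abs(individual_rarefaction(counts, n) - mc["mean"]),
              3 * mc["se"] + 1e-9)
  }
  for (i in 1:5) {
    m <- matrix(stats::runif(20 * 6) < 0.4, nrow = 20)
    m <- m[rowSums(m) > 0, , drop = FALSE]
    t <- sample(2:5, 1)
    mc <- mc_sample(m, t, draws)
    expect_lt(abs(sample_rarefaction(m, t) - mc["mean"]),
              3 * mc["se"] + 1e-9)
  }
})

test_that("rarefaction curves are concave non-decreasing and end at richness", {
  set.seed(53)
  counts <- sample(1:30, 15, replace = TRUE)
  N <- sum(counts)
  curve <- vapply(0:N, function(n) individual_rarefaction(counts, n),
                  numeric(1))
  expect_true(all(diff(curve) >= -1e-10))
  expect_true(all(diff(diff(curve)) <= 1e-10))
  expect_equal(curve[N + 1], length(counts))
})

test_that("stratified curves restrict to clones above each presence cut-off", {
  set.seed(59)
  m <- matrix(stats::runif(30 * 5) < 0.5, nrow = 30,
              dimnames = list(1:30, paste0("R", 1:5)))
  m <- m[rowSums(m) > 0, , drop = FALSE]
  curves <- stratified_sample_rarefaction(m, cutoffs = c(1L, 3L, 6L))

  full <- curves[curves$cutoff == 1, ]
  expect_equal(full$expected_richness[full$t == 5], nrow(m))
  strat3 <- curves[curves$cutoff == 3, ]
  expect_equal(strat3$expected_richness[strat3$t == 5],
               sum(rowSums(m) >= 3))
  # cut-off above the deepest presence: empty stratum, all-zero curve
  expect_true(all(curves$expected_richness[curves$cutoff == 6] == 0))
  # ubiquitous clones contribute 1 at every t
  m_ubiq <- matrix(TRUE, nrow = 3, ncol = 5)
  expect_equal(sample_rarefaction(m_ubiq, 1), 3)
})

test_that("plateau detection returns the smallest leveled-off cut-off", {
  flat <- tibble::tibble(cutoff = 2L, t = 1:5,
                         expected_richness = c(3, 5, 6, 6.5, 6.5))
  linear <- tibble::tibble(cutoff = 1L, t = 1:5,
                           expected_richness = seq(10, 50, by = 10))
  expect_equal(plateau_cutoff(dplyr::bind_rows(linear, flat)), 2L)
  expect_true(is.na(plateau_cutoff(linear)))

  # deeply-replicated repertoire: high-presence strata saturate early, so a
  # finite cut-off is returned and matches a direct increment-rule scan
  set.seed(61)
  T_total <- 19
  pres_prob <- stats::rbeta(400, 0.4, 1.2)
  m <- matrix(stats::runif(400 * T_total) <
                matrix(pres_prob, 400, T_total), nrow = 400)
  m <- m[rowSums(m) > 0, , drop = FALSE]
  cutoffs <- c(1L, 2L, 3L, 4L, 5L, 6L, 10L)
  curves <- stratified_sample_rarefaction(m, cutoffs)
  got <- plateau_cutoff(curves)
  manual <- NA_integer_
  for (k in cutoffs) {
    v <- curves$expected_richness[curves$cutoff == k]
    if (v[T_total] > 0 &&
        (v[T_total] - v[T_total - 1]) / v[T_total] < 0.01) {
      manual <- k
      break
    }
  }
  expect_false(is.na(got))
  expect_equal(got, manual)
})

test_that("cosine similarity follows the two-sample overlap formula", {
  expect_equal(cosine_similarity(c(3, 1, 4), c(3, 1, 4)), 1.0)
  expect_equal(cosine_similarity(c(1, 0, 2, 0), c(0, 3, 0, 5)), 0.0)
  expect_equal(cosine_similarity(c(1, 2), c(2, 1)), 0.8)
  expect_error(cosine_similarity(c(0, 0), c(1, 2)), "all-zero")

  # named vectors align on the clone union, absent clones counting 0
  a <- c(cl1 = 2, cl2 = 1)
  b <- c(cl2 = 1, cl3 = 5)
  expect_equal(cosine_similarity(a, b),
               1 / (sqrt(5) * sqrt(26)))
})

test_that("cosine is symmetric, scale-invariant and bounded", {
  set.seed(67)
  for (i in 1:20) {
    a <- stats::runif(10)
    b <- stats::runif(10)
    expect_equal(cosine_similarity(a, b), cosine_similarity(b, a))
    expect_equal(cosine_similarity(3.7 * a, b), cosine_similarity(a, b))
    expect_gte(cosine_similarity(a, b), 0)
    expect_lte(cosine_similarity(a, b), 1 + 1e-12)
  }
})

test_that("replicate overlap and presence matrix agree with clone sets", {
  clones <- make_clones(
    copies = c(6L, 4L, 2L),
    replicate_presence = list(c("R1", "R2"), "R1", "R2"),
    copies_by_replicate = list(c(R1 = 3L, R2 = 3L), c(R1 = 4L),
                               c(R2 = 2L))
  )
  ov <- replicate_overlap(clones)
  expect_equal(nrow(ov), 1L)
  # vectors over the clone union: R1 = (3,4,0), R2 = (3,0,2)
  expect_equal(ov$cosine, 9 / (5 * sqrt(13)))

  m <- presence_matrix(clones)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(rowSums(m), c(`1` = 2, `2` = 1, `3` = 1))
})

test_that("overlap counts form a consistent Venn summary", {
  same <- overlap_counts(list(A = letters[1:5], B = letters[1:5]))
  expect_equal(same$counts$exactly_k, c(0L, 5L))

  two <- overlap_counts(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
  expect_equal(two$counts$at_least_k, c(4L, 2L))
  expect_equal(two$shared$clone_id, c("b", "c"))

  # shared-clone count equals presence-matrix rows with >= 2 replicates
  sim <- simulate_repertoire(small_sim_config(seed = 13))
  useqs <- collapse_subject(sim$rearrangements)
  cl <- assign_clones(eligible(useqs))
  m <- presence_matrix(cl)
  sets <- lapply(colnames(m), function(r) rownames(m)[m[, r]])
  names(sets) <- colnames(m)
  oc <- overlap_counts(sets)
  expect_equal(oc$counts$at_least_k[2], sum(rowSums(m) >= 2))
})
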