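test_that("eligibility excludes low-copy, stopped-CDR3 and indel-like sequences", {
  germ <- strrep("ACGT", 30)  # 120 nt
  # 13 mismatches inside one fully comparable 30-nt window: 17/30 < 0.6
  indel_like <- paste0(
    substr(germ, 1, 30),
    chartr("ACGT", "TGCA", substr(germ, 31, 43)), substr(germ, 44, 120)
  )
  useqs <- make_useq(
    cdr3_aa = c("CARDYW", "CARDY*W", "CARDYW", "CARDYW"),
    total_copies = c(1L, 5L, 5L, 5L),
    sequence = c(germ, germ, indel_like, germ)
  )
  useqs$germline <- germ
  out <- eligible(useqs)
  expect_equal(out$excluded_reason,
               c("low_copy", "cdr3_stop", "indel_window", "none"))
})

test_that("window identity matches a brute-force all-windows oracle", {
  oracle <- function(seq, germ, w = 30, thr = 0.6) {
    s <- strsplit(seq, "")[[1]]
    g <- strsplit(germ, "")[[1]]
    L <- min(length(s), length(g))
    for (start in seq_len(max(0, L - w + 1))) {
      idx <- start:(start + w - 1)
      ok <- s[idx] != "N" & g[idx] != "N"
      if (sum(ok) >= w / 2 && sum(s[idx][ok] == g[idx][ok]) <
            thr * sum(ok)) {
        return(TRUE)
      }
    }
    FALSE
  }
  set.seed(31)
  germ <- random_read(150)$bases
  for (i in 1:40) {
    seq <- germ
    n_mut <- sample(0:40, 1)
    pos <- sample(150, n_mut)
    chars <- strsplit(seq, "")[[1]]
    chars[pos] <- sample(c("A", "C", "G", "T", "N"), n_mut,
                         replace = TRUE)
    seq <- paste(chars, collapse = "")
    useqs <- make_useq("CARW", 5L, sequence = seq)
    useqs$germline <- germ
    got <- eligible(useqs)$excluded_reason == "indel_window"
    expect_equal(got, oracle(seq, germ), label = paste("case", i))
  }
})

test_that("missing germline skips the indel check with a warning", {
  useqs <- make_useq("CARW", 5L)
  expect_warning(out <- eligible(useqs), "germline")
  expect_equal(out$excluded_reason, "none")
})

test_that("CDR3 similarity is one minus normalized Hamming distance", {
  expect_equal(cdr3_similarity("CARDYYGMDV", "CARDYYGMDV"), 1.0)
  expect_equal(cdr3_similarity("CARDYYGMDV", "CARDYFGMDV"), 0.9)
  expect_equal(cdr3_similarity("CARDYYGMDV", "CARDYFGMDW"), 0.8)
  expect_equal(cdr3_similarity("CXRDYYGMDV", "CARDYFGMDV"), 0.9)  # X wild
  expect_error(cdr3_similarity("CARW", "CARDW"), "equal")
})

test_that("similar same-V/J/length CDR3s form one clone, others stay apart", {
  # similarity 0.9 (1 mismatch in 10)
  pair <- make_useq(c("CARDYYGMDV", "CARDYFGMDV"), c(5L, 3L))
  cl <- assign_clones(pair)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$uniques, 2L)
  expect_equal(cl$copies, 8L)

  # different CDR3 nucleotide length: never compared
  diff_len <- make_useq(c("CARDYYGMDV", "CARDYYGMD"), c(5L, 3L))
  expect_equal(nrow(assign_clones(diff_len)), 2L)

  # different J gene
  diff_j <- make_useq(c("CARDYYGMDV", "CARDYFGMDV"), c(5L, 3L),
                      j_call = c("IGHJ4", "IGHJ6"))
  expect_equal(nrow(assign_clones(diff_j)), 2L)
})

test_that("greedy complete linkage splits a chain that violates the pairwise rule", {
  # sims: (A,B)=0.9, (A,C)=0.9, (B,C)=0.8; copies A>B>C
  useqs <- make_useq(
    c("CARDYYGMDV",   # A
      "CARDYFGMDV",   # B: differs from A at 1
      "CARDYYGMDW"),  # C: differs from A at 1, from B at 2
    c(5L, 3L, 2L)
  )
  expect_equal(cdr3_similarity("CARDYFGMDV", "CARDYYGMDW"), 0.8)
  cl <- assign_clones(useqs)
  expect_equal(nrow(cl), 2L)
  expect_equal(sort(vapply(cl$members, length, integer(1))), c(1L, 2L))
  ab <- cl[vapply(cl$members, length, integer(1)) == 2L, ]
  expect_setequal(ab$members[[1]], c("U001", "U002"))
  # exhaustive check: {A,B} is the unique complete-linkage partition
  # reachable greedily in descending copy order
  expect_equal(cl$copies, c(8L, 2L))
})

test_that("tied gene calls are compatible through set intersection", {
  useqs <- make_useq(c("CARDYYGMDV", "CARDYFGMDV"), c(5L, 3L),
                     v_call = c("IGHV1-2,IGHV1-69", "IGHV1-69"))
  cl <- assign_clones(useqs)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$v_gene, "IGHV1-69")  # running intersection

  disjoint <- make_useq(c("CARDYYGMDV", "CARDYFGMDV"), c(5L, 3L),
                        v_call = c("IGHV1-2", "IGHV1-69"))
  expect_equal(nrow(assign_clones(disjoint)), 2L)
})

test_that("every emitted clone satisfies complete linkage and conserves copies", {
  sim <- simulate_repertoire(small_sim_config(seed = 9))
  useqs <- collapse_subject(sim$rearrangements)
  el <- eligible(useqs)
  cl <- assign_clones(el)

  # conservation over the eligible set
  elig <- el[el$excluded_reason == "none", ]
  expect_equal(sum(cl$copies), sum(elig$total_copies))
  expect_equal(sum(cl$uniques), nrow(elig))

  # post-hoc pairwise similarity >= 0.85 inside every clone
  aa_of <- stats::setNames(el$cdr3_aa, el$useq_id)
  for (i in seq_len(nrow(cl))) {
    aas <- aa_of[cl$members[[i]]]
    if (length(aas) < 2) next
    prs <- utils::combn(aas, 2)
    sims <- apply(prs, 2, function(x) cdr3_similarity(x[1], x[2]))
    expect_true(all(sims >= 0.85))
  }

  # determinism under row shuffle
  set.seed(1)
  cl2 <- assign_clones(el[sample(nrow(el)), ])
  expect_equal(cl2$cdr3_aa, cl$cdr3_aa)
  expect_equal(cl2$copies, cl$copies)
  expect_equal(cl2$members, cl$members)
})
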