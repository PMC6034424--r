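#' Configuration for the synthetic repertoire simulator
#'
#' Bundles the parameters of [simulate_repertoire()] with the defaults
#' used throughout the test suite: a duplicate-amplified subject (two
#' replicate libraries of 600 sampled cells each), 200 clones with a
#' heavy-tailed (Pareto) cell-count distribution, star-topology somatic
#' hypermutation variants at 5% per base around a founder sequence,
#' log-normal PCR copy-number noise, and a 0.1% per-base sequencing error
#' rate.
#'
#' @param seed Integer RNG seed; identical seeds give identical output.
#' @param n_clones Number of true clones (>= 1).
#' @param size_distribution Cell counts per clone: either
#'   `list(type = "powerlaw", shape, min_cells, max_cells)` (Pareto with
#'   the given shape, rounded) or `list(type = "lognormal", mu, sigma)`.
#' @param shm_rate Per-base substitution probability of each mutated
#'   lineage variant relative to the clone founder (also applied to the
#'   founder relative to its germline V/J).
#' @param n_variants_model `list(lambda, founder_weight)`: each clone has
#'   `1 + Poisson(lambda)` sequence variants, and each cell belongs to the
#'   founder variant with probability `founder_weight` (remaining mass
#'   split evenly among the mutated variants).
#' @param n_replicates Number of replicate libraries (>= 1).
#' @param cells_sampled_per_replicate Cells drawn (without replacement)
#'   into each replicate library.
#' @param pcr_lognormal_sigma Log-scale spread of the per-variant PCR
#'   amplification factor (meanlog 0).
#' @param seq_error_rate Per-base miscall probability per read.
#' @param quality_model `list(mean_q, sd_q, low_fraction, low_mean_q)`:
#'   most base qualities are drawn around `mean_q`, a `low_fraction` tail
#'   around `low_mean_q`.
#' @return A validated configuration list of class `sim_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_clones = 200L,
    size_distribution = list(type = "powerlaw", shape = 1.5,
                             min_cells = 3, max_cells = 500),
    shm_rate = 0.05,
    n_variants_model = list(lambda = 0.5, founder_weight = 0.85),
    n_replicates = 2L,
    cells_sampled_per_replicate = 600L,
    pcr_lognormal_sigma = 0.5,
    seq_error_rate = 0.001,
    quality_model = list(mean_q = 35, sd_q = 3, low_fraction = 0.02,
                         low_mean_q = 12)) {
  cfg <- list(
    seed = as.integer(seed), n_clones = as.integer(n_clones),
    size_distribution = size_distribution, shm_rate = shm_rate,
    n_variants_model = n_variants_model,
    n_replicates = as.integer(n_replicates),
    cells_sampled_per_replicate = as.integer(cells_sampled_per_replicate),
    pcr_lognormal_sigma = pcr_lognormal_sigma,
    seq_error_rate = seq_error_rate, quality_model = quality_model
  )
  if (cfg$n_clones < 1L || cfg$n_replicates < 1L ||
      cfg$cells_sampled_per_replicate < 1L) {
    stop("infeasible simulation config: n_clones, n_replicates and ",
         "cells_sampled_per_replicate must all be positive", call. = FALSE)
  }
  stopifnot(cfg$shm_rate >= 0, cfg$shm_rate <= 1,
            cfg$seq_error_rate >= 0, cfg$seq_error_rate <= 1,
            cfg$pcr_lognormal_sigma >= 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Bundled synthetic germline gene set
#'
#' Loads the small synthetic IGHV/IGHJ gene set shipped with the package
#' (plain FASTA under `extdata/`). These sequences are randomly generated
#' stand-ins carrying IMGT-style gene names across families IGHV1-IGHV6
#' and IGHJ1-IGHJ6; clone inference only consumes the gene labels and
#' CDR3s, so no real germline alleles are required.
#'
#' @return A list with character vectors `v` and `j`, named by gene.
#' @export
synthetic_germlines <- function() {
  v_path <- system.file("extdata", "synthetic_ighv.fasta",
                        package = "clonescape", mustWork = TRUE)
  j_path <- system.file("extdata", "synthetic_ighj.fasta",
                        package = "clonescape", mustWork = TRUE)
  v <- Biostrings::readDNAStringSet(v_path)
  j <- Biostrings::readDNAStringSet(j_path)
  list(v = stats::setNames(as.character(v), names(v)),
       j = stats::setNames(as.character(j), names(j)))
}

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

random_cdr3 <- function() {
  len_aa <- sample(9:22, 1)
  codons <- c("TGT",
              replicate(len_aa - 2L, random_nonstop_codon()),
              "TGG")
  paste(codons, collapse = "")
}

random_nonstop_codon <- function() {
  repeat {
    codon <- paste(sample(BASES, 3, replace = TRUE), collapse = "")
    if (!codon %in% STOP_CODONS) return(codon)
  }
}

# substitute each base independently with probability `rate`
mutate_sequence <- function(sequence, rate) {
  if (rate <= 0) return(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(BASES, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

draw_clone_sizes <- function(dist, n) {
  if (dist$type == "powerlaw") {
    u <- stats::runif(n)
    x <- dist$min_cells * u^(-1 / dist$shape)
    latent <- pmin(x, dist$max_cells)
  } else if (dist$type == "lognormal") {
    latent <- stats::rlnorm(n, dist$mu, dist$sigma)
  } else {
    stop("unknown size_distribution type: ", dist$type, call. = FALSE)
  }
  list(cells = pmax(1L, as.integer(round(latent))), latent = latent)
}

#' Simulate a multi-replicate subject repertoire with ground truth
#'
#' Draws a clonal population (cell counts from the configured heavy-tailed
#' distribution; each clone a germline V/J pair plus a random in-frame
#' CDR3 and star-topology SHM variants), samples cells into replicate
#' libraries, applies log-normal PCR copy-number noise, and emits one
#' annotated read per sequenced copy with independent per-base miscalls
#' and matching Phred qualities. Identical seeds give identical output.
#'
#' The annotated table mirrors what an upstream aligner would produce:
#' IMGT-aligned sequence starting at position 1, a germline alignment with
#' the CDR3 region masked as `N`, the (error-bearing) annotated CDR3, and
#' the observed V-segment germline identity.
#'
#' @param cfg Configuration from [simulation_config()].
#' @return A list with
#'   * `rearrangements`: canonical rearrangement tibble (see
#'     [read_airr()]), one row per read, `copies = 1`;
#'   * `reads`: tibble `read_id`, `replicate_id`, `bases`, `quals` for
#'     FASTQ export (identical base calls to `rearrangements`);
#'   * `truth`: list with `clones` (tibble `clone_id`, `v_gene`,
#'     `j_gene`, `cdr3_nt`, `cells`, `latent_size`, `n_variants`),
#'     `sequences` (tibble `sequence_id`, `replicate_id`, `true_clone`,
#'     `variant`) and `sampled_cells` (tibble `replicate_id`,
#'     `true_clone`, `variant`, `cells`).
#' @export
simulate_repertoire <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  germ <- synthetic_germlines()

  v_genes <- sample(names(germ$v), cfg$n_clones, replace = TRUE)
  j_genes <- sample(names(germ$j), cfg$n_clones, replace = TRUE)
  sizes <- draw_clone_sizes(cfg$size_distribution, cfg$n_clones)

  # founder + mutated variants per clone; cells assigned founder-heavily
  clones <- vector("list", cfg$n_clones)
  for (ci in seq_len(cfg$n_clones)) {
    v_seq <- germ$v[[v_genes[ci]]]
    j_seq <- germ$j[[j_genes[ci]]]
    cdr3 <- random_cdr3()
    founder <- paste0(
      mutate_sequence(v_seq, cfg$shm_rate), cdr3,
      mutate_sequence(j_seq, cfg$shm_rate)
    )
    n_var <- 1L + stats::rpois(1, cfg$n_variants_model$lambda)
    variants <- c(founder,
                  vapply(seq_len(n_var - 1L), function(i) {
                    mutate_sequence(founder, cfg$shm_rate)
                  }, character(1)))
    w <- if (n_var == 1L) 1 else {
      fw <- cfg$n_variants_model$founder_weight
      c(fw, rep((1 - fw) / (n_var - 1L), n_var - 1L))
    }
    cell_split <- as.integer(stats::rmultinom(1, sizes$cells[ci], w))
    germline <- paste0(v_seq, strrep("N", nchar(cdr3)), j_seq)
    clones[[ci]] <- list(
      variants = variants, cells = cell_split, germline = germline,
      v_len = nchar(v_seq), cdr3_len = nchar(cdr3),
      v_gene = v_genes[ci], j_gene = j_genes[ci]
    )
  }

  # cell population: one row per (clone, variant) with a positive count
  pop <- dplyr::bind_rows(lapply(seq_len(cfg$n_clones), function(ci) {
    keep <- clones[[ci]]$cells > 0L
    tibble::tibble(true_clone = ci,
                   variant = which(keep),
                   cells = clones[[ci]]$cells[keep])
  }))
  total_cells <- sum(pop$cells)
  if (cfg$cells_sampled_per_replicate > total_cells) {
    stop("cells_sampled_per_replicate (",
         cfg$cells_sampled_per_replicate, ") exceeds the simulated ",
         "population of ", total_cells, " cells", call. = FALSE)
  }

  rear_rows <- list()
  read_rows <- list()
  sampled_rows <- list()
  truth_rows <- list()
  for (r in seq_len(cfg$n_replicates)) {
    rep_id <- sprintf("R%02d", r)
    drawn <- sample_cells(pop, cfg$cells_sampled_per_replicate)
    sampled_rows[[r]] <- tibble::tibble(replicate_id = rep_id, drawn)
    pcr <- stats::rlnorm(nrow(drawn), 0, cfg$pcr_lognormal_sigma)
    copies <- pmax(1L, as.integer(round(drawn$cells * pcr)))
    emitted <- emit_reads(drawn, copies, clones, cfg, rep_id)
    rear_rows[[r]] <- emitted$rearr
    read_rows[[r]] <- emitted$reads
    truth_rows[[r]] <- emitted$truth_seq
  }

  rearrangements <- dplyr::bind_rows(rear_rows)
  truth_clones <- tibble::tibble(
    clone_id = seq_len(cfg$n_clones),
    v_gene = v_genes, j_gene = j_genes,
    cdr3_nt = vapply(clones, function(cl)
      substr(cl$variants[1L], cl$v_len + 1L, cl$v_len + cl$cdr3_len),
      character(1)),
    cells = sizes$cells, latent_size = sizes$latent,
    n_variants = vapply(clones, function(cl) length(cl$variants),
                        integer(1))
  )
  list(
    rearrangements = rearrangements,
    reads = dplyr::bind_rows(read_rows),
    truth = list(
      clones = truth_clones,
      sequences = dplyr::bind_rows(truth_rows),
      sampled_cells = dplyr::bind_rows(sampled_rows)
    )
  )
}

# draw `n` cells without replacement from the (clone, variant) population
sample_cells <- function(pop, n) {
  idx <- rep.int(seq_len(nrow(pop)), pop$cells)
  drawn <- sample(idx, n)
  counts <- tabulate(drawn, nbins = nrow(pop))
  keep <- counts > 0L
  tibble::tibble(true_clone = pop$true_clone[keep],
                 variant = pop$variant[keep],
                 cells = counts[keep])
}

# one annotated read per copy, with per-base miscalls and quality strings
emit_reads <- function(drawn, copies, clones, cfg, rep_id) {
  n_reads <- sum(copies)
  src <- rep.int(seq_len(nrow(drawn)), copies)
  template <- vapply(src, function(i) {
    clones[[drawn$true_clone[i]]]$variants[drawn$variant[i]]
  }, character(1))
  observed <- vapply(template, mutate_sequence, character(1),
                     rate = cfg$seq_error_rate, USE.NAMES = FALSE)
  quals <- lapply(nchar(observed), draw_qualities, qm = cfg$quality_model)

  clone_of <- drawn$true_clone[src]
  v_len <- vapply(clone_of, function(ci) clones[[ci]]$v_len, integer(1))
  cdr3_len <- vapply(clone_of, function(ci) clones[[ci]]$cdr3_len,
                     integer(1))
  cdr3_nt <- substr(observed, v_len + 1L, v_len + cdr3_len)
  cdr3_aa <- as.character(suppressWarnings(Biostrings::translate(
    Biostrings::DNAStringSet(cdr3_nt), if.fuzzy.codon = "solve")))
  germline <- vapply(clone_of, function(ci) clones[[ci]]$germline,
                     character(1))
  v_identity <- mapply(function(obs, germ, vl) {
    ro <- charToRaw(substr(obs, 1L, vl))
    rg <- charToRaw(substr(germ, 1L, vl))
    sum(ro == rg) / vl
  }, observed, germline, v_len, USE.NAMES = FALSE)

  ids <- sprintf("%s_%06d", rep_id, seq_len(n_reads))
  rearr <- tibble::tibble(
    sequence_id = ids,
    subject_id = "SIM1",
    replicate_id = rep_id,
    v_call = vapply(clone_of, function(ci) clones[[ci]]$v_gene,
                    character(1)),
    j_call = vapply(clone_of, function(ci) clones[[ci]]$j_gene,
                    character(1)),
    sequence = observed,
    germline = germline,
    cdr3_nt = cdr3_nt,
    cdr3_aa = cdr3_aa,
    v_identity = v_identity,
    copies = 1L
  )
  reads <- tibble::tibble(
    read_id = ids, replicate_id = rep_id, bases = observed, quals = quals
  )
  truth_seq <- tibble::tibble(
    sequence_id = ids, replicate_id = rep_id,
    true_clone = clone_of, variant = drawn$variant[src]
  )
  list(rearr = rearr, reads = reads, truth_seq = truth_seq)
}

draw_qualities <- function(len, qm) {
  low <- stats::runif(len) < qm$low_fraction
  q <- ifelse(low,
              stats::rnorm(len, qm$low_mean_q, qm$sd_q),
              stats::rnorm(len, qm$mean_q, qm$sd_q))
  pmin(40L, pmax(2L, as.integer(round(q))))
}

#' Pairwise clustering recovery against simulated ground truth
#'
#' Scores an inferred clonal partition against the simulator's true clone
#' labels by same-clone sequence pairs: precision is the fraction of
#' inferred same-clone pairs that are truly clonal, recall the fraction of
#' true same-clone pairs (among sequences that received a clone
#' assignment) that were recovered, and F1 their harmonic mean. Sequences
#' dropped before clustering (e.g. copy-filtered) are excluded from the
#' contingency.
#'
#' @param truth_sequences Tibble `sequence_id`, `true_clone` from
#'   `simulate_repertoire()$truth$sequences`.
#' @param useqs Unique-sequence tibble from [collapse_subject()] (carries
#'   `sequence_ids`).
#' @param clones Clone tibble from [assign_clones()].
#' @return A list with `precision`, `recall`, `f1` and `n_sequences`
#'   (number of reads scored).
#' @export
evaluate_recovery <- function(truth_sequences, useqs, clones) {
  useq_clone <- stats::setNames(
    rep(clones$clone_id, lengths(clones$members)),
    unlist(clones$members)
  )
  seq_useq <- stats::setNames(
    rep(useqs$useq_id, lengths(useqs$sequence_ids)),
    unlist(useqs$sequence_ids)
  )
  inferred <- useq_clone[seq_useq[truth_sequences$sequence_id]]
  scored <- !is.na(inferred)
  truth <- truth_sequences$true_clone[scored]
  inferred <- inferred[scored]
  if (sum(scored) < 2L) {
    return(list(precision = NA_real_, recall = NA_real_, f1 = NA_real_,
                n_sequences = sum(scored)))
  }
  cont <- table(truth, inferred)
  pairs2 <- function(x) sum(choose(x, 2))
  tp <- pairs2(cont)
  pred <- pairs2(colSums(cont))
  act <- pairs2(rowSums(cont))
  precision <- if (pred > 0) tp / pred else NA_real_
  recall <- if (act > 0) tp / act else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(precision = precision, recall = recall, f1 = f1,
       n_sequences = sum(scored))
}
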