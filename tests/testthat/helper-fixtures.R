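# In-code fixtures: small builders used across the suite.

make_reads <- function(bases, quals, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("read%02d", seq_along(bases))
  tibble::tibble(read_id = ids, bases = bases, quals = quals)
}

random_read <- function(len, q_range = c(2, 40)) {
  list(
    bases = paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  collapse = ""),
    quals = sample(seq(q_range[1], q_range[2]), len, replace = TRUE)
  )
}

# minimal annotated rearrangement rows with sensible defaults
make_rearr <- function(sequence, replicate_id = "R01", copies = 1L,
                       sequence_id = NULL, subject_id = "S1",
                       v_call = "IGHV1-2", j_call = "IGHJ4",
                       cdr3_nt = "TGTGCGAGATGG", cdr3_aa = "CARW",
                       germline = NA_character_, v_identity = 0.95) {
  n <- length(sequence)
  if (is.null(sequence_id)) {
    sequence_id <- sprintf("seq%03d", seq_len(n))
  }
  tibble::tibble(
    sequence_id = sequence_id, subject_id = subject_id,
    replicate_id = rep_len(replicate_id, n),
    v_call = rep_len(v_call, n), j_call = rep_len(j_call, n),
    sequence = sequence, germline = rep_len(germline, n),
    cdr3_nt = rep_len(cdr3_nt, n), cdr3_aa = rep_len(cdr3_aa, n),
    v_identity = rep_len(v_identity, n),
    copies = rep_len(as.integer(copies), n)
  )
}

# unique-sequence rows ready for assign_clones(), bypassing collapse
make_useq <- function(cdr3_aa, total_copies, v_call = "IGHV1-2",
                      j_call = "IGHJ4", sequence = NULL,
                      replicate_id = "R01") {
  n <- length(cdr3_aa)
  if (is.null(sequence)) {
    sequence <- sprintf("ACGTACGTAC%02d", seq_len(n))
  }
  tibble::tibble(
    useq_id = sprintf("U%03d", seq_len(n)),
    subject_id = "S1",
    sequence = sequence,
    v_call = rep_len(v_call, n), j_call = rep_len(j_call, n),
    cdr3_nt = strrep("A", nchar(cdr3_aa) * 3L), cdr3_aa = cdr3_aa,
    germline = NA_character_,
    sequence_ids = lapply(seq_len(n), function(i) sprintf("s%03d", i)),
    copies_by_replicate = lapply(as.integer(total_copies), function(k) {
      stats::setNames(k, replicate_id)
    }),
    total_copies = as.integer(total_copies),
    instances = rep(1L, n)
  )
}

# clone table stub for metric/diversity/overlap tests
make_clones <- function(copies, instances = NULL, uniques = NULL,
                        replicate_presence = NULL,
                        copies_by_replicate = NULL) {
  n <- length(copies)
  if (is.null(instances)) instances <- copies
  if (is.null(uniques)) uniques <- rep(1L, n)
  if (is.null(replicate_presence)) {
    replicate_presence <- rep(list("R01"), n)
  }
  if (is.null(copies_by_replicate)) {
    copies_by_replicate <- lapply(seq_len(n), function(i) {
      cbr <- rep(copies[i] / length(replicate_presence[[i]]),
                 length(replicate_presence[[i]]))
      stats::setNames(as.integer(round(cbr)), replicate_presence[[i]])
    })
  }
  tibble::tibble(
    clone_id = seq_len(n), subject_id = "S1",
    v_gene = "IGHV1-2", j_gene = "IGHJ4", cdr3_len_nt = 12L,
    cdr3_aa = "CARW",
    copies = as.integer(copies), instances = as.integer(instances),
    uniques = as.integer(uniques),
    members = lapply(seq_len(n), function(i) sprintf("U%03d", i)),
    copies_by_replicate = copies_by_replicate,
    replicate_presence = replicate_presence
  )
}

# small, fast simulator configuration for pipeline-level tests
small_sim_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(
    seed = seed, n_clones = 40L,
    size_distribution = list(type = "powerlaw", shape = 1.5,
                             min_cells = 3, max_cells = 100),
    cells_sampled_per_replicate = 120L
  ), list(...))
  do.call(simulation_config, args)
}

# quality profile with a modest low-quality tail, so QC keeps most reads
mixed_quality_read <- function(len, n_low = 8L) {
  quals <- sample(28:40, len, replace = TRUE)
  quals[sample(len, min(n_low, len))] <- sample(2:19, min(n_low, len),
                                                replace = TRUE)
  list(bases = random_read(len)$bases, quals = quals)
}
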