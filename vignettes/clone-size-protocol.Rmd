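---
title: "Evaluating B-cell clone sizes in bulk heavy-chain repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating B-cell clone sizes in bulk heavy-chain repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonescape)
```

## The problem

Bulk sequencing of antibody heavy-chain (IGH) gene rearrangements from
genomic DNA turns a tissue sample into a list of reads, each a VDJ
rearrangement carrying the hypervariable CDR3. Because every B cell
carries (on average 1.4) rearrangements in its genome, gDNA-based
sequencing has a property that mRNA-based protocols lack: copy counts are
interpretable in units of cells. The analytical task is to move from
reads to *clones* — sets of sequences descending from one progenitor
cell, diversified by somatic hypermutation (SHM) — and then to make
defensible quantitative statements about clone sizes, repertoire
diversity, and the overlap of clones between samples.

`clonescape` implements this protocol end to end, together with a
simulator that generates repertoires with known clonal ground truth, so
that every stage has a testable target.

## Pipeline stages and their parameters

### Read-level quality control

Three operations are applied in order, mirroring common practice for
amplicon quality filtering:

1. **Sliding-window trim** (`trim_sliding_window`): windows of
   `window = 10` bases slide one base at a time; at the first window
   whose mean Phred quality drops below `threshold = 20`, the read is
   truncated at that window's *start*, keeping the clean prefix. The
   wording "trimmed from its beginning to the end of the window" admits
   two readings (cut at window start vs. window end); we truncate at the
   start, the conservative choice that never retains a base from a
   failing window. The mean test is computed as
   `sum(quals) < threshold * window` on integers, so no floating-point
   tie can flip a boundary decision.
2. **Low-quality masking** (`mask_low_quality`): bases strictly below
   Q20 become `N`. The threshold is strict (`< 20`): a Q20 base is kept.
3. **Read filter** (`filter_read`): a read is discarded iff it has more
   than `max_n = 10` masked bases or fewer than `min_len = 100` bases.
   Both boundaries keep the read ("more than", "less than").

The pipeline is idempotent — re-running it on its own output is a no-op —
and order-deterministic. Paired-read assembly is deliberately out of
scope: the module accepts already-merged reads.

Run-level criteria (`check_run_quality`) require at least 90% of
clusters passing the instrument filter and at least 70% of bases at Q30
or better, both inclusive.

### Post-annotation filters

Germline V/J assignment is an *input* (AIRR `v_call`/`j_call` columns),
not something this package computes. Before collapsing:

* sequences under 60% V-germline identity are discarded (strictly
  below; 60.0% survives);
* sequences are trimmed to IMGT position 150, because FR1 primers
  overlap the 5′ V segment and would bias any mutation-bearing analysis;
  a sequence whose alignment *begins after* position 150 is dropped
  ("after" is strict — a position-150 starter stays). Trimming removes
  positions ≤ 150 rather than > 150: the purpose of the rule is to
  excise the primer-proximal region, which is the 5′ end;
* a sequence carrying V-gene ties from two or more IMGT families
  (`IGHV1-2` with `IGHV3-23`) is discarded as a likely hybrid PCR
  artifact; same-family V ties and *any* J ties are kept, since several
  human J genes are nearly indistinguishable;
* within a subject, a replicate whose valid-read count is five-fold or
  more below the best other replicate is flagged for re-amplification
  (`replicate_imbalance`). Five-fold exactly flags.

### Subject-wide collapsing

Copies are pooled across *all* replicates of a subject before any copy
filter is applied. Two sequences are equal if they differ only where
either carries an `N`. This relation is not transitive (`ANG` matches
both `AAG` and `ACG`, which differ), so the partition is defined
procedurally: distinct strings are processed in descending total-copy
order (lexicographic on ties) and each joins the first established
group whose *founding* sequence it matches, else founds a group. This
makes the result deterministic and independent of input row order,
which we verify by property test. Each group's representative is the
member with fewest `N`s (ties: more copies, then lexicographic), so
downstream CDR3 translation is maximally informative.

Pooling before filtering has a rescue effect worth reporting: a
sequence seen once in each of two replicates reaches the copy ≥ 2
eligibility bar even though it would fail it in either library alone.
`rescue_low_copy()` counts these.

### Clone eligibility and grouping

To prevent spurious clones, a unique sequence is excluded from clonal
assignment if (i) its subject-wide copy count is below 2, (ii) its CDR3
contains a stop codon, or (iii) any 30-nt window of its germline
alignment falls below 60% identity — the signature of an uncorrected
indel shifting the frame. For the window identity, positions where
either strand is `N` (or an alignment gap) count in neither numerator
nor denominator. One guard is ours: a window is only judged when at
least half of its 30 positions remain comparable. Near the junction the
germline is masked, and an identity estimated from 3–5 comparable
positions is noise — without the guard, ordinary SHM excluded ~4% of
clean simulated sequences as pseudo-indels.

Clone membership requires identical V gene, J gene and CDR3 nucleotide
length, and ≥ 85% CDR3 amino-acid similarity (1 − Hamming/length)
between *every* pair of members. `X` (ambiguous) residues match
anything, mirroring nucleotide-level N-tolerance. Since the pairwise
requirement does not by itself determine a unique partition, we use
greedy complete linkage: sequences in descending copy order, each
joining the first clone whose every member it matches at ≥ 0.85, else
founding a new clone. Gene-call ties are handled by set intersection —
two call sets are compatible if they intersect, and a clone's gene set
is the running intersection of its members', which preserves the
shared-gene requirement exactly. The emitted partition is checked post
hoc in the test suite: every member pair of every clone satisfies the
threshold, and total copies are conserved exactly through collapse and
assignment.

### Clone-size metrics

Three sizes are attached to every clone:

* **copies** — summed read counts across all replicates; sensitive to
  PCR amplification bias but has the largest dynamic range;
* **instances** — the number of (unique sequence, replicate)
  occurrences; robust to per-library copy jackpots;
* **uniques** — distinct sequence variants; reflects SHM
  diversification.

On top of the size table: `d20` (fraction of total copies in the 20
largest clones — a one-number screen for clonal expansion), top-n
rankings under any metric (ties broken copies → instances → uniques →
clone id, documented and deterministic), clone counts at size cut-offs,
and the fraction of copies retained at increasing copy cut-offs.

The sampling estimators use fixed constants — 1000 pg/ng, 1.4
rearrangements per cell, 6.7 pg of gDNA per cell. The rearrangement
bound is floored to an integer (20,895 for 100 ng), and the
input-DNA normalization `target/b_fraction` is truncated (not rounded)
to one decimal (142.8 ng for 50 ng at a 35% B-cell fraction), with the
exact quotient attached as an attribute; truncation matches the
convention used when these worked examples are quoted.

## Diversity

All diversity statistics consume a vector of proportional abundances
`p_i` built by `abundance_from_clones()`: clones below an *instance*
cut-off are dropped, then the chosen size metric is renormalized over
the survivors. The Hill number

$$ {}^qD = \Big( \sum_{i=1}^{R} p_i^{\,q} \Big)^{1/(1-q)} $$

is the effective number of clones at order $q$: $q = 0$ counts clones
(richness), $q = 1$ is the exponential of Shannon entropy (taken as the
analytic limit when $|q-1| \le 10^{-9}$), $q = 2$ the inverse Simpson
index; higher orders weight large clones more. Profiles over a grid of
orders (default 0 to 4 by 0.1) are non-increasing in $q$ — a property
the tests assert — and a profile that is flat indicates perfectly even
clone sizes.

Two conventions needed fixing where the common formulations disagree:

* **Pielou's evenness** is implemented as $J = H/\ln R$, the standard
  definition with range $[0, 1]$ (a formulation without the minus sign
  on $H$ would be negative and is a typographical slip wherever it
  appears);
* **clonality** is the normalized complement $C = 1 - J$, the usual
  repertoire convention: 0 for a maximally even repertoire, approaching
  1 near monoclonality. The alternative reading "inverse of entropy" as
  $1/H$ is unbounded and was rejected. Both $J$ and $C$ are undefined
  at $R = 1$ ($\ln 1 = 0$) and return `NA` with a warning.

## Rarefaction and overlap

Sampling sufficiency is judged by rarefaction — the expected number of
distinct clones in a random subsample. Both estimators are analytic
hypergeometric expectations, not resampling:

* individual-based, over $n$ of $N$ copies:
  $E[S(n)] = \sum_i \big(1 - \binom{N-N_i}{n}/\binom{N}{n}\big)$;
* sample-based, over $t$ of $T$ replicate libraries:
  $E[S(t)] = \sum_i \big(1 - \binom{T-T_i}{t}/\binom{T}{t}\big)$,
  where $T_i$ is the number of replicates containing clone $i$.

Binomial coefficients are evaluated with `lchoose` in log space, so the
expectations are exact at any size; Monte-Carlo resampling appears in
the tests only as an independent oracle. For stratified curves, clone
size is measured as *replicate presence* ($T_i$, Boolean per library) —
the natural unit for sample-based expectations — while the
per-unique-sequence instance count is used everywhere else; both are
reported.

The judgement that a curve "levels off" is made reproducible by
`plateau_cutoff()`: a stratum plateaus when the relative increment of
expected richness over the final replicate step falls below a
configurable `epsilon` (default 1%). The smallest plateauing cut-off is
the smallest clone size the data can reliably track across samples.
With only two replicates no curve can plateau meaningfully (the rule
requires $T \ge 3$); this mirrors practice, where duplicate designs
rely on individual-based rarefaction instead.

Two-sample overlap is the cosine similarity of clone abundance vectors
aligned on the union of clones (absent clones contribute 0). Cosine is
scale-invariant, so any of the three size metrics can feed it, and it
is bounded in $[0, 1]$ for the non-negative abundances used here. For
more than two samples, Boolean presence matrices
(`presence_matrix`) support Venn-style counts (`overlap_counts`) and
export for string-plot/heat-map rendering in external tools; graphical
rendering itself is out of scope.

## The simulator

`simulate_repertoire()` emulates the experimental design the package
targets: one subject, several independently amplified replicate
libraries from the same cell population, one template per cell (gDNA
semantics). Defaults describe a duplicate-amplified survey:

| parameter | default | meaning |
|---|---|---|
| `n_clones` | 200 | true clones in the population |
| `size_distribution` | Pareto, shape 1.5, min 3, cap 500 | cells per clone (heavy-tailed, as real clone-size distributions are) |
| `shm_rate` | 0.05 | per-base divergence of a variant from its clone founder (5% is the upper end of typical IGH SHM loads) |
| `n_variants_model` | λ = 0.5, founder weight 0.85 | 1 + Poisson(λ) variants per clone; most cells carry the founder sequence |
| `n_replicates` | 2 | replicate libraries |
| `cells_sampled_per_replicate` | 600 | cells drawn without replacement per library |
| `pcr_lognormal_sigma` | 0.5 | log-scale spread of per-variant amplification |
| `seq_error_rate` | 0.001 | per-base miscall probability per read |
| `quality_model` | Q35 ± 3, 2% tail at Q12 | Phred score generator for FASTQ output |

SHM uses a *star topology*: each variant mutates independently from the
clone founder, and cells are allocated founder-heavily. This is the
lineage shape of a dominant expanded variant with satellite mutants,
and it keeps within-clone CDR3 distances concentrated around the
founder — under a model where variants mutate independently of each
other at 5% per base, typical variant-variant CDR3 distances would
exceed the 15% Hamming allowance and *no* complete-linkage procedure
could recover the clone, which would say something about the model, not
the method. Mutations are placed uniformly (no hotspot model), indels
and chimeras are not simulated, and replicates draw cells independently
from the same population (equivalent to aliquoting at small sampling
fractions; strict template partitioning is not modelled). Passing tests
on simulated data therefore demonstrate correctness of the protocol's
logic and estimators — not robustness to indels, hotspot-clustered SHM,
primer bias, or contamination, none of which the generator produces.

Ground truth (true clone of every read, true cell counts, per-replicate
sampled cells) accompanies every simulation, and
`evaluate_recovery()` scores an inferred partition by same-clone
sequence pairs (precision/recall/F1). Pairs are computed over reads
that received a clone assignment; reads dropped by the copy filter are
excluded from both numerator and denominator. On the default
configuration the pipeline recovers simulated clones with pairwise F1
above 0.99 (precision is essentially 1; the rare misses are
heavily-mutated satellite variants splitting off, as complete linkage
is designed to let them).

## Problem sizes and runtime

The test suite runs entirely on generated data: simulations use 40–300
clones and 120–600 sampled cells per replicate (seconds per run);
rarefaction oracles enumerate populations of at most 8 individuals
exhaustively and cross-check larger instances against $10^5$
Monte-Carlo draws; recovery is evaluated over five independent
simulation seeds at the default configuration. These sizes were chosen
so that a full check of every stage — including the brute-force oracles
— completes in about a minute.

## Known limitations

* Germline assignment, paired-read assembly, and UMI consensus are
  upstream of this package and must be supplied (AIRR TSV / merged
  FASTQ).
* The greedy complete-linkage partition is deterministic but, like any
  resolution of a non-transitive pairwise rule, not the unique partition
  satisfying the constraints; the copy-ordered seeding mirrors the
  behaviour of copy-weighted clustering tools.
* Asymptotic richness estimators (Chao1, ACE) and extrapolation beyond
  observed sample sizes are intentionally absent: the protocol's
  question is whether the *observed* sampling suffices.
* Cross-subject collapsing is not performed; all pooling is within
  subject.
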