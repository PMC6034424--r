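# clonescape

Clone-size metrics and sampling-sufficiency analysis for bulk antibody
heavy-chain (IGH) repertoire sequencing.

When B-cell receptor repertoires are sequenced in bulk from genomic DNA,
the central analytical objects are *clones*: groups of rearranged
heavy-chain sequences descending from a common progenitor B cell.
`clonescape` implements a complete, file-based protocol for going from raw
reads to quantitative clone-size statements, aimed at immunologists and
bioinformaticians working with replicate-amplified gDNA libraries
(e.g. spleen or other tissue repertoires sequenced in duplicate or deeper):

* **Read QC** — sliding-window quality trimming (10 bp windows, mean
  Phred < 20 truncates), masking of bases below Q20 as `N`, and discarding
  of reads with more than 10 `N`s or shorter than 100 bases; run-level
  pass criteria (≥ 90% clusters passing filter, ≥ 70% of bases ≥ Q30).
* **Post-annotation filters** — V-germline identity ≥ 60%, trimming to
  IMGT position 150 (FR1 primers bias the 5′ V segment), discarding of
  cross-family V-gene ties, and flagging of replicates with five-fold
  lower valid-read yield.
* **Subject-wide collapsing** — sequences identical up to `N` positions
  are merged across all replicates of a subject, pooling copy counts.
* **Clonal inference** — eligible unique sequences (subject-wide copies
  ≥ 2, no CDR3 stop codon, no 30-nt window below 60% germline identity)
  are grouped into clones that share V gene, J gene, and CDR3 nucleotide
  length, with every member pair at ≥ 85% CDR3 amino-acid similarity
  (complete linkage, greedy by copy count).
* **Three clone-size metrics** — *copies* (total reads), *instances*
  (unique-sequence × replicate occurrences) and *unique sequences*, each
  exposing a different facet of expansion.
* **Diversity** — Hill-number profiles
  `^qD = (Σ p_i^q)^(1/(1−q))` across orders q, plus Shannon entropy
  `H = −Σ p_i ln p_i`, Simpson's index `λ = Σ p_i²`, Pielou's evenness
  `J = H / ln R` and clonality `C = 1 − J`.
* **Sampling sufficiency** — individual-based and sample-based
  rarefaction, `E[S(t)] = Σ_i (1 − C(T−T_i, t)/C(T, t))`, stratified by
  clone-size cut-off, with an explicit plateau rule for choosing the
  smallest reliably-sampled clone size.
* **Clonal overlap** — cosine similarity
  `Σ A_i B_i / (√ΣA_i² √ΣB_i²)` between replicate abundance vectors, and
  Boolean clone-by-replicate presence matrices for clone tracking.
* **Synthetic repertoires** — a simulator with full ground truth
  (heavy-tailed clone sizes, somatic-hypermutation variants, PCR
  copy-number noise, sequencing error), so the whole pipeline is testable
  without any external data.

Back-of-envelope sampling estimators are included: a sample of `n` ng of
B-cell DNA can contain at most `n × 1000 pg/ng × 1.4 rearrangements/cell
÷ 6.7 pg/cell` distinct rearrangements (≈ 150 B cells per ng).

## Worked example

Simulate a duplicate-amplified subject, run the pipeline, and summarise
clone sizes:

```r
library(clonescape)

sim   <- simulate_repertoire(simulation_config(seed = 42))
useqs <- collapse_subject(sim$rearrangements)
clones <- assign_clones(eligible(useqs))
tab   <- clone_size_table(clones)

nrow(sim$rearrangements)   # 1228 annotated reads over 2 replicates
nrow(useqs)                # 610 unique sequences after N-tolerant collapse
rescue_low_copy(useqs)     # 29 rescued by cross-replicate copy pooling
tab$totals
#>    copies instances   uniques    clones
#>       718       236       132       126

d20(tab)                   # 0.5209 — fraction of copies in the top 20 clones

p <- abundance_from_clones(clones, "copies")
shannon(p)                 # 4.2477
simpson(p)                 # 0.0314
pielou(p)                  # 0.8783
clonality(p)               # 0.1217
sapply(c(0, 1, 2), function(q) hill_diversity(p, q))
#> 126.00  69.94  31.89    # richness, exp(Shannon), inverse Simpson

replicate_overlap(clones)
#>   replicate_a replicate_b    cosine
#> 1         R01         R02 0.8161

evaluate_recovery(sim$truth$sequences, useqs, clones)
#> precision 1.000, recall 0.989, F1 0.994
```

The 610 unique sequences collapse into 126 clones whose top 20 hold 52%
of all copies; the two replicates agree strongly on clonal abundances
(cosine 0.82), and the inferred partition recovers the simulated clonal
truth with pairwise F1 0.994.

A command-line interface mirrors the R API:

```sh
clonescape simulate --out-dir sim --seed 17
clonescape qc        --in sim/R01.fastq --out kept.fastq --summary qc.json
clonescape collapse  --in sim/rearrangements.tsv --out uniques.tsv
clonescape clones    --in uniques.tsv --out clones.tsv
clonescape stats     --in clones.tsv --out stats.json
clonescape diversity --in clones.tsv --metric copies --out diversity.tsv
clonescape rarefaction --in clones.tsv --mode sample --out curves.tsv
clonescape overlap   --in clones.tsv --out overlap.tsv --presence-out presence_matrix.tsv
```

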