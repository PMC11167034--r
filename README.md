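# clonolink

Integrated analysis of **paired single-cell transcriptomes and TCR/BCR
repertoires** from matched tissue and blood, built around the questions that
arise when profiling lymphocytes at an inflamed site (the motivating system
is rheumatoid arthritis synovium with paired peripheral blood): which T and
B cell states are clonally expanded, whether clones traffic between blood and
tissue, how much somatic hypermutation and class switching each B cell state
carries, and whether expanded CD8 clones look like known virus-reactive
receptors.

The package is aimed at computational immunologists who have per-cell subset
annotations (clustering is *not* done here), 10x-style
`filtered_contig_annotations.csv` or AIRR Rearrangement exports, and
optionally a gene-count matrix, donor HLA types and a viral TCR reference.

## What it computes

* **Receptor QC** — cell-level thresholds (>= 1000 reads, > 500 genes, < 20%
  mitochondrial), retention of the two most-expressed TCR chains with removal
  of unpaired cells, BCR chain filters (high-confidence, full-length,
  CDR3 >= 5 aa / >= 15 nt, <= 2 heavy and <= 2 light chains), and
  cross-lineage (TCR+BCR) doublet flagging.
* **Clonotypes** — TCR clones by exact `(locus, V, J, CDR3nt)` key within
  donors; BCR clones by greedy centroid clustering of IgH CDR3 nucleotide
  identity (default threshold 96.5%, with 80% for relaxed lineages); clone
  size bins 1 / 2–5 / 6–19 / 20–100 / >100; MAIT flags for
  TRAV1-2 + TRAJ33/20/12.
* **Clonal statistics** — per-donor expansion fractions; pairwise
  Morisita–Horn overlap `MH = 2 Σ aᵢbᵢ / ((Dₐ + D_b) Nₐ N_b)` with
  `Dₐ = Σ aᵢ²/Nₐ²`; top-N clone composition with cross-tissue flags;
  trafficking summaries; CDR3 length/charge; paired two-sided t-tests (or
  Wilcoxon, with optional Holm correction) of subset abundance between
  tissues.
* **SHM and class switch** — nearest-germline assignment by maximal ungapped
  identity, substitution counts, and the combined rate
  `(V-shm + J-shm) / length excluding CDR3`; class-switch state (IgG/IgA vs
  IgM/IgD); linear and logistic mixed models with a donor random intercept
  (via lme4) and Wald 95% CIs.
* **Viral specificity** — exact CDR3β + HLA matching against a reference
  table; simplified GLIPH-style interior k-mer enrichment with one-sided
  Fisher tests, retained only with reference + sample members, p < 0.01 and a
  donor-carried restricting allele.
* **Signatures** — control-binned module scores (24 bins, 100 controls per
  gene) and paired expanded-vs-unexpanded comparisons.
* **Lineage trees** — per-clone Ward (`ward.D`) dendrograms on
  `(v_identity, j_identity, v_shm, j_shm, vj_shm_rate)` features, serialized
  to Newick.
* **Synthetic cohorts** — `paper_default_config()` encodes the study's
  printed cohort-level values (45%/5% naive CD4 in blood/synovium, 64.5%/9.1%
  naive B, 12.5% expanded synovial Tph, 84.7%/93.1% receptor recovery,
  0/40/65/75/>95% class switch by B state) and returns full ground truth, so
  every stage is testable without controlled-access data.

## Worked example

```r
library(clonolink)

cfg    <- paper_default_config(seed = 1)
cohort <- generate_cohort(cfg)                    # 12 SYN + 10 PBL samples
ing    <- ingest(cohort$cells, cohort$chains)     # QC + chain filters

receptor_recovery(ing$cells)[, .(mean_recovery = round(100 * mean(frac), 1)),
                             by = tissue]
#>    tissue mean_recovery
#> 1:    PBL          92.9
#> 2:    SYN          84.0

tcr <- call_tcr_clones(ing$cells, ing$chains)
#> <clone_table> 14700 cells in 12860 clones ( TCR , threshold: exact )

ef <- expansion_fraction(ing$cells, tcr, "CD4-Tph", tissue = "SYN")
#> synovial Tph cells in expanded clones: 14.3% (range 5.7-21.4%)

sw <- classify_switch(ing$chains)
merge(sw, ing$cells[doublet_flag == FALSE, .(cell_id, subset)],
      by = "cell_id")[subset %in% c("B-memory", "B-ABC", "B-activated"),
                      .(pct_switched = round(100 * mean(switched), 1)),
                      by = subset]
#>         subset pct_switched
#> 1:    B-memory         76.1
#> 2:       B-ABC         61.4
#> 3: B-activated         40.4

shm <- assign_germline(ing$chains, cohort$germline)
fit_shm_model(shm, ing$cells, reference_subset = "B-naive-IgD-high")
#>               level estimate ci_lo ci_hi     p
#> 1: B-naive-IgD-high    0.000    NA    NA    NA
#> 2:      B-activated    0.013 0.013 0.014     0
#> 3:         B-memory    0.028 0.027 0.028     0   (excerpt)
#> 4:         B-plasma    0.042 0.042 0.043     0
```

The recovery fractions reproduce the generator's dropout (84.7% SYN / 93.1%
PBL up to sampling noise); the synovial Tph expansion is one donor-set draw
around the 12.5% preset; the switch percentages match the per-state
probabilities; and the SHM model recovers each state's excess mutation rate
over the naive reference (e.g. memory 0.030 − 0.002 = 0.028 per site).

A command-line interface covering simulate/ingest/clonotype/stats/shm/models/
specificity/score/lineage/run is installed under `exec/clonolink`; e.g.

```sh
clonolink simulate --out fixture/ --seed 5
clonolink run --cohort fixture/ --out results/
```

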