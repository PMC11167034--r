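---
title: "Methods: models, conventions and the synthetic stated world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and the synthetic stated world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Paired single-cell RNA + V(D)J profiling of lymphocytes from an inflamed
tissue and matched blood lets one ask which annotated T and B cell states are
clonally expanded, whether the same clones appear in both compartments, how
much somatic hypermutation (SHM) and class switching each B state carries,
and whether expanded CD8 clones resemble known virus-reactive receptors.
clonolink implements that analysis chain — receptor QC, clonotyping, clonal
statistics, SHM/switch models, specificity matching, signature scoring and
lineage trees — for inputs where subset labels, doublet scores and HLA types
are already available. Clustering, batch correction, doublet detection
algorithms and cell–cell interaction inference are deliberately out of scope.

# Receptor QC

Cells pass QC with >= 1000 mapped reads, > 500 detected genes and < 20%
mitochondrial reads (all exposed as arguments). For TCRs, the two chains with
the highest UMI counts are retained per cell (ties broken by read count then
contig id, making the filter deterministic); a cell whose retained chains
cover only one locus class loses all TCR information but **keeps its
expression profile** — we remove receptor annotations, not cells, since the
downstream expression analyses remain valid for such cells. TRG/TRD are
treated as the alpha-like/beta-like pair for this rule. BCR chains must be
high-confidence, full-length, with CDR3 >= 5 aa and >= 15 nt; cells with more
than two heavy or two light surviving chains lose their BCR annotations.
Cells retaining at least one TCR and one BCR chain are flagged as
cross-lineage doublets and excluded from every repertoire statistic and
model.

# Clonotype definitions

**TCR.** Within a donor, the clone key is the sorted tuple of
`(locus, v_call, j_call, cdr3_nt)` over the retained chains. This is stricter
than "identical CDR3": including V and J genes of both chains prevents
convergent CDR3s from merging, and matches the defaults of the standard
single-cell repertoire tools. Keys are never compared across donors; "public"
clones are not merged.

**BCR.** Within a donor, IgH CDR3 nucleotide sequences are clustered greedily
(CD-HIT style): sequences ordered by descending length, then descending cell
count, then lexicographically; each joins the earliest-founded cluster whose
*representative* (founder) reaches the identity threshold, else founds a new
cluster. Identity is the maximal number of matching positions over all
ungapped offsets divided by the **longer** sequence's length — a conservative
choice; the CD-HIT convention (shorter denominator) is available via
`denominator = "shorter"`. The default threshold is 0.965, with 0.80 for the
relaxed lineage analysis. Clustering is donor-partitioned but *not*
V/J-partitioned, because the clone definition names CDR3 DNA similarity only.
Greedy clustering coincides with all-pairs single linkage whenever identity
is transitive at the threshold; where it is not, every member still satisfies
the identity bound against its representative (both properties are tested).

Clone sizes are binned 1 / 2–5 / 6–19 / 20–100 / >100. The outer bins (the
published "smaller" and "large" categories) pin 2–5 and 20–100; the 6–19
middle bin is our choice, as the middle edges are not published.

# Clonal statistics

Overlap uses the **Morisita–Horn** index
`MH = 2 Σ aᵢbᵢ / ((Dₐ + D_b) Nₐ N_b)`, `Dₐ = Σ aᵢ²/Nₐ²`, over the union of
clone ids. It is bounded in [0, 1] (the classical Morisita index can exceed
1), equals 1 iff relative abundances coincide, 0 iff the clone sets are
disjoint; the implementation is symmetric and scale-invariant. Count vectors
are **cells per clone per subset** (not clone-collapsed); this convention is
recorded in the matrix metadata.

Expansion fractions divide a subset's cells in clones of size >= 2
(donor-wide size) by its receptor-bearing, clone-assigned cells — cells
without a receptor cannot be assessed and are excluded from the denominator.
Differential abundance between tissues uses per-donor subset fractions of
lineage (or compartment) cells and a two-sided paired t-test on complete
SYN−PBL pairs; raw p-values by default (matching the headline panels), with
Holm correction and a Wilcoxon signed-rank variant selectable (used in the
paired activation-signature comparisons).

# SHM and class switch

The nearest germline is the reference segment with maximal ungapped identity
over the aligned (fully contained) region, ties broken by reference order; no
indel model, consistent with substitution-count quantification. The V region
is the heavy-chain sequence before CDR3 and the J region the sequence after
it; `vj_shm_rate = (v_shm + j_shm) / (sequence length excluding CDR3)`. The
source text counts substitutions "in the CDR3 sequence" yet divides by the
length *excluding* CDR3; counting V/J substitutions outside CDR3 is the only
internally consistent reading and is what we implement.

Class switch is binary: IgG/IgA switched, IgM/IgD not; IgE and unresolvable
constant calls are excluded with a warning rather than pooled, since the
binary definition names only the four classes.

Both models include a donor random intercept (lme4; the contract is the model
structure, reference coding and Wald 95% CIs, not a particular estimator):
a linear model of `vj_shm_rate` on subset (reference: the IgD-high naive
state, whose estimate is 0 by the identifiability convention) or on tissue
within subset; and a logistic model of switch state on subset + tissue
(reference tissue PBL). Subsets with all-0 or all-1 outcomes are reported
with a separation warning — with the paper-default preset the naive states
have switch probability exactly 0, so this path is exercised by design.
Single-donor inputs fall back to fixed-effects fits with a warning.

# Viral specificity

Exact matching requires equality of the TRB CDR3 amino-acid sequence with a
reference row *and* that the row's MHC allele, truncated to two-field
resolution, is carried by the donor. Motif matching is a simplified
GLIPH-style procedure: contiguous interior k-mers (k = 3 or 4; 3 N-terminal
and 2 C-terminal residues trimmed, the cited tool's convention) are
enumerated per virus from reference and sample clones; each motif is tested
one-sidedly (enrichment of reference + sample clones over a background clone
set) with Fisher's exact test; groups are retained only with p < 0.01, at
least one reference and one sample member, and a reference allele carried by
a member's donor. Per-virus runs are unioned into the per-cell flags without
deduplicating motifs across viruses. There is no local/global split and no
V-gene bias correction — this is documented as a simplification.

# Module scores

Genes are ranked by mean expression over the analyzed cells (pooled, not
per sample) and cut into 24 equal-frequency bins; each signature gene draws
100 control genes from its bin (with replacement only when the bin is
smaller); the per-cell score is mean(signature) − mean(all control draws).
Scores are exactly invariant to adding a constant everywhere, deterministic
given the seed, and identically 0 under uniform expression. Caveat: if the
signature genes monopolize their expression bin, controls are drawn from the
signature itself and the score compresses; the recovery tests therefore
spread baselines across bins, which is also what real transcriptomes look
like.

# Lineage trees

Per-clone features are `(v_identity, j_identity, v_shm, j_shm, vj_shm_rate)`
— counts and rates mixed on their native scales, reproducing the published
recipe, which lists no standardization step; a `standardize` flag z-scores
them if desired. Euclidean distances feed `hclust(method = "ward.D")` — the
classical Ward update on *unsquared* distances, deliberately not `ward.D2`,
matching the named method. Input rows are sorted by cell id so permuted
input yields an isomorphic tree. Newick output is ultrametric with node
depth = merge height / 2; `newick_heights()` inverts this exactly. Leaves
are cells (not collapsed identical sequences).

# The synthetic stated world

`paper_default_config()` encodes the printed cohort-level values: 12 donors
with synovial samples, 10 with paired blood; naive cells at 45% of blood CD4
T cells vs 5% in synovium; naive states at 64.5% of blood B cells vs 9.1% in
synovium; 12.5% of synovial Tph cells in expanded clones; receptor recovery
84.7% (SYN) / 93.1% (PBL); class-switch probabilities 0% naive, 40%
activated, 65% ABC, 75% memory, >95% (encoded 0.97) plasma. Where only plots
or no values are printed, defaults are fixed choices a practitioner would
call realistic and are **not** revisited:

* per-subset SHM rates are ordinal only (naive < activated/ABC < memory <
  plasma): 0.002/0.004, 0.015, 0.018, 0.030, 0.040, 0.045 per site;
* clone sizes follow a truncated geometric law on sizes >= 2 (heavy singleton
  mode, long tail, matching the published categorical spectra); tail
  parameters are larger for cytotoxic CD8 states;
* non-headline composition entries are plausible splits that preserve the
  printed ratios;
* CDR3s are 30–60 nt in codon multiples, C...F-anchored and stop-free; TCR
  clone members share both chains exactly; BCR clone members share germline
  and CDR3 but receive independent SHM draws (intraclonal diversification);
* the germline mini-reference is synthetic (10 V + 6 J per class, uniform
  segment lengths 288/48 nt, IMGT-style names, fixed internal seed) —
  mutually ~75% divergent, so nearest-germline assignment is unambiguous at
  realistic SHM rates; it stands in for a licensed germline database and is
  labelled synthetic;
* receptor dropout is per cell (the receptor as a unit), because the
  recovery parameter is defined as "the probability a cell's receptor is
  recovered" and the printed recovery fractions are cell-level quantities;
* expansion parameters refer to receptor-bearing cells, because the printed
  expansion fractions are post-recovery observations; clone membership is
  therefore sampled after dropout;
* trafficking selects **expanded** clones only: seeding singletons into the
  second tissue would raise every realized expansion fraction above its
  configured value;
* expression is a small negative-binomial model (500 genes, 30 signature
  genes, log fold-change 0.5 in expanded cells of the target subset,
  dispersion 0.5) — the pipeline never needs transcriptome scale;
* cells per sample default to 800 T + 500 B, a desk-scale fraction of the
  study's ~2900–4900 cells/sample; every reported statistic is a per-cell
  fraction and unbiased in sample size.

What a green test establishes: the pipeline recomputes the stated generative
quantities from its own outputs within Monte-Carlo error, and each algorithm
agrees with an independent oracle (brute-force single linkage, direct
hypergeometric tails, hand-rolled Ward agglomeration, direct means). What it
does not establish: realism of V(D)J recombination (no generation
probabilities), SHM hot-spot structure, isotype–SHM coupling, ambient RNA or
other technical artifacts, or correctness of upstream clustering — subset
labels are inputs here.

Mixed-model coverage simulations use a dedicated configuration with switch
probabilities strictly inside (0, 1) and moderate SHM rates, because the
paper-default naive probability of 0 has infinite log-odds; the default
preset is still used to exercise the separation-warning path. The acceptance
script disables the expression matrix in its 20 replicate cohorts (none of
the ten targets consumes expression) — a runtime scale-down only.

# Numerical conventions

One root seed determines everything; per-stage seeds derive from it by a
stable integer hash (always < 2^31). Identity thresholds are closed
("≥ threshold"). Ties: chain retention by UMIs, then reads, then contig
id; germline assignment by reference order; greedy clustering order by
length, cell count, then sequence; top-clone ranking by size then clone id;
lineage trees by cell id. Wald CIs use the normal quantile. Empty inputs
return empty outputs rather than errors wherever the operation is a filter;
undefined statistics (overlap of an empty repertoire, paired tests with < 2
pairs) are `NA`, never 0.

# Known limitations

Ungapped identity everywhere (no indel tolerance in CDR3 clustering or
germline assignment); light chains carry no SHM information; the motif
procedure is a deliberately reduced re-implementation; classical Morisita is
not offered; no multiple-testing correction by default in the abundance
panels (by design, matching the headline figures); HLA comparison is
two-field only.
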