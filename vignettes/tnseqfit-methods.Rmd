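---
title: "Methods: Tn-seq fitness classification and constraint-based deletion screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Tn-seq fitness classification and constraint-based deletion screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical and numerical choices behind
`tnseqfit`: the model each stage assumes, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the known limitations.

## The Tn-seq fitness model

A pooled transposon mutant library is grown competitively. If a clone
carrying an insertion in gene $g$ grows at relative rate $f_g$ per
generation (1 = neutral, 0 = lethal), then after $G$ generations its
abundance — and hence its expected share of sequencing reads — is scaled by
$f_g^G$. Read density over a gene is therefore a monotone readout of the
fitness cost of disrupting it.

**GEI scoring (`gei_profiles`).** The chain is:

1. *Intergenic normalization* (`normalize_samples`). Reads in intergenic
   intervals are assumed selectively neutral, so each sample is multiplied
   by one scalar that equalizes its intergenic read density (reads per
   intergenic nucleotide) across samples. The anchor is the across-sample
   median density; the anchor choice only rescales all GEI values jointly
   and does not affect classification, which operates on relative scores.
2. *3' trimming* (`effective_gene_window`). Insertions in the last 5% of a
   gene often leave a functional truncated protein, so reads mapping there
   are discarded: `floor(0.05 * length)` nucleotides are removed from the
   3' end (high coordinates on the + strand, low coordinates on the −
   strand). Window boundaries are closed: an insertion exactly on the
   boundary counts.
3. *GEI* (`compute_gei`). With normalized replicate counts $c_1, c_2$
   aggregated over the trimmed window and the full gene length $L$,
   $\mathrm{GEI} = ((c_1+1)+(c_2+1))/L$. Adding the pseudocount to each
   replicate *before* summing puts zero-insertion genes exactly on the
   $2/L$ floor (0.002 for 1 kb, 0.001 for 2 kb), which is the convention
   the rest of the pipeline (and the worked examples) relies on. Read
   counts, not unique sites, enter the score; unique insertion sites are
   reported separately.

## Fitness classification

`classify_fitness` works per condition:

1. Genes with zero raw reads in both replicates (before normalization and
   pseudocounts) are called Group I outright. This is deliberately taken on
   raw reads: normalization cannot create reads where none were observed,
   and the rule must not depend on the anchor.
2. log10 GEI of *all* genes (zero-insertion genes sit at their floors) is
   fitted with a univariate Gaussian mixture (`fit_log_gmm`). EM runs from
   10 k-means++ initializations per candidate, for $k$ in 1–7 and both an
   equal-variance and a per-component-variance family; the fit with the
   highest BIC wins. Convergence: tolerance $10^{-8}$ on the log-likelihood
   increment, at most 2000 iterations; a run that hits the cap is accepted
   when its remaining increment is below $10^{-4}$ (immaterial for model
   selection) and rejected with an error otherwise. Component variances are
   floored at $10^{-8}\cdot\mathrm{var}(x)$ to avoid singular components.
3. Each mixture cluster is refined by affinity propagation
   (`refine_affinity_propagation`): similarity $-(x_i-x_j)^2$, preference =
   median off-diagonal similarity, damping 0.9, at most 1000 iterations,
   convergence declared after 100 iterations of a stable exemplar set. How
   the refinement should interact with the mixture fit is genuinely open;
   the package runs AP *within* each mixture cluster and splits the cluster
   only where AP exemplars are separated by more than `split_tol` (default
   0.5 log10 units). This preserves the mixture's coarse structure —
   with a median preference AP on a tight Gaussian cluster happily returns
   many exemplars, and honouring every one of them would shatter the
   groups — while letting genuinely bimodal clusters split. A refinement
   run that oscillates leaves its cluster unsplit rather than aborting.
4. Clusters are mapped to groups ordinally (`assign_groups`). Clusters are
   first made contiguous in GEI (sizes preserved), then merged
   smallest-gap-first until at most five remain, so group severity is a
   monotone step function of GEI. The lowest cluster becomes Group I
   (fused with the zero-insertion genes), then II, III, IV. A fifth, top
   cluster becomes Group V (growth improvement) only when its mean exceeds
   the next cluster's by `v_margin` (default 0.25 log10 units ≈ 1.8-fold);
   otherwise it fuses into IV — some conditions simply have no
   distinguishable growth-improvement class. With fewer than four non-V
   clusters, middle groups are dropped (III first, then II): a 3-cluster
   solution maps to I, II, IV. The mapping when clusters ≠ 5 is not
   canonical; this ordinal scheme is the package's documented choice.

**Differential calls (`call_differential`).** Per-gene
$\log_{10}(\mathrm{GEI}_A/\mathrm{GEI}_B)$ is clustered with the same
mixture machinery ($k$ in 1–5). Clusters whose mean absolute fold change is
below `equal_zone` (default 0.3, i.e. 2-fold) are "equal"; clusters beyond
it are direction-specific calls. The zone is deliberately wide: planted
true differences in the recovery experiments are ~20-fold, and reported
fold changes for genuinely strain-dependent genes are larger still, so a
2-fold equal zone costs little sensitivity while absorbing replicate noise.

## Enrichment and orthology

Enrichment uses the standard two-sided Fisher exact test per category with
Bonferroni correction for the fixed family of 18 categories; fold
enrichment is the in-set category fraction over the background fraction.
An enumeration oracle (`fisher_p_enumerated`) sums hypergeometric
probabilities of tables at most as probable as the observed one and is used
in the tests to verify the p-values exactly.

Reciprocal best hits are computed from BLAST outfmt-6 tables: per query the
top bit-score hit (ties broken by identity, then lexicographic subject id;
multiple HSPs collapse to the best one), kept when mutual and when identity
≥ 30% and aligned coverage ≥ 60%. Whether coverage should be anchored to
the query, subject, or shorter protein is unspecified in common usage; the
default anchors to the *shorter* protein (the strictest symmetric choice)
and is configurable.

## Constraint-based modeling

Models are stoichiometric: maximize biomass flux subject to $Sv = 0$ and
bounds (all bounds finite; ±1000 mmol·gDW⁻¹·h⁻¹ plays the role of
unconstrained). FBA is solved by simplex after shifting fluxes by their
lower bounds so all variables are non-negative. MOMA predicts a knockout's
flux state as the closest feasible point to a wild-type reference:
$\min \sum_i (v_i - v^{\mathrm{ref}}_i)^2$ subject to $Sv=0$, bounds, and
zero flux through deleted reactions, solved as a convex QP (dual active-set
method); a linear (L1) variant is available behind `linear = TRUE`.

The wild-type reference is the *lexicographic* optimum: maximize growth,
then pick the minimum-Euclidean-norm flux vector at that growth. The
quadratic norm is used (rather than a minimum-$\sum|v|$ LP) because the L2
problem has a unique minimizer, making the reference — and therefore every
MOMA prediction — deterministic; L1 solutions can be degenerate. Redundant
mass-balance rows are removed by pivoted QR before the QP.

Numerical conventions: mass-balance residuals above $10^{-6}$ invalidate a
solution; growth below $10^{-6}$ counts as zero (lethal); grRatio defect
threshold 0.9; a double deletion is synthetic-negative when observed
grRatio < 0.9 × (product of single grRatios), with a $10^{-9}$ slack so
exact equality is not flagged. In background comparisons each screen is
normalized to its own wild-type growth (ratios, not absolute rates, are
compared) and a 0.01 grRatio margin absorbs solver noise. Double deletions
are enumerated over all sorted gene pairs; pairs containing a lethal single
are computed like any other — the expected-product rule neutralizes them
(expected 0, observed 0).

Model IO covers SBML Level 3 with the fbc extension (species, reactions,
parameter-backed flux bounds, nested gene-product associations, an active
objective; the replicon tag rides in `fbc:name`) written and read with a
round-trip identity guarantee, plus a four-file tabular dialect
(metabolites/reactions/stoichiometry/genes TSVs) because hand-editing SBML
fixtures is error-prone. GPR rules use case-insensitive AND/OR with
parentheses; there is no NOT, matching fbc practice. The FBA optimum of a
model written by the SBML writer is cross-checked in the tests against the
reference COBRA implementation available through the system Python.

## The synthetic-data generator

`sim_config` defaults encode the study conditions the pipeline is designed
for: 3,500 genes on a 3.65-Mb replicon; log-normal gene lengths (sdlog 0.4)
with mean 950 nt, matching typical bacterial annotations; insertion-site
density set so the median gene carries 39 unique sites (~160,000 sites
genome-wide); two replicate selections of 9 generations; 2×10⁷ reads per
sample; class fractions {essential 0.12, strong defect 0.05, moderate
defect 0.15, neutral 0.66, improved 0.02} with per-generation fitness
values {0, 0.5, 0.8, 1.0, 1.15}. The improved-class value 1.15 is a
realistic modest gain (≈3.5-fold read enrichment after 9 generations) —
large enough to form its own mixture component, small enough that the
Group-V margin decision is actually exercised.

Mechanics: insertion sites are uniform over the replicon (an optional
`bias_fun` hook can impose sequence-motif bias; off by default because
insertion-site composition generally shows little relationship to
essentiality scores); pre-selection clone abundances are Dirichlet-uniform
(independent exponential weights — the simplest exchangeable prior; the
true pre-selection distribution of a real library is unknown and the
package deliberately does not claim one); post-selection site weights are
abundance × $f_g^G$; read counts are one multinomial draw per sample at
exactly `read_depth` reads, so totals are conserved. Replicates share the
site set and abundances (both derive from one library) and resample reads
independently.

What the generator does *not* emulate: sequencing error, PCR jackpotting,
positional bias within genes, polar effects on operons, cross-feeding
between mutants, and genuinely new biology in a second genomic background
(strain effects are planted as per-condition fitness overrides). Passing
recovery tests therefore demonstrates that the statistical machinery
recovers the planted model — not that real libraries satisfy that model.

The toy metabolic models are a linear substrate→biomass backbone (uptake
10) whose stages encode known redundancy: isozyme stages (one reaction,
`a or b` across replicons) and parallel-pathway stages (branch capacities 6
and 4, chromosomal and plasmid genes). Hand linear programming gives the
expected screen values: wild-type growth 10; deleting the 4-capacity branch
leaves 6 (grRatio 0.6), the 6-capacity branch 4 (grRatio 0.4); each
engineered pair is synthetic-negative (e.g. parallel pair: expected
0.4 × 0.6 = 0.24, observed 0).

## Problem sizes and reproducibility

The shipped analyses use: the full 3,500-gene simulation for the
classification and differential recovery checks (single condition, ~15 s
each); a 300-gene demo configuration in `run_pipeline` covering four
conditions end to end; toy models of ~10 reactions for the solver oracles.
These sizes were chosen so the complete test suite and the acceptance
script each run comfortably on a single CPU while keeping every recovery
check at the study-scale gene count where mixture selection is stable.

All stochastic stages consume explicit seeds (`sim_config(seed=)`,
`fit_gmm1d(seed=)`, `run_pipeline` propagates one seed everywhere), and
seeded runs are bit-reproducible, including the run manifest checksums
(GFF3 headers carry a date line; the manifest is otherwise content-only).

## Known limitations

- The cluster→group mapping with fewer than five clusters is a documented
  convention, not an inference; datasets whose true structure is, say,
  {essential, moderate defect, neutral} will see the middle cluster
  labelled II.
- The Gaussian mixture is fitted on log GEI; heavy-tailed read noise or
  strong within-class length effects would call for a different density
  family.
- The simplex/active-set solvers target the small-to-medium models used
  here; genome-scale double-deletion screens (millions of QPs) need an
  industrial LP/QP stack and are out of scope.
- The SBML support is the fbc subset needed for flux models, not a general
  SBML implementation (no kinetics, events, or annotations).
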