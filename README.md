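# tnseqfit

Tools for inferring per-gene fitness from transposon insertion sequencing
(Tn-seq) of bacterial mutant libraries, and for probing genetic redundancy
with constraint-based metabolic models. The package is aimed at microbial
functional genomicists comparing gene essentiality across genomic
backgrounds (e.g. a wild-type multi-replicon genome versus a strain cured of
its secondary replicons) or across growth media, and at modelers running
in-silico single/double gene deletion screens.

## What it computes

**Gene essentiality index (GEI).** After a pooled transposon library is
grown competitively for ~9 generations, insertions in genes needed for
growth are depleted. Reads from two replicate selections are normalized so
intergenic read density matches across samples, reads in the 3'-most 5% of
each gene are discarded, a pseudocount of one is added to each replicate's
normalized gene count, and

```
GEI = ((c1 + 1) + (c2 + 1)) / L
```

with `L` the gene length in nucleotides. A gene with no insertions sits
exactly on the floor `2/L` (0.002 for a 1-kb gene).

**Fitness groups I–V.** Genes with zero reads in both replicates are called
essential outright. log10 GEI scores of all genes are clustered with a
BIC-selected univariate Gaussian mixture (EM, k-means++ starts), each
cluster is refined by affinity propagation, and clusters are mapped in mean
order to Group I (essential), II (strong growth defect), III (moderate
defect), IV (little/no impact) and — only when separated by a margin — V
(growth improvement on disruption). Differential fitness between two
conditions is called by clustering per-gene `log10(GEI_A / GEI_B)` and
labelling clusters outside an equal zone.

**Enrichment and orthology.** Gene sets are tested per functional category
(fixed 18-label vocabulary) with a two-sided Fisher exact test, Bonferroni
corrected for the 18 tests. Orthologs are called from precomputed BLAST
tabular files by reciprocal best hit, kept at >= 30% identity over >= 60% of
the (shorter) protein.

**Constraint-based screens.** Metabolic models (SBML Level 3 + fbc, or a
tabular dialect) are screened by FBA and quadratic MOMA. Every deletion
reports `grRatio = mutant growth / wild-type growth`; a single deletion is a
growth defect when grRatio < 0.9, and a double deletion is a synthetic
negative interaction when its observed grRatio is below 90% of the expected
one (the product of the single grRatios). Whole replicons can be removed in
silico and single-deletion screens compared across backgrounds.

A synthetic-data module simulates annotations, fitness ground truth and
post-selection insertion libraries (multinomial reads over Dirichlet-uniform
clone abundances, site reads scaled by `fitness^generations`), and builds
toy metabolic models whose isozyme pairs and parallel pathways are known
synthetic-negative interactions — so every stage of the pipeline is testable
against ground truth.

## Worked example

```r
library(tnseqfit)

# simulate a study-scale library (3,500 genes, 2 replicates, 9 generations)
cfg   <- sim_config(seed = 1L)
ann   <- simulate_annotation(cfg)
truth <- simulate_truth(ann, cfg, conditions = "WT_rich")
tabs  <- simulate_library(ann, truth, cfg)

prof  <- gei_profiles(tabs, ann)          # normalized GEI per gene
calls <- classify_fitness(prof, seed = 1L)
round(100 * cumsum(table(calls$group)) / nrow(calls), 1)
#>     I    II   III    IV     V
#>  12.1  17.0  32.0  98.2 100.0
```

The cumulative percentages are the GEI-percentile breakpoints of the five
fitness groups: essential genes occupy the bottom 12.1% of GEI scores and
strong-defect genes extend to 17.0%. Against the simulation's ground truth,
99.8% of genes of at least 500 nt are assigned to their true class.

```r
tm      <- build_toy_model(toy_model_spec())
singles <- single_gene_deletion(tm$model)
subset(singles, status != "no_effect")
#>    gene_id grRatio status
#> 1     gC01     0.0 lethal
#> ...
#> 9    gPC01     0.4 defect
#> 10   gPP01     0.6 defect

doubles <- double_gene_deletion(tm$model, singles = singles)
subset(doubles, synthetic_negative)[, 1:5]
#>    gene_a gene_b grRatio_observed grRatio_expected synthetic_negative
#> 40  gIC01  gIP01                0             1.00               TRUE
#> 47  gIC02  gIP02                0             1.00               TRUE
#> 61  gPC01  gPP01                0             0.24               TRUE
```

Deleting the 4-capacity parallel branch leaves 6 of the 10 flux units
(grRatio 0.6); the flagged pairs are exactly the engineered isozyme and
parallel-pathway interactions.

`run_pipeline(default_pipeline_config())` chains all stages (simulate, GEI,
classify, differential, enrichment, model screens) and writes per-stage
TSV/GFF3/SBML/JSON outputs plus a summary and a checksummed run manifest.

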