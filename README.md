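# symbiopop

Strain-level population genomics of host-associated and free-living
bacterial symbionts from shotgun metagenomes.

Deep-sea vent snails such as *Alviniconcha hessleri* acquire their
sulfur-oxidizing gammaproteobacterial symbionts horizontally from the
environment. Each gill or vent-fluid metagenome is then a *strain mixture*
of one symbiont species, and the question "is symbiont population structure
driven by geography (vent field) or by lifestyle (host-associated vs
free-living)?" becomes a pooled population-genomics problem. `symbiopop`
implements that analysis end to end, for scientists working on microbial
population structure in host-associated systems:

- **Synthetic data with ground truth** — a Balding–Nichols island-model
  generator: deme allele frequencies drawn
  `Beta(p(1-F)/F, (1-p)(1-F)/F)` so the expected Hudson fixation index
  between demes equals `F`; strain haplotypes, deme-private accessory
  genes, strain-mixed 150-bp reads with substitution errors and host-read
  contamination, all recorded in a truth set.
- **Mapping and counts** — an ungapped seed-and-extend k-mer mapper (Rcpp)
  against a pangenome of gene clusters, SAM import/export (Rsamtools),
  per-site nucleotide-count matrices, coverage QC (10× retention
  threshold), and biallelic variant filtering (complete-case depth, pooled
  allele counts, minor-allele frequency).
- **Population structure** — Hudson F<sub>ST</sub> with finite-sample
  correction combined across sites as a ratio of averages,

  `F_ST = Σ[(p1-p2)² - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)] / Σ[p1(1-p2) + p2(1-p1)]`,

  per sample pair or pooled by vent field / lifestyle; Bray–Curtis
  dissimilarities on per-site nucleotide proportions; classical-MDS PCoA;
  weak/moderate/strong differentiation bands (0.2 and 0.5 cut points).
- **Gene content** — coverage-normalized presence/absence calls with an
  explicit "uncertain" band, Jaccard distances, and strict group-unique
  gene extraction.
- **Marker-ratio validation** — canonical k-mer classification of reads
  against symbiont-16S and host-CO1 databases with mandatory background
  decoys; the per-sample 16S:CO1 read-percentage ratio flags free-living
  symbiont populations (fluid samples run orders of magnitude above gill
  samples).

## Worked example

Simulate the geography-versus-lifestyle design (two vent fields at
island-model F = 0.4; each field sampled as two gill metagenomes and one
fluid metagenome sharing the field's 20-strain pool), then map, call
variants, and estimate pooled fixation indices:

```r
library(symbiopop)

cfg <- geography_lifestyle_config(seed = 1, fst_target = 0.4)
sim <- simulate_metagenomes(cfg)
aln <- lapply(names(sim$reads), function(s)
  map_reads(sim$reads[[s]], sim$pangenome, sample_id = s))
names(aln) <- names(sim$reads)
pc  <- pileup_counts(aln, sim$pangenome)
v   <- call_variants(pc$counts, sample_qc(pc$coverage)$retained)
md  <- sample_metadata(sim)

v
#> variant_table: 1348 biallelic sites x 6 samples

round(pairwise_fst(v, md, "vent_field")$fst, 3)
#>        field1 field2
#> field1  0.000  0.445
#> field2  0.445  0.000

round(pairwise_fst(v, md, "lifestyle")$fst, 3)
#>                 free_living host_associated
#> free_living           0.000           0.013
#> host_associated       0.013           0.000
classify_differentiation(0.445)
#> [1] "moderate"
```

Geography (0.445, moderate differentiation, recovering the simulated
F = 0.4 up to the finite-strain founder effect) dominates lifestyle
(0.013, weak): the two lifestyles draw from the same strain pools, the two
fields do not. The numbered scripts under `analysis/` run this study as a
narrative sequence — `01_simulate.R` through `05_marker_ratio.R` — writing
their tables under `results/study/`. The methods vignette
(`vignettes/symbiont-population-genomics.Rmd`) documents the model, the
filters, and every numerical convention.

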