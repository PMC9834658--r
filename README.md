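# flocknet

Within-breed SNP diversity, identity-by-state networks and mixed-model
association for livestock genotyping panels.

`flocknet` is aimed at animal-breeding researchers working with medium-density
SNP-array data (e.g. ovine 50K panels) who want, from a single PLINK-text
input, the standard within-breed workup:

* **QC** — mapped/polymorphic marker filters (MAF > 0.05, call rate > 0.95),
  sample call-rate filtering, IBS-based duplicate detection.
* **Diversity** — observed/expected heterozygosity per breed, breed inbreeding
  coefficient F<sub>IS</sub> = 1 − H<sub>o</sub>/H<sub>e</sub>, individual
  inbreeding from observed vs expected homozygous-marker counts
  (E[hom] = Σ<sub>j</sub> (1 − 2p<sub>j</sub>q<sub>j</sub>T<sub>j</sub>/(T<sub>j</sub> − 1))).
* **Differentiation** — pairwise Weir–Cockerham θ (ratio of sums over loci)
  and principal components of the standardized relationship matrix.
* **Relatedness networks** — pairwise identity-by-state
  (IBS = [2·shared-both + 1·shared-one] / [2·markers]), the largest edge
  threshold that keeps the graph connected (maximum-spanning-tree bottleneck),
  normalized betweenness centrality, network diameter, and hub-removal
  re-analysis of the largest remaining component. Heavy use of one sire shows
  up as a "spoked wheel" whose hub is the top-betweenness animal.
* **Phenotype + GWAS** — lamb daily weight gain standardized to a 60-day
  reference (60·BM/d, gain = BM/d), then a multi-locus mixed model
  y = Xβ + Zu + e with an IBS kinship for u, EMMA-style REML variance
  components, forward cofactor selection with Benjamini–Hochberg FDR, and
  allele-substitution effects per minor-allele copy.
* **Simulation** — Balding–Nichols multi-breed genotypes, Mendelian hub-sire
  pedigrees and QTL-plus-polygenic phenotypes, so every stage is testable
  without external data.

Everything user-facing takes/returns tibbles, fitted objects have
`tidy()`/`glance()` methods, and each result type has an `autoplot()`.

## Worked example

Simulate a Merino-like flock — 120 lambs, one sire covering 60% of matings
and nine of his sons covering the rest, one planted growth QTL at 20% of the
phenotypic variance — then run the whole pipeline:

```r
library(flocknet)

cfg <- sim_config(seed = 2024, n_markers = 1500, n_offspring = 120,
                  n_sires = 10, dominant_sire_frac = 0.6, n_dams = 120,
                  qtl_var = 0.2)
paths <- simulate_study(cfg, "demo", design = "hub")

rc <- run_config(ped = paths$ped, map = paths$map, samples = paths$samples,
                 phenotypes = paths$phenotypes, out_dir = "demo_out",
                 max_cofactors = 5, seed = 2024)
res <- run_pipeline(rc)

res$network_summary
#> <network_summary> 130 nodes, 129 edges, average degree 1.985, diameter 4
#>   top betweenness:
#>     sire01: 0.981
#>     sire02: 0.091
#>     sire03: 0.091
#>     sire04: 0.091
#>     sire05: 0.076

res$gwas
#> <mlmm_fit> 130 samples, 1379 markers tested, 1 cofactor(s)
#>   variance components: vg = 3683, ve = 82.02 (h2 = 0.978)
#>   cofactors: snp00001
```

Reading: the auto-selected IBS threshold (0.787 here) retains essentially the
pedigree tree, so the similarity network is a spoked wheel whose hub is the
heavily used `sire01` (betweenness 0.981 — removing it fragments the network,
`res$hub_removal`). The association scan promotes the planted QTL `snp00001`
to a cofactor; its allele-substitution effect (44.2 ± 7.3 g/day per
minor-allele copy, `tidy(res$gwas)`) brackets the simulated effect of
40 g/day. All tables are also written as TSV under `demo_out/`, with a JSON
manifest recording parameters, seed and per-stage row counts.

`autoplot(res$network)` draws the wheel, `autoplot(res$pca)` the score plot,
and `autoplot(res$gwas)` a Manhattan plot.

## Vignette

`vignettes/flocknet-methods.Rmd` documents the statistical methods, the
simulation design (and what it does *not* emulate), numerical choices and
known limitations.
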