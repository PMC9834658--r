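---
title: "flocknet: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{flocknet: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flocknet)
```

`flocknet` packages the within-breed genetic workup of a SNP-array study of a
livestock population — quality control, diversity and differentiation
statistics, an identity-by-state (IBS) relatedness network with hub
detection, phenotype standardization and a multi-locus mixed-model
association scan — together with a synthetic-data generator that emulates the
population structure such studies encounter. This vignette explains each
method, the parameters that matter, the numerical conventions, and what the
simulations do and do not establish.

## Genotype model and input conventions

Genotypes are diploid biallelic dosages in `{0, 1, 2, NA}` counting copies of
the **minor** allele. PLINK-text PED/MAP input is supported with both ACGT
and 1/2 allele coding; `"0"` is the only missing token, and a genotype with
either allele missing is treated as a missing call. Allele orientation is
always recomputed from observed frequencies (major = `allele_a`), with
lexicographic tie-breaking at frequency 0.5, so that write/read round-trips
are exact; file order is never trusted. Coordinates are 1-based, chromosomes
are stored as labels, and chromosome `"0"` means unplaced.

A deliberate consequence: a matrix is only written/read reproducibly if its
dosages are minor-allele oriented. `orient_minor()` converts any matrix to
that convention; the simulators apply it before emitting files.

## Quality control

Filters run in a fixed order — unplaced markers, marker call rate, minor
allele frequency (computed after the call-rate removal), sample call rate,
then duplicate detection — so removal counts are reproducible. All
inequalities are **strict** (`MAF > 0.05`, `call rate > 0.95`, duplicate
`IBS > 0.95`): boundary markers are removed and boundary pairs are not
flagged, matching the usual phrasing "higher than". Duplicates are reported,
not removed, unless removal is requested (the higher-call-rate member is then
kept). Filtering is idempotent and order-preserving, and the QC report
reconciles exactly with the matrix dimensions; these properties are asserted
in the test suite.

## Diversity statistics

Observed heterozygosity H~o~ for a breed is the mean over markers of the
heterozygote fraction among that breed's non-missing calls. Expected
heterozygosity H~e~ is the mean of 2pq; by default the allele frequencies are
**pooled-panel** frequencies, so a multi-breed table carries one shared H~e~
column — the convention under which a single H~e~ is printed for every breed
in published multi-breed diversity tables. Breed-wise frequencies are
available via `he_frequencies = "breed"`. The breed inbreeding coefficient is
F~IS~ = 1 − H~o~/H~e~ (undefined when H~e~ = 0).

Because published tables print H~o~ and H~e~ rounded to three decimals while
their F~IS~ column is computed from unrounded values, recomputing
1 − H~o~/H~e~ from printed numbers can deviate from the printed coefficient
by up to (0.0005 + 0.0005·H~o~/H~e~)/H~e~ ≈ 0.0025; the tests assert exactly
this propagated-rounding bound, and observe that a substantial subset of rows
(13 of 31 in the bundled published table) reproduces exactly at printed
precision.

Individual inbreeding uses homozygous-marker counts:
F = (observed − expected)/(L − expected) with
expected = Σ~j~ (1 − 2p~j~q~j~T~j~/(T~j~ − 1)), where T~j~ is twice the
number of non-missing genotypes at marker j and frequencies come from the
full sample set. The T/(T−1) small-sample correction appears **only** here,
where the formula demands it; breed-level H~e~ uses plain 2pq. Markers with
T ≤ 2 are excluded, and each sample's sums run over the markers at which it
is genotyped.

## Weir–Cockerham F~ST~

Pairwise differentiation between breeds uses the Weir–Cockerham (1984)
variance-component estimator for two populations at biallelic loci, combined
as a **ratio of sums** θ = Σa / Σ(a+b+c) — not a mean of per-locus ratios,
which is biased at low-information loci. Negative per-locus components are
retained, so undifferentiated pairs can give slightly negative θ. Loci
monomorphic across the pair, or where either breed has fewer than two
genotyped samples, carry no information and are excluded. The implementation
is vectorized; the tests compare it to an independently written per-locus
textbook version (agreement to 1e−12) and to closed forms (θ = 1 at a fixed
difference).

## PCA of the standardized relationship matrix

Genotype columns are standardized as (x − 2p)/√(p(1−p)) with observed allele
frequencies; missing dosages are imputed to the column mean (zero after
centering) — a neutral choice that adds no structure. The relationship matrix
is (1/L)·SSᵀ and its top-k eigenpairs are reported; scores are eigenvectors
scaled by √eigenvalue so the plotted geometry reflects variance. Monomorphic
columns are an error by design: the PCA expects post-QC input.

## IBS and the similarity network

IBS between two animals is (markers sharing two alleles + 0.5 × markers
sharing one)/markers, over jointly called markers only; with dosages a, b the
shared-allele count is 2 − |a − b|. A pair with no jointly called marker is
missing, which the kinship and network layers refuse rather than guess.

The network threshold can be chosen automatically as the **largest t such
that the graph {IBS ≥ t} is connected**, computed exactly as the minimum
edge of a maximum spanning tree of the complete IBS graph. The default edge
rule is `>=`: a strictly-greater rule cannot guarantee connectivity at the
bottleneck value, while `>=` does; both rules are exposed.

Summaries use **unweighted** shortest paths: betweenness excludes endpoints
and is normalized by (n−1)(n−2)/2 (so values live in [0, 1]), computed on the
full graph; the diameter is reported for the largest connected component,
the only consistent convention once hub removal fragments the graph. Average
degree is defined as 2E/N. Hub removal deletes the k top-betweenness nodes
(ties broken by sample id, as everywhere in the package) and re-summarizes
the largest remaining component. GraphML export attaches betweenness to nodes
and, to edges, the IBS weight plus a `highlight` flag for weights at or above
the nearest-rank 85th percentile of retained edge weights (the percentile of
a constant sample is that constant, and the rule is ≥).

## Phenotype standardization

Daily weight gain comes from one body-mass measurement (grams) at an age of
30–80 days: the 60-day standardized weight is 60·BM/d and the gain is BM/d
(g/day). Only the unit-consistent gain is used as the association response;
both columns are carried so either convention can be exported. Ages outside
[30, 80] and non-positive masses are rejected with a per-row reason. No
birth-weight subtraction is applied.

## Mixed-model association scan

The model is y = Xβ + Zu + e with one record per animal (Z = I),
u ~ N(0, v~g~K) and e ~ N(0, v~e~I). The kinship K is the IBS matrix floored
to positive semi-definiteness (negative eigenvalues, numerically tiny for IBS,
set to zero); a GRM alternative can be supplied by the caller since K is just
a matrix argument. Variance components are estimated by EMMA-style REML: one
spectral decomposition, a 100-point log-spaced grid over δ = v~e~/v~g~ on
[1e−5, 1e5], and local refinement around the grid optimum. With K = I the
restricted likelihood is flat in δ and collapses to the OLS restricted
likelihood — an identity the tests verify to 1e−6, alongside equality of the
scan's p-values with OLS t-tests to 1e−8 and of the rotated GLS effect with a
direct full-covariance solve.

Scanning holds the variance components fixed within a scan and re-estimates
them whenever the fixed effects change (the
population-parameters-previously-determined approximation): each marker is
tested by a Wald t-test on its dosage coefficient in the rotated model, with
the residual scale estimated per marker. Markers monomorphic in the sample or
collinear with covariates return `NA`. The allele-substitution effect is per
copy of the minor allele.

The multi-locus scheme is forward selection — the most significant marker
(ties by name) enters the fixed effects while its Benjamini–Hochberg q-value
is below 0.05, up to `max_cofactors` — followed by backward pruning of
cofactors with joint Wald p ≥ 0.05. Reported statistics keep, for each
surviving cofactor, the scan at which it entered; everything else comes from
a final scan under the final cofactor set, and the FDR column is recomputed
across the reported table. FDR is Benjamini–Hochberg with m = number of
tested markers; published tools vary in their FDR conventions, so the
procedure is fixed and named here rather than matched to any one program. The
q ≥ 0.05 stopping rule stands in for model-selection criteria (extended BIC,
multiple-Bonferroni) that the package deliberately does not implement.

Birth covariates enter as categorical factors; birth dates are reduced to
birth **year** because cohort effects at finer resolution are unidentifiable
with typical sample sizes (a ten-cohort design motivates the default
generator setting).

## The synthetic-data generator

The generator exists so that every pipeline stage runs on data whose truth is
known. Its defaults describe the study conditions the package targets:

* **Breeds** — ancestral frequencies Uniform(0.05, 0.95); breed frequencies
  Beta(p(1−F)/F, (1−p)(1−F)/F) (Balding–Nichols), genotypes Binomial(2, p)
  under Hardy–Weinberg. F is the Weir–Cockerham estimand, so
  `pairwise_fst()` recovers the configured divergence (±0.015 at 2×50
  samples, 5000 markers in the acceptance checks); the divergence range seen
  across Merino-derived breeds (θ ≈ 0.004–0.31) is reachable by setting F.
* **Hub pedigree** — one dominant sire fathers 60% of 100 offspring by
  default; the minor sires are his sons (line breeding), each offspring has
  its own dam, and dams are ungenotyped. This layout is what makes the
  similarity network a spoked wheel: parent–offspring IBS (~0.82 under
  uniform founder frequencies) stays above the connectivity bottleneck while
  half-sib IBS (~0.76) falls below it, so the retained graph is close to the
  pedigree tree rooted at the dominant sire. An earlier design with unrelated
  sires and a shared dam pool was rejected because the dominant family formed
  a half-sib clique at the threshold and betweenness concentrated on bridging
  lambs instead of the sire. `related_sires = FALSE` restores unrelated sires
  for the balanced-usage negative control, in which no animal should exceed
  betweenness 0.5.
* **Phenotypes** — y = Σβ~q~·dosage + birth-year + birth-place + u + e with
  u ~ MVN(0, v~g~K); each component is empirically standardized before
  weighting so realized variance fractions track the configured ones, then
  the gain is linearly rescaled into 261.6–494.7 g/day (the range such
  studies report). Ages are Uniform{30..80} and body mass is back-solved as
  gain × age, so the emitted table exercises the real standardization code
  path and reproduces the simulated response exactly.

**What the simulations do not emulate:** linkage disequilibrium (markers are
independent given frequencies), selection, genotyping error beyond uniform
missingness, multi-generation pedigrees deeper than sire–son, assortative
mating, and family structure in the covariates. Passing recovery tests
therefore shows the estimators are correct under their assumed models, not
that real data meet those assumptions — in particular, LD will spread real
association signals across neighbouring markers, which the one-QTL-per-locus
simulations cannot show.

## Numerical choices and degenerate inputs

* Strict threshold inequalities throughout QC; ties in betweenness, cofactor
  entry and duplicate ordering broken lexicographically by id for
  determinism.
* REML δ grid [1e−5, 1e5] with 100 log-spaced points; the kinship eigenvalue
  floor is 0; the scan declares a marker collinear when its residual sum of
  squares after projection falls below 1e−10 of its rotated norm.
* Single-node components have undefined (NA) diameter; an empty post-QC panel
  warns rather than silently returning; constant responses and missing IBS
  pairs are errors.
* Problem sizes used by the test suite and acceptance script — 200 random
  graphs of ≤ 8 nodes against an exhaustive path-enumeration oracle, 50
  random two-population toys against the textbook F~ST~ oracle, 100
  hub-recovery and 50 QTL-recovery replicates, 2000-marker null scans — were
  chosen so the full suite runs in minutes on one core while keeping Monte
  Carlo error well inside the asserted margins.

## Known limitations

* Two populations per F~ST~ estimate (pairwise design); no global multi-population
  θ, jackknife intervals, or Hudson/Nei estimators.
* The scan's per-marker tests use the PPD approximation; an exact per-marker
  REML would be slower and differs negligibly at these scales, but is not
  currently exposed.
* Betweenness and diameter are unweighted; IBS weights affect only edge
  retention and display.
* PED/MAP and delimited text only — no binary PLINK, VCF or intensity
  formats.
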