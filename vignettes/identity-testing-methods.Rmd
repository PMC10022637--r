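---
title: "Deciding whether two GWAS peaks are the same QTL: models and methods"
author: "crossGWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding whether two GWAS peaks are the same QTL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossGWAS)
```

## The problem

Genebanks accumulate decades of phenotype records — "legacy data" —
measured across many locations and years on largely overlapping sets of
crop varieties. A GWAS run on such legacy phenotypes (call it the
L-GWAS) is cheap, but its peaks need corroboration: a second,
independently phenotyped and genotyped panel (the M-GWAS, on newly
measured data) may show a peak in the same genomic region, and the
question is whether the two peaks point at the *same* QTL or merely at
two linked ones. crossGWAS implements the full workflow for that
question on rice-like inbred panels: mixed-model association scans,
multiplicity-corrected thresholds, peak calling, a two-part *identity
test*, multi-environment phenotype adjustment, standardized effect
sizes for cross-trait comparison, and haplotype-group pleiotropy
analysis. A founder-mosaic simulator generates panels with the
statistical structure these analyses assume, so every stage is testable
without external data.

## The association model

For a quantitative trait the engine fits the standard linear mixed
model

$$y = X\alpha + g + e, \qquad
  g \sim N(0, \sigma^2_g K), \quad e \sim N(0, \sigma^2_e I),$$

where $K$ is the realized genomic relationship matrix (VanRaden form:
$K = WW^\top / 2\sum_k p_k(1-p_k)$ with $W$ the column-centered dosage
matrix), and no principal components are included as fixed effects —
the kinship term alone carries the structure correction. Variance
components are estimated by REML through a single spectral
decomposition of $K$ with one-dimensional optimization over
$\delta = \sigma^2_e/\sigma^2_g$ (the EMMA formulation; grid search on
$\log\delta \in [-10, 10]$ followed by local refinement, tolerance
1e-6). Per-marker tests use generalized least squares under
$\hat V = \hat\sigma^2_g K + \hat\sigma^2_e I$; by default the variance
components are estimated once under the null and reused for every
marker (the P3D/EMMAX approximation, `p3d = TRUE`), with exact
per-marker REML available behind the flag. Wald statistics are referred
to the F distribution with $n - \mathrm{rank}$ denominator degrees of
freedom rather than the normal approximation; the test suite verifies
the whole path against an independent explicit-inverse GLS oracle to a
relative error of 1e-6.

Binary (0/1) traits are scanned with a score test under the same linear
mixed model — $U = x_j^\top \hat V^{-1}(y - \hat y_{null})$, with
$U^2/\operatorname{Var}(U)$ referred to $\chi^2_1$ — not with a
logistic mixed model. This matches the contract of the common
binary-trait GWAS engines for inbred diversity panels and keeps the
quantitative and binary paths numerically comparable.

Numerical edge cases are handled explicitly: markers collinear with the
covariate set (including monomorphic markers) are excluded with reason
`"collinear"`; when the covariates explain the phenotype exactly
(a noiseless trait conditioned on its own causal marker) every
remaining marker reports $p = 1$ rather than a 0/0 artifact; p-values
are floored at 1e-300 so $-\log_{10} P$ stays finite.

## Significance thresholds

Markers in LD do not constitute independent tests. The effective number
of markers $M_{\mathrm{eff}}$ is computed SimpleM-style: per
chromosome, consecutive windows of at most 200 markers are
eigendecomposed on their dosage correlation matrix, and the window's
count is the smallest number of eigenvalues explaining 99.5% of the
total variance (the fraction the original SimpleM work recommends; both
parameters are configurable and echoed in outputs). Genome-wide
cutoffs are then $-\log_{10}(\alpha / M_{\mathrm{eff}})$ at
$\alpha = 0.1$ (stringent, used for peak calling) and $\alpha = 0.2$
(lenient, used for judging peak disappearance).

Peak regions are called deterministically: markers at or above the
cutoff are clustered per chromosome, joining consecutive significant
markers at most `merge_gap = 300` kb apart, and the significant span is
padded on both sides (`pad`, default 100 kb; the half-open [start, end)
convention is used throughout). The padding stands in for the
megabase-scale windows a human would draw around a Manhattan-plot peak.

## The identity test

Two methods are combined into a verdict for a peak region found in
panel A when panel B shows signal in the same region:

**Method 1 (conditional disappearance).** The panel-A scan is rerun
with the dosage of panel B's top marker (mapped through the shared
marker set, reorienting dosage at ref/alt-swapped sites) as a fixed
covariate. If both studies tag the same QTL, the covariate removes the
peak's explainability. The conditioning marker and any perfect proxy
($|r| \ge 1 - 10^{-10}$) are excluded from testing. Because
"disappeared" is a judgment call in the original visual workflow, it is
operationalized here against the lenient threshold: *disappeared* if
the region's conditional maximum falls below the $0.2/M_{\mathrm{eff}}$
cutoff, *attenuated* if it stays above but drops by at least 50% of the
unconditional maximum, *persisted* otherwise. Both parameters are
config-exposed and echoed in reports. When panel B's exact top marker
is not shared, the shared marker with the highest $|r|$ to it in panel
B substitutes (required $|r| \ge 0.8$, logged).

**Method 2 (local signal-shape correlation).** Over the shared markers
inside the region tested in both scans, the squared Pearson correlation
$R^2$ of the paired $-\log_{10} P$ values. At least 3 shared markers
are required; the decision default `r2_min = 0.4` is the smallest value
the motivating study still treated as a high correlation.

**Verdict.** *identical* = disappeared with $R^2 \ge$ `r2_min`;
*partially_shared* = attenuated with high $R^2$ (one cohort may harbor
an additional linked QTL); *distinct* = persisted with low $R^2$;
anything else is *inconclusive*. The per-direction outcomes (A
conditioned on B's top marker vs B conditioned on A's) are both
available; interpretation of asymmetric cases is left to the user.

A statistical caveat that shaped the defaults: with $k$ shared markers
in a region, the null distribution of Method 2's $R^2$ is
Beta$(1/2, (k-2)/2)$ — for $k = 3$ its median is 0.5. The region
therefore needs a dozen or more shared markers before a low $R^2$ is
informative, which is why the identity-test analyses in this package
call regions with `pad = 500` kb on marker maps of roughly 50 kb
spacing (the motivating study's example region contained 60 shared
polymorphisms).

## Phenotype preparation

Legacy records arrive as one value per (variety, location, year).
`adjustEnv()` fits, by REML through `lme4`,

$$\mathrm{value} = \mu + \mathrm{variety} + u_{(\mathrm{loc,year})}
  + \varepsilon, \qquad u \sim N(0, \sigma^2_u),$$

with variety as a *fixed* effect and the location-by-year combination
random, returning per-variety BLUEs. Fixed-variety BLUEs avoid the
shrinkage that random-variety BLUPs would apply, which would attenuate
downstream GWAS effect estimates; BLUPs remain available via
`variety_as = "random"`. With a single environment the model reduces to
raw values (per-variety means when replicated).

Other preparation steps: heading dates are converted to days after
July 1 (months May–December of one season; `headingDays(8, 10)` is 40);
traits whose modal level holds at least 80% of observations, or which
take exactly two levels, are designated binary (the 0.8 cutoff
operationalizes "extremely unidirectional" histograms and is
configurable); ordinal color scales are split by threshold (score 1 vs
2–9 for colored/non-colored, 2–4 vs 5–9 for light/dark);
`standardize()` z-scores a phenotype so SNP effects are comparable
across traits. The wording "mean = 0, SE = 1" in the motivating
description is interpreted as unit standard deviation — ordinary
z-scoring — since a unit standard *error* would rescale by
$\sqrt{n}$ and break cross-trait comparability; scan p-values are
invariant under either choice.

## Pleiotropy analysis

`standardizedEffects()` refits the mixed-model GLS per (marker, trait)
on standardized phenotypes and tabulates $|\hat\beta|$ — the same
machinery as the scan, so each entry is reproducible from
`scanQuantitative()` on the standardized trait. `assignHaplotypes()`
matches varieties to user-supplied gene haplotype definitions
(defining marker dosages plus a functional/null classification);
heterozygous calls at defining markers are left unassigned, as expected
for inbred panels. `pleiotropyPanel()` cross-classifies varieties by
gene functionality (labels like `OsC1/osdfr` follow the
upper/lower-case convention for functional/null) and runs, per trait,
one-way ANOVA followed — only when the F test is significant — by
all-pairs Tukey–Kramer HSD with a compact letter display computed by
the insertion-absorption algorithm. Ties at exactly $p_{adj} = 0.05$
count as non-significant, and the letter-sharing relation is tested to
coincide exactly with the non-significance relation.

## The synthetic panels

`simulateGenotypes()` uses a founder-mosaic (Li–Stephens-style copying)
model: founder haplotypes drawn with allele frequencies uniform on
$[\texttt{maf\_floor}, 1-\texttt{maf\_floor}]$, each chromosome copy a
mosaic of founders with switch probability `switch_rate = 0.02` per
marker interval. This produces block-wise LD with monotone decay —
sufficient for kinship, SimpleM and peak-calling to behave as on real
data — while staying fully deterministic given a seed. Two independent
haplotype mosaics form a diploid (an `inbred` flag doubles a single
mosaic instead; both modes exercise identical downstream math, so
outbred is the default even though rice selfs). Missing genotypes are
injected uniformly at rate 0.02 to exercise QC and imputation.

Traits are simulated as $g_i = \sum_j \beta_j x_{ij}$ plus Gaussian
noise scaled so $\operatorname{Var}(g)/\operatorname{Var}(y)$ equals
the requested $h^2$ in expectation (the realized ratio is within
±0.02 of target on average at $n = 1000$, verified in the tests).
Binary traits threshold a latent liability at its empirical
$(1-\mathrm{prevalence})$-quantile, so the sample prevalence is exact —
an intentional departure from the Gaussian-inverse-CDF threshold, which
would only hit prevalence in expectation. The two-panel generator
draws both panels from one founder pool with configurable variety and
marker overlap (defaults 0.5 and 0.7; the first is a free parameter
because the real panels' overlap is not documented), force-retains
causal markers in both marker subsets so cross-panel conditioning is
always possible, and supports shared-QTL, distinct-QTL (different
chromosomes) and null scenarios. The epistatic ordinal generator
mirrors a switch/tone two-gene architecture: switch-null varieties
score 1, functional-switch tone-null draw 2–4, functional/functional
draw 5–9.

What the simulator does *not* emulate: realistic rice demography or
selection, recombination hot/cold spots, multi-allelic sites,
genotyping error correlated with MAF, and phenotype distributions with
outliers or skew. Passing tests therefore demonstrate that the
machinery is correct and calibrated under its stated model, not that
any particular real-data analysis will be well-powered.

## Study conditions used by the acceptance analyses

The packaged end-to-end analyses (in `scripts/acceptance.R` and the
acceptance tests) use these problem sizes, chosen once as this
package's canonical synthetic study conditions:

* **Scan calibration**: 20 null replicates at $n = 500$, $m = 2000$
  markers on a weak-LD panel (32 founders, switch rate 0.2) so the
  marker set is close to independent — a genomic-control band check
  over a fixed marker count presumes nearly independent tests; on the
  default blocky-LD panel the median-based $\lambda_{GC}$ has roughly
  double the sampling spread and the band check would mostly measure
  LD, not calibration.
* **Identity test**: 50 replicates per scenario, two panels of
  $n = 300$ varieties, 4 chromosomes × 300 markers over 15 Mb
  (≈50 kb spacing), 70% marker overlap, 50% variety overlap,
  $h^2_{QTL} = 0.3$, peak regions padded ±500 kb.
* **Parameter recovery**: 20 replicates at $n = 500$ for REML $h^2$
  (target 0.5) and 20 single-QTL scenarios with planted standardized
  effects 0.1–0.72.

## Known limitations

* The binary scan is a linear-model score test; for very rare classes a
  logistic mixed model would be preferable (out of scope; a class with
  fewer than 5 members triggers a warning).
* P3D shares one variance-component estimate across markers; a marker
  explaining a large share of variance on a small marker panel can be
  conservatively tested (the exact per-marker REML flag exists for such
  cases).
* Exactly duplicated individuals make the mixed model degenerate
  (duplicate pairs carry zero residual information), so kinship
  matrices with exactly repeated rows should be deduplicated upstream.
* Strand-ambiguous (A/T, C/G) sites are matched by exact alleles only;
  unmatched same-position sites are counted and dropped.

## A worked example

```{r example, eval = FALSE}
cfg <- runConfig(scenario = "shared_qtl", seed = 1,
                 out_dir = tempfile("demo"),
                 sim = list(n_individuals = 300, n_chromosomes = 4,
                            markers_per_chromosome = 300,
                            chromosome_length_bp = 15e6),
                 peaks = list(pad = 5e5))
run <- runPipeline(cfg)
attr(run, "verdict")$verdict   # "identical" for the planted shared QTL
```

The run directory contains, per panel, the scan TSV, Manhattan- and
Q-Q-ready tables, the $M_{\mathrm{eff}}$/threshold JSON, the peak BED,
the identity verdict JSON, and a manifest with the seed and a config
hash, so a run is reproducible byte-for-byte from its config.
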