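---
title: "Methods: junction-based XBP1s quantification and downstream analysis"
author: "xbp1flux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction-based XBP1s quantification and downstream analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

`xbp1flux` implements the computational arm of a study linking
IRE1α–XBP1s pathway inhibition to transcriptome changes in prostate cancer
cells: two perturbations of the same pathway (siRNA knockdown of *XBP1*;
small-molecule inhibition of the IRE1α RNase) are profiled by bulk RNA-seq
and compared, and an XBP1-derived gene signature is evaluated as a prognostic
marker in survival cohorts. The package covers six analysis stages —
spliced-isoform quantification from splice-junction tables, simplified
negative-binomial differential expression, concordance and overlap
statistics, gene-set enrichment of fold-change shifts, signature scoring
with survival stratification, and a drug-synergy criterion — plus a seeded
synthetic-data generator so the whole pipeline runs and is testable without
any external download.

## Spliced-isoform quantification

IRE1α removes a 26-nt intron from *XBP1* mRNA; a read spanning the excised
intron (chr22:28,796,122–28,796,147 on hg38, the package default) uniquely
identifies the spliced isoform XBP1s. Junction tables follow the STAR
`SJ.out.tab` dialect: 1-based inclusive intron bounds, strand codes 0/1/2
for unknown/+/−, and unique- and multi-mapping read counts per junction.
The abundance measure is

$$\mathrm{usage} = \frac{\text{unique spliced reads at the focal junction}}
{\text{total unique spliced reads}} \times 10^6 ,$$

i.e. reads per million total spliced reads. Only unique-mapping reads enter
either numerator or denominator: multi-mappers can attribute one read to
several loci and would break the ratio's scaling invariance. Focal matching
is by exact coordinate key; a strand code of 0 (unknown) in the table
matches any query strand, since STAR leaves the strand undefined for
non-canonical motifs.

Differential usage between groups is tested with a negative-binomial GLM
(log link) on the focal counts with three terms: intercept, treatment
indicator, and a library-depth covariate. Depth enters as
log10(total unique spliced reads) by default, making the covariate act as
an approximate offset; the raw total is available via
`depth_scale = "raw"`. Total *spliced* reads is used as the depth measure
because it is the only depth the junction table itself carries and it is a
monotone proxy for sequencing depth. A constant depth across samples is
collinear with the intercept and is dropped automatically.

## The negative-binomial engine

Both the junction test and differential expression share one fitting
routine, `fit_nb_glm()`. It uses the NB2 parameterization
$\mathrm{Var}(Y) = \mu + \phi\mu^2$ and estimates coefficients by
iteratively reweighted least squares (IRLS, working weights
$\mu/(1+\phi\mu)$), capped at 100 iterations with convergence declared when
the largest coefficient change drops below 1e-8. Linear predictors are
clamped to ±30 to keep exponentials finite on degenerate data.

The dispersion $\phi$ is profiled by maximizing the **Cox–Reid adjusted**
likelihood — the profile NB log-likelihood minus
$\tfrac12 \log\det(X^\top W X)$. Plain profile ML underestimates $\phi$
when few residual degrees of freedom remain, which inflates Wald
statistics; the Cox–Reid term is the standard correction for that bias in
GLM dispersion estimation. Profiling walks a fixed log-spaced grid
(1e-8 to 10) seeded with a method-of-moments estimate and refines the best
neighborhood with one-dimensional optimization; the method-of-moments value
doubles as the fallback when the likelihood is flat. Setting
`cr_adjust = FALSE` recovers plain profile ML, which matches
`MASS::glm.nb` to machine precision on shared fixtures (a unit test
asserts this).

The treatment effect is tested two-sided by Wald with a normal reference,
mirroring default GLM summaries. The normal reference is asymptotic:
with triplicate groups the test is anticonservative even after the
Cox–Reid correction, which is why the calibration checks in the test suite
simulate at 20 samples per group (the package's choice of a size where the
asymptotics have taken hold), while effect-recovery checks run at the
triplicate study scale where bias, not level, is the quantity of interest.

## Differential expression

The DE stage is a deliberately simplified re-implementation of the
NB/Wald core of count-based DE frameworks:

* **Filter** — a gene is tested only if, in *each* group, at least one
  sample exceeds 5 counts (strictly more than five). The alternative
  reading — any single qualifying sample overall — is exposed as
  `per_group = FALSE`.
* **Size factors** — median-of-ratios: genes with all-positive counts form
  the reference by per-gene geometric means; a sample's factor is the
  median ratio to that reference, rescaled to unit geometric mean. A unit
  test checks agreement with `DESeq2::estimateSizeFactors` up to that
  rescaling.
* **Per-gene NB Wald test** with the size factor as a log offset and a
  per-gene Cox–Reid ML dispersion. No dispersion shrinkage, no outlier
  replacement, no independent filtering: the aim is distributional
  correctness (calibrated p-values, unbiased log2FC), not numerical
  equality with any particular DE package, and the acceptance checks are
  phrased accordingly.
* **BH adjustment** over the genes that converged; non-converging genes
  carry `NA` p-values and shrink the BH family.
* log2 fold change is the group coefficient divided by ln 2; no
  pseudo-counts are involved anywhere.

One numerical subtlety: rescaling a single sample's counts together with
its size factor is *not* an exact invariance of the NB fit (the weights
$\mu/(1+\phi\mu)$ are not scale-free), only of its Poisson limit. The test
suite asserts the exact group-ratio closed form under unit factors and
bounds the rescaling perturbation instead of asserting exact invariance.

`top_n()` ranks by ascending p within a fold-change sign, breaking ties by
larger |log2FC| and then gene id, so top-lists are deterministic.

## Concordance, overlap and enrichment

Paired log2 fold changes from the two contrasts are summarized by sign
quadrants (genes with a zero fold change in either contrast are excluded)
with a Pearson correlation inside the down/down quadrant.

The overlap of two top-*n* lists is tested exactly: under the null the
overlap is Binomial(*n*, *p*) with *p* = *n*/universe, and the upper tail
P(X ≥ k) is summed in log space so values far below 1e-16 remain exact.
The universe — the number of genes included in differential expression —
is a required explicit argument, never defaulted: the package's convention
for a two-contrast analysis is the intersection of genes passing the filter
in both contrasts (`"filtered_intersection"` in the pipeline config).

Two per-set enrichment procedures coexist because they answer the question
differently, and the field uses both:

* `ks_set_enrichment()` compares the log2 fold-change distribution of a
  set's tested members against all other tested genes with a two-sided
  two-sample Kolmogorov–Smirnov test (asymptotic p). Sidedness is not
  assumed; the direction (sign of the in-set minus out-of-set median) is
  reported separately so activated/repressed calls remain possible.
* `fisher_set_enrichment()` tests over-representation of a *selected* gene
  list (default rule: BH-adjusted p < 0.05 with a fold-change sign filter,
  both configurable) with a one-sided Fisher's exact test.

Sets with fewer than `min_set_size` tested members (default 15, the scale
below which hallmark-style sets become uninformative) are skipped with a
warning.

## Signatures and survival

Cross-cohort comparability is handled by quantile normalization: every
column is forced to the reference distribution formed by the across-column
mean of sorted values at each rank; ties within a column receive the mean
of the reference values their ranks span. The operation is idempotent and
a unit test checks agreement with `limma::normalizeQuantiles`.

A signature score is the per-sample mean of per-gene z-scores (each gene
centered and scaled across the cohort's samples). The mean z-score was
chosen as the simplest score that is comparable across cohorts after
quantile normalization and invariant to gene order and per-gene location
shifts; a rank-based variant sits behind `method = "rank"`. Scoring is
per-cohort: cohorts are normalized and scored independently rather than
pooled, avoiding residual cohort effects dominating a joint z-scale.
Zero-variance and absent signature genes are dropped with warnings; an
all-absent signature is an error.

Prognostic stratification splits a cohort at the *median* signature score
(ties to the low group — the same convention as the AR-activity
stratification helper), estimates Kaplan–Meier curves per half, and
compares them with the standard 1-df log-rank test. At tied times, events
are processed before censorings. KM and log-rank computations go through
the `survival` package; the test suite verifies them against hand-computed
product-limit tables and a brute-force hypergeometric log-rank oracle, plus
a label-permutation calibration. The five-gene signature
(*ANLN*, *CSNK1G3*, *RRM2*, *SLC35A2*, *UBAC2*) ships as the default
`xbp1_five_gene_signature()`; it is an input taken as given, not an output
of this package (the feature-selection algorithm that produced it is out of
scope).

## Synergy criterion

A combination is synergistic when its fractional response strictly exceeds
the null threshold. The default (`mode = "literal"`) implements the literal
rule Fc > Fa·(1 − Fb). Classic Bliss independence would be
Fa + Fb − Fa·Fb; both are exposed and neither is silently corrected,
because the two thresholds differ qualitatively (the literal rule is
*non-increasing* in Fb). Which convention is appropriate depends on whether
"fractional response" is read as fraction inhibited or fraction surviving —
for fraction *surviving*, Fa·Fb-style products are the natural null — so
callers must fix that interpretation for their data; the margin
(Fc − threshold) is reported either way for ranking.

## Synthetic data: what it emulates, what it does not

All generators hang off one `sim_config()` whose root seed expands to
per-component child seeds by a fixed derivation (seed + 77003·k mod 2³¹−1),
so each component regenerates independently and byte-identically.

Defaults mirror a desk-scale shadow of the study design: 10,000 genes,
3 vs 3 samples per contrast, NB dispersion 0.05, log-normal baseline means
(meanlog 3, sdlog 1.5 — median ~20 counts with a heavy right tail),
~5×10⁶ total unique spliced reads per sample, a focal junction at 100 reads
per million depleted 10-fold under treatment, 10% truly-DE genes of which
30% are down-regulated in both contrasts with a shared negative log2FC,
named gene sets receiving additional mean log2FC shifts, a 300-patient
cohort with exponential event times (log hazard ratio ln 3 per unit latent
score, ~30% independent exponential censoring), and 30 combination rows.
These are the conditions under which the recovery and power checks run.

The generator reproduces the *distributional* structure the statistics
consume — NB mean–variance, depth variation, set-structured shifts,
proportional hazards — but not several features of real data: no
gene–gene correlation beyond set-shift structure, no batch or lane
effects, no GC/length biases, no cohort-specific censoring patterns, no
multi-mapping reads (simulated junction tables have zero multi-mapper
counts). Passing tests therefore demonstrate correctness of the
implementations under their own model assumptions, not robustness to every
artifact of real RNA-seq. Censoring calibration is approximate (the
censoring hazard is solved from the baseline hazard, ignoring the score's
effect on event rates), which the tests bound rather than pin.

## Numerical choices and degenerate inputs

* IRLS: max 100 iterations, convergence 1e-8 on coefficients, linear
  predictor clamped to ±30; non-convergence is an error for the junction
  test and a flagged, BH-excluded gene in DE.
* Dispersion grid 1e-8…10 (log-spaced) + Brent refinement; boundary fits
  report the near-zero boundary value (Poisson-like data).
* All-zero responses, rank-deficient designs, and groups with fewer than
  two samples are errors, not warnings.
* P-values are clamped into (0, 1] and never reported as exactly zero
  except through floating-point underflow of the KS tail, which is clamped
  to the smallest positive double.
* Binomial tails are summed in log space (max-shifted), exact to double
  precision at k = 26 and far beyond.
* Zero fold changes are excluded from quadrant counts; fewer than three
  down/down genes yields a missing Pearson r rather than a spurious one.
* Readers reject rather than coerce: wrong column counts name the
  offending line, non-integer counts and design gaps are errors, and
  junction round-trips are byte-identical.

## Problem sizes in the test suite

Unit tests run on fixtures of tens to hundreds of genes. The
statistically heavy checks use: 200 replicates for junction and DE effect
recovery; 100 replicates for survival power at n = 300; 1,000 simulations
per null-calibration check (junction and DE at 20 samples per group, where
the normal-reference Wald test is within its nominal band); 2,000
permutations for the KS oracle and 5,000 for the log-rank oracle; and an
exhaustive Fisher-vs-hypergeometric enumeration over every 2×2 table on a
12-gene universe. These sizes are the package's own trade-off between
Monte-Carlo error and runtime; the full suite completes in under two
minutes on a laptop-class core.

## Known limitations

* The Wald/normal reference is anticonservative for triplicate designs;
  interpret triplicate p-values qualitatively (the study-scale conclusions
  rest on effects orders of magnitude beyond the inflation).
* No dispersion shrinkage or outlier handling: per-gene dispersions are
  noisy at small n, so single-gene DE results are less stable than those
  of shrinkage-based frameworks.
* The KS enrichment p is asymptotic and slightly conservative at small set
  sizes.
* Genome-wide differential splicing, inclusion-read PSI, GSEA-style
  weighted enrichment, Cox modeling, and gene-id alias mapping are out of
  scope.
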