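# xbp1flux

Analysis pipeline for studying IRE1α–XBP1s pathway inhibition in prostate
cancer transcriptomes. Two perturbations of the same pathway — siRNA
knockdown of *XBP1* and small-molecule inhibition of the IRE1α RNase
(MKC8866 class) — are profiled by bulk RNA-seq; the package quantifies the
spliced XBP1 isoform directly from splice junctions, tests differential
expression, measures how concordant the two perturbations are, scores
gene-set shifts, evaluates an XBP1-derived gene signature as a survival
marker, and classifies drug-combination synergy. A seeded synthetic-data
generator emulates every input, so the complete pipeline runs and is tested
with no external data.

It is aimed at computational biologists who want the statistical core of
this kind of pathway-perturbation study as small, audited, reusable
functions rather than a monolithic workflow.

## What it computes

* **XBP1s abundance** — IRE1α excises a 26-nt intron from *XBP1* mRNA
  (chr22:28,796,122–28,796,147, hg38); reads spanning that junction
  uniquely mark the spliced isoform. Abundance is measured as unique
  spliced reads at the focal junction per million total unique spliced
  reads, and differential usage is tested with a negative-binomial GLM
  (log link, Cox–Reid profiled dispersion) with a log10 library-depth
  covariate: log E[y] = β₀ + β₁·treatment + β₂·log10(depth).
* **Differential expression** — genes with >5 counts in at least one
  sample of each group; median-of-ratios size factors as log offsets;
  per-gene NB Wald tests; Benjamini–Hochberg adjustment (no dispersion
  shrinkage — a documented simplification).
* **Concordance** — sign-quadrant counts of paired log2 fold changes and
  an exact binomial test for the overlap of two top-n lists:
  P(X ≥ k), X ~ Binomial(n, n/universe), summed in log space so tails
  below 1e-16 stay exact.
* **Enrichment** — per gene set, a two-sample Kolmogorov–Smirnov test
  comparing log2 fold changes of members vs all other tested genes
  (direction reported separately), and a Fisher's-exact variant on a
  significance-selected gene list.
* **Signatures and survival** — quantile normalization, mean per-gene
  z-score signature activity, Pearson score–score correlation, median-split
  Welch t comparisons, Kaplan–Meier curves and the 1-df log-rank test; the
  default prognostic signature is the five-gene list *ANLN*, *CSNK1G3*,
  *RRM2*, *SLC35A2*, *UBAC2*.
* **Synergy** — a combination is synergistic when Fc > Fa·(1 − Fb)
  (strict); classic Bliss independence (Fa + Fb − Fa·Fb) is exposed
  alongside for comparison.

## Worked example

The `analysis/` directory holds the numbered end-to-end workflow; each
script is a thin driver over the package and writes its tables under
`results/`:

```sh
Rscript analysis/01_simulate.R                # inputs with known truth
Rscript analysis/02_junction_usage.R          # XBP1s usage + NB GLM
Rscript analysis/03_differential_expression.R # DE for both contrasts
Rscript analysis/04_concordance_enrichment.R  # quadrants, overlap, KS/Fisher
Rscript analysis/05_signature_survival.R      # scores, KM, log-rank
Rscript analysis/06_synergy.R                 # synergy calls
```

With the default seed the run prints, among other lines:

```
Treated vs control: log fold change -2.559 (fold 0.08x, SE 0.209), Wald p = 2.3e-34.
sixbp1: 8169/10000 genes pass the filter; 256 down / 191 up at adjusted p < 0.05; ...
Top-100 down-regulated overlap: 25 genes (universe 7849), binomial p = 4.1e-25.
Top-100 up-regulated overlap: 10 genes (universe 7849), binomial p = 6.87e-07.
sixbp1: top KS-enriched set SECRETION_LIKE (D = 0.40, p = 2.2e-308, direction -1).
Median-split survival: 150 high vs 150 low; log-rank chi-square = 75.0, p = 4.78e-18.
30 of 30 combinations synergistic under Fc > Fa*(1-Fb); median margin 0.097.
```

Reading the output: the junction GLM recovers the simulated 10-fold XBP1s
depletion (e^−2.56 ≈ 0.08); the top-100 down-regulated lists of the two
contrasts share far more genes than the ~1.3 expected by chance in a
7,849-gene universe; the gene sets given true negative shifts rank first
by KS p-value with negative direction; and the high-signature half of the
cohort relapses earlier, as built into the simulation's hazard ratio of 3.

The same stages are available programmatically, e.g.:

```r
library(xbp1flux)
jt  <- read_sj_tab("sample1.SJ.out.tab")
focal_usage(jt, xbp1s_junction())$ratio_per_million
ov  <- topn_overlap_test(top_a, top_b, universe = 15000)  # exact tail
```

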