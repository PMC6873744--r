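---
title: "Two-sample Mendelian randomization of telomere length on Alzheimer's disease: models and methods"
author: "telomr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR of telomere length on Alzheimer's disease: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telomr)
```

## The question and the design

Observational studies repeatedly associate shorter leukocyte telomere
length with Alzheimer's disease (AD), but cross-sectional associations
cannot separate cause from consequence or from shared confounding (age
above all). Two-sample Mendelian randomization (MR) sidesteps this by using
germline variants as instruments: SNPs robustly associated with telomere
length are, by the randomness of meiosis, unconfounded proxies for a
lifelong shift in telomere length, and their effects on AD risk can be read
from an independent case-control GWAS. `telomr` implements this design
end-to-end for summary statistics: harmonization, LD clumping, five causal
estimators, and the pleiotropy/heterogeneity/outlier diagnostics that probe
the design's assumptions.

The package ships, as `load_paper_instruments()`, the 16 published
genome-wide significant telomere-length instruments (exposure GWAS of 9,190
Europeans; outcome GWAS of 71,880 AD cases / 383,378 controls) with their
AD associations, so the whole pipeline runs and is tested without any
download.

## Model

For instrument $i$, let $\hat\beta_{Xi}$ (SE $\sigma_{Xi}$) be its
per-allele effect on telomere length in SD units and $\hat\beta_{Yi}$ (SE
$\sigma_{Yi}$) its log-odds effect on AD, both aligned to the
telomere-lengthening allele. Under a linear causal model with effect
$\beta$ and no horizontal pleiotropy, each Wald ratio
$\hat\beta_{Yi}/\hat\beta_{Xi}$ estimates $\beta$. The estimators differ in
how they pool the ratios and which invalid-instrument patterns they
tolerate:

* **IVW** — weighted mean of ratios with weights
  $w_i = (\hat\beta_{Xi}/\sigma_{Yi})^2$; equivalently WLS regression of
  $\hat\beta_{Yi}$ on $\hat\beta_{Xi}$ through the origin. Default
  variance model is multiplicative random effects: the fixed-effect SE is
  scaled by $\max(1, \sqrt{Q/(n-1)})$, so mild over-dispersion widens the
  interval and under-dispersion never narrows it.
* **Maximum likelihood** — joint model
  $\hat\beta_{Xi} \sim N(\gamma_i, \sigma_{Xi}^2)$,
  $\hat\beta_{Yi} \sim N(\beta\gamma_i, \sigma_{Yi}^2)$, maximized over
  $(\gamma_1..\gamma_n, \beta)$ by coordinate ascent (both conditional
  updates are closed-form) from the IVW start; the SE comes from the
  observed information profiled over the $\gamma_i$. Unlike IVW it models
  the exposure sampling error.
* **MR-Egger** — WLS with a free intercept. The intercept estimates the
  average directional pleiotropic effect per SNP (its test is the
  pleiotropy test); the slope remains consistent for $\beta$ under InSIDE.
  Instruments are re-oriented to the exposure-increasing allele inside the
  fit, since the regression is not invariant to per-SNP sign flips.
  Residual scaling is multiplicative and floored at 1; inference uses
  $t_{n-2}$.
* **Weighted median** — interpolated median of ratios under cumulative
  inverse-variance weights; consistent while valid instruments carry more
  than half the weight.
* **Weighted mode** — argmax of the weighted Gaussian KDE of the ratios
  (bandwidth $\varphi \cdot 0.9\,\min(\mathrm{sd},
  1.4826\,\mathrm{MAD})\,n^{-1/5}$, evaluated on a 512-point grid spanning
  the ratios $\pm 3$ bandwidths); consistent under plurality validity.

Median and mode SEs come from a parametric bootstrap (resampling
$\hat\beta_{Xi}, \hat\beta_{Yi}$ from their sampling distributions, 1000
replicates by default) with a recorded seed.

### Ratio weights: a deliberate choice

The weights of the median and mode estimators use the **second-order**
delta-method Wald-ratio variance
$\sigma_{Yi}^2/\hat\beta_{Xi}^2 +
\hat\beta_{Yi}^2\sigma_{Xi}^2/\hat\beta_{Xi}^4$ by default
(`weighting = "delta2"`), the convention of the widely used two-sample MR
toolchain, with the first-order variance available as `"delta1"`. The
choice is visible in this dataset: on the 10-instrument panel the
second-order weights give a weighted-median OR of 1.01 — the value the
published analysis reports — while first-order weights give 1.03, and
similarly 1.01 vs 1.05 for the mode. Single-ratio SEs reported by
`wald_ratio()` stay first-order by default (`second_order = FALSE`).

## Harmonization and clumping

`harmonize_pair()` aligns the outcome record to the exposure's effect
allele (reversed order flips the sign and frequency; otherwise the strand
complement is tried; irreconcilable allele sets are dropped, never passed
silently), then orients the pair so $\hat\beta_{Xi} > 0$. Palindromic A/T
and C/G SNPs carry no strand information in their allele labels, so they
are resolved by allele-frequency concordance when the exposure MAF is below
0.42 (default) and dropped as ambiguous otherwise. Frequency discordance
above 0.1 between datasets warns without dropping — the packaged rs6028466
(0.17 vs 0.06) is the motivating case, retained in the source analysis.

`greedy_clump()` visits SNPs in ascending exposure p-value (ties broken
lexicographically on rsID, documented and deterministic) and keeps a SNP
unless an already-kept SNP on the same chromosome within the 2 Mb window
has $r^2 > 0.001$ with it. Cross-chromosome pairs never clump. The true
pairwise $r^2$ among the 16 packaged SNPs is not published — only which
SNPs were removed — so the packaged reproduction builds a block LD matrix
from the locus structure (`locus_blocks()`: shared gene annotation, or
within 200 kb on the same chromosome, merged transitively; $r^2 = 0.8$
within a block, 0 elsewhere). The 200 kb proximity rule matters: the two
chr19 zinc-finger instruments carry different gene labels but sit 144 kb
apart and the published analysis clumped them together. Under this matrix
the greedy pass keeps exactly the 10 published survivors, each the
locus-minimum p-value.

## Diagnostics

* `cochran_q(panel, "ivw")` — Cochran's Q about the fixed-effect IVW fit,
  $n-1$ df; `"egger"` gives Rücker's Q′ about the Egger fit, $n-2$ df.
* `leave_one_out()` — re-estimates on every $n-1$ subset.
* `mr_presso()` — residual-sum-of-squares resampling: observed RSS uses
  leave-one-out IVW predictions with residuals standardized by
  $\sigma_{Yi}$ (weights $1/\sigma_{Yi}^2$, the reference convention for
  this test; `weighted = FALSE` gives raw residuals); the null distribution
  comes from parametric simulation under no pleiotropy; the global p is
  floored at $1/(n_{\mathrm{sim}}+1)$ and per-SNP outlier p-values are
  Bonferroni-adjusted. When outliers are flagged, a distortion test
  compares the IVW estimate with and without them against random same-size
  exclusions.
* `compare_estimates_q()` — 1-df Q contrast of two estimates on a common
  scale, e.g. against an observational meta-analysis log-OR supplied by the
  user.

## Sign convention

Estimators work internally per SD *increase* of telomere length; the
reporting layer (`instrument_panel(..., sign_convention =
"per_sd_decrease")`) negates the pooled log-OR at report time, matching
the convention in which the published odds ratios are stated (risk of AD
per 1-SD *decrease*). Flipping the convention negates every beta and
inverts every OR throughout a report bundle; it never touches the data.

## The synthetic-data generator

`simulate_panel(sim_config(...))` draws
$\gamma_i \sim U(0.02, 0.15)$, $\hat\beta_{Xi} \sim N(\gamma_i,
\sigma_X)$, $\hat\beta_{Yi} \sim N(\beta\gamma_i + \alpha_i, \sigma_Y)$,
with $\alpha_i = 0$ for valid instruments and, for the invalid fraction,
balanced (mean-zero), directional (mean $\neq 0$), or InSIDE-violating
($\alpha_i$ constructed proportional to the standardized $\gamma_i$)
direct effects. The default ranges and SE scales ($\sigma_X = 0.012$,
$\sigma_Y = 0.003$) mirror the magnitudes of the packaged instruments, so
synthetic panels are numerically comparable to the fixture. A single root
seed streams all per-replicate seeds (`replicate_seeds()`).

What the generator does *not* emulate: linkage between instruments (panels
are independent draws; LD enters only through the separate block-LD
builder), winner's curse in instrument selection, case-control sampling of
the outcome GWAS, or allele-frequency-dependent power. Passing recovery
tests therefore validates the estimators' statistical behaviour under the
stated sampling model, not robustness to those real-data features.

### Test regimes, and a known attenuation

Mean-recovery checks ("the estimator's average over 200 replicates equals
the truth within 2 Monte-Carlo SEs") are run in a strong-instrument
configuration (effects 0.08–0.2 SD, $\sigma_X = 0.004$). This is
deliberate: with the fixture-like weak-instrument defaults, ratio-based
estimators carry a regression-dilution attenuation of order
$\sum_i\sigma_{Xi}^2 / \sum_i\gamma_i^2 \approx 1.6\%$ — about
$-0.0008$ on a true effect of $0.05$ — which is a mathematical property of
using noisy exposure betas, not an implementation defect, and is larger
than the Monte-Carlo resolution of a 200-replicate mean. The robustness
*comparisons* (median vs IVW bias under 40% invalid instruments; mode
under 60% diffuse invalidity; Egger-intercept recovery of directional
pleiotropy) are insensitive to this and some run under the default weak
regime. The same reasoning applies to the MR-PRESSO null calibration: its
resampling scheme redraws exposure betas about their observed values,
which doubles the exposure noise in the null distribution and makes the
global test slightly conservative for weak instruments; calibration is
checked where that term is second-order.

## Numerical choices

* ML convergence: relative tolerance $10^{-12}$ on $\beta$, cap 500
  iterations, error (never a silent fallback) on non-convergence; the
  optimizer is deterministic, so repeated fits are bit-identical.
* Mode grid: 512 points; the grid step is far below reporting precision.
  Degenerate panels (all ratios identical) return the common ratio rather
  than a zero-bandwidth density.
* Bootstrap and simulation seeds are explicit arguments with fixed
  defaults, recorded in every result object; `run_pipeline()` derives all
  stage seeds from one root seed, and identical configurations produce
  byte-identical report bundles.
* p-values are floored at the smallest positive double, and resampling
  p-values at $1/(n_{\mathrm{sim}}+1)$; neither is ever reported as 0.
* `mr_presso()` refuses $n_{\mathrm{sim}} < 100$ (p resolution) and
  $n < 4$ instruments; Egger and the median/mode need $n \ge 3$.

## The packaged reproduction, and two honest discrepancies

`reproduce_paper()` runs the full pipeline on the fixture. The IVW OR per
1-SD decrease is 1.03 (95% CI 1.01–1.05, p = 0.0120), maximum likelihood
1.03 (1.01–1.05), weighted median 1.01, weighted mode 1.01; heterogeneity
p = 0.41 (IVW context) and 0.32 (Egger context); Egger intercept
p = 0.98. These match the published values at their printed precision.

Two published numbers do not reproduce from the published per-SNP table,
and the package does not force them:

* the published maximum-likelihood p-value (1.13e-3) is inconsistent with
  the CI printed beside it (1.01–1.05, which implies z ≈ 2.5 and hence
  p ≈ 0.01); a converged ML fit here gives p = 0.0104 with exactly that
  CI;
* the MR-PRESSO global p computed from the table is ≈ 0.35 at
  $n_{\mathrm{sim}} = 5000$ (stable across seeds, under both residual
  weightings), versus a published 0.29.

Both are asserted at their published values in the acceptance test suite
and the assertions fail, by design, with this analysis as the explanation.

## Limitations

Beyond the generator's scope above: the package performs no proxy-SNP
search, no liftover, no Steiger directionality filtering, and no
multivariable MR; LD must be supplied (or constructed from locus blocks)
rather than estimated from genotypes; and the observational-comparison
operation (`compare_estimates_q()`) requires the user to supply the
external estimate on the log-OR scale.
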