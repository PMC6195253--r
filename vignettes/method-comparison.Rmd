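---
title: "Comparing worm-counting methods for competitive fitness assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing worm-counting methods for competitive fitness assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compfit)
```

## The assay and its estimators

A dual-label competition assay starts one unmarked focal worm and one
GFP-marked competitor on a plate, lets the populations grow to a fixed
endpoint, and samples the mixture. Counting the sample twice — total worms
under brightfield, fluorescent worms under GFP excitation — yields the focal
frequency $p = (n - g)/n$, the competitive index $CI = p/(1-p)$, and
$\log CI$, the focal log-odds. All three are monotone transforms of the same
quantity; they differ in how their *sampling variability* relates to their
mean, which matters as soon as one wants to compare variability between
groups whose means differ.

Boundary samples ($p \in \{0, 1\}$) have undefined $CI$ or $\log CI$. The
package represents these as explicit `NA` flags rather than infinities, and
every group summary carries an `n_excluded_boundary` count, mirroring the
practice of filtering sorter wells to $0.01 < p < 0.99$.

The natural logarithm is the default for $\log CI$ (the standard scale for
log-odds); a `base` argument is provided since published tables sometimes
use base 10. `p` is always recomputed from the stored counts, never stored
by itself, so the invariant $0 \le g \le n$ stays enforceable at the edges
of the pipeline.

## Choosing the analysis scale

Measures of dispersion tend to be correlated with the mean. For each
estimator the package computes, per focal × competitor × method × block
group, the sample SD ($n-1$ denominator) and the Median-Levene statistic
$Md = \tfrac1n \sum_i |x_i - \tilde x|$ (with the even-$n$ median the
midpoint of the central order statistics) — a robust dispersion measure
that, unlike the SD, does not square outlying replicates. Pearson
correlations of group mean against group SD and Md across all block-groups
(pooled; the grouping already spans methods) form the diagnostic for
choosing the analysis scale.

On assay-like simulations the pattern is stable: $CI$, being an
exponential-type transform of the log-odds, has dispersion nearly
proportional to its mean ($|r| \approx 0.9$); $p$ shows a moderate
correlation through the $p(1-p)$ factor; $\log CI$ is nearly free of the
mean ($|r| \approx 0.1$). The variability analysis therefore uses
$SD_{\log CI}$ as its response.

A note on the simulator's role here: with the neutral default
($\mu_{\log CI} = 0$ in every cell) all group means coincide and the $p$
versus $\log CI$ part of that ordering is undetectable in principle. The
`paper_like_config()` preset exists for exactly this reason: it assigns the
three focal strains genuinely different competitive abilities against the
two markers (group-level $p$ from about 0.51 to 0.80), which is what real
strain panels look like and what gives the diagnostic something to measure.

## Repeatability analyses

Two designs quantify technical (counting) error:

* **Re-counts.** The same image counted twice. The report gives Pearson
  correlations between passes for total count, GFP count and $p$, and the
  mean absolute difference scaled by the pass average,
  $|c_1-c_2|/\bar c$, in percent. Both statistics are symmetric in the two
  passes.
* **Split samples.** Sorter samples are ephemeral, so one well is split
  volumetrically into a ~1/4 and a ~3/4 aliquot counted separately. Records
  pass the filter only if *both* aliquots have more than 10 worms and $p$
  strictly inside $(0.01, 0.99)$. The headline discordance statistic,
  mean $|p_{small}-p_{large}|$, is reported in **percentage points of p**
  (the relative version is also returned): $p$ is already a proportion,
  and the wording that describes the re-count statistic — which *is*
  relative — differs. The binomial standard error $\sqrt{pq/n}$ implies the
  small aliquot is noisier by $\sqrt{n_{large}/n_{small}}$; at mean aliquot
  sizes 143 and 551 that ratio is 1.96, i.e. about 2.

The decomposition `variance_decomposition()` (on the $p$ scale) and
`estimate_logci_components()` (on the log-odds scale, using the
delta-method counting variance $1/(n p q)$ and within-block centring)
separate among-plate biological variance from binomial counting variance.
The moment estimate of biological variance is floored at zero; the
unfloored value is reported alongside, since averaging floored estimates
over simulations would bias recovery checks.

## The heteroscedastic linear model

The variability analysis models the block-group response
$y_{ijkl} = \mu + f_i + c_j + m_k + t_{ij} + u_{ik} + v_{jk} + w_{ijk} + \varepsilon_{l|ijk}$
(focal, competitor, method main effects and all interactions), with the
residual variance *grouped*: every observation's variance is the parameter
of its residual group (per design cell, per method, or pooled). The
replicate-level analysis of $p$ adds a block random intercept, with
replicate nested in block as the unit of observation; design cells missing
from the data (e.g. a block without by-eye counts) are simply omitted.

Implementation choices that matter:

* **Fitting.** Fixed effects are profiled out by GLS at each variance
  iterate; variance parameters live on the log scale and are optimized by
  Nelder-Mead (Brent for one parameter) from moment starts, relative
  tolerance $10^{-13}$, making fits deterministic. The block intercept uses
  the Woodbury identity per block, so no dense $n \times n$ covariance is
  formed. Estimates at the boundary (block variance $\to 0$) are reported
  as exactly 0.
* **REML vs ML.** Restricted likelihoods of models with different fixed
  effects are not comparable, so `model_search()` uses ML AICc when
  candidates differ in fixed effects and REML AICc when only the variance
  structure differs; the criterion used is recorded on every search. The
  two-stage `analyze_*()` pipelines choose the residual grouping first
  (REML, at the full fixed model), then the fixed-effect ladder (ML), then
  refit the winner by REML. This deviates deliberately from older software
  defaults that compare REML likelihoods across fixed-effect sets.
* **AICc.** $AICc = -2\ell + 2k + 2k(k+1)/(n-k-1)$, with $k$ counting
  fixed coefficients plus variance parameters under ML, variance parameters
  only under REML. Conventions for $k$ differ across packages; this one is
  documented and applied consistently, which is what AICc *ranking* needs.
* **REML constant.** The restricted likelihood depends on the fixed-effect
  parameterization through $\log|X'V^{-1}X|$. The package codes factors
  sum-to-zero (which also makes the type-III hypotheses the natural
  per-term coefficient tests); its intercept-only and treatment-coded
  values coincide with base R's `logLik(lm, REML = TRUE)`, and all
  comparisons happen at a fixed coding, where the constant cancels.
* **F-tests.** Type-III Wald F per term, with Satterthwaite denominator
  degrees of freedom: each eigen-contrast of the term's covariance gets
  $\nu_i = 2\lambda_i^2 / (g_i' A g_i)$, with $g_i$ the numerical gradient
  of $\lambda_i$ in the variance parameters and $A$ the inverse observed
  information; the $\nu_i$ pool by the standard multi-df formula. In the
  two-group free-variance case this reproduces the Welch–Satterthwaite df
  to $10^{-6}$, and in balanced pooled-variance layouts the textbook
  integer df. Fractional df such as $F_{2,69.1}$ are expected output, not
  an anomaly.

The default candidate ladder keeps the method term — the factor under
study — in every fixed-effect set and crosses five fixed sets (full model
down to method-only) with three residual groupings. An intercept-only rung
is available for null calibrations.

## The synthetic-data generator

The generator is the package's study-conditions document. Defaults: 5
blocks × 3 focal strains × 2 competitors × 3 methods × 24 replicates;
Poisson plate totals with mean 176 worms (the typical brightfield count of
an imaged sample; an overdispersion knob is available); biological
variation placed on the log-CI scale as
$\log CI_{true} = \mu_{\log CI} + b_{block} + N(0, \sigma_{bio})$ with
$\sigma_{block} = 0.25$, $\sigma_{bio} = 1.0$ — magnitudes back-calculated
from split-sample summary statistics of a real assay of this design (an SE
of mean log CI near 0.095 over ~280 wells implies a total SD of ~1.6
including strain and block structure) — and binomial sampling of the focal
count at the plate's true $p$.

Counting error is applied per method: GFP false negatives thin the GFP
count binomially, false positives add Poisson extra objects, and a rounded
Gaussian miscount perturbs the total (floored at the GFP count so the count
invariant holds). **No empirical per-method error rates exist**; the
defaults are order-of-magnitude guesses, labelled as such, chosen so that
image analysis errs slightly more than a careful human and both mechanisms
push $p$ upward for the image method — the bias direction one expects when
debris is called worms and fluorescent loci are occasionally missed.

Split samples draw the small aliquot size as Binomial($n$, fraction) — a
volumetric split of a mixed suspension — and its GFP composition
hypergeometrically. Rendered well images draw worms as random-curvature
tubes inside a circular well, a radial illumination field (bright centre,
dark edge), additive noise, optional edge-biased debris, and a compact
fluorescent locus near the head of each GFP worm, with per-worm ground
truth embedded.

What the generator does *not* emulate: sorter optics and E. coli event
noise (only a false-positive rate), worm size/stage structure, overlapping
image tiles, or any spatial correlation between plates. Passing tests on
synthetic data therefore validate the estimators and the machinery, not the
photometric realism of any particular microscope.

## The image counter

The counter is a deliberately simplified version of a production pipeline:
illumination correction by normalized Gaussian smoothing (default scale
1/16 of the image side — heavy relative to a worm, light enough to track
the field near the border; the estimate is unreliable within ~2σ of the
image edge, which is part of why cropping exists) and division; rectangular
border cropping; Otsu thresholding of the inverted brightfield behind a
minimum-contrast guard (a worm-free image must not have its noise floor
sliced into objects); connected components filtered by area; and **clump
resolution by area quantization** — components larger than ~1.6× the
reference single-worm area count as `round(area / reference)` worms, with
the reference estimated per image as the median single-sized component.
This replaces probabilistic worm-shape untangling entirely; it needs no
training and is exact when clumps are pairwise touches, but it will
miscount dense many-worm tangles and is one reason real pipelines train
shape models. GFP children are thresholded with a robust background guard
and assigned to the worm object containing their centroid; a clump's
multiplicity is floored at its child count (each locus is a distinct
worm), and a worm with no child is called focal — which reproduces the
false-negative mechanism when a locus falls in a cropped-off head region.

## Numerical and testing choices

Problem sizes in the test-suite calibrations are the package's own: 1,000
null simulations for the F-test size check, 100 searches for structure
recovery, 100–200 rendered wells for counting accuracy, 500-well split
simulations. Monte-Carlo assertions use 3-SE bands; exact assertions
(closed forms, Welch df, dense-likelihood cross-checks) use $10^{-6}$
tolerances and 1-ulp-aware comparisons for the Md oracle. Degenerate inputs
are first-class: single-level factors, empty wells, boundary $p$,
zero-variance blocks and singleton variance groups all have defined,
tested behavior.

## Limitations

* The model engine supports one random intercept and grouped-diagonal
  residual covariances only — no crossed random effects, no Kenward–Roger
  correction. Reproduction of other software's F statistics to printed
  precision also depends on their AICc parameter counting and df
  conventions, which differ.
* Area-quantized clump resolution degrades for dense tangles.
* The split-sample filter and analysis assume integer counts from the
  sorter; event-gating physics is out of scope.
* Whether a published "odds ratio $p_i/p_j$" means the ratio of proportions
  or of odds is ambiguous in places; `focal_odds_comparison()` returns
  both, labelled.
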