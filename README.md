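# compfit

Quantifying competitive fitness in *Caenorhabditis elegans* from dual-label
worm counts, and asking whether automated counting methods (image analysis,
large-particle flow cytometry) are as trustworthy as a human counting by eye.

## The problem

A standard competitive fitness assay competes an unmarked **focal** strain
against a GFP-marked **competitor** on the same plate. At the assay endpoint
the population is sampled and counted twice: all worms (brightfield / total
event count) and fluorescent worms (GFP). Three estimators of competitive
fitness derive from those two counts for a sample of `n` worms of which `g`
fluoresce:

- the focal frequency  `p = (n − g) / n`,
- the competitive index `CI = p / (1 − p)` (the odds a sampled worm is focal),
- the log competitive index `log(CI)` (the focal log-odds).

Automated counting is only worth adopting if its **bias** and **technical
variance** are small relative to the biological variance among replicate
plates. `compfit` implements the statistical machinery for that comparison:

- within-block variability statistics per focal × competitor × method ×
  block group — sample SD and the Median-Levene statistic
  `Md = mean |x − median(x)|` — plus mean–variance diagnostics used to pick
  the analysis scale (SD of log(CI), whose variance is least coupled to its
  mean);
- repeatability analyses: image re-counts (two passes over the same wells)
  and sorter split samples (a well divided into ~1/4 and ~3/4 aliquots),
  with the strict filter `n > 10`, `0.01 < p < 0.99`, and the binomial
  SE comparison `sqrt(p q / n)`;
- a technical-vs-biological variance decomposition on the p and log-CI
  scales;
- a heteroscedastic Gaussian linear-model engine
  `y = μ + f + c + m + (interactions) + ε` with grouped residual variances
  (per cell / per method / pooled), an optional block random intercept,
  REML/ML fitting, AICc-guided structure search, and type-III F-tests with
  Satterthwaite (fractional) denominator degrees of freedom;
- a simplified dual-channel well-image counter (illumination correction,
  cropping, Otsu segmentation, area-quantized clump resolution, GFP child
  assignment by centroid containment);
- a synthetic-data generator covering all of the above: plate-level
  competition outcomes with biological variation on the log-CI scale,
  method-specific counting error, volumetric split samples, and rendered
  brightfield/fluorescence well images with embedded ground truth.

## Worked example

```r
library(compfit)

cfg <- paper_like_config(seed = 1)      # 5 blocks x 18 cells x 24 replicates
sim <- simulate_assay(cfg)
est <- fitness_estimates(sim$observations)
mean(est$p)                              # 0.6327251

# is any counting method more variable? (SD of log(CI) scale)
ana <- analyze_sd_logci(sim$observations)
ana$f_test_method
#> # A tibble: 1 x 5
#>   term   f_value num_df denom_df p_value
#>   <chr>    <dbl>  <int>    <dbl>   <dbl>
#> 1 method   0.983      2     87.0   0.378
```

The F-test says: with this seed's simulated data (mild, realistic counting
error for all three methods), the among-block variability of log(CI) does
not differ detectably between by-eye, image-analysis, and sorter counting —
the situation in which switching to automated counting is safe.

The numbered scripts under `analysis/` run the full study end to end
(simulation → variability diagnostics → repeatability → model-based method
comparison → image-counter validation), writing tables under `results/`:

```sh
Rscript analysis/01_simulate_assay.R
Rscript analysis/02_variability.R
# ...
```

## Data formats

Canonical observation CSV (UTF-8, header required):
`block_id, focal_strain, competitor_strain, method, replicate_id, n_total, n_gfp`
with `0 ≤ n_gfp ≤ n_total`. Re-count tables use
`image_id, n_total_1, n_gfp_1, n_total_2, n_gfp_2`; split-sample tables use
`well_id, n_total_small, n_gfp_small, n_total_large, n_gfp_large`.
Spreadsheets (XLSX) can be ingested read-only via
`read_observations(..., format = "xlsx", mapping = ...)` with a column
mapping.
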