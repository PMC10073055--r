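# effortdiv

Sampling-effort analysis of stream fish diversity from seine surveys.

## The problem

In wadable sand-bed rivers, fish assemblages are surveyed with a beach
seine: a site is a ~200-m stream section, and each seine haul sweeps one
mesohabitat (run, riffle, pool, backwater). Every haul is a small
sub-sample, so estimates of α-diversity (site richness and evenness),
γ-diversity (regional richness), and β-diversity (between-site
dissimilarity) all depend on how many hauls were made. Crews designing
monitoring programs need to know where the curves flatten: how many hauls
per site are enough, and whether a site's conditions predict that number.

effortdiv answers this with a collector-order effort-accumulation pipeline
for haul-level count data:

- **α-diversity**: observed richness S_obs; the bias-corrected Chao1
  estimator S_obs + f₁(f₁−1)/(2(f₂+1)) from singleton/doubleton counts;
  and the Gini–Simpson index 1 − Σ pᵢ², each evaluated on counts pooled
  over hauls 1..k in the actual field order (rare habitats are seined
  first, so the field order is itself part of the design under study).
- **β-diversity**: the abundance-based multiple-site Bray–Curtis
  dissimilarity d_tot, partitioned into balanced variation d_bal
  (abundance substitution between sites) and abundance gradient d_gra
  (abundance loss without substitution), with d_tot = d_bal + d_gra,
  tracked as within-site effort grows.
- **Effort sufficiency**: H_p, the smallest number of consecutive hauls
  whose cumulative richness reaches a fraction p of the full-effort
  richness (unrounded threshold, ≥ convention), plus stabilization
  detection and univariate OLS regressions of H_75/H_100 on wetted width,
  mean haul depth, and proportion of run habitat (adjusted R², unclamped).
- **Synthetic surveys**: a calibrated generator (20 sites × 40 hauls,
  11-species geometric-series pool, log-normal site effects, Poisson
  counts, habitat protocol with rare habitats confined to early hauls) so
  the whole pipeline is testable without field data.

The package also ships a transcribed site-summary table from a real
40-haul-per-site survey of 20 Middle Rio Grande sites
(`table1_fixture()`), used by the worked example below.

## A worked example

Regressing effort-to-richness thresholds on site covariates for the
packaged survey table:

```r
library(effortdiv)
study_report(NULL, summaries = table1_fixture())$regressions
#> # A tibble: 6 × 6
#>   response predictor      slope slope_se   adj_r2 p_value
#>   <chr>    <chr>          <dbl>    <dbl>    <dbl>   <dbl>
#> 1 h_75     wetted_width -0.0284   0.0455 -0.0332    0.540
#> 2 h_75     mean_depth    5.65    12.3    -0.0433    0.652
#> 3 h_75     prop_run      8.34     7.66    0.00969   0.291
#> 4 h_100    wetted_width  0.0732   0.0745 -0.00174   0.338
#> 5 h_100    mean_depth    7.22    20.5    -0.0483    0.729
#> 6 h_100    prop_run      6.27    13.1    -0.0422    0.637
```

No covariate predicts required effort (all p > 0.05, adjusted R² at or
below zero): wider, deeper, or more habitat-uniform sites do not need
systematically more or fewer hauls. The slopes are in response units per
predictor unit, e.g. −0.028 hauls per metre of wetted width.

The full pipeline on a synthetic survey, including the β-partition effort
curve:

```r
sim <- generate_study(mrg_like_preset(), seed = 42)
beta_effort_curve(sim$hauls)
#> # A tibble: 40 × 5
#>       k n_sites d_tot d_bal d_gra
#>   <int>   <int> <dbl> <dbl> <dbl>
#> 1     1      19 0.844 0.660 0.184
#> 2     5      19 0.795 0.606 0.188
#> 3    10      20 0.794 0.592 0.202
#> 4    20      20 0.785 0.574 0.211
#> 5    40      20 0.786 0.553 0.233   (selected rows)
```

Total dissimilarity starts high and noisy under minimal effort (at k = 1
one site is still fishless and is excluded, with a warning) and settles as
effort grows, with balanced variation contributing roughly 70% of the
total — between-site structure in this kind of assemblage is mostly
abundance substitution, not nested loss. `study_report()` bundles the
curves, summary table, regressions, and stabilization efforts;
`autoplot()` draws the standard figures; `write_report()` serialises
everything to CSV/JSON/PNG.

A thin command-line wrapper covering validation, curves, reports, and
simulation lives at `inst/cli/effortdiv.R`
(`Rscript $(Rscript -e 'cat(system.file("cli","effortdiv.R",package="effortdiv"))') simulate --seed 42 --outdir sim/`).

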