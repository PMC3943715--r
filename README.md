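# rodentcam

Analysis pipeline for motion-triggered camera-trap surveys of invasive
rodents — black rats and house mice on high-conservation-value islands
being the motivating case. Live traps under-detect trap-adverse rodents
and endanger non-target wildlife; horizontally mounted cameras over a
bait lure detect many species at once with minimal impact. This package
turns the resulting trigger-level records into defensible statistics for
two management questions: *how many survey nights are needed to trust an
absence?* and *what habitat features drive rodent activity?*

The pipeline has four stages, each usable on its own:

1. **Events** — triggers are collapsed to discrete 15-min presence
   "events" per site, night (noon-to-noon) and clock-aligned interval;
   from these, per-site activity indices (events per 24 h) and nightly
   binary detection histories.
2. **Occupancy** — single-season occupancy models with constant or
   night-varying detection, fitted by maximum likelihood on the site
   likelihood
   `L_s = psi * prod_t p_t^y (1-p_t)^(1-y) + (1-psi) * 1[no detections]`,
   compared by information criteria. The fitted detection vector gives
   the cumulative detection probability `P_n = 1 - prod(1 - p_i)` and
   the smallest `n` with `P_n >= 0.95` — the nights needed to be 95%
   confident of site-level absence.
3. **Habitat** — site covariates: point-centre-quarter seabird burrow
   densities (`D = 10^4 / mu^2` per ha, with Pollard and pooled
   alternatives), structure-pole complexity bands (`C10_40`), visual
   covers (`C_gt1m`, floristics).
4. **Model selection** — negative-binomial GLMs for activity counts
   (log link, log-nights offset) over a-priori candidate sets, ranked by
   AICc (`-2logLik + 2K + 2K(K+1)/(n-K-1)`) with Akaike weights
   `w_i ∝ exp(-Δ_i/2)`, and full model averaging with
   Burnham–Anderson unconditional SEs when no model dominates.

A synthetic-study generator (`simulate_study()`) emulates a 276-site,
8-night survey with known occupancy, detection and habitat-linked
negative-binomial activity, so the whole pipeline can be exercised and
parameter recovery verified without field data.

## Worked example

```r
library(rodentcam)

study <- simulate_study(study_config(n_sites = 100, seed = 42))
run   <- run_pipeline(pipeline_config(study = study, out = "run_out"))

run$events$occurrence
#>       species sites_present pct_sites prop_sites n_events
#> 1   black rat            95        95       0.95     3180
#> 2 house mouse            59        59       0.59      613

rat <- run$occupancy[[1]]
rat$comparison
#> Model selection (AIC, n = 100)
#>           model K   logLik minus2LL      AIC     AICc  delta weight
#>  psi(.)p(night) 9 -501.374 1002.748 1020.748 1022.748  0.000      1
#>      psi(.)p(.) 2 -543.922 1087.844 1091.844 1091.967 69.219      0

rat$fits[["psi(.)p(night)"]]
#> Occupancy model [psi(.) p(night)]
#>   sites: 100  nights: 8  K: 9  logLik: -501.374  [ok]
#>   psi = 0.951 (SE 0.022)  naive = 0.950
#>   p   = 0.715 0.768 0.641 0.610 0.557 0.347 0.379 0.305

rat$nights
#> $nights
#> [1] 3
#> $reached
#> [1] TRUE
#> $achieved
#> [1] 0.9762356
```

Reading the output: rats were recorded at 95 of 100 sites; the
night-varying detection model wins outright (Akaike weight 1); occupancy
is estimated at 0.95 with nightly detection falling from 0.77 to 0.31
over the deployment; and three undetected nights suffice to call a site
rat-free with 95% confidence.

The activity GLMs for the same run recover the generating habitat
effect — upper-storey structural cover (`C_gt1m`) tops the candidate set:

```r
run$models[[1]]$table[1:4, c("model", "K", "AICc", "delta", "weight")]
#>                model K     AICc  delta   weight
#>               C_gt1m 3 865.0956  0.000 6.44e-01
#>            C_gt1m+BD 4 867.2526  2.157 2.19e-01
#>  C_gt1m+BD+C_gt1m*BD 5 868.1870  3.091 1.37e-01
#>             Constant 2 891.0241 25.929 1.51e-06
```

All stage outputs (events, activity indices, detection histories and
curves, covariates, IC tables, averaged coefficients, manifest) are
written as CSV/JSON under the run directory. A thin command-line wrapper
lives at `inst/scripts/rodentcam.R` (`simulate` and `run` subcommands).

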