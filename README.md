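# occudesign

Design and evaluation of detection/non-detection monitoring programmes for
rare species under imperfect detection. The package grew out of the planning
problem faced by monitoring schemes for narrowly endemic, hard-to-detect
animals — the motivating case is a bromeliad-dwelling frog surveyed at ~143
bromeliad sites across three altitudinal zones on an isolated mountaintop —
but every component is parameterised and reusable.

It covers the full planning loop:

1. **Occupancy model fitting.** Single-season site-occupancy models with
   imperfect detection. For site *i* with detection history *y<sub>it</sub>*
   over visits *t*, the likelihood contribution is

   - ψ<sub>i</sub> ∏<sub>t</sub> p<sub>it</sub><sup>y<sub>it</sub></sup> (1−p<sub>it</sub>)<sup>1−y<sub>it</sub></sup> if the species was ever detected,
   - ψ<sub>i</sub> ∏<sub>t</sub> (1−p<sub>it</sub>) + (1−ψ<sub>i</sub>) otherwise,

   with ψ (occupancy) and p (per-visit detection) on logit-linear predictors
   of site and survey covariates. Fitting is multi-start quasi-Newton
   maximum likelihood; model ranking uses AIC, ΔAIC and Akaike weights, with
   a two-stage stepwise search (detection covariates first, then occupancy).
2. **Minimum visits to infer absence.** The smallest K with
   1−(1−p)<sup>K</sup> ≥ p\*: `K = ⌈log(1−p*) / log(1−p)⌉`.
3. **Design simulation.** Monte-Carlo sampling distributions of the (ψ̂, p̂)
   MLEs over grids of sites × occasions: bias, RMSE, quantiles, boundary-fit
   rate.
4. **Power analysis.** Two-tailed Wald test on the probability scale for an
   occupancy change between two survey periods:
   G = Φ(Δ/SE − z<sub>α/2</sub>) + Φ(−Δ/SE − z<sub>α/2</sub>), with
   Δ = ψ₁ − ψ₂, SE² = (v₁+v₂)/S and per-site variance factor
   v = ψ[(1−ψ) + (1−p\*)/(p\* − K p (1−p)<sup>K−1</sup>)]. Includes the
   required number of sites for a target power, and an empirical
   (simulation) version of the same test.
5. **Synthetic data.** A generator that emulates the study design
   (zone-dependent occupancy, observer-dependent detection, ragged monthly
   visit schedules) with a known-truth ledger, so the whole pipeline is
   testable end-to-end.

## Worked example

```r
library(occudesign)

study <- generate_study(study_config(), seed = 42)
study
#> Detection history: 143 sites x 16 occasions
#>   detections: 525 | non-detections: 1763 | missing visits: 0
#>   naive occupancy: 0.448

sel <- stepwise_select(study$history, study$site_covs, study$survey_covs,
                       p_candidates  = c("observer_experience", "time_after_dusk"),
                       psi_candidates = c("zone", "elevation", "bromeliad_size"),
                       seed = 42)
as.data.frame(sel$table)[, c("model", "k", "aic", "delta_aic", "weight")]
#>                                       model k  aic delta_aic    weight
#> 1           psi(zone)p(observer_experience) 5 1553      0.00 9.985e-01
#> 2      psi(elevation)p(observer_experience) 4 1566     13.01 1.495e-03
#> 3              psi(.)p(observer_experience) 3 1588     34.77 2.819e-08
#> 4 psi(bromeliad_size)p(observer_experience) 4 1589     36.11 1.437e-08
```

The selection recovers the generating structure (detection driven by
observer experience, occupancy by zone). The fitted zone-level occupancy
probabilities, with delta-method 95% CIs back-transformed from the logit
scale:

```r
pr <- predict_parameters(sel$best_fit, study$history, study$site_covs, study$survey_covs)
unique(round(pr$psi[, c("estimate", "lower", "upper")], 3))
#>    estimate lower upper
#> 1     0.104 0.044 0.227     # low zone    (truth 0.14)
#> 49    0.646 0.502 0.767     # medium zone (truth 0.66)
#> 97    0.596 0.451 0.725     # high zone   (truth 0.66)
```

Design arithmetic — how many visits are needed to call a site unoccupied,
and what the current design can detect:

```r
min_occasions(0.56, c(0.8, 0.9, 0.95))
#> [1] 2 3 4          # visits needed for 80/90/95% cumulative detection

wald_power(power_spec(0.49, 0.30, "proportional", p = 0.61, K = 20,
                      S = 143, alpha = 0.1))
#> [1] 0.8172943      # 82% power to detect a 30% occupancy decline

required_sites(power_spec(0.49, 0.15, "proportional", p = 0.61, K = 20,
                          alpha = 0.1, target_power = 0.8))
#> [1] 565            # sites needed for 80% power against a 15% decline
```

`run_pipeline()` (or `Rscript inst/cli/occudesign.R pipeline`) wires these
stages into a reproducible report bundle with a manifest.

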