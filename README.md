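# metamove

Two-timescale analysis of animal GPS telemetry for movement ecologists
studying territorial species — the motivating case is European badger
(*Meles meles*) populations monitored under bovine-tuberculosis management,
where culling and vaccination programmes can reshape social organisation.

`metamove` separates the two timescales of a movement SDE

$$dX_t = b(X_t)\,dt + \sigma(X_t)\,dW_t, \qquad \sigma(x) = cI,$$

and provides:

* **Fast scale — diffusion.** A Kramers–Moyal finite-difference estimator of
  the isotropic diffusion constant,

  $$\hat c^2 = \frac{1}{2(m-1)} \sum_{i=1}^{m-1} \frac{(x_{i+1}-x_i)^2 + (y_{i+1}-y_i)^2}{\Delta t_i},$$

  computed per individual and calendar month (overnight rest gaps excluded,
  animal-months with ≤ 10 fixes dropped), followed by a log-link
  mixed-effects model `c ~ month + sex + (1 | site:animal) +
  (capture_year | site)` whose coefficients convert to multiplicative rate
  ratios via `exp(·)`.

* **Slow scale — metastability.** An EDMD (extended dynamic mode
  decomposition) approximation of the Koopman operator on an
  indicator-function dictionary over a ~100 m box grid — equivalent to
  Ulam's method for a Markov state model:
  $K^\top = \Psi_{Y'}\Psi_Y^+$ over snapshot pairs exactly one lag τ apart.
  The number of metastable home-range clusters is read off the spectral gap
  (first successive eigenvalue drop exceeding δ, with a
  maximum-successive-difference fall-back), and boxes are clustered by
  k-means on the dominant eigenfunctions. Clusters and social-group home
  ranges are summarised as convex hulls with areas in km².

* **Ground truth.** A synthetic telemetry generator: SDE movement in a
  multi-well Gaussian potential (one well per social group), sex- and
  month-dependent diffusion multipliers, individual random intercepts, and a
  realistic GPS observation process (nightly windows, fix-time jitter,
  dropout, gross outliers, satellite/DOP metadata, mid-study removals).

* **Cleaning.** The full preparation pipeline for raw fix tables: quality
  filter (≥ 4 satellites, DOP ≤ 4), 26.2 m min⁻¹ speed filter, 1500 m
  two-step spike filter, snapping to the programmed schedule,
  monitoring-period splitting, origin shift, and linear interpolation to a
  uniform within-night grid.

## Worked example

Simulate a four-group population with strongly territorial wells, clean it,
and run both analyses:

```r
library(metamove)

sch   <- observation_schedule("18:00", "06:00", fix_interval = 20)
study <- generate_study(n_groups = 4, badgers_per_group = 3, months = 2,
                        seed = 11, schedule = sch,
                        well_depth = 20 * exp(3.397)^2, well_width = 200,
                        well_spacing = 1200, intercept_sd = 0.1, sim_dt = 0.25)

cleaned <- clean_fixes(study$fixes, sch, dt = 20)
est     <- monthly_estimates(cleaned$diffusion_fixes)
fit     <- fit_glmm(est, diffusion_model_spec(year_slopes = FALSE))
print(fit)
#> Log-link mixed model for diffusion estimates
#>   formula: c ~ month + sex + (1 | animal_id)
#>   n = 24, AIC = 53.547, BIC = 59.437, residual SD = 0.205
#>         term estimate     se     t ci_lower ci_upper        p
#>  (Intercept)    2.330 0.0429 54.30    2.250   2.4100 0.00e+00
#>     monthFeb    0.119 0.0080 14.90    0.104   0.1350 1.83e-50
#>    sexfemale   -0.188 0.0740 -2.54   -0.333  -0.0431 1.10e-02
```

The generator was run with a February log-effect of 0.106 and a female
effect of −0.152; both recovered coefficients bracket the truth, and
`effect_multiplier(-0.188) = 0.83` says females diffuse about 17% slower
than males in this realisation.

```r
grid <- build_grid(cleaned$fixes)          # ~100 m boxes
K    <- estimate_koopman(build_pairs(cleaned$fixes), grid)
spec <- spectral_decompose(K)
print(spec)
#> <koopman_spectrum> leading eigenvalues (real part):
#>  [1] 1.0000 1.0000 1.0000 1.0000 0.1604 0.1412 0.1316 0.1274 0.1274 0.1253

N    <- spectral_gap(spec, delta = 0.05)   # -> 4: four near-unit eigenvalues
part <- cluster_metastable(spec, N, seed = 1)
summarise_partition(label_fixes(part, cleaned$fixes))$table
#>   subset n_groups n_clusters group_area_mean group_area_sd cluster_area_mean
#> 1  Total        4          4          0.0589        0.0164            0.0589
#>   cluster_area_sd n_fixes
#> 1          0.0164   25915
```

Four near-unit eigenvalues signal four regions the animals rarely leave; the
k-means partition of the eigenfunctions recovers the four social-group
territories exactly, and cluster hull areas coincide with the group
home-range hulls. `run_pipeline(run_config(...))` chains all of the above
(simulate → clean → diffusion → glmm → koopman → report) with a
checksummed manifest for reproducibility.

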