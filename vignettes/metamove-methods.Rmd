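---
title: "Two-timescale movement analysis: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-timescale movement analysis: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`metamove` treats an animal's position $X_t \in \mathbb{R}^2$ as a diffusion

$$dX_t = b(X_t)\,dt + \sigma(X_t)\,dW_t,$$

with two standing assumptions:

* **Isotropy.** $\sigma(x) = cI$: random movement has no preferred
  direction, so a single positive constant $c$ (units m·min^−1/2^; time is
  minutes throughout the package) summarises the fast, erratic component of
  movement — foraging, local exploration.
* **Territorial drift.** $b = -\nabla U$ for a smooth potential $U$. The
  drift encodes the slow component: attraction to a home range, territory
  structure, the features that persist over months.

The two components live on different timescales, and the package analyses
them separately: a finite-difference estimator for $c$ from displacements
minutes apart, and a spectral (Koopman) analysis for the long-run structure
induced by $b$.

## The synthetic generator

Real telemetry of this kind is typically confidential (site locations are
sensitive), so the package carries a first-class simulator whose output has
the statistical structure the analyses assume. `potential_field()` builds
$U$ as a sum of inverted Gaussian wells,

$$U(x) = -\sum_k d_k \exp\!\left(-\tfrac{|x - m_k|^2}{2 w_k^2}\right),$$

one well per social group. This form is a modelling choice of the package:
it gives smooth, bounded drift everywhere (no blow-up), a single
interpretable attraction centre per territory, and tunable metastability
through the depths. `simulate_sde()` integrates the SDE by Euler–Maruyama
($X_{k+1} = X_k + b(X_k)\,dt + c\sqrt{dt}\,Z_k$) in compiled code;
`observe()` passes the true path through a GPS observation model (nightly
windows with slots anchored to the collar's midnight cycle, uniform
recording delays, dropout, ring-shaped gross outliers at 2–5 km so that
realistic filters can catch them, synthetic satellite-count and DOP
metadata); `generate_study()` assembles a population in which individual
$i$'s diffusion in month $m$ is

$$c_{im} = c_0 \exp\big(\beta_{\mathrm{month}(m)} + \beta_{\mathrm{sex}}\,
  \mathbf{1}[\text{female}] + a_i\big), \qquad a_i \sim N(0, \sigma_a^2).$$

Default effect sizes are the field-typical values used throughout the
package's tests: $c_0 = e^{3.397} \approx 29.9$, a February effect of
$0.106$, a female effect of $-0.152$, and $\sigma_a = \sqrt{0.229} \approx
0.48$. Each individual draws from its own pseudo-random stream derived from
`(seed, individual index)`, so removing one animal (e.g. to emulate
culling via `removal_schedule`) leaves every other animal's data
byte-identical.

### Why the default wells are shallow and wide

The default territory well has width 300 m and depth $c_0^2$, giving a
positional relaxation time of roughly 100 minutes and a stationary spread
of roughly 200 m for a typical animal — a realistic nightly range. This
choice matters for estimator validity: displacements sampled every 20–60
minutes remain informative about $c$ (the sampling interval is not long
relative to relaxation, so $\hat c \propto c$ with only a small common
shrinkage). Very deep wells would pin every animal to a quasi-stationary
cloud whose spread — not $c$ — determines observed displacements, and
because a Gaussian well's pull dies beyond a few widths, individuals with
large random intercepts would escape entirely and roam, breaking the
proportionality in a heterogeneous way. When the object of study is
*metastability* rather than diffusion recovery, deep wells are exactly what
is wanted, and the tests use `well_depth = 20 * base_c^2`, `well_width =
200`, a smaller individual spread and a finer integration step (`sim_dt =
0.25`; keep `theta * sim_dt` well below 1, where `theta = depth / width^2`,
for Euler accuracy) to realise rare inter-well transitions.

The generator emulates: multi-group territorial structure, nightly fix
schedules (20/35/60-minute variants including the 30-minute midnight quirk
of 35-minute programmes), timing jitter up to 3 minutes, dropout, gross
outliers, sex/month/individual diffusion structure, and mid-study removal.
It does **not** emulate habitat covariates, roads or landscape geometry,
social interaction forces, state-switching behaviour (resting vs
travelling), or autocorrelated GPS error — so green tests certify the
estimators under the model's own assumptions, not robustness to every
feature of field data.

# Cleaning raw fixes

`clean_fixes()` applies the stages in a fixed order — quality, speed, jump,
snap, split, shift, interpolate — and records per-stage counts in an audit
table (written as JSON lines by `write_audit_log()`).

* **Quality** (`filter_quality`): drop fixes with fewer than 4 satellites
  or dilution of precision above 4; fixes lacking the metadata pass.
  Boundaries are inclusive (`n_sats = 4`, `dop = 4` are kept).
* **Speed** (`filter_speed`): walking the series in time order, any fix
  implying more than 26.2 m min^−1^ from the last surviving fix is dropped
  and scanning resumes from that survivor. Dropping the *later* fix is a
  package decision; the alternative (dropping the earlier) differs only for
  the first fix of an excursion. The filter's output has no offending pair,
  so it is idempotent.
* **Jump** (`filter_jump`): removes lone out-and-back spikes — middle fixes
  with legs summing past 1500 m over two consecutive steps, both legs
  substantial (> 375 m), neighbours mutually close (return distance under
  half the shorter leg). The three thresholds operationalise "a single
  biologically unrealistic excursion"; passes repeat until no spike
  remains.
* **Snap** (`snap_times`): timestamps move to the nearest programmed slot
  (ties round down); displacements over 3 minutes (configurable) discard
  the fix, mirroring the exclusion of fixes that fail to register near
  their appointed time; duplicates per slot collapse to the first.
* **Split** (`split_periods`): a gap above 7 days (the package default; no
  canonical value exists) starts a new monitoring period, so one animal can
  contribute several independent series.
* **Shift** (`shift_origin`): per-site translation to a (0,0) base — an
  exact isometry, so distances, estimators and areas are unaffected.
* **Interpolate** (`interpolate_uniform`): linear interpolation inside
  nights only, onto an exact grid of step `dt`; original fixes are kept
  bit-for-bit and flagged, so removing interpolated rows recovers the
  input exactly. Pairs separated by more than `night_gap` (default 120 min,
  the daytime rest gap) are never bridged; they delimit `segment_id`s.
  An interval that is not an integer multiple of `dt` is an error by
  default; `on_indivisible = "break"` instead starts a new segment, which
  is the practical treatment of the 30-minute midnight interval of
  35-minute schedules resampled at 17.5 minutes. Resampling hourly data at
  20 minutes makes the interpolated fraction $(2(n-1))/(3n-2) \to 2/3$ —
  two-thirds of such a dataset is inferred, which should temper
  interpretation of fine-scale results derived from it.

Diffusion estimation uses the cleaned *non-interpolated* fixes (the
estimator handles unequal intervals); the Koopman analysis uses the
interpolated fixes (EDMD requires exactly uniform lags).

# Diffusion estimation and the mixed model

`estimate_c()` implements the finite-difference (Kramers–Moyal) estimator

$$\hat c^2 = \frac{1}{2 n_{\text{pairs}}} \sum_i
  \frac{(x_{i+1}-x_i)^2 + (y_{i+1}-y_i)^2}{\Delta t_i},$$

over within-night consecutive pairs. Exact properties asserted in the test
suite: scale equivariance ($x \mapsto sx \Rightarrow \hat c \mapsto s\hat
c$), the time-unit contract (relabelling minutes as half-minutes multiplies
$\hat c$ by $\sqrt2$), consistency on zero-drift simulations (within 2% at
$m = 5\times10^4$), and the direction of drift bias — during relaxation
into a steep well the $b^2\,dt$ term inflates $\hat c$. Conversely, under
strong confinement sampled at long intervals $\hat c$ shrinks toward the
stationary spread; with the default generator this shrinkage is a small
factor common to all animals, so *ratios* (the quantities the mixed model
estimates) are preserved.

`monthly_estimates()` produces one estimate per animal-month with at least
11 fixes ("ten or fewer" are excluded as too unstable); a pair spanning a
month boundary belongs to the month of its earlier fix. `lognormality_check()`
applies a Shapiro–Wilk test to $\log c$ — diffusion constants are
empirically log-normal, which motivates the log link.

`fit_glmm()` delegates to `glmmTMB` with a normal response and log link:
fixed month (reference January) and sex (reference male) effects, a random
intercept for animals within site, and optionally per-site random slopes
for capture year. The package deliberately does **not** chase numerical
agreement with any particular penalised-likelihood implementation —
penalisation details are solver-specific — and instead validates by
parameter recovery: across replicate synthetic studies the 95% Wald CI for
a known sex effect covers the truth at the nominal rate. Reported p-values
are the fitter's Wald z-tests. Degenerate designs (one site, one capture
year) reduce the random structure with a warning; singular fits and
convergence failures are flagged, never silent. `effect_multiplier()` is
`exp(·)`: a coefficient of 0.106 is a multiplier of 1.112, and −0.152 of
0.859, with rounding left to presentation. `compare_models()` ranks fits on
identical data by AIC, reporting BIC alongside and flagging ranking
disagreements rather than resolving them.

One caveat is worth stating: the gaussian log-link likelihood assumes
additive homoscedastic error around a multiplicative mean, while the
generator's heterogeneity is multiplicative. Coefficients remain consistent
(the mean structure is correct), but single-study estimates are noisier
than their nominal SEs suggest when individual spread is large; the
acceptance script therefore averages the recovered sex coefficient over 12
replicate studies.

# Koopman analysis (EDMD / Ulam)

The Koopman operator $\mathcal K_\tau$ advances observables:
$[\mathcal K_\tau \psi](x) = E[\psi(F_\tau(x))]$. Its eigenvalues near 1
encode the slow dynamics; each metastable region — a territory the process
rarely leaves — contributes one near-unit eigenvalue, and the corresponding
eigenfunctions are nearly constant on the region.

The finite-dimensional approximation follows the standard EDMD recipe with
an indicator dictionary:

1. **Grid** (`build_grid`): boxes of approximately 100 m; the count per
   axis is the span divided by the target edge, rounded to an integer, so
   edges are exactly `span/n`. Boxes are half-open with a closed final box.
   The dictionary is restricted to *occupied* boxes — empty boxes
   contribute zero rows and are dropped. The grid is rebuilt per analysis
   subset (e.g. per capture year), so box sizes vary slightly with the
   domain extent.
2. **Pairs** (`build_pairs`): source/destination matrices concatenated
   across track segments, first-to-penultimate against second-to-last; no
   pair crosses a segment boundary or an overnight gap, so every pair is
   separated by exactly $\tau$ = the interpolation step (17.5 min for
   35-minute schedules, 20 min otherwise). Mixed steps are an error.
3. **Operator** (`estimate_koopman`): the least-squares solution
   $K^\top = \Psi_{Y'}\Psi_Y^+$, computed through the Gram matrices
   $A = \Psi_{Y'}\Psi_Y^\top$, $G = \Psi_Y\Psi_Y^\top$ and the
   Moore–Penrose pseudoinverse. With indicators this *is* Ulam's method,
   and the package keeps an independent brute-force
   `transition_count_oracle()` (count transitions, normalise rows); the
   central invariant of the module — asserted over hundreds of random pair
   sets — is entrywise agreement within $10^{-8}$. Boxes occupied only as
   destinations have no outgoing data; both routes make them absorbing
   (unit diagonal) so $K$ stays row-stochastic, the one convention this
   package adds where the theory is silent.
4. **Spectrum** (`spectral_decompose`): full eigendecomposition, sorted by
   descending real part. Row-stochasticity guarantees $\lambda_1 = 1$ with
   a constant eigenfunction (the reported eigenvector is constant whenever
   $\lambda_1$ is simple; with several absorbing components the unit
   eigenspace has higher dimension and any basis is valid). Near-reversible
   dynamics give near-real spectra; imaginary parts are retained and
   printed when non-negligible, and real parts are used for sorting and
   clustering.
5. **Gap** (`spectral_gap`): the number of metastable states is the first
   $i$ with $\lambda_i - \lambda_{i+1} > \delta$ (default $\delta = 0.05$,
   a package default — small enough to respect genuine near-degeneracies,
   large enough to ignore sampling noise), searched up to `n_max`. With no
   such drop, the fall-back takes the largest successive difference within
   the first `n_max` (logged via a message). Differences are rounded to 10
   decimals so exact ties resolve to the first index deterministically.
6. **Clusters** (`cluster_metastable`): k-means (seeded, 10 restarts) on
   the real parts of the first $N$ eigenfunctions evaluated per occupied
   box — the trivial constant eigenfunction included, which is harmless (a
   constant feature) and keeps the feature count equal to $N$. Clustering
   operates on boxes, not raw fixes: eigenfunctions are piecewise constant
   on boxes, so fix-level clustering would differ only by occupancy
   weighting. Labels propagate to fixes through box membership
   (`label_fixes`).

On a block-diagonal operator ($B$ disconnected components) the package
recovers exactly $B$ unit eigenvalues and `cluster_metastable` with $N = B$
reproduces the blocks — asserted in the tests, along with recovery of a
four-well study: four near-unit eigenvalues, $N = 4$ from the gap, and
complete agreement between box labels and nearest-well truth. A
quantitative oracle pins the spectrum itself: for an Ornstein–Uhlenbeck
process with rate $\theta$ observed at lag $\tau$, the second Koopman
eigenvalue is $e^{-\theta\tau}$; a finely discretised long trajectory
reproduces it within a fraction of a percent (the test allows 5% for
discretisation and sampling error).

# Territory summaries

`convex_hull_area()` computes the convex hull (via `chull`) and the
shoelace area in km². Fewer than three distinct or non-collinear points
give a zero-area hull with a warning — sparse clusters are reported, not
dropped. `summarise_partition()` tabulates, per subset and pooled, the
number of clusters against the number of social groups and the mean (SD)
hull areas of each; group home ranges are hulls of all member fixes,
mirroring how field home ranges are drawn from raw movement data. Pooled
("Total") rows use the pooled fixes under a single grid. Hulls serialise to
GeoJSON (`export_overlay`) in planar metre coordinates with a `role`
property distinguishing cluster from group polygons.

# Pipeline and reproducibility

`run_config()` validates every tunable once, eagerly (thresholds positive,
`dt` dividing the fix interval, jitter below half the interval) and
round-trips through JSON. `run_pipeline()` executes simulate → clean →
diffusion → glmm → koopman → report, writes each intermediate artifact as
CSV/JSON, and emits a manifest with per-stage record counts, timings and
MD5 checksums of every output; identical configuration and seed give
identical checksums. A failing stage aborts naming the stage. Per-year
analyses are subset loops over one cleaned dataset, not separate cleaning
runs.

# Problem sizes and numerical choices

The test suite and acceptance script run at deliberately modest sizes
chosen to exercise every code path with tight Monte-Carlo error: studies of
2–4 groups × 3–6 animals × 2 months, zero-drift consistency at
$5\times10^4$ steps, OU spectra from $2\times10^5$-step series over ~60
boxes, and 12–20 replicate fits for recovery/coverage checks. Determinism
contracts (fixed seeds ⇒ byte-identical tables and checksums) are asserted
throughout. Known numerical conventions: Euler–Maruyama requires
`theta * sim_dt` well below 1; eigen-decomposition of the non-symmetric $K$
may return complex pairs (real parts used, imaginary magnitudes reported);
k-means requires at least $N$ distinct feature rows, which is guaranteed
whenever $N$ does not exceed the number of occupied boxes with distinct
eigenfunction values.

# Known limitations

* Linear interpolation shortens paths; distances and hence $c$ are
  underestimated on coarse schedules, and heavily interpolated datasets
  (hourly → 20 min) are two-thirds inferred.
* The speed/jump filters are greedy heuristics; a genuine fast excursion
  adjacent to missing data can survive (if the implied speed over a long
  gap is modest) or an extreme real movement can be removed.
* The gaussian log-link model underweights nothing but assumes
  homoscedastic additive error; with strongly multiplicative noise its SEs
  are approximate (see above).
* EDMD with an indicator dictionary estimates a Markov model at lag τ; it
  cannot resolve dynamics faster than τ, and box occupancy — not geometry —
  defines the dictionary, so sparsely visited corridors can attach to
  either neighbouring cluster.
* Kalman-filter EDMD for genuinely non-uniform series is out of scope, as
  are anisotropic or state-dependent diffusion, coordinate-system
  transformations (inputs are assumed already in metric projected
  coordinates), and utilisation-distribution home ranges.
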