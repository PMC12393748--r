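test_that("drift is the negative potential gradient with the expected symmetries", {
  pf <- potential_field(c(0, 0), depths = 50, widths = 150)
  expect_equal(drift_at(pf, c(0, 0)), matrix(0, 1, 2))
  # east of a single well the drift points west
  b <- drift_at(pf, c(200, 0))
  expect_lt(b[1, 1], 0)
  expect_equal(b[1, 2], 0)
  # two equal wells cancel at the midpoint
  pf2 <- potential_field(rbind(c(-500, 0), c(500, 0)), depths = 50, widths = 150)
  expect_equal(drift_at(pf2, c(0, 0)), matrix(0, 1, 2), tolerance = 1e-12)
  # numerical gradient check at a generic point
  p <- c(130, -70); h <- 1e-4
  num <- -c(potential_at(pf, p + c(h, 0)) - potential_at(pf, p - c(h, 0)),
            potential_at(pf, p + c(0, h)) - potential_at(pf, p - c(0, h))) / (2 * h)
  expect_equal(as.numeric(drift_at(pf, p)), num, tolerance = 1e-6)
})

test_that("potential field rejects invalid wells", {
  expect_error(potential_field(c(0, 0), depths = 10, widths = 0), "positive")
  expect_error(potential_field(c(0, 0), depths = -1, widths = 10), "non-negative")
  expect_error(potential_field(cbind(1, 2, 3), depths = 1, widths = 1), "two columns")
})

test_that("simulate_sde is deterministic and degenerates correctly", {
  pf <- flat_field()
  tr0 <- simulate_sde(pf, c = 0, x0 = c(3, 4), dt = 1, n_steps = 50, seed = 1)
  expect_true(all(tr0$x == 3) && all(tr0$y == 4))  # no noise, no drift
  tr1 <- simulate_sde(pf, c = 7, x0 = c(0, 0), dt = 2, n_steps = 100, seed = 9)
  tr2 <- simulate_sde(pf, c = 7, x0 = c(0, 0), dt = 2, n_steps = 100, seed = 9)
  expect_identical(tr1, tr2)
  expect_equal(diff(tr1$t_min), rep(2, 100))
  expect_error(simulate_sde(pf, c = 1, x0 = c(0, 0), dt = 0, n_steps = 5), "dt")
})

test_that("zero-drift displacement follows the Brownian mean-square law", {
  # E|X_t - X_0|^2 = 2 c^2 t for isotropic 2-D Brownian motion; windows of a
  # long trajectory serve as independent replicates (independent increments)
  pf <- flat_field(); cc <- 5; L <- 100
  tr <- simulate_sde(pf, c = cc, x0 = c(0, 0), dt = 1, n_steps = 1e5, seed = 4)
  i0 <- seq(1, 1e5 - L, by = L)
  d2 <- (tr$x[i0 + L] - tr$x[i0])^2 + (tr$y[i0 + L] - tr$y[i0])^2
  se <- sd(d2) / sqrt(length(d2))
  expect_lt(abs(mean(d2) - 2 * cc^2 * L), 3 * se)
})

test_that("a steep well reproduces the OU stationary variance", {
  # near its minimum a Gaussian well of depth d, width w behaves as a
  # quadratic potential with curvature theta = d / w^2, so the stationary
  # per-coordinate variance is c^2 / (2 theta)
  theta <- 0.1; w <- 100; d <- theta * w^2; cc <- 5
  pf <- potential_field(c(0, 0), depths = d, widths = w)
  tr <- simulate_sde(pf, c = cc, x0 = c(0, 0), dt = 0.05, n_steps = 2e5, seed = 12)
  xs <- tr$x[-(1:2e4)]  # burn-in
  expect_equal(stats::var(xs), cc^2 / (2 * theta), tolerance = 0.15)
})

test_that("the observation schedule reproduces nightly fix programmes", {
  # 20:00-04:00 at 35 min: 14 slots with one 30-min interval at midnight
  sch <- observation_schedule("20:00", "04:00", 35, jitter_max = 0,
                              dropout_prob = 0, outlier_prob = 0)
  slots <- metamove:::schedule_slots(sch)
  expect_length(slots, 14)
  pf <- flat_field()
  tr <- simulate_sde(pf, c = 1, x0 = c(0, 0), dt = 0.5, n_steps = 2 * 2880, seed = 2)
  fx <- observe(tr, sch, seed = 5)
  expect_equal(nrow(fx), 28)  # two full nights
  per_night <- diff(sort(as.numeric(fx$timestamp) / 60))
  expect_true(any(abs(per_night - 30) < 1e-9))   # midnight boundary interval
  expect_true(all(per_night[per_night < 100] %in% c(30, 35)))
})

test_that("identity observation returns exact trajectory samples and full dropout none", {
  sch <- observation_schedule("20:00", "04:00", 35, jitter_max = 0,
                              dropout_prob = 0, outlier_prob = 0)
  pf <- flat_field()
  tr <- simulate_sde(pf, c = 3, x0 = c(0, 0), dt = 0.5, n_steps = 2880, seed = 8)
  fx <- observe(tr, sch, seed = 1)
  idx <- match(round(as.numeric(difftime(fx$timestamp, attr(tr, "start"),
                                         units = "mins")) / 0.5) + 1L,
               seq_len(nrow(tr)))
  expect_equal(fx$x_m, tr$x[idx])
  expect_equal(fx$y_m, tr$y[idx])
  sch1 <- observation_schedule("20:00", "04:00", 35, dropout_prob = 1)
  expect_equal(nrow(observe(tr, sch1, seed = 1)), 0L)
})

test_that("schedule validation enforces jitter and probability bounds", {
  expect_error(observation_schedule(fix_interval = 20, jitter_max = 10), "jitter")
  expect_error(observation_schedule(dropout_prob = 1.2), "probabilities")
  expect_error(observation_schedule("25:00", "04:00", 35), "HH:MM")
})

test_that("generate_study applies the sex multiplier exactly and is reproducible", {
  st <- generate_study(n_groups = 1, badgers_per_group = 2, months = 1,
                       seed = 3, intercept_sd = 0,
                       schedule = observation_schedule("21:00", "04:00", 60))
  tr <- st$truth
  cm <- tr$c_true[tr$sex == "male"]
  cf <- tr$c_true[tr$sex == "female"]
  expect_equal(cf / cm, exp(-0.152))
  # byte-identical reruns
  st2 <- generate_study(n_groups = 1, badgers_per_group = 2, months = 1,
                        seed = 3, intercept_sd = 0,
                        schedule = observation_schedule("21:00", "04:00", 60))
  expect_identical(st, st2)
})

test_that("removing one animal leaves the others' streams untouched", {
  sch <- observation_schedule("21:00", "04:00", 60)
  full <- generate_study(n_groups = 1, badgers_per_group = 3, months = 1,
                         seed = 6, schedule = sch)
  cut_at <- t_base + 10 * 24 * 60 * 60
  culled <- generate_study(n_groups = 1, badgers_per_group = 3, months = 1,
                           seed = 6, schedule = sch,
                           removal_schedule = data.frame(animal_id = "B002",
                                                         time = cut_at))
  expect_identical(strip_rn(full$fixes[full$fixes$animal_id != "B002", ]),
                   strip_rn(culled$fixes[culled$fixes$animal_id != "B002", ]))
  kept <- culled$fixes[culled$fixes$animal_id == "B002", ]
  expect_true(all(kept$timestamp < cut_at))
})

test_that("small diffusion keeps animals inside their own territory", {
  # metastability premise: with wells far apart relative to their width and
  # small c, essentially all true positions stay within 3 widths of the well
  st <- generate_study(n_groups = 2, badgers_per_group = 2, months = 1,
                       seed = 5, base_c = 8, intercept_sd = 0,
                       well_spacing = 3000, well_width = 200,
                       well_depth = 20 * 64,
                       schedule = observation_schedule("18:00", "06:00", 20,
                                                       outlier_prob = 0))
  m <- merge(st$fixes, unique(st$truth[c("animal_id", "well_x", "well_y")]),
             by = "animal_id")
  r <- sqrt((m$x_m - m$well_x)^2 + (m$y_m - m$well_y)^2)
  expect_gte(mean(r < 3 * 200), 0.99)
})

test_that("fix tables round-trip through CSV", {
  st <- generate_study(n_groups = 1, badgers_per_group = 1, months = 1,
                       seed = 2, schedule = observation_schedule("21:00", "04:00", 60))
  p <- withr::local_tempfile(fileext = ".csv")
  write_fix_csv(st$fixes, p)
  back <- read_fix_csv(p)
  expect_equal(back$timestamp, st$fixes$timestamp, tolerance = 1e-6)
  expect_equal(back$x_m, st$fixes$x_m, tolerance = 1e-9)
  expect_equal(back$animal_id, st$fixes$animal_id)
})
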