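#' Simulate movement from the SDE model
#'
#' Integrates the movement model
#' \deqn{dX_t = b(X_t)\,dt + c\,dW_t}
#' by the Euler--Maruyama scheme
#' \eqn{X_{k+1} = X_k + b(X_k)\,dt + c\sqrt{dt}\,Z_k}, with \eqn{Z_k}
#' standard bivariate normal, drift \eqn{b = -\nabla U} from a
#' [potential_field()], and isotropic diffusion \eqn{\sigma = cI}.
#' Time is measured in minutes throughout, so `c` carries units
#' m·min^(-1/2) and estimates from observed displacements need no unit
#' conversion.
#'
#' @param field a [potential_field()].
#' @param c diffusion constant (m·min^(-1/2), `>= 0`); may be a vector, one
#'   value per step, for piecewise schedules.
#' @param x0 length-2 numeric start position (m).
#' @param dt integration step (minutes, `> 0`).
#' @param n_steps number of steps (`>= 1`).
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used (so callers can manage their own streams).
#' @param start POSIXct absolute time of the first position (UTC); carried
#'   as an attribute so the trajectory can be placed on a clock for the
#'   observation model.
#' @return A `true_trajectory`: data frame with columns `t_min` (minutes from
#'   `start`), `x`, `y`; attributes `dt` and `start`.
#' @seealso [observe()], [generate_study()]
#' @examples
#' pf <- potential_field(c(0, 0), depths = 50, widths = 150)
#' tr <- simulate_sde(pf, c = 5, x0 = c(0, 0), dt = 1, n_steps = 100, seed = 1)
#' head(tr)
#' @export
simulate_sde <- function(field, c, x0, dt, n_steps, seed = NULL,
                         start = as.POSIXct("2019-01-01 00:00:00", tz = "UTC")) {
  stopifnot(inherits(field, "potential_field"))
  if (dt <= 0) stop("dt must be positive")
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (any(c < 0)) stop("diffusion constant c must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  xy <- sde_sim_cpp(as.numeric(x0), as.integer(n_steps), as.numeric(dt),
                    as.numeric(c), field$centres, field$depths, field$widths)
  out <- data.frame(t_min = seq(0, by = dt, length.out = n_steps + 1L),
                    x = xy[, 1], y = xy[, 2])
  attr(out, "dt") <- dt
  attr(out, "start") <- start
  class(out) <- c("true_trajectory", "data.frame")
  out
}

#' GPS observation schedule
#'
#' Describes the nightly fix-collection programme of a GPS collar: a clock
#' window (possibly crossing midnight), a nominal fix interval, timing jitter,
#' dropout and outlier rates. Scheduled slot times are anchored to midnight
#' (the collar's internal midnight-to-midnight cycle), so a window such as
#' 20:00--04:00 with a 35-minute interval produces fixes
#' 20:00, 20:35, ..., 23:30, then 00:00, 00:35, ..., giving one 30-minute
#' interval at the midnight boundary.
#'
#' @param window_start,window_end clock times `"HH:MM"`; if `window_start`
#'   is later than `window_end` the window crosses midnight.
#' @param fix_interval nominal interval between fixes (minutes, `> 0`).
#' @param jitter_max maximum recording delay (minutes, `< fix_interval / 2`).
#' @param dropout_prob probability a scheduled fix is missed entirely.
#' @param outlier_prob probability a fix is replaced by a gross position error.
#' @param outlier_range range (m) of the ring in which outliers are placed
#'   around the true position, chosen so that plausible speed/jump filters can
#'   catch them.
#' @return An `observation_schedule` object.
#' @export
observation_schedule <- function(window_start = "20:00", window_end = "04:00",
                                 fix_interval = 35, jitter_max = 3,
                                 dropout_prob = 0.05, outlier_prob = 0.01,
                                 outlier_range = c(2000, 5000)) {
  ws <- parse_clock(window_start)
  we <- parse_clock(window_end)
  if (fix_interval <= 0) stop("fix_interval must be positive")
  if (jitter_max < 0 || jitter_max >= fix_interval / 2)
    stop("jitter_max must be in [0, fix_interval / 2)")
  if (dropout_prob < 0 || dropout_prob > 1 || outlier_prob < 0 || outlier_prob > 1)
    stop("probabilities must lie in [0, 1]")
  structure(list(window_start = ws, window_end = we,
                 fix_interval = fix_interval, jitter_max = jitter_max,
                 dropout_prob = dropout_prob, outlier_prob = outlier_prob,
                 outlier_range = as.numeric(outlier_range)),
            class = "observation_schedule")
}

parse_clock <- function(s) {
  if (is.numeric(s)) return(as.numeric(s))
  p <- as.integer(strsplit(s, ":", fixed = TRUE)[[1]])
  if (length(p) != 2L || anyNA(p) || p[1] > 23 || p[2] > 59)
    stop("clock times must be 'HH:MM'")
  p[1] * 60 + p[2]
}

# Minutes-of-day of the scheduled slots, anchored at window_start and
# re-anchored at midnight when the window crosses it.
schedule_slots <- function(sched) {
  ws <- sched$window_start; we <- sched$window_end; iv <- sched$fix_interval
  if (ws <= we) {
    seq(ws, we, by = iv)
  } else {
    c(seq(ws, 1439.999, by = iv), seq(0, we, by = iv))
  }
}

#' Observe a trajectory through a GPS collar
#'
#' Applies the observation process to a true trajectory: samples positions at
#' the scheduled slot times inside the nightly window, delays recorded
#' timestamps by uniform jitter (late fixes, up to `jitter_max` minutes),
#' drops each fix independently with `dropout_prob`, replaces fixes with
#' distant outliers with `outlier_prob`, and attaches synthetic quality
#' metadata (`n_sats`, `dop`).
#'
#' @param traj a `true_trajectory` from [simulate_sde()]; its step `dt` must
#'   divide the fix interval.
#' @param sched an [observation_schedule()].
#' @param seed optional integer seed (`NULL` = use current RNG stream).
#' @param animal_id,group_id,sex,site identifiers copied into the fix table.
#' @return Fix table: data frame with columns `animal_id`, `group_id`, `sex`,
#'   `site`, `timestamp` (POSIXct UTC), `x_m`, `y_m`, `n_sats`, `dop`.
#' @export
observe <- function(traj, sched, seed = NULL,
                    animal_id = "A1", group_id = "G1", sex = "male", site = "S1") {
  stopifnot(inherits(traj, "true_trajectory"), inherits(sched, "observation_schedule"))
  dt <- attr(traj, "dt")
  if (abs(sched$fix_interval / dt - round(sched$fix_interval / dt)) > 1e-8)
    stop("trajectory step dt must divide the fix interval")
  if (!is.null(seed)) set.seed(as.integer(seed))
  start <- attr(traj, "start")
  span_min <- traj$t_min[nrow(traj)]

  slots <- schedule_slots(sched)
  day0 <- as.POSIXct(trunc(start, "days"), tz = "UTC")
  ndays <- ceiling(as.numeric(difftime(start, day0, units = "mins")) + span_min) %/% 1440 + 1L
  slot_min <- as.numeric(outer(slots, (seq_len(ndays) - 1L) * 1440, "+"))
  # offset of trajectory start within its day
  off <- as.numeric(difftime(start, day0, units = "mins"))
  t_sched <- sort(slot_min[slot_min >= off & slot_min < off + span_min]) - off
  if (length(t_sched) == 0L) return(empty_fix_table())

  n <- length(t_sched)
  jit <- if (sched$jitter_max > 0) runif(n, 0, sched$jitter_max) else numeric(n)
  t_rec <- t_sched + jit
  idx <- pmin(nrow(traj), pmax(1L, round(t_rec / dt) + 1L))
  x <- traj$x[idx]; y <- traj$y[idx]

  is_out <- runif(n) < sched$outlier_prob
  if (any(is_out)) {
    r <- runif(sum(is_out), sched$outlier_range[1], sched$outlier_range[2])
    th <- runif(sum(is_out), 0, 2 * pi)
    x[is_out] <- x[is_out] + r * cos(th)
    y[is_out] <- y[is_out] + r * sin(th)
  }
  n_sats <- 4L + stats::rbinom(n, 8L, 0.55)
  bad <- runif(n) < 0.04
  n_sats[bad] <- sample(2:3, sum(bad), replace = TRUE)
  dop <- round(1 + stats::rexp(n, rate = 1), 2)
  keep <- runif(n) >= sched$dropout_prob
  if (!any(keep)) return(empty_fix_table())

  data.frame(animal_id = animal_id, group_id = group_id, sex = sex, site = site,
             timestamp = start + t_rec[keep] * 60,
             x_m = x[keep], y_m = y[keep],
             n_sats = n_sats[keep], dop = dop[keep],
             stringsAsFactors = FALSE)
}

empty_fix_table <- function() {
  data.frame(animal_id = character(), group_id = character(), sex = character(),
             site = character(),
             timestamp = as.POSIXct(character(), tz = "UTC"),
             x_m = numeric(), y_m = numeric(),
             n_sats = integer(), dop = numeric(), stringsAsFactors = FALSE)
}

#' Monthly fixed-effect multipliers used by the study generator
#'
#' Log-scale month effects on the diffusion constant (reference January),
#' matching the seasonal pattern reported for badgers: elevated movement in
#' late winter/early spring, reduced movement from June to December.
#' @return Named numeric vector of length 12.
#' @export
default_month_effects <- function() {
  c(Jan = 0, Feb = 0.106, Mar = 0.050, Apr = 0.036, May = 0.006,
    Jun = -0.106, Jul = -0.069, Aug = -0.116, Sep = -0.236,
    Oct = -0.370, Nov = -0.442, Dec = -0.290)
}

#' Generate a ground-truthed synthetic telemetry study
#'
#' Simulates a multi-group territorial population: one Gaussian potential well
#' per social group, individuals attached to their group's well, and
#' individual diffusion constants
#' \deqn{c_{im} = c_0 \exp(\beta_{month(m)} + \beta_{sex} 1[female] + a_i),}
#' with \eqn{a_i \sim N(0, \sigma_a^2)} an individual random intercept.
#' Each individual's trajectory is integrated with [simulate_sde()] and
#' observed through the GPS schedule with [observe()]. One pseudo-random
#' stream is derived per individual from `(seed, individual index)`, so
#' removing one animal leaves all others' data unchanged.
#'
#' @param n_groups number of social groups (one well each, laid out on a
#'   square lattice with spacing `well_spacing`).
#' @param badgers_per_group individuals per group (sexes alternate).
#' @param months number of consecutive calendar months simulated, starting at
#'   `start`.
#' @param sex_effect log-scale female effect on `c` (reference male).
#' @param month_effects 12 log-scale calendar-month effects (reference
#'   January); see [default_month_effects()].
#' @param base_c baseline diffusion constant (m·min^(-1/2)) for a male in
#'   January with zero random intercept.
#' @param removal_schedule optional data frame `animal_id`, `time` (POSIXct):
#'   fixes at or after `time` are discarded for that animal (culling-style
#'   removal mid-study).
#' @param seed integer master seed.
#' @param schedule an [observation_schedule()].
#' @param start first day of the first simulated month (date or POSIXct).
#' @param site_id site label written to the fix table.
#' @param well_spacing lattice spacing between well centres (m).
#' @param well_width common well width (m).
#' @param well_depth common well depth (energy units). The default,
#'   `base_c^2`, gives a realistic nightly range: positional relaxation over
#'   about 100 minutes and a stationary spread of roughly 200 m around the
#'   sett for a typical individual, so displacement sampling at 20--60 minute
#'   fix intervals remains informative about `c`. Pass a larger multiple of
#'   `base_c^2` (and a smaller `sim_dt`) for strongly metastable dynamics
#'   with rare inter-well transitions.
#' @param intercept_sd standard deviation of the individual random intercept
#'   on the log scale.
#' @param sim_dt integration step of the underlying SDE (minutes).
#' @return List with elements `fixes` (fix table, see [observe()]) and
#'   `truth` (data frame `animal_id`, `group_id`, `sex`, `month`, `year`,
#'   `c_true`, `well_x`, `well_y`, one row per animal-month).
#' @examples
#' \donttest{
#' st <- generate_study(n_groups = 2, badgers_per_group = 2, months = 1, seed = 1)
#' head(st$fixes); head(st$truth)
#' }
#' @export
generate_study <- function(n_groups, badgers_per_group, months,
                           sex_effect = -0.152,
                           month_effects = default_month_effects(),
                           base_c = exp(3.397),
                           removal_schedule = NULL,
                           seed = 1,
                           schedule = observation_schedule(),
                           start = "2019-01-01",
                           site_id = "S1",
                           well_spacing = 1500, well_width = 300,
                           well_depth = NULL,
                           intercept_sd = sqrt(0.229),
                           sim_dt = 1) {
  stopifnot(n_groups >= 1, badgers_per_group >= 1, months >= 1)
  if (length(month_effects) != 12L) stop("month_effects must have 12 values")
  if (is.null(well_depth)) well_depth <- base_c^2
  start <- as.POSIXct(paste(as.Date(start), "00:00:00"), tz = "UTC")

  ncw <- ceiling(sqrt(n_groups))
  wells <- cbind(((seq_len(n_groups) - 1L) %% ncw) * well_spacing,
                 ((seq_len(n_groups) - 1L) %/% ncw) * well_spacing)
  field <- potential_field(wells, depths = well_depth, widths = well_width)

  # calendar month boundaries
  m0 <- as.POSIXlt(start)
  month_starts <- as.POSIXct(vapply(seq_len(months + 1L), function(k) {
    mm <- m0$mon + (k - 1L)
    sprintf("%04d-%02d-01 00:00:00", 1900L + m0$year + mm %/% 12L, mm %% 12L + 1L)
  }, character(1)), tz = "UTC")
  cal_month <- as.POSIXlt(month_starts[seq_len(months)])$mon + 1L
  cal_year <- 1900L + as.POSIXlt(month_starts[seq_len(months)])$year

  n_anim <- n_groups * badgers_per_group
  ids <- sprintf("B%03d", seq_len(n_anim))
  grp <- sprintf("G%02d", rep(seq_len(n_groups), each = badgers_per_group))
  sex <- rep_len(c("male", "female"), badgers_per_group)[
    rep(seq_len(badgers_per_group), times = n_groups)]

  fixes <- list(); truth <- list()
  for (i in seq_len(n_anim)) {
    set.seed(as.integer((as.numeric(seed) * 100003 + i) %% 2147483647))
    a_i <- rnorm(1, 0, intercept_sd)
    gidx <- (i - 1L) %/% badgers_per_group + 1L
    x0 <- wells[gidx, ]
    c_m <- base_c * exp(month_effects[cal_month] +
                          sex_effect * (sex[i] == "female") + a_i)
    anim_fix <- list()
    for (m in seq_len(months)) {
      span <- as.numeric(difftime(month_starts[m + 1L], month_starts[m], units = "mins"))
      n_steps <- as.integer(round(span / sim_dt))
      tr <- simulate_sde(field, c = c_m[m], x0 = x0, dt = sim_dt,
                         n_steps = n_steps, seed = NULL, start = month_starts[m])
      x0 <- c(tr$x[nrow(tr)], tr$y[nrow(tr)])
      anim_fix[[m]] <- observe(tr, schedule, seed = NULL,
                               animal_id = ids[i], group_id = grp[i],
                               sex = sex[i], site = site_id)
    }
    fixes[[i]] <- do.call(rbind, anim_fix)
    truth[[i]] <- data.frame(animal_id = ids[i], group_id = grp[i], sex = sex[i],
                             month = cal_month, year = cal_year,
                             c_true = unname(c_m),
                             well_x = wells[gidx, 1], well_y = wells[gidx, 2],
                             stringsAsFactors = FALSE)
  }
  fixes <- do.call(rbind, fixes)
  truth <- do.call(rbind, truth)
  rownames(fixes) <- rownames(truth) <- NULL

  if (!is.null(removal_schedule)) {
    stopifnot(all(c("animal_id", "time") %in% names(removal_schedule)))
    for (r in seq_len(nrow(removal_schedule))) {
      drop <- fixes$animal_id == removal_schedule$animal_id[r] &
        fixes$timestamp >= removal_schedule$time[r]
      fixes <- fixes[!drop, , drop = FALSE]
    }
    rownames(fixes) <- NULL
  }
  list(fixes = fixes, truth = truth, field = field)
}

#' Read and write fix tables as CSV
#'
#' Fix tables are exchanged as plain CSV with ISO-8601 timestamps (UTC) and
#' projected metric coordinates.
#'
#' @param fixes a fix table (see [observe()]).
#' @param path file path.
#' @return `read_fix_csv` returns the fix table with `timestamp` parsed to
#'   POSIXct; `write_fix_csv` returns `path` invisibly.
#' @export
write_fix_csv <- function(fixes, path) {
  out <- fixes
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%OS2Z", tz = "UTC")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fix_csv
#' @export
read_fix_csv <- function(path) {
  fx <- read.csv(path, stringsAsFactors = FALSE)
  fx$timestamp <- as.POSIXct(fx$timestamp, format = "%Y-%m-%dT%H:%M:%OS",
                             tz = "UTC")
  fx
}
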