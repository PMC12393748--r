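# End-to-end orchestration: simulate/load -> clean -> diffusion -> mixed
# model -> Koopman/EDMD -> territory report, with a reproducible manifest.

#' Build and validate a pipeline configuration
#'
#' Collects every tunable of the analysis in one validated object that
#' round-trips losslessly through JSON ([write_config()] / [read_config()]).
#' Exactly one input source is used: `input_csv` (a fix table on disk) or
#' `sim` (arguments for [generate_study()]).
#'
#' @param input_csv path to a fix-table CSV, or `NULL` to simulate.
#' @param sim named list of arguments for [generate_study()] (used when
#'   `input_csv` is `NULL`).
#' @param window_start,window_end,fix_interval,jitter_max,dropout_prob,outlier_prob
#'   observation schedule, see [observation_schedule()].
#' @param dt interpolation step (minutes); must divide `fix_interval`.
#'   Defaults to `fix_interval` when that is at most 20 minutes (native
#'   resolution) and to `fix_interval / 2` otherwise.
#' @param min_sats,max_dop,max_speed,max_two_step,snap_tol,max_gap_min,night_gap
#'   cleaning thresholds, see [clean_fixes()].
#' @param target_edge box edge for the EDMD grid (m).
#' @param delta,n_max spectral-gap parameters, see [spectral_gap()].
#' @param kmeans_seed,kmeans_nstart clustering parameters.
#' @param year_slopes include capture-year random slopes in the mixed model?
#' @param by_year also run the Koopman analysis per capture year?
#' @param exclude_animals animal ids dropped before cleaning.
#' @param seed master seed.
#' @param out_dir output directory.
#' @return A validated `run_config` (named list).
#' @export
run_config <- function(input_csv = NULL,
                       sim = list(n_groups = 4, badgers_per_group = 3, months = 2),
                       window_start = "20:00", window_end = "04:00",
                       fix_interval = 35, jitter_max = 3,
                       dropout_prob = 0.05, outlier_prob = 0.01,
                       dt = NULL,
                       min_sats = 4, max_dop = 4, max_speed = 26.2,
                       max_two_step = 1500, snap_tol = 3,
                       max_gap_min = 7 * 24 * 60, night_gap = 120,
                       target_edge = 100, delta = 0.05, n_max = 10,
                       kmeans_seed = 1, kmeans_nstart = 10,
                       year_slopes = FALSE, by_year = FALSE,
                       exclude_animals = NULL,
                       seed = 1, out_dir = tempfile("metamove_run")) {
  if (is.null(dt)) dt <- if (fix_interval <= 20) fix_interval else fix_interval / 2
  cfg <- list(input_csv = input_csv, sim = sim,
              window_start = window_start, window_end = window_end,
              fix_interval = fix_interval, jitter_max = jitter_max,
              dropout_prob = dropout_prob, outlier_prob = outlier_prob,
              dt = dt, min_sats = min_sats, max_dop = max_dop,
              max_speed = max_speed, max_two_step = max_two_step,
              snap_tol = snap_tol, max_gap_min = max_gap_min,
              night_gap = night_gap, target_edge = target_edge,
              delta = delta, n_max = n_max,
              kmeans_seed = kmeans_seed, kmeans_nstart = kmeans_nstart,
              year_slopes = year_slopes, by_year = by_year,
              exclude_animals = exclude_animals,
              seed = seed, out_dir = out_dir)
  validate_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_config <- function(cfg) {
  pos <- c("fix_interval", "dt", "min_sats", "max_dop", "max_speed",
           "max_two_step", "snap_tol", "max_gap_min", "night_gap",
           "target_edge", "delta", "n_max", "kmeans_nstart")
  for (nm in pos)
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] <= 0)
      stop(sprintf("config field '%s' must be a positive scalar", nm))
  k <- cfg$fix_interval / cfg$dt
  if (abs(k - round(k)) > 1e-8)
    stop("interpolation dt must divide the fix interval")
  if (cfg$jitter_max < 0 || cfg$jitter_max >= cfg$fix_interval / 2)
    stop("jitter_max must be in [0, fix_interval / 2)")
  if (is.null(cfg$input_csv) && !all(c("n_groups", "badgers_per_group",
                                       "months") %in% names(cfg$sim)))
    stop("sim must provide n_groups, badgers_per_group and months")
  invisible(cfg)
}

#' Write / read a pipeline configuration as JSON
#'
#' @param cfg a [run_config()].
#' @param path file path.
#' @return `read_config` returns the validated `run_config`; `write_config`
#'   returns `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(raw$sim)) raw$sim <- as.list(raw$sim)
  do.call(run_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in fixed order -- `simulate` (or load), `clean`,
#' `diffusion`, `glmm`, `koopman`, `report` -- writing every intermediate
#' artifact under `cfg$out_dir` and returning a manifest with per-stage
#' record counts, timings and output checksums. Identical configuration and
#' seed give identical outputs. A failing stage aborts with the stage name.
#'
#' @param cfg a [run_config()].
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(cfg) {
  validate_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  sched <- observation_schedule(cfg$window_start, cfg$window_end,
                                cfg$fix_interval, cfg$jitter_max,
                                cfg$dropout_prob, cfg$outlier_prob)
  manifest <- list(package = "metamove",
                   version = as.character(utils::packageVersion("metamove")),
                   seed = cfg$seed, config = unclass(cfg), stages = list())
  env <- new.env(parent = emptyenv())

  stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- c(res,
      list(elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)))
  }
  out <- function(f) file.path(cfg$out_dir, f)

  stage("simulate", function() {
    if (is.null(cfg$input_csv)) {
      sim_args <- cfg$sim
      sim_args$seed <- cfg$seed
      sim_args$schedule <- sched
      st <- do.call(generate_study, sim_args)
      env$fixes <- st$fixes
      env$truth <- st$truth
      write_fix_csv(st$fixes, out("fixes_raw.csv"))
      write.csv(st$truth, out("truth.csv"), row.names = FALSE)
      list(outputs = c("fixes_raw.csv", "truth.csv"), n_records = nrow(st$fixes))
    } else {
      env$fixes <- read_fix_csv(cfg$input_csv)
      env$truth <- NULL
      list(outputs = character(0), n_records = nrow(env$fixes))
    }
  })

  stage("clean", function() {
    cl <- clean_fixes(env$fixes, sched, dt = cfg$dt,
                      min_sats = cfg$min_sats, max_dop = cfg$max_dop,
                      max_speed = cfg$max_speed, max_two_step = cfg$max_two_step,
                      snap_tol = cfg$snap_tol, max_gap_min = cfg$max_gap_min,
                      night_gap = cfg$night_gap,
                      exclude_animals = cfg$exclude_animals)
    env$clean <- cl
    write_fix_csv(cl$fixes, out("fixes_clean.csv"))
    write_audit_log(cl$audit, out("cleaning_audit.jsonl"))
    list(outputs = c("fixes_clean.csv", "cleaning_audit.jsonl"),
         n_records = nrow(cl$fixes))
  })

  stage("diffusion", function() {
    est <- monthly_estimates(env$clean$diffusion_fixes, max_dt = cfg$night_gap)
    env$estimates <- est
    write.csv(est, out("diffusion_estimates.csv"), row.names = FALSE)
    ln <- if (nrow(est) >= 3 && all(est$c > 0)) lognormality_check(est) else NULL
    list(outputs = "diffusion_estimates.csv", n_records = nrow(est),
         lognormal_p = if (is.null(ln)) NA else ln$p_value)
  })

  stage("glmm", function() {
    fit <- fit_glmm(env$estimates,
                    diffusion_model_spec(year_slopes = cfg$year_slopes))
    env$fit <- fit
    export_fit(fit, csv_path = out("glmm_coefficients.csv"),
               json_path = out("glmm_fit.json"))
    list(outputs = c("glmm_coefficients.csv", "glmm_fit.json"),
         n_records = nrow(fit$coefficients), AIC = fit$AIC, BIC = fit$BIC)
  })

  stage("koopman", function() {
    fx <- env$clean$fixes
    grid <- build_grid(fx, target_edge = cfg$target_edge)
    pairs <- build_pairs(fx)
    K <- estimate_koopman(pairs, grid)
    spec <- spectral_decompose(K)
    N <- spectral_gap(spec, delta = cfg$delta, n_max = cfg$n_max)
    part <- cluster_metastable(spec, N, seed = cfg$kmeans_seed,
                               nstart = cfg$kmeans_nstart)
    env$partition <- part
    env$labelled <- label_fixes(part, fx)
    write_koopman_csv(K, out("koopman_matrix.csv"))
    write_eigen_csv(spec, out("koopman_eigenvalues.csv"))
    write_partition_csv(part, out("partition.csv"))
    write_fix_csv(env$labelled, out("fixes_labelled.csv"))
    list(outputs = c("koopman_matrix.csv", "koopman_eigenvalues.csv",
                     "partition.csv", "fixes_labelled.csv"),
         n_records = pairs$n, n_clusters = N,
         gap_method = attr(N, "method"))
  })

  stage("report", function() {
    lab <- env$labelled
    by <- NULL
    if (cfg$by_year && "timestamp" %in% names(lab)) {
      yr <- as.POSIXlt(lab$timestamp)$year + 1900L
      lab$capture_year <- yr - min(yr) + 1L
      by <- "capture_year"
    }
    summ <- summarise_partition(lab, by = by)
    write.csv(summ$table, out("territory_summary.csv"), row.names = FALSE)
    export_overlay(summ$cluster_hulls$Total, summ$group_hulls$Total,
                   out("hull_overlay.geojson"))
    list(outputs = c("territory_summary.csv", "hull_overlay.geojson"),
         n_records = nrow(summ$table))
  })

  files <- sort(unique(unlist(lapply(manifest$stages, `[[`, "outputs"))))
  sums <- tools::md5sum(file.path(cfg$out_dir, files))
  manifest$checksums <- setNames(as.character(sums), files)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE, force = TRUE)
  invisible(manifest)
}
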