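# Cleaning, segmentation and regularisation of raw GPS fix tables.
#
# All functions take and return "fix tables": data frames with at least
# animal_id, timestamp (POSIXct), x_m, y_m; optional n_sats, dop, period_id.
# Filters are idempotent and operate per animal (per monitoring period once
# period_id exists).

grouping_key <- function(fixes) {
  if ("period_id" %in% names(fixes)) fixes$period_id else fixes$animal_id
}

order_fixes <- function(fixes) {
  fixes[order(grouping_key(fixes), fixes$timestamp), , drop = FALSE]
}

dist2d <- function(x1, y1, x2, y2) sqrt((x2 - x1)^2 + (y2 - y1)^2)

#' Quality filter on satellite count and dilution of precision
#'
#' Removes fixes recorded with fewer than `min_sats` satellites or with
#' dilution of precision greater than `max_dop`. Fixes missing a quality
#' field are judged on the fields they do have; fixes lacking both pass
#' unfiltered.
#'
#' @param fixes fix table.
#' @param min_sats minimum satellite count retained (default 4).
#' @param max_dop maximum dilution of precision retained (default 4).
#' @return Filtered fix table.
#' @export
filter_quality <- function(fixes, min_sats = 4, max_dop = 4) {
  if (nrow(fixes) == 0L) return(fixes)
  ns <- if ("n_sats" %in% names(fixes)) fixes$n_sats else rep(NA_real_, nrow(fixes))
  dp <- if ("dop" %in% names(fixes)) fixes$dop else rep(NA_real_, nrow(fixes))
  keep <- (is.na(ns) | ns >= min_sats) & (is.na(dp) | dp <= max_dop)
  out <- fixes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Speed filter on consecutive fixes
#'
#' Scans consecutive fixes of each animal (or monitoring period) in time
#' order and drops any fix implying a straight-line speed above `max_speed`
#' from the last surviving fix; scanning then resumes from that survivor.
#' The default threshold is 26.2 m/min, the fastest sustained badger
#' movement reported in field studies. A fix with non-positive time
#' separation from its surviving predecessor is also dropped.
#'
#' @param fixes fix table.
#' @param max_speed maximum plausible speed (m/min).
#' @return Filtered fix table.
#' @export
filter_speed <- function(fixes, max_speed = 26.2) {
  if (nrow(fixes) == 0L) return(fixes)
  fixes <- order_fixes(fixes)
  key <- grouping_key(fixes)
  keep <- logical(nrow(fixes))
  for (g in split(seq_len(nrow(fixes)), key)) {
    last <- g[1]
    keep[last] <- TRUE
    for (i in g[-1]) {
      dt <- as.numeric(difftime(fixes$timestamp[i], fixes$timestamp[last],
                                units = "mins"))
      d <- dist2d(fixes$x_m[last], fixes$y_m[last], fixes$x_m[i], fixes$y_m[i])
      if (dt > 0 && d / dt <= max_speed) {
        keep[i] <- TRUE
        last <- i
      }
    }
  }
  out <- fixes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Jump filter for lone out-and-back spikes
#'
#' Removes single fixes whose recorded movement over two consecutive
#' intervals is biologically unrealistic: the path out and back exceeds
#' `max_two_step` in total, both legs are substantial, and the neighbouring
#' fixes are mutually close (so deleting the middle fix removes the
#' excursion). Passes repeat until no spike remains, which makes the filter
#' idempotent.
#'
#' @param fixes fix table.
#' @param max_two_step maximum plausible distance (m) travelled over two
#'   consecutive time steps (default 1500).
#' @return Filtered fix table.
#' @export
filter_jump <- function(fixes, max_two_step = 1500) {
  if (nrow(fixes) == 0L) return(fixes)
  fixes <- order_fixes(fixes)
  drop_spikes <- function(idx) {
    repeat {
      n <- length(idx)
      if (n < 3L) return(idx)
      x <- fixes$x_m[idx]; y <- fixes$y_m[idx]
      out <- dist2d(x[1:(n - 2)], y[1:(n - 2)], x[2:(n - 1)], y[2:(n - 1)])
      back <- dist2d(x[2:(n - 1)], y[2:(n - 1)], x[3:n], y[3:n])
      ret <- dist2d(x[1:(n - 2)], y[1:(n - 2)], x[3:n], y[3:n])
      spike <- (out + back > max_two_step) &
        (pmin(out, back) > max_two_step / 4) &
        (ret < 0.5 * pmin(out, back))
      if (!any(spike)) return(idx)
      idx <- idx[-(which(spike)[1] + 1L)]
    }
  }
  keep_idx <- unlist(lapply(split(seq_len(nrow(fixes)), grouping_key(fixes)),
                            drop_spikes), use.names = FALSE)
  out <- fixes[sort(keep_idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Shift coordinates to a (0,0) base
#'
#' Subtracts the per-site minimum easting and northing so all coordinates are
#' non-negative and site locations stay confidential. A pure translation:
#' every pairwise distance is preserved exactly.
#'
#' @param fixes non-empty fix table.
#' @return Fix table with shifted `x_m`, `y_m`.
#' @export
shift_origin <- function(fixes) {
  if (nrow(fixes) == 0L) stop("cannot shift an empty fix table")
  site <- if ("site" %in% names(fixes)) fixes$site else rep("site", nrow(fixes))
  fixes$x_m <- fixes$x_m - ave(fixes$x_m, site, FUN = min)
  fixes$y_m <- fixes$y_m - ave(fixes$y_m, site, FUN = min)
  fixes
}

# Nearest scheduled slot (in minutes from the fix's own midnight, possibly
# borrowing the neighbouring day's slots); ties round down.
snap_to_slots <- function(mod, slots) {
  cand <- c(slots - 1440, slots, slots + 1440)
  vapply(mod, function(m) {
    d <- abs(cand - m)
    hit <- cand[d == min(d)]
    min(hit)  # tie -> earlier slot
  }, numeric(1))
}

#' Snap recorded times to the programmed fix schedule
#'
#' GPS recording can lag the programmed capture time by up to a few minutes.
#' Each timestamp is replaced by the nearest scheduled slot time (ties round
#' down to the earlier slot). Fixes displaced by more than `tol_min` minutes
#' are discarded, and fixes of the same animal collapsing onto one slot are
#' reduced to the first.
#'
#' @param fixes fix table.
#' @param sched an [observation_schedule()] defining the nominal slot grid.
#' @param tol_min maximum allowed snap displacement (minutes, default 3).
#' @return Fix table with snapped timestamps.
#' @export
snap_times <- function(fixes, sched, tol_min = 3) {
  if (nrow(fixes) == 0L) return(fixes)
  stopifnot(inherits(sched, "observation_schedule"))
  fixes <- order_fixes(fixes)
  day0 <- as.POSIXct(trunc(fixes$timestamp, "days"), tz = "UTC")
  mod <- as.numeric(difftime(fixes$timestamp, day0, units = "mins"))
  slot <- snap_to_slots(mod, schedule_slots(sched))
  disp <- abs(slot - mod)
  snapped <- day0 + slot * 60
  keep <- disp <= tol_min
  fixes$timestamp <- snapped
  fixes <- fixes[keep, , drop = FALSE]
  dup <- duplicated(data.frame(grouping_key(fixes), fixes$timestamp))
  out <- fixes[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split fixes into collar monitoring periods
#'
#' Collars lose power or fail for days at a time; a fresh monitoring period
#' (new `period_id`) starts whenever the gap between consecutive fixes of an
#' animal exceeds `max_gap_min`. Downstream steps treat periods as
#' independent series.
#'
#' @param fixes fix table.
#' @param max_gap_min gap (minutes) above which a new period starts;
#'   default 7 days.
#' @return Fix table with a `period_id` column (`"<animal>.p<k>"`).
#' @export
split_periods <- function(fixes, max_gap_min = 7 * 24 * 60) {
  if (nrow(fixes) == 0L) {
    fixes$period_id <- character(0)
    return(fixes)
  }
  fixes <- fixes[order(fixes$animal_id, fixes$timestamp), , drop = FALSE]
  pieces <- lapply(split(seq_len(nrow(fixes)), fixes$animal_id), function(g) {
    gaps <- diff(as.numeric(fixes$timestamp[g])) / 60
    cumsum(c(1L, as.integer(gaps > max_gap_min)))
  })
  idx <- unlist(split(seq_len(nrow(fixes)), fixes$animal_id), use.names = FALSE)
  per <- unlist(pieces, use.names = FALSE)
  fixes$period_id[idx] <- sprintf("%s.p%d", fixes$animal_id[idx], per)
  out <- fixes[order(fixes$period_id, fixes$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Linear interpolation onto a uniform time grid
#'
#' Inserts linearly interpolated fixes so that, within each night, consecutive
#' fixes are exactly `dt` minutes apart, as required by EDMD. Original fixes
#' are preserved exactly and flagged `interpolated = FALSE`. Interpolation is
#' performed only within nights: pairs separated by more than `night_gap`
#' minutes (the daytime rest gap) start a new `segment_id` and are never
#' bridged.
#'
#' @param fixes fix table (typically snapped and split into periods).
#' @param dt target spacing (minutes); must divide every within-night
#'   inter-fix interval. A native-resolution `dt` leaves the data unchanged.
#' @param night_gap gap (minutes) above which a pair is treated as an
#'   overnight break (default 120).
#' @param on_indivisible what to do with a within-night interval that is not
#'   an integer multiple of `dt`: `"error"` (default) aborts naming the
#'   offending pair; `"break"` starts a new segment there (used for schedules
#'   with a boundary quirk, e.g. a 30-minute midnight interval in an otherwise
#'   35-minute programme resampled at 17.5 minutes).
#' @return Fix table with logical `interpolated` and character `segment_id`
#'   columns; within each segment consecutive time differences equal `dt`.
#' @export
interpolate_uniform <- function(fixes, dt, night_gap = 120,
                                on_indivisible = c("error", "break")) {
  on_indivisible <- match.arg(on_indivisible)
  if (dt <= 0) stop("dt must be positive")
  fixes$interpolated <- rep(FALSE, nrow(fixes))
  if (nrow(fixes) == 0L) {
    fixes$segment_id <- character(0)
    return(fixes)
  }
  fixes <- order_fixes(fixes)
  res <- lapply(split(seq_len(nrow(fixes)), grouping_key(fixes)), function(g) {
    sub <- fixes[g, , drop = FALSE]
    n <- nrow(sub)
    key <- grouping_key(sub)[1]
    if (n == 1L) {
      sub$segment_id <- paste0(key, ".s1")
      return(sub)
    }
    gap <- diff(as.numeric(sub$timestamp)) / 60
    if (any(gap <= 0))
      stop(sprintf("non-increasing timestamps at %s (%s)",
                   sub$animal_id[1], format(sub$timestamp[which(gap <= 0)[1]])))
    brk <- gap > night_gap                 # overnight break: new segment
    k <- round(gap / dt)
    bad <- !brk & abs(gap - k * dt) > 1e-6
    if (any(bad)) {
      if (on_indivisible == "error")
        stop(sprintf(
          "interval of %.6g min between fixes of %s at %s is not a multiple of dt = %g",
          gap[which(bad)[1]], sub$animal_id[1],
          format(sub$timestamp[which(bad)[1]]), dt))
      brk <- brk | bad
    }
    seg <- cumsum(c(1L, as.integer(brk)))
    sub$segment_id <- paste0(key, ".s", seg)
    jj <- which(!brk & k > 1)
    if (length(jj) == 0L) return(sub)
    src <- rep(jj, k[jj] - 1L)
    w <- unlist(lapply(jj, function(j) seq_len(k[j] - 1L) / k[j]), use.names = FALSE)
    ins <- sub[src, , drop = FALSE]
    ins$timestamp <- sub$timestamp[src] + w * gap[src] * 60
    ins$x_m <- (1 - w) * sub$x_m[src] + w * sub$x_m[src + 1L]
    ins$y_m <- (1 - w) * sub$y_m[src] + w * sub$y_m[src + 1L]
    if ("n_sats" %in% names(ins)) ins$n_sats <- NA_integer_
    if ("dop" %in% names(ins)) ins$dop <- NA_real_
    ins$interpolated <- TRUE
    rbind(sub, ins)
  })
  out <- do.call(rbind, res)
  out <- out[order(grouping_key(out), out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full cleaning pipeline
#'
#' Applies the cleaning stages in fixed order -- quality filter, speed filter,
#' jump filter, time snapping, period splitting, origin shift, interpolation --
#' and keeps an audit trail of record counts per stage.
#'
#' @param fixes raw fix table.
#' @param sched [observation_schedule()] used for time snapping.
#' @param dt interpolation step (minutes); defaults to the schedule's fix
#'   interval (native resolution).
#' @param min_sats,max_dop,max_speed,max_two_step,snap_tol,max_gap_min,night_gap
#'   stage thresholds, see the individual filters.
#' @param exclude_animals optional character vector of animal ids removed
#'   before any stage (e.g. individuals judged spatially isolated on visual
#'   inspection).
#' @param on_indivisible passed to [interpolate_uniform()].
#' @return List with `fixes` (interpolated, EDMD-ready), `diffusion_fixes`
#'   (cleaned but not interpolated, for diffusion estimation) and `audit`
#'   (data frame: stage, n_in, n_out, removed).
#' @export
clean_fixes <- function(fixes, sched, dt = NULL,
                        min_sats = 4, max_dop = 4, max_speed = 26.2,
                        max_two_step = 1500, snap_tol = 3,
                        max_gap_min = 7 * 24 * 60, night_gap = 120,
                        exclude_animals = NULL,
                        on_indivisible = "error") {
  if (is.null(dt)) dt <- sched$fix_interval
  audit <- list()
  log_stage <- function(stage, n_in, n_out) {
    audit[[length(audit) + 1L]] <<- data.frame(
      stage = stage, n_in = n_in, n_out = n_out, removed = n_in - n_out,
      stringsAsFactors = FALSE)
  }
  n0 <- nrow(fixes)
  if (!is.null(exclude_animals))
    fixes <- fixes[!fixes$animal_id %in% exclude_animals, , drop = FALSE]
  log_stage("exclude_animals", n0, nrow(fixes))

  for (st in list(
    list("quality", function(f) filter_quality(f, min_sats, max_dop)),
    list("speed",   function(f) filter_speed(f, max_speed)),
    list("jump",    function(f) filter_jump(f, max_two_step)),
    list("snap",    function(f) snap_times(f, sched, snap_tol)),
    list("split",   function(f) split_periods(f, max_gap_min)),
    list("shift",   function(f) if (nrow(f) == 0L) f else shift_origin(f)))) {
    n_in <- nrow(fixes)
    fixes <- st[[2]](fixes)
    log_stage(st[[1]], n_in, nrow(fixes))
  }
  diffusion_fixes <- fixes
  n_in <- nrow(fixes)
  fixes <- interpolate_uniform(fixes, dt, night_gap, on_indivisible)
  log_stage("interpolate", n_in, nrow(fixes))
  list(fixes = fixes, diffusion_fixes = diffusion_fixes,
       audit = do.call(rbind, audit))
}

#' Write a per-stage audit log as JSON lines
#'
#' @param audit audit data frame from [clean_fixes()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_audit_log <- function(audit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(audit)))
    writeLines(jsonlite::toJSON(as.list(audit[i, ]), auto_unbox = TRUE), con)
  invisible(path)
}
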