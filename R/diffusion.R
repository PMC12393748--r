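# Fast-timescale analysis: Kramers-Moyal estimation of the isotropic
# diffusion constant c from cleaned (non-interpolated) tracks.

#' Estimate the isotropic diffusion constant of a track
#'
#' Finite-difference Kramers--Moyal estimator of the diffusion constant `c`
#' of the movement SDE with \eqn{\sigma = cI}: over consecutive fixes
#' \eqn{(x_i, y_i)} at times \eqn{t_i},
#' \deqn{\hat c^2 = \frac{1}{2 n_{pairs}} \sum_i \frac{(x_{i+1}-x_i)^2 +
#'   (y_{i+1}-y_i)^2}{\Delta t_i},}
#' with \eqn{\Delta t_i} in minutes, so \eqn{\hat c} is in m·min^(-1/2).
#' Unequal intervals are supported. Pairs separated by more than `max_dt`
#' minutes (overnight rest gaps, during which the animals are assumed
#' inactive underground) are excluded from the sum.
#'
#' @param track fix table for one animal/period, or any data frame with
#'   `timestamp` (POSIXct) or `t_min` (minutes) plus `x_m`/`y_m` (or `x`/`y`)
#'   columns; must be time-sorted with at least 2 fixes.
#' @param max_dt maximum pair separation (minutes) entering the estimator
#'   (default `Inf`, i.e. the caller has already excluded overnight pairs).
#' @return List with `c` (the estimate, `>= 0`) and `n_pairs` (pairs used).
#' @examples
#' tr <- data.frame(t_min = 0:2, x = c(0, 1, 1), y = c(0, 0, 1))
#' estimate_c(tr)  # c^2 = (1 + 1) / (2 * 2) = 0.5
#' @export
estimate_c <- function(track, max_dt = Inf) {
  t <- if ("timestamp" %in% names(track)) as.numeric(track$timestamp) / 60 else track$t_min
  x <- if ("x_m" %in% names(track)) track$x_m else track$x
  y <- if ("y_m" %in% names(track)) track$y_m else track$y
  if (length(t) < 2L) stop("at least 2 fixes are required to estimate c")
  dt <- diff(t)
  if (any(dt <= 0)) stop("time differences must be strictly positive")
  use <- dt <= max_dt
  if (!any(use)) stop("no pairs within max_dt; cannot estimate c")
  sq <- (diff(x)^2 + diff(y)^2)[use] / dt[use]
  list(c = sqrt(sum(sq) / (2 * sum(use))), n_pairs = sum(use))
}

#' Per-animal, per-month diffusion estimates
#'
#' Computes one diffusion estimate per animal and calendar month from cleaned
#' non-interpolated fixes. Displacement pairs are formed within monitoring
#' periods only, pairs longer than `max_dt` minutes (overnight gaps) are
#' excluded, and a pair spanning a month boundary is assigned to the month of
#' its earlier fix. Animal-months with `min_fixes` or fewer fixes are dropped:
#' too few points hinder accurate estimation of the diffusion metric.
#'
#' @param fixes cleaned fix table (with `period_id` if periods were split);
#'   interpolated rows, if present, are ignored.
#' @param covariates optional data frame keyed by `animal_id` with `sex` and
#'   `site` (taken from the fix table when present there).
#' @param max_dt maximum pair separation in minutes (default 120).
#' @param min_fixes exclusion threshold: months with `<= min_fixes` fixes for
#'   an animal yield no estimate (default 10).
#' @return Data frame `animal_id`, `site`, `sex`, `month` (1--12),
#'   `year`, `capture_year` (ordinal year within site), `c`, `n_pairs`,
#'   `n_fixes`.
#' @export
monthly_estimates <- function(fixes, covariates = NULL, max_dt = 120,
                              min_fixes = 10) {
  empty <- data.frame(animal_id = character(), site = character(),
                      sex = character(), month = integer(), year = integer(),
                      capture_year = integer(), c = numeric(),
                      n_pairs = integer(), n_fixes = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(fixes) == 0L) return(empty)
  if ("interpolated" %in% names(fixes))
    fixes <- fixes[!fixes$interpolated, , drop = FALSE]
  fixes <- order_fixes(fixes)
  lt <- as.POSIXlt(fixes$timestamp)
  fixes$.month <- lt$mon + 1L
  fixes$.year <- lt$year + 1900L

  key <- grouping_key(fixes)
  out <- list()
  for (g in split(seq_len(nrow(fixes)), key)) {
    if (length(g) < 2L) next
    t <- as.numeric(fixes$timestamp[g]) / 60
    dt <- diff(t)
    use <- dt > 0 & dt <= max_dt
    if (!any(use)) next
    sq <- ((diff(fixes$x_m[g])^2 + diff(fixes$y_m[g])^2) / dt)[use]
    df <- data.frame(animal_id = fixes$animal_id[g[1]],
                     month = fixes$.month[g][-length(g)][use],
                     year = fixes$.year[g][-length(g)][use],
                     sq = sq, stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- df
  }
  if (length(out) == 0L) return(empty)
  pairs <- do.call(rbind, out)

  # fixes available per animal-month (exclusion rule counts points, not pairs)
  nfix <- aggregate(list(n_fixes = fixes$timestamp),
                    by = list(animal_id = fixes$animal_id,
                              month = fixes$.month, year = fixes$.year),
                    FUN = length)
  agg <- aggregate(list(sq_sum = pairs$sq),
                   by = list(animal_id = pairs$animal_id,
                             month = pairs$month, year = pairs$year),
                   FUN = sum)
  agg$n_pairs <- aggregate(list(n = pairs$sq),
                           by = list(animal_id = pairs$animal_id,
                                     month = pairs$month, year = pairs$year),
                           FUN = length)$n
  agg <- merge(agg, nfix, by = c("animal_id", "month", "year"))
  agg$c <- sqrt(agg$sq_sum / (2 * agg$n_pairs))
  agg <- agg[agg$n_fixes > min_fixes, , drop = FALSE]

  # covariates: prefer columns carried on the fix table
  cov_cols <- c("sex", "site")
  have <- intersect(cov_cols, names(fixes))
  cov_fix <- unique(fixes[c("animal_id", have)])
  if (!is.null(covariates))
    cov_fix <- merge(unique(covariates[intersect(c("animal_id", cov_cols),
                                                 names(covariates))]),
                     cov_fix[setdiff(names(cov_fix), setdiff(names(covariates),
                                                             "animal_id"))],
                     by = "animal_id", all.y = TRUE)
  agg <- merge(agg, cov_fix, by = "animal_id", all.x = TRUE)
  if (!"site" %in% names(agg)) agg$site <- "site"
  if (!"sex" %in% names(agg)) agg$sex <- NA_character_
  # capture year: ordinal calendar year within site
  agg$capture_year <- as.integer(ave(agg$year, agg$site,
                                     FUN = function(y) y - min(y) + 1L))
  agg <- agg[order(agg$animal_id, agg$year, agg$month),
             c("animal_id", "site", "sex", "month", "year", "capture_year",
               "c", "n_pairs", "n_fixes")]
  rownames(agg) <- NULL
  agg
}

#' Shapiro-Wilk check of log-normality of diffusion estimates
#'
#' The diffusion constant is strictly positive and empirically log-normal;
#' this applies a Shapiro--Wilk normality test to `log(c)` and reports
#' whether normality is retained at the 5% level.
#'
#' @param estimates numeric vector of diffusion estimates, or the data frame
#'   from [monthly_estimates()] (its `c` column is used). All values must be
#'   `> 0` and at least 3 are required.
#' @return List with `statistic` (W), `p_value` and `pass`
#'   (`TRUE` if `p > 0.05`).
#' @export
lognormality_check <- function(estimates) {
  cvals <- if (is.data.frame(estimates)) estimates$c else as.numeric(estimates)
  if (length(cvals) < 3L) stop("at least 3 estimates are required")
  if (any(cvals <= 0)) stop("all diffusion estimates must be > 0 (log undefined)")
  sw <- shapiro.test(log(cvals))
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       pass = sw$p.value > 0.05)
}
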