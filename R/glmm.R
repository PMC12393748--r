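# Log-link mixed-effects modelling of monthly diffusion estimates.
# The model is delegated to glmmTMB (gaussian family, log link, maximum
# likelihood); validation is by parameter recovery on synthetic truth, not by
# matching any particular solver's output.

#' Specification of the diffusion mixed model
#'
#' Fixed effects: calendar month (12 levels, reference January) and sex
#' (reference male). Random effects: an intercept for animals within site
#' and, optionally, per-site random slopes for capture year (an ordinal
#' factor within site), the structure used for multi-site telemetry studies
#' whose monitoring years differ in management regime.
#'
#' @param year_slopes include per-site random slopes for capture year?
#' @param animal_intercept include the animal-within-site random intercept?
#' @return A `diffusion_model_spec` object.
#' @export
diffusion_model_spec <- function(year_slopes = TRUE, animal_intercept = TRUE) {
  structure(list(year_slopes = year_slopes,
                 animal_intercept = animal_intercept),
            class = "diffusion_model_spec")
}

prepare_model_frame <- function(estimates) {
  need <- c("animal_id", "site", "sex", "month", "c")
  miss <- setdiff(need, names(estimates))
  if (length(miss))
    stop("missing covariates/columns in estimates: ", paste(miss, collapse = ", "))
  if (anyNA(estimates[need]))
    stop("missing covariate values in estimates")
  d <- estimates
  d$month <- factor(month.abb[d$month], levels = month.abb)
  d$month <- droplevels(d$month)
  d$sex <- factor(d$sex, levels = c("male", "female"))
  d$animal_id <- factor(d$animal_id)
  d$site <- factor(d$site)
  if ("capture_year" %in% names(d))
    d$capture_year <- factor(paste0("Year", d$capture_year),
                             levels = paste0("Year", sort(unique(d$capture_year))))
  d
}

#' Fit the log-link mixed model to diffusion estimates
#'
#' Fits `c ~ month + sex + (1 | site:animal_id) + (capture_year | site)` with
#' a normal response and log link, dropping random terms that the design
#' cannot identify (single site, or single capture year) with a warning.
#' Convergence problems and singular fits are reported, never silent.
#'
#' @param estimates data frame from [monthly_estimates()] (columns
#'   `animal_id`, `site`, `sex`, `month`, `capture_year`, `c`).
#' @param spec a [diffusion_model_spec()].
#' @return A `diffusion_fit` object: list with `coefficients` (estimate, SE,
#'   t, 95% CI, p per fixed effect), `ranef_sd`, `ranef_corr`, `dispersion`
#'   (residual SD), `AIC`, `BIC`, `logLik`, `n`, `converged`, `singular`,
#'   `formula`, `data_hash`, and the underlying `fit`.
#' @export
fit_glmm <- function(estimates, spec = diffusion_model_spec()) {
  stopifnot(inherits(spec, "diffusion_model_spec"))
  d <- prepare_model_frame(estimates)
  terms <- c("month", "sex")[c(nlevels(d$month) > 1, nlevels(d$sex) > 1)]
  if (length(terms) == 0L) terms <- "1"
  re <- character(0)
  if (spec$animal_intercept) {
    re <- if (nlevels(d$site) > 1) "(1 | site:animal_id)" else "(1 | animal_id)"
  }
  if (spec$year_slopes) {
    if (!"capture_year" %in% names(d) || nlevels(d$capture_year) < 2) {
      warning("capture-year random slopes requested but only one capture year ",
              "is present; fitting a reduced model without them")
    } else if (nlevels(d$site) < 2) {
      warning("capture-year random slopes requested but only one site is ",
              "present; fitting a reduced model without them")
    } else {
      re <- c(re, "(capture_year | site)")
    }
  }
  fml <- stats::as.formula(paste("c ~", paste(c(terms, re), collapse = " + ")))
  fit <- glmmTMB::glmmTMB(fml, data = d,
                          family = stats::gaussian(link = "log"))
  converged <- isTRUE(fit$sdr$pdHess) && fit$fit$convergence == 0
  if (!converged)
    warning("mixed-model fit did not converge cleanly; treat estimates with caution")

  co <- summary(fit)$coefficients$cond
  z <- stats::qnorm(0.975)
  coefs <- data.frame(term = rownames(co),
                      estimate = co[, 1], se = co[, 2], t = co[, 3],
                      ci_lower = co[, 1] - z * co[, 2],
                      ci_upper = co[, 1] + z * co[, 2],
                      p = co[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)

  vc <- glmmTMB::VarCorr(fit)$cond
  ranef_sd <- lapply(vc, function(m) attr(m, "stddev"))
  ranef_corr <- lapply(vc, function(m) {
    cr <- attr(m, "correlation")
    if (is.null(cr)) matrix(1, 1, 1) else cr
  })
  singular <- any(unlist(ranef_sd) < 1e-6)
  if (singular)
    warning("singular fit: at least one random-effect standard deviation is ~0")

  structure(list(coefficients = coefs,
                 ranef_sd = ranef_sd, ranef_corr = ranef_corr,
                 dispersion = sigma(fit),
                 AIC = AIC(fit), BIC = BIC(fit),
                 logLik = as.numeric(logLik(fit)),
                 n = nrow(d), converged = converged, singular = singular,
                 formula = fml,
                 data_hash = data_fingerprint(d),
                 fit = fit),
            class = "diffusion_fit")
}

data_fingerprint <- function(d) {
  paste(nrow(d), signif(sum(d$c), 12), signif(sum(d$c^2), 12), sep = "|")
}

#' @export
print.diffusion_fit <- function(x, digits = 3, ...) {
  cat("Log-link mixed model for diffusion estimates\n")
  cat("  formula:", deparse(x$formula), "\n")
  cat(sprintf("  n = %d, AIC = %.3f, BIC = %.3f, residual SD = %.3f\n",
              x$n, x$AIC, x$BIC, x$dispersion))
  if (!x$converged) cat("  WARNING: fit did not converge cleanly\n")
  if (x$singular) cat("  WARNING: singular fit\n")
  cf <- x$coefficients
  cf[, -1] <- lapply(cf[, -1], signif, digits)
  print(cf, row.names = FALSE)
  invisible(x)
}

#' Multiplicative effect of a log-scale coefficient
#'
#' Converts a log-link coefficient into a multiplicative rate ratio,
#' `exp(coefficient)`; e.g. a month coefficient of 0.106 corresponds to a
#' rate 1.112 times the reference month, and a sex coefficient of -0.152 to
#' 0.859 times the reference sex. Rounding is left to presentation.
#'
#' @param coefficient finite numeric log-scale estimate(s).
#' @return `exp(coefficient)`.
#' @export
effect_multiplier <- function(coefficient) {
  if (any(!is.finite(coefficient))) stop("coefficient must be finite")
  exp(coefficient)
}

#' Compare mixed-model fits by information criteria
#'
#' @param ... two or more `diffusion_fit` objects on the same data, or a
#'   single list of them.
#' @param labels optional model labels.
#' @return Data frame with `model`, `AIC`, `BIC`, `logLik`, sorted by AIC,
#'   with attribute `ic_disagreement` flagging (and a message reporting) an
#'   AIC/BIC ranking disagreement.
#' @export
compare_models <- function(..., labels = NULL) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) && !inherits(fits[[1]], "diffusion_fit"))
    fits <- fits[[1]]
  if (length(fits) < 2L) stop("at least two fits are required for comparison")
  if (!all(vapply(fits, inherits, logical(1), "diffusion_fit")))
    stop("all arguments must be diffusion_fit objects")
  hashes <- vapply(fits, `[[`, character(1), "data_hash")
  if (length(unique(hashes)) != 1L)
    stop("fits were made on different data; information criteria are not comparable")
  if (is.null(labels))
    labels <- vapply(fits, function(f) deparse(f$formula), character(1))
  tab <- data.frame(model = labels,
                    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
                    BIC = vapply(fits, `[[`, numeric(1), "BIC"),
                    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$AIC), , drop = FALSE]
  rownames(tab) <- NULL
  disagree <- !identical(order(tab$AIC), order(tab$BIC))
  attr(tab, "ic_disagreement") <- disagree
  if (disagree)
    message("AIC and BIC rank the models differently; report both criteria")
  tab
}

#' Serialise a fit result
#'
#' Writes the coefficient table as CSV and the full fit summary (fixed
#' effects, random-effect SDs and correlations, dispersion, AIC/BIC) as JSON.
#'
#' @param fit a `diffusion_fit`.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the list serialised to JSON.
#' @export
export_fit <- function(fit, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(fit, "diffusion_fit"))
  if (!is.null(csv_path)) write.csv(fit$coefficients, csv_path, row.names = FALSE)
  out <- list(formula = deparse(fit$formula),
              coefficients = fit$coefficients,
              ranef_sd = fit$ranef_sd,
              ranef_corr = lapply(fit$ranef_corr, function(m) unclass(as.matrix(m))),
              dispersion = fit$dispersion,
              AIC = fit$AIC, BIC = fit$BIC, logLik = fit$logLik,
              n = fit$n, converged = fit$converged, singular = fit$singular)
  if (!is.null(json_path))
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(out)
}
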