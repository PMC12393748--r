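#' Multi-well potential field for territorial movement
#'
#' Defines a smooth energy landscape as a sum of inverted Gaussian wells,
#' \deqn{U(x) = -\sum_k d_k \exp(-|x - m_k|^2 / (2 w_k^2)),}
#' where each well (centre \eqn{m_k}, depth \eqn{d_k}, width \eqn{w_k})
#' represents the core of one social group's territory. The drift of the
#' movement model is the negative gradient of this potential, so animals are
#' attracted towards well centres and the attraction decays smoothly with
#' distance; drift is bounded and finite everywhere.
#'
#' @param centres numeric matrix with one row per well and columns `x`, `y`
#'   (metres), or a length-2 vector for a single well.
#' @param depths positive numeric vector of well depths (energy units),
#'   recycled to the number of wells.
#' @param widths positive numeric vector of well widths (metres), recycled.
#' @return An object of class `potential_field`.
#' @examples
#' pf <- potential_field(rbind(c(0, 0), c(1000, 0)), depths = 50, widths = 150)
#' drift_at(pf, c(500, 0))  # equidistant between equal wells: zero drift
#' @export
potential_field <- function(centres, depths, widths) {
  if (is.null(dim(centres))) centres <- matrix(centres, ncol = 2L)
  centres <- as.matrix(centres)
  if (ncol(centres) != 2L || nrow(centres) < 1L)
    stop("'centres' must have one row per well and two columns (x, y)")
  k <- nrow(centres)
  depths <- rep_len(as.numeric(depths), k)
  widths <- rep_len(as.numeric(widths), k)
  if (any(!is.finite(centres)) || any(!is.finite(depths)) || any(!is.finite(widths)))
    stop("well parameters must be finite")
  if (any(depths < 0) || any(widths <= 0))
    stop("well widths must be strictly positive and depths non-negative")
  structure(list(centres = unname(centres), depths = depths, widths = widths),
            class = "potential_field")
}

#' @export
print.potential_field <- function(x, ...) {
  cat("<potential_field> ", nrow(x$centres), " Gaussian well(s)\n", sep = "")
  df <- data.frame(x = x$centres[, 1], y = x$centres[, 2],
                   depth = x$depths, width = x$widths)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Potential energy at points
#'
#' @param field a [potential_field()].
#' @param x numeric matrix of points (rows) or a length-2 vector.
#' @return numeric vector of potential values \eqn{U(x)} (all \eqn{\le 0}).
#' @export
potential_at <- function(field, x) {
  stopifnot(inherits(field, "potential_field"))
  if (is.null(dim(x))) x <- matrix(x, ncol = 2L)
  u <- numeric(nrow(x))
  for (k in seq_along(field$depths)) {
    dx <- x[, 1] - field$centres[k, 1]
    dy <- x[, 2] - field$centres[k, 2]
    u <- u - field$depths[k] * exp(-(dx^2 + dy^2) / (2 * field$widths[k]^2))
  }
  u
}

#' Drift (negative potential gradient) at points
#'
#' Evaluates the deterministic drift term \eqn{b(x) = -\nabla U(x)} of the
#' movement SDE at one or more locations. The drift is a total function:
#' finite and smooth on the whole plane.
#'
#' @inheritParams potential_at
#' @return numeric matrix of drift vectors (m/min), one row per input point.
#' @export
drift_at <- function(field, x) {
  stopifnot(inherits(field, "potential_field"))
  if (is.null(dim(x))) x <- matrix(x, ncol = 2L)
  b <- matrix(0, nrow(x), 2L)
  for (k in seq_along(field$depths)) {
    dx <- x[, 1] - field$centres[k, 1]
    dy <- x[, 2] - field$centres[k, 2]
    w2 <- field$widths[k]^2
    e <- field$depths[k] * exp(-(dx^2 + dy^2) / (2 * w2)) / w2
    b[, 1] <- b[, 1] - dx * e
    b[, 2] <- b[, 2] - dy * e
  }
  b
}
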