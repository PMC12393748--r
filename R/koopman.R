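# Slow-timescale analysis: EDMD approximation of the Koopman operator over
# an indicator-function dictionary on a box grid (equivalently Ulam's method
# for a Markov state model), spectral decomposition, spectral-gap selection
# of the number of metastable states, and k-means clustering of the dominant
# eigenfunctions.

#' Build a box grid over a point cloud
#'
#' Superimposes a rectangular grid over the points. The number of boxes per
#' axis is the span divided by `target_edge`, rounded to the nearest integer
#' (clamped to at least 1), so box edges are approximately `target_edge`
#' (exactly `span / n`). Boxes are half-open on their lower edge,
#' `[lo, hi)`, except the final box along each axis, which is closed.
#' The grid's indicator functions over its occupied boxes form the EDMD
#' dictionary.
#'
#' @param points two-column matrix or data frame of locations (m); fix tables
#'   (`x_m`, `y_m`) are accepted.
#' @param target_edge target box edge length (m, default 100).
#' @return A `box_grid`: bounding box, `nx`, `ny`, exact edge lengths and the
#'   indices of occupied boxes.
#' @export
build_grid <- function(points, target_edge = 100) {
  xy <- as_xy(points)
  if (nrow(xy) < 1L) stop("at least one point is required")
  xr <- range(xy[, 1]); yr <- range(xy[, 2])
  span_x <- diff(xr); span_y <- diff(yr)
  if (span_x == 0 && span_y == 0)
    warning("degenerate point cloud (zero span); using a 1x1 grid")
  nx <- max(1L, as.integer(round(span_x / target_edge)))
  ny <- max(1L, as.integer(round(span_y / target_edge)))
  grid <- structure(list(x_min = xr[1], x_max = xr[2],
                         y_min = yr[1], y_max = yr[2],
                         nx = nx, ny = ny,
                         edge_x = if (span_x > 0) span_x / nx else target_edge,
                         edge_y = if (span_y > 0) span_y / ny else target_edge),
                    class = "box_grid")
  grid$occupied <- sort(unique(assign_box(grid, xy)))
  grid
}

as_xy <- function(points) {
  if (is.data.frame(points)) {
    if (all(c("x_m", "y_m") %in% names(points)))
      return(cbind(points$x_m, points$y_m))
    if (all(c("x", "y") %in% names(points)))
      return(cbind(points$x, points$y))
    points <- as.matrix(points)
  }
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  unname(points[, 1:2, drop = FALSE])
}

#' @export
print.box_grid <- function(x, ...) {
  cat(sprintf("<box_grid> %d x %d boxes of %.6g x %.6g m over [%.6g, %.6g] x [%.6g, %.6g]; %d occupied\n",
              x$nx, x$ny, x$edge_x, x$edge_y, x$x_min, x$x_max, x$y_min,
              x$y_max, length(x$occupied)))
  invisible(x)
}

#' Map points to box indices
#'
#' @param grid a [build_grid()] result.
#' @param points points as for [build_grid()].
#' @return Integer vector of linear box indices (`ix + nx * (iy - 1)`);
#'   `NA` for points outside the bounding box.
#' @export
assign_box <- function(grid, points) {
  xy <- as_xy(points)
  ix <- floor((xy[, 1] - grid$x_min) / grid$edge_x) + 1
  iy <- floor((xy[, 2] - grid$y_min) / grid$edge_y) + 1
  ix[xy[, 1] == grid$x_max] <- grid$nx      # final box closed
  iy[xy[, 2] == grid$y_max] <- grid$ny
  out <- ifelse(ix >= 1 & ix <= grid$nx & iy >= 1 & iy <= grid$ny,
                as.integer(ix + grid$nx * (iy - 1)), NA_integer_)
  as.integer(out)
}

box_centres <- function(grid, boxes) {
  ix <- (boxes - 1L) %% grid$nx + 1L
  iy <- (boxes - 1L) %/% grid$nx + 1L
  cbind(grid$x_min + (ix - 0.5) * grid$edge_x,
        grid$y_min + (iy - 0.5) * grid$edge_y)
}

#' Snapshot pairs for EDMD
#'
#' `build_pairs()` assembles the source/destination snapshot matrices from
#' regularised tracks: within every track segment the source set runs from
#' the first to the penultimate fix and the destination set from the second
#' to the last, so no pair crosses a track boundary or an overnight gap and
#' every pair is separated by exactly the lag `tau` (the interpolation step).
#' `snapshot_pairs()` is the low-level constructor for pre-paired data.
#'
#' @param tracks an interpolated fix table from [interpolate_uniform()] (or
#'   any fix table with a `segment_id` column and uniform within-segment
#'   spacing).
#' @return A `snapshot_pairs` object: matrices `src` and `dst` (one row per
#'   pair) and the common lag `tau` (minutes).
#' @export
build_pairs <- function(tracks) {
  seg <- if ("segment_id" %in% names(tracks)) tracks$segment_id
         else grouping_key(tracks)
  ord <- order(seg, tracks$timestamp)
  tracks <- tracks[ord, , drop = FALSE]
  seg <- seg[ord]
  xy <- as_xy(tracks)
  t <- as.numeric(tracks$timestamp) / 60
  n <- nrow(tracks)
  if (n < 2L) stop("at least two fixes are required to build snapshot pairs")
  same <- seg[-n] == seg[-1]
  dt <- (t[-1] - t[-n])[same]
  if (length(dt) == 0L) stop("no within-segment pairs available")
  tau <- stats::median(dt)
  if (any(abs(dt - tau) > 1e-6))
    stop("tracks have mixed time steps; interpolate to a common dt first")
  src_idx <- which(same)
  snapshot_pairs(xy[src_idx, , drop = FALSE], xy[src_idx + 1L, , drop = FALSE],
                 tau = tau)
}

#' @rdname build_pairs
#' @param src,dst two-column matrices of paired source/destination points.
#' @param tau time separation of every pair (minutes).
#' @export
snapshot_pairs <- function(src, dst, tau = NA_real_) {
  src <- as_xy(src); dst <- as_xy(dst)
  if (nrow(src) != nrow(dst)) stop("src and dst must contain the same number of points")
  structure(list(src = src, dst = dst, tau = tau, n = nrow(src)),
            class = "snapshot_pairs")
}

#' @export
print.snapshot_pairs <- function(x, ...) {
  cat(sprintf("<snapshot_pairs> %d pairs, tau = %s min\n", x$n, format(x$tau)))
  invisible(x)
}

#' EDMD estimate of the Koopman matrix
#'
#' Computes the Galerkin approximation of the Koopman operator on the
#' indicator dictionary of the grid's occupied boxes by solving the EDMD
#' least-squares problem
#' \deqn{K^\top = \arg\min_K \|\Psi_{Y'} - K^\top \Psi_Y\| = \Psi_{Y'} \Psi_Y^+}
#' through the Gram matrices \eqn{A = \Psi_{Y'}\Psi_Y^\top},
#' \eqn{G = \Psi_Y\Psi_Y^\top} and the Moore--Penrose pseudoinverse
#' (\eqn{K^\top = A G^+}). With indicator basis functions this is Ulam's
#' method: the result equals the row-normalised transition-count matrix (see
#' [transition_count_oracle()]). Boxes with no outgoing pair (occupied only
#' as destinations) are made absorbing (unit diagonal) so the matrix stays
#' row-stochastic.
#'
#' @param pairs a [snapshot_pairs()] object; every endpoint must lie inside
#'   the grid's bounding box.
#' @param grid a [build_grid()] result.
#' @return A `koopman_matrix`: row-stochastic matrix `K` over the dictionary
#'   boxes (row = source box), with `boxes` (dictionary box indices), `grid`,
#'   `tau` and `n_pairs`.
#' @export
estimate_koopman <- function(pairs, grid) {
  stopifnot(inherits(pairs, "snapshot_pairs"), inherits(grid, "box_grid"))
  if (pairs$n < 1L) stop("at least one snapshot pair is required")
  bs <- assign_box(grid, pairs$src)
  bd <- assign_box(grid, pairs$dst)
  if (anyNA(bs) || anyNA(bd))
    stop("snapshot pair endpoint outside the grid's bounding box")
  dict <- sort(unique(c(grid$occupied, bs, bd)))
  N <- length(dict)
  M <- pairs$n
  psi_y <- Matrix::sparseMatrix(i = match(bs, dict), j = seq_len(M), x = 1,
                                dims = c(N, M))
  psi_yp <- Matrix::sparseMatrix(i = match(bd, dict), j = seq_len(M), x = 1,
                                 dims = c(N, M))
  A <- as.matrix(psi_yp %*% Matrix::t(psi_y))
  G <- as.matrix(psi_y %*% Matrix::t(psi_y))
  K <- t(A %*% MASS::ginv(G))
  sink <- Matrix::rowSums(psi_y) == 0
  if (any(sink)) {
    K[sink, ] <- 0
    K[cbind(which(sink), which(sink))] <- 1
  }
  dimnames(K) <- list(dict, dict)
  structure(list(K = K, boxes = dict, grid = grid, tau = pairs$tau,
                 n_pairs = M),
            class = "koopman_matrix")
}

#' Transition-count (Ulam) oracle
#'
#' Independent brute-force construction of the Markov state model: counts
#' transitions between boxes, `C[j, i] = #` pairs from box `j` to box `i`,
#' and divides each row by its sum. Rows without outgoing transitions are
#' made absorbing, mirroring [estimate_koopman()]. Used as the module's
#' cross-check: EDMD with indicator functions must reproduce this matrix.
#'
#' @inheritParams estimate_koopman
#' @return A `koopman_matrix` (same structure as [estimate_koopman()]).
#' @export
transition_count_oracle <- function(pairs, grid) {
  stopifnot(inherits(pairs, "snapshot_pairs"), inherits(grid, "box_grid"))
  bs <- assign_box(grid, pairs$src)
  bd <- assign_box(grid, pairs$dst)
  if (anyNA(bs) || anyNA(bd))
    stop("snapshot pair endpoint outside the grid's bounding box")
  dict <- sort(unique(c(grid$occupied, bs, bd)))
  N <- length(dict)
  C <- matrix(0, N, N, dimnames = list(dict, dict))
  js <- match(bs, dict); is <- match(bd, dict)
  for (k in seq_along(js)) C[js[k], is[k]] <- C[js[k], is[k]] + 1
  rs <- rowSums(C)
  K <- C / ifelse(rs == 0, 1, rs)
  zero <- rs == 0
  if (any(zero)) K[cbind(which(zero), which(zero))] <- 1
  structure(list(K = K, boxes = dict, grid = grid, tau = pairs$tau,
                 n_pairs = pairs$n),
            class = "koopman_matrix")
}

#' @export
print.koopman_matrix <- function(x, ...) {
  cat(sprintf("<koopman_matrix> %d x %d over occupied boxes, %d pairs, tau = %s min\n",
              nrow(x$K), ncol(x$K), x$n_pairs, format(x$tau)))
  invisible(x)
}

#' Spectral decomposition of a Koopman matrix
#'
#' Full eigendecomposition with eigenvalues sorted by descending real part.
#' For a row-stochastic matrix the leading eigenvalue is 1 and its (right)
#' eigenfunction is constant over the occupied boxes; eigenvalues close to 1
#' encode the slow, metastable dynamics, small eigenvalues the fast
#' within-territory mixing. Eigenfunctions are piecewise constant on boxes:
#' \eqn{\varphi_j(x) = \xi_j[\mathrm{box}(x)]}.
#'
#' @param K a `koopman_matrix` (or plain square matrix).
#' @return A `koopman_spectrum`: `values` (complex, sorted), `vectors`
#'   (columns are eigenvectors \eqn{\xi_j}), plus the dictionary `boxes` and
#'   `grid` when available.
#' @export
spectral_decompose <- function(K) {
  boxes <- NULL; grid <- NULL; tau <- NA_real_
  if (inherits(K, "koopman_matrix")) {
    boxes <- K$boxes; grid <- K$grid; tau <- K$tau; K <- K$K
  }
  if (!all(is.finite(K))) stop("Koopman matrix contains non-finite entries")
  e <- eigen(K)
  ord <- order(Re(e$values), decreasing = TRUE)
  structure(list(values = e$values[ord],
                 vectors = e$vectors[, ord, drop = FALSE],
                 boxes = boxes, grid = grid, tau = tau),
            class = "koopman_spectrum")
}

#' @export
print.koopman_spectrum <- function(x, ...) {
  cat("<koopman_spectrum> leading eigenvalues (real part):\n")
  print(signif(Re(utils::head(x$values, 10)), 4))
  if (any(abs(Im(x$values)) > 1e-8))
    cat(sprintf("  max |imaginary part| = %.3g\n", max(abs(Im(x$values)))))
  invisible(x)
}

#' Evaluate Koopman eigenfunctions at points
#'
#' @param spectrum a [spectral_decompose()] result with grid information.
#' @param points locations (m).
#' @param j eigenfunction indices (default all).
#' @return Matrix of eigenfunction values (possibly complex), one row per
#'   point, `NA` for points in unoccupied boxes.
#' @export
eigenfunction_at <- function(spectrum, points, j = NULL) {
  stopifnot(inherits(spectrum, "koopman_spectrum"))
  if (is.null(spectrum$grid)) stop("spectrum carries no grid; cannot evaluate")
  if (is.null(j)) j <- seq_along(spectrum$values)
  b <- assign_box(spectrum$grid, points)
  spectrum$vectors[match(b, spectrum$boxes), j, drop = FALSE]
}

#' Number of metastable states from the spectral gap
#'
#' Sorts eigenvalue real parts in descending order and returns the first
#' index `i` (up to `n_max`) at which the drop to the next eigenvalue
#' exceeds `delta`. When no drop exceeds `delta`, the fall-back rule selects
#' the largest successive difference within the first `n_max` eigenvalues
#' (reported via a message).
#'
#' @param values eigenvalues (complex allowed; real parts are used) or a
#'   `koopman_spectrum`.
#' @param delta gap threshold (default 0.05).
#' @param n_max largest number of metastable states considered (default 10).
#' @return Integer `N`, with attribute `method` (`"gap"` or
#'   `"max_successive_diff"`).
#' @export
spectral_gap <- function(values, delta = 0.05, n_max = 10) {
  if (inherits(values, "koopman_spectrum")) values <- values$values
  if (length(values) < 2L) stop("at least two eigenvalues are required")
  re <- sort(Re(values), decreasing = TRUE)
  d <- round(-diff(re), 10)  # rounded so exact ties resolve to the first index
  imax <- min(n_max, length(d))
  hit <- which(d[seq_len(imax)] > delta)
  if (length(hit)) {
    out <- hit[1]
    attr(out, "method") <- "gap"
  } else {
    out <- which.max(d[seq_len(imax)])
    attr(out, "method") <- "max_successive_diff"
    message(sprintf(
      "no successive eigenvalue difference exceeds delta = %g within the first %d; using the maximum successive difference (N = %d)",
      delta, imax, out))
  }
  out
}

#' Partition occupied boxes into metastable clusters
#'
#' Clusters the occupied boxes by k-means on the real parts of the first `N`
#' Koopman eigenfunctions (including the trivial constant one), the features
#' that separate regions the process rarely leaves. Each box gets a label in
#' `1..N`; fixes inherit the label of their box via [label_fixes()].
#'
#' @param spectrum a [spectral_decompose()] result.
#' @param N number of clusters (e.g. from [spectral_gap()]); must not exceed
#'   the number of occupied boxes.
#' @param seed integer seed for the k-means restarts.
#' @param nstart number of k-means restarts (default 10).
#' @return A `metastable_partition`: `N`, `boxes`, integer `labels` per box,
#'   `grid`, and per-cluster box counts.
#' @export
cluster_metastable <- function(spectrum, N, seed = 1, nstart = 10) {
  stopifnot(inherits(spectrum, "koopman_spectrum"))
  nb <- nrow(spectrum$vectors)
  if (N < 1) stop("N must be >= 1")
  if (N > nb) stop("N exceeds the number of occupied boxes")
  if (N == 1L) {
    labels <- rep(1L, nb)
  } else {
    feat <- Re(spectrum$vectors[, seq_len(N), drop = FALSE])
    set.seed(as.integer(seed))
    labels <- kmeans(feat, centers = N, nstart = nstart)$cluster
  }
  structure(list(N = as.integer(N), boxes = spectrum$boxes,
                 labels = as.integer(labels), grid = spectrum$grid,
                 box_counts = tabulate(labels, nbins = N)),
            class = "metastable_partition")
}

#' @export
print.metastable_partition <- function(x, ...) {
  cat(sprintf("<metastable_partition> %d clusters over %d occupied boxes\n",
              x$N, length(x$boxes)))
  print(setNames(x$box_counts, paste0("cluster", seq_len(x$N))))
  invisible(x)
}

#' Propagate cluster labels from boxes to fixes
#'
#' @param partition a [cluster_metastable()] result.
#' @param fixes fix table (or points).
#' @return The fix table with an integer `cluster` column (`NA` for fixes in
#'   unoccupied boxes).
#' @export
label_fixes <- function(partition, fixes) {
  stopifnot(inherits(partition, "metastable_partition"))
  b <- assign_box(partition$grid, fixes)
  cl <- partition$labels[match(b, partition$boxes)]
  if (is.data.frame(fixes)) {
    fixes$cluster <- cl
    fixes
  } else {
    cl
  }
}

#' Export Koopman artefacts as CSV
#'
#' `write_koopman_csv` writes the matrix in sparse triplet form
#' (`from_box`, `to_box`, `prob`), `write_eigen_csv` the eigenvalues
#' (`index`, `re`, `im`), and `write_partition_csv` the box partition
#' (`box_ix`, `box_iy`, `cluster`).
#'
#' @param x the object to serialise.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_koopman_csv <- function(x, path) {
  stopifnot(inherits(x, "koopman_matrix"))
  nz <- which(x$K != 0, arr.ind = TRUE)
  write.csv(data.frame(from_box = x$boxes[nz[, 1]], to_box = x$boxes[nz[, 2]],
                       prob = x$K[nz]),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_koopman_csv
#' @export
write_eigen_csv <- function(x, path) {
  stopifnot(inherits(x, "koopman_spectrum"))
  write.csv(data.frame(index = seq_along(x$values),
                       re = Re(x$values), im = Im(x$values)),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_koopman_csv
#' @export
write_partition_csv <- function(x, path) {
  stopifnot(inherits(x, "metastable_partition"))
  ix <- (x$boxes - 1L) %% x$grid$nx + 1L
  iy <- (x$boxes - 1L) %/% x$grid$nx + 1L
  write.csv(data.frame(box_ix = ix, box_iy = iy, cluster = x$labels),
            path, row.names = FALSE)
  invisible(path)
}
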