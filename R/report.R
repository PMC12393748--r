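# Convex-hull summaries of metastable clusters and social-group home ranges.

#' Convex hull and area of a point set
#'
#' Computes the convex hull (the smallest convex polygon containing all the
#' points) and its area by the shoelace formula, reported in km². Fewer than
#' three distinct, non-collinear points yield a zero-area hull with a
#' warning rather than an error, so sparse clusters are reported, not
#' dropped.
#'
#' @param points locations in metres (matrix, or fix table with
#'   `x_m`/`y_m`).
#' @param label identifier carried into the summary.
#' @return A `hull_summary`: `label`, `vertices` (ordered hull points, a
#'   subset of the input), `area_km2`, `n_fixes`.
#' @examples
#' convex_hull_area(rbind(c(0, 0), c(2000, 0), c(0, 2000)))$area_km2  # 2
#' @export
convex_hull_area <- function(points, label = NA) {
  xy <- as_xy(points)
  n <- nrow(xy)
  uq <- unique(xy)
  if (nrow(uq) < 3L) {
    warning("fewer than 3 distinct points; zero-area hull")
    return(structure(list(label = label, vertices = uq, area_km2 = 0,
                          n_fixes = n), class = "hull_summary"))
  }
  h <- chull(xy)
  v <- xy[h, , drop = FALSE]
  if (nrow(v) < 3L) {
    warning("collinear points; zero-area hull")
    return(structure(list(label = label, vertices = v, area_km2 = 0,
                          n_fixes = n), class = "hull_summary"))
  }
  x <- v[, 1]; y <- v[, 2]
  area_m2 <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  structure(list(label = label, vertices = v, area_km2 = area_m2 / 1e6,
                 n_fixes = n),
            class = "hull_summary")
}

#' @export
print.hull_summary <- function(x, ...) {
  cat(sprintf("<hull_summary> %s: %d vertices, %.4g km2, %d fixes\n",
              format(x$label), nrow(x$vertices), x$area_km2, x$n_fixes))
  invisible(x)
}

hull_set <- function(fixes, by) {
  keys <- fixes[[by]]
  keep <- !is.na(keys)
  lapply(split(which(keep), keys[keep]), function(idx)
    convex_hull_area(fixes[idx, , drop = FALSE],
                     label = as.character(keys[idx[1]])))
}

mean_sd <- function(x) {
  if (length(x) == 0L) return(c(mean = NA_real_, sd = NA_real_))
  c(mean = mean(x), sd = if (length(x) > 1L) sd(x) else 0)
}

#' Compare metastable clusters with social-group home ranges
#'
#' For each requested subset of the data (and for the pooled data) computes
#' the number of metastable clusters and of social groups, the mean (SD)
#' convex-hull area of each, and the hull polygons themselves. Group home
#' ranges are the convex hulls of all fixes of each group's members; cluster
#' hulls are the convex hulls of the fixes labelled with each cluster.
#'
#' @param fixes labelled fix table (see [label_fixes()]) with a `cluster`
#'   column and a group membership column.
#' @param group_col name of the group membership column (default
#'   `"group_id"`).
#' @param by optional character vector of subset columns (e.g. `"site"`,
#'   `"capture_year"`); a pooled `"Total"` row is always included.
#' @return List with `table` (one row per subset: counts and mean/SD areas
#'   in km²), `cluster_hulls` and `group_hulls` (lists of [hull_summary][convex_hull_area]
#'   lists per subset).
#' @export
summarise_partition <- function(fixes, group_col = "group_id", by = NULL) {
  stopifnot("cluster" %in% names(fixes), group_col %in% names(fixes))
  subsets <- list(Total = seq_len(nrow(fixes)))
  if (!is.null(by) && nrow(fixes) > 0L) {
    keys <- interaction(fixes[by], drop = TRUE, sep = ":")
    subsets <- c(subsets, split(seq_len(nrow(fixes)), keys))
  }
  rows <- list(); ch <- list(); gh <- list()
  for (nm in names(subsets)) {
    sub <- fixes[subsets[[nm]], , drop = FALSE]
    cl_h <- if (nrow(sub)) suppressWarnings(hull_set(sub, "cluster")) else list()
    gr_h <- if (nrow(sub)) suppressWarnings(hull_set(sub, group_col)) else list()
    ca <- mean_sd(vapply(cl_h, `[[`, numeric(1), "area_km2"))
    ga <- mean_sd(vapply(gr_h, `[[`, numeric(1), "area_km2"))
    rows[[nm]] <- data.frame(subset = nm,
                             n_groups = length(gr_h), n_clusters = length(cl_h),
                             group_area_mean = ga["mean"], group_area_sd = ga["sd"],
                             cluster_area_mean = ca["mean"], cluster_area_sd = ca["sd"],
                             n_fixes = nrow(sub), stringsAsFactors = FALSE)
    ch[[nm]] <- cl_h; gh[[nm]] <- gr_h
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, cluster_hulls = ch, group_hulls = gh)
}

#' Export hull overlays as GeoJSON
#'
#' Serialises cluster hulls and group home-range hulls as a GeoJSON
#' FeatureCollection in planar (metre) coordinates, each polygon tagged with
#' `role` (`"cluster"` or `"group"`), its label and its area, for plotting
#' or GIS overlay.
#'
#' @param cluster_hulls,group_hulls lists of [hull_summary][convex_hull_area]
#'   objects (either may be empty).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_overlay <- function(cluster_hulls, group_hulls, path) {
  feat <- function(h, role) {
    ring <- rbind(h$vertices, h$vertices[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(role = role, label = as.character(h$label),
                           area_km2 = h$area_km2, n_fixes = h$n_fixes),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  }
  features <- c(lapply(cluster_hulls, feat, role = "cluster"),
                lapply(group_hulls, feat, role = "group"))
  fc <- list(type = "FeatureCollection", features = unname(features))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a hull overlay written by [export_overlay()]
#'
#' @param path GeoJSON file.
#' @return List of [hull_summary][convex_hull_area]-like entries with `role`,
#'   `label`, `area_km2` and `vertices`.
#' @export
read_overlay <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(fc$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    list(role = f$properties$role, label = f$properties$label,
         area_km2 = f$properties$area_km2,
         n_fixes = f$properties$n_fixes,
         vertices = ring[-nrow(ring), , drop = FALSE])
  })
}
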