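# Shared fixtures, built in code at test time.

t_base <- as.POSIXct("2019-01-01 00:00:00", tz = "UTC")

# Minimal fix table from minute offsets and coordinates.
fx_table <- function(t_min, x, y, animal = "A1", group = "G1",
                     sex = "male", site = "S1", n_sats = NA_integer_,
                     dop = NA_real_, base = t_base) {
  n <- length(t_min)
  data.frame(animal_id = rep_len(animal, n), group_id = rep_len(group, n),
             sex = rep_len(sex, n), site = rep_len(site, n),
             timestamp = base + t_min * 60, x_m = x, y_m = y,
             n_sats = rep_len(n_sats, n), dop = rep_len(dop, n),
             stringsAsFactors = FALSE)
}

strip_rn <- function(d) { rownames(d) <- NULL; d }

# A flat (zero-drift) potential for pure-diffusion simulations.
flat_field <- function() potential_field(c(0, 0), depths = 0, widths = 100)

# Random snapshot pairs on a fixed domain, plus their grid.
random_pair_set <- function(seed, n = 60, extent = 500, edge = 100) {
  set.seed(seed)
  src <- cbind(runif(n, 0, extent), runif(n, 0, extent))
  dst <- cbind(runif(n, 0, extent), runif(n, 0, extent))
  grid <- build_grid(rbind(src, dst), target_edge = edge)
  list(pairs = snapshot_pairs(src, dst, tau = 20), grid = grid)
}

# Study-generator settings for a strongly metastable population:
# deep narrow wells (rare inter-well transitions) and modest individual
# variation, sampled on the 20-minute nightly schedule.
metastable_args <- function(seed, n_groups = 4, badgers_per_group = 3,
                            months = 2) {
  list(n_groups = n_groups, badgers_per_group = badgers_per_group,
       months = months, seed = seed,
       schedule = observation_schedule("18:00", "06:00", 20),
       well_depth = 20 * exp(3.397)^2, well_width = 200,
       well_spacing = 1200, intercept_sd = 0.1, sim_dt = 0.25)
}

# Nearest true well centre for each of a partition's occupied boxes.
nearest_well_labels <- function(partition, field) {
  cen <- with(partition$grid, {
    ix <- (partition$boxes - 1L) %% nx + 1L
    iy <- (partition$boxes - 1L) %/% nx + 1L
    cbind(x_min + (ix - 0.5) * edge_x, y_min + (iy - 0.5) * edge_y)
  })
  apply(cen, 1, function(p) which.min(colSums((t(field$centres) - p)^2)))
}

# Fraction of occupied boxes whose cluster label is consistent with the
# nearest-well truth (best label matching via contingency maxima).
box_label_agreement <- function(partition, field) {
  truth <- nearest_well_labels(partition, field)
  tab <- table(partition$labels, truth)
  sum(apply(tab, 2, max)) / length(truth)
}
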