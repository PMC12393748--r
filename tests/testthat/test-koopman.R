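test_that("grid construction rounds the span to integer box counts", {
  pts <- rbind(c(0, 0), c(1000, 500))
  g <- build_grid(pts, target_edge = 100)
  expect_equal(c(g$nx, g$ny), c(10L, 5L))
  expect_equal(c(g$edge_x, g$edge_y), c(100, 100))
  g2 <- build_grid(rbind(c(0, 0), c(1050, 100)), target_edge = 100)
  expect_true(g2$nx %in% c(10L, 11L))
  expect_equal(g2$edge_x, 1050 / g2$nx)
  expect_warning(g1 <- build_grid(c(5, 5)), "degenerate")
  expect_equal(c(g1$nx, g1$ny), c(1L, 1L))
  expect_equal(g1$occupied, 1L)
})

test_that("box assignment is half-open with a closed final box", {
  g <- build_grid(rbind(c(0, 0), c(400, 0)), target_edge = 100)
  x <- c(0, 99.99, 100, 399.99, 400)
  expect_equal(assign_box(g, cbind(x, 0)), c(1L, 1L, 2L, 4L, 4L))
  expect_true(is.na(assign_box(g, c(401, 0))))
  expect_true(is.na(assign_box(g, c(-1, 0))))
})

test_that("snapshot pairs never cross segment boundaries", {
  fx <- rbind(fx_table(seq(0, by = 20, length.out = 3), x = 1:3, y = 0,
                       animal = "A1"),
              fx_table(seq(1e4, by = 20, length.out = 4), x = 11:14, y = 0,
                       animal = "A2"))
  fx$segment_id <- fx$animal_id
  pr <- build_pairs(fx)
  expect_equal(pr$n, 5L)                       # (3-1) + (4-1)
  expect_equal(pr$tau, 20)
  expect_false(any(pr$src[, 1] == 3 & pr$dst[, 1] == 11))
  one <- fx[1, ]
  expect_error(build_pairs(one), "at least two")
  mixed <- fx
  mixed$timestamp[7] <- mixed$timestamp[6] + 31 * 60
  expect_error(build_pairs(mixed), "mixed time steps")
})

test_that("EDMD on indicator functions equals the transition-count oracle", {
  for (s in 1:25) {
    ps <- random_pair_set(s)
    K1 <- estimate_koopman(ps$pairs, ps$grid)
    K2 <- transition_count_oracle(ps$pairs, ps$grid)
    expect_lt(max(abs(K1$K - K2$K)), 1e-8)
    expect_equal(unname(rowSums(K1$K)), rep(1, nrow(K1$K)), tolerance = 1e-8)
  }
})

test_that("hand-counted transitions match the oracle", {
  # 3 pairs j -> i and 1 pair j -> j: row j = (0.25, 0.75)
  src <- rbind(c(50, 0), c(50, 0), c(50, 0), c(50, 0))
  dst <- rbind(c(350, 0), c(350, 0), c(350, 0), c(50, 0))
  g <- build_grid(rbind(c(0, 0), c(400, 0)), target_edge = 200)
  K <- transition_count_oracle(snapshot_pairs(src, dst), g)
  expect_equal(unname(K$K[1, ]), c(0.25, 0.75))
  # single pair: a single unit entry in its row
  K1 <- transition_count_oracle(snapshot_pairs(src[1, , drop = FALSE],
                                               dst[1, , drop = FALSE]), g)
  expect_equal(unname(K1$K["1", "2"]), 1)
  # symmetric pair set is doubly stochastic
  Ks <- transition_count_oracle(snapshot_pairs(rbind(src[1:2, ], dst[1:2, ]),
                                               rbind(dst[1:2, ], src[1:2, ])), g)
  expect_equal(unname(colSums(Ks$K)), c(1, 1))
})

test_that("permutation dynamics and degenerate cases give exact spectra", {
  g <- build_grid(rbind(c(0, 0), c(150, 0)), target_edge = 75)
  # deterministic alternation A -> B -> A -> ...
  pr <- snapshot_pairs(rbind(c(10, 0), c(140, 0)), rbind(c(140, 0), c(10, 0)))
  K <- estimate_koopman(pr, g)
  expect_equal(unname(K$K), rbind(c(0, 1), c(1, 0)))
  sp <- spectral_decompose(K)
  expect_equal(Re(sp$values), c(1, -1))
  expect_equal(sd(Re(sp$vectors[, 1])), 0, tolerance = 1e-12)
  # all pairs inside one box
  pr1 <- snapshot_pairs(rbind(c(10, 0), c(20, 0)), rbind(c(30, 0), c(10, 0)))
  g1 <- build_grid(rbind(c(0, 0), c(50, 0)), target_edge = 100)
  expect_equal(unname(estimate_koopman(pr1, g1)$K), matrix(1, 1, 1))
  # identity matrix: all eigenvalues one
  expect_equal(Re(spectral_decompose(diag(3))$values), rep(1, 3))
  expect_error(spectral_decompose(matrix(c(1, NaN, 0, 1), 2)), "non-finite")
})

test_that("spectra of estimated operators live in the unit disk", {
  for (s in 31:35) {
    ps <- random_pair_set(s, n = 80)
    sp <- spectral_decompose(estimate_koopman(ps$pairs, ps$grid))
    expect_lte(max(Mod(sp$values)), 1 + 1e-6)
    expect_equal(Re(sp$values[1]), 1, tolerance = 1e-6)
    # the constant function is always invariant; when the unit eigenvalue is
    # simple, the leading eigenvector itself is constant
    K1 <- estimate_koopman(ps$pairs, ps$grid)$K
    expect_equal(as.numeric(K1 %*% rep(1, ncol(K1))), rep(1, nrow(K1)),
                 tolerance = 1e-8)
    if (Re(sp$values[2]) < 1 - 1e-8) {
      v1 <- Re(sp$vectors[, 1])
      expect_lt(sd(v1) / abs(mean(v1)), 1e-6)
    }
  }
})

test_that("the spectral gap rule and its fall-back match hand evaluation", {
  expect_equal(as.integer(spectral_gap(c(1.0, 0.2, 0.1), delta = 0.5)), 1L)
  n3 <- spectral_gap(c(1.0, 0.98, 0.95, 0.30, 0.20), delta = 0.5)
  expect_equal(as.integer(n3), 3L)
  expect_equal(attr(n3, "method"), "gap")
  expect_message(nf <- spectral_gap(c(1.0, 0.9, 0.8, 0.7), delta = 0.5),
                 "successive difference")
  expect_equal(as.integer(nf), 1L)
  expect_equal(attr(nf, "method"), "max_successive_diff")
  expect_error(spectral_gap(1), "at least two")
})

test_that("block dynamics yield unit eigenvalues per block and exact recovery", {
  # boxes {1,2} mix with each other, {3,4} likewise, no cross transitions
  g <- build_grid(rbind(c(0, 0), c(400, 0)), target_edge = 100)
  at <- function(b) cbind(b * 100 - 50, 0)
  src <- rbind(at(1), at(1), at(2), at(2), at(3), at(3), at(4), at(4))
  dst <- rbind(at(2), at(1), at(1), at(2), at(4), at(3), at(3), at(4))
  K <- estimate_koopman(snapshot_pairs(src, dst), g)
  sp <- spectral_decompose(K)
  expect_equal(sum(abs(Re(sp$values) - 1) < 1e-9), 2L)  # one per block
  part <- cluster_metastable(sp, N = 2, seed = 1)
  expect_equal(part$labels[1], part$labels[2])
  expect_equal(part$labels[3], part$labels[4])
  expect_false(part$labels[1] == part$labels[3])
  # N = 1 puts every box in one cluster
  p1 <- cluster_metastable(sp, N = 1, seed = 1)
  expect_equal(p1$labels, rep(1L, 4))
  expect_error(cluster_metastable(sp, N = 10, seed = 1), "exceeds")
})

test_that("pair order does not affect the operator or the partition", {
  ps <- random_pair_set(77, n = 100)
  K <- estimate_koopman(ps$pairs, ps$grid)
  set.seed(99)
  perm <- sample(ps$pairs$n)
  ps2 <- snapshot_pairs(ps$pairs$src[perm, ], ps$pairs$dst[perm, ], tau = 20)
  K2 <- estimate_koopman(ps2, ps$grid)
  expect_equal(K$K, K2$K)
  p1 <- cluster_metastable(spectral_decompose(K), 3, seed = 5)
  p2 <- cluster_metastable(spectral_decompose(K2), 3, seed = 5)
  expect_equal(p1$labels, p2$labels)
})

test_that("eigenfunction evaluation is piecewise constant on boxes", {
  ps <- random_pair_set(5, n = 80)
  sp <- spectral_decompose(estimate_koopman(ps$pairs, ps$grid))
  pt <- ps$pairs$src[1, , drop = FALSE]
  v <- eigenfunction_at(sp, pt, j = 2)
  b <- assign_box(ps$grid, pt)
  expect_equal(v[1, 1], sp$vectors[match(b, sp$boxes), 2])
  # any point of the same box evaluates identically
  shift <- pmin(pt + 1, c(ps$grid$x_max, ps$grid$y_max))
  if (identical(assign_box(ps$grid, shift), b))
    expect_equal(eigenfunction_at(sp, shift, j = 2)[1, 1], v[1, 1])
})

test_that("a finely discretised OU process reproduces its Koopman eigenvalue", {
  theta <- 0.05; tau <- 20; sig <- 10
  rho <- exp(-theta * tau)
  n <- 1.5e5
  set.seed(22)
  innov <- rnorm(n, 0, sig * sqrt((1 - rho^2) / (2 * theta)))
  x <- as.numeric(stats::filter(innov, rho, method = "recursive"))
  pts <- cbind(x, 0)
  grid <- build_grid(pts, target_edge = diff(range(x)) / 50)
  K <- estimate_koopman(snapshot_pairs(pts[-n, , drop = FALSE],
                                       pts[-1, , drop = FALSE], tau = tau),
                        grid)
  l2 <- Re(spectral_decompose(K)$values[2])
  expect_lt(abs(l2 - rho) / rho, 0.05)
})

test_that("Koopman artefacts round-trip through their CSV exports", {
  ps <- random_pair_set(8, n = 60)
  K <- estimate_koopman(ps$pairs, ps$grid)
  sp <- spectral_decompose(K)
  part <- cluster_metastable(sp, 2, seed = 3)
  pk <- withr::local_tempfile(fileext = ".csv")
  pe <- withr::local_tempfile(fileext = ".csv")
  pp <- withr::local_tempfile(fileext = ".csv")
  write_koopman_csv(K, pk); write_eigen_csv(sp, pe); write_partition_csv(part, pp)
  trip <- read.csv(pk)
  Kback <- matrix(0, nrow(K$K), ncol(K$K), dimnames = dimnames(K$K))
  Kback[cbind(match(trip$from_box, K$boxes), match(trip$to_box, K$boxes))] <- trip$prob
  expect_equal(Kback, K$K, tolerance = 1e-12)
  expect_equal(read.csv(pe)$re, Re(sp$values), tolerance = 1e-12)
  expect_equal(nrow(read.csv(pp)), length(part$boxes))
})
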