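# Comparison metrics: shell statistics, orientation probabilities,
# consensus and shape analysis.

test_that("radial profiles average shells and flag empty bins", {
  g <- detector_geometry(32, pixel_q_step = 0.1, beam_center = c(17, 17))
  pr <- radial_profile(matrix(5, 32, 32), g, n_bins = 10)
  expect_true(all(abs(pr$values[pr$counts > 0] - 5) < 1e-12))
  expect_true(all(is.na(pr$values[pr$counts == 0])))
  # masked pixels are excluded
  mask <- matrix(FALSE, 32, 32); mask[1:16, ] <- TRUE
  gm <- detector_geometry(32, pixel_q_step = 0.1, beam_center = c(17, 17),
                          mask = mask)
  x <- matrix(5, 32, 32); x[1:16, ] <- 1e6
  prm <- radial_profile(x, gm, n_bins = 10)
  expect_true(all(abs(prm$values[prm$counts > 0] - 5) < 1e-12))
  # shell means are invariant under in-shell permutation: rotating the
  # pattern by 90 degrees leaves the profile unchanged
  set.seed(2)
  y <- matrix(rexp(32 * 32), 32, 32)
  y_sym <- (y + y[32:1, ] + y[, 32:1] + y[32:1, 32:1]) / 4
  g0 <- detector_geometry(32, pixel_q_step = 0.1,
                          beam_center = c(16.5, 16.5))
  p1 <- radial_profile(y_sym, g0, n_bins = 8)
  p2 <- radial_profile(t(y_sym), g0, n_bins = 8)
  expect_equal(p1$values, p2$values, tolerance = 1e-12)
})

test_that("R factor identities and the sqrt(2) closed form hold", {
  set.seed(3)
  v <- intensity_volume(array(runif(16^3) + 0.1, c(16, 16, 16)))
  r0 <- r_factor(v, v)
  expect_equal(r0$overall, 0)
  expect_true(all(abs(r0$shells$values[r0$shells$counts > 0]) < 1e-12))
  # amplitudes scale by sqrt(2): R = 2(sqrt(2)-1)/(sqrt(2)+1) everywhere
  v2 <- intensity_volume(2 * v$intensities)
  r2 <- r_factor(v, v2)
  expected <- 2 * (sqrt(2) - 1) / (sqrt(2) + 1)
  expect_equal(r2$overall, expected, tolerance = 1e-12)
  expect_true(all(abs(r2$shells$values[r2$shells$counts > 0] - expected)
                  < 1e-9))
  # symmetry in the arguments
  expect_equal(r_factor(v2, v)$overall, r2$overall, tolerance = 1e-12)
})

test_that("FSC identities, null level and resolution query", {
  set.seed(4)
  a <- array(rnorm(24^3), c(24, 24, 24))
  f1 <- fsc(a, a, n_shells = 8)
  expect_true(all(abs(f1$shells$values[f1$shells$counts > 0] - 1) < 1e-9))
  fneg <- fsc(a, -a, n_shells = 8)
  expect_true(all(abs(fneg$shells$values[fneg$shells$counts > 0] + 1)
                  < 1e-9))
  # independent white noise: |FSC| < 3/sqrt(shell count) in >= 95% of
  # shells
  b <- array(rnorm(24^3), c(24, 24, 24))
  fn <- fsc(a, b, n_shells = 8)
  ok <- fn$shells$counts > 0
  frac <- mean(abs(fn$shells$values[ok]) <
                 3 / sqrt(fn$shells$counts[ok]))
  expect_gte(frac, 0.95)
  # resolution = 1/q of the first crossing
  expect_true(is.finite(fn$resolution))
  expect_equal(fn$resolution, 1 / fn$resolution_q)
})

test_that("orientation probabilities are a proper Poisson E-step", {
  # symmetry-broken particle (offset core): an icosahedrally symmetric
  # one would make 60 orientations indistinguishable
  model <- particle_model(core_offset = c(4, 2, 0))
  vol <- ground_truth_intensity(make_icosahedron_density(model), 4,
                                keep_amplitude = FALSE)
  geom <- detector_geometry(64L, pixel_q_step = vol$q_step,
                            beam_center = c(33, 33))
  fx <- list(volume = vol, geom = geom)
  # odd in-plane count: with a flat Ewald sphere, psi and psi + pi give
  # Friedel-identical slices, so an even grid would hold an exact twin
  # of every orientation
  grid <- orientation_grid(n_axes = 40, n_inplane = 3)
  expect_equal(grid$n_orientations, 120)
  expect_true(all(abs(sqrt(rowSums(grid$quaternions^2)) - 1) < 1e-12))
  # beam axis ignores the in-plane angle
  rots <- quat_to_matrix(grid$quaternions)
  ax <- t(vapply(rots, function(r) as.vector(r %*% c(0, 0, 1)), numeric(3)))
  expect_equal(ax, grid$axes, tolerance = 1e-9)

  # bright noiseless patterns rendered at grid orientations are
  # assigned back to those orientations (Gibbs inequality; brightness
  # keeps integer rounding well below the inter-orientation divergence)
  pick <- c(7L, 61L, 113L)
  frames <- array(0, c(64, 64, length(pick)))
  for (i in seq_along(pick))
    frames[, , i] <- render_noiseless_slice(fx$volume,
                                            grid$quaternions[pick[i], ],
                                            fx$geom, 1e6)
  ps <- pattern_stack(round(frames), geometry = fx$geom,
                      type = "photons")
  pm <- orientation_probabilities(ps, fx$volume, grid)
  expect_equal(unname(rowSums(pm)), rep(1, 3), tolerance = 1e-9)
  expect_identical(unname(apply(pm, 1, which.max)), pick)
})

test_that("p-max summaries report the uniform baseline and low fraction", {
  # uniform rows: p_max = 1/n below any larger cutoff
  m <- matrix(1 / 1e5, 4, 1e5)
  st <- pmax_stats(m, low_cutoff = 1e-4)
  expect_equal(st$baseline, 1e-5)
  expect_equal(st$fraction_low, 1)
  # one-hot rows are never uncertain
  m2 <- diag(4)
  st2 <- pmax_stats(m2, low_cutoff = 0.99)
  expect_equal(st2$fraction_low, 0)
  expect_error(pmax_stats(matrix(0.3, 2, 2)), "sum to 1")
})

test_that("orientation sphere maps conserve the selected mass", {
  grid <- orientation_grid(n_axes = 30, n_inplane = 4)
  n_or <- grid$n_orientations
  # every pattern concentrated on one orientation -> single hot axis
  pm <- matrix(0, 5, n_or); pm[, 17] <- 1
  sm <- orientation_sphere_map(pm, grid, top_n = 10)
  expect_equal(sum(sm$weight > 0), 1)
  expect_equal(which(sm$weight > 0), grid$axis_index[17])
  expect_equal(sum(sm$weight), 5)
  # uniform rows spread evenly within combinatorial tolerance
  pu <- matrix(1 / n_or, 6, n_or)
  su <- orientation_sphere_map(pu, grid, top_n = n_or)
  expect_lt(diff(range(su$weight)) / mean(su$weight), 1e-9)
  # top-n mass is bounded by the pattern count
  expect_lte(sum(orientation_sphere_map(pu, grid, 10)$weight), 6)
})

test_that("consensus reproduces hand-counted Venn intersections", {
  mk <- function(sel, universe = sprintf("p%d", 1:5))
    label_set(universe, as.numeric(universe %in% sel))
  a <- mk(c("p1", "p2", "p3"))
  b <- mk(c("p2", "p3", "p4"))
  c3 <- mk(c("p3", "p4", "p5"))
  cv <- consensus(list(cnn = a, gc = b, dm = c3))
  expect_identical(unname(cv$sizes), c(3L, 3L, 3L))
  expect_identical(unname(cv$pairwise), c(2L, 1L, 2L))
  expect_identical(cv$triple, 1L)
  expect_identical(cv$common$pattern_id, "p3")
  # identical sets: everything equals the set size
  ci <- consensus(list(a, a, a))
  expect_true(all(ci$pairwise == 3))
  expect_identical(ci$triple, 3L)
  # disjoint sets: empty intersection
  cd <- consensus(list(mk("p1"), mk("p2"), mk("p3")))
  expect_identical(cd$triple, 0L)
  expect_identical(nrow(cd$common), 0L)
  # |A n B n C| <= min pairwise
  expect_lte(cv$triple, min(cv$pairwise))
  # mismatched universes are rejected with the orphans named
  expect_error(consensus(list(a, mk("p1", sprintf("q%d", 1:5)))),
               "orphan")
})

test_that("Fibonacci lattice spacing is near-uniform", {
  p <- fibonacci_sphere(100)
  expect_equal(rowSums(p^2), rep(1, 100), tolerance = 1e-12)
  # nearest-neighbour angular spacing within [0.7, 1.3] x the uniform
  # expectation sqrt(4 pi / n)... up to the lattice constant
  d <- as.matrix(dist(p))
  diag(d) <- Inf
  nn_ang <- 2 * asin(apply(d, 1, min) / 2)
  expected <- sqrt(4 * pi / 100)  # area-per-point spacing
  expect_true(all(nn_ang > 0.7 * expected))
  expect_true(all(nn_ang < 1.3 * expected))
})

test_that("cross-section eccentricity separates balls from ellipsoids", {
  ax <- seq_len(96) - 49
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  ball <- array(0, c(96, 96, 96)); ball[r2 <= 40^2] <- 1
  eb <- eccentricity_analysis(ball, n_planes = 60)
  expect_lt(attr(eb, "mean_eccentricity"), 0.05)

  ax64 <- seq_len(64) - 33
  ell <- array(0, c(64, 64, 64))
  ell[outer(outer((ax64 / 28)^2, (ax64 / 14)^2, `+`),
            (ax64 / 14)^2, `+`) <= 1] <- 1
  ee <- eccentricity_analysis(ell, n_planes = 60)
  # sections through the long axis approach e = sqrt(1 - 1/4) = 0.866
  expect_gt(max(ee$eccentricity), 0.8)
  expect_lt(max(ee$eccentricity), 0.9)
  expect_gt(attr(ee, "mean_eccentricity"),
            attr(eb, "mean_eccentricity"))
  expect_error(suppressWarnings(
    eccentricity_analysis(array(0, c(8, 8, 8)))), "usable")
})
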