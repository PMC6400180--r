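# Graph-cut classifier: similarity graph, region force, primal-dual
# TV minimization and the exhaustive-search cross-check.

# brute-force minimizer of the discrete Potts energy over {0,1}^V;
# returns the best labelling, its energy and the runner-up energy
brute_force_potts <- function(graph, force, lambda) {
  n <- graph$n_vertices
  best <- NULL; best_en <- Inf; second <- Inf
  for (code in 0:(2^n - 1)) {
    u <- as.numeric(bitwAnd(bitwShiftR(code, 0:(n - 1)), 1L))
    en <- potts_energy(graph, force, u, lambda)
    if (en < best_en) {
      second <- best_en; best_en <- en; best <- u
    } else if (en < second) second <- en
  }
  list(u = best, energy = best_en, second = second)
}

# random geometric instance: two Gaussian blobs in 2D, one seed each
random_gc_instance <- function(n, seed) {
  set.seed(seed)
  n1 <- ceiling(n / 2)
  x <- rbind(matrix(rnorm(2 * n1, 0, 1), ncol = 2),
             matrix(rnorm(2 * (n - n1), 3, 1), ncol = 2))
  g <- build_similarity_graph(x, k = min(3, n - 1))
  sl <- rep(NA_integer_, n); sl[1] <- 0L; sl[n] <- 1L
  f <- compute_region_force(g, sl)
  list(graph = g, force = f)
}

test_that("similarity weights follow the locally scaled kernel", {
  # hand-worked collinear example: points 0, 1, 10 with k = 2;
  # sigma = RMS neighbour distance: sigma0 = sqrt((1+100)/2),
  # sigma1 = sqrt((1+81)/2); w01 = exp(-1 / (sigma0 sigma1))
  g <- build_similarity_graph(matrix(c(0, 1, 10), ncol = 1), k = 2)
  expect_equal(g$sigma, c(sqrt(50.5), sqrt(41), sqrt(90.5)),
               tolerance = 1e-12)
  i <- which(g$edges[, 1] == 1 & g$edges[, 2] == 2)
  expect_equal(g$weights[i], exp(-1 / (sqrt(50.5) * sqrt(41))),
               tolerance = 1e-12)

  # weights live in (0, 1]; duplicate points hit w = 1 via sigma floor
  set.seed(3)
  x <- matrix(rnorm(40), 20, 2)
  gg <- build_similarity_graph(x, k = 4)
  expect_true(all(gg$weights > 0 & gg$weights <= 1))
  expect_true(all(gg$edges[, 1] < gg$edges[, 2]))
  xdup <- rbind(x, x[1, , drop = FALSE])
  gd <- build_similarity_graph(xdup, k = 4)
  i <- which(gd$edges[, 1] == 1 & gd$edges[, 2] == 21)
  expect_equal(gd$weights[i], 1)  # d = 0 -> exp(0)

  expect_error(build_similarity_graph(x[1:3, ], k = 4), "k\\+1")
})

test_that("region force interpolates seed votes and pins the seeds", {
  # 3 points on a line; ends are seeds of opposite class
  g <- build_similarity_graph(matrix(c(0, 1, 2), ncol = 1), k = 2)
  sl <- c(0L, NA, 1L)
  f <- compute_region_force(g, sl)
  expect_equal(f$prior_1[1], 1e-6)
  expect_equal(f$prior_1[3], 1 - 1e-6)
  # the midpoint is equidistant: prior 0.5, equal costs
  expect_equal(f$prior_1[2], 0.5, tolerance = 1e-12)
  expect_equal(f$cost_0[2], f$cost_1[2], tolerance = 1e-12)
  expect_error(compute_region_force(g, c(1L, NA, 1L)), "each class")
})

test_that("primal-dual solution matches the exhaustive minimizer", {
  # unary-only case decouples
  inst <- random_gc_instance(8, 1)
  fld0 <- solve_potts_primal_dual(inst$graph, inst$force, lambda = 0)
  expect_identical(fld0$u,
                   as.numeric(inst$force$cost_1 < inst$force$cost_0))

  # randomized instances vs 2^V enumeration (unique-optimum ones only)
  checked <- 0L; seed <- 0L
  while (checked < 12L && seed < 60L) {
    seed <- seed + 1L
    inst <- random_gc_instance(sample(6:10, 1), seed + 100)
    bf <- brute_force_potts(inst$graph, inst$force, 0.5)
    if (bf$second - bf$energy < 1e-7) next  # tie: undefined rounding
    fld <- solve_potts_primal_dual(inst$graph, inst$force, 0.5,
                                   tol = 1e-8)
    expect_identical(as.numeric(fld$u > 0.5), bf$u)
    # relaxed minimum is a lower bound within the duality gap
    expect_lte(fld$energy, bf$energy + 1e-6)
    checked <- checked + 1L
  }
  expect_gte(checked, 12L)
})

test_that("thresholding the relaxed solution is stable across theta", {
  # TV + unary co-area: on unique-optimum instances every threshold in
  # (0,1) cuts out the same discrete labelling
  found <- 0L; seed <- 200L
  while (found < 5L && seed < 240L) {
    seed <- seed + 1L
    inst <- random_gc_instance(8, seed)
    bf <- brute_force_potts(inst$graph, inst$force, 0.5)
    if (bf$second - bf$energy < 1e-6) next
    fld <- solve_potts_primal_dual(inst$graph, inst$force, 0.5,
                                   tol = 1e-9)
    for (th in c(0.25, 0.5, 0.75))
      expect_identical(as.numeric(fld$u > th), bf$u)
    found <- found + 1L
  }
  expect_gte(found, 5L)
})

test_that("two dissimilar cliques each take their seed's class", {
  set.seed(9)
  x <- rbind(matrix(rnorm(8, 0, 0.05), 4, 2),
             matrix(rnorm(8, 10, 0.05), 4, 2))
  g <- build_similarity_graph(x, k = 3)
  sl <- rep(NA_integer_, 8); sl[1] <- 0L; sl[5] <- 1L
  f <- compute_region_force(g, sl)
  bf <- brute_force_potts(g, f, 5)
  fld <- solve_potts_primal_dual(g, f, 5)
  expect_identical(as.numeric(fld$u > 0.5), c(0, 0, 0, 0, 1, 1, 1, 1))
  expect_identical(bf$u, c(0, 0, 0, 0, 1, 1, 1, 1))
})

test_that("classify_gc is deterministic, respects seeds and scale", {
  set.seed(4)
  x <- rbind(matrix(rnorm(30, 0, 0.5), ncol = 3),
             matrix(rnorm(30, 4, 0.5), ncol = 3))
  rownames(x) <- sprintf("p%02d", 1:20)
  sl <- c(p01 = 0L, p02 = 0L, p11 = 1L, p12 = 1L)
  l1 <- classify_gc(x, sl, k = 4)
  l2 <- classify_gc(x, sl, k = 4)
  expect_identical(l1, l2)
  expect_identical(l1$class, rep(0:1, each = 10))
  # seeds keep their own label
  expect_identical(l1$class[match(names(sl), l1$pattern_id)],
                   as.integer(sl))
  # global feature scaling is absorbed by the local sigma normalization
  l3 <- classify_gc(x * 37, sl, k = 4)
  expect_equal(l1$score, l3$score, tolerance = 1e-8)
  # theta = 0: every positive score goes to class 1
  l4 <- classify_gc(x, sl, k = 4, theta = 0)
  expect_identical(l4$class, as.integer(l4$score > 0))
})
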