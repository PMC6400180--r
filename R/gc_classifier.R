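# Semi-supervised graph-cut classification: locally scaled k-NN
# similarity graph, region-force unary costs from labelled seeds, and a
# total-variation Potts functional minimized by a Chambolle-Pock style
# primal-dual (continuous max-flow) algorithm.

#' Build a locally scaled k-nearest-neighbour similarity graph
#'
#' Vertices are patterns; vertex `i` is joined to its `k` nearest
#' neighbours under Euclidean distance on the flattened feature images,
#' and the edge set is symmetrized by union.  Edge weights follow the
#' locally scaled radial basis function
#' `w_ij = exp(-d(x_i, x_j)^2 / (sigma_i * sigma_j))`, with `sigma_i`
#' the local scale of vertex `i`: the root-mean-square of the distances
#' from `x_i` to its `k` nearest neighbours (the standard deviation of
#' the neighbours about `x_i` itself).  Taking the spread about the
#' point -- rather than the centred spread of the neighbour distances --
#' keeps `d^2 / (sigma_i sigma_j)` of order one, so weights neither
#' saturate nor underflow in high dimension.  Zero scales (duplicate
#' points) are floored at `1e-12 * median pairwise distance`.
#'
#' @param features a [pattern_stack()] of feature images, or a numeric
#'   matrix with one pattern per row.
#' @param k neighbours per vertex (>= 2).
#' @return An object of class `similarity_graph`: `edges` (m x 2 integer
#'   matrix, i < j), `weights`, `sigma`, `n_vertices`, `k`, `ids`, and
#'   the feature matrix used.
#' @export
build_similarity_graph <- function(features, k = 10L) {
  x <- if (inherits(features, "pattern_stack")) as_feature_matrix(features)
       else as.matrix(features)
  n <- nrow(x)
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2")
  if (n < k + 1) stop("need at least k+1 = ", k + 1, " patterns")
  dm <- as.matrix(stats::dist(x))
  sigma <- numeric(n)
  nn <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(dm[i, -i])
    nb <- seq_len(n)[-i][ord[seq_len(k)]]
    nn[i, ] <- nb
    dd <- dm[i, nb]
    sigma[i] <- sqrt(mean(dd^2))
  }
  floor_sig <- 1e-12 * median(dm[upper.tri(dm)])
  if (any(sigma <= 0)) {
    warning("duplicate vertices at distance 0; sigma floor applied")
    sigma[sigma <= floor_sig] <- max(floor_sig, .Machine$double.xmin)
  }
  ii <- rep(seq_len(n), each = k)
  jj <- as.vector(t(nn))
  e <- cbind(pmin(ii, jj), pmax(ii, jj))
  e <- unique(e)
  w <- exp(-dm[e]^2 / (sigma[e[, 1]] * sigma[e[, 2]]))
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("pat%06d", seq_len(n))
  structure(list(n_vertices = n, edges = e, weights = w, sigma = sigma,
                 k = k, ids = ids, features = x),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("<similarity_graph> %d vertices, %d edges (k = %d)\n",
              x$n_vertices, nrow(x$edges), x$k))
  invisible(x)
}

#' Region force from labelled seeds
#'
#' The prior probability of vertex `x` belonging to class 1 is the
#' similarity-weighted vote of the seeds,
#' `prior_1(x) = sum_{y in seeds_1} w(x, y) / sum_{y in seeds} w(x, y)`,
#' with `w` evaluated directly between `x` and every seed using the
#' graph's locally scaled kernel.  Seeds receive `1 - eps` (class 1) or
#' `eps` (class 0).  Unary costs are `cost_1 = -log(prior_1)`,
#' `cost_0 = -log(1 - prior_1)`.
#'
#' @param graph a `similarity_graph`.
#' @param seed_labels named integer vector (values 0/1) keyed by pattern
#'   id, or an integer vector with NA for unlabelled vertices.
#' @param eps probability clip, keeping priors inside `[eps, 1 - eps]`.
#' @return An object of class `region_force` with `prior_1`, `cost_0`,
#'   `cost_1`, `seed_idx`, `seed_class`.
#' @export
compute_region_force <- function(graph, seed_labels, eps = 1e-6) {
  stopifnot(inherits(graph, "similarity_graph"))
  sl <- resolve_seed_labels(graph$ids, seed_labels)
  seed_idx <- which(!is.na(sl))
  seed_class <- sl[seed_idx]
  if (!any(seed_class == 1) || !any(seed_class == 0))
    stop("need at least one seed of each class")
  x <- graph$features
  n <- graph$n_vertices
  prior <- numeric(n)
  xs <- x[seed_idx, , drop = FALSE]
  # direct locally-scaled similarities vertex -> every seed
  d2 <- outer(rowSums(x^2), rowSums(xs^2), `+`) - 2 * (x %*% t(xs))
  d2 <- pmax(d2, 0)
  w <- exp(-d2 / outer(graph$sigma, graph$sigma[seed_idx]))
  w1 <- rowSums(w[, seed_class == 1, drop = FALSE])
  wt <- rowSums(w)
  prior <- ifelse(wt > 0, w1 / wt, 0.5)
  prior[seed_idx] <- ifelse(seed_class == 1, 1 - eps, eps)
  prior <- pmin(pmax(prior, eps), 1 - eps)
  structure(list(prior_1 = prior, cost_1 = -log(prior),
                 cost_0 = -log(1 - prior), seed_idx = seed_idx,
                 seed_class = seed_class),
            class = "region_force")
}

#' @noRd
resolve_seed_labels <- function(ids, seed_labels) {
  n <- length(ids)
  if (!is.null(names(seed_labels))) {
    sl <- rep(NA_integer_, n)
    m <- match(names(seed_labels), ids)
    if (anyNA(m)) stop("seed labels refer to unknown pattern ids")
    sl[m] <- as.integer(seed_labels)
  } else {
    if (length(seed_labels) != n)
      stop("unnamed seed_labels must have one entry per vertex (NA = unlabelled)")
    sl <- as.integer(seed_labels)
  }
  if (any(!is.na(sl) & !(sl %in% c(0L, 1L))))
    stop("seed labels must be 0 or 1")
  sl
}

#' Minimize the total-variation Potts functional by primal-dual iteration
#'
#' Minimizes, over `u` in `[0,1]^V`,
#' `E(u) = sum_x [cost_1(x) u(x) + cost_0(x) (1 - u(x))]
#'         + lambda * sum_(i,j) w_ij |u_i - u_j|`,
#' the convex relaxation of the binary min-cut problem, using a
#' Chambolle-Pock primal-dual scheme (the dual variable is the edge flow,
#' so this is simultaneously a continuous max-flow solver).  Steps obey
#' `tau * sigma * L^2 <= 1` with `L` the weighted-gradient operator norm
#' estimated by power iteration.  Iteration stops at relative duality gap
#' `tol`.
#'
#' @param graph a `similarity_graph`.
#' @param force a `region_force`.
#' @param lambda total-variation weight (> 0 unless exactly 0, which
#'   reduces to a per-vertex unary decision).
#' @param tol relative duality-gap tolerance.
#' @param max_iter iteration cap; non-convergence returns the best
#'   iterate with `converged = FALSE` and a warning.
#' @param theta classification threshold stored with the field.
#' @return An object of class `labeling_field`: `u`, `theta`, `energy`,
#'   `gap`, `iterations`, `converged`.
#' @export
solve_potts_primal_dual <- function(graph, force, lambda = 0.1,
                                    tol = 1e-6, max_iter = 4000L,
                                    theta = 0.5) {
  stopifnot(inherits(graph, "similarity_graph"),
            inherits(force, "region_force"), lambda >= 0)
  n <- graph$n_vertices
  s <- force$cost_1 - force$cost_0
  const <- sum(force$cost_0)
  if (lambda == 0 || nrow(graph$edges) == 0) {
    u <- as.numeric(s < 0)
    en <- sum(pmin(force$cost_0, force$cost_1))
    return(structure(list(u = u, theta = theta, energy = en, gap = 0,
                          iterations = 0L, converged = TRUE,
                          ids = graph$ids),
                     class = "labeling_field"))
  }
  e <- graph$edges
  wl <- lambda * graph$weights
  m <- nrow(e)
  D <- Matrix::sparseMatrix(i = rep(seq_len(m), 2),
                            j = c(e[, 1], e[, 2]),
                            x = c(rep(1, m), rep(-1, m)),
                            dims = c(m, n))
  Dt <- Matrix::t(D)
  # operator norm by power iteration
  v <- rnorm(n); v <- v / sqrt(sum(v^2))
  for (it in 1:30) {
    v <- as.vector(Dt %*% (D %*% v))
    nv <- sqrt(sum(v^2)); if (nv == 0) break
    v <- v / nv
  }
  L <- sqrt(max(nv, 1e-12))
  tau <- 0.99 / L; sig <- 0.99 / L
  u <- rep(0.5, n); ubar <- u; p <- numeric(m)
  primal_energy <- function(u)
    sum(s * u) + const + sum(wl * abs(as.vector(D %*% u)))
  dual_value <- function(p)
    const + sum(pmin(0, s + as.vector(Dt %*% p)))
  best_u <- u; best_en <- primal_energy(u)
  gap <- Inf; iter <- 0L; converged <- FALSE
  for (iter in seq_len(max_iter)) {
    p <- p + sig * as.vector(D %*% ubar)
    p <- pmin(pmax(p, -wl), wl)
    u_new <- u - tau * (s + as.vector(Dt %*% p))
    u_new <- pmin(pmax(u_new, 0), 1)
    ubar <- 2 * u_new - u
    u <- u_new
    if (iter %% 10L == 0L || iter == max_iter) {
      en <- primal_energy(u)
      if (en < best_en) { best_en <- en; best_u <- u }
      dv <- dual_value(p)
      gap <- (en - dv) / max(abs(en), abs(dv), 1e-12)
      if (is.finite(gap) && gap <= tol) { converged <- TRUE; break }
    }
  }
  if (!converged)
    warning("primal-dual solver hit max_iter with relative gap ",
            signif(gap, 3), "; returning best iterate")
  en <- primal_energy(u)
  if (en < best_en) { best_en <- en; best_u <- u }
  structure(list(u = best_u, theta = theta, energy = best_en, gap = gap,
                 iterations = iter, converged = converged,
                 ids = graph$ids),
            class = "labeling_field")
}

#' Potts energy of a labelling
#'
#' The discrete objective evaluated at an arbitrary (possibly fractional)
#' labelling; used by the exhaustive-search cross-checks.
#'
#' @param graph a `similarity_graph`.
#' @param force a `region_force`.
#' @param u per-vertex labelling in `[0, 1]`.
#' @param lambda total-variation weight.
#' @return scalar energy.
#' @export
potts_energy <- function(graph, force, u, lambda = 1) {
  du <- abs(u[graph$edges[, 1]] - u[graph$edges[, 2]])
  sum(force$cost_1 * u + force$cost_0 * (1 - u)) +
    lambda * sum(graph$weights * du)
}

#' Graph-cut classification of feature images
#'
#' Composition of [build_similarity_graph()], [compute_region_force()]
#' and [solve_potts_primal_dual()]; the relaxed labelling is thresholded
#' at `theta` (strict inequality: `u = theta` goes to class 0).  The
#' classification is transductive and fully deterministic.
#'
#' @inheritParams build_similarity_graph
#' @inheritParams compute_region_force
#' @param lambda total-variation weight.
#' @param theta score threshold for class 1.
#' @param tol,max_iter solver controls, see [solve_potts_primal_dual()].
#' @return A label set data.frame: `pattern_id`, `score`, `class`.
#' @export
classify_gc <- function(features, seed_labels, k = 10L, lambda = 0.1,
                        theta = 0.5, tol = 1e-6, max_iter = 4000L) {
  graph <- build_similarity_graph(features, k)
  force <- compute_region_force(graph, seed_labels)
  fld <- solve_potts_primal_dual(graph, force, lambda, tol, max_iter,
                                 theta)
  label_set(graph$ids, fld$u, theta)
}
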