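# Diffusion-map embedding and nearest-centroid labelling in diffusion
# coordinates.

#' Gaussian affinity matrix over feature images
#'
#' `A_ij = exp(-d(x_i, x_j)^2 / epsilon)` with Euclidean `d`; symmetric
#' with unit diagonal.  `kernel_scale = "auto"` sets epsilon to the
#' median of the squared k-nearest-neighbour distances, which makes the
#' embedding invariant to a global rescaling of the features.
#'
#' @param features a [pattern_stack()] or numeric matrix (patterns in
#'   rows).
#' @param kernel_scale positive scalar epsilon, or `"auto"`.
#' @param k neighbour count used by the `"auto"` scale.
#' @return symmetric affinity matrix with the ids as dimnames.
#' @export
build_affinity <- function(features, kernel_scale = "auto", k = 10L) {
  x <- if (inherits(features, "pattern_stack")) as_feature_matrix(features)
       else as.matrix(features)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 patterns")
  d2 <- as.matrix(stats::dist(x))^2
  if (identical(kernel_scale, "auto")) {
    k <- min(as.integer(k), n - 1)
    knn2 <- apply(d2, 1, function(r) sort(r[-which.min(r)])[seq_len(k)])
    kernel_scale <- median(knn2)
    if (kernel_scale <= 0) kernel_scale <- max(d2[d2 > 0], 1e-12)
  }
  stopifnot(kernel_scale > 0)
  a <- exp(-d2 / kernel_scale)
  dimnames(a) <- list(rownames(x), rownames(x))
  attr(a, "kernel_scale") <- kernel_scale
  a
}

#' Diffusion-map embedding of an affinity matrix
#'
#' Row-normalizes the kernel, `P = D^-1 A`, via the symmetric conjugate
#' `S = D^-1/2 A D^-1/2` (same spectrum, numerically stable), drops the
#' trivial constant eigenvector (eigenvalue 1) and returns the next `m`
#' eigenvectors, each scaled by `eigenvalue^t`.
#'
#' @param affinity symmetric non-negative matrix from [build_affinity()].
#' @param m number of non-trivial diffusion coordinates.
#' @param t diffusion time used for the eigenvalue scaling.
#' @return An object of class `diffusion_embedding`: `coordinates`
#'   (n x m), `eigenvalues` (descending, leading entry 1), `m`, `t`,
#'   `kernel_scale`.
#' @export
diffusion_embedding <- function(affinity, m = 5L, t = 1) {
  a <- as.matrix(affinity)
  n <- nrow(a)
  m <- as.integer(m)
  if (m < 1) stop("m must be >= 1")
  if (m > n - 1) stop("m exceeds the available non-trivial spectrum")
  deg <- rowSums(a)
  if (any(deg <= 0)) stop("affinity has an isolated vertex")
  dh <- 1 / sqrt(deg)
  s <- a * outer(dh, dh)
  es <- eigen(s, symmetric = TRUE)
  lam <- es$values
  # eigenvectors of P = D^-1 A are D^-1/2 v
  vec <- es$vectors * dh
  ord <- order(lam, decreasing = TRUE)
  lam <- lam[ord]; vec <- vec[, ord, drop = FALSE]
  coords <- vec[, 1 + seq_len(m), drop = FALSE] *
    rep(lam[1 + seq_len(m)]^t, each = n)
  rownames(coords) <- rownames(a)
  structure(list(coordinates = coords, eigenvalues = lam, m = m, t = t,
                 kernel_scale = attr(affinity, "kernel_scale"),
                 ids = rownames(a)),
            class = "diffusion_embedding")
}

#' Classify patterns in diffusion coordinates
#'
#' Class centroids are computed from the seeds in diffusion space; the
#' class-1 score of a pattern is
#' `d0^2 / (d0^2 + d1^2)` (squared distance to the class-0 centroid over
#' the sum), so a pattern at the class-1 centroid scores 1 and an
#' equidistant pattern scores 0.5 (class 0 under the strict threshold).
#'
#' @param embedding a `diffusion_embedding`.
#' @param seed_labels named 0/1 vector keyed by pattern id, or per-vertex
#'   vector with NA for unlabelled.
#' @param theta score threshold for class 1 (strict inequality).
#' @return A [label_set()].
#' @export
classify_dm <- function(embedding, seed_labels, theta = 0.5) {
  stopifnot(inherits(embedding, "diffusion_embedding"))
  ids <- embedding$ids
  if (is.null(ids)) ids <- sprintf("pat%06d", seq_len(nrow(embedding$coordinates)))
  sl <- resolve_seed_labels(ids, seed_labels)
  if (!any(sl == 1, na.rm = TRUE) || !any(sl == 0, na.rm = TRUE))
    stop("need at least one seed of each class")
  x <- embedding$coordinates
  c0 <- colMeans(x[which(sl == 0), , drop = FALSE])
  c1 <- colMeans(x[which(sl == 1), , drop = FALSE])
  d0 <- colSums((t(x) - c0)^2)
  d1 <- colSums((t(x) - c1)^2)
  tot <- d0 + d1
  score <- ifelse(tot > 0, d0 / tot, 0.5)
  label_set(ids, score, theta)
}
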