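# Comparison statistics: radially binned shell curves (profiles,
# R factors, FSC, PRTF), orientation log-likelihoods with p-max
# analysis, orientation sphere maps, consensus/Venn selection and
# cross-section eccentricity.

#' Radially binned shell curve
#'
#' @param q_edges strictly increasing bin edges (length `n + 1`).
#' @param values per-shell statistic (NA where the shell is empty).
#' @param counts elements contributing to each shell.
#' @return data.frame of class `shell_curve` with columns `q_lo`, `q_hi`,
#'   `q_centers`, `values`, `counts`.
#' @export
shell_curve <- function(q_edges, values, counts) {
  stopifnot(all(diff(q_edges) > 0),
            length(values) == length(q_edges) - 1,
            length(counts) == length(values))
  out <- data.frame(q_lo = q_edges[-length(q_edges)],
                    q_hi = q_edges[-1],
                    q_centers = (q_edges[-1] + q_edges[-length(q_edges)]) / 2,
                    values = values, counts = counts)
  class(out) <- c("shell_curve", "data.frame")
  out
}

#' First q at which a shell curve crosses below a cutoff
#'
#' @param curve a [shell_curve()].
#' @param cutoff threshold value.
#' @return the centre q of the first non-empty shell with
#'   `value < cutoff`, or NA if the curve never crosses.
#' @export
curve_crossing <- function(curve, cutoff) {
  below <- which(curve$values < cutoff & curve$counts > 0)
  if (length(below)) curve$q_centers[below[1]] else NA_real_
}

# radial q magnitude of every element of a centred 2D/3D array
#' @noRd
radial_q <- function(dims, q_step) {
  ax <- lapply(dims, centered_axis)
  if (length(dims) == 2) {
    sqrt(outer(ax[[1]]^2, ax[[2]]^2, `+`)) * q_step
  } else {
    r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
    array(sqrt(r2) * q_step, dims)
  }
}

# mean of `x` in radial shells; NA marks empty shells
#' @noRd
radial_shell_mean <- function(x, q_step, n_bins, exclude = NULL,
                              qmax = NULL) {
  q <- radial_q(dim(x), q_step)
  keep <- if (is.null(exclude)) rep(TRUE, length(x)) else !exclude
  if (is.null(qmax)) qmax <- max(q)
  edges <- seq(0, qmax * (1 + 1e-9), length.out = n_bins + 1)
  bin <- findInterval(q[keep], edges, rightmost.closed = TRUE)
  inside <- bin >= 1 & bin <= n_bins
  vals <- x[keep][inside]
  bin <- bin[inside]
  counts <- tabulate(bin, n_bins)
  sums <- rep(0, n_bins)
  agg <- tapply(vals, bin, sum)
  sums[as.integer(names(agg))] <- agg
  means <- ifelse(counts > 0, sums / counts, NA_real_)
  shell_curve(edges, means, counts)
}

#' Radial intensity profile of a pattern or volume
#'
#' Mean intensity per q shell, with
#' `q = (4*pi/lambda) * sin(theta/2) ~ pixel_q_step * r` in the
#' small-angle regime.  Masked pixels (or unmeasured voxels) are
#' excluded; empty shells are NA, not zero.
#'
#' @param data a 2D matrix with a [detector_geometry()], a
#'   [pattern_stack()] (frames are averaged first), an
#'   [intensity_volume()], or a plain 3D array with `q_step`.
#' @param geometry a [detector_geometry()] (2D input).
#' @param n_bins number of q shells.
#' @param q_step reciprocal step per voxel for plain-array input.
#' @return A [shell_curve()].
#' @export
radial_profile <- function(data, geometry = NULL, n_bins = 32L,
                           q_step = NULL) {
  if (inherits(data, "pattern_stack")) {
    if (is.null(geometry)) geometry <- data$geometry
    avg <- apply(data$values, c(1, 2), mean)
    return(radial_profile(avg, geometry, n_bins))
  }
  if (inherits(data, "intensity_volume"))
    return(radial_shell_mean(data$intensities, data$q_step, n_bins,
                             exclude = !data$measured_mask))
  if (is.matrix(data)) {
    if (is.null(geometry)) stop("2D input needs a detector geometry")
    q <- sqrt(outer((seq_len(nrow(data)) - geometry$beam_center[1])^2,
                    (seq_len(ncol(data)) - geometry$beam_center[2])^2,
                    `+`)) * geometry$pixel_q_step
    edges <- seq(0, max(q) * (1 + 1e-9), length.out = n_bins + 1)
    keep <- !geometry$mask
    bin <- findInterval(q[keep], edges, rightmost.closed = TRUE)
    counts <- tabulate(bin, n_bins)
    sums <- rep(0, n_bins)
    agg <- tapply(data[keep], bin, sum)
    sums[as.integer(names(agg))] <- agg
    return(shell_curve(edges, ifelse(counts > 0, sums / counts, NA),
                       counts))
  }
  if (length(dim(data)) == 3) {
    if (is.null(q_step)) q_step <- 1
    return(radial_shell_mean(data, q_step, n_bins))
  }
  stop("unsupported input to radial_profile")
}

#' R factor between two intensity volumes
#'
#' Per shell, `R = sum | |F_a| - |F_b| | / sum (|F_a| + |F_b|) / 2` with
#' `|F| = sqrt(intensity)`; the overall value uses the same sums over
#' all measured voxels.  The symmetrized denominator makes
#' `r_factor(a, b) = r_factor(b, a)`.
#'
#' @param volume_a,volume_b [intensity_volume()]s on the same grid
#'   (assumed aligned).
#' @param n_shells number of q shells.
#' @return list `overall` (scalar) and `shells` (a [shell_curve()]).
#' @export
r_factor <- function(volume_a, volume_b, n_shells = 16L) {
  ia <- if (inherits(volume_a, "intensity_volume")) volume_a$intensities else volume_a
  ib <- if (inherits(volume_b, "intensity_volume")) volume_b$intensities else volume_b
  stopifnot(all(dim(ia) == dim(ib)))
  meas <- if (inherits(volume_a, "intensity_volume") &&
              inherits(volume_b, "intensity_volume"))
    volume_a$measured_mask & volume_b$measured_mask
  else array(TRUE, dim(ia))
  qs <- if (inherits(volume_a, "intensity_volume")) volume_a$q_step else 1
  fa <- sqrt(pmax(ia, 0)); fb <- sqrt(pmax(ib, 0))
  den_tot <- sum((fa[meas] + fb[meas]) / 2)
  if (den_tot == 0) stop("all-zero amplitudes: R factor undefined")
  overall <- sum(abs(fa[meas] - fb[meas])) / den_tot
  num_c <- radial_shell_mean(abs(fa - fb), qs, n_shells, exclude = !meas)
  den_c <- radial_shell_mean((fa + fb) / 2, qs, n_shells, exclude = !meas)
  vals <- ifelse(den_c$counts > 0 & den_c$values > 0,
                 num_c$values / den_c$values, NA_real_)
  list(overall = overall,
       shells = shell_curve(c(num_c$q_lo, num_c$q_hi[length(num_c$q_hi)]),
                            vals, num_c$counts))
}

#' Fourier shell correlation between two density maps
#'
#' `FSC(shell) = Re(sum F_a conj(F_b)) / sqrt(sum |F_a|^2 sum |F_b|^2)`
#' per q shell; the resolution is the first shell centre with
#' `FSC < cutoff`, reported as the real-space length `1/q`.
#'
#' @param map_a,map_b [density_map()]s or 3D arrays on the same grid
#'   (assumed aligned).
#' @param n_shells number of shells.
#' @param cutoff FSC resolution cutoff (0.5 by convention).
#' @param voxel_size real-space voxel edge (nm) used for the q axis.
#' @return list `shells` (a [shell_curve()]), `resolution_q`,
#'   `resolution` (= 1/q, NA if never crossing).
#' @export
fsc <- function(map_a, map_b, n_shells = 16L, cutoff = 0.5,
                voxel_size = NULL) {
  va <- if (inherits(map_a, "density_map")) map_a$values else map_a
  vb <- if (inherits(map_b, "density_map")) map_b$values else map_b
  stopifnot(all(dim(va) == dim(vb)))
  if (is.null(voxel_size))
    voxel_size <- if (inherits(map_a, "density_map")) map_a$voxel_size else 1
  fa <- cfft(va); fb <- cfft(vb)
  q_step <- 2 * pi / (dim(va)[1] * voxel_size)
  cross <- Re(fa * Conj(fb))
  pa <- Mod(fa)^2; pb <- Mod(fb)^2
  n <- n_shells
  cx <- radial_shell_mean(cross, q_step, n)
  ca <- radial_shell_mean(pa, q_step, n)
  cb <- radial_shell_mean(pb, q_step, n)
  vals <- ifelse(cx$counts > 0 & ca$values > 0 & cb$values > 0,
                 cx$values / sqrt(ca$values * cb$values), NA_real_)
  sc <- shell_curve(c(cx$q_lo, cx$q_hi[length(cx$q_hi)]), vals,
                    cx$counts)
  rq <- curve_crossing(sc, cutoff)
  list(shells = sc, resolution_q = rq,
       resolution = if (is.na(rq) || rq == 0) NA_real_ else 1 / rq)
}

# ---- orientation analysis ---------------------------------------------

#' Fibonacci sphere lattice
#'
#' Point `i` of `n` sits at `z = 1 - (2i + 1)/n` with azimuth
#' `2*pi*i / golden_ratio`, giving a near-uniform spread over the unit
#' sphere.
#'
#' @param n number of points.
#' @return `n x 3` matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- 2 * pi * i / ((1 + sqrt(5)) / 2)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Build an orientation grid
#'
#' Beam axes from a Fibonacci sphere lattice, each combined with
#' `n_inplane` in-plane detector rotations.  Orientation
#' `j = (axis, psi)` has quaternion `q_axis (x) q_z(psi)`, so the
#' rotated beam axis depends only on the axis index.
#'
#' @param n_axes number of beam-axis samples.
#' @param n_inplane in-plane rotation steps (uniform in `[0, 2*pi)`).
#' @return An object of class `orientation_grid`: `quaternions`
#'   (`n x 4`), `axes` (`n x 3` rotated beam axes), `axis_index`,
#'   `n_orientations`.
#' @export
orientation_grid <- function(n_axes = 500L, n_inplane = 8L) {
  ax <- fibonacci_sphere(n_axes)
  qs <- matrix(0, n_axes * n_inplane, 4)
  axi <- integer(n_axes * n_inplane)
  axes <- matrix(0, n_axes * n_inplane, 3)
  z <- c(0, 0, 1)
  row <- 0L
  for (a in seq_len(n_axes)) {
    v <- ax[a, ]
    cth <- sum(v * z)
    if (cth > 1 - 1e-12) {
      qa <- c(1, 0, 0, 0)
    } else if (cth < -1 + 1e-12) {
      qa <- c(0, 1, 0, 0)  # 180 deg about x
    } else {
      axis <- c(z[2] * v[3] - z[3] * v[2],
                z[3] * v[1] - z[1] * v[3],
                z[1] * v[2] - z[2] * v[1])
      axis <- axis / sqrt(sum(axis^2))
      th <- acos(cth)
      qa <- c(cos(th / 2), sin(th / 2) * axis)
    }
    for (p in seq_len(n_inplane)) {
      psi <- 2 * pi * (p - 1) / n_inplane
      qp <- c(cos(psi / 2), 0, 0, sin(psi / 2))
      row <- row + 1L
      qs[row, ] <- quat_multiply(qa, qp)
      axi[row] <- a
      axes[row, ] <- v
    }
  }
  structure(list(quaternions = qs, axes = axes, axis_index = axi,
                 n_orientations = nrow(qs), n_axes = n_axes,
                 n_inplane = n_inplane),
            class = "orientation_grid")
}

#' Orientation probabilities of photon patterns (one EMC E-step)
#'
#' For every pattern `k` and grid orientation `j`, the Poisson
#' log-likelihood `sum_i [K_i log W_ij - W_ij]` of the observed counts
#' `K` under the model slice `W` rendered at orientation `j` (floored at
#' `1e-12`), over unmasked pixels; rows are converted to probabilities
#' by a softmax (uniform orientation prior).  The full iterative EMC
#' merge is out of scope; this is its expectation step against a fixed
#' intensity volume.
#'
#' @param patterns a [pattern_stack()] of photon counts.
#' @param volume an [intensity_volume()].
#' @param grid an [orientation_grid()].
#' @param geometry a [detector_geometry()]; defaults to the stack's.
#' @param mean_photons photon scale of the model slices; defaults to the
#'   mean total count of the patterns.
#' @return `n_patterns x n_orientations` probability matrix (rows sum to
#'   1) with attributes `grid` and `log_likelihood`.
#' @export
orientation_probabilities <- function(patterns, volume, grid,
                                      geometry = NULL,
                                      mean_photons = NULL) {
  stopifnot(inherits(patterns, "pattern_stack"),
            inherits(grid, "orientation_grid"))
  if (is.null(geometry)) geometry <- patterns$geometry
  if (is.null(geometry)) stop("calibrated detector geometry required")
  keep <- !geometry$mask
  kmat <- as_feature_matrix(patterns)[, as.vector(keep), drop = FALSE]
  if (is.null(mean_photons)) mean_photons <- mean(rowSums(kmat))
  n_or <- grid$n_orientations
  wlog <- matrix(0, sum(keep), n_or)
  wsum <- numeric(n_or)
  for (j in seq_len(n_or)) {
    w <- render_noiseless_slice(volume, grid$quaternions[j, ], geometry,
                                mean_photons)
    w <- pmax(w[keep], 1e-12)
    wlog[, j] <- log(w)
    wsum[j] <- sum(w)
  }
  ll <- kmat %*% wlog - rep(wsum, each = nrow(kmat))
  ll <- ll - apply(ll, 1, max)
  p <- exp(ll)
  p <- p / rowSums(p)
  rownames(p) <- patterns$ids
  attr(p, "grid") <- grid
  attr(p, "log_likelihood") <- ll
  p
}

#' Summary of per-pattern maximum orientation probabilities
#'
#' @param prob_matrix patterns x orientations probability matrix (rows
#'   summing to 1).
#' @param low_cutoff probability below which a pattern's orientation is
#'   considered uncertain.
#' @param n_breaks histogram breaks over log10(p_max).
#' @return list: `p_max` (per pattern), `fraction_low`, `n_low`,
#'   `baseline` (= 1/n_orientations, the uniform-prior expectation),
#'   `histogram`.
#' @export
pmax_stats <- function(prob_matrix, low_cutoff = 1e-4, n_breaks = 30L) {
  stopifnot(is.matrix(prob_matrix))
  rs <- rowSums(prob_matrix)
  if (any(abs(rs - 1) > 1e-9))
    stop("probability rows must sum to 1")
  p_max <- apply(prob_matrix, 1, max)
  h <- graphics::hist(log10(p_max), breaks = n_breaks, plot = FALSE)
  list(p_max = p_max,
       fraction_low = mean(p_max < low_cutoff),
       n_low = sum(p_max < low_cutoff),
       baseline = 1 / ncol(prob_matrix),
       histogram = h)
}

#' Accumulate top orientations on the unit sphere
#'
#' For each pattern, its `top_n` largest probabilities are added to the
#' sphere points given by the corresponding orientations' rotated beam
#' axes (in-plane rotation discarded).
#'
#' @param prob_matrix patterns x orientations probability matrix with an
#'   `orientation_grid` attached (or passed via `grid`).
#' @param grid an [orientation_grid()].
#' @param top_n orientations kept per pattern.
#' @return data.frame: axis coordinates `x, y, z` and accumulated
#'   `weight` per grid axis.
#' @export
orientation_sphere_map <- function(prob_matrix, grid = NULL,
                                   top_n = 10L) {
  if (is.null(grid)) grid <- attr(prob_matrix, "grid")
  stopifnot(inherits(grid, "orientation_grid"),
            ncol(prob_matrix) == grid$n_orientations)
  acc <- numeric(grid$n_axes)
  top_n <- min(top_n, ncol(prob_matrix))
  for (k in seq_len(nrow(prob_matrix))) {
    row <- prob_matrix[k, ]
    sel <- order(row, decreasing = TRUE)[seq_len(top_n)]
    ai <- grid$axis_index[sel]
    for (s in seq_along(sel)) acc[ai[s]] <- acc[ai[s]] + row[sel[s]]
  }
  ax <- fibonacci_sphere(grid$n_axes)
  data.frame(x = ax[, 1], y = ax[, 2], z = ax[, 3], weight = acc)
}

# ---- consensus --------------------------------------------------------

#' Consensus (Venn) analysis of 2-3 label sets
#'
#' Computes all pairwise and triple intersection sizes of the class-1
#' selections and returns the common subset.  All sets must be keyed by
#' the same pattern-id universe.
#'
#' @param label_sets named list of 2 or 3 [label_set()]s.
#' @return list: `sizes` (per-method class-1 counts), `pairwise`
#'   (named intersection sizes), `triple` (size, NA for 2 sets),
#'   `common` (a [label_set()] of the patterns selected by every
#'   method, score = minimum score across methods).
#' @export
consensus <- function(label_sets) {
  stopifnot(is.list(label_sets),
            length(label_sets) >= 2, length(label_sets) <= 3)
  if (is.null(names(label_sets)) || any(names(label_sets) == ""))
    names(label_sets) <- paste0("method", seq_along(label_sets))
  universe <- sort(label_sets[[1]]$pattern_id)
  for (i in seq_along(label_sets)) {
    ids <- sort(label_sets[[i]]$pattern_id)
    if (!identical(ids, universe)) {
      orphans <- c(setdiff(ids, universe), setdiff(universe, ids))
      stop("label sets cover different patterns; orphan ids: ",
           paste(head(orphans, 10), collapse = ", "))
    }
  }
  sel <- lapply(label_sets, function(l) l$pattern_id[l$class == 1])
  nm <- names(label_sets)
  pairs <- utils::combn(seq_along(sel), 2)
  pairwise <- apply(pairs, 2, function(p)
    length(intersect(sel[[p[1]]], sel[[p[2]]])))
  names(pairwise) <- apply(pairs, 2, function(p)
    paste(nm[p[1]], nm[p[2]], sep = "&"))
  common_ids <- Reduce(intersect, sel)
  triple <- if (length(sel) == 3) length(common_ids) else NA_integer_
  score_min <- rep(1, length(common_ids))
  for (l in label_sets) {
    s <- l$score[match(common_ids, l$pattern_id)]
    score_min <- pmin(score_min, s)
  }
  common <- if (length(common_ids))
    label_set(common_ids, score_min, attr(label_sets[[1]], "theta"))
  else label_set(character(), numeric(), attr(label_sets[[1]], "theta"))
  list(sizes = vapply(sel, length, 1L), pairwise = pairwise,
       triple = triple, common = common)
}

# ---- shape analysis ---------------------------------------------------

#' Cross-section eccentricity distribution of a density map
#'
#' Plane normals are drawn from a Fibonacci sphere lattice.  For each
#' central cross-section the boundary contour at
#' `contour_level x section maximum` is traced with sub-voxel precision
#' along radial rays from the centre; the filled region enclosed by the
#' polar contour `r(theta)` is then fit by an ellipse through its exact
#' area moments (`A = int r^2/2 dtheta`,
#' `I_xx = int r^4 cos^2(theta)/4 dtheta`, ...), whose covariance
#' eigenvalues `l1 >= l2` give `e = sqrt(1 - (b/a)^2) = sqrt(1 - l2/l1)`.
#' A light Gaussian pre-filter (`presmooth` voxels) suppresses the
#' voxelization anisotropy of hard-edged maps; the contour location of a
#' centred convex body is unchanged to first order.
#'
#' @param map a [density_map()] or 3D array.
#' @param n_planes number of section planes.
#' @param contour_level threshold as a fraction of each section's
#'   maximum.
#' @param n_angles radial rays per section.
#' @param dr radial sampling step, voxels.
#' @param presmooth anti-aliasing Gaussian sigma in voxels (0 = off).
#' @return data.frame (`plane`, `nx`, `ny`, `nz`, `eccentricity`,
#'   `area`) with attribute `mean_eccentricity`; empty sections are
#'   dropped with a warning.
#' @export
eccentricity_analysis <- function(map, n_planes = 100L,
                                  contour_level = 0.5, n_angles = 180L,
                                  dr = 0.1, presmooth = 1.5) {
  v <- if (inherits(map, "density_map")) map$values else map
  stopifnot(length(dim(v)) == 3, contour_level > 0, contour_level < 1)
  d <- dim(v)
  if (presmooth > 0) {
    g1 <- lapply(d, function(n)
      exp(-centered_axis(n)^2 / (2 * presmooth^2)))
    kern <- outer(outer(g1[[1]], g1[[2]]), g1[[3]])
    kern <- kern / sum(kern)
    v <- pmax(Re(icfft(cfft(v) * cfft(kern))), 0)
  }
  normals <- fibonacci_sphere(n_planes)
  rmax <- floor(min(d) / 2) - 1
  rr <- seq(0, rmax, by = dr)
  th <- seq(0, 2 * pi, length.out = n_angles + 1)[-(n_angles + 1)]
  co <- cos(th); si <- sin(th)
  res <- vector("list", n_planes)
  dropped <- 0L
  for (pl in seq_len(n_planes)) {
    nv <- normals[pl, ]
    ref <- if (abs(nv[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- c(nv[2] * ref[3] - nv[3] * ref[2],
            nv[3] * ref[1] - nv[1] * ref[3],
            nv[1] * ref[2] - nv[2] * ref[1])
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(nv[2] * e1[3] - nv[3] * e1[2],
            nv[3] * e1[1] - nv[1] * e1[3],
            nv[1] * e1[2] - nv[2] * e1[1])
    dirs <- cbind(co, si) %*% rbind(e1, e2)
    pts <- cbind(as.vector(outer(rr, dirs[, 1])),
                 as.vector(outer(rr, dirs[, 2])),
                 as.vector(outer(rr, dirs[, 3])))
    vals <- matrix(trilinear(v, pts, fill = 0), length(rr), n_angles)
    mx <- max(vals)
    if (mx <= 0) { dropped <- dropped + 1L; next }
    lev <- contour_level * mx
    radii <- rep(NA_real_, n_angles)
    for (a in seq_len(n_angles)) {
      below <- which(vals[, a] < lev)[1]
      if (is.na(below) || below == 1) next
      v1 <- vals[below - 1, a]; v2 <- vals[below, a]
      radii[a] <- if (abs(v2 - v1) < 1e-12) rr[below - 1] else
        rr[below - 1] + (lev - v1) / (v2 - v1) * dr
    }
    if (sum(!is.na(radii)) < n_angles / 2) { dropped <- dropped + 1L; next }
    r <- radii; r[is.na(r)] <- 0
    A <- mean(r^2 / 2)
    if (A <= 0) { dropped <- dropped + 1L; next }
    cx <- mean(r^3 * co / 3) / A; cy <- mean(r^3 * si / 3) / A
    cxx <- mean(r^4 * co^2 / 4) / A - cx^2
    cyy <- mean(r^4 * si^2 / 4) / A - cy^2
    cxy <- mean(r^4 * co * si / 4) / A - cx * cy
    tr <- cxx + cyy; det <- cxx * cyy - cxy^2
    disc <- sqrt(max(tr^2 / 4 - det, 0))
    l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
    ecc <- if (l1 > 0) sqrt(max(1 - l2 / l1, 0)) else NA_real_
    res[[pl]] <- data.frame(plane = pl, nx = nv[1], ny = nv[2],
                            nz = nv[3], eccentricity = ecc,
                            area = A * 2 * pi)
  }
  if (dropped > 0)
    warning(dropped, " empty cross-section(s) skipped")
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(out)) stop("no usable cross-sections")
  attr(out, "mean_eccentricity") <- mean(out$eccentricity, na.rm = TRUE)
  out
}
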