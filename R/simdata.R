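# Synthetic single-particle-imaging data: an icosahedral virus-like
# particle, its oversampled 3D Fourier intensities, and rendered detector
# frames (single hits, interfering double hits, droplet/blank frames).

#' Icosahedral particle model
#'
#' Describes a solid icosahedral capsid with a denser interior core
#' (mimicking packaged DNA), optionally displaced toward a vertex.
#'
#' @param grid_size voxels per edge of the cubic density grid.
#' @param inradius icosahedron inradius in voxels (face-centre distance).
#' @param capsid_density dimensionless capsid density.
#' @param core_density dimensionless core density (typically > capsid).
#' @param core_radius radius of the interior core sphere, voxels.
#' @param core_offset length-3 displacement of the core centre, voxels.
#' @param edge_softness Gaussian blur sigma in voxels applied to the map.
#' @param voxel_size voxel edge in nm.
#' @return An object of class `particle_model`.
#' @export
particle_model <- function(grid_size = 32L, inradius = 10,
                           capsid_density = 1, core_density = 1.5,
                           core_radius = inradius / 2,
                           core_offset = c(0, 0, 0),
                           edge_softness = 1, voxel_size = 2.8) {
  stopifnot(grid_size >= 4, inradius > 0, capsid_density >= 0,
            core_density >= 0, core_radius >= 0,
            length(core_offset) == 3, edge_softness >= 0, voxel_size > 0)
  if (inradius >= grid_size / 2)
    stop("inradius (", inradius, ") must be < grid_size/2 (",
         grid_size / 2, ")")
  structure(list(grid_size = as.integer(grid_size), inradius = inradius,
                 capsid_density = capsid_density,
                 core_density = core_density, core_radius = core_radius,
                 core_offset = core_offset, edge_softness = edge_softness,
                 voxel_size = voxel_size),
            class = "particle_model")
}

# The 20 face-normal directions of a regular icosahedron are the vertex
# directions of its dual dodecahedron.
#' @noRd
icosahedron_face_normals <- function() {
  phi <- (1 + sqrt(5)) / 2
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  rect <- rbind(
    cbind(0, c(-1, -1, 1, 1) / phi, c(-phi, phi, -phi, phi)),
    cbind(c(-1, -1, 1, 1) / phi, c(-phi, phi, -phi, phi), 0),
    cbind(c(-phi, phi, -phi, phi), 0, c(-1, -1, 1, 1) / phi))
  v <- rbind(unname(cube), rect)
  v / sqrt(rowSums(v^2))
}

#' Analytic volume of a regular icosahedron given its inradius
#' @param inradius face-centre distance.
#' @return volume in the same cubed units.
#' @export
icosahedron_volume <- function(inradius) {
  a <- inradius / (sqrt(3) / 12 * (3 + sqrt(5)))  # edge length
  (5 / 12) * (3 + sqrt(5)) * a^3
}

#' Rasterise the icosahedral particle density
#'
#' A voxel at centred position `v` belongs to the capsid solid iff
#' `max_n (v . n_hat) <= inradius` over the 20 face normals.  The interior
#' core adds `core_density - capsid_density` inside a sphere of
#' `core_radius` centred at `core_offset`.  The map is then blurred with a
#' Gaussian of sigma `edge_softness` and truncated to a bounding sphere.
#'
#' @param model a [particle_model()].
#' @return A [density_map()] on a `grid_size^3` grid.
#' @export
make_icosahedron_density <- function(model) {
  stopifnot(inherits(model, "particle_model"))
  n <- model$grid_size
  r_circ <- model$inradius * 1.2584086  # circumradius/inradius ratio
  extent <- max(r_circ, sqrt(sum(model$core_offset^2)) + model$core_radius)
  if (extent + 2 * model$edge_softness >= n / 2)
    stop("particle extent ", round(extent, 2), " + blur exceeds half-grid ",
         n / 2, "; enlarge grid_size or shrink the particle")
  ax <- centered_axis(n)
  vx <- rep(ax, times = n * n)
  vy <- rep(rep(ax, each = n), times = n)
  vz <- rep(ax, each = n * n)
  nrm <- icosahedron_face_normals()
  proj_max <- rep(-Inf, n^3)
  for (f in seq_len(nrow(nrm)))
    proj_max <- pmax(proj_max, vx * nrm[f, 1] + vy * nrm[f, 2] +
                       vz * nrm[f, 3])
  dens <- ifelse(proj_max <= model$inradius, model$capsid_density, 0)
  core <- (vx - model$core_offset[1])^2 + (vy - model$core_offset[2])^2 +
    (vz - model$core_offset[3])^2 <= model$core_radius^2
  dens[core] <- dens[core] + (model$core_density - model$capsid_density)
  dens <- array(pmax(dens, 0), c(n, n, n))
  if (model$edge_softness > 0) {
    g1 <- exp(-centered_axis(n)^2 / (2 * model$edge_softness^2))
    kern <- outer(outer(g1, g1), g1)
    kern <- kern / sum(kern)
    dens <- pmax(Re(icfft(cfft(dens) * cfft(kern))), 0)
  }
  rad2 <- array(vx^2 + vy^2 + vz^2, c(n, n, n))
  bound <- (extent + 3 * model$edge_softness + 1)^2
  dens[rad2 > bound] <- 0
  density_map(dens, voxel_size = model$voxel_size)
}

#' Ground-truth oversampled intensity volume
#'
#' Zero-pads the density to `oversampling * grid_size` per edge and takes
#' `|F|^2` of the centred discrete Fourier transform.  Friedel symmetry
#' `I(q) = I(-q)` holds exactly for real densities.
#'
#' @param density a [density_map()].
#' @param oversampling linear oversampling ratio (>= 2).
#' @param keep_amplitude retain the complex structure factor (needed to
#'   render multi-particle interference frames).
#' @return An [intensity_volume()].
#' @export
ground_truth_intensity <- function(density, oversampling = 4,
                                   keep_amplitude = TRUE) {
  stopifnot(inherits(density, "density_map"))
  if (oversampling < 2)
    stop("oversampling must be >= 2 (support update is ill-posed below)")
  n <- dim(density$values)[1]
  nv <- as.integer(round(oversampling * n))
  pad <- array(0, c(nv, nv, nv))
  off <- floor(nv / 2) - floor(n / 2)
  pad[off + seq_len(n), off + seq_len(n), off + seq_len(n)] <-
    density$values
  fa <- cfft(pad)
  q_step <- 2 * pi / (nv * density$voxel_size)
  intensity_volume(Mod(fa)^2, q_step = q_step,
                   amplitude = if (keep_amplitude) fa else NULL)
}

#' Uniform-sphere form factor
#'
#' Relative scattered intensity of a homogeneous sphere,
#' `I(q)/I(0) = [3 (sin(qR) - qR cos(qR)) / (qR)^3]^2`, with the analytic
#' limit 1 at `q = 0`.
#'
#' @param q scattering vector magnitude, nm^-1 (angular convention).
#' @param radius sphere radius, nm.
#' @return relative intensity in `[0, 1]`.
#' @export
sphere_form_factor <- function(q, radius) {
  stopifnot(radius > 0)
  x <- q * radius
  out <- rep(1, length(x))
  big <- abs(x) > 1e-4
  xb <- x[big]
  out[big] <- (3 * (sin(xb) - xb * cos(xb)) / xb^3)^2
  out[!big] <- (1 - x[!big]^2 / 10)^2
  out
}

# ---- central-slice rendering ------------------------------------------

# Trilinear interpolation of a 3D array at centred coordinates (rows of
# `pts`).  Complex arrays are handled component-wise.  Out-of-volume
# points are an error unless `fill` is given, in which case they take
# that value.
#' @noRd
trilinear <- function(vol, pts, fill = NULL) {
  n <- dim(vol)
  ctr <- floor(n / 2) + 1
  px <- pts[, 1] + ctr[1]; py <- pts[, 2] + ctr[2]; pz <- pts[, 3] + ctr[3]
  outside <- px < 1 | px > n[1] | py < 1 | py > n[2] | pz < 1 | pz > n[3]
  if (any(outside)) {
    if (is.null(fill))
      stop("requested slice exits the intensity volume")
    px <- pmin(pmax(px, 1), n[1])
    py <- pmin(pmax(py, 1), n[2])
    pz <- pmin(pmax(pz, 1), n[3])
  }
  x0 <- pmin(floor(px), n[1] - 1); y0 <- pmin(floor(py), n[2] - 1)
  z0 <- pmin(floor(pz), n[3] - 1)
  tx <- px - x0; ty <- py - y0; tz <- pz - z0
  idx <- function(i, j, k) (k - 1) * n[1] * n[2] + (j - 1) * n[1] + i
  v000 <- vol[idx(x0, y0, z0)];         v100 <- vol[idx(x0 + 1, y0, z0)]
  v010 <- vol[idx(x0, y0 + 1, z0)];     v110 <- vol[idx(x0 + 1, y0 + 1, z0)]
  v001 <- vol[idx(x0, y0, z0 + 1)];     v101 <- vol[idx(x0 + 1, y0, z0 + 1)]
  v011 <- vol[idx(x0, y0 + 1, z0 + 1)]; v111 <- vol[idx(x0 + 1, y0 + 1, z0 + 1)]
  out <- (v000 * (1 - tx) + v100 * tx) * (1 - ty) * (1 - tz) +
    (v010 * (1 - tx) + v110 * tx) * ty * (1 - tz) +
    (v001 * (1 - tx) + v101 * tx) * (1 - ty) * tz +
    (v011 * (1 - tx) + v111 * tx) * ty * tz
  if (any(outside)) out[outside] <- fill
  out
}

# Centred detector-pixel q coordinates in volume-voxel units (n_pix^2 x 3,
# z = 0 plane before rotation), plus the scale pixels -> voxels.
#' @noRd
detector_plane_coords <- function(volume, geometry) {
  s <- geometry$pixel_q_step / volume$q_step
  np <- geometry$n_pixels
  u <- (seq_len(np) - geometry$beam_center[1]) * s
  v <- (seq_len(np) - geometry$beam_center[2]) * s
  cbind(rep(u, times = np), rep(v, each = np), 0)
}

#' Noiseless central-slice intensity for one orientation
#'
#' Samples the central plane of the rotated intensity volume by trilinear
#' interpolation (flat-Ewald approximation) and scales it so that the
#' identity-orientation slice sums to `mean_photons` expected photons.
#'
#' @param volume an [intensity_volume()].
#' @param orientation unit quaternion `(w, x, y, z)`.
#' @param geometry a [detector_geometry()].
#' @param mean_photons expected photons in a single hit; `NULL` leaves the
#'   slice on the volume's intensity scale.
#' @return `n_pixels x n_pixels` matrix of expected photon counts.
#' @export
render_noiseless_slice <- function(volume, orientation, geometry,
                                   mean_photons = NULL) {
  stopifnot(inherits(volume, "intensity_volume"),
            inherits(geometry, "detector_geometry"))
  pts <- detector_plane_coords(volume, geometry)
  rot <- quat_to_matrix(orientation)
  slice <- trilinear(volume$intensities, pts %*% t(rot))
  m <- matrix(slice, geometry$n_pixels, geometry$n_pixels)
  if (!is.null(mean_photons))
    m <- m * photon_scale(volume, geometry, mean_photons)
  m
}

# photons-per-intensity-unit factor: identity slice integrates to
# mean_photons
#' @noRd
photon_scale <- function(volume, geometry, mean_photons) {
  pts <- detector_plane_coords(volume, geometry)
  ref <- sum(trilinear(volume$intensities, pts))
  if (ref <= 0) 0 else mean_photons / ref
}

# Shared detection model: Poisson counts -> ADU with gain and Gaussian
# read noise; bad pixels get the sentinel value -1.
#' @noRd
detect_frame <- function(lambda, geometry, gain, read_noise,
                         poisson = TRUE) {
  counts <- if (poisson) {
    matrix(rpois(length(lambda), lambda), nrow(lambda), ncol(lambda))
  } else lambda
  adu <- counts * gain
  if (read_noise > 0)
    adu <- adu + matrix(rnorm(length(adu), 0, read_noise),
                        nrow(adu), ncol(adu))
  adu[geometry$mask] <- -1
  adu
}

#' Render a single-hit detector frame
#'
#' @inheritParams render_noiseless_slice
#' @param mean_photons expected total photons in the frame.
#' @param gain ADU per photon.
#' @param read_noise Gaussian read-noise sigma, ADU.
#' @param poisson draw Poisson photon counts (`FALSE` gives the noiseless
#'   expectation, useful for tests).
#' @return `n_pixels x n_pixels` ADU matrix; masked pixels hold -1.
#' @export
render_single_hit <- function(volume, orientation, geometry,
                              mean_photons = 10000, gain = 28,
                              read_noise = 4, poisson = TRUE) {
  lam <- render_noiseless_slice(volume, orientation, geometry,
                                mean_photons)
  detect_frame(lam, geometry, gain, read_noise, poisson)
}

#' Render a two-particle interference frame
#'
#' Complex structure factors of the two (identically shaped) particles are
#' combined before squaring:
#' `F_tot(q) = F(R1 q) + exp(i q . d) F(R2 q)`, producing the
#' inter-particle fringes characteristic of multiple hits.
#'
#' @inheritParams render_single_hit
#' @param orientations 2 x 4 matrix of unit quaternions, one per particle.
#' @param displacement length-3 inter-particle displacement in voxels of
#'   the intensity grid.
#' @export
render_multi_hit <- function(volume, orientations, displacement, geometry,
                             mean_photons = 10000, gain = 28,
                             read_noise = 4, poisson = TRUE) {
  stopifnot(inherits(volume, "intensity_volume"))
  if (is.null(volume$amplitude))
    stop("volume was built without keep_amplitude; complex structure ",
         "factors are required for multi-particle frames")
  stopifnot(is.matrix(orientations), nrow(orientations) == 2,
            length(displacement) == 3)
  pts <- detector_plane_coords(volume, geometry)
  nv <- dim(volume$intensities)[1]
  f1 <- trilinear(volume$amplitude, pts %*% t(quat_to_matrix(orientations[1, ])))
  f2 <- trilinear(volume$amplitude, pts %*% t(quat_to_matrix(orientations[2, ])))
  # DFT phase ramp for a real-space shift of `displacement` voxels
  phase <- 2 * pi * (pts %*% displacement) / nv
  ftot <- f1 + exp(1i * as.vector(phase)) * f2
  lam <- matrix(Mod(ftot)^2, geometry$n_pixels, geometry$n_pixels) *
    photon_scale(volume, geometry, mean_photons)
  detect_frame(lam, geometry, gain, read_noise, poisson)
}

#' Render a non-hit frame (solvent droplet and/or blank background)
#'
#' The droplet contributes a uniform-sphere form-factor profile; the
#' background contributes flat Poisson counts at `background_photon_rate`
#' photons per pixel.
#'
#' @inheritParams render_single_hit
#' @param droplet_radius droplet radius in nm (0 = pure background).
#' @param background_photon_rate expected background photons per pixel.
#' @param droplet_photons expected total photons scattered by the droplet.
#' @export
render_nonhit <- function(geometry, droplet_radius = 0,
                          background_photon_rate = 0,
                          droplet_photons = 10000, gain = 28,
                          read_noise = 4, poisson = TRUE) {
  stopifnot(inherits(geometry, "detector_geometry"), droplet_radius >= 0,
            background_photon_rate >= 0)
  np <- geometry$n_pixels
  lam <- matrix(background_photon_rate, np, np)
  if (droplet_radius > 0) {
    u <- seq_len(np) - geometry$beam_center[1]
    v <- seq_len(np) - geometry$beam_center[2]
    qr <- sqrt(outer(u^2, v^2, `+`)) * geometry$pixel_q_step
    ff <- matrix(sphere_form_factor(as.vector(qr), droplet_radius), np, np)
    lam <- lam + ff * droplet_photons / sum(ff)
  }
  detect_frame(lam, geometry, gain, read_noise, poisson)
}

# ---- dataset generation -----------------------------------------------

#' Simulation configuration
#'
#' @param n_patterns number of frames to generate.
#' @param fraction_single,fraction_multi,fraction_nonhit class proportions
#'   (must sum to 1); counts are apportioned by largest remainder.
#' @param mean_photons expected photons per single hit.
#' @param multi_hit_separation_range inter-particle distance range,
#'   voxels of the intensity grid.
#' @param droplet_radius_range droplet radius range, nm (min 0 allowed).
#' @param background_photon_rate background photons per pixel on all
#'   frames.
#' @param gain ADU per photon.
#' @param read_noise Gaussian read noise sigma, ADU.
#' @param n_bad_pixels number of randomly placed dead pixels in the
#'   default detector mask.
#' @param oversampling linear oversampling of the ground-truth volume.
#' @param n_train labelled training patterns to flag.
#' @param n_train_single how many of the training patterns are single
#'   hits (the remainder are non-single).
#' @param rng_seed integer seed controlling every random draw.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patterns = 700, fraction_single = 0.5,
                       fraction_multi = 0.3, fraction_nonhit = 0.2,
                       mean_photons = 10000,
                       multi_hit_separation_range = c(26, 60),
                       droplet_radius_range = c(20, 60),
                       background_photon_rate = 0.05,
                       gain = 28, read_noise = 4, n_bad_pixels = 40,
                       oversampling = 4, n_train = 200,
                       n_train_single = 79, rng_seed = 1L) {
  fr <- c(fraction_single, fraction_multi, fraction_nonhit)
  if (any(fr < 0) || any(fr > 1) || abs(sum(fr) - 1) > 1e-9)
    stop("class fractions must lie in [0,1] and sum to 1")
  stopifnot(n_patterns >= 1, mean_photons > 0,
            length(multi_hit_separation_range) == 2,
            length(droplet_radius_range) == 2, oversampling >= 2)
  structure(list(n_patterns = as.integer(n_patterns),
                 fraction_single = fraction_single,
                 fraction_multi = fraction_multi,
                 fraction_nonhit = fraction_nonhit,
                 mean_photons = mean_photons,
                 multi_hit_separation_range = multi_hit_separation_range,
                 droplet_radius_range = droplet_radius_range,
                 background_photon_rate = background_photon_rate,
                 gain = gain, read_noise = read_noise,
                 n_bad_pixels = as.integer(n_bad_pixels),
                 oversampling = oversampling,
                 n_train = as.integer(n_train),
                 n_train_single = as.integer(n_train_single),
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' Largest-remainder apportionment of counts to stated fractions
#'
#' @param n total count.
#' @param fractions non-negative proportions summing to 1.
#' @return integer counts summing to `n`; remainders tied are resolved in
#'   index order.
#' @export
apportion_counts <- function(n, fractions) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, all(fractions >= 0))
  exact <- n * fractions
  base <- floor(exact + 1e-9)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(-(exact - base), seq_along(fractions))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Generate a complete synthetic SPI dataset
#'
#' Produces `n_patterns` raw ADU frames with ground-truth labels
#' (`single`, `multi`, `nonhit`), per-pattern orientations, multi-hit
#' displacements, a flagged labelled training subset, and the
#' ground-truth oversampled intensity volume.  Everything is reproducible
#' from `config$rng_seed`.
#'
#' @param config a [sim_config()].
#' @param model a [particle_model()].
#' @param geometry optional [detector_geometry()]; by default a 64 x 64
#'   detector whose pixel q-step equals the volume voxel q-step, with
#'   `n_bad_pixels` randomly placed dead pixels.
#' @param path optional file path; when given the dataset is also written
#'   in the CXI-style HDF5 layout via [write_cxi()].
#' @return A list with elements `stack` (raw [pattern_stack()]), `truth`
#'   (data.frame: `pattern_id`, `label`, `class` with 1 = single),
#'   `orientations` (n x 4), `orientations2` (second particle of multi
#'   hits, NA elsewhere), `displacement` (n x 3), `train_idx`,
#'   `volume`, `density`, `config`.
#' @export
generate_dataset <- function(config = sim_config(),
                             model = particle_model(),
                             geometry = NULL, path = NULL) {
  stopifnot(inherits(config, "sim_config"),
            inherits(model, "particle_model"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$rng_seed)

  density <- make_icosahedron_density(model)
  volume <- ground_truth_intensity(density, config$oversampling)

  if (is.null(geometry)) {
    mask <- matrix(FALSE, 64, 64)
    if (config$n_bad_pixels > 0)
      mask[sample.int(64 * 64, config$n_bad_pixels)] <- TRUE
    geometry <- detector_geometry(64L, pixel_q_step = volume$q_step,
                                  beam_center = c(33, 33), mask = mask)
  }

  n <- config$n_patterns
  counts <- apportion_counts(n, c(config$fraction_single,
                                  config$fraction_multi,
                                  config$fraction_nonhit))
  labels <- sample(rep(c("single", "multi", "nonhit"), counts))
  quats <- random_quaternions(n)
  quats2 <- matrix(NA_real_, n, 4)
  disp <- matrix(0, n, 3)

  frames <- array(0, c(geometry$n_pixels, geometry$n_pixels, n))
  for (i in seq_len(n)) {
    if (labels[i] == "single") {
      frames[, , i] <- render_single_hit(
        volume, quats[i, ], geometry, config$mean_photons,
        config$gain, config$read_noise)
    } else if (labels[i] == "multi") {
      quats2[i, ] <- random_quaternions(1)
      r <- runif(1, config$multi_hit_separation_range[1],
                 config$multi_hit_separation_range[2])
      dirv <- rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
      disp[i, ] <- r * dirv
      frames[, , i] <- render_multi_hit(
        volume, rbind(quats[i, ], quats2[i, ]), disp[i, ], geometry,
        config$mean_photons, config$gain, config$read_noise)
    } else {
      rad <- runif(1, config$droplet_radius_range[1],
                   config$droplet_radius_range[2])
      frames[, , i] <- render_nonhit(
        geometry, rad, config$background_photon_rate,
        droplet_photons = config$mean_photons / 2,
        gain = config$gain, read_noise = config$read_noise)
    }
    if (config$background_photon_rate > 0 && labels[i] != "nonhit") {
      bg <- matrix(rpois(geometry$n_pixels^2,
                         config$background_photon_rate),
                   geometry$n_pixels, geometry$n_pixels) * config$gain
      bg[geometry$mask] <- 0
      frames[, , i] <- frames[, , i] + bg
    }
  }

  ids <- sprintf("pat%06d", seq_len(n))
  stack <- pattern_stack(frames, ids, geometry$mask, geometry, "adu")
  truth <- data.frame(pattern_id = ids, label = labels,
                      class = as.integer(labels == "single"),
                      stringsAsFactors = FALSE)

  singles <- which(labels == "single")
  others <- which(labels != "single")
  n1 <- min(config$n_train_single, length(singles))
  n0 <- min(config$n_train - config$n_train_single, length(others))
  if (n1 < config$n_train_single ||
      n0 < config$n_train - config$n_train_single)
    warning("training split truncated by class availability")
  train_idx <- sort(c(sample(singles, n1), sample(others, n0)))

  out <- list(stack = stack, truth = truth, orientations = quats,
              orientations2 = quats2, displacement = disp,
              train_idx = train_idx, volume = volume, density = density,
              config = config)
  if (!is.null(path)) write_cxi(out, path)
  out
}
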