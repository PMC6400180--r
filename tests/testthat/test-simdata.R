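# Synthetic diffraction data: particle rasterisation, Fourier volumes,
# frame rendering and dataset assembly.

test_that("icosahedron density has the right symmetry, volume and zeros", {
  # centred particle: icosahedral point group contains inversion
  d <- fix_particle()$density$values
  n <- dim(d)[1]
  inv <- d[c(1, n:2), c(1, n:2), c(1, n:2)]
  expect_lt(max(abs(d - inv)), 1e-12)

  # hard-edged voxel count vs the analytic volume (within digitization)
  m0 <- particle_model(grid_size = 64, inradius = 10, edge_softness = 0,
                       core_density = 1, core_radius = 0)
  d0 <- make_icosahedron_density(m0)
  expect_lt(abs(sum(d0$values > 0) - icosahedron_volume(10)) /
              icosahedron_volume(10), 0.03)

  # zero densities give the all-zero map
  mz <- particle_model(capsid_density = 0, core_density = 0)
  expect_equal(max(abs(make_icosahedron_density(mz)$values)), 0)

  # an oversized particle is rejected with the violated bound named
  expect_error(make_icosahedron_density(
    particle_model(grid_size = 16, inradius = 7.8)), "grid")
})

test_that("ground-truth intensity obeys Friedel symmetry and scaling", {
  fx <- fix_particle()
  I <- fx$volume$intensities
  n <- dim(I)[1]
  flip <- function(a) a[c(1, n:2), c(1, n:2), c(1, n:2)]
  expect_lt(max(abs(I - flip(I))) / max(I), 1e-12)

  # density scaled by c -> intensities scaled by c^2
  d2 <- density_map(3 * fx$density$values, fx$density$voxel_size)
  I2 <- ground_truth_intensity(d2, 4, keep_amplitude = FALSE)$intensities
  expect_equal(I2, 9 * I, tolerance = 1e-10)

  expect_error(ground_truth_intensity(fx$density, 1.5), "oversampling")
})

test_that("sphere form factor matches closed-form values", {
  expect_equal(sphere_form_factor(0, 10), 1)
  # qR = pi: [3 (0 - pi * (-1)) / pi^3]^2 = (3/pi^2)^2
  expect_equal(sphere_form_factor(pi, 1), (3 / pi^2)^2, tolerance = 1e-12)
  q <- seq(0, 5, by = 0.01)
  expect_true(all(sphere_form_factor(q, 2) >= 0))
  # radial average of the sphere volume matches the analytic curve up to
  # the 3rd minimum (digitized sphere, so a few percent)
  ax <- centeraxis <- seq_len(64) - 33
  sph <- array(0, c(64, 64, 64))
  sph[outer(outer(ax^2, ax^2, `+`), ax^2, `+`) <= 12^2] <- 1
  vol <- ground_truth_intensity(density_map(sph, voxel_size = 1), 2,
                                keep_amplitude = FALSE)
  pr <- radial_profile(vol, n_bins = 80)
  qmax3 <- 10 / 12  # past the 3rd minimum of qR ~ 9.1 at R = 12
  sel <- which(pr$q_centers < qmax3 & pr$counts > 0 & pr$q_centers > 0)
  analytic <- sphere_form_factor(pr$q_centers[sel], 12)
  measured <- pr$values[sel] / pr$values[sel][1] *
    analytic[1]
  # compare on a log-envelope basis: relative error of the envelope
  expect_lt(median(abs(measured - analytic) / (analytic + 1e-3)), 0.25)
})

test_that("central-slice rendering reduces to the volume slab and is
           deterministic", {
  fx <- fix_particle()
  # identity orientation, no noise: frame = central z slab (up to the
  # photon rescaling)
  s <- render_noiseless_slice(fx$volume, c(1, 0, 0, 0), fx$geom, 1e4)
  n <- dim(fx$volume$intensities)[1]
  slab <- fx$volume$intensities[33:96, 33:96, floor(n / 2) + 1]
  expect_equal(s / sum(s), slab / sum(slab), tolerance = 1e-12)

  # mean_photons 0, no read noise -> all-zero frame
  z <- render_single_hit(fx$volume, c(1, 0, 0, 0), fx$geom, 0,
                         read_noise = 0)
  expect_equal(max(abs(z)), 0)

  # fixed RNG state -> bitwise identical frames
  set.seed(42)
  f1 <- render_single_hit(fx$volume, c(1, 0, 0, 0), fx$geom, 1000)
  set.seed(42)
  f2 <- render_single_hit(fx$volume, c(1, 0, 0, 0), fx$geom, 1000)
  expect_identical(f1, f2)

  # a slice leaving the volume errors
  geom_big <- detector_geometry(64L, pixel_q_step = fx$volume$q_step * 3,
                                beam_center = c(33, 33))
  expect_error(render_noiseless_slice(fx$volume, c(1, 0, 0, 0), geom_big),
               "exits")

  # noiseless frames obey Friedel symmetry about the beam centre
  q <- random_quaternions(1)
  f <- render_noiseless_slice(fx$volume, q[1, ], fx$geom)
  fr <- f[2:64, 2:64]
  expect_lt(max(abs(fr - fr[63:1, 63:1])) / max(f), 0.05)
})

test_that("two-particle interference behaves like |F1 + e^{iqd} F2|^2", {
  fx <- fix_particle()
  idq <- c(1, 0, 0, 0)
  # d = 0, same orientations: |2F|^2 = 4 |F|^2
  f1 <- render_single_hit(fx$volume, idq, fx$geom, 1000, gain = 1,
                          read_noise = 0, poisson = FALSE)
  f4 <- render_multi_hit(fx$volume, rbind(idq, idq), c(0, 0, 0),
                         fx$geom, 1000, gain = 1, read_noise = 0,
                         poisson = FALSE)
  expect_equal(f4, 4 * f1, tolerance = 1e-10)

  # |d| > 0: the Patterson (FT of the frame) shows side lobes at the
  # projected separation; d = (40,0,0) voxels maps to lag 40 * 64/128
  f <- render_multi_hit(fx$volume, rbind(idq, idq), c(40, 0, 0),
                        fx$geom, 1000, gain = 1, read_noise = 0,
                        poisson = FALSE)
  pat <- Mod(fft(f))[, 1]
  expect_equal(which.max(pat[14:31]) + 12, 20)

  # volume without stored amplitudes cannot render interference
  vol_i <- ground_truth_intensity(fx$density, 4, keep_amplitude = FALSE)
  expect_error(render_multi_hit(vol_i, rbind(idq, idq), c(0, 0, 0),
                                fx$geom), "amplitude")
})

test_that("non-hit frames give sphere fringes and Poisson background", {
  geom <- detector_geometry(64L, pixel_q_step = 0.02,
                            beam_center = c(33, 33))
  # radius 0, rate 0 -> all zero
  z <- render_nonhit(geom, 0, 0, gain = 1, read_noise = 0)
  expect_equal(max(abs(z)), 0)

  # pure background: per-pixel mean -> lambda within 3 standard errors
  set.seed(5)
  lam <- 0.7; nrep <- 40
  tot <- 0
  for (i in seq_len(nrep))
    tot <- tot + render_nonhit(geom, 0, lam, gain = 1, read_noise = 0)
  m <- mean(tot / nrep)
  se <- sqrt(lam / (nrep * 64 * 64))
  expect_lt(abs(m - lam), 3 * se)

  # droplet: radial minima at qR = 4.493, 7.725 (roots of tan x = x)
  f <- render_nonhit(geom, 60, 0, droplet_photons = 1, gain = 1,
                     read_noise = 0, poisson = FALSE)
  pr <- radial_profile(f, geom, n_bins = 120)
  ok <- which(pr$counts > 0 & pr$q_centers * 60 < 10)
  v <- pr$values[ok]; qr <- pr$q_centers[ok] * 60
  mins <- qr[which(diff(sign(diff(v))) == 2) + 1]
  expect_lt(abs(mins[1] - 4.493), 0.35)
  expect_lt(abs(mins[2] - 7.725), 0.35)
})

test_that("largest-remainder apportionment is deterministic and exact", {
  expect_identical(apportion_counts(200, c(0.395, 0.35, 0.255)),
                   c(79L, 70L, 51L))
  expect_identical(apportion_counts(10, c(1, 0, 0)), c(10L, 0L, 0L))
  # brute-force check: counts sum to n and differ from n*f by < 1
  set.seed(2)
  for (i in 1:20) {
    f <- runif(3); f <- f / sum(f)
    n <- sample(10:500, 1)
    cts <- apportion_counts(n, f)
    expect_equal(sum(cts), n)
    expect_true(all(abs(cts - n * f) < 1))
  }
})

test_that("generate_dataset honours fractions, split and seed", {
  ds <- fix_small_dataset()
  expect_identical(as.vector(table(factor(ds$truth$label,
                                          c("single", "multi", "nonhit")))),
                   c(20L, 12L, 8L))
  expect_length(ds$train_idx, 20)
  expect_identical(sum(ds$truth$class[ds$train_idx]), 8L)
  expect_true(all(abs(sqrt(rowSums(ds$orientations^2)) - 1) < 1e-12))

  # same config, same seed -> identical payload
  cfg <- sim_config(n_patterns = 12, fraction_single = 1,
                    fraction_multi = 0, fraction_nonhit = 0,
                    n_train = 4, n_train_single = 2, rng_seed = 3)
  # all-singles data cannot fill the non-single training quota
  expect_warning(d1 <- generate_dataset(cfg, particle_model()),
                 "truncated")
  expect_warning(d2 <- generate_dataset(cfg, particle_model()),
                 "truncated")
  expect_identical(d1$stack$values, d2$stack$values)
  expect_identical(d1$truth, d2$truth)
  expect_true(all(d1$truth$label == "single"))

  expect_error(sim_config(fraction_single = 0.5, fraction_multi = 0.5,
                          fraction_nonhit = 0.2), "sum to 1")
})

test_that("ensemble-averaged single hits converge to the noiseless slice", {
  # chi-square per pixel ~ 1: mean of Poisson frames vs expectation
  fx <- fix_particle()
  q <- c(1, 0, 0, 0)
  lam <- render_noiseless_slice(fx$volume, q, fx$geom, 500)
  nrep <- 60
  set.seed(8)
  tot <- 0
  for (i in seq_len(nrep))
    tot <- tot + render_single_hit(fx$volume, q, fx$geom, 500, gain = 1,
                                   read_noise = 0)
  avg <- tot / nrep
  keep <- lam > 0.2
  chi2 <- sum((avg[keep] - lam[keep])^2 / (lam[keep] / nrep)) / sum(keep)
  expect_gt(chi2, 0.8)
  expect_lt(chi2, 1.25)
})
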