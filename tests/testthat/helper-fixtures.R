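# Shared fixtures, built once per test run and memoized.

.fix <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  got <- .fix[[key]]
  if (!is.null(got)) return(got)
  val <- builder()
  .fix[[key]] <- val
  val
}

# default icosahedral particle and its oversampled intensity volume
fix_particle <- function() memo("particle", function() {
  model <- particle_model()
  density <- make_icosahedron_density(model)
  volume <- ground_truth_intensity(density, 4)
  geom <- detector_geometry(64L, pixel_q_step = volume$q_step,
                            beam_center = c(33, 33))
  list(model = model, density = density, volume = volume, geom = geom)
})

# small mixed dataset (fast; used by io / profile / preprocess tests)
fix_small_dataset <- function() memo("small_ds", function() {
  cfg <- sim_config(n_patterns = 40, fraction_single = 0.5,
                    fraction_multi = 0.3, fraction_nonhit = 0.2,
                    n_train = 20, n_train_single = 8, rng_seed = 11)
  generate_dataset(cfg, particle_model())
})

# hard-edged 16-grid particle, oversampling 2: the 32^3 phasing benchmark
fix_phasing <- function() memo("phasing", function() {
  model <- particle_model(grid_size = 16, inradius = 5,
                          edge_softness = 0, core_radius = 2.5)
  density <- make_icosahedron_density(model)
  volume <- ground_truth_intensity(density, 2, keep_amplitude = FALSE)
  truth32 <- array(0, c(32, 32, 32))
  truth32[8 + 1:16, 8 + 1:16, 8 + 1:16] <- density$values
  list(model = model, density = density, volume = volume,
       truth = truth32, support_size = sum(density$values > 0))
})

# correlation of a run (or plain density array) with the padded truth,
# after integer-shift + inversion alignment
phasing_truth_cor <- function(density, truth) {
  ens <- structure(list(runs = list(list(density = truth),
                                    list(density = density))),
                   class = "phasing_ensemble")
  al <- align_and_average(ens)
  stats::cor(as.vector(al$runs[[1]]$density),
             as.vector(al$runs[[2]]$density))
}
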