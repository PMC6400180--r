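# Iterative phase retrieval: error-reduction and difference-map cycles
# between the Fourier-modulus constraint and a dynamic real-space
# support, ensembles of independent runs with alignment/averaging, and
# the phase-retrieval transfer function.

# modulus projection: replace Fourier amplitudes by sqrt(I) on measured
# voxels, keep phases; unmeasured voxels float freely
#' @noRd
project_modulus <- function(x, volume) {
  fx <- cfft(x)
  amp <- Mod(fx)
  meas <- volume$measured_mask
  sqrtI <- sqrt(pmax(volume$intensities, 0))
  phase_ok <- amp > 1e-300
  fac <- array(1, dim(fx))
  fac[meas & phase_ok] <- (sqrtI / amp)[meas & phase_ok]
  fx <- fx * fac
  # zero-amplitude measured voxels take sqrt(I) with phase 0
  fx[meas & !phase_ok] <- sqrtI[meas & !phase_ok]
  Re(icfft(fx))
}

# support(+positivity) projection onto the set of maps with at most
# n_voxels non-negative non-zero voxels: keep the n_voxels largest
# positive parts (this ranking makes the operation the exact Euclidean
# projection, which is what guarantees the monotone error-reduction
# error)
#' @noRd
project_support_dynamic <- function(y, n_voxels) {
  supp <- update_support(y, n_voxels)
  out <- y
  out[!supp] <- 0
  out[out < 0] <- 0
  list(density = out, support = supp)
}

#' Select the support as the highest-density voxels
#'
#' Returns a mask of exactly `n_voxels` voxels, the ones with the
#' largest positive density of the current iterate (ties broken by voxel
#' index order, so the result is deterministic).
#'
#' @param density 3D numeric array (or [density_map()]).
#' @param n_voxels support size in voxels.
#' @return logical array with `sum == n_voxels`.
#' @export
update_support <- function(density, n_voxels = 2000L) {
  v <- if (inherits(density, "density_map")) density$values else density
  n_voxels <- as.integer(n_voxels)
  if (n_voxels > length(v)) stop("n_voxels exceeds the grid size")
  supp <- array(FALSE, dim(v))
  if (n_voxels == 0L) return(supp)
  supp[top_voxel_idx(pmax(as.vector(v), 0), n_voxels)] <- TRUE
  supp
}

# indices of the n largest values of `key` (>= 0), ties resolved toward
# the smallest voxel index; partial sort keeps this O(N)
#' @noRd
top_voxel_idx <- function(key, n) {
  if (n >= length(key)) return(seq_along(key))
  m <- length(key) - n + 1L
  thr <- sort(key, partial = m)[m]
  above <- which(key > thr)
  c(above, which(key == thr)[seq_len(n - length(above))])
}

#' One error-reduction iteration
#'
#' Modulus projection followed by the support(+positivity) projection;
#' the support is re-selected from the modulus-projected iterate when
#' `dynamic_support` is `TRUE`, otherwise `support` is used as given.
#'
#' @param density 3D array, current real-space iterate.
#' @param volume an [intensity_volume()] holding the measured `|F|^2`.
#' @param support logical array (fixed support) or an integer voxel
#'   count (dynamic support of that size).
#' @return list `density`, `support`.
#' @export
er_iterate <- function(density, volume, support) {
  y <- project_modulus(density, volume)
  if (is.numeric(support) && length(support) == 1) {
    project_support_dynamic(y, support)
  } else {
    out <- y
    out[!support] <- 0
    out[out < 0] <- 0
    list(density = out, support = support)
  }
}

#' One difference-map iteration
#'
#' `x <- x + beta * (P_S(2 P_M(x) - x) - P_M(x))` with `P_M` the modulus
#' projection and `P_S` the support(+positivity) projection; `beta = 1`
#' is the common two-projection form.  With `beta = 0` the map is the
#' identity.
#'
#' @inheritParams er_iterate
#' @param beta relaxation parameter.
#' @return list `density`, `support`.
#' @export
dm_iterate <- function(density, volume, support, beta = 1) {
  if (beta == 0)
    return(list(density = density,
                support = if (is.numeric(support) && length(support) == 1)
                  update_support(density, support) else support))
  pm <- project_modulus(density, volume)
  r <- 2 * pm - density
  if (is.numeric(support) && length(support) == 1) {
    ps <- project_support_dynamic(r, support)
    list(density = density + beta * (ps$density - pm),
         support = ps$support)
  } else {
    rs <- r
    rs[!support] <- 0
    rs[rs < 0] <- 0
    list(density = density + beta * (rs - pm), support = support)
  }
}

#' Convergence and modulus-error of an iterate
#'
#' `convergence = ||rho_k - rho_km1||_2 / ||rho_k||_2` measures the
#' change between consecutive models;
#' `modulus_error = || |F(rho_k)| - sqrt(I) ||_2 / ||sqrt(I)||_2` over
#' the measured voxels measures agreement with the data.  A zero-norm
#' denominator with a zero numerator gives 0; otherwise it is an error.
#'
#' @param model_k,model_km1 3D arrays (consecutive iterates);
#'   `model_km1 = NULL` skips the convergence value (NA).
#' @param volume an [intensity_volume()].
#' @return list `convergence`, `modulus_error`.
#' @export
phasing_errors <- function(model_k, model_km1, volume) {
  conv <- NA_real_
  if (!is.null(model_km1)) {
    num <- sqrt(sum((model_k - model_km1)^2))
    den <- sqrt(sum(model_k^2))
    conv <- if (den > 0) num / den else if (num == 0) 0 else
      stop("zero-norm current model with nonzero difference")
  }
  meas <- volume$measured_mask
  sqrtI <- sqrt(pmax(volume$intensities[meas], 0))
  amp <- Mod(cfft(model_k))[meas]
  den <- sqrt(sum(sqrtI^2))
  num <- sqrt(sum((amp - sqrtI)^2))
  merr <- if (den > 0) num / den else if (num == 0) 0 else
    stop("zero measured intensities with nonzero model amplitudes")
  list(convergence = conv, modulus_error = merr)
}

#' One complete phase-retrieval run
#'
#' Starts from random phases, then applies the iteration schedule
#' (`ER1` error-reduction, `DM` difference-map, `ER2` error-reduction
#' cycles), re-selecting the `support_size`-voxel support at every
#' iteration.  Convergence and modulus-error traces are recorded per
#' iteration.
#'
#' @param volume an [intensity_volume()].
#' @param schedule integer triple `(ER1, DM, ER2)`.
#' @param support_size support voxel count.
#' @param seed RNG seed for the initial phases.
#' @param beta difference-map relaxation parameter.
#' @return An object of class `phasing_run`: `density` (3D array),
#'   `support`, `convergence` and `modulus_error` traces, `schedule`,
#'   `support_size`, `seed`.
#' @export
run_phasing <- function(volume, schedule = c(100L, 200L, 200L),
                        support_size = 2000L, seed = 1L, beta = 1) {
  stopifnot(inherits(volume, "intensity_volume"), length(schedule) == 3)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  d <- dim(volume$intensities)
  phases <- array(runif(prod(d), 0, 2 * pi), d)
  f0 <- sqrt(pmax(volume$intensities, 0)) * exp(1i * phases)
  f0[!volume$measured_mask] <- 0
  x <- Re(icfft(f0))
  n_iter <- sum(schedule)
  conv <- merr <- numeric(n_iter)
  stage <- rep(c("ER", "DM", "ER"), schedule)

  # fused loop in FFT-native (unshifted) layout: exactly one forward and
  # one inverse FFT per iteration, the forward transform serving both
  # the modulus projection and the modulus-error trace
  meas_n <- as.vector(ifftshift(volume$measured_mask))
  sqrtI_n <- pmax(as.vector(ifftshift(sqrt(pmax(volume$intensities, 0)))), 0)
  sqrtI_norm <- sqrt(sum(sqrtI_n[meas_n]^2))
  nvox <- prod(d)
  x <- as.vector(ifftshift(x))
  supp_idx <- NULL
  for (it in seq_len(n_iter)) {
    fx <- fft(array(x, d))
    amp <- Mod(fx)
    # modulus error of the incoming iterate (recorded for it-1); the
    # final iterate's error is computed after the loop
    if (it > 1)
      merr[it - 1] <- sqrt(sum((amp[meas_n] - sqrtI_n[meas_n])^2)) /
        sqrtI_norm
    fac <- rep(1, nvox)
    ok <- meas_n & amp > 1e-300
    fac[ok] <- sqrtI_n[ok] / amp[ok]
    fxp <- fx * fac
    bad <- meas_n & amp <= 1e-300
    if (any(bad)) fxp[bad] <- sqrtI_n[bad]
    pm <- Re(fft(fxp, inverse = TRUE)) / nvox
    if (stage[it] == "ER") {
      supp_idx <- top_voxel_idx(pmax(pm, 0), support_size)
      xn <- numeric(nvox)
      xn[supp_idx] <- pmax(pm[supp_idx], 0)
    } else {
      r <- 2 * pm - x
      supp_idx <- top_voxel_idx(pmax(r, 0), support_size)
      ps <- numeric(nvox)
      ps[supp_idx] <- pmax(r[supp_idx], 0)
      xn <- x + beta * (ps - pm)
    }
    if (any(!is.finite(xn)))
      stop("phasing diverged to non-finite values at iteration ", it)
    dn <- sqrt(sum(xn^2))
    conv[it] <- if (dn > 0) sqrt(sum((xn - x)^2)) / dn else 0
    x <- xn
  }
  fx <- fft(array(x, d))
  merr[n_iter] <- sqrt(sum((Mod(fx)[meas_n] - sqrtI_n[meas_n])^2)) /
    sqrtI_norm
  supp <- array(FALSE, d)
  supp[supp_idx] <- TRUE
  structure(list(density = fftshift(array(x, d)),
                 support = fftshift(supp), convergence = conv,
                 modulus_error = merr, stage = stage,
                 schedule = as.integer(schedule),
                 support_size = as.integer(support_size),
                 seed = as.integer(seed)),
            class = "phasing_run")
}

#' Run an ensemble of independent phase retrievals
#'
#' @inheritParams run_phasing
#' @param n_runs number of independent runs.
#' @param seeds explicit per-run seeds (default `seed + 0:(n_runs-1)`).
#' @param seed base seed.
#' @return An object of class `phasing_ensemble`: list of `runs`,
#'   `aligned = FALSE`.
#' @export
run_phasing_ensemble <- function(volume, n_runs = 40L,
                                 schedule = c(100L, 200L, 200L),
                                 support_size = 2000L, seed = 1L,
                                 seeds = seed + seq_len(n_runs) - 1L,
                                 beta = 1) {
  runs <- lapply(seeds, function(s)
    run_phasing(volume, schedule, support_size, s, beta))
  structure(list(runs = runs, aligned = FALSE),
            class = "phasing_ensemble")
}

# best integer circular shift (and inversion flag) aligning `x` to `ref`
# by FFT cross-correlation
#' @noRd
best_alignment <- function(ref, x) {
  fr <- fft(ref)
  score <- function(y) {
    cc <- Re(fft(fr * Conj(fft(y)), inverse = TRUE))
    list(val = max(cc), shift = which.max(cc))
  }
  inv_idx <- function(n) c(1, n:2)
  d <- dim(x)
  xi <- x[inv_idx(d[1]), inv_idx(d[2]), inv_idx(d[3])]
  s1 <- score(x); s2 <- score(xi)
  use_inv <- s2$val > s1$val
  best <- if (use_inv) s2 else s1
  idx <- arrayInd(best$shift, d) - 1L
  list(invert = use_inv, shift = idx)
}

#' @noRd
apply_shift <- function(x, shift) {
  d <- dim(x)
  idx <- lapply(1:3, function(a) {
    s <- shift[a] %% d[a]
    if (s == 0) seq_len(d[a]) else c((d[a] - s + 1):d[a], 1:(d[a] - s))
  })
  x[idx[[1]], idx[[2]], idx[[3]]]
}

#' Align phasing runs and average them
#'
#' Each run is aligned to the first by the integer circular shift
#' maximizing the cross-correlation, testing both the run and its
#' inverted twin `rho(-r)` (the Friedel/twin ambiguity), then averaged
#' voxelwise.
#'
#' @param ensemble a `phasing_ensemble` (or plain list of `phasing_run`s).
#' @return the ensemble with `aligned = TRUE`, aligned densities in
#'   `runs`, and the voxelwise `average` density array.
#' @export
align_and_average <- function(ensemble) {
  runs <- if (inherits(ensemble, "phasing_ensemble")) ensemble$runs
          else ensemble
  stopifnot(length(runs) >= 1)
  ref <- runs[[1]]$density
  aligned <- vector("list", length(runs))
  aligned[[1]] <- ref
  inv_idx <- function(n) c(1, n:2)
  d <- dim(ref)
  for (k in seq_along(runs)[-1]) {
    x <- runs[[k]]$density
    al <- best_alignment(ref, x)
    if (al$invert)
      x <- x[inv_idx(d[1]), inv_idx(d[2]), inv_idx(d[3])]
    aligned[[k]] <- apply_shift(x, al$shift)
  }
  avg <- Reduce(`+`, aligned) / length(aligned)
  out <- if (inherits(ensemble, "phasing_ensemble")) ensemble
         else structure(list(runs = runs), class = "phasing_ensemble")
  for (k in seq_along(out$runs)) out$runs[[k]]$density <- aligned[[k]]
  out$aligned <- TRUE
  out$average <- avg
  out
}

#' Phase-retrieval transfer function of an aligned ensemble
#'
#' Per reciprocal voxel, `PRTF = |(1/N) sum_k exp(i phi_k)|` with
#' `phi_k` the phase of the k-th aligned run; the voxel values are then
#' averaged in q shells.  Identical runs give PRTF 1 everywhere; fully
#' random phases give about `N^-1/2`.  The resolution estimate is the
#' first shell centre where the curve drops below `cutoff` (1/e by
#' convention).
#'
#' @param ensemble an aligned `phasing_ensemble` (see
#'   [align_and_average()]).
#' @param n_shells number of q shells.
#' @param q_step reciprocal step per voxel (for the shell axis); 1 if
#'   unknown.
#' @param cutoff resolution cutoff on the PRTF value.
#' @return A [shell_curve()] with extra attribute `resolution_q` (NA if
#'   the curve never crosses the cutoff).
#' @export
prtf_curve <- function(ensemble, n_shells = 16L, q_step = 1,
                       cutoff = exp(-1)) {
  stopifnot(inherits(ensemble, "phasing_ensemble"))
  if (!isTRUE(ensemble$aligned))
    stop("runs must be aligned first (align_and_average)")
  if (length(ensemble$runs) < 2)
    stop("PRTF needs at least 2 runs")
  phasors <- NULL
  for (r in ensemble$runs) {
    fx <- cfft(r$density)
    u <- fx / ifelse(Mod(fx) > 1e-300, Mod(fx), 1)
    phasors <- if (is.null(phasors)) u else phasors + u
  }
  prtf_vox <- Mod(phasors) / length(ensemble$runs)
  sc <- radial_shell_mean(prtf_vox, q_step, n_shells)
  vals <- sc$values
  below <- which(vals < cutoff & sc$counts > 0)
  attr(sc, "resolution_q") <-
    if (length(below)) sc$q_centers[below[1]] else NA_real_
  attr(sc, "cutoff") <- cutoff
  sc
}
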