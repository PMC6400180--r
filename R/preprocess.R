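# Detector preprocessing: pixel binning, Friedel bad-pixel repair,
# ADU-to-photon conversion, log scaling and mean normalization.
# Two branches leave the chain: integer photon patterns (for orientation
# work) and log-scaled mean-normalized feature images (classifier input).

#' Bin detector pixels by summation
#'
#' Each output pixel is the sum over its `factor x factor` block of
#' unmasked input pixels, so unmasked photon content is conserved.  An
#' output pixel is masked iff every contributing input pixel is masked.
#' Frames whose dimensions are not divisible by `factor` are padded with
#' masked pixels.
#'
#' @param stack a [pattern_stack()] of raw frames.
#' @param factor integer binning factor (>= 1).
#' @return A [pattern_stack()] with binned values and mask; the geometry
#'   is rescaled (`pixel_q_step * factor`, beam centre remapped).
#' @export
bin_pixels <- function(stack, factor = 4L) {
  stopifnot(inherits(stack, "pattern_stack"))
  factor <- as.integer(factor)
  if (factor < 1) stop("binning factor must be >= 1")
  if (factor == 1) return(stack)
  d <- dim(stack$values)
  hw <- ceiling(d[1:2] / factor) * factor
  nb <- hw / factor
  vals <- stack$values
  mask <- stack$mask
  if (any(hw != d[1:2])) {
    pv <- array(0, c(hw, d[3])); pm <- matrix(TRUE, hw[1], hw[2])
    pv[seq_len(d[1]), seq_len(d[2]), ] <- vals
    pm[seq_len(d[1]), seq_len(d[2])] <- mask
    vals <- pv; mask <- pm
  }
  keep <- !mask
  # block-sum via two reshapes; masked pixels contribute 0
  blocksum <- function(m) {
    m1 <- matrix(colSums(matrix(m, factor)), hw[1] / factor)   # rows
    t(matrix(colSums(matrix(t(m1), factor)), hw[2] / factor))  # cols
  }
  out <- array(0, c(nb, d[3]))
  for (i in seq_len(d[3]))
    out[, , i] <- blocksum(vals[, , i] * keep)
  out_mask <- blocksum(keep) == 0
  geom <- stack$geometry
  if (!is.null(geom) && nb[1] == nb[2] && nb[1] >= 2) {
    geom <- detector_geometry(
      n_pixels = nb[1], pixel_q_step = geom$pixel_q_step * factor,
      wavelength = geom$wavelength,
      beam_center = (geom$beam_center - 0.5) / factor + 0.5,
      mask = out_mask)
  } else geom <- NULL
  pattern_stack(out, stack$ids, out_mask, geom, stack$type)
}

#' Repair bad pixels from their Friedel mates
#'
#' Diffraction from a real density obeys `I(q) = I(-q)`, so a masked
#' pixel can take the value of its point reflection through the beam
#' centre.  The mate is located by nearest pixel (fractional beam centres
#' allowed).  Pixels whose mate is off-detector or also masked stay
#' masked with value 0.  Unmasked pixels are never altered, which makes
#' the operation idempotent.
#'
#' @param stack a [pattern_stack()].
#' @param beam_center length-2 beam centre; defaults to the stack
#'   geometry's.
#' @return A [pattern_stack()] with repaired values and reduced mask.
#' @export
friedel_fix <- function(stack, beam_center = NULL) {
  stopifnot(inherits(stack, "pattern_stack"))
  if (is.null(beam_center)) {
    if (is.null(stack$geometry)) stop("beam_center required")
    beam_center <- stack$geometry$beam_center
  }
  d <- dim(stack$values)
  bad <- which(stack$mask, arr.ind = TRUE)
  vals <- stack$values
  mask <- stack$mask
  if (nrow(bad) > 0) {
    mate <- cbind(round(2 * beam_center[1] - bad[, 1]),
                  round(2 * beam_center[2] - bad[, 2]))
    ok <- mate[, 1] >= 1 & mate[, 1] <= d[1] &
      mate[, 2] >= 1 & mate[, 2] <= d[2]
    ok[ok] <- !stack$mask[mate[ok, , drop = FALSE]]
    src <- (mate[ok, 2] - 1) * d[1] + mate[ok, 1]
    dst <- (bad[ok, 2] - 1) * d[1] + bad[ok, 1]
    px <- d[1] * d[2]
    for (i in seq_len(d[3]))
      vals[dst + (i - 1) * px] <- vals[src + (i - 1) * px]
    mask[dst] <- FALSE
    still <- which(mask)
    for (i in seq_len(d[3])) vals[still + (i - 1) * px] <- 0
  }
  geom <- stack$geometry
  if (!is.null(geom)) geom$mask <- mask
  pattern_stack(vals, stack$ids, mask, geom, stack$type)
}

#' Convert ADU values to integer photon counts
#'
#' Counts are `round(values / gain)` with round-half-even; any pixel whose
#' analogue signal is below one photon (`values/gain < 1`, including
#' negatives) is set to zero.  Masked pixels are zeroed; the mask is
#' retained on the result.
#'
#' @param stack a [pattern_stack()] of ADU frames.
#' @param gain ADU per photon (> 0).
#' @return A [pattern_stack()] of type `"photons"`.
#' @export
adu_to_photons <- function(stack, gain = 28) {
  stopifnot(inherits(stack, "pattern_stack"), gain > 0)
  ph <- stack$values / gain
  counts <- round(ph)          # round half to even
  counts[ph < 1] <- 0
  px <- prod(dim(counts)[1:2])
  bad <- which(stack$mask)
  for (i in seq_len(dim(counts)[3]))
    counts[bad + (i - 1) * px] <- 0
  pattern_stack(counts, stack$ids, stack$mask, stack$geometry, "photons")
}

#' Log-scale photon counts
#'
#' `values = log(1 + counts)` (natural log); the +1 shift avoids the log
#' of zero and compresses the dynamic range so weak high-angle features
#' survive.
#'
#' @param stack a [pattern_stack()] of photon counts.
#' @return A [pattern_stack()] of type `"features"`.
#' @export
log_scale <- function(stack) {
  stopifnot(inherits(stack, "pattern_stack"))
  if (any(stack$values < 0)) stop("photon counts must be non-negative")
  pattern_stack(log1p(stack$values), stack$ids, stack$mask,
                stack$geometry, "features")
}

#' Scale each feature image to a common mean
#'
#' Every image is multiplied by `target_mean / mean(image)` so that a
#' chi-square style distance weights all patterns equally.  All-zero
#' images are passed through unchanged with a warning.
#'
#' @param stack a [pattern_stack()] of feature images.
#' @param target_mean the common per-pixel mean after scaling.
#' @return A [pattern_stack()] with identical per-image means.
#' @export
mean_normalize <- function(stack, target_mean = 1) {
  stopifnot(inherits(stack, "pattern_stack"), target_mean > 0)
  d <- dim(stack$values)
  mu <- apply(stack$values, 3, mean)
  zero <- mu == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero image(s) passed through unnormalized")
    mu[zero] <- target_mean
  }
  scl <- rep(target_mean / mu, each = d[1] * d[2])
  pattern_stack(stack$values * scl, stack$ids, stack$mask,
                stack$geometry, "features")
}

#' Full preprocessing chain
#'
#' Pipeline: bin -> Friedel fix -> ADU-to-photon conversion, then the
#' photon patterns branch off for orientation work while classification
#' inputs continue through log scaling and mean normalization.  The
#' photon branch is unaffected by the log/normalization parameters.
#'
#' @param stack raw ADU [pattern_stack()].
#' @param gain ADU per photon.
#' @param bin_factor pixel binning factor (1 = no binning).
#' @param beam_center optional override of the geometry beam centre
#'   (applied after binning).
#' @param target_mean common feature-image mean.
#' @return list with elements `photons` and `features`, both
#'   [pattern_stack()]s with ids preserved.
#' @export
preprocess_stack <- function(stack, gain = 28, bin_factor = 1L,
                             beam_center = NULL, target_mean = 1) {
  stopifnot(inherits(stack, "pattern_stack"))
  if (length(stack) == 0L || dim(stack$values)[3] == 0L)
    return(list(photons = stack, features = stack))
  s <- bin_pixels(stack, bin_factor)
  s <- friedel_fix(s, beam_center)
  photons <- adu_to_photons(s, gain)
  features <- mean_normalize(log_scale(photons), target_mean)
  list(photons = photons, features = features)
}
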