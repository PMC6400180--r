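#' @importFrom stats fft rnorm runif rpois sd median quantile
#' @importFrom graphics hist
#' @importFrom utils head read.csv write.csv
NULL

#' Detector geometry
#'
#' Describes a square pixel detector in the small-angle regime.  `q` per
#' pixel is taken as `pixel_q_step * r` with `r` the radial pixel distance
#' from the beam centre, consistent with `q = (4*pi/lambda) * sin(theta/2)`
#' at small scattering angles.
#'
#' @param n_pixels pixels per detector edge (square detector).
#' @param pixel_q_step reciprocal-space step per pixel, in nm^-1.
#' @param wavelength X-ray wavelength in nm.
#' @param beam_center length-2 pixel coordinates of the beam centre
#'   (1-based pixel-centre convention; fractional values allowed).
#' @param mask logical `n_pixels x n_pixels` matrix, `TRUE` marking bad or
#'   missing pixels.  Default: no bad pixels.
#' @return An object of class `detector_geometry`.
#' @export
detector_geometry <- function(n_pixels = 64L, pixel_q_step = 0.02,
                              wavelength = 0.75,
                              beam_center = c((n_pixels + 2) / 2,
                                              (n_pixels + 2) / 2),
                              mask = NULL) {
  n_pixels <- as.integer(n_pixels)
  stopifnot(n_pixels >= 2L, pixel_q_step > 0, length(beam_center) == 2L)
  if (any(beam_center < 1) || any(beam_center > n_pixels))
    stop("beam_center must lie inside the detector")
  if (is.null(mask)) mask <- matrix(FALSE, n_pixels, n_pixels)
  stopifnot(is.logical(mask), all(dim(mask) == n_pixels))
  structure(list(n_pixels = n_pixels, pixel_q_step = pixel_q_step,
                 wavelength = wavelength, beam_center = beam_center,
                 mask = mask),
            class = "detector_geometry")
}

#' Stack of detector frames
#'
#' A `pattern_stack` bundles a set of 2D frames with per-pattern ids, a
#' shared bad-pixel mask and the detector geometry.  `values` is an
#' `H x W x n` array; for raw frames the values are ADU, for photon
#' patterns non-negative integer counts, for feature images non-negative
#' reals.
#'
#' @param values numeric `H x W x n` array (a single matrix is promoted).
#' @param ids character vector of `n` unique pattern identifiers.
#' @param mask logical `H x W` bad-pixel mask shared by all frames.
#' @param geometry optional [detector_geometry()].
#' @param type one of `"adu"`, `"photons"`, `"features"`.
#' @return An object of class `pattern_stack`.
#' @export
pattern_stack <- function(values, ids = NULL, mask = NULL, geometry = NULL,
                          type = c("adu", "photons", "features")) {
  type <- match.arg(type)
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(length(dim(values)) == 3L)
  n <- dim(values)[3]
  if (is.null(ids)) ids <- sprintf("pat%06d", seq_len(n))
  if (anyDuplicated(ids)) stop("pattern ids must be unique")
  stopifnot(length(ids) == n)
  if (is.null(mask)) mask <- matrix(FALSE, dim(values)[1], dim(values)[2])
  stopifnot(all(dim(mask) == dim(values)[1:2]))
  structure(list(values = values, ids = as.character(ids), mask = mask,
                 geometry = geometry, type = type),
            class = "pattern_stack")
}

#' @export
print.pattern_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<pattern_stack> %d frames of %dx%d (%s), %d masked pixels\n",
              d[3], d[1], d[2], x$type, sum(x$mask)))
  invisible(x)
}

#' @export
length.pattern_stack <- function(x) dim(x$values)[3]

#' Subset a pattern stack by frame index or id
#' @param x a [pattern_stack()].
#' @param i integer or character index of frames to keep.
#' @param ... ignored.
#' @export
`[.pattern_stack` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$ids)
  if (anyNA(i)) stop("unknown pattern id in subset")
  pattern_stack(x$values[, , i, drop = FALSE], x$ids[i], x$mask,
                x$geometry, x$type)
}

#' Flatten a pattern stack to an n x (H*W) matrix
#' @param x a [pattern_stack()].
#' @return numeric matrix, one row per pattern, rownames = pattern ids.
#' @export
as_feature_matrix <- function(x) {
  stopifnot(inherits(x, "pattern_stack"))
  d <- dim(x$values)
  m <- t(matrix(x$values, d[1] * d[2], d[3]))
  rownames(m) <- x$ids
  m
}

#' Real-space density map on a cubic grid
#'
#' @param values 3D numeric array (cubic).
#' @param voxel_size edge length of one voxel in nm.
#' @param support optional logical array of the same shape.
#' @return An object of class `density_map`.
#' @export
density_map <- function(values, voxel_size = 1, support = NULL) {
  stopifnot(length(dim(values)) == 3L)
  if (!is.null(support)) stopifnot(all(dim(support) == dim(values)))
  structure(list(values = values, voxel_size = voxel_size,
                 support = support),
            class = "density_map")
}

#' Oversampled 3D Fourier intensity volume
#'
#' Stores `|F(q)|^2` on a centred cubic grid (the zero-frequency voxel sits
#' at index `floor(n/2) + 1` on each axis).  `amplitude`, when retained,
#' holds the complex structure factor F used to build multi-particle
#' interference frames.
#'
#' @param intensities non-negative 3D array.
#' @param q_step reciprocal-space step per voxel, nm^-1.
#' @param measured_mask logical array, `TRUE` where data exist.
#' @param amplitude optional complex array of structure factors.
#' @return An object of class `intensity_volume`.
#' @export
intensity_volume <- function(intensities, q_step = 1,
                             measured_mask = NULL, amplitude = NULL) {
  stopifnot(length(dim(intensities)) == 3L)
  if (is.null(measured_mask))
    measured_mask <- array(TRUE, dim(intensities))
  stopifnot(all(dim(measured_mask) == dim(intensities)))
  structure(list(intensities = intensities, q_step = q_step,
                 measured_mask = measured_mask, amplitude = amplitude),
            class = "intensity_volume")
}

# ---- centred FFT helpers ----------------------------------------------

#' @noRd
fftshift <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  idx <- lapply(d, function(n) c((floor(n / 2) + 1):n, 1:floor(n / 2)))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' @noRd
ifftshift <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  idx <- lapply(d, function(n) c((ceiling(n / 2) + 1):n, 1:ceiling(n / 2)))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# Centred forward/inverse FFT: real-space origin and q = 0 both at the
# centre voxel floor(n/2)+1.
#' @noRd
cfft <- function(x) fftshift(fft(ifftshift(x)))

#' @noRd
icfft <- function(x) fftshift(fft(ifftshift(x), inverse = TRUE)) / length(x)

# Centred coordinate vector for an axis of length n: 0 at floor(n/2)+1.
#' @noRd
centered_axis <- function(n) seq_len(n) - (floor(n / 2) + 1)

# ---- quaternion helpers -----------------------------------------------

#' Convert unit quaternions to rotation matrices
#' @param q numeric length-4 vector `(w, x, y, z)` or an `n x 4` matrix.
#' @return a 3x3 rotation matrix, or a list of them for matrix input.
#' @export
quat_to_matrix <- function(q) {
  if (is.matrix(q)) return(lapply(seq_len(nrow(q)),
                                  function(i) quat_to_matrix(q[i, ])))
  stopifnot(length(q) == 4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Draw uniform random rotations as unit quaternions
#'
#' Normalised 4-vectors of independent standard Gaussians, which are
#' uniform on SO(3) up to the double cover.
#'
#' @param n number of quaternions.
#' @return `n x 4` matrix of unit quaternions.
#' @export
random_quaternions <- function(n) {
  q <- matrix(rnorm(4 * n), n, 4)
  q / sqrt(rowSums(q^2))
}

#' Quaternion product
#' @param a,b length-4 quaternions `(w, x, y, z)`.
#' @return their Hamilton product `a * b`.
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}
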