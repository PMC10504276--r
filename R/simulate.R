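# Complex OCT frame synthesis.
#
# Per voxel the complex field is a static + dynamic circular-Gaussian
# mixture,
#   A(t) = sqrt(I) * ( sqrt(f) * g_s + sqrt(1 - f) * g_d(t) ) + n(t),
# where g_s is a frozen unit circular complex Gaussian draw, g_d(t) is a
# unit circular complex Gaussian AR(1) process with autocorrelation
# exp(-dt / tau) (exact discrete update using the actual inter-timestamp
# gaps), and n(t) is i.i.d. detector noise of variance sigma_n^2. A lateral
# Gaussian PSF blur applied to the signal field (before noise) produces
# realistic speckle grain; the blur operator is row-wise L2-normalised so
# mean intensity and temporal autocorrelation are preserved.

#' Construct a complex frame stack
#'
#' @param frames complex array `nz x nx x n_frames`.
#' @param timestamps acquisition time of each frame in seconds, strictly
#'   increasing.
#' @param location_index slow-axis (y) index the stack belongs to.
#' @param noise_variance detector noise variance used at synthesis (ground
#'   truth for noise-correction tests), or `NA` for measured data.
#' @return object of class `frame_stack`.
#' @export
frame_stack <- function(frames, timestamps, location_index = 1L,
                        noise_variance = NA_real_) {
  if (length(dim(frames)) != 3) stopf("frames must be nz x nx x n_frames")
  n <- dim(frames)[3]
  if (n < 2) stopf("a frame stack needs at least 2 frames")
  if (length(timestamps) != n)
    stopf("timestamps length (%d) must match frame count (%d)",
          length(timestamps), n)
  if (any(diff(timestamps) <= 0)) stopf("timestamps must be strictly increasing")
  if (any(!is.finite(frames))) stopf("frames contain non-finite values")
  structure(list(frames = frames, timestamps = timestamps,
                 location_index = as.integer(location_index),
                 noise_variance = noise_variance),
            class = "frame_stack")
}

#' Simulate a time-sequential complex B-scan stack
#'
#' Synthesises the repeated frames at one slow-axis location of a phantom
#' under the given acquisition timestamps. Deterministic given
#' `(phantom$seed, location_index, stream)`; different locations and streams
#' draw independent fields.
#'
#' @param phantom a `phantom_spec`.
#' @param location_index 1-based y-index of the B-scan location.
#' @param timestamps frame acquisition times in seconds (strictly
#'   increasing, length >= 2), typically from [protocol_timestamps()].
#' @param psf_fwhm_px lateral Gaussian PSF full width at half maximum in
#'   pixels; `0` disables the blur.
#' @param stream extra stream discriminator so several independent stacks
#'   (e.g. one per protocol) can be drawn at the same location.
#' @return `frame_stack`.
#' @export
simulate_frame_stack <- function(phantom, location_index, timestamps,
                                 psf_fwhm_px = 2.5, stream = 0L) {
  stopifnot(inherits(phantom, "phantom_spec"))
  d <- phantom$grid_shape
  if (location_index < 1 || location_index > d[3])
    stopf("location_index %d outside 1..%d", location_index, d[3])
  if (length(timestamps) < 2 || any(diff(timestamps) <= 0))
    stopf("timestamps must be strictly increasing with length >= 2")
  nz <- d[1]; nx <- d[2]; n <- length(timestamps)

  I <- phantom$backscatter_map[, , location_index]
  f <- phantom$static_fraction_map[, , location_index]
  tau <- phantom$tau_map[, , location_index]
  s2n <- phantom$noise_variance
  npx <- nz * nx

  set.seed(derive_seed(phantom$seed, location_index, stream))
  W <- lateral_blur_operator(nx, psf_fwhm_px)

  gs <- matrix(rcgauss(npx), nz, nx)
  gd <- matrix(rcgauss(npx), nz, nx)
  amp_s <- sqrt(I * f)
  amp_d <- sqrt(I * (1 - f))
  frames <- array(0i, dim = c(nz, nx, n))
  for (k in seq_len(n)) {
    if (k > 1) {
      a <- exp(-(timestamps[k] - timestamps[k - 1]) / tau)
      gd <- a * gd + sqrt(1 - a^2) * matrix(rcgauss(npx), nz, nx)
    }
    sig <- amp_s * gs + amp_d * gd
    if (psf_fwhm_px > 0) sig <- sig %*% t(W)
    if (s2n > 0) sig <- sig + matrix(rcgauss(npx, s2n), nz, nx)
    frames[, , k] <- sig
  }
  frame_stack(frames, timestamps, location_index, noise_variance = s2n)
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame_stack: %d frames of %d x %d at location %d\n",
              d[3], d[1], d[2], x$location_index))
  cat(sprintf("  t = %.4g .. %.4g s, noise variance %.3g\n",
              x$timestamps[1], x$timestamps[length(x$timestamps)],
              x$noise_variance))
  invisible(x)
}
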