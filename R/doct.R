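# Dynamic-OCT contrasts from repeated complex B-scan frames.
#
# LIV (logarithmic intensity variance): per-pixel population variance
# (divisor N) of the dB-scale intensity over the N repeated frames,
#   LIV(x, z) = (1/N) sum_i [ I_dB(x,z,t_i) - <I_dB(x,z)> ]^2 ,
# computed without any noise correction. Sensitive to second-scale
# fluctuations of the speckle intensity.
#
# Fast-DOCT: one minus the magnitude of the noise-corrected first-order
# complex correlation between consecutive frames milliseconds apart,
# spatially kernel-averaged; the detector-noise energy |K| * n_pairs *
# sigma_n^2 is subtracted from both correlation denominators so that pure
# noise does not masquerade as decorrelation. Pixels whose corrected energy
# falls below a guard are flagged invalid instead of being rendered.

#' Convert complex frames to dB-scale intensity
#'
#' `10 * log10(|A|^2 + eps)`; the floor `eps` keeps log-intensity finite in
#' signal-free (air) regions.
#'
#' @param frames complex array (any shape) or a `frame_stack`.
#' @param eps intensity floor in linear units.
#' @return numeric array of the same shape, in dB.
#' @export
to_db_intensity <- function(frames, eps = 1e-12) {
  if (inherits(frames, "frame_stack")) frames <- frames$frames
  10 * log10(Mod(frames)^2 + eps)
}

#' Logarithmic intensity variance (LIV)
#'
#' @param db_frames dB-intensity array `nz x nx x N` (see
#'   [to_db_intensity()]), or a `frame_stack` (converted internally).
#' @param window_seconds optional evaluation window recorded in the result;
#'   taken from the timestamps when a `frame_stack` is given.
#' @param eps intensity floor used when converting a `frame_stack`.
#' @return object of class `liv_image`: `values` (dB^2, `nz x nx`),
#'   `n_frames`, `window_seconds`.
#' @export
liv <- function(db_frames, window_seconds = NA_real_, eps = 1e-12) {
  if (inherits(db_frames, "frame_stack")) {
    window_seconds <- diff(range(db_frames$timestamps))
    db_frames <- to_db_intensity(db_frames$frames, eps)
  }
  if (length(dim(db_frames)) != 3) stopf("db_frames must be nz x nx x N")
  n <- dim(db_frames)[3]
  if (n < 2) stopf("LIV needs at least 2 frames")
  if (any(!is.finite(db_frames))) stopf("db_frames contain non-finite values")
  m <- rowMeans(db_frames, dims = 2)
  v <- rowMeans((db_frames - array(rep(m, n), dim = dim(db_frames)))^2,
                dims = 2)
  structure(list(values = v, n_frames = n, window_seconds = window_seconds),
            class = "liv_image")
}

#' Remove global per-frame phase offsets (bulk phase correction)
#'
#' Phase instability (bulk motion, trigger jitter) adds a global phase to
#' each frame, which corrupts complex correlation. For each consecutive
#' pair the global phase is estimated as
#' `arg sum_pixels A_i^* A_{i+1}` over an intensity-selected pixel mask and
#' removed cumulatively from the later frame.
#'
#' @param frames complex array `nz x nx x N` or a `frame_stack`.
#' @param intensity_quantile pixels with mean intensity above this quantile
#'   enter the phase estimate (the product itself is intensity-weighted).
#' @return list with `frames` (corrected array), `phases` (removed
#'   cumulative phase per frame), and `skipped` (pairs skipped because a
#'   frame was all-zero).
#' @export
bulk_phase_correct <- function(frames, intensity_quantile = 0.5) {
  ts <- NULL
  if (inherits(frames, "frame_stack")) { ts <- frames; frames <- frames$frames }
  if (length(dim(frames)) != 3 || dim(frames)[3] < 2)
    stopf("need a complex array nz x nx x N with N >= 2")
  n <- dim(frames)[3]
  mean_int <- rowMeans(Mod(frames)^2, dims = 2)
  sel <- mean_int >= stats::quantile(mean_int, intensity_quantile)
  phases <- numeric(n)
  skipped <- integer(0)
  cum <- 0
  out <- frames
  for (k in 2:n) {
    s <- sum(Conj(frames[, , k - 1][sel]) * frames[, , k][sel])
    if (Mod(s) == 0) {
      skipped <- c(skipped, k - 1L)
      phi <- 0
    } else phi <- Arg(s)
    cum <- cum + phi
    phases[k] <- cum
    out[, , k] <- frames[, , k] * exp(-1i * cum)
  }
  res <- list(frames = out, phases = phases, skipped = skipped)
  if (!is.null(ts)) {
    ts$frames <- out
    res$stack <- ts
  }
  res
}

#' Noise-corrected complex-decorrelation contrast (Fast-DOCT)
#'
#' With spatial kernel K (a `kernel x kernel` window) and the consecutive
#' lag-1 frame pairs,
#' `rho = |S_num| / sqrt(max(S_i - E_n, delta) * max(S_j - E_n, delta))`
#' where `S_num = sum_K sum_pairs A_i^* A_{i+1}`, `S_i`, `S_j` are the
#' kernel-and-pair summed energies of the earlier/later frames and
#' `E_n = |K| * n_pairs * sigma_n^2` is the expected noise energy. The
#' output is `clip(1 - rho, 0, 1)`. Pixels whose corrected energy falls at
#' or below the guard are reported in a validity mask (low-SNR decorrelation
#' is an artifact, not signal).
#'
#' @param frames complex array `nz x nx x N` (N >= 2, typically 4,
#'   bulk-phase-corrected) or a `frame_stack`.
#' @param noise_variance detector noise variance `sigma_n^2`; taken from the
#'   `frame_stack` when available.
#' @param kernel odd spatial averaging window size in pixels; `NA` pools
#'   over the whole frame (used for unbiased global estimates).
#' @param delta_rel guard threshold as a fraction of the expected noise
#'   energy; pixels with corrected energy below
#'   `max(delta_rel * E_n, delta_abs)` are invalid.
#' @param delta_abs absolute floor of the guard, in linear intensity units.
#' @return object of class `fast_doct_image`: `values` in `[0, 1]`, logical
#'   `valid` mask, `n_pairs`, `kernel`, `noise_variance`.
#' @export
fast_doct <- function(frames, noise_variance = NULL, kernel = 3L,
                      delta_rel = 0.5, delta_abs = 1e-12) {
  if (inherits(frames, "frame_stack")) {
    if (is.null(noise_variance)) noise_variance <- frames$noise_variance
    frames <- frames$frames
  }
  if (is.null(noise_variance) || is.na(noise_variance))
    stopf("noise_variance must be supplied (or carried by the frame_stack)")
  if (length(dim(frames)) != 3 || dim(frames)[3] < 2)
    stopf("need a complex array nz x nx x N with N >= 2")
  nz <- dim(frames)[1]; nx <- dim(frames)[2]; n <- dim(frames)[3]
  n_pairs <- n - 1L

  num <- matrix(0i, nz, nx); e_i <- matrix(0, nz, nx); e_j <- matrix(0, nz, nx)
  for (k in seq_len(n_pairs)) {
    num <- num + Conj(frames[, , k]) * frames[, , k + 1]
    e_i <- e_i + Mod(frames[, , k])^2
    e_j <- e_j + Mod(frames[, , k + 1])^2
  }
  if (is.na(kernel)) {
    num_s <- matrix(sum(num), nz, nx)
    ei_s <- matrix(sum(e_i), nz, nx)
    ej_s <- matrix(sum(e_j), nz, nx)
    counts <- matrix(nz * nx * n_pairs, nz, nx)
  } else {
    kernel <- as.integer(kernel)
    if (kernel < 1 || kernel %% 2L == 0L) stopf("kernel must be a positive odd integer")
    if (kernel > nz || kernel > nx)
      stopf("kernel (%d) larger than frame (%d x %d)", kernel, nz, nx)
    half <- kernel %/% 2L
    num_s <- window_sum_complex(num, half)
    ei_s <- window_sum(e_i, half)
    ej_s <- window_sum(e_j, half)
    counts <- window_count(nz, nx, half) * n_pairs
  }
  noise_energy <- counts * noise_variance
  guard <- pmax(delta_rel * noise_energy, delta_abs)
  ci <- ei_s - noise_energy
  cj <- ej_s - noise_energy
  valid <- ci > guard & cj > guard
  rho <- Mod(num_s) / sqrt(pmax(ci, guard) * pmax(cj, guard))
  structure(list(values = clip01(1 - rho), valid = valid,
                 n_pairs = n_pairs, kernel = kernel,
                 noise_variance = noise_variance),
            class = "fast_doct_image")
}

#' Pooled noise-corrected decorrelation at a given lag
#'
#' Pools the lag-`lag` complex correlation over all pixels and frame pairs
#' of a stack; with many pooled terms the magnitude estimator is essentially
#' unbiased, so this is the reference measurement for comparing against the
#' closed-form `1 - exp(-lag * dt / tau)` of the AR(1) field model.
#'
#' @param frames complex array `nz x nx x N` or a `frame_stack`.
#' @param noise_variance detector noise variance.
#' @param lag frame lag (>= 1).
#' @param mask optional logical `nz x nx` matrix restricting the pooled
#'   pixels.
#' @return scalar decorrelation in `[0, 1]`.
#' @export
pooled_decorrelation <- function(frames, noise_variance = NULL, lag = 1L,
                                 mask = NULL) {
  if (inherits(frames, "frame_stack")) {
    if (is.null(noise_variance)) noise_variance <- frames$noise_variance
    frames <- frames$frames
  }
  n <- dim(frames)[3]
  if (lag < 1 || lag >= n) stopf("lag must be in 1..(n_frames - 1)")
  if (is.null(mask)) mask <- matrix(TRUE, dim(frames)[1], dim(frames)[2])
  num <- 0i; ei <- 0; ej <- 0; cnt <- 0
  for (k in seq_len(n - lag)) {
    a <- frames[, , k][mask]; b <- frames[, , k + lag][mask]
    num <- num + sum(Conj(a) * b)
    ei <- ei + sum(Mod(a)^2)
    ej <- ej + sum(Mod(b)^2)
    cnt <- cnt + length(a)
  }
  den <- sqrt(max(ei - cnt * noise_variance, 1e-300) *
                max(ej - cnt * noise_variance, 1e-300))
  clip01(1 - Mod(num) / den)
}

#' Estimate detector noise variance from signal-free voxels
#'
#' Mean linear intensity over air voxels and frames.
#'
#' @param frames complex array `nz x nx x N` or a `frame_stack`.
#' @param air_mask logical `nz x nx` matrix marking signal-free pixels
#'   (above the segmented surface).
#' @return estimated `sigma_n^2`.
#' @export
estimate_noise_variance <- function(frames, air_mask) {
  if (inherits(frames, "frame_stack")) frames <- frames$frames
  if (!any(air_mask))
    stopf("air_mask is empty; supply sigma_n^2 from configuration instead")
  n <- dim(frames)[3]
  mean(vapply(seq_len(n), function(k) mean(Mod(frames[, , k][air_mask])^2),
              numeric(1)))
}

#' Estimate a temporal correlation-time map from multi-lag decorrelation
#'
#' For each pixel the kernel-averaged noise-corrected correlation magnitude
#' `rho_k` is computed at lags `1..max_lag` and the AR(1) model
#' `rho(t) = exp(-t / tau)` is fitted by weighted least squares of
#' `log rho_k` against lag time through the origin (weights `rho_k^2`,
#' lags with `rho_k` outside `(rho_floor, rho_ceiling)` are excluded).
#'
#' @param frames complex array `nz x nx x N` or a `frame_stack`; more frames
#'   give more pairs per lag and a less biased fit.
#' @param timestamps frame times in seconds (taken from a `frame_stack`).
#' @param noise_variance detector noise variance.
#' The kernel-summed `|sum|` has a Rayleigh-type noise floor: under zero
#' true correlation `E rho_hat^2 = var_inflation / N` for `N` pooled
#' products. Two defences keep that floor out of the fit. First, a lag only
#' enters at all if the frame-pooled (essentially unbiased) correlation
#' magnitude at that lag clears `gate_factor` times the per-voxel floor —
#' this drops lags whose true correlation has decayed into the noise.
#' Second, the per-voxel floor is removed in quadrature
#' (`rho^2 = max(rho_hat^2 - var_inflation / N, 0)`) before the log-linear
#' fit. `var_inflation` is 1 for spatially white speckle; a lateral Gaussian
#' PSF of standard deviation `sigma` pixels correlates neighbouring products
#' and inflates the floor by about `sqrt(2*pi)*sigma`.
#'
#' @param kernel odd spatial window for the per-lag correlation.
#' @param max_lag largest frame lag used.
#' @param rho_floor,rho_ceiling usable per-voxel correlation range (after
#'   the floor correction).
#' @param gate_factor multiple of the per-voxel noise floor that the pooled
#'   correlation of a lag must exceed for the lag to be used.
#' @param var_inflation variance inflation of the kernel-sum noise floor due
#'   to spatially correlated speckle (1 = white).
#' @return list with `tau` (`nz x nx` map in seconds, `NA` where no lag was
#'   usable), `n_lags_used` map, and `lags_used` (the gated lag set).
#' @export
estimate_tau_map <- function(frames, timestamps = NULL, noise_variance = NULL,
                             kernel = 5L, max_lag = 4L, rho_floor = 0.02,
                             rho_ceiling = 0.999, gate_factor = 1,
                             var_inflation = 1) {
  if (inherits(frames, "frame_stack")) {
    if (is.null(timestamps)) timestamps <- frames$timestamps
    if (is.null(noise_variance)) noise_variance <- frames$noise_variance
    frames <- frames$frames
  }
  if (is.null(timestamps)) stopf("timestamps required")
  nz <- dim(frames)[1]; nx <- dim(frames)[2]; n <- dim(frames)[3]
  max_lag <- min(max_lag, n - 1L)
  half <- as.integer(kernel) %/% 2L
  # gate each lag on the frame-pooled correlation vs the per-voxel floor
  voxel_floor <- sqrt(var_inflation / (kernel^2 * (n - seq_len(max_lag))))
  pooled <- vapply(seq_len(max_lag), function(lag)
    1 - pooled_decorrelation(frames, noise_variance, lag), numeric(1))
  lags_used <- which(pooled >= gate_factor * voxel_floor)
  if (!length(lags_used)) lags_used <- 1L  # fall back to the shortest lag
  sw <- 0; sy <- 0; used <- matrix(0L, nz, nx)
  for (lag in lags_used) {
    num <- matrix(0i, nz, nx); ei <- matrix(0, nz, nx); ej <- matrix(0, nz, nx)
    for (k in seq_len(n - lag)) {
      num <- num + Conj(frames[, , k]) * frames[, , k + lag]
      ei <- ei + Mod(frames[, , k])^2
      ej <- ej + Mod(frames[, , k + lag])^2
    }
    counts <- window_count(nz, nx, half) * (n - lag)
    ne <- counts * noise_variance
    rho <- Mod(window_sum_complex(num, half)) /
      sqrt(pmax(window_sum(ei, half) - ne, 1e-300) *
             pmax(window_sum(ej, half) - ne, 1e-300))
    # remove the finite-sum Rayleigh floor in quadrature
    rho <- sqrt(pmax(rho^2 - var_inflation / counts, 0))
    # mean lag time over the pairs (uniform sampling: lag * dt)
    tl <- mean(timestamps[(1 + lag):n] - timestamps[1:(n - lag)])
    ok <- rho > rho_floor & rho < rho_ceiling
    w <- ifelse(ok, rho^2, 0)
    lr <- ifelse(ok, log(pmax(rho, 1e-300)), 0)
    sw <- sw + w * tl^2
    sy <- sy + w * tl * lr
    used <- used + ok
  }
  tau <- ifelse(used > 0 & sy < 0, -sw / sy, NA_real_)
  list(tau = tau, n_lags_used = used, lags_used = lags_used)
}

#' Assemble per-location images into a volume
#'
#' @param images list of `nz x nx` matrices (or `liv_image` /
#'   `fast_doct_image` objects), one per B-scan location.
#' @param location_indices 1-based slow-axis index of each image; defaults
#'   to `seq_along(images)`. Must cover `1..ny` exactly once.
#' @param pitch_um physical pitch per axis `(z, x, y)` in micrometres.
#' @param contrast label, e.g. `"dB"`, `"LIV"`, `"FDOCT"`.
#' @param window_s evaluation time window metadata.
#' @return object of class `oct_volume` with `values` ordered `(z, x, y)`.
#' @export
volume_assemble <- function(images, location_indices = seq_along(images),
                            pitch_um = c(z = 7.24, x = 5.859375, y = 5.859375),
                            contrast = "dB", window_s = NA_real_) {
  mats <- lapply(images, function(im) {
    if (inherits(im, c("liv_image", "fast_doct_image"))) im$values else im
  })
  ny <- length(mats)
  if (ny < 1) stopf("no images supplied")
  if (!setequal(location_indices, seq_len(ny)) ||
      length(location_indices) != ny)
    stopf("location_indices must cover 1..%d exactly once (missing or duplicated locations)", ny)
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1))))
    stopf("all images must share one shape")
  vol <- array(NA_real_, dim = c(d[1], d[2], ny))
  for (i in seq_len(ny)) vol[, , location_indices[i]] <- mats[[i]]
  oct_volume(vol, pitch_um, contrast, window_s)
}

#' Construct an OCT volume container
#'
#' @param values numeric array ordered `(z, x, y)`.
#' @param pitch_um physical pitch per axis in micrometres, named `(z, x, y)`.
#' @param contrast contrast label.
#' @param window_s evaluation window metadata in seconds.
#' @return object of class `oct_volume`.
#' @export
oct_volume <- function(values, pitch_um = c(z = 7.24, x = 5.859375,
                                            y = 5.859375),
                       contrast = "dB", window_s = NA_real_) {
  if (length(dim(values)) != 3) stopf("values must be a 3D array (z, x, y)")
  structure(list(values = values, pitch_um = pitch_um, contrast = contrast,
                 window_s = window_s), class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("oct_volume [%s]: %d x %d x %d (z,x,y), pitch %.3g/%.3g/%.3g um\n",
              x$contrast, d[1], d[2], d[3], x$pitch_um[["z"]],
              x$pitch_um[["x"]], x$pitch_um[["y"]]))
  invisible(x)
}
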