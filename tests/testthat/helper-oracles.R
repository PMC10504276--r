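# independent oracles and small fixture builders used across tests

# two-pass population-variance oracle (divisor N), plain loops
brute_force_liv <- function(db) {
  d <- dim(db)
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      x <- db[i, j, ]
      m <- sum(x) / length(x)
      out[i, j] <- sum((x - m)^2) / length(x)
    }
  }
  out
}

# closed-form expected decorrelation of K pooled products of independent
# circular complex Gaussians: E|sum| = sqrt(pi K / 4) * sigma^2, so the
# uncorrected estimator floors at 1 - sqrt(pi / (4 K))
decorr_floor <- function(K) 1 - sqrt(pi / (4 * K))

# one frozen speckle field replicated n times, optional global phases
static_speckle_stack <- function(nz = 32, nx = 48, n = 4, phases = NULL,
                                 seed = 42) {
  set.seed(seed)
  base <- matrix(complex(real = rnorm(nz * nx), imaginary = rnorm(nz * nx)),
                 nz, nx) / sqrt(2)
  fr <- array(0i, dim = c(nz, nx, n))
  for (k in seq_len(n)) {
    ph <- if (is.null(phases)) 0 else phases[k]
    fr[, , k] <- base * exp(1i * ph)
  }
  fr
}

# mean pairwise correlation magnitude between consecutive frames
mean_pair_correlation <- function(frames) {
  n <- dim(frames)[3]
  r <- vapply(seq_len(n - 1), function(k) {
    a <- frames[, , k]; b <- frames[, , k + 1]
    Mod(sum(Conj(a) * b)) / sqrt(sum(Mod(a)^2) * sum(Mod(b)^2))
  }, numeric(1))
  mean(r)
}

# small uniform AR(1) stack straight from the simulator
uniform_stack <- function(tau_s, n_frames, dt, grid = c(64L, 160L, 1L),
                          static_fraction = 0, snr_db = 30, seed = 1,
                          psf_fwhm_px = 2.5, backscatter = 1) {
  ph <- build_uniform_phantom(grid, tau_s = tau_s,
                              static_fraction = static_fraction,
                              backscatter = backscatter, snr_db = snr_db,
                              seed = seed)
  simulate_frame_stack(ph, 1L, (seq_len(n_frames) - 1) * dt,
                       psf_fwhm_px = psf_fwhm_px)
}
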