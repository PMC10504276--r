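test_that("dB conversion follows 10*log10(|A|^2 + eps)", {
  expect_equal(to_db_intensity(array(1 + 0i, c(1, 1, 2)))[1], 0,
               tolerance = 1e-9)
  expect_equal(to_db_intensity(array(10 + 0i, c(1, 1, 2)))[1], 20,
               tolerance = 1e-9)
  expect_equal(to_db_intensity(array(0i, c(1, 1, 2)), eps = 1e-12)[1], -120)
})

test_that("LIV matches a brute-force two-pass variance oracle", {
  set.seed(10)
  db <- array(rnorm(20 * 30 * 16, mean = 40, sd = 5), c(20, 30, 16))
  expect_equal(liv(db)$values, brute_force_liv(db), tolerance = 1e-10)
})

test_that("LIV basics: zero for constants, direct two-frame value, shift invariance", {
  expect_true(all(liv(array(7, c(4, 5, 8)))$values == 0))

  db2 <- array(0, c(1, 1, 2)); db2[1, 1, ] <- c(10, 20)
  expect_equal(liv(db2)$values[1, 1], 25)  # mean 15, ((-5)^2 + 5^2)/2

  set.seed(11)
  db <- array(rnorm(10 * 10 * 16), c(10, 10, 16))
  expect_equal(liv(db + 1000)$values, liv(db)$values, tolerance = 1e-8)

  expect_error(liv(array(0, c(2, 2, 1))), "at least 2")
  dbn <- db; dbn[1] <- NaN
  expect_error(liv(dbn), "non-finite")
})

test_that("LIV expectation is sigma^2 (N-1)/N for i.i.d. Gaussian input", {
  set.seed(12)
  n_px <- 1e5
  db <- array(rnorm(n_px * 16, sd = 2), c(250, 400, 16))
  v <- liv(db)$values
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - 4 * 15 / 16), 3 * se)
})

test_that("LIV is frame-order invariant; Fast-DOCT is not", {
  set.seed(13)
  db <- array(rnorm(8 * 8 * 6), c(8, 8, 6))
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_equal(liv(db[, , perm])$values, liv(db)$values)

  st <- uniform_stack(0.05, 4, 0.0128, grid = c(24, 32, 1), snr_db = Inf,
                      seed = 14)
  f1 <- fast_doct(st$frames, 0)
  f2 <- fast_doct(st$frames[, , c(1, 3, 2, 4)], 0)
  expect_false(isTRUE(all.equal(f1$values, f2$values)))
})

test_that("bulk phase correction removes arbitrary global per-frame phases", {
  phases <- c(0, 2.1, -1.3, 0.7)
  fr <- static_speckle_stack(phases = phases)
  out <- bulk_phase_correct(fr)
  expect_gte(mean_pair_correlation(out$frames), 0.999)
  # frames differing only by a global phase collapse onto frame 1
  for (k in 2:4)
    expect_equal(out$frames[, , k], fr[, , 1], tolerance = 1e-10)

  # already aligned frames are unchanged
  aligned <- static_speckle_stack(phases = rep(0, 4))
  out2 <- bulk_phase_correct(aligned)
  expect_equal(out2$frames, aligned, tolerance = 1e-12)
  expect_equal(out2$phases, rep(0, 4))

  # an all-zero frame is skipped and flagged, not an error
  fz <- fr; fz[, , 2] <- 0
  out3 <- bulk_phase_correct(fz)
  expect_true(1 %in% out3$skipped || 2 %in% out3$skipped)
})

test_that("Fast-DOCT is zero for identical noiseless frames", {
  fr <- static_speckle_stack(n = 4)
  fd <- fast_doct(fr, noise_variance = 0)
  expect_true(all(fd$values < 1e-6))
  expect_true(all(fd$valid))
})

test_that("independent frames decorrelate to the closed-form estimator floor", {
  set.seed(15)
  nz <- 80; nx <- 160; n <- 4
  fr <- array(complex(real = rnorm(nz * nx * n), imaginary = rnorm(nz * nx * n)),
              c(nz, nx, n)) / sqrt(2)
  for (kern in c(3L, 7L)) {
    fd <- fast_doct(fr, noise_variance = 0, kernel = kern)
    K <- kern^2 * 3
    inner <- fd$values[kern:(nz - kern), kern:(nx - kern)]
    expect_equal(mean(inner), decorr_floor(K), tolerance = 0.02)
  }
  # the floor rises towards 1 as the kernel grows; >= 0.9 needs K >= 79
  expect_gte(mean(fast_doct(fr, 0, kernel = 7L)$values), 0.9)
})

test_that("measured decorrelation matches 1 - exp(-dt/tau) on the AR(1) phantom", {
  st <- uniform_stack(tau_s = 0.02, n_frames = 4, dt = 0.0128,
                      grid = c(64, 160, 1), snr_db = 30, seed = 16)
  meas <- pooled_decorrelation(st)
  expect_lt(abs(meas - (1 - exp(-0.0128 / 0.02))), 0.02)
})

test_that("noise correction flags noise-only pixels instead of rendering them", {
  ph <- build_uniform_phantom(c(64, 160, 1), backscatter = 0, snr_db = 0,
                              seed = 17)
  st <- simulate_frame_stack(ph, 1, (0:3) * 0.0128)
  with_corr <- fast_doct(st$frames, noise_variance = 1)
  expect_gt(mean(!with_corr$valid), 0.99)
  # without correction the same pixels masquerade as strong decorrelation
  no_corr <- fast_doct(st$frames, noise_variance = 0, kernel = 7L)
  expect_gte(mean(no_corr$values), 0.9)
  expect_true(all(no_corr$valid))
})

test_that("kernel validation", {
  fr <- static_speckle_stack(nz = 8, nx = 8)
  expect_error(fast_doct(fr, 0, kernel = 9L), "larger than frame")
  expect_error(fast_doct(fr, 0, kernel = 4L), "odd")
})

test_that("noise variance estimation from air voxels", {
  ph <- build_uniform_phantom(c(80, 160, 1), backscatter = 1, snr_db = 0,
                              air_px = 40, seed = 18)  # noise variance 1
  st <- simulate_frame_stack(ph, 1, (0:3) * 0.0128)
  air <- matrix(FALSE, 80, 160); air[1:38, ] <- TRUE
  est <- estimate_noise_variance(st, air)
  expect_equal(est, 1, tolerance = 0.03)
  # a mask covering tissue is biased high and detectable
  tissue <- matrix(FALSE, 80, 160); tissue[45:80, ] <- TRUE
  expect_gt(estimate_noise_variance(st, tissue), 1.5)
  expect_error(estimate_noise_variance(st, matrix(FALSE, 80, 160)), "empty")

  ph0 <- build_uniform_phantom(c(16, 16, 1), backscatter = 0, snr_db = Inf,
                               seed = 19)
  st0 <- simulate_frame_stack(ph0, 1, c(0, 0.1))
  expect_lt(estimate_noise_variance(st0, matrix(TRUE, 16, 16)), 1e-12)
})

test_that("decorrelation and LIV both increase as tau decreases", {
  taus <- c(10, 1, 0.1)  # spans correlated..decorrelated within each window
  fd_means <- liv_means <- numeric(3)
  for (i in seq_along(taus)) {
    stf <- uniform_stack(taus[i], 4, 0.0128, grid = c(48, 96, 1),
                         snr_db = 30, seed = 20)
    fd_means[i] <- pooled_decorrelation(stf)
    stl <- uniform_stack(taus[i], 16, 0.4096, grid = c(48, 96, 1),
                         snr_db = 30, seed = 20)
    liv_means[i] <- mean(liv(stl)$values)
  }
  expect_true(all(diff(fd_means) > 0))
  expect_true(all(diff(liv_means) > 0))
})

test_that("scale separation: second-scale dynamics seen by LIV, not Fast-DOCT", {
  st_fast <- uniform_stack(1.5, 4, 0.0128, grid = c(48, 96, 1),
                           static_fraction = 0.05, snr_db = 30, seed = 21)
  expect_lt(mean(fast_doct(st_fast)$values), 0.1)
  st_liv <- uniform_stack(1.5, 16, 0.4096, grid = c(48, 96, 1),
                          static_fraction = 0.05, snr_db = 30, seed = 21)
  st_par <- uniform_stack(30, 16, 0.4096, grid = c(48, 96, 1),
                          static_fraction = 0.97, snr_db = 30, seed = 21)
  expect_gte(mean(liv(st_liv)$values), 3 * mean(liv(st_par)$values))
})

test_that("tau maps are recovered from multi-lag decorrelation", {
  st <- uniform_stack(0.05, 16, 0.0128, grid = c(48, 96, 1), snr_db = 30,
                      seed = 22, psf_fwhm_px = 0)
  est <- estimate_tau_map(st)
  med <- median(est$tau, na.rm = TRUE)
  expect_lt(abs(med - 0.05) / 0.05, 0.2)
})

test_that("volume assembly is order-independent and validates input", {
  set.seed(23)
  mats <- lapply(1:5, function(i) matrix(rnorm(12), 3, 4))
  v1 <- volume_assemble(mats)
  expect_identical(dim(v1$values), c(3L, 4L, 5L))
  v2 <- volume_assemble(mats[c(3, 1, 5, 2, 4)],
                        location_indices = c(3, 1, 5, 2, 4))
  expect_identical(v1$values, v2$values)
  expect_error(volume_assemble(mats, location_indices = c(1, 2, 3, 4, 6)),
               "missing or duplicated")
  expect_error(volume_assemble(c(mats, list(matrix(0, 2, 2))),
                               location_indices = 1:6), "one shape")
  v3 <- volume_assemble(mats[1], location_indices = 1)
  expect_identical(dim(v3$values)[3], 1L)
})
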