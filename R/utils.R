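# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw circular complex Gaussian variates
#'
#' Zero-mean circularly symmetric complex normal draws with total variance
#' `var` (i.e. `E|z|^2 = var`, split equally between real and imaginary parts).
#'
#' @param n number of draws.
#' @param var total variance per draw.
#' @return complex vector of length `n`.
#' @keywords internal
rcgauss <- function(n, var = 1) {
  s <- sqrt(var / 2)
  complex(real = stats::rnorm(n, 0, s), imaginary = stats::rnorm(n, 0, s))
}

# truncated-window box sum via integral image; window is (2*half+1)^2,
# clipped at the borders (no padding values enter the sum)
window_sum <- function(m, half) {
  nr <- nrow(m); nc <- ncol(m)
  P <- rbind(0, apply(m, 2, cumsum))
  P <- cbind(0, t(apply(P, 1, cumsum)))
  r <- seq_len(nr); cl <- seq_len(nc)
  r1 <- pmax(r - half, 1L); r2 <- pmin(r + half, nr)
  c1 <- pmax(cl - half, 1L); c2 <- pmin(cl + half, nc)
  P[r2 + 1, c2 + 1] - P[r1, c2 + 1] - P[r2 + 1, c1] + P[r1, c1]
}

window_sum_complex <- function(m, half) {
  window_sum(Re(m), half) + 1i * window_sum(Im(m), half)
}

window_count <- function(nr, nc, half) {
  r <- seq_len(nr); cl <- seq_len(nc)
  nr_win <- pmin(r + half, nr) - pmax(r - half, 1L) + 1L
  nc_win <- pmin(cl + half, nc) - pmax(cl - half, 1L) + 1L
  outer(nr_win, nc_win)
}

# 2D median filter on a matrix with NA-aware window, used to smooth surface
# height maps; cells that are NA stay NA
median_filter2 <- function(m, half = 2L) {
  nr <- nrow(m); nc <- ncol(m)
  k <- 2L * half + 1L
  stack <- array(NA_real_, dim = c(nr, nc, k * k))
  idx <- 0L
  for (dr in -half:half) {
    for (dc in -half:half) {
      idx <- idx + 1L
      rs <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
      cs <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
      stack[, , idx] <- m[rs, cs]
    }
  }
  out <- apply(stack, c(1, 2), stats::median, na.rm = TRUE)
  out[is.na(m)] <- NA_real_
  out[is.nan(out)] <- NA_real_
  out
}

# row-convolution operator for a lateral (x-axis) Gaussian PSF.
# Rows are L2-normalised (also at truncated borders) so that convolving a
# field of i.i.d. unit-variance voxels preserves the per-voxel variance;
# the blur then adds speckle grain without changing mean intensity or
# temporal autocorrelation.
lateral_blur_operator <- function(nx, fwhm_px) {
  if (fwhm_px <= 0) return(diag(nx))
  sigma <- fwhm_px / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(3 * sigma))
  offs <- -half:half
  kern <- exp(-offs^2 / (2 * sigma^2))
  W <- matrix(0, nx, nx)
  for (j in seq_len(nx)) {
    cols <- j + offs
    ok <- cols >= 1 & cols <= nx
    w <- kern[ok]
    W[j, cols[ok]] <- w / sqrt(sum(w^2))
  }
  W
}

# bilinear sampling of a matrix at fractional (row, col) coordinates;
# coordinates outside the grid are clamped to the border
bilinear_sample <- function(m, rows, cols) {
  nr <- nrow(m); nc <- ncol(m)
  rows <- pmin(pmax(rows, 1), nr)
  cols <- pmin(pmax(cols, 1), nc)
  r0 <- pmin(floor(rows), nr - 1L); c0 <- pmin(floor(cols), nc - 1L)
  fr <- rows - r0; fc <- cols - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

# deterministic per-location RNG stream derivation from one master seed;
# stays within 32-bit signed integer range
derive_seed <- function(master_seed, location_index, stream = 0L) {
  m <- as.double(master_seed %% 1000003L)
  ((m * 1009 + as.double(stream) * 100003 + as.double(location_index)) %%
      2147483647) + 1
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# standard hexcone HSV -> RGB in double precision (h, s, v in [0, 1]);
# returns a list of r, g, b vectors without 8-bit quantisation
hsv_to_rgb <- function(h, s, v) {
  h6 <- pmin(h, 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
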