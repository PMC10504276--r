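# Synthetic speckle phantoms with known ground-truth dynamics.
#
# A phantom is a voxel grid (z, x, y) carrying per-voxel temporal correlation
# time tau, static field fraction f, and mean backscatter intensity, plus a
# smooth curved tissue surface with empty (noise-only) space above it.
# Kidney presets place convoluted tubular structures (fast-dynamics walls
# around hypo-scattering lumina) in a static-dominated parenchyma, or a
# superficial fast-ish shell mimicking the appearance of obstructed kidneys.

#' Construct a phantom specification
#'
#' Low-level constructor; most users should call [build_kidney_phantom()] or
#' [build_uniform_phantom()]. All arrays are ordered (z, x, y).
#'
#' @param grid_shape integer triple `(nz, nx, ny)`.
#' @param pixel_pitch_um physical pitch per axis in micrometres, named
#'   `(z, x, y)`.
#' @param surface_height `nx x ny` matrix of the first tissue z-index
#'   (1-based); voxels above it are air.
#' @param masks named list of disjoint logical `nz x nx x ny` arrays whose
#'   union covers the grid (must include `"air"`).
#' @param tau_map per-voxel temporal correlation time in seconds (> 0).
#' @param static_fraction_map per-voxel fraction in `[0, 1]` of the field
#'   that is temporally frozen.
#' @param backscatter_map per-voxel mean linear backscatter intensity (>= 0).
#' @param noise_variance detector noise variance in linear intensity units.
#' @param seed master RNG seed for frame synthesis.
#' @param preset label of the generating preset.
#' @param structures optional list of generating geometry (tube centerlines).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, pixel_pitch_um, surface_height, masks,
                         tau_map, static_fraction_map, backscatter_map,
                         noise_variance, seed, preset = "custom",
                         structures = list()) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 1))
    stopf("grid_shape must be a positive integer triple (nz, nx, ny)")
  p <- structure(list(
    grid_shape = grid_shape, pixel_pitch_um = pixel_pitch_um,
    surface_height = surface_height, masks = masks, tau_map = tau_map,
    static_fraction_map = static_fraction_map,
    backscatter_map = backscatter_map, noise_variance = noise_variance,
    seed = as.integer(seed), preset = preset, structures = structures
  ), class = "phantom_spec")
  validate_phantom_spec(p)
  p
}

#' Validate phantom invariants
#'
#' Checks positivity of tau, range of static fractions and backscatter,
#' mutual disjointness and full coverage of the masks, and that all voxels
#' above the surface belong to air.
#'
#' @param p a `phantom_spec`.
#' @return `p` invisibly; errors on violation.
#' @export
validate_phantom_spec <- function(p) {
  d <- p$grid_shape
  for (nm in c("tau_map", "static_fraction_map", "backscatter_map"))
    if (!identical(dim(p[[nm]]), d)) stopf("%s has wrong dimensions", nm)
  if (any(p$tau_map <= 0)) stopf("tau_map must be > 0 everywhere")
  if (any(p$static_fraction_map < 0 | p$static_fraction_map > 1))
    stopf("static_fraction_map must lie in [0, 1]")
  if (any(p$backscatter_map < 0)) stopf("backscatter_map must be >= 0")
  if (p$noise_variance < 0) stopf("noise_variance must be >= 0")
  if (!"air" %in% names(p$masks)) stopf("masks must include 'air'")
  cover <- array(0L, dim = d)
  for (m in p$masks) cover <- cover + m
  if (any(cover != 1L))
    stopf("structure masks must be disjoint and cover the grid exactly once")
  zidx <- array(rep(seq_len(d[1]), prod(d[2:3])), dim = d)
  habove <- array(rep(p$surface_height, each = d[1]), dim = d)
  above <- zidx < habove
  if (any(above & !p$masks$air))
    stopf("all voxels above surface_height must be air")
  if (any(p$backscatter_map[p$masks$air] != 0))
    stopf("air voxels must have zero backscatter")
  invisible(p)
}

# smooth wander track of length n with given max amplitude (pixels)
smooth_track <- function(n, amp, smooth_width = 15L) {
  if (amp <= 0) return(rep(0, n))
  w <- cumsum(stats::rnorm(n))
  k <- rep(1 / smooth_width, smooth_width)
  w <- stats::filter(c(rep(w[1], smooth_width), w, rep(w[n], smooth_width)),
                     k, sides = 2)
  w <- as.numeric(w)[smooth_width + seq_len(n)]
  w <- w - mean(w)
  m <- max(abs(w))
  if (m < 1e-9) rep(0, n) else amp * w / m
}

default_dynamics <- function() {
  list(
    parenchyma = list(tau = 30, f = 0.97, backscatter = 1),
    tubule_wall = list(tau = 0.05, f = 0.05, backscatter = 1),
    tubule_lumen = list(tau = 30, f = 0.97, backscatter = 0.1),
    superficial_shell = list(tau = 1.5, f = 0.05, backscatter = 1)
  )
}

#' Build a kidney-like phantom
#'
#' Three presets mirror the imaging phenotypes of normal and
#' ureter-obstructed kidneys:
#'
#' * `"normal"`: at least three non-intersecting convoluted tubes below the
#'   surface; the tube walls carry fast dynamics (short tau), the lumina are
#'   hypo-scattering, and the parenchyma is static-dominated.
#' * `"obstructed_1w"`: at most two residual short tube segments plus a
#'   superficial shell of intermediate (second-scale) dynamics following the
#'   surface.
#' * `"obstructed_2w"`: shell only, no tubes.
#'
#' All presets share a smooth curved tissue surface with noise-only air
#' above it.
#'
#' @param preset one of `"normal"`, `"obstructed_1w"`, `"obstructed_2w"`.
#' @param grid_shape integer triple `(nz, nx, ny)`.
#' @param seed master RNG seed (drives geometry and downstream synthesis).
#' @param tube_diameter_um outer (wall-to-wall) tube diameter.
#' @param wall_thickness_um thickness of the fast-dynamics wall.
#' @param n_tubes number of tubes for the normal preset.
#' @param shell_thickness_um thickness of the superficial shell.
#' @param wall_tau_s correlation time of tube-wall dynamics in seconds.
#' @param wall_tau_scale multiplier on `wall_tau_s`; emulates the
#'   between-sample variability of millisecond-scale wall dynamics.
#' @param shell_tau_s correlation time of the shell.
#' @param parenchyma_tau_s correlation time of the parenchyma.
#' @param parenchyma_static static field fraction of the parenchyma.
#' @param dynamic_static static fraction of wall/shell voxels.
#' @param lumen_backscatter linear backscatter of the hypo-scattering lumen.
#' @param snr_db phantom signal-to-noise ratio: parenchyma backscatter (1.0)
#'   over the detector noise variance, in dB.
#' @param pixel_pitch_um pitch per axis `(z, x, y)` in micrometres.
#' @param slab_limit_px tubes are constrained to lie within this many pixels
#'   below the surface.
#' @return `phantom_spec`.
#' @export
build_kidney_phantom <- function(preset = c("normal", "obstructed_1w",
                                            "obstructed_2w"),
                                 grid_shape = c(64L, 128L, 48L),
                                 seed = 7L,
                                 tube_diameter_um = 40,
                                 wall_thickness_um = 12,
                                 n_tubes = 4L,
                                 shell_thickness_um = 60,
                                 wall_tau_s = 0.05,
                                 wall_tau_scale = 1,
                                 shell_tau_s = 1.5,
                                 parenchyma_tau_s = 30,
                                 parenchyma_static = 0.97,
                                 dynamic_static = 0.05,
                                 lumen_backscatter = 0.1,
                                 snr_db = 30,
                                 pixel_pitch_um = c(z = 7.24, x = 5.859375,
                                                    y = 5.859375),
                                 slab_limit_px = 100L) {
  preset <- tryCatch(match.arg(preset), error = function(e)
    stopf("unknown preset; valid presets: normal, obstructed_1w, obstructed_2w"))
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape < 1)) stopf("grid_shape must be positive")
  nz <- grid_shape[1]; nx <- grid_shape[2]; ny <- grid_shape[3]
  pz <- pixel_pitch_um[["z"]]; px <- pixel_pitch_um[["x"]]
  py <- pixel_pitch_um[["y"]]
  set.seed(derive_seed(seed, 0L, stream = 999L))

  # smooth curved surface (first tissue z-index), at least 4 voxels of air
  xn <- (seq_len(nx) - 0.5) / nx
  yn <- (seq_len(ny) - 0.5) / ny
  h <- outer(3 * sin(pi * xn + 0.4), rep(1, ny)) +
    outer(rep(1, nx), 2 * cos(1.3 * pi * yn))
  surface_height <- pmax(round(10 + h), 5L)
  if (any(surface_height >= nz))
    stopf("grid too shallow for the curved surface")

  masks <- list(
    air = array(FALSE, grid_shape),
    tubule_wall = array(FALSE, grid_shape),
    tubule_lumen = array(FALSE, grid_shape),
    superficial_shell = array(FALSE, grid_shape),
    parenchyma = array(FALSE, grid_shape)
  )
  zidx <- array(rep(seq_len(nz), nx * ny), dim = grid_shape)
  hvol <- array(rep(surface_height, each = nz), dim = grid_shape)
  masks$air <- zidx < hvol

  shell_px <- max(1L, round(shell_thickness_um / pz))
  has_shell <- preset %in% c("obstructed_1w", "obstructed_2w")
  if (has_shell)
    masks$superficial_shell <- zidx >= hvol & zidx < hvol + shell_px

  r_out <- tube_diameter_um / 2
  r_in <- max(r_out - wall_thickness_um, 0)
  centerlines <- list()

  rasterize_tube <- function(x_range, y_center, z_center, wander_y, wander_z) {
    # returns centerline data frame; fills masks in the enclosing env
    xs <- x_range[1]:x_range[2]
    n <- length(xs)
    yc <- y_center + smooth_track(n, wander_y)
    zc <- z_center + smooth_track(n, wander_z)
    # keep the tube inside tissue and inside the sub-surface slab band
    for (i in seq_len(n)) {
      hx <- surface_height[xs[i], pmin(pmax(round(yc[i]), 1L), ny)]
      shell_gap <- if (has_shell) shell_px else 0L
      zmin <- hx + shell_gap + r_out / pz + 2
      zmax <- min(nz - r_out / pz - 1, hx + slab_limit_px - r_out / pz - 1)
      zc[i] <- min(max(zc[i], zmin), zmax)
    }
    for (i in seq_len(n)) {
      dy2 <- ((seq_len(ny) - yc[i]) * py)^2
      dz2 <- ((seq_len(nz) - zc[i]) * pz)^2
      d2 <- outer(dz2, dy2, "+")            # nz x ny at this x
      masks$tubule_wall[, xs[i], ] <<-
        masks$tubule_wall[, xs[i], ] | (d2 <= r_out^2 & d2 > r_in^2)
      masks$tubule_lumen[, xs[i], ] <<-
        masks$tubule_lumen[, xs[i], ] | (d2 <= r_in^2)
    }
    data.frame(x = xs, y = yc, z = zc)
  }

  if (preset == "normal") {
    if (n_tubes < 3) stopf("normal preset requires n_tubes >= 3")
    band <- ny / n_tubes
    r_out_y_px <- r_out / py
    amp_y <- band / 2 - r_out_y_px - 1
    if (amp_y < 0)
      stopf("grid_shape[3] = %d too small for %d non-intersecting tubes", ny,
            n_tubes)
    for (j in seq_len(n_tubes)) {
      y0 <- (j - 0.5) * band
      z0 <- 22 + ((j - 1) %% 3) * 8
      centerlines[[j]] <- rasterize_tube(c(1L, nx), y0, z0,
                                         wander_y = min(amp_y, 2),
                                         wander_z = 3)
    }
  } else if (preset == "obstructed_1w") {
    seg_len <- max(8L, round(0.12 * nx))
    for (j in 1:2) {
      x0 <- sample.int(nx - seg_len, 1)
      y0 <- ny * (0.25 + 0.5 * (j - 1))
      centerlines[[j]] <- rasterize_tube(c(x0, x0 + seg_len - 1L), y0, 30,
                                         wander_y = 1, wander_z = 2)
    }
  }

  # precedence: air > lumen > wall > shell > parenchyma
  masks$tubule_wall <- masks$tubule_wall & !masks$air & !masks$tubule_lumen
  masks$tubule_lumen <- masks$tubule_lumen & !masks$air
  masks$superficial_shell <- masks$superficial_shell & !masks$air &
    !masks$tubule_wall & !masks$tubule_lumen
  masks$parenchyma <- !(masks$air | masks$tubule_wall | masks$tubule_lumen |
                          masks$superficial_shell)

  dyn <- default_dynamics()
  dyn$tubule_wall$tau <- wall_tau_s * wall_tau_scale
  dyn$superficial_shell$tau <- shell_tau_s
  dyn$parenchyma$tau <- parenchyma_tau_s
  dyn$parenchyma$f <- parenchyma_static
  dyn$tubule_wall$f <- dyn$superficial_shell$f <- dynamic_static
  dyn$tubule_lumen$tau <- parenchyma_tau_s
  dyn$tubule_lumen$f <- parenchyma_static
  dyn$tubule_lumen$backscatter <- lumen_backscatter

  tau_map <- array(parenchyma_tau_s, grid_shape)
  f_map <- array(parenchyma_static, grid_shape)
  i_map <- array(1, grid_shape)
  for (nm in intersect(names(dyn), names(masks))) {
    tau_map[masks[[nm]]] <- dyn[[nm]]$tau
    f_map[masks[[nm]]] <- dyn[[nm]]$f
    i_map[masks[[nm]]] <- dyn[[nm]]$backscatter
  }
  i_map[masks$air] <- 0
  f_map[masks$air] <- 1

  phantom_spec(grid_shape, pixel_pitch_um, surface_height, masks,
               tau_map, f_map, i_map,
               noise_variance = 10^(-snr_db / 10), seed = seed,
               preset = preset, structures = centerlines)
}

#' Build a spatially uniform phantom
#'
#' One dynamics class everywhere below an optional air gap; convenient for
#' estimator-oracle and parameter-recovery experiments where the
#' autocorrelation has a closed form.
#'
#' @param grid_shape integer triple `(nz, nx, ny)`.
#' @param tau_s correlation time in seconds.
#' @param static_fraction frozen field fraction in `[0, 1]`.
#' @param backscatter mean linear intensity of the tissue voxels.
#' @param snr_db signal-to-noise ratio in dB referenced to unit backscatter
#'   (the noise variance is `10^(-snr_db/10)`); `Inf` for noise-free.
#' @param seed master RNG seed.
#' @param air_px number of noise-only voxels at the top of every A-line.
#' @param pixel_pitch_um pitch per axis in micrometres.
#' @return `phantom_spec`.
#' @export
build_uniform_phantom <- function(grid_shape = c(64L, 128L, 8L),
                                  tau_s = 0.1, static_fraction = 0,
                                  backscatter = 1, snr_db = 30, seed = 1L,
                                  air_px = 0L,
                                  pixel_pitch_um = c(z = 7.24, x = 5.859375,
                                                     y = 5.859375)) {
  grid_shape <- as.integer(grid_shape)
  nz <- grid_shape[1]
  if (air_px >= nz) stopf("air_px must be < nz")
  surface_height <- matrix(air_px + 1L, grid_shape[2], grid_shape[3])
  zidx <- array(rep(seq_len(nz), prod(grid_shape[2:3])), dim = grid_shape)
  air <- zidx <= air_px
  masks <- list(air = air, parenchyma = !air)
  i_map <- array(backscatter, grid_shape); i_map[air] <- 0
  f_map <- array(static_fraction, grid_shape); f_map[air] <- 1
  phantom_spec(grid_shape, pixel_pitch_um, surface_height, masks,
               tau_map = array(tau_s, grid_shape),
               static_fraction_map = f_map, backscatter_map = i_map,
               noise_variance = if (is.finite(snr_db)) 10^(-snr_db / 10) else 0,
               seed = seed, preset = "uniform")
}

#' Export ground-truth maps of a phantom
#'
#' Lossless export of the phantom's per-voxel ground truth for
#' parameter-recovery tests and reports.
#'
#' @param phantom a `phantom_spec`.
#' @return list with `tau_map`, `static_fraction_map`, `backscatter_map`,
#'   `masks`, `surface_height`, and per-mask `voxel_counts`.
#' @export
ground_truth_maps <- function(phantom) {
  stopifnot(inherits(phantom, "phantom_spec"))
  list(tau_map = phantom$tau_map,
       static_fraction_map = phantom$static_fraction_map,
       backscatter_map = phantom$backscatter_map,
       masks = phantom$masks,
       surface_height = phantom$surface_height,
       voxel_counts = vapply(phantom$masks, sum, numeric(1)))
}

#' @export
print.phantom_spec <- function(x, ...) {
  d <- x$grid_shape
  cat(sprintf("phantom_spec '%s': %d x %d x %d (z,x,y), seed %d\n",
              x$preset, d[1], d[2], d[3], x$seed))
  cat(sprintf("  pitch (um): z %.3g, x %.3g, y %.3g; noise variance %.3g\n",
              x$pixel_pitch_um[["z"]], x$pixel_pitch_um[["x"]],
              x$pixel_pitch_um[["y"]], x$noise_variance))
  cnt <- vapply(x$masks, sum, numeric(1))
  cat("  mask voxels:", paste(sprintf("%s=%d", names(cnt), cnt),
                              collapse = ", "), "\n")
  invisible(x)
}
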