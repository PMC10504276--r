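# Quantitative metrics on projections: structure diameters by FWHM profile
# analysis, per-region statistics against ground-truth masks, and phenotype
# reports that condense a phantom run into the contrast ratios used for
# acceptance checks.

#' Estimate a structure diameter by FWHM profile analysis
#'
#' Samples the image along a line segment by bilinear interpolation, takes
#' the baseline as the median of the profile tails, and measures the full
#' width at half maximum between the linearly interpolated half-maximum
#' crossings around the profile peak. For dark (hypo-scattering) structures
#' set `polarity = "dip"` to measure the inverted profile.
#'
#' @param image numeric matrix (e.g. a projection), `slab_projection`, or
#'   `liv_image`. Rows are x, columns y for projections.
#' @param p0,p1 numeric `(row, col)` endpoints of the profile line in pixel
#'   coordinates; the line must cross exactly one structure.
#' @param pitch_um physical pitch `(row, col)` in micrometres per pixel.
#' @param n_samples number of profile samples.
#' @param tail_fraction fraction of samples at each end used for the
#'   baseline.
#' @param polarity `"peak"` for bright structures, `"dip"` for dark ones.
#' @return object of class `diameter_estimate`: `fwhm_um`, `profile`,
#'   `positions_um`, `baseline`, `peak`, `method = "fwhm"`.
#' @export
estimate_diameter <- function(image, p0, p1,
                              pitch_um = c(5.859375, 5.859375),
                              n_samples = 200L, tail_fraction = 0.2,
                              polarity = c("peak", "dip")) {
  polarity <- match.arg(polarity)
  m <- as_image_matrix(image)
  t_ <- seq(0, 1, length.out = n_samples)
  rows <- p0[1] + t_ * (p1[1] - p0[1])
  cols <- p0[2] + t_ * (p1[2] - p0[2])
  prof <- bilinear_sample(m, rows, cols)
  if (any(!is.finite(prof)))
    stopf("profile crosses invalid (non-finite) pixels")
  step_um <- sqrt(((p1[1] - p0[1]) * pitch_um[1])^2 +
                    ((p1[2] - p0[2]) * pitch_um[2])^2) / (n_samples - 1)
  pos_um <- (seq_len(n_samples) - 1) * step_um
  y <- if (polarity == "dip") -prof else prof
  n_tail <- max(2L, round(tail_fraction * n_samples))
  baseline <- stats::median(c(y[seq_len(n_tail)],
                              y[seq(n_samples - n_tail + 1, n_samples)]))
  ipk <- which.max(y)
  peak <- y[ipk]
  half <- baseline + (peak - baseline) / 2
  if (peak <= baseline)
    stopf("no structure found above the baseline along the profile")
  cross_left <- cross_right <- NA_real_
  if (ipk >= 2) for (i in ipk:2) {
    if (y[i - 1] <= half && y[i] > half) {
      frac <- (half - y[i - 1]) / (y[i] - y[i - 1])
      cross_left <- pos_um[i - 1] + frac * step_um
      break
    }
  }
  if (ipk <= n_samples - 1) for (i in ipk:(n_samples - 1)) {
    if (y[i] > half && y[i + 1] <= half) {
      frac <- (y[i] - half) / (y[i] - y[i + 1])
      cross_right <- pos_um[i] + frac * step_um
      break
    }
  }
  if (is.na(cross_left) || is.na(cross_right))
    stopf("no half-maximum crossing on %s side of the peak; profile may not cross a single structure",
          if (is.na(cross_left)) "the left" else "the right")
  structure(list(fwhm_um = cross_right - cross_left,
                 profile = prof, positions_um = pos_um,
                 baseline = if (polarity == "dip") -baseline else baseline,
                 peak = if (polarity == "dip") -peak else peak,
                 method = "fwhm"),
            class = "diameter_estimate")
}

#' Per-region summary statistics
#'
#' @param map numeric matrix or array.
#' @param masks named list of logical masks with the same dimensions.
#' @return data.frame with one row per mask: `n`, `mean`, `median`, `sd`,
#'   `q25`, `q75`.
#' @export
region_stats <- function(map, masks) {
  if (inherits(map, "slab_projection")) map <- map$image
  rows <- lapply(names(masks), function(nm) {
    msk <- masks[[nm]]
    if (!identical(dim(msk), dim(map)))
      stopf("mask '%s' does not match the map dimensions", nm)
    vals <- map[msk]
    vals <- vals[is.finite(vals)]
    if (!length(vals)) stopf("mask '%s' is empty (or all invalid)", nm)
    q <- stats::quantile(vals, c(0.25, 0.75), names = FALSE)
    data.frame(mask = nm, n = length(vals), mean = mean(vals),
               median = stats::median(vals), sd = stats::sd(vals),
               q25 = q[1], q75 = q[2])
  })
  do.call(rbind, rows)
}

#' Project a 3D mask onto the en face plane within a slab
#'
#' A column is marked if any mask voxel lies within `[height, height +
#' slab_pixels)` of the segmented surface.
#'
#' @param mask3d logical array `(z, x, y)`.
#' @param surface a `surface_map`.
#' @param slab_pixels slab depth in pixels.
#' @return logical `nx x ny` matrix.
#' @export
project_mask_enface <- function(mask3d, surface, slab_pixels = 100L) {
  d <- dim(mask3d)
  out <- matrix(FALSE, d[2], d[3])
  for (y in seq_len(d[3])) {
    for (x in seq_len(d[2])) {
      h <- surface$height[x, y]
      if (is.na(h)) next
      zmax <- min(h + slab_pixels - 1L, d[1])
      if (zmax >= h) out[x, y] <- any(mask3d[h:zmax, x, y])
    }
  }
  out
}

#' Count pipe-like connected components in a projection
#'
#' Thresholds the projection and labels connected components
#' (8-connectivity); components smaller than `min_area` pixels are ignored.
#'
#' @param projection `slab_projection` or numeric matrix.
#' @param threshold binarisation threshold.
#' @param min_area minimum component area in pixels.
#' @return integer component count, with attribute `"areas"`.
#' @export
count_pipe_components <- function(projection, threshold, min_area = 20L) {
  img <- as_image_matrix(projection)
  bin <- matrix(0, nrow(img), ncol(img))
  bin[is.finite(img) & img >= threshold] <- 1
  lab <- EBImage::bwlabel(bin)
  areas <- tabulate(lab[lab > 0])
  areas <- areas[areas >= min_area]
  structure(length(areas), areas = areas)
}

visibility_label <- function(ratio, visible = 3, moderate = 1.5) {
  if (is.na(ratio)) return("absent")
  if (ratio >= visible) "clearly visible"
  else if (ratio >= moderate) "moderately visible"
  else "not visible"
}

#' Phenotype report for a phantom run
#'
#' Condenses LIV and Fast-DOCT results into the summary quantities that
#' distinguish the presets: the tubule-wall/parenchyma contrast ratio in the
#' LIV slab projection, the shell/parenchyma LIV ratio in the volume, the
#' mean Fast-DOCT decorrelation over tubule walls (with a visibility call),
#' and the apparent thickness of the superficial high-dynamics layer.
#'
#' The tubule ratio is reported as `NA` ("absent") when wall structures
#' cover less than `min_coverage` of the valid en face area — the regime in
#' which residual fragments are no longer measurable as structures.
#' Continuous ratios are mapped to visibility labels (`>= 3` clearly
#' visible, `1.5..3` moderately visible, `< 1.5` not visible) for reporting
#' only.
#'
#' @param phantom the `phantom_spec` ground truth.
#' @param liv_vol `oct_volume` of LIV.
#' @param fdoct_vol `oct_volume` of Fast-DOCT decorrelation.
#' @param surface `surface_map` used for the projections.
#' @param liv_proj LIV `slab_projection`.
#' @param slab_pixels slab depth in pixels.
#' @param fdoct_visible_threshold mean wall decorrelation at or above which
#'   tubules count as visible in Fast-DOCT.
#' @param min_coverage minimum en face wall coverage for a defined tubule
#'   ratio.
#' @param layer_liv_threshold LIV threshold (dB^2) used to measure the
#'   superficial high-dynamics layer thickness.
#' @return one-row data.frame.
#' @export
phenotype_report <- function(phantom, liv_vol, fdoct_vol, surface, liv_proj,
                             slab_pixels = 100L,
                             fdoct_visible_threshold = 0.25,
                             min_coverage = 0.05,
                             layer_liv_threshold = 8) {
  masks <- phantom$masks
  has_wall <- !is.null(masks$tubule_wall) && any(masks$tubule_wall)
  has_shell <- !is.null(masks$superficial_shell) &&
    any(masks$superficial_shell)

  # tubule contrast: en face projection medians over wall vs tubule-free cols
  tub_ratio <- NA_real_
  coverage <- 0
  if (has_wall) {
    wall_cols <- project_mask_enface(masks$tubule_wall, surface, slab_pixels)
    tube_cols <- wall_cols |
      project_mask_enface(masks$tubule_lumen, surface, slab_pixels)
    ok <- liv_proj$valid
    coverage <- sum(wall_cols & ok) / max(sum(ok), 1)
    if (coverage >= min_coverage) {
      wall_med <- stats::median(liv_proj$image[wall_cols & ok])
      par_med <- stats::median(liv_proj$image[!tube_cols & ok])
      tub_ratio <- wall_med / par_med
    }
  }

  # shell contrast: 3D mask means on the LIV volume
  shell_ratio <- NA_real_
  if (has_shell) {
    shell_mean <- mean(liv_vol$values[masks$superficial_shell])
    par_mean <- mean(liv_vol$values[masks$parenchyma])
    shell_ratio <- shell_mean / par_mean
  }

  # Fast-DOCT over walls: mean decorrelation, absolute visibility call
  fdoct_wall <- NA_real_
  if (has_wall) fdoct_wall <- mean(fdoct_vol$values[masks$tubule_wall])

  # apparent superficial layer thickness from the LIV volume
  d <- dim(liv_vol$values)
  runs <- c()
  for (y in seq_len(d[3])) {
    for (x in seq_len(d[2])) {
      h <- surface$height[x, y]
      if (is.na(h)) next
      col <- liv_vol$values[h:d[1], x, y] >= layer_liv_threshold
      n0 <- which(!col)[1]
      runs <- c(runs, if (is.na(n0)) length(col) else n0 - 1L)
    }
  }
  layer_um <- stats::median(runs) * liv_vol$pitch_um[["z"]]

  data.frame(
    preset = phantom$preset,
    tubule_contrast_ratio = tub_ratio,
    tubule_coverage = coverage,
    tubule_visibility_liv = visibility_label(tub_ratio),
    shell_contrast_ratio = shell_ratio,
    shell_visibility_liv = visibility_label(shell_ratio),
    fdoct_wall_mean = fdoct_wall,
    fdoct_tubule_visible = !is.na(fdoct_wall) &&
      fdoct_wall >= fdoct_visible_threshold,
    surface_layer_thickness_um = layer_um,
    stringsAsFactors = FALSE
  )
}
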