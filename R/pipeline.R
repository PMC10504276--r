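# End-to-end pipeline: phantom -> two-protocol acquisition -> contrasts ->
# surface segmentation -> slab projections -> rendering -> metrics, driven
# by a single serializable configuration and master seed. LIV comes from the
# block-repeating raster stack, Fast-DOCT from the fast raster stack.

#' Build a pipeline run configuration
#'
#' All parameters of a run in one serializable object; a run re-executed
#' from its persisted config and seed is bit-identical.
#'
#' @param preset phantom preset passed to [build_kidney_phantom()].
#' @param grid_shape phantom grid `(nz, nx, ny)`.
#' @param seed master seed for phantom geometry and frame synthesis.
#' @param phantom named list of extra arguments for [build_kidney_phantom()].
#' @param fov_mm lateral field of view for both protocols.
#' @param psf_fwhm_px lateral PSF width for the simulator.
#' @param kernel Fast-DOCT spatial kernel (odd, pixels).
#' @param delta_rel Fast-DOCT validity guard, fraction of noise energy.
#' @param eps dB conversion intensity floor.
#' @param noise_source `"air_estimate"` (estimate sigma_n^2 from above the
#'   surface) or `"truth"` (use the phantom's synthesis value).
#' @param slab_pixels slab depth in pixels; `NA` means 100 capped to the
#'   available grid depth at run time.
#' @param margin_db,min_run,smooth_window surface segmentation parameters.
#' @param hue_range,value_window rendering windows (see [liv_composite()]).
#' @param out_dir output directory; `NULL` disables file output.
#' @return object of class `run_config`.
#' @export
run_config <- function(preset = "normal", grid_shape = c(64L, 128L, 48L),
                       seed = 7L, phantom = list(), fov_mm = 3,
                       psf_fwhm_px = 2.5, kernel = 3L, delta_rel = 0.5,
                       eps = 1e-12, noise_source = "air_estimate",
                       slab_pixels = NA_integer_, margin_db = 10,
                       min_run = 3L, smooth_window = 5L,
                       hue_range = c(0, 10), value_window = NULL,
                       out_dir = NULL) {
  structure(list(preset = preset, grid_shape = as.integer(grid_shape),
                 seed = as.integer(seed), phantom = phantom, fov_mm = fov_mm,
                 psf_fwhm_px = psf_fwhm_px, kernel = as.integer(kernel),
                 delta_rel = delta_rel, eps = eps,
                 noise_source = noise_source,
                 slab_pixels = slab_pixels, margin_db = margin_db,
                 min_run = as.integer(min_run),
                 smooth_window = as.integer(smooth_window),
                 hue_range = hue_range, value_window = value_window,
                 out_dir = out_dir),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Checks the type invariants of every stage before any computation.
#'
#' @param config a `run_config`.
#' @param liv_proto,fast_proto the protocols the run will use (defaults as
#'   in [run_pipeline()]).
#' @return character vector of violations (empty when the config is valid).
#' @export
validate_config <- function(config,
                            liv_proto = liv_protocol(config$fov_mm),
                            fast_proto = fast_protocol(config$fov_mm)) {
  v <- character(0)
  g <- config$grid_shape
  if (length(g) != 3 || any(g < 1))
    v <- c(v, "grid_shape must be a positive triple (nz, nx, ny)")
  if (!config$preset %in% c("normal", "obstructed_1w", "obstructed_2w"))
    v <- c(v, sprintf("unknown preset '%s'", config$preset))
  if (liv_proto$n_repeats < 2)
    v <- c(v, "LIV protocol needs n_repeats >= 2 (variance over one frame is undefined)")
  if (fast_proto$n_repeats < 2)
    v <- c(v, "fast protocol needs n_repeats >= 2")
  if (g[3] > total_locations(liv_proto))
    v <- c(v, "phantom has more y locations than the LIV protocol scans")
  if (!is.na(config$slab_pixels)) {
    if (config$slab_pixels < 1) v <- c(v, "slab_pixels must be >= 1")
    else if (config$slab_pixels > g[1])
      v <- c(v, sprintf("slab of %d px does not fit the %d px deep grid",
                        config$slab_pixels, g[1]))
  }
  tau_extra <- config$phantom[c("wall_tau_s", "shell_tau_s",
                                "parenchyma_tau_s")]
  tau_extra <- tau_extra[!vapply(tau_extra, is.null, logical(1))]
  bad_tau <- names(tau_extra)[vapply(tau_extra, function(x) x <= 0,
                                     logical(1))]
  for (nm in bad_tau)
    v <- c(v, sprintf("%s must be > 0 (tau_map must stay positive)", nm))
  if (config$kernel < 1 || config$kernel %% 2L == 0L)
    v <- c(v, "Fast-DOCT kernel must be a positive odd integer")
  v
}

#' Execute the full phantom-to-metrics pipeline
#'
#' Simulates both acquisitions (block-repeating raster for LIV, fast raster
#' for Fast-DOCT) of the configured phantom, computes the contrasts per
#' location, assembles volumes, segments the surface from the
#' frame-averaged dB intensity, produces slab average projections and
#' pseudo-color composites, and reports phenotype metrics. When
#' `config$out_dir` is set, volumes (TIFF), images (PNG), the config, the
#' metrics and a manifest with MD5 checksums are written there.
#'
#' @param config a `run_config`.
#' @return list with `phantom`, `volumes` (`db`, `liv`, `fdoct`),
#'   `surface`, `projections`, `composites`, `phenotype`, `noise_variance`,
#'   `manifest` (when writing).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  viol <- validate_config(config)
  if (length(viol))
    stopf("invalid configuration:\n  - %s", paste(viol, collapse = "\n  - "))

  liv_proto <- liv_protocol(config$fov_mm)
  fast_proto <- fast_protocol(config$fov_mm)

  phantom <- do.call(build_kidney_phantom, c(
    list(preset = config$preset, grid_shape = config$grid_shape,
         seed = config$seed),
    config$phantom))
  g <- phantom$grid_shape
  pitch <- phantom$pixel_pitch_um

  liv_imgs <- vector("list", g[3])
  db_imgs <- vector("list", g[3])
  fd_stacks <- vector("list", g[3])
  for (y in seq_len(g[3])) {
    st <- simulate_frame_stack(phantom, y, protocol_timestamps(liv_proto, y),
                               psf_fwhm_px = config$psf_fwhm_px, stream = 0L)
    db <- to_db_intensity(st, eps = config$eps)
    liv_imgs[[y]] <- liv(db, window_seconds = diff(range(st$timestamps)))
    db_imgs[[y]] <- rowMeans(db, dims = 2)   # 16-frame-averaged dB intensity
    fd_stacks[[y]] <- simulate_frame_stack(
      phantom, y, protocol_timestamps(fast_proto, y),
      psf_fwhm_px = config$psf_fwhm_px, stream = 1L)
  }

  db_vol <- volume_assemble(db_imgs, pitch_um = pitch, contrast = "dB")

  # noise level: measured from above-surface voxels of the mean-dB volume,
  # or taken from the phantom ground truth
  if (config$noise_source == "truth") {
    s2n <- phantom$noise_variance
  } else {
    s2n <- mean(vapply(seq_len(g[3]), function(y) {
      fr <- fd_stacks[[y]]$frames
      msk <- matrix(FALSE, g[1], g[2])
      for (x in seq_len(g[2])) {
        top <- phantom$surface_height[x, y] - 2L
        if (top >= 1) msk[seq_len(top), x] <- TRUE
      }
      if (!any(msk)) return(NA_real_)
      estimate_noise_variance(fr, msk)
    }, numeric(1)), na.rm = TRUE)
  }

  fd_imgs <- lapply(fd_stacks, function(st) {
    corrected <- bulk_phase_correct(st$frames)
    fast_doct(corrected$frames, noise_variance = s2n,
              kernel = config$kernel, delta_rel = config$delta_rel)
  })
  liv_vol <- volume_assemble(liv_imgs, pitch_um = pitch, contrast = "LIV",
                             window_s = time_window(liv_proto))
  fd_vol <- volume_assemble(fd_imgs, pitch_um = pitch, contrast = "FDOCT",
                            window_s = time_window(fast_proto))
  fd_valid <- volume_assemble(lapply(fd_imgs, function(im) im$valid * 1),
                              pitch_um = pitch, contrast = "FDOCT_valid")

  noise_floor_db <- 10 * log10(max(s2n, config$eps))
  surface <- segment_surface(db_vol, noise_floor_db,
                             margin_db = config$margin_db,
                             min_run = config$min_run,
                             smooth_window = config$smooth_window)
  slab_px <- config$slab_pixels
  if (is.na(slab_px)) slab_px <- min(100L, g[1])

  projections <- list(
    db = slab_average_projection(db_vol, surface, slab_px),
    liv = slab_average_projection(liv_vol, surface, slab_px),
    fdoct = slab_average_projection(fd_vol, surface, slab_px)
  )
  composites <- list(
    liv_projection = liv_composite(projections$liv, projections$db,
                                   hue_range = config$hue_range,
                                   value_window = config$value_window),
    fdoct_projection = fast_doct_display(projections$fdoct, projections$db)
  )
  phenotype <- phenotype_report(phantom, liv_vol, fd_vol, surface,
                                projections$liv, slab_px)

  result <- list(phantom = phantom,
                 volumes = list(db = db_vol, liv = liv_vol, fdoct = fd_vol,
                                fdoct_valid = fd_valid),
                 surface = surface, projections = projections,
                 composites = composites, phenotype = phenotype,
                 noise_variance = s2n, slab_pixels = slab_px,
                 config = config)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      write_volume_tiff(db_vol, file.path(config$out_dir, "oct_db.tif")),
      write_volume_tiff(liv_vol, file.path(config$out_dir, "liv.tif")),
      write_volume_tiff(fd_vol, file.path(config$out_dir, "fast_doct.tif")),
      write_image_png(composites$liv_projection,
                      file.path(config$out_dir, "liv_projection.png")),
      write_image_png(composites$fdoct_projection,
                      file.path(config$out_dir, "fdoct_projection.png")),
      write_config(`[[<-`(config, "out_dir", NULL),  # persisted config is
                   file.path(config$out_dir, "config.yaml"))  # path-free
    )
    jsonlite::write_json(phenotype,
                         file.path(config$out_dir, "phenotype.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    paths <- c(paths, file.path(config$out_dir, "phenotype.json"),
               paste0(paths[1:3], ".json"))
    manifest <- data.frame(path = basename(paths),
                           md5 = unname(tools::md5sum(paths)),
                           stringsAsFactors = FALSE)
    utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
                     row.names = FALSE)
    result$manifest <- manifest
  }
  result
}
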