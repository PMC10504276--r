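# Tissue surface segmentation and surface-following slab projections.
#
# The surface is found per A-line column as the first depth at which the
# frame-averaged dB intensity exceeds the noise floor by a margin for a
# minimum run of consecutive pixels; the height map is then median-smoothed.
# Columns with no crossing are invalid and stay invalid in every downstream
# projection (rendered black, never silently filled).

#' Segment the tissue surface from an averaged dB-intensity volume
#'
#' @param volume `oct_volume` of frame-averaged dB intensity.
#' @param noise_floor_db noise floor in dB (e.g. `10*log10(sigma_n^2)`).
#' @param margin_db threshold margin above the noise floor.
#' @param min_run minimum number of consecutive supra-threshold pixels.
#' @param smooth_window odd width of the 2D median smoothing of the height
#'   map; `1` disables smoothing.
#' @return object of class `surface_map`: integer `height` matrix
#'   (`nx x ny`, first tissue z-index, `NA` where invalid) and logical
#'   `valid`.
#' @export
segment_surface <- function(volume, noise_floor_db, margin_db = 10,
                            min_run = 3L, smooth_window = 5L) {
  stopifnot(inherits(volume, "oct_volume"))
  v <- volume$values
  d <- dim(v)
  if (any(d == 0)) stopf("empty volume")
  thr <- noise_floor_db + margin_db
  above <- v > thr
  nz <- d[1]
  first_run_start <- function(col) {
    r <- rle(col)
    ends <- cumsum(r$lengths)
    hit <- which(r$values & r$lengths >= min_run)
    if (!length(hit)) return(NA_real_)
    ends[hit[1]] - r$lengths[hit[1]] + 1
  }
  height <- apply(above, c(2, 3), first_run_start)
  if (smooth_window > 1)
    height <- median_filter2(height, half = as.integer(smooth_window) %/% 2L)
  height <- round(height)
  structure(list(height = height, valid = !is.na(height), nz = nz),
            class = "surface_map")
}

#' Extract a surface-following slab
#'
#' For every valid column the voxels `[height, height + slab_pixels)` are
#' extracted; where the slab runs past the bottom of the volume the missing
#' depths are `NA` (excluded from any averaging, never zero-filled into a
#' mean). Invalid columns are entirely `NA`.
#'
#' @param volume an `oct_volume`.
#' @param surface a `surface_map` from [segment_surface()].
#' @param slab_pixels slab depth extent in pixels (default 100, i.e. 724 um
#'   at the 7.24 um axial pitch).
#' @return numeric array `slab_pixels x nx x ny` with attribute `slab_um`.
#' @export
extract_slab <- function(volume, surface, slab_pixels = 100L) {
  stopifnot(inherits(volume, "oct_volume"), inherits(surface, "surface_map"))
  slab_pixels <- as.integer(slab_pixels)
  if (slab_pixels < 1) stopf("slab_pixels must be >= 1")
  if (!any(surface$valid)) stopf("surface has no valid columns")
  v <- volume$values
  d <- dim(v)
  out <- array(NA_real_, dim = c(slab_pixels, d[2], d[3]))
  for (y in seq_len(d[3])) {
    for (x in seq_len(d[2])) {
      h <- surface$height[x, y]
      if (is.na(h)) next
      zmax <- min(h + slab_pixels - 1L, d[1])
      if (zmax < h) next
      out[seq_len(zmax - h + 1L), x, y] <- v[h:zmax, x, y]
    }
  }
  attr(out, "slab_um") <- slab_pixels * volume$pitch_um[["z"]]
  out
}

#' Slab average projection
#'
#' Arithmetic mean (or maximum) over the valid slab voxels of each column.
#'
#' @inheritParams extract_slab
#' @param reducer `"mean"` (default; better contrast than maximum
#'   projection) or `"max"`.
#' @return object of class `slab_projection`: `image` (`nx x ny`, `NA` on
#'   invalid columns), `valid`, `slab_pixels`, `slab_um`, `reducer`.
#' @export
slab_average_projection <- function(volume, surface, slab_pixels = 100L,
                                    reducer = c("mean", "max")) {
  reducer <- match.arg(reducer)
  slab <- extract_slab(volume, surface, slab_pixels)
  red <- if (reducer == "mean") {
    function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  } else {
    function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  }
  img <- apply(slab, c(2, 3), red)
  structure(list(image = img, valid = !is.na(img),
                 slab_pixels = as.integer(slab_pixels),
                 slab_um = attr(slab, "slab_um"), reducer = reducer),
            class = "slab_projection")
}

#' Fixed-depth en face slice
#'
#' A fixed-z slice (not surface-following). The depth may be given as a
#' 1-based z-index or in micrometres from the top of the volume; a depth of
#' `d` um addresses the slice at offset `round(d / pitch_z)` below the top
#' (0 um is the top slice).
#'
#' @param volume an `oct_volume`.
#' @param depth_index 1-based z-index.
#' @param depth_um depth in micrometres (alternative to `depth_index`).
#' @return `nx x ny` matrix with attribute `depth_index`.
#' @export
en_face_slice <- function(volume, depth_index = NULL, depth_um = NULL) {
  stopifnot(inherits(volume, "oct_volume"))
  nz <- dim(volume$values)[1]
  if (is.null(depth_index)) {
    if (is.null(depth_um)) stopf("give depth_index or depth_um")
    depth_index <- round(depth_um / volume$pitch_um[["z"]]) + 1L
  }
  if (depth_index < 1 || depth_index > nz)
    stopf("depth index %d outside 1..%d", depth_index, nz)
  sl <- volume$values[depth_index, , ]
  attr(sl, "depth_index") <- as.integer(depth_index)
  sl
}

#' @export
print.surface_map <- function(x, ...) {
  cat(sprintf("surface_map: %d x %d columns, %.1f%% valid, height %s..%s\n",
              nrow(x$height), ncol(x$height), 100 * mean(x$valid),
              if (any(x$valid)) min(x$height, na.rm = TRUE) else "-",
              if (any(x$valid)) max(x$height, na.rm = TRUE) else "-"))
  invisible(x)
}

#' @export
print.slab_projection <- function(x, ...) {
  cat(sprintf("slab_projection (%s): %d x %d, slab %d px (%.0f um), %.1f%% valid\n",
              x$reducer, nrow(x$image), ncol(x$image), x$slab_pixels,
              x$slab_um, 100 * mean(x$valid)))
  invisible(x)
}
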