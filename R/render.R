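# Pseudo-color composites and grayscale displays.
#
# The LIV composite follows the standard dynamics rendering: the hue channel
# carries the LIV (low -> red at 0 deg, high -> green at 120 deg), the value
# (brightness) channel carries the windowed dB-scale OCT intensity, and the
# saturation is 1 everywhere. Pixels below the intensity window, and invalid
# pixels, are black.

#' Pseudo-color LIV composite image
#'
#' @param liv_values `liv_image`, `slab_projection`, or numeric matrix of
#'   LIV in dB^2.
#' @param db_values matching dB-intensity matrix (same source type allowed).
#' @param hue_range LIV values mapped onto the red-to-green hue axis; LIV at
#'   or above the top maps to pure green.
#' @param value_window dB window for brightness; `NULL` uses the 1st and
#'   99th percentiles of the finite dB values.
#' @param invalid optional logical matrix of pixels to render black.
#' @return object of class `composite_image` with `rgb`
#'   (`nrow x ncol x 3` in `[0, 1]`), `hue_range`, `value_window`.
#' @export
liv_composite <- function(liv_values, db_values, hue_range = c(0, 10),
                          value_window = NULL, invalid = NULL) {
  liv_m <- as_image_matrix(liv_values)
  db_m <- as_image_matrix(db_values)
  if (!identical(dim(liv_m), dim(db_m)))
    stopf("LIV and dB images must have identical shapes")
  if (is.null(value_window))
    value_window <- stats::quantile(db_m[is.finite(db_m)], c(0.01, 0.99),
                                    names = FALSE)
  bad <- !is.finite(liv_m) | !is.finite(db_m)
  if (!is.null(invalid)) bad <- bad | invalid
  h <- clip01((liv_m - hue_range[1]) / diff(hue_range)) / 3  # 0 red .. 1/3 green
  v <- clip01((db_m - value_window[1]) / diff(value_window))
  h[bad] <- 0; v[bad] <- 0
  ch3 <- hsv_to_rgb(as.vector(h), 1, as.vector(v))
  rgb <- array(0, dim = c(nrow(liv_m), ncol(liv_m), 3))
  rgb[, , 1] <- ch3$r; rgb[, , 2] <- ch3$g; rgb[, , 3] <- ch3$b
  structure(list(rgb = rgb, hue_range = hue_range,
                 value_window = value_window),
            class = "composite_image")
}

#' Grayscale Fast-DOCT display
#'
#' Brightness proportional to decorrelation, gated by the validity mask and
#' (optionally) by a dB-intensity window; invalid or gated pixels are black.
#'
#' @param fdoct_values `fast_doct_image`, `slab_projection`, or numeric
#'   matrix of decorrelation in `[0, 1]`.
#' @param db_values optional matching dB image used as a brightness gate.
#' @param valid optional logical validity matrix (taken from a
#'   `fast_doct_image` automatically).
#' @param value_window dB gate window when `db_values` is given.
#' @return numeric matrix in `[0, 1]` with attribute `"gated"`.
#' @export
fast_doct_display <- function(fdoct_values, db_values = NULL, valid = NULL,
                              value_window = NULL) {
  if (inherits(fdoct_values, "fast_doct_image") && is.null(valid))
    valid <- fdoct_values$valid
  g <- clip01(as_image_matrix(fdoct_values))
  g[!is.finite(g)] <- 0
  if (!is.null(valid)) g[!valid] <- 0
  gated <- FALSE
  if (!is.null(db_values)) {
    db_m <- as_image_matrix(db_values)
    if (is.null(value_window))
      value_window <- stats::quantile(db_m[is.finite(db_m)], c(0.01, 0.99),
                                      names = FALSE)
    g[!is.finite(db_m) | db_m < value_window[1]] <- 0
    gated <- TRUE
  }
  attr(g, "gated") <- gated
  g
}

#' Write an image to PNG
#'
#' @param image a `composite_image`, or a numeric matrix/array in `[0, 1]`.
#' @param path output file path.
#' @return `path` invisibly.
#' @export
write_image_png <- function(image, path) {
  x <- if (inherits(image, "composite_image")) image$rgb else clip01(image)
  x[!is.finite(x)] <- 0
  png::writePNG(x, path)
  invisible(path)
}

as_image_matrix <- function(x) {
  if (inherits(x, c("liv_image", "fast_doct_image"))) return(x$values)
  if (inherits(x, "slab_projection")) return(x$image)
  if (is.matrix(x)) return(x)
  stopf("expected an image object or matrix")
}
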