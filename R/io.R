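# Serialization: volumes as multi-page 32-bit TIFF (page = z-slice) with a
# JSON sidecar carrying axis order, pitch and the affine normalisation, and
# configs as YAML.

#' Write an OCT volume to a multi-page TIFF
#'
#' Values are affinely mapped to `[0, 1]` for storage; the scale, offset and
#' axis metadata (`axes = "zxy"`, pitch in um, contrast, window) go into a
#' JSON sidecar `<path>.json` so [read_volume_tiff()] restores the original
#' values.
#'
#' @param volume an `oct_volume`.
#' @param path output `.tif` path.
#' @return `path` invisibly.
#' @export
write_volume_tiff <- function(volume, path) {
  stopifnot(inherits(volume, "oct_volume"))
  v <- volume$values
  finite <- is.finite(v)
  lo <- if (any(finite)) min(v[finite]) else 0
  hi <- if (any(finite)) max(v[finite]) else 1
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(v)[3]), function(y) {
    m <- (v[, , y] - lo) / scale
    m[!is.finite(m)] <- 0
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(axes = "zxy", page_axis = "y",
               pitch_um = as.list(volume$pitch_um),
               contrast = volume$contrast, window_s = volume$window_s,
               offset = lo, scale = scale,
               invalid = which(!finite) - 1L)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an OCT volume written by [write_volume_tiff()]
#'
#' @param path the `.tif` path (the `.json` sidecar must sit next to it).
#' @return an `oct_volume`.
#' @export
read_volume_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  v <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (y in seq_along(pages)) v[, , y] <- pages[[y]]
  v <- v * meta$scale + meta$offset
  if (length(meta$invalid)) v[meta$invalid + 1] <- NA_real_
  oct_volume(v, pitch_um = unlist(meta$pitch_um), contrast = meta$contrast,
             window_s = meta$window_s %||% NA_real_)
}

#' Write a run configuration to YAML
#' @param config a `run_config` (see [run_config()]).
#' @param path output `.yaml` path.
#' @return `path` invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path a `.yaml` file written by [write_config()].
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}

#' Export a protocol timestamp table as CSV
#' @param protocol a `raster_protocol`.
#' @param path output `.csv` path.
#' @return `path` invisibly.
#' @export
write_timestamp_csv <- function(protocol, path) {
  utils::write.csv(timestamp_table(protocol), path, row.names = FALSE)
  invisible(path)
}
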