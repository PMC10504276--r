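# Scan-timing protocols.
#
# Two raster protocols drive the acquisition of repeated B-scan frames:
#
# * a block-repeating raster ("liv"): the lateral field is divided into
#   blocks; within one block every B-scan location is visited once per pass
#   and the pass is repeated n_repeats times, so consecutive frames at one
#   location are separated by the pass period (409.6 ms by default).
# * a fast raster ("fast"): all repeats at one location are acquired
#   back-to-back (12.8 ms apart by default) before moving on.

#' Construct a raster scan protocol
#'
#' Encodes the scan-timing parameters from which frame counts, time windows,
#' total acquisition times, and per-location timestamp tables are derived.
#'
#' @param n_blocks number of lateral blocks scanned sequentially.
#' @param locations_per_block B-scan locations inside one block.
#' @param a_lines_per_frame A-lines per B-scan frame.
#' @param n_repeats repeated frames per location.
#' @param repeat_interval time between consecutive frames at one location,
#'   in seconds.
#' @param a_line_rate A-line acquisition rate in Hz.
#' @param fov_mm lateral field of view per axis in mm.
#' @param style `"block_repeat"` (pass-repeating raster) or `"fast"`
#'   (back-to-back repeats per location).
#' @return object of class `raster_protocol`.
#' @seealso [liv_protocol()], [fast_protocol()], [protocol_timestamps()]
#' @export
raster_protocol <- function(n_blocks, locations_per_block, a_lines_per_frame,
                            n_repeats, repeat_interval,
                            a_line_rate = 50000, fov_mm = 3,
                            style = c("block_repeat", "fast")) {
  style <- match.arg(style)
  counts <- c(n_blocks = n_blocks, locations_per_block = locations_per_block,
              a_lines_per_frame = a_lines_per_frame, n_repeats = n_repeats)
  if (any(counts < 1) || any(counts != round(counts)))
    stopf("all protocol counts must be positive integers")
  frame_time <- a_lines_per_frame / a_line_rate
  if (repeat_interval < frame_time)
    stopf("repeat_interval (%.4g s) shorter than one frame acquisition (%.4g s)",
          repeat_interval, frame_time)
  if (style == "block_repeat" &&
      locations_per_block * frame_time > repeat_interval + 1e-12)
    stopf("one block pass (%d locations x %.4g s) cannot fit in repeat_interval %.4g s",
          locations_per_block, frame_time, repeat_interval)
  structure(list(
    n_blocks = as.integer(n_blocks),
    locations_per_block = as.integer(locations_per_block),
    a_lines_per_frame = as.integer(a_lines_per_frame),
    n_repeats = as.integer(n_repeats),
    repeat_interval = repeat_interval,
    a_line_rate = a_line_rate,
    fov_mm = fov_mm,
    style = style
  ), class = "raster_protocol")
}

#' Default block-repeating protocol for LIV acquisition
#'
#' Four blocks of 32 B-scan locations, 512 A-lines per frame, 16 repeats per
#' location with a 409.6 ms pass period: 2048 frames over 128 locations.
#'
#' @param fov_mm lateral field of view in mm (3 or 6).
#' @return `raster_protocol`.
#' @export
liv_protocol <- function(fov_mm = 3) {
  raster_protocol(4, 32, 512, 16, 0.4096, fov_mm = fov_mm,
                  style = "block_repeat")
}

#' Default fast raster protocol for complex-decorrelation acquisition
#'
#' 128 B-scan locations, 4 back-to-back repeats per location 12.8 ms apart
#' (512 frames per volume). The inter-frame interval is commonly quoted
#' rounded to 13 ms; `display_rounded = TRUE` builds the protocol with that
#' rounded interval so that derived display quantities (e.g. the 39 ms time
#' window) match the quoted values.
#'
#' @param fov_mm lateral field of view in mm.
#' @param display_rounded use the display-rounded 13 ms interval instead of
#'   the internal 12.8 ms.
#' @return `raster_protocol`.
#' @export
fast_protocol <- function(fov_mm = 3, display_rounded = FALSE) {
  raster_protocol(1, 128, 512, 4,
                  if (display_rounded) 0.013 else 0.0128,
                  fov_mm = fov_mm, style = "fast")
}

#' Total number of frames in one volume
#' @param protocol a `raster_protocol`.
#' @return integer frame count (`n_blocks * locations_per_block * n_repeats`).
#' @export
frames_per_volume <- function(protocol) {
  stopifnot(inherits(protocol, "raster_protocol"))
  protocol$n_blocks * protocol$locations_per_block * protocol$n_repeats
}

#' Total number of B-scan locations in one volume
#' @param protocol a `raster_protocol`.
#' @return integer location count.
#' @export
total_locations <- function(protocol) {
  stopifnot(inherits(protocol, "raster_protocol"))
  protocol$n_blocks * protocol$locations_per_block
}

#' Evaluation time window at one location
#'
#' Span from the first to the last repeated frame at a single location,
#' `(n_repeats - 1) * repeat_interval` seconds.
#'
#' @param protocol a `raster_protocol`.
#' @return seconds.
#' @export
time_window <- function(protocol) {
  stopifnot(inherits(protocol, "raster_protocol"))
  if (protocol$n_repeats < 2)
    stopf("time window needs n_repeats >= 2 (got %d)", protocol$n_repeats)
  (protocol$n_repeats - 1) * protocol$repeat_interval
}

#' Total volume acquisition time
#'
#' For the block-repeating style each block occupies
#' `n_repeats * repeat_interval`, blocks are sequential; for the fast style
#' every location occupies `n_repeats * repeat_interval`.
#'
#' @param protocol a `raster_protocol`.
#' @return seconds.
#' @export
total_acquisition_time <- function(protocol) {
  stopifnot(inherits(protocol, "raster_protocol"))
  if (protocol$style == "block_repeat")
    protocol$n_blocks * protocol$n_repeats * protocol$repeat_interval
  else
    total_locations(protocol) * protocol$n_repeats * protocol$repeat_interval
}

#' Frame timestamps at one B-scan location
#'
#' Arithmetic sequence of `n_repeats` times with step `repeat_interval`,
#' offset by the start time of the containing block (block-repeating style)
#' or of the location itself (fast style). Location indices are 1-based.
#'
#' @param protocol a `raster_protocol`.
#' @param location_index 1-based location index.
#' @return numeric vector of seconds, strictly increasing.
#' @export
protocol_timestamps <- function(protocol, location_index) {
  stopifnot(inherits(protocol, "raster_protocol"))
  n_loc <- total_locations(protocol)
  if (location_index < 1 || location_index > n_loc)
    stopf("location_index %d outside 1..%d", location_index, n_loc)
  start <- if (protocol$style == "block_repeat") {
    block <- (location_index - 1L) %/% protocol$locations_per_block
    block * protocol$n_repeats * protocol$repeat_interval
  } else {
    (location_index - 1L) * protocol$n_repeats * protocol$repeat_interval
  }
  start + (seq_len(protocol$n_repeats) - 1L) * protocol$repeat_interval
}

#' Full timestamp table for a protocol
#'
#' @param protocol a `raster_protocol`.
#' @return data.frame with columns `location_index`, `frame_index`,
#'   `t_seconds`, suitable for CSV export.
#' @export
timestamp_table <- function(protocol) {
  n_loc <- total_locations(protocol)
  do.call(rbind, lapply(seq_len(n_loc), function(l) {
    data.frame(location_index = l,
               frame_index = seq_len(protocol$n_repeats),
               t_seconds = protocol_timestamps(protocol, l))
  }))
}

#' Lateral pixel pitch implied by a protocol
#' @param protocol a `raster_protocol`.
#' @return fast-axis pixel pitch in micrometres (`fov / a_lines_per_frame`).
#' @export
lateral_pitch_um <- function(protocol) {
  protocol$fov_mm * 1000 / protocol$a_lines_per_frame
}

#' @export
print.raster_protocol <- function(x, ...) {
  cat(sprintf(
    "raster_protocol (%s): %d block(s) x %d location(s) x %d repeat(s)\n",
    x$style, x$n_blocks, x$locations_per_block, x$n_repeats))
  cat(sprintf("  repeat interval %.4g s, %d A-lines @ %g Hz, FOV %g mm\n",
              x$repeat_interval, x$a_lines_per_frame, x$a_line_rate, x$fov_mm))
  cat(sprintf("  frames/volume %d, window %.4g s, total %.4g s\n",
              frames_per_volume(x),
              if (x$n_repeats >= 2) time_window(x) else NA,
              total_acquisition_time(x)))
  invisible(x)
}
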