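#' Acquisition configuration for a dissolution movie
#'
#' Bundles the physical calibration of a dark-field time-lapse acquisition:
#' frame interval, pixel size, electrode geometry and the frame at which the
#' oxidising potential is switched on. Conventions used throughout the
#' package: image origin top-left, 0-based (row, col) pixel indices, physical
#' coordinates in micrometres, time in seconds with t = 0 at
#' `potential_on_frame`.
#'
#' @param frame_interval Frame interval in seconds (> 0).
#' @param pixel_size Pixel size in micrometres per pixel (> 0).
#' @param electrode_edge_xy Numeric length-2, (col, row) image coordinates in
#'   pixels of the nearest point of the electrode edge. Distances from the
#'   electrode are measured from this edge to the lith centre.
#' @param electrode_radius Electrode fibre radius in micrometres. Default 3.5
#'   (a 7 um diameter carbon fibre).
#' @param potential_on_frame 0-based index of the frame at which the potential
#'   is applied. Default 0.
#'
#' @return An object of class `acquisition_config`.
#' @export
#' @examples
#' acquisition_config(frame_interval = 2, pixel_size = 0.1)
acquisition_config <- function(frame_interval,
                               pixel_size,
                               electrode_edge_xy = c(0, 0),
                               electrode_radius = 3.5,
                               potential_on_frame = 0L) {
  stopifnot(
    is.numeric(frame_interval), length(frame_interval) == 1L, frame_interval > 0,
    is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0,
    is.numeric(electrode_edge_xy), length(electrode_edge_xy) == 2L,
    is.numeric(electrode_radius), length(electrode_radius) == 1L, electrode_radius > 0,
    is.numeric(potential_on_frame), length(potential_on_frame) == 1L,
    potential_on_frame >= 0
  )
  structure(
    list(
      frame_interval = as.numeric(frame_interval),
      pixel_size = as.numeric(pixel_size),
      electrode_edge_xy = as.numeric(electrode_edge_xy),
      electrode_radius = as.numeric(electrode_radius),
      potential_on_frame = as.integer(potential_on_frame)
    ),
    class = "acquisition_config"
  )
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat("Acquisition config:\n")
  cat(sprintf("  frame interval : %g s\n", x$frame_interval))
  cat(sprintf("  pixel size     : %g um/px\n", x$pixel_size))
  cat(sprintf("  electrode edge : (%g, %g) px, radius %g um\n",
              x$electrode_edge_xy[1], x$electrode_edge_xy[2], x$electrode_radius))
  cat(sprintf("  potential on   : frame %d\n", x$potential_on_frame))
  invisible(x)
}

#' Electrolyte composition descriptor
#'
#' Describes the ionic composition of the electrolyte in which a dissolution
#' experiment is run. Concentrations are in mol/L. Used by the kinetics
#' module to derive dissolution-rate modifiers (Mg2+ surface inhibition,
#' HCO3- proton scavenging).
#'
#' @param kno3,mg,hco3,h2bq Concentrations in mol/L (>= 0). `h2bq` is the
#'   acid-precursor (hydroquinone) concentration, default 0.010.
#' @param label Free-text label, e.g. `"K/2"`.
#'
#' @return An object of class `electrolyte_spec`.
#' @export
#' @examples
#' electrolyte_spec(kno3 = 0.7, mg = 0.0546, label = "KNO3 + Mg")
electrolyte_spec <- function(kno3 = 0, mg = 0, hco3 = 0, h2bq = 0.010,
                             label = "") {
  conc <- c(kno3 = kno3, mg = mg, hco3 = hco3, h2bq = h2bq)
  stopifnot(is.numeric(conc), all(conc >= 0), is.character(label))
  structure(
    list(kno3 = kno3, mg = mg, hco3 = hco3, h2bq = h2bq, label = label),
    class = "electrolyte_spec"
  )
}

#' @export
print.electrolyte_spec <- function(x, ...) {
  cat(sprintf("Electrolyte '%s': KNO3 %g M, Mg2+ %g M, HCO3- %g M, H2BQ %g M\n",
              x$label, x$kno3, x$mg, x$hco3, x$h2bq))
  invisible(x)
}

# internal: standard K/2-like presets used in examples and the CLI
.electrolyte_presets <- function() {
  list(
    "kno3" = electrolyte_spec(kno3 = 0.7, label = "0.7 M KNO3"),
    "kno3+mg" = electrolyte_spec(kno3 = 0.7, mg = 0.0546, label = "0.7 M KNO3 + 54.6 mM Mg2+"),
    "kno3+hco3" = electrolyte_spec(kno3 = 0.7, hco3 = 0.0024, label = "0.7 M KNO3 + 2.4 mM HCO3-"),
    "k2" = electrolyte_spec(kno3 = 0.7, mg = 0.0546, hco3 = 0.0024, label = "K/2")
  )
}
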