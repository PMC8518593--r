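#' In-memory time-lapse image stack
#'
#' Thin container for a monochrome movie: an H x W x T numeric array plus its
#' acquisition calibration. Frame times (seconds, t = 0 at potential-on) are
#' derived from the config.
#'
#' @param frames H x W x T numeric array (T >= 2), or a list of equally sized
#'   matrices.
#' @param config An [acquisition_config()].
#' @return An object of class `image_stack` with elements `frames` and
#'   `config`.
#' @export
image_stack <- function(frames, config) {
  if (is.list(frames)) {
    shp <- unique(lapply(frames, dim))
    if (length(shp) != 1L)
      stop("inconsistent frame shapes in stack", call. = FALSE)
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(shp[[1]], length(frames)))
  }
  stopifnot(inherits(config, "acquisition_config"))
  if (length(dim(frames)) != 3L)
    stop("frames must be an H x W x T array", call. = FALSE)
  if (dim(frames)[3] < 2L)
    stop("a stack needs at least 2 frames", call. = FALSE)
  structure(list(frames = frames, config = config), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image_stack: %d frames of %d x %d px (%.3g um/px, dt %g s)\n",
              d[3], d[1], d[2], x$config$pixel_size, x$config$frame_interval))
  invisible(x)
}

#' Frame times of a stack, in seconds relative to potential-on
#' @param stack An [image_stack()] (or anything with a `config` element and
#'   frame count `n`).
#' @param n Number of frames; defaults to the stack's.
#' @return Numeric vector of times, one per frame.
#' @export
frame_times <- function(stack, n = dim(stack$frames)[3]) {
  cfg <- stack$config
  (seq_len(n) - 1L - cfg$potential_on_frame) * cfg$frame_interval
}

#' Read a multi-page TIFF movie
#'
#' Reads a single- or multi-page monochrome TIFF bit-exactly (integer samples
#' are returned as stored) and attaches the physical calibration.
#'
#' @param path Path to a TIFF file.
#' @param config An [acquisition_config()].
#' @return An [image_stack()].
#' @export
read_stack <- function(path, config) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path, call. = FALSE)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) stop("not a readable TIFF: ", path, " (", conditionMessage(e), ")",
                             call. = FALSE)
  )
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # collapse accidental channels
    p
  })
  image_stack(pages, config)
}

#' Write a movie as a multi-page TIFF
#'
#' Integer-valued stacks are stored as 8- or 16-bit unsigned samples and
#' round-trip bit-exactly through [read_stack()]. Non-integer stacks are
#' linearly quantized to 16 bits over `[0, max]` (recorded on the returned
#' path as an attribute).
#'
#' @param stack An [image_stack()] or H x W x T array.
#' @param path Output path.
#' @param bits Bits per sample (8 or 16). Default 16.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  fr <- if (inherits(stack, "image_stack")) stack$frames else stack
  stopifnot(length(dim(fr)) == 3L, bits %in% c(8L, 16L))
  top <- 2^bits - 1
  if (max(fr) > top || min(fr) < 0)
    stop("stack values outside [0, 2^bits - 1]; rescale before writing",
         call. = FALSE)
  if (any(fr != round(fr)))
    stop("write_stack() stores integer samples; quantize first (see quantize_stack)",
         call. = FALSE)
  pages <- lapply(seq_len(dim(fr)[3]), function(k) fr[, , k] / top)
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits),
                  compression = "none")
  invisible(path)
}

#' Quantize a floating-point movie to unsigned integers
#'
#' @param frames H x W x T numeric array.
#' @param bits Bits per sample (8 or 16).
#' @param lo,hi Intensity range mapped to the integer range; defaults to the
#'   array range.
#' @return Integer-valued array of the same shape.
#' @export
quantize_stack <- function(frames, bits = 16L, lo = min(frames), hi = max(frames)) {
  top <- 2^bits - 1
  if (hi <= lo) hi <- lo + 1
  x <- round((pmin(pmax(frames, lo), hi) - lo) / (hi - lo) * top)
  array(x, dim = dim(frames))
}

# tiff::writeTIFF only preserves float samples inside [0, 1]; thickness maps
# (um, up to a few) are stored scaled by this factor and unscaled on read.
.thickness_tiff_scale <- 1e-3

#' Write / read a thickness map as 32-bit float TIFF
#'
#' The map is in micrometres; on disk the samples are scaled by `1e-3` (the
#' scale is recorded in the provenance sidecar written by [write_results()]).
#' The round trip is lossless at float32 precision.
#'
#' @param h_map Numeric matrix of thicknesses in um.
#' @param path File path.
#' @return `path` (write) or the thickness matrix in um (read).
#' @export
write_thickness_tiff <- function(h_map, path) {
  stopifnot(is.matrix(h_map), all(h_map >= 0), max(h_map) * .thickness_tiff_scale <= 1)
  tiff::writeTIFF(h_map * .thickness_tiff_scale, path, bits.per.sample = 32L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_thickness_tiff
#' @export
read_thickness_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m / .thickness_tiff_scale
}

#' Write reconstruction results to disk
#'
#' Emits the three artefacts of a reconstruction run into `dir`:
#' * `<name>_thickness.tif` - 32-bit float thickness map (um; see
#'   [write_thickness_tiff()] for the storage scale),
#' * `<name>_summary.csv` - one row of summary metrics
#'   (`length_um, area_um2, volume_um3, mass_pg, v_initial_um_s, distance_um,
#'   status`),
#' * `<name>_provenance.json` - full provenance (configuration, parameters,
#'   seed, package version) sufficient to re-run the analysis.
#'
#' A failed/empty reconstruction writes a CSV row of `NA` metrics with its
#' status flag, and no TIFF.
#'
#' @param recon A `lith_reconstruction` (see [reconstruct()]), possibly with
#'   status flags.
#' @param dir Output directory (created if needed).
#' @param name Base name for the three files. Default `"lith"`.
#' @param extra Named list merged into the provenance sidecar (e.g. RNG seed).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_results <- function(recon, dir, name = "lith", extra = list()) {
  stopifnot(inherits(recon, "lith_reconstruction"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir, call. = FALSE)
  paths <- c(
    tiff = file.path(dir, paste0(name, "_thickness.tif")),
    csv = file.path(dir, paste0(name, "_summary.csv")),
    json = file.path(dir, paste0(name, "_provenance.json"))
  )
  ok <- isTRUE(recon$status == "ok")
  row <- data.frame(
    length_um = if (ok) recon$length else NA_real_,
    area_um2 = if (ok) recon$area else NA_real_,
    volume_um3 = if (ok) recon$volume else NA_real_,
    mass_pg = if (ok) recon$mass else NA_real_,
    v_initial_um_s = if (ok) recon$v_initial else NA_real_,
    distance_um = if (ok) recon$distance_to_electrode else NA_real_,
    status = as.character(recon$status)
  )
  utils::write.csv(row, paths["csv"], row.names = FALSE)
  prov <- c(list(
    package = "lithomass",
    version = as.character(utils::packageVersion("lithomass")),
    config = unclass(recon$config),
    density_pg_um3 = recon$density,
    subtract_lag = recon$subtract_lag,
    threshold = recon$threshold,
    thickness_tiff_scale = .thickness_tiff_scale,
    status = as.character(recon$status)
  ), extra)
  jsonlite::write_json(prov, paths["json"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (ok && !is.null(recon$thickness$h_map)) {
    write_thickness_tiff(recon$thickness$h_map, paths["tiff"])
  } else {
    paths <- paths[c("csv", "json")]
  }
  invisible(paths)
}
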