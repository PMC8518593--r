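#' Segment one coccolith in a dissolution movie
#'
#' Produces per-frame binary masks of a single lith. The threshold is
#' estimated once on the pre-dissolution frame and then frozen for the whole
#' movie - re-estimating per frame becomes unstable as the foreground
#' vanishes, and a frozen threshold gives a well-defined dissolution end
#' point. The automatic threshold is background-referenced, as appropriate
#' for dark-field images where any signal above the dark background noise is
#' calcite: Otsu's method on the reference frame provides an initial
#' foreground/background split, and the frozen threshold is then set to
#' `mean(bg) + max(2.5 sd(bg), 0.02 (mean(fg) - mean(bg)))` - 2.5 standard
#' deviations above the background, floored at 2% of the foreground contrast
#' so noise-free images are not thresholded at zero. Each thresholded frame
#' is cleaned by small-object removal (< `min_size` px) and filling of small
#' interior holes (< `min_hole` px; genuine dissolution holes, e.g. a thin
#' placolith centre clearing first, are deliberately kept), then restricted
#' to the connected component(s) tracked by maximal overlap from frame 0.
#' All statistics are computed on a min-max normalized copy of the stack, so
#' masks are invariant to positive intensity rescaling.
#'
#' @param stack An [image_stack()].
#' @param roi Optional bounding box `c(x, y, w, h)` in 0-based pixel
#'   coordinates restricting the analysis to one lith.
#' @param min_size Minimum object size in pixels. Default 5.
#' @param min_hole Maximum hole size to fill, pixels. Default 5.
#' @param median_radius Radius of the per-frame median filter applied before
#'   thresholding (suppresses shot noise and so lowers the detection
#'   threshold, recovering thin calcite that would otherwise be lost below
#'   it); 0 disables. Default 1 (a 3 x 3 window).
#' @return An object of class `mask_stack`: logical H x W x T array `masks`,
#'   per-frame `areas` (um^2), and `provenance` (method and frozen
#'   threshold).
#' @export
# vectorized 3x3 median (Paeth's 19-comparison selection network), edges
# handled by replication
.median3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- function(s) pmin(pmax(seq_len(nr) + s, 1L), nr)
  ci <- function(s) pmin(pmax(seq_len(nc) + s, 1L), nc)
  p <- vector("list", 9L)
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1L
    p[[k]] <- m[ri(dr), ci(dc)]
  }
  sw <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  sw(1,2); sw(4,5); sw(7,8); sw(2,3); sw(5,6); sw(8,9); sw(1,2); sw(4,5)
  sw(7,8); sw(1,4); sw(6,9); sw(5,8); sw(4,7); sw(2,5); sw(3,6); sw(5,8)
  sw(5,3); sw(7,5); sw(5,3)
  p[[5]]
}

segment_stack <- function(stack, roi = NULL, min_size = 5L, min_hole = 5L,
                          median_radius = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  fr <- stack$frames
  d <- dim(fr)
  cfg <- stack$config

  keep <- matrix(TRUE, d[1], d[2])
  if (!is.null(roi)) {
    stopifnot(length(roi) == 4L)
    keep[] <- FALSE
    rows <- (roi[2] + 1):min(d[1], roi[2] + roi[4])
    cols <- (roi[1] + 1):min(d[2], roi[1] + roi[3])
    keep[rows, cols] <- TRUE
  }

  rng <- range(fr)
  if (rng[2] <= rng[1])
    stop("no lith found: stack has no contrast", call. = FALSE)
  nrm <- (fr - rng[1]) / (rng[2] - rng[1])
  if (median_radius == 1L) {
    for (k in seq_len(d[3])) nrm[, , k] <- .median3x3(nrm[, , k])
  } else if (median_radius > 1L) {
    for (k in seq_len(d[3]))
      nrm[, , k] <- as.matrix(EBImage::medianFilter(EBImage::Image(nrm[, , k]),
                                                    size = median_radius))
  }

  ref <- cfg$potential_on_frame + 1L
  if (ref > d[3]) ref <- 1L
  ref_img <- nrm[, , ref]
  split0 <- EBImage::otsu(EBImage::Image(ref_img), range = c(0, 1))
  bg <- ref_img[ref_img <= split0 & keep]
  fg <- ref_img[ref_img > split0 & keep]
  if (!length(fg)) stop("no lith found in reference frame", call. = FALSE)
  mu_bg <- mean(bg); sd_bg <- stats::sd(bg)
  if (!is.finite(sd_bg)) sd_bg <- 0
  if (sd_bg > 0 && (mean(fg) - mu_bg) < 4 * sd_bg)
    stop("no lith found: foreground not separable from background noise",
         call. = FALSE)
  thr <- mu_bg + max(2.5 * sd_bg, 0.02 * (mean(fg) - mu_bg))

  fill_small_holes <- function(bw) {
    inv <- !bw
    lab <- EBImage::bwlabel(inv)
    border_ids <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    sz <- tabulate(lab[lab > 0])
    fill <- setdiff(which(sz < min_hole), border_ids)
    if (length(fill)) bw[lab %in% fill] <- TRUE
    bw
  }
  clean <- function(bw) {
    bw <- bw & keep
    if (!any(bw)) return(bw)
    lab <- EBImage::bwlabel(bw)
    sz <- tabulate(lab[lab > 0])
    small <- which(sz < min_size)
    if (length(small)) bw[lab %in% small] <- FALSE
    if (any(bw)) bw <- fill_small_holes(bw)
    bw
  }

  masks <- array(FALSE, d)
  prev <- NULL
  for (k in seq_len(d[3])) {
    bw <- clean(nrm[, , k] > thr)
    if (k == 1L) {
      if (!any(bw))
        stop("no lith found in frame 0", call. = FALSE)
      lab <- EBImage::bwlabel(bw)
      sz <- tabulate(lab[lab > 0])
      if (length(sz) > 1L && is.null(roi) && sort(sz, decreasing = TRUE)[2] > 0.5 * max(sz))
        stop("multiple comparable objects in frame 0; supply an roi", call. = FALSE)
      bw <- lab == which.max(sz)
    } else if (any(bw)) {
      lab <- EBImage::bwlabel(bw)
      ids <- setdiff(unique(lab[lab > 0 & prev]), 0)
      bw <- matrix(lab %in% ids & lab > 0, d[1], d[2])
    }
    masks[, , k] <- bw
    prev <- bw
  }
  structure(
    list(masks = masks,
         areas = apply(masks, 3, sum) * cfg$pixel_size^2,
         config = cfg,
         provenance = list(method = "background-referenced (otsu-initialized)",
                           threshold = thr, otsu_split = split0,
                           reference_frame = ref - 1L,
                           min_size = min_size, min_hole = min_hole)),
    class = "mask_stack"
  )
}

#' @export
print.mask_stack <- function(x, ...) {
  cat(sprintf("mask_stack: %d frames, frame-0 area %.3g um^2 (threshold %.4g)\n",
              dim(x$masks)[3], x$areas[1], x$provenance$threshold))
  invisible(x)
}

#' Effective-radius time series of a mask stack
#'
#' `r_eff[t] = sqrt(area[t] / pi)`, the radius of the circle with the lith's
#' thresholded projection area. Dissolution onset (the lag behind
#' potential-on caused by acid diffusion) is located in two steps: the first
#' time `r_eff` has dropped more than `lag_tol` (default 2%) below its
#' pre-onset mean marks a detection, and the onset is then refined by
#' back-extrapolating an ordinary-least-squares line through the first few
#' post-detection samples to where it re-crosses the pre-onset level (the
#' raw threshold crossing is systematically late by `lag_tol * r0 / v` when
#' the initial slope is shallow). The end time is the first frame with an
#' empty mask.
#'
#' @param masks A `mask_stack` from [segment_stack()].
#' @param config Optional [acquisition_config()] (defaults to the one carried
#'   by `masks`).
#' @param lag_tol Fractional drop defining onset detection. Default 0.02.
#' @param refine_pts Number of post-detection samples used for the onset
#'   back-extrapolation. Default 6.
#' @return An object of class `radius_series` with `t` (s, relative to
#'   potential-on), `r_eff` (um), `lag_time`, `end_time`, the pre-onset
#'   level `r0` and `status` (`"ok"`, `"no-onset"` or `"incomplete"`).
#' @export
radius_series <- function(masks, config = masks$config, lag_tol = 0.02,
                          refine_pts = 6L) {
  stopifnot(inherits(masks, "mask_stack"))
  r <- sqrt(masks$areas / pi)
  tt <- (seq_along(r) - 1L - config$potential_on_frame) * config$frame_interval

  pre <- r[tt <= 0]
  r0 <- if (length(pre)) mean(pre) else r[1]
  det <- which(tt > 0 & r < (1 - lag_tol) * r0)
  lag_time <- NA_real_
  if (length(det)) {
    i <- det[1]
    j <- i:min(i + refine_pts - 1L, length(r))
    j <- j[r[j] > 0]          # collapse frames would bias the line
    if (length(j) >= 2L) {
      f <- stats::lm.fit(cbind(1, tt[j]), r[j])
      b <- f$coefficients[2]
      lag_time <- if (is.finite(b) && b < 0) (r0 - f$coefficients[1]) / b else tt[i] - config$frame_interval
    } else {
      lag_time <- tt[i] - config$frame_interval
    }
    lag_time <- min(max(0, lag_time), tt[i])
  }

  empty <- which(masks$areas == 0 & tt >= 0)
  end_time <- if (length(empty)) tt[empty[1]] else NA_real_

  status <- if (!length(det)) "no-onset" else if (!length(empty)) "incomplete" else "ok"
  structure(
    list(t = tt, r_eff = r, lag_time = unname(lag_time),
         end_time = end_time, r0 = r0, status = status, config = config),
    class = "radius_series"
  )
}

#' @export
print.radius_series <- function(x, ...) {
  cat(sprintf("radius_series: %d frames, r0 %.3g um, lag %s s, end %s s [%s]\n",
              length(x$t), x$r0,
              format(x$lag_time), format(x$end_time), x$status))
  invisible(x)
}

#' Coccolith length (maximum Feret diameter) of a mask
#'
#' The maximum calliper distance across the frame-0 mask, in um. Computed as
#' the largest pairwise distance between convex-hull pixel centres plus one
#' pixel (so a single-pixel mask has length one pixel).
#'
#' @param mask Logical matrix (e.g. `masks$masks[, , 1]`).
#' @param config An [acquisition_config()] supplying the pixel size.
#' @return Length in um.
#' @export
lith_length <- function(mask, config) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask", call. = FALSE)
  if (nrow(idx) == 1L) return(config$pixel_size)
  hull <- idx[grDevices::chull(idx[, 2], idx[, 1]), , drop = FALSE]
  dmax <- max(stats::dist(hull))
  (dmax + 1) * config$pixel_size
}
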