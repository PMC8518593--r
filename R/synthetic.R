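#' Parametric coccolith (placolith) geometry
#'
#' Describes an idealized disk-like placolith as an elliptical outline with a
#' radially symmetric thickness profile. The default profile is thinnest at
#' the centre and rises to a thick rim annulus, the shape commonly seen in
#' placolith cross-sections: for normalized elliptical radius `u` in [0, 1],
#' `h(u) = h_max * (centre_fraction + (1 - centre_fraction) *
#' (u / rim_peak)^power)` up to the rim peak at `u = rim_peak`, after which
#' the profile tapers quadratically to `edge_fraction * h_max` at the outer
#' margin (placolith margins close smoothly rather than ending in a vertical
#' calcite cliff).
#'
#' @param a,b Ellipse semi-axes in um (`a >= b > 0`).
#' @param max_thickness Rim-peak (maximum) thickness in um; placoliths are
#'   typically 0.2-2 um thick.
#' @param profile `"placolith"` (default) or `"uniform"`.
#' @param centre_fraction Centre thickness as a fraction of the rim-peak
#'   thickness (placolith profile only). Default 0.3.
#' @param power Radial power of the inner profile. Default 2.
#' @param rim_peak Normalized radius of the rim-thickness maximum.
#'   Default 0.75.
#' @param edge_fraction Margin thickness as a fraction of the rim peak.
#'   Default 0.15.
#' @param centre_xy Optional lith centre in um, (x, y) from the image origin;
#'   `NULL` centres the lith in the frame.
#' @param species Free-text label.
#'
#' @return An object of class `lith_model` whose `thickness_profile` element
#'   maps normalized radius to thickness in um.
#' @export
#' @examples
#' m <- lith_model(a = 4, b = 3, max_thickness = 1)
#' lith_volume(m)
lith_model <- function(a, b = a, max_thickness,
                       profile = c("placolith", "uniform"),
                       centre_fraction = 0.3, power = 2, rim_peak = 0.75,
                       edge_fraction = 0.15,
                       centre_xy = NULL, species = "synthetic") {
  profile <- match.arg(profile)
  stopifnot(a >= b, b > 0, max_thickness >= 0,
            centre_fraction >= 0, centre_fraction <= 1, power > 0,
            rim_peak > 0, rim_peak < 1, edge_fraction >= 0, edge_fraction <= 1)
  h_max <- max_thickness
  tp <- if (profile == "uniform") {
    function(u) ifelse(u <= 1, h_max, 0)
  } else {
    function(u) {
      inner <- centre_fraction + (1 - centre_fraction) * (u / rim_peak)^power
      outer <- 1 - (1 - edge_fraction) * ((u - rim_peak) / (1 - rim_peak))^2
      h_max * ifelse(u <= rim_peak, inner, ifelse(u <= 1, outer, 0))
    }
  }
  structure(
    list(a = a, b = b, max_thickness = max_thickness, profile = profile,
         centre_fraction = centre_fraction, power = power,
         rim_peak = rim_peak, edge_fraction = edge_fraction,
         thickness_profile = tp, centre_xy = centre_xy, species = species),
    class = "lith_model"
  )
}

#' Analytic volume of a parametric lith
#'
#' Integrates the thickness profile over the elliptical outline:
#' `V = 2 pi a b * int_0^1 u h(u) du` (the elliptical map scales the area
#' element by `a b`).
#'
#' @param model A [lith_model()].
#' @return Volume in um^3.
#' @export
lith_volume <- function(model) {
  2 * pi * model$a * model$b *
    stats::integrate(function(u) u * model$thickness_profile(u), 0, 1,
                     rel.tol = 1e-10)$value
}

#' Discretize a lith model onto a pixel grid
#'
#' @param model A [lith_model()].
#' @param pixel_size Pixel size in um/px. Default 0.1.
#' @param dim Frame size in pixels, `c(rows, cols)`. Default `c(256, 256)`.
#' @return H x W thickness matrix in um, with attributes `pixel_size` and
#'   `centre_px` (row, col of the lith centre, 1-based).
#' @export
make_lith <- function(model, pixel_size = 0.1, dim = c(256, 256)) {
  H <- dim[1]; W <- dim[2]
  ctr <- model$centre_xy
  if (is.null(ctr)) ctr <- c(W, H) / 2 * pixel_size
  if (ctr[1] - model$a < 0 || ctr[1] + model$a > W * pixel_size ||
      ctr[2] - model$b < 0 || ctr[2] + model$b > H * pixel_size)
    stop("lith does not fit in the frame", call. = FALSE)
  # pixel-centre coordinates in um (0-based pixel i spans [i, i+1]*pixel_size)
  xs <- (seq_len(W) - 0.5) * pixel_size
  ys <- (seq_len(H) - 0.5) * pixel_size
  u <- sqrt(outer((ys - ctr[2])^2 / model$b^2, (xs - ctr[1])^2 / model$a^2, "+"))
  h <- matrix(model$thickness_profile(u), H, W)
  h[u > 1] <- 0
  attr(h, "pixel_size") <- pixel_size
  attr(h, "centre_px") <- c(row = ctr[2] / pixel_size + 0.5, col = ctr[1] / pixel_size + 0.5)
  h
}

#' Dissolution scenario for the synthetic movie generator
#'
#' @param v Surface-normal retreat rate in um/s (> 0).
#' @param rate_gradient Fractional near/far rate asymmetry per um along the
#'   image x-axis (electrode assumed to the left); 0 disables it.
#' @param lag_time Diffusive onset delay in seconds (frames before `lag_time`
#'   are static).
#' @param frame_interval Frame interval in seconds. Default 2 (typical
#'   acquisition rate for these experiments).
#' @param noise_sigma Additive Gaussian noise, in units of the saturated
#'   foreground intensity (1.0).
#' @param psf_sigma Gaussian point-spread sigma in um; 0 disables blurring.
#' @param seed Integer RNG seed; one generator per movie.
#' @return An object of class `dissolution_scenario`.
#' @export
dissolution_scenario <- function(v, rate_gradient = 0, lag_time = 0,
                                 frame_interval = 2, noise_sigma = 0,
                                 psf_sigma = 0, seed = 1L) {
  stopifnot(v > 0, lag_time >= 0, frame_interval > 0, noise_sigma >= 0,
            psf_sigma >= 0)
  structure(
    list(v = v, rate_gradient = rate_gradient, lag_time = lag_time,
         frame_interval = frame_interval, noise_sigma = noise_sigma,
         psf_sigma = psf_sigma, seed = as.integer(seed)),
    class = "dissolution_scenario"
  )
}

# per-pixel rate multiplier for the proximal/distal asymmetry; clamped >= 0
.gradient_field <- function(h_map, gradient) {
  if (gradient == 0) return(1)
  p <- attr(h_map, "pixel_size")
  ctr <- attr(h_map, "centre_px")
  xs <- (seq_len(ncol(h_map)) - ctr["col"]) * p  # um right of centre
  G <- matrix(rep(1 - gradient * xs, each = nrow(h_map)), nrow(h_map))
  # near (left) side dissolves faster when gradient > 0
  pmax(G, 0)
}

#' Erode a thickness map by one time step
#'
#' Each wet pixel loses `v * dt` from the top face (clipped at zero) and the
#' lateral support boundary retreats by the same normal distance, implemented
#' as a Euclidean-distance-transform erosion. This is one-shot erosion from
#' the current state; [render_movie()] propagates the front from the initial
#' state instead so that sub-pixel per-frame retreat accumulates exactly.
#'
#' @param h H x W thickness map in um (from [make_lith()], or any matrix with
#'   a `pixel_size` attribute).
#' @param v Retreat rate in um/s.
#' @param dt Time step in seconds (>= 0).
#' @param gradient Optional proximal/distal rate asymmetry per um (see
#'   [dissolution_scenario()]).
#' @return Eroded thickness map (same attributes).
#' @export
erode_lith <- function(h, v, dt, gradient = 0) {
  if (dt < 0) stop("negative time step", call. = FALSE)
  p <- attr(h, "pixel_size")
  stopifnot(!is.null(p), v * dt >= 0)
  G <- .gradient_field(h, gradient)
  out <- pmax(h - v * dt * G, 0)
  support <- h > 0
  if (any(support)) {
    d_um <- .support_distance(support, p)
    out[d_um <= v * dt] <- 0
  }
  attributes(out) <- attributes(h)
  out
}

# continuum distance of each support pixel centre to the support boundary:
# the EDT to the nearest background pixel centre overshoots the true boundary
# by half a pixel, so half a pixel is subtracted
.support_distance <- function(support, pixel_size) {
  pmax(EBImage::distmap(support) - 0.5, 0) * pixel_size
}

#' Render a dissolution movie with known ground truth
#'
#' Emulates a dark-field acquisition of a dissolving lith: per-frame intensity
#' is a saturating function of local thickness, `I = 1 - exp(-h / h_sat)`
#' (mimicking a weak signal that varies radially, brightest where the calcite
#' is thickest), optionally blurred by a Gaussian PSF and corrupted by
#' Gaussian noise. Frames before `lag_time` are static; the movie runs until
#' the support is empty and ends with an all-background frame. The
#' reconstruction pipeline only ever uses thresholded masks, so the intensity
#' transfer function affects realism, not correctness.
#'
#' @param model A [lith_model()].
#' @param scenario A [dissolution_scenario()].
#' @param pixel_size um/px. Default 0.1.
#' @param dim Frame size in px. Default `c(256, 256)`.
#' @param h_sat Saturation thickness of the intensity map, um. Default 0.5.
#' @param config Optional [acquisition_config()]; built from the arguments
#'   when missing.
#' @return A list of class `synthetic_movie`: `stack` (an [image_stack()])
#'   and `truth` (initial thickness map, analytic and discrete volume, v,
#'   per-frame support volumes, scenario and seed).
#' @export
render_movie <- function(model, scenario, pixel_size = 0.1, dim = c(256, 256),
                         h_sat = 0.5, config = NULL) {
  h0 <- make_lith(model, pixel_size, dim)
  if (is.null(config))
    config <- acquisition_config(frame_interval = scenario$frame_interval,
                                 pixel_size = pixel_size)
  G <- .gradient_field(h0, scenario$rate_gradient)
  support0 <- h0 > 0
  d0 <- .support_distance(support0, pixel_size)
  v <- scenario$v; dt <- scenario$frame_interval

  # per-pixel disappearance time (erosion clock): top-face or side attack
  Gm <- if (is.matrix(G)) G else matrix(G, nrow(h0), ncol(h0))
  t_top <- ifelse(support0 & Gm > 0, h0 / (v * Gm), ifelse(support0, Inf, 0))
  t_side <- ifelse(support0, pmax(d0, 1e-9) / v, 0)
  t_gone <- pmin(t_top, t_side)
  t_empty <- max(t_gone)
  n_frames <- ceiling((scenario$lag_time + t_empty) / dt) + 2L

  frame_of <- function(te) {  # te: erosion-clock time
    h <- pmax(h0 - v * te * Gm, 0)
    h[d0 <= v * te] <- 0
    h
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(scenario$seed)

  frames <- array(0, dim = c(dim[1], dim[2], n_frames))
  vol <- numeric(n_frames)
  for (k in seq_len(n_frames)) {
    te <- max(0, (k - 1) * dt - scenario$lag_time)
    hk <- frame_of(te)
    vol[k] <- sum(hk) * pixel_size^2
    img <- 1 - exp(-hk / h_sat)
    if (scenario$psf_sigma > 0)
      img <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                      sigma = scenario$psf_sigma / pixel_size))
    if (scenario$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, scenario$noise_sigma),
                          nrow(img))
    frames[, , k] <- img
  }

  truth <- list(
    thickness = h0,
    volume = sum(h0) * pixel_size^2,
    volume_analytic = lith_volume(model),
    v = v,
    frame_volumes = vol,
    t_empty = t_empty,
    lag_time = scenario$lag_time,
    seed = scenario$seed,
    model = model,
    scenario = scenario
  )
  structure(list(stack = image_stack(frames, config), truth = truth),
            class = "synthetic_movie")
}
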