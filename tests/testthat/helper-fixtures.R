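# shared fixtures and independent oracles

# radius_series object built directly from (t, r) samples, bypassing imaging
make_series <- function(t, r, lag = 0, dt = t[2] - t[1]) {
  end <- if (any(r == 0)) t[which(r == 0)[1]] else NA_real_
  structure(
    list(t = t, r_eff = r, lag_time = lag, end_time = end, r0 = r[1],
         status = if (is.na(end)) "incomplete" else "ok",
         config = acquisition_config(frame_interval = dt, pixel_size = 0.1)),
    class = "radius_series"
  )
}

# exact two-slope decay: slope s1 until breakpoint b, then s2 down to zero
# exactly at the grid point t_end (so every sample lies on the broken line)
piecewise_series <- function(s1 = 0.056, s2 = 0.95, b = 4.74, dt = 0.25,
                             t_end = 9.75) {
  stopifnot(t_end > b, t_end %% dt == 0)
  r0 <- s1 * b + s2 * (t_end - b)
  t <- seq(0, t_end + dt, by = dt)
  r <- ifelse(t <= b, r0 - s1 * t, pmax(r0 - s1 * b - s2 * (t - b), 0))
  make_series(t, r, dt = dt)
}

# brute-force maximum Feret diameter oracle: max pairwise distance over all
# mask pixel centres, plus one pixel
brute_feret <- function(mask, pixel_size) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 1L) return(pixel_size)
  (max(stats::dist(idx)) + 1) * pixel_size
}

# standard fixtures used across reconstruction tests
thin_disk_model <- function() lith_model(a = 5, b = 5, max_thickness = 0.25,
                                         profile = "uniform")
placolith_model <- function() lith_model(a = 4, b = 3, max_thickness = 1)

# a minimal mask_stack built from a logical array
make_mask_stack <- function(arr, dt = 2, pixel_size = 0.1, potential_on = 0L) {
  cfg <- acquisition_config(frame_interval = dt, pixel_size = pixel_size,
                            potential_on_frame = potential_on)
  structure(
    list(masks = arr, areas = apply(arr, 3, sum) * pixel_size^2, config = cfg,
         provenance = list(method = "manual", threshold = NA_real_)),
    class = "mask_stack"
  )
}
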