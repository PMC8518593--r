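# Physical constants used by the kinetics module
.D_H_default <- 9.31e-5   # proton diffusivity, cm^2/s
.D_S_default <- 7.4e-6    # hydroquinone (H2BQ) diffusivity, cm^2/s
.D_B_default <- 1.18e-5   # bicarbonate diffusivity, cm^2/s
.V_m_calcite <- 36.93     # calcite molar volume, cm^3/mol

#' Electro-generated proton source description
#'
#' Describes transport-limited oxidation of the acid precursor (hydroquinone,
#' releasing two protons per molecule) at a cylindrical fibre microelectrode,
#' together with the radial simulation grid. The cell geometry is simplified
#' to an axisymmetric (1D radial) domain around the fibre; optionally the
#' face areas can be capped at `2 * layer_height` to emulate the
#' cylindrical-to-planar transition imposed by a thin-layer cell.
#'
#' @param r_e Electrode fibre radius, um. Default 3.5 (7 um diameter fibre).
#' @param D_H Proton diffusivity, cm^2/s. Default 9.31e-5.
#' @param D_H2BQ Precursor diffusivity, cm^2/s. Default 7.4e-6.
#' @param c_H2BQ Bulk precursor concentration, mol/L. Default 0.010.
#' @param hco3 Bicarbonate concentration, mol/L (scavenges protons
#'   irreversibly on these time scales; its pKa of 6.3 is far above the pH of
#'   the generated acid). Default 0 (unbuffered).
#' @param D_HCO3 Bicarbonate diffusivity, cm^2/s. Default 1.18e-5.
#' @param r_out Outer radius of the simulated domain, um (held at bulk
#'   composition). Default 3000.
#' @param n_cells Number of geometrically stretched radial cells. Default 200.
#' @param layer_height Optional thin-layer height in um capping the radial
#'   face areas; `NULL` (default) leaves the cylindrical geometry open.
#' @return An object of class `proton_field`.
#' @export
proton_field <- function(r_e = 3.5, D_H = .D_H_default, D_H2BQ = .D_S_default,
                         c_H2BQ = 0.010, hco3 = 0, D_HCO3 = .D_B_default,
                         r_out = 3000, n_cells = 200L, layer_height = NULL) {
  stopifnot(r_e > 0, D_H > 0, D_H2BQ > 0, c_H2BQ >= 0, hco3 >= 0,
            r_out > 10 * r_e, n_cells >= 20L)
  structure(
    list(r_e = r_e, D_H = D_H, D_H2BQ = D_H2BQ, c_H2BQ = c_H2BQ,
         hco3 = hco3, D_HCO3 = D_HCO3, r_out = r_out,
         n_cells = as.integer(n_cells), layer_height = layer_height),
    class = "proton_field"
  )
}

#' Calcite dissolution kinetics parameters
#'
#' First-order surface consumption, `flux = k1_eff * [H+]` with
#' `k1_eff = k1 * roughness * mg_inhibition`. The literature heterogeneous
#' rate constant for calcite at pH < 4 is 0.043 cm/s; coccoliths expose
#' roughly 4-8 times the area of a smooth particle of the same size
#' (`roughness`), while adsorbed Mg2+ inhibits the surface reaction
#' (`mg_inhibition` in (0, 1]).
#'
#' @param k1 Heterogeneous rate constant, cm/s. Default 0.043.
#' @param roughness Surface roughness factor >= 1. Default 1 (smooth).
#' @param mg_inhibition Multiplicative surface inhibition in (0, 1].
#'   Default 1.
#' @param hco3 Bicarbonate concentration, mol/L (solution-phase proton
#'   scavenging). Default 0.
#' @return An object of class `dissolution_kinetics` with an extra
#'   `k1_eff` element.
#' @export
dissolution_kinetics <- function(k1 = 0.043, roughness = 1, mg_inhibition = 1,
                                 hco3 = 0) {
  stopifnot(k1 > 0, roughness >= 1, mg_inhibition > 0, mg_inhibition <= 1,
            hco3 >= 0)
  structure(
    list(k1 = k1, roughness = roughness, mg_inhibition = mg_inhibition,
         hco3 = hco3, k1_eff = k1 * roughness * mg_inhibition),
    class = "dissolution_kinetics"
  )
}

# finite-volume geometry of the radial grid; areas/volumes per unit length of
# fibre with the 2*pi factor kept (it cancels in concentrations anyway)
.radial_grid <- function(field) {
  faces <- exp(seq(log(field$r_e), log(field$r_out), length.out = field$n_cells + 1L))
  rc <- 0.5 * (faces[-1] + faces[-length(faces)])
  A <- 2 * pi * faces
  if (!is.null(field$layer_height)) A <- pmin(A, 2 * field$layer_height)
  vol <- if (is.null(field$layer_height)) {
    pi * diff(faces^2)
  } else {
    rstar <- field$layer_height / pi
    v <- numeric(field$n_cells)
    for (i in seq_len(field$n_cells)) {
      a <- faces[i]; b <- faces[i + 1L]
      cyl_hi <- min(b, max(a, rstar))
      v[i] <- pi * (max(cyl_hi, a)^2 - a^2) +
        2 * field$layer_height * (b - max(a, rstar)) * (b > rstar)
    }
    v
  }
  list(faces = faces, rc = rc, A = A, vol = vol)
}

#' Simulate the electro-generated proton field
#'
#' Finite-volume method-of-lines solution of radial diffusion of the acid
#' precursor and protons around the fibre: the precursor is held at zero at
#' the electrode surface (transport-limited oxidation), protons are released
#' there at twice the precursor consumption flux, and the outer boundary is
#' held at bulk composition. When the field carries bicarbonate, a third
#' species scavenges protons via a fast irreversible bimolecular reaction.
#' Time integration uses a stiff banded solver (lsoda), so no explicit
#' stability (CFL) limit applies.
#'
#' @param field A [proton_field()].
#' @param t_end Final time, s. Default 30.
#' @param times Output times; default a grid dense at early times.
#' @return An object of class `proton_solution`: `times`, `x` (distance from
#'   the electrode edge, um), concentration matrices `H`, `S` (and `B`)
#'   of dimension (time x cell), in mol/L, plus the grid and field.
#' @export
simulate_protons <- function(field, t_end = 30,
                             times = NULL) {
  stopifnot(inherits(field, "proton_field"))
  if (is.null(times))
    times <- unique(c(seq(0, min(2, t_end), by = 0.05),
                      seq(0, t_end, by = 0.25), t_end))
  times <- sort(unique(times))
  g <- .radial_grid(field)
  n <- field$n_cells
  D_S <- field$D_H2BQ * 1e8  # um^2/s
  D_H <- field$D_H * 1e8
  D_B <- field$D_HCO3 * 1e8
  buffered <- field$hco3 > 0
  k_scav <- 1e6  # L/(mol s); effectively instantaneous vs transport

  dmid <- diff(g$rc)
  Afin <- g$A[2:n]          # interior faces
  A0 <- g$A[1]; An <- g$A[n + 1L]
  d0 <- g$rc[1] - g$faces[1]
  dn <- g$faces[n + 1L] - g$rc[n]

  rhs <- function(t, y, parms) {
    S <- y[1:n]; H <- y[(n + 1):(2 * n)]
    FS <- D_S * Afin * diff(S) / dmid
    FH <- D_H * Afin * diff(H) / dmid
    JS0 <- D_S * A0 * S[1] / d0          # precursor flux into electrode
    FSn <- D_S * An * (field$c_H2BQ - S[n]) / dn
    FHn <- D_H * An * (0 - H[n]) / dn
    dS <- (c(FS, FSn) - c(JS0, FS)) / g$vol
    dH <- (c(FH, FHn) - c(-2 * JS0, FH)) / g$vol
    if (buffered) {
      B <- y[(2 * n + 1):(3 * n)]
      FB <- D_B * Afin * diff(B) / dmid
      FBn <- D_B * An * (field$hco3 - B[n]) / dn
      dB <- (c(FB, FBn) - c(0, FB)) / g$vol
      r <- k_scav * H * B
      list(c(dS, dH - r, dB - r))
    } else {
      list(c(dS, dH))
    }
  }

  y0 <- c(rep(field$c_H2BQ, n), rep(0, n), if (buffered) rep(field$hco3, n))
  out <- deSolve::ode.1D(y = y0, times = times, func = rhs, parms = NULL,
                         nspec = if (buffered) 3L else 2L, dimens = n,
                         method = "lsoda", rtol = 1e-7, atol = 1e-12)
  S <- out[, 1 + 1:n, drop = FALSE]
  H <- out[, 1 + (n + 1):(2 * n), drop = FALSE]
  B <- if (buffered) out[, 1 + (2 * n + 1):(3 * n), drop = FALSE] else NULL
  structure(
    list(times = out[, 1], x = g$rc - field$r_e, rc = g$rc, grid = g,
         S = S, H = H, B = B, field = field),
    class = "proton_solution"
  )
}

# accept a field (solve on demand) or an existing solution
.as_proton_solution <- function(obj, t_end = 30) {
  if (inherits(obj, "proton_solution")) obj else simulate_protons(obj, t_end = t_end)
}

# bilinear interpolation of a (time x cell) concentration matrix
.interp_ct <- function(sol, mat, t, x) {
  t <- pmin(pmax(t, min(sol$times)), max(sol$times))
  sapply(seq_along(t), function(i) {
    prof <- apply(mat, 2, function(col) stats::approx(sol$times, col, xout = t[i])$y)
    stats::approx(sol$x, prof, xout = x, rule = 2)$y
  })
}

#' Proton concentration at a time and distance
#'
#' @param obj A [proton_field()] (solved on demand) or a `proton_solution`
#'   from [simulate_protons()].
#' @param t Time(s) in seconds (>= 0).
#' @param x Distance(s) from the electrode edge, um (>= 0).
#' @return Proton concentration(s) in mol/L; a matrix when both `t` and `x`
#'   have length > 1 (x in rows).
#' @export
proton_profile <- function(obj, t, x) {
  stopifnot(all(t >= 0), all(x >= 0))
  sol <- .as_proton_solution(obj, t_end = max(30, max(t)))
  res <- .interp_ct(sol, sol$H, t, x)
  if (length(x) == 1L || length(t) == 1L) drop(res) else res
}

#' Surface pH of the electro-generated acid
#'
#' `-log10` of the proton concentration at the electrode surface (activity
#' taken as concentration) at a late, quasi-steady time.
#'
#' @inheritParams proton_profile
#' @param t Evaluation time, s. Default 30 (late-time/quasi-steady).
#' @return pH (``Inf`` if the concentration is zero).
#' @export
surface_ph <- function(obj, t = 30) {
  sol <- .as_proton_solution(obj, t_end = t)
  cs <- .interp_ct(sol, sol$H, t, sol$x[1])
  if (cs <= 0) return(Inf)
  -log10(cs)
}

#' Time to reach a near-steady proton concentration
#'
#' First time at which the concentration at distance `x` is within `tol` of
#' its long-time value, `|c(x, t) - c(x, t_ref)| / c(x, t_ref) < tol`.
#'
#' @inheritParams proton_profile
#' @param x Distance from the electrode edge, um.
#' @param tol Fractional tolerance. Default 0.10.
#' @param t_ref Reference ("long") time, s. Default 30.
#' @return Time in seconds; `NA` with a warning if the band is never entered
#'   before `t_ref`.
#' @export
steady_state_time <- function(obj, x, tol = 0.10, t_ref = 30) {
  stopifnot(x >= 0, tol > 0)
  sol <- .as_proton_solution(obj, t_end = t_ref)
  if (max(sol$x) < x) stop("x outside the simulated domain", call. = FALSE)
  ct <- apply(sol$H, 1, function(row) stats::approx(sol$x, row, xout = x)$y)
  cref <- stats::approx(sol$times, ct, xout = t_ref)$y
  if (cref <= 0) return(0)
  rel <- abs(ct - cref) / cref
  ok <- which(rel < tol & sol$times <= t_ref)
  # first crossing: earliest time after which interpolation stays in band
  if (!length(ok)) {
    warning("concentration never reaches the steady band before t_ref")
    return(NA_real_)
  }
  i <- ok[1]
  if (i == 1L) return(sol$times[1])
  # linear interpolation of the crossing between the bracketing samples
  t0 <- sol$times[i - 1L]; t1 <- sol$times[i]
  r0 <- rel[i - 1L]; r1 <- rel[i]
  if (r0 <= r1) return(t1)
  t0 + (r0 - tol) / (r0 - r1) * (t1 - t0)
}

#' Proton mass balance of a simulation
#'
#' Verifies conservation: protons generated (twice the precursor consumed,
#' all of it at the electrode) must equal protons in solution plus protons
#' scavenged by bicarbonate, up to the negligible loss through the far
#' boundary.
#'
#' @param sol A `proton_solution`.
#' @param t Time at which to audit (defaults to the final time).
#' @return A list with `generated`, `in_solution`, `scavenged` (mol per unit
#'   cell, arbitrary but consistent units) and `relative_imbalance`.
#' @export
proton_mass_balance <- function(sol, t = max(sol$times)) {
  i <- which.min(abs(sol$times - t))
  vol <- sol$grid$vol
  gen <- 2 * sum((sol$field$c_H2BQ - sol$S[i, ]) * vol)
  inh <- sum(sol$H[i, ] * vol)
  scav <- if (is.null(sol$B)) 0 else sum((sol$field$hco3 - sol$B[i, ]) * vol)
  list(generated = gen, in_solution = inh, scavenged = scav,
       relative_imbalance = abs(gen - inh - scav) / gen)
}

#' Steady surface-to-bulk proton ratio at a dissolving sphere
#'
#' For a smooth sphere of radius `r` consuming protons at first order
#' (`flux = k1_eff [H+]_surface`) in a solution of uniform bulk acid, the
#' steady ratio is `m_T / (m_T + k1_eff)` with mass-transport coefficient
#' `m_T = D / r` (closed form). `surface_ratio_sphere_fd()` solves the same
#' steady radial-diffusion problem by finite volumes with a Robin boundary
#' condition and serves as an independent numerical cross-check.
#'
#' @param radius Sphere radius, um.
#' @param kinetics A [dissolution_kinetics()].
#' @param D_H Proton diffusivity, cm^2/s.
#' @return Dimensionless ratio in (0, 1).
#' @export
surface_ratio_sphere <- function(radius, kinetics = dissolution_kinetics(),
                                 D_H = .D_H_default) {
  stopifnot(all(radius > 0))
  m_T <- D_H / (radius * 1e-4)  # cm/s
  m_T / (m_T + kinetics$k1_eff)
}

#' @rdname surface_ratio_sphere
#' @param n_cells,r_out_factor Grid resolution and outer-domain factor of the
#'   finite-volume solver.
#' @export
surface_ratio_sphere_fd <- function(radius, kinetics = dissolution_kinetics(),
                                    D_H = .D_H_default, n_cells = 600L,
                                    r_out_factor = 4000) {
  stopifnot(length(radius) == 1L, radius > 0)
  a <- radius * 1e-4            # cm
  D <- D_H
  k1 <- kinetics$k1_eff
  faces <- exp(seq(log(a), log(r_out_factor * a), length.out = n_cells + 1L))
  rc <- 0.5 * (faces[-1] + faces[-length(faces)])
  Af <- 4 * pi * faces^2
  # steady state: flux divergence zero in every shell; Robin at inner face,
  # Dirichlet c_b = 1 at the outer face; tridiagonal Thomas solve
  n <- n_cells
  dmid <- diff(rc)
  w_in <- D * Af[2:n] / dmid                       # interior conductances
  g0 <- D * Af[1] / (rc[1] - faces[1])             # surface half-cell
  # Robin elimination: c_s = g0 c_1 / (g0 + k1 A0) -> inner conductance
  k_in <- g0 * (k1 * Af[1]) / (g0 + k1 * Af[1])
  gn <- D * Af[n + 1L] / (faces[n + 1L] - rc[n])
  lower <- c(0, w_in)
  upper <- c(w_in, 0)
  diag0 <- -(c(k_in, w_in) + c(w_in, gn))
  rhs <- c(rep(0, n - 1L), -gn * 1.0)
  # Thomas algorithm
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- upper[1] / diag0[1]; dp[1] <- rhs[1] / diag0[1]
  for (i in 2:n) {
    m <- diag0[i] - lower[i] * cp[i - 1L]
    cp[i] <- upper[i] / m
    dp[i] <- (rhs[i] - lower[i] * dp[i - 1L]) / m
  }
  cc <- numeric(n); cc[n] <- dp[n]
  for (i in (n - 1L):1) cc[i] <- dp[i] - cp[i] * cc[i + 1L]
  c1 <- cc[1]
  g0 * c1 / (g0 + k1 * Af[1])  # c_surface (c_b = 1)
}

#' Radius of the surface- to transport-limited regime switch
#'
#' The smooth-particle radius at which the steady surface-to-bulk proton
#' ratio equals one half, i.e. where the interfacial reaction and proton
#' mass transport are equally limiting: `r = D / k1_eff`. Higher surface
#' roughness (larger `k1_eff`) moves the switch to smaller particles.
#'
#' @param kinetics A [dissolution_kinetics()].
#' @param D_H Proton diffusivity, cm^2/s.
#' @return Radius in um.
#' @export
#' @examples
#' regime_switch_radius()  # ~21.7 um for k1 = 0.043 cm/s
regime_switch_radius <- function(kinetics = dissolution_kinetics(),
                                 D_H = .D_H_default) {
  (D_H / kinetics$k1_eff) * 1e4
}

#' Predicted retreat rate of a smooth calcite particle
#'
#' Linear dissolution (surface-retreat) rate of a smooth, solid, non-porous
#' calcite particle exposed to acid concentration `c_H` in the
#' surface-limited regime: `rate = k1_eff * c_H * V_m` with the calcite molar
#' volume `V_m` = 36.93 cm^3/mol. Used as the baseline against which
#' measured coccolith rates are expressed (their ratio reflects surface
#' roughness and inhibitors).
#'
#' @param c_H Acid concentration at the particle, mol/L.
#' @param kinetics A [dissolution_kinetics()].
#' @param r_particle Optional particle radius, um; a warning is issued if the
#'   particle is in the transport-limited regime where this prediction is
#'   invalid.
#' @param D_H Proton diffusivity, cm^2/s.
#' @return Retreat rate in um/s.
#' @export
#' @examples
#' predicted_smooth_rate(1e-3)  # ~0.0159 um/s at 1 mM acid
predicted_smooth_rate <- function(c_H, kinetics = dissolution_kinetics(),
                                  r_particle = NULL, D_H = .D_H_default) {
  stopifnot(all(c_H >= 0))
  if (!is.null(r_particle) && r_particle > regime_switch_radius(kinetics, D_H))
    warning("particle is transport-limited; smooth-rate prediction invalid")
  flux <- kinetics$k1_eff * c_H / 1000      # mol cm^-2 s^-1
  flux * .V_m_calcite * 1e4                 # um/s
}

# saturating inhibition factors, calibrated once against the measured
# relative rates at seawater-level Mg2+ (54.6 mM) and HCO3- (2.4 mM)
.mg_alpha <- (6.5 / 4.5 - 1) / 0.0546     # L/mol
.hco3_beta <- (6.5 / 3.8 - 1) / 0.0024    # L/mol

#' Electrolyte rate modifiers and relative dissolution rates
#'
#' Multiplicative modifiers of the calcite dissolution rate for a given
#' electrolyte: Mg2+ adsorption inhibits the surface reaction and HCO3-
#' scavenges part of the generated acid. Both are saturating factors
#' `1 / (1 + alpha * c)` calibrated at seawater-level concentrations; neither
#' can increase the rate. `relative_dissolution_rate()` expresses a
#' coccolith's expected initial rate relative to a smooth particle of the
#' same size in plain inert electrolyte: `roughness * f_Mg * f_HCO3`.
#'
#' @param electrolyte An [electrolyte_spec()].
#' @return `rate_modifiers()`: list with `f_mg`, `f_hco3` in (0, 1].
#' @export
rate_modifiers <- function(electrolyte) {
  stopifnot(inherits(electrolyte, "electrolyte_spec"))
  list(f_mg = 1 / (1 + .mg_alpha * electrolyte$mg),
       f_hco3 = 1 / (1 + .hco3_beta * electrolyte$hco3))
}

#' @rdname rate_modifiers
#' @param roughness Coccolith surface roughness factor; default 6.5, the
#'   enhancement measured for detached liths in plain KNO3.
#' @return `relative_dissolution_rate()`: dimensionless rate relative to the
#'   smooth-particle prediction.
#' @export
relative_dissolution_rate <- function(electrolyte, roughness = 6.5) {
  m <- rate_modifiers(electrolyte)
  roughness * m$f_mg * m$f_hco3
}

#' @rdname rate_modifiers
#' @return `relative_rates_table()`: data.frame of the four standard
#'   electrolytes (plain KNO3, +Mg2+, +HCO3-, K/2 medium) with their
#'   predicted relative rates, in decreasing order.
#' @export
relative_rates_table <- function(roughness = 6.5) {
  el <- .electrolyte_presets()
  data.frame(
    electrolyte = vapply(el, `[[`, "", "label"),
    relative_rate = vapply(el, relative_dissolution_rate, numeric(1),
                           roughness = roughness),
    row.names = NULL
  )
}
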