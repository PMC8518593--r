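#' Shape-factor estimate of coccolith mass
#'
#' The classical morphometric mass estimate `mass[pg] = 2.7 * ks * L^3` with
#' `L` the coccolith length in um, `ks` a dimensionless species shape factor
#' (recommended 0.06, typical range 0.04-0.07) and 2.7 the calcite density in
#' g/cm^3. Used as the literature baseline against which per-lith
#' reconstructed masses are compared.
#'
#' @param length Coccolith length(s), um (> 0; 0 is allowed and gives 0).
#' @param ks Shape factor. Default 0.06.
#' @param density Calcite density in pg/um^3 (numerically equal to g/cm^3).
#'   Default 2.7, the value conventionally used with shape factors.
#' @return Mass in pg.
#' @export
#' @examples
#' shape_factor_mass(9)  # ~118 pg
shape_factor_mass <- function(length, ks = 0.06, density = 2.7) {
  stopifnot(all(length >= 0), ks > 0, density > 0)
  density * ks * length^3
}

#' Build a per-lith results table
#'
#' @param species Character vector of species labels.
#' @param length Lengths, um (> 0).
#' @param mass Masses, pg (>= 0).
#' @param max_thickness Optional maximum reconstructed thickness, um.
#' @param electrolyte,experiment Optional labels.
#' @return A `data.frame` of class `lith_table`, one row per lith.
#' @export
lith_table <- function(species, length, mass, max_thickness = NA_real_,
                       electrolyte = NA_character_, experiment = NA_character_) {
  stopifnot(all(length > 0), all(mass >= 0))
  out <- data.frame(species = species, length = length, mass = mass,
                    max_thickness = max_thickness, electrolyte = electrolyte,
                    experiment = experiment, stringsAsFactors = FALSE)
  class(out) <- c("lith_table", "data.frame")
  out
}

#' Log-log mass-length regression
#'
#' Ordinary least squares of `log10(mass)` on `log10(length)` pooled over all
#' liths. The slope is the allometric exponent (about 3 for geometrically
#' similar liths), its standard error comes from OLS normal theory, and
#' Pearson's r is computed on the log-transformed pairs. Rows with
#' non-positive mass are excluded and counted.
#'
#' @param table A [lith_table()] (or data.frame with `length` and `mass`).
#' @return List with `slope`, `stderr`, `intercept`, `pearson_r`, `n` and
#'   `n_excluded`.
#' @export
loglog_fit <- function(table) {
  keep <- table$mass > 0
  n_excluded <- sum(!keep)
  d <- table[keep, , drop = FALSE]
  if (nrow(d) < 3L)
    stop("need at least 3 liths with positive mass", call. = FALSE)
  lx <- log10(d$length); ly <- log10(d$mass)
  fit <- stats::lm(ly ~ lx)
  sm <- suppressWarnings(summary(fit))  # perfect fits trip summary.lm
  list(slope = unname(stats::coef(fit)[2]),
       stderr = sm$coefficients[2, 2],
       intercept = unname(stats::coef(fit)[1]),
       pearson_r = stats::cor(lx, ly),
       n = nrow(d), n_excluded = n_excluded)
}

#' Thickness-length correlation
#'
#' Pearson correlation between maximum reconstructed thickness and coccolith
#' length; across species this correlation is characteristically weak, which
#' is why dissolution time (thickness) alone is a poor mass proxy.
#'
#' @param table A [lith_table()] with a `max_thickness` column.
#' @return Pearson's r (`NA` with a warning for a constant column).
#' @export
thickness_length_corr <- function(table) {
  d <- table[stats::complete.cases(table$length, table$max_thickness), ,
             drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 rows", call. = FALSE)
  if (stats::sd(d$max_thickness) == 0 || stats::sd(d$length) == 0) {
    warning("constant column; correlation undefined")
    return(NA_real_)
  }
  stats::cor(d$length, d$max_thickness)
}

#' Per-species mass summary
#'
#' @param table A [lith_table()].
#' @return data.frame with one row per species: `mean_mass`, `sd_mass`
#'   (sample sd, `NA` for n = 1) and `n`.
#' @export
species_summary <- function(table) {
  stopifnot(nrow(table) > 0)
  sp <- split(table$mass, table$species)
  out <- data.frame(
    species = names(sp),
    mean_mass = vapply(sp, mean, numeric(1)),
    sd_mass = vapply(sp, function(x) if (length(x) > 1) stats::sd(x) else NA_real_,
                     numeric(1)),
    n = vapply(sp, length, integer(1)),
    row.names = NULL
  )
  out[order(out$species), , drop = FALSE]
}

#' Simulate a lith table with a known allometric law
#'
#' Draws lith lengths uniformly and masses from
#' `mass = 10^intercept * L^exponent` with lognormal scatter of `scatter_dex`
#' decades - the generator used to calibrate the regression's coverage.
#'
#' @param n Number of liths.
#' @param exponent True allometric exponent. Default 2.8.
#' @param intercept log10 intercept (mass in pg at L = 1 um). Default -0.7.
#' @param scatter_dex Lognormal scatter, in decades. Default 0.2.
#' @param length_range Length range, um. Default `c(2, 10)`.
#' @param seed RNG seed.
#' @return A [lith_table()].
#' @export
simulate_lith_table <- function(n, exponent = 2.8, intercept = -0.7,
                                scatter_dex = 0.2, length_range = c(2, 10),
                                seed = 1L) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  L <- stats::runif(n, length_range[1], length_range[2])
  m <- 10^(intercept + exponent * log10(L) + stats::rnorm(n, 0, scatter_dex))
  lith_table(species = "synthetic", length = L, mass = m,
             max_thickness = 0.1 * L * 10^stats::rnorm(n, 0, scatter_dex))
}
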