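#' Arrhenius thermal-damage parameters
#'
#' Constants of the first-order Arrhenius damage integral
#' \deqn{\Omega(t) = \int_0^t A \exp(-E_a / (R_{gas} T))\, dt}
#' with the frequency factor \code{A = 4.575e72} 1/s, activation energy
#' \code{Ea = 4.71e5} J/mol and gas constant 8.314 J/(mol K), plus the
#' burn-degree thresholds on Omega (first 0.58, second 1.0, third 1e4) and
#' the Omega cutoff defining "damaged" for the thresholded volume fraction.
#'
#' @param A frequency factor (1/s).
#' @param Ea activation energy (J/mol).
#' @param Rgas universal gas constant (J/(mol K)).
#' @param thresholds increasing Omega thresholds for first/second/third
#'   degree burns.
#' @param damage_threshold Omega cutoff for \code{\link{damaged_volume_fraction}}.
#' @return An object of class \code{damage_params}.
#' @export
damage_params <- function(A = 4.575e72, Ea = 4.71e5, Rgas = 8.314,
                          thresholds = c(first = 0.58, second = 1.0, third = 1e4),
                          damage_threshold = 1.0) {
  if (A <= 0 || Ea <= 0 || Rgas <= 0) stop("A, Ea, Rgas must be positive")
  if (length(thresholds) != 3 || any(diff(thresholds) <= 0))
    stop("burn thresholds must be three strictly increasing values")
  if (damage_threshold <= 0) stop("damage_threshold must be positive")
  structure(list(A = A, Ea = Ea, Rgas = Rgas,
                 log_A = log(A), thresholds = thresholds,
                 damage_threshold = damage_threshold),
            class = "damage_params")
}

#' Arrhenius damage-rate and increment
#'
#' \code{arrhenius_rate} evaluates \code{A exp(-Ea/(Rgas T))} (1/s) in log
#' space, so the 1e72 frequency factor never overflows;
#' \code{arrhenius_increment} multiplies by a time step (rectangle rule --
#' the solver accumulates trapezoidally across steps).
#'
#' @param T_kelvin absolute temperature (K), vectorised.
#' @param dt time step (s).
#' @param params a \code{\link{damage_params}}.
#' @return rate in 1/s, or dimensionless Omega increment.
#' @export
#' @examples
#' arrhenius_increment(310.15, 1)  # ~2e-7: negligible at body temperature
arrhenius_rate <- function(T_kelvin, params = damage_params()) {
  if (any(T_kelvin <= 0)) stop("temperature must be positive Kelvin")
  exp(params$log_A - params$Ea / (params$Rgas * T_kelvin))
}

#' @rdname arrhenius_rate
#' @export
arrhenius_increment <- function(T_kelvin, dt, params = damage_params()) {
  if (any(dt < 0)) stop("dt must be >= 0")
  arrhenius_rate(T_kelvin, params) * dt
}

#' Burn-degree classification from cumulative damage
#'
#' Maps Omega to the clinical burn degree: below 0.58 none, [0.58, 1)
#' first degree, [1, 1e4) second degree, >= 1e4 third degree. Boundaries are
#' inclusive on the left.
#'
#' @param omega cumulative damage Omega (vectorised, >= 0).
#' @param params a \code{\link{damage_params}}.
#' @return factor with levels \code{none < first < second < third}.
#' @export
#' @examples
#' classify_burn(c(0, 0.58, 1, 1e4))
classify_burn <- function(omega, params = damage_params()) {
  if (any(omega < 0)) stop("Omega must be >= 0")
  th <- params$thresholds
  cut(omega, breaks = c(-Inf, th, Inf), right = FALSE,
      labels = c("none", "first", "second", "third"), ordered_result = TRUE)
}

# logical mask of region cells
region_mask <- function(grid, region = c("scar_subvolume", "whole_domain", "vessel")) {
  region <- match.arg(region)
  switch(region,
         scar_subvolume = grid$label == "tissue",
         vessel = grid$label == "vessel",
         whole_domain = matrix(TRUE, grid$nr, grid$nz))
}

#' Thresholded damaged-volume fraction
#'
#' Fraction of a region's volume whose cumulative damage meets or exceeds a
#' cutoff: \code{sum(V[Omega >= threshold]) / sum(V)} over the region's
#' annular cell volumes. The default region is the scar tissue (cells not
#' labelled vessel), the lesion a treatment targets.
#'
#' @param omega matrix of cumulative damage on the grid (\code{nr x nz}).
#' @param grid a \code{tissue_grid}.
#' @param region \code{"scar_subvolume"} (default), \code{"whole_domain"}
#'   or \code{"vessel"}.
#' @param threshold Omega cutoff; default from \code{params}.
#' @param params a \code{\link{damage_params}}.
#' @return fraction in [0, 1].
#' @export
damaged_volume_fraction <- function(omega, grid, region = "scar_subvolume",
                                    threshold = NULL,
                                    params = damage_params()) {
  if (is.null(threshold)) threshold <- params$damage_threshold
  sel <- region_mask(grid, region)
  if (!any(sel)) stop("region '", region, "' contains no cells")
  v <- grid$vol_mm3
  sum(v[sel & omega >= threshold]) / sum(v[sel])
}

#' Expected damaged-volume fraction (first-order kinetics)
#'
#' Volume-weighted mean of the damaged tissue fraction
#' \code{theta = 1 - exp(-Omega)} over a region. Under the first-order
#' Arrhenius model, \code{theta} is the fraction of native tissue
#' constituents already denatured in each cell, so this average is the
#' expected proportion of thermally damaged volume -- a smooth dose-response
#' measure that remains informative when no cell crosses a hard Omega
#' threshold.
#'
#' @inheritParams damaged_volume_fraction
#' @return fraction in [0, 1].
#' @export
expected_damage_fraction <- function(omega, grid, region = "scar_subvolume") {
  sel <- region_mask(grid, region)
  if (!any(sel)) stop("region '", region, "' contains no cells")
  v <- grid$vol_mm3
  sum(v[sel] * (1 - exp(-omega[sel]))) / sum(v[sel])
}
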