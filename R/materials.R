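#' Optical and thermophysical properties of a tissue compartment
#'
#' Bundles the optical coefficients of a tissue (absorption \code{mu_a},
#' scattering \code{mu_s}, surface reflectivity \code{R}) with its
#' thermophysical properties (density \code{rho}, specific heat \code{c},
#' thermal conductivity \code{k}) and the blood/perfusion parameters entering
#' the Pennes equation (\code{rho_b}, \code{c_b}, \code{w_b}, arterial
#' temperature \code{T_art}). The total attenuation \code{mu_t = mu_a + mu_s}
#' is always derived, never supplied.
#'
#' @param mu_a absorption coefficient (1/cm).
#' @param mu_s scattering coefficient (1/cm).
#' @param R surface reflectivity, dimensionless fraction in [0, 1).
#' @param rho tissue density (kg/m^3).
#' @param c tissue specific heat (J/(kg K)).
#' @param k tissue thermal conductivity (W/(m K)).
#' @param rho_b blood density (kg/m^3).
#' @param c_b blood specific heat (J/(kg K)).
#' @param w_b blood perfusion rate (1/s).
#' @param T_art arterial temperature (degrees C).
#' @param T0 initial tissue temperature (degrees C).
#' @param T1 ambient temperature (degrees C).
#' @return An object of class \code{material_properties} (a named list with
#'   the fields above plus \code{mu_t}).
#' @export
#' @examples
#' m <- material_properties(mu_a = 5.574, mu_s = 118.37, R = 0.2,
#'                          rho = 1200, c = 3600, k = 0.5)
#' m$mu_t  # 123.944
material_properties <- function(mu_a, mu_s, R, rho, c, k,
                                rho_b = 1000, c_b = 4180, w_b = 6.4e-3,
                                T_art = 37, T0 = 37, T1 = 25) {
  stopifnot(is.numeric(mu_a), is.numeric(mu_s), is.numeric(R))
  if (mu_a < 0 || mu_s < 0) stop("absorption/scattering coefficients must be >= 0")
  if (R < 0 || R >= 1) stop("reflectivity R must be in [0, 1)")
  if (rho <= 0 || c <= 0 || k <= 0) stop("rho, c, k must be positive")
  if (rho_b < 0 || c_b < 0 || w_b < 0) stop("blood parameters must be >= 0")
  if (T_art < 30 || T_art > 45) stop("T_art must be physiologic (30-45 C)")
  if (T0 < 30 || T0 > 45) stop("T0 must be physiologic (30-45 C)")
  structure(list(mu_a = mu_a, mu_s = mu_s, mu_t = mu_a + mu_s, R = R,
                 rho = rho, c = c, k = k,
                 rho_b = rho_b, c_b = c_b, w_b = w_b,
                 T_art = T_art, T0 = T0, T1 = T1),
            class = "material_properties")
}

#' @export
print.material_properties <- function(x, ...) {
  cat("<material_properties>\n")
  cat(sprintf("  optics : mu_a = %g, mu_s = %g, mu_t = %g (1/cm), R = %g\n",
              x$mu_a, x$mu_s, x$mu_t, x$R))
  cat(sprintf("  thermal: rho = %g kg/m^3, c = %g J/(kg K), k = %g W/(m K)\n",
              x$rho, x$c, x$k))
  cat(sprintf("  blood  : rho_b = %g, c_b = %g, w_b = %g 1/s, T_art = %g C\n",
              x$rho_b, x$c_b, x$w_b, x$T_art))
  invisible(x)
}

# Published optical parameter sets for normal skin and hypertrophic scar.
# mu_a/mu_s in 1/cm, R dimensionless; blood and temperature parameters shared.
.optics_table <- list(
  hps         = list(mu_s = 118.37, mu_a = 5.574, R = 0.2),
  normal_skin = list(mu_s = 183.92, mu_a = 1.395, R = 0.58)
)

#' Thermophysical closure values for skin tissue
#'
#' The published optical table stops at optics and blood parameters; the
#' tissue density, specific heat and conductivity must be supplied to close
#' the bioheat equation. The defaults are standard dermal values and apply
#' identically to scar and normal skin; they are deliberately exposed because
#' simulated temperatures depend on them.
#'
#' @param rho tissue density (kg/m^3), default 1200.
#' @param c tissue specific heat (J/(kg K)), default 3600.
#' @param k tissue thermal conductivity (W/(m K)), default 0.5.
#' @return A named list with elements \code{rho}, \code{c}, \code{k}.
#' @export
closure_defaults <- function(rho = 1200, c = 3600, k = 0.5) {
  if (any(!is.finite(c(rho, c, k))) || rho <= 0 || c <= 0 || k <= 0)
    stop("closure values rho, c, k must be positive and finite")
  list(rho = rho, c = c, k = k)
}

#' Material properties for a tissue preset and cell label
#'
#' Resolves the full \code{\link{material_properties}} set for a preset
#' (\code{"hps"} or \code{"normal_skin"}) and a grid label. \code{"tissue"}
#' cells take the preset's optical column plus the thermophysical closure;
#' \code{"vessel"} cells take blood density and specific heat (the vessel is
#' blood-filled) with the same optics and conductivity as the surrounding
#' tissue, since the published table gives tissue-level optics only.
#'
#' @param preset \code{"hps"} or \code{"normal_skin"}.
#' @param label \code{"tissue"} or \code{"vessel"}.
#' @param closure thermophysical closure list, see \code{\link{closure_defaults}}.
#' @return A \code{\link{material_properties}} object.
#' @export
#' @examples
#' material_for("hps", "tissue")$mu_a      # 5.574
#' material_for("normal_skin", "tissue")$R # 0.58
material_for <- function(preset = c("hps", "normal_skin"),
                         label = c("tissue", "vessel"),
                         closure = closure_defaults()) {
  preset <- match.arg(preset)
  label <- match.arg(label)
  for (fld in c("rho", "c", "k"))
    if (is.null(closure[[fld]]))
      stop("thermophysical closure is missing field '", fld, "'")
  op <- .optics_table[[preset]]
  rho <- if (label == "vessel") 1000 else closure$rho
  cc  <- if (label == "vessel") 4180 else closure$c
  material_properties(mu_a = op$mu_a, mu_s = op$mu_s, R = op$R,
                      rho = rho, c = cc, k = closure$k)
}
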