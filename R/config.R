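#' Default run configuration
#'
#' The full parameter set of a simulation run as a nested list, serialisable
#' to YAML: geometry, the two optical material columns, the thermophysical
#' closure, grid resolution, solver settings, damage constants, the dose
#' grid and the selection rule. Loading a saved configuration reproduces a
#' run exactly; all simulation paths are deterministic.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    geometry = list(radius_mm = 10, depth_mm = 4,
                    vessel_radius_hps_mm = 0.5, vessel_radius_normal_mm = 0.3,
                    vessel_depth_mm = 2.0, vessel_top_offset_mm = 0),
    materials = list(
      hps = list(mu_a = 5.574, mu_s = 118.37, R = 0.2),
      normal = list(mu_a = 1.395, mu_s = 183.92, R = 0.58),
      blood = list(rho_b = 1000, c_b = 4180, w_b = 6.4e-3),
      temperatures = list(T_art = 37, T0 = 37, T1 = 25)
    ),
    closure = closure_defaults(),
    grid = list(dr_mm = 0.2, dz_mm = 0.025),
    solver = list(t_end_s = 1, scheme = "implicit", h = 10,
                  dt_pulse_frac = 1 / 40, dt_cool_frac = 1 / 10,
                  cool_ratio = 1.25, dt_max_s = 0.05, boundary_T_C = 37),
    damage = list(A = 4.575e72, Ea = 4.71e5, Rgas = 8.314,
                  thresholds = c(0.58, 1.0, 1e4), damage_threshold = 1.0),
    dose_grid = list(q = c(4, 7.5, 10), tau_ms = c(0.5, 4, 10),
                     spot_mm = c(5, 6, 7),
                     tau_ms_printed_variant = c(0.4, 4, 10),
                     reference = list(q = 7.5, tau_ms = 4, spot_mm = 7)),
    selection = list(threshold_C = 50, objective = "expected_fraction")
  )
}

#' Write / read a run configuration
#'
#' YAML round-trip of the configuration dialect of
#' \code{\link{default_config}}.
#'
#' @param config nested configuration list.
#' @param path file path.
#' @return \code{read_config} returns the configuration list;
#'   \code{write_config} returns \code{path} invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (sec in c("geometry", "materials", "closure", "grid", "solver", "damage"))
    if (is.null(cfg[[sec]]))
      stop("malformed config: missing section '", sec, "'")
  cfg
}

# helpers translating a config into package objects ------------------------
config_solver_spec <- function(cfg) {
  s <- cfg$solver
  solver_spec(t_end = s$t_end_s, scheme = s$scheme, h = s$h,
              dt_pulse_frac = s$dt_pulse_frac, dt_cool_frac = s$dt_cool_frac,
              cool_ratio = s$cool_ratio, dt_max = s$dt_max_s,
              boundary_T = s$boundary_T_C)
}

config_damage_params <- function(cfg) {
  d <- cfg$damage
  damage_params(A = d$A, Ea = d$Ea, Rgas = d$Rgas,
                thresholds = stats::setNames(unlist(d$thresholds),
                                             c("first", "second", "third")),
                damage_threshold = d$damage_threshold)
}

config_domain <- function(cfg, preset) {
  vr <- if (preset == "hps") cfg$geometry$vessel_radius_hps_mm
        else cfg$geometry$vessel_radius_normal_mm
  build_domain(preset, dr = cfg$grid$dr_mm, dz = cfg$grid$dz_mm,
               radius = cfg$geometry$radius_mm, depth = cfg$geometry$depth_mm,
               vessel_radius = vr, vessel_depth = cfg$geometry$vessel_depth_mm,
               closure = closure_defaults(rho = cfg$closure$rho,
                                          c = cfg$closure$c,
                                          k = cfg$closure$k))
}

#' Generate reproducible fixtures
#'
#' Writes small plain-text/raster fixtures: \code{"default_config"} emits
#' the canonical YAML configuration; \code{"perturbed_materials"} emits
#' \code{n} configurations with the thermophysical closure (rho, c, k, h)
#' independently perturbed by up to \code{rel} relative (for sensitivity
#' studies of the simulated temperatures); \code{"masks"} emits synthetic
#' binary PNG masks at the requested collagen fractions. Identical seeds
#' give byte-identical fixtures.
#'
#' @param kind one of \code{"default_config"}, \code{"perturbed_materials"},
#'   \code{"masks"}.
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed for the randomised kinds.
#' @param n number of perturbed material sets.
#' @param rel maximum relative perturbation of each closure value.
#' @param fractions target collagen fractions for mask fixtures.
#' @return character vector of written file paths.
#' @export
generate_fixtures <- function(kind = c("default_config", "perturbed_materials", "masks"),
                              out_dir = ".", seed = 1, n = 5, rel = 0.15,
                              fractions = c(0.84, 0.56)) {
  kind <- match.arg(kind)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  if (kind == "default_config") {
    p <- file.path(out_dir, "default_config.yaml")
    write_config(default_config(), p)
    return(p)
  }
  if (kind == "perturbed_materials") {
    set.seed(seed)
    paths <- character(n)
    for (i in seq_len(n)) {
      cfg <- default_config()
      f <- stats::runif(4, 1 - rel, 1 + rel)
      cfg$closure$rho <- cfg$closure$rho * f[1]
      cfg$closure$c <- cfg$closure$c * f[2]
      cfg$closure$k <- cfg$closure$k * f[3]
      cfg$solver$h <- cfg$solver$h * f[4]
      cfg$meta <- list(fixture = "perturbed_materials", index = i, seed = seed,
                       rel = rel)
      paths[i] <- file.path(out_dir, sprintf("perturbed_%02d.yaml", i))
      write_config(cfg, paths[i])
    }
    return(paths)
  }
  # masks
  paths <- character(length(fractions))
  for (i in seq_along(fractions)) {
    m <- make_mask(fractions[i], seed = seed + i - 1)
    paths[i] <- file.path(out_dir, sprintf("mask_%03d.png", round(100 * fractions[i])))
    png::writePNG(m + 0.0, paths[i])
  }
  paths
}
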