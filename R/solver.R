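#' Time-stepping specification for the bioheat solver
#'
#' Controls the transient integration of the Pennes equation. The default
#' scheme is implicit backward Euler (unconditionally stable) with an
#' adaptive step: fine steps (\code{tau * dt_pulse_frac}) while the pulse
#' envelope is active, then geometric coarsening through the cooling phase
#' out to \code{t_end}. The explicit scheme is provided for verification and
#' refuses to run when its stability bound is violated.
#'
#' @param t_end simulation horizon (s); the cooling tail matters for damage.
#' @param scheme \code{"implicit"} (default) or \code{"explicit"}.
#' @param h convective film coefficient at the irradiated surface
#'   (W/(m^2 K)); natural convection in air by default.
#' @param dt_pulse_frac pulse-phase step as a fraction of the pulse width.
#' @param dt_cool_frac initial cooling step as a fraction of the pulse width.
#' @param cool_ratio geometric growth factor of the cooling step.
#' @param dt_max cap on the cooling step (s).
#' @param boundary_T fixed temperature of the deep and lateral boundaries (C).
#' @param snapshot_times times (s) at which full temperature fields are kept.
#' @return An object of class \code{solver_spec}.
#' @export
solver_spec <- function(t_end = 1, scheme = c("implicit", "explicit"),
                        h = 10, dt_pulse_frac = 1 / 40,
                        dt_cool_frac = 1 / 10, cool_ratio = 1.25,
                        dt_max = 0.05, boundary_T = 37,
                        snapshot_times = numeric(0)) {
  scheme <- match.arg(scheme)
  if (t_end <= 0 || dt_pulse_frac <= 0 || dt_cool_frac <= 0)
    stop("t_end and step fractions must be positive")
  if (cool_ratio < 1) stop("cool_ratio must be >= 1")
  if (h < 0) stop("convective coefficient h must be >= 0")
  structure(list(t_end = t_end, scheme = scheme, h = h,
                 dt_pulse_frac = dt_pulse_frac, dt_cool_frac = dt_cool_frac,
                 cool_ratio = cool_ratio, dt_max = dt_max,
                 boundary_T = boundary_T, snapshot_times = snapshot_times),
            class = "solver_spec")
}

# ---------------------------------------------------------------------------
# Finite-volume assembly on the axisymmetric cell-centred grid.
#
# Volume-weighted form: for cell p, V_p rho c dT_p/dt = sum_f G_f (T_q - T_p)
#   + boundary terms + perfusion + V_p Q. Face conductances G = k_f A_f / d
# with harmonic-mean face conductivity make the operator symmetric, so the
# backward-Euler matrix is SPD and is factorised once per distinct time step.
#
# Boundaries: top (z = 0) Robin, series resistance of the half cell and the
# film h; bottom and outer radius Dirichlet at boundary_T through the half
# cell; axis r = 0 is a natural zero-area face.
# ---------------------------------------------------------------------------
assemble_operator <- function(grid, spec) {
  nr <- grid$nr; nz <- grid$nz
  dr <- grid$dr * 1e-3; dz <- grid$dz * 1e-3          # m
  r_c <- grid$r_mm * 1e-3                              # cell-centre radii (m)
  r_f <- (seq_len(nr)) * dr                            # outer face radii (m)
  V <- grid$vol_mm3 * 1e-9                             # m^3

  kmat <- grid_property(grid, "k")
  rho_c <- grid_property(grid, "rho") * grid_property(grid, "c")
  tis <- grid$materials$tissue
  perf <- tis$rho_b * tis$c_b * tis$w_b                # W/(m^3 K), everywhere

  idx <- function(i, j) i + (j - 1L) * nr
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_acc <- numeric(nr * nz)
  b <- numeric(nr * nz)

  add_face <- function(p, q, G) {
    ii <<- c(ii, p, q); jj <<- c(jj, q, p); xx <<- c(xx, G, G)
    diag_acc[c(p, q)] <<- diag_acc[c(p, q)] - G
  }

  hmean <- function(k1, k2) 2 * k1 * k2 / (k1 + k2)

  # radial interior faces
  for (i in seq_len(nr - 1L)) {
    A_f <- 2 * pi * r_f[i] * dz
    for (j in seq_len(nz)) {
      G <- hmean(kmat[i, j], kmat[i + 1L, j]) * A_f / dr
      add_face(idx(i, j), idx(i + 1L, j), G)
    }
  }
  # axial interior faces
  for (j in seq_len(nz - 1L)) {
    for (i in seq_len(nr)) {
      A_f <- 2 * pi * r_c[i] * dr
      G <- hmean(kmat[i, j], kmat[i, j + 1L]) * A_f / dz
      add_face(idx(i, j), idx(i, j + 1L), G)
    }
  }
  # outer radius: Dirichlet through half cell
  A_out <- 2 * pi * r_f[nr] * dz
  for (j in seq_len(nz)) {
    p <- idx(nr, j)
    G <- kmat[nr, j] * A_out / (dr / 2)
    diag_acc[p] <- diag_acc[p] - G
    b[p] <- b[p] + G * spec$boundary_T
  }
  # bottom: Dirichlet through half cell
  for (i in seq_len(nr)) {
    p <- idx(i, nz)
    G <- kmat[i, nz] * (2 * pi * r_c[i] * dr) / (dz / 2)
    diag_acc[p] <- diag_acc[p] - G
    b[p] <- b[p] + G * spec$boundary_T
  }
  # top: Robin (film h in series with half-cell conduction)
  T1 <- grid$materials$tissue$T1
  for (i in seq_len(nr)) {
    p <- idx(i, 1L)
    if (spec$h > 0) {
      U <- 1 / (dz / (2 * kmat[i, 1L]) + 1 / spec$h)
      G <- U * (2 * pi * r_c[i] * dr)
      diag_acc[p] <- diag_acc[p] - G
      b[p] <- b[p] + G * T1
    }
  }
  # perfusion sink toward arterial temperature, all cells
  Gp <- perf * as.vector(V)
  diag_acc <- diag_acc - Gp
  b <- b + Gp * tis$T_art

  n <- nr * nz
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(xx, diag_acc), dims = c(n, n))
  list(A = Matrix::forceSymmetric(A), b = b, V = as.vector(V),
       cap = as.vector(rho_c) * as.vector(V))   # J/K per cell
}

# adaptive time grid: fine during pulse, geometric growth afterwards
time_grid <- function(tau_s, spec) {
  t_pulse <- min(3 * tau_s, spec$t_end)
  dt_p <- tau_s * spec$dt_pulse_frac
  ts <- seq(0, t_pulse, by = dt_p)
  if (abs(ts[length(ts)] - t_pulse) > 1e-12) ts <- c(ts, t_pulse)
  t <- t_pulse
  dt <- tau_s * spec$dt_cool_frac
  while (t < spec$t_end - 1e-12) {
    t <- min(t + dt, spec$t_end)
    ts <- c(ts, t)
    dt <- min(dt * spec$cool_ratio, spec$dt_max)
  }
  # make sure requested snapshot times are hit exactly
  ts <- sort(unique(c(ts, spec$snapshot_times[spec$snapshot_times <= spec$t_end])))
  ts
}

#' Transient solution of the Pennes bioheat equation
#'
#' Integrates
#' \deqn{\rho c \,\partial T/\partial t = \nabla\cdot(k \nabla T)
#'   + \rho_b c_b w_b (T_{art} - T) + Q}
#' on the axisymmetric grid, with a convective surface at z = 0 and the
#' remaining boundaries held at 37 C. The laser heat source is taken from
#' \code{dose} unless a custom \code{source} function is supplied. The
#' Arrhenius damage field is accumulated trapezoidally at every solver step,
#' together with damaged-fraction traces, because damage is dominated by the
#' brief peak-temperature window.
#'
#' @param domain a \code{tissue_grid} from \code{\link{build_domain}}, or a
#'   preset name (\code{"hps"}/\code{"normal_skin"}) built at default
#'   resolution.
#' @param dose a \code{\link{dose_params}} object (may be \code{NULL} when a
#'   custom \code{source} is given).
#' @param spec a \code{\link{solver_spec}}.
#' @param source optional \code{function(t)} returning an \code{nr x nz}
#'   matrix of volumetric heating (W/m^3); overrides the laser source.
#' @param damage a \code{\link{damage_params}}.
#' @param T_init initial temperature: scalar or \code{nr x nz} matrix (C);
#'   defaults to the material \code{T0}.
#' @param radial_form,axial_form,temporal_form heat-source factor variants,
#'   see \code{\link{heat_source}}.
#' @return An object of class \code{bioheat_result}: the probe trace
#'   (\code{times}, \code{T_center}), center-column temperature history,
#'   final temperature and damage fields, damage-fraction traces, peak
#'   temperature and its time, snapshots, and the inputs.
#' @export
#' @examples
#' \donttest{
#' g <- build_domain("hps", dr = 0.5, dz = 0.05)
#' r <- solve_transient(g, dose_params(7.5, 4, 7),
#'                      solver_spec(t_end = 0.05))
#' r$peak_T_C
#' }
solve_transient <- function(domain, dose = NULL, spec = solver_spec(),
                            source = NULL, damage = damage_params(),
                            T_init = NULL,
                            radial_form = "gaussian",
                            axial_form = "beer_lambert",
                            temporal_form = "gaussian") {
  grid <- if (is.character(domain)) build_domain(domain) else domain
  stopifnot(inherits(grid, "tissue_grid"))
  if (is.null(dose) && is.null(source))
    stop("either a dose or a custom source function is required")

  op <- assemble_operator(grid, spec)
  n <- grid$nr * grid$nz
  tis <- grid$materials$tissue

  if (is.null(source)) {
    S <- source_field(dose, grid, radial_form, axial_form)   # W/m^3
    src_fun <- function(t) S * temporal_envelope(t, dose, temporal_form)
    tau_s <- dose$tau_s
  } else {
    src_fun <- source
    tau_s <- if (!is.null(dose)) dose$tau_s else spec$t_end / 100
  }

  ts <- time_grid(tau_s, spec)
  nt <- length(ts)
  T_vec <- if (is.null(T_init)) rep(tis$T0, n) else rep_len(as.vector(T_init), n)
  sane_lo <- min(T_vec, tis$T0, tis$T1) - 1

  center <- matrix(NA_real_, nt, grid$nz)   # T along the axis column
  center[1, ] <- matrix(T_vec, grid$nr, grid$nz)[1L, ]
  omega <- matrix(0, grid$nr, grid$nz)
  rate_prev <- arrhenius_rate(matrix(T_vec, grid$nr, grid$nz) + 273.15, damage)

  dmg_trace <- data.frame(time_s = ts,
                          fraction_scar = NA_real_, fraction_domain = NA_real_,
                          expected_scar = NA_real_, expected_domain = NA_real_,
                          max_Omega = NA_real_)
  record_damage <- function(k) {
    dmg_trace$fraction_scar[k] <<- damaged_volume_fraction(omega, grid, "scar_subvolume",
                                                           params = damage)
    dmg_trace$fraction_domain[k] <<- damaged_volume_fraction(omega, grid, "whole_domain",
                                                             params = damage)
    dmg_trace$expected_scar[k] <<- expected_damage_fraction(omega, grid, "scar_subvolume")
    dmg_trace$expected_domain[k] <<- expected_damage_fraction(omega, grid, "whole_domain")
    dmg_trace$max_Omega[k] <<- max(omega)
  }
  record_damage(1L)

  snapshots <- list()
  snap_set <- spec$snapshot_times

  if (spec$scheme == "explicit") {
    # forward Euler stability: dt <= min(cap / total conductance out)
    dt_all <- diff(ts)
    dt_stab <- min(op$cap / pmax(-Matrix::diag(op$A), .Machine$double.eps))
    if (max(dt_all) > dt_stab)
      stop(sprintf("explicit scheme unstable: max dt %.3g s exceeds bound %.3g s; reduce the step",
                   max(dt_all), dt_stab))
  }

  fac <- NULL; fac_dt <- NA_real_
  for (k in 2:nt) {
    dt <- ts[k] - ts[k - 1L]
    Qv <- as.vector(src_fun(ts[k])) * op$V          # W per cell
    if (spec$scheme == "implicit") {
      if (is.na(fac_dt) || abs(dt - fac_dt) > 1e-15) {
        M <- Matrix::Diagonal(x = op$cap / dt) - op$A
        fac <- Matrix::Cholesky(M, LDL = FALSE)
        fac_dt <- dt
      }
      rhs <- op$cap / dt * T_vec + op$b + Qv
      T_vec <- as.numeric(Matrix::solve(fac, rhs, system = "A"))
    } else {
      Qv0 <- as.vector(src_fun(ts[k - 1L])) * op$V
      T_vec <- T_vec + dt / op$cap *
        (as.numeric(op$A %*% T_vec) + op$b + Qv0)
    }
    if (any(!is.finite(T_vec)) || any(T_vec < sane_lo) || any(T_vec > 120))
      stop(sprintf("solver aborted at t = %.4g s: temperature left sanity bounds [%g, 120] C",
                   ts[k], sane_lo))

    Tm <- matrix(T_vec, grid$nr, grid$nz)
    center[k, ] <- Tm[1L, ]
    rate <- arrhenius_rate(Tm + 273.15, damage)
    omega <- omega + 0.5 * (rate_prev + rate) * dt
    rate_prev <- rate
    record_damage(k)
    if (length(snap_set) && any(abs(snap_set - ts[k]) < 1e-12))
      snapshots[[sprintf("t=%.6g", ts[k])]] <- Tm
  }

  # probe: axis cell hottest at the end of the pulse phase
  k_pulse <- max(which(ts <= min(3 * tau_s, spec$t_end)))
  probe_j <- which.max(center[k_pulse, ])
  trace <- center[, probe_j]
  k_peak <- which.max(trace)

  structure(list(
    times = ts, T_center = trace, center_history = center,
    probe_z_mm = grid$z_mm[probe_j], probe_j = probe_j,
    peak_T_C = trace[k_peak], t_peak_s = ts[k_peak],
    T_final = matrix(T_vec, grid$nr, grid$nz),
    omega = omega, damage_trace = dmg_trace,
    snapshots = snapshots, grid = grid, dose = dose, spec = spec,
    damage_params = damage
  ), class = "bioheat_result")
}

#' @export
print.bioheat_result <- function(x, ...) {
  cat("<bioheat_result>\n")
  if (!is.null(x$dose))
    cat(sprintf("  dose  : q = %g, tau = %g ms, spot = %g mm (preset '%s')\n",
                x$dose$q, x$dose$tau_ms, x$dose$spot_mm, x$grid$preset))
  cat(sprintf("  peak  : %.2f C at t = %.4g s (probe depth %.3g mm)\n",
              x$peak_T_C, x$t_peak_s, x$probe_z_mm))
  n <- nrow(x$damage_trace)
  cat(sprintf("  damage: max Omega %.3g; expected scar fraction %.3g at t = %g s\n",
              x$damage_trace$max_Omega[n], x$damage_trace$expected_scar[n],
              x$times[n]))
  invisible(x)
}

#' Steady-state solution of the bioheat operator
#'
#' Solves the stationary Pennes problem \code{-div(k grad T) +
#' perfusion = Q + boundary terms} with the same discretisation and boundary
#' conditions as \code{\link{solve_transient}}. Used for verification
#' (manufactured solutions) and long-time limits.
#'
#' @param grid a \code{tissue_grid}.
#' @param source_matrix \code{nr x nz} matrix of volumetric heating (W/m^3).
#' @param spec a \code{\link{solver_spec}} (boundary data and h).
#' @return \code{nr x nz} temperature matrix (C).
#' @export
solve_steady <- function(grid, source_matrix, spec = solver_spec()) {
  op <- assemble_operator(grid, spec)
  rhs <- op$b + as.vector(source_matrix) * op$V
  T_vec <- as.numeric(Matrix::solve(-op$A, rhs))
  matrix(T_vec, grid$nr, grid$nz)
}

#' Grid-convergence report for the transient solver
#'
#' Re-runs the same dose at a ladder of grid resolutions (the time step
#' scales with the pulse-phase fraction unchanged) and reports the peak
#' probe temperature per resolution with successive differences -- a
#' Richardson-style consistency check.
#'
#' @param dose a \code{\link{dose_params}}.
#' @param resolutions list of \code{c(dr, dz)} pairs (mm), coarsest first;
#'   at least 3.
#' @param preset tissue preset.
#' @param spec a \code{\link{solver_spec}}.
#' @return data.frame with dr, dz, peak temperature and successive deltas.
#' @export
grid_convergence_report <- function(dose, resolutions, preset = "hps",
                                    spec = solver_spec()) {
  if (length(resolutions) < 3) stop("need at least 3 resolutions")
  peaks <- vapply(resolutions, function(res) {
    g <- build_domain(preset, dr = res[1], dz = res[2])
    solve_transient(g, dose, spec)$peak_T_C
  }, numeric(1))
  out <- data.frame(dr_mm = vapply(resolutions, `[`, numeric(1), 1),
                    dz_mm = vapply(resolutions, `[`, numeric(1), 2),
                    peak_T_C = peaks)
  out$delta <- c(NA, abs(diff(peaks)))
  out
}
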