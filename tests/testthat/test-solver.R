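test_that("uniform body temperature with matched boundaries is a fixed point", {
  g <- coarse_grid()
  # ambient equal to body temperature and no source: T = T_art = 37 solves
  # the stationary problem exactly
  g$materials$tissue$T1 <- 37
  g$materials$vessel$T1 <- 37
  res <- solve_transient(g, dose_params(0.0001, 4, 7), fast_spec(t_end = 0.1),
                         source = function(t) matrix(0, g$nr, g$nz))
  expect_lt(max(abs(res$T_final - 37)), 1e-8)
})

test_that("maximum principle: sourceless relaxation never exceeds the initial maximum", {
  g <- coarse_grid(dz = 0.1)
  res <- solve_transient(g, dose_params(1, 4, 7), fast_spec(t_end = 0.5),
                         source = function(t) matrix(0, g$nr, g$nz),
                         T_init = 45)
  expect_lt(max(res$center_history), 45 + 1e-9)
  # relaxation toward 37 is monotone at the probe
  trace <- res$T_center
  expect_true(all(diff(trace) <= 1e-9))
  expect_lt(tail(trace, 1), 45)
  expect_gte(min(res$T_final), 37 - 1e-6)
})

test_that("with conduction suppressed each cell follows the perfusion ODE closed form", {
  # k ~ 0 and h = 0 decouple the cells; with a constant uniform source Q the
  # exact solution is T(t) = T_art + Q/perf (1 - exp(-perf t / (rho c)))
  g <- coarse_grid(dr = 1, dz = 0.4, closure = closure_defaults(k = 1e-9))
  Q <- 5e6   # W/m^3
  spec <- solver_spec(t_end = 0.5, h = 0, dt_pulse_frac = 1 / 200,
                      dt_cool_frac = 1 / 200, cool_ratio = 1.0, dt_max = 2.5e-4)
  res <- solve_transient(g, dose_params(1, 1000, 7), spec,
                         source = function(t) matrix(Q, g$nr, g$nz))
  tis <- g$materials$tissue
  perf <- tis$rho_b * tis$c_b * tis$w_b
  rc <- tis$rho * tis$c
  exact <- 37 + Q / perf * (1 - exp(-perf * 0.5 / rc))
  # probe is a tissue cell? pick a mid-domain tissue cell instead
  i <- g$nr; j <- g$nz %/% 2
  expect_equal(res$T_final[i, j], exact, tolerance = 5e-3)
})

test_that("temperature rise is linear in energy density", {
  # rise is measured against a zero-dose baseline run so the dose-independent
  # ambient-cooling drift (T1 = 25 C at the surface) cancels exactly
  g <- coarse_grid()
  spec <- fast_spec(t_end = 0.05)
  r0 <- solve_transient(g, dose_params(5, 4, 7), spec,
                        source = function(t) matrix(0, g$nr, g$nz))
  r1 <- solve_transient(g, dose_params(5, 4, 7), spec)
  r2 <- solve_transient(g, dose_params(10, 4, 7), spec)
  rise1 <- r1$T_final - r0$T_final
  rise2 <- r2$T_final - r0$T_final
  expect_equal(rise2, 2 * rise1, tolerance = 1e-6)
  j <- r1$probe_j
  expect_equal(max(r2$center_history[, j] - r0$center_history[, j]),
               2 * max(r1$center_history[, j] - r0$center_history[, j]),
               tolerance = 1e-6)
})

test_that("peak occurs on the axis inside the scar and exceeds the normal-skin rise", {
  spec <- fast_spec(t_end = 0.05)
  gh <- coarse_grid("hps")
  gn <- coarse_grid("normal_skin")
  d <- ref_dose()
  rh <- solve_transient(gh, d, spec)
  rn <- solve_transient(gn, d, spec)
  # hottest cell of the final pulse-phase field is on the axis
  expect_equal(max(rh$T_final), max(rh$T_final[1, ]), tolerance = 1e-9)
  expect_gt(rh$peak_T_C - 37, rn$peak_T_C - 37)
})

test_that("explicit scheme refuses an unstable step and matches implicit when stable", {
  g <- coarse_grid(dr = 1, dz = 0.05)
  expect_error(
    solve_transient(g, ref_dose(), solver_spec(t_end = 0.5, scheme = "explicit")),
    "unstable")
  # tiny fixed steps: both schemes agree on a short sourceless relaxation
  spec_base <- list(t_end = 0.02, dt_pulse_frac = 1 / 1000, dt_cool_frac = 1 / 1000,
                    cool_ratio = 1, dt_max = 4e-6)
  zsrc <- function(t) matrix(0, g$nr, g$nz)
  ri <- solve_transient(g, ref_dose(), do.call(solver_spec, c(spec_base, scheme = "implicit")),
                        source = zsrc, T_init = 42)
  re <- solve_transient(g, ref_dose(), do.call(solver_spec, c(spec_base, scheme = "explicit")),
                        source = zsrc, T_init = 42)
  expect_equal(re$T_final, ri$T_final, tolerance = 1e-3)
})

test_that("manufactured steady solution converges at second order in space", {
  # T* = 37 + a cos(pi r / (2 R)) sin(gamma (D - z)) satisfies the lateral
  # and bottom Dirichlet conditions exactly; gamma is chosen so the top
  # Robin condition -k dT/dz = h (T - T1) holds with T1 = 37.
  closure <- closure_defaults()
  h <- 10; k <- closure$k
  D <- 4e-3; R <- 10e-3; a <- 5
  gamma <- uniroot(function(g) g * cos(g * D) + (h / k) * sin(g * D),
                   c(1, 700))$root
  spec <- solver_spec(h = h, boundary_T = 37)
  errs <- c()
  hs <- c(0.5, 0.25, 0.125)
  for (sc in hs) {
    g <- suppressWarnings(build_domain("hps", dr = sc, dz = sc * 0.4,
                                       closure = closure))
    # force uniform properties (vessel shares tissue thermophysics) so the
    # analytic source below is exact everywhere
    g$materials$vessel <- g$materials$tissue
    g$materials$tissue$T1 <- 37
    r_m <- g$r_mm * 1e-3; z_m <- g$z_mm * 1e-3
    gr <- cos(pi * r_m / (2 * R))
    lap_gr <- -(pi / (2 * R))^2 * gr - (pi / (2 * R)) * sin(pi * r_m / (2 * R)) / r_m
    pz <- sin(gamma * (D - z_m))
    tis <- g$materials$tissue
    perf <- tis$rho_b * tis$c_b * tis$w_b
    # -k lap(T*) + perf (T* - 37) = Q_mms
    Q <- -k * a * (outer(lap_gr, pz) - gamma^2 * outer(gr, pz)) +
      perf * a * outer(gr, pz)
    Tn <- solve_steady(g, Q, spec)
    Tex <- 37 + a * outer(gr, pz)
    errs <- c(errs, sqrt(sum((Tn - Tex)^2 * g$vol_mm3) / sum(g$vol_mm3)))
  }
  order12 <- log2(errs[1] / errs[2])
  order23 <- log2(errs[2] / errs[3])
  expect_gt(order23, 1.7)
  expect_lt(order23, 2.5)
  expect_gt(order12, 1.5)
})

test_that("grid convergence report shows a settling peak", {
  d <- ref_dose(q = 10)
  rep <- suppressWarnings(grid_convergence_report(
    d, list(c(0.8, 0.2), c(0.4, 0.1), c(0.2, 0.05)),
    spec = fast_spec(t_end = 0.03)))
  expect_equal(nrow(rep), 3)
  expect_true(all(is.finite(rep$peak_T_C)))
  # successive changes shrink
  expect_lt(rep$delta[3], rep$delta[2])
})

test_that("damage traces from a transient run are monotone and consistent", {
  g <- coarse_grid()
  res <- solve_transient(g, dose_params(10, 4, 7), fast_spec(t_end = 0.3))
  dt <- res$damage_trace
  expect_true(all(diff(dt$max_Omega) >= 0))
  expect_true(all(diff(dt$expected_scar) >= 0))
  expect_true(all(diff(dt$fraction_scar) >= 0))
  expect_true(all(dt$expected_scar >= 0 & dt$expected_scar <= 1))
  # omega field non-negative
  expect_gte(min(res$omega), 0)
})

test_that("solver aborts when the field leaves sanity bounds", {
  g <- coarse_grid(dz = 0.1)
  huge <- function(t) matrix(1e13, g$nr, g$nz)
  expect_error(
    solve_transient(g, ref_dose(), fast_spec(t_end = 0.05), source = huge),
    "sanity bounds")
})
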