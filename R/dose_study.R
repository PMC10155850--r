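#' Factorial or one-factor dose-parameter sweep
#'
#' Runs the transient photothermal simulation over a grid of dose
#' parameters. \code{mode = "factorial"} covers the full cross of the three
#' axes (used for dose selection); \code{mode = "one_factor"} varies one
#' axis at a time around the reference dose (q = 7.5, tau = 4 ms, spot =
#' 7 mm), mirroring how dose-response curves are usually reported. The
#' pipeline is fully deterministic: identical configuration gives identical
#' results.
#'
#' @param presets character vector of tissue presets to sweep.
#' @param q,tau_ms,spot_mm dose-axis values. The default pulse-width grid is
#'   \code{c(0.5, 4, 10)} ms, matching the treatment device's lower limit of
#'   0.5 ms; the historically quoted 0.4 ms variant can be passed explicitly.
#' @param mode \code{"factorial"} or \code{"one_factor"}.
#' @param reference reference dose triple for one-factor mode.
#' @param spec a \code{\link{solver_spec}}.
#' @param damage a \code{\link{damage_params}}.
#' @param resolution \code{c(dr, dz)} grid spacing (mm) for the built
#'   domains.
#' @param keep_results keep the full \code{bioheat_result} objects (memory
#'   heavy); scalar summaries and traces are always kept.
#' @param verbose print one line per completed run.
#' @return An object of class \code{sweep_result}: a list of per-candidate
#'   records, each holding the dose triple, preset, peak probe temperature
#'   and its time, the probe trace, the damage traces, the final thresholded
#'   and expected damaged fractions, the maximum Omega and its burn class,
#'   and the 50 C threshold verdict.
#' @export
run_sweep <- function(presets = "hps",
                      q = c(4, 7.5, 10),
                      tau_ms = c(0.5, 4, 10),
                      spot_mm = c(5, 6, 7),
                      mode = c("factorial", "one_factor"),
                      reference = c(q = 7.5, tau_ms = 4, spot_mm = 7),
                      spec = solver_spec(), damage = damage_params(),
                      resolution = c(0.2, 0.025),
                      keep_results = FALSE, verbose = FALSE) {
  mode <- match.arg(mode)
  if (!length(q) || !length(tau_ms) || !length(spot_mm) || !length(presets))
    stop("empty dose grid or preset list")
  doses <- if (mode == "factorial") {
    expand.grid(q = q, tau_ms = tau_ms, spot_mm = spot_mm,
                KEEP.OUT.ATTRS = FALSE)
  } else {
    unique(rbind(
      data.frame(q = q, tau_ms = reference[["tau_ms"]], spot_mm = reference[["spot_mm"]]),
      data.frame(q = reference[["q"]], tau_ms = tau_ms, spot_mm = reference[["spot_mm"]]),
      data.frame(q = reference[["q"]], tau_ms = reference[["tau_ms"]], spot_mm = spot_mm)))
  }
  records <- list()
  for (preset in presets) {
    g <- build_domain(preset, dr = resolution[1], dz = resolution[2])
    for (row in seq_len(nrow(doses))) {
      d <- dose_params(doses$q[row], doses$tau_ms[row], doses$spot_mm[row])
      res <- tryCatch(
        solve_transient(g, d, spec, damage = damage),
        error = function(e)
          stop(sprintf("sweep aborted at (preset=%s, q=%g, tau=%g ms, spot=%g mm): %s",
                       preset, d$q, d$tau_ms, d$spot_mm, conditionMessage(e)),
               call. = FALSE))
      nlast <- nrow(res$damage_trace)
      rec <- list(preset = preset, q = d$q, tau_ms = d$tau_ms, spot_mm = d$spot_mm,
                  peak_T_C = res$peak_T_C, t_peak_s = res$t_peak_s,
                  probe_z_mm = res$probe_z_mm,
                  times = res$times, T_center = res$T_center,
                  damage_trace = res$damage_trace,
                  final_fraction_scar = res$damage_trace$fraction_scar[nlast],
                  final_expected_scar = res$damage_trace$expected_scar[nlast],
                  final_expected_domain = res$damage_trace$expected_domain[nlast],
                  max_Omega = res$damage_trace$max_Omega[nlast],
                  burn_class = as.character(classify_burn(res$damage_trace$max_Omega[nlast],
                                                          damage)),
                  threshold_pass = res$peak_T_C <= 50)
      if (keep_results) rec$result <- res
      records[[length(records) + 1L]] <- rec
      if (verbose)
        message(sprintf("[sweep] %s q=%g tau=%gms spot=%gmm: peak %.2f C, expected scar fraction %.3g",
                        preset, d$q, d$tau_ms, d$spot_mm,
                        rec$peak_T_C, rec$final_expected_scar))
    }
  }
  structure(list(records = records, mode = mode,
                 axes = list(q = q, tau_ms = tau_ms, spot_mm = spot_mm),
                 presets = presets, resolution = resolution, spec = spec),
            class = "sweep_result")
}

#' Tabular summary of a dose sweep
#'
#' One row per candidate with all scalar outcomes and the temperature
#' constraint flag, in stable lexicographic order of
#' (preset, q, tau, spot).
#'
#' @param object a \code{sweep_result}.
#' @param ... unused.
#' @return data.frame.
#' @export
summary.sweep_result <- function(object, ...) {
  df <- do.call(rbind, lapply(object$records, function(r)
    data.frame(preset = r$preset, q = r$q, tau_ms = r$tau_ms,
               spot_mm = r$spot_mm, peak_T_C = r$peak_T_C,
               t_peak_s = r$t_peak_s, probe_z_mm = r$probe_z_mm,
               final_fraction_scar = r$final_fraction_scar,
               final_expected_scar = r$final_expected_scar,
               final_expected_domain = r$final_expected_domain,
               max_Omega = r$max_Omega, burn_class = r$burn_class,
               threshold_pass = r$threshold_pass)))
  df[order(df$preset, df$q, df$tau_ms, df$spot_mm), , drop = FALSE]
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d runs (%s mode) over presets: %s\n",
              length(x$records), x$mode, paste(x$presets, collapse = ", ")))
  print(utils::head(summary(x), 10))
  invisible(x)
}

#' Constrained optimal-dose selection
#'
#' Applies the dose-selection rule: among scar-preset candidates whose peak
#' probe temperature stays at or below the protein-denaturation threshold
#' (50 C by default), pick the dose maximising the final damaged fraction of
#' the scar. The default objective is the expected damaged fraction
#' \code{\link{expected_damage_fraction}}; the hard-thresholded
#' \code{\link{damaged_volume_fraction}} is available as an alternative
#' objective. Ties are broken toward lower q, then lower tau, then smaller
#' spot, and the tie-break is reported.
#'
#' @param sweep a \code{sweep_result} or its \code{summary} data.frame.
#' @param threshold_C peak-temperature constraint (C).
#' @param objective \code{"expected_fraction"} (default) or
#'   \code{"threshold_fraction"}.
#' @param preset which preset's candidates to select among.
#' @return An object of class \code{dose_verdict}: \code{admissible} flag
#'   per candidate, the chosen triple (or \code{NULL} with status
#'   \code{"no admissible dose"}), the objective value and a tie-break note.
#' @export
select_optimal <- function(sweep, threshold_C = 50,
                           objective = c("expected_fraction", "threshold_fraction"),
                           preset = "hps") {
  objective <- match.arg(objective)
  df <- if (inherits(sweep, "sweep_result")) summary(sweep) else as.data.frame(sweep)
  df <- df[df$preset == preset, , drop = FALSE]
  if (!nrow(df)) stop("no candidates for preset '", preset, "'")
  obj_col <- if (objective == "expected_fraction") "final_expected_scar"
             else "final_fraction_scar"
  df$admissible <- df$peak_T_C <= threshold_C
  df$objective <- df[[obj_col]]
  adm <- df[df$admissible, , drop = FALSE]
  if (!nrow(adm)) {
    return(structure(list(status = "no admissible dose", chosen = NULL,
                          threshold_C = threshold_C, objective = objective,
                          candidates = df),
                     class = "dose_verdict"))
  }
  best <- max(adm$objective)
  top <- adm[adm$objective >= best - .Machine$double.eps * max(1, abs(best)), ,
             drop = FALSE]
  top <- top[order(top$q, top$tau_ms, top$spot_mm), , drop = FALSE]
  chosen <- top[1, ]
  structure(list(
    status = "ok",
    chosen = list(q = chosen$q, tau_ms = chosen$tau_ms, spot_mm = chosen$spot_mm,
                  objective = chosen$objective, peak_T_C = chosen$peak_T_C),
    threshold_C = threshold_C, objective = objective,
    tie_break = if (nrow(top) > 1)
      sprintf("%d candidates tied at objective %.6g; broke toward lower q, tau, spot",
              nrow(top), best) else "unique maximum",
    candidates = df), class = "dose_verdict")
}

#' @export
print.dose_verdict <- function(x, ...) {
  cat("<dose_verdict>", x$status, "\n")
  if (identical(x$status, "ok"))
    cat(sprintf("  chosen: q = %g, tau = %g ms, spot = %g mm (objective %.4g, peak %.2f C <= %g C)\n  %s\n",
                x$chosen$q, x$chosen$tau_ms, x$chosen$spot_mm,
                x$chosen$objective, x$chosen$peak_T_C, x$threshold_C,
                x$tie_break))
  invisible(x)
}
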