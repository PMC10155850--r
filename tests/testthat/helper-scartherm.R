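# Small grids and short horizons for fast tests; physics unchanged.
coarse_grid <- function(preset = "hps", dr = 0.5, dz = 0.05, ...)
  suppressWarnings(build_domain(preset, dr = dr, dz = dz, ...))

fast_spec <- function(t_end = 0.25, ...) solver_spec(t_end = t_end, ...)

ref_dose <- function(q = 7.5, tau = 4, spot = 7) dose_params(q, tau, spot)
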