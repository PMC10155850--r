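# Property tests run on a deliberately coarse grid and short horizon: the
# orderings they check are resolution-robust, and the full working-resolution
# dose study is exercised separately.
sweep_spec <- function() solver_spec(t_end = 0.2)

test_that("peak temperature rises with energy density and damage with spot size", {
  sw <- run_sweep(presets = "hps", q = c(4, 7.5, 10), tau_ms = 4, spot_mm = 7,
                  spec = sweep_spec(), resolution = c(0.5, 0.05))
  s <- summary(sw)
  expect_true(all(diff(s$peak_T_C[order(s$q)]) > 0))
  expect_true(all(diff(s$final_expected_scar[order(s$q)]) > 0))

  sw2 <- run_sweep(presets = "hps", q = 7.5, tau_ms = 4, spot_mm = c(5, 6, 7),
                   spec = sweep_spec(), resolution = c(0.5, 0.05))
  s2 <- summary(sw2)
  expect_true(all(diff(s2$final_expected_scar[order(s2$spot_mm)]) > 0))
})

test_that("long pulses damage less than the reference pulse width", {
  sw <- run_sweep(presets = "hps", q = 7.5, tau_ms = c(4, 10), spot_mm = 7,
                  spec = sweep_spec(), resolution = c(0.5, 0.05))
  s <- summary(sw)
  expect_gt(s$final_expected_scar[s$tau_ms == 4],
            s$final_expected_scar[s$tau_ms == 10])
  expect_gt(s$peak_T_C[s$tau_ms == 4], s$peak_T_C[s$tau_ms == 10])
})

test_that("scar heats more than normal skin at every shared dose", {
  sw <- suppressWarnings(
    run_sweep(presets = c("hps", "normal_skin"), q = c(4, 10), tau_ms = 4,
              spot_mm = 7, spec = sweep_spec(), resolution = c(0.5, 0.05)))
  s <- summary(sw)
  for (qq in c(4, 10)) {
    expect_gt(s$peak_T_C[s$preset == "hps" & s$q == qq],
              s$peak_T_C[s$preset == "normal_skin" & s$q == qq])
  }
})

test_that("normal skin is far less dose-sensitive than scar", {
  sw <- suppressWarnings(
    run_sweep(presets = c("hps", "normal_skin"), q = c(4, 7.5, 10),
              tau_ms = 4, spot_mm = 7,
              spec = sweep_spec(), resolution = c(0.5, 0.05)))
  s <- summary(sw)
  rng <- function(p) diff(range(s$max_Omega[s$preset == p]))
  expect_gt(rng("hps") / rng("normal_skin"), 1)
  # temperature ranges tell the same story
  trng <- function(p) diff(range(s$peak_T_C[s$preset == p]))
  expect_gt(trng("hps") / trng("normal_skin"), 1)
})

test_that("sweep bookkeeping: row counts, stable order, determinism", {
  sw <- suppressWarnings(
    run_sweep(presets = "hps", q = c(7.5, 4), tau_ms = 4, spot_mm = c(7, 5),
              spec = sweep_spec(), resolution = c(1, 0.1)))
  s <- summary(sw)
  expect_equal(nrow(s), 4)  # |presets| x |grid|
  expect_false(is.unsorted(s$q))
  # identical config => identical output
  sw2 <- suppressWarnings(
    run_sweep(presets = "hps", q = c(7.5, 4), tau_ms = 4, spot_mm = c(7, 5),
              spec = sweep_spec(), resolution = c(1, 0.1)))
  expect_identical(summary(sw2), s)
  # one-factor mode covers each axis around the reference
  swf <- suppressWarnings(
    run_sweep(presets = "hps", q = c(4, 7.5), tau_ms = c(4, 10),
              spot_mm = 7, mode = "one_factor",
              spec = sweep_spec(), resolution = c(1, 0.1)))
  expect_equal(nrow(summary(swf)), 3)  # 2 q-values + tau=10 (+dedup of reference)
  expect_error(run_sweep(presets = "hps", q = numeric(0)), "empty")
})

test_that("selection maximises damage under the temperature constraint", {
  df <- data.frame(
    preset = "hps", q = c(4, 7.5, 10), tau_ms = 4, spot_mm = 7,
    peak_T_C = c(43, 48, 52),
    final_fraction_scar = 0,
    final_expected_scar = c(1e-7, 3e-7, 9e-7))
  v <- select_optimal(df, threshold_C = 50)
  expect_equal(v$status, "ok")
  expect_equal(v$chosen$q, 7.5)   # q = 10 violates the 50 C constraint
  # brute-force re-scan reproduces the verdict
  adm <- df[df$peak_T_C <= 50, ]
  expect_equal(v$chosen$objective, max(adm$final_expected_scar))
  # threshold below every peak: explicit no-admissible verdict, not an error
  v2 <- select_optimal(df, threshold_C = 40)
  expect_equal(v2$status, "no admissible dose")
  expect_null(v2$chosen)
  # single admissible candidate is chosen
  v3 <- select_optimal(df[2, ], threshold_C = 50)
  expect_equal(v3$chosen$q, 7.5)
})

test_that("ties break toward lower q, then tau, then spot", {
  df <- data.frame(
    preset = "hps",
    q = c(10, 4, 4), tau_ms = c(4, 10, 4), spot_mm = c(7, 7, 7),
    peak_T_C = 45, final_fraction_scar = 0, final_expected_scar = 5e-7)
  v <- select_optimal(df)
  expect_equal(v$chosen$q, 4)
  expect_equal(v$chosen$tau_ms, 4)
  expect_match(v$tie_break, "tied")
})

test_that("a failing run aborts the sweep naming the offending dose", {
  suppressWarnings(expect_error(
    run_sweep(presets = "hps", q = 1e7, tau_ms = 4, spot_mm = 7,
              spec = sweep_spec(), resolution = c(1, 0.1)),
    "q=1e\\+07"))
})
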