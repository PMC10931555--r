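test_that("a pure linear baseline corrects to zero", {
  Tg <- seq(2, 40, by = 0.1)
  tg <- thermogram(Tg, 0.3 + 0.01 * Tg)
  cor <- baseline_correct(tg, c(2, 8), c(36, 40))
  expect_lt(max(abs(cor$cp_excess)), 1e-12)
})

test_that("the generating baseline slope is recovered within 5%", {
  tg <- gen_thermogram(endotherm_params(baseline_intercept = 0.05,
                                        baseline_slope = 0.002))
  cor <- baseline_correct(tg, c(2, 8), c(36, 40))
  expect_equal(cor$meta$baseline$slope, 0.002, tolerance = 0.05)
  expect_equal(cor$meta$baseline$intercept, 0.05, tolerance = 0.05)
})

test_that("correction bias on the enthalpy is below 2% for the surfactant
           transition with standard windows", {
  tg <- gen_thermogram(endotherm_params())
  cor <- baseline_correct(tg, c(2, 8), c(36, 40))
  dH <- pracma::trapz(cor$T, cor$cp_excess)
  expect_lt(abs(dH - 18) / 18, 0.02)
})

test_that("windows overlapping the peak are rejected", {
  tg <- gen_thermogram(endotherm_params(noise_level = 0.002, seed = 5))
  expect_error(baseline_correct(tg, c(2, 8), c(26, 32)), "overlaps")
  expect_error(baseline_correct(tg, c(2, 2.1), c(36, 40)), "fewer than 5")
})

test_that("transition parameters of a symmetric Gaussian endotherm are
           recovered to stated precision", {
  p <- endotherm_params(asymmetry = 0, flank_exponent = 2,
                        T_grid = seq(0, 56.2, by = 0.05))
  tp <- transition_params(gen_thermogram(p))
  expect_equal(tp$Tm, 28.1, tolerance = 0.05)
  expect_equal(tp$dH, 18.0, tolerance = 18 * 0.005)
  expect_equal(tp$fwhm, 12.5, tolerance = 0.1)
})

test_that("a unit triangle peak gives the closed-form parameters", {
  Tg <- seq(-2, 2, by = 0.01)
  cp <- pmax(1 - abs(Tg), 0)  # area 1, apex 0, half base 1
  tp <- transition_params(thermogram(Tg, cp), smooth_n = 5L)
  expect_equal(tp$Tm, 0, tolerance = 0.02)
  expect_equal(tp$dH, 1, tolerance = 1e-3)
  expect_equal(tp$fwhm, 1, tolerance = 0.02)
})

test_that("Tm of a skewed endotherm equals the brute-force argmax of the
           dense noise-free curve", {
  p <- endotherm_params(asymmetry = -1.5, T_grid = seq(2, 40, by = 0.02))
  pk <- surfbiophys:::endotherm_peak(p$T_grid, p)
  oracle <- oracle_mode_fwhm(p$T_grid, pk)
  tp <- transition_params(gen_thermogram(p))
  expect_equal(tp$Tm, oracle$mode, tolerance = 0.05)
})

test_that("enthalpy is invariant under added linear baselines", {
  tg0 <- gen_thermogram(endotherm_params())
  dH0 <- transition_params(baseline_correct(tg0))$dH
  for (b in list(c(0.2, 0), c(-0.1, 0.004), c(1, -0.01))) {
    tg <- tg0
    tg$cp_excess <- tg0$cp_excess + b[1] + b[2] * tg0$T
    dH <- transition_params(baseline_correct(tg))$dH
    expect_lt(abs(dH - dH0) / dH0, 0.005)
  }
})

test_that("enthalpy converges under grid refinement and Tm is invariant
           under intensity rescaling", {
  dHs <- vapply(c(0.2, 0.1, 0.05), function(step) {
    tp <- transition_params(gen_thermogram(
      endotherm_params(T_grid = seq(2, 40, by = step))))
    tp$dH
  }, numeric(1))
  expect_lt(abs(dHs[3] - dHs[2]), abs(dHs[2] - dHs[1]) + 1e-9)
  expect_lt(max(abs(dHs - 18)) / 18, 0.005)

  tg <- gen_thermogram(endotherm_params(noise_level = 0.002, seed = 9))
  cor <- baseline_correct(tg)
  tp1 <- transition_params(cor)
  cor$cp_excess <- cor$cp_excess * 12
  tp2 <- transition_params(cor)
  expect_equal(tp2$Tm, tp1$Tm, tolerance = 1e-9)
})

test_that("mean Tm over 100 noisy replicates is within 0.1 degC of truth", {
  # smoothing over ~2 degC is appropriate for a 12.5 degC-wide transition
  Tms <- vapply(1:100, function(s) {
    tg <- gen_thermogram(endotherm_params(noise_level = 0.002, seed = s,
                                          baseline_intercept = 0.05,
                                          baseline_slope = 0.002))
    transition_params(baseline_correct(tg), smooth_n = 41L)$Tm
  }, numeric(1))
  expect_lt(abs(mean(Tms) - 28.1), 0.1)
})

test_that("cooling-like scans (no positive peak) are rejected", {
  Tg <- seq(2, 40, by = 0.05)
  tg <- thermogram(Tg, -surfbiophys:::endotherm_peak(
    Tg, endotherm_params()))
  expect_error(transition_params(tg), "no positive")
})

test_that("scan averaging reports means and SDs and rejects mixed
           directions", {
  r <- function(Tm, dH, fwhm, dir = "heating") {
    list(Tm = Tm, dH = dH, fwhm = fwhm, direction = dir)
  }
  dup <- average_scans(list(r(28.1, 18, 12.5), r(28.1, 18, 12.5)))
  expect_identical(dup$Tm, 28.1)
  expect_identical(dup$Tm_sd, 0)
  two <- average_scans(list(r(28.0, 18, 12.5), r(28.2, 18, 12.5)))
  expect_equal(two$Tm, 28.1)
  expect_equal(two$Tm_sd, 0.1414, tolerance = 1e-3)
  expect_error(average_scans(list(r(28, 18, 12), r(28, 18, 12, "cooling"))),
               "mixed")
  expect_error(average_scans(list(r(28, 18, 12))), "at least 2")
})

test_that("averaging noisy replicates recovers the generating Tm", {
  results <- lapply(1:10, function(s) {
    tg <- gen_thermogram(endotherm_params(noise_level = 0.002, seed = s))
    transition_params(baseline_correct(tg), smooth_n = 41L)
  })
  avg <- average_scans(results)
  expect_lt(abs(avg$Tm - 28.1), 0.2)
  expect_lt(abs(avg$dH - 18) / 18, 0.01)
})
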