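test_that("guinier sheet evaluates the closed form exactly", {
  # thickness sqrt(12) gives Rg = 1, so I(1) = exp(-1) with C = 1, B = 0
  p <- sans_model_params(model_kind = "guinier_sheet",
                         thickness_true = sqrt(12), scale_C = 1,
                         background_B = 0, q_grid = c(0.5, 1, 2))
  crv <- gen_sans_curve(p)
  expect_equal(crv$I[2], exp(-1), tolerance = 1e-12)
  expect_equal(crv$I, exp(-crv$q^2) / crv$q^2, tolerance = 1e-12)
})

test_that("noise-free unsmeared generation equals the model pointwise", {
  q <- seq(0.1, 4, length.out = 120)
  for (kind in c("guinier_sheet", "uniform_slab", "core_shell_vesicle")) {
    p <- sans_model_params(model_kind = kind, thickness_true = 4,
                           scale_C = 2.5, background_B = 0.03, q_grid = q)
    crv <- gen_sans_curve(p)
    expect_identical(crv$I,
                     surfbiophys:::sans_model_intensity(q, p) + 0.03,
                     info = kind)
  }
})

test_that("uniform slab matches a numerical Fourier-transform oracle", {
  q <- seq(0.31, 1.14, length.out = 40)
  p <- sans_model_params(model_kind = "uniform_slab", thickness_true = 4,
                         scale_C = 1, background_B = 0, q_grid = q)
  crv <- gen_sans_curve(p)
  oracle <- oracle_slab_intensity(q, L = 4)
  expect_lt(max(abs(crv$I - oracle) / oracle), 1e-3)
})

test_that("wavelength-spread smearing matches adaptive quadrature and is the
           identity at zero spread", {
  q <- c(0.3, 0.8, 1.5, 3)
  p <- sans_model_params(thickness_true = 3.88, q_grid = q)
  f <- function(qq) surfbiophys:::sans_model_intensity(qq, p)
  expect_identical(surfbiophys:::smear_model(f, q, 0), f(q))
  sm <- surfbiophys:::smear_model(f, q, 0.10)
  expect_equal(sm, oracle_smear(f, q, 0.10), tolerance = 1e-4)
  expect_false(any(sm == f(q)))
})

test_that("Kratky-Porod representation of a noise-free guinier sheet is
           exactly linear with slope -Rg^2", {
  p <- sans_model_params(thickness_true = 3.88, scale_C = 3,
                         background_B = 0.1)
  crv <- gen_sans_curve(p)
  # inside the thin-sheet window, where the coherent term dominates the
  # subtracted constant (outside it, I - B is pure cancellation noise)
  sel <- crv$q >= 0.31 & crv$q <= 1.14
  x <- crv$q[sel]^2
  y <- log((crv$I[sel] - 0.1) * x)
  fit <- lm(y ~ x)
  Rg <- 3.88 / sqrt(12)
  expect_equal(unname(coef(fit)[2]), -Rg^2, tolerance = 1e-9)
  expect_equal(cor(x, y)^2, 1, tolerance = 1e-10)
})

test_that("lamellar generator puts diffraction orders at 2 pi n / d", {
  crv <- gen_saxs_waxs_pattern(lamellar_model_params(d_true = 7.8,
                                                     n_orders = 2))
  qs <- crv$q[crv$q < 5]
  Is <- crv$I[crv$q < 5]
  i1 <- which.max(Is)
  expect_equal(qs[i1], 2 * pi / 7.8, tolerance = 2e-3)  # 0.8055 nm^-1
  second <- abs(qs - 2 * pi * 2 / 7.8) < 0.1
  i2 <- which(second)[which.max(Is[second])]
  expect_equal(qs[i2], 2 * pi * 2 / 7.8, tolerance = 2e-3)  # 1.6111 nm^-1
})

test_that("noise-free WAXS band without crystalline peaks has exactly one
           local maximum", {
  crv <- gen_saxs_waxs_pattern(lamellar_model_params())
  Iw <- crv$I[crv$q >= 10]
  n <- length(Iw)
  n_max <- sum(Iw[2:(n - 1)] > Iw[1:(n - 2)] & Iw[2:(n - 1)] > Iw[3:n])
  expect_identical(n_max, 1L)
})

test_that("symmetric Gaussian endotherm has the analytic height and width", {
  p <- endotherm_params(asymmetry = 0, flank_exponent = 2,
                        T_grid = seq(0, 56.2, by = 0.05))
  tg <- gen_thermogram(p)
  sigma <- 12.5 / 2.3548
  expect_equal(max(tg$cp_excess), 18 / (sigma * sqrt(2 * pi)),
               tolerance = 1e-4)
  expect_equal(tg$T[which.max(tg$cp_excess)], 28.1, tolerance = 0.051)
  expect_equal(pracma::trapz(tg$T, tg$cp_excess), 18, tolerance = 1e-3)
})

test_that("endotherm area equals dH for any asymmetry in [-2, 2]", {
  for (a in seq(-2, 2, by = 0.5)) {
    p <- endotherm_params(asymmetry = a, T_grid = seq(-50, 110, by = 0.05))
    pk <- surfbiophys:::endotherm_peak(p$T_grid, p)
    expect_equal(pracma::trapz(p$T_grid, pk), 18, tolerance = 0.005,
                 info = paste("asymmetry", a))
  }
})

test_that("numerical mode and FWHM of an asymmetric endotherm equal the
           ground truth within grid resolution", {
  p <- endotherm_params(Tm_true = 28.1, fwhm_true = 12.5, asymmetry = -1,
                        T_grid = seq(2, 40, by = 0.01))
  pk <- surfbiophys:::endotherm_peak(p$T_grid, p)
  o <- oracle_mode_fwhm(p$T_grid, pk)
  expect_equal(o$mode, 28.1, tolerance = 0.011)
  expect_equal(o$fwhm, 12.5, tolerance = 0.011)
})

test_that("a tiny-enthalpy endotherm conserves its area", {
  p <- endotherm_params(dH_true = 1e-6)
  tg <- gen_thermogram(p)
  expect_equal(pracma::trapz(tg$T, tg$cp_excess), 1e-6, tolerance = 0.005)
})

test_that("grids that truncate the endotherm are rejected", {
  expect_error(gen_thermogram(endotherm_params(T_grid = seq(20, 30, 0.05))),
               "truncates")
  expect_error(endotherm_params(dH_true = 0), "dH_true")
  expect_error(endotherm_params(fwhm_true = -1), "fwhm_true")
})

test_that("noise-free fluorescence traces are constant with exact ratio", {
  out <- gen_fluorescence(fluorescence_params(eta_true = 1))
  expect_true(all(out$monomer$I == out$monomer$I[1]))
  expect_identical(out$monomer$I, out$excimer$I)
  out2 <- gen_fluorescence(fluorescence_params(eta_true = 1.13))
  expect_equal(mean(out2$excimer$I) / mean(out2$monomer$I), 1.13,
               tolerance = 1e-12)
})

test_that("noise-free spectrum satisfies the excimer/monomer contract", {
  out <- gen_fluorescence(fluorescence_params(eta_true = 1.87))
  sp <- out$spectrum
  I376 <- sp$I[sp$wavelength == 376]
  I480 <- sp$I[sp$wavelength == 480]
  expect_equal(I480 / I376, 1.87, tolerance = 1e-10)
  # band I is the global maximum of the monomer progression
  mono <- sp$wavelength < 430
  expect_equal(sp$wavelength[mono][which.max(sp$I[mono])], 376)
})

test_that("noisy trace ratio is unbiased: mean over seeds within 3 SEM", {
  etas <- vapply(1:300, function(s) {
    out <- gen_fluorescence(fluorescence_params(eta_true = 1.13,
                                                noise_level = 0.02,
                                                seed = s))
    mean(out$excimer$I) / mean(out$monomer$I)
  }, numeric(1))
  sem <- sd(etas) / sqrt(length(etas))
  expect_lt(abs(mean(etas) - 1.13), 3 * sem)
})

test_that("equal seeds are bit-identical and different seeds differ", {
  a <- gen_sans_curve(sans_model_params(noise_level = 0.02, seed = 7))
  b <- gen_sans_curve(sans_model_params(noise_level = 0.02, seed = 7))
  c <- gen_sans_curve(sans_model_params(noise_level = 0.02, seed = 8))
  expect_identical(a$I, b$I)
  expect_false(identical(a$I, c$I))

  d1 <- gen_thermogram(endotherm_params(noise_level = 0.01, seed = 3))
  d2 <- gen_thermogram(endotherm_params(noise_level = 0.01, seed = 3))
  d3 <- gen_thermogram(endotherm_params(noise_level = 0.01, seed = 4))
  expect_identical(d1$cp_excess, d2$cp_excess)
  expect_false(identical(d1$cp_excess, d3$cp_excess))

  f1 <- gen_fluorescence(fluorescence_params(noise_level = 0.05, seed = 1))
  f2 <- gen_fluorescence(fluorescence_params(noise_level = 0.05, seed = 1))
  expect_identical(f1$monomer$I, f2$monomer$I)
})

test_that("generator parameter validation rejects degenerate inputs", {
  expect_error(sans_model_params(thickness_true = -1), "thickness")
  expect_error(sans_model_params(q_grid = c(0, 1, 2)), "positive")
  expect_error(sans_model_params(q_grid = c(2, 1)), "increasing")
  expect_error(lamellar_model_params(peak_widths = 0), "widths")
  expect_error(lamellar_model_params(n_orders = 0), "n_orders")
  expect_error(fluorescence_params(eta_true = 0), "eta_true")
})
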