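test_that("a constant offset is recovered from the high-q tail", {
  # model term below 1% of the constant in the tail window
  p <- sans_model_params(thickness_true = 3.88, scale_C = 1,
                         background_B = 0.07)
  crv <- gen_sans_curve(p)
  tail_model <- surfbiophys:::sans_model_intensity(c(4, 5), p)
  expect_true(all(tail_model < 0.01 * 0.07))
  sub <- subtract_incoherent_background(crv, c(4, 5))
  expect_equal(sub$meta$background_subtracted, 0.07, tolerance = 0.02)
})

test_that("with zero true background the subtracted constant equals the mean
           model value in the tail (documented small bias)", {
  p <- sans_model_params(thickness_true = 3.88, background_B = 0)
  crv <- gen_sans_curve(p)
  sub <- subtract_incoherent_background(crv, c(4, 5))
  sel <- crv$q >= 4 & crv$q <= 5
  bias <- mean(surfbiophys:::sans_model_intensity(crv$q[sel], p))
  expect_equal(sub$meta$background_subtracted, bias, tolerance = 1e-12)
  expect_lt(bias, 1e-10)  # negligible for a ~4 nm bilayer
})

test_that("noisy background recovery is unbiased over 100 seeds", {
  vals <- vapply(1:100, function(s) {
    crv <- gen_sans_curve(sans_model_params(background_B = 0.05,
                                            noise_level = 0.02, seed = s))
    subtract_incoherent_background(crv, c(4, 5))$meta$background_subtracted
  }, numeric(1))
  expect_lt(abs(mean(vals) - 0.05), 3 * sd(vals) / sqrt(length(vals)))
})

test_that("tail-window contract is enforced", {
  crv <- gen_sans_curve(sans_model_params(q_grid = seq(0.1, 2, 0.01)))
  expect_error(subtract_incoherent_background(crv, c(4, 5)), "outside")
  expect_error(subtract_incoherent_background(crv, c(1.99, 2)),
               "at least 5")
})

test_that("noise-free Kratky-Porod fit is exact", {
  crv <- gen_sans_curve(sans_model_params(thickness_true = sqrt(12)))
  fit <- kratky_porod_fit(subtract_incoherent_background(crv))
  expect_equal(fit$d_g, sqrt(12), tolerance = 1e-6)
  expect_equal(fit$Rg, 1, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_true(fit$conforming)
})

test_that("the surfactant bilayer thickness round-trips exactly", {
  crv <- gen_sans_curve(sans_model_params(thickness_true = 3.88))
  fit <- kratky_porod_fit(subtract_incoherent_background(crv))
  expect_equal(fit$d_g, 3.88, tolerance = 1e-6)
})

test_that("slab fit over the standard window matches an independent OLS
           oracle on the exact slab curve (Guinier bias quantified)", {
  q <- seq(0.2, 5, by = 0.005)
  p <- sans_model_params(model_kind = "uniform_slab", thickness_true = 4,
                         q_grid = q)
  crv <- gen_sans_curve(p)
  fit <- kratky_porod_fit(crv)
  oracle <- oracle_kp_dg(q, oracle_slab_intensity(q, L = 4))
  expect_equal(fit$d_g, oracle, tolerance = 1e-3)
  # and the bias relative to the true 4 nm is real but bounded (~12% here,
  # since q Rg reaches 1.3 over the standard window)
  expect_gt(abs(fit$d_g - 4), 0.01)
  expect_lt(abs(fit$d_g - 4) / 4, 0.20)
})

test_that("restricting the window to q Rg <= 0.5 recovers L / sqrt(12)
           within 2% for a slab", {
  L <- 4
  Rg <- L / sqrt(12)
  q <- seq(0.05, 5, by = 0.002)
  crv <- gen_sans_curve(sans_model_params(model_kind = "uniform_slab",
                                          thickness_true = L, q_grid = q))
  fit <- kratky_porod_fit(crv, q_window = c(0.06, 0.5 / Rg))
  expect_equal(fit$Rg, Rg, tolerance = 0.02)
})

test_that("d_g = sqrt(12) Rg identity and scale invariance hold", {
  for (s in 1:5) {
    crv <- gen_sans_curve(sans_model_params(thickness_true = 3 + s / 2,
                                            noise_level = 0.01, seed = s,
                                            background_B = 0.02))
    sub <- subtract_incoherent_background(crv)
    fit <- kratky_porod_fit(sub)
    expect_identical(fit$d_g, sqrt(12) * fit$Rg)

    scaled <- sub
    scaled$I <- sub$I * 37.5
    fit2 <- kratky_porod_fit(scaled)
    expect_equal(fit2$Rg, fit$Rg, tolerance = 1e-12)
    expect_equal(fit2$d_g, fit$d_g, tolerance = 1e-12)
    expect_equal(fit2$r2, fit$r2, tolerance = 1e-12)
    expect_equal(fit2$intercept - fit$intercept, log(37.5),
                 tolerance = 1e-9)
  }
})

test_that("noisy parameter recovery: mean d_g within 1% and ~2 SD coverage
           of at least 90% over 100 seeds", {
  # sigma-weighted regression: counting noise is strongly heteroscedastic
  # on the log scale, so the weighted fit is the one whose standard errors
  # are interpretable
  truth <- 3.88
  res <- vapply(1:100, function(s) {
    crv <- gen_sans_curve(sans_model_params(thickness_true = truth,
                                            background_B = 0.05,
                                            noise_level = 0.02, seed = s))
    fit <- kratky_porod_fit(subtract_incoherent_background(crv),
                            weighted = TRUE)
    c(fit$d_g, fit$d_g_sd)
  }, numeric(2))
  expect_lt(abs(mean(res[1, ]) - truth) / truth, 0.01)
  covered <- abs(res[1, ] - truth) <= 2 * res[2, ]
  expect_gte(mean(covered), 0.90)
})

test_that("fit errors are informative for degenerate inputs", {
  crv <- gen_sans_curve(sans_model_params(thickness_true = 3.88,
                                          background_B = 0))
  over <- crv
  over$I <- crv$I - 2 * min(crv$I[crv$q >= 0.31 & crv$q <= 1.14])
  expect_error(kratky_porod_fit(over), "non-positive")

  flat <- scattering_curve(q = seq(0.3, 1.2, 0.05),
                           I = rep(1, 19), modality = "SANS")
  expect_error(kratky_porod_fit(flat), "slope|regime")

  few <- scattering_curve(q = c(0.4, 0.5, 0.6), I = c(3, 2, 1))
  expect_error(kratky_porod_fit(few), "6 points")
})

test_that("Guinier validity diagnostic flags q Rg > 1", {
  mk <- function(Rg, qmax) {
    structure(list(Rg = Rg, qRg_max = qmax * Rg),
              class = "kratky_porod_result")
  }
  expect_true(guinier_validity(mk(1.12, 1.14))$flag)
  expect_equal(guinier_validity(mk(1.12, 1.14))$qRg_max, 1.2768)
  expect_false(guinier_validity(mk(0.5, 1.14))$flag)
  expect_false(guinier_validity(mk(1 / 1.14 * (1 - 1e-9), 1.14))$flag)
  expect_true(guinier_validity(mk(1 / 1.14 * (1 + 1e-9), 1.14))$flag)
})

test_that("sigma-weighted fit agrees with OLS on homoscedastic data", {
  crv <- gen_sans_curve(sans_model_params(thickness_true = 3.88,
                                          noise_level = 0.005, seed = 11,
                                          background_B = 0.02))
  sub <- subtract_incoherent_background(crv)
  f1 <- kratky_porod_fit(sub)
  f2 <- kratky_porod_fit(sub, weighted = TRUE)
  expect_equal(f2$d_g, f1$d_g, tolerance = 0.01)
})
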