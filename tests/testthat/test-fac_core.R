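# Expected retardations computed independently by explicit unit tracking:
# Bt [nmol] / ((Kd + A0) [mol/L] * 1e3) = Bt / (Kd + A0 in mmol/L) = uL.
# 0.63 / ((3.01e-5 + 2.5e-9) * 1e3) = 20.9285 uL (PPL3s column ligand)
# 0.98 / ((2.0e-5 + 2.5e-9) * 1e3) = 48.9939 uL (PPL4 column ligand)

test_that("forward retardation model matches hand unit-conversion arithmetic", {
  expect_equal(retardation_forward(0.63, 3.01e-5, 2.5e-9), 20.93,
               tolerance = 1e-3)
  expect_equal(retardation_forward(0.98, 2.0e-5, 2.5e-9), 48.99,
               tolerance = 1e-3)
  expect_identical(retardation_forward(0, 1e-5, 2.5e-9), 0)
  # dimensional sanity: 1 nmol / 1000 uL = 1 uM
  expect_equal(kd_simplified(1, 1000), 1e-6)
})

test_that("forward model is monotone in each argument", {
  expect_true(retardation_forward(0.63, 3.01e-5, 2.5e-9) >
                retardation_forward(0.63, 3.02e-5, 2.5e-9))
  expect_true(retardation_forward(0.63, 3.01e-5, 2.5e-9) >
                retardation_forward(0.63, 3.01e-5, 2.5e-8))
  expect_true(retardation_forward(0.64, 3.01e-5, 2.5e-9) >
                retardation_forward(0.63, 3.01e-5, 2.5e-9))
})

test_that("Kd inversion closes the round trip to 1e-9 over a log grid", {
  expect_equal(kd_from_retardation(0.63, 20.93, 2.5e-9), 3.01e-5,
               tolerance = 1e-4)
  expect_equal(kd_from_retardation(0.02, 98.77, 2.5e-9), 2.0e-7,
               tolerance = 1e-3)
  grid <- expand.grid(Bt = 10^seq(-3, 1, length.out = 5),
                      Kd = 10^seq(-8, -3, length.out = 6))
  for (i in seq_len(nrow(grid))) {
    v <- retardation_forward(grid$Bt[i], grid$Kd[i], 2.5e-9)
    expect_equal(kd_from_retardation(grid$Bt[i], v, 2.5e-9), grid$Kd[i],
                 tolerance = 1e-9)
  }
})

test_that("below-detection and noise-inverted measurements map to NA", {
  expect_true(is.na(kd_from_retardation(0.63, 0, 2.5e-9)))
  expect_true(is.na(kd_simplified(0.63, -1)))
  # retardation beyond the Bt/[A]0 limit implies Kd <= 0 under the model
  expect_warning(res <- kd_from_retardation(0.02, 1e7, 2.5e-9),
                 "non-positive Kd")
  expect_true(is.na(res))
})

test_that("simplified Kd deviates from the full equation by exactly A0/Kd", {
  for (Kd in c(2e-7, 2e-5, 3.01e-5)) {
    A0 <- 2.5e-9
    v <- retardation_forward(0.63, Kd, A0)
    rel <- (kd_simplified(0.63, v) - kd_from_retardation(0.63, v, A0)) / Kd
    expect_equal(rel, A0 / Kd, tolerance = 1e-9)
    expect_lt(rel, 0.013)  # negligible-analyte regime at 2.5 nM loading
  }
})

test_that("Ka is the reciprocal dissociation constant", {
  expect_equal(ka_from_kd(2.0e-7), 5.0e6)
  expect_equal(ka_from_kd(3.01e-5), 3.32e4, tolerance = 1e-3)
  expect_error(ka_from_kd(0), class = "fac_validation_error")
})

test_that("Woolf-Hofstee fit recovers generating parameters from noiseless series", {
  for (truth in list(c(Bt = 0.63, Kd = 3.01e-5), c(Bt = 0.98, Kd = 2.0e-5),
                     c(Bt = 0.02, Kd = 2.0e-7))) {
    pts <- simulate_calibration_series(truth[["Bt"]], truth[["Kd"]])
    cal <- woolf_hofstee_fit(pts)
    expect_equal(cal$Kd_ref, truth[["Kd"]], tolerance = 1e-6)
    expect_equal(cal$Bt, truth[["Bt"]], tolerance = 1e-6)
    expect_equal(cal$r2, 1, tolerance = 1e-9)
  }
})

test_that("Woolf-Hofstee fit rejects degenerate and non-saturable designs", {
  pts <- data.frame(A0 = rep(3e-5, 3), v_minus_v0 = rep(10, 3))
  expect_error(woolf_hofstee_fit(pts), "insufficient|degenerate|distinct",
               class = "fac_validation_error")
  expect_error(woolf_hofstee_fit(data.frame(A0 = c(1e-5, 2e-5),
                                            v_minus_v0 = c(10, 9))),
               class = "fac_validation_error")
  # retardation increasing with A0: positive slope, no saturable binding
  up <- data.frame(A0 = c(1e-5, 3e-5, 1e-4), v_minus_v0 = c(5, 10, 20))
  expect_error(woolf_hofstee_fit(up), "no saturable binding",
               class = "fac_fit_error")
})

test_that("calibration estimator tolerates 2% multiplicative noise", {
  kds <- vapply(1:500, function(s) {
    pts <- simulate_calibration_series(0.63, 3.01e-5, noise_cv = 0.02,
                                       seed = s)
    woolf_hofstee_fit(pts)$Kd_ref
  }, numeric(1))
  expect_lt(median(abs(kds - 3.01e-5) / 3.01e-5), 0.10)
})

test_that("nonlinear refit agrees with the linearized estimator on clean data", {
  pts <- simulate_calibration_series(0.98, 2.0e-5)
  refit <- woolf_hofstee_refit_nls(pts)
  expect_equal(refit$Kd, 2.0e-5, tolerance = 1e-6)
  expect_equal(refit$Bt, 0.98, tolerance = 1e-6)
})

test_that("cylindrical bed volume follows pi r^2 L in uL", {
  expect_equal(bed_volume(2, 10), pi * 10, tolerance = 1e-12)
})
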