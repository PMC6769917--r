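test_that("MIC picks the lowest concentration of the inhibiting block", {
  # 250 mM start, wells 0-5 inhibiting: 250/2^5 = 7.8125 mM, shown as 7.8
  s <- dilution_series(250, c(rep(TRUE, 6), rep(FALSE, 2)))
  m <- mic(s)
  expect_equal(m$value, 7.8125)
  expect_false(m$censored)
  expect_identical(format(m, sigfigs = 2), "7.8")
  # 200 mM start, wells 0-5: 6.25 mM
  m2 <- mic(dilution_series(200, c(rep(TRUE, 6), rep(FALSE, 2))))
  expect_equal(m2$value, 6.25)
  expect_identical(format(m2), "6.25")
  # 200 mM start, wells 0-4: 12.5 mM
  m3 <- mic(dilution_series(200, c(rep(TRUE, 5), rep(FALSE, 3))))
  expect_equal(m3$value, 12.5)
})

test_that("a non-inhibiting starting well censors the MIC at the ceiling", {
  m <- mic(dilution_series(250, rep(FALSE, 8)))
  expect_true(m$censored)
  expect_equal(m$value, 250)
  expect_identical(format(m), ">250")
})

test_that("MIC is invariant to appended non-inhibiting wells and grid shifts", {
  base <- mic(dilution_series(250, c(rep(TRUE, 6), rep(FALSE, 2))))
  extended <- mic(dilution_series(250, c(rep(TRUE, 6), rep(FALSE, 6))))
  expect_equal(extended$value, base$value)
  # halving the start with outcomes shifted one well leaves the MIC unchanged
  shifted <- mic(dilution_series(125, c(rep(TRUE, 5), rep(FALSE, 2))))
  expect_equal(shifted$value, base$value)
})

test_that("non-monotone plates resolve conservatively with a warning", {
  s <- dilution_series(250, c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_warning(m <- mic(s), "non-monotone")
  expect_equal(m$value, 125)
  expect_warning(m2 <- mic(dilution_series(250, c(FALSE, TRUE, TRUE))),
                 "non-monotone")
  expect_true(m2$censored)
})

test_that("titer reports 2^-n at the last positive well of the leading block", {
  t1 <- hai_titer(c(rep(TRUE, 4), rep(FALSE, 4)))
  expect_identical(t1$titer_exponent, 3L)
  expect_equal(t1$titer, 2^-3)
  t2 <- hai_titer(rep(FALSE, 8))
  expect_identical(t2$titer_exponent, 0L)
  expect_false(t2$positive_at_start)
  t3 <- hai_titer(rep(TRUE, 8))
  expect_identical(t3$titer_exponent, 7L)
  expect_error(hai_titer(logical(0)), class = "fac_validation_error")
})

test_that("simulated plates return the smallest grid value >= the true MIC", {
  cases <- data.frame(true_mic = c(7, 250, 0.9, 33), start = c(250, 250, 200, 200))
  for (i in seq_len(nrow(cases))) {
    s <- simulate_hai_plate(cases$true_mic[i], cases$start[i], n_wells = 8)
    m <- mic(s)
    grid <- well_concentrations(s)
    if (cases$true_mic[i] > cases$start[i]) {
      expect_true(m$censored)
    } else {
      expect_false(m$censored)
      expect_equal(m$value, min(grid[grid >= cases$true_mic[i]]))
    }
  }
  expect_true(mic(simulate_hai_plate(300, 250))$censored)
  expect_equal(mic(simulate_hai_plate(250, 250))$value, 250)
  expect_equal(mic(simulate_hai_plate(7, 250))$value, 7.8125)
})

test_that("HAI CSV records tabulate into a censored report", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(
    saccharide = c("Trehalose", "Trehalose", "Isomaltose"),
    lectin = c("PPL2A", "PPL2B", "PPL3"),
    start_conc = c(250, 250, 200),
    unit = "mM",
    outcomes = c("11111100", "00000000", "11111000")
  ), path, row.names = FALSE)
  records <- read_hai_csv(path)
  report <- hai_report(records)
  expect_identical(report$PPL2A[report$saccharide == "Trehalose"], "7.81")
  expect_identical(report$PPL2B[report$saccharide == "Trehalose"], ">250")
  expect_identical(report$PPL3[report$saccharide == "Isomaltose"], "12.5")
})
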