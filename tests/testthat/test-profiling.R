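test_that("profiles chain retardation through Kd to Ka over the panel", {
  panel <- tiny_panel()
  meas <- data.frame(glycan_id = c("003", "017", "901"),
                     A0 = 2.5e-9,
                     v_minus_v0 = c(20.93, 0.2, -0.1))
  prof <- build_profile(meas, ref_cals$PPL3s, panel)
  expect_equal(prof$data$Ka[1], 3.32e4, tolerance = 1e-3)
  # 0.2 uL sits under the 0.5 uL floor: below detection, Ka rendered as 0
  expect_true(prof$data$below_detection[2])
  expect_identical(prof$data$Ka[2], 0)
  expect_true(prof$data$below_detection[3])
})

test_that("profiles reject unknown glycans and flag missing ones", {
  panel <- tiny_panel()
  bad <- data.frame(glycan_id = "999", A0 = 2.5e-9, v_minus_v0 = 10)
  expect_error(build_profile(bad, ref_cals$PPL3s, panel), "999",
               class = "fac_validation_error")
  partial <- data.frame(glycan_id = "003", A0 = 2.5e-9, v_minus_v0 = 10)
  expect_warning(prof <- build_profile(partial, ref_cals$PPL3s, panel),
                 "without measurement")
  expect_true(all(prof$data$below_detection[prof$data$glycan_id != "003"]))
})

test_that("PPL2A-like runs leave every glycolipid-class glycan undetected", {
  panel <- make_archetype_panel(1)
  meas <- simulate_measurements("PPL2A_like", panel, ref_cals$PPL2A,
                                sim_config(), seed = 2)
  prof <- build_profile(meas, ref_cals$PPL2A, panel)
  gly <- panel$class[match(prof$data$glycan_id, panel$id)] == "glycolipid"
  expect_true(all(prof$data$below_detection[gly]))
})

test_that("relative affinity is a max-normalized percentage", {
  ka <- c(g1 = 2e6, g2 = 1e6, g3 = 0)
  prof <- profile_from_ka(ka, ref_cals$PPL2A)
  expect_equal(relative_affinity(prof),
               c(g1 = 100, g2 = 50, g3 = 0))
  scaled <- profile_from_ka(ka * 10, ref_cals$PPL2A)
  expect_equal(relative_affinity(scaled), relative_affinity(prof))
  single <- profile_from_ka(c(g1 = NA, g2 = 5e4), ref_cals$PPL2A)
  expect_equal(unname(relative_affinity(single)), c(0, 100))
  empty <- profile_from_ka(c(g1 = NA, g2 = NA), ref_cals$PPL2A)
  expect_error(relative_affinity(empty), "empty",
               class = "fac_validation_error")
})

test_that("archetype profiles classify into the expected mJRL groups", {
  panel <- make_archetype_panel(1)
  cfg <- sim_config()
  cals <- list(PPL2A_like = ref_cals$PPL2A, PPL3_like = ref_cals$PPL3s,
               PPL4_like = ref_cals$PPL4)
  out <- lapply(names(cals), function(a) {
    meas <- simulate_measurements(a, panel, cals[[a]], cfg, seed = 9)
    classify_mjrl(build_profile(meas, cals[[a]], panel), panel)
  })
  expect_identical(out[[1]]$group, "A"); expect_identical(out[[1]]$subgroup, "1")
  expect_identical(out[[2]]$group, "A"); expect_identical(out[[2]]$subgroup, "1")
  expect_identical(out[[3]]$group, "A")
  expect_identical(out[[3]]$subgroup, "unclassified")
  expect_lt(out[[3]]$evidence[["complex_fraction"]], 0.1)
})

test_that("a complex-only binder falls into group B", {
  panel <- make_archetype_panel(1)
  complex_ids <- panel$id[panel$class %in%
                            c("agalacto", "galactosylated", "sialylated")]
  ka <- setNames(rep(NA_real_, nrow(panel)), panel$id)
  ka[complex_ids] <- 1e5
  prof <- profile_from_ka(ka, ref_cals$PPL3s)
  a <- classify_mjrl(prof, panel)
  expect_identical(a$group, "B")
  expect_identical(a$evidence[["mannose_axis_fraction"]], 0)
})

test_that("classification is invariant to uniform Ka rescaling", {
  panel <- make_archetype_panel(1)
  meas <- simulate_measurements("PPL2A_like", panel, ref_cals$PPL2A,
                                sim_config(), seed = 13)
  prof <- build_profile(meas, ref_cals$PPL2A, panel)
  ka <- setNames(prof$data$Ka, prof$data$glycan_id)
  ka[ka == 0] <- NA
  for (scale in c(1, 0.01, 1000)) {
    a <- classify_mjrl(profile_from_ka(ka * scale, ref_cals$PPL2A), panel)
    expect_identical(a$group, "A")
    expect_identical(a$subgroup, "1")
  }
  expect_error(
    classify_mjrl(prof, panel, thresholds = list(theta_A = 1.5)),
    class = "fac_validation_error")
})

test_that("profile comparison separates rank agreement from discordance", {
  ka <- c(g1 = 2e6, g2 = 1e6, g3 = 0)
  p1 <- profile_from_ka(ka, ref_cals$PPL2A)
  self <- compare_profiles(p1, p1)
  expect_equal(self$concordance, 1)
  expect_identical(self$discordant, character(0))
  # uniform ~100x offset: perfect rank agreement, nothing discordant
  p2 <- profile_from_ka(ka * 0.01, ref_cals$PPL2A)
  off <- compare_profiles(p1, p2)
  expect_equal(off$concordance, 1)
  expect_identical(off$discordant, character(0))
  # disjoint detectable sets: concordance undefined
  p3 <- profile_from_ka(c(g1 = NA, g2 = NA, g3 = 5e4), ref_cals$PPL2A)
  dis <- compare_profiles(p1, p3)
  expect_true(is.na(dis$concordance))
  expect_match(dis$note, "disjoint")
})

test_that("the PPL2A-like / PPL3-like pair is discordant exactly at 017", {
  panel <- make_archetype_panel(1)
  cfg <- sim_config()
  m2a <- simulate_measurements("PPL2A_like", panel, ref_cals$PPL2A, cfg,
                               seed = 21)
  m3 <- simulate_measurements("PPL3_like", panel, ref_cals$PPL3s, cfg,
                              seed = 21)
  cmp <- compare_profiles(build_profile(m2a, ref_cals$PPL2A, panel),
                          build_profile(m3, ref_cals$PPL3s, panel))
  expect_identical(cmp$discordant, "017")
  expect_gt(cmp$concordance, 0.9)
})
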