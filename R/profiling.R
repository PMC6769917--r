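#' @title Specificity profiling and mJRL classification
#' @description A specificity profile collects, for one lectin column, the
#'   per-glycan retardation, Kd and Ka over a glycan panel, with explicit
#'   below-detection flags. Profiles are normalized to relative affinities
#'   (percent of the strongest binder), classified into mannose-binding
#'   jacalin-related lectin (mJRL) specificity groups A/B with subgroups, and
#'   compared pairwise.
#' @name profiling
NULL

#' Build a specificity profile from retardation measurements
#'
#' Applies the below-detection floor, then [kd_from_retardation()] and
#' [ka_from_kd()] per glycan. The profile always covers the full panel:
#' panel glycans without a measurement are flagged below detection with a
#' warning. Below-detection entries carry `Kd = NA` and `Ka = 0`.
#'
#' @param measurements data.frame with columns `glycan_id`, `A0` (mol/L) and
#'   `v_minus_v0` (uL).
#' @param calibration a [column_calibration()].
#' @param panel a [glycan_panel()].
#' @param v_min below-detection floor on the retardation, uL (default 0.5):
#'   measurements with `v_minus_v0 <= v_min` are reported as no affinity.
#' @return object of class `specificity_profile`: list with `lectin_name`,
#'   `calibration`, `v_min` and `data` (data.frame `glycan_id`,
#'   `v_minus_v0`, `Kd`, `Ka`, `below_detection`, panel order).
#' @export
build_profile <- function(measurements, calibration, panel, v_min = 0.5) {
  stopifnot(inherits(calibration, "column_calibration"),
            inherits(panel, "glycan_panel"))
  if (!is.data.frame(measurements) ||
      !all(c("glycan_id", "A0", "v_minus_v0") %in% names(measurements)))
    stop_validation("measurements must have columns glycan_id, A0, v_minus_v0")
  measurements$glycan_id <- as.character(measurements$glycan_id)
  unknown <- setdiff(measurements$glycan_id, panel$id)
  if (length(unknown))
    stop_validation(paste0("glycan id(s) not in panel: ",
                           paste(unknown, collapse = ", ")))
  idx <- match(panel$id, measurements$glycan_id)
  if (anyNA(idx))
    warning(sum(is.na(idx)), " panel glycan(s) without measurement flagged ",
            "below detection")
  v <- measurements$v_minus_v0[idx]
  a0 <- measurements$A0[idx]
  below <- is.na(v) | v <= v_min
  kd <- rep(NA_real_, nrow(panel))
  ok <- !below
  if (any(ok))
    kd[ok] <- suppressWarnings(
      kd_from_retardation(calibration$Bt, v[ok], a0[ok]))
  below <- below | is.na(kd)      # noise-inverted entries count as undetected
  kd[below] <- NA_real_
  ka <- ifelse(below, 0, 1 / kd)
  structure(
    list(lectin_name = calibration$lectin_name, calibration = calibration,
         v_min = v_min,
         data = data.frame(glycan_id = panel$id, v_minus_v0 = v, Kd = kd,
                           Ka = ka, below_detection = below,
                           stringsAsFactors = FALSE)),
    class = "specificity_profile"
  )
}

#' @export
print.specificity_profile <- function(x, ...) {
  n <- nrow(x$data)
  det <- sum(!x$data$below_detection)
  cat(sprintf("Specificity profile: %s (%d glycans, %d detectable)\n",
              x$lectin_name, n, det))
  invisible(x)
}

#' Relative affinity of a profile
#'
#' Per-lectin max normalization: `100 * Ka / max(Ka)` so the strongest binder
#' scores 100 and below-detection entries score 0. Invariant under uniform
#' rescaling of Ka.
#'
#' @param profile a [build_profile()] result.
#' @return named numeric vector of percentages over all panel glycans.
#' @export
relative_affinity <- function(profile) {
  stopifnot(inherits(profile, "specificity_profile"))
  ka <- profile$data$Ka
  if (all(profile$data$below_detection))
    stop_validation("profile empty: every glycan is below detection")
  setNames(100 * ka / max(ka), profile$data$glycan_id)
}

#' Classification thresholds for mJRL grouping
#'
#' @param theta_A minimum detectable-binding fraction over the high-mannose
#'   axis (high-mannose class plus core-pentasaccharide glycans) for group A.
#' @param theta_C minimum detectable fraction over the complex-type classes
#'   (agalacto, galactosylated, sialylated) for subgroup 1.
#' @param theta_min below this complex-type fraction the subgroup is
#'   `unclassified` (no binding to complex-type glycans).
#' @param rho maximum ratio of mean relative affinity on bisecting-GlcNAc
#'   glycans to that on non-bisected complex glycans for subgroup 1 (binding
#'   "reduced by a bisecting GlcNAc").
#' @return named list of thresholds, all in (0, 1).
#' @export
mjrl_thresholds <- function(theta_A = 0.2, theta_C = 0.5, theta_min = 0.1,
                            rho = 0.5) {
  th <- list(theta_A = theta_A, theta_C = theta_C, theta_min = theta_min,
             rho = rho)
  if (any(unlist(th) <= 0) || any(unlist(th) >= 1))
    stop_validation("all classification thresholds must lie in (0, 1)")
  th
}

#' Classify a lectin into mJRL specificity groups
#'
#' mJRLs split into two major groups by their specificity towards
#' high-mannose-type glycans (group A binds them, group B does not), each
#' further divided by the preference for complex-type glycans. Implemented as
#' explicit, configurable decision rules on detectable-binding fractions:
#' group A iff the detectable fraction over the high-mannose axis
#' (high-mannose class plus core-pentasaccharide-flagged glycans, which are
#' the mannose core the group definition keys on) is at least `theta_A`.
#' Within a group, subgroup 1 requires a complex-type detectable fraction of
#' at least `theta_C` together with binding reduced by a bisecting GlcNAc
#' (mean relative affinity on bisecting-flagged complex glycans at most
#' `rho` times that on non-bisected ones); a complex-type fraction below
#' `theta_min` leaves the subgroup `unclassified`; anything else is
#' subgroup 2. All computed fractions are returned as evidence. The rules
#' depend only on detectability fractions and affinity ratios, so the
#' assignment is invariant to uniform rescaling of Ka.
#'
#' @param profile a [build_profile()] result.
#' @param panel the companion [glycan_panel()].
#' @param thresholds a [mjrl_thresholds()] list.
#' @return object of class `mjrl_assignment`: list with `lectin_name`,
#'   `group` (`"A"`/`"B"`), `subgroup` (`"1"`/`"2"`/`"unclassified"`) and
#'   `evidence` (named numeric vector; `unclassified` always carries the
#'   failing `complex_fraction` criterion).
#' @export
classify_mjrl <- function(profile, panel, thresholds = mjrl_thresholds()) {
  stopifnot(inherits(profile, "specificity_profile"),
            inherits(panel, "glycan_panel"))
  if (!setequal(profile$data$glycan_id, panel$id))
    stop_validation("profile and panel cover different glycan sets")
  th <- do.call(mjrl_thresholds, thresholds)
  dat <- profile$data[match(panel$id, profile$data$glycan_id), ]
  detected <- !dat$below_detection

  mannose_axis <- panel$class == "high_mannose" | panel$core_pentasaccharide
  complex_set <- panel$class %in% c("agalacto", "galactosylated", "sialylated")
  frac_mannose <- if (any(mannose_axis)) mean(detected[mannose_axis]) else 0
  frac_complex <- if (any(complex_set)) mean(detected[complex_set]) else 0

  rel <- tryCatch(relative_affinity(profile)[match(panel$id, dat$glycan_id)],
                  fac_validation_error = function(e) rep(0, nrow(panel)))
  bisect <- complex_set & panel$bisecting_glcnac
  nonbisect <- complex_set & !panel$bisecting_glcnac
  mean_bisect <- if (any(bisect)) mean(rel[bisect]) else NA_real_
  mean_nonbisect <- if (any(nonbisect)) mean(rel[nonbisect]) else NA_real_
  # vacuously satisfied when the panel carries no bisected glycans to compare
  bisect_reduced <- is.na(mean_bisect) ||
    (!is.na(mean_nonbisect) && mean_nonbisect > 0 &&
       mean_bisect <= th$rho * mean_nonbisect)

  group <- if (frac_mannose >= th$theta_A) "A" else "B"
  subgroup <- if (frac_complex < th$theta_min) {
    "unclassified"
  } else if (frac_complex >= th$theta_C && bisect_reduced) {
    "1"
  } else {
    "2"
  }

  evidence <- c(
    mannose_axis_fraction = frac_mannose,
    complex_fraction = frac_complex,
    bisecting_mean_relative = mean_bisect,
    nonbisecting_mean_relative = mean_nonbisect,
    theta_A = th$theta_A, theta_C = th$theta_C, theta_min = th$theta_min,
    rho = th$rho
  )
  structure(list(lectin_name = profile$lectin_name, group = group,
                 subgroup = subgroup, evidence = evidence),
            class = "mjrl_assignment")
}

#' @export
print.mjrl_assignment <- function(x, ...) {
  cat(sprintf("%s: group %s, subgroup %s\n", x$lectin_name, x$group,
              x$subgroup))
  invisible(x)
}

#' Compare two specificity profiles
#'
#' Concordance is the Spearman rank correlation of `log10(Ka + floor)` over
#' the shared glycans, where each profile's floor is its association constant
#' at the detection limit (`Ka_floor = v_min * 1e3 / Bt`), keeping
#' below-detection entries comparable without infinities. Discordant glycans
#' are those detectable in exactly one profile, plus glycans whose
#' log10-affinity difference departs from the global median offset by more
#' than `gap` (so a uniform, e.g. ~100-fold, potency shift between two
#' otherwise-identical profiles produces no discordance).
#'
#' @param p1,p2 [build_profile()] results over the same panel.
#' @param gap log10 deviation from the median offset flagged as discordant
#'   (default 1 = 10-fold).
#' @return list with `concordance` (NA with a `note` when the detectable sets
#'   are disjoint) and `discordant` (character vector of glycan ids).
#' @export
compare_profiles <- function(p1, p2, gap = 1.0) {
  stopifnot(inherits(p1, "specificity_profile"),
            inherits(p2, "specificity_profile"))
  if (!identical(p1$data$glycan_id, p2$data$glycan_id))
    stop_validation("profiles cover different glycan panels")
  ids <- p1$data$glycan_id
  det1 <- !p1$data$below_detection
  det2 <- !p2$data$below_detection
  floor1 <- p1$v_min * 1e3 / p1$calibration$Bt
  floor2 <- p2$v_min * 1e3 / p2$calibration$Bt
  x1 <- log10(p1$data$Ka + floor1)
  x2 <- log10(p2$data$Ka + floor2)

  note <- NULL
  both <- det1 & det2
  if (!any(both)) {
    concordance <- NA_real_
    note <- "disjoint detectable sets: concordance undefined"
  } else {
    concordance <- suppressWarnings(cor(x1, x2, method = "spearman"))
  }

  disc_one <- ids[xor(det1, det2)]
  disc_gap <- character(0)
  if (sum(both) >= 2L) {
    d <- log10(p1$data$Ka[both]) - log10(p2$data$Ka[both])
    disc_gap <- ids[both][abs(d - median(d)) > gap]
  }
  list(concordance = concordance,
       discordant = sort(unique(c(disc_one, disc_gap))),
       note = note)
}
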