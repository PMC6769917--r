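#' @title FAC quantitation core
#' @description The basic equation of frontal affinity chromatography relates
#'   the retardation of the analyte's elution front to the binding
#'   equilibrium: `Kd = Bt / (V - V0) - [A]0`, with `Bt` the effective ligand
#'   content of the column (nmol), `V - V0` the front retardation against a
#'   non-binding standard (uL), and `[A]0` the infused analyte concentration
#'   (mol/L). The unit identity nmol/uL == mmol/L supplies the `1e3` factor
#'   that appears throughout.
#' @name fac_core
NULL

#' Column calibration (effective ligand content and reference Kd)
#'
#' @param lectin_name name of the immobilized lectin.
#' @param Bt effective ligand content, nmol (> 0).
#' @param Kd_ref equilibrium dissociation constant of the calibration ligand,
#'   mol/L (> 0).
#' @param bed_volume optional column bed volume, uL.
#' @param r2 optional goodness of fit of the calibration line.
#' @return object of class `column_calibration`.
#' @export
column_calibration <- function(lectin_name, Bt, Kd_ref, bed_volume = NA_real_,
                               r2 = NA_real_) {
  if (!is.numeric(Bt) || length(Bt) != 1L || !is.finite(Bt) || Bt <= 0)
    stop_validation("Bt must be a single positive number (nmol)")
  if (!is.numeric(Kd_ref) || length(Kd_ref) != 1L || !is.finite(Kd_ref) ||
      Kd_ref <= 0)
    stop_validation("Kd_ref must be a single positive number (mol/L)")
  if (!is.na(bed_volume) && bed_volume <= 0)
    stop_validation("bed_volume must be positive (uL) when given")
  structure(
    list(lectin_name = as.character(lectin_name), Bt = Bt, Kd_ref = Kd_ref,
         bed_volume = bed_volume, r2 = r2),
    class = "column_calibration"
  )
}

#' @export
print.column_calibration <- function(x, ...) {
  cat(sprintf("Column calibration: %s\n  Bt = %.3g nmol, Kd = %.3g M",
              x$lectin_name, x$Bt, x$Kd_ref))
  if (!is.na(x$r2)) cat(sprintf(", r2 = %.6g", x$r2))
  cat("\n")
  invisible(x)
}

#' Bed volume of a cylindrical miniature column
#'
#' @param diameter_mm internal diameter, mm.
#' @param length_mm bed length, mm.
#' @return bed volume in uL (1 mm^3 = 1 uL).
#' @examples
#' bed_volume(2, 10)  # 31.4 uL, the standard FAC miniature column
#' @export
bed_volume <- function(diameter_mm, length_mm) {
  stopifnot(diameter_mm > 0, length_mm > 0)
  pi * (diameter_mm / 2)^2 * length_mm
}

#' Forward retardation model
#'
#' Predicted elution-front retardation `V - V0 = Bt / (Kd + [A]0)` with the
#' denominator taken in mmol/L, so nmol / (mmol/L) = uL. Strictly increasing
#' (linear) in `Bt`, strictly decreasing in `Kd` and `A0`. Vectorized.
#'
#' @param Bt effective ligand content, nmol (>= 0).
#' @param Kd dissociation constant, mol/L (> 0).
#' @param A0 infused analyte concentration, mol/L (>= 0).
#' @return retardation `V - V0` in uL.
#' @examples
#' retardation_forward(Bt = 0.63, Kd = 3.01e-5, A0 = 2.5e-9)  # ~20.93 uL
#' @export
retardation_forward <- function(Bt, Kd, A0) {
  if (any(Bt < 0)) stop_validation("Bt must be >= 0 (nmol)")
  if (any(A0 < 0)) stop_validation("A0 must be >= 0 (mol/L)")
  if (any(Kd + A0 <= 0)) stop_validation("Kd + A0 must be > 0 (mol/L)")
  Bt / ((Kd + A0) * 1e3)
}

#' Dissociation constant from front retardation
#'
#' Inverts the forward model: `Kd = Bt / ((V - V0) * 1e3) - [A]0` in mol/L.
#' Non-positive retardations signal below-detection measurements and yield
#' `NA` (the caller applies its detection floor and flags the entry); a
#' non-positive result (noise exceeded the model) also yields `NA` with a
#' warning. Vectorized.
#'
#' @param Bt effective ligand content, nmol (> 0).
#' @param v_minus_v0 front retardation, uL.
#' @param A0 infused analyte concentration, mol/L.
#' @return Kd in mol/L, `NA` where undefined.
#' @examples
#' kd_from_retardation(Bt = 0.63, v_minus_v0 = 20.93, A0 = 2.5e-9)  # ~3.01e-5
#' @export
kd_from_retardation <- function(Bt, v_minus_v0, A0) {
  if (any(Bt <= 0)) stop_validation("Bt must be > 0 (nmol)")
  kd <- Bt / (v_minus_v0 * 1e3) - A0
  kd[v_minus_v0 <= 0] <- NA_real_
  bad <- !is.na(kd) & kd <= 0
  if (any(bad)) {
    warning("non-positive Kd for ", sum(bad),
            " measurement(s): retardation exceeds Bt/[A]0 limit; set to NA")
    kd[bad] <- NA_real_
  }
  kd
}

#' Simplified dissociation constant (negligible analyte concentration)
#'
#' `Kd = Bt / ((V - V0) * 1e3)`, valid when `[A]0` (e.g. < 1e-8 M) is
#' negligible against Kd (e.g. > 1e-6 M). Its relative error against
#' [kd_from_retardation()] is exactly `A0 / Kd`.
#'
#' @inheritParams kd_from_retardation
#' @return Kd in mol/L, `NA` where `v_minus_v0 <= 0` (below detection).
#' @export
kd_simplified <- function(Bt, v_minus_v0) {
  if (any(Bt <= 0)) stop_validation("Bt must be > 0 (nmol)")
  kd <- Bt / (v_minus_v0 * 1e3)
  kd[v_minus_v0 <= 0] <- NA_real_
  kd
}

#' Association constant from dissociation constant
#'
#' @param Kd dissociation constant, mol/L (> 0).
#' @return Ka = 1/Kd in L/mol. `NA` input propagates (below-detection entries
#'   are rendered as Ka = 0 at the profile level, not here).
#' @export
ka_from_kd <- function(Kd) {
  if (any(!is.na(Kd) & Kd <= 0)) stop_validation("Kd must be > 0 (mol/L)")
  1 / Kd
}

#' Woolf-Hofstee calibration of a lectin column
#'
#' Determines the effective ligand content `Bt` and the dissociation constant
#' `Kd` of the calibration ligand from a concentration-dependence series by
#' the Woolf-Hofstee linearization: plotting `y = (V - V0)` against
#' `x = (V - V0) * [A]0` turns the binding isotherm into a straight line with
#' `slope = -1/Kd` and `intercept = Bt/Kd` (in uL; multiplied by Kd in mmol/L
#' it returns Bt in nmol). Fitted by unweighted ordinary least squares, which
#' is the estimator the linearized plot defines; see
#' [woolf_hofstee_refit_nls()] for a nonlinear cross-check.
#'
#' @param points data.frame with columns `A0` (mol/L, > 0) and `v_minus_v0`
#'   (uL, > 0); at least 3 rows and at least 2 distinct `A0` values.
#' @param lectin_name stored in the returned calibration.
#' @param bed_volume optional, uL.
#' @return a [column_calibration()] with `r2` of the calibration line.
#' @export
woolf_hofstee_fit <- function(points, lectin_name = "", bed_volume = NA_real_) {
  if (!is.data.frame(points) || !all(c("A0", "v_minus_v0") %in% names(points)))
    stop_validation("points must have columns A0 and v_minus_v0")
  if (nrow(points) < 3L)
    stop_validation("insufficient data: need at least 3 calibration points")
  if (any(points$A0 <= 0))
    stop_validation("all A0 must be > 0 (mol/L)")
  if (any(points$v_minus_v0 <= 0))
    stop_validation("all v_minus_v0 must be > 0 (uL)")
  if (length(unique(points$A0)) < 2L)
    stop_validation("insufficient data: need at least 2 distinct A0 values")
  x <- points$v_minus_v0 * points$A0
  y <- points$v_minus_v0
  if (diff(range(x)) == 0)
    stop_validation("insufficient data: degenerate (collinear) design in x")
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2L])
  intercept <- unname(coef(fit)[1L])
  if (!is.finite(slope) || slope >= 0)
    stop_fit("no saturable binding: Woolf-Hofstee slope is non-negative")
  Kd <- -1 / slope
  Bt <- intercept * Kd * 1e3   # uL * mmol/L = nmol
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  column_calibration(lectin_name, Bt = Bt, Kd_ref = Kd,
                     bed_volume = bed_volume, r2 = r2)
}

#' Nonlinear refit of the retardation isotherm (cross-check)
#'
#' Refits `v = Bt / ((Kd + A0) * 1e3)` directly by nonlinear least squares,
#' started from the Woolf-Hofstee estimates. Offered as a diagnostic
#' cross-check of the primary linearized estimator, not as a replacement.
#'
#' @inheritParams woolf_hofstee_fit
#' @return list with elements `Bt` and `Kd`.
#' @export
woolf_hofstee_refit_nls <- function(points, lectin_name = "") {
  start <- woolf_hofstee_fit(points, lectin_name)
  fit <- stats::nls(
    v_minus_v0 ~ Bt / ((Kd + A0) * 1e3),
    data = points,
    start = list(Bt = start$Bt, Kd = start$Kd_ref),
    control = stats::nls.control(scaleOffset = 1)  # tolerate zero residuals
  )
  as.list(coef(fit))
}

#' Published reference calibrations of the three pearl-shell lectin columns
#'
#' Effective ligand content and reference dissociation constants reported for
#' the PPL2A, PPL3s and PPL4 miniature columns (calibration ligands:
#' Man3GlcNAc2-Asn(Fmoc) for PPL2A/PPL3s, Man-alpha1-pNP for PPL4; bed
#' volume 31.4 uL each). These serve as inputs for simulation and as
#' recovery-test ground truth.
#'
#' @return named list of [column_calibration()] objects.
#' @export
ppl_reference_calibrations <- function() {
  bv <- bed_volume(2, 10)
  list(
    PPL2A = column_calibration("PPL2A", Bt = 0.02, Kd_ref = 2.0e-7,
                               bed_volume = bv),
    PPL3s = column_calibration("PPL3s", Bt = 0.63, Kd_ref = 3.01e-5,
                               bed_volume = bv),
    PPL4  = column_calibration("PPL4", Bt = 0.98, Kd_ref = 2.0e-5,
                               bed_volume = bv)
  )
}
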