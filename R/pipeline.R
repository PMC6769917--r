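#' @title Workflow drivers
#' @description File-level orchestration of the pipeline stages: generate a
#'   complete synthetic fixture set, calibrate a column from a
#'   concentration-dependence CSV, quantify a panel run into a specificity
#'   profile, and classify/compare profiles. All reports are JSON-first
#'   (machine-checkable); the same functions back the `inst/cli/facprofile.R`
#'   command-line script. Every driver is deterministic given identical
#'   inputs and seed.
#' @name cli_workflow
NULL

write_json_report <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Write a synthetic fixture set
#'
#' Creates, under `dir`: `panel.tsv` (the 130-glycan archetype panel),
#' `calibration_<lectin>.csv` (noiseless concentration series at the
#' reference column parameters), `retardation_<lectin>.csv` (seeded noisy
#' panel measurements), and `hai.csv` (two-fold dilution plates). With
#' `curves = TRUE` also writes per-glycan breakthrough-curve CSVs under
#' `curves_<lectin>/` including `standard.csv`.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param cfg a [sim_config()].
#' @param lectins archetype names to generate (default all three).
#' @param curves also write raw elution curves (large; default `FALSE`).
#' @return `dir`, invisibly.
#' @export
fac_generate <- function(dir, seed = 1, cfg = sim_config(),
                         lectins = c("PPL2A_like", "PPL3_like", "PPL4_like"),
                         curves = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  panel <- make_archetype_panel(seed)
  write_panel(panel, file.path(dir, "panel.tsv"))
  refs <- ppl_reference_calibrations()
  ref_of <- c(PPL2A_like = "PPL2A", PPL3_like = "PPL3s", PPL4_like = "PPL4")
  for (lec in lectins) {
    cal <- refs[[ref_of[[lec]]]]
    series <- simulate_calibration_series(cal$Bt, cal$Kd_ref, seed = seed)
    write.csv(data.frame(A0_M = series$A0, v_minus_v0_uL = series$v_minus_v0),
              file.path(dir, paste0("calibration_", lec, ".csv")),
              row.names = FALSE)
    meas <- simulate_measurements(lec, panel, cal, cfg, seed = seed)
    write.csv(data.frame(glycan_id = meas$glycan_id, A0_M = meas$A0,
                         v_minus_v0_uL = meas$v_minus_v0),
              file.path(dir, paste0("retardation_", lec, ".csv")),
              row.names = FALSE, quote = TRUE)
    if (curves) {
      run <- simulate_fac_run(lec, panel, cal, cfg, seed = seed)
      cdir <- file.path(dir, paste0("curves_", lec))
      dir.create(cdir, showWarnings = FALSE)
      write_curve(run$standard, file.path(cdir, "standard.csv"))
      for (id in names(run$curves))
        write_curve(run$curves[[id]], file.path(cdir, paste0(id, ".csv")))
    }
  }
  hai <- data.frame(
    saccharide = c("Trehalose", "Isomaltose", "N-Acetyl-D-glucosamine"),
    lectin = c("PPL2A", "PPL3", "PPL4"),
    start_conc = c(250, 200, 200),
    unit = "mM",
    outcomes = c("11111100", "11111000", "11111100"),
    stringsAsFactors = FALSE
  )
  write.csv(hai, file.path(dir, "hai.csv"), row.names = FALSE)
  invisible(dir)
}

#' Calibrate a lectin column from a concentration-dependence CSV
#'
#' Reads a calibration series (columns `A0_M` plus either `v_minus_v0_uL` or
#' `V_uL` and `V0_uL`), fits the Woolf-Hofstee line, and optionally writes
#' the calibration as JSON (including r2 and the plot points).
#'
#' @param path calibration CSV.
#' @param lectin_name stored in the calibration.
#' @param out optional JSON output path.
#' @return a [column_calibration()].
#' @export
fac_calibrate <- function(path, lectin_name = "", out = NULL) {
  if (!file.exists(path)) stop_io(paste0("calibration file not found: ", path))
  df <- read.csv(path)
  if (!"A0_M" %in% names(df))
    stop_validation(paste0("calibration CSV needs column A0_M: ", path))
  if ("v_minus_v0_uL" %in% names(df)) {
    v <- df$v_minus_v0_uL
  } else if (all(c("V_uL", "V0_uL") %in% names(df))) {
    v <- df$V_uL - df$V0_uL
  } else {
    stop_validation(
      "calibration CSV needs v_minus_v0_uL or both V_uL and V0_uL")
  }
  points <- data.frame(A0 = df$A0_M, v_minus_v0 = v)
  cal <- woolf_hofstee_fit(points, lectin_name = lectin_name)
  if (!is.null(out)) {
    write_json_report(list(
      lectin = cal$lectin_name, Bt_nmol = cal$Bt, Kd_M = cal$Kd_ref,
      r2 = cal$r2,
      points = list(v_minus_v0_uL = points$v_minus_v0,
                    x_uL_M = points$v_minus_v0 * points$A0)
    ), out)
  }
  cal
}

#' Quantify a panel run into a specificity profile
#'
#' Input is either a retardation CSV (columns `glycan_id`, `A0_M`,
#' `v_minus_v0_uL`) or a directory of breakthrough-curve CSVs (one
#' `<glycan_id>.csv` per glycan plus `standard.csv`), from which retardations
#' are measured with [retardation_from_curves()]. Per-curve detection
#' failures are logged to stderr and the glycan flagged below detection; the
#' run continues.
#'
#' @param input retardation CSV path or curves directory.
#' @param calibration a [column_calibration()] (e.g. from [fac_calibrate()]).
#' @param panel a [glycan_panel()] or panel TSV path.
#' @param v_min below-detection floor, uL.
#' @param method front-detection method for curve input.
#' @param A0 analyte concentration for curve input, mol/L.
#' @param out optional JSON output path.
#' @return a [build_profile()] result.
#' @export
fac_quantify <- function(input, calibration, panel, v_min = 0.5,
                         method = c("equal_area", "half_height"),
                         A0 = 2.5e-9, out = NULL) {
  method <- match.arg(method)
  if (is.character(panel)) panel <- load_panel(panel)
  if (dir.exists(input)) {
    std_path <- file.path(input, "standard.csv")
    if (!file.exists(std_path))
      stop_io(paste0("standard curve not found: ", std_path))
    files <- setdiff(list.files(input, pattern = "\\.csv$"), "standard.csv")
    if (length(files) == 0L)
      stop_io(paste0("no glycan curve files in: ", input))
    standard <- read_curve(std_path)
    v0 <- detect_front(standard, method)$v_front
    meas <- do.call(rbind, lapply(files, function(f) {
      id <- sub("\\.csv$", "", f)
      v <- tryCatch(
        detect_front(read_curve(file.path(input, f)), method)$v_front - v0,
        fac_error = function(e) {
          message("glycan ", id, ": ", conditionMessage(e),
                  " (flagged below detection)")
          NA_real_
        })
      data.frame(glycan_id = id, A0 = A0,
                 v_minus_v0 = ifelse(is.na(v), 0, v),
                 stringsAsFactors = FALSE)
    }))
  } else {
    if (!file.exists(input))
      stop_io(paste0("retardation file not found: ", input))
    df <- read.csv(input, colClasses = c(glycan_id = "character"))
    if (!all(c("glycan_id", "A0_M", "v_minus_v0_uL") %in% names(df)))
      stop_validation(
        "retardation CSV needs columns glycan_id, A0_M, v_minus_v0_uL")
    meas <- data.frame(glycan_id = df$glycan_id, A0 = df$A0_M,
                       v_minus_v0 = df$v_minus_v0_uL,
                       stringsAsFactors = FALSE)
  }
  profile <- build_profile(meas, calibration, panel, v_min = v_min)
  if (!is.null(out)) write_profile(profile, out)
  profile
}

#' Write a specificity profile as JSON
#' @param profile a [build_profile()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  entries <- lapply(seq_len(nrow(profile$data)), function(i) {
    r <- profile$data[i, ]
    list(glycan_id = r$glycan_id,
         Kd_M = r$Kd,               # null in JSON when below detection
         Ka_per_M = r$Ka,
         below_detection = r$below_detection)
  })
  write_json_report(list(
    lectin = profile$lectin_name,
    calibration = list(Bt_nmol = profile$calibration$Bt,
                       Kd_M = profile$calibration$Kd_ref),
    v_min_uL = profile$v_min,
    entries = entries
  ), path)
}

#' Read a specificity profile from JSON
#' @param path JSON written by [write_profile()].
#' @return a `specificity_profile`.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop_io(paste0("profile file not found: ", path))
  j <- jsonlite::read_json(path)
  dat <- do.call(rbind, lapply(j$entries, function(e)
    data.frame(glycan_id = e$glycan_id,
               v_minus_v0 = NA_real_,
               Kd = if (length(e$Kd_M) != 1L || is.na(e$Kd_M)) NA_real_
                    else e$Kd_M,
               Ka = e$Ka_per_M,
               below_detection = e$below_detection,
               stringsAsFactors = FALSE)))
  cal <- column_calibration(j$lectin, Bt = j$calibration$Bt_nmol,
                            Kd_ref = j$calibration$Kd_M)
  structure(list(lectin_name = j$lectin, calibration = cal,
                 v_min = j$v_min_uL, data = dat),
            class = "specificity_profile")
}

#' Classify profiles into mJRL groups and compare them pairwise
#'
#' @param profiles list of `specificity_profile` objects (or JSON paths).
#' @param panel a [glycan_panel()] or panel TSV path.
#' @param thresholds a [mjrl_thresholds()] list.
#' @param out optional JSON report path.
#' @return list with `assignments` (one [classify_mjrl()] result per profile)
#'   and `comparisons` (pairwise [compare_profiles()] results, present only
#'   with two or more profiles).
#' @export
fac_classify <- function(profiles, panel, thresholds = mjrl_thresholds(),
                         out = NULL) {
  if (is.character(panel)) panel <- load_panel(panel)
  profiles <- lapply(profiles, function(p)
    if (is.character(p)) read_profile(p) else p)
  for (p in profiles)
    if (!setequal(p$data$glycan_id, panel$id))
      stop_validation(paste0("profile ", p$lectin_name,
                             " does not match the panel"))
  assignments <- lapply(profiles, classify_mjrl, panel = panel,
                        thresholds = thresholds)
  comparisons <- list()
  if (length(profiles) >= 2L) {
    for (i in seq_len(length(profiles) - 1L)) {
      for (j in seq.int(i + 1L, length(profiles))) {
        key <- paste(profiles[[i]]$lectin_name, profiles[[j]]$lectin_name,
                     sep = " vs ")
        comparisons[[key]] <- compare_profiles(profiles[[i]], profiles[[j]])
      }
    }
  }
  result <- list(assignments = assignments, comparisons = comparisons)
  if (!is.null(out)) {
    write_json_report(list(
      assignments = lapply(assignments, function(a)
        list(lectin = a$lectin_name, group = a$group, subgroup = a$subgroup,
             evidence = as.list(a$evidence))),
      comparisons = lapply(comparisons, function(cp)
        list(concordance = cp$concordance, discordant = as.list(cp$discordant),
             note = cp$note))
    ), out)
  }
  result
}
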