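#' @title Hemagglutination inhibition (HAI) assay logic
#' @description Two-fold serial dilution plates: a saccharide is diluted down
#'   the plate, mixed with lectin at a fixed titer, and each well is scored
#'   for complete inhibition of erythrocyte agglutination. The minimum
#'   inhibitory concentration (MIC) is the lowest concentration whose well
#'   (and every higher-concentration well) shows complete inhibition; series
#'   where even the starting well fails are censored and reported as
#'   `"> start"`. Concentrations are stored exactly (7.8125 mM) and rounded
#'   only for display, matching the mixed 2-3 significant-figure convention
#'   of published inhibition tables.
#' @name hai_assay
NULL

#' Construct a dilution series
#'
#' Well `k` (0-based) holds concentration `start_conc / factor^k`; `outcomes[k+1]`
#' is `TRUE` when that well shows complete inhibition (negative
#' hemagglutination).
#'
#' @param start_conc starting concentration (> 0).
#' @param outcomes logical vector of well outcomes, highest concentration first.
#' @param factor dilution factor (> 1, default 2).
#' @param unit concentration unit tag, `"mM"` (saccharides) or `"%w/v"`
#'   (polysaccharides/glycoproteins); carried through, never converted.
#' @return object of class `dilution_series`.
#' @export
dilution_series <- function(start_conc, outcomes, factor = 2, unit = "mM") {
  if (!is.numeric(start_conc) || length(start_conc) != 1L || start_conc <= 0)
    stop_validation("start_conc must be a single positive number")
  if (factor <= 1) stop_validation("dilution factor must be > 1")
  if (length(outcomes) == 0L || anyNA(outcomes) || !is.logical(outcomes))
    stop_validation("outcomes must be a non-empty logical vector")
  structure(list(start_conc = start_conc, factor = factor,
                 outcomes = outcomes, unit = unit),
            class = "dilution_series")
}

#' Well concentrations of a dilution series
#' @param series a [dilution_series()].
#' @return numeric vector, highest first.
#' @export
well_concentrations <- function(series) {
  series$start_conc / series$factor^(seq_along(series$outcomes) - 1L)
}

#' Censored concentration
#'
#' @param value concentration (> 0).
#' @param censored `TRUE` when the true value exceeds the measured range and
#'   is reported as `"> value"`.
#' @param unit unit tag.
#' @return object of class `censored_conc`.
#' @export
censored_conc <- function(value, censored = FALSE, unit = "mM") {
  if (!is.numeric(value) || length(value) != 1L || value <= 0)
    stop_validation("censored_conc value must be a single positive number")
  structure(list(value = value, censored = censored, unit = unit),
            class = "censored_conc")
}

#' Display a censored concentration
#'
#' Rounds to at most `sigfigs` significant figures and prefixes `">"` for
#' censored values (e.g. `"7.8"`, `">250"`).
#'
#' @param x a [censored_conc()].
#' @param sigfigs significant figures for display (default 3).
#' @param ... unused.
#' @return character scalar.
#' @export
format.censored_conc <- function(x, sigfigs = 3, ...) {
  paste0(if (x$censored) ">" else "",
         format(signif(x$value, sigfigs), scientific = FALSE, trim = TRUE))
}

#' @export
print.censored_conc <- function(x, ...) {
  cat(format(x), x$unit, "\n")
  invisible(x)
}

#' Minimum inhibitory concentration of a dilution series
#'
#' The lowest concentration in the topmost contiguous block of inhibiting
#' wells. If the starting well does not inhibit, the MIC exceeds the tested
#' range and the result is censored at `start_conc`. An inhibiting well below
#' a non-inhibiting one violates the assumed monotone dose response and is
#' resolved conservatively (the stray well is ignored) with a warning.
#'
#' @param series a [dilution_series()].
#' @return a [censored_conc()] holding the exact grid value.
#' @examples
#' s <- dilution_series(250, c(rep(TRUE, 6), rep(FALSE, 2)))
#' mic(s)  # 7.8125 mM, displayed "7.8" at 2 significant figures
#' @export
mic <- function(series) {
  stopifnot(inherits(series, "dilution_series"))
  out <- series$outcomes
  if (!out[1L]) {
    if (any(out))
      warning("non-monotone inhibition pattern: inhibiting well(s) below a ",
              "non-inhibiting one ignored")
    return(censored_conc(series$start_conc, censored = TRUE,
                         unit = series$unit))
  }
  runs <- rle(out)
  k <- runs$lengths[1L]            # leading contiguous inhibiting block
  if (any(out[-seq_len(k)]))
    warning("non-monotone inhibition pattern: inhibiting well(s) below a ",
            "non-inhibiting one ignored")
  censored_conc(series$start_conc / series$factor^(k - 1L),
                censored = FALSE, unit = series$unit)
}

#' Hemagglutination titer
#'
#' The titer is `2^-n` where `n` indexes the last agglutination-positive well
#' of the leading contiguous positive block in a 2-fold lectin dilution
#' series (well 0 = undiluted). With no positive well, `n = 0` and
#' `positive_at_start = FALSE`.
#'
#' @param outcomes logical vector, `TRUE` = positive agglutination, highest
#'   lectin concentration first.
#' @return object of class `titer_result`: list with `titer_exponent` (n),
#'   `titer` (2^-n) and `positive_at_start`.
#' @export
hai_titer <- function(outcomes) {
  if (length(outcomes) == 0L || anyNA(outcomes) || !is.logical(outcomes))
    stop_validation("outcomes must be a non-empty logical vector")
  if (!outcomes[1L]) {
    res <- list(titer_exponent = 0L, titer = 1, positive_at_start = FALSE)
  } else {
    n <- rle(outcomes)$lengths[1L] - 1L
    res <- list(titer_exponent = n, titer = 2^-n, positive_at_start = TRUE)
  }
  structure(res, class = "titer_result")
}

#' @export
print.titer_result <- function(x, ...) {
  cat(sprintf("Hemagglutination titer: 2^-%d%s\n", x$titer_exponent,
              if (!x$positive_at_start) " (no agglutination at start)" else ""))
  invisible(x)
}

#' Read HAI plate records from CSV
#'
#' Expects columns `saccharide`, `lectin`, `start_conc`, `unit`, `outcomes`
#' where `outcomes` is a string of 1/0 well scores such as `"111111000"`
#' (1 = complete inhibition), highest concentration first.
#'
#' @param path CSV path.
#' @return data.frame with one [dilution_series()] per row in the
#'   `series` list-column.
#' @export
read_hai_csv <- function(path) {
  if (!file.exists(path)) stop_io(paste0("HAI file not found: ", path))
  df <- read.csv(path, colClasses = "character")
  needed <- c("saccharide", "lectin", "start_conc", "unit", "outcomes")
  if (!all(needed %in% names(df)))
    stop_validation(paste0("HAI CSV needs columns: ",
                           paste(needed, collapse = ", ")))
  df$series <- lapply(seq_len(nrow(df)), function(i) {
    bits <- strsplit(df$outcomes[i], "")[[1]]
    if (!all(bits %in% c("0", "1")))
      stop_validation(paste0("outcomes must be a 0/1 string, got: ",
                             df$outcomes[i]))
    dilution_series(as.numeric(df$start_conc[i]), bits == "1",
                    unit = df$unit[i])
  })
  df
}

#' Tabulate MICs for a set of HAI records
#'
#' Builds a saccharide-by-lectin table of displayed MIC strings mirroring a
#' published inhibition table, including `">"` censoring.
#'
#' @param records data.frame from [read_hai_csv()].
#' @param sigfigs significant figures for display.
#' @return data.frame, one row per saccharide, one column per lectin.
#' @export
hai_report <- function(records, sigfigs = 3) {
  mics <- vapply(records$series,
                 function(s) format(mic(s), sigfigs = sigfigs), character(1))
  wide <- reshape(
    data.frame(saccharide = records$saccharide, lectin = records$lectin,
               mic = mics, stringsAsFactors = FALSE),
    idvar = "saccharide", timevar = "lectin", direction = "wide"
  )
  names(wide) <- sub("^mic\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}
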