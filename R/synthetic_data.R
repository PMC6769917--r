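#' @title Synthetic data generator
#' @description Seeded generators for every input the pipeline consumes: a
#'   130-glycan archetype panel, true per-glycan affinity maps for three
#'   lectin binding archetypes, sigmoid breakthrough curves with fluorescence
#'   noise, concentration-dependence calibration series, and two-fold HAI
#'   dilution plates. Everything is bit-reproducible given (seed, config);
#'   each operation draws from its own RNG stream keyed by (seed, operation)
#'   so fixtures stay independent.
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' @param A0 infused analyte concentration, mol/L (default 2.5e-9: the 2.5 nM
#'   standard loading of PA-oligosaccharide FAC runs).
#' @param front_sigma breakthrough-front width (normal-CDF sigma), uL.
#' @param noise_cv fluorescence noise, fraction of the plateau.
#' @param v_grid `c(start, stop, step)` volume grid, uL.
#' @param v0_true elution-front volume of the non-binding standard, uL
#'   (default 31.4, the miniature-column bed volume).
#' @param plateau saturation signal level, arbitrary units.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(A0 = 2.5e-9, front_sigma = 1.5, noise_cv = 0.02,
                       v_grid = c(0, 1200, 0.5), v0_true = 31.4,
                       plateau = 1) {
  if (A0 <= 0) stop_validation("A0 must be > 0")
  if (noise_cv < 0) stop_validation("noise_cv must be >= 0")
  if (length(v_grid) != 3L || v_grid[3] <= 0)
    stop_validation("v_grid must be c(start, stop, step) with step > 0")
  structure(list(A0 = A0, front_sigma = front_sigma, noise_cv = noise_cv,
                 v_grid = v_grid, v0_true = v0_true, plateau = plateau),
            class = "sim_config")
}

#' Lectin binding archetypes
#' @export
LECTIN_ARCHETYPES <- c("PPL2A_like", "PPL3_like", "PPL4_like", "nonbinder")

#' Construct a lectin binding archetype
#'
#' Encodes the qualitative binding rules of the three pearl-shell lectin
#' archetypes as class/motif support rules plus a log-normal Kd dispersion:
#' \describe{
#'   \item{PPL2A_like}{binds agalacto-, galactosylated- and sialylated-type
#'     N-glycans (skipping bisecting-GlcNAc and four-branch glycans and the
#'     plant-core glycan "017") plus the core pentasaccharide; Kd centered at
#'     2e-7 M.}
#'   \item{PPL3_like}{same support plus "017", ~100x weaker (center 2e-5 M).}
#'   \item{PPL4_like}{binds high-mannose- and hybrid-type N-glycans,
#'     Man-alpha1-6-Man-flagged glycans and chitin-type oligomers, but no
#'     complex-type glycans and nothing carrying only the Man-alpha1-3-Man
#'     arm; center 2e-5 M.}
#'   \item{nonbinder}{binds nothing.}
#' }
#'
#' @param name one of [LECTIN_ARCHETYPES].
#' @return list of class `lectin_archetype` with fields `name`, `Kd_center`
#'   (mol/L), `log10_sd`, and a `support` function mapping a panel to a
#'   logical vector.
#' @export
lectin_archetype <- function(name = LECTIN_ARCHETYPES) {
  name <- match.arg(name)
  complex_support <- function(panel) {
    panel$class %in% c("agalacto", "galactosylated", "sialylated") &
      !panel$bisecting_glcnac & !panel$four_branch
  }
  spec <- switch(
    name,
    PPL2A_like = list(
      Kd_center = 2e-7,
      support = function(panel)
        (complex_support(panel) & panel$id != "017") | panel$core_pentasaccharide
    ),
    PPL3_like = list(
      Kd_center = 2e-5,
      support = function(panel)
        (complex_support(panel) | panel$id == "017") | panel$core_pentasaccharide
    ),
    PPL4_like = list(
      Kd_center = 2e-5,
      support = function(panel)
        (panel$class %in% c("high_mannose", "hybrid") |
           panel$man_a1_6_man | panel$chitin_type) &
          !(panel$man_a1_3_man & !panel$man_a1_6_man)
    ),
    nonbinder = list(
      Kd_center = 1,
      support = function(panel) rep(FALSE, nrow(panel))
    )
  )
  structure(list(name = name, Kd_center = spec$Kd_center, log10_sd = 0.3,
                 support = spec$support),
            class = "lectin_archetype")
}

#' Generate the 130-glycan archetype panel
#'
#' A synthetic stand-in for a real profiling panel: 130 glycans of which 61
#' are N-linked (9 high-mannose, 8 hybrid, 12 agalacto, 20 galactosylated,
#' 12 sialylated), 39 glycolipid-type, and 30 others. Sentinel records mirror
#' glycans named in the profiling literature: "003"/"015" (high-mannose core
#' pentasaccharide), "017" (plant-type Man3Fuc1Xyl1GlcNAc2 core), "913"
#' (Man-alpha1-3-Man only), "914"/"915" (Man-alpha1-6-Man without the
#' alpha1-3 arm), and "701"-"710" (chitin-type GlcNAc oligomers). The panel
#' is deterministic; the seed argument is kept for interface symmetry with
#' the other generators.
#'
#' @param seed unused (the panel composition is fixed); kept so all
#'   generators share the `(seed)` calling convention.
#' @return a [glycan_panel()] of 130 records.
#' @export
make_archetype_panel <- function(seed = 1) {
  id3 <- function(x) sprintf("%03d", x)
  rec <- function(ids, class, name = NULL) {
    data.frame(id = ids,
               name = if (is.null(name))
                 paste0(gsub("_", "-", class), " glycan ", ids) else name,
               class = class, stringsAsFactors = FALSE)
  }
  df <- rbind(
    rec(id3(c(1:6, 9, 10, 15)), "high_mannose"),
    rec(id3(51:58), "hybrid"),
    rec(id3(c(101:105, 201:207)), "agalacto"),
    rec(id3(c(301:314, 401:406)), "galactosylated"),
    rec(id3(501:512), "sialylated"),
    rec(id3(901:939), "glycolipid"),
    rec(id3(16:35), "other"),
    rec(id3(701:710), "other")
  )
  named <- c("003" = "Man3GlcNAc2 core pentasaccharide",
             "015" = "Man3GlcNAc2 core pentasaccharide (agalacto arm)",
             "017" = "Man3Fuc1Xyl1GlcNAc2 (plant-type core)",
             "913" = "glycolipid glycan with Man-a1-3Man arm",
             "914" = "glycolipid glycan with Man-a1-6Man arm",
             "915" = "glycolipid glycan with extended Man-a1-6Man arm")
  df$name[match(names(named), df$id)] <- named

  flags <- list(
    core_pentasaccharide = c("003", "015"),
    plant_fuc_xyl_core = "017",
    man_a1_6_man = c("914", "915"),
    man_a1_3_man = "913",
    bisecting_glcnac = id3(c(104, 203, 204, 303, 305, 308, 310, 406, 511, 512)),
    four_branch = id3(c(205, 206, 207, 309, 311, 312)),
    chitin_type = id3(701:710)
  )
  for (m in names(flags)) df[[m]] <- df$id %in% flags[[m]]
  glycan_panel(df, provenance = "synthetic archetype panel")
}

#' True per-glycan affinities for a lectin archetype
#'
#' Draws one standard-normal deviate per panel glycan from the stream keyed
#' by (seed, panel) and maps supported glycans to
#' `Kd = Kd_center * 10^(log10_sd * z)`. Because the deviates are keyed to
#' the panel and not to the archetype, archetypes sharing support (the
#' PPL2A-like and PPL3-like pair) yield glycan-by-glycan correlated profiles
#' separated by the ratio of their centers - matching the "same specificity,
#' ~100-fold weaker" relationship the archetypes model.
#'
#' @param archetype a [lectin_archetype()] or archetype name.
#' @param panel a [glycan_panel()].
#' @param seed integer seed.
#' @return named numeric vector over `panel$id`: Kd in mol/L, `NA` for
#'   unbound glycans.
#' @export
true_affinities <- function(archetype, panel, seed = 1) {
  if (is.character(archetype)) archetype <- lectin_archetype(archetype)
  stopifnot(inherits(archetype, "lectin_archetype"),
            inherits(panel, "glycan_panel"))
  z <- withr::with_seed(stream_seed(seed, "glycan_deviates"),
                        rnorm(nrow(panel)))
  kd <- rep(NA_real_, nrow(panel))
  sup <- archetype$support(panel)
  kd[sup] <- archetype$Kd_center * 10^(archetype$log10_sd * z[sup])
  setNames(kd, panel$id)
}

#' Simulate a breakthrough elution curve
#'
#' Signal = `plateau * pnorm((v - v_front_true) / front_sigma)` plus Gaussian
#' noise with sd `noise_cv * plateau`; the normal CDF is the simplest
#' dispersion surrogate for a breakthrough front. Deterministic per seed.
#'
#' @param v_front_true true front volume, uL; must lie inside the grid.
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return an [elution_curve()].
#' @export
simulate_elution_curve <- function(v_front_true, cfg = sim_config(),
                                   seed = 1) {
  g <- cfg$v_grid
  if (v_front_true < g[1] || v_front_true > g[2])
    stop_validation("v_front_true must lie within the volume grid")
  if (g[3] > cfg$front_sigma)
    warning("volume grid step exceeds front_sigma: front undersampled")
  v <- seq(g[1], g[2], by = g[3])
  clean <- cfg$plateau * pnorm((v - v_front_true) / cfg$front_sigma)
  noise <- if (cfg$noise_cv > 0)
    withr::with_seed(stream_seed(seed, "elution_noise"),
                     rnorm(length(v), 0, cfg$noise_cv * cfg$plateau))
  else 0
  elution_curve(v, clean + noise)
}

#' Simulate a concentration-dependence calibration series
#'
#' `v_minus_v0 = retardation_forward(Bt, Kd, A0) * (1 + eps)` with
#' `eps ~ Normal(0, noise_cv)`. The default design spans 0.1-10 x Kd in five
#' points, bracketing the isotherm's informative range.
#'
#' @param Bt effective ligand content, nmol.
#' @param Kd dissociation constant of the calibration ligand, mol/L.
#' @param A0_list analyte concentrations, mol/L (default
#'   `Kd * c(0.1, 0.3, 1, 3, 10)`).
#' @param noise_cv multiplicative noise fraction (default 0: noiseless).
#' @param seed integer seed.
#' @return data.frame with columns `A0`, `v_minus_v0`.
#' @export
simulate_calibration_series <- function(Bt, Kd,
                                        A0_list = Kd * c(0.1, 0.3, 1, 3, 10),
                                        noise_cv = 0, seed = 1) {
  if (length(A0_list) == 0L || any(A0_list <= 0))
    stop_validation("A0_list must be non-empty and positive")
  v <- retardation_forward(Bt, Kd, A0_list)
  if (noise_cv > 0) {
    eps <- withr::with_seed(stream_seed(seed, "calibration_noise"),
                            rnorm(length(v), 0, noise_cv))
    v <- v * (1 + eps)
  }
  data.frame(A0 = A0_list, v_minus_v0 = v)
}

#' Simulate retardation measurements for an archetype over a panel
#'
#' Converts the archetype's true affinity map to expected retardations under
#' the given calibration and applies multiplicative front noise; unbound
#' glycans get a small additive jitter around zero (sd `null_sd`), emulating
#' front-detection scatter on non-retarded curves.
#'
#' @param archetype a [lectin_archetype()] or name.
#' @param panel a [glycan_panel()].
#' @param calibration a [column_calibration()].
#' @param cfg a [sim_config()] (supplies `A0` and `noise_cv`).
#' @param seed integer seed.
#' @param null_sd additive jitter for unbound glycans, uL (default 0.1).
#' @return data.frame with columns `glycan_id`, `A0`, `v_minus_v0`.
#' @export
simulate_measurements <- function(archetype, panel, calibration,
                                  cfg = sim_config(), seed = 1,
                                  null_sd = 0.1) {
  kd <- true_affinities(archetype, panel, seed)
  v <- rep(0, nrow(panel))
  bound <- !is.na(kd)
  v[bound] <- retardation_forward(calibration$Bt, kd[bound], cfg$A0)
  withr::with_seed(stream_seed(seed, "measurement_noise"), {
    if (cfg$noise_cv > 0)
      v[bound] <- v[bound] * (1 + rnorm(sum(bound), 0, cfg$noise_cv))
    if (null_sd > 0)
      v[!bound] <- rnorm(sum(!bound), 0, null_sd)
  })
  data.frame(glycan_id = panel$id, A0 = cfg$A0, v_minus_v0 = v,
             stringsAsFactors = FALSE)
}

#' Simulate a full FAC run as elution curves
#'
#' One standard (non-binding) curve at `v0_true` plus one curve per panel
#' glycan at `v0_true + retardation`; unbound glycans elute with the
#' standard. Curve seeds are offset per glycan so noise realizations differ.
#'
#' @inheritParams simulate_measurements
#' @return list with `standard` (an [elution_curve()]) and `curves` (named
#'   list of [elution_curve()] per glycan id).
#' @export
simulate_fac_run <- function(archetype, panel, calibration,
                             cfg = sim_config(), seed = 1) {
  kd <- true_affinities(archetype, panel, seed)
  bound <- !is.na(kd)
  v_true <- rep(cfg$v0_true, length(kd))
  v_true[bound] <- v_true[bound] +
    retardation_forward(calibration$Bt, kd[bound], cfg$A0)
  v_true <- pmin(v_true, cfg$v_grid[2])  # clip pathological tails to the grid
  curves <- lapply(seq_along(v_true), function(i)
    simulate_elution_curve(v_true[i], cfg, seed = seed + i))
  names(curves) <- panel$id
  list(standard = simulate_elution_curve(cfg$v0_true, cfg, seed = seed),
       curves = curves)
}

#' Simulate an HAI dilution plate
#'
#' Deterministically, well k inhibits iff its concentration
#' `start_conc / factor^k` is at least `true_mic`; an optional flip rate
#' introduces scoring errors for robustness tests.
#'
#' @param true_mic true minimum inhibitory concentration.
#' @param start_conc starting concentration (> 0).
#' @param factor dilution factor.
#' @param n_wells number of wells.
#' @param flip_rate per-well probability of flipping the outcome (default 0).
#' @param seed integer seed (used only when `flip_rate > 0`).
#' @param unit unit tag.
#' @return a [dilution_series()].
#' @export
simulate_hai_plate <- function(true_mic, start_conc = 250, factor = 2,
                               n_wells = 8, flip_rate = 0, seed = 1,
                               unit = "mM") {
  if (start_conc <= 0) stop_validation("start_conc must be > 0")
  conc <- start_conc / factor^(seq_len(n_wells) - 1L)
  outcomes <- conc >= true_mic
  if (flip_rate > 0) {
    flips <- withr::with_seed(stream_seed(seed, "hai_flips"),
                              runif(n_wells) < flip_rate)
    outcomes <- xor(outcomes, flips)
  }
  dilution_series(start_conc, outcomes, factor = factor, unit = unit)
}
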