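#' @title Glycan panels
#' @description A glycan panel is an ordered table of glycan records: a string
#'   id (zero-padded codes such as `"017"` are preserved verbatim), a free-text
#'   name, a structural class, and a set of independent boolean motif flags.
#'   The structural classes are the axes of an affinity bar profile:
#'   high-mannose, hybrid, agalacto, galactosylated and sialylated N-linked
#'   glycans, glycolipid-type glycans, and others.
#' @name glycan_panel
NULL

#' Recognized glycan structural classes
#' @export
GLYCAN_CLASSES <- c(
  "high_mannose", "hybrid", "agalacto", "galactosylated", "sialylated",
  "glycolipid", "other"
)

#' Recognized glycan motif flags
#'
#' Independent booleans carried per glycan: Man-alpha1-6-Man and
#' Man-alpha1-3-Man arms, bisecting GlcNAc, the N-glycan core pentasaccharide,
#' the plant-type core (alpha1-3 fucose / beta1-2 xylose), four-branch
#' (tetra-antennary) complex glycans, and chitin-type GlcNAc oligomers.
#' Motifs are supplied as input columns, not derived from structures.
#'
#' @export
GLYCAN_MOTIFS <- c(
  "man_a1_6_man", "man_a1_3_man", "bisecting_glcnac", "core_pentasaccharide",
  "plant_fuc_xyl_core", "four_branch", "chitin_type"
)

#' Construct a glycan panel
#'
#' @param records data.frame with columns `id` (character), `name`, `class`
#'   (one of [GLYCAN_CLASSES]), and one logical/0-1 column per motif in
#'   [GLYCAN_MOTIFS] (missing motif columns are filled with `FALSE`).
#' @param provenance free-text provenance note.
#' @return An object of class `glycan_panel`: the validated data.frame with
#'   logical motif columns, row order as supplied.
#' @export
glycan_panel <- function(records, provenance = "") {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop_validation("a glycan panel needs at least one record")
  needed <- c("id", "name", "class")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop_validation(paste0("panel is missing column(s): ",
                           paste(missing_cols, collapse = ", ")))
  records$id <- as.character(records$id)
  records$name <- as.character(records$name)
  records$class <- as.character(records$class)
  dup <- unique(records$id[duplicated(records$id)])
  if (length(dup))
    stop_validation(paste0("duplicate glycan id(s): ",
                           paste(dup, collapse = ", ")))
  bad <- setdiff(unique(records$class), GLYCAN_CLASSES)
  if (length(bad))
    stop_validation(paste0("unknown glycan class label(s): ",
                           paste(bad, collapse = ", ")))
  for (m in GLYCAN_MOTIFS) {
    if (m %in% names(records)) {
      v <- records[[m]]
      if (is.numeric(v)) v <- v != 0
      if (!is.logical(v) || anyNA(v))
        stop_validation(paste0("motif column '", m, "' must be 0/1 or logical"))
      records[[m]] <- v
    } else {
      records[[m]] <- FALSE
    }
  }
  records <- records[, c(needed, GLYCAN_MOTIFS)]
  rownames(records) <- NULL
  structure(records, provenance = provenance,
            class = c("glycan_panel", "data.frame"))
}

#' Read a glycan panel from a TSV file
#'
#' The file must be UTF-8, tab-separated, with a header row providing `id`,
#' `name`, `class` and optionally one 0/1 column per motif flag. Ids are read
#' as character so leading zeros survive. Record order is preserved.
#'
#' @param path path to the panel TSV.
#' @return a [glycan_panel()].
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop_io(paste0("panel file not found: ", path))
  df <- read.delim(path, sep = "\t", colClasses = "character",
                   check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop_validation(paste0("panel file is empty: ", path))
  for (m in intersect(GLYCAN_MOTIFS, names(df))) df[[m]] <- as.integer(df[[m]])
  glycan_panel(df, provenance = path)
}

#' Write a glycan panel to a TSV file
#'
#' Inverse of [load_panel()]: `load_panel(write_panel(panel, path))` returns a
#' panel with identical records.
#'
#' @param panel a [glycan_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  df <- as.data.frame(panel)
  for (m in GLYCAN_MOTIFS) df[[m]] <- as.integer(df[[m]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Count panel records per structural class
#'
#' @param panel a [glycan_panel()].
#' @return named integer vector over [GLYCAN_CLASSES]; values sum to
#'   `nrow(panel)`.
#' @export
class_counts <- function(panel) {
  stopifnot(inherits(panel, "glycan_panel"))
  tab <- table(factor(panel$class, levels = GLYCAN_CLASSES))
  setNames(as.integer(tab), names(tab))
}

#' @export
print.glycan_panel <- function(x, ...) {
  cat("Glycan panel:", nrow(x), "records\n")
  cc <- class_counts(x)
  cc <- cc[cc > 0]
  cat(paste0("  ", names(cc), ": ", cc, collapse = "\n"), "\n")
  invisible(x)
}
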