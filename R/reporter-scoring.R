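#' Reporter measurement entering the expression index
#'
#' Holds the four total fluorescence intensities (TFI) of a ratiometric
#' promoter-activity assay: the TFBS-driven GFP construct and the
#' co-transfected AsRed2 transfection control in the test well, and the
#' ARE-driven GFP control construct (ARE is the binding site of the
#' prokaryotic factor ampR, non-responsive in eukaryotic cells) and its
#' AsRed2 control in the control well.
#'
#' @param tfi_tfbs,tfi_asred2_test,tfi_are,tfi_asred2_ctrl Total
#'   fluorescence intensities, all strictly positive.
#' @param condition Label, `"activator"` or `"medium"`.
#' @return An object of class `reporter_measurement`.
#' @export
reporter_measurement <- function(tfi_tfbs, tfi_asred2_test, tfi_are,
                                 tfi_asred2_ctrl,
                                 condition = c("activator", "medium")) {
  condition <- match.arg(condition)
  vals <- list(tfi_tfbs = tfi_tfbs, tfi_asred2_test = tfi_asred2_test,
               tfi_are = tfi_are, tfi_asred2_ctrl = tfi_asred2_ctrl)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stopf("'%s' must be a single positive finite intensity", nm)
    }
  }
  structure(c(vals, list(condition = condition)),
            class = "reporter_measurement")
}

#' Ratiometric expression index of a promoter construct
#'
#' Computes the normalized activity of a TFBS-driven reporter:
#' \deqn{\mathrm{Index} = \frac{\mathrm{TFI}_{\mathrm{TFBS\mbox{-}GFP}} /
#'   \mathrm{TFI}_{\mathrm{AsRed2,test}}}{\mathrm{TFI}_{\mathrm{ARE\mbox{-}GFP}} /
#'   \mathrm{TFI}_{\mathrm{AsRed2,ctrl}}}}
#' Each GFP signal is first normalized by its own well's AsRed2 signal
#' (transfection efficiency), then the test ratio is referenced to the
#' non-responsive ARE control ratio. The index is strictly positive,
#' equals 1 when a construct is measured against itself, and is
#' invariant under common rescaling of all four intensities.
#'
#' By default each well uses its matched AsRed2 value;
#' `shared_denominator = TRUE` uses the test well's AsRed2 for both
#' ratios (a single-denominator reading of the formula).
#'
#' @param m A [reporter_measurement()].
#' @param shared_denominator Use the test-well AsRed2 in both ratios.
#' @return A positive number.
#' @examples
#' m <- reporter_measurement(200, 100, 50, 100)
#' expression_index(m)  # 4
#' @export
expression_index <- function(m, shared_denominator = FALSE) {
  stopifnot(inherits(m, "reporter_measurement"))
  check_flag(shared_denominator, "shared_denominator")
  ctrl_red <- if (shared_denominator) m$tfi_asred2_test else
    m$tfi_asred2_ctrl
  (m$tfi_tfbs / m$tfi_asred2_test) / (m$tfi_are / ctrl_red)
}

#' Map a stained/fluorescent area fraction to its area level
#'
#' Section-area bins: `[0,5%) = 0`, `[5,20%) = 1`, `[20,40%) = 2`,
#' `[40,60%) = 3`, `[60,80%) = 4`, `[80,100%] = 5`. Bins are half-open
#' on the right with the last bin closed, so every fraction maps to
#' exactly one level and the function is a total, monotone step
#' function on `[0, 1]`.
#'
#' @param area_fraction Numeric vector of fractions in `[0, 1]`.
#' @return Integer vector of levels in `0..5`.
#' @export
area_level <- function(area_fraction) {
  if (!is.numeric(area_fraction) || anyNA(area_fraction) ||
      any(area_fraction < 0 | area_fraction > 1)) {
    stopf("'area_fraction' must be numeric in [0, 1]")
  }
  findInterval(area_fraction, c(0.05, 0.20, 0.40, 0.60, 0.80))
}

#' Intensity-by-area expression score
#'
#' H-score-style quantification of a micrograph field: the score is the
#' intensity grade (0-3) times the area level (0-5 via [area_level()]),
#' giving an integer in `0..15`. Vectorized over fields.
#'
#' @param intensity_level Integer grades in `{0, 1, 2, 3}`.
#' @param area_fraction Fractions in `[0, 1]` (recycled against
#'   `intensity_level`).
#' @return A data frame with columns `intensity_level`,
#'   `area_fraction`, `area_level`, `score`.
#' @examples
#' quant_score(3, 0.9)$score  # 15
#' @export
quant_score <- function(intensity_level, area_fraction) {
  if (!is.numeric(intensity_level) || anyNA(intensity_level) ||
      any(intensity_level != round(intensity_level)) ||
      any(intensity_level < 0 | intensity_level > 3)) {
    stopf("'intensity_level' must be integers in {0, 1, 2, 3}")
  }
  lvl <- area_level(area_fraction)
  n <- max(length(intensity_level), length(lvl))
  intensity_level <- rep_len(as.integer(intensity_level), n)
  area_fraction <- rep_len(area_fraction, n)
  lvl <- rep_len(lvl, n)
  data.frame(intensity_level = intensity_level,
             area_fraction = area_fraction,
             area_level = lvl,
             score = intensity_level * lvl)
}

#' Average expression score over random fields of a section
#'
#' Sections are scored over several random microscope fields (typically
#' ten at 200x magnification) and summarized by the mean
#' intensity-by-area score.
#'
#' @param intensity_levels,area_fractions Per-field grades and area
#'   fractions (equal length).
#' @return The mean score, a number in `[0, 15]`.
#' @export
mean_field_score <- function(intensity_levels, area_fractions) {
  if (length(intensity_levels) != length(area_fractions)) {
    stopf("per-field vectors must have equal length")
  }
  mean(quant_score(intensity_levels, area_fractions)$score)
}

#' Quantize a raw intensity summary into a 0-3 grade
#'
#' A configurable three-threshold quantizer for synthetic image
#' summaries (visual grading of real sections is out of scope): values
#' below the first threshold grade 0, then 1, 2 and 3.
#'
#' @param raw Numeric vector of raw intensity summaries.
#' @param thresholds Increasing vector of three cut points.
#' @return Integer grades in `0..3`.
#' @export
intensity_grade <- function(raw, thresholds = c(50, 120, 200)) {
  if (length(thresholds) != 3L || is.unsorted(thresholds,
                                              strictly = TRUE)) {
    stopf("'thresholds' must be three strictly increasing cut points")
  }
  findInterval(raw, thresholds)
}

#' Tumor volume from caliper dimensions
#'
#' Volume in cubic millimetres as length x width x height; invariant
#' under permutation of the three dimensions. Vectorized.
#'
#' @param length,width,height Dimensions in mm, all > 0.
#' @return Volumes in mm^3.
#' @export
tumor_volume <- function(length, width, height) {
  dims <- list(length = length, width = width, height = height)
  for (nm in names(dims)) {
    v <- dims[[nm]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)) || any(v <= 0)) {
      stopf("'%s' must be positive and finite", nm)
    }
  }
  length * width * height
}

#' Two-group comparison of independent measurements
#'
#' Welch's unequal-variance two-sample t-test by default (the classical
#' equal-variance test is selectable), as used to compare two
#' independent trials with significance at p < 0.05.
#'
#' @param a,b Numeric vectors, each with at least 2 finite values.
#' @param var_equal Assume equal variances (classical t-test).
#' @return A list with elements `t` (statistic), `p` (two-sided
#'   p-value), `df`, and `method`.
#' @export
compare_groups <- function(a, b, var_equal = FALSE) {
  for (g in list(a = a, b = b)) {
    if (!is.numeric(g) || length(g) < 2L || any(!is.finite(g))) {
      stopf("each group needs >= 2 finite values")
    }
  }
  check_flag(var_equal, "var_equal")
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    # identical constant groups: no evidence of difference
    return(list(t = 0, p = 1, df = length(a) + length(b) - 2,
                method = if (var_equal) "t-test" else "Welch t-test"))
  }
  fit <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(fit$statistic), p = fit$p.value,
       df = unname(fit$parameter), method = fit$method)
}
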