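# Quantification arithmetic: reference normalisation, time courses,
# drop-off frequency (+/- tylosin), drop-off rate from n-mer ratios, and
# calibration-curve absolute quantification.

#' Normalise peak areas against a reference species
#'
#' In the pep-tRNA workflow, areas of acetyl-aminoacyl- and
#' acetyl-peptidyl-adenosine species are normalised against the peak area of
#' formyl-Met-adenosine (f-Met-Ado), whose steady-state level is unaffected
#' by short PTH inactivation.
#'
#' @param area numeric peak area(s), >= 0.
#' @param refArea reference peak area(s), > 0 (recycled).
#' @return area / refArea, elementwise.
#' @export
relToReference <- function(area, refArea) {
  if (any(!is.finite(refArea)) || any(refArea <= 0))
    stop("reference area must be positive")
  area / refArea
}

#' Relative time course of a species
#'
#' Two conventions: \code{"to_t0"} (amino-acyl species) first normalises
#' each timepoint against the reference area at that timepoint, then divides
#' by the t=0 value; \code{"to_reference"} (dipeptidyl species) reports the
#' per-timepoint reference-normalised value directly.
#'
#' @param areas numeric vector of peak areas, ordered by timepoint.
#' @param refAreas optional reference areas per timepoint (required
#'   for meaningful \code{to_t0} on raw areas; omit if already normalised).
#' @param mode \code{"to_t0"} or \code{"to_reference"}.
#' @param t0Index index of the baseline timepoint (default 1).
#' @return numeric vector of relative values; a zero baseline in
#'   \code{to_t0} mode yields \code{NA} with a warning.
#' @export
timecourseRelative <- function(areas, refAreas = NULL,
                               mode = c("to_t0", "to_reference"),
                               t0Index = 1L) {
  mode <- match.arg(mode)
  x <- if (is.null(refAreas)) areas else relToReference(areas, refAreas)
  if (mode == "to_reference") return(x)
  if (t0Index < 1L || t0Index > length(x))
    stop("t0Index out of range")
  if (!is.finite(x[t0Index]) || x[t0Index] == 0) {
    warning("zero/undefined baseline at t0: relative values are NA")
    return(rep(NA_real_, length(x)))
  }
  x / x[t0Index]
}

#' Summed abundance of a series set, optionally percent of baseline
#'
#' Sums reference-normalised series (rows = species, columns = timepoints)
#' per timepoint; in percent mode the summed profile is rescaled so the
#' baseline timepoint reads 100 (rescaling leaves between-timepoint ratios
#' invariant).
#'
#' @param series numeric matrix (species x timepoints) or list of equal
#'   length numeric vectors.
#' @param percent rescale to percent of the baseline timepoint?
#' @param baseline baseline timepoint index (default 1, i.e. t=0).
#' @return numeric per-timepoint vector.
#' @export
summedAbundance <- function(series, percent = FALSE, baseline = 1L) {
  if (is.list(series)) series <- do.call(rbind, series)
  if (!is.matrix(series)) series <- matrix(series, nrow = 1L)
  if (!nrow(series)) stop("need at least one series")
  s <- colSums(series)
  if (percent) {
    if (baseline < 1L || baseline > length(s) || s[baseline] == 0)
      stop("invalid baseline timepoint for percent scaling")
    s <- s / s[baseline] * 100
  }
  s
}

#' Drop-off frequency from the tylosin ratio
#'
#' The apparent drop-off frequency of a dipeptidyl-tRNA is its relative
#' abundance in the absence of tylosin divided by its relative abundance in
#' the presence of a saturating tylosin concentration (0.1 mg/ml), which
#' represents the maximum dissociable pool. Values above 100 percent are
#' possible with noisy inputs and are flagged with a warning rather than
#' clipped.
#'
#' @param noDrugRel relative abundance without drug (vectorised).
#' @param tylRel relative abundance with saturating tylosin, > 0.
#' @param percent report as percentage (default) or fraction.
#' @return elementwise ratio.
#' @export
dropoffFrequency <- function(noDrugRel, tylRel, percent = TRUE) {
  if (any(!is.finite(tylRel)) || any(tylRel <= 0))
    stop("tylosin-treated relative abundance must be positive")
  r <- noDrugRel / tylRel
  if (any(r > 1, na.rm = TRUE))
    warning(sum(r > 1, na.rm = TRUE),
            " drop-off frequency value(s) exceed 100%; not clipped")
  if (percent) r * 100 else r
}

#' Drop-off rate from consecutive n-mer amounts
#'
#' The drop-off rate at codon k is the amount of k-mer pep-tRNA divided by
#' the summed amounts of the k-mer and (k+1)-mer pep-tRNAs, i.e. the
#' fraction of ribosomes at that codon whose pep-tRNA dissociated rather
#' than elongated (applied to the 4-mer/5-mer reporter pair in the original
#' study).
#'
#' @param nK amount of the k-mer species (vectorised).
#' @param nKplus1 amount of the (k+1)-mer species.
#' @return nK / (nK + nKplus1), in [0, 1]; both-zero input is an error.
#' @export
dropoffRate <- function(nK, nKplus1) {
  if (any(nK < 0 | nKplus1 < 0)) stop("amounts must be non-negative")
  tot <- nK + nKplus1
  if (any(tot == 0)) stop("undefined drop-off rate: both amounts are zero")
  nK / tot
}

#' Fit a log-log calibration curve
#'
#' Ordinary least squares of \code{log10(area)} on \code{log10(amount)}
#' (double-logarithmic plot; the slope is not constrained to 1).
#'
#' @param amount known amounts of the synthetic standard (> 0), length >= 2.
#' @param area measured MS peak areas (> 0).
#' @param peptide label.
#' @return a \code{\linkS4class{CalibrationCurve}}.
#' @export
fitCalibration <- function(amount, area, peptide = "peptide") {
  if (length(amount) < 2L || length(amount) != length(area))
    stop("need >= 2 calibration points with matching areas")
  if (any(amount <= 0) || any(area <= 0))
    stop("calibration amounts and areas must be positive")
  fit <- stats::lm(log10(area) ~ log10(amount))
  new("CalibrationCurve", peptide = peptide,
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      amountRange = range(amount))
}

#' Absolute quantification from a calibration curve
#'
#' Inverts the log-log fit: \code{amount = 10^((log10(area) - intercept) /
#' slope)}. Amounts outside the fitted calibration range are flagged via the
#' \code{extrapolated} attribute and a warning.
#'
#' @param area observed peak area(s), > 0.
#' @param curve a \code{\linkS4class{CalibrationCurve}}.
#' @return numeric amount(s), with attribute \code{extrapolated}.
#' @export
absoluteQuantify <- function(area, curve) {
  stopifnot(is(curve, "CalibrationCurve"))
  if (any(!is.finite(area)) || any(area <= 0))
    stop("area must be positive")
  if (curve@slope == 0) stop("degenerate calibration curve (zero slope)")
  amount <- 10^((log10(area) - curve@intercept) / curve@slope)
  # small relative slack so calibration-point round-trips are not flagged
  extra <- amount < curve@amountRange[1L] * (1 - 1e-9) |
    amount > curve@amountRange[2L] * (1 + 1e-9)
  if (any(extra))
    warning(sum(extra), " quantification(s) extrapolate beyond the ",
            "calibration range")
  attr(amount, "extrapolated") <- extra
  amount
}

#' Predicted area at a given amount (calibration forward model)
#'
#' @param amount amount(s) > 0.
#' @param curve a \code{\linkS4class{CalibrationCurve}}.
#' @return predicted MS peak area(s).
#' @export
predictArea <- function(amount, curve) {
  stopifnot(is(curve, "CalibrationCurve"))
  10^(curve@slope * log10(amount) + curve@intercept)
}
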