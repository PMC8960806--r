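#' Gross heat of combustion from bomb calorimetry
#'
#' `Hg = delta_t * E / w`: heat loss times the benzoic-acid calibration
#' energy equivalent, per unit wet weight. Units of `E` are instrument-
#' specific and carried through unchanged.
#'
#' @param delta_t measured heat loss (degrees), vectorized.
#' @param e calibration energy equivalent of the thermochemical standard
#'   (> 0).
#' @param w sample wet weight in g (> 0).
#' @return gross heat of combustion.
#' @export
#' @examples
#' gross_heat(2, 2420, 0.7)
gross_heat <- function(delta_t, e, w) {
  if (any(w <= 0)) stop2("wet weight must be > 0")
  if (any(e <= 0)) stop2("energy equivalent must be > 0")
  delta_t * e / w
}

# subtract a background measurement; negative results are preserved and
# flagged (clipping would hide assay problems)
subtract_background <- function(total, background, what) {
  if (any(total < 0) || any(background < 0))
    stop2("measurements must be >= 0")
  out <- total - background
  flagged <- out < 0
  if (any(flagged))
    warning(sum(flagged), " negative ", what,
            " value(s): background exceeded total", call. = FALSE)
  attr(out, "flagged") <- flagged
  out
}

#' Relative trehalose after free-glucose subtraction
#'
#' Trehalose is measured as glucose after enzymatic digestion; the free
#' glucose present before digestion is subtracted. Negative results (assay
#' noise) are preserved and flagged via the `"flagged"` attribute, not
#' clipped.
#'
#' @param total_glucose_after_digest,free_glucose non-negative measurements,
#'   vectorized.
#' @return total minus free, with a logical `"flagged"` attribute marking
#'   negatives.
#' @export
trehalose_relative <- function(total_glucose_after_digest, free_glucose) {
  subtract_background(total_glucose_after_digest, free_glucose, "trehalose")
}

#' TAG-derived glycerol after free-glycerol subtraction
#'
#' Triglycerides are measured as glycerol after lipase conversion; the free
#' glycerol originally present is subtracted. Negative results are flagged,
#' not clipped.
#'
#' @param total_glycerol,free_glycerol non-negative measurements, vectorized.
#' @return total minus free, with a logical `"flagged"` attribute.
#' @export
triglyceride_net <- function(total_glycerol, free_glycerol) {
  subtract_background(total_glycerol, free_glycerol, "triglyceride")
}

#' Weight-normalized food intake from dye absorbance
#'
#' Inverts a linear standard curve (`absorbance = slope * amount +
#' intercept`) and normalizes the recovered dye amount to larval weight:
#' `((absorbance - intercept) / slope) / weight`.
#'
#' @param absorbance measured absorbance, vectorized.
#' @param slope,intercept linear standard-curve coefficients; `slope` must
#'   be non-zero.
#' @param larval_weight sample weight (> 0).
#' @return weight-normalized intake.
#' @export
#' @examples
#' food_intake(0.5, slope = 0.02, intercept = 0.1, larval_weight = 0.04)
food_intake <- function(absorbance, slope, intercept, larval_weight) {
  if (any(slope == 0)) stop2("standard-curve slope must be non-zero")
  if (any(larval_weight <= 0)) stop2("larval weight must be > 0")
  ((absorbance - intercept) / slope) / larval_weight
}

#' Starvation time of death from an activity series
#'
#' The time of death of an individually housed fly is the timestamp of its
#' last activity bout (last bin with a non-zero beam-break count). A series
#' with no activity at all yields `NA` with a `"no_activity"` attribute.
#'
#' @param timestamps strictly increasing bin timestamps.
#' @param counts activity counts per bin (same length).
#' @return timestamp of the last non-zero bin, or `NA` if none.
#' @export
#' @examples
#' time_of_death(1:6, c(3, 1, 0, 2, 0, 0))  # 4
time_of_death <- function(timestamps, counts) {
  if (length(timestamps) < 1) stop2("need >= 1 activity bin")
  if (length(timestamps) != length(counts))
    stop2("timestamps and counts must have equal length")
  if (any(diff(timestamps) <= 0))
    stop2("timestamps must be strictly increasing")
  if (any(counts < 0)) stop2("activity counts must be >= 0")
  alive <- which(counts > 0)
  if (!length(alive)) {
    out <- NA_real_
    attr(out, "no_activity") <- TRUE
    return(out)
  }
  timestamps[max(alive)]
}
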