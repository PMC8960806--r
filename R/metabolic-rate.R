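#' Fixed coefficient set for indirect-calorimetry conversion
#'
#' Bundles the empirical relationships used to turn CO2 production into
#' standardized resting metabolic rate:
#'
#' * the respiratory quotient (RQ) as a function of the dietary
#'   sugar-to-yeast ratio, `RQ = 0.872 + 0.125 log10(S:Y + 1)`;
#' * the energy equivalent of CO2 as a linear interpolation in RQ between
#'   mixed protein catabolism in a uricotelic species (25.4 J/mL at RQ 0.74)
#'   and pure carbohydrate catabolism (21.1 J/mL at RQ 1):
#'   `EE = 37.64 - 16.54 RQ`;
#' * per-library reference fresh masses (mg) for mass standardization
#'   (GD 0.83, kk 0.77, Trip 0.81).
#'
#' The constructor asserts that the energy line passes through both anchor
#' points to within 0.01 J/mL.
#'
#' @param rq_intercept,rq_slope RQ-vs-log10(S:Y+1) coefficients.
#' @param ee_intercept,ee_slope energy-equivalent line (J/mL; slope per RQ
#'   unit).
#' @param reference_masses named numeric, mg per library label.
#' @param anchors two-point check of the energy line (named numeric: RQ ->
#'   J/mL).
#' @return An object of class `energy_model`.
#' @export
#' @examples
#' em <- energy_model()
#' energy_equivalent(0.74, em)  # 25.4
energy_model <- function(rq_intercept = 0.872, rq_slope = 0.125,
                         ee_intercept = 37.64, ee_slope = -16.54,
                         reference_masses = c(GD = 0.83, kk = 0.77,
                                              Trip = 0.81),
                         anchors = c("0.74" = 25.4, "1" = 21.1)) {
  m <- structure(list(rq_intercept = rq_intercept, rq_slope = rq_slope,
                      ee_intercept = ee_intercept, ee_slope = ee_slope,
                      reference_masses = reference_masses,
                      anchors = anchors),
                 class = "energy_model")
  rq_anchor <- as.numeric(names(anchors))
  pred <- ee_intercept + ee_slope * rq_anchor
  if (any(abs(pred - anchors) > 0.01))
    stop2("energy-equivalent line misses its anchor points by > 0.01 J/mL")
  m
}

#' Built-in diet compositions
#'
#' Sucrose and yeast content (% w/v) of the six defined diets: all share a
#' 10% yeast base; the high-sucrose diet adds 20% sucrose, the western diet
#' 10% sucrose (plus 10% lard), the high-fat and high-starch diets add no
#' sucrose.
#'
#' @return data frame with columns `diet`, `sucrose`, `yeast` (% w/v).
#' @export
diet_compositions <- function() {
  data.frame(
    diet = c("HPD", "HSD", "HFDcoco", "HFDlard", "WD", "HStD"),
    sucrose = c(0, 20, 0, 0, 10, 0),
    yeast = rep(10, 6),
    stringsAsFactors = FALSE
  )
}

#' Dietary sugar-to-yeast ratio
#'
#' @param diet a diet label found in `compositions`, or a list/data frame
#'   row with elements `sucrose` and `yeast` (% w/v).
#' @param compositions lookup table, see [diet_compositions()].
#' @return sucrose / yeast (w/v ratio).
#' @export
#' @examples
#' diet_sy_ratio("HSD")  # 2
diet_sy_ratio <- function(diet, compositions = diet_compositions()) {
  if (is.character(diet)) {
    i <- match(diet, compositions$diet)
    if (anyNA(i)) stop2("unknown diet label: ",
                        paste(diet[is.na(i)], collapse = ", "))
    diet <- compositions[i, ]
  }
  if (any(diet$yeast <= 0)) stop2("diet has no yeast: S:Y ratio undefined")
  diet$sucrose / diet$yeast
}

#' Predict the respiratory quotient from the diet's sugar-to-yeast ratio
#'
#' `RQ = rq_intercept + rq_slope * log10(sy_ratio + 1)`. Values outside the
#' physiological range (0.7, 1\] trigger a warning but are returned
#' unclamped.
#'
#' @param sy_ratio dietary sugar-to-yeast ratio (>= 0), vectorized.
#' @param model an [energy_model()].
#' @return predicted RQ.
#' @export
#' @examples
#' predict_rq(0)  # 0.872: the relationship's intercept
predict_rq <- function(sy_ratio, model = energy_model()) {
  if (any(sy_ratio < 0)) stop2("sy_ratio must be >= 0")
  rq <- model$rq_intercept + model$rq_slope * log10(sy_ratio + 1)
  if (any(rq <= 0.7 | rq > 1))
    warning("predicted RQ outside (0.7, 1]", call. = FALSE)
  rq
}

#' Energy equivalent of CO2 at a given respiratory quotient
#'
#' Linear in RQ; passes through the protein-catabolism (25.4 J/mL, RQ 0.74)
#' and carbohydrate-catabolism (21.1 J/mL, RQ 1) anchors.
#'
#' @param rq respiratory quotient, vectorized.
#' @param model an [energy_model()].
#' @return J per mL CO2.
#' @export
energy_equivalent <- function(rq, model = energy_model()) {
  if (any(rq < 0.7 | rq > 1))
    warning("RQ outside [0.7, 1]: extrapolating the energy line",
            call. = FALSE)
  model$ee_intercept + model$ee_slope * rq
}

#' Convert a CO2 production rate to metabolic power
#'
#' `vco2` in uL/h times the energy equivalent in J/mL gives mJ/h (the unit
#' identity uL x J/mL = mJ).
#'
#' @param vco2 CO2 production rate (uL/h), vectorized; must be >= 0.
#' @param rq respiratory quotient at which to evaluate the energy
#'   equivalent.
#' @param model an [energy_model()].
#' @return metabolic rate in mJ/h.
#' @export
vco2_to_power <- function(vco2, rq, model = energy_model()) {
  if (any(vco2 < 0)) stop2("vco2 must be >= 0")
  vco2 * energy_equivalent(rq, model)
}

#' Add converted metabolic rates to respirometry records
#'
#' Computes each record's RQ from its diet label (via [diet_sy_ratio()] and
#' [predict_rq()]) and fills/overwrites the `mr_mj_per_h` column with
#' [vco2_to_power()].
#'
#' @param records a `respirometry_records` data frame (needs `vco2` and
#'   `diet`).
#' @param compositions diet lookup table.
#' @param model an [energy_model()].
#' @return `records` with `rq` and `mr_mj_per_h` columns.
#' @export
convert_respirometry <- function(records, compositions = diet_compositions(),
                                 model = energy_model()) {
  records <- as.data.frame(records)
  rq <- predict_rq(diet_sy_ratio(records$diet, compositions), model)
  records$rq <- rq
  records$mr_mj_per_h <- vco2_to_power(records$vco2, rq, model)
  structure(records, class = c("respirometry_records", "data.frame"))
}

#' Fit the metabolic-rate standardization model
#'
#' Ordinary least squares of metabolic rate (mJ/h) on experimental condition
#' (categorical), fresh body mass and activity. The mass and activity
#' slopes are what [adjust_mr()] uses to standardize rates to a reference
#' mass and zero activity. The condition factor defaults to the genotype
#' library x diet cell; pass `condition` to override, or `per_library =
#' TRUE` to fit one model per library.
#'
#' @param records a `respirometry_records` data frame with `mr_mj_per_h`,
#'   `fresh_mass`, `activity` and the condition columns.
#' @param condition character vector of column names whose interaction
#'   defines the condition factor (default `c("library", "diet")`, reduced
#'   to those present).
#' @param per_library fit separately per library? Returns a named list of
#'   fits.
#' @return An object of class `standardization_fit`: `condition_means`,
#'   `mass_slope`, `activity_slope`, their SEs and t-statistics, residual
#'   `df`, and the `lm` fit in `$model`.
#' @export
fit_standardization <- function(records, condition = c("library", "diet"),
                                per_library = FALSE) {
  records <- as.data.frame(records)
  if (!nrow(records)) stop2("no respirometry records to fit")
  need <- c("mr_mj_per_h", "fresh_mass", "activity")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop2("records lack columns: ",
                          paste(miss, collapse = ", "))
  if (per_library) {
    fits <- lapply(split(records, records$library), fit_standardization,
                   condition = setdiff(condition, "library"),
                   per_library = FALSE)
    return(fits)
  }
  condition <- intersect(condition, names(records))
  cond <- if (length(condition)) {
    interaction(records[condition], drop = TRUE, sep = ":")
  } else {
    factor(rep("all", nrow(records)))
  }
  if (nlevels(cond) < 2) cond <- NULL   # single condition: intercept only
  d <- data.frame(mr = records$mr_mj_per_h,
                  fresh_mass = records$fresh_mass,
                  activity = records$activity)
  form <- mr ~ fresh_mass + activity
  p <- 3
  if (!is.null(cond)) {
    d$condition <- cond
    form <- mr ~ condition + fresh_mass + activity
    p <- nlevels(cond) + 2
  }
  if (nrow(d) < p + 2)
    stop2("need at least ", p + 2, " records for ", p, " parameters")
  fit <- lm(form, data = d)
  cf <- coef(fit)
  if (anyNA(cf))
    stop2("rank deficiency: aliased terms: ",
          paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- summary(fit)$coefficients
  structure(list(
    condition_means = cf[grep("^\\(Intercept\\)|^condition", names(cf))],
    mass_slope = unname(cf["fresh_mass"]),
    mass_se = sm["fresh_mass", "Std. Error"],
    mass_t = sm["fresh_mass", "t value"],
    activity_slope = unname(cf["activity"]),
    activity_se = sm["activity", "Std. Error"],
    activity_t = sm["activity", "t value"],
    df = fit$df.residual,
    model = fit
  ), class = "standardization_fit")
}

#' @export
print.standardization_fit <- function(x, ...) {
  cat("Metabolic-rate standardization (OLS)\n")
  cat(sprintf("  mass slope: %.2f +/- %.2f mJ/h/mg (t[%d] = %.2f)\n",
              x$mass_slope, x$mass_se, x$df, x$mass_t))
  cat(sprintf("  activity slope: %.2f +/- %.2f mJ/h/count (t[%d] = %.2f)\n",
              x$activity_slope, x$activity_se, x$df, x$activity_t))
  invisible(x)
}

#' Standardize metabolic rates to reference mass and zero activity
#'
#' `mr_adjusted = mr - mass_slope (fresh_mass - reference_mass) -
#' activity_slope x activity`, with the reference mass looked up per
#' genotype library. The adjusted value is interpretable as a
#' mass-independent resting metabolic rate. A fly already at its library's
#' reference mass with zero activity is unchanged.
#'
#' @param records a `respirometry_records` data frame with `mr_mj_per_h`,
#'   `fresh_mass`, `activity` and `library`.
#' @param fit a [fit_standardization()] result.
#' @param reference_masses named numeric (mg per library); defaults to the
#'   energy model's values.
#' @return `records` with an `mr_adjusted` column (mJ/h).
#' @export
adjust_mr <- function(records, fit,
                      reference_masses = energy_model()$reference_masses) {
  stopifnot(inherits(fit, "standardization_fit"))
  records <- as.data.frame(records)
  unknown <- setdiff(unique(records$library), names(reference_masses))
  if (length(unknown))
    stop2("no reference mass for library: ", paste(unknown, collapse = ", "))
  ref <- reference_masses[records$library]
  records$mr_adjusted <- records$mr_mj_per_h -
    fit$mass_slope * (records$fresh_mass - ref) -
    fit$activity_slope * records$activity
  structure(records, class = c("respirometry_records", "data.frame"))
}
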