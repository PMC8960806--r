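#' Fit a binomial mixed model to a survival panel
#'
#' Fits the vial-level pupation counts with a binomial (logit link)
#' generalized linear mixed model via [lme4::glmer()] (Laplace approximation
#' to the marginal likelihood). With `random_slopes = FALSE` the model has
#' diet as a categorical fixed effect and a random intercept per strain
#' ("GLMM1"); with `random_slopes = TRUE` it adds a per-strain random slope
#' for diet with an unstructured covariance over (intercept + treatment-coded
#' slopes) ("GLMM2"). The difference in parameter count between the two is
#' what carries the genotype-by-environment signal.
#'
#' @param panel a [panel_table()] (vial-level rows). The reference diet is
#'   the first label of `attr(panel, "diets")`.
#' @param random_slopes add per-strain random diet slopes?
#' @param pool_vials if `TRUE`, vials are summed into one binomial
#'   observation per strain x diet before fitting (the default models vials
#'   individually).
#' @param ... passed to [lme4::glmer()] (e.g. `control`).
#' @return An object of class `glmm_fit`: fixed effects (reference-coded
#'   per-diet log-odds), the estimated strain-level covariance matrix, the
#'   maximized log-likelihood, `deviance = -2 logLik`, AIC (from the AIC
#'   identity), parameter count, a convergence flag with diagnostics, and
#'   the underlying `merMod` in `$model`.
#' @seealso [compare_gxe()], [count_parameters()]
#' @export
fit_binomial_glmm <- function(panel, random_slopes = TRUE,
                              pool_vials = FALSE, ...) {
  panel <- panel_table(panel, diets = attr(panel, "diets"))
  diets <- attr(panel, "diets")
  if (length(unique(panel$strain)) < 2) stop2("need >= 2 strains")
  if (length(unique(panel$diet)) < 2) stop2("need >= 2 diets")
  ref_strains <- unique(panel$strain[panel$diet == diets[1]])
  if (!all(unique(panel$strain) %in% ref_strains))
    stop2("every strain must be observed on the reference diet '", diets[1],
          "'")
  if (pool_vials) {
    agg <- stats::aggregate(cbind(n_seeded, n_pupated, n_eclosed) ~
                              strain + diet, data = panel, FUN = sum)
    agg$vial <- 1L
    panel <- panel_table(agg, diets = diets)
  }
  d <- data.frame(strain = factor(panel$strain),
                  diet = factor(panel$diet, levels = diets),
                  succ = panel$n_pupated,
                  fail = panel$n_seeded - panel$n_pupated)
  form <- if (random_slopes) {
    cbind(succ, fail) ~ diet + (diet | strain)
  } else {
    cbind(succ, fail) ~ diet + (1 | strain)
  }
  warn <- character()
  model <- withCallingHandlers(
    tryCatch(
      lme4::glmer(form, data = d, family = stats::binomial("logit"), ...),
      error = function(e) {
        # a constant response pins every variance component to zero; the
        # marginal likelihood then equals the fixed-effects GLM's
        if (grepl("Response is constant", conditionMessage(e))) {
          stats::glm(cbind(succ, fail) ~ diet, data = d,
                     family = stats::binomial("logit"))
        } else {
          stop(e)
        }
      }),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  k <- length(diets)
  if (inherits(model, "glmerMod")) {
    opt_ok <- isTRUE(model@optinfo$conv$opt == 0)
    singular <- lme4::isSingular(model, tol = 1e-4)
    vc <- lme4::VarCorr(model)$strain
    cov_mat <- matrix(as.numeric(vc), nrow = nrow(vc),
                      dimnames = list(rownames(vc), colnames(vc)))
    fixed <- lme4::fixef(model)
  } else {
    opt_ok <- model$converged
    singular <- TRUE
    dim_re <- if (random_slopes) k else 1L
    cov_mat <- matrix(0, dim_re, dim_re)
    fixed <- coef(model)
    warn <- c(warn, "constant response: variance components fixed at zero")
  }
  conv_warn <- any(grepl("failed to converge", warn, ignore.case = TRUE))
  ll <- as.numeric(logLik(model))
  npar <- count_parameters(k, random_slopes)
  fit <- list(
    fixed_effects = fixed,
    random_structure = if (random_slopes) "intercept_plus_slopes" else
      "intercept_only",
    random_covariance = cov_mat,
    log_likelihood = ll,
    deviance = -2 * ll,
    aic = -2 * ll + 2 * npar,
    n_parameters = npar,
    converged = opt_ok && !conv_warn,
    singular = singular,
    messages = warn,
    n_diets = length(diets),
    diets = diets,
    fingerprint = panel_fingerprint(panel),
    model = model
  )
  if (singular)
    fit$messages <- c(fit$messages,
                      "singular random-effect covariance (boundary fit)")
  structure(fit, class = "glmm_fit")
}

panel_fingerprint <- function(panel) {
  list(n = nrow(panel),
       seeded = sum(panel$n_seeded),
       pupated = sum(panel$n_pupated),
       strains = sort(unique(as.character(panel$strain))),
       diets = attr(panel, "diets"))
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Binomial GLMM (", x$random_structure, "), ",
      x$n_diets, " diets\n", sep = "")
  cat("  logLik:", format(x$log_likelihood, digits = 8),
      " AIC:", format(x$aic, digits = 8),
      " parameters:", x$n_parameters, "\n")
  cat("  converged:", x$converged,
      if (x$singular) " (singular covariance)" else "", "\n")
  invisible(x)
}

#' Parameter count of the survival GLMMs
#'
#' Number of estimated parameters: `n_diets` fixed effects plus one variance
#' parameter (random intercept only) or `n_diets (n_diets + 1) / 2`
#' covariance parameters (unstructured covariance over intercept +
#' treatment-coded slopes). For six diets the two structures differ by 20
#' parameters — the degrees of freedom of the GxE likelihood-ratio test.
#'
#' @param n_diets number of diets (>= 1).
#' @param random_slopes parameter count of the random-slopes model?
#' @return integer parameter count.
#' @export
#' @examples
#' count_parameters(6, FALSE)  # 7
#' count_parameters(6, TRUE)   # 27
count_parameters <- function(n_diets, random_slopes) {
  if (!is.numeric(n_diets) || n_diets < 1 || n_diets != round(n_diets))
    stop2("n_diets must be a count >= 1")
  n_diets <- as.integer(n_diets)
  if (random_slopes) n_diets + (n_diets * (n_diets + 1L)) %/% 2L
  else n_diets + 1L
}

#' Compare nested survival GLMMs for genotype-by-environment interaction
#'
#' Compares a random-intercept fit against a random-slopes fit of the same
#' panel by AIC and a chi-square test on the reduction in deviance. A
#' significant improvement of the slopes model indicates non-zero among-
#' strain variance in the response to diet (GxE). Because the null pins
#' variance components to the boundary of their space, the naive chi-square
#' reference is conservative; a warning notes this.
#'
#' @param fit_null `glmm_fit` with `random_structure = "intercept_only"`.
#' @param fit_gxe `glmm_fit` with at least as many parameters, fit to the
#'   same panel.
#' @return An object of class `gxe_comparison` with `delta_aic`
#'   (slopes − intercept), `chi_square` (deviance reduction), `df` and
#'   `p_value`.
#' @export
compare_gxe <- function(fit_null, fit_gxe) {
  stopifnot(inherits(fit_null, "glmm_fit"), inherits(fit_gxe, "glmm_fit"))
  if (!identical(fit_null$fingerprint, fit_gxe$fingerprint))
    stop2("fits are not on the same panel (data fingerprints differ)")
  df <- fit_gxe$n_parameters - fit_null$n_parameters
  if (df < 0)
    stop2("fit_gxe must not have fewer parameters than fit_null")
  chi <- fit_null$deviance - fit_gxe$deviance
  p <- if (df == 0) {
    if (chi <= sqrt(.Machine$double.eps)) 1 else NA_real_
  } else {
    pchisq(max(chi, 0), df = df, lower.tail = FALSE)
  }
  if (df > 0)
    warning("variance components lie on the boundary under the null; ",
            "the chi-square p-value is conservative", call. = FALSE)
  structure(list(delta_aic = fit_gxe$aic - fit_null$aic,
                 chi_square = chi, df = df, p_value = p,
                 converged = fit_null$converged && fit_gxe$converged),
            class = "gxe_comparison")
}

#' @export
print.gxe_comparison <- function(x, ...) {
  cat("GxE model comparison (random slopes vs random intercept)\n")
  cat(sprintf("  delta AIC: %.1f   chi-square: %.1f on %d df   p: %s\n",
              x$delta_aic, x$chi_square, x$df,
              format.pval(x$p_value, digits = 3)))
  if (!x$converged) cat("  note: at least one fit did not converge\n")
  invisible(x)
}
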