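#' Logistic pupation curve
#'
#' Evaluates the three-parameter sigmoid `I(t) = i_max / (1 + exp(-a1 (t -
#' t_mid)))`: `i_max` is the asymptotic number of pupae, `a1` the slope (per
#' day) and `t_mid` the midpoint day at which half of `i_max` have pupated.
#'
#' @param t time (days after egg laying), vectorized.
#' @param i_max,a1,t_mid curve parameters (or pass a `sigmoid_fit` as
#'   `i_max`).
#' @return expected cumulative pupae at `t`.
#' @export
sigmoid_curve <- function(t, i_max, a1 = NULL, t_mid = NULL) {
  if (inherits(i_max, "sigmoid_fit")) {
    f <- i_max
    i_max <- f$i_max; a1 <- f$a1; t_mid <- f$t_mid
  }
  i_max / (1 + exp(-a1 * (t - t_mid)))
}

#' Fit the logistic pupation model to a cumulative time course
#'
#' Least-squares fit of the three-parameter sigmoid to cumulative pupation
#' counts, via bounded Levenberg-Marquardt ([minpack.lm::nlsLM()]) with a
#' deterministic initialization rule: `i_max` starts at the maximum observed
#' count, `t_mid` at the first day reaching half of it, and `a1` at
#' 4 / (rise interval), the logistic slope whose central rise spans that
#' interval. `i_max` is constrained to (0, 1.1 x seeded\] so truncated
#' curves cannot run away.
#'
#' @param tc a `pupation_timecourse` data frame for a single vial (columns
#'   `day`, `cum_pupae`, `seeded`), or anything coercible with those columns.
#' @param seeded larvae seeded; defaults to the table's `seeded` column.
#' @return An object of class `sigmoid_fit`: `i_max`, `a1`, `t_mid`,
#'   `residual_sse`, `converged`, `reason`, `seeded`.
#' @export
fit_sigmoid <- function(tc, seeded = NULL) {
  tc <- as.data.frame(tc)
  if (!all(c("day", "cum_pupae") %in% names(tc)))
    stop2("time course needs columns day and cum_pupae")
  day <- as.numeric(tc$day)
  y <- as.numeric(tc$cum_pupae)
  seeded <- seeded %||% tc$seeded[1]
  if (is.null(seeded) || is.na(seeded)) stop2("seeded count required")
  if (length(day) < 4) stop2("need >= 4 observations")
  if (any(diff(order(day)) < 0)) {
    o <- order(day)
    day <- day[o]; y <- y[o]
  }
  fail <- function(reason) {
    structure(list(i_max = NA_real_, a1 = NA_real_, t_mid = NA_real_,
                   residual_sse = NA_real_, converged = FALSE,
                   reason = reason, seeded = seeded),
              class = "sigmoid_fit")
  }
  if (max(y) == 0) return(fail("all-zero counts"))
  i0 <- max(y)
  half <- which(y >= i0 / 2)
  if (!length(half)) return(fail("no half-rise in observation window"))
  t0 <- day[half[1]]
  lo <- day[which(y >= 0.25 * i0)[1]]
  hi <- day[which(y >= 0.75 * i0)[1]]
  rise <- max(hi - lo, 1)   # steepest plausible start: full rise in one day
  a0 <- 4 / rise
  span <- diff(range(day))
  dat <- data.frame(day = day, y = y)
  try_fit <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ imax / (1 + exp(-a1 * (day - tmid))),
        data = dat,
        start = start,
        lower = c(imax = 1e-6, a1 = 1e-6, tmid = min(day) - span),
        upper = c(imax = seeded * 1.1, a1 = Inf, tmid = max(day) + span),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }
  fit <- try_fit(list(imax = i0, a1 = a0, tmid = t0))
  if (is.null(fit))   # step-like data can make the default start singular
    fit <- try_fit(list(imax = i0, a1 = 1, tmid = stats::median(day)))
  if (is.null(fit)) return(fail("least-squares fit failed"))
  cf <- coef(fit)
  structure(list(i_max = unname(cf["imax"]), a1 = unname(cf["a1"]),
                 t_mid = unname(cf["tmid"]),
                 residual_sse = sum(stats::residuals(fit)^2),
                 converged = TRUE, reason = NA_character_,
                 seeded = seeded),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (!x$converged) {
    cat("sigmoid fit failed:", x$reason, "\n")
  } else {
    cat(sprintf(
      "sigmoid fit: i_max = %.3f, a1 = %.3f /day, t_mid = %.3f d (SSE %.3g)\n",
      x$i_max, x$a1, x$t_mid, x$residual_sse))
  }
  invisible(x)
}

#' Closed-form time to a pupation threshold
#'
#' Inverts the fitted sigmoid to the day at which the cumulative count
#' reaches `threshold`: `t = t_mid - ln(i_max / threshold - 1) / a1`. By
#' construction the curve evaluated at the returned time equals the
#' threshold to machine precision. The default is the fixed count 15 (half
#' of a 30-larva vial); `mode = "half-of-max"` instead uses half of the
#' fitted asymptote, for which the answer is `t_mid` itself.
#'
#' @param fit a converged `sigmoid_fit`.
#' @param threshold pupae count to reach (ignored for `mode =
#'   "half-of-max"`).
#' @param mode `"count"` (fixed threshold) or `"half-of-max"`.
#' @return day at which the fitted curve reaches the threshold.
#' @export
time_to_threshold <- function(fit, threshold = 15,
                              mode = c("count", "half-of-max")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (!fit$converged) stop2("cannot invert an unconverged fit")
  if (mode == "half-of-max") threshold <- fit$i_max / 2
  if (threshold <= 0) stop2("threshold must be positive")
  if (fit$i_max <= threshold)
    stop2("threshold unreachable: fitted asymptote ",
          signif(fit$i_max, 4), " <= threshold ", threshold)
  fit$t_mid - log(fit$i_max / threshold - 1) / fit$a1
}

#' Pairwise comparison of half-pupation times
#'
#' Welch (unequal-variance) two-sample t-tests between every pair of groups
#' of half-pupation times, Bonferroni-corrected over the number of pairs
#' tested. Groups with fewer than two values are skipped with a warning.
#'
#' @param groups named list of numeric vectors (e.g. per genotype or diet).
#' @return data frame with one row per tested pair: `group1`, `group2`,
#'   `estimate` (mean difference), `t`, `df`, `p`, `p_bonferroni`.
#' @export
compare_half_times <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2, !is.null(names(groups)))
  usable <- vapply(groups, function(g) sum(!is.na(g)) >= 2, TRUE)
  if (any(!usable))
    warning("skipping groups with < 2 values: ",
            paste(names(groups)[!usable], collapse = ", "), call. = FALSE)
  groups <- groups[usable]
  if (length(groups) < 2) stop2("fewer than 2 usable groups")
  pairs <- combn(names(groups), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    tt <- t.test(groups[[g1]], groups[[g2]], var.equal = FALSE)
    data.frame(group1 = g1, group2 = g2,
               estimate = unname(diff(rev(tt$estimate))),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out
}

#' Paired t-tests of overall pupation between diet pairs
#'
#' For every pair of diets, a paired t-test over lines of the line-level
#' survival proportions, Bonferroni-corrected over the number of pairs
#' tested (15 for six diets). Lines missing either diet of a pair are
#' dropped from that pair; pairs with fewer than two complete lines are
#' skipped with a warning.
#'
#' @param phenos a `line_phenotypes` matrix (lines x diets).
#' @return data frame with one row per tested pair: `diet1`, `diet2`,
#'   `mean_difference` (diet1 - diet2), `t`, `df`, `p`, `p_bonferroni`.
#' @export
paired_diet_comparison <- function(phenos) {
  Y <- as.matrix(unclass(phenos))
  if (ncol(Y) < 2) stop2("need >= 2 diets")
  pairs <- combn(colnames(Y), 2)
  rows <- list()
  skipped <- character()
  for (i in seq_len(ncol(pairs))) {
    d1 <- pairs[1, i]; d2 <- pairs[2, i]
    ok <- complete.cases(Y[, c(d1, d2)])
    if (sum(ok) < 2) {
      skipped <- c(skipped, paste(d1, d2, sep = "-"))
      next
    }
    diffs <- Y[ok, d1] - Y[ok, d2]
    if (stats::sd(diffs) == 0) {
      # identical columns: no evidence of a difference
      rows[[length(rows) + 1]] <- data.frame(
        diet1 = d1, diet2 = d2, mean_difference = mean(diffs),
        t = 0, df = sum(ok) - 1, p = 1, stringsAsFactors = FALSE)
      next
    }
    tt <- t.test(Y[ok, d1], Y[ok, d2], paired = TRUE)
    rows[[length(rows) + 1]] <- data.frame(
      diet1 = d1, diet2 = d2, mean_difference = unname(tt$estimate),
      t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
      stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("skipped pairs with < 2 complete lines: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  out <- do.call(rbind, rows)
  if (is.null(out)) stop2("no testable diet pairs")
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out
}
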