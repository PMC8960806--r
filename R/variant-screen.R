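#' Aggregate vial-level counts to line-level survival proportions
#'
#' Computes the per-line, per-diet survival proportion used as the
#' association-screen phenotype: the unweighted mean of vial proportions
#' (with equal seeding this equals the pooled-count proportion). The
#' pupation stage uses pupated/seeded; the eclosion stage uses
#' eclosed/seeded by default ("survival to adult"), or eclosed/pupated with
#' `eclosion_denominator = "pupated"`.
#'
#' @param panel a [panel_table()].
#' @param stage `"pupation"` or `"eclosion"`.
#' @param eclosion_denominator denominator convention for the eclosion stage.
#' @return A `line_phenotypes` matrix (lines x diets, values in \[0, 1\],
#'   `NA` where a line lacks a diet) with attributes `stage`,
#'   `phase = "raw"` and `reference` (the reference diet).
#' @export
aggregate_line_phenotypes <- function(panel,
                                      stage = c("pupation", "eclosion"),
                                      eclosion_denominator = c("seeded",
                                                               "pupated")) {
  stage <- match.arg(stage)
  eclosion_denominator <- match.arg(eclosion_denominator)
  panel <- panel_table(panel, diets = attr(panel, "diets"))
  diets <- attr(panel, "diets")
  num <- if (stage == "pupation") panel$n_pupated else panel$n_eclosed
  den <- if (stage == "pupation" || eclosion_denominator == "seeded")
    panel$n_seeded else panel$n_pupated
  prop <- ifelse(den > 0, num / den, NA_real_)
  lines <- unique(as.character(panel$strain))
  m <- matrix(NA_real_, nrow = length(lines), ncol = length(diets),
              dimnames = list(lines, diets))
  agg <- tapply(prop, list(as.character(panel$strain),
                           as.character(panel$diet)),
                function(v) mean(v, na.rm = TRUE))
  m[rownames(agg), colnames(agg)] <- agg
  line_phenotypes(m, stage = stage, phase = "raw", reference = diets[1])
}

line_phenotypes <- function(m, stage, phase, reference) {
  structure(m, stage = stage, phase = phase, reference = reference,
            class = c("line_phenotypes", class(m)))
}

#' Normalize line phenotypes to the reference diet
#'
#' Subtracts each line's reference-diet (high-protein) value from its value
#' on every other diet and drops the reference column, turning absolute
#' survival into a per-line diet response in \[-1, 1\].
#'
#' @param m a raw `line_phenotypes` matrix containing the reference-diet
#'   column.
#' @return A `line_phenotypes` matrix with `phase = "hpd_normalized"` and
#'   one column fewer.
#' @export
normalize_phenotypes <- function(m) {
  stopifnot(inherits(m, "line_phenotypes"))
  if (attr(m, "phase") != "raw")
    stop2("input is already normalized")
  ref <- attr(m, "reference")
  if (!ref %in% colnames(m))
    stop2("reference diet column '", ref, "' absent")
  out <- m[, setdiff(colnames(m), ref), drop = FALSE] - m[, ref]
  line_phenotypes(unclass(out), stage = attr(m, "stage"),
                  phase = "hpd_normalized", reference = ref)
}

#' Filter variants by minor line count
#'
#' Restricts a genotype matrix to the phenotyped lines, then keeps only
#' variants for which, among lines with non-missing calls, at least
#' `min_lines` carry the reference allele and at least `min_lines` carry the
#' alternate allele. Missing-call lines are excluded per variant, never
#' imputed. Variant order is preserved.
#'
#' @param g a [genotype_matrix()].
#' @param phenotyped_lines character vector of line ids with phenotypes.
#' @param min_lines minimum lines per allele group (default 5).
#' @return The filtered `genotype_matrix`.
#' @export
filter_variants <- function(g, phenotyped_lines, min_lines = 5) {
  stopifnot(inherits(g, "genotype_matrix"))
  keep_lines <- intersect(colnames(g$calls), phenotyped_lines)
  if (!length(keep_lines))
    stop2("no lines in common between genotypes and phenotypes")
  calls <- g$calls[, keep_lines, drop = FALSE]
  n_alt <- rowSums(calls == 1L, na.rm = TRUE)
  n_ref <- rowSums(calls == 0L, na.rm = TRUE)
  keep <- n_ref >= min_lines & n_alt >= min_lines
  genotype_matrix(g$variants[keep, , drop = FALSE],
                  calls[keep, , drop = FALSE],
                  wolbachia = g$wolbachia[keep_lines])
}

#' MANOVA association test for one variant
#'
#' Tests the genotype term in a multivariate linear model of the per-diet
#' phenotype vector on Wolbachia status + genotype (sequential sums of
#' squares, so the genotype term is adjusted for the covariate). The default
#' statistic is Pillai's trace with its standard F approximation; Wilks'
#' lambda is available via `statistic`. Lines with any missing phenotype or
#' a missing genotype call are excluded (complete-case).
#'
#' @param phenos a `line_phenotypes` matrix.
#' @param genotype per-line allele calls (0/1/NA), named by line id.
#' @param wolbachia per-line logical covariate, named by line id; a constant
#'   covariate is dropped from the model.
#' @param statistic `"Pillai"` (default) or `"Wilks"`.
#' @return The p-value of the genotype term.
#' @export
manova_test <- function(phenos, genotype, wolbachia = NULL,
                        statistic = c("Pillai", "Wilks")) {
  statistic <- match.arg(statistic)
  Y <- as.matrix(unclass(phenos))
  lines <- rownames(Y)
  geno <- genotype[lines]
  wol <- if (is.null(wolbachia)) rep(FALSE, length(lines)) else
    wolbachia[lines]
  ok <- complete.cases(Y) & !is.na(geno) & !is.na(wol)
  Y <- Y[ok, , drop = FALSE]
  geno <- geno[ok]
  wol <- wol[ok]
  tab <- table(geno)
  if (length(tab) < 2)
    stop2("genotype is constant among tested lines; test undefined")
  if (any(tab < 2))
    stop2("need >= 2 lines in each allele group")
  use_wol <- length(unique(wol)) > 1
  n_terms <- 2L + use_wol              # intercept + genotype (+ wolbachia)
  if (nrow(Y) < ncol(Y) + n_terms)
    stop2("rank deficiency: fewer lines (", nrow(Y), ") than phenotype ",
          "dimensions plus model terms (", ncol(Y) + n_terms, ")")
  df <- data.frame(geno = factor(geno))
  if (use_wol) df$wol <- factor(wol)
  if (ncol(Y) == 1L) {
    # univariate degenerate case: covariate-adjusted two-group F test
    df$y <- Y[, 1]
    fit <- lm(if (use_wol) y ~ wol + geno else y ~ geno, data = df)
    an <- anova(fit)
    return(an["geno", "Pr(>F)"])
  }
  df$Y <- Y
  fit <- manova(if (use_wol) Y ~ wol + geno else Y ~ geno, data = df)
  s <- summary(fit, test = statistic)$stats
  unname(s["geno", "Pr(>F)"])
}

# --- Wilcoxon rank-sum -----------------------------------------------------

# cache of enumeration tables, keyed "N:k"
.wilcox_combo_cache <- new.env(parent = emptyenv())

wilcox_combos <- function(N, k) {
  key <- paste0(N, ":", k)
  if (!is.null(.wilcox_combo_cache[[key]])) return(.wilcox_combo_cache[[key]])
  cmb <- combn(N, k)
  .wilcox_combo_cache[[key]] <- cmb
  cmb
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Two-sample rank-sum test on raw values. For combined sample size at most
#' `exact_max_n` the p-value is computed by exhaustive enumeration of all
#' `choose(n1 + n2, n1)` group assignments (valid under ties); above that, a
#' tie-corrected normal approximation with continuity correction and an
#' Edgeworth skewness/kurtosis refinement is used (the second-to-fourth
#' moments of the permutation rank-sum distribution are computed exactly
#' from the midrank population, so the tie correction is exact through the
#' fourth moment). For untied data the refined approximation agrees with
#' exact enumeration to well under 0.01 from combined n = 16 up; heavily
#' tied (few-valued) data make any smooth approximation lumpy-tailed, which
#' is why enumeration is the default below `exact_max_n`.
#'
#' @param x,y numeric samples for the two groups.
#' @param exact_max_n largest combined n for exact enumeration (default 20).
#' @return two-sided p-value.
#' @export
#' @examples
#' wilcoxon_ranksum(1:5, 6:10)  # complete separation: 2/252
wilcoxon_ranksum <- function(x, y, exact_max_n = 20) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (n1 == 0 || n2 == 0) return(NA_real_)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  if (N <= exact_max_n) {
    cmb <- wilcox_combos(N, n1)
    stats <- colSums(matrix(r[cmb], nrow = n1))
    eps <- 1e-9
    return(mean(abs(stats - mu) >= abs(W - mu) - eps))
  }
  # exact central moments of the rank sum under sampling n1 midranks
  # without replacement from the centered midrank population
  xc <- r - mean(r)
  p2 <- sum(xc^2); p3 <- sum(xc^3); p4 <- sum(xc^4)
  ff <- function(a, b) prod(a:(a - b + 1))
  f1 <- n1 / N
  f2 <- ff(n1, 2) / ff(N, 2)
  f3 <- ff(n1, 3) / ff(N, 3)
  f4 <- ff(n1, 4) / ff(N, 4)
  mu2 <- (f1 - f2) * p2
  mu3 <- (f1 - 3 * f2 + 2 * f3) * p3
  mu4 <- f1 * p4 + f2 * (3 * p2^2 - 7 * p4) + f3 * (12 * p4 - 6 * p2^2) +
    f4 * (3 * p2^2 - 6 * p4)
  if (mu2 <= 0) return(1)
  s <- sqrt(mu2)
  g1 <- mu3 / s^3
  g2 <- mu4 / s^4 - 3
  edgeworth_cdf <- function(q) {
    z <- q / s
    pnorm(z) - stats::dnorm(z) *
      (g1 / 6 * (z^2 - 1) + g2 / 24 * (z^3 - 3 * z) +
         g1^2 / 72 * (z^5 - 10 * z^3 + 15 * z))
  }
  d <- abs(W - mu)
  p <- edgeworth_cdf(-(d - 0.5)) + 1 - edgeworth_cdf(d - 0.5)
  min(1, max(p, 0))
}

#' Per-diet Wilcoxon rank-sum tests for one variant
#'
#' Applies [wilcoxon_ranksum()] to the alternate- vs reference-allele line
#' phenotypes of each diet column.
#'
#' @inheritParams manova_test
#' @param exact_max_n passed to [wilcoxon_ranksum()].
#' @return named numeric of two-sided p-values, one per diet (`NA` where an
#'   allele group is empty).
#' @export
wilcoxon_per_diet <- function(phenos, genotype, exact_max_n = 20) {
  Y <- as.matrix(unclass(phenos))
  geno <- genotype[rownames(Y)]
  vapply(colnames(Y), function(d) {
    v <- Y[, d]
    ok <- !is.na(v) & !is.na(geno)
    wilcoxon_ranksum(v[ok & geno == 1L], v[ok & geno == 0L],
                     exact_max_n = exact_max_n)
  }, numeric(1))
}

#' Per-diet median-difference effect sizes for one variant
#'
#' @inheritParams manova_test
#' @return named numeric: `median(alternate lines) - median(reference lines)`
#'   per diet (`NA` where an allele group is empty).
#' @export
effect_sizes <- function(phenos, genotype) {
  Y <- as.matrix(unclass(phenos))
  geno <- genotype[rownames(Y)]
  vapply(colnames(Y), function(d) {
    v <- Y[, d]
    alt <- v[!is.na(v) & !is.na(geno) & geno == 1L]
    ref <- v[!is.na(v) & !is.na(geno) & geno == 0L]
    if (!length(alt) || !length(ref)) return(NA_real_)
    median(alt) - median(ref)
  }, numeric(1))
}

#' Multivariate per-variant association screen
#'
#' For every variant of a (pre-filtered) genotype matrix, runs the MANOVA
#' test with Wolbachia covariate, the per-diet Wilcoxon rank-sum tests, and
#' the per-diet median-difference effect sizes, then applies the
#' multi-criterion selection rule: a variant is selected iff its MANOVA
#' p-value is below `manova_p` AND at least one diet has Wilcoxon p below
#' `wilcoxon_p` with an absolute median difference of at least `effect` on
#' that same diet. Thresholds default to (1e-5, 0.01) with effect 0.3 for
#' raw phenotypes and 0.2 for normalized ones. Unadjusted p-values drive
#' selection; Bonferroni- and BH-adjusted MANOVA p columns are emitted for
#' information only. Per-variant test failures are recorded in the `error`
#' column, never abort the screen.
#'
#' @param g a filtered [genotype_matrix()].
#' @param phenos a `line_phenotypes` matrix (raw or normalized).
#' @param manova_p,wilcoxon_p,effect selection thresholds; `effect = NULL`
#'   picks 0.3 (raw) or 0.2 (normalized) from the phenotype phase.
#' @param statistic MANOVA statistic, see [manova_test()].
#' @param exact_max_n see [wilcoxon_ranksum()].
#' @return A `screen_result` data frame, one row per variant: `variant`,
#'   `manova_p`, per-diet `wilcoxon_p_*` and `median_diff_*` columns,
#'   `n_ref_lines`, `n_alt_lines`, per-diet `hit_*` flags (Wilcoxon and
#'   effect criteria both met), `selected`, `manova_p_bonferroni`,
#'   `manova_p_bh`, `error`.
#' @export
screen_variants <- function(g, phenos, manova_p = 1e-5, wilcoxon_p = 0.01,
                            effect = NULL, statistic = "Pillai",
                            exact_max_n = 20) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(phenos, "line_phenotypes"))
  if (is.null(effect))
    effect <- if (attr(phenos, "phase") == "hpd_normalized") 0.2 else 0.3
  diets <- colnames(phenos)
  m <- nrow(g$calls)
  res <- vector("list", m)
  for (v in seq_len(m)) {
    geno <- g$calls[v, ]
    row <- list(variant = rownames(g$calls)[v],
                manova_p = NA_real_,
                n_ref_lines = sum(geno == 0L, na.rm = TRUE),
                n_alt_lines = sum(geno == 1L, na.rm = TRUE),
                error = NA_character_)
    wp <- setNames(rep(NA_real_, length(diets)), diets)
    md <- wp
    err <- tryCatch({
      row$manova_p <- manova_test(phenos, geno, g$wolbachia,
                                  statistic = statistic)
      wp <- wilcoxon_per_diet(phenos, geno, exact_max_n = exact_max_n)
      md <- effect_sizes(phenos, geno)
      NA_character_
    }, error = function(e) conditionMessage(e))
    row$error <- err
    hits <- !is.na(wp) & wp < wilcoxon_p & !is.na(md) & abs(md) >= effect
    row$selected <- !is.na(row$manova_p) && row$manova_p < manova_p &&
      any(hits)
    res[[v]] <- c(row[c("variant", "manova_p")],
                  setNames(as.list(wp), paste0("wilcoxon_p_", diets)),
                  setNames(as.list(md), paste0("median_diff_", diets)),
                  row[c("n_ref_lines", "n_alt_lines")],
                  setNames(as.list(hits), paste0("hit_", diets)),
                  row[c("selected", "error")])
  }
  out <- do.call(rbind, lapply(res, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  out$manova_p_bonferroni <- pmin(1, out$manova_p * sum(!is.na(out$manova_p)))
  out$manova_p_bh <- NA_real_
  ok <- !is.na(out$manova_p)
  out$manova_p_bh[ok] <- stats::p.adjust(out$manova_p[ok], method = "BH")
  structure(out, thresholds = list(manova_p = manova_p,
                                   wilcoxon_p = wilcoxon_p, effect = effect),
            class = c("screen_result", "data.frame"))
}
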