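make_phenos <- function(Y, phase = "raw", reference = "HPD",
                        stage = "pupation") {
  dietgxe:::line_phenotypes(Y, stage = stage, phase = phase,
                            reference = reference)
}

test_that("vial-to-line aggregation averages proportions", {
  d <- data.frame(strain = "s1", diet = "HPD", vial = 1:4, n_seeded = 30,
                  n_pupated = c(10, 20, 30, 0), n_eclosed = 0)
  ph <- aggregate_line_phenotypes(panel_table(d))
  expect_equal(unname(ph["s1", "HPD"]), 0.5)

  d2 <- data.frame(strain = "s1", diet = "HPD", vial = 1:2, n_seeded = 30,
                   n_pupated = c(30, 0), n_eclosed = c(15, 0))
  ph2 <- aggregate_line_phenotypes(panel_table(d2))
  expect_equal(unname(ph2["s1", "HPD"]), 0.5)  # equal-n pooled equivalence
  # eclosion denominated by seeded larvae (default) vs by pupae
  pe_seeded <- aggregate_line_phenotypes(panel_table(d2), stage = "eclosion")
  expect_equal(unname(pe_seeded["s1", "HPD"]), 0.25)
  pe_pupae <- aggregate_line_phenotypes(panel_table(d2), stage = "eclosion",
                                        eclosion_denominator = "pupated")
  expect_equal(unname(pe_pupae["s1", "HPD"]), 0.5)
})

test_that("a line missing a diet yields NA, never an imputed value", {
  d <- data.frame(strain = c("s1", "s1", "s2"), diet = c("A", "B", "A"),
                  vial = 1, n_seeded = 30, n_pupated = 15, n_eclosed = 10)
  ph <- aggregate_line_phenotypes(panel_table(d, diets = c("A", "B")))
  expect_true(is.na(ph["s2", "B"]))
  expect_equal(unname(ph["s1", "B"]), 0.5)
})

test_that("reference-diet normalization subtracts and drops the column", {
  Y <- rbind(l1 = c(HPD = 0.9, HSD = 0.2, WD = 0.9),
             l2 = c(HPD = 0.7, HSD = 0.7, WD = 0.7))
  ph <- make_phenos(Y)
  norm <- normalize_phenotypes(ph)
  expect_equal(unname(norm["l1", "HSD"]), -0.7)
  expect_equal(unname(norm["l2", ]), c(0, 0), ignore_attr = TRUE)
  expect_false("HPD" %in% colnames(norm))
  expect_equal(attr(norm, "phase"), "hpd_normalized")
  expect_error(normalize_phenotypes(norm), "already normalized")
  no_ref <- make_phenos(Y[, c("HSD", "WD")])
  expect_error(normalize_phenotypes(no_ref), "absent")
})

test_that("variant filtering applies the five-line rule per allele", {
  lines <- sprintf("L%03d", 1:100)
  calls <- matrix(0L, nrow = 3, ncol = 100,
                  dimnames = list(paste0("v", 1:3), lines))
  calls[1, 1:4] <- 1L                          # 4 alt lines: removed
  calls[2, 1:5] <- 1L                          # 5 alt, rest ref: kept
  calls[3, 1:5] <- 1L; calls[3, 11:100] <- NA  # 5 alt, 5 ref, 90 missing
  g <- genotype_matrix(
    data.frame(id = paste0("v", 1:3), chrom = "2L", pos = 1:3,
               ref = "A", alt = "T"), calls)
  filt <- filter_variants(g, lines)
  expect_equal(rownames(filt$calls), c("v2", "v3"))
})

test_that("filter survivors match a brute-force per-variant count", {
  cfg <- simulation_config(n_strains = 40, n_variants = 500,
                           minor_line_count_distribution = function(n)
                             sample(0:12, n, replace = TRUE),
                           missing_rate = 0.1, seed = 14)
  g <- simulate_genotypes(cfg)$genotypes
  lines <- g$lines
  brute <- 0L
  for (v in seq_len(nrow(g$calls))) {
    cc <- g$calls[v, ]
    if (sum(cc == 0L, na.rm = TRUE) >= 5 && sum(cc == 1L, na.rm = TRUE) >= 5)
      brute <- brute + 1L
  }
  expect_equal(nrow(filter_variants(g, lines)$calls), brute)
})

test_that("MANOVA degenerates to the covariate-adjusted F test univariately", {
  set.seed(31)
  n <- 24
  Y <- matrix(rnorm(n), n, 1, dimnames = list(sprintf("L%02d", 1:n), "HSD"))
  geno <- setNames(rep(c(0L, 1L), each = n / 2), rownames(Y))
  wol <- setNames(rep(c(TRUE, FALSE), n / 2), rownames(Y))
  p <- manova_test(make_phenos(Y), geno, wol)
  ref <- anova(lm(Y[, 1] ~ factor(wol) + factor(geno)))["factor(geno)",
                                                        "Pr(>F)"]
  expect_equal(p, ref, tolerance = 1e-12)
})

test_that("MANOVA rejects degenerate designs explicitly", {
  set.seed(32)
  Y <- matrix(rnorm(30), 10, 3,
              dimnames = list(sprintf("L%02d", 1:10), c("a", "b", "c")))
  const <- setNames(rep(0L, 10), rownames(Y))
  expect_error(manova_test(make_phenos(Y), const), "constant")
  one_alt <- setNames(c(rep(0L, 9), 1L), rownames(Y))
  expect_error(manova_test(make_phenos(Y), one_alt), ">= 2 lines")
  tiny <- Y[1:4, ]
  g4 <- setNames(c(0L, 0L, 1L, 1L), rownames(tiny))
  expect_error(manova_test(make_phenos(tiny), g4), "rank")
})

test_that("rank-sum p-values: exact values, symmetry, tie handling", {
  expect_equal(wilcoxon_ranksum(6:10, 1:5), 2 / 252)
  expect_equal(wilcoxon_ranksum(1:5, 6:10), 2 / 252)      # label symmetry
  expect_equal(wilcoxon_ranksum(c(1, 2, 2, 3), c(1, 2, 2, 3)), 1)
  # agrees with wilcox.test exact path when there are no ties
  set.seed(40)
  for (i in 1:20) {
    x <- rnorm(7); y <- rnorm(6)
    expect_equal(wilcoxon_ranksum(x, y),
                 suppressWarnings(stats::wilcox.test(x, y,
                                                     exact = TRUE)$p.value),
                 tolerance = 1e-12)
  }
  expect_true(is.na(wilcoxon_ranksum(numeric(0), 1:3)))
})

test_that("per-diet effect sizes are alt-minus-ref median differences", {
  Y <- rbind(l1 = c(A = 0.1), l2 = c(A = 0.2), l3 = c(A = 0.9),
             l4 = c(A = 0.5), l5 = c(A = 0.6), l6 = c(A = 0.7))
  geno <- setNames(c(1L, 1L, 1L, 0L, 0L, 0L), rownames(Y))
  ph <- make_phenos(Y, reference = "A")
  expect_equal(unname(effect_sizes(ph, geno)["A"]), -0.4)
  same <- setNames(c(1L, 0L), c("l1", "l2"))
  Y2 <- rbind(l1 = c(A = 0.5), l2 = c(A = 0.3))
  expect_equal(unname(effect_sizes(make_phenos(Y2, reference = "A"),
                                   same)["A"]), 0.2)   # singleton difference
  geno_na <- setNames(c(1L, 1L, 1L, 1L, 1L, 1L), rownames(Y))
  expect_true(is.na(effect_sizes(ph, geno_na)["A"]))
})

test_that("screen selection is a conjunction with per-diet reasons", {
  set.seed(50)
  n <- 30
  lines <- sprintf("L%03d", 1:n)
  Y <- matrix(runif(n * 2, 0.4, 0.6), n, 2,
              dimnames = list(lines, c("HPD", "HSD")))
  geno <- setNames(rep(c(0L, 1L), each = n / 2), lines)
  # strong separation on HSD only, but effect size below the raw cut-off
  Y[geno == 1L, "HSD"] <- Y[geno == 1L, "HSD"] + 0.2
  calls <- matrix(geno, nrow = 1, dimnames = list("v1", lines))
  g <- genotype_matrix(data.frame(id = "v1", chrom = "X", pos = 1,
                                  ref = "A", alt = "T"), calls)
  ph <- make_phenos(Y)
  res <- screen_variants(g, ph)
  expect_false(res$selected[1])                 # fails only the effect rule
  expect_lt(res$manova_p[1], 1e-5)
  expect_lt(res$wilcoxon_p_HSD[1], 0.01)
  expect_false(res$hit_HSD[1])
  # vacuous thresholds select every testable variant
  all_in <- screen_variants(g, ph, manova_p = 1, wilcoxon_p = 1, effect = 0)
  expect_true(all(all_in$selected))
  # loosening the effect threshold alone flips the selection (monotonicity)
  loose <- screen_variants(g, ph, effect = 0.1)
  expect_true(loose$selected[1])
})

test_that("screen is invariant to variant order and line relabeling", {
  cfg <- simulation_config(n_strains = 40, diets = c("HPD", "HSD"),
                           n_variants = 30,
                           minor_line_count_distribution = 12,
                           missing_rate = 0, seed = 21)
  g <- simulate_genotypes(cfg)$genotypes
  panel <- simulate_survival_panel(cfg)
  ph <- aggregate_line_phenotypes(panel)
  res <- screen_variants(filter_variants(g, rownames(ph)), ph,
                         manova_p = 0.05, wilcoxon_p = 0.1, effect = 0.05)
  # permute variant rows
  perm <- sample(nrow(g$calls))
  g_perm <- genotype_matrix(g$variants[perm, ], g$calls[perm, ],
                            wolbachia = g$wolbachia)
  res_perm <- screen_variants(filter_variants(g_perm, rownames(ph)), ph,
                              manova_p = 0.05, wilcoxon_p = 0.1,
                              effect = 0.05)
  expect_equal(res[order(res$variant), ],
               res_perm[order(res_perm$variant), ], ignore_attr = TRUE)
  # relabel lines consistently everywhere
  relab <- setNames(sprintf("Q%03d", seq_along(g$lines)), g$lines)
  g2 <- g
  colnames(g2$calls) <- unname(relab[colnames(g2$calls)])
  names(g2$wolbachia) <- unname(relab[names(g2$wolbachia)])
  g2 <- genotype_matrix(g2$variants, g2$calls, g2$wolbachia)
  ph2 <- ph
  rownames(ph2) <- unname(relab[rownames(ph2)])
  res2 <- screen_variants(filter_variants(g2, rownames(ph2)), ph2,
                          manova_p = 0.05, wilcoxon_p = 0.1, effect = 0.05)
  expect_equal(res$manova_p, res2$manova_p)
  expect_equal(res$selected, res2$selected)
})

test_that("per-variant failures are flagged rows, not screen aborts", {
  lines <- sprintf("L%03d", 1:20)
  calls <- rbind(v1 = c(rep(0L, 10), rep(1L, 10)),
                 v2 = rep(1L, 20))                 # constant: test undefined
  colnames(calls) <- lines
  g <- genotype_matrix(data.frame(id = c("v1", "v2"), chrom = "X",
                                  pos = 1:2, ref = "A", alt = "T"), calls)
  set.seed(60)
  Y <- matrix(runif(40), 20, 2, dimnames = list(lines, c("HPD", "HSD")))
  res <- screen_variants(g, make_phenos(Y))
  expect_true(is.na(res$manova_p[2]))
  expect_match(res$error[2], "constant")
  expect_false(res$selected[2])
  expect_false(is.na(res$manova_p[1]))
})
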