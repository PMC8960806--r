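test_that("config validation rejects malformed inputs", {
  expect_error(simulation_config(n_strains = 1), "n_strains")
  bad_cov <- matrix(c(1, 0.9, 0.2, 1), 2, 2)
  expect_error(
    simulation_config(n_strains = 10, diets = c("A", "B"),
                      random_effect_covariance = bad_cov),
    "symmetric")
  neg_cov <- matrix(c(1, 2, 2, 1), 2, 2)   # eigenvalues 3, -1
  expect_error(
    simulation_config(n_strains = 10, diets = c("A", "B"),
                      random_effect_covariance = neg_cov),
    "positive semi-definite")
  expect_error(
    simulation_config(n_strains = 10, n_variants = 5,
                      causal_variants = data.frame(variant = 6, diet = "HSD",
                                                   shift = 0.3)),
    "out of range")
  expect_error(
    simulation_config(n_strains = 10, n_variants = 2,
                      causal_variants = data.frame(variant = 1:3,
                                                   diet = "HSD",
                                                   shift = 0.3)),
    "more causal variants")
  expect_error(simulation_config(n_strains = 10, wolbachia_prevalence = 1.2),
               "wolbachia")
})

test_that("null config gives 50% survival and the design forces row counts", {
  cfg <- simulation_config(
    n_strains = 40, diets = c("D1", "D2"), n_vials_per_diet = 4,
    n_larvae_per_vial = 30,
    fixed_diet_effects = c(D1 = 0, D2 = 0),
    random_effect_covariance = matrix(0, 2, 2), seed = 4)
  panel <- simulate_survival_panel(cfg)
  expect_equal(nrow(panel), 40 * 2 * 4)
  prop <- panel$n_pupated / panel$n_seeded
  se <- sqrt(0.5 * 0.5 / (30 * nrow(panel)))
  expect_lt(abs(mean(prop) - 0.5), 3 * se)

  cfg_full <- simulation_config(seed = 1)   # full screen design
  panel_full <- simulate_survival_panel(cfg_full)
  expect_equal(nrow(panel_full), 196 * 6 * 4)
})

test_that("generated panels satisfy the count conservation invariant", {
  for (s in 1:3) {
    cfg <- simulation_config(n_strains = 15, diets = c("HPD", "HSD", "WD"),
                             seed = s)
    p <- simulate_survival_panel(cfg)
    expect_true(all(p$n_eclosed <= p$n_pupated))
    expect_true(all(p$n_pupated <= p$n_seeded))
    expect_true(all(p$n_eclosed >= 0))
  }
})

test_that("generators are pure functions of the config seed", {
  cfg <- simulation_config(n_strains = 12, n_variants = 30, seed = 11)
  expect_identical(simulate_survival_panel(cfg), simulate_survival_panel(cfg))
  expect_identical(simulate_genotypes(cfg), simulate_genotypes(cfg))
  # and they do not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(simulate_survival_panel(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("a planted slope variance inflates that diet's among-strain SD", {
  sd_gap <- matrix(NA_real_, 20, 2)
  for (s in 1:20) {
    cfg <- simulation_config(
      n_strains = 50, diets = c("REF", "TRT"), n_vials_per_diet = 4,
      n_larvae_per_vial = 30,
      fixed_diet_effects = c(REF = 0, TRT = 0),
      random_effect_covariance = diag(c(0.1, 0.25)), seed = s)
    ph <- aggregate_line_phenotypes(simulate_survival_panel(cfg))
    sd_gap[s, ] <- c(sd(ph[, "REF"]), sd(ph[, "TRT"]))
  }
  expect_gt(mean(sd_gap[, 2]), mean(sd_gap[, 1]))
  expect_gte(sum(sd_gap[, 2] > sd_gap[, 1]), 18)
})

test_that("genotype generation honours minor line counts and missingness", {
  cfg0 <- simulation_config(n_strains = 30, n_variants = 25,
                            minor_line_count_distribution = 0,
                            missing_rate = 0, seed = 2)
  g0 <- simulate_genotypes(cfg0)
  expect_true(all(g0$genotypes$calls == 0L))   # monomorphic
  ph_lines <- sprintf("line_%03d", 1:30)
  expect_error(filter_variants(g0$genotypes, character(0)), "no lines")
  filt <- filter_variants(g0$genotypes, ph_lines)
  expect_equal(nrow(filt$calls), 0L)           # downstream filter removes all

  cfg <- simulation_config(n_strains = 30, n_variants = 200,
                           minor_line_count_distribution = 8,
                           missing_rate = 0, seed = 2)
  g <- simulate_genotypes(cfg)
  expect_true(all(rowSums(g$genotypes$calls == 1L) == 8))
})

test_that("causal variants shift alt-line phenotypes when composed", {
  cfg <- simulation_config(
    n_strains = 60, diets = c("HPD", "HSD"), n_variants = 10,
    minor_line_count_distribution = 20,
    causal_variants = data.frame(variant = 3, diet = "HSD", shift = -0.35),
    missing_rate = 0, seed = 8)
  g <- simulate_genotypes(cfg)
  panel <- simulate_survival_panel(cfg, g$genotypes)
  panel_null <- simulate_survival_panel(cfg)   # same seed, no genotypes
  ph <- aggregate_line_phenotypes(panel)
  alt <- names(which(g$genotypes$calls[3, ] == 1L))
  ref <- names(which(g$genotypes$calls[3, ] == 0L))
  expect_lt(median(ph[alt, "HSD"]) - median(ph[ref, "HSD"]), -0.2)
  # reference diet untouched by an HSD-only shift
  expect_lt(abs(median(ph[alt, "HPD"]) - median(ph[ref, "HPD"])), 0.15)
  expect_equal(g$truth$variant, 3)
  expect_equal(g$truth$n_alt_lines, 20)
  # without genotypes the same seed gives the unshifted panel
  expect_false(identical(panel, panel_null))
})

test_that("pupation time-course generator matches the sigmoid", {
  par <- data.frame(vial = 1, i_max = 30, a1 = 2, t_mid = 6, seeded = 30)
  tc <- simulate_pupation_timecourse(par, days = 0:14, noise = "none")
  expect_equal(tc$cum_pupae[tc$day == 6], 15L)  # midpoint of the sigmoid
  expect_true(all(diff(tc$cum_pupae) >= 0))
  expect_true(all(tc$cum_pupae <= 30))

  expect_error(simulate_pupation_timecourse(par, days = c(3, 2, 4)),
               "increasing")
  expect_error(simulate_pupation_timecourse(
    data.frame(vial = 1, i_max = 31, a1 = 2, t_mid = 6, seeded = 30), 0:10),
    "exceed")
  expect_error(simulate_pupation_timecourse(
    data.frame(vial = 1, i_max = 20, a1 = -1, t_mid = 6, seeded = 30), 0:10),
    "a1")

  n1 <- simulate_pupation_timecourse(par, 0:14, noise = "sampling", seed = 5)
  n2 <- simulate_pupation_timecourse(par, 0:14, noise = "sampling", seed = 5)
  expect_identical(n1, n2)
  expect_true(all(diff(n1$cum_pupae) >= 0))
})

test_that("respirometry generator supports the noiseless recovery limit", {
  rec <- simulate_respirometry(120, residual_sd = 0, seed = 9)
  # lm warns that a zero-residual fit makes the summary unreliable; the
  # point estimates are exactly what the noiseless limit should recover
  fit <- suppressWarnings(fit_standardization(rec))
  expect_equal(fit$mass_slope, 39.35, tolerance = 1e-8)
  expect_equal(fit$activity_slope, 7.64, tolerance = 1e-8)
  expect_equal(max(abs(stats::residuals(fit$model))), 0, tolerance = 1e-9)

  empty <- simulate_respirometry(0)
  expect_equal(nrow(empty), 0L)
  expect_error(fit_standardization(empty), "no respirometry")
  expect_error(simulate_respirometry(10, residual_sd = -1), "residual_sd")
})

test_that("respirometry slopes are recovered under realistic noise", {
  # residual SD calibrated so the mass slope carries t ~ 3.5 at n = 150
  slopes <- t(vapply(1:10, function(s) {
    rec <- simulate_respirometry(150, residual_sd = 13.6, seed = s)
    f <- fit_standardization(rec)
    c(f$mass_slope, f$mass_se, f$activity_slope, f$activity_se)
  }, numeric(4)))
  expect_true(all(abs(slopes[, 1] - 39.35) < 2.5 * slopes[, 2]))
  expect_true(all(abs(slopes[, 3] - 7.64) < 2.5 * slopes[, 4]))
})
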