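# Independent oracles used across the suite. These deliberately share no
# code with the package's fitting paths.

# Marginal log-likelihood of the binomial random-effects model by dense
# Gauss-Hermite quadrature: for each strain, integrate the vial-level
# binomial likelihood over the strain's (intercept, slopes) vector under
# N(0, Sigma). Evaluated at given fixed effects / covariance, typically the
# ones a Laplace fit produced, to measure the approximation error directly.
glmm_loglik_quadrature <- function(panel, beta, Sigma, nodes = 35) {
  gh <- pracma::gaussHermite(nodes)
  diets <- attr(panel, "diets")
  d <- data.frame(strain = as.character(panel$strain),
                  diet = factor(panel$diet, levels = diets),
                  succ = panel$n_pupated,
                  fail = panel$n_seeded - panel$n_pupated)
  X <- stats::model.matrix(~diet, d)
  eta_fixed <- drop(X %*% beta)
  Sigma <- as.matrix(Sigma)
  # random-effect design: intercept only (1 column) or intercept + slopes
  Z <- if (nrow(Sigma) == 1) X[, 1, drop = FALSE] else X
  ev <- eigen(Sigma, symmetric = TRUE)
  keep <- ev$values > 1e-10 * max(ev$values, 1e-12)
  k <- sum(keep)
  if (k == 0) {  # degenerate covariance: no integral left
    return(sum(stats::dbinom(d$succ, d$succ + d$fail,
                             stats::plogis(eta_fixed), log = TRUE)))
  }
  # transform b = sqrt(2) * A u, A = V sqrt(D) over non-null directions
  A <- ev$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(ev$values[keep]), nrow = k)
  grids <- do.call(expand.grid, rep(list(seq_len(nodes)), k))
  U <- as.matrix(grids)
  logw <- rowSums(matrix(log(gh$w[U]), nrow = nrow(U)))
  B <- sqrt(2) * (matrix(gh$x[U], nrow = nrow(U)) %*% t(A))  # points x dim(Sigma)
  total <- 0
  for (s in unique(d$strain)) {
    idx <- which(d$strain == s)
    eta <- outer(rep(1, nrow(B)), eta_fixed[idx]) +
      B %*% t(Z[idx, , drop = FALSE])
    ll_vials <- sapply(seq_along(idx), function(j)
      stats::dbinom(d$succ[idx[j]], d$succ[idx[j]] + d$fail[idx[j]],
                    stats::plogis(eta[, j]), log = TRUE))
    ll_vials <- matrix(ll_vials, nrow = nrow(B))
    lse <- logw + rowSums(ll_vials)
    m <- max(lse)
    total <- total + (m + log(sum(exp(lse - m)))) - k / 2 * log(pi)
  }
  total
}

# Pillai's trace for the genotype term of lm(Y ~ [wol +] geno), computed
# from residual cross-products directly (no stats::manova involvement).
pillai_trace <- function(Y, geno, wol = NULL) {
  X1 <- if (is.null(wol)) stats::model.matrix(~geno) else
    stats::model.matrix(~ wol + geno)
  X0 <- if (is.null(wol)) stats::model.matrix(~1, data.frame(g = geno)) else
    stats::model.matrix(~wol)
  # a permutation can make geno collinear with wol; lsfit then pivots and
  # warns, and the genotype increment is correctly zero
  E <- crossprod(suppressWarnings(
    stats::lsfit(X1, Y, intercept = FALSE))$residuals)
  E0 <- crossprod(suppressWarnings(
    stats::lsfit(X0, Y, intercept = FALSE))$residuals)
  H <- E0 - E
  sum(diag(H %*% solve(H + E)))
}

# Permutation oracle for the MANOVA genotype p-value: permute genotype
# labels (exact under the null that genotype is independent of phenotype
# and covariate), recompute Pillai's trace each draw.
manova_permutation_p <- function(Y, geno, wol = NULL, B = 20000, seed = 1) {
  obs <- pillai_trace(Y, geno, wol)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(B)) {
    stat <- pillai_trace(Y, sample(geno), wol)
    if (stat >= obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (B + 1)
}

# small helper: a deterministic toy panel for oracle checks
toy_panel <- function(n_strains = 3, diets = c("A", "B"), vials = 4,
                      larvae = 30, seed = 7) {
  cfg <- simulation_config(
    n_strains = n_strains, diets = diets, n_vials_per_diet = vials,
    n_larvae_per_vial = larvae,
    fixed_diet_effects = setNames(c(0.5, rep(-0.8, length(diets) - 1)),
                                  diets),
    random_effect_covariance = diag(c(0.4, rep(0.3, length(diets) - 1))),
    seed = seed)
  simulate_survival_panel(cfg)
}
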