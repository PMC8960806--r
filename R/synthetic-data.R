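#' Configuration for a synthetic diet-screen panel
#'
#' Collects every parameter of the synthetic-data generators in one validated
#' object. The defaults reproduce the design of the panel screen the package
#' targets: 196 inbred strains, six diets (high-protein reference plus
#' high-sucrose, two high-fat, western and high-starch), four replicate vials
#' of 30 larvae per strain and diet, and diet-level survival centred on the
#' screen's observed pupation rates (e.g. ~76% on the high-sucrose diet
#' against ~95% on the reference).
#'
#' Strain effects are drawn from a multivariate normal on the logit scale over
#' (intercept, one slope per non-reference diet); `random_effect_covariance`
#' is the covariance of that vector and must be symmetric positive
#' semi-definite. Causal variants shift the survival proportion of
#' alternate-allele lines on the proportion scale (clipped to \[0.01, 0.99\]
#' before conversion back to the logit scale).
#'
#' @param n_strains number of inbred strains (>= 2).
#' @param diets character vector of diet labels; the first is the reference.
#' @param n_vials_per_diet replicate vials per strain x diet.
#' @param n_larvae_per_vial larvae seeded per vial.
#' @param fixed_diet_effects named numeric of per-diet log-odds: the value for
#'   the reference diet is the intercept, other values are offsets from it.
#' @param random_effect_covariance k x k covariance (k = number of diets) of
#'   the strain-level (intercept, slopes) vector on the logit scale.
#' @param n_variants number of biallelic variants to simulate.
#' @param minor_line_count_distribution number of alternate-allele lines per
#'   variant: a single integer, a length-`n_variants` integer vector, or a
#'   function `f(n)` returning `n` counts.
#' @param causal_variants `NULL` or a data frame with columns `variant`
#'   (index), `diet` (label) and `shift` (proportion-scale phenotype shift of
#'   alternate-allele lines on that diet).
#' @param wolbachia_prevalence fraction of lines carrying Wolbachia.
#' @param missing_rate per-call genotype missingness rate.
#' @param eclosion_mean,eclosion_sd mean eclosion probability (of pupae) and
#'   the logit-scale SD of its per-strain variation; eclosion is a binomial
#'   thinning of pupated counts, which guarantees eclosed <= pupated.
#' @param seed integer seed; all generators derive per-component substreams
#'   from it, so each generator is a pure function of the config.
#'
#' @return An object of class `simulation_config`.
#' @seealso [simulate_survival_panel()], [simulate_genotypes()]
#' @export
#' @examples
#' cfg <- simulation_config(n_strains = 10, n_variants = 20, seed = 1)
#' panel <- simulate_survival_panel(cfg)
#' head(panel)
simulation_config <- function(n_strains = 196,
                              diets = c("HPD", "HSD", "HFDcoco", "HFDlard",
                                        "WD", "HStD"),
                              n_vials_per_diet = 4,
                              n_larvae_per_vial = 30,
                              fixed_diet_effects = NULL,
                              random_effect_covariance = NULL,
                              n_variants = 500,
                              minor_line_count_distribution = NULL,
                              causal_variants = NULL,
                              wolbachia_prevalence = 0.5,
                              missing_rate = 0.02,
                              eclosion_mean = 0.9,
                              eclosion_sd = 0.3,
                              seed = 1L) {
  if (!is.numeric(n_strains) || n_strains < 2)
    stop2("n_strains must be >= 2")
  diets <- as.character(diets)
  if (anyDuplicated(diets)) stop2("diet labels must be unique")
  k <- length(diets)
  if (is.null(fixed_diet_effects)) {
    # survival on the reference diet ~95%; offsets give the screen-scale
    # diet means (HSD ~0.76, HFDcoco ~0.67, HFDlard ~0.93, WD ~0.85,
    # HStD ~0.95); unknown labels default to the reference level
    defaults <- c(HPD = qlogis(0.95),
                  HSD = qlogis(0.76) - qlogis(0.95),
                  HFDcoco = qlogis(0.67) - qlogis(0.95),
                  HFDlard = qlogis(0.93) - qlogis(0.95),
                  WD = qlogis(0.85) - qlogis(0.95),
                  HStD = 0)
    fixed_diet_effects <- setNames(rep(0, k), diets)
    fixed_diet_effects[diets[1]] <- defaults[["HPD"]]
    hit <- intersect(diets[-1], names(defaults))
    fixed_diet_effects[hit] <- defaults[hit]
  }
  if (is.null(names(fixed_diet_effects)) ||
      !setequal(names(fixed_diet_effects), diets))
    stop2("fixed_diet_effects must be named by diet")
  fixed_diet_effects <- fixed_diet_effects[diets]
  if (is.null(random_effect_covariance)) {
    # intercept SD 0.7, slope SD 0.8 on the logit scale, uncorrelated:
    # yields among-line proportion SDs of the order seen in real panels
    random_effect_covariance <- diag(c(0.49, rep(0.64, k - 1)), nrow = k)
  }
  S <- as.matrix(random_effect_covariance)
  if (nrow(S) != k || ncol(S) != k)
    stop2("random_effect_covariance must be ", k, " x ", k,
          " (intercept + one slope per non-reference diet)")
  if (max(abs(S - t(S))) > 1e-8)
    stop2("random_effect_covariance must be symmetric")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop2("random_effect_covariance is not positive semi-definite ",
          "(smallest eigenvalue ", signif(min(ev), 3), ")")
  if (!is.numeric(n_variants) || n_variants < 0)
    stop2("n_variants must be a non-negative count")
  if (!is.null(causal_variants)) {
    causal_variants <- as.data.frame(causal_variants)
    need <- c("variant", "diet", "shift")
    if (!all(need %in% names(causal_variants)))
      stop2("causal_variants needs columns: ", paste(need, collapse = ", "))
    if (length(unique(causal_variants$variant)) > n_variants)
      stop2("more causal variants than n_variants")
    if (any(causal_variants$variant < 1 | causal_variants$variant > n_variants))
      stop2("causal variant index out of range 1..n_variants")
    if (!all(causal_variants$diet %in% diets))
      stop2("causal variant diet label not among diets")
  }
  if (wolbachia_prevalence < 0 || wolbachia_prevalence > 1)
    stop2("wolbachia_prevalence must be in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop2("missing_rate must be in [0, 1)")
  if (eclosion_mean <= 0 || eclosion_mean >= 1)
    stop2("eclosion_mean must be in (0, 1)")

  cfg <- list(
    n_strains = as.integer(n_strains),
    diets = diets,
    n_vials_per_diet = as.integer(n_vials_per_diet),
    n_larvae_per_vial = as.integer(n_larvae_per_vial),
    fixed_diet_effects = fixed_diet_effects,
    random_effect_covariance = S,
    n_variants = as.integer(n_variants),
    minor_line_count_distribution = minor_line_count_distribution,
    causal_variants = causal_variants,
    wolbachia_prevalence = wolbachia_prevalence,
    missing_rate = missing_rate,
    eclosion_mean = eclosion_mean,
    eclosion_sd = eclosion_sd,
    seed = as.integer(seed)
  )
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Synthetic diet-screen configuration\n")
  cat("  strains:", x$n_strains, " diets:", paste(x$diets, collapse = ", "),
      "\n")
  cat("  vials/diet:", x$n_vials_per_diet, " larvae/vial:",
      x$n_larvae_per_vial, "\n")
  cat("  variants:", x$n_variants, " causal:",
      if (is.null(x$causal_variants)) 0 else
        length(unique(x$causal_variants$variant)), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

config_line_ids <- function(cfg) sprintf("line_%03d", seq_len(cfg$n_strains))

# Strain-level linear predictors (logit scale), strains x diets, with causal
# shifts (proportion scale, clipped) applied for alternate-allele lines.
strain_linear_predictors <- function(cfg, genotypes = NULL) {
  k <- length(cfg$diets)
  b <- MASS::mvrnorm(cfg$n_strains, mu = rep(0, k),
                     Sigma = cfg$random_effect_covariance)
  b <- matrix(b, nrow = cfg$n_strains)
  fixed <- cfg$fixed_diet_effects
  eta <- matrix(fixed[1] + c(0, fixed[-1]),
                nrow = cfg$n_strains, ncol = k, byrow = TRUE)
  eta <- eta + b[, 1]                       # random intercept
  if (k > 1) eta[, -1] <- eta[, -1] + b[, -1, drop = FALSE]  # random slopes
  dimnames(eta) <- list(config_line_ids(cfg), cfg$diets)
  if (!is.null(cfg$causal_variants) && !is.null(genotypes)) {
    calls <- genotypes$calls
    for (r in seq_len(nrow(cfg$causal_variants))) {
      cv <- cfg$causal_variants[r, ]
      alt_lines <- colnames(calls)[!is.na(calls[cv$variant, ]) &
                                     calls[cv$variant, ] == 1L]
      alt_lines <- intersect(alt_lines, rownames(eta))
      if (!length(alt_lines)) next
      p <- plogis(eta[alt_lines, cv$diet])
      p <- pmin(pmax(p + cv$shift, 0.01), 0.99)
      eta[alt_lines, cv$diet] <- qlogis(p)
    }
  }
  eta
}

#' Simulate a strain x diet x vial survival panel
#'
#' Draws vial-level pupation counts from a binomial model whose logit success
#' probability is (fixed diet effect) + (strain random intercept) + (strain x
#' diet random slope), the generative model implied by a random-slopes
#' binomial GLMM. Eclosed counts are a binomial thinning of pupated counts
#' with a per-strain eclosion probability, so `eclosed <= pupated <= seeded`
#' holds by construction.
#'
#' When `genotypes` (from [simulate_genotypes()] under the same config) is
#' supplied and the config declares causal variants, alternate-allele lines
#' have their survival proportion shifted by the configured per-diet amounts.
#'
#' @param config a [simulation_config()].
#' @param genotypes optional result of [simulate_genotypes()] for the same
#'   config, used to apply causal-variant phenotype shifts.
#' @return A `panel_table` data frame with one row per strain x diet x vial
#'   and columns `strain`, `diet`, `vial`, `n_seeded`, `n_pupated`,
#'   `n_eclosed`. The diet level order (reference first) is kept in
#'   `attr(, "diets")`.
#' @export
simulate_survival_panel <- function(config, genotypes = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  with_rng(substream_seed(config$seed, "survival"), {
    eta <- strain_linear_predictors(config, genotypes)
    lines <- rownames(eta)
    k <- length(config$diets)
    p_ecl <- plogis(rnorm(config$n_strains, qlogis(config$eclosion_mean),
                          config$eclosion_sd))
    nv <- config$n_vials_per_diet
    nl <- config$n_larvae_per_vial
    grid <- expand.grid(vial = seq_len(nv), diet = config$diets,
                        strain = lines, stringsAsFactors = FALSE)
    grid <- grid[, c("strain", "diet", "vial")]
    p_pup <- plogis(eta[cbind(grid$strain, grid$diet)])
    n_pup <- rbinom(nrow(grid), nl, p_pup)
    n_ecl <- rbinom(nrow(grid), n_pup, p_ecl[match(grid$strain, lines)])
    out <- data.frame(strain = grid$strain, diet = grid$diet,
                      vial = grid$vial, n_seeded = nl,
                      n_pupated = n_pup, n_eclosed = n_ecl,
                      stringsAsFactors = FALSE)
    panel_table(out, diets = config$diets)
  })
}

#' Construct / validate a panel table
#'
#' @param x data frame with columns `strain`, `diet`, `vial`, `n_seeded`,
#'   `n_pupated`, `n_eclosed`.
#' @param diets diet level order; first label is the reference diet. Defaults
#'   to order of appearance.
#' @return `x` with class `panel_table` and a `diets` attribute.
#' @export
panel_table <- function(x, diets = NULL) {
  need <- c("strain", "diet", "vial", "n_seeded", "n_pupated", "n_eclosed")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop2("panel table lacks columns: ",
                          paste(miss, collapse = ", "))
  if (any(x$n_pupated > x$n_seeded) || any(x$n_eclosed > x$n_pupated) ||
      any(x$n_eclosed < 0))
    stop2("count invariant violated: need 0 <= eclosed <= pupated <= seeded")
  diets <- diets %||% unique(as.character(x$diet))
  if (!all(x$diet %in% diets)) stop2("diet labels outside declared levels")
  structure(as.data.frame(x), diets = as.character(diets),
            class = c("panel_table", "data.frame"))
}

#' Simulate biallelic genotypes over the panel's lines
#'
#' Generates an `n_variants` x `n_strains` matrix of biallelic calls
#' (0 = reference, 1 = alternate, `NA` = missing), with the number of
#' alternate-allele lines per variant drawn from
#' `minor_line_count_distribution`, a per-line Wolbachia infection indicator,
#' and a truth table of the planted causal variants.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `genotypes` (a `genotype_matrix`: variant
#'   annotations, call matrix, line ids, Wolbachia status) and `truth`
#'   (data frame of planted variants: index, id, diet, shift, number of
#'   alternate lines).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_rng(substream_seed(config$seed, "genotypes"), {
    n <- config$n_strains
    m <- config$n_variants
    lines <- config_line_ids(config)
    dist <- config$minor_line_count_distribution
    counts <- if (is.null(dist)) {
      sample(seq_len(max(1L, n %/% 2L)), m, replace = TRUE)
    } else if (is.function(dist)) {
      dist(m)
    } else if (length(dist) == 1L) {
      rep(as.integer(dist), m)
    } else if (length(dist) == m) {
      as.integer(dist)
    } else {
      stop2("minor_line_count_distribution must be a function, a single ",
            "count, or a vector of length n_variants")
    }
    if (any(counts < 0 | counts > n))
      stop2("minor line counts must lie in [0, n_strains]")
    calls <- matrix(0L, nrow = m, ncol = n,
                    dimnames = list(sprintf("var_%05d", seq_len(m)), lines))
    for (v in seq_len(m)) {
      if (counts[v] > 0)
        calls[v, sample.int(n, counts[v])] <- 1L
    }
    if (config$missing_rate > 0) {
      calls[runif(length(calls)) < config$missing_rate] <- NA_integer_
    }
    bases <- c("A", "C", "G", "T")
    chrom <- sample(c("2L", "2R", "3L", "3R", "X"), m, replace = TRUE)
    pos <- integer(m)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      pos[idx] <- sort(sample.int(2.2e7, length(idx)))
    }
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
    variants <- data.frame(id = rownames(calls), chrom = chrom, pos = pos,
                           ref = ref, alt = unname(alt),
                           stringsAsFactors = FALSE)
    wol <- setNames(runif(n) < config$wolbachia_prevalence, lines)
    g <- genotype_matrix(variants, calls, wolbachia = wol)
    truth <- if (is.null(config$causal_variants)) {
      data.frame(variant = integer(), id = character(), diet = character(),
                 shift = numeric(), n_alt_lines = integer())
    } else {
      cv <- config$causal_variants
      data.frame(variant = cv$variant, id = rownames(calls)[cv$variant],
                 diet = cv$diet, shift = cv$shift,
                 n_alt_lines = counts[cv$variant],
                 stringsAsFactors = FALSE)
    }
    list(genotypes = g, truth = truth)
  })
}

#' Construct / validate a genotype matrix
#'
#' @param variants data frame with columns `id`, `chrom`, `pos`, `ref`, `alt`
#'   (one row per biallelic variant).
#' @param calls integer matrix (variants x lines) with values 0 (reference),
#'   1 (alternate) or `NA` (missing); dimnames are variant and line ids.
#' @param wolbachia named logical vector of per-line infection status.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(variants, calls, wolbachia = NULL) {
  variants <- as.data.frame(variants)
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variants)))
    stop2("variants needs columns: ", paste(need, collapse = ", "))
  calls <- as.matrix(calls)
  if (nrow(calls) != nrow(variants))
    stop2("calls must have one row per variant")
  if (is.null(colnames(calls))) stop2("calls must have line ids as colnames")
  if (anyDuplicated(colnames(calls))) stop2("line ids must be unique")
  if (anyDuplicated(variants$id)) stop2("variant ids must be unique")
  storage.mode(calls) <- "integer"
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    stop2("calls must be 0 (ref), 1 (alt) or NA (missing): biallelic only")
  rownames(calls) <- variants$id
  if (is.null(wolbachia)) {
    wolbachia <- setNames(rep(FALSE, ncol(calls)), colnames(calls))
  }
  if (!all(colnames(calls) %in% names(wolbachia)))
    stop2("wolbachia status missing for some lines")
  structure(list(variants = variants, calls = calls,
                 lines = colnames(calls),
                 wolbachia = wolbachia[colnames(calls)]),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "variants x", ncol(x$calls),
      "lines;", sum(x$wolbachia), "Wolbachia-infected\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Simulate cumulative pupation time courses
#'
#' Inverts the logistic pupation model to generate data: for each vial the
#' expected cumulative count at day t is `i_max / (1 + exp(-a1 (t - t_mid)))`.
#' With `noise = "none"` the rounded expectation is returned; with
#' `noise = "sampling"` each larva pupates with probability `i_max/seeded` at
#' a time drawn from the logistic distribution with location `t_mid` and
#' scale `1/a1`, so counts are the cumulative histogram of pupation times —
#' integer, non-decreasing by construction.
#'
#' @param params data frame with one row per vial: `vial`, `i_max`, `a1`,
#'   `t_mid`, `seeded`, and optionally `strain` and `diet` labels.
#' @param days increasing numeric observation grid (days after egg laying).
#' @param noise `"none"` or `"sampling"`.
#' @param seed integer seed (used only for `noise = "sampling"`).
#' @return A `pupation_timecourse` data frame: `vial`, `strain`, `diet`,
#'   `day`, `cum_pupae`, `seeded`.
#' @export
simulate_pupation_timecourse <- function(params, days,
                                         noise = c("none", "sampling"),
                                         seed = 1L) {
  noise <- match.arg(noise)
  params <- as.data.frame(params)
  need <- c("vial", "i_max", "a1", "t_mid", "seeded")
  if (!all(need %in% names(params)))
    stop2("params needs columns: ", paste(need, collapse = ", "))
  if (any(diff(days) <= 0)) stop2("days must be strictly increasing")
  if (any(params$a1 <= 0)) stop2("a1 must be > 0")
  if (any(params$i_max > params$seeded))
    stop2("i_max cannot exceed larvae seeded")
  gen_vial <- function(row) {
    counts <- if (noise == "none") {
      round(row$i_max * plogis(row$a1 * (days - row$t_mid)))
    } else {
      n_pup <- rbinom(1, row$seeded, row$i_max / row$seeded)
      times <- rlogis(n_pup, location = row$t_mid, scale = 1 / row$a1)
      vapply(days, function(d) sum(times <= d), 0L)
    }
    data.frame(vial = row$vial,
               strain = row$strain %||% NA_character_,
               diet = row$diet %||% NA_character_,
               day = days, cum_pupae = as.integer(counts),
               seeded = row$seeded, stringsAsFactors = FALSE)
  }
  res <- with_rng(substream_seed(seed, "pupation"), {
    do.call(rbind, lapply(seq_len(nrow(params)), function(i)
      gen_vial(as.list(params[i, ]))))
  })
  structure(res, class = c("pupation_timecourse", "data.frame"))
}

#' Simulate per-fly respirometry records
#'
#' Metabolic rates are generated under the linear standardization model:
#' condition mean + mass_slope * fresh mass + activity_slope * activity +
#' Gaussian residual. The CO2-production column is back-computed from the
#' generated rate at the supplied respiratory quotient, so the conversion
#' path ([vco2_to_power()]) round-trips exactly.
#'
#' @param n_flies number of records.
#' @param condition_means named numeric of condition-level mean metabolic
#'   rates (mJ/h); conditions are assigned round-robin.
#' @param mass_mean,mass_sd fresh-mass distribution (mg, normal truncated at
#'   0.1 mg).
#' @param activity_shape,activity_rate gamma parameters of the activity-count
#'   distribution.
#' @param mass_slope,activity_slope true standardization slopes
#'   (mJ/h per mg; mJ/h per count).
#' @param residual_sd Gaussian residual SD (mJ/h); must be >= 0 (0 gives the
#'   noiseless limit).
#' @param libraries RNAi library labels assigned round-robin (used for
#'   reference-mass lookup downstream).
#' @param rq respiratory quotient used to back-compute the CO2 column.
#' @param seed integer seed.
#' @return A `respirometry_records` data frame: `fly`, `library`, `diet`
#'   (condition label), `vco2`, `fresh_mass`, `activity`, `mr_mj_per_h`.
#' @export
simulate_respirometry <- function(n_flies,
                                  condition_means = c(HPD = 60, HSD = 75),
                                  mass_mean = 0.85, mass_sd = 0.1,
                                  activity_shape = 2, activity_rate = 0.4,
                                  mass_slope = 39.35, activity_slope = 7.64,
                                  residual_sd = 13.6,
                                  libraries = c("GD", "kk", "Trip"),
                                  rq = 0.872,
                                  seed = 1L) {
  if (residual_sd < 0) stop2("residual_sd must be >= 0")
  if (mass_mean <= 0) stop2("mass_mean must be positive")
  n_flies <- as.integer(n_flies)
  if (n_flies == 0) {
    out <- data.frame(fly = character(), library = character(),
                      diet = character(), vco2 = numeric(),
                      fresh_mass = numeric(), activity = numeric(),
                      mr_mj_per_h = numeric())
    return(structure(out, class = c("respirometry_records", "data.frame")))
  }
  with_rng(substream_seed(seed, "respirometry"), {
    cond <- rep_len(names(condition_means), n_flies)
    lib <- rep_len(libraries, n_flies)
    mass <- pmax(rnorm(n_flies, mass_mean, mass_sd), 0.1)
    act <- stats::rgamma(n_flies, shape = activity_shape,
                         rate = activity_rate)
    mr <- condition_means[cond] + mass_slope * mass + activity_slope * act +
      rnorm(n_flies, 0, residual_sd)
    ee <- 37.64 - 16.54 * rq            # J per mL CO2
    out <- data.frame(fly = sprintf("fly_%04d", seq_len(n_flies)),
                      library = lib, diet = cond,
                      vco2 = pmax(as.numeric(mr), 0) / ee,
                      fresh_mass = mass, activity = act,
                      mr_mj_per_h = as.numeric(mr),
                      stringsAsFactors = FALSE)
    structure(out, class = c("respirometry_records", "data.frame"))
  })
}
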