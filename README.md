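# dietgxe

Genetic variation in macronutrient tolerance: an analysis pipeline for diet
screens on panels of inbred *Drosophila* strains.

Large diet screens raise a chain of statistical questions that this package
answers as one tested toolkit: *do strains differ genetically in how diet
affects survival?* (genotype-by-environment interaction), *which variants
track that variation?* (a multivariate association screen), *how does diet
shift developmental timing?* (pupation kinetics), and *what does diet do to
energy metabolism?* (indirect calorimetry). It is aimed at quantitative
geneticists and fly physiologists working with panel designs — strain ×
diet × replicate-vial survival counts, biallelic genotypes over inbred
lines, daily pupation counts, and flow-through respirometry records.

## What it computes

**Survival GxE.** Vial-level pupation counts are fitted with binomial
(logit-link) mixed models: diet as a categorical fixed effect with a random
intercept per strain, against the same model plus per-strain random diet
slopes under a full covariance. For *k* diets the two differ by
*k(k+1)/2 − 1* parameters (20 for six diets), and the slopes model's gain
in fit — ΔAIC and a χ² test on the deviance reduction — is the evidence for
among-strain variance in diet response.

**Variant screen.** Line-level survival proportions (raw, or normalized by
subtracting each line's reference-diet value) are screened per variant
after a ≥5-lines-per-allele filter: MANOVA (Pillai's trace) of the
per-diet phenotype vector on Wolbachia status + genotype, two-sided
Wilcoxon rank-sum tests per diet (exact enumeration up to combined n = 20,
an Edgeworth-refined tie-corrected normal approximation above), and
median-difference effect sizes. Selection is the conjunction: MANOVA
p < 10⁻⁵ and, on the same diet, Wilcoxon p < 0.01 with |median difference|
≥ 0.3 raw (0.2 normalized).

**Pupation kinetics.** Cumulative pupation is fitted with the logistic
I(t) = I_max / (1 + exp(−a₁(t − t_mid))) and the day a vial reaches a count
threshold comes from the closed-form inverse
t = t_mid − ln(I_max/threshold − 1)/a₁, with Welch-t and paired-t group
comparisons (Bonferroni-corrected).

**Metabolic rate.** CO₂ production (μL h⁻¹) converts to mJ h⁻¹ through the
diet's sugar-to-yeast ratio: RQ = 0.872 + 0.125·log₁₀(S:Y + 1), energy
equivalent EE = 37.64 − 16.54·RQ (J mL⁻¹), power = V̇CO₂ × EE. Rates are
standardized to a per-library reference mass and zero activity with slopes
from an OLS model on condition + mass + activity.

**Synthetic data.** A generator module reproduces the statistical structure
of all four inputs (logit-normal strain effects with correlated diet
slopes, planted causal variants, logistic pupation sampling, linear
respirometry) so the full pipeline runs and is tested without any external
download.

## Worked example

```r
library(dietgxe)

cfg <- simulation_config(
  n_strains = 60, diets = c("HPD", "HSD", "HFDcoco"),
  n_variants = 200, minor_line_count_distribution = 15,
  causal_variants = data.frame(variant = 7, diet = "HSD", shift = -0.35),
  seed = 42)
geno  <- simulate_genotypes(cfg)
panel <- simulate_survival_panel(cfg, geno$genotypes)

fit_null <- fit_binomial_glmm(panel, random_slopes = FALSE)
fit_gxe  <- fit_binomial_glmm(panel, random_slopes = TRUE)
compare_gxe(fit_null, fit_gxe)
#> GxE model comparison (random slopes vs random intercept)
#>   delta AIC: -1066.4   chi-square: 1076.4 on 5 df   p: <2e-16
```

The slopes model wins decisively: strains differ genetically in how diet
changes their survival (the naive χ² p is conservative here, as the warning
notes). Screening the 200 variants recovers the planted one:

```r
phenos <- aggregate_line_phenotypes(panel, stage = "pupation")
hits <- screen_variants(filter_variants(geno$genotypes, rownames(phenos)),
                        phenos)
subset(as.data.frame(hits), selected,
       select = c(variant, manova_p, wilcoxon_p_HSD, median_diff_HSD))
#>     variant     manova_p wilcoxon_p_HSD median_diff_HSD
#> 7 var_00007 1.518699e-08              0      -0.3208333
```

Variant 7 — the planted high-sucrose survival deficit — is the only
selected variant: MANOVA p ≈ 1.5 × 10⁻⁸, complete rank separation on HSD,
and a median survival deficit of 0.32 in alternate-allele lines. The
calorimetry side is a one-liner; the energy equivalent on a 2:1
sugar-to-yeast diet:

```r
round(energy_equivalent(predict_rq(diet_sy_ratio("HSD"))), 3)
#> [1] 22.231
```

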