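---
title: "Methods: models and design choices behind dietgxe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models and design choices behind dietgxe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietgxe)
```

dietgxe implements the computational pipeline of a large diet screen on a
panel of inbred *Drosophila* strains: vial-level survival counts across six
defined diets, a genome-wide multivariate association screen over line-level
survival proportions, logistic pupation-kinetics fitting, and
indirect-calorimetry conversion of respirometry data. This vignette explains
each model, the parameters that matter, and the design decisions taken where
more than one reasonable choice existed.

## Survival genotype-by-environment model

The unit of observation is a replicate vial: of `n_seeded` larvae, some
number pupate and, of those, some eclose. Pupation counts are modelled as
binomial with a logit-linear predictor. Two nested generalized linear mixed
models are compared:

* **intercept model** — diet as a categorical fixed effect, a random
  intercept per strain. Strains differ in overall robustness, but every
  strain responds to diet the same way.
* **random-slopes model** — additionally a random slope per non-reference
  diet at the strain level, with a full (unstructured) covariance over the
  (intercept, slopes) vector. Strains are allowed to respond to diets
  differently; the slope (co)variances *are* the genotype-by-environment
  signal.

For $k$ diets the intercept model estimates $k$ fixed effects plus one
variance ($k+1$ parameters) and the slopes model $k$ fixed effects plus
$k(k+1)/2$ covariance parameters, so the likelihood-ratio comparison has
$k(k+1)/2 - 1$ degrees of freedom — 20 for the six-diet design
(`count_parameters(6, TRUE) - count_parameters(6, FALSE)`). The comparison
(`compare_gxe()`) reports $\Delta$AIC, the deviance reduction as a
$\chi^2$ statistic, and its upper-tail p-value.

Fitting uses the Laplace approximation to the marginal likelihood
(`lme4::glmer`). Two numerical caveats are handled explicitly. First, under
the no-GxE null the slope variances sit on the boundary of the parameter
space, so the naive $\chi^2$ reference is conservative; `compare_gxe()`
emits a warning saying so, and the test suite checks the type-I rate from
below only. Second, a panel in which every vial shows the same proportion
makes the binomial response constant; `glmer` refuses such data, and
`fit_binomial_glmm()` then falls back to the fixed-effects GLM with all
variance components pinned at zero, which is the exact maximum of the
marginal likelihood in that degenerate case.

Vials are modelled individually by default. The counts within a strain and
diet could equally be pooled into a single binomial observation — with no
overdispersion the two are likelihood-equivalent — and `pool_vials = TRUE`
provides that entry point.

The suite validates the Laplace fit against an independent dense
Gauss–Hermite quadrature of the marginal likelihood on two- and three-strain
panels (agreement within 0.05 log-units), and checks calibration and power
on simulated 60-strain two-diet panels (100 replicates each): with slope
variance zero the rejection rate stays at or below the nominal 5%, and with
slope SD 0.5 on the logit scale power exceeds 90%. Variance-component
recovery is checked on 40-strain three-diet panels (15 replicates) — a
three-diet covariance has the same unstructured form as the six-diet one at
a fraction of the fitting cost, which keeps the default suite fast.

## Variant screen

Phenotypes are line-level survival proportions per diet: the unweighted mean
of vial proportions (with equal seeding this equals the pooled-count
proportion, and the package's generator always seeds vials equally).
Pupation uses pupated/seeded. For eclosion the screen's "survival to adult"
reading — eclosed/seeded — is the default; eclosed/pupated is available via
`eclosion_denominator = "pupated"` since the denominator convention is a
genuine ambiguity. Normalized phenotypes subtract each line's
reference-diet (high-protein) value and drop that column, so the normalized
response vector over six diets has five components.

Variants are filtered to those with at least five reference-allele and five
alternate-allele lines among non-missing calls; missing calls exclude a line
from that variant only (never imputed). Each surviving variant is tested
three ways:

* **MANOVA** of the per-diet phenotype vector on Wolbachia status +
  genotype, sequential sums of squares so the genotype term is
  covariate-adjusted. The statistic is Pillai's trace with its standard F
  approximation — the conventional, most robust default when no statistic
  is dictated; Wilks' lambda sits behind `statistic = "Wilks"`. The
  Wolbachia covariate enters additively as a binary indicator and never
  interacts with genotype. With a single-diet (univariate) response the
  test degenerates, exactly, to the covariate-adjusted two-group F test.
* **Wilcoxon rank-sum tests per diet**, two-sided, on the untransformed
  line proportions. For combined n ≤ 20 the p-value is computed by
  exhaustive enumeration of all group assignments, which is valid under
  ties. Above that, a tie-corrected normal approximation with continuity
  correction and an Edgeworth skewness/kurtosis refinement is used: the
  second-to-fourth moments of the permutation rank-sum distribution are
  computed exactly from the midrank population, so ties are handled exactly
  through the fourth moment. For untied (continuous-phenotype) data the
  refined approximation tracks exact enumeration to well under 0.01
  absolute from combined n = 16; heavily tied few-valued data make any
  smooth approximation inaccurate in the tails, which is exactly why
  enumeration is the default below the cut-over.
* **Effect sizes** as median(alternate) − median(reference) per diet.

Selection is the conjunction used for candidate-gene screens with relaxed
cut-offs: unadjusted MANOVA p < 10⁻⁵, and on at least one diet both
Wilcoxon p < 0.01 and |median difference| ≥ 0.3 (raw) or 0.2 (normalized).
No multiple-testing correction enters the selection rule — the screen is
deliberately permissive because candidates face downstream validation — but
Bonferroni- and BH-adjusted MANOVA columns are emitted for information.
Per-variant test failures (e.g. a variant monomorphic among complete-case
lines) are flagged rows, never screen aborts.

The suite checks MANOVA type-I calibration (200 null simulations, exact
binomial consistency with 5%), agreement with a 20,000-draw permutation
oracle on a 12-line instance (within 0.02, i.e. three Monte-Carlo standard
errors plus a finite-sample allowance for the normal-theory-vs-permutation
gap at n = 12), the analytic 2/252 rank-sum value under complete
separation at 5 vs 5, and planted-variant recovery: a variant giving its 20
alternate-allele lines a 0.4 survival deficit on the high-sucrose diet is
recovered in at least 18 of 20 replicate synthetic panels of 100 lines and
500 variants at the default thresholds. The planted deficit is negative
(survival loss) because diet-level survival baselines sit near the top of
the unit interval; an additive gain of 0.4 would be truncated by the
[0.01, 0.99] proportion clip and is not a realistic planted effect.

## Pupation kinetics

Cumulative pupation of a vial over days after egg laying is fitted with the
three-parameter logistic
$I(t) = I_{\max} / (1 + e^{-a_1 (t - t_{\mathrm{mid}})})$:
$I_{\max}$ the asymptotic pupae count, $a_1$ the slope (per day),
$t_{\mathrm{mid}}$ the midpoint day. The fit is bounded
Levenberg–Marquardt least squares with a deterministic initialization:
$I_{\max}$ starts at the maximum observed count, $t_{\mathrm{mid}}$ at the
first day reaching half of it, and $a_1$ at 4/(rise interval) with the rise
interval floored at one day (the logistic's central rise spans roughly
$4/a_1$). $I_{\max}$ is constrained to at most 1.1 × seeded so truncated
curves cannot run to an unbounded asymptote. Step-like data can make the
default start's gradient singular; a single deterministic fallback start
($a_1 = 1$, midpoint at the median day) covers that case. All-zero curves
and curves that never reach half their maximum in the window return
`converged = FALSE` with a reason rather than a fit.

The time at which the fitted curve reaches a count threshold is closed-form:
$t = t_{\mathrm{mid}} - \ln(I_{\max}/\text{threshold} - 1)/a_1$, and the
package asserts the round-trip $I(t) = \text{threshold}$ to machine
precision. Two threshold semantics exist in practice — a fixed count of 15
(half of a standard 30-larva vial) and half of the fitted asymptote — and
the discrepancy is real, not resolvable from first principles: a vial in
which only 20 pupate reaches "half of the pupated flies" at $t_{\mathrm{mid}}$
but 15 pupae strictly later. Both are exposed; the fixed count 15 is the
default, and `mode = "half-of-max"` selects the relative rule (whose answer
is always $t_{\mathrm{mid}}$). A threshold at or above $I_{\max}$ is an
explicit "threshold unreachable" error: that vial never attains the count.

Group comparisons of half-pupation times use Welch (unequal-variance)
two-sample t-tests over all group pairs with Bonferroni correction by the
number of pairs tested; overall pupation between diets uses paired t-tests
over lines for each diet pair (15 pairs for six diets), same correction.

## Metabolic rate

CO₂ production (μL h⁻¹) is converted to energy expenditure in three steps,
all parameterized in one validated `energy_model()` object:

1. the diet's sugar-to-yeast mass ratio (from % w/v sucrose over % w/v
   yeast; the six built-in diets share a 10% yeast base);
2. the respiratory quotient RQ = 0.872 + 0.125 log₁₀(S:Y + 1), reflecting
   the assumption that flies catabolize the substrate mixture they eat;
3. the energy equivalent of CO₂, linear in RQ between the mixed-protein
   (uricotelic) anchor (25.4 J mL⁻¹ at RQ 0.74) and the carbohydrate
   anchor (21.1 J mL⁻¹ at RQ 1.0): EE = 37.64 − 16.54·RQ. The constructor
   asserts the line passes through both anchors to within 0.01 J mL⁻¹, so a
   mistyped coefficient fails at load time, not in results.

μL h⁻¹ × J mL⁻¹ = mJ h⁻¹ with no further constants. Rates are then
standardized by an OLS model of metabolic rate on experimental condition,
fresh mass (mg) and activity (counts). The condition factor defaults to the
genotype-library × diet cell; the model pools libraries by default (a
per-library option exists) because the mass and activity slopes are
physiological quantities expected to be shared, and pooling gives them the
most degrees of freedom. Adjusted rates subtract
mass_slope × (mass − reference mass) and activity_slope × activity, with
per-library reference masses (GD 0.83, kk 0.77, Trip 0.81 mg), and are
interpretable as resting metabolic rates of a mass-standardized, inactive
fly. Rank deficiency (e.g. a constant mass column) is an explicit error
naming the aliased terms.

## Bench-assay calculators

Five small calculators are exact formulas with validation: bomb-calorimetry
gross heat Δt·E/w; trehalose and triglyceride backgrounds subtracted with
negative results *flagged, not clipped* — clipping would silently hide
pipetting or calibration problems; dye-based food intake inverting a linear
standard curve and normalizing by larval weight; and starvation time of
death as the timestamp of the last non-zero activity bin, with an explicit
no-activity result.

## The synthetic-data generator

Every stage is testable without external data because the generator
reproduces the statistical structure the models assume:

* **Survival**: strain effects drawn from a multivariate normal on the
  logit scale over (intercept, per-diet slopes) — the generative model the
  random-slopes GLMM implies — plus per-diet fixed effects; vial counts are
  binomial. Default design: 196 strains, six diets, 4 vials × 30 larvae,
  matching the screen scale; default diet means (~95% reference survival,
  ~76% high-sucrose, ~67% high-fat-coconut) reflect screen-scale diet
  effects, and default random-effect SDs (0.7 intercept, 0.8 slope, logit
  scale) give among-line proportion SDs of the order real panels show.
  Eclosion is a binomial thinning of pupated counts with per-strain
  eclosion probabilities, so eclosed ≤ pupated ≤ seeded holds by
  construction rather than by post-hoc clamping.
* **Genotypes**: biallelic variant × line calls with a configurable
  distribution of alternate-allele line counts, per-call missingness
  (default 2%), and Wolbachia infection (default prevalence 0.5, the order
  observed in reference panels). Causal variants shift alternate lines'
  survival on the proportion scale, clipped to [0.01, 0.99] before logit
  conversion, matching the effect-size filter's proportion-scale semantics.
  No attempt is made to mimic real linkage-disequilibrium structure or
  allele-frequency spectra — synthetic power results therefore speak to
  marginal per-variant behaviour, not to LD-induced clumping of hits.
* **Pupation curves**: each larva pupates with probability
  $I_{\max}/\text{seeded}$ at a logistic-distributed time, so cumulative
  counts are integer, non-decreasing, and exactly the sigmoid in
  expectation; a noiseless mode returns the rounded curve.
* **Respirometry**: condition mean + mass slope + activity slope + Gaussian
  noise, with the CO₂ column back-computed so the conversion path
  round-trips. The default residual SD (13.6 mJ h⁻¹) makes the mass slope
  carry t ≈ 3.5 at n = 150, the precision regime of real flow-through
  respirometry.

Reproducibility is strict: every generator is a pure function of its config
(including seed), restores the caller's RNG state, and derives a fixed
per-component substream from the global seed by a counter scheme, so adding
a generator later cannot perturb existing streams.

What passing tests on synthetic data do *not* show: robustness to
overdispersion beyond binomial (real vials share micro-environment),
non-normal strain effects, LD between variants, batch/cohort structure
(strains were phenotyped in cohorts), or respirometry drift — these are
outside the generative model and are listed as known limitations.

## Numerical conventions

* Proportion-scale causal shifts clip to [0.01, 0.99] before logit
  conversion.
* Wilcoxon exact/approximate cut-over at combined n = 20; enumeration
  tables are cached per (n, n₁).
* The zero-df self-comparison of identical model structures returns
  χ² = 0, p = 1.
* `fit_sigmoid` sorts unordered day grids, rejects fewer than four
  observations, and treats a missing half-rise as non-convergence, not an
  error.
* Negative assay subtractions carry a `flagged` attribute; downstream code
  decides what to do with them.
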