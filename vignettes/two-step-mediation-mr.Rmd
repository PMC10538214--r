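---
title: "Two-step mediation Mendelian randomization: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step mediation Mendelian randomization: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The scientific problem

Observational studies report that people with psoriasis have elevated
myocardial-infarction (MI) risk, but cannot separate causation from
confounding. Two-sample Mendelian randomization (MR) uses genetic variants
as instrumental variables: because alleles assort randomly at conception, a
variant robustly associated with an exposure provides a quasi-randomized
contrast that is immune to classical confounding, provided the variant
affects the outcome only through the exposure. `mrmediate` implements the
complete summary-statistics workflow for this design, including the
two-step mediation extension that asks *how much* of an exposure's effect
on an outcome flows through intermediate traits (here, lipid fractions such
as LDL cholesterol, apolipoprotein B and lipoprotein A).

Everything operates on GWAS summary statistics: per-variant effect sizes
(`beta`), standard errors, allele pair, effect-allele frequency, p-value
and sample size for each trait, from non-overlapping cohorts. Binary traits
are on the log-odds scale, continuous traits in SD units.

## The causal model and its decomposition

Write $\beta_1$ for the MR effect of the exposure on a mediator, $\beta_{2k}$
for the effect of mediator $k$ on the outcome *adjusted for the exposure*
(from multivariable MR), and $\beta_3$ for the direct effect of the exposure
on the outcome adjusted for the mediator(s). The product method gives the
indirect effect through mediator $k$ as $\beta_1^{(k)} \beta_{2k}$, with the
Sobel standard error
$\sqrt{\beta_{2k}^2 se_1^2 + (\beta_1^{(k)})^2 se_{2k}^2}$, and the
proportion mediated as

$$E\% = 100 \times \frac{\sum_k \beta_1^{(k)} \beta_{2k}}
{\beta_3 + \sum_k \beta_1^{(k)} \beta_{2k}}.$$

The denominator uses the *reconstructed* total ($\beta_3$ plus the summed
indirects), not the independently estimated total effect. In finite samples
the two denominators disagree; `run_two_step()` reports the formula above
as `proportion_pct` and the ratio against the independently estimated total
as `proportion_vs_total`, so the discrepancy is visible rather than hidden.
Values outside $[0, 100]$ arise when paths have opposite signs and are
flagged `inconsistent` rather than truncated.

## Estimators

All univariable estimators consume a harmonized set of per-variant pairs
$(\hat b_{x i}, \hat b_{y i})$ with standard errors. Weights are
$w_i = b_{xi}^2 / se_{yi}^2$ throughout (equivalently, $1/se_{yi}^2$ on the
regression scale).

* **IVW** pools the per-variant Wald ratios $b_{yi}/b_{xi}$; it is exact
  zero-intercept weighted least squares. The fixed-effect standard error is
  $1/\sqrt{\sum w_i}$; the multiplicative random-effects version scales it
  by $\sqrt{\max(Q/(L-1), 1)}$, so it can never be narrower than the fixed
  one. Following the source design, the effects model is chosen by
  Cochran's $Q$: multiplicative random effects if and only if the $Q$-test
  p-value is strictly below 0.05.
* **MR-Egger** adds an unconstrained intercept: the slope remains
  consistent under directional pleiotropy whose magnitude is independent of
  instrument strength, and the intercept estimates the average pleiotropic
  effect. Because the regression is not invariant to allele
  re-orientation, instruments are sign-fixed to $b_x \ge 0$ first.
  Standard errors use the multiplicative overdispersion convention with the
  residual variance factor bounded below by 1.
* **Weighted median** is consistent when valid instruments carry at least
  half the weight. The implementation uses the mid-point
  cumulative-weight convention with linear interpolation at weight 0.5;
  its standard error is a seeded parametric bootstrap (default 1000
  resamples, seed 20230828) perturbing both coordinate sets by their
  standard errors.
* **Maximum likelihood** models $b_{xi} \sim N(\xi_i, se_{xi}^2)$,
  $b_{yi} \sim N(\theta \xi_i, se_{yi}^2)$ and profiles out the nuisance
  means, leaving the one-dimensional objective
  $\tfrac12\sum_i (b_{yi}-\theta b_{xi})^2/(se_{yi}^2+\theta^2 se_{xi}^2)$;
  the standard error comes from the numerical observed information. As
  $se_x \to 0$ this reproduces fixed-effect IVW (a property the tests pin
  down).
* **MR-RAPS** solves the robustified profile-score equation with
  standardized residuals
  $t_i = (b_{yi}-\theta b_{xi})/\sqrt{se_{yi}^2+\theta^2 se_{xi}^2+\tau^2}$
  and a Huber $\psi$ (tuning constant 1.345, the conventional 95%
  Gaussian-efficiency choice), optionally profiling the overdispersion
  $\tau^2 \ge 0$ by matching $\mathrm{mean}(\psi(t)t)$ to its
  standard-normal expectation $2\Phi(k)-1$. The root is bracketed around
  the IVW estimate; standard errors use the sandwich formula.

Confidence intervals are normal-theory $\pm 1.96\,se$ everywhere, and every
estimate is reported on both the beta and the odds-ratio scale, matching
the forest-plot convention of the analysis layout.

## Instrument selection and strength

Instruments pass a significance threshold (default $p < 5\times10^{-8}$,
strict), an exclusion list (user-supplied variant ids associated with
confounders such as BMI or hypertension), and greedy pruning in ascending
p-value order within a 10,000 kb window at LD $r^2 < 0.001$. Ties at equal
p-values break lexicographically by variant id, which makes selection
invariant to row permutation. Without positions or an LD matrix the input
is assumed pre-pruned (a message is logged). In the two-step design,
variants genome-wide significant for both the exposure and a mediator
instrument *neither* trait.

Instrument strength uses $F = [(N-K-1)/K]\,[R^2/(1-R^2)]$ with
$R^2 = 2\,\mathrm{MAF}(1-\mathrm{MAF})(\beta/se)^2$. The $R^2$ formula is
implemented exactly as printed in the source design, and additionally in a
normalized mode (divided by $N$) which the pipeline uses internally: the
printed form is dimensionally a non-normalized quantity and can exceed 1
(e.g. MAF 0.1, $\beta/se = 3$ gives 1.62), so it is unsuitable as a
proportion. Variants with missing allele frequency are retained for
estimation but excluded from $R^2$/F summaries. A per-set $F$ below the
conventional threshold of 10 triggers a weak-instrument warning.

## Multivariable MR and the errors-in-variables correction

The direct effects come from weighted multiple regression of the outcome
coefficients on all exposure-coefficient columns jointly, without
intercept, weights $1/se_y^2$ (`mr_mvmr(correction = "none")`). This
conventional estimator has a known weakness that matters for exactly the
design this package targets: when one exposure's instruments are few and
modest (a binary exposure with ~10 genome-wide-significant variants)
while another contributes hundreds of rows, the weak column consists
mostly of sampling noise across the other exposure's instruments. The
noise inflates the weighted cross-product matrix and attenuates that
exposure's direct effect — in the shipped `paper_shaped` scenario by
6–9%, enough to drop the nominal 95% CI coverage of the direct effect to
roughly 75–83%. This is the regime the per-exposure *conditional F*
diagnostic (reported with every fit) is designed to flag; here it sits
near 15.

`mr_mvmr(correction = "eiv")`, the default inside `run_two_step()`,
removes the attenuation by the classical method-of-moments
errors-in-variables correction: the known measurement variances
$se_x^2$ are subtracted from the diagonal of the weighted cross-product
matrix, giving an unbiased estimate of the true-signal matrix. Standard
errors take the larger of a delete-one jackknife (which captures the
variability of the corrected design matrix that the first-order sandwich
formula misses) and the model-based standard error with the
overdispersion floor. In the simulation suite this restores median bias
below 0.2 Monte-Carlo SDs and CI coverage to ~93–96% for all path
coefficients. The uncorrected fit remains available and is the documented
reduction to IVW in the single-exposure case.

## The synthetic-data generator

`simulate_sumstats()` draws, per variant, a minor-allele frequency
$\mathrm{U}(0.1, 0.5)$, a true exposure effect $\xi_i \sim N(0,
\texttt{beta\_x\_scale}^2)$ on the exposure block and mediator-own effects
$\zeta \sim N(0, \texttt{beta\_m\_scale}^2)$ on each mediator block; each
trait's standard error is $1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})N}$
(so doubling $N$ shrinks it by exactly $\sqrt 2$), and observed betas add
independent normal noise from per-trait child RNG streams derived from one
root seed. Mediator truth is $\beta_1 \xi$ plus own instruments; outcome
truth is $\theta\,\xi + \sum_k \beta_{2k}(\text{mediator truth})$ plus an
optional pleiotropy term. Directional pleiotropy is expressed relative to
the trait-increasing allele of each variant's parent trait — the
orientation Egger regression uses after sign-fixing — because a
directional mean attached to arbitrary allele labels would cancel under
re-orientation and be undetectable by construction. Variants are placed
>10 Mb apart on cycling chromosomes, so they are independent under the
default pruning window; allele pairs are non-palindromic unless a
palindromic fraction is requested.

The default configuration mirrors the motivating study's shape: a binary
exposure cohort of 216,752, mediator cohorts of 403,943, an outcome cohort
of 171,875, 12 candidate exposure instruments and mediator instrument
counts of 146/178/14. Causal truths (`beta1` = 0.04/0.05/0.03, `beta2` =
0.35/0.40/0.30, `theta_direct` = 0.25, proportion mediated 14.7%) are
chosen so that paths are individually estimable at these cohort sizes
while keeping the mediated share modest, echoing the real analysis where
lipid traits carry a minority of the psoriasis–MI effect; effect sizes
this large are what a well-powered recovery test needs, whereas the real
per-SD lipid effects of the source study are an order of magnitude
smaller and not resolvable with ~10 instruments. The per-SNP effect scale
0.05 puts selected instruments at per-variant $F \approx 100$–300,
typical of genome-wide-significant hits.

Named scenarios (`scenario_library()`): `paper_shaped` as above; `null`
(all causal paths zero) for type-I-error and $Q$-uniformity calibration;
`pleiotropic` (directional, scale 0.01) for the Egger intercept;
`weak_instrument`, which pairs many small effects
(`beta_x_scale` = 0.006 across 200 candidates) with a relaxed selection
threshold of $10^{-4}$ carried in the config — genome-wide significance
mechanically forces every selected variant above per-variant $F \approx
30$, so the weak-instrument boundary $F \approx 10$ is only reachable
with a liberal threshold.

What the generator does *not* emulate: LD between variants (real clumping
decisions), sample overlap between cohorts, winner's-curse-free external
selection, non-normal effect distributions, and the liability-scale
subtleties of binary traits (betas are simulated directly on the log-odds
scale, as two-sample MR consumes them). Passing tests therefore establish
the pipeline's correctness under the stated sampling model, not
robustness to those real-data complications.

## Numerical and procedural choices

* Harmonization intersects on variant id, flips swapped outcome alleles
  (negating beta, reflecting eaf), and treats palindromic (A/T, C/G)
  variants by frequency: dropped when either study's MAF is within 0.08 of
  0.5 or missing, otherwise oriented by frequency-side agreement. The 0.08
  window is the conservative convention of standard two-sample MR practice;
  the source design does not state one.
* Duplicate variant ids within a file keep the smallest p-value,
  deterministically, and log the rest.
* Problem sizes in the test suite (e.g. 100 recovery replicates, 200
  calibration replicates, 100-variant null sets) are chosen to give
  Monte-Carlo standard errors comfortably inside the asserted bands while
  keeping the whole suite under a minute.
* All bootstrap and simulation randomness is seeded and restores the
  caller's RNG state; rerunning any pipeline with the same config and seed
  is byte-identical.
* `p < 0.05` is the significance wording throughout, with no
  multiple-testing correction, matching the source design; the run log
  states this explicitly.

## Known limitations

* The mediation decomposition is linear; total = direct + indirect holds
  as a consistency property at large cohort sizes, not as a finite-sample
  identity, and `proportion_pct` can leave $[0,100]$ under opposite-sign
  paths (flagged, not truncated).
* Bidirectional exposure–mediator relationships are not modelled.
* LD-aware pruning requires a user-supplied LD matrix; the package never
  estimates LD from genotypes.
* The weighted-median standard error is bootstrap-based and therefore
  stochastic (seeded); analytic alternatives exist but are less faithful
  to the estimator actually used.
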