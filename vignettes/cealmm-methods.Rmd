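---
title: "Methods: likelihood-based CEA with incomplete repeated measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: likelihood-based CEA with incomplete repeated measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cealmm)
```

## Scope and model

`cealmm` analyses two-arm trial cost-utility data measured at a common grid
of `J >= 2` time points, the first being baseline. Both outcome series —
health utilities and costs — are modelled by separate univariate mixed
models for repeated measures (MMRM); a joint bivariate model is a possible
extension but is not implemented, the bootstrap being what ties the two
series together for decision summaries.

For one outcome the model is

$$Y_{ij} = \mu_j + \delta_j \mathrm{TRT}_i + x_i^\top\gamma + \varepsilon_{ij},
  \qquad \varepsilon_i \sim N(0, \Sigma),$$

with categorical time effects $\mu_j$, time-by-arm interactions $\delta_j$
(and $\delta_1 \equiv 0$ under the default *constrained baseline*),
optional time-constant effects of baseline covariates, and a residual
covariance $\Sigma$ that is unstructured (`"un"`, the default) or compound
symmetry (`"cs"`, the structure implied by a participant-level random
intercept: constant variance $\sigma_\omega^2 + \sigma_\epsilon^2$ and
constant covariance $\sigma_\omega^2$).

The baseline constraint deserves emphasis: because randomization rules out
a true baseline treatment effect, omitting the baseline treatment term both
respects the design and makes each follow-up contrast $\delta_j$ adjusted
for the baseline outcome — the constrained longitudinal data analysis
(cLDA) device. The estimand of the incremental QALY is therefore a
*baseline-adjusted* contrast; the synthetic generator accordingly gives
both arms the same true baseline distribution, as randomization does.

## Missing data and the observed-data likelihood

Each participant contributes the marginal multivariate-normal density of
their *observed* subvector: the rows of their design matrix and the
submatrix of $\Sigma$ restricted to observed time points. Maximizing this
observed-data likelihood gives valid inference under missingness at random
(MAR) given the observed outcomes and the model covariates — without
imputation, and deterministically. The implementation groups participants
by observed/missing pattern, whitens each group with the Cholesky factor
of its $\Sigma$ submatrix, and profiles the fixed effects out by
generalized least squares, so each objective evaluation costs a handful of
small (at most $J \times J$) factorizations per pattern.

Numerical choices:

- **Parameterization.** $\Sigma = LL^\top$ with free log-diagonal and
  off-diagonal Cholesky entries (unstructured), guaranteeing positive
  definiteness; compound symmetry uses $(\log\sigma^2, \mathrm{logit})$ of
  the intraclass correlation mapped onto its valid range
  $(-1/(J-1), 1)$.
- **Estimation.** REML by default (standard MMRM practice); ML is available
  and is what likelihood-ratio comparisons and several exact complete-data
  identities require.
- **Optimizer.** BFGS on the covariance parameters with numeric gradients
  (step $10^{-5}$), relative tolerance $10^{-12}$, up to 3 jittered
  restarts on non-convergence. The response is standardized internally
  (and the fit transformed back) so that currency-scale outcomes do not
  ill-condition the parameterization.
- **Starting values.** Pairwise-complete sample covariance of arm-centered
  responses, eigenvalue-floored at $10^{-6}$ of its trace.
- **Degenerate inputs.** Participants with entirely missing series are
  dropped from that outcome's model (with a message; they still enter the
  other outcome's model); an arm-time cell with no observations makes that
  mean inestimable and is a hard error; non-convergence is always reported,
  and inside the bootstrap a non-converged replicate is excluded and
  counted rather than retried.

Confidence intervals for coefficient contrasts are Wald intervals from the
GLS information at the optimum; no small-sample degrees-of-freedom
correction is applied, since decision-level uncertainty is carried by the
bootstrap.

## Estimands

Per-arm QALYs apply trapezoidal area-under-the-curve weights
($w_1 = (t_2-t_1)/2$, interior $w_j = (t_{j+1}-t_{j-1})/2$,
$w_J = (t_J-t_{J-1})/2$; they sum to the horizon) to the model's arm-time
utility means — linear interpolation between measurements, the standard
QALY convention, with times in years (0/3/9 months = 0, 0.25, 0.75). Under
the constrained baseline the common $\mu_1$ cancels from the incremental
QALY, which reduces to $\sum_{j\ge2} w_j \hat\delta_j$. Total cost per arm
sums the follow-up cost means; the baseline-period (pre-randomization)
cost is excluded from the total but remains in the model as the time-1
response, providing baseline-cost adjustment. No discounting is applied
within the short horizon. Standard errors use $c^\top V c$ with the
contrast vector $c$ and coefficient covariance $V$.

## Uncertainty and decision summaries

The nonparametric bootstrap resamples *participants* (both series jointly,
preserving the within-person cost-utility correlation that a valid CEAC
needs), stratified by arm so every replicate keeps the original arm sizes;
an unstratified option exists. Baseline-covariate mean-imputation is redone
inside each replicate so its uncertainty propagates. The default is
B = 10,000 replicates; tests and examples use far fewer.

The CEAC evaluates `P(k·ΔE − ΔC > 0)` over a willingness-to-pay grid
(default 0–50,000 by 500, always containing 25,000); ties at exactly zero
net benefit count as not cost-effective (strict inequality, a
measure-zero convention for continuous draws). The ICER is always reported
with its plane quadrant, and an incremental effect of exactly zero flags
the ratio undefined rather than erroring.

## Comparators

`cca_estimates()` implements the complete-case analysis: completers only,
per-participant QALY (trapezoidal AUC of their own utilities) and total
follow-up cost, and an ordinary regression of each on arm plus the baseline
value of the same outcome (plus any covariates). Adjusting CCA for baseline
mirrors the MMRM's built-in adjustment, so CCA-vs-MMRM differences isolate
the handling of missing data rather than the estimand. Missing baseline
covariates are handled for both analyses by single mean-imputation, pooled
across arms by default (randomization makes the arms' baseline
distributions exchangeable); binary covariates take the observed mode with
ties broken toward 0.

## What the synthetic generator emulates

`sadd_like_config()` encodes the study conditions the package is tested
under, shaped like a 9-month antidepressants-in-dementia trial: arms of
111/108, measurements at 0/0.25/0.75 years, utility means rising from 0.68
to 0.73–0.83 with SD ≈ 0.24–0.28, lognormal costs with means ≈ 1100–2600
and SDs exceeding the means, baseline always observed, and non-monotone
missingness (each post-baseline indicator drawn separately) with marginal
missingness 32%/47% for follow-up utilities, 15.5%/26% for costs, and
roughly 46% completers — utilities more often missing than costs.

Design choices in the generator, each made once:

- **Common true baseline.** Both arms share the baseline distribution
  (pooled moments), as randomization guarantees; the per-arm observed
  baseline means of any single trial realization differ only by sampling
  noise, and a generator that hard-coded such a difference would make the
  baseline-adjusted estimand diverge from the configured "truth".
- **One utility covariance.** Utilities are multivariate normal with a
  single covariance (exchangeable correlation 0.5, common SDs), matching
  the MMRM's common-$\Sigma$ assumption so that recovery simulations test
  the missing-data property, not covariance misspecification. Costs, by
  contrast, are deliberately generated skewed (lognormal by default, gamma
  and normal available) with per-arm dispersions, so the cost model runs
  with a misspecified error distribution — a standing robustness exercise,
  reflecting the large-sample robustness argument usually made for linear
  models on cost data, and reported as such rather than asserted.
- **Gaussian copula.** A latent normal vector over the `2J` outcomes
  (exchangeable within blocks, correlation −0.2 between same-time utility
  and cost) induces the cross-outcome dependence; cost marginals are
  matched to the configured mean/SD exactly through the quantile
  transform.
- **Missingness mechanisms.** MCAR, MAR on the most recent *observed*
  earlier outcome of the same block, or MNAR on the current (possibly
  unobserved) value — each a logistic model on the standardized outcome
  plus a shared participant frailty that clusters missingness within
  participants (reproducing the overlap of utility and cost missingness
  seen in real pattern tables). Intercepts are not free parameters: the
  user states target marginal missingness probabilities and the intercepts
  are solved by integrating the logistic over the latent load, so margins
  stay calibrated as the dependence parameters change. Two consequences
  are worth knowing: with strong outcome dependence the realized
  late-time margins drift a few points below their nominal targets
  (selection shifts the distribution of the last observed value), and the
  preset's completer fraction (≈ 46% at large n, frailty SD 3.5–5) was set
  against that large-n value, not against any test outcome.
- **Selection on the absolute outcome.** The standardization uses pooled
  across-arm reference moments: dropout responds to how well or how
  expensive a participant actually is, not to their arm-relative rank.
  This matters: an arm-relative mechanism selects both arms identically in
  score space and its effect cancels exactly from baseline-adjusted
  between-arm contrasts, making complete-case analysis spuriously
  unbiased. Similarly, the preset's slopes (−4 per utility SD, +1.5 per
  log-cost SD, diluted by the frailty to effective marginal slopes near
  −2/+0.75) are strong enough that the selection is materially nonlinear;
  a weak or heavily frailty-smoothed selection is effectively linear in
  the score and again cancels from adjusted contrasts. Sicker participants
  (lower utility, higher cost) drop out more, which is the clinically
  expected direction.

What the generator does **not** emulate: bounded/discrete EQ-5D utility
values (a truncation range is available but off by default; the generator
draws continuous normals), zero-inflated or clustered costs, covariate-rich
case mix, arm-specific missingness mechanisms, and any claim about the
dependence structure of the motivating trial's real missingness — the
preset mechanism is a documented assumption. Passing tests therefore show
that the estimator does what likelihood theory promises under a
well-specified utility model and MAR; they do not certify behaviour under
model misspecification beyond the cost-skewness exercise, nor under MNAR,
where the MNAR_current mechanism exists precisely so the user can observe
the method's bias boundary.

## Problem sizes used by the test suite

Oracle comparisons use tiny datasets (8–20 participants). Recovery and
bias demonstrations use the preset scaled to 500 per arm with 500
replicates — enough that the Monte-Carlo standard error of the mean
incremental QALY is ≈ 0.0004, resolving the complete-case bias (≈ −0.002)
while leaving the MMRM's bias statistically indistinguishable from zero.
Moment checks on the generator use 40,000–100,000 draws. Bootstrap
correctness uses B = 200–1,000 on complete-data fixtures where every
replicate converges in well under a second.

## Known limitations

- Two arms only; no cluster randomization; no multi-comparator CEAC
  frontier.
- Covariate effects are time-constant; no random slopes, AR(1)/Toeplitz
  structures, robust/sandwich variances, or small-sample df corrections.
- Multiple imputation and MNAR sensitivity analyses are out of scope; the
  complete-case comparator and the MNAR_current generator are provided so
  both boundaries of the method can be demonstrated, not repaired.
- Exact replication of the motivating trial's published estimates is not
  possible from this package alone: the underlying individual-level data
  are available only on request, and the package's anchors are the
  published linear-combination worked examples and pattern-table structure.
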