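---
title: "The extended crosswise model: estimation, fit testing and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The extended crosswise model: estimation, fit testing and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosswise)
```

## The problem

Asking people directly whether they have done something stigmatized —
doping, illicit drug use, breaking lockdown rules — invites underreporting.
Randomized response techniques insert a known random element between the
respondent's true status and the recorded answer, so that no individual
answer is incriminating while the population prevalence stays estimable.

In the crosswise design the respondent answers a sensitive question and an
innocuous *unrelated question* jointly, with one of two neutral options:
"I have TWO 'Yes' or TWO 'No' answers" (coded 2) or "I have ONE 'Yes'
answer" (coded 1). The *extended* crosswise model (ECWM) splits the sample
into two sub-samples with complementary, known probabilities $p_1$ and
$p_2 = 1 - p_1$ of a "Yes" to the unrelated question. The split buys one
degree of freedom that can be spent on a goodness-of-fit test — something
the plain crosswise model, being saturated, cannot offer.

This package implements the ECWM end to end: estimation (moment and
maximum likelihood, including logistic regression on the randomized
responses), the boundary-aware goodness-of-fit test, comparisons against
direct questioning, a respondent-level simulator for validation, and the
construction of number-sequence randomizer items whose randomization
probabilities are exact by design.

## Model and estimators

Let $\pi$ be the prevalence of the sensitive characteristic. Within
sub-sample $s$ the probability of response 2 is
$$\pi^*_{2|s} = p_s \pi + (1 - p_s)(1 - \pi),$$
and $\pi^*_{1|s} = 1 - \pi^*_{2|s}$. Inverting this within one sub-sample
gives the per-arm moment estimator
$$\hat\pi_s = \frac{n_{2s}/n_s - 1 + p_s}{2 p_s - 1}, \qquad p_s \ne 0.5,$$
which is deliberately *not* clipped: values below 0 (or above 1) are
legitimate outcomes of sampling error and are informative in their own
right. The overall estimate pools the arms with weights $n_s / n$
(`moment_pooled()`), with variance
$$V(\hat\pi) = \frac{1}{n}\left[\pi(1-\pi) +
  \frac{p_1(1-p_1)}{(2p_1-1)^2}\right].$$
Since the true $\pi$ is unknown, the pooled estimate is substituted,
clipped into $[0,1]$ inside $\pi(1-\pi)$ so that out-of-range moment
estimates keep a nonnegative variance. Confidence intervals are Wald at
95% ($z = 1.959964$) with endpoints truncated to $[0,1]$; truncation is
purely presentational and does not feed back into the point estimate.

An equivalent one-step estimator (`moment_matrix()`) writes the model as
$\pi^*_{y|s} = P \,(\pi, 1-\pi)'$ with a $4 \times 2$ transition matrix
$P$ in the fixed row order $(2|1,\; 1|1,\; 2|2,\; 1|2)$, and estimates
$\hat\pi = 2 P^- \hat\pi^*_{ys}$ via the Moore–Penrose inverse
(`MASS::ginv`). With equal arm sizes it reproduces the weighted average to
machine precision; with unequal arms the two differ slightly in how they
weight the arms. All vectorized input/output in the package uses that row
order.

### Maximum likelihood and regression

The same model, read per respondent with
$\pi_i = \mathrm{logit}^{-1}(x_i'\beta)$, is an ordinary binary regression
with a misclassification kernel. `ecwm_fit()` maximizes the resulting
likelihood. Two numerical paths are used:

* **Aggregated counts, intercept only.** The likelihood is unimodal in
  $\pi$ on $[0,1]$; it is maximized with `stats::optimize()` on the closed
  interval, the interior candidate is polished with up to three Newton
  steps on the analytic score, and both endpoints are checked explicitly.
  A solution within $10^{-6}$ of 0 or 1 is declared a *boundary solution*
  and pinned there. At interior optima the MLE coincides with the pooled
  moment estimate (we test agreement to $10^{-6}$).
* **Respondent-level data with covariates.** Unconstrained BFGS on the
  logit scale with the analytic gradient, starting from $\beta = 0$,
  relative tolerance $10^{-12}$, at most 200 iterations; the covariance
  matrix is the inverse of the numerically differentiated observed
  information.

`prevalence_from_fit()` returns the estimate on the probability scale.
Two variance conventions are exposed: the closed-form (expected
information) variance above — the default, which reproduces the intervals
of the bundled studies — and the observed-information delta-method
variance $\hat\pi^2(1-\hat\pi)^2 \, \widehat{Var}(x'\hat\beta)$. On
near-balanced data the two agree within a couple of percent; the published
sources for such tables rarely state which was used, so both are
available.

### Goodness of fit and the boundary rule

`gof_test()` compares the intercept-only model against the model with one
prevalence per sub-sample (equivalently, a sub-sample-membership covariate
in the regression). The likelihood-ratio statistic
$LR = 2(\ell_{\text{full}} - \ell_{\text{null}})$ is referred to
$\chi^2_1$. The discrepancy statistic
$G^2 = 2\sum_{y,s} n_{ys} \ln(n_{ys}/\hat n_{ys})$, with fitted counts
from the intercept-only fit and the $0\ln 0 = 0$ convention, equals $LR$
whenever the null estimate is interior — because the full model then fits
the four cells exactly. On a boundary solution the constrained full-model
arms collapse onto the same boundary, $LR$ becomes 0 while $G^2 > 0$, and
the result carries a `boundary` flag; the two statistics must be kept
distinct there, which is why the package computes both rather than one.
Questions are tested independently; no multiplicity adjustment is applied.

### Informed self-protection is invisible — and that is the point

A respondent who knows which response is incriminating in their arm can
always emit the other one. If carriers do this with probability
$\theta_c$ and non-carriers with $\theta_{nc}$, the transition matrix
becomes (`sp_transition_matrix()`, for $p_1 > p_2$)
$$Q = \begin{pmatrix}
p_1(1-\theta_c) & (1-\theta_{nc})(1-p_1)\\
1 - p_1(1-\theta_c) & p_1 + \theta_{nc}(1-p_1)\\
1 - p_1(1-\theta_c) & p_1 + \theta_{nc}(1-p_1)\\
p_1(1-\theta_c) & (1-\theta_{nc})(1-p_1)
\end{pmatrix}.$$
The second-row entries are forced by column stochasticity (each column of
a transition matrix must sum to one within a sub-sample); they are the
complements of the first row. $Q$ retains the equality of rows 1 and 4
and of rows 2 and 3 that characterizes $P$, so data generated from $Q$
are *exactly* representable by the clean model with a smaller prevalence:
$\theta_c$ and $\theta_{nc}$ are unidentified, the fit test has zero
power against them, and the naive estimator converges to
$$\pi - \frac{\pi p_1 \theta_c + (1-\pi)(1-p_1)\theta_{nc}}{2p_1 - 1}$$
(`sp_expected_naive_estimate()`), e.g. $0.1$ for $\pi = 0.3$, $p_1 = 0.8$,
$\theta_c = 0.5$, $\theta_{nc} = 0$. The acceptance suite demonstrates
this exactly: expected counts built from $Q$ yield $G^2 = 0$ and recover
the biased value to machine precision. The practical conclusion is a
design one — use a randomizer that hides which response is incriminating —
not an estimation fix.

## The number-sequence randomizer

The randomizer realizes $p_s$ physically: the respondent memorizes one
number from a first sequence and later reports whether it appears in a
second sequence. With sequence length $L \in \{5, 10, 15\}$ and exactly
$L \cdot p$ first-sequence numbers reappearing, the randomization
probability is a ratio of integers — overlap 1, 2, 3 for $p = 1/5$ and
4, 8, 12 for $p = 4/5$ — with no appeal to birthday distributions, and no
practical way for the respondent to track which response is
incriminating. First sequences are drawn from the 72 two-digit numbers
that remain after removing repeated-digit numbers and multiples of ten
(easy-to-memorize values would bias the choice); fillers for the second
sequence may be any number 1–99 not in the first sequence, because
nothing is memorized from the second sequence. Both sequences are kept
duplicate-free — a duplicate would corrupt the designed overlap ratio.
Control items use $p = 1$ (the second sequence is the first, reshuffled
until the order differs) or $p = 0$ (disjoint sequences); with a known
100% prevalence question they measure instruction non-adherence.
`design_survey()` alternates $(1/5, 4/5)$ and $(4/5, 1/5)$ across
consecutive questions within each sub-sample and emits a deployment
sheet. Sequences for different questions are generated independently, so
filler numbers may repeat across questions.

## What the simulator emulates — and what it does not

`simulate_ecwm()` generates respondent-level data in three layers:
truthful crosswise responding (carrier status Bernoulli($\pi$), unrelated
answer Bernoulli($p_s$), response 2 iff the two agree), informed
self-protection per the $Q$ matrix, and random responding (a fraction of
respondents answer with a fair coin, the standard account of
inattentiveness, which biases estimates toward 50%). Sub-sample sizes are
fixed rather than binomially split, matching how surveys allocate
respondents deterministically; the latent truth columns are retained so
tests can condition on them. `simulate_dq()` adds the direct-question
side with one-sided underreporting: carriers confess with probability
`dq_report_prob`, non-carriers never false-confess.

The generator deliberately omits features of real surveys: item
nonresponse, memory errors in the randomizer (empirically 4–13% on
control questions, larger for longer sequences), covariate-dependent
behavior, and correlation across questions within a respondent. Passing
recovery and calibration tests therefore validates the *estimators under
the stated model*, not the behavioral realism of any particular survey.

Validation harnesses built on the generator:

* `recovery_study()` — bias, RMSE and 95% CI coverage of the moment and
  ML estimators over replicated surveys.
* `gof_calibration()` — the rejection rate of the fit test at the
  $\chi^2_1$ 0.05 critical value (3.84). Under the null it should sit at
  5%; under self-protection it *stays* at 5% (the non-detectability
  result); under an asymmetric bias (`flip_subsample1 = TRUE`) it rises
  toward 1.
* `ecwm_power()` — analytic power of the two-sided Wald test of
  $H_0\!: \pi = 0$, using the closed-form variance at each hypothesis,
  with a Monte Carlo verification mode. The test specification (null
  value, sidedness, $\alpha$, allocation) is an explicit argument rather
  than a hidden convention.

The default Monte Carlo problem sizes in the test suite — 2000 replicates
at 367 per arm for calibration, 500 replicates at 5000 per arm for
recovery, 2000 replicates for power verification — are large enough that
the binomial Monte Carlo error (about $\pm 0.01$ on a rejection rate,
$\pm 0.02$ on coverage) is small against the effects being checked, while
keeping a full run in the tens of seconds on one core.

## Numerical and design choices

* Row order everywhere: $(2|1,\; 1|1,\; 2|2,\; 1|2)$; sub-sample 1 is the
  $p = 1/5$ arm in the bundled data (presentational only — the estimators
  are invariant to relabeling both arms, and to the joint response/arm
  flip $y \to 3 - y$, $s \to 3 - s$, which is the model's symmetry).
* $p_1 = 0.5$ is rejected at construction; $p_1 \in \{0, 1\}$ requires
  `control = TRUE` (control-question designs only).
* Boundary tolerance $10^{-6}$ on the probability scale; moment point
  estimates unclipped, CI endpoints truncated; variance plug-in clipped.
* Display convention (`format_table2()`): percentages to 1 decimal, test
  statistics to 2, p-values to 3; machine-precision values are retained
  in the underlying data frames and in JSON output.
* Degenerate inputs: empty sub-samples raise errors (not NaN); zero cells
  flow through the $0 \ln 0 = 0$ convention; degenerate control designs
  ($p_s \in \{0,1\}$) give $\pm\infty$-free likelihoods only when the
  data are consistent with them, which is exactly the control-question
  use case.

## Limitations

Estimation of the self-protection rates is impossible within this design
(proved, not a software gap), and no cheater-detection or unrelated
question model estimators are included. The regression machinery assumes
independent respondents and simple random sub-sampling; complex survey
weights, multilevel structure and Bayesian estimation are out of scope.
The direct-question comparison inherits the Wald interval's known
undercoverage very close to prevalence 0 or 1.
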