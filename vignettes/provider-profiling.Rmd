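---
title: "Profiling providers from public summaries under cluster-level confounding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling providers from public summaries under cluster-level confounding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rppclc)
library(dplyr)
```

## The problem

National evaluations of healthcare providers — the motivating case is U.S.
kidney transplant programs — are built on *indirect standardization*: a
registry publishes, for each provider $i$, an observed outcome count $O_i$,
an expected count $E_i$ from a patient-level risk model fitted to the whole
nation, and an effective size $\tilde n_i$. The naive score statistic

$$Z_i = \frac{O_i - E_i}{\sqrt{a(\psi)\,\tilde n_i}}$$

is adjusted for patient case mix only. Two further sources of variation
contaminate it:

* **observed cluster-level confounders** $W_i$ (e.g. the donor organ supply
  in a provider's service area), with effects $\nu$, and
* **unobserved cluster-level heterogeneity** $\alpha_i \sim N(0,
  \sigma^2_\alpha)$ (e.g. latent pandemic-era disruption), which
  overdisperses the scores.

Ignoring them biases the conditional null distribution of $Z_i$ away from
$N(0, 1)$ and leads to unfair flagging: providers in disadvantaged regions
are penalized for circumstances outside their control. The privacy
constraint is that only the published summaries $(O_i, E_i, \tilde n_i,
W_i)$ are available — never patient records.

The generating model behind those summaries is a clustered GLM with
canonical link,
$$g(E[Y_{ij}]) = \mu^* + \gamma^*_i + X_{ij}^\top\beta + W_i^\top\nu +
\alpha_i,$$
where $\gamma^*_i$ is the provider's true quality effect — the quantity an
evaluation should isolate.

## Conditional null moments

For a provider with $\gamma^*_i = 0$ the first two moments of $Z_i$ can be
written in terms of $(\nu, \sigma^2_\alpha)$. With Poisson outcomes and log
link they are exact:

$$E[Z_i] = \sqrt{\tilde n_i}\,(e^{W_i^\top\nu + \sigma^2_\alpha/2} - 1),
\qquad
Var[Z_i] = e^{m_i}\left\{1 + e^{m_i}(e^{\sigma^2_\alpha} - 1)\tilde
n_i\right\},\quad m_i = W_i^\top\nu + \sigma^2_\alpha/2 .$$

With normal outcomes the scores follow a heteroskedastic linear model
exactly: mean $\sqrt{n_i/\sigma^2_\epsilon}\,W_i^\top\nu$, variance
$1 + \varphi n_i$, $\varphi = \sigma^2_\alpha / \sigma^2_\epsilon$. For
other exponential families `null_moments()` uses first-order
approximations; because the approximate variance is linear in
$W_i^\top\nu$ it can go nonpositive for extreme covariates, and it is then
floored at $10^{-6}$ with a warning. A quasi-Poisson dispersion
$a(\psi) > 1$ is supported by evaluating the Poisson formulas on the
standardized scale (mean divided by $\sqrt{a(\psi)}$, $\tilde n_i$ replaced
by $\tilde n_i/a(\psi)$ in the variance), which reduces to the exact case
at $a(\psi) = 1$; the dispersion is always supplied by the user, since the
summary data carry no information to estimate it.

## Robust estimation via a truncated-normal empirical null

Most providers are *null* (their deviation from the norm is clinically
meaningless), but a minority are genuine outliers, and fitting plain normal
densities to all scores lets those outliers drag $\hat\nu$ and
$\hat\sigma^2_\alpha$ (the `fit_normal_mle()` baseline demonstrates
exactly this). The robust fit assumes each null provider's score lies in a
central interval $[A_i, B_i]$ and each outlier's score lies outside it,
giving the likelihood

$$L(\nu, \sigma^2_\alpha, \pi_0) = \prod_{i \in S_0} \pi_0\,
\phi_i(Z_i)\; \prod_{i \notin S_0} \{1 - \pi_0 Q_i\},$$

with $S_0$ the set of scores inside their intervals, $\phi_i$ the normal
density at the conditional null moments, $Q_i$ its mass on $[A_i, B_i]$
and $\pi_0$ the null proportion.

Design choices that the estimator's behaviour depends on, all configurable:

* **Initialization.** Huber M-estimation (tuning 1.345) of the scores on
  the design $\sqrt{\tilde n_i / a(\psi)}\,W_i$ through the origin; the
  overdispersion start is the median of $\max\{0, (r_i^2 -
  1)a(\psi)/\tilde n_i\}$ over residuals, a method-of-moments estimate
  under the null variance $1 + \varphi \tilde n_i$ made robust by the
  median; $\pi_0$ starts at 0.95.
* **Null intervals.** $A_i, B_i = m_i \mp c\,s_i$ at the pilot moments with
  $c = 2.5$ by default, then exactly one refinement pass: intervals are
  recomputed at the first optimum and the likelihood re-maximized
  (`refine = FALSE` disables). A fixed two-stage scheme keeps the
  estimator deterministic. We also implemented and evaluated a skew-aware
  alternative (intervals at exact quantiles of the Poisson-lognormal null
  law); it improved nothing material, degraded robustness under heavy
  contamination, and cost five times as much, so the symmetric rule stays.
* **Optimization.** L-BFGS-B on $(\nu, \log(\sigma^2_\alpha + 10^{-8}),
  \mathrm{logit}\,\pi_0)$ with $\pi_0 \in (10^{-4}, 1]$, objective
  tolerance `factr = 1e4` (about $10^{-12}$ relative), at most 500
  iterations. Non-convergence is reported in the fit object rather than
  thrown.
* **Degeneracy.** Covariate columns that are identically zero get a zero
  coefficient and drop out of the design (the fit degenerates to a
  variance-only empirical null); genuinely collinear designs are an error
  naming the offending columns; a null set smaller than the number of
  covariates aborts rather than silently widening intervals.

### A known finite-sample property

Under a lognormal confounding factor the null scores are right-skewed,
while $\phi_i$ is normal with the correct first two moments. Clipping at
$m_i \pm 2.5 s_i$ removes more probability mass from the heavy right tail
than from the left, so the truncated fit underestimates
$\sigma^2_\alpha$ — by roughly 15–20% in the reference design below
(e.g. mean $\hat\sigma^2_\alpha \approx 0.082$ against a true 0.1), while
the no-truncation fit is unbiased on null data. The cost shows up as
adjusted credible intervals that run slightly anti-conservative (empirical
coverage near 0.90 rather than 0.95 in the coverage study). $\hat\nu$ is
unaffected. We keep the symmetric rule because every alternative we tried
traded this small calibration loss for worse robustness, which is the
estimator's first job.

## Inference

Two flagging routes share the fitted $(\hat\nu, \hat\sigma^2_\alpha)$:

* **Corrected frequentist scores.** $Z^*_i = (Z_i - \hat m_i)/\hat s_i$
  compared to a threshold (default 1.96, strict inequality: a score
  exactly at the threshold is not flagged).
* **Pseudo-Bayesian measure ratios.** With a modest number of providers,
  $\hat\nu$'s sampling error is not ignorable. A normal prior
  $\nu \sim MVN(0, \Sigma_{prior})$ (default: diagonal, variance 100 per
  centered-covariate coefficient — weakly informative, flat-prior limit
  recovering the frequentist plug-in) is combined with the sandwich
  distribution of $\hat\nu$ over the null set. The total confounding
  factor $\Lambda_i = \exp(W_i^\top\nu + \alpha_i)$ then has a lognormal
  posterior whose log-variance adds $W_i^\top\Sigma_{post}W_i$ and the
  *full* $\sigma^2_\alpha$ — the latter plugged in as a known nuisance
  parameter, which is the "pseudo" in pseudo-Bayesian. The corrected
  measure ratio has the mixture posterior
  $$f_{R^*_i}(r) = \int \mathrm{Gamma}(r;\,O_i + 2,\; E_i\lambda + 2)\,
  f_{\Lambda_i}(\lambda)\,d\lambda,$$
  extending the standard $\mathrm{Gamma}(O_i + 2, E_i + 2)$ posterior used
  in transplant reporting, which it reproduces exactly when the
  confounding terms vanish.

The mixture is evaluated by Gauss–Hermite quadrature in $\log\lambda$ (64
nodes by default) so that densities, CDFs and quantiles are deterministic;
quantiles come from monotone root finding on the CDF, bracketed by the
component Gamma quantiles. Credible intervals are equal-tailed — the
convention of Gamma-quantile reporting in this field — and a provider is
flagged when the interval excludes 1. Intervals are two-sided; for
transplant-rate outcomes a `low` flag means under-transplanting.

## The synthetic-data generator

`gen_estimation_data()` draws complete national cohorts from the clustered
Poisson (or normal) model: 200 clusters with sizes equally spaced from 50
to 450 (deterministic spacing for reproducibility), $W_i \sim N(0,1)$ with
effect $\nu = 0.25$, $\alpha_i \sim N(0, 0.1)$, patient risk factor
$X_{ij} \sim N(-0.4, 0.5)$ (all pairs are read as mean and *variance*)
with effect $\beta = 1$, and outlying providers $\gamma^*_i = c + 0.5
W_i$ for a configurable fraction, $c = 2$ by default. For Poisson outcomes
the cluster total is drawn as $O_i \sim
\mathrm{Pois}(E_i e^{\gamma^*_i + \nu W_i + \alpha_i})$, the exact
distribution of the patient-level sum given the case mix, so the generator
is both faithful and fast.

The outcome scale is set by $\mu^*$. The default $\mu^* = 0.15$ makes the
marginal per-patient expected count equal to 1, so expected counts span
the same 50–450 range as the cluster sizes — the scale on which national
transplant-program summaries actually live, and the scale at which the
summary statistics are informative about $\sigma^2_\alpha$ (the
overdispersion term enters the null variance as $\sigma^2_\alpha \tilde
n_i$, so effective sizes of order $10^{-1}$ would leave it essentially
unidentified). For the flagging and coverage studies the audited provider
(index 1) defaults to $W_1 = 1$ with a large panel ($n_1 = 10^4$), so that
its own Poisson noise is small relative to cluster-level confounding —
the regime the coverage comparison is designed to expose — and its
quality effect $\gamma^*_1$ is placed on the negative (low-quality) axis.

`gen_cre_data()` emulates the correlated-random-effects world in which the
quality effect is tied to the cluster mean of the patient covariate,
$\gamma^*_i = \xi \bar X_i + \tau_i$ with $X_{ij} \sim N(m_{X,i}, 0.25)$,
$m_{X,i} \sim N(-0.4, 0.25)$, $\xi = 0.25$, normal outcomes with $\mu^* =
-6$, and contamination added to $\tau_i$ for the first fraction of
clusters. Treating $\bar X_i$ as the cluster covariate, the summary-level
fit estimates $\xi$ without patient-level data.

What the generator does *not* emulate: informative cluster size, spatial
autocorrelation in $\alpha_i$, measurement error in $W_i$, multiple
correlated confounders, or small-cluster exact-inference regimes. Passing
tests on these designs therefore demonstrate correctness of the estimator
under its own assumptions, not robustness to every feature of registry
data.

## Study drivers and problem sizes

`run_estimation_study()`, `run_inference_study()` and
`run_coverage_table()` are pure functions of a configuration and a seed.
The package's own experiments (tests and the acceptance script) run the
200-cluster designs at 150–500 replicates per condition, a size chosen so
a complete experiment takes minutes on one core while keeping binomial
Monte-Carlo error near 0.01 for the coverage and flag-rate estimates;
the same drivers scale to thousands of replicates unchanged. Failed
replicates (non-converged fits) are excluded and counted, never silently
retried.

## A worked example

```{r example}
sim <- gen_estimation_data(
  sim_config(I = 200, outlier_prop = 0.1, outlier_c = -2, seed = 7)
)
fit <- fit_rppclc(sim$providers)
tidy(fit)
glance(fit)

res <- evaluate_providers(sim$providers, fit = fit)
res |> count(flag_freq, flag_bayes)

# which flagged providers are genuine outliers?
res |>
  filter(flag_bayes != "null") |>
  left_join(sim$truth, by = "id") |>
  summarise(flagged = n(), truly_outlying = sum(is_outlier))
```

```{r plots, fig.width = 6, fig.height = 4}
autoplot(fit)
autoplot(res)
```

## Limitations

* $\sigma^2_\alpha$ is treated as known during inference; its sampling
  error (and the finite-sample truncation bias described above) is not
  propagated into the credible intervals.
* The prior scale for $\nu$ is a genuine user choice; the default variance
  of 100 per coefficient is effectively flat for confounders on a
  standardized scale, but should be revisited when covariates are not
  centered and scaled.
* No multiple-testing machinery beyond a user-set threshold/level; in
  provider monitoring, missed low-quality care is usually costlier than a
  false flag, so corrections are left to the analyst.
* The measure-ratio posterior is defined for count outcomes; for normal
  outcomes the corrected Z-scores are the supported inference route.
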