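---
title: "Estimating prevalence from two-phase screening surveys with misclassification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating prevalence from two-phase screening surveys with misclassification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Population prevalence of a condition such as autism spectrum disorder (ASD)
is rarely measurable by examining everyone. Two-phase surveys screen a whole
sampled population cheaply (here: the 39-item SCQ parent questionnaire, with
children scoring at or above a cutoff — default 11 — classified
screen-positive) and then apply expensive gold-standard diagnostics only to
screen-positives. Two systematic distortions stand between the resulting
counts and the population prevalence:

1. **Misclassification.** The ascertainment pipeline is an imperfect test
   with sensitivity Se and specificity Sp; the apparent positive fraction
   mixes true and false positives.
2. **Differential participation.** Only a fraction of screen-positive
   families attend the diagnostic phase, and attendance correlates with
   symptom severity, so participants are not a random subsample.

`twophaseprev` implements a Bayesian latent-status model that addresses both
at once, plus the surrounding machinery: cohort simulation with known ground
truth, screening bookkeeping, participation modelling, post-stratification,
deterministic and probabilistic sensitivity analyses, convergence
diagnostics, and administrative-prevalence arithmetic.

## The latent-status model

For screen-positive child $i$ with SCQ total $s_i$ (centered at the
screen-positive sample mean), true status $z_i$ is latent:

$$z_i \sim \mathrm{Bernoulli}(p_i), \qquad
  \operatorname{logit}(p_i) = \beta_0 + \beta_1 s_i .$$

Participants additionally contribute an error-prone measurement — the
diagnostic outcome $y_i$:

$$y_i \mid z_i \sim \mathrm{Bernoulli}\!\bigl(z_i\,Se + (1-z_i)(1-Sp)\bigr).$$

Non-participants contribute no measurement; their $z_i$ is imputed from
$p_i$. Because the SCQ score drives both participation and $p_i$, carrying
it in the latent model adjusts implicitly for differential participation —
the package's `fit_participation()` (a `glm` logistic fit of participation
on SCQ score, sex and grade among screen-positives) documents that the
adjustment is needed. In the primary analysis Se and Sp are fixed at 0.85
and 0.75; coefficient priors are independent Normal(0, 2.5²) on the
centered-covariate scale, a weakly informative default for logistic models.

Both interpretations of what Se/Sp describe are available: applied to the
diagnostic outcome (as above, the primary path), or as a screening-stage
property via `post_stratify(..., screening_sensitivity = )`, which divides
stratum case totals by an assumed screening sensitivity — the explicit
what-if correction for false negatives below the cutoff, which a design
that never diagnoses screen-negatives cannot estimate from data.

### Sampler

`fit_latent_model()` runs a partially collapsed Gibbs sampler written for
this model:

* **$\beta$ update.** $z$ is integrated out analytically: a participant's
  outcome is marginally Bernoulli with
  $q_i = p_i Se + (1-p_i)(1-Sp)$, and non-participants drop out of the
  $\beta$-likelihood entirely. A componentwise random-walk Metropolis step
  ($\beta_0$ then $\beta_1$, three sweeps per scan) moves against this
  marginal posterior; each proposal SD adapts toward ~44% acceptance during
  burn-in only and is frozen afterwards, preserving the correct stationary
  distribution. Collapsing matters: the naive data-augmented update, which
  conditions on hundreds of freshly imputed $z_i$, mixes an order of
  magnitude more slowly.
* **$z$ update.** Exact full-conditional Bernoulli draws: participants weigh
  the measurement likelihood
  ($\Pr(z_i{=}1 \mid y_i) \propto p_i\,Se^{y_i}(1-Se)^{1-y_i}$, etc.),
  non-participants draw from $p_i$.
* **Se, Sp (probabilistic sensitivity mode).** Conditional on $z$, the
  measurement likelihood is a pair of binomials over participants, so Beta
  priors are conjugate and Se/Sp get exact Gibbs draws — no Metropolis step
  is needed.

Defaults are the reference survey settings: 3 chains, 5,000 burn-in and 10,000
retained iterations per chain. Chains run sequentially with seeds derived
deterministically from the single MCMC seed (`simulation = seed`,
`chain c = split(seed, c)`, `grid cell k = split(seed, 1000 + k)`), so every
run is bit-reproducible and grid cells are comparable.

### Post-stratification

Per posterior draw, the stratum prevalence is the drawn case count among
sampled screen-positives divided by **all** screened children in the
stratum (screen-negatives count zero cases — prevalence is a whole-stratum
fraction), and the overall estimate is the population-weighted mix
$\sum_s N_s \hat\pi_s / \sum_s N_s$ with known stratum sizes $N_s$. The
convex-combination identity holds exactly for every draw, and summaries are
the posterior median with the equal-tailed 2.5%–97.5% credible interval,
reported per 1,000 by default.

Sex and grade breakdowns post-stratify within subgroups; subgroup population
sizes are the stratum sizes shared out in proportion to the subgroup's
sampled share (the sample's composition is taken to represent the stratum).
The adjusted male:female ratio is the ratio of posterior median rates, with
a CrI from the per-draw ratio.

**A caveat worth stating plainly:** the latent model carries no sex term, so
a child's sex reaches the subgroup estimates only through that child's own
diagnosis. When participation is incomplete or the measurement weak, the
sex-blind imputation genuinely shrinks subgroup rates toward each other —
the same mechanism by which model adjustment reduces crude sex ratios in
real surveys. The test suite therefore checks subgroup recovery in the
full-participation, perfect-measurement limit (where it is an exact
identity) and checks only effect detection under imperfect measurement.

### The Rogan–Gladen oracle

With no covariate ($\beta_1$ absent) and full participation, the model's
large-sample limit is the closed-form misclassification back-correction
$\pi = (p + Sp - 1)/(Se + Sp - 1)$ applied to the apparent prevalence $p$.
`rogan_gladen()` implements it (clamped to $[0,1]$, clamping flagged), and
the test suite holds the intercept-only sampler to it within Monte-Carlo
error — as well as cross-checking the sampler against rjags, the engine a
practitioner would otherwise write this model in.

## Sensitivity analyses

* `deterministic_grid()` refits the model over a 16-cell lattice,
  Se ∈ {0.80, 0.85, 0.90, 0.95} × Sp ∈ {0.65, 0.70, 0.75, 0.80}; in the
  intercept-only limit cell medians are ordered exactly as the
  Rogan–Gladen correction predicts.
* `probabilistic_sensitivity()` treats Se ~ Beta(85, 15) and
  Sp ~ Beta(60, 40) (prior means 0.85 and 0.60 — specificity deliberately
  more conservative, reflecting uncertainty under a lowered screening
  cutoff) and reports prevalence plus Se/Sp posteriors. With no participant
  data the Se/Sp posterior equals the prior, which the package permits (with
  a warning) precisely so that limit is checkable.
* `cap_hr()` bounds the high-risk stratum's per-draw prevalence at
  100/95/90/85% before post-stratification — a what-if for the assumption
  that resource-class enrollment implies near-certain case status. Capping
  is monotone by construction (`min` is applied per draw).

## Convergence diagnostics

`gelman_rubin()` is the rank-normalized split R-hat: chains are split in
half, pooled draws are converted to average ranks $r$ and normal scores
$z = \Phi^{-1}\bigl((r - 3/8)/(S + 1/4)\bigr)$, and the classic
$\sqrt{(\tfrac{n-1}{n}W + B/n)/W}$ statistic is computed on the scores.
`effective_sample_size()` is the combined-chain autocorrelation ESS with
Geyer initial-monotone truncation of paired autocorrelation sums
(autocovariances via FFT). Constant parameters yield `NaN` with a warning
rather than an error. `diagnose_fit()` applies modern thresholds — warn at
R-hat > 1.01 or ESS < 400, fail a report at R-hat > 1.05. The classic
(non-rank) variant would behave identically on well-mixed chains; the
rank-normalized form is the package's choice, made for its robustness to
heavy tails, not a claim about what any particular prior analysis used.

## Synthetic cohorts: what they emulate and what they do not

`simulate_population()` generates the mechanistic study conditions: three
strata (LR mainstream, ER special-education, HR resource classes) with
populations 34,392 / 292 / 112 and screened samples 2,792 / 190 / 90 (a
~32.6% screening response applied to the 8,565 invited mainstream children;
higher response in the two small special-education strata, consistent with
special schools responding more readily); true prevalence 0.017 / 0.30 /
0.95 — chosen once so the population mix sits near 22 per 1,000 with the HR
stratum "approaching certainty"; SCQ totals as discretized truncated
normals, non-case mean 5 SD 3, case mean 17 SD 5 (so both screen-negative
cases and screen-positive non-cases occur — the structures the model must
correct for); participation logit $-3.2 + 0.15 \times$ SCQ (mean
diagnostic-phase response near 25.6% at the screen-positive mean score). An
optional within-stratum male:female case odds ratio preserves stratum
prevalence exactly (the sex-specific probabilities are solved by root
finding). Sex and grade are otherwise independent decoration, which is what
makes the participation-model null checks meaningful.

Under this mechanistic generator the analysis model is *deliberately
misspecified* — $\Pr(z{=}1 \mid s, \text{stratum})$ is not a single
logistic in $s$ — just as it is for real data. For calibration studies the
package therefore also ships `simulate_logistic_cohort()`, which draws SCQ
scores first (stratum-specific distributions) and then status from the
analysis model's own law $\operatorname{logit}^{-1}(\beta_0 + \beta_1 s)$,
identical across strata. Coverage statements (95% CrIs covering the
realized post-stratified prevalence and the generator's $\beta$ in ≥ 90% of
100 replicates) are made under this correctly specified generator, against
the *realized* finite-sample truth
$\sum_s N_s (\sum_{i \in s} z_i / n_s) / \sum_s N_s$ — the quantity the
model actually estimates. Passing tests show the machinery is correct and
calibrated under its own assumptions; they cannot show that a single
logistic in the SCQ score is adequate for any particular real population,
that SCQ distributions match any real stratum, or anything about
school-level clustering, which the generators do not model.

The coverage study runs 100 replicates of roughly 280 screen-positive
children (strata sampled 1,500 / 190 / 90) at 2 chains × (1,000 + 2,000)
iterations, and the oracle-agreement check uses a 2,000-child single-stratum
census cohort — sizes chosen to make the Monte-Carlo error small relative
to the tolerances being asserted while the whole suite stays comfortably
runnable on a laptop.

## Numerical and design notes

* SCQ centering (at the screen-positive sample mean) decorrelates
  $\beta_0$ and $\beta_1$; `tidy()` reports the intercept on both scales.
* `log(1 + e^x)` is computed overflow-safely; measurement probabilities are
  floored at `1e-300` inside logs so perfect tests (Se = Sp = 1) remain
  valid inputs, where the latent status collapses onto the observed
  diagnosis exactly.
* Participation fits use IRLS with relative tolerance 1e-8 and at most 100
  iterations; fitted probabilities pinned at 0/1 flag
  (quasi-)separation and such fits refuse to produce weights. The
  participation model defaults to the joint SCQ + sex + grade specification
  ("age" is represented by grade, the cohort's natural ordinal); marginal
  fits are available by passing a single covariate.
* `ipw_prevalence()` is a non-Bayesian cross-check: inverse-participation-
  probability weighting of diagnosed cases, post-stratified. How a
  pre-model "participation-adjusted" pooled figure should be computed is
  genuinely underdetermined; this utility is labelled as the package's
  interpretation and plays no role in the primary path.
* Zero-count administrative cells make the Wald interval degenerate; the
  output flags this and always carries the Clopper–Pearson exact interval
  alongside. The Wald form remains the primary interval because it is what
  administrative reports print.
* All tabular results are tibbles; `autoplot()` methods cover traces and
  prevalence results, `plot_sensitivity_grid()` and `plot_hr_caps()` the
  sensitivity outputs.

## Known limitations

Single logistic link, no school-level random effects, no joint model of
screening-phase non-response (handled by post-stratification alone), no
correlation between Se and Sp priors, and subgroup breakdowns inherit the
sex-blind shrinkage discussed above. These mirror the scope of the
reference survey design rather than technical necessity.
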