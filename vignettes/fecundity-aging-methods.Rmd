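---
title: "Models and methods: age-specific fecundity effects of deleterious mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: age-specific fecundity effects of deleterious mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the design

Whether deleterious mutations have negative effects that *grow* with age
matters for how aging evolves: if they do, and if the among-mutation
variance in age-specific fitness increases with age, such mutations can
respond to age-specific selection just like the classical aging alleles.
This package analyses the experimental design built to measure that: a
panel of mutation lines, each assayed in replicate vials that house mutant
and wildtype females together. From every vial, matched numbers of females
of both genotype classes (25 by default) lay eggs for 24 h at three adult
ages — days 5, 19 and 33 — and the two class totals are counted. The
pairing within a vial is the heart of the design: both classes share the
vial environment, so the mutant/wildtype contrast is internally controlled.

`fecage` implements the full inference pipeline over this design, together
with a synthetic-data generator that emulates it with known ground truth,
so that every estimand can be verified by parameter recovery rather than by
reference to any particular dataset.

## Data model

One record is `(mutation, vial, age_day, class, n_females, eggs)`.
Validation (`fecundity_dataset()`) enforces: non-negative counts, at least
one laying female, and — per vial-age — exactly one mutant and one wildtype
record with equal `n_females`. Relative fecundity of a vial is
`ln((mut + 1) / (wt + 1))`; the +1 offset is applied to *all* counts, not
only when a zero occurs, which keeps the statistic continuous in the
counts. Per-vial totals (not per-female rates) are compared because the
design matches female numbers within a vial; `n_females` is retained for
validation and for the attrition option of the simulator.

## The two model families

**Deleteriousness (Poisson/log).** Vial-level egg counts per class:

    log E(eggs) = alpha[m] + theta[m] * I(class = mut) + u[vial]

fit once to day-5 counts and once to counts summed across the three ages.
`theta[m]` is the log mutant/wildtype fecundity ratio of line `m`;
deleteriousness is reported as `s = 1 - exp(theta)` (positive = harmful).
We parameterize cell means per mutation (one `alpha`, one `theta` per line)
rather than treatment contrasts, so per-line estimands need no
reference-level arithmetic.

**Aging (binomial/logit).** Per vial-age, mutant eggs out of
(mutant + wildtype) eggs. If both class counts are Poisson with means
sharing the vial factor, then conditional on their total the mutant count
is binomial with `logit(p) = log(lambda_mut / lambda_wt)` — the vial effect
cancels, and the model tracks the age trajectory of the log fecundity
ratio directly. Two codings:

* age as covariate: `logit(p) = eta[m] + beta[m] * (age - 5) + u[vial]`,
  where `beta[m]` is the per-day rate of reproductive aging (negative =
  the mutant declines faster);
* age as factor: `logit(p) = phi[m, age] + u[vial]`, the cell-means form
  from which interval differences, the acceleration contrast and
  among-line variances are derived.

Age enters in raw days centred at the first assay age, so slopes are per
day and `theta`/`phi` at day 5 describe young adults.

## Priors, sampler, convergence

Priors are weakly informative normals: SD 10 for intercept-like terms
(cell means included) and SD 2.5 for coefficients. Coefficient priors are
autoscaled: divided by the empirical SD of the predictor column for
non-binary predictors (the centred-age column; SD 2.5/14 per day at the
default ages), left at 2.5 for binary indicators. Defaults are four chains
of 4000 iterations with the first 1000 discarded as warm-up, i.e. 12,000
kept draws.

Sampling uses JAGS (Gibbs/slice), which is asymptotically correct for
these conjugate-ish GLMM structures; the settings contract and the
convergence bar (split R-hat < 1.05 for every parameter) are what we hold
fixed, not the sampler's internals. Convergence is monitored with the
split form of the Gelman-Rubin potential scale reduction factor (each
chain halved before computing the between/within variance ratio, so
within-chain drift is caught); a fit whose worst R-hat exceeds 1.05
carries a warning, never a silent pass.

Two parameterization choices matter numerically and were selected by
measuring mixing, not taste:

* the Poisson models use *hierarchical centring* — vial means are drawn
  around their mutation's mean — because egg counts pin each vial's level
  tightly, and the flat-centred form lets the mutation mean and its vial
  effects trade off almost freely in the Gibbs updates (split R-hat in the
  tens at short chains);
* the binomial models use a *non-centred* vial intercept
  (`sigma_vial * z`, `z ~ N(0, 1)`), because the paired design makes the
  vial effect on the ratio scale near zero, and the centred form mixes
  badly at that boundary (split R-hat 1.18 vs 1.002 at the default
  settings in our benchmarks).

Binomial rows with zero total eggs are dropped with a logged message (a
size-0 trial carries no information); the generator makes these
vanishingly rare at default means.

## Posterior estimands

All estimands are per-draw functionals of the coefficients, summarized by
the posterior mean, the central 95% credibility interval (2.5% and 97.5%
quantiles, R's type-7), and `p_mcmc` — twice the smaller tail proportion
of the draws relative to zero, capped at 1 — a two-tailed posterior
significance analogue.

* deleteriousness `s = 1 - exp(theta)` from either Poisson run;
* aging coefficient `beta` (per day) from the covariate coding;
* interval-specific aging `phi[m, a2] - phi[m, a1]`; these telescope
  exactly — `diff(5,19) + diff(19,33) = diff(5,33)` per draw — because
  they are linear in the same draws;
* acceleration `diff(19,33) - diff(5,19)`; with negative meaning faster
  decline, a negative contrast is acceleration (the two intervals are both
  14 days, so no per-day normalization is needed);
* among-line variance: per draw, the sample variance (n−1 denominator; this
  convention only scales the quantity, never the sign of a change) across a mutation subset's `phi[., age]`, on the logit/log-ratio
  scale on which the model is linear; variance *increases* between ages
  get a `p_mcmc`.

Classification (two-tailed, alpha = 0.05, uncorrected per line, with the
full p vectors exposed for anyone who wants corrections): *deleterious* if
the day-5 **or** the summed test is significant with `s > 0` (the union
rule; the report records which fired); *aging* if deleterious and the
covariate slope is significantly negative; *accelerating* if aging and the
acceleration contrast is significantly negative. Two calibration facts we
verified by simulation rather than assumed: (i) the sign restriction means
a directional classification fires on only the harmful half of two-tailed
null rejections, so its null rate is alpha/2, not alpha — the two-tailed
`p_mcmc` itself is the quantity calibrated at alpha; (ii) the two Poisson
tests share the day-5 data, so the union's null rate sits between one
directional test's rate and twice it — slightly anticonservative by
construction, the price of the disjunctive definition.

## Rank-correlation suite

Pleiotropy across ages is tested on per-mutation *median* relative
fecundities with Kendall's tau. We use tau-b (tie-corrected), since
medians of log ratios can tie; without ties tau-b equals the plain
statistic. Two-tailed p values: for untied data with n ≤ 10, the exact
permutation null of the concordance statistic via the inversion-count
recursion; for tied data with n ≤ 8, full enumeration of the n!
permutations (the tie pattern is fixed, so this is exact); otherwise the
normal approximation with tie-corrected variance and no continuity
correction. Tied data with n of 9–10 therefore falls to the approximation:
full enumeration at 10! is not tractable at interactive cost, and the
approximation error there is far below the decisions made with these p
values. All-tied input yields an explicit degenerate flag rather than a
number.

The deleteriousness-vs-aging test correlates the *change* in median
relative fecundity between two ages with its *level* at the earlier age.
This is conservatively biased: noise in the earlier median enters the
change with opposite sign, dragging tau negative under the null — the
suite reproduces that bias on pure-noise medians, and users should read
small positive taus accordingly.

Survival pleiotropy correlates day-5 fecundity medians with day-33
relative survival `ln((alive_mut + 1)/(alive_wt + 1))`, pooled across
vials by default (a per-vial-median option exists; pooling uses all
individuals where per-vial ratios of small counts are noisy).

## The generator

`sim_config()` encodes the generative law: vial intercept
`u ~ N(0, vial_sd^2)` shared by both classes; wildtype mean
`exp(mu + gamma_age + u)`; mutant mean multiplied by
`exp(delta + beta * (age - 5) + kappa * (age - 5)^2)`; counts Poisson, or
negative binomial when overdispersion is requested. Defaults mirror the
experiment: 20 lines, 20–22 vials per line, 25 females per class, ages
5/19/33. The scientific quantities of interest map onto `delta` (day-5 log ratio),
`beta` (aging rate per day) and `kappa` (acceleration).

Values the design does not fix were set once to field-plausible levels and
not revisited: baseline `log(100)` total eggs per class (4 eggs per female
per day for 25 females — a deliberately modest laying rate for mated
females on standard medium); a declining wildtype age trajectory
(0, −0.2, −0.6 on the log scale); `vial_sd = 0.2` (vial-to-vial
variation of ~±20%). The study-shaped panel (`sim_config_study()`) has 4
neutral lines, 16 deleterious with day-5 `s` spread over 0.10–0.55, aging
in the 14 most deleterious with rate proportional to deleteriousness
(`beta = 0.04 * delta` per day, which is what makes among-line variance
fan out with age), `kappa = -8e-4` in the 10 most deleterious aging lines,
and day-33 survival coupled to deleteriousness
(`logit = 2 + 1.5 * delta`).

What the generator does **not** emulate: block structure (the real assay
ran in experimental blocks), male effects, within-line heterogeneity in
frailty, egg-counting error, and attrition is off by default (all vials
survive to day 33; an attrition switch limits laying females at the final
age to the surviving count, matched across classes, mirroring the
protocol's matched-laying rule). Passing recovery tests therefore shows
the inference machinery is correct under the stated law, not that the law
captures every feature of real fly data.

## Verification sizes

The test suite verifies, under fixed seeds: oracle equivalence of the
rank statistics (1,000 random vectors against a brute-force pair count;
exact p against full enumeration); 95%-interval coverage of `delta` over
8 lines × 20 vials × 20 seeds and of `beta`/acceleration over a
3 × 2 effect grid × 20 seeds; null calibration over 50 seeds of
8 lines × 20 vials (the study's vial count) in a fast sampler mode
(2 chains × 900, 300 warm-up, labelled non-publication-grade); variance
fanning over 10 seeds of the 16-line deleterious panel; and split R-hat
< 1.05 for all four model runs at the full default settings on the
20-line panel. These sizes are the package's scaled study conditions:
large enough for the binomial error bands asserted, small enough to run
routinely.

## Known limitations

* The binomial aging model conditions away vial-level fecundity, which is
  exactly right under the shared-vial-mean law; real data with class-by-
  vial interactions would push variance into `sigma_vial`, widening
  intervals but not biasing the ratio estimands.
* `p_mcmc` inherits Monte-Carlo error of order `2/sqrt(draws)`; at the
  default 12,000 draws this is negligible for 0.05-level decisions, but
  borderline p values in fast mode should be re-run at full settings.
* The union classification rule is slightly anticonservative under the
  null (see above); single-test classifications are exposed alongside it.
* Summed-fecundity fits sum over the ages a vial actually has; vials
  missing an age are flagged, and their sums are smaller — with the
  default no-attrition generator this path is exercised only by user data.
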