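---
title: "Probabilistic exposure and margin-of-exposure assessment for e-cigarette liquids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic exposure and margin-of-exposure assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaporisk)
```

## The model

For a daily e-cigarette user, the intake of an agent dissolved in the
liquid is

$$E = c \cdot a \cdot \frac{v}{100} \cdot \frac{1}{bw}
\quad \left[\mathrm{mg\,kg^{-1}\,bw\,day^{-1}}\right]$$

with concentration $c$ (mg/ml), daily liquid consumption $a$ (ml/day),
vaporized percentage $v$ (the fraction of consumed liquid that is actually
aerosolized) and bodyweight $bw$ (kg).  Each input is an uncertain
quantity described by a *risk function* — a parametric distribution,
possibly shifted and truncated, or an empirical resampling distribution —
and the model propagates them by Monte-Carlo simulation.  The approach
assumes the inputs are independent and that the vaporized amount is 100%
bioavailable; no pharmacokinetics are modelled, and oral reference points
are used in the absence of inhalation thresholds.  Both assumptions are
deliberately conservative.

The margin of exposure is $\mathrm{MOE} = T / E$ per iteration, where $T$
is the agent's toxicological reference point (the most sensitive of
LOAEL/NOAEL/NOEL/BMDL10; see `tox_thresholds()`).  MOE always uses this
primary threshold — ADI/MRL guidance values, which already embed
uncertainty factors, are carried in the registry only for comparison
statements.  Band classification keys on the *median* of the MOE
distribution — below 100 "risk" and below 10 "high risk" for
animal-derived endpoints (the conventional $10 \times 10$ uncertainty
factor), below 10 and 1 respectively for human-derived endpoints — and
the MOE at the mean exposure, $T/\bar E$, is reported alongside because
risk statements are made in both framings.  The mean of the per-iteration
MOE ratios themselves is *not* reported: with near-zero exposures in the
denominator it is heavy-tailed to the point of being meaningless.
Iterations with a zero concentration draw produce an infinite MOE; these
are kept (they are genuine "non-exposed" scenarios), so upper MOE
percentiles of low-incidence agents are infinite by design and serialize
to CSV as the literal string `"inf"`.

## Distribution library

Seven families cover all inputs: normal, normal-from-quantiles (the
unique normal matching two stated quantiles, solved through standard
normal scores), shifted Weibull, triangular, three-parameter log-logistic
with CDF $F(x) = \left[1 + ((x-\gamma)/\beta)^{-\alpha}\right]^{-1}$ for
$x > \gamma$, uniform, and empirical resampling with replacement (zeros
for non-detects included).  Everything is built on the inverse CDF:

* **Truncation** restricts the inverse CDF to $[F(lo), F(hi)]$ — exact,
  no rejection loop (a test verifies distributional equality against
  rejection sampling).  One-sided truncation leaves the other side open.
  A shift is applied before truncation, so bounds refer to the shifted
  variable.
* **Sampling**: simple random sampling inverts i.i.d. uniforms; Latin
  Hypercube sampling inverts exactly one uniform per stratum
  $[(i-1)/n, i/n)$ in randomly permuted order, per input independently.
  Any seeded draw restores the caller's RNG state.
* **Moments**: closed-form means where they exist (truncated normal,
  uniform, untruncated triangular/Weibull, log-logistic with
  $\alpha > 1$; a log-logistic with $\alpha \le 1$ has a divergent mean
  and is reported as unavailable).  Otherwise the mean is computed
  numerically in the survival form
  $E[X] = \int_0^\infty (1-F) - \int_{-\infty}^0 F$, which stays smooth
  where the quantile function has integrable singularities.  General
  expectations $E[g(X)]$ integrate $g(Q(u))$ over $(\varepsilon,
  1-\varepsilon)$ with $\varepsilon = 10^{-9}$: the shaved tail mass is
  negligible while avoiding $g$ blowing up exactly on a truncation bound
  (relevant for $E[1/bw]$).

The independence factorisation
$E[E] = E[c]\,E[a]\,E[v]/100\,E[1/bw]$ serves as an analytic oracle for
the whole simulation chain and is asserted within three Monte-Carlo
standard errors for every packaged agent model.

## Fitting and model selection

Concentration vectors include non-detects as literal zeros.  Candidate
families are fitted by maximum likelihood (the shifted Weibull and
log-logistic over their shift/location too, bounded by the sample
minimum; the triangular by constrained ML over $(\min, \mathrm{mode},
\max)$ with the minimum allowed negative, since a best-fitting triangle
may extend below zero).  The winner is the family with the smallest
Kolmogorov–Smirnov statistic.  Two deliberate choices:

* The KS ranking is computed against the *untruncated* fitted
  distributions, because the data contain the zeros; the selected spec is
  returned with lower truncation at 0, which is how it enters simulation.
* No Lilliefors correction: KS with estimated parameters is used only to
  rank candidates, never as a hypothesis test, and no goodness-of-fit
  p-values are produced.

When fewer than `min_positive_fraction` (default 0.30) of values are
positive, parametric fitting is abandoned and the full data vector is
resampled instead.  The 0.30 default is chosen so that analytes detected
in roughly a quarter of samples or less — where a parametric shape is
driven almost entirely by the zero mass — take the resampling route,
while analytes detected in two-thirds or more are fitted parametrically.

## Packaged study configuration

`load_agent_specs()` ships the concentration risk functions of a
54-sample market survey of seven agents: nicotine
Normal(11.023, 13.134) mg/ml; glycerol Weibull(1.8104, 44.812) shifted by
−2.8327 g/100 g; propylene glycol Triang(−18.939, 91.8, 100.45) g/100 g;
ethylene glycol LogLogistic(−0.40204, 5.15, 1.8215) g/100 g; and
empirical resampling vectors for 1,3-propanediol, thujone and ethyl
vanillin (mg/L), all truncated at zero.  Exposure factors are the
quartile-solved Normal(4, 1.483) ml/day consumption, Uniform(6, 81) %
vaporization and Normal(73.9, 12) kg bodyweight.  Mass fractions convert
to mg/ml at an assumed liquid density of 1 g/ml (a config knob:
`density`); only that convention reproduces the packaged summary
statistics from the inputs.

The thujone vector — two detects, 183 and 178 mg/L, among 54 samples —
is exactly known.  The raw 1,3-propanediol and ethyl vanillin values are
not public, so their positive vectors are *synthetic*: constructed once
so the full 54-sample vector matches the reported incidence, mean, SD and
range (`synthetic_positive_values()`), and not revisited.  They support
the same summary statistics but cannot reproduce individual resampling
draws of the original data.

## Simulation choices

The headline analysis uses 10,000 LHS iterations (a few hundred
milliseconds per agent); tests use 300–20,000 depending on the assertion.
Empirical quantiles use the inverse-ECDF (type 1) definition — at
$n = 10^4$ the estimator choice is immaterial at reported precision.
Per-iteration draws, summaries and downstream CSVs are bit-identical for
a fixed `(model, n, seed, sampler)`.  Sub-seeds for multi-agent runs are
derived as `seed + agent index`.

The bodyweight distribution is truncated at zero like every other input;
at $(73.9 - 0)/12 \approx 6.2$ standard deviations the clipped mass
($\sim 10^{-9}$) is cosmetic.  Similarly, the quartile-solved consumption
normal is solved first and truncated after; the order of those two
operations is not observable at these parameter values (mass below zero
$\approx 0.003$).

## Sensitivity analysis

Influence ranking regresses the z-scored exposure on the four z-scored
inputs; with independent inputs the standardized coefficient of input $i$
is effectively its correlation with the output, which for the
multiplicative model scales with the input's coefficient of variation.
Plain OLS coefficients are the default (matching the convention of
spreadsheet risk tools); a rank-based variant is available via
`rank_based = TRUE`.  One instructive outcome: for propylene glycol the
truncated triangular concentration has CV $\approx 0.43$, *below* the
Uniform(6, 81) vaporization input's $\approx 0.50$, so vaporization
narrowly outranks concentration for that one agent under either
convention — concentration dominates for the other six.  The regression
$R^2$ is reported as a reminder that a linear surrogate of a
multiplicative model is an approximation.

## Synthetic data generator

`generate_sample_table()` emulates the study-shaped input: per
sample × analyte, a detect with the analyte's incidence probability, then
a concentration draw from its risk function.  `exact_counts = TRUE`
conditions the table on the expected detect counts instead of Bernoulli
detection — used when an assertion depends on which side of the 30%
resampling threshold an analyte falls, since an incidence near the
boundary (ethyl vanillin's 26%) would otherwise flip strategy in a
non-trivial fraction of tables.  Label metadata emulates market-survey
labelling discordance: by default one nicotine-free sample declared as
containing nicotine and a 5/23 fraction of declared-free samples actually
containing it.

What the generator does *not* emulate: measurement error of the assay,
between-batch structure, correlations between analytes (e.g. glycerol vs
propylene glycol formulations trade off in reality), or censoring at a
reported LOD (non-detects are exact zeros).  Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
model, not robustness to those real-data features.

Calibration fixtures are straight lines plus Gaussian noise; spectrum
traces are a Lorentzian peak plus white noise.  The wide-range
calibration fixture's noise SD (0.25 response units over levels
5–10,000 mg/L) is set so the emulated assay exhibits the linearity
(R ≈ 0.999) characteristic of the validated method it stands in for; the
near-LOD fixture's noise-to-slope ratio (≈0.5 mg/L) likewise emulates a
method whose detection limit is of order 1.6 mg/L.

## NMR validation statistics

Calibration is ordinary least squares of the intensity ratio (analyte
integral over the internal reference) on concentration, with residual SD
$s_{y/x}$ on $n-2$ degrees of freedom.  The regression rule uses
$\mathrm{LOD} = 3.3\,s_{y/x}/\mathrm{slope}$ and
$\mathrm{LOQ} = 10\,s_{y/x}/\mathrm{slope}$ (multipliers configurable; no
downstream result depends on them).  The SNR rule divides the peak
amplitude by twice the noise-window SD — the factor 2 mirrors the
peak-to-peak noise convention of spectrometer software and is also
configurable — and scales concentration to SNR 3 and 10.  Method
comparison defaults to treating paired non-detects as zeros: two methods
agreeing that an analyte is absent is genuine agreement, and dropping
those pairs (`nd_policy = "drop"`) discards exactly the concordant lower
range, weakening the correlation from ≈0.98 to ≈0.85 on the packaged
nicotine table.

## Known limitations

* Inputs are sampled independently; no copula/correlation structure.
* No censored-likelihood treatment of values below LOD.
* The linear sensitivity surrogate understates interactions of the
  multiplicative model (visible in $R^2 < 1$).
* Oral toxicological thresholds stand in for inhalation ones, and
  nicotine-dependence hazard is out of scope for lack of dose–response
  data.
* MOE percentiles for low-incidence agents are dominated by the zero/non-
  zero mixture of the resampling vector, not by its positive tail.
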