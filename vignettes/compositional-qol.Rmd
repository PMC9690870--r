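---
title: "Methods: compositional time-use analysis of child quality of life"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional time-use analysis of child quality of life}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codaqol)
```

## The problem and the model

Daily physical activity (PA), sedentary behaviour (SB) and sleep (SL) of a
preschool child jointly exhaust the 24-hour day. Statistically this makes
the three durations a *composition*: only the relative sizes of the parts
are informative, the parts are negatively coupled by construction, and
ordinary regression on raw hours is misspecified (the covariates sum to a
constant). The package therefore works in log-ratio coordinates throughout.

Each record's durations are closed to $\kappa = 24$ h and mapped to
isometric log-ratio (ilr) pivot coordinates $z = V\,\ln x$, where for the
pivot order $(x_1 \mid x_2, x_3)$

$$V = \begin{pmatrix} \sqrt{2/3} & -1/\sqrt6 & -1/\sqrt6 \\
0 & 1/\sqrt2 & -1/\sqrt2 \end{pmatrix},$$

so $z_1 = \sqrt{2/3}\,\ln\!\big(x_1/\sqrt{x_2 x_3}\big)$ contrasts the pivot
behaviour against the geometric mean of the rest. The adjusted outcome model
is ordinary least squares on these coordinates plus covariates,

$$\mathrm{QoL} = b_0 + b_1 z_1 + b_2 z_2 + c_{\text{age}}\,\mathrm{age}
  + c_{\text{sex}}\,\mathrm{sex} + \varepsilon,$$

with sex coded girl = 0, boy = 1. Its assumptions are the usual ones —
linearity in the log-ratio coordinates, homoscedastic errors, and records
treated as independent — and `model_diagnostics()` reports residual skewness,
excess kurtosis and Q–Q data rather than gatekeeping on them.

Fitting the model three times, once with each behaviour as pivot, yields the
per-behaviour coefficients $\beta_p$ reported by `pivot_betas()`. All three
fits describe the same prediction surface, so $\sum_p \beta_p = 0$ holds to
numerical precision; this identity is enforced as a regression test and used
to screen published coefficient sets (`clr_gradient()` warns above
$|\sum\beta| = 0.05$ — one published yearly row fails this check and is
flagged rather than reproduced). On the centred log-ratio scale
$a_p = \beta_p/\sqrt{3/2}$, predictions differ between two days $x, x'$ by
$\sum_p a_p(\ln x'_p - \ln x_p)$, which is the isotemporal substitution
predictor: covariates cancel, and the result is invariant to the ilr basis
and to the closure constant.

Confidence intervals for a substitution effect use the delta method exactly:
the effect is linear in the fitted coefficients with contrast
$d = (0, \Delta z_1, \Delta z_2, 0, 0)$, so
$\mathrm{Var}(\Delta) = d^\top \Sigma_{\hat\beta} d$ and the interval is
$\Delta \pm t_{n-p,\,0.975}\sqrt{\mathrm{Var}(\Delta)}$ (a normal quantile is
available by option).

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `kappa` | 24 | h | the day is the whole; analyses operate on closed compositions even when reported raw means total less (their pre-closure total stays in the logs) |
| `epsilon` | 0.25 | h | multiplicative zero replacement; 15 min matches the substitution granularity |
| `amounts` | 0.25–1.0 | h | 15-min reallocation steps up to one hour |
| quantile groups `k` | 4 | — | quartile QoL profiles |
| CI level | 0.95 | — | conventional |
| sleep plausibility | 11–14 h (< 3 y), 10–13 h (3–6 y) | h | guideline bands, configurable because the original screening thresholds are not published |

## What the generator emulates — and what it does not

`generate_survey()` draws the stated world the analysis assumes: clr vectors
from a multivariate normal whose mean is the clr of the published 2021 mean
day (PA 3.83, SB 4.59, SL 11.17 h closed to 24 h) and whose covariance is
derived from a target pairwise log-ratio variation matrix on the published
scale (off-diagonals 0.36–0.50) via $\Sigma = -\tfrac12 G T G$; ages uniform
on [2, 6) (mean 4, approximating the reported ~3.8 ± 1.3); balanced sex; an
outcome linear in $\ln x$ with clr gradient defaulting to the published 2021
pivot coefficients rescaled by $1/\sqrt{3/2}$, $c_{\text{age}} = 0.5$,
$c_{\text{sex}} = 1$, residual sd 13 QoL points (the reported outcome sd is
~14.7, most of it unexplained); and missingness under 5% (defaults 2–3%).
`sigma_for_r2()` instead picks the residual sd that fixes the model $R^2$
analytically — the recovery tests use $R^2 = 0.03$, the published 2021 value,
which corresponds to a residual sd near 10 rather than the illustrative 13.

The generator deliberately does *not* emulate: year-on-year trend dynamics
(one call is one wave; multiple waves are loops over configs), reporting
heaping in parent recall (durations are continuous), correlation between
behaviours and demographics, or the bounded 0–100 outcome — clipping exists
(`clip_outcome`) but is off by default because truncation biases the OLS
recovery the generator is there to test. A green simulation test therefore
establishes internal correctness of the estimators under the assumed
logistic-normal model, not the field validity of parent-reported time use.

Item-level PedsQL generation distributes the target total over the 0–4 item
grid with per-item Gaussian noise; internal consistency is controlled
empirically by `item_noise`, not analytically.

## Numerical and design choices

- **Closure vs raw totals.** Published arithmetic behaviour means sum to
  19.59 h, not 24 h. Compositions are closed at analysis time (log-ratio
  quantities are unaffected); the substitution worked example feeds the
  published means through unclosed, and the acceptance tolerance of ±0.05
  QoL points absorbs the resulting ambiguity — both baselines land inside it.
- **Substitution baseline.** Default is the sample's compositional
  (geometric) mean, the standard centre for compositional substitution; the
  arithmetic mean is available (`baseline = "arithmetic"`) for reproducing
  analyses that tabulated arithmetic means.
- **Variance estimators.** Unbiased ($n-1$) throughout, including the
  variation matrix.
- **Quantile grouping.** Type-7 (linear interpolation) sample quantiles; a
  score exactly on a cut point goes to the lower group; an all-ties sample
  collapses to group 1 with a warning.
- **PedsQL scoring.** Scores average over *completed* items with no minimum
  (a configurable ≥ 50%-answered rule exists but is off, matching the scale's
  literal scoring text); the psychosocial summary is the item-level mean over
  emotional + social + school items, with the dimension-level mean available
  by option. The 23-item form applies from the fifth birthday.
- **Imputation.** QoL by `floor(age)` group mean with overall-mean fallback;
  age by overall mean (the group-mean rule is circular for age itself); sex
  by mode with a deterministic first-observed tie-break.
- **Zero durations.** Multiplicative replacement: zeros become `epsilon`,
  non-zero parts shrink proportionally so the total is preserved; an all-zero
  record is rejected as invalid.
- **Degenerate fits.** Constant outcomes return $R^2 = 0$ (the textbook 0/0
  limit), rank-deficient designs raise an explicit error, and a noiseless fit
  yields zero-width intervals.

## Limitations

Only the three-part day is exercised (the basis construction generalises to
$D$ parts, but nothing beyond $D = 3$ is tested). Models are single-level
OLS — no survey weights, clustering, or multiple-imputation variance
corrections. Substitution moves time between exactly two behaviours around a
fixed baseline; three-way redistributions and curvature (quadratic ilr
terms) are out of scope. The published descriptives and $R^2$ values cannot
be reproduced without the restricted records; only the algebraic identities
and the printed-input substitution predictions are reproduced exactly.
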