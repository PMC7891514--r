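---
title: "Personal reference ranges for longitudinal laboratory monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personal reference ranges for longitudinal laboratory monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(persref)
library(dplyr)
```

## The problem

Conventional laboratory reference ranges are *inter-individual*: a 95%
interval over a healthy reference population, mean ± 1.96 SD. For analytes
with marked biological individuality — serum nutrition markers such as
transferrin (TRF), albumin (ALB), retinol-binding protein (RBP) and
transthyretin (TTR) are the running example in this package — a person's own
measurements cluster far more tightly than the population spreads. A patient
can drift a long way from their personal baseline while remaining comfortably
inside the population range, so clinically relevant deterioration (for
example of nutritional state under close monitoring) goes unflagged.

`persref` implements and compares four estimators of an *intra-individual*
(personal) reference range built from a subject's own repeated measurements,
against the population range, on balanced longitudinal panels (every subject
measured at every visit; the canonical design is 20 subjects × 5 visits).

## The model

All methods sit on the additive mixed model

$$X_{ij} = \mu_i + v_j + e_{ij},$$

where $\mu_i \sim N(\mu_0, \sigma_0^2)$ is subject $i$'s true level
(between-subject variance $\sigma_0^2$), $v_j$ is a fixed visit effect shared
by all subjects (zero in the default generator), and
$e_{ij} \sim N(0, \sigma^2)$ pools temporal biological variation $\tau^2$ and
analytical error $\sigma_\epsilon^2$. With a single measurement per visit
only the sum $\sigma^2 = \tau^2 + \sigma_\epsilon^2$ is identifiable, and
that is all the package reports. Normality on the raw measurement scale is
assumed throughout — reasonable for these analytes, whose repeated
measurements pass skewness/kurtosis checks; a transformation hook is a
deliberate non-feature of this version.

## The four personal-range methods

**Naive (`naive_interval`).** $\bar X \pm z S$ from the subject's own mean
and sample SD ($n-1$ denominator), $z = 1.96$ by default. Simple, but it
treats $S$ as the true dispersion: with $n = 5$ visits a fresh draw from the
same distribution lands inside only ~85% of the time (the package's Monte
Carlo reproduces this), not 95%.

**RCV (`rcv`, `rcv_interval`).** The reference change value
$RCV = \sqrt{2}\,Z\sqrt{CV_a^2 + CV_i^2}$ (percent) combines the analytical
CV ($CV_a$, a property of the assay, supplied in the analyte configuration)
with the within-subject biological CV ($CV_i$). The personal range is
$\bar X (1 \pm RCV/100)$. Two sources for $CV_i$ are supported: the
subject's own cumulative CV (default in trajectories, available from the
second visit) or the panel-level mean CV(intra) (`cvi_source = "panel"`),
which yields one RCV per analyte as in a summary table.

**Prediction interval (`cn`, `tango_interval`).** The acceptance region of
the t test of a new observation against the history:
$\bar X \pm C_n S$ with $C_n = t_{n-1}(\alpha/2)\sqrt{(n+1)/n}$. The
multiplier is 3.041 at $n = 5$ — half again the naive 1.96 — and decreases
to 1.96 as visits accumulate. This is the only method with exact finite-sample
coverage under the model, which the test suite verifies by simulation. The
$\sqrt{(n+1)/n}$ form (rather than an exponent) is fixed by the anchored
value 3.041 at $n = 5$.

**Empirical-Bayes shrinkage (`estimate_components`, `posterior`,
`bayes_interval`).** With components $(\mu_0, \sigma_0^2, \sigma^2)$ known,
the conjugate normal–normal posterior for a subject's level after $n$
observations is

$$\mu_n = \frac{\sigma^2}{n\sigma_0^2+\sigma^2}\,\mu_0 +
  \frac{\sigma_0^2}{n\sigma_0^2+\sigma^2}\sum_j X_j,
  \qquad
  \sigma_n^2 = \frac{\sigma^2\sigma_0^2}{\sigma^2+n\sigma_0^2},$$

and the 95% range for the *next measurement* is
$\mu_n \pm z\sqrt{\sigma_n^2 + \sigma^2}$. At $n = 0$ this is exactly the
population range $\mu_0 \pm z\sqrt{\sigma_0^2+\sigma^2}$; the width falls
monotonically in $n$ to the floor $2z\sigma$ set by irreducible
within-subject variation. The "$N(\mu_n, \sigma_n)$" notation is resolved as
a *variance* $\sigma_n^2$, forced by the reciprocal-addition form
$1/\sigma_n^2 = 1/\sigma_0^2 + n/\sigma^2$. Plugging in panel-estimated
components ignores their estimation uncertainty; that plug-in behaviour is
implemented as specified and is a known limitation, not a bug.

### Estimating the components

`estimate_components()` uses the closed-form method-of-moments solution for
the balanced two-way layout: visit effects are visit means minus the grand
mean; the residual mean square with divisor $(S-1)(T-1)$ estimates
$\sigma^2$ unbiasedly after removing subject and visit means; and
$\hat\sigma_0^2 = \max\{0, (MS_{between} - MS_{within})/T\}$. In balance this
equals the REML solution (a test cross-checks against `lme4::lmer`), is
dependency-free and has no convergence failures. Negative moment estimates
are truncated to zero with a warning. Unbalanced panels are rejected: every
closed form above assumes a common visit count, and silently dropping
subjects would change the inferential target.

### Numerical and degenerate-input choices

* **Zero within-variance.** `posterior()` returns the continuous
  $\sigma^2 \to 0$ limit rather than erroring: noise-free observations pin
  the posterior at their mean (at $\mu_0$ for a point-mass prior). This keeps
  the all-constant panel — where every method's width collapses to zero — a
  well-defined edge case rather than a failure.
* **Zero SD subjects.** A subject observed once, or with all-equal values,
  gets an `NA`-flagged SD/CV or test statistic, never a silent zero; a CV at
  mean zero is likewise flagged, since these analytes are strictly positive.
* **Rounding.** All computation is full precision. Display rounding is
  half-away-from-zero (`round_half_up()`) at the analyte's configured
  decimals, matching how laboratory tables are printed; tests compare
  unrounded values with explicit tolerances.
* **Boundary convention.** Reference intervals are closed: a value exactly on
  a limit is `"within"`.
* **Visit gaps.** Visit indices must be contiguous from 1 per subject;
  `reindex_visits = TRUE` renumbers observed visits 1..k. Cumulative methods
  depend on visit *order*, not calendar spacing, so spacing is deliberately
  not modelled.

## Sequential evaluation

`cumulative_trajectory()` re-estimates the chosen interval at every visit.
Two modes:

* **prospective** (default): the interval judging visit $k$ uses visits
  $1..k{-}1$ only — the alarm semantics relevant to monitoring, since a new
  result must be compared with what was known before it arrived;
* **retrospective**: the interval at $k$ uses visits $1..k$, reproducing
  cumulative trajectory curves.

Until a method can be formed (the naive, RCV and prediction-interval methods
need at least two prior values for an SD or CV), the subject's population
range stands in — so the very first measurement is judged against the
conventional range, and the `interval_method` column records which interval
actually did the judging. The Bayesian method is evaluable from the first
observation, and even at $n=0$, where it *is* the population range.

## What the generator emulates — and what it does not

`simulate_panel()` draws exactly from the additive model above, and
`study_like_bundle()` packages four panels at the canonical study scale
(20 × 5) with published mixed-model components where available:

| analyte | $\mu_0$ | $\sigma_0$ | within-SD $\sigma$ |
|---|---|---|---|
| TRF (mg/dL) | 280 | 27.77 | 12.88 |
| ALB (g/dL) | 4.7 | $\sqrt{0.05}$ | $\sqrt{0.28^2-0.05}$ (imputed) |
| RBP (mg/dL) | 3.5 | $\sqrt{1.13}$ | $\sqrt{0.10}$ |
| TTR (mg/dL) | 29.8 | $\sqrt{47.29}$ | $\sqrt{7.14^2-47.29}$ (imputed) |

The ALB and TTR within-SDs are imputed from the published total and
between-subject dispersions because their within-subject components were not
printed; they are flagged in `study_params()` and never used as test anchors.
Visit effects default to zero (no common trend is reported for these data; a
nonzero option exists to exercise the fixed-effect removal path). Sex is
assigned by ratio but does not shift values — it only selects sex-specific
population ranges. The generator does **not** produce: serial correlation in
$e_{ij}$ (unidentifiable in this design and assumed away by the model),
skewed or heteroscedastic analytes, covariate effects (age, diet), or missed
visits. Passing tests therefore demonstrate correctness *under the stated
model*, not robustness to violations of it.

One calibration finding worth knowing: under these TRF components, the event
"all 20 subjects show CV(intra) < CV(inter)" has probability only ≈ 0.87 per
panel — a real 20/20 observation is compatible with the model but not its
near-certain outcome. The weaker statement "mean CV(intra) < CV(inter)" holds
essentially always, and the test suite asserts both at their measured
frequencies' appropriate levels.

## Problem sizes used by the test suite

The suite's simulation sizes are chosen so each property is measured with a
standard error well inside its asserted tolerance: coverage at $10^5$
replicates (module tests use $2\times10^4$), parameter recovery at 500 × 5
with a 10% band and 20 × 5 with a 25% small-sample band, unbiasedness of the
between-subject moment estimator over 200 panels of 100 subjects, and the
CV-comparison frequency over 500 study-scale panels.

## A worked trajectory

```{r trajectory}
panel <- simulate_panel(mu0 = 280, sigma0 = 27.77, sigma_eps = 12.88,
                        seed = 1, analyte = "TRF")
comp <- estimate_components(panel)
tidy(comp)

cumulative_trajectory(panel, "S01", "bayes", components = comp,
                      mode = "retrospective")
```

```{r report}
comparison_report(panel)
```

```{r plot, fig.width = 7, fig.height = 4}
plot_cv_comparison(panel)
```

## Known limitations

* Plug-in variance components: posterior widths ignore the uncertainty of
  $\hat\sigma_0^2$ and $\hat\sigma^2$ (material at 20 subjects).
* Balanced designs only; no calendar-time modelling; no log-normal/skewed
  variants of the RCV; no multiplicity correction in the per-subject t/F
  screen (deliberate, mirroring per-subject flagging practice).
* The population ranges shipped in `analyte_defaults()` are adult Japanese
  routine-assay ranges; users elsewhere should supply their own via
  `read_analyte_config()`.
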