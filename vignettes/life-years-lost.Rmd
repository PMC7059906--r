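---
title: "Estimating excess Life Years Lost after disease onset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating excess Life Years Lost after disease onset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifelost)
```

## The model

Life Years Lost (LYL) measures premature mortality in a group of people
with a disease by starting each person's clock at their observed age of
onset rather than at birth or at an arbitrary fixed age. For a person at
risk at age $a$, the $\tau$-restricted remaining life expectancy is the
area under the conditional survivor curve,
$$
{}_{\tau-a}e_a = \int_a^\tau S(t \mid a)\, dt ,
$$
and the life lost before $\tau$ is its complement,
$$
\mathrm{LYL}(a) = (\tau - a) - {}_{\tau-a}e_a
               = \sum_k \int_a^\tau F_k(t \mid a)\, dt ,
$$
where $F_k$ is the cumulative incidence function (CIF) of death cause $k$.
The second equality holds because the survivor function and the CIFs
partition the unit probability at every age; graphically, the CIFs stacked
above the survivor curve split the area above it into one band per cause,
and the band areas are the cause-specific LYL. The restriction to a finite
$\tau$ is essential: with censored observations the unrestricted mean is
ill-determined because the survivor curve need not reach zero. Under
administrative censoring at some age, $\tau$ should be at most that age,
and LYL reads as "life lost after $a$ and before $\tau$".

Excess LYL is the difference between the diseased cohort and a reference
population at the same conditioning age, either at one age or averaged over
the observed age-at-onset distribution with weights $n_i$ (new cases at
age $i$):
$$
\overline{\mathrm{LYL}} = \frac{\sum_i n_i\, \mathrm{LYL}(i)}{\sum_i n_i}.
$$
These estimates are descriptive: they compare mortality experiences and do
not correspond to an intervention, so no causal reading is intended.

## Estimators and conventions

**Survivor curve.** The conditional survivor function is the product-limit
(Kaplan–Meier) estimator over event ages beyond the landmark $a$, with
delayed entry: an individual contributes to the risk set from
$\max(\text{entry}, a)$ until exit. Individuals whose entry age exceeds
$a$ *do* join the risk set at their entry age; this is the standard
left-truncated behaviour and uses all available information (the
alternative — restricting to people already under observation at $a$ —
discards late entrants; with onset-age entry the two coincide whenever the
landmark exceeds all onsets in the subgroup). Follow-up for a diseased
group starts at onset, never at birth, to avoid immortal time bias.

**CIFs.** Aalen–Johansen: at event age $t_j$ with risk set $n_j$ and
$d_{kj}$ deaths of cause $k$, the CIF gains $S(t_{j-1})\, d_{kj}/n_j$.
Because the survivor decrement at $t_j$ is the sum of these increments,
$S + \sum_k F_k = 1$ holds at every jump up to float round-off; the test
suite enforces $10^{-12}$.

**Ties.** Ages are continuous and never rounded internally. Multiple events
at one age are processed jointly against the risk set just before that age;
censorings tied with a death remain in the risk set for that event; a
record entering exactly at an event age counts as at risk.

**Step convention.** All curves are right-continuous; integration uses the
value on $[t_j, t_{j+1})$ and is exact (no quadrature).

**Degenerate inputs.** A landmark age with no exits beyond it raises an
error naming the age; inside `lyl_over_range()` such ages become flagged
missing rows instead, so one sparse old age cannot abort a 95-age run, and
putting positive weight on a missing row is an error rather than silent
interpolation. An all-censored cohort yields a flat survivor curve and zero
LYL, which is valid.

**Weights.** Onset ages are binned by flooring (an onset at 45.9 counts at
age 45), matching the integer conditioning grid; zero-count ages stay in
the table and contribute nothing. The binning choice is immaterial in
practice because adjacent integer ages have nearly identical estimates.

## Bootstrap

Confidence intervals are percentile-bootstrap: resample $n$ individuals
with replacement (the record — entry, exit, status, onset — is the
resampling unit, preserving within-person structure), re-run the full
estimator, and take the $\alpha/2$ and $1-\alpha/2$ empirical quantiles
(`stats::quantile` type 7, R's default interpolation). Percentile rather
than BCa is the simplest defensible default for these smooth functionals.
Each iteration's RNG stream derives deterministically from the master seed
(`seed + i`), so runs are reproducible and extensible without recomputing
earlier replicates. Iterations whose resample empties a needed risk set are
redrawn, with a capped retry count. For range estimates the replicate is
the whole per-age table; `weighted_summary()` applies the weights within
each replicate, so the CI of a weighted summary reflects the joint
sampling variability across ages. `ci_stability()` recomputes the interval
from the first $m$ replicates and flags convergence when both endpoints
move less than a tolerance (default 0.05 years) over the last 20% of
iterations — the practical check that the iteration count suffices.

When comparing two results, a side without replicates is treated as fixed
(reasonable when it is a whole population or an official life table); if
both sides carry replicates they are paired by iteration index, which
requires equal iteration counts.

## Life tables and aggregated data

A reference given as a standard life table is converted to conditional
survival assuming a constant hazard within each year of age (piecewise
exponential). Survivor proportions and mortality rates are interchangeable
under this convention — rates follow from survivor ratios as
$r_x = -\log(S(x+1)/S(x))$ and vice versa — and when both columns are
present they are cross-checked (tolerance $10^{-6}$ on the one-year
survival ratio) with the survivor column taking precedence; a silent choice
between inconsistent columns would hide data errors. Restricted areas use
the closed form $S(x)\,(1-e^{-r_x})/r_x$ per segment, with partial years
pro-rated and fractional conditioning ages interpolated by the same
within-year exponential. A survivor-only table determines survival up to
its last age; a rates table one year further — requesting $\tau$ beyond
that errors.

The fully aggregated mode applies the same machinery to the diseased group:
its age-specific mortality table is read as the conditional-on-onset
mortality from each age onward, so the landmark construction is implicit.
Only totals are available (no causes in aggregated inputs) and there is no
bootstrap (no individual resampling unit), matching what such data can
support. The weights at the first conditioning age are included in range
summaries. `aggregate_cohort()` bridges the modes by occurrence/exposure
tabulation of an individual-level cohort (deaths over person-years per year
of age); the aggregated estimate then converges to the individual-level
one as the cohort grows — the suite checks agreement within 0.2 years at
$n = 100{,}000$.

## The simulator

`simulation_scenario()` / `simulate_population()` generate registry-style
populations: everyone followed from birth, administratively censored at 95,
two mutually exclusive death causes, and a disease whose onset can occur
from age 1 on. Hazards are piecewise constant on one-year age intervals;
competing causes are realized as independent piecewise-exponential latent
times per cause (earliest wins), which is equivalent to simulating from
cause-specific hazards; after onset the post-onset hazards take over from
the onset age. The default parameters — Gompertz-like natural mortality
$4.4\times10^{-5} e^{0.092\,x}$, unnatural $5.8\times10^{-4}$ per year,
onset rate $5.3\times10^{-3}$ from age 1, post-onset hazards 2.5× (natural)
and 4× (unnatural) the baseline — were chosen once so that the aggregate
shape is realistic for a Scandinavian-register-style cohort: roughly a
third of the population acquires the disease, onsets span childhood to old
age (mean in the late 30s), a few percent survive to 95, and unnatural
causes account for ~6% of deaths. The generator emulates the *structure* of
such data, not any particular registry: real cohorts have non-exponential
onset distributions, cohort effects, dependence between onset and frailty,
and non-administrative censoring, none of which are modelled. Passing tests
therefore demonstrate correctness of the estimators under the stated
sampling models, not fidelity to any specific population's numbers.

`closed_form_lyl()` is the analytic oracle used throughout validation:
under constant cause-specific hazards $\lambda_k$ with
$\Lambda=\sum_k\lambda_k$, the restricted life expectancy is
$(1-e^{-\Lambda(\tau-a)})/\Lambda$ and each cause takes the share
$\lambda_k/\Lambda$ of the life lost.

## Problem sizes and numerical choices

The validation suite uses cohorts of $50{,}000$–$100{,}000$ for
convergence checks (sup-norm agreement with closed forms within 0.01 on
curves, 0.3 years on LYL), 200 replicate cohorts of $2{,}000$ with 200
bootstrap iterations for the coverage study (nominal 95% within ±0.04),
and exhaustive enumeration of all $3^n$ event/censor patterns for cohorts
of up to six records against an independent hand recursion, matched to
$10^{-14}$. These sizes keep a full run to about a minute while leaving
Monte-Carlo error well below the asserted tolerances.

## Limitations

Independent censoring is assumed, as in any standard time-to-event
analysis. No covariate adjustment, smoothing, parametric fits or interval
censoring are offered. Small risk sets at old ages make per-age estimates
unstable — inspect `numbers_at_risk()` before trusting them. Negative
excess LYL for a specific cause is meaningful (the reference loses more
life to that cause, typically because the diseased die earlier of something
else) and should not be read as lower cause-specific mortality. Estimating
the onset distribution from illness–death transition intensities, as an
alternative to observed onset counts, is out of scope.
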