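---
title: "Inferring MEP-pathway flux from 13CO2 labeling: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring MEP-pathway flux from 13CO2 labeling: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mepflux)
```

## The problem

The methylerythritol 4-phosphate (MEP) pathway is the plastidial route to
the universal C5 isoprenoid precursors IDP and DMADP, and hence to
chlorophyll side chains, carotenoids and isoprene. When a plant's
atmosphere is switched from `^12^CO2` to `^13^CO2`, newly fixed carbon
carries the label into the pathway, and the fractional `^13^C` enrichment of
each intermediate rises toward a plateau. Because isoprene is made from
DMADP in a single enzymatic step and escapes the leaf as a gas, its
isotopologue pattern — monitored on-line by PTR-MS at m/z 69–74 — reads out
the instantaneous labeling state of the IDP + DMADP pool without
destructive sampling. This package turns such labeling time courses,
together with measured pool sizes, into an estimate of the metabolic flux
through the pathway.

## The labeling model

At metabolic steady state the three measurable pools form a series
cascade: DXP (pool size $A$), MEcDP ($B$) and IDP + DMADP ($C$), all in
nmol g$^{-1}$ needle dry weight, traversed by a constant flux $J$
(nmol g$^{-1}$ DW min$^{-1}$). Writing $l_A, l_B, l_C$ for the fractional
labeling of each pool, label balance gives

$$A\,\dot l_A = J(m - l_A),\qquad B\,\dot l_B = J(l_A - l_B),\qquad
  C\,\dot l_C = J(l_B - l_C),$$

with $l(0)=0$. The driving plateau $m \le 1$ is the maximal fractional
labeling approached at long times; $m<1$ means part of the carbon entering
the pathway comes from unlabeled ("alternative") sources rather than
freshly fixed CO2. Integrating the chain yields the closed form
implemented in `cascade_fraction()`:

$$f(t) = m\left[1 - \tfrac{A^2}{(A-B)(A-C)}e^{-Jt/A}
  - \tfrac{B^2}{(B-A)(B-C)}e^{-Jt/B}
  - \tfrac{C^2}{(C-A)(C-B)}e^{-Jt/C}\right],$$

where $f(t)=l_C(t)$ is the observed isoprene labeling. The three rates are
the pool turnover times $A/J$, $B/J$, $C/J$; only ratios pool/flux enter,
so the curve is invariant under joint rescaling of all pools and the flux.
The partial-fraction coefficients sum to one for any distinct $A,B,C$,
which is exactly the statement $f(0)=0$. The intermediates between the
measured pools (MEP, CDP-ME, CDP-MEP, HMBDP) are below detection and are
taken as too small to delay label transit; the model has no provision for
them.

Because this closed form was re-derived here (the cascade step response),
the package carries an independent oracle: `cascade_fraction_ode()`
integrates the defining ODE system directly with `deSolve` (lsoda, tight
tolerances). The test suite holds the two routes to within $10^{-6}$ over
a randomized grid spanning three orders of magnitude in pools and flux.

**Confluent pools.** The closed form has removable singularities wherever
two pool sizes coincide; near-coincidence causes catastrophic
cancellation. When the smallest relative pool gap falls below $10^{-6}$,
`cascade_fraction()` silently delegates to the ODE route, which is smooth
through the confluence. The Erlang-3 limit $A=B=C$, for which
$f(t) = m[1-e^{-Jt/A}(1+Jt/A+(Jt/A)^2/2)]$, is checked by hand algebra in
the tests.

## Fitting flux and plateau

`fit_flux()` estimates $(J, m)$ by least squares on the fraction scale
with bounded Levenberg–Marquardt (`minpack.lm::nls.lm`; $J \ge 0$,
$0 \le m \le 1$, box bounds handled natively by the optimizer). The pool
sizes are not estimated: they are entered from the quantification arm of
the experiment (plastidial pools, see below). Starting values are
deterministic and data-driven: $m_0$ is the last observed fraction
(clipped into $(0,1]$) and $J_0 = \max(A,B,C)/t_{1/2}$, with $t_{1/2}$ the
first time the curve exceeds $m_0/2$. Standard errors come from the
least-squares covariance; no resampling or Bayesian machinery is offered.
Both co-fitting $m$ (the default) and fixing it at the final observation
(`fit_plateau = FALSE`) are supported, since either reading of the
original procedure is defensible; co-fitting is the default because it
propagates plateau uncertainty into the flux.

Two flags qualify each fit:

* **`detectable`** — `FALSE` when the time course never exceeds 0.05
  fractional enrichment, or the fitted plateau falls below 0.05. This is
  the package's operational version of "too little incorporation to
  calculate a flux"; the threshold is configurable and deliberately
  conservative.
* **`span_warning`** — `TRUE` when the labeling window is shorter than
  twice the slowest time constant $\max(A,B,C)/\hat J$. Such curves are
  still far from plateau, and $(m, J)$ are then nearly confounded (with
  only late-time data they are not separately identifiable at all).

`fit_flux_table()` applies the fitter per replicate (one tree, one fit);
treatment summaries are means over trees, not pooled fits, so between-tree
variation stays visible.

## Supporting quantification arithmetic

**Enrichment.** For an $n$-carbon analyte with isotopologue intensities
$I_0,\dots,I_n$, the atom fraction of `^13^C` is
$\sum_i i I_i / (n \sum_i I_i)$ (`enrichment_fraction()`).

**Natural abundance.** Observed spectra include mass shifts from naturally
occurring `^13^C` (abundance $p = 0.0107$ by default) on the carbons not
carrying tracer label. The forward operator is binomial per column —
entry $(j+k, j)$ is $\binom{n-j}{k}p^k(1-p)^{n-j-k}$ — lower-triangular
with unit column sums, so it conserves total intensity and is exactly
invertible; `correct_natural_abundance()` solves the triangular system.
Only carbon is corrected: the monitored transitions track carbon mass
shifts. Noise can push small corrected components negative; these are
clamped to zero and the spectrum rescaled, with a loud warning when
clamping removes more than 5% of the signal. The default order of
operations is correct-then-quantify, configurable by calling the steps
separately.

**Quantification.** Pathway metabolites are quantified by single-point
standard addition (`standard_addition_amount()`: each extract run with and
without a known unlabeled spike), sugars by an external OLS calibration
line with inverse prediction and an extrapolation flag
(`external_standard_quantify()`).

**Plastidial partitioning.** Whole-tissue DXP and MEcDP include
extra-plastidial pools that stay unlabeled on the 50-min time scale, while
IDP + DMADP is taken as purely plastidial. The plastidial share of a pool
is therefore the ratio of its final enrichment to that of IDP + DMADP,
capped at 1 (`plastidial_pool()`).

**PTR-MS.** Raw counts are normalized to a conventional primary-ion
signal of $10^6$ cps (primary ion + water cluster) and to a reference
drift pressure of 2.2 mbar (`normalize_ptrms()`); both references are
configurable, as the conventional ncps definition fixes only their role,
not their values. Emission rates are background-subtracted, slope-scaled
and divided by needle dry weight (`emission_rate()`). Channel m/z 69+k
maps to isotopologue M+k; interference from other C5 species at these
channels is ignored.

**Drought staging.** FTSW anchors at 1 (pot at capacity) and 0 (endpoint);
RTR is daily transpiration relative to the well-watered reference group's
average. Stage triggers are the experiment's sampling rules — moderate at
RTR ≤ 50%, severe at ≤ 20%, endpoint at ≤ 10% — with inclusive
boundaries, since sampling happens when the target is *achieved*. ATR
defaults to a per-day mean over the reference trees, excluding
re-irrigation intervals (weight gains carry no transpiration
information); an experiment-wide mean is available as an option.

**Statistics.** One-way ANOVA, Tukey HSD (Tukey–Kramer for unbalanced
groups) and Shapiro–Wilk are delegated to base R. The compact letter
display is authored here with the insert-and-absorb algorithm; the letter
count is not guaranteed minimal, but the sharing relation is exact —
verified in the tests by brute force over every significance pattern on 3
and 4 groups. A Shapiro–Wilk rejection is reported, never acted on, as no
transformation rule was specified for that case.

## The synthetic-experiment generator

`simulate_experiment()` produces complete input bundles with known ground
truth. Its defaults are the study conditions, fixed once:

| Setting | Control | Moderate | Severe |
|---|---|---|---|
| pools $(A,B,C)$, nmol/gDW | (2, 1, 0.5) | (1.2, 0.6, 0.5) | (1, 0.55, 0.5) |
| flux $J$, nmol/gDW/min | 0.2 | 0.126 | 0.02 |
| plateau (isoprene / IDP+DMADP / DXP, MEcDP) | 0.85 / 0.87 / 0.75 | 0.60 / 0.60 / 0.45 | 0.15 (all) |

Five trees per treatment; 25 time points over 0–50 min; multiplicative
Gaussian noise with CV 3% on fractions and 5% on intensities plus a 0.005
additive floor on fractions (typical MRM/PTR-MS repeatability); natural
abundance 0.0107. The control pools and flux put the 50-min window at
five times the slowest time constant, matching curves that are
essentially at plateau by the end of the run; the moderate flux encodes a
37% reduction; the severe preset combines a 0.15 plateau with a collapsed
flux, so the window captures only the first part of a slow rise and the
observed enrichment stays below the 0.05 detection threshold — the
regime in which a flux cannot be calculated. Pot weights dry down
exponentially toward the endpoint weight and are rounded to the 1 g
balance precision; the well-watered reference sheds a matched daily water
mass and is re-irrigated every other day. The physiology table
(photosynthesis, ABA) is drawn around treatment means encoding the
reported effect sizes (−70%/−96%; 6.7-/12.8-fold) with 8% CV.

Isotopologue spectra assume positional independence: at atom enrichment
$f$ the isotopologue distribution is Binomial$(n, f)$, convolved with
natural abundance. This is the simplest generative model consistent with
the dominance of the fully labeled molecule at high enrichment; real
spectra can deviate (positional biases, incompletely mixed precursor
pools), so passing recovery tests demonstrates correctness of the
arithmetic, not validity of the binomial assumption for field data. The
final-time spectra are drawn at each species' plateau enrichment (a
steady-state reading); for the severe preset this overstates the
within-window enrichment of the destructively sampled intermediates,
which is immaterial to how the pipeline uses them (plastidial ratios).
Other idealizations: no chromatographic peak picking, no ion suppression,
no instrument drift, no between-tree variance in the true flux.

## Numerical choices

* ODE oracle: lsoda with rtol = atol = $10^{-10}$; integration failure is
  an error with parameter diagnostics, never silently degraded.
* Confluence switch at relative pool gap $10^{-6}$; below it the ODE
  route's error (≲$10^{-9}$) is far smaller than the cancellation error
  of the closed form.
* Optimizer: `nls.lm` with `ftol = ptol = 1e-12`, max 200 iterations;
  convergence codes 1–4 count as converged.
* Negative corrected intensities: clamp to 0, rescale to conserve total
  signal; sub-$10^{-12}$ (relative) negatives from the triangular solve
  are clamped silently as round-off.
* FTSW marginally outside $[0,1]$ (1 g weighing precision) is clamped
  with a warning; weigh-in errors larger than that still warn but are not
  distinguished.
* Time origin is the moment of the 13CO2 switch; instrument dead time, if
  any, is an explicit offset the caller applies to the time grid
  (default 0).

## Problem sizes used in validation

The shipped checks run at desk scale, chosen to estimate each property
stably: $10^4$ parameter sets for the partial-fraction identity, 150 sets
× 6 times for the closed-form/ODE sweep, 200 noisy fits for the recovery
study, 100 severe-preset fits for the detectability rate, 2000 null
replicates for the ANOVA type-I calibration, and 5-tree experiments for
the end-to-end pipeline — the same replicate count as the study design.

## Known limitations

* The model assumes metabolic and isotopic steady state of the driving
  plateau; transient source switching within the run is not modeled.
* A single throughput $J$ is fitted; no branch-point partitioning
  (isoprene vs. pigments) is attempted.
* With data far from plateau, $(m, J)$ are jointly weakly identified; the
  span flag marks this but cannot repair it — only longer labeling can.
* Flux units follow the pool units (nmol g$^{-1}$ DW min$^{-1}$); if pools
  are supplied in other units, $J$ scales accordingly.
* Uncertainty is per-fit asymptotic; treatment-level inference uses the
  per-tree fits as replicates.
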