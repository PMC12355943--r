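---
title: "Multi-route buffered GUTS survival models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-route buffered GUTS survival models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bufferguts)
```

## The problem

Above-ground terrestrial arthropods — honeybees in the regulatory
setting this package is built around — take up plant-protection
compounds through several routes at once: topical contact (overspray,
droplet application to the thorax) and orally through contaminated
food. Standard regulatory tests probe these routes separately (acute
contact, acute oral, chronic oral designs), but realistic field
exposure combines them. `bufferguts` implements a
toxicokinetic–toxicodynamic (TKTD) survival model family that
calibrates one mechanistic model jointly to all designs of a substance
and predicts survival under arbitrary combined, pulsed exposure.

## The state system

Each uptake route $i = 1 \dots N$ has a piecewise-constant external
exposure $C_i(t)$ in its own unit (route 1 = contact, µg a.i./bee;
route 2 = oral, mg a.i./kg food) and a *buffer* state representing
residues on the exoskeleton or in the gut:

$$\frac{dB_i}{dt} = \eta\,(C_i(t) - B_i), \qquad B_i(0) = 0.$$

The buffer speed constant $\eta$ (per day) is a fixed structural
constant, not calibrated — the variant parameter counts (below) require
it. The default of 2/d, a transfer half-time of about 8 h, is a
documented placeholder; it is a single argument of `model_spec()` and
the buffer operator is isolated in one function, so an alternative
buffer law is a one-place change.

Damage accrual follows the reduced-GUTS convention with a dominant
rate constant $k_d$, in two route-combination variants:

* **Concentration addition (CA)** — all routes share one kinetic
  profile; the weighted buffer sum drives a single scaled damage:
  $B_\Sigma = \sum_i w_i B_i$, $\;dD/dt = k_d (B_\Sigma - D)$.
* **Damage addition (DA)** — route-specific kinetics
  $dD_i/dt = k_{d,i} (B_i - D_i)$, combined as $D = \sum_i w_i D_i$.

The weights convert route units into route-1 units; $w_1 \equiv 1$
fixes identifiability and anchors $D$, the threshold $z$ and the
median tolerance $\alpha$ to route-1 units. With one shared $k_d$ the
cascade is linear and summation order is irrelevant, so DA with equal
rate constants collapses to CA exactly — a property the test suite
checks to 1e-8, and to 1e-10 for $N = 1$ where both variants are the
plain buffered model. Free-parameter counts excluding background
mortality are $N + 2$ (CA) and $2N + 1$ (DA), i.e. 3 for one route and
4 vs 5 for the contact + oral case (`n_free_parameters()`).

The combined damage drives one of the two GUTS death mechanisms:

* **Stochastic death (SD):** hazard
  $h(t) = k_k \max(0, D(t) - z) + h_b$, so
  $S(t) = \exp(-\int_0^t h)$. `kk` is the killing rate per route-1
  unit per day, `z` the population-wide threshold.
* **Individual tolerance (IT):** individuals draw a fixed threshold
  from a log-logistic distribution
  $F(x) = 1/(1 + (x/\alpha)^{-\beta})$ and die when the running
  maximum of $D$ first exceeds it:
  $S(t) = (1 - F(\max_{\tau \le t} D(\tau)))\,e^{-h_b t}$. The running
  maximum is taken over the *combined* damage — the death mechanism
  sees only $D$, not the per-route states.

$h_b$ (per day) is background mortality shared by all treatments of a
calibration — every variant carries exactly one, hence the "+1" in
the parameter counts.

## Solving the system

Because exposure is piecewise constant on a 1-hour grid and the
cascade is linear, the default backend is exact: between exposure
breakpoints every state is an exponential polynomial
$c_0 + \sum_j (a_j + b_j \tau) e^{-r_j \tau}$ (the $b_j$ terms arise
only in the confluent case $k_d = \eta$, entered when the rates agree
to a relative 1e-8). The SD exceedance integral has a closed-form
antiderivative on this representation; threshold crossings and
stationary points are bracketed on a 33-point scan per interval and
refined by bisection to ~1e-14 of the interval length, which makes the
hazard and the IT running maximum exact to floating-point for the
damage shapes this cascade can produce (at most one exponential term
per distinct rate plus the constant). A fully independent numeric
backend (`backend = "ode"`, `deSolve::lsoda` at rtol 1e-10 segment by
segment, IT maxima sharpened by parabolic interpolation on a 1-minute
internal grid) agrees with the analytic backend to better than 1e-6 in
survival on randomized instances; the suite checks 100 of them.

Degenerate inputs are handled explicitly: empty profiles (no exposure)
give $S \equiv e^{-h_b t}$, levels must be non-negative, segments
half-open `[t_start, t_end)`, time grids strictly increasing from 0.

## Exposure preprocessing

The discretisation conventions mirror the regulatory designs: an
instantaneous topical dose becomes a 1-hour pulse (so an "instant"
exposure carries a well-defined area under the curve), acute-oral
feeding windows (≤ 6 h, default 6 h when unreported) are snapped up to
whole hours, and chronic-oral exposure is one constant segment over
the whole test despite daily replenishment — the concentration of the
replenished food, not the consumed dose, is the exposure that matters.
Acute-oral doses (µg a.i./bee) are converted to food concentrations
(mg a.i./kg food) by dividing by the consumed food mass, 20 mg/bee by
default (regulatory tests aim at this consumption), making acute and
chronic oral exposures commensurable: 0.0336 µg/bee ↔ 1.68 mg/kg.

Replicate batches of a treatment are pooled by summing survivor
counts; the conditional-binomial likelihood changes only by a
parameter-free combinatorial constant, so estimates are unaffected
(tested on a one-parameter sweep). Discordant acute-oral tests are
flagged by `exclude_outlier_tests()`: a test whose 48-h LD50 differs
by ≥ 8-fold from *every* other acute-oral test of the compound *and*
whose implied food-concentration LC50 lies below the compound's
chronic 10-day LC50 is excluded. "Considerably lower" is
operationalised as strictly lower; both thresholds are arguments. On
the bundled 29-test honeybee summary this flags exactly 3 tests,
leaving 26.

## Likelihood and calibration

Deaths are multinomial over observation intervals: interval $j$
contributes $d_j \log(S_{j-1} - S_j)$ and final survivors
$n_J \log S_J$, summed over treatments; interval probabilities are
floored at 1e-12 so an impossible observation yields a large finite
penalty rather than $-\infty$.

Calibration is Bayesian by default: adaptive random-walk Metropolis on
log-parameters (all free parameters have positive support; the
Jacobian is included), with proposal covariance estimated from the
chain history and Robbins–Monro scale tuning towards 25% acceptance
during warm-up. Defaults are 16 chains with 2000 warm-up and 2000
retained draws. A maximum-likelihood mode (multi-start L-BFGS-B from
prior draws) shares the identical likelihood. Priors are log-normal
and deliberately broad by default (`default_priors()`); replace them
with substance-specific ones whenever available.

Chains occasionally stall on pseudolocal modes with tiny step sizes.
`filter_chains()` drops a chain when any parameter's sample standard
deviation is ≤ 1e-6 or when its mean log-likelihood is more than 100%
worse than the best chain's — operationalised on the log scale as
worse than twice the best mean log-likelihood, the multiplier being an
argument, with the best chain always retained. Whether "100% worse"
should live on the likelihood or log-likelihood scale is genuinely
open; the log scale is used because mean likelihoods underflow for any
realistically sized dataset.

Because this filter *tolerates* chains up to twice as bad as the best,
a retained secondary mode can make the pooled posterior strongly
skewed. The package therefore uses the marginal posterior **median**
as its point estimate (`point_estimate()`), not the mean: on synthetic
studies a single tolerated wrong-mode chain moved the posterior-mean
in-sample NRMSE from ~6% to ~42% while the median was
indistinguishable from the truth's fit.

## Model selection

Four variants (CA/DA × SD/IT) are compared per substance with
`BIC = k \ln n - 2 \log L` ($n$ = survival observations after
pooling, excluding the $t=0$ counts — a convention, since $n$ is not
canonically defined; `logL` at the point estimate), the normalised
root-mean-square error of survivor counts
`NRMSE = RMSE / mean(observed)`, and the parameter uncertainty index
`PUI = mean over non-hb parameters of log10(Q97.5/Q2.5)`. BIC is only
comparable within one dataset; `choose_variant()` enforces this.
Selection prefers the best NRMSE with BIC agreement; variants within
0.05 NRMSE of the best (or with overlapping NRMSE intervals) are tied
and split by lower PUI, then fewer parameters, then BIC, with a text
rationale recording each applied rule.

## Synthetic data and what passing tests show

`generate_dataset()` emulates the regulatory designs: batches of 10
bees (default; 40/treatment in the recovery study), daily observation
from 0 to 2 d (acute) or 10 d (chronic), geometric concentration
ladders (factor 2.5) centred on the level giving ~50% end-of-test
mortality, always including a control, and sequential conditional
binomial death draws
$n_j \sim \mathrm{Bin}(n_{j-1}, S(t_j)/S(t_{j-1}))$. The recovery
ground truth (CA-SD, $k_d$ 0.7/d, $w_2$ 0.05, $z$ 0.08 µg/bee, $k_k$
3 per unit·day, $h_b$ 0.02/d) was chosen once as honeybee-realistic
scales. Twenty seeded studies calibrated at reduced sampler settings
(4 chains × 500 + 500) put each true parameter inside its 95%
credible interval in ≥ 90% of runs; the test suite reruns this
end-to-end in about a minute, and `scripts/acceptance.R` recomputes it
from scratch.

The generator draws deaths from the model's own survival curve, so
passing recovery says the pipeline is self-consistent and identifiable
under these designs — it does not validate the buffer law, the
constant-consumption assumption, or behaviour absent from the
generator (food avoidance at high concentrations, consumption
decline, time-varying contact residues). Predictions for real
substances inherit those assumptions.

`make_validation_suite()` emits the proposed terrestrial validation
grid — a single contact pulse crossed with 1- and 2-day oral windows
at varying delays — since repeated topical applications would require
re-sedation and confound the substance effect.

## Numerical choices, sizes and limitations

* Internal unit: days; discretisation grid 1 h = 1/24 d.
* Confluent-rate switch at relative 1e-8; bisection tolerance 1e-14 of
  an interval; likelihood floor 1e-12.
* Test-suite problem sizes: 100–200 random instances for solver and
  monotonicity properties, 20 × (18 treatments × 40 bees) for
  recovery — chosen to exercise every code path at comfortable
  runtime on a single core.
* The sampler is a general-purpose adaptive Metropolis; for
  high-dimensional DA models with strong correlations, longer warm-up
  or substance-informed priors may be needed (mixing is reported via
  per-chain acceptance rates and the chain filter).
* LD50/LC50 values in the bundled table are inputs, not outputs: the
  package does not estimate dose–response summaries, it models the
  full time course.
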