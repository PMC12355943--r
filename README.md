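# bufferguts

Toxicokinetic–toxicodynamic (TKTD) survival modelling for above-ground
terrestrial arthropods exposed to one chemical through several uptake
routes at once — topical contact and oral uptake from contaminated
food, the situation honeybees face in regulatory risk assessment.
Standard tests probe each route separately (acute contact, acute oral,
chronic oral); `bufferguts` calibrates a single mechanistic model
jointly to all of them and predicts survival under combined, pulsed
exposure scenarios no standard test covers.

## The model

Each route *i* has a piecewise-constant exposure *C<sub>i</sub>(t)* and
a buffer state (residues on the exoskeleton / in the gut):

    dB_i/dt = eta * (C_i(t) - B_i)

with a fixed buffer speed constant `eta`. Scaled damage *D* follows the
reduced-GUTS convention in two route-combination variants —
**concentration addition** (CA, one shared dominant rate constant
acting on the weighted buffer sum) and **damage addition** (DA,
route-specific rate constants, weighted sum of damages):

    CA:  dD/dt   = kd  * (sum_i w_i B_i - D)
    DA:  dD_i/dt = kd_i * (B_i - D_i),   D = sum_i w_i D_i

Weights convert route units into route-1 (contact) units; `w_1 = 1` is
fixed for identifiability. Damage drives either of the two GUTS death
mechanisms: **stochastic death** (SD), with hazard
`kk * max(0, D - z) + hb`, or **individual tolerance** (IT), with a
log-logistic threshold distribution (median `alpha`, shape `beta`) and
the running maximum of *D*. With one route, CA and DA collapse to the
same 3(+1)-parameter model; with two routes CA has 4(+1) and DA 5(+1)
free parameters.

The package covers the full workflow:

* exact piecewise-analytic forward simulation (with an independent
  `deSolve` numeric cross-check backend),
* regulatory-design preprocessing: 1-h exposure discretisation,
  acute-oral dose → food-concentration conversion at 20 mg food/bee,
  replicate summation, discordant-test exclusion,
* multinomial survival likelihood, adaptive-MCMC Bayesian calibration
  (or maximum likelihood), pseudolocal-minimum chain filtering,
* model-selection metrics (BIC, NRMSE, PUI) and a documented
  variant-choice procedure,
* a synthetic-data generator emulating honeybee test designs, and
  combined contact+oral validation-scenario prediction,
* a config-driven pipeline (`run_calibrate()`, `run_predict_unseen()`)
  with a thin CLI at `inst/cli/bufferguts.R`.

## Worked example

Simulate a combined exposure — a 0.262 µg a.i./bee contact pulse plus
chronic oral feeding at 18 mg a.i./kg food — then calibrate the CA-SD
variant to a synthetic three-design study generated from known
parameters:

```r
library(bufferguts)

spec   <- model_spec("CA", "SD", n_routes = 2, eta = 2)
params <- param_set(spec, kd = 0.7, w = c(1, 0.05), z = 0.08,
                    kk = 3, hb = 0.02)

contact <- discretize_design("acute_contact", 0.262)
oral    <- discretize_design("chronic_oral", 18.0, test_duration_d = 10)
simulate_bufferguts(spec, params, list(contact, oral), times = 0:10)
#>    time_d      D      S
#>         0 0.0000 1.0000
#>         1 0.2823 0.8239
#>         2 0.5702 0.2764
#>         3 0.7331 0.0475
#>         4 0.8167 0.0057
#>         ...
```

The damage (in contact units, µg a.i./bee) climbs towards its
steady state under constant feeding; once it exceeds the threshold
`z = 0.08` the hazard drives survival down to ~0.5% by day 4.

```r
templates <- default_study_templates(spec, params, n_levels = 5,
                                     n_per_treatment = 40)
ds  <- generate_dataset(spec, params, templates, seed = 1)
fit <- calibrate(spec, ds,
                 settings = calibration_settings(n_chains = 4,
                                                 n_warmup = 500,
                                                 n_draws = 500, seed = 1))
fit
#> <bg_calibration> MCMC: 4/4 chains kept, 500 draws each
#>  parameter       q2.5        q50      q97.5
#>         kd 0.40768182 0.63038642 0.83822959
#>        w_2 0.03812338 0.04618136 3.95205871
#>          z 0.05150732 0.06914332 8.11104545
#>         kk 0.04463715 3.03399572 4.52849223
#>         hb 0.01333933 0.02056497 0.08534618

variant_metrics(fit, ds, dataset_id = "synthetic")[c("k", "n", "bic",
                                                     "nrmse", "pui")]
#>   k  n      bic nrmse   pui
#>   5 84 1107.565 0.062 1.633
```

Every true parameter sits inside its 95% credible interval; the
posterior-median fit reproduces the observed survivor counts with an
NRMSE of 6.2%. The wide upper quantiles of `w_2` and `z` come from one
chain on a tolerated secondary mode — exactly the situation the chain
filter and the posterior-median point estimate are designed around
(see the methods vignette).

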