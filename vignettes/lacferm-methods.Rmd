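---
title: "Modelling pH-regulated lactic acid production: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pH-regulated lactic acid production: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lacferm)
```

## The problem

*Lactobacillus delbrueckii* subsp. *bulgaricus* keeps producing lactic acid
after yogurt fermentation is complete, acidifying the product during cold
storage (post-acidification). Industrial counter-measures either work
poorly or kill the culture. A synthetic-biology alternative is to leave the
metabolism intact and instead place a repressor gene (*lacR*) under a
pH-induced promoter: when the medium pH falls to the promoter threshold,
LacR accumulates and shuts down transcription of the *lacSZ* operon
(lactose permease + beta-galactosidase), throttling further acid
production without starving the cells during the main fermentation.

`lacferm` implements a kinetic model of this design and the analyses needed
to reason about it: batch simulation of the engineered and wild-type
strains, calibration of the one free transcription parameter, local and
global (Sobol) parameter sensitivity of the lactic-acid output, and the
two-level promoter/RBS scenario study that identifies workable design
windows.

## The model

Eleven state variables: extracellular and intracellular lactose
(`LAC_out`, `LAC_in`), glucose `GLU`, pyruvate `PYR`, extracellular lactic
acid `LA` (all molar), the *lacR* and *lacSZ* mRNAs `M` and `N`, the
proteins `LR` (LacR), `LS` (permease), `LZ` (beta-galactosidase), and
biomass `X` (g/L). Concentrations are population totals; energy
metabolism, the galactose pool and the acetyl-CoA/butanedione branches are
outside the model's scope.

Metabolism is Michaelis--Menten throughout: reversible lactose transport
(`R1`, `R2`, both scaled by `Kcat_LP * LS`), hydrolysis (`R3`), a lumped
glycolysis step (`R4`, two pyruvate per glucose) and lactate dehydrogenase
(`R5`). A fixed fraction `f_conv = 0.8` of the LDH flux appears as lactic
acid, reflecting the 80--90 % practical carbon conversion of
homofermentation; the remaining 20 % of the `R5` flux is simply removed
from the pyruvate balance, not routed anywhere (implemented as printed in
the source model, and worth remembering when reading the pyruvate pool).

Growth is Monod in extracellular lactose with linear product inhibition,

$$\mu = \mu_{max}\,\frac{LAC_{out}}{LAC_{out}+K_s}\Bigl(1-\frac{LA}{K_{LA}}\Bigr),$$

which goes negative once `LA > K_LA = 0.448` M. The raw value is reported
in trajectories, but every place it acts as a rate — the dilution terms
`(d + mu)` and biomass growth `R19` — uses `max(mu, 0)`: dilution by
growth cannot run backwards. Biomass does not feed back into any reaction
rate; enzyme concentrations are modelled as absolute pools, so uptake
capacity tracks gene expression, not population size.

Gene regulation: *lacR* mRNA is produced at `(V0 + V1 * F(pH)) * GR` with

$$F(pH) = 1 - \tanh\bigl(n\,(pH - 5.5)\bigr),$$

a smoothed step that is exactly 1 at the threshold and saturates at **2**
(not 1) in acid. The switch is used as printed, so a fully induced
promoter contributes up to `2 * V1 * GR`; nothing is renormalized. *lacSZ*
transcription is `V2*G` minus the repression term
`T_max * S*LR/(1+S*LR) * G`; the sensitivity constant `S` is treated as
having units 1/M so that `S*LR` is dimensionless. LacR also binds
intracellular lactose (`R10 = Kb * LR * LAC_in`), which sequesters the
repressor while substrate is plentiful — this is what delays repression
until acidification is well underway.

Medium pH is slaved to lactic acid through the milk buffering quadratic
`pH = c0 - c1*LA + c2*LA^2`. The wild-type variant (constitutive *lacSZ*,
no *lacR* gene) fixes `M = LR = 0` and drops `R6`--`R11` and `R13`.

### The negative-transcription pathology and its floor

With the default constants, the repression term `R13` exceeds the basal
rate `R12` as soon as `LR > V2/(S\,T_{max}) \approx 6\times10^{-8}` M, at
which point the printed net transcription `R12 - R13` is strongly negative
and would drive the mRNA pool `N` below zero. By default the package
floors the *production* term at zero (`max(R12 - R13, 0) - R14`):
repression can silence the gene but cannot destroy existing transcripts,
and `N` stays a concentration. Two alternatives are selectable on the
parameter object: `strict_as_printed = TRUE` integrates the raw form, and
`repression_form = "hill"` replaces production by `T_max*G/(1+S*LR)` — a
maximal rate divided down by repressor. The hill form changes the
repressor-free production from `V2*G` to `T_max*G` and is offered for
structural comparison, not as a calibrated model.

## Parameters, initial conditions, and the pH curve

All kinetic constants default to the published literature values for this
organism and its enzymes (see `?lacferm_params` for the full glossary with
units); `V2 = 3.5` 1/h is the one fitted quantity. Three groups of values
are package assumptions because no published numbers exist, chosen once
and documented here:

* **Buffering constants** `c0 = 6.7`, `c1 = 24` pH/M, `c2 = 30` pH/M²:
  fresh milk at pH 6.7, acidifying monotonically to about pH 4.6 at 0.1 M
  lactic acid, with the quadratic's vertex (0.4 M) safely beyond the
  fermentation range. Every reported pH is conditional on this curve;
  replace the constants via `fit_pH_curve()` on your own titration data.
* **Initial conditions**: 0.117 M lactose (about 8 % reconstituted
  skim-milk solids), biomass 0.05 g/L standing in for a 4 % inoculum, no
  intracellular metabolites or acid, and the expression cascade `N, LS,
  LZ` at its wild-type steady state for a stationary pre-culture
  (`equilibrate_expression()` at frozen growth rate 0). All overridable in
  `default_initial_state()`.
* **Measurement noise** in the synthetic generators: additive Gaussian,
  truncated at zero, sd = 2 % of each observable's range — the scale of
  replicate scatter in routine fermentation assays.

## Numerics

The expression cascade decays at ~41.6 1/h while metabolites evolve on
hour scales, so the system is moderately stiff; `simulate_batch()` uses
deSolve's `lsoda` with `rtol = 1e-8`, `atol = 1e-12` on a uniform grid
(default 8 h, 161 points). The right-hand side evaluates on the state
clipped at zero; after integration, undershoots smaller than `neg_tol =
1e-9` M are clipped and anything larger aborts the run. A compiled C
implementation of the right-hand side is used by default for speed (a
Sobol analysis costs `n_base * (k+2)` integrations); the R reference
implementation (`ode_rhs()`) is kept in exact agreement by a test and can
be selected with `use_compiled = FALSE`. With `Kb = 0` the stoichiometry
implies conservation of `LAC_out + LAC_in + GLU + (PYR + LA)/2`, which the
test suite tracks as an integrator-correctness check (drift below 1e-6 M
over 8 h).

## Calibration

`fit_V2()` minimizes the joint sum of squares of lactose and lactic acid
against a wild-type time series over `V2` alone, each observable's
residuals normalized by its observed range so neither series dominates
(the source data weight the two series jointly without stating weights).
Minimization is bounded golden-section search on [0.1, 50] 1/h; an
estimate at a bound triggers a warning. Unless an initial state is
supplied, the pre-culture equilibrium is recomputed from each candidate
`V2`, keeping the generative loop self-consistent: on noiseless synthetic
data the generating `V2` is recovered to optimizer precision and both R²
equal 1. `fit_pH_curve()` is ordinary least squares on the quadratic (via
`lm`), reported in the `c0 - c1*LA + c2*LA^2` sign convention.

## Sensitivity analysis

*Local*: each parameter is perturbed by +1 % and the normalized
forward-difference coefficient `(dLA/LA)/(dp/p)` of final lactic acid is
reported, with ranking by absolute value (ties alphabetical). The initial
state is held fixed at the nominal equilibrium so coefficients measure the
dynamics, not the assumed inoculum. The default output functional is LA at
the end of the horizon — the post-acidification quantity of interest — with
the time-integral of LA as an option.

*Global*: Sobol first-order and total indices of the same output,
estimated by the Saltelli radial scheme with the Saltelli-2010 first-order
and Jansen total-order estimators and percentile-bootstrap confidence
intervals. Sampling is plain Monte Carlo, uniform and independent per
parameter over ±50 % of each nominal value — ranges are not published for
this analysis, and ±50 % keeps all samples in the physically valid
positive region while exercising each constant strongly; ranges are
configurable per parameter. Failed integrations (possible at extreme
corners) are imputed by neighbour means and counted; more than 1 %
failures aborts. Slightly negative indices are estimator noise and are
reported as-is, flagged below −0.05. The estimator is validated in the
test suite against the analytic Ishigami indices (S1 ≈ 0.3139, S2 ≈
0.4424, S3 = 0) and an additive linear model.

Replication-scale runs use `n_base = 10000`; the test suite exercises the
model-based Sobol analysis at `n_base` 256--1024 and the Ishigami oracle
at 1024--10000, sizes at which the estimator's error is already well
inside the decisions it supports.

Two findings from these analyses are worth flagging. First, with the
default inoculum the 8-hour batch does not exhaust lactose, so the
uptake/expression rate constants (`V2`, `Kcat_LP`, `K_LS`) retain
first-order control of the final titre and rank alongside or above the
repression-circuit constants (`T_max`, `GR`, `K_LR`, `S`). Second, the
promoter leak parameter `V0` has very little influence at the default
design point: below threshold the `V1` term already leaks at
`F(6.7)*V1 ≈ 3.3` 1/h (versus `V0 = 1`), and LacR is sequestered by
lactose binding while substrate is abundant. Both are structural features
of the published constants, visible equally in the local and the Sobol
rankings computed by the test suite.

## The two-level scenario study

`run_two_level()` compares a low and a high setting of one design
parameter — `V1` (induced promoter strength, 10.5/21 1/h), `V0` (leakiness,
0.1/1 1/h) or `K_LR` (RBS strength, 564/1128 1/h) — against a wild-type
blank control, holding the published companion values fixed (`V1` study:
`V0 = 1`, `K_LR = 564`; `V0` study: `V1 = 10.5`, `K_LR = 564`; `K_LR`
study: `V0 = 1`, `V1 = 10.5`). Summaries report final lactic acid, final
pH (conditional on the buffering curve), the threshold-crossing time
(linearly interpolated within the bracketing output interval) and lactose
consumed. Under the defaults the expected design orderings hold: raising
`V1` or `K_LR` lowers the titre below the wild type, doubling either from
the same base has nearly the same effect (both act through the LacR
level), and the two `V0` levels are nearly indistinguishable once the
switch can activate.

## What the synthetic data do and do not show

`generate_fermentation_data()` emulates the structure of the wild-type
calibration experiment — batch fermentation without pH control, sampled
every two hours over 8 h — and `generate_buffering_data()` the
three-replicate titration behind the pH curve. They reproduce sampling
schedule, noise scale and replicate structure, with ground truth and seed
recorded for exact regeneration. They do not emulate systematic
measurement bias, heteroscedastic error, biological batch-to-batch
variation, or any misfit between this model family and a real organism:
parameter-recovery tests passing on these data demonstrate the estimation
machinery is correct and well-conditioned, not that the model is an
adequate description of any particular fermentation.

## Known limitations

* The buffering constants and initial conditions are assumptions (above);
  absolute pH values and crossing times move with them.
* Enzyme pools are not scaled by biomass, so predictions are sensible over
  a batch but should not be extrapolated across inoculum sizes.
* The promoter model is untested below pH 3.5; the switch simply stays on.
* Storage-phase (multi-day) simulation runs but is unvalidated.
* No energy bookkeeping: designs that starve the cell of ATP will look
  healthier here than in reality.
* Only `V2` is fitted; the remaining constants are literature values for
  related organisms and conditions.
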