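---
title: "Models, solvers and inference in pmxbayes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, solvers and inference in pmxbayes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmxbayes)
```

`pmxbayes` fits compartmental PK and PK/PD models to clinical event
schedules by full Bayesian inference.  This vignette is the package's
account of the science: the models and their assumptions, the numerical
choices, the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the design decisions that were
genuinely open.

## Event schedules

A study is described NONMEM-style: one row per event with `time` (h), `amt`
(mg), `rate` (mg/h; 0 means an instantaneous bolus), `ii` (h), `addl`,
`cmt` (1-based), `evid` (0 = measurement, 1 = dose), `ss` and `dv`.  Only
`evid` 0 and 1 are defined; reset codes (2–4) are *rejected*, not ignored,
because silently dropping an event the user believed in is worse than an
error.  `addl = k` expands to `k + 1` identical doses at `t, t + ii, ...,
t + k·ii`; expanded copies sort *after* any explicit row at the same time,
so a trough ("predose") observation listed at a nominal dose time reads the
pre-dose state.  For the same reason dose rows report **post-dose** amounts:
the convention that makes trough rows listed before a dose row and
peak/trough pairs come out right.  Ties between records at one timestamp are
broken by input order; a lag-shifted dose is applied at `t + tlag`, and an
observation inside the lag window reads the pre-absorption state (at exactly
`t + tlag` the dose has been applied).  Bioavailability scales a bolus
amount and an infusion's *duration* (`F·amt/rate`), keeping the rate.

## Linear PK solvers

The one- and two-compartment models with first-order absorption are linear,
`du/dt = A u + b(t)`, with `b` piecewise-constant (infusions).  Between
events the package uses the spectral form of the exact solution: with
eigenvalues `-ka` and the hybrid disposition rates `-λ₁, -λ₂` (roots of
`λ² − (k10+k12+k21)λ + k10·k21`),

    exp(At) = Σᵢ e^{μᵢt} Pᵢ,   ∫₀ᵗ exp(As) ds = Σᵢ φ(μᵢ,t) Pᵢ,

with Lagrange projectors `Pᵢ = Π_{j≠i}(A − μⱼI)/(μᵢ − μⱼ)` and
`φ(μ,t) = expm1(μt)/μ` (`= t` at `μ = 0`, so the conservative `CL = 0`
limit is exact).  This *is* the classical tri-exponential solution, but in a
form that handles any initial state and constant input with one code path.
When `ka` comes within `1e-8` (relative) of a hybrid rate the decomposition
is ill-conditioned and the solver falls back to a Padé/scaling-and-squaring
matrix exponential on an augmented matrix — one fallback rather than
L'Hôpital special cases, because it is testable against the same oracle.
Steady state under periodic dosing solves the linear fixed-point equation
`u* = exp(A·ii)u* + F·amt·e_cmt` (bolus; the infusion case handles the
zero-order segment inside the interval).  A non-dissipative system has no
steady state and is rejected.  `ss = 1` *replaces* the state (the history of
infinitely many prior doses makes the pre-dose state irrelevant), and when
combined with `addl` only the first dose initializes from steady state.

## Numerical and coupled solvers

Arbitrary right-hand sides are integrated with an adaptive embedded
Runge–Kutta pair (Dormand–Prince 4(5), via deSolve) under `rtol`, `atol`
and `max_num_step` control.  Defaults are `rtol = atol = 1e-6`,
`max_num_step = 1e5` — common practice for concentrations on the mg/L scale;
all three are exposed in code and in the run configuration because the right
values are problem-dependent (if a state is negligible below some threshold,
`atol` above that threshold avoids wasted, error-prone work).  Stiff/BDF
methods are out of scope.

The PK/PD system has one-way coupling: the drug drives the PD but not vice
versa.  The coupled solver therefore propagates the PK sub-state in closed
form and integrates only the PD states numerically; at every *internal*
integrator time the PD right-hand side receives the exact analytic PK state
evaluated from the current event segment's initial condition — not an
interpolation or a per-event zero-order hold — so reducing the ODE dimension
from 8 to 5 costs no PK accuracy.

## The Friberg–Karlsson model

Neutrophil dynamics use the semimechanistic myelosuppression model: a
proliferating pool, three transit compartments and a circulating pool, all
with transit rate `ktr`, feedback `(Circ0/Circ)^γ` on proliferation, and a
linear drug effect `Edrug = min(α·ĉ, 1)` on the proliferation rate.  Two
conventions deserve justification:

* `ktr = (n+1)/MTT` with `n = 3` transit compartments.  The mean transit
  time through a chain of four first-order stages (proliferation + three
  transits) at rate `ktr` is `4/ktr`; the alternative reading
  `MTT = 3 + 1/ktr` would add a pure number to a time and is dimensionally
  inconsistent.  `MTT = 125 h` gives the familiar `ktr = 0.032/h`.
* `kprol = ktr`.  Required for the drug-free baseline to be an equilibrium
  (`dprol/dt = 0` at `Circ = Circ0`), and the canonical assumption for this
  model.

The states are written as differences from baseline so the initial condition
is the zero vector rather than a parameter-dependent value.  Inside the
dynamics the actual counts are floored at machine precision (`≈2.2e-16`):
an MCMC sampler *will* visit implausible parameter regions, and the floor
keeps the feedback term finite (and the loop un-flipped) instead of crashing
the likelihood.  The cap on `Edrug` plays the same role for large
concentrations.  A consequence worth knowing: perturbations decay at roughly
`0.14·ktr` (the feedback slows the slowest mode), so return-to-baseline
checks need ~20 mean transit times.

## Statistical model

Concentrations are lognormal about the model prediction
`ĉ = u_central/Vcent` with log-scale sd `σ`; ANC observations get an
independent `σ_ANC`.  A lognormal error model is the natural choice for a
strictly positive quantity with roughly proportional error; observations the
model predicts as exactly zero (the sample before any drug is given) carry
no lognormal likelihood and are recorded as missing by the simulator and
excluded from fits.

Population models place lognormal inter-individual variability around the
population-typical values, `ϑⱼ ~ LogNormal(log ϑ_pop, Ω)` with **diagonal**
`Ω` (correlated random effects are out of scope), and allometric body-weight
scaling with defaults `e_CL = 0.75`, `e_V = 1`, reference 70 kg — the
standard exponents; all three are configurable.  The population absorption
rate can carry an expression lower bound `ka_pop > λ₂(ϑ_pop)`: absorption
slower than the slowest disposition rate makes the two rates swap roles in
the observed curve ("flip-flop") and the model unidentifiable.  The bound's
expression is a package decision (the constraint's intent, evaluated at the
current population parameters) and is configurable.

Default single-subject priors are weakly informative lognormals centred on
textbook values (CL 10 L/h, Q 15 L/h, Vcent 35 L, Vperi 105 L, ka 2/h;
log-sd 0.5 ≈ a factor 1.65 at one sd) with a half-normal(0.5) prior on `σ`.
Priors are data, not code: they live in the model/run configuration.

## Inference

Constrained parameters are transformed to an unconstrained space
(shifted-log for one-sided bounds, scaled logistic for two-sided; bound
expressions may reference earlier parameters and are re-evaluated per draw),
and the log joint density accumulates priors, population terms, likelihood
and transform Jacobians.  A solver failure at a proposed value maps to `-∞`
— a rejection — rather than an exception, which is what keeps early, wild
MCMC exploration alive.

Sampling uses adaptive Hamiltonian Monte Carlo: leapfrog integration with
dual-averaging step-size adaptation to a target acceptance of 0.8, a
diagonal metric estimated in doubling warmup windows (75-iteration opening
and 50-iteration closing step-size buffers), and a trajectory length
jittered ±30% around a configured integration time (default 1.5) to avoid
resonances.  Full dynamic trajectory-building (NUTS) is deliberately not
implemented: the package's outputs — posterior summaries, diagnostics,
predictive checks — do not depend on the tree algorithm, and a fixed-budget
jittered trajectory is simpler to reason about and to test.  Divergences are
flagged when the Hamiltonian error exceeds 1000 (configurable) or turns
non-finite.  Defaults are 1000 warmup and 1000 sampling iterations; the
examples and checks use shorter runs where the model is simple.  Gradients
are central finite differences with step `ε_mach^{1/3}·max(1,|x|)`
(pluggable, so an exact-gradient provider can replace them); this keeps the
practical dimension modest, hence population examples default to tens of
subjects, not hundreds.  For the bundled compartment models the entire log
density and its gradient are compiled (RcppArmadillo), which makes the
finite-difference approach fast in practice; the compiled path is tested to
agree with the generic R assembly to double precision.

## Diagnostics, PPC and LOO

Convergence is monitored with rank-normalized split R-hat (maximum of the
bulk statistic and the folded variant) and bulk/tail effective sample sizes
using Geyer's initial-monotone truncation of the multi-chain
autocorrelation sum; these are the current published estimators, adopted
wholesale.  Two reporting decisions: ESS is *uncapped* (values above the
draw count reflect antithetic chains and estimator noise; truncating would
hide information), and constant chains yield `NA` rather than a misleading
1.0.  Summaries report mean, median, sd, scaled MAD (×1.4826, consistent
for a normal sd), type-7 5%/95% quantiles, R-hat and both ESS values, with
a warning whenever an ESS falls below 100 (at `n_eff = 100` the estimator's
variance is 1% of the posterior's — usually sufficient in practice).

Posterior predictive checks follow the two-step recipe — draw `θ̃` from the
posterior, then `ỹ` from the likelihood — and are summarized as central
50%/90% bands per observation.  PSIS-LOO estimates
`elpd_loo = Σᵢ log p(yᵢ|y₋ᵢ)` from one fit: per observation the largest 20%
of importance ratios (minimum tail 5) are replaced by expected order
statistics of a generalized Pareto distribution fitted by the
profile-likelihood method with a weak prior shrinking the shape towards 0.5,
truncated at the raw maximum.  The fitted shape `k̂` is the reliability
diagnostic: estimates with `k̂ > 0.7` are flagged and should not be trusted.
The comparison standard error uses the pointwise differences, which respects
their correlation across models.

## The synthetic-data generator

`build_tutorial_regimen()` encodes the reference design: 1200 mg boluses
q12h × 14, sampling at 0.083–8 h after doses 1, 2 and 14, a trough before
every dose, and 12/18/24 h washout samples — 53 observations ending at
180 h.  `simulate_dataset()` adds lognormal residual noise
(default truth in examples: the textbook parameter values above with
`σ = 0.2`); `simulate_population()` adds lognormal inter-individual
variability and allometric scaling.  Seeds are explicit arguments recorded
in output attributes, so any fixture can be regenerated exactly.

What the generator does *not* emulate matters for interpreting green tests:
no model misspecification (the fitted structure is the data-generating
structure), no below-limit-of-quantification censoring beyond the
no-drug-yet case, no missed visits or dosing-history errors, no covariate
effects beyond body weight, and no correlated random effects.  Passing
recovery and calibration checks therefore demonstrate the *inference
machinery* is correct, not that real datasets will be this well behaved.

## Problem sizes used in the checks

The bundled checks run at deliberate scales chosen to exercise each claim:
the full 67-event reference schedule for solver agreement (analytic vs
tolerance-1e-10 integration), 100 accumulated doses for steady state, the
8-state coupled system at tolerance 1e-8, 4 chains × 1000 draws for
known-target sampler checks, 2 chains × 500/500 for the model-comparison
and recovery fits, and 20 seeded replicates for 90%-interval calibration.

## Known limitations

Three-compartment closed forms, nonlinear (Michaelis–Menten) elimination,
Emax drug effects, correlated `Ω`, stiff ODE solvers, NUTS, variational
inference and penalized MLE are all out of scope.  Finite-difference
gradients make very high-dimensional population fits expensive.  NPDE/PIT
and cross-validated predictive checks are not provided.
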