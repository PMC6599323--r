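---
title: "Unstructured kinetics of ganoderic acid fermentation: model, fitting and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unstructured kinetics of ganoderic acid fermentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gakinetics)
```

## The model and its assumptions

`gakinetics` implements the classical unstructured description of a
secondary-metabolite batch fermentation. Biomass is a single lumped
state; no intracellular structure, pH, oxygen or fed-batch terms are
modelled. Three coupled rates define the system:

* **Growth** — logistic: `dX/dt = mu_max X (1 - X/X_max)`. The culture
  grows exponentially at rate `mu_max` while far from the carrying
  capacity `X_max` and saturates sigmoid-fashion. (The source
  publication prints the growth equation without the `X` factor; that
  form is linear, cannot produce the sigmoid curves shown alongside it,
  and contradicts its own "logistic model" label, so the standard
  logistic law is implemented.)
* **Product** — Luedeking–Piret: `dP/dt = alpha dX/dt + beta X`,
  partitioning production into a growth-associated channel (`alpha`, g
  product per g new biomass) and a non-growth-associated channel
  (`beta`, g product per g biomass per day).
* **Sugar** — Luedeking–Piret-like: `-dS/dt = (1/Y_XS) dX/dt + M_s X`,
  with yield `Y_XS` on growth and maintenance drain `M_s`; sugar spent
  on product formation is assumed negligible.

Because the logistic equation decouples, all three states have closed
forms through `X(t)` and its running integral
`I(t) = (X_max/mu_max) log((X_max - X0 + X0 e^{mu t})/X_max)`:
`P(t) = P0 + alpha (X - X0) + beta I` and
`S(t) = S0 - (X - X0)/Y_XS - M_s I`. The package evaluates these closed
forms everywhere; `simulate_timecourse(..., method = "ode")` integrates
the raw ODEs with a step-halved fourth-order Runge–Kutta scheme purely
as a cross-check (the two routes agree to better than 1e-8 relative; the
test suite also checks the closed forms against an *independently coded*
RK4 oracle, keeping implementation and oracle on separate paths).

Time is in days throughout, matching every rate unit (day⁻¹); titers
are g/L internally, and the CSV reader converts a declared mg/L product
column on ingestion.

## Parameters that matter

| parameter | unit | default (wild type) | meaning |
|---|---|---|---|
| `mu_max` | day⁻¹ | 0.45 | maximum specific growth rate |
| `X_max`  | g DW/L | 9.41 | carrying capacity |
| `alpha`  | g/g | 0.015 | growth-associated product yield |
| `beta`   | g/g/day | 0 | non-growth-associated production rate |
| `Y_XS`   | g/g | 0.63 | biomass yield on sugar |
| `M_s`    | g/g/day | 0.12 | maintenance coefficient |
| `X0, S0, P0` | g/L | 0.5, 35, 0 | initial conditions |

The kinetic constants are the published estimates for the wild-type
strain (`wt_params()`); `fps_params()` carries the transgenic column.
The initial conditions are *not* published: X0 = 0.5 g/L is a typical
mycelial inoculum, S0 = 35 g/L a typical initial sugar load for a
medium containing 20 g/L glucose plus 10 g/L maltose and other
carbohydrates, and P0 = 0 is a product-free inoculum. They were chosen
once as the package's stated convention and are user-overridable.

`V_max`, the peak volumetric growth rate, is computed as
`mu_max X_max / 4`, the logistic inflection-point rate — consistent
within rounding with the published value (0.45·9.41/4 = 1.059 vs the
printed 1.05). When a culture starts above `X_max/2` the maximum over
`t >= 0` is instead attained at `t = 0` and is computed accordingly.

## Fitting

The model is triangular: growth feeds product and sugar but not vice
versa, and given `X(t)` both remaining equations are **linear** in their
parameters. The default *sequential* strategy exploits this:

1. `(mu_max, X_max, X0)` by bounded multi-start least squares on the
   biomass series (L-BFGS-B with a Nelder–Mead polish);
2. `(alpha, beta)` as the non-negative least-squares solution of
   `P - P0 ~ [X - X0, I]` (two-variable active-set enumeration);
3. `(1/Y_XS, M_s)` likewise from consumed sugar `S0 - S`.

A *joint* strategy minimises a single criterion over all parameters,
each response's squared error scaled by 1/SST so no response dominates
by virtue of its units; it is initialised at the sequential solution.
The original study used proprietary global-optimisation software whose
algorithm is unspecified; both strategies here are the package's own
open replacements and neither claims to replicate that software's
internals. On noiseless data they agree to < 1e-3 in every parameter.

Start points are drawn from a seeded stream of uniform samples within
the bounds (first start = data-driven heuristic: `X_max` from 1.05× the
observed maximum, `mu_max` from the log-slope of the first three
points). A sequential stream rather than a Latin hypercube was chosen
deliberately: start *k* does not depend on the total budget, so
enlarging `n_starts` only appends candidates and the best SSE is
monotone in the budget — a testable guarantee a re-drawn hypercube
cannot give. Default bounds: all parameters ≥ 0, `mu_max ≤ 5 day⁻¹`,
`X_max ≤ 5× max observed X`.

Goodness of fit is reported per response: `R² = 1 - SSE/SST` and an F
statistic defined as regression mean square over residual mean square,
`F = ((SST-SSE)/p) / (SSE/(n-p-1))` — the source never defines its
printed F, so this conventional definition is stated explicitly. A
perfect fit reports `F = Inf`; constant observations raise a
degenerate-statistic error rather than returning 0/0. Replicates are
pooled as independent observations (no random effects).

Degenerate inputs: fewer than four distinct biomass time points is
underdetermined; a constant biomass series is rejected unless `X0` is
fixed at that constant (stationary culture, `mu_max = 0`); a constant
biomass curve also makes `alpha` and `1/Y_XS` unidentifiable, so the
conditional fits refuse it. Predicted sugar may cross zero
mathematically; the package warns and never clamps, so the fitter sees
the model as it is.

## What the synthetic generator emulates — and what it does not

`generate_timecourse()` evaluates the closed-form trajectory on a
sampling grid (default: every 2 days over a 12-day batch, triplicate,
matching the visual cadence and replication of the original shake-flask
experiment) and perturbs each replicate with Gaussian noise, either
additive (sd in g/L) or proportional (sd as a fraction; 5% is the
working default in the tests — a realistic CV for gravimetric dry-weight
and spectrophotometric assays). Negative draws are clipped to zero by
default, since concentrations are measured non-negative. Everything is
seed-deterministic; identical spec and seed give byte-identical CSVs.

The original trajectories exist only as published figures, so the
generator is a *stand-in world*, not a reconstruction: a green
recovery test establishes that the pipeline inverts its own model under
the stated noise, **not** that the published parameter values are
correct for the real culture. Real data would additionally carry
sampling-time irregularities, autocorrelated process noise and
between-flask variance components, none of which are modelled.

## Strain comparison

`compare_strains()` assembles the derived quantities used to judge the
transgenic strain: `V_max`, final titer `P_max` = P(duration),
productivity = `P_max / duration` (this definition reproduces the
published wild-type figure 0.112/12 ≈ 0.009 g/L/day), percent increases
of every kinetic constant, fold changes of metabolite contents, and
pooled two-tailed Student t tests computed directly from mean ± SD
summaries (raw replicate values are never published; the textbook
summary-statistics formula is used and is verified against
hand-computed arithmetic in the tests). Display rounding follows the
published precision — folds to 2 decimals, percents to integers — while
raw values are always retained.

## Known inconsistencies, reproduced not repaired

* The transgenic `beta = 1.151 g/g/day` is dimensionally incompatible
  with the reported final titer of 0.209 g/L: integrating the printed
  transgenic column yields a final titer near 68 g/L. The package
  reports what the inputs imply and leaves the published number in the
  reference set untouched; fitting *data* will simply return whatever
  the data support.
* Published productivity for the transgenic strain is 0.018 g/L/day,
  but 0.209/12 = 0.0174; the package computes 0.0174.
* The growth-rate increase prints as "8%" where the underlying ratio
  0.49/0.45 gives 8.9%; the package rounds half-even to integers in
  summaries and keeps the raw value.
* The wild-type final titer appears both as 0.112 g/L and, in a later
  comparative sentence, as a 0.171 g/L "control"; the reference tables
  here carry 0.112.

## Numerical choices

* Closed forms are evaluated with `exp(-mu t)` factorisations so large
  `mu t` cannot overflow.
* The RK4 cross-check halves its global step until two refinements
  agree to 1e-10 relative (cap 4096 substeps).
* The optimiser treats `X0 > X_max` with a smooth penalty rather than a
  hard error so bounded line searches stay finite; the log argument of
  the biomass integral is clamped away from zero because
  finite-difference gradients probe just outside the feasible box.
* Two-variable non-negative least squares is solved exactly by
  enumerating the four active sets — no iterative NNLS needed.

## Limitations

Single lumped biomass state; no substrate limitation feedback on growth
(logistic, not Monod); no confidence intervals on parameters (bootstrap
SEs are future work); no model selection across rival growth laws; no
multiple-testing correction in the content comparisons (none was applied
in the source analysis).
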