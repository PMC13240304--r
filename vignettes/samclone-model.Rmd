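---
title: "Modelling ara-C treatment of oligoclonal AML under SAMHD1's dual role"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ara-C treatment of oligoclonal AML under SAMHD1's dual role}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(samclone)
```

## The treatment dilemma

SAMHD1 is a dNTP triphosphohydrolase with two opposing roles in acute
myeloid leukaemia. As a tumour suppressor it restrains leukaemic
proliferation; as an ara-CTPase it hydrolyses ara-CTP, the active metabolite
of cytarabine (ara-C), and thereby blunts the backbone drug of AML
induction therapy. Inhibiting SAMHD1 pharmacologically therefore trades a
gain (restored ara-C potency) against a loss (a silenced suppressor).
`samclone` formalises that trade as a small probabilistic model and works
out its consequences: when the trade is worth making, how the answer changes
across a heterogeneous clonal population, and how treatment itself shifts
the clonal mix cycle by cycle.

## Monoclonal model

One clone is characterised by three probabilities, each the efficacy of a
directed inhibitory interaction:

| symbol | meaning | unit |
|---|---|---|
| `x` | ara-C suppresses the clone, absent SAMHD1 interference | probability per cycle |
| `y` | SAMHD1 suppresses the clone directly | probability per cycle |
| `z` | SAMHD1 blocks ara-C's action (ara-CTP hydrolysis) | fraction of `x` removed |

A cell survives a cycle only if it escapes both suppression routes, which
are assumed statistically independent: the attenuated ara-C route kills
with probability `(1 − z)·x`, the suppressor route with probability `y`.
Hence

$$e = 1 - \bigl(1 - (1-z)x\bigr)(1-y) = y + x - xz - yx + xyz .$$

```{r}
base_efficacy(clone_params(0.8, 0.1, 0.7))
```

This expanded polynomial and the factorised survival product agree to
1e-12 over random grids (a test asserts this), and a Monte-Carlo two-route
simulation (`monte_carlo_efficacy()`), kept deliberately independent of the
closed form, reproduces it within binomial error at one million cells.

## Adding a SAMHD1 inhibitor

An inhibitor is parameterised by `d` (efficacy against the ara-CTPase
function, `d = d_z`) and the specificity ratio `alpha = d_y/d_z`, both in
[0, 1]. We chose the (d, α) parameterisation over (d_y, d_z) because the
benefit condition is most legible in it; converters
(`drug_spec_from_dy_dz()`, `drug_dy_dz()`) are provided. The drug rescales
the SAMHD1 parameters,

$$y_{red} = (1-\alpha d)\,y, \qquad z_{red} = (1-d)\,z,$$

and the combined efficacy is the monoclonal formula evaluated at the
reduced values. Requiring `e(d) > e(0)` gives, in closed form,
$e(d)-e(0) = d\,(B d + A)$ with $B = \alpha xyz$ and
$A = xz + \alpha xy - \alpha y - (1{+}\alpha)xyz$, so for interior
parameters benefit occurs exactly above

$$d^* = \frac{1+\alpha}{\alpha} - \frac{1}{z} - \frac{1}{\alpha y} + \frac{1}{xz}.$$

Two consequences worth knowing: a clone with `y > x` (suppressor stronger
than fully active ara-C) never benefits from a symmetric inhibitor, and for
any `d` there is a cap `y > 1/(1 + α − αd)` above which the drug is
detrimental regardless of `x` and `z`. Lowering α (more ara-CTPase-specific
drugs) lowers `d*` monotonically for `y < 1`, so specificity can substitute
for potency.

### Degenerate parameters and regime classification

The threshold formula divides by `x`, `y`, `z` and `α`. Rather than return
silent infinities, `benefit_threshold()` raises a degenerate-parameter
error when `x·y·z·α = 0`, and `classify_regime()` resolves every case from
the analytic sign of `e(d) − e(0)`: when `B = 0` the gain is linear in `d`
and the sign of `A` decides between always-beneficial (threshold `−Inf`),
never-beneficial (`+Inf`) and neutral (`NA`, the drug has identically zero
effect, e.g. `y = z = 0`). "Beneficial" means *strictly* greater efficacy;
differences within 1e-12 are treated as ties so that numerical noise is
never classified as benefit. Construction tolerates inputs outside [0, 1]
by at most 1e-9 (upstream arithmetic) and clamps them.

`classify_grid()` evaluates the classification over a regular grid of the
unit cube (default 41 points per axis, ~6.9e4 closed-form evaluations —
instantaneous on one core) and `boundary_surface()` extracts the `z*(x, y)`
surface at a given `d` by bisection to 1e-10, which is valid because the
threshold is strictly decreasing in `z` whenever `x < 1` (tested
numerically). Absence of a root in (0, 1] is recorded as `NA`: the surface
simply does not cut that column of the cube.

## Oligoclonal populations and treatment sequences

A population is `N` clones with fractions `f_i` summing to 1 (validated to
1e-9). By the law of total probability, one cycle's efficacy is
`e_total = Σ f_i e_i`; clinicians may substitute priority weights `w_i`
(`weighted_efficacy()`), which we expose as an alternative objective only —
the selection dynamics below always follow the true fractions. Selection
updates fractions as

$$f_i' = \frac{f_i(1-e_i)}{1-e_{total}},$$

so clones hit harder than average shrink. `simulate_regimen()` iterates
this deterministically and tracks the remaining burden
`Π_k (1 − e_total,k)`, the surviving population relative to untreated
growth (growth cancels in that normalisation, which is why the simulator
needs no growth-rate parameter). Eradication (`e_total = 1` within 1e-12)
terminates the trace at burden 0 instead of dividing by zero; populations
cannot gain or lose clones mid-regimen — parameter changes between cycles
are expressed explicitly through per-cycle dose labels.

`min_cycles_until_drug_beneficial()` operationalises "when does the
inhibitor start to pay off" myopically: the smallest number of drug-free
cycles after which the *next* cycle's `e_total` is strictly larger with the
drug than without. We chose the per-cycle comparison (rather than comparing
cumulative burdens over a horizon) because the fraction dynamics make the
per-cycle gap the quantity that flips sign as selection proceeds;
full-horizon searches can be built from `optimize_next_cycle()`, the greedy
single-cycle maximiser (ties broken by earliest candidate).

For the bundled three-clone example (`example_populations(
"three_clone_sequential")`: equal thirds, x = (0.9, 0.8, 0.7),
y = (0.6, 0.7, 0.8), z = (0.4, 0.5, 0.6)) the answer at `d = 1` is 4
cycles, and the five-cycle burden with the drug on the final cycle drops
below the ara-C-only burden only for `d` near 1 — both are asserted in the
test suite by direct simulation.

### Fitting the drug efficacy from observed fraction shifts

In practice `d` is unknown; the fraction-update law makes the observed
ratios `f_i'/f_i` a function of `d` alone once the clone parameters are
known. `fit_drug_efficacy()` minimises the sum of squared ratio residuals.
No loss function is canonical here; we chose least squares on the ratios
(the measured quantity) and solve the 1-D bounded problem by a dense grid
(step 1e-3) followed by local refinement, which is immune to the local
minima a single Newton start could fall into. A flat residual profile
(e.g. identical clones, whose ratios are 1 for every `d`) raises a
non-identifiability warning rather than returning an arbitrary number.

## Estimating x, y, z from viability assays

The experimental design the estimators expect: cells at controlled SAMHD1
levels (Vpx-loaded virus-like particles degrade SAMHD1; empty-VLP and
no-VLP samples are endogenous-SAMHD1 controls) treated across an ara-C
concentration series, with replicate viability fractions.

- **x(c)** — in SAMHD1-null cells `y = z = 0`, so `e = x` and
  `x = 1 − viability` per concentration (`estimate_x()`).
- **y** — at zero ara-C, `e = y`. Viabilities are normalised to the
  best-surviving condition group before applying `1 − v`
  (`estimate_y()`), making the estimate invariant to the assay's absolute
  scale; with Vpx-treated samples at the reference and controls at 90.18%
  of it, the endogenous estimate is `y = 0.0982`. The reduced-SAMHD1
  conditions get `y = 0` (a step function of SAMHD1 level — no
  interpolation, since viability does not decline further once SAMHD1 is
  below endogenous levels).
- **z(c)** — inverting the efficacy formula at known `x` and `y`:
  `z = (1 − v − y − x + xy)/(xy − x)` (`estimate_z()`), undefined at
  `x = 0` or `y = 1`. Estimates slightly outside [0, 1] are expected near
  complete protection; they are reported raw, flagged, and clamped for
  downstream use — never silently truncated.

Uncertainty uses the replicate coefficient of variation: per concentration
`CV = SD/mean` with the sample (n−1) standard deviation — the standard
small-sample convention — averaged into one relative-error scale, and
`σ_v = CV·v` thereafter. `propagate_z_sd()` propagates independent errors
through the inversion with analytic partials
(`∂z/∂v = 1/(x(1−y))`, `∂z/∂x = (1−v−y)/(x²(1−y))`,
`∂z/∂y = v/(x(1−y)²)`); the v-partial diverges as `x → 0`, so z is
unidentifiable at concentrations where ara-C does nothing — the
dose-response builder therefore skips the zero-concentration row. A
Monte-Carlo resampling oracle in the tests confirms the delta-method sd
within 20% away from the singular boundaries. For the y uncertainty from a
handful of control samples, both the standard error of the mean and the
single-measurement SD are defensible; we default to the SEM (the estimate
is a mean) and expose the choice via `sd_method`.

## What the synthetic generators emulate — and what they do not

`gen_viability_table()` produces the assay structure above from true
`x(c)`, `y`, `z(c)` profiles with multiplicative Gaussian noise
`σ = CV·v`, truncated to [0, 1]; the default CV of 0.094 is a realistic
replicate variability for such viability assays, and the default
dose-response fixture spans full protection (`z = 1`) at low ara-C falling
to `z = 0.11` at the top concentration. The noise model is a choice — real
assays report only a CV summary, not a distribution — and the truncation
at 1 slightly biases groups whose true viability sits at the ceiling.
`gen_clone_trajectory()` draws per-clone binomial survivor counts from `K`
initial cells (largest-remainder integer allocation), converging to the
deterministic update law as `K` grows (checked at `K = 1e7` to 1e-3).
Passing tests on these fixtures shows the estimators invert the model they
assume; it does not validate the model against biology — no growth between
cycles, no de novo clones, no dNTP-pool mechanism (the model is
deliberately phenomenological), and no pharmacokinetics: ara-C dose enters
only through per-dose `(x, z)` values.

Every stochastic operation takes a mandatory or defaulted explicit seed and
restores the caller's RNG state; identical seeds give identical output.

## Problem sizes used in the checks

The bundled checks run at desk scale, chosen once: closed-form identities
on 1e4-point random grids; threshold sign correctness on 1e4 random
parameter sets; Monte-Carlo agreement at 1e6 cells across 20 parameter
sets; drug-efficacy recovery at 1e6 cells across 20 random populations
(tolerance 0.02); viability-table recovery at 6 replicates and CV 0.094
(within 3 propagated sds); phase grids at 15–41 points per axis. The whole
suite completes in about a minute on one core.

## Known limitations

- Fixed per-clone parameters within a cycle sequence unless the user
  supplies per-dose values; plasticity and microenvironmental adaptation
  are out of scope.
- The benefit analysis concerns a single inhibitor added to ara-C; other
  resistance pathways and co-administered drugs are not modelled.
- The deterministic simulator propagates expected fractions; stochastic
  extinction of small clones appears only in the synthetic trajectory
  generator.
- `region_fractions()` summarises a finite grid, not the continuous
  measure of each regime.
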