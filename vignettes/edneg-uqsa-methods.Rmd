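---
title: "Uncertainty and sensitivity analysis of an electrodiffusive neuron-glia model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`edneguq` simulates a six-compartment electrodiffusive system: a two-compartment
neuron (soma and dendrite), a two-compartment astrocytic domain, and the two
extracellular compartments between them. The state has 34 components: 22 ion
amounts (Na⁺, K⁺ and Cl⁻ in all six compartments; Ca²⁺ only in the four
neuronal/extracellular ones), six Hodgkin–Huxley gating variables, and six
compartment volumes. Electrical potentials are not state variables: at every
instant the six absolute potentials follow algebraically from the ion amounts
through the Kirchhoff–Nernst–Planck construction — each membrane is a
capacitor whose charge is the net ionic charge of the intracellular
compartment (plus a static background charge), the bulk is electroneutral,
and axial current conservation across the soma/dendrite boundary fixes the
one remaining extracellular potential. The gauge sets the
dendritic-extracellular potential to zero. Membrane potentials are
intracellular minus extracellular; transmembrane fluxes are positive
outward; axial fluxes positive from soma to dendrite layer.

Storing **amounts** rather than concentrations makes conservation exact under
volume change: concentrations are recomputed as amount/volume at every
evaluation, so per-species totals and total volume are conserved to numerical
round-off along any stimulus-free trajectory (the test suite checks 1e-9
relative over 240 s; in practice the error is at machine precision).

The membrane mechanisms follow the classical inventory of this model family:
Na⁺/K⁺/Cl⁻ leaks, a 3Na⁺/2K⁺ pump, KCC2 and NKCC1 cotransporters and a
Ca²⁺/2Na⁺ exchanger on both neuronal membranes; transient Na⁺ and
delayed-rectifier K⁺ channels on the soma; a voltage-gated Ca²⁺ channel with
slow inactivation, a Ca²⁺-gated K⁺ channel and an afterhyperpolarization
(AHP) K⁺ channel on the dendrite; Na⁺/Cl⁻ leaks, an inward-rectifying K⁺
channel and a pump on the glial membranes. Osmotic water flow couples the
volumes: each membrane moves water toward its hyperosmolar side, with an
impermeant intracompartmental species contributing both osmolarity and the
static background charge.

### The kinetics component

The channel rate functions, pump and cotransporter forms, geometry and
physical constants live behind a single kinetics component
(`edneg_parameters()$kinetics` and `$geometry`), so alternative kinetics can
be substituted without touching the pipeline. The defaults are a
reconstruction in the Pinsky–Rinzel lineage: the six gating variables use the
classical CA3 two-compartment rate functions shifted to absolute membrane
potentials (≈ −60 mV shift), the pump activity is sigmoidal in intracellular
Na⁺ and extracellular K⁺, the cotransporters are log-driven
(thermodynamic) forms, and the glial inward rectifier uses the standard
astrocytic rectification factor with a √([K⁺]ₑ/[K⁺]ₑ,base) conductance
scaling and a saturating (Michaelis–Menten) glial pump.

Several constants of this component are free choices that the original
model-definition source pins down but the present reconstruction had to fix.
They were chosen **once**, by requiring the nominal-parameter model to
reproduce the qualitative study conditions — a stable stimulus-free resting
state; sustained regular firing with a final firing frequency near 8.7 Hz
under the physiological 8×10⁻⁵ µA somatic K⁺ injection; depolarization block
a few seconds into the pathological 20×10⁻⁵ µA protocol, with the
extracellular K⁺ concentration staying near baseline physiologically and
climbing past ~10 mM pathologically:

* soma–dendrite coupling cross-section 150 µm² at 667 µm separation
  (electrotonic coupling of the right order for a two-compartment CA3
  reduction);
* glial membrane area 200 µm² per layer; extracellular volume 590 µm³ per
  layer (≈ 0.17 extracellular volume fraction);
* Ca²⁺-channel inactivation: midpoint −45 mV, slope 2 mV, τ = 200 ms (keeps
  dendritic Ca²⁺ spikes from dominating the ion budget);
* Ca²⁺→AHP coupling: 1% free Ca²⁺, activity scale 10⁷ per mM free excess,
  AHP gate closing rate 3.5×10⁻⁵ ms⁻¹ (slow, cumulative spike-frequency
  adaptation — the mechanism that sets the ~9 Hz steady firing rate).

The package's resulting nominal behaviour is: 70 action potentials and a
final firing frequency of 8.67 Hz under the physiological protocol, and
depolarization-block onset at ≈ 3.7 s under the pathological one. A known
limitation of this reconstruction is that a small tonic AHP/Ca²⁺ current
persists at rest (it is what keeps the resting potential near −75 mV); as a
consequence the resting state retains a weak sensitivity to the active-channel
conductances (grouped total-order index of the non-active group ≈ 0.93 for
the neuronal membrane potentials rather than ≳ 0.99; the four other resting
quantities reach 1.00). Eliminating the tone (threshold-gating the Ca²⁺
activity) restores the clean separation but destroys the firing behaviour,
because no leak/pump mechanism in the fixed parameter set can replace the
resting hyperpolarization; the behaviour-faithful variant was kept.

### Numerics

The model is integrated in a rescaled unit system (mV, ms, µm, amol, mM;
1 amol/µm³ = 1 mM) chosen so that all state magnitudes lie within about six
orders of magnitude, and with an **exact Jacobian**: the right-hand side is
templated over a dual-number scalar type, and one forward seeded pass per
state variable yields derivatives exact to the implemented equations (no
finite-difference truncation). The solver is the implicit Radau IIA method
(deSolve's `radau`) with a 10 ms maximum step, relative tolerance 1e-8 and
block-scaled absolute tolerances (amounts are O(1e5) amol, gates O(1),
volumes O(1e3) µm³). The indicator-function stimulus is handled by splitting
the integration at onset and offset and restarting, which is exact for a
piecewise-constant input. States are reported on a uniform 1 ms analysis
grid; the ten potentials are emitted at every grid point by the compiled
model. Halving the maximum step or the grid spacing changes no spike count
and moves interpolated event times by less than one grid step.

The resting state is regenerated, not stored from any external source: the
documented baseline composition (physiological concentrations, osmotic
balance via the impermeant species, target membrane charge) is relaxed
stimulus-free for 1000 s and polished by damped Newton iterations on the
right-hand side, solved through the singular-value pseudo-inverse restricted
to the conservation-preserving subspace — the Jacobian is exactly
rank-deficient along the per-species totals and per-layer volumes, and the
restriction keeps those invariants untouched. The calibrated state (relative
drift ≈ 4e-11 per ms, far below the 1e-9 target) ships as a plain-text
fixture and is validated at load time by the test suite.

## Feature extraction

Spike detection: an action potential is an upward crossing of −20 mV
followed by a local maximum, with a 2 ms refractory period; the spike time
is the interpolated threshold-crossing time (robust when spikes ride into a
depolarization-block plateau, where peaks are undefined). The final firing
frequency divides the spike count in (4.0, 5.5) s by 1.5 s, exactly. The
first-spike latency is measured from stimulus onset and propagates an
explicit undefined marker when no spike exists. Depolarization-block onset
is the earliest time after the first spike from which |dφ/dt| (central
differences on the 1 ms grid, threshold 10⁻¹ mV/ms) stays below threshold
for a 100 ms stationarity window while the trace remains depolarized above
the pre-stimulus level + 10 mV. The window and guard make "consistently
constant" operational; all three constants are arguments. The guard level
matters: between slow spikes the derivative can dip below threshold, so the
detector is meaningful for traces that actually plateau (the pathological
QoI), which is how the pipeline uses it.

## Uncertainty propagation

All uncertain parameters carry independent uniform priors
U(nominal − |σ̂·nominal|, nominal + |σ̂·nominal|), with one hyper-parameter σ̂
controlling every width (0.15 for the screening study; 0, 0.01, 0.05, 0.10
for the dynamical studies). σ̂ = 0 degenerates to a point mass and skips the
sensitivity analysis.

Two designs are used. The factor-fixing screening uses the Saltelli
radial scheme over two **grouped** inputs — the 11 leak/pump/cotransporter
("non-dynamic") parameters versus the 5 active-channel ("dynamic")
conductances — with second-order blocks: 512 base samples give 3072 rows at
full scale; the desk profile (64 base samples, 60 s rest instead of 240 s)
reproduces the same conclusion with 384 cheap simulations. Indices come from
the standard Monte-Carlo estimators (Saltelli-2010 first-order,
Jansen total-order), no surrogate — the rest protocol is cheap enough.
Negative raw estimates are clipped for reporting and retained in the
diagnostics columns.

The dynamical studies use point collocation: a randomized Latin-hypercube
design over the prior box (twice as many points as basis terms; 252 for five
inputs at order 4) feeds an ordinary-least-squares fit of an orthonormal
Legendre expansion with total-degree truncation. No pre-installed package
provides low-discrepancy Sobol' sequences, and a space-filling LHS is an
accepted alternative for regression-based collocation; estimator accuracy is
verified against closed-form benchmarks rather than assumed. With uniform
inputs the basis is orthonormal under the input law, so the surrogate mean is
the constant coefficient, the variance is the sum of squared non-constant
coefficients, and Sobol' indices are coefficient sums — first-order over
terms involving only the input, total-order over terms involving it at all.
An order-4 expansion represents any total-degree ≤ 4 polynomial exactly,
which the synthetic-spiker benchmark exploits to make the entire pipeline
testable to 1e-6. Failed or undefined-QoI rows are excluded before fitting;
if more than 5% of rows are lost the fit aborts rather than risk silent
bias. Ill-conditioned bases (condition number > 1e10) fall back to a ridge
solve and record the fact in the fit diagnostics.

## Time-dependent sensitivity

For the slow variable [K⁺]ₛₑ the pipeline computes, per 1 ms grid point,
first- and total-order indices (one multi-output surrogate shares a single
least-squares factorization across all 6001 time points), and from them the
two functional summaries: the **weighted** total-order index
S^W(t) = S_T(t)·√Var(t), which de-emphasizes instants of negligible
variance, and the **generalized** indices, the trapezoid-integrated
conditional-variance ratios over [0, t] — the numerator integrand of the
generalized total-order index is S_T(t)·Var(t), so the generalized index is
the variance-weighted time average of the pointwise one. Columns with zero
(integrated) variance yield explicit undefined markers, never silent zeros.
The surrogate also provides the mean and the empirical 5th–95th percentile
band (the 90% prediction interval) through prior Monte Carlo.

## Validation strategy

Every estimator is validated against an analytic oracle before it touches
the neuron model: the Ishigami function (closed-form variance decomposition,
including its pure-interaction input), additive linear models, a toy
time-dependent process t·P₁ + (1−t)·P₂ with closed-form pointwise and
generalized indices, and a synthetic spike-trace generator whose extracted
features are explicit polynomials of its parameters. The closed forms are
themselves cross-checked by an independent tensor-grid Gauss–Legendre
quadrature oracle to 1e-8. The generator renders spikes as triangular bumps
with a linear upstroke several grid steps wide, so interpolated crossing
times are exact and end-to-end recovery of the latency decomposition holds
to 1e-6.

What the synthetic stage does **not** emulate: stiffness, solver error,
feature-extraction edge cases on real waveforms (bursts, plateau entry), or
correlations between QoIs. Passing the synthetic suite therefore certifies
the estimator and extraction code paths, not the biophysics; the
model-level tests (conservation, Jacobian exactness, resting stability,
protocol behaviour) cover the rest.

## Problem sizes

The shipped defaults are the desk profile: factor fixing at 64 base samples
and 60 s rest (384 simulations, seconds on one core thanks to the quiescent
dynamics and large implicit steps), dynamical studies at 252 collocation
points of 6 s each (a few minutes), and the full-scale values (512 base
samples, 240 s rest) available by argument. The full-scale screening matches
the desk-profile conclusion; it is simply slower.

## Known limitations

* The kinetics are a documented reconstruction, not the original source's
  parameterization; nominal spike counts and block-onset times agree with
  the study's reported values only approximately (70 vs 64 spikes; block at
  3.71 s vs ≈ 3.7 s; final firing frequency 8.67 Hz exactly), and the
  late-time dominance of the AHP conductance in the [K⁺]ₛₑ sensitivity is
  reproduced qualitatively but with a larger index.
* The factor-fixing separation for the neuronal membrane potentials is
  ≈ 0.93 rather than ≥ 0.99 (tonic AHP/Ca²⁺ current at rest; see above).
* No spatial discretization beyond six compartments, no synapses, fixed
  temperature; no sparse/adaptive chaos expansions or Gaussian-process
  surrogates; higher-order (pairwise) indices are not reported even though
  second-order Saltelli blocks are generated.
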