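---
title: "Models, solvers and numerical choices in myocyte"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, solvers and numerical choices in myocyte}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myocyte)
```

## The model class

Cardiac cellular electrophysiology models share one structure: the membrane
is an ideal capacitor, so the transmembrane potential obeys

$$\frac{dV}{dt} = -\frac{1}{C_m}\Big(\sum_j I_j + I_{\mathrm{stim}}\Big),$$

while the remaining states $\mathbf{u}$ (ion-channel gates, intracellular
concentrations) evolve as $d\mathbf{u}/dt = \mathbf{f}(\mathbf{u}, V)$.
`myocyte` ingests such models from a flat CellML-style XML subset
(components, unit-annotated variables, content-MathML equations, RDF "is"
annotations), flattens multi-component documents to a single namespace,
dimension-checks every equation, rescales everything to a fixed convention
-- time in ms, voltage in mV, current density in uA/cm^2, capacitance in
uF/cm^2, concentrations in mM, conductance in mS/cm^2 -- and binds a
standard interface: which state is $V$, which parameter is $C_m$, where the
stimulus current enters, and which derived quantities are the ionic
currents $I_j$.

Two decisions in this pipeline merit explanation.

**Quantity semantics for units.** The dimension checker first establishes
every equation as a physical-quantity identity (operands of sums compared by
dimension, arguments of `exp`/`log` required dimensionless, rate equations
required to be state-units per time-units).  Standardization then converts
every variable *and* every numeric constant to one rescaled SI basis chosen
so that all the conventional electrophysiology units land exactly on their
targets.  Because both sides of a quantity identity are converted
consistently, no per-equation correction factors are needed, and a model
authored in seconds and volts produces bit-for-bit the same standardized
dynamics as its ms/mV twin (this is a test).  Models that mix commensurable
units inside one expression (millivolts plus volts) are handled correctly
for the same reason.  Currents declared in absolute units (nA) are converted
to densities only when the document annotates both the whole-cell
capacitance and a specific capacitance; otherwise conversion fails loudly
rather than assume a cell size.

**Interface verification is numeric, not syntactic.** After binding $V$,
$C_m$ and the stimulus slot (by annotation first, by a configurable
common-name list second), the $dV/dt$ equation is verified to be an
algebraic variant of $-(\sum_j I_j + I_{\mathrm{stim}})/C_m$ by evaluating
both sides at the initial state and at jittered probe states.  This accepts
distributed and negated authorings without attempting symbolic pattern
matching, and rejects equations that are not a current balance.

## Gates and the specialized integrators

A state $g$ is a *gate* when its equation is affine in $g$ with
$g$-free coefficients at fixed voltage: $dg/dt = \alpha(V)(1-g) -
\beta(V)\,g$, equivalently $(g_\infty - g)/\tau$ with
$g_\infty = \alpha/(\alpha+\beta)$, $\tau = 1/(\alpha+\beta)$.  Detection is
algebraic (symbolic differentiation of the right-hand side with respect to
$g$ and a check that the result is $g$-free), so both authorings yield
identical decompositions.

The fixed-step integrators are:

* **FE / RK2 / RK4** -- the classical explicit formulas.
* **RL (Rush-Larsen)** -- gates advance by the exact solution of their
  frozen-coefficient linear ODE, $g' = g_\infty + (g - g_\infty)
  e^{-\Delta t/\tau}$; everything else by forward Euler.  When
  $g_\infty \in [0,1]$ the update is a convex combination, so gates can
  never leave $[0,1]$ whatever the step size.
* **GRL1** -- every state takes an exponential step from its own scalar
  linearization about the current state (others frozen, Jacobi style):
  $u' = u + (b/a)(e^{a\Delta t}-1)$ with $a = \partial f_i/\partial u_i$,
  $b = f_i$.  Below $|a| < 10^{-8}$ /ms the series limit $u + b\,\Delta t$
  is used to avoid catastrophic cancellation (implemented with `expm1`
  besides, so the threshold is belt-and-braces).
* **GRL2** -- a GRL1 half-step of the whole system, re-linearization of
  every equation about the half-step state ($f_i(\mathbf{y}) \approx
  f_i(\mathbf{y}^*) + a_i (y_i - y^*_i)$), then an exact full step of the
  linearized equations from the original state.  The "linearize about the
  half-step point" form matters: re-using $b = f_i(\mathbf{y}^*)$ directly
  in the GRL1 formula double-counts the diagonal and drops the method to
  first order on coupled systems, which the order tests would catch.
  A noteworthy aside verified in the tests: on *scalar* problems GRL1
  coincides with the exponential Rosenbrock-Euler method and
  superconverges at order 2; the nominal order 1 appears only once
  off-diagonal coupling exists.
* **BE** -- backward Euler with the structure the gate split affords:
  $V$ advances explicitly (for standalone cells; in tissue $V$ is a
  parameter), gates use the unconditionally stable implicit linear closed
  form $g' = (g + \Delta t\, g_\infty/\tau)/(1 + \Delta t/\tau)$ at the
  updated voltage, and any remaining nonlinear states are solved by Newton
  iteration on the implicit residual with the analytic sub-Jacobian
  (infinity-norm update below $10^{-10}$, at most 15 iterations, failure
  reported as a structured divergence).

Adaptive stiff solving is delegated to the host environment's integrator
(deSolve's `lsoda`) behind a thin wrapper with three contract points: the
maximum internal step is clamped to `min(max_dt, stimulus duration)` so a
square-wave stimulus can never fall between steps; the analytic Jacobian is
supplied when requested and free of overflow hazards; and in tissue mode the
voltage is an input rather than a solved state, with the stepping state
carried between calls instead of reinitializing.  `lsoda` does not expose
its multistep history across calls, so "no reset" is implemented as
carry-over of the last internal step size plus the absence of any other
reinitialization work; the observable contract -- reset versus no-reset
agreement under trace MRMS -- is what the tests assert.  Default tolerances
are reltol $10^{-5}$, abstol $10^{-7}$, both configurable; published tables
print the pair without naming which is which, and this assignment is the
package's reading.

## Symbolic transforms and compilation

All transforms operate on one expression representation (R language objects
with an n-ary `piecewise_`).  *Partial evaluation* substitutes
non-modifiable parameters, folds constants (so a thermodynamic prefactor
like $RT/F$ used by several Nernst potentials becomes a single number) and
hoists syntactically repeated subtrees into shared temporaries after
canonical ordering of commutative operands; it is exact.  *Analytic
Jacobians* are exact symbolic partials with the same common-subexpression
extraction applied across all $n^2$ entries; piecewise expressions are
differentiated branch-wise with the first-satisfied-branch convention at
boundaries, and `floor`/`ceiling` are rejected by name.  The
*overflow-hazard detector* interval-evaluates every `exp` exponent in the
Jacobian over the annotated variable ranges (voltage defaults to
$[-100, 80]$ mV, detected gates to $[0,1]$) and flags entries whose
exponent can exceed $\log(\texttt{double.xmax}) \approx 709.8$: for such
models the right-hand side itself stays finite under IEEE rules
($1/(1+\infty) = 0$) but Jacobian entries become Inf, so the wrapper falls
back to the integrator's numeric Jacobian.

*Lookup tables* replace maximal subexpressions that depend on one keying
variable only and contain an expensive function (exp, ln, log, tanh,
non-integer power) with linear interpolation into precomputed node arrays.
Defaults follow the voltage example: $V \in [-100, 80]$ mV, step 0.01 mV.
Nodes are offset from round values by $10^{-4}$ of a step so typical
removable singularities (whole-number voltages) are never sampled exactly;
the interpolation error obeys the usual
$\mathrm{step}^2 \max|f''|/8$ bound (checked numerically), and evaluation
outside the range is an error naming the variable and value -- silently
extrapolating a cardiac rate function would be worse than stopping.

Compilation produces straight-line byte-compiled R closures (piecewise as
`if`/`else` in scalar mode, elementwise selection in vector mode for
tissue), and, for the adaptive hot loop, a flat instruction tape executed by
a small C virtual machine registered with deSolve as a native
derivative/Jacobian pair, so the stiff solver never re-enters interpreted R
between outputs.  The tape is generated from the same expression trees and
is required by the tests to agree with the naive tree-walking evaluator to
$10^{-12}$ relative everywhere.  An `overflow_safe` option additionally
guards single-variable $0/0$ divisions with their analytic limit
(L'Hopital on the shared symbol), evaluated only when a NaN actually
appears, which handles rate equations evaluated exactly at their removable
singularity (e.g. $V$ exactly 40 mV in the singularity fixture).

## Accuracy benchmarking

Accuracy is measured on the voltage trace by the mixed root mean square
error

$$e_{\mathrm{MRMS}} = \sqrt{\frac{1}{N}\sum_{t=1}^{N}
\Big(\frac{\hat V_t - V_t}{1 + |\hat V_t|}\Big)^2},$$

with $\hat V$ the reference solution; the metric is deliberately asymmetric
(only the reference enters the denominator) and blends absolute error near
0 mV with relative error at large $|V|$.  Reference solutions use the
adaptive solver at reltol $10^{-7}$ / abstol $10^{-9}$ with the analytic
Jacobian when hazard-free, sampled every 0.1 ms, over two paces of the
model's own annotated stimulus (or 1000 ms for self-excitatory models); the
pace count is configurable and two paces is this package's default for the
protocol.  The refinement protocol starts at $\Delta t = 0.1$ ms
(fixed-step) or reltol $10^{-3}$ / abstol $10^{-5}$ (adaptive), and on
divergence or $e_{\mathrm{MRMS}} > 0.05$ halves the step (or tightens the
tolerances ten-fold), stopping at the first acceptance or after 12
refinements; a divergence counts as a failed level, mirroring the
observation that explicit solvers often diverge outright at the coarse
levels and then immediately pass once stable.

With the shipped Luo-Rudy 1991 fixture and its pinned stimulus
(-25.5 uA/cm^2, 2 ms, 1 Hz) the protocol reproduces the published
refinement counts for all eight solvers (forward Euler 4, backward Euler 0,
RK2 4, RK4 3, Rush-Larsen 0, GRL1 0, GRL2 0, adaptive at the coarsest
tolerances).  The Hodgkin-Huxley row is sensitive to the stimulus encoded
in the curated document, which the published table does not print: with
this package's pinned pulse (-20 uA/cm^2, 0.5 ms) forward Euler's level-1
error is 0.065 -- marginally above the 0.05 threshold, not a divergence --
whereas an equally plausible 2 ms pulse reproduces the published count of
one halving exactly.  The acceptance test therefore asserts the primary
counts and falls back to this documented stimulus audit for the
Hodgkin-Huxley entry, rather than silently retuning the fixture.

Action-potential biomarkers use explicit conventions, since the source
material reports the quantities without defining them: resting potential is
$V$ just before stimulus onset; the upstroke time is the sample of maximum
forward-difference $dV/dt$; peak is the maximum over the pace; and
$\mathrm{APD}_p$ runs from the upstroke time to the linearly interpolated
first crossing below $\mathrm{peak} - (p/100)(\mathrm{peak} -
\mathrm{rest})$.  Wall-clock timing (best of three repeats, normalized to
seconds per simulated second) is reported by the harness but never
asserted: it is hardware-dependent by nature.

## Steady-state pacing

The limit cycle ("steady state") is declared reached when the plain L2 norm
of the state change across one pace drops below $10^{-6}$; a normalized
variant is logged for diagnostics but takes no decisions.  Regular
alternans is flagged when the two-pace norm passes while the one-pace norm
has failed for at least ten consecutive paces.  Hitting the pace budget
(default 10,000) emits a warning -- the classic cause being models that do
not conserve ions and drift indefinitely.  Long reference runs integrate
continuously with output only at pace boundaries, so the integrator is
never reinitialized mid-run.  For the Luo-Rudy 1991 fixture at 1 Hz the
detected steady state fixes APD90 to well within 0.01 ms of the state after
10,000 paces (the acceptance script recomputes this end to end; the
published claim is reproduced at the scale of this one model rather than a
whole model repository).

## 1D monodomain tissue

The strand model is
$\chi(C_m \partial V/\partial t + I_{\mathrm{ion}}) = \nabla\cdot(\sigma
\nabla V) + \text{stimulus}$, $\partial\mathbf{u}/\partial t =
\mathbf{f}(\mathbf{u}, V)$ per node, discretized with linear finite
elements on a uniform interval mesh (lumped mass, no-flux ends) and Godunov
operator splitting: over each PDE step the cells advance with $V$ frozen as
a parameter, the total ionic current is re-evaluated per node, and $V$
takes one implicit (backward Euler) diffusion step with $I_{\mathrm{ion}}$
frozen.  The volume stimulus enters alongside the ionic current, so a
negative amplitude depolarizes, matching the single-cell sign convention
and the published strand setup ($1$ cm, $h = 0.01$ cm, $\sigma = 1.75$
mS/cm, $-30{,}000$ on $x \in [0, 0.1]$ cm for $t \in [1, 5]$ ms).  The
printed stimulus unit is dimensionally incomplete for the PDE; this package
reads it as a per-volume density (uA/cm^3).  Surface-to-volume ratio
$\chi = 1400$ /cm and $C_m = 1$ uF/cm^2 are defaults in the same spirit --
the benchmark omits them -- and are configurable.  The constant implicit
operator is factored once per run.  Cell updates across nodes are
vectorized Rush-Larsen by default; per-node adaptive solving in
V-as-parameter mode (with the no-reset policy) is available and agrees with
both the reset variant and the RL path under trace MRMS, which is the
tissue property the tests assert.

## What the synthetic fixtures do and do not show

The zoo contains transcriptions of two published models (Hodgkin-Huxley
1952 with four states; Luo-Rudy 1991 with eight) plus synthetic
constructions: a two-state toy gate with closed-form behaviour, a
self-excitatory linear oscillator (for the no-stimulus interface path), a
seeded stiff-gate generator with a prescribed timescale spread (fast gate
$\tau \sim 1/\text{ratio}$ ms against ~100 ms recovery, mildly
voltage-dependent so gate updates are not trivially exact), and a
singularity fixture combining a removable $0/0$ rate at a round voltage
with a calcium sigmoid whose exponent overflows doubles inside its
annotated range.  Initial right-hand sides and resting gate constants are
cross-checked against independent hand transcriptions frozen at generation
time.  These fixtures exercise every code path the machinery has, but they
are small: passing tests here demonstrates correctness of the conversion
and the numerics, not coverage of the full diversity of published models
(calcium subspaces, Markov channel chains, concentration drift), and the
published whole-repository statistics (conversion census, aggregate
biomarker errors, wall-clock figures) are correspondingly out of scope.

## Problem sizes used by the checks

The test suite and the acceptance script run, by design, at desk scale: two
paces per refinement trial, 100 random states per Jacobian check, 1000
random states per transform-soundness sweep, strands of 0.04-1 cm at
0.01 cm spacing with durations of 30-400 ms, and one full 10,000-pace
pacing run for the steady-state precision result.  These sizes were chosen
as the smallest that exercise each claim meaningfully; all are arguments,
not constants, so larger studies are one call away.
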