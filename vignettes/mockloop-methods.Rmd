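---
title: "Methods: a lumped-parameter model of a CMR-compatible mock circulatory loop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a lumped-parameter model of a CMR-compatible mock circulatory loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mockloop)
```

## The system being modelled

`mockloop` simulates a bench mock circulatory loop built to test 3D-printed
aortic-arch phantoms inside an MR scanner: a pulsatile piston pump drives
water through the phantom, each of the four outlets (innominate, carotid,
subclavian arteries and descending aorta) drains through a metered
needle-pinch valve and an air-chamber Windkessel, and all outlets merge into
a return line that empties into a reservoir held at a constant "atrial"
pressure of 8 mmHg. In the companion computational model the phantom is a 3D
CFD domain coupled to a lumped-parameter network (LPN) representing the rest
of the rig. This package replaces the 3D domain with a single junction
pressure node, so that the whole coupled system becomes a five-state 0D
model that runs in well under a second — at the price of discarding every
spatially resolved quantity (streamlines, velocity vectors, local wall shear
stress hot-spots). What remains is exactly what the bulk validation
statistics need: node pressures, branch flows, and their cycle summaries.

## Network topology and element laws

Each downstream branch $j$ is, in series from the junction to the common
return node:

1. a junction internal resistance $r_{\mathrm{int},j}$, the small viscous
   loss of the flow domain between the inlet and outlet $j$;
2. a branch pressure node carrying the Windkessel compliance $C_j$ to
   ground;
3. the calibrated tap, a non-linear resistance with
   $\Delta P = a_j Q^2 + b_j Q$;
4. the tube resistance $R_{j2}$, a linear element.

All four branches meet a common node with the terminal compliance $C_t$,
which drains through $R_t$ into the constant source $P_\mathrm{atrium}$.
The compliance sits upstream of the tap, the classic Windkessel
arrangement matching the physical rig, where the air chambers precede the
metered valves; $R_t$ lumps the final stretch of tubing shared by all
outlets.

The tap coefficients come from a forward-flow calibration, so $b_j < 0$ for
every branch and $\Delta P_{j1}$ alone is negative for
$0 < Q < |b_j|/a_j$ (below $\approx 0.05$ L/min). The solver never sees the
tap in isolation: only the series law
$\Delta P = a_j Q^2 + (b_j + R_{j2}) Q$ is exposed, and $b_j + R_{j2} > 0$
holds for all four calibrated rows, making the series law strictly
increasing for forward flow. For reverse flow the law is extended
antisymmetrically, $\Delta P(-Q) = -\Delta P(Q)$: taps resist reverse flow
too, and an odd, monotone law keeps the integrator total. The closed-form
inverse used at every step is the positive quadratic root
$Q = \left(-(b + R_2) + \sqrt{(b + R_2)^2 + 4 a\,\Delta P}\right) / (2a)$.

Internal units are strictly SI (Pa, m$^3$/s, s); mmHg and L/min exist only
at the I/O boundary, through `convert_pressure()` and `convert_flow()` with
1 mmHg = 133.322 Pa.

The default $r_{\mathrm{int}} = 10^6$ Pa·s/m$^3$ per branch gives a drop of
roughly 0.4 mmHg at descending-aorta flow — of the order of the small 3D
pressure losses implied by the calibrated branch drops — and is
configurable per branch.

## The governing equations

With $p_j$ the branch node pressures and $p_c$ the common node pressure,
the junction node is algebraic (it stores no volume): given the inlet flow
$q_\mathrm{in}(t)$,

$$p_a = \frac{q_\mathrm{in} + \sum_j p_j / r_{\mathrm{int},j}}
             {\sum_j 1 / r_{\mathrm{int},j}}, \qquad
  q_j = \frac{p_a - p_j}{r_{\mathrm{int},j}},$$

which enforces $\sum_j q_j = q_\mathrm{in}$ to machine precision at every
instant. The five ODEs are

$$C_j \frac{dp_j}{dt} = q_j - q_{\mathrm{out},j}(p_j - p_c), \qquad
  C_t \frac{dp_c}{dt} = \sum_j q_{\mathrm{out},j}
   - \frac{p_c - P_\mathrm{atrium}}{R_t},$$

with $q_{\mathrm{out},j}$ the inverse series law above.

## The inlet waveform

The bench pump's waveform shape was recorded but never published, so the
generator emulates a piston pump: a half-sine ejection over the first
$f_s T$ of the cycle, an optional brief negative lobe right after ejection
(the loop has no aortic valve), and zero flow in diastole. The peak is set
from the closed-form half-sine mean, $Q_\mathrm{peak} = \mathrm{CO}\,\pi /
(2 f_s)$, and the samples are then rescaled so the discrete cycle mean
equals the cardiac output exactly.

Defaults: $T = 0.8$ s and $f_s = 0.5$, consistent with the comparison
instants used in the validation (0.1, 0.2 and 0.4 s labelled early, peak
and late systole, 0.6 s diastole), which place end-systole near 0.4–0.45 s;
cardiac output 5.48 L/min for the TGA run and 5.25 L/min for the control
run, the sums of the computed outlet means of each anatomy. These are the
study conditions, not tuning knobs.

`emulate_pcmr_sampling()` reproduces what a gated 2D phase-contrast
acquisition does to the inlet curve: the cycle is split into a whole number
of phase bins of width close to the 29.9 ms temporal resolution, native
samples are averaged within bins (retrospective gating averages within
phase bins, so bin averaging, not decimation), and seeded Gaussian noise is
added. This module is the only stochastic component in the package; given a
seed, the whole pipeline is deterministic. `interpolate_to_solver_grid()`
then maps any waveform onto the uniform integration grid by periodic linear
interpolation, wrapping the cycle end onto $t = 0$.

## Numerics

Integration is fixed-step explicit Euler with $\Delta t = 10^{-4}$ s, the
scheme and step the network was calibrated at. The terminal compliance is
four orders of magnitude smaller than the branch compliances
($C_t = 0.36\cdot10^{-11}$ m$^3$/Pa), which makes the common node
marginally stiff: its local time constant at the operating point,
$C_t / (\sum_j g_j + 1/R_t)$ with $g_j$ the series-law conductances
linearised at the operating flows, is about $1.2\cdot10^{-4}$ s, so
$\Delta t = 10^{-4}$ s sits inside but not far from the explicit stability
bound ($2\tau$). `run_to_periodic()` therefore computes the bound at the
waveform's mean flow and, when $\Delta t$ exceeds 0.8 of it, transparently
sub-divides each step. Near zero mean flow the subclavian series
conductance grows to $1/(b+R_2) = 5\cdot10^{-7}$ m$^3$/(Pa·s) and the bound
tightens to about $10^{-5}$ s; the zero-flow relaxation test exercises this
path. An independent hard guard aborts if any node pressure exceeds
$10^6$ Pa.

All pressures start at 80 mmHg, near the operating point, which keeps the
transient to a handful of cycles; the converged cycle is independent of
this choice (asserted from 40 and 120 mmHg starts). Cycles repeat until
the maximum node-pressure change between consecutive cycles falls below
0.1 mmHg (13.3 Pa), up to 50 cycles; the default TGA run converges in 8
cycles. At that tolerance the net volume stored per cycle in any
compliance, $C_j\,\Delta p$, is below 0.05% of the stroke volume, and
halving $\Delta t$ moves the cycle-mean aortic pressure by less than
0.05 mmHg, the first-order Richardson behaviour expected of Euler.

Degenerate inputs are total: the tap law and its inverse are odd
extensions, zero flow is an exact fixed point at atrial pressure, and tie
resolution in `max_split_error()` goes to the earlier branch in canonical
order (innominate, carotid, subclavian, descending aorta).

## Validation statistics

The comparison machinery mirrors how the bench and computational results
were compared: per-branch cycle-mean flows as percentages of a reference
flow, percentage error $100\,|s - m|/m$ for pressures, squared Pearson
correlation for waveform agreement, and Bland–Altman bias with
bias $\pm\,1.96\,\mathrm{SD}$ limits of agreement (the 1.96 multiplier is
the standard convention; SD uses the $n-1$ denominator). For simulation
output the split reference defaults to the cycle-mean inlet flow, which at
periodicity equals the outlet sum by mass conservation. For the bundled
printed summary tables the reference is an explicit argument, because the
published bracketed percentages are not consistent with the printed L/min
values under any single denominator (0.86/5.42 gives 15.9%, not the
printed 15.7%); they appear to be normalised by the unprinted inlet mean
(about 5.48 L/min for the TGA run), which is exactly what the `reference`
argument expresses. Both the instantaneous series and the four sampled
instants feed the agreement statistics, since it is not recorded which of
the two the published correlation plots used.

## Derived mechanical quantities

`wss_poiseuille()` gives the bulk wall-shear-stress estimate
$\tau_w = 4 \mu Q / (\pi r^3)$ of fully developed laminar tube flow — a
cross-section average, structurally unable to reproduce local 3D hot-spots
(values up to 35 Pa were seen on the anterior ascending aorta of the TGA
geometry; the bulk estimate at the inlet peaks well below 1 Pa).

`power_dissipation()` is the energy-flux bookkeeping of the junction
domain: cycle mean of
$(p_a + \tfrac12\rho v_\mathrm{in}^2)\,q_\mathrm{in} -
 \sum_j (p_j + \tfrac12\rho v_j^2)\,q_j$ with $v = q/A$. The static part
equals $\sum_j r_{\mathrm{int},j}\,\overline{q_j^2}$ identically. The
kinetic part deserves a caveat: with equal internal resistances the
junction distributes the flow *pulse* essentially equally across branches,
while the default outlet areas are scaled by the mean-flow fractions, so
under a strongly pulsatile inflow the kinetic fluxes do not cancel and the
full index can undershoot the viscous loss or even turn negative. At
steady flow, with outlet areas proportional to the actual flow fractions,
the kinetic terms cancel exactly and the index reduces to the per-element
sum $\sum_j r_{\mathrm{int},j} q_j^2$ — that regime is where the exact
tests live. `include_kinetic = FALSE` selects the static-pressure
bookkeeping unconditionally.

## What the synthetic data do and do not show

The generator reproduces the study conditions — the calibrated element
constants, atrial head, fluid, cardiac outputs, cycle length, MR sampling
rate — but emulates the unpublished pump waveform with a parametric
half-sine. Passing tests therefore demonstrate that the network, driven by
a waveform of the right mean, period and systolic fraction, lands on the
reported operating point (cycle-mean aortic pressure, flow splits) and
within broad bands of the reported pressure extremes; they do not
demonstrate waveform-shape fidelity, and no 3D quantity (streamline
patterns, velocity-vector symmetry, local WSS, mesh sensitivity) is
reproduced or claimed. The same network preset serves the TGA and control
runs, as the rig's R and C settings were kept constant across both; the two
runs differ only in cardiac output, so anatomy-driven differences are out
of scope by construction.

## Problem sizes

The default runs integrate 8 000 Euler steps per 0.8 s cycle and converge
within 8–20 cycles depending on tolerance; the full test suite, including
the convergence-order study at halved step size and a 10^5-sample
distributional check of the limits of agreement, completes in well under a
minute on one core.

## A worked run

```{r, eval = FALSE}
library(mockloop)

sim <- simulate_loop() # bench preset, TGA pump settings
glance(sim) # mean/peak/min aortic pressure, CO, convergence
tidy(sim) # per-branch mean flows and % splits

rpt <- build_report(sim, measured = list(
  flows_lmin = c(0.92, 0.54, 1.17, 2.92),
  reference_lmin = 5.48,
  pressure_mmhg = list(mean = 84.6, peak = 106, min = 60)
))
rpt
```

## Known limitations

* No inertance elements (the physical network has none) and no distributed
  1D segments; wave travel and flow eccentricity are invisible.
* The junction surrogate has one pressure; inter-branch 3D pressure
  differences are represented only through the internal resistances.
* Explicit Euler is first-order; the step is part of the model definition
  here, and the sub-stepping guard protects stability, not accuracy.
* The pump waveform shape is configuration, so pressure extremes inherit
  its uncertainty; cycle means are insensitive to it.
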