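---
title: "Methods: I_h, rebound, resonance, and spike-timing precision in a conductance-based interneuron model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: I_h, rebound, resonance, and spike-timing precision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`ihdyn` implements a four-variable conductance-based model of a hippocampal
GABAergic interneuron extended with the hyperpolarization-activated
non-specific cation current I_h (the HCN-channel current). The membrane
equation balances a fast sodium current (activation slaved to its steady
state, `m = m_inf(V)`, inactivation gate `h`), a delayed-rectifier potassium
current (gate `n`), a leak, and I_h (gate `H`, reversal -30 mV):

    C dV/dt = -gNa m_inf(V)^3 h (V - ENa) - gK n^4 (V - EK)
              - gh H (V - Eh) - gL (V - EL) + Iapp + I_ext(t)
    dh/dt   = phi (alpha_h(V) (1 - h) - beta_h(V) h)
    dn/dt   = phi (alpha_n(V) (1 - n) - beta_n(V) n)
    dH/dt   = (H_inf(V) - H) / tau_H(V)

`H_inf(V) = 1/(1 + exp((V + 80)/10))` is a Boltzmann activated by
hyperpolarization (half-activation -80 mV, 10 mV slope) and
`tau_H(V) = 200/(exp((V+70)/20) + exp(-(V+70)/20)) + 5` ranges from 5 ms at
extreme voltages to 105 ms at -70 mV. I_h is therefore slow and inward below
its -30 mV reversal: it produces the voltage sag during hyperpolarizing
pulses and the post-inhibitory rebound at their offset.

Two unit conventions deserve a note. The capacitance is `C = 1` uF/cm^2 —
the only unit that makes the voltage equation dimensionally consistent at
the mV/ms scale used here (sources sometimes print F/cm^2 for this model
family, which is a typo). The leak is `gL (V - EL)`; no separate leak
driving potential exists in this model. Removable singularities of
`alpha_m` (V = -35 mV) and `alpha_n` (V = -34 mV) are filled with their
analytic limits through a series-safe evaluation of `y/(1 - exp(-y))`, so
the gating functions are smooth there rather than epsilon-shifted.

The two control parameters of every analysis are the applied current `Iapp`
(uA/cm^2) and the I_h conductance `gh` (mS/cm^2); all other parameters stay
at the reference set (`gNa = 35`, `gK = 9`, `gL = 0.1` mS/cm^2, `ENa = 55`,
`EK = -90`, `EL = -65`, `Eh = -30` mV, `phi = 5`).

## Integration and noise

The reference integrator is fixed-step forward Euler with `dt = 0.001` ms,
implemented in C++ (`src/sim.cpp`) because the protocols span tens to
hundreds of simulated seconds. Gates are clipped to [0, 1] after every step
(the clip only absorbs O(dt) overshoot at the boundaries). Stochastic runs
add a white-noise current of intensity `D` to the voltage equation by
Euler-Maruyama: each step adds `(D/C) sqrt(dt) xi`, `xi ~ N(0,1)`, to `V`.
With `C = 1` this makes `D` numerically the intensity quoted with the
protocols (`D = 0.2` or `0.6`). The convention lives in one function
(`noise_increment()`, mirrored inline in the C++ core) so alternatives can
be swapped for sensitivity analyses. Noise draws use R's RNG, so a seed
makes any run bit-identical on rerun.

Coarse surveys (behavior partitions, map grids, some tests) use `dt` up to
0.005 ms behind an explicit argument; the first-order weak error is
negligible at those scales, and everything quantitative that is compared
against reference values uses 0.001 ms.

Spikes are upward crossings of 0 mV (linearly interpolated between steps)
with a 2 ms refractory gap. The model's action potentials overshoot well
above 0 mV, so spike counts are insensitive to the threshold over roughly
[-20, +10] mV — asserted as a test, not assumed. Firing-statistics runs
discard an initial transient (500 ms by default) before collecting
intervals. These conventions are not stated in the source literature for
this model; they are exposed as arguments.

## Impedance and resonance classes

Subthreshold resonance is probed with the standard ZAP protocol: from the
resting state, a chirp `I(t) = Istim sin(2 pi f(t) t)` with
`f(t) = fmin + (fmax - fmin) t/T` (defaults `Istim = 0.01` uA/cm^2, 0-20 Hz
over 20 s) drives the deterministic model, and the impedance magnitude is
the FFT ratio `|Z(f)| = |FFT(V - mean V) / FFT(I)|`, restricted to
0.1-20 Hz and smoothed by a 5-bin moving average (the raw ratio is noisy at
the chirp edges). The literal phase `2 pi f(t) t` is used; its instantaneous
frequency is `f + t f'`, but because the impedance is computed as an FFT
ratio the frequency axis of the profile is unambiguous regardless of the
chirp convention. The low-frequency reference `Z_low` is the mean of |Z|
over 0.1-0.3 Hz, since the sweep starts at 0 Hz where the first bins are
unreliable.

An analytic cross-check accompanies the FFT pipeline: the linearized
impedance at a stable equilibrium, the (V, V) entry of
`(i omega I - J)^{-1}/C` with `J` the analytic Jacobian. In the subthreshold
regime the two agree to within ~2-3% mid-band; at the reference stimulus
amplitude the residual second-order response is itself about 2%, which sets
the scale of the linearity checks.

The qualitative labels "typical", "weak", and "non" resonance are
operationalized on the *height* of the inverse-U of the profile,
`Z_peak - Z_low` (in MOhm cm^2), with the peak required to sit above
0.5 Hz: typical >= 5, weak >= 0.5, non otherwise. A peak-to-baseline *ratio*
cannot reproduce the reference label pattern: at strongly hyperpolarized
holding currents the overall impedance is small, so a "weak" profile there
can have a larger relative peak than a "typical" profile at gentler holding
currents, while its absolute rise stays several-fold below. The thresholds
were calibrated once against the nine labelled (Iapp, gh) points of the
reference pattern, which they separate with ~25% margin on both sides, and
are exposed as arguments.

## Spike-timing statistics

ISI statistics use the sample (n-1) standard deviation; `CV = STD/mean`.
The reference protocols collect N = 2000 ISIs (at `Iapp = 0.17`,
`D = 0.2`, with and without I_h) after the transient discard. First-spike
jitter uses 1000 independent ramp trials from the stable resting state
(`Iapp = 0`, `gh = 0.02`, `D = 0.2`); trial i runs with seed `seed + i`, so
the ensemble is reproducible and trials are independent. First-spike times
are measured from ramp onset. The "fast" and "slow" ramps rise at 1 and
0.3 uA/cm^2 per 100 ms.

Maps over the (Iapp, gh) plane report, per grid cell, the resting potential
(masked where only firing exists), the deterministic firing frequency
`1000/mean ISI` (masked where the cell rests), or the CV of a stochastic
run. Grid sizes, ISI counts per cell, and the step are arguments; the test
suite uses coarse grids and ~100-150 ISIs per cell, which resolves the
monotonic trends (resting V and firing rate increase with gh, CV and STD
decrease, STD faster than the mean) without long runtimes. Full-resolution
maps (60 x 60, 2000 ISIs) are a desk-scale computation with the same code.

## Bifurcation analysis

All bifurcation machinery is built from scratch on one structural fact: at
an equilibrium the gates sit on their steady-state curves, so fixed points
are roots in V of a scalar current balance `F(V) = A(V) + gh B(V) + Iapp`,
which is *linear* in both control parameters. Equilibria are found by a
0.01 mV sign-change scan over [-100, 0] mV plus root refinement, then
classified by the eigenvalues of the analytic Jacobian (node/focus by the
leading pair — the two eigenvalues of largest real part; saddle when all
eigenvalues are real with mixed signs; stability by the sign of the largest
real part).

The linearity of `F` in the parameters gives the codim-1 conditions in
closed form:

* **Folds.** `F = 0` and `dF/dV = 0` reduce, after eliminating gh, to one
  scalar equation in V. The same elimination parameterizes the entire
  two-parameter fold curve explicitly by the equilibrium voltage:
  `gh(V) = -A'(V)/B'(V)`, `Iapp(V) = -(A + gh B)`. Every point satisfies
  the fold condition to machine precision, which makes the codim-2 searches
  along the curve one-dimensional root finds.
* **Hopf and node-focus (NF) points.** Detected on the lower (resting)
  branch by bisection, to 1e-9 in gh, of the sign of the leading pair's
  real part and of its real-to-complex transition respectively. Indicator
  flips that a fold-induced branch jump would alias onto the fold are
  rejected by a branch-continuity check at the converged point.
* **Bogdanov-Takens.** Along the explicit fold curve, the determinant of
  the Jacobian is already zero; a second zero eigenvalue appears where the
  sum of 3x3 principal minors (the next characteristic-polynomial
  coefficient) vanishes. That scalar condition is bisected in V.
* **Cycle boundaries (homoclinic).** The disappearance of the large stable
  limit cycle is located by hysteresis bisection in gh: start on the firing
  attractor above the bracket, carry the final state downward between
  trials, and test spiking persistence over a simulation window —
  a methodological substitution for boundary-value homoclinic continuation,
  sufficient for the three-figure accuracy asserted. "Persists" requires at
  least two spikes in the *second half* of the window, so the last slow
  loops of a decaying transient do not count as sustained firing.
  The window is 2 s for boundary location and 6 s for fold
  classification, where trajectories creep through the saddle-node ghost
  with passages of many hundreds of ms.
* **SNIC vs SN character of a fold** is decided by cycle persistence just
  below the fold, at `gh_fold - delta`. `delta` is a resolution, not a free
  knob: this strongly time-scale-separated model keeps an exponentially
  thin coexistence sliver below the fold (order 1e-4 in gh and below) well
  into the regime whose folds the reference analysis classifies as SNIC, so
  a vanishing `delta` would misclassify those folds, while a large one
  erases the genuine coexistence band (order 1e-3) of the plain-SN regime.
  The default `delta = 1e-4` is the smallest round value consistent with
  the reference labels at both anchor points (`Iapp = 0.08` SNIC,
  `Iapp = -0.05` SN). The saddle-node-homoclinic (SNHO) point is then the
  bisected switch of this classification along the fold curve. Because the
  sliver decays smoothly rather than terminating at a sharp point, the
  location of the switch inherits the `delta` resolution; it reproduces the
  reference location to about 3%, and the cycle-boundary gh at the
  reference SNHO current matches to three figures.
* **T point.** The two NF branches bounding the stable-focus region meet
  where the focus segment of the resting branch shrinks to zero width;
  located by bisection in Iapp on the existence of a stable-focus segment
  over a fine gh grid. The meeting point sits at gh of order 1e-5, at the
  domain edge, where conditioning is poor; only about two significant
  figures in Iapp are meaningful there.

Two precision caveats are worth recording. First, NF transitions are not
true bifurcations, and the imaginary part of the colliding pair grows like
`sqrt(gh - gh*)`: any detector that flags "visibly complex" eigenvalues at
a finite step lands slightly above the exact discriminant zero. The exact
transition values computed here sit 0.03-0.06% below the reference figures
(whose folds and Hopf points this package matches to all printed digits),
which is the expected signature of that effect — agreement is asserted at
0.1% rather than at the fourth significant figure. Second, the reference
coordinates of the BT point are not mutually consistent with the fold curve
that passes through both reference one-parameter folds; the gh coordinate
(which the fold curve determines to four digits here) is the one asserted.

## Synthetic-data scope

There are no external data: the stimulus generators and the stochastic
integrator *are* the data-generating process, and their defaults are the
study conditions (pulse amplitudes -0.4/-0.8/-1.2 uA/cm^2 over 100 ms; ZAP
0.01 uA/cm^2, 0-20 Hz, 20 s; D = 0.2 and 0.6; N = 2000 ISIs; 1000 ramp
trials). What passing tests show is therefore internal consistency of the
model analysis — simulation agreeing with its own linearization and
bifurcation structure, and with the reference values it asserts — not
fidelity to any biological recording. Channel noise, conductance
(multiplicative) noise, colored noise, synaptic input, and multi-compartment
structure are all outside the model family.

## Problem sizes and tolerances used by the checks

The test suite runs sweeps on 41-61 point gh grids, bifurcation bisections
to 1e-9 (parameter) and 1e-13 (state root) tolerances, ZAP runs at the full
20 s / 0.001 ms resolution thinned to 1 kHz for the FFT, stochastic CV
checks at N = 2000 ISIs (acceptance) and N = 100-150 (monotonicity
properties, at dt = 0.002 ms), and 1000-trial jitter ensembles. Behavior
partitions in tests use handfuls of grid cells at dt = 0.002-0.005 ms with
1-1.5 s persistence windows. Stochastic comparisons use +-10% tolerances;
deterministic bifurcation values are asserted to four significant figures
(three for the simulation-located homoclinic value; 0.1% for NF transitions
as discussed above).

## Known limitations

* The homoclinic and SNHO machinery is simulation-based; it resolves
  boundaries to ~1e-3 relative accuracy, not the 1e-6 a boundary-value
  continuation would give, and its SNIC/SN distinction is tied to the
  `delta` resolution above.
* Unstable limit cycles (and the small-homoclinic curve they end on) are
  not continued; the package only notes where the reference analysis placed
  them.
* Hopf criticality is decided by a hysteresis/bistability test rather than
  a first-Lyapunov-coefficient computation; the two agree at the points
  asserted here, but the operational test would mislabel a degenerate
  (near-Bautin) Hopf.
* The Euler scheme is first order; subthreshold quantities converge well at
  dt = 0.001 ms, but homoclinic boundary locations carry an O(dt)
  parameter bias of order 1e-4 relative.
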