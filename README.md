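# ihdyn

Dynamics of the hyperpolarization-activated cation current (I_h) in a
conductance-based hippocampal interneuron model.

## What this package is for

HCN channels carry a slow inward current, I_h, that activates on
hyperpolarization. In recordings it shows up three ways: a voltage *sag*
during hyperpolarizing pulses followed by a post-inhibitory *rebound*
(sometimes a rebound spike), a *subthreshold resonance* — a peaked impedance
profile under swept-sine (ZAP) stimulation — and greater *spike-timing
precision*, i.e. a lower coefficient of variation (CV) of interspike
intervals under noise. `ihdyn` reproduces and explains all three in a single
four-variable conductance-based model, for computational neuroscientists who
want the full chain from simulation to dynamical-systems analysis in
reusable, tested form.

The model is a fast-spiking interneuron (Wang–Buzsáki-type kinetics) plus
I_h:

    C dV/dt = -gNa m_inf(V)^3 h (V-ENa) - gK n^4 (V-EK)
              - gh H (V-Eh) - gL (V-EL) + Iapp + I_ext(t)
    dh/dt   = phi [alpha_h(V)(1-h) - beta_h(V) h]
    dn/dt   = phi [alpha_n(V)(1-n) - beta_n(V) n]
    dH/dt   = [H_inf(V) - H] / tau_H(V)

with `H_inf(V) = 1/(1+exp((V+80)/10))`, `tau_H(V) = 200/(exp((V+70)/20) +
exp(-(V+70)/20)) + 5` ms, and the two control parameters `Iapp` (applied
current) and `gh` (I_h conductance).

The package provides:

* the vector field, ionic currents, gating kinetics, and an analytic
  Jacobian (`ih_rhs`, `ionic_currents`, `gating_rates`, `ih_jacobian`);
* stimulus generators (square pulses, ramps, ZAP chirps, sinusoids,
  white-noise current) and a compiled fixed-step Euler / Euler–Maruyama
  integrator at the reference step dt = 0.001 ms (`stim_protocol`,
  `integrate_model`, `run_spike_train`);
* FFT-based impedance profiles with an analytic linearized-impedance
  cross-check and typical/weak/non resonance classification
  (`impedance_profile`, `analytic_impedance`, `classify_resonance`);
* ISI and first-spike-latency statistics and (Iapp, gh) maps
  (`isi_stats`, `noisy_isi_stats`, `first_spike_ensemble`, `param_map`);
* from-scratch bifurcation analysis: equilibrium continuation in gh,
  fold/Hopf/node–focus detection, SNIC-vs-SN classification, hysteresis
  location of the homoclinic cycle boundary, two-parameter curves, and the
  Bogdanov–Takens and saddle-node-homoclinic codimension-2 points
  (`find_equilibria`, `sweep_1d`, `locate_cycle_boundary`,
  `trace_curve_2d`, `locate_codim2`, `stable_behavior_partition`);
* figure-level experiment drivers (`rebound_assay`, `run_experiment`).

## Worked example

Classify the resting state and locate the bifurcations that bound it at
Iapp = 0.08 uA/cm^2:

```r
library(ihdyn)

p <- ih_params(Iapp = 0.08, gh = 0.02)
find_equilibria(p)[[1]]
#> equilibrium: V = -60.524489 mV, type stable_focus
#> eigenvalues (1/ms): -0.0137124+0.0079836i -0.0137124-0.0079836i
#>                     -0.5661915+0.0000000i -0.8556176+0.0000000i

sweep_1d(ih_params(Iapp = 0.08), gh_range = c(0.01, 0.03), n_grid = 41)$points
#>  kind         gh         V
#>    nf 0.01692268 -60.96723
#>  fold 0.02299193 -59.60927
```

The resting state is a stable focus; lowering gh past 0.0169 turns it into a
node (no subthreshold oscillation, hence no resonance), and raising gh to
0.0230 destroys it in a saddle-node on an invariant circle, where firing
begins. The resonance itself, at a hyperpolarized holding current:

```r
p <- ih_params(Iapp = -0.05, gh = 0.05)
tr <- integrate_model(p, stim_protocol("zap"), t_end = 20000, thin = 1000L)
impedance_profile(tr)
#> impedance_profile: peak |Z| = 30.016 at 3.25 Hz (low-f ref 22.227): typical
```

The impedance peaks at ~3 Hz, 35% above its low-frequency level — a
"typical" resonance, which disappears when gh = 0. And the sag/rebound
protocol:

```r
rebound_assay(ih_params(Iapp = -0.05, gh = 0.05))
#>  amplitude       outcome sag_mV rebound_spike_latency_ms
#>       -0.4       rebound  0.352                       NA
#>       -0.8 rebound_spike  0.739                     85.3
#>       -1.2 rebound_spike  1.234                     61.7
```

Stronger hyperpolarizing pulses deepen the sag and evoke the rebound spike
earlier; with gh = 0 every outcome is `no_rebound` and the sag vanishes.

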