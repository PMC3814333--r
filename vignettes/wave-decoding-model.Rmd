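---
title: "A hierarchical model of traveling-wave decoding in the descending motor system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hierarchical model of traveling-wave decoding in the descending motor system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavedecode)
```

# The model

`wavedecode` simulates a complete descending motor pathway in which motor
commands are carried by the *orientation of traveling beta-band waves* in
motor cortex and decoded by the spatial structure of pyramidal tract
neuron (PTN) dendritic receptor fields. The pipeline has four stages:

1. **Cortex** — a 128 x 128 sheet of spatially coupled Kuramoto phase
   oscillators with periodic boundaries. Each oscillator advances as
   `dtheta/dt = 2*pi*omega + g * sum_j K(x_j - x_i) sin(theta_j - theta_i)`,
   with intrinsic frequencies `omega ~ Normal(20 Hz, 4 Hz)`. The coupling
   kernel `K` has a positive centre and an inhibitory surround (the fourth
   radial derivative of a Gaussian, full-width-half-height 11 nodes);
   the surround strength varies with angle between `s_major` on the major
   axis and `s_minor` on the minor axis, which orients the emergent
   traveling waves along the major axis. The simulated LFP is the spatial
   mean of `cos(theta)`.
2. **PTN dendrites** — each PTN's receptor field is a two-dimensional
   Gabor filter. In the conductance-based formulation the excitatory and
   inhibitory receptor *density surfaces* combine (signed sum) into the
   target Gabor; discrete receptors sampled from those surfaces are
   bombarded by Poisson events whose rate follows a moving grating, and a
   point-compartment membrane integrates the resulting conductances. In
   the phase-only formulation the dendritic current is directly the
   Gabor-weighted sum of `cos(theta)` around the PTN's cortical position.
3. **PTN soma** — a two-variable quadratic (Izhikevich-type) model:
   `C dv/dt = k (v - v_rest)(v - v_thresh) - u + I`,
   `du/dt = a (b (v - v_rest) - u)`, spike at `v >= v_peak` with reset
   `v <- c`, `u <- u + d`. With the standard constants (`C` = 80 pF,
   `k` = 4, `a` = 0.04, `b` = 10, `c` = -60 mV, `d` = 800 pA) its f-I
   curve has a ~42 Hz/nA suprathreshold slope and a discontinuous onset
   of roughly 10 Hz firing near 0.5 nA; under 20 Hz sinusoidal forcing it
   mode-locks on a devil's staircase with major plateaus at 20 and 40 Hz.
4. **Spinal stage** — 200 PTNs project onto 100 leaky integrate-and-fire
   motor neurons (60 afferents each, ~30% pairwise shared); each afferent
   spike contributes a rise-1 ms / fall-3 ms post-synaptic current scaled
   by `V0 = 20`. Motor-neuron spikes are convolved with bi-phasic MUAP
   templates (random amplitude in [0, 1], random polarity) and summed
   into a surface EMG. Corticomuscular coupling is quantified by Welch
   magnitude-squared coherence between LFP and EMG (0.5 s Hamming
   windows, 50% overlap, 1000 Hz), with the per-bin significance level
   `1 - 0.05^(1/(N-1))` for `N` windows.

Spike-train variability is quantified by the interval CV and by the
irregularity metric `IR = mean |ln(ISI_{i+1} / ISI_i)|`, which measures
relative changes of consecutive intervals and is exactly invariant to
uniform time rescaling (a Poisson train gives `IR = 2 ln 2`).

# What is principled and what is calibrated

All constants printed in the model's parameter tables are taken as-is
(`dendrite_params()`, `soma_params()`, `motor_pool()` defaults,
`coupling_kernel()` geometry). A handful of quantities are *not* fixed by
any published table, and we close them as follows. They were each
calibrated once, against the stated reference behaviour, and then frozen
as package defaults; none is re-tuned per run.

* **Coupling gain** (`gain = 60`, in rad/s of summed excitatory weight
  after L1-normalising the kernel's positive lobe). The gain must exceed
  the synchronisation threshold set by the 2*pi*4 Hz intrinsic frequency
  spread; g = 60 produces patchy traveling waves within ~2 s, a beta-band
  LFP peak, and wave orientation aligned with the kernel's major axis.
  Much larger gains over-synchronise the sheet and suppress the
  wave-pattern variability that the model needs.
* **Surround anisotropy** (`s_major = 1`, `s_minor = 0.4`). The minor-axis
  surround strength controls how often wave patches form away from the
  dominant orientation, and therefore the breadth of the population
  orientation tuning. 0.4 reproduces the reference population rate
  profile across filter offsets (see below); larger values leave too much
  orthogonally oriented wave power.
* **PTN Gabor wavelength** (13 nodes). Defined as the dominant spatial
  frequency of the emergent waves; measured from the time-averaged 2-D
  spectrum of `cos(theta)` in calibration runs of the default cortex
  (radial spectral peak at 13.0-13.5 nodes) and frozen.
* **PTN Gabor envelope and current scale** (`sigma = 2.5` nodes, ideal
  plane-wave response 2.2 nA). Neither the envelope width nor the current
  scale of the phase-only filter is published, but the reference
  *population* behaviour is: mean PTN rates of (22.4, 18.0, 9.7, 2.4) Hz
  at filter-orientation offsets of (0, 30, 60, 90) degrees. These two
  parameters were calibrated jointly against that profile on a single
  calibration run (cortex seed 2002) and frozen; an independent seed
  reproduces all four rates within +/-16%. The calibrated scale places
  well-aligned PTNs on the 20-40 Hz entrainment plateaus (mixed single
  and double spikes per beta cycle), consistent with the reference
  single-neuron behaviour. The kernels are zero-mean ("DC-corrected")
  Gabors, the classical convention, so that spatially uniform synchrony
  does not drive PTNs at all orientations.
* **Motor-neuron firing threshold.** Not part of the published constants;
  it is *defined* by the closure that the pool fires at 9.2 Hz under the
  aligned (0-degree offset) reference drive. `calibrate_mn_threshold()`
  performs this closure by bisection against a fixed drive realisation;
  the package default (140 mV on the model's dimensionless-leak voltage
  scale) is the value logged from the reference calibration run.
  Pool firing is fluctuation-driven, so the rate at a *fixed* threshold
  is sensitive (roughly 2x) to the ~10% seed-to-seed variation in mean
  PTN drive; analyses that quote the pool rate should therefore either
  perform the closure on their own run (as `scripts/acceptance.R` does)
  or quote the spread.
* **MUAP shape.** Only "bi-phasic, with a time constant and a duration"
  is specified; we use the first derivative of a Gaussian (tau = 3 ms,
  support 15 ms), zero-mean by construction.
* **Receptor densities.** The target Gabor has sigma = 100 um,
  wavelength 300 um, peak 0.2 synapses/um^2 (printed). The nominated
  Gaussian's width is not printed; we use sigma = 115 um, which is the
  value that simultaneously satisfies two printed constraints: the total
  receptor count falls in the physiological 60,000-100,000 range
  (~65,000), and the time-averaged excitatory and inhibitory conductances
  under the preferred grating balance at ~10 nS each (with the published
  per-event conductance of 0.01 nS and 20 Hz mean receptor rate, the
  mean population conductance is N * 20 Hz * 0.01 nS * 1.50 ms, so
  ~33,000 receptors per polarity give 10 nS).

# Numerical choices

* Cortex: explicit Euler at dt = 0.5 ms (halving dt changes the
  default-run LFP spectrum peak and dominant wavelength by less than one
  bin); phases wrapped to [0, 2 pi) every step; the pairwise coupling sum
  is computed exactly as a periodic convolution via FFT (`exp(i theta)`
  packing, one forward and one inverse transform per step, implemented in
  C++; the pure-R `step_sheet()` path is tested equal to within 1e-9).
* Soma and dendrite: Euler at dt = 0.1 ms (the published integration
  step); spike times are recorded at the start of the step on which the
  threshold crossing is detected; currents sampled at 1 kHz are linearly
  interpolated onto the soma step.
* Synaptic transients are exact discrete superpositions of the
  double-exponential kernel (two first-order recursive filters), with the
  per-event peak normalised to the published receptor conductance.
* Poisson bombardment uses per-step Bernoulli draws (p <= 0.004 at the
  default step, bias negligible). The population fast path draws the
  *summed* per-polarity event counts from the aggregated sinusoidal rate
  (exact in distribution for the population conductances; tested against
  the per-receptor path).
* The complement-density solver clips negative solution values at zero
  and records the clipped mass; with the default parameters the clipped
  mass is negligible, and a clipped mass above 5% (a nominated surface
  too small to dominate the target's lobes) is an error.
* Steady-state rates are spike counts over a window after a settle
  period: 1 s settle throughout; 2 s windows for f-I curves, 5 s for
  staircases, the remainder of the run for population rates.
* Tuning-curve intervals are percentile intervals at a configurable
  level (default 90%).
* Orientation selectivity of the conductance-based dendrite is quantified
  by the variance of the net synaptic current within the grating band
  (12-30 Hz): the ~65,000 Poisson receptors contribute an identical
  broadband shot-noise floor in every condition, and it is the
  grating-frequency modulation that the receptor geometry does or does
  not transmit (the preferred/orthogonal band-variance ratio is ~90,
  against ~5 for raw whole-band variances dominated by that floor).

# The synthetic cortex as a study system

The oscillator sheet is the model's own data generator: there are no
external inputs. Heterogeneous intrinsic frequencies (SD = 4 Hz) produce
*metastable* wave patterns — patches that form, drift and dissolve
deterministically — and this single mechanism produces the waxing and
waning of the LFP, the irregular PTN inter-spike intervals (IR is lowest
near 20 Hz where 1:1 entrainment regularises the train), and the
weakness of corticomuscular coherence. What the generator does *not*
emulate: solitary wave fronts of the kind seen in vivo (the model tiles
waves across the whole sheet), centimetre-scale wavelengths (the
dendritic mechanism operates at sub-millimetre scale), empirical
recording noise, and any plasticity or development of the receptor
fields. Passing tests therefore establish internal consistency of the
model and agreement with its reference behaviour, not validation against
physiological recordings.

# Problem sizes used by the test suite

The paper-scale experiment (128 x 128 cortex, 30 s, 200 PTNs, 100 motor
neurons) is what `run_offset_experiment(default_config())` and the
acceptance script run. The test suite exercises the same pipeline at
reduced sizes chosen so the whole suite stays fast while every stage is
still in its operating regime: a 64 x 64 sheet for 15 s for the
orientation-offset profile (the population rates are grid-size stable to
within a few percent), 12 s trials at full 128 x 128 for the coherence
contrast (coherence needs the full sheet: with fewer wave patches the
LFP-EMG coupling is artificially strong), and 8 x 8 sheets for the
exact convolution oracles.

# Known limitations

* With the frequency heterogeneity removed (SD = 0), every PTN sits at
  its maximal dendritic amplitude; rates lock at the top entrainment
  plateaus and the descending drive roughly doubles relative to the
  heterogeneous operating point at which the motor-neuron threshold is
  calibrated. The pool then fires tonically (~100 Hz) and the 20 Hz EMG
  component is buried in reset noise, so the simulated coherence *drops*
  rather than rising toward 0.5 as the reference results describe. The
  reference does not print its SD = 0 pool rates, so this discrepancy
  cannot be localised further; see the repository notes for the analysis.
* The motor-pool mean rate at a fixed threshold is seed-sensitive (see
  above); only the calibrated closure is stable.
* The devil's-staircase boundary currents (e.g. 1:3 vs 1:2 locking at
  0.50 vs 0.51 nA) are reproduced exactly at the published integration
  step; they are properties of the discretised system and shift slightly
  under other integrators.

# A worked example

A scaled-down end-to-end run (a 64 x 64 sheet for 15 s — the same
configuration the test suite uses):

```{r example, eval = FALSE}
cfg <- default_config(cortex = list(grid_size = 64),
                      run = list(duration_s = 15, seed = 2))
rep <- run_offset_experiment(cfg)
rep$summary
#>   offset_deg ptn_rate_hz mn_rate_hz   emg_rms beta_coherence
#> 1          0   25.166429 10.0857143 1.7173844      0.6876221
#> 2         30   18.458571  0.8721429 0.5376743      0.7291592
#> 3         60    8.035714  0.0000000 0.0000000      0.0000000
#> 4         90    3.144643  0.0000000 0.0000000      0.0000000
```

The PTN population mean rate falls from ~25 Hz when the dendritic
filters are aligned with the wave pattern to ~3 Hz when they are rotated
90 degrees away, and the motor pool and EMG inherit the tuning. (At this
reduced scale the mid-offset EMG carries too few motor-unit potentials
for a stable coherence estimate, which is why the 30-degree coherence
bin exceeds the 0-degree one here; the full-scale run is monotone.)
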