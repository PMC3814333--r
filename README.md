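# wavedecode

Simulation of a hierarchical model of the descending motor system in
which motor commands are encoded in the **orientation of traveling
beta-band waves** in motor cortex and decoded by the **spatial structure
of pyramidal tract neuron (PTN) dendritic receptor fields**, which act as
two-dimensional Gabor filters of the oscillatory phase pattern. The
package is aimed at computational neuroscientists studying oscillatory
coding, dendritic computation and corticomuscular coupling.

## The model

Four stages, each exposed as ordinary R functions:

1. **Cortex** (`oscillator_sheet`, `coupling_kernel`, `simulate_cortex`,
   `compute_lfp`, `lfp_spectrum`) — a 128 x 128 sheet of spatially
   coupled Kuramoto phase oscillators,

   dθᵢ/dt = 2π ωᵢ + g Σⱼ K(xⱼ − xᵢ) sin(θⱼ − θᵢ),

   with ω ~ N(20 Hz, 4 Hz), periodic boundaries, and an anisotropic
   inhibitory-surround kernel K (fourth radial derivative of a Gaussian;
   surround strength s(φ) = s_minor + (s_major − s_minor) cos²(φ − φ_k))
   that orients emergent traveling waves along its major axis. The LFP
   is the spatial mean of cos θ.
2. **PTN dendrite** — conductance-based: excitatory/inhibitory receptor
   *density surfaces* whose signed sum is a target Gabor filter
   (`gabor_profile`, `solve_complement_density`, `sample_receptors`,
   `receptor_field`), Poisson bombardment rate-modulated by a moving
   grating, and point-compartment membrane integration
   (`integrate_dendrite`, `simulate_dendrite_response`,
   `field_frequency_response`). Phase-only: the dendritic current is the
   Gabor-weighted sum of cos θ around the PTN's cortical position
   (`phase_gabor_kernel`, `dendritic_current`).
3. **PTN soma** (`simulate_soma`, `fi_curve`, `staircase_curve`) — a
   two-variable quadratic (Izhikevich-type) neuron,
   C dv/dt = k(v − v_r)(v − v_t) − u + I, du/dt = a(b(v − v_r) − u),
   tuned to pyramidal-tract response properties (f-I slope ≈ 42 Hz/nA,
   discontinuous ≈10 Hz onset near 0.5 nA, devil's-staircase mode
   locking under 20 Hz forcing).
4. **Spinal stage** (`wire_pool`, `motor_pool`, `simulate_motor_pool`,
   `calibrate_mn_threshold`, `muap_templates`, `synthesize_emg`) — 200
   PTNs wired 60-to-1 onto 100 leaky integrate-and-fire motor neurons
   with stochastic membrane resets; surface EMG by MUAP convolution.

Analysis utilities: interval statistics `cv_isi` / `ir_isi` (IR = mean
|ln ISIᵢ₊₁/ISIᵢ|), `irregularity_vs_rate`, Welch spectra and
magnitude-squared coherence with per-bin confidence levels
(`welch_psd`, `welch_coherence`, `coherence_confidence`), and the
end-to-end orientation-offset experiment (`run_offset_experiment`).

## A worked example

```r
library(wavedecode)

# steady-state soma responses
fi <- fi_curve(seq(0.5, 2.5, by = 0.1))
fi_slope(fi)                       # 42.27273 Hz/nA
staircase_curve(c(0.50, 0.51, 1.00, 1.50))$rate_hz
#  6.666667 10.000000 20.000000 40.000000   (1:3, 1:2, 1:1 and 2:1 locking)

# a scaled-down descending-motor run (64 x 64 cortex, 15 s)
cfg <- default_config(cortex = list(grid_size = 64),
                      run = list(duration_s = 15, seed = 2))
rep <- run_offset_experiment(cfg)
rep$summary
#   offset_deg ptn_rate_hz mn_rate_hz   emg_rms beta_coherence
# 1          0   25.166429 10.0857143 1.7173844      0.6876221
# 2         30   18.458571  0.8721429 0.5376743      0.7291592
# 3         60    8.035714  0.0000000 0.0000000      0.0000000
# 4         90    3.144643  0.0000000 0.0000000      0.0000000
```

The PTN population decodes wave orientation: its mean rate falls from
~25 Hz with dendritic filters aligned to the waves down to ~3 Hz at 90°
offset, and the motor pool and EMG inherit that tuning. At full scale
the aligned pool fires at ~9 Hz and LFP-EMG coherence shows a weak but
significant beta-band peak.

A thin command-line wrapper over the same functions is provided in
`exec/wavedecode` (`simulate-cortex`, `fi-curve`, `staircase`,
`build-field`, `run-offsets` subcommands).

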