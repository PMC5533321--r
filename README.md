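# ewdyn

Early-warning signals of critical transitions in two perturbed model
systems: a noisy mean-field Kuramoto oscillator ensemble and a cellular
automaton of atrial tissue that fibrillates through reentry.

Complex systems near a bifurcation display *critical slowing down*, and
with it statistical early warnings (EWs): rising variance, drifting
skewness and kurtosis, lag-1 autocorrelation approaching 1, and power
spectra approaching a power law.  A practical question for anyone hoping
to use EWs on real data — ecosystems, climate, physiology — is whether the
noise that real systems are bathed in hides these signals or sharpens
them.  `ewdyn` lets you generate both model systems under controlled
perturbation and measure the full EW battery, reproducing the finding
that external perturbations *enhance* early warnings: the stronger and
more complex the noise, the clearer the warning.

It is aimed at researchers in complex-systems/theoretical biology who
want a reproducible, seeded, desk-scale laboratory for EW methodology.

## The models

**Kuramoto ensemble.** N phase oscillators with natural frequencies
drawn from g(ω), coupled through the mean field, with white frequency
noise of intensity σ²:

    dθ_i = [ω_i + K r sin(ψ − θ_i)] dt + σ dW_i,
    r e^{iψ} = (1/N) Σ_j e^{iθ_j}.

The order parameter r jumps from ≈0 to ≈1 at a critical coupling K_C
(≈1.6 for standard Gaussian frequencies); noise shifts the transition to
larger K.  The EW analysis is done on the r(t) time series across
coupling sweeps at several noise amplitudes.

**Atrial automaton.** A 200×200 cylindrical lattice of tissue blocks
(rest / excited / τ-step refractory countdown).  Horizontal neighbours
always conduct; vertical links exist with probability ν; 5% of blocks
fail to excite with probability 5% per opportunity.  Pacemaker pulses
excite the left boundary on fixed, uniformly jittered, Gaussian, or
RR-interval-derived schedules (a synthetic 1/f-correlated RR surrogate is
included).  Below a critical connectivity ν_C ≈ 0.14, conduction failure
plus sparse vertical links lets wavefronts re-enter behind their
refractory tails — self-sustained fibrillation — and the region-averaged
excitation intensity changes abruptly across ν_C.

**Measurement layer.** `moments()`, `lag1_autocorrelation()`,
`ensemble_ew()`, Welch `psd()` with `powerlaw_fit()` (slope, log-log
curvature, R²), critical-point estimators (`estimate_cp()`: variance
peak, or maximum mean slope) and CP alignment across perturbation levels
(`align_to_cp()`).  `run_experiment()` orchestrates full sweeps with
deterministic per-cell seeds and CSV/JSON outputs;
`inst/cli/ewdyn.R` is a thin command-line wrapper.

## Worked example

Sweep the coupling across the synchronization transition and summarize
the early warnings:

```r
library(ewdyn)
cfg <- kuramoto_config(n_oscillators = 1000, coupling = 0, noise_sigma = 0,
                       n_steps = 16000, transient_steps = 8000, seed = 101)
sw <- sweep_coupling(cfg, seq(1.2, 2.2, by = 0.1), n_runs = 5)
ss <- summarize_sweep(sw, cp_method = "max_variance")
ss
#> sweep summary: 11 control values in [1.2, 2.2], CP = 1.7 (max_variance)
round(subset(ss$summaries, control_value %in% c(1.2, 1.5, 1.6, 1.7, 2.0)), 4)
#>     control_value   mean variance skewness excess_kurtosis lag1_ac n_samples
#> 1.2           1.2 0.0622   0.0011   0.6600          0.2217  0.8924       800
#> 1.5           1.5 0.1543   0.0033   0.1855         -0.2684  0.9518       800
#> 1.6           1.6 0.2662   0.0067  -0.0993          0.1353  0.9277       800
#> 1.7           1.7 0.4410   0.0246  -0.6485         -0.5490  0.8865       800
#> 2.0           2.0 0.7298   0.0005  -0.2432         -0.7854  0.7328       800
```

Reading the table: the ensemble variance of r swells by an order of
magnitude approaching the transition and collapses beyond it, locating
the critical coupling at 1.7 on this small, coarse sweep (it sharpens to
1.6 at the default N = 2000 with 10 runs per K); the lag-1
autocorrelation peaks near the transition; the skewness changes sign
across it.  Those are the early warnings.

A fibrillating automaton run and the RR-surrogate round trip:

```r
tr <- run_simulation(atrial_config(nu = 0.08, n_steps = 6000,
                                   warmup_steps = 1000, seed = 7),
                     fixed_schedule(4))
tr
#> intensity trace: 6000 steps (360.0 ms), mean = 0.4632 (nu = 0.08, pacing = fixed)

s <- synthetic_rr_schedule(4096, spectral_beta = 1, seed = 2)
powerlaw_fit(psd(s$intervals_ms, sampling_interval = 1))
#> PSD: 455 bins, f in [0.001099, 0.5] (8 segments of 910)
#>   power-law fit on [0.003297, 0.5]: slope = -1.032, curvature = 0.031, R^2 = 0.8726
```

At ν = 0.08 (below ν_C) the mean intensity sits around 0.46 because
reentrant activity keeps most of the tissue cycling; above ν_C it falls
to ≈0.12, the paced-wave baseline.  The surrogate's fitted spectral
slope recovers the requested 1/f exponent.

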