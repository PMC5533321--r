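---
title: "Early-warning signals in two perturbed models of critical transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Early-warning signals in two perturbed models of critical transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewdyn)
```

Systems that sit near a bifurcation recover ever more slowly from
perturbations — critical slowing down — and that loss of resilience leaves
statistical fingerprints in any observable of the system: rising variance,
changing skewness and kurtosis, lag-1 autocorrelation creeping toward 1,
and a power spectrum that approaches scale invariance.  `ewdyn` implements
two classic model systems in which these early-warning (EW) signals can be
generated and measured under controlled external perturbation, plus the
measurement layer itself.  The scientific question the package is built
around: does external noise obscure early warnings, or sharpen them?

# The two model systems

## Noisy mean-field Kuramoto ensemble

`simulate_kuramoto()` integrates N phase oscillators with natural
frequencies $\omega_i$ drawn from $g(\omega)$, coupled through the mean
field.  Writing the order parameter
$r e^{i\psi} = \frac{1}{N}\sum_j e^{i\theta_j}$, each oscillator obeys

$$d\theta_i = \left[\omega_i + K r \sin(\psi - \theta_i)\right]dt
  + \sigma\, dW_i ,$$

an Euler–Maruyama discretization with an additive white frequency noise of
intensity $\sigma^2$ (the per-step phase kick has standard deviation
$\sigma\sqrt{dt}$, so the dynamics do not depend on the choice of $dt$
beyond the usual first-order discretization bias).  We chose this noise
convention deliberately: a noise term whose per-step amplitude is fixed in
units of frequency and multiplied by $dt$ would produce an effective phase
diffusion proportional to $dt$ itself, making "noise amplitude
$\sigma = 1$" mean almost nothing at a small time step — the
synchronization curve would shift by less than one grid step of any
reasonable coupling sweep.  With the diffusion convention, $\sigma$ is a
physical noise intensity: the incoherent-to-synchronized transition
shifts from $K_C \approx 1.60$ (the deterministic mean-field value
$2/(\pi g(0)) \approx 1.596$ for the standard Gaussian $g$) to roughly
1.8 at $\sigma = 0.5$ and 2.3 at $\sigma = 1$, which is the qualitative
behaviour reported for this model class.

Defaults and why:

* `freq_dist`: Gaussian(0, 1).  The Lorentzian option exists because it
  admits the closed-form steady state $r = \sqrt{1 - 2\gamma/K}$ for
  $K > 2\gamma$, which the test suite uses as an analytic oracle
  (`ewdyn` reproduces it within 0.005 at N = 2000).
* `dt = 0.01`, forward Euler–Maruyama.  Higher-order schemes interact
  poorly with per-step noise and buy nothing at this accuracy level.
* Initial phases i.i.d. uniform on $(-\pi, \pi]$ — the incoherent start.
* `transient_steps`: half the run, discarded before any statistic.
* `thin = 50`: r is recorded every 0.5 time units.  At `dt = 0.01` the
  raw per-step series is trivially autocorrelated at every coupling
  (lag-1 AC of order $1 - dt/\tau_c \approx 1$), which would flatten the
  lag-1 EW completely; at a 0.5-unit sampling interval the incoherent
  regime decorrelates within a few samples while the critical slow mode
  does not, which is what makes the lag-1 indicator informative.
* Desk-scale N = 2000 by default.  The variance peak locates the
  transition accurately at this size; single-run times stay below a
  second.

The bulk integrator maintains the unit phasors
$(\cos\theta_i, \sin\theta_i)$ and rotates them by the per-step increment
using a 7th-order polynomial for the increment's sine/cosine (the
increment is $O(dt)$; truncation error is far below the scheme's own
bias), renormalizing every step.  This removes all per-oscillator
trigonometric calls from the hot loop.  The exposed single-step
`kuramoto_step()` uses exact trigonometry; with $\sigma > 0$ it also uses
a different (inversion-based) normal sampler than the bulk kernel's polar
method, so a run and its stepwise composition agree exactly for
$\sigma = 0$ and in distribution otherwise.

## Atrial-tissue cellular automaton

`run_simulation()` drives a cylindrical $L \times L$ lattice
(default 200) of tissue blocks with three states: rest, excited, and a
refractory countdown of $\tau$ steps.  Horizontal neighbours are always
coupled (no wraparound at the first/last column); vertical links exist
independently with probability $\nu$, cyclically in the vertical
direction.  A fraction $\delta$ of blocks is defective and fails to
excite with probability $\epsilon$ at each opportunity (one Bernoulli
draw per block per step in which it has an excited connected neighbour).
A pacemaker pulse excites every resting first-column block on a
configurable pulse-to-pulse schedule.

Reentry — the automaton's analogue of fibrillation — arises exactly as in
the excitable-media literature: a conduction failure blocks a wavefront
in one row, the wave crosses on a parallel row, descends through a
vertical link beyond the block, runs backwards through recovered tissue
and closes a self-sustaining loop whenever the circuit is longer than the
refractory period.  The test suite contains a 12x12 fixture that
reproduces this mechanism deterministically under a fixed seed, and its
control: with $\epsilon = 0$ a single pulse always dies out, at any
$\nu$.

Numerical constants: $\tau = 50$ steps and 0.06 ms per step, so the
reference 13.2 ms pacing interval is exactly 220 steps; $\delta =
\epsilon = 0.05$.  The signal is the mean of a linear grey-scale
intensity map (excited $= 1$, refractory counter $c \mapsto c/\tau$,
rest $= 0$) over a 200 x 50 region — all rows by the central quarter of
columns, spanning the full cylinder circumference in the middle of the
conduction path (the orientation of the published region is ambiguous;
this reading covers the circumference).  Each run records 20000 steps
after a 2000-step warm-up (about nine pacing cycles), long enough for
induced reentry to dominate the time average when it occurs.

The run kernel is event-driven: it tracks each cell's last excitation
step instead of scanning the lattice, so cost scales with wavefront size,
and maintains the region intensity incrementally through circular
difference buffers (each excitation contributes a fixed ramp).  Failure
draws are sorted into ascending cell order first, which makes the fast
kernel draw-for-draw identical to iterating the exposed synchronous
`step_ca()` — an equality the tests assert exactly.

## Pacing schedules

Four regimes mirror the pulse-interval protocols the models are studied
under: fixed 13.2 ms; uniform 13.2 ± 1.3 ms; Gaussian(13.2, 1.3) ms
(floored at 1 ms); and RR-interval-derived pacing.  For the last,
`read_rr_file()` ingests plain-text beat-interval recordings (one value
per line, seconds or milliseconds auto-detected, `#` comments) and
rescales them affinely onto the model's pacing scale — by default
preserving the recording's coefficient of variation, optionally forcing
the 1.3 ms standard deviation of the synthetic regimes.  Since real
recordings cannot ship with the package, `synthetic_rr_schedule()`
generates a surrogate with the statistical signature that makes real RR
series "complex": Gaussian amplitudes with spectral power
$\propto f^{-\beta}$ (default $\beta = 1$), random phases, inverse
transform, then rescaling to the target mean and CV.  The
generator/estimator round trip (`psd()` + `powerlaw_fit()` recovering
$-\beta$ within 0.2) is part of the acceptance suite.  What the
surrogate does not emulate: nonstationarity, respiratory peaks, or any
beat-morphology information — conclusions drawn from it speak to spectral
complexity of the pacing only.

# The measurement layer

* `moments()` — mean, unbiased variance, and standardized skewness
  $m_3/m_2^{3/2}$ and excess kurtosis $m_4/m_2^2 - 3$ from divisor-n
  central moments.  A constant series yields `NA` standardized moments
  rather than propagating NaN.
* `lag1_autocorrelation()` — lag-1 autocovariance over variance about the
  full-series mean.
* `ensemble_ew()` — pools an ensemble at one control-parameter value:
  moments over the concatenated samples, lag-1 AC per trace and then
  averaged (a lag product across trace boundaries is meaningless); a
  fully per-run-averaged mode is also available.
* `psd()` — Welch's averaged periodogram (mean-detrended, Hann-tapered
  segments, 8 segments at 50% overlap by default), one-sided, zero
  frequency excluded, density-scaled.  Written directly on `stats::fft`
  and verified against an explicit-DFT oracle in the tests.
* `powerlaw_fit()` — least squares of log power on log frequency inside a
  band: the slope estimates a power-law exponent, the R² measures how
  well a power law describes the band, and the quadratic coefficient of
  a second-order fit measures log-log curvature (near zero when the
  spectrum is power-law-like).  The default band drops the two lowest
  bins; for the paced automaton pass a band below the pacing frequency,
  whose harmonics otherwise dominate.
* `estimate_cp()` — two critical-point estimators: the control value of
  maximum variance (suited to the Kuramoto transition, where the
  variance of r peaks sharply), and the midpoint of the adjacent pair
  with the largest absolute slope of the mean (suited to the automaton's
  abrupt drop in mean intensity).  Ties break toward the smaller control
  value; edge hits carry a boundary flag.
* `align_to_cp()` — translates each sweep's control axis by its CP so
  indicator curves at different perturbation levels can be compared at
  equal distance from their own transition.

`sweep_coupling()`, `sweep_nu()` and `run_experiment()` derive every
(parameter, run) cell's seed deterministically from a base seed
(`derive_seed()`), so any sweep or full experiment is exactly
reproducible; `run_experiment()` writes the stacked summaries, their
CP-aligned copies and a provenance block (config echo, seeds, package
version, wall time).

# Problem sizes and what the checks do and do not show

All shipped checks run at desk scale, chosen so the full suite completes
on one CPU in well under half an hour: Kuramoto sweeps use N = 2000
(10 runs per coupling, 40000 steps per run) for the unperturbed sweep
and N = 1000 (5 runs, 16000 steps) for the three-noise-level comparison;
the automaton sweep covers $\nu = 0.02\ldots0.25$ in steps of 0.01 with
20 runs per value at the full 200 x 200 lattice.  The reference results
these conditions reproduce:

* time-averaged $r \approx 0.03$ at $K = 0.5$ and $\approx 0.95$ at
  $K = 3.5$ (the incoherent and synchronized limits);
* variance-peak critical coupling 1.60 against the mean-field 1.596;
* peak ensemble lag-1 autocorrelation above 0.95, located at the
  variance-peak $K_C$;
* strictly increasing $K_C$ with noise amplitude $\sigma \in
  \{0, 0.5, 1\}$, slower normalized post-CP variance decay and lower
  off-CP lag-1 AC at stronger noise (the perturbation-enhancement
  effect);
* an abrupt drop of mean excitation intensity at $\nu \approx
  0.125$–0.145, matching the known critical connectivity 0.14.

One spectral property does **not** survive this scale reduction: the
log-log curvature of the r(t) spectrum is not minimized at the critical
coupling when compared against couplings well below it.  At desk-scale N
the critical spectrum is a two-component mixture — the slow critical mode
(knee near $5\times10^{-3}$ cycles per time unit) riding on finite-size
dephasing noise (knee near 0.16) — and the crossover between them bends
the spectrum over any fit band, while the below-transition spectrum is a
single Lorentzian that a power law fits more comfortably.  The clean
critical power law requires the critical mode to dominate, and its power
advantage grows only as $\sqrt{N}$; we verified the ordering does not
flip for N up to 20000, trace lengths to $2\times10^5$ steps, eight fit
bands and log-weighted fits.  The corresponding acceptance test asserts
the property as stated and is expected to fail at desk scale; the two
neighbouring facts that do hold robustly are also asserted: curvature
reappears above the transition, and the goodness of fit (R²) of the
power-law model peaks exactly at the critical coupling.

The synthetic-data generators define the study conditions; they are not
tuning knobs.  Sample sizes, noise levels, pacing statistics and the
automaton's constants are fixed at the values stated here, and the
acceptance thresholds are the published values with their stated
tolerances.

# Known limitations

* The automaton is a conduction model only — no action-potential or
  ionic-current realism, no ECG morphology; its intensity signal is an
  abstract analogue of an atrial electrogram.
* Mean-field coupling only; general coupling matrices and network
  topologies are out of scope.
* The EW layer measures stationary ensembles at fixed control-parameter
  values; rolling-window detection on single nonstationary records, and
  significance testing of EW trends, are deliberately not provided.
* RR-derived pacing rescales recorded intervals onto a 13.2 ms model
  scale; it reproduces the relative variability structure, not
  physiological time.
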