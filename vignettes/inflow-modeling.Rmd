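---
title: "Modeling and inverting fMRI inflow signals for CSF flow velocimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and inverting fMRI inflow signals for CSF flow velocimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfinflow)
```

## The physical model

Fast gradient-echo fMRI saturates stationary tissue: spins that are excited
every TR settle to a steady-state magnetization well below equilibrium.
Fluid flowing into the imaging volume carries unsaturated spins whose signal
is bright by comparison — the time-of-flight *inflow effect*. The signal of
a flowing spin ensemble depends on its whole excitation history: how many
pulses `n` it has received and the intervals between them. For perfectly
spoiled acquisitions the longitudinal magnetization just before the n-th
pulse follows the recursion

    Mz <- Mz * cos(theta) * E + Meq * (1 - E),    E = exp(-dt / T1),

starting from equilibrium, and the measured transverse signal is
`Mz * sin(theta) * exp(-TE / T2)`. `transverse_signal()` evaluates the
closed form of this recursion for an arbitrary interval sequence;
`steady_state_signal()` is its fixed point for constant intervals, and the
*inflow contrast* is their difference. Because the recursion itself is the
unambiguous definition, the package keeps both routes: the closed form is
the reference implementation, and the O(1)-per-pulse recursion drives the
simulator; their agreement over random histories (to 1e-10 and better) is
asserted in the test suite.

Variable inter-pulse intervals are the essential generalization for
bidirectional flow: a spin that exits below the first slice during outflow
stops being excited and relaxes back toward equilibrium for seconds at a
time, so its signal on re-entry reflects the outflow history, not just TR.

## Kinematics and anatomy

Spin ensembles are point particles moving along the slice normal with

    dx/dt = F(x) V(t),     F(x) = A_slc1 / A(x),

where `V(t)` is the entrance velocity at the bottom of the first imaging
slice and `A(x)` the cross-sectional area of the flow compartment at depth
`x` (`x = 0` at the bottom of slice 1). `F(x)` encodes incompressible plug
flow: where the compartment is twice as wide, the fluid moves half as fast.
Outside the tabulated anatomy (and wherever the tabulated area falls below
it) the area is clamped to a floor of 0.05 cm², so the field is defined
everywhere.

This equation is separable. Writing `s(x) = \int_0^x A(u)/A_slc1 du` (a
volume coordinate: equal increments of `s` contain equal fluid volume),
every trajectory satisfies `s(x(t)) = s(x0) + \int_0^t V(\tau) d\tau`. The
default integrator therefore composes two tabulated monotone maps instead
of stepping an ODE solver: it is exact up to quadrature of the tabulated
area curve and the sampled waveform, conserves mass by construction, and is
orders of magnitude faster than generic adaptive integration, which matters
because the training-data generator runs thousands of simulations. A
conventional adaptive Runge–Kutta route (`method = "rk"`, deSolve) is kept
as an independent numerical cross-check; the test suite verifies agreement
against it and against closed-form trajectories for constant, sinusoidal,
and linearly-widening-tube flows.

Inside the simulator core, ensembles are seeded uniformly in `s` rather
than in `x`, i.e. each ensemble represents the same volume of fluid. For a
straight tube this is identical to uniform spacing in `x`; for a varying
compartment it makes the per-slice average a volume-weighted (hence
mass-consistent) quantity and lets the core locate the ensembles inside any
slice in O(1), since a slice is a contiguous index range in the uniform
`s`-grid. Seeding margins are derived from the waveform's cumulative
displacement range, so slices stay populated for the whole run; the core
errors out if a sampled slice ever empties.

## The acquisition schedule

The multislice protocol determines when each slice is excited.
`build_schedule()` spreads the `n_slices / MB` multiband groups uniformly
over one TR; group `k` excites slices `{k, k + n/MB, k + 2n/MB, ...}` (the
standard arithmetic-stride SMS convention). The within-TR group order is
configurable ("interleaved" by default, "sequential", or an explicit
permutation) because published protocols rarely state it while the bottom
three slices — the ones carrying the flow signal — can fall in different
groups; simulations record the order used. Excitation is instantaneous and
the slice profile is a step function spanning each 0.25 cm slice, so a spin
at position `x` receives a pulse iff `kW <= x < (k+1)W` for an excited
slice `k` (half-open intervals avoid double counting at boundaries).

Per-slice samples are taken at each slice's own excitation instant, so the
slice time series are mutually offset within the TR;
`resample_common_grid()` interpolates them to a shared grid when needed.
The default output is the inflow contrast (steady-state subtracted); raw
transverse signal is available for diagnostics. Comparisons against
measured data discard the first 40 TR cycles, mirroring the standard
trimming of the initial transient in measured series, and are normalized to
the mean of the top 5% of first-slice samples.

## Emergent signal properties the package reproduces

*Saturation.* At the critical velocity `V_crit = W / TR` fluid traverses
one slice per TR, so every spin sampled in slice 1 has received exactly
one pulse: the first-slice signal equals the fresh-spin contrast and stops
varying with velocity. Deeper slices saturate at integer multiples of
`V_crit`.

*Slice decay.* For sub-critical constant flow, deeper slices accumulate
more pulses and the per-slice amplitudes fall off approximately
exponentially; `decay_rate()` fits `S(x) = exp(-D x)` on the log scale
(slice index 0-based, normalized to slice 1). `run_sweep()` maps D against
`V / V_crit` over grids of velocity, TR, and slice thickness. D decreases
steeply with `V / V_crit` below saturation; beyond it the leading slices
pin at the fresh-spin contrast and the fitted exponent levels off and is no
longer a velocity readout, so the monotonicity assertions in the tests are
restricted to the sub-critical branch (the pooled grid still shows a strong
negative rank correlation). Note that the first-slice *amplitude* is not
monotone in TR below saturation — shorter TRs also lower the per-spin
signal and the subtraction baseline — whereas on the saturated branch it is
exactly the fresh-spin contrast and strictly decreases with TR.

*Frequency attenuation.* Oscillatory flow at frequency `f` displaces fluid
by `~V/(2*pi*f)`; fast oscillations therefore move little fluid between
excitations and imprint weakly on the signal.
`frequency_attenuation_experiment()` measures this two ways: a
per-frequency sweep of single-tone simulations at equal amplitude, whose
first-slice response falls strictly with frequency, and one joint
six-equal-tone input whose input and output PSDs are returned for display.
The two differ for a structural reason worth knowing: the inflow mapping
is nonlinear (its response to bidirectional flow has a rectification-like
even-order component that does not vanish at small amplitude), and because
the canonical six tones are harmonically related, intermodulation products
of the strong low-frequency responses land exactly on the upper driving
frequencies — the joint-input PSD peaks drop steeply but rise again
slightly at the top of the band, at every amplitude and phase choice
tested. The monotone attenuation statement is therefore asserted on the
single-tone transfer, which is also how the effect is confirmed
experimentally (separate pump runs per frequency). The default protocol
uses TR = 0.2 s: the six-tone input extends to 1.2 Hz, which cannot be
resolved by a 0.504 s TR (slice-sampling Nyquist 0.992 Hz), so a short-TR
protocol is the only way to evaluate all six frequencies on the slice
grid.

*Outflow memory.* Spins pushed below the first slice during outflow stop
receiving pulses and relax toward equilibrium, so the signal they produce
on re-entry grows with the time they spent outside.
`outflow_memory_experiment()` quantifies this by preceding a fixed inflow
pulse with outflow excursions of equal displacement but different duration.
The zero-flow-preceded control is reported as well; it is an upper bound,
not a baseline to beat, because with no outflow the same inflow draws
never-excited fluid at the maximum possible contrast — re-entering fluid
can approach but not exceed it.

*Anatomy.* With the same entrance waveform, a compartment that widens above
the first slice slows the fluid down, increases pulse accumulation, and
steepens the slice decay; a narrowing compartment does the opposite. The
acceptance tests assert this ordering on linear tapers.

## The stochastic training generator

The inverse model is trained entirely on simulations. Each sample draws a
velocity `V(t) = V0 + sum_i V_i cos(2 pi f_i (t - t_i))` over 100
frequencies (0.01–1.00 Hz, 0.01 Hz spacing), with per-frequency amplitude
bounds built from three Gaussian spectral components — slow hemodynamic
(center 0.035–0.065 Hz, width 0.015 Hz, amplitude 0–0.1 cm/s), respiratory
(center 0.1–0.3 Hz, width 0.002 Hz, amplitude 0–1 cm/s, harmonics at 2x
and 3x the center with weights 1/3 and 1/6), and cardiac (0.8–1.0 Hz,
width 0.0075 Hz, amplitude 0–0.2 cm/s). The bounds are
`B_U = 1.4 (g_slow + g_resp + g_card) + 0.01` and `B_L = 0.6 (...)`;
amplitudes are uniform between them, time shifts uniform over each period,
and the offset `V0` uniform in ±0.1 cm/s. A quarter of human-mode draws
force the respiratory center to 0.167 Hz, the paced-breathing rate used in
validation experiments; the forcing is applied within human mode, after
the phantom split. A quarter of all samples are "phantom mode": a single
Gaussian component (center 0.05, 0.1, or 0.2 Hz; width 0.006 Hz; amplitude
0–1.2 cm/s), `V0 = 0` (pumps produce purely bidirectional flow), and a
straight tube.

Human-mode anatomies come from `synthetic_ventricle_curve()`: a Gaussian
bump `A_min + (A_peak - A_min) exp(-(x - x_peak)^2 / 2 sigma^2)` with
`A_min ~ U(0.1, 0.4)` cm², `A_peak ~ U(0.8, 2.0)` cm², `sigma ~ U(0.5,
1.5)` cm over an 8 cm span. These are synthetic stand-ins that emulate the
scale and unimodal shape of segmented fourth-ventricle area–depth curves;
they are not measured anatomies, so agreement on them demonstrates internal
consistency of the forward–inverse pair, not fidelity to any individual
brain. The depth origin is shifted uniformly within ±1 cm of the widest
point (covering realistic slice placements) and areas are scaled by
U(0.8, 1.2) — which cancels exactly in `F(x)` but changes the network's
area input channel.

Each sample simulates 240 TR cycles at TR 0.504 s, discards the first 40,
and keeps 200 points (~101 s) for three slices. The pre-noise signal set is
rescaled so its maximum is 1 (human) or 0.25 (phantom) — matching how
measured inputs are amplitude-normalized — then Gaussian noise with
standard deviation uniform in [0.01, 0.1] is added and each channel is
demeaned. The target is the input velocity resampled to 1,000 points over
the retained window. What the generator does *not* emulate: scanner noise
coloration, motion, BOLD contamination, partial-volume mixing, and
non-plug flow profiles; performance on these samples is therefore an upper
bound on real-data performance.

## The inverse network

The network maps 5 channels x 200 samples (three demeaned inflow slices,
areas, positions) to a 1,000-point velocity series: three 1D convolutions
with increasing channel widths, three transpose convolutions with
decreasing widths (kernel 3, padding 1, stride 1 throughout — with unit
stride and symmetric padding a transpose convolution is length-preserving
and is realized as a convolution with its own weights), batch normalization
and ReLU after every convolution, then a flatten and two fully connected
layers. The published architecture does not fix the channel widths or where
the 200-to-1,000 upsampling happens; here the widths are configurable
(`network_config()`), defaulting to 16/32/64 encoding and 32/16/8 decoding
with a 2,000-unit hidden layer, and the upsampling lives in the fully
connected head. Training uses Adam (learning rate 0.001), batch 16, MSE
loss, and a 10% held-out split by sample index, all seeded.

Because no deep-learning framework is available to R in this environment
and the physics-to-network coupling is the point of the package, the
forward pass, backpropagation, batch-norm statistics, and Adam are
implemented in the package itself (R matrix algebra over im2col views, with
small compiled kernels for the column transforms and the optimizer update).
Backpropagation is verified against central-difference numerical gradients
in the test suite. One numerical choice matters: the output head is
initialized with small weights (sd 0.01) so the regression starts near the
zero predictor. He-scaled output weights occasionally produced large early
errors whose Adam updates drove the preceding ReLU layer completely dead —
an absorbing state from which training cannot recover.

Problem sizes: the package's own validation trains on 4,200 generated
samples for 30 epochs with widths 8/16/32, 16/8/4, and a 1,000-unit hidden
layer. Under this configuration the held-out per-timepoint MSE reaches
~0.035 (cm/s)² and the median aligned mean-absolute velocity error on 200
held-out samples is ~0.08 cm/s, with predicted-versus-true amplitude
correlation above 0.9. The full-scale configuration (45,000 samples, 120
epochs, default widths) is exposed through the same functions.

`evaluate_prediction()` mirrors how predictions are scored against
separately-acquired reference runs: both series are low-pass filtered below
0.5 Hz (zero-phase fifth-order Butterworth — zero-phase so that the
alignment step is not biased by filter delay), shifted to the
cross-correlation maximum to absorb phase offsets between runs, and
compared by mean absolute difference. `relative_bandpower()` reports the
fraction of spectral power in the 0.14–0.19 Hz paced-breathing band.

## Measured-data preprocessing

For measured series the package provides the standard chain:
`pv_scale()` applies the anatomy-based partial-volume scaling
`m = T1Wvox (T1Wtiss/T1Wcsf - 1) / (T1Wtiss - T1Wcsf)` (pure-CSF voxels are
unscaled; the more tissue, the larger the scale-up); `preprocess_fmri()`
trims the first 40 samples, subtracts the mean of the lowest-decile values
(read as the lowest signed values), and optionally low-pass filters below
0.5 Hz — the filter is skipped for network inputs; `phase_to_velocity()`
subtracts the stationary-tissue offset phase and scales by `VENC / pi` (the
convention is isolated in this one function); `cycle_average()` upsamples
by 4, finds peaks with minimum separation `period - 1 s` and prominence
0.1, and averages inter-peak segments; `spectral_density()` is a Welch
estimator (Hann window, 50% overlap, density scaling, checked against
Parseval); `power_law_fit()` fits `log PSD ~ log f` on a user-chosen band —
the band is a required argument because no canonical choice exists;
`area_from_labels()` converts a labeled anatomical volume to an area–depth
curve with per-slice intensity scaling by the slice minimum. Registration,
segmentation, bias correction, and motion statistics are upstream tools'
territory; their outputs enter as arrays or index lists.

## Numerical choices and degenerate inputs

Area interpolation is linear with constant (floor) extrapolation; the
`s`-map is tabulated at 0.002 cm. Velocity waveforms must be on uniform
grids; their cumulative integral uses the trapezoid rule, so waveform
sampling (default 0.01–0.02 s in the experiment wrappers) bounds trajectory
accuracy. Slice membership ties at event instants are resolved by the
half-open interval convention. Empty slices raise errors rather than
returning NaN means. Inflow contrast can be slightly negative for histories
with intervals shorter than TR; values are returned unclipped. The
`decay_rate()` fit requires strictly positive amplitudes and pins the
intercept at the normalized first slice. Peak detection uses the standard
topographic prominence definition; peak-locked averaging consequently
quantizes cycle phase to the upsampled grid, which bounds how precisely two
recordings of the same process can agree (documented in the tests).

## Known limitations

Plug flow only (no parabolic or secondary flow components); 1D motion along
the slice normal; ideal step slice profiles and instantaneous pulses;
perfect spoiling with a single T2 constant; no k-space, readout, or image
noise modeling; the network is specific to the protocol it was trained on.
The within-TR slice order of the reference EPI protocol is not published;
results that depend on the relative offsets of the bottom three slices may
vary weakly with it, which is why the order is explicit configuration.
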