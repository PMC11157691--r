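---
title: "Real-time homogeneous field correction for OPM arrays: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Real-time homogeneous field correction for OPM arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the interference model, the closed-loop plant, what the synthetic scenarios
do and do not emulate, and the numerical choices that were genuinely open.

## 1. The interference model

Zero-field OPMs clip near ±1.5 nT and lose gain well before that, so the
background field across a wearable array must be held near zero while the
wearer moves. The key observation exploited here is that the environmental
field varies smoothly in space: across a ~20 cm rigid sensor array it is
well approximated by the gradient of a low-order regular solid harmonic
expansion. At order 1 that is simply a spatially homogeneous field
`B = [Bx, By, Bz]`, and channel `i` with unit orientation `ρᵢ` sees
`yᵢ = B·ρᵢ`, i.e. `Y = N B` with `N` the stacked orientation matrix. Three
parameters then describe the interference over the whole array at one
instant, no matter how many channels there are.

`fit_field_model()` estimates `B` by least squares, `B̂ = N⁺Y`; the
pseudo-inverse is computed by SVD with a relative singular-value cutoff of
`1e-10 · σmax`, and directions below the cutoff are dropped and counted
(`hfc_projector()$dropped`) rather than inverted, so a degenerate geometry
(e.g. near-coplanar orientations) degrades loudly instead of amplifying
noise. `build_basis(order = 2)` appends the five independent linear
gradient terms, taken as the gradients of the degree-2 harmonic polynomials
`xy, xz, yz, x² − y², 2z² − x² − y²` — an explicit Cartesian choice of the
traceless-symmetric gradient basis, stated here because several equivalent
parameterisations exist.

Because recording channels and feedback coils are rigid with respect to one
another (and on these sensors the coils share the recording-channel
orientations), the feedback projector `M N⁺` is a constant matrix in the
array frame: participant movement changes the fitted coefficients, not the
projector. `apply_hfc_offline()` uses the complementary projector
`I − N N⁺` for offline denoising, and `correct_lead_fields()` applies the
same matrix to forward-model lead fields — a consistency requirement of any
projector-based cleaning.

The saturation question at fit time is handled by exclusion, not
imputation: clipped samples do not represent the field, so the caller drops
those rows of `N` and `Y`. The real-time controller, however, fits to all
channels including any momentarily clipped ones (the simplest reading of
how the original system behaved); a clipped chunk mean underestimates the
field and the loop catches up on subsequent ticks.

## 2. The closed loop

The simulated plant follows the real implementation closely:

* **Chunking.** The 6 kHz stream is read in 60-sample (10 ms) chunks and
  each chunk is averaged before fitting. Averaging n samples is a
  moving-average low-pass; `moving_average_response(60, 6000)` has its
  −3 dB corner at 44 Hz, which bounds the aliasing entering the model.
* **Control law.** Each tick adds the latest chunk mean to the previously
  applied (intended) feedback to estimate `u`, the field with no feedback,
  then projects `M N⁺ u`. Using the *intended* rather than the actual coil
  field is deliberate: the real controller cannot observe cross-talk.
* **Output filter.** The projected feedback passes through a 4th-order
  Butterworth low-pass at 1 Hz, implemented as two transposed
  direct-form-II biquads stepped once per chunk (100 Hz). The filter runs
  at the chunk rate because the model output only exists once per chunk;
  an option (`filter_input`) additionally filters the input. Pole pairs
  are assigned to sections by proximity with the low-Q section first —
  section ordering changes internal state trajectories, not the output,
  and is documented for reproducibility. The group delay of this filter at
  drift frequencies (~0.4 s near DC) is the dominant term in the loop's
  effective latency and the main reason feedback hurts above ~1 Hz.
* **Quantization.** Coil DACs are 16-bit; the least-significant bit is
  1.8 pT (radial/Y) and 3.1 pT (tangential/Z). `quantize()` rounds
  half-away-from-zero and clips at ±2¹⁵·LSB. Exercised over many steps the
  RMS error is LSB/√12: 0.520 and 0.895 pT rms respectively.
* **Timing.** Commands are issued every 10 ms, Y axes first and Z axes
  5 ms later (the serial link can address one axis per 5 ms). The default
  lag from chunk end to command effect is 31 ms, so chunk accumulation
  plus processing totals ≈ 41 ms; whether the measured 41 ms already
  contained the 10 ms accumulation is not knowable from the outside, so
  both terms are separate configuration fields with this documented
  default. Uniform jitter up to 3 ms and a 15 ms overrun penalty with
  probability 0.19 model the serial link. Commands act as zero-order
  holds, matching DAC behaviour.
* **Sensors.** `y = G(e·ρ + B_neural) + noise`, hard-clipped at ±1.5 nT.
  The default noise floor is 15 fT/√Hz. Gain is linear by default with a
  hook for a field-dependent gain function; cross-axis projection error is
  intentionally not modelled. 3% of a coil's field couples into the
  nearest neighbouring sensor's same-axis channel. On-sensor nulling at
  the start of a run is modelled as subtracting each channel's t = 0
  field. The unmeasured laser (X) axis is neither recorded nor driven, but
  the full field vector at the array origin is tracked for diagnostics
  (`true_field_center`).

## 3. The synthetic scenarios

The generator replaces the shielded room, the walking participant, the
motion-capture system and the auditory paradigm:

* **Room field** (`room_field_spec()`): `B(r,t) = offset + G·r + d(t)` over
  a 3 × 4 m footprint centred at the origin. Defaults give ≈1 nT at the
  centre, <2 nT within 0.5 m, and ≈3.6 nT at the front wall — the regime in
  which an uncorrected walking recording saturates outside the central
  half-metre. The drift `d(t)` is homogeneous; the default is a random walk
  band-limited below 0.5 Hz with 200 pT rms per component. The true drift
  spectrum of a shielded room is only known here through its qualitative
  shape (power concentrated at very low frequency), so these drift
  parameters are free, documented choices — they were not calibrated
  against any recording.
* **Walking** (`make_walk()`): a periodic spline through a rounded
  rectangle in the front half of the room at 0.6 m/s, sampled at 120 Hz,
  with yaw following the walking direction. The yaw is a 1.5 s
  moving-average-smoothed version of the path tangent: heads do not snap
  along the instantaneous tangent at corners, and with raw tangent yaw the
  rotation-induced field slew (ω × |B| up to ~3.5 nT/s against the ~0.45 s
  effective loop lag) saturates even corrected channels far more than a
  compliant human walker does. Tracking dropouts are injected near the
  room edges, where occlusion and camera-coverage loss occur in practice.
* **Gap filling** (`fill_gaps()`): gaps under 0.2 s are filled linearly
  and trusted; longer gaps use shape-preserving piecewise-cubic (pchip)
  interpolation and are distrusted by the trial classifier, which forces
  such trials to "outside". Quaternions are nlerp-interpolated and
  renormalised. Boundary gaps are left unfilled and flagged.
* **Stimuli** (`make_stimuli()`): a roving oddball — sets of identical
  tones at one of seven frequencies (500–800 Hz in 50 Hz steps, always
  different from the previous set), set length drawn from the weighted
  distribution over 1–11 tones (2.5% each for 1–2, 2.75% each for 3–4,
  12.5% each for 5–11; the printed weights total 98% and are
  renormalised), 0.5 s inter-stimulus interval with no jitter. Eighty
  deviants yield ≈590 tones per block in expectation.
* **Evoked signal** (`make_neural()`): a fixed bilateral dipolar-like
  spatial pattern times a Gaussian template peaking 100 ms after onset,
  ~100 fT at the best channel. This is plumbing for the evoked pipeline,
  not auditory physiology: it provides a known ground truth for averaging
  and t-statistics.

What passing tests on these scenarios do **not** show: performance under
real MSR drift spectra, vibration, non-rigid arrays, cross-axis projection
errors, gain nonlinearity, or real head dynamics. The scenarios establish
that the algorithmic chain behaves as designed, with the qualitative
signatures in the right places — not that any particular dB figure will be
achieved in a given room.

## 4. Saturation detection and trial handling

Saturation levels vary between sensors, so detection is distributional:
each channel's block is histogrammed by amplitude in 1 pT bins (anchored at
the per-channel minimum; empty interior bins count as zero). If the extreme
5 bins at either end hold **more than** double the count of the adjacent
previous 5 bins, those bins are marked saturated — a tie at exactly double
is not marked. No sample below 1 nT magnitude can be masked (the floor
rule), which suppresses spurious detections when a block is not
approximately Gaussian. Channels occupying fewer than 50 bins are skipped
with a warning rather than guessed at. Any trial (−200…+500 ms around a
tone) containing a masked sample on any channel is rejected;
`classify_trials_by_radius()` crosses this with a 0.5 m-radius cylinder
criterion on the motion track, trusting linearly-filled gaps and forcing
cubic-filled ones to "outside".

## 5. Evaluation statistics

`welch_psd()` uses 20 s segments, Hann window, 50% overlap, mean averaging,
no detrending (so the slowest resolvable bins keep their drift power), and
returns amplitude spectral density (field/√Hz). The median shielding
factor is `mSF(f) = 20·log₁₀(median_ch ASD_off / median_ch ASD_on)` — the
median is taken over channels of each condition's spectrum first, then the
ratio, as the formula is written. On amplitude spectra `20·log₁₀` expresses
field attenuation in dB, the convention of OPM noise-floor plots; a
`db_factor = 10` switch expresses the same ratio as a power quantity. The
uncertainty band propagates the standard error of each median
(`1.2533·sd/√n`, normal approximation) to the dB ratio.

Evoked preprocessing follows the offline chain: downsample to 1 kHz,
band-stops at 50/83/120 Hz (±2 Hz, a width the original description leaves
open), 2 Hz high-pass, 40 Hz low-pass, all 5th-order Butterworth run
forward-backward for zero phase. Epochs are not baseline-corrected by
default — the 2 Hz high-pass already centres them — with pre-stimulus mean
subtraction available. SNR is the square of the maximum |t| over channels
and time in 95–105 ms, so SNR changes are power ratios.

## 6. Problem sizes and numerical tolerances

The simulations in the test suite run at 600–1200 Hz with 10 ms chunks
(6–12-sample chunks) rather than the full 6 kHz: the controller operates at
the 100 Hz chunk rate either way, so loop dynamics, quantization and timing
are identical while arrays stay small; 100–200 s runs with 24–42 channels
characterise spectra down to 0.01–0.05 Hz. Projector identities are checked
to 1e-10, the streaming filter against a naive direct-form oracle to 1e-10,
gap filling against an independent pchip implementation to 1e-9, and
Monte-Carlo quantities (quantizer RMS, stimulus counts) to 2–10%
depending on their sampling noise at the sizes used.

## 7. Known limitations

* Order-1 correction leaves the gradient component of the room field as a
  residual across the array (~0.15 nT over 10 cm at the default gradient);
  order-2 feedback is available but the default mirrors the homogeneous
  system.
* The controller is a pure proportional loop on the model coefficients; no
  integral action, so a constant disturbance settles at the quantization
  floor rather than zero.
* The simulator's linearity (verified by the superposition test) holds
  only with quantization, clipping and noise disabled; the real system is
  mildly nonlinear through all three.
* Cross-talk uses a nearest-neighbour, same-axis approximation with a
  single coefficient; a measured cross-talk matrix can be substituted in
  principle but no interface is exposed for it yet.
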