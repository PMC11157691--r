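# opmloop

Real-time, model-based magnetic field correction for wearable OPM-MEG, as a
desk-scale simulation and evaluation toolkit.

## The problem

Zero-field optically pumped magnetometers (OPMs) only operate in a narrow
field range: their gain degrades as the background field grows and their
output clips hard near ±1.5 nT. Inside a magnetically shielded room the
residual field still varies by a few nT across the walkable space, so a
participant who stands up and walks during an OP-MEG recording drives the
sensors out of range. `opmloop` implements, and lets you study in
simulation, a closed-loop correction scheme for this problem: the
background field across the rigid sensor array is modelled every 10 ms with
low-order regular solid harmonics (homogeneous field correction, HFC), and
the modelled field is cancelled at each sensor using the coils already on
board every OPM.

The package is aimed at people building or evaluating OPM feedback systems:
it contains the projector algebra, the streaming filters, a faithful plant
simulator (quantized 16-bit coil DACs, serial command latency and jitter,
axis staggering, cross-talk, hard clipping), a synthetic stand-in for the
room, the walking participant and the auditory paradigm, the
amplitude-histogram saturation detector with trial rejection, and the
spectral/evoked evaluation statistics.

## The model

At one instant, the interference seen by channel *i* with unit orientation
ρᵢ under a spatially homogeneous background **B** = [Bx, By, Bz] is

    yᵢ = B · ρᵢ          →   Y = N B,   N = [ρ₁ ρ₂ …]ᵀ

so the field estimate is **B̂** = N⁺Y (Moore–Penrose pseudo-inverse) and the
field to feed back at the coils with orientations M is

    DesiredFeedback = M N⁺ Y.

Because the array is rigid, M N⁺ is a constant matrix in the array frame and
is precomputed. The same algebra denoises recordings offline through the
projector I − N N⁺, and an order-2 option appends the five independent
linear field-gradient terms (gradients of the degree-2 harmonic polynomials)
to N. In the closed loop, the controller adds each new 10 ms chunk average
to the previously applied feedback to estimate the uncorrected field *u*,
projects M N⁺ u, low-pass filters the result at 1 Hz (two transposed
direct-form-II biquads at the chunk rate), quantizes per axis to the coil
DAC grid (LSB 1.8 pT radial / 3.1 pT tangential), and schedules the commands
with the measured ~41 ms loop lag, ≤3 ms jitter and occasional 15 ms serial
overruns.

## Worked example

Simulate a stationary 42-channel array in a drifting room field with
feedback on 22 channels, then compute the median shielding factor (mSF)
between the simultaneously recorded feedback-off and feedback-on channel
groups:

```r
library(opmloop)

array <- example_noise_array()            # 21 OPMs, feedback on 11
field <- make_field(
  room_field_spec(drift = list(type = "random_walk", sd = 200e-12,
                               cutoff_hz = 0.5, seed = 7)),
  duration = 100
)
cfg <- loop_config(sample_rate = 1200, chunk_size = 12)  # 10 ms chunks
sim <- simulate_closed_loop(array, field, duration = 100, config = cfg, seed = 3)
sim
#> <sim_result> 42 channels x 120000 samples @ 1200 Hz; feedback ON
#>   saturated samples: 0.00%

on  <- feedback_channels(array)
off <- setdiff(seq_len(n_channels(array)), on)
psd_on  <- welch_psd(recording(sim$recorded$data[on,  ], 1200), segment_s = 20)
psd_off <- welch_psd(recording(sim$recorded$data[off, ], 1200), segment_s = 20)
msf <- median_shielding_factor(psd_off, psd_on)
head(msf[msf$frequency <= 0.25, ], 5)
#>   frequency msf_db se_db
#> 1      0.05  22.62 0.632
#> 2      0.10  12.85 0.528
#> 3      0.15   6.97 0.370
#> 4      0.20   5.10 0.783
#> 5      0.25   2.50 0.689
```

The loop attenuates the slow drift by ~23 dB at 0.05 Hz (positive mSF =
beneficial), while above 1 Hz the quantized, delayed feedback raises the
sensor noise floor (mSF ≈ −10 dB at 1 Hz, ≈ −18 dB at 2–5 Hz) — the
characteristic trade-off of this kind of on-sensor feedback. The walking
scenario (`make_walk`, `make_stimuli`, `make_neural` +
`detect_saturation`/`reject_trials`) shows the complementary benefit:
without feedback roughly two-thirds of auditory trials recorded outside a
0.5 m radius of the room centre contain saturated samples and are lost;
with feedback essentially none are.

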