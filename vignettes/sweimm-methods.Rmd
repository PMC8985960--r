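---
title: "Reflected-wave time-of-flight shear-wave elastometry: model and estimator design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reflected-wave time-of-flight shear-wave elastometry: model and estimator design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweimm)
```

## The measurement and its model

A single focused 20 MHz transducer is mounted on a fixture above a
roughly cubic hydrogel sample (15 mm × 15.4 mm laterally), with its
14 mm focus inside the gel and the four side boundaries at staggered
one-way distances d = 3.0, 6.2, 9.2, 12.0 mm from the focal point. A
2000-cycle tone burst (0.1 ms) delivers an acoustic-radiation-force push;
the transducer then fires 400 pulse-echo A-lines at a 5 kHz PRF. The
shear wave launched at the focus travels laterally, reflects from each
side boundary, and returns to the focal point, where phase-sensitive
Doppler processing sees it as an axial-velocity transient. With the
two-way paths 2d_i known, the four arrival times t_i give

$$\mathrm{SWS} = \frac{1}{4}\sum_{i=1}^{4} \frac{2\,d_i}{t_i},$$

an average of per-path speeds (not total distance over total time — the
distinction matters and is asserted in the tests). All internal units are
mm and ms, so speeds come out in m/s without conversion factors.

Working assumptions: the gel is homogeneous and isotropic at the
millimeter scale (so the axial propagation speed seen in the M-mode data
equals the lateral speed toward the boundaries), the staggered distances
keep the four returns separable in time, and ARF-induced displacements
are micrometer-scale — far below the λ/8 ≈ 9.6 µm Doppler aliasing limit.

## The forward simulator

`simulate_velocity_field()` is an image-source model of the on-axis
(M-mode) observation, not a full elastodynamic solver: the pipeline only
ever sees the beam axis, and the closed-form model keeps every arrival
time exact by construction, which is what a parameter-recovery oracle
needs. The field is a sum of Gaussian packets:

* a **direct push packet** on the locus $t = |z - z_f|/c$;
* **top/bottom-face reflections**, sloped bands from image sources in
  depth. Their default amplitude is 0.15 of the direct packet: a shear
  wave traveling axially is transversely polarized, so its *axial*
  velocity signature on-axis is weak even though the band is conspicuous
  in the 2D plot. (A much larger value would also merge with the first
  side reflection, whose focal-point arrival it trails by only 0.6 mm of
  path in this fixture — physically real interference that the estimator
  has to live with, but not at arbitrary amplitude.)
* **four side-boundary packets** from lateral image sources at 2d_i,
  arriving at $t_i(z) = \sqrt{(2d_i)^2 + (z-z_f)^2}/c$ with amplitude
  $r_i/(2d_i)^{0.5}$ — cylindrical spreading, reflection coefficients
  defaulting to 0.6 for the gel/agarose-buffer walls (both unmeasured in
  practice and exposed as parameters);
* optional distance-proportional packet broadening (a minimal viscosity
  surrogate; no rheological model is fitted), an optional second-bounce
  term for late reverberation, and seeded white noise.

The default packet FWHM of 1.33 ms makes the spatial wavelength about
2 mm at 1.5 m/s, the scale observed for ARF-generated shear waves in
these gels. `simulate_rf_ensemble()` layers pulse-echo physics on top:
~50+ scatterers per resolution cell drawn uniformly in depth, each frame
an A-line of Gaussian-modulated 20 MHz echoes (50% fractional bandwidth),
scatterer depths advanced by integrating the simulated velocity at their
location (1 µm peak inter-frame displacement by default), plus electronic
noise scaled to the RF RMS.

What the simulator deliberately does **not** emulate: resonance of the
small sample, mode conversion, beam-shape effects (the f-number is
metadata only), ARF magnitude calibration, and speckle decorrelation from
lateral or elevational motion. Passing recovery tests on this model
therefore demonstrates the *estimator's* correctness and its noise
robustness, not hardware performance.

## Motion estimation

`demodulate()` mixes each A-line down by the carrier and applies a
zero-phase 4th-order Butterworth low-pass at 0.75 × f0. Forty fast-time
samples are trimmed from each end afterwards: even a zero-phase filter
rings at the window edges, and on real use the ringing masquerades as
large spurious velocities at the extreme depths. `autocorrelation_velocity()`
is the classic lag-one phase estimator: $R(z) = \sum \overline{IQ_n}\,IQ_{n+1}$
over a 1.5-wavelength axial kernel, displacement $= c\,\arg R/(4\pi f_0)$,
velocity = displacement × PRF; motion toward the transducer is positive.
Phase steps at ±π are flagged per sample, never unwrapped — micrometer ARF
displacements should not alias, so aliasing indicates a misconfiguration
that silent unwrapping would mask. The output is thinned to ~0.05 mm
depth spacing; RF-rate rows are redundant after kernel averaging.

## Wave separation and the initial estimate

`directional_filter()` separates up- from down-going waves by masking the
two complementary quadrant pairs of the 2D spectrum, with a raised-cosine
taper 5% of each axis' band wide. Quadrant masking is the minimal linear
directional separator; the two components tile the spectrum, so their
energies sum to the input's away from the tapered DC ridge.

The initial speed comes from the depth–time slope of the down-going
wavefield. Two numerical points matter here:

* **Envelope choice.** Shear packets are low-pass (about one cycle), and
  the Hilbert-transform component of a low-pass packet decays only as
  1/t, so an analytic-signal magnitude leaks every packet's energy into
  its neighbors' windows — on the default grid this biased peak times by
  more than one PRF sample. All detection and centroid timing therefore
  uses the rectified amplitude |v|, smoothed only for peak picking.
* **Taper before the f–k transform.** A packet truncated mid-amplitude at
  the crop boundary is a periodic discontinuity to the DFT and leaks
  ~10% of the strong push packet into the wrong direction component. The
  pipeline tapers the field (10% Tukey in depth, 2 ms in time) before
  filtering and divides the taper back out afterwards (clipped at 0.25) —
  without the unshading, packets peaking inside the ramp have their
  apparent peaks dragged toward the window interior, tilting the slope.

`initial_sws_slope()` is a two-stage robust regression. Single
"dominant packet per row" statistics proved fragile: depending on speed
and depth, a row's largest peak may be the top-surface reflection, the
half-amplitude near-flat side packets, or residual push-packet leakage.
Instead, *every* detectable row envelope peak becomes a (depth, time,
amplitude) point; a deterministic consensus search (every pair of strong
points proposes a line, slopes restricted to 0.25–5 m/s equivalents,
inlier span ≥ 1.2 mm) selects the most collinear, amplitude-weighted
structure; weighted least squares on the inliers' energy centroids
refines the slope, and the speed is |1/slope|. Rows within 0.5 mm of the
focus are excluded — the push packet's apex and the side packets'
hyperbola vertices carry no direction information. In an isotropic
medium the down-going branch of the push packet and the top-surface
reflection share the same axial speed, so whichever dominates, the slope
estimates the SWS. On noise-free fields this lands within ±3% over
0.4–1.8 m/s; it only needs to be good enough to seed the assignment.

## Two-stage wavefront selection

The focal trace averages v(z, t) over ±0.5 mm around the focus. Arrivals
are predicted as $\hat t_i = 2d_i/\hat c$; the trace window adapts to
1.3 × the slowest prediction (rather than a fixed 40 ms) because at
0.4 m/s the fourth arrival lands at 60 ms, well past a fixed window that
would have discarded it, while the 80 ms recording still contains it.
Samples before $\hat t_1/2$ are excluded as push residue.

`detect_candidates()` keeps local envelope maxima with topographic
prominence ≥ 10% of the admissible maximum, each windowed to the 20%
level (capped at ±1.5 ms so packets nominally ~6 ms of two-way path apart
cannot swallow each other), and timed by `time_to_centroid()` — the
energy-weighted centroid $\sum tE/\sum E$ with $E$ the squared envelope,
which is less sensitive than time-to-peak to packet-shape distortion. A
trace whose maximum stands less than 3× above its median envelope is
declared wavefront-free rather than mined for peaks.

Stage 1 assigns each boundary, in ascending-distance order, the
unassigned candidate nearest its prediction. Stage 2 exhaustively
searches the ≤ 3^4 combinations of, per boundary, the three candidates
nearest the stage-1 choice, discards reused or non-ascending sets, and
keeps the combination minimizing the sample variance of the four
per-path speeds (ties broken by proximity to stage 1). Eighty-one
combinations need no heuristics, and the returned variance provably
never exceeds stage 1's. Centroid times are used throughout, so the
final `compute_sws()` is exactly the printed formula applied to the
selected centroids.

Two guards close failure modes observed with speckle-derived fields
rather than hypothesized ones. First, a refined set must contain the
strongest admissible candidate: the nearest boundary returns the largest
reflection under the spreading law, and the only sets that violate this
are self-consistent arrangements of noise — most insidiously a half-speed
alias that pairs every second packet with a noise peak and scores an
excellent variance. Second, if the slope stage fails or its selection is
vetoed, a fallback grid of initial speeds (0.3–2.0 m/s, step 0.1) is
scanned and ranked by the same containment rule then minimum variance;
the result is flagged `fallback_initial`, since a measurement that needed
the fallback deserves a second look.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `one_way_distances` | 3.0, 6.2, 9.2, 12.0 | mm | fixture stagger; sets arrival separation |
| `prf` | 5000 | Hz | slow-time resolution (0.2 ms) |
| `n_frames` | 400 | — | 80 ms recording |
| `center_frequency` | 20e6 | Hz | carrier; λ/8 aliasing bound |
| `rf_sampling_rate` | 100e6 | Hz | conventional choice; never printed on the hardware |
| `compressional_sound_speed` | 1540 | m/s | conventional tissue value; assumption |
| `packet_width` | 1.33 | ms | ≈2 mm wavelength at 1.5 m/s |
| `reflection_coefficients` | 0.6 ×4 | — | free parameters of the walls |
| `spreading_exponent` | 0.5 | — | cylindrical spreading |
| `noise_sigma` | 0.05 | of peak | measurement noise level |
| `crop_halfwidth` | 2 | mm | focus band retained for the trace |
| `trace_halfwidth` | 0.5 | mm | focal averaging half-width |
| `min_prominence` | 0.1 | of max | candidate threshold |
| `k_alternatives` | 3 | — | stage-2 neighborhood |

## Numerical choices and degenerate inputs

Ties in stage-2 variance break toward stage-1 proximity; candidate
windows are half-open interval intersections; the crop window is
half-open in time (40 ms at 5 kHz keeps exactly 200 samples). Division
guards: zero or non-ascending arrival times, zero-speed predictions, and
empty crops all raise classed errors (`sweimm_no_wavefront`,
`sweimm_implausible_speed`, `sweimm_assignment_error`, ...), and the CLI
maps them to a non-zero exit naming the failing stage. A pure-noise field
errors out rather than returning a number.

## Validation design and problem sizes

The test suite checks each stage against an independent oracle — discrete
Hilbert quadrature for envelopes, the phase–displacement identity for
the Kasai estimator, exact DFT modes for the directional filter,
brute-force enumeration for stage 2 — and then closes the loop with
parameter recovery: noise-free fields over 0.4–1.6 m/s recover within
3%; with 10% additive noise, at least 95% of 50 seeded replicates land
within 5%; the full speckle chain (RF synthesis → demodulation → Kasai →
estimation) recovers within 5%. Simulation sizes (400-frame fields,
~1500-scatterer ensembles over a ±3 mm window) were chosen so a full
study runs in seconds on a laptop while keeping ≥50 scatterers per
resolution cell and all arrivals inside the recording.

One spec-level property was corrected during implementation: averaging
cannot reduce the velocity variance of *pure* complex white noise (its
phase is uniform regardless of kernel length), so the kernel-averaging
test drives the estimator with uniform motion plus noise, where the
averaging genuinely helps.

## Known limitations

The isotropy assumption makes the axial initial estimate transferable to
the lateral paths; layered or fibrous samples would break it. The
image-source model omits resonance, so very stiff samples in very small
fixtures (where wavelength approaches sample size) are outside the
validated regime — as are samples without defined boundaries, which the
time-of-flight principle cannot serve at all. Viscous dispersion is only
a packet-broadening surrogate; no phase-velocity spectrum is estimated.
The half-speed-alias guard assumes the nearest boundary's reflection is
the strongest admissible packet, which strong absorption gradients could
violate. Finally, recovery percentages quoted here are properties of the
simulator's study conditions; real-hardware accuracy must be established
against an independent reference instrument.
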