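---
title: "Extended signal-space separation: model, simulations and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended signal-space separation: model, simulations and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megshield)
```

## The problem

MEG measures femtotesla-scale neuromagnetic fields with hundreds of
sensors inside a magnetically shielded room. Even so, residual
environmental interference (power-line infrastructure, traffic, moving
magnetic objects, vibration of the room itself) can exceed brain signals
by orders of magnitude. Two spatial suppression methods are standard:

* **SSS** (signal-space separation) expands the measured field in vector
  spherical harmonics about an origin in the middle of the sensor helmet.
  Because interior and exterior sources produce expansions with different
  radial dependence (`r^-(l+2)` vs `r^(l-1)`), the signal vector can be
  uniquely decomposed as `phi = S_in x_in + S_out x_out`, and dropping the
  exterior part suppresses interference. SSS is general (no prior
  measurement of the interference needed) but needs an accurate forward
  model: calibration errors at the 1% level mix the subspaces and limit
  the shielding factor to order 15; 0.1% calibration brings it to 150-200.
* **SSP** (signal-space projection) measures the dominant interference
  field patterns from an empty-room recording by PCA and projects the data
  onto their orthogonal complement, `P = I - U U'`. It is insensitive to
  calibration but only removes what it has seen, and the orthogonal
  projection distorts brain signals, which must be compensated in source
  modeling.

**eSSS** combines the two: the computational external basis is augmented
with the empty-room principal components and orthogonalized,
`S_out_e = orth([S_out, PC_out])`, and the extended basis
`S_e = [S_in, S_out_e]` is used exactly as in SSS. The empirical columns
absorb precisely the part of the real interference patterns that
calibration and geometry errors keep outside the span of the computational
model, while the decomposition remains an oblique projection that neither
removes nor biases signals in `span(S_in)`. A further extension (eSSS')
adds principal components of band-pass-filtered data to capture
narrow-band artifacts (e.g. mechanical vibration of the room) whose
patterns no external harmonic expansion represents.

## Model components and key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `L_in`, `L_out` | 8, 3 | truncation degrees; 80 + 15 = 95 basis vectors, adequate for SQUID arrays a few cm from the scalp |
| `n_pcs` | 8 | empty-room PCs merged into the basis; homogeneous + first-order-gradient fields occupy 3 + 5 degrees of freedom |
| `mag_scale` | 100 | magnetometer multiplier for joint PC estimation, bringing T and T/m channels to a similar numeric range |
| `mag_scale_length` | 0.0168 m | decomposition-side channel-type scale (magnetometer rows divided by the gradiometer baseline length) |
| `rank_tol` | 1e-8 | relative singular-value cutoff of `orth()`; merged components already inside `span(S_out)` are dropped |
| `sv_tol` | 1e-10 | relative cutoff of the truncated-SVD pseudoinverse used for the moment estimate |
| SSP `k` | 5 per sensor type | classic projector dimension (5 magnetometer + 5 gradiometer directions) |

Orthogonalization and PC merging are carried out in the basis's scaled
channel units, consistent with joint PC estimation; basis columns are
normalized to unit norm before pseudoinversion and the normalization
factors are retained so multipole moments can be mapped back to physical
units. These conventions affect conditioning, never the subspace spans.

## What the synthetic testbench emulates

`build_synthetic_helmet(102)` generates a 306-channel array (102
magnetometers + 204 planar gradiometers on a Fibonacci lattice covering
the spherical cap `z > -0.1 R`, `R = 0.12` m), a deterministic stand-in
for a triple-sensor MEG helmet. Coils are discretized into Gauss
integration points; gradiometers are balanced two-loop differences over a
16.8 mm baseline.

`perturb_calibration()` injects the calibration uncertainty of a real
device: per-channel gain errors, and loop-imbalance errors for the planar
gradiometers (default `sqrt(2) * gain_sd`, the differential of two
independent loop-area errors). The imbalance term is essential: a
perfectly balanced gradiometer is exactly blind to homogeneous fields, so
a gains-only error model cannot reproduce the observed calibration
sensitivity of SSS; with it, the synthetic testbench reproduces the
shielding-factor regimes quoted above (median ~23 at 1% error, ~230 at
0.1% on this array).

The interference presets excite homogeneous fields below 2 Hz (18 + 4 nT)
and first-order gradients near 20 Hz at ~10% relative amplitude, the
dynamic-range regime of magnetometers inside a shielded room. The
"known" scenario reuses the empty-room multipole directions at shifted
frequencies; the "unknown" scenario adds a homogeneous component along a
direction deliberately left out of the empty room. On a cap-shaped array
the `l=1` and `l=2` harmonics of the same azimuthal sector are strongly
collinear in sensor space (over the cap `cos(theta)` never changes sign),
so the whole `sin(phi)` sector — both the `(1,-1)` and the `(2,-1)`
degree of freedom — is excluded from the empty room; otherwise the
"novel" field would be partially known to SSP and eSSS and the scenario
would not test what it claims to.

Sensor noise defaults to 3 fT/sqrt(Hz) (magnetometers) and
3 fT/cm/sqrt(Hz) (gradiometers) with a 10% rank-5 spatially correlated
part — representative SQUID noise figures. Dipole simulations follow the
study protocol: tangential 1000 nAm dipoles at radii 10-70 mm in the
upper hemisphere, one 10 Hz cycle followed by 100 ms of silence per
200 ms trial.

What the generator does **not** emulate: non-spherical helmet geometry
(all sites at one radius on a cap; a real helmet's closest sensors are
nearer the head and cover more solid angle), sensor cross-talk,
head movement, drifting interference sources, and physiological
artifacts. Passing tests therefore demonstrate the algebraic and
statistical behavior of the methods under controlled conditions, not
performance on any particular real device.

## Estimation choices

* **Moments** are estimated by truncated-SVD pseudoinversion rather than
  the normal equations: the joint basis has a condition number of order
  10^3 on this array, where `(S'S)^{-1}S'` loses half the available
  precision.
* **Noise covariance** is estimated from the unaveraged zero-signal trial
  halves with 1e-3 relative diagonal loading, and the whitener is
  restricted to the covariance's numerical rank. Rank-aware whitening is
  essential for processed data: SSS/eSSS output lives in the 80-dimensional
  reconstruction span, and an unrestricted inverse square root would give
  the empty directions enormous weight — exactly where the forward
  model's truncation mismatch lies, which would distort fits of
  superficial sources by centimeters.
* **Dipole fits** search position with a multi-start grid (two coarse
  inner shells plus a finer angular grid at 0.8 of the search radius,
  because superficial-source fields decorrelate over a few centimeters)
  followed by Nelder-Mead refinement from the three best well-separated
  seeds; the moment is solved linearly in whitened space. For
  SSP-processed data the projector is applied to the forward model as
  well, which removes the amplitude bias caused by SSP's signal
  distortion.
* **Band-limited components** for eSSS' are extracted after a zero-phase
  FFT band-pass with exact stopband (0.5 Hz raised-cosine edges). A
  low-order IIR band-pass is not selective enough here: interference
  lines a few Hz outside the band can exceed the artifact by orders of
  magnitude, and any leakage dominates the band PCA.
* **Shielding factors**: the norm-based definition uses the ratio of
  time-averaged magnetometer vector norms over the 2 s window of the
  largest raw swing (ratio of averaged norms, not average of ratios); the
  FFT-based definition takes amplitude peaks within one bin of the target
  frequency so that an internal source at another frequency cannot
  contaminate the estimate.

## Scale of the shipped experiments

The config-driven testbench defaults to desk scale: 30 s empty rooms,
20 s interference runs, 2 dipoles per radius and 50 trials per dipole
(half the full study's trial count); `experiment_config()` exposes every
knob, and the acceptance script runs the depth sweep at the full 10
dipoles per radius. These sizes keep a complete run in minutes while
leaving every qualitative conclusion unchanged.

## Known limitations

* At the deepest simulated radius (10 mm) the dipole amplitude is
  scatter-limited on this array: the field shape of a near-origin dipole
  barely changes with depth, so position and amplitude trade along a
  ridge. A Cramer-Rao computation with the true whitener gives a radial
  position sigma of ~1.5 mm at 50 trials, i.e. an amplitude sigma of
  ~15%, and the fitted scatter matches that bound — the mean absolute
  amplitude error of ~10-15% at 10 mm is an information limit of the
  synthetic geometry (single-radius cap, farthest-sensor distance
  0.12 m), not an estimator defect. Mean localization stays near 2 mm at
  that depth and well below elsewhere. Arrays whose closest sensors are
  nearer the head, or longer recordings, lower both numbers.
* The condition number of the synthetic basis (~2.7e3) is an order of
  magnitude above values reported for real 306-channel geometry; the
  reconstruction-noise amplification it implies is visible as slightly
  elevated magnetometer noise after processing. The eSSS extension
  leaves it essentially unchanged (ratio < 1.1), which is the property
  that matters.
* The spherical-conductor forward model is exact for the simulations
  here but is itself an approximation for real heads; no realistic head
  conductor is included.
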