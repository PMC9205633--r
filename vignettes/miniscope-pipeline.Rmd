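---
title: "Source extraction for single-photon miniscope recordings: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source extraction for single-photon miniscope recordings: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miniscopr)
```

## The problem and the model

Head-mounted single-photon miniature microscopes record wide-field
fluorescence movies in freely behaving animals. The raw video mixes the
calcium-dependent fluorescence of individual neurons with out-of-focus
background, vignetting, sensor noise, and rigid brain motion. The goal of
this package is to recover, from such a movie `Y` (frames x height x
width), the locations and activities of the recorded cells.

The movie is modelled as a constrained non-negative matrix factorization

    Y = A C' + b f' + E

where `A` (pixels x units) holds the non-negative *spatial footprints*,
`C` (frames x units) the non-negative *calcium traces*, `b` and `f` a
rank-one spatial/temporal background term, and `E` the residual. Calcium
dynamics are tied to an autoregressive model: each trace satisfies
`c_t = gamma_1 c_{t-1} + ... + gamma_p c_{t-p} + s_t` with a non-negative
*spike signal* `s = G c`, where `G` is the AR difference operator. `s` is
a deconvolved, continuous proxy for neural activity, not binary firing.

The pipeline has five stages: preprocessing, rigid motion correction,
seed-based initialization, and alternating spatial and temporal CNMF
updates (typically two cycles, with unit merging between but never after
them).

## Preprocessing

* **Vignetting** (`remove_vignette`) — the static illumination profile is
  the per-pixel minimum over time and is subtracted; this keeps the data
  on the raw linear 0–255 scale and is idempotent.
* **Denoising** (`denoise`) — a per-frame median filter removes
  salt-and-pepper sensor noise. The window (px, odd) should be about one
  cell *radius*: large enough to kill single-pixel outliers, small enough
  not to blend neighbouring cells.
* **Background removal** (`remove_background`) — the white top-hat: each
  frame minus its grayscale morphological opening with a flat disc whose
  diameter matches the expected cell diameter. The opening is a size
  filter: structures larger than the disc (out-of-focus haze, residual
  illumination) survive the opening and are subtracted; cell-sized bright
  features remain. The output is non-negative by construction.

A practical note: the grayscale morphology backend clips intensities to
[0, 1], so the package rescales each frame around the opening (morphology
commutes with positive scaling).

## Motion correction

Only rigid translation is estimated (`estimate_motion`), by normalized
cross-correlation template matching over integer shifts, in a
divide-and-conquer scheme: leaf chunks of `chunk_nfm` frames (default 3)
register their frames to the chunk's middle frame; chunks are then merged
three at a time, registering the max projections of the flanking chunks
to the middle one, so registered spans grow in powers of three until they
cover the movie. Because the input is background-subtracted, the
landmarks are the cells themselves; when two chunks happen to contain
disjoint active cells the projection match can be wrong, so each merge is
cross-checked against the shift implied by the frames bordering the two
chunks, and when the two estimates disagree by more than
`fallback_thres` px (default 5) the border-frame estimate wins.

Three numerical choices matter in practice:

* The correlation is evaluated on a fixed interior window of the template
  (margin = search radius), so the compared region is identical for every
  candidate shift and the zero-filled bands left at the borders of
  already-registered frames cannot bias the peak.
* The border-frame ("consecutive") estimate is the per-axis median over
  the frame pairs within two frames of the boundary (six pairs), which
  suppresses single-frame matching noise while estimating the same
  quantity.
* A rigid registration only determines shifts up to one global
  translation (the choice of reference); the estimates are median-centred
  so the correction moves the movie as little as possible. Comparisons
  against an external reference (e.g. simulation ground truth) must first
  remove this gauge; `match_neurons()` does so by template-matching the
  summed footprint images.

Frames that contain no active cells — e.g. the first seconds of a
recording before any cell has fired, after background subtraction — carry
no landmarks, and no algorithm can register them; analyses here drop a
short burn-in when exactness matters.

## Initialization

Candidate cell centres ("seeds") are local maxima of max projections over
rolling windows of frames (`seeds_init`; window 1,000 frames, step 200 by
default), unioned across windows so briefly active cells are not masked.
A pixel qualifies if it is the maximum within a neighbourhood of one cell
diameter and exceeds the projection minimum by `diff_thres` (default 3 on
the 8-bit scale). Seeds are then refined:

* **Peak-to-noise** (`pnr_refine`) — each seed trace is split at
  `noise_freq` (default 1 Hz, chosen so calcium kinetics stay below and
  sensor noise above) into "signal" and "noise"; seeds whose
  peak-to-peak ratio is at or below 1 are discarded. The two filter
  outputs always sum exactly to the input (frequency-domain brick-wall
  partition, `filter_trace`).
* **Normality** (`ks_refine`) — a one-sample Kolmogorov–Smirnov test of
  the z-scored trace against the standard normal; traces that look
  Gaussian (p >= 0.05) contain no transients and are discarded.
* **Merging** (`seeds_merge`) — seeds closer than about one cell radius
  whose low-pass-smoothed traces correlate above 0.8 are collapsed to the
  brightest member.

Footprints are initialized as the cosine similarity between each seed's
trace and its neighbouring pixels (zeroed below 0.5, window of one cell
diameter); traces as the footprint-weighted projection of the movie; the
background footprint/trace as the spatial/temporal means of the cell-free
residual.

## CNMF updates

**Noise map.** Every pixel's noise level `sn(p)` is the standard
deviation of its trace's band above `noise_freq`, rescaled by the band
fraction so white noise of sd `sigma` gives `sn -> sigma`
(`estimate_noise`).

**Spatial update** (`update_spatial`). With traces fixed, each pixel's
weights are re-solved as a non-negative lasso over the units whose
(dilated) footprints reach that pixel:

    minimize  || Y(p,:) - A(p,:) C - b(p) f ||^2 + lambda_p ||A(p,:)||_1
    subject to A, b >= 0,   lambda_p = sparse_penalty * sn(p) * sqrt(T)

The background footprint is one extra, unpenalized component solved
alongside the cells; afterwards `f` is recomputed as the projection of the
cell-free residual onto the new `b`. The noise level sets the scale of the
l1 term; the user multiplier (`sparse_spatial`, default 0.1) balances it,
and the `sqrt(T)` factor keeps the residual and penalty terms commensurate
as recording length grows. Solved by cyclic coordinate descent with
non-negative clipping (convergence at max coefficient change < 1e-5 or
500 sweeps); an all-zero footprint drops its unit.

**Temporal update** (`update_temporal`). The movie (minus background) is
projected onto the footprints and the contribution of overlapping
neighbours subtracted, giving each unit a raw trace `y_ra`
(`project_traces`). Each unit's AR coefficients are estimated from its
autocovariance and its noise sd from the high band; then

    minimize  || y_ra - c - b0 - c0 d ||^2 + lambda ||G c||_1
    subject to c >= 0, G c >= 0, b0, c0 >= 0

with `d` the AR impulse response (the single-spike transient), `b0` a
constitutive baseline, `c0` the decaying contribution of calcium present
before the recording, and `lambda = sparse_temporal * sd_unit * sqrt(T)`
(default multiplier 0.008). The problem is solved by coordinate descent
on the spike parametrization `s = G c` (for a calcium kernel `d >= 0`, so
`c = D s >= 0` is automatic and the two constraint sets coincide). The l1
penalty shrinks amplitudes as a side effect, so a post-hoc scale
`alpha = argmin || y_ra - alpha * fit ||^2` restores them. Units whose
Jaccard footprint overlap is below `jac_thres` (default 0.2) may be
solved concurrently; each unit's problem depends only on the
pre-computed projections, so solving order cannot change results.

**AR estimation** (`estimate_ar_coefs`). The Yule–Walker recursion
`r(k) = sum_j gamma_j r(k-j)` holds at every lag `k >= 1`, and white
measurement noise contributes only to `r(0)`; the coefficients are
therefore solved from the relations at lags `p+1 .. 2p`, which are free
of the noise term. This addresses the same bias a pre-smoothing step
targets, without distorting the autocovariance the estimate rests on (a
sharp low-pass filter changes the autocovariance at all lags and drags
the estimated poles toward the unit circle, which in our experiments
collapsed deconvolution quality). Unstable estimates are shrunk to
spectral radius 0.99.

**Merging and curation.** Between iterations, units sharing at least one
footprint pixel with trace correlation above `unit_merge_corr` (default
0.9) merge to a summed footprint and mean trace (`unit_merge`); this is a
bookkeeping correction outside the model, so it is never applied after
the final temporal update. `apply_unit_labels` applies keep/drop/merge
labels from manual curation without modifying its input.

## The simulator

`simulate_miniscope` generates the reference synthetic recordings with
full ground truth: Gaussian-blob cells (sd 2.5 px, truncated at 4 sigma,
uniform centres with 2-sigma minimum separation), Bernoulli spikes
(0.25 Hz per cell), AR(2) calcium with 0.1 s rise and 1.0 s decay, a
smooth background field (correlation length ~H/8, amplitude 0–20) with
slow ±15% temporal modulation, a static radial vignetting profile (peak
60), rigid motion as a Gaussian-smoothed integer random walk (clipped to
±4 px), and white sensor noise of sd 1, all on the 8-bit 0–255 scale. One
isolated spike peaks at 20 intensity units when `signal_level = 1`; the
`signal_level` parameter scales only the clean cell signal. Frames are
composed on a padded canvas and cropped at the shifted window, so motion
reveals real scene content at the borders, as a moving brain does.

These constants were fixed once so that the simulated regime matches the
published behaviour of this family of pipelines: near-perfect detection
and footprint recovery for signal levels 0.6 and above, temporal
correlation that degrades at 0.2, and deconvolved-spike fidelity that
approaches 1 above signal level 1.

What the simulator does *not* emulate: non-rigid tissue deformation,
photobleaching, overlapping dendrites/axons, correlated (shot) noise,
frame drops, and cell densities high enough to create heavily overlapping
somata. Passing the synthetic checks therefore validates the machinery —
the solvers, the registration, the bookkeeping — not performance on any
particular real preparation.

## Validation metrics

Recovered units are matched to ground truth by optimal one-to-one
centroid assignment (maximum matches within 8 px — about one cell
diameter — then minimum total distance), after removing the global
registration gauge. Reported metrics: detection F1 (harmonic mean of
precision and recall), median Pearson correlation of matched footprints
and traces, and the mean Pearson correlation of spike signals after
5-frame bin-summing (the ground truth is binary, the deconvolved signal
real-valued; binning makes them comparable).

Cross-session registration (`cross_register`) aligns sessions by
template-matching summary images, matches weighted footprint centroids
mutually-nearest within 5 px (exact distance ties discarded), and
resolves multi-session groups transitively, discarding any group whose
member sessions lack a direct pairwise match — a conservative rule that
trades recall for unambiguous identities.

## Problem sizes and determinism

The reference checks run the full pipeline on 128 x 128 px, 3,000-frame,
30-cell recordings (about 100 s at 30 fps) — the same construction as the
published validation, scaled to desk size; solver cross-checks use <= 5
units and <= 200 frames against independent oracles (a generic lasso
solver and a long-run projected-gradient QP). Everything is deterministic
given the configuration and the simulation seed; parallelism and the
execution chunk plan are required not to change results (outputs agree
within 1e-6 across chunkings).

## Known limitations

* Only integer-pixel rigid translation is corrected; rotation, scaling
  and non-rigid deformation are out of scope, as is subpixel alignment.
* Featureless frames (no active cells after background subtraction)
  cannot be registered by any content-based method.
* The rank-one background term cannot express spatially local
  fluctuations that change shape over time; the morphological step must
  remove them first.
* AVI containers are not read; sessions are ingested from multi-page
  TIFF stacks (or from the package's chunked store).
* The spike signal is a deconvolved amplitude, not a firing rate; its
  scale depends on the local background and indicator kinetics.
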