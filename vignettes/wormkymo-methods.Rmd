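---
title: "Methods: curvature kymographs, behavioral states, and ratiometric traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curvature kymographs, behavioral states, and ratiometric traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormkymo)
```

This vignette explains the models and procedures behind wormkymo, the
parameters that matter, the design choices made where the methodology was
genuinely open, and what the synthetic generator does and does not emulate.

## The posture model and the curvature map

A crawling worm is described by its midline: K ordered points from head to
tail at equal arc length (default K = 50; the interval count is a free
choice, and all downstream quantities are reported per body segment so they
are invariant to worm size). The tangent angle of segment *i* is
`θ_i = atan2(Δy_i, Δx_i)`, and the signed curvature at interior junction
*i* is the wrapped difference

> c_i = wrap(θ_{i+1} − θ_i) ∈ (−180°, 180°],

in degrees per body segment, positive for counter-clockwise tangent
rotation (the dorsoventral identity of the two bend directions is not
resolved by a single camera view, so the sign convention is geometric).
Rows of the curvature map are frames; columns are the K − 2 interior
junctions. This telescopes exactly: the row sum equals the net tail-versus-
head tangent rotation, which the tests assert.

The map is smoothed with a 3×3 **mean** filter. A mean (box) filter is the
simplest filter consistent with noise reduction, and its two testable
properties — each interior output is exactly the mean of its 3×3
neighborhood, and constant maps are fixed points — pin the implementation
down. Invalid (omega) frames are masked **before** smoothing; masked
entries are excluded from their neighbors' averages and edge neighborhoods
are renormalized over the available entries, so masking never bleeds into
valid data and smoothing never unmasks. Rendering clips to ±30 degrees per
segment on a diverging blue–white–red scale, draws masked frames white,
and draws black bars above/below the map for forward/backward intervals.

## Midline extraction from video

Each frame is thresholded (Otsu by default), the largest connected
component is kept, and the mask is thinned to a topological skeleton
(Zhang–Suen). The skeleton pixel graph uses m-adjacency — diagonal
neighbors connect only when no orthogonal two-step path exists — which
suppresses the spurious degree-3 staircase edges of 8-connected skeletons.
Spurs shorter than one body width (estimated as twice the maximum of the
distance transform) are pruned. If the pruned skeleton is a simple path
with exactly two endpoints it is accepted; a cycle means the worm touches
itself (`self_contact`), more than two endpoints mean `skeleton_branch`,
and a path shorter than 70% of the running-median body length is
`too_short`. These failures are the operational definition of the omega
pose: when the head touches the body the silhouette stops being a simple
tube, so extraction failure is a detection signal, not an error.

Thinning retracts from the tube tips by roughly the local half-width, so
the accepted path is extended at both ends by a short walk that follows
the ridge of the distance transform (steering ±20° per half-pixel step
toward the locally deepest pixel, which tracks curved tails) to the mask
boundary, then pulls back by the endpoint's medial radius. The path is
smoothed with a 3-pixel moving average and resampled to K points at equal
spacing; a few fixed-point iterations equalize consecutive chord lengths
(plain arc-length placement leaves chords unequal wherever the path
curves). On noiseless synthetic frames the recovered midline lies within
0.2 px of the true one on average and within 1% of the true body length.

**Head/tail identity.** Per-frame orientation is matched to the previous
valid frame by nearest-endpoint distance. Global polarity is set on the
longest run of consistent wave propagation, taken to be forward movement:
the head is the end that leads the net centroid displacement in that run.
Stage-centered recordings have no usable centroid displacement, so
polarity falls back to the mostly-forward assumption (dominant wave
direction = head to tail), applied independently to each contiguous run of
valid frames because endpoint matching cannot be trusted across an omega
gap — the posture reorganizes completely during the turn. The fallback is
flagged `low_confidence`. Time-reversed input would swap forward and
backward and is not recoverable: wave direction plus displacement
determine head identity only up to the forward-dominance assumption.

## Behavioral state segmentation

**Omega turns.** A frame is an omega candidate if extraction failed or if
the minimum distance between midline points more than 25% of the body
apart falls below one body width. Candidate runs merge across gaps
< 0.3 s and runs shorter than 0.2 s are discarded — one-to-few-frame
glitch immunity at 30 frames/s. Omega intervals and the curvature-map mask
coincide exactly by construction.

**Forward/backward.** The undulatory wave travels head→tail during forward
crawling and tail→head during reversals, while the worm's translation is
opposite in sign; wave direction needs no stage-motion correction, which
is why it was chosen over centroid heading. For profiles at times t and
t + Δ the body shift δ* ∈ ±10 positions maximizing the Pearson correlation
is found; correlation curves are averaged over a 1-s sliding window, and
frames with peak correlation < 0.5 or δ* = 0 are UNKNOWN. Δ defaults to
0.1 s rather than one frame: at 30 fps the wave advances only ~0.7
positions per frame, and pixelation error — which is strongly correlated
between adjacent frames because the worm moves sub-pixel distances —
otherwise pins δ* to zero. Each column's temporal mean is subtracted
before correlating for the same reason (static extraction artifacts
correlate fully at zero shift). Direction runs shorter than 0.5 s are
absorbed into their surroundings, mirroring how modest direction changes
are not reflected in published curvature maps.

**Inter-omega durations** are successive onset-to-onset differences within
the first 1000 s. Onset-to-onset (rather than end-to-onset) is invariant
to the detector's duration bias, which matters because the detector sees
only the self-contact portion of a turn, not its full scripted duration.
Fewer than two onsets give an empty duration list and a missing (never 0)
mean. Group summaries average per-animal means with SEM across animals.

## Ratiometric trace quantification

`ratio_change()` divides the channels sample-wise and references the ratio
to its mean over a baseline window; the default window is the 10 s ending
at stimulus onset, detected from the temperature channel when present
(first sample departing > 0.2 °C from the initial temperature), otherwise
the first 10 s. Ten seconds is long enough to average sensor noise and
short enough to sit inside the stable pre-stimulus period of a
two-minute equilibration protocol. Bleach detrending (log-linear fit to
the reference channel) is available but off by default because bleaching
common to both channels cancels in the ratio exactly — a property the
tests check to machine precision.

`max_ratio_change()` reports the signed extremum over the post-baseline
window (maximum by default; minimum or absolute extremum selectable for
inhibitory responses). Its `smooth_s` parameter trades exactness for
robustness: the default 0 reports the raw sample extremum, which equals
the injected amplitude exactly on noiseless data, while the recommended
setting for noisy recordings is a boxcar of about the response rise time
(3 s), because the raw extremum of a noisy trace is biased upward by
selection. Both behaviors are by design and both are tested: raw recovery
is exact at 5–40% injected amplitude, and the smoothed group estimate at
SNR 10 with n = 10 stays within a few points of truth with the residual
extremum bias matching a resimulation oracle.

The generator's `noise_snr` is response-amplitude-referenced — peak ratio
change over per-sample ratio noise SD — the usual convention for evoked
responses (SNR 10 on a 17% response means 1.7 points of ratio noise per
sample, realized as independent multiplicative noise split across the two
channels). Null responses use a 10% reference amplitude so noise-only
traces are still defined. Traces default to 5 Hz sampling (200-ms
exposures) for 90 s with onset at 30 s and rise/decay time constants of
5/15 s.

**Puncta spacing**: local maxima above a prominence threshold after
rolling-median baseline subtraction, 3-point parabolic center refinement,
adjacent differences, and a sixteen-class equal-width histogram. The class
edges are not standardized anywhere, so they default to 0–8 µm (covering
the 1–4 µm spacings typical of presynaptic puncta with headroom) and are
always emitted with the results; out-of-range spacings are clamped into
the end classes so fractions sum to 1.

## Behavioral scoring rules

Thermotaxis tracks are scored by which temperature zones they occupy on a
radial gradient (default linear, 17 °C center to 25 °C periphery on a
45-mm-radius plate; a measured radius→temperature table can be plugged in
since real plates have non-linear gradients). "Moved to" a zone is
operationalized as occupancy ≥ 10% of the recording — published scoring of
this kind is done by eye, so the threshold is configurable and the
occupancies are always reported for re-thresholding. '17/25' requires both
extreme zones; otherwise the visited zone with the largest occupancy wins;
tracks visiting no zone are labeled by largest sub-threshold occupancy and
flagged. The default zones are T < 18.5 ('17'), 19–21 ('20'), > 23.5
('25'); assays run at other cultivation temperatures use the same scheme
with shifted, user-supplied zones.

NaCl tracks count distinct entries into the 5-mm peak region (entries
separated by ≥ 30 s outside) and total dwell: ≥ 2 entries or ≥ 50% dwell
is normal, one entry with less dwell is partially defective, zero entries
is defective. "Repeatedly" and "very briefly" are not quantified anywhere
in the scoring tradition, so the thresholds are explicit configuration.
The chemotaxis index uses only the counts at the odorant and control
regions; the scoring-circle geometry is left to the assay.

## The synthetic generator: what it emulates, and what it does not

The generator produces the statistical structure the analysis assumes:

* a sinusoidal tangent-angle wave θ(s,t) = A·sin(2π(s/λ − f·t)) with the
  phase running backward during reversals; defaults A = 0.6 rad, λ = 0.9
  body lengths, f = 0.5 Hz, 1.0-mm body, 0.15 mm/s — typical adult
  crawling values, all configurable;
* omega turns and reversals as independent Poisson processes (defaults
  0.03/s and 0.02/s — turn rates are treated as free parameters since no
  standard values exist; durations 1.5 s and 3 s). The raw onset lists are
  stored, so inter-onset intervals are exactly exponential; in the frame
  labels omega turns truncate overlapping reversals (the states are
  treated as exclusive);
* the omega pose as a scripted bend: a trapezoidal envelope (15% rise,
  70% plateau, 15% fall) on a uniform body bend of 1.05 · 2π rad, which
  brings the head within one body width of the posterior body for most of
  the event, while the heading ramps by a random ±120–180°. This is
  sufficient to exercise the self-contact detector; it is not a model of
  turn biomechanics;
* rasterization as a tube of width w(s) = (L/12)(0.4 + 0.6 sin πs) with
  anti-aliased edges, re-centered per frame like a tracking stage;
* run-and-tumble plate tracks with drift archetypes (stay-center,
  stay-ring, stay-periphery, scheduled center/periphery alternation, and
  k scripted approaches to a concentration peak);
* dual-channel traces with a common bleach factor, a rise-decay response
  kernel normalized to a sampled peak of exactly 1, and per-channel noise.

Passing tests on these data show that the pipeline recovers what it is
defined to recover under its own assumptions — single worm, dark
background, no self-occlusion beyond the omega pose, no stage drift, no
body-mechanics or neural dynamics. They do not certify performance on real
video with debris, lighting gradients, coiled postures outside omega
turns, or multi-worm collisions.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: empty masks are flagged
`no_worm` rather than erroring; a single valid frame yields a
`single_frame` low-confidence orientation; fewer than two omega onsets
yield a missing mean; fewer than two puncta yield empty spacings. Ties in
the ridge-walk steering prefer the straight continuation. All generators
accept a seed and restore the caller's RNG state; identical configuration
and seed reproduce outputs bit-exactly, which the pipeline manifest hash
makes checkable.

The test suite exercises the full video chain on a 600-s, 30-fps, 128×128
noiseless recording (18,000 frames, about 2.5 minutes of compute), mixed
forward/reversal direction accuracy on 300 s, and turn statistics for 20
animals × 1000 s against a vectorized Monte-Carlo oracle of exponential
gaps; shorter recordings are used where a property does not need length.
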