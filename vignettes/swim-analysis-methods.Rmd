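---
title: "Quantifying C. elegans swim behavior: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying C. elegans swim behavior: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemaswim)
```

## The measurement problem

A nematode swimming in liquid is, for measurement purposes, a bending
tube. Everything interesting about its gait — how often it strokes, how
many wave cycles its body carries, whether waves travel head-to-tail or
tail-to-head, how deeply it bends, whether the wave survives all the way
to the tail — is encoded in the *signed body curvature* as a function of
body position and time. `nemaswim` reduces video of swimming animals (or
externally tracked centerlines) to that representation and scores ten
behavioral measures from it.

The analysis proceeds in four stages:

1. **Tracking** — locate each animal per frame and extract its
   centerline (the mid-line of lateral symmetry) with per-point body
   half-widths.
2. **Geometry** — resample each centerline to 12 equal arc-length body
   segments and estimate signed curvature at the segment midpoints,
   giving a 12 × T *curvature kymograph*.
3. **Spectral analysis** — at every frame, estimate the dominant
   traveling-wave mode (spatial frequency in cycles per body length,
   signed temporal frequency in Hz) from an averaged multi-window
   short-time 2D Fourier transform of the kymograph.
4. **Measures** — compute ten per-frame series and summarize each trial
   by temporal medians and 10–90 percentile ranges.

## Curvature: definition, units and estimator

Curvature is the derivative of the tangent angle with respect to the
curvilinear coordinate $s \in [0,1]$ (tail $s=0$, head $s=1$). We report
the dimensionless $\hat\kappa = \kappa \cdot L$ (curvature per body
length), so animal size, optical magnification and image resolution
cancel out of every downstream measure.

The estimator fits a least-squares (Kåsa) circle to the arc surrounding
each of the 12 segment midpoints and reports the signed inverse radius;
straight (collinear) windows return 0 rather than failing. The sign
convention is fixed by image coordinates with the y-axis pointing down:
positive $\hat\kappa$ means the body turns clockwise on screen as one
walks tail to head; a stroke-averaged positive asymmetry therefore means
a clockwise-bent animal.

**Fitting window.** The window is `window_fraction` of the body length,
default **1/12 — exactly one body segment**. A circle fit acts as a
moving average of curvature over its arc: a window of length $w$ (body
lengths) applied to a wave with $n$ cycles per body attenuates the
recovered amplitude by roughly $\operatorname{sinc}(\pi w n)$. At
$w = 1/4$ the bias is ~20% for $n = 1.5$, which would corrupt
amplitude-based measures (stretch, attenuation numerators); at $w =
1/12$ it is under 3% for every wavenumber the analysis targets
($n \le 3$). One segment is also the natural resolution limit of the
12-segment discretization, and on postures built from piecewise-constant
segment curvatures the one-segment circle fit is exact, making posture
reconstruction and curvature estimation true inverses (verified to
$3\times10^{-5}$ relative RMS in the tests). The fraction remains a
user-visible argument for anyone wanting the smoother, stronger-bias
estimate.

Centerline resampling uses piecewise cubic Hermite interpolation with
tangents taken from the circle through each vertex and its neighbors.
This is exact on circular arcs — a quarter circle described by only 4
points resamples back onto the circle to ~0.03 px — and, unlike a global
spline, never oscillates on noisy tracked points. The densified curve is
re-parameterized by its own arc length, correcting the chord-length bias
of sparse input polylines.

## The averaged short-time 2D Fourier transform

A single traveling wave $\hat\kappa = A\sin(2\pi(f_s s + f_t t))$
appears in the 2D Fourier plane as a point mass at $(f_s, f_t)$; with
$s$ oriented tail→head, $f_t > 0$ is forward (head-to-tail) propagation
and $f_t < 0$ is reverse. Because curvature is real, the full-plane
spectrum is centro-symmetric and the $f_s \ge 0$ half-plane carries all
information.

Swimmers change behavior within a trial, so a whole-trial transform is
useless for per-frame scoring (the tests demonstrate this on a trial
whose frequency steps from 1 Hz to 2 Hz). Instead, at every frame the
transform is taken over five window lengths — 32, 40, 48, 56 and 64
frames — each zero-padded onto one fixed raster (64 spatial × 256
temporal bins) so their magnitude spectra can be averaged pointwise.
Short windows track fast behavioral changes; long windows sharpen
frequency resolution; the average trades between them.

Numerical choices, in the order they are applied:

* **Windows clipped at trial edges** use their valid truncation.
  Invalid frames inside a window are zero-filled; a window with fewer
  than 8 valid frames, or under 25% valid, is undefined.
* **Taper**: the patch mean is subtracted, then a Hann window along
  time. No spatial taper — 12 samples are too few to sacrifice; the
  zero-padding supplies interpolation.
* **Mode search**: the argmax over $f_s > 0$, restricted to bins that
  are *strict local maxima along* $f_s$ (compared against the
  $f_s = 0$ line too). The $f_s = 0$ line holds the DC/asymmetry
  component and static postures; its rectangular-window leakage decays
  monotonically across the low-$f_s$ bins and can therefore never
  qualify, while a genuine traveling-wave lobe always does. Without
  this, a curled (frozen) stretch of trial sheds leakage ridges that
  masquerade as slow reverse waves.
* **Sub-bin refinement** by 2D parabolic interpolation around the
  discrete peak (temporal axis wraps across Nyquist).
* **Dominance threshold**: the mode is kept only if the energy in the
  3 × 3 bin neighborhood of the peak (the parabolic stencil) is at
  least `eps_mode = 0.02` of the total half-plane energy. Synthetic
  waves score 0.12–0.19 under this statistic and white noise below
  0.012, so the threshold sits well between. Quiescent or curled frames
  come out *undefined* rather than contributing junk frequencies.

**Resolution limits.** Recovery is essentially exact (≤1% error) across
$f \in [0.25, 4]$ Hz and $n \in [0.5, 3]$ cycles/body — *except* at the
joint corner $f = 0.25$ **and** $n = 0.5$, where the mirrored ± lobes of
the real-valued signal overlap in both axes simultaneously (at 18 fps
even the 64-frame window's Hann main lobe is wider than the 0.5 Hz
mirror separation) and $|f_t|$ biases high by ~8%. This is a windowing
limit, not an estimator defect; applications needing such slow, long
waves need longer windows than this window set provides.

The *stroke clock* inverts the temporal frequency: stroke duration
$D(t) = \mathrm{fps}/|f_t^*(t)|$ frames. Frames without a defined mode
inherit the nearest defined duration, so window-based measures remain
computable across brief undefined runs; the frames themselves stay out
of every summary. Two-stroke windows $[t - D, t + D)$ are half-open and
clipped at trial edges; a window is usable when at least half its frames
are valid.

## The ten measures

| measure | units | definition |
|---|---|---|
| wave initiation rate | waves/min | $60\,|f_t^*|$; direction ignored |
| body wave number | cycles/body | $|f_s^*|$ |
| asymmetry | dimensionless | mean $\hat\kappa$ over body × two-stroke window |
| stretch | dimensionless | largest per-segment $\hat\kappa$ range in the window |
| attenuation | % | $100(1 - R_\text{tail}/R_\text{head})$, quarter-body ranges |
| reverse swimming | % of time | share of defined frames with $f_t^* < 0$ |
| curling | % of time | tip-to-far-body distance $\le L/3$ |
| travel speed | body lengths/s | displacement of stroke-averaged body centers |
| brush stroke | body areas | painted-area ratio over two strokes, minus one |
| activity index | body areas/s | brush stroke / two-stroke duration |

Details that matter in practice:

* **Ranges are 5–95% quantile bands**, not max − min. On a pure
  sinusoid the band is 1.3% below the true peak-to-peak range —
  negligible against every stated tolerance — but unlike the absolute
  range it is immune to single-frame curvature spikes near the body
  tips of *tracked* (as opposed to ground-truth) centerlines, which
  would otherwise inflate every window containing one.
* **Attenuation** guards against a motionless head with
  `eps_range = 0.1` (dimensionless curvature): if the head-quarter
  range is below it, the frame is undefined rather than an unstable
  ratio. Negative attenuation (amplification) is expected during
  reverse swimming and is reported as such. Its ranges are taken on a
  lightly time-smoothed copy of the kymograph (3-point binomial):
  uniform attenuation of the wave cancels in the tail/head ratio, but
  the inflation frame noise adds to a quantile band does not — it hits
  the small tail range harder than the large head range and biases the
  ratio upward on noisy tracked data.
* **Asymmetry** is averaged directly over the two-stroke window (for
  stationary behavior this is identical to averaging per stroke and
  then over strokes). For group statistics the per-animal score is the
  *absolute* median, so left- and right-biased animals do not cancel.
* **Curling** is postural, not spectral: the score is the smaller, over
  the two tips, of the distance to the nearest centerline point at arc
  separation ≥ L/2, in body lengths; a frame is curled when the score
  is ≤ 1/3 (inclusive). A closed "O" scores ≈ 0; a "6" fires through
  the tip-to-mid-body distance; a straight worm scores exactly 0.5.
* **Travel speed** averages the arc-length centroid over one stroke on
  each side of $t$ and divides the displacement by the elapsed time.
  Both windows use the same *integer* frame count (rounding the
  fractional stroke duration): if one window were even a single frame
  shorter than the other, the periodic lateral wobble of the center
  would stop cancelling and an in-place swimmer would score a spurious
  0.05–0.15 body lengths/s at high stroke rates.
* **Brush stroke** rasterizes the body tube on a normalized grid of 128
  raster units per body length (round tube caps; union by cell-count
  accumulation), making the measure resolution- and size-independent by
  construction; the per-frame series is smoothed by a two-stroke moving
  average, matching the reported "averages of successive pairs of
  strokes".

Trials are summarized by temporal medians with 10–90 percentile ranges
(linear interpolation between order statistics): behavioral episodes —
a few seconds of reversal, a burst of fast stroking — skew means but
barely move medians. Reverse swimming and curling are binary series and
are summarized as percentage of time instead.

If a first pass scores more than 50% (strictly) of defined frames as
reverse, the head/tail labels are swapped and everything is recomputed:
the tracker cannot tell head from tail, but sustained tail-initiated
wave propagation is rare, so the wave direction itself is the best
orientation cue.

## Tracking

Segmentation follows the classic pipeline for dark animals on a light
background: a local standard-deviation filter (kernel ≈ one body width,
default 5 px) enhances edges; closed contours are grown greedily along
the gradient magnitude of the filtered image from its strongest maxima;
each closed contour's region is then refined by local Otsu thresholding,
and the component under the contour is kept, with the region of interest
grown until the component no longer touches its border (a contour that
enclosed only part of the animal must never crop it mid-body). The
ordered outline is split at its two sharpest turning points (the tips),
the two sides are averaged pairwise into the centerline, and the
interior Euclidean distance transform supplies the half-widths.
Thresholding truncates the faint tapered tips, so each end is extended
along its own fitted arc while the image stays darker than background.
Candidate detections must be elongated (length ≥ 8 × mean half-width)
and darker than their surroundings by `min_contrast` (default 0.15),
which rejects blobs cut from pure noise; candidates that substantially
overlap an already-accepted body are duplicates (a second walk around
the same animal, or a mis-split fragment of it) and the longer
interpretation is kept.

Frame-to-frame propagation holds two *anchor* points fixed — body
points whose local intensity is least changed between consecutive
frames and which still lie on a dark pixel — and marches a chain
outward from each anchor at fixed arc spacing, choosing at each step the
direction (±60° around the previous frame's local tangent) that
maximizes darkness, with a turn penalty. The two chains are blended
with weights decaying away from their anchors, recentered on the tube
along the normals, smoothed, and re-spaced to the previous body length.
Because a tube is featureless along its own axis the fit can slide
longitudinally; both tips are therefore snapped to the dark extent of
the body every frame, moving along the tip's own fitted arc (a straight
tangent would zero the tip curvature that the mean-curvature and range
measures read). Orientation stays continuous by construction: if a step
comes out reversed — a crossing body part can capture an anchor — the
previous frame's point order is restored; head/tail identity is never
decided frame-locally, only globally from the wave direction. A fresh
segmentation every 20 frames is merged in pointwise — the candidate
with better local image support wins, and the segmentation wins ties,
since a slid-but-still-dark tracked point has the same darkness but the
wrong arc position. When the two candidates disagree beyond any
plausible drift, blending would splice two interpretations of the
scene, so whichever lies on darker pixels is adopted wholesale: a lost
track is recovered by the segmentation, and a bad segmentation cannot
destroy a good track — the frame is flagged instead.

The quality rule flags frames whose body length drops two (robust)
standard deviations below the animal's own (robust) mean — median and
scaled MAD rather than mean/SD, because the contaminated frames the rule
must catch are exactly the ones that would inflate a plain SD — and
rejects an animal when more than 20% (strictly) of its frames are
flagged. Contact between animals (and self-overlap of a curled body) is
flagged from intersecting displacement envelopes; flagged frames are
excluded from all measures but can be re-validated through a manual
review file, which can also override the whole-animal verdict.

On rendered synthetic scenes (five animals, SNR 10, 18 fps) the tracker
holds a mean centerline deviation of ~0.35 px with ≥95% of frames under
1 px, and ground-truth versus tracked centerlines give the same trial
summaries within the recovery tolerances above — the
tracking/measures separation the package is designed around.

## The synthetic swimmer generator

The generator works in curvature space: because every measure is defined
on the kymograph, synthesising $\hat\kappa(s,t)$ directly makes the
ground truth *exact by construction* — no hydrodynamics is modelled, and
none is needed for validating the measurement chain. A scenario
specifies wave frequency $f$, wavenumber $n$, amplitude $A$, curvature
bias, attenuation $\alpha$, reversal episodes (phase-continuous across
direction switches, so no spectral splatter is injected at the
boundaries), curling episodes ("O": constant $\hat\kappa = 2\pi$; "6":
straight tail half, tightly closed head half), drift, body size, frame
rate, duration and noise.

The amplitude envelope is $(1-\alpha)$ over the tail quarter, 1 over the
head quarter, with a linear ramp between. This makes the generator's
truth *consistent with the attenuation measure's own definition* (ratio
of tail-quarter to head-quarter range): a naive linear-to-zero envelope
would measure ≈78% at $\alpha = 1$, because the tail *quarter* tops out
at $s = 0.25$ where a linear envelope is far from zero — the generator
must control the quantity the measure actually reads.

Postures are reconstructed by integrating the tangent angle with each
segment's curvature held constant over its arc (the exact inverse of the
one-segment circle fit), and rendered as dark anti-aliased tubes with
~1 px Gaussian blur plus seeded Gaussian noise. Geometry is
deterministic given the scenario; the seed affects only the noise, and
rendering restores the caller's RNG state.

What the generator deliberately does **not** emulate: hydrodynamic
coupling (real drift is propulsion, not a kinematic overlay),
out-of-plane bending, body-size change within a trial, illumination
gradients, debris, and animal-animal occlusion beyond simple crossings.
Passing the recovery grid therefore validates the measurement chain —
segmentation through summaries — not any claim about the biology of
real videos.

## Problem sizes and validation design

The test suite validates against independent oracles: brute-force DFT
argmax (direct summation, no FFT) for the spectral peak; analytic
circles, sinusoids and arc centroids for geometry; constructed principal
directions for covariance ellipses; relabeling identities (head–tail
swap maps reverse % $p \mapsto 100-p$ and flips the asymmetry sign) for
the pipeline. The acceptance checks run 30 s trials at 18 fps (540
frames): three analytic anchors (a symmetric swimmer scores asymmetry
≈ 0; equal head/tail amplitude scores attenuation 0%; a motionless tail
scores 100%), a 72-scenario recovery grid ($f \in \{0.5,1,2,3\}$,
$n \in \{0.7,1.5,2.5\}$, $\alpha \in \{0,0.5,1\}$, reversal share
$\in \{0,0.2\}$), a five-animal 30 s rendered tracking benchmark, and
invariance of all ten measures under 2× spatial scaling, a 2× resolution
re-render, and an 18→36 fps frame-rate change. The re-render comparison
averages five replicate noise realizations per resolution (10 s trials):
the single-trial repeatability of the noise-sensitive measures is of
the same order as the invariance band, so a one-realization comparison
would measure noise rather than drift. These sizes keep the full suite
within a half hour on one core while exercising every code path at the
study's native frame rate and trial length.

## Known limitations

* Identity is not preserved through full occlusions; contact frames are
  flagged and excluded rather than disentangled.
* The $f = 0.25$ Hz + $n = 0.5$ corner of the frequency box biases
  $|f_t|$ ~8% high (see above).
* Attenuation compares body *quarters*; envelopes varying within a
  quarter are seen only through that quarter's maximum.
* The curl rule reproduces the "O"/"6" taxonomy through one geometric
  criterion; postures exactly at the L/3 boundary are scored curled
  (inclusive), and other self-approaching shapes may differ from a
  human rater's call.
* Centerline import/export is CSV; video input is multi-page TIFF or
  in-memory arrays.
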