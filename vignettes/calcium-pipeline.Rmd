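---
title: "Methods: somatic calcium event detection and network synchrony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic calcium event detection and network synchrony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catrace)
```

## The measurement problem

Cultured neurons expressing a genetically encoded calcium indicator
(GCaMP6s) report action-potential-driven calcium influx as fluorescence
transients with a fast rise (~0.2 s) and slow decay (~1.5 s). A second,
activity-independent cell-fill fluorophore (mRuby) marks every transduced
neuron, active or not. catrace converts a two-channel acquisition — one
static reference image plus one calcium movie per field — into per-image
and per-ROI activity metrics suitable for downstream group-level modeling.

The pipeline is deliberately segmentation-first: ROIs come from the
cell-fill channel, not from activity, so silent neurons are counted and a
field's "proportion active" is meaningful. This matters for pharmacology:
a field silenced by TTX still yields its full ROI complement, each with
zero events.

## Segmentation of somata

Somata are found in the reference image in four stages:

1. **h-minima suppression.** The h-minima transform (grayscale
   reconstruction-by-erosion of `image + h` under `image`,
   8-connectivity) removes every regional minimum shallower than `h`,
   with `h = hmin_factor * sd(image)` (default factor 2). In practice
   this levels the textured background *and* the thin neurite signal —
   anything whose relief above the background pour level is below `h` —
   leaving the bright somata standing. One boundary convention is worth
   stating: a perfectly constant image is a single boundary-less plateau
   and is returned unchanged (raw reconstruction would lift it uniformly
   by `h`, which suppresses nothing). Note the transform is *not*
   idempotent — a basin of depth `d > h` re-emerges with depth `d - h` —
   which is inherent to the definition, so the package makes no
   idempotence claim.
2. **Background region growing.** The global-minimum pixel seeds a
   region that is grown one pixel at a time: among 4-connected frontier
   pixels, the one whose intensity is closest to the *running* region
   mean is admitted and the mean updated, until that smallest difference
   exceeds `tolerance = grow_tolerance_factor * sd(suppressed image)`
   (default factor 1). The fully grown region is the background; its
   complement is the candidate soma mask. Two choices the algorithm's
   prose description leaves open are pinned down for reproducibility:
   ties in the frontier ordering break to the smallest row-major pixel
   index, and the tolerance uses the standard deviation of the
   *suppressed* image — the image actually being grown. The greedy
   frontier loop is implemented in C++ (`src/morphology.cpp`); a
   brute-force R re-implementation serves as the oracle in the tests.
3. **Watershed splitting.** The mask is partitioned by
   marker-controlled watershed (EBImage's `propagate`). Markers are the
   regional maxima of a score image combining the Gaussian-smoothed
   intensity and the mask's Euclidean distance transform, each min-max
   normalized inside the mask. The distance term is load-bearing: two
   equally bright somata whose centers are 1.5 half-maximum radii apart
   have *already merged* into a single intensity peak (two equal
   Gaussians merge below 2 sigma separation), but round cells still
   pinch the mask at the contact waist, and the distance transform keeps
   a maximum per lobe. Intensity-only markers cannot split that case.
4. **Shape filtering.** ROIs are dropped if smaller than `min_size_px`
   (default: the pixel area of a 5 µm-radius disk at the image's pixel
   size), more eccentric than 0.99 (eccentricity from the second central
   moments of the pixel mask: 0 = circle, 1 = line; neurite fragments
   and debris score near 1), or touching the image border. Survivors are
   relabeled `1..K`.

## Traces, dF/F, resampling

Each ROI's trace is the plain mean of its pixels per frame. Baseline
normalization uses a rolling average: `F0(t)` is the mean over a
**centered** window of 50 frames (truncated at the ends) and
`dff = (F - F0)/F0`. A centered window was chosen over a trailing one
because a trailing window lags the baseline through every event onset,
biasing early-event amplitudes; both the window length and the alignment
are arguments. `F0 = 0` yields `NA` (never fabricated signal); event
detection treats `NA` as sub-threshold. dF/F is exactly invariant to
positive rescaling of a trace.

Because the motif library is sampled at 10 frames/s, traces acquired at
other rates (e.g. 4 Hz) are linearly interpolated onto a 10 Hz grid
spanning the same time interval. Linear interpolation is monotone-safe
and preserves endpoints; a same-rate call is the identity.

One caveat the tests make explicit: with a 50-frame window at 4 Hz
(12.5 s) a ~1.5 s-decay transient still inflates its own baseline by a
few percent, so recovered amplitudes run ~10-20% low for long events.
This is a property of rolling-baseline dF/F generally, not of this
implementation; amplitude fidelity improves as the window-to-event
ratio grows.

## Motif-correlation event detection

Events are detected by correlating each 10 Hz dF/F trace against a
library of 23 unit-peak templates: 16 single transients on a grid of
rise times {0.1, 0.2} s x decay times {0.5, 1, 2, 4} s x two durations
(tagged `fluorosnnap`, after the software whose template set they
parallel), plus 7 data-driven shapes (tagged `capture`): three double
transients at 0.5/1/2 s inter-peak gaps, a rise-hold-decay plateau, and
three slow-onset transients. The library serializes to CSV so a measured
template set can be dropped in for exact parity with other tools.

The correlation map `Ca[m, t]` holds the Pearson correlation of motif
`m` with the trace window *starting* at frame `t` (so an event's onset
is its run start). Columns where the trace sits below the **height
threshold** are zeroed: sub-background samples cannot seed events, which
is what keeps noise from correlating its way into the event list.
Zero-variance windows map to 0 — an undefined correlation is no match.

The per-column maximum over motifs forms a single row; maximal runs
strictly above the correlation threshold (default 0.7) become events,
with duration = run length and motif = the row attaining the run's peak
(ties to the lowest index). Event counts are monotone non-increasing in
both thresholds.

The automatic height threshold is `median + 3 * 1.4826 * MAD` of the
pooled dF/F samples — a robust 3-sigma noise ceiling that sparse,
strongly positive transients barely inflate. For pharmacology pairs the
baseline field's threshold is passed explicitly to the treated field
(`height_threshold = <value>`), since a silenced field's own noise floor
would otherwise rescale the threshold to its (tiny) residual noise.

## Synchrony and eigen-clusters

Field synchrony is computed on the dF/F traces (not binarized event
trains). All pairwise Pearson correlations are compared against a
surrogate null: 100 rounds of circularly shifting every trace by an
independent uniform offset — preserving each trace's autocorrelation
while destroying cross-correlation — and recomputing the matrix. Pairs
not exceeding their null's 95th percentile are zeroed.

The synchronization index is `SI = (lambda_max - 1)/(R - 1)` from the
largest eigenvalue of the thresholded matrix, clipped to [0, 1]: an
identity matrix (independent ROIs) gives 0, an all-ones matrix (perfect
synchrony) gives 1, and a uniform off-diagonal `r` gives exactly `r`.
Clusters are eigenvalues exceeding the largest eigenvalue observed in
any surrogate matrix; ROI `i`'s participation in cluster `k` is
`lambda_k * v_ki^2`, each ROI joins its best cluster, and a best
participation below the uninformative level `1/R` leaves the ROI
unclustered — silent ROIs are not forced into ensembles. Computing SI
and clusters on the *thresholded* matrix (the surrogate-corrected one)
is a deliberate choice: it makes the independent-field limit land at
SI ~ 0 rather than at the positive bias a finite-sample raw correlation
matrix carries.

## Drift registration

Perfusion can drag a field across the sensor during acquisition. The
model is translation-only (the drift is physical, directional, without
rotation): each frame is registered to its predecessor by phase
correlation, incremental shifts are composed, and each frame is
resampled **once** with its composed shift (bilinear, frame-median
fill), avoiding compounded interpolation blur. Finally the movie can be
aligned to the cell-fill reference by a single global translation
between the temporal mean image and the reference.

The phase correlation itself uses two numerical safeguards worth
recording. First, the cross-power spectrum is whitened with its
magnitude floored at `1e-3` of the maximum: smooth, low-texture images
(a few Gaussian somata on a flat background) have spectra that decay to
numerical zero, and full whitening would amplify those bins into noise
phases that bury the true peak. Second, sub-pixel refinement is
two-stage: the integer peak comes from the un-windowed correlation
(unbiased for large shifts), the frame is shifted back by that integer,
and the residual is refined on a 10x-upsampled local DFT grid under a
Hann window (which removes the edge-discontinuity bias that otherwise
pulls fractional peaks by ~0.1 px). The refinement grid is centered on
the integer peak so exact integer drifts are recovered exactly.

The per-frame Pearson correlation with the temporal mean image is the
standard before/after diagnostic; registration of a drifting field
raises its mean markedly.

## The synthetic generator: what it emulates, what it does not

`make_reference_image` renders somata as Gaussian-profile disks (half
maximum at the nominal radius) taken as a pointwise *maximum* over the
background — a monolayer cell fill where overlapping cells occlude
rather than add, which keeps the half-maximum ground-truth contour exact
even for touching cells — plus 1-2 px straight neurite distractors at
roughly a quarter of the soma brightness, and additive Gaussian noise.
`make_movie` drives each soma's pixels as `baseline * (1 + dff(t))`
with `dff` a sum of double-exponential kernels
`(1 - exp(-t/rise)) * exp(-t/decay)` (defaults 0.2 s / 1.5 s, the
GCaMP6s regime) at scheduled onsets, over a dim constant photon
background, with per-pixel Gaussian noise and optional cumulative rigid
drift. Event schedules are uniform with a refractory gap, drawn by the
exact order-statistics construction so schedules are independent across
ROIs at any rate the gap allows.

Deliberately out of scope: optics (no PSF), photobleaching, Poisson
photon statistics (Gaussian noise is analytically tractable and a good
approximation at these intensities), neuropil contamination, and any
spiking/biophysics model. Passing tests on these fixtures therefore
demonstrate algorithmic correctness — recovery of known structure under
the pipeline's own assumptions — not robustness to every artifact of
real microscopy.

Study-condition defaults used by the test fixtures, chosen once:

* segmentation field: 256 x 256 px at 1 µm/px, 30 somata (radius
  6 ± 0.5 px), 40 neurites, soma contrast 130 over background 20, noise
  sd 5;
* event recovery: 20 ROIs, 8 min at 4 Hz, 2 events/min/ROI, amplitude
  1.0 dF/F, pixel noise 0.1 x baseline (trace-level noise ~0.01 dF/F
  after averaging ~100 soma pixels);
* synchrony: 10 ROIs, 5 min at 10 Hz, network bursts at 10/min with
  amplitude 2.0 dF/F (fully synchronous fields in culture are compound
  multi-spike bursts, severalfold a single event) and trace noise 0.1;
* drift: 6 somata on 64 x 64 px, ±1 px/frame over 20 frames,
  noise-free;
* pharmacology pair: 15 ROIs, 4 min at 4 Hz; the TTX analog has zero
  seeded events and is scored with the *baseline* field's height
  threshold.

These sizes keep the full suite around a minute on one core while
leaving every statistical margin (recall/precision at 0.9, SI bounds)
far from its threshold.

## Known limitations

* Rigid translation only; rotation, scaling or non-rigid tissue motion
  are not modeled.
* Event amplitudes are correlation-detected, not calibrated to calcium
  concentration; the motif match identifies shape, not magnitude.
* The rolling baseline underestimates amplitudes of events comparable in
  length to the window (see above).
* Surrogate counts (100) and the 95% pair quantile are defaults, not
  claims of parity with any other tool's significance rule; both are
  configurable and seeded.
* The segmentation assumes somata are the brightest round structures in
  the cell-fill channel; fields dominated by debris of soma-like size
  and roundness will pass the filters.
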