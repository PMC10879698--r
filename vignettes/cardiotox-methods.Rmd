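---
title: "Methods: quantitative readouts for cardiomyocyte toxicity assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative readouts for cardiomyocyte toxicity assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiotox)
```

This vignette describes the models and procedures the package
implements, the parameters that matter, the design choices made where a
procedure was genuinely open, and what the synthetic-data tests do and
do not demonstrate about real data.

## Preprocessing of α-actinin micrographs

Two steps precede sarcomere analysis, mirroring the standard ImageJ
workflow for this channel:

* `subtract_background()` — a rolling-ball style background estimate
  implemented as a grayscale morphological **opening with a disc
  structuring element** (default radius 50 px), subtracted and clipped
  at zero. We chose the plain disc opening rather than ImageJ's
  paraboloid approximation because it is deterministic, exactly
  testable against a brute-force erosion/dilation oracle, and the
  downstream analysis depends only on the removal of smooth shading
  wider than the disc. The disc is defined by `dr² + dc² ≤ r²`, the same
  definition the test oracle uses.
* `enhance_contrast()` — a linear stretch mapping the `f/2` and
  `1 − f/2` intensity quantiles to the dtype extremes (default
  `f = 0.003`, i.e. 0.3% saturated pixels), clipping outside. Quantiles
  use R's default linear interpolation (type 7); the exact histogram-bin
  rule of the original macro is unspecified, and any monotone stretch
  differing only in tie handling changes the mask negligibly. Quantiles
  are computed **per image**; users comparing wells should be aware that
  a per-batch stretch would be an alternative convention.

`to_8bit()` converts 16-bit acquisitions by a linear min–max scale with
round-half-up, since the fixed mask threshold below is defined on the
8-bit scale.

## Sarcomere striation detection

Organized sarcomeres appear as periodic striations whose period equals
the sarcomere length, 1.2–2 μm in these cells. `bandpass_filter()`
applies a 2D FFT and zeroes every coefficient whose radial spatial
frequency (cycles/μm, computed from the integer frequency indices and
the pixel size Δ) lies outside `[1/2.0, 1/1.2]`. Design points:

* The annulus is **isotropic**: striations occur at arbitrary
  orientations, so no angular selection is applied.
* The **DC term is always removed**, even though ρ = 0 is "below band"
  only in a limiting sense — flat regions must produce empty masks.
* The inverse transform's real part is **clipped to [0, 255] and not
  re-stretched**. Re-stretching would make the fixed threshold
  image-dependent and defeat its purpose.
* The filter is applied to the whole image, not per tile.
* A Nyquist precondition (`period_min ≥ 2Δ`) is enforced with an error
  stating the required pixel size.

`make_mask()` then thresholds strictly at 21 (8-bit scale), giving the
binary mask of organized sarcomere signal. The implementation is tested
against an explicit O(N⁴) double-sum DFT oracle (agreement < 1e−6 on
32×32 images) and against pure gratings: in-band periods are retained at
full amplitude and out-of-band periods suppressed by > 100× in energy
(gratings commensurate with the test window, so that spectral leakage
does not blur the comparison).

## Z-lines, myofibrils and the six structure metrics

Z-lines are the 8-connected components of the mask with area at least
`min_area_px` (default 4 px, which discards thresholding specks smaller
than any plausible z-line at Δ = 0.2 μm/px). Orientation is the
principal axis of the component's pixel coordinates; length is the
extent along that axis (in pixels, inclusive) times Δ.

The grouping of z-lines into myofibrils is not specified by the
measurement itself, so the package defines it explicitly. Two z-lines
are linkable when

1. their centroid distance lies in the sarcomere band widened by
   `spacing_tol` (default 0.15),
2. their orientations differ by ≤ `angle_tol_deg` (default 20°), and
3. the centroid-link direction is within `angle_tol_deg` of the
   perpendicular to both z-lines (this rejects laterally offset parallel
   z-lines that belong to neighboring fibrils).

Myofibrils are maximal simple chains in this graph, found by a greedy
longest-chain decomposition: chains are grown from every unassigned
z-line (extension picks the neighbor best aligned with the running chain
direction, lowest id on ties), the longest chain is committed, and the
process repeats. Chains need ≥ `min_zlines_per_fibril` members (default
3, i.e. at least two sarcomeres in series); each z-line joins at most
one fibril. The decomposition is deterministic, so repeated runs agree
exactly.

The six per-image metrics are: mask pixel count (sarcomere presence),
fibril count, a fibril orientation index, mean z-line length (sarcomere
width), mean fibril length, and the fraction of z-lines assigned to any
fibril. The orientation index is defined here as the length-weighted
resultant of the doubled fibril-axis angles (a 180°-periodic order
parameter in [0, 1]; 1 = all fibrils parallel). A per-image orientation
percentage is reported in this field without a printed formula; our
order parameter is a documented stand-in, not a reconstruction of any
particular macro. `normalize_to_baseline()` expresses each metric as a
percentage of its value at the experiment's first timepoint.

## Viability coverage

`coverage_fraction()` counts pixels strictly above a hard threshold that
the user supplies per replicate batch — deliberately never
auto-computed, because the assay holds acquisition settings and the
threshold constant within a batch. No morphological cleanup is applied
by default (`min_object_px = 0`). Per-well readouts average 12 (Calcein)
or 55 (time-lapse GFP) fields; normalization is to timepoint 0 and
optionally to the DMSO control.

## Transient kinetics

Traces are whole-frame mean intensities of 70-fps videos (or force
recordings treated identically; pacing frequency, typically 2 Hz, is
metadata). `detect_transients()` finds peaks with prominence ≥ 20% of
the global range; per beat, the local baseline is the trace minimum over
the adjacent inter-peak segments, the onset is the last sample at or
below `baseline + 10%` of the amplitude before the peak, and the end is
the first sample at or below the 90%-decayed level after it. The 10%/90%
fractions are conventions of this package (the underlying definitions
are not standardized) and are exposed as arguments. Frequency is
computed from peak intervals rather than a Fourier estimate because
recordings are short (~10 s) and possibly irregular. Velocities are the
per-event extreme first differences times the frame rate, averaged
across events; the diastolic (baseline) load is the global minimum,
matching the practice of reading the lowest-intensity frame of the
video.

The recovery tests synthesize traces as linear rises over the
time-to-peak followed by exponential decays (time-to-decay truth is
`τ·ln 10`, the 90% decay point). Noise in these tests is the **frame-mean
noise of a video**: per-pixel noise of 2% of the beat amplitude averaged
over a 64×64 frame leaves σ/√4096 on the trace. At that level the
recovered baseline sits within `3σ/√n` of truth and the crossing times
within 2 frames. A trace carrying 2%-of-amplitude noise *per sample*
(i.e. no spatial averaging) would not meet these bounds — the minimum of
~700 noisy samples is biased low by roughly 2.8σ, and the first passage
below the decay level occurs several frames early. The bounds are
therefore statements about the video pipeline, which is how the data
are actually acquired.

## γH2AX focus scoring

Nuclei: global Otsu threshold on the DAPI channel (typical DAPI fields
are globally bimodal), distance-transform watershed to split touching
nuclei, then an area filter (default ≥ 80 px). Foci: white top-hat with
a disc of radius `3σ` removes diffuse nuclear background, and local
maxima of the top-hat image above `min_spot_intensity` with pairwise
separation ≥ `2σ` are counted (greedy brightest-first suppression,
deterministic tie-breaks). Maxima outside any nucleus label are
discarded. A nucleus is positive with ≥ 1 focus by default
(`positivity_min` is exposed; the original CellProfiler settings are not
published, so these are documented stand-ins). On noise-free synthetic
scenes with spot separation ≥ 4σ, counts are exact; a 200-nucleus
Poisson(3) scene reproduces the closed-form positivity
`100(1 − e⁻³) ≈ 95.0%` within sampling error.

## Uptake and washout models

Flow-cytometry uptake series (fraction positive or MFI against exposure
time) are fitted by `minpack.lm` least squares to the mono-exponential
saturation `v(t) = v0 + (P − v0)(1 − e^{−kt})`, with `v0 = 0` fixed by
default and fraction data fitted on the raw scale. The observed curves
show a single plateau and monotone approach, which a mono-exponential
captures with the fewest parameters; parameter uncertainty comes from a
seeded residual bootstrap. Constant series abort with an explicit
unidentifiability error. Washout series fit
`v(t) = B + (I0 − B)e^{−λt}`; the time-to-background is defined by the
excess falling below 5% of its initial value, which inverts to
`ln(20)/λ` in closed form — a decay with `λ = ln(20)/6` per day reaches
background in exactly 6 days. `saturation_at()` maps an exposure
duration to `1 − e^{−k·t}`, connecting incubation regimens (e.g. a 2-h
pulse) to the fraction of full saturation reached.

## Synthetic generators and what the tests show

Every generator takes an explicit seed and uses a local RNG stream, so
outputs are bit-reproducible and never disturb the caller's RNG. Truth
is computed from the noise-free construction.

* **Striated scenes**: fibrils are chains of anti-aliased bright
  segments perpendicular to the fibril axis. Segments are rendered with
  a lateral tent falloff and *flat end caps*, so the footprint spans
  exactly the nominal z-line length — sub-pixel spacings such as 1.8 μm
  at 0.2 μm/px are representable, and length recovery is meaningful to
  ±1 px. Degradation deletes z-lines Bernoulli-independently; the truth
  fibrils are the surviving runs of ≥ 3 consecutive z-lines. Fibril
  bounding circles are placed by rejection sampling with ≥ 4 μm gaps;
  the multi-fibril recovery study uses 384×384 px fields (76.8 μm at
  Δ = 0.2) so that up to 8 fibrils place reliably, with 20 scenes per
  run — sizes chosen once as representative of a 40× field. Because
  deletion draws share the seed across a degradation sweep, deletions
  are nested and the *presence* readout is monotone per realization;
  the *assigned z-line fraction* is a ratio whose denominator (detected
  z-lines) also falls with degradation, so isolated realizations can
  tick upward at high degradation even though the metric decreases in
  expectation — a property of the metric, not a pipeline defect.
* **Coverage fields**: random disks accumulate until the covered
  fraction is within 0.005 of target; the truth is the exactly realized
  pixel fraction.
* **Traces**: stereotyped beats (linear rise, exponential decay) at
  exact intervals on an optionally drifting baseline, with Gaussian
  noise on top.
* **Foci scenes**: non-overlapping ellipses with Poisson focus counts
  and ≥ 4σ-separated Gaussian spots (placement restarts on dead ends).
* **Uptake samples**: exact curve values plus Gaussian noise, clipped to
  [0, 1] for fraction data.

Passing these tests shows that the implementation measures what it
claims on images whose ground truth is known. It does not show
robustness to the full texture of real micrographs: out-of-focus light,
anisotropic PSFs, photobleaching, overlapping myofibrils at crossing
angles, nuclear debris, or drug autofluorescence bleeding into the
nuclear channel are all outside the generators' scope. The generators
emulate geometry and additive Gaussian noise only; no optics simulation
beyond Gaussian spots is attempted.

## Numerical conventions and degenerate inputs

* Thresholds are strict (`>`) everywhere a mask is formed.
* 8-bit conversion and contrast stretch round half-up.
* Constant images: contrast stretch returns the input with a warning;
  8-bit conversion returns zeros with a warning; transient detection
  returns no events; uptake fitting errors (k unidentifiable).
* Empty masks yield zero z-lines (not an error); images with no z-lines
  report width/length/orientation as missing and an assigned fraction
  of 0; zero baselines in any normalization yield missing values with a
  warning rather than infinities.
* Chain assembly tie-breaks are by lowest z-line id, making every
  decomposition deterministic.

## Known limitations

* The fibril orientation index and the fibril-grouping rule are this
  package's documented definitions; absolute values need not match any
  other implementation, though trends under degradation do.
* The bandpass assumes isotropic pixels; anisotropic data are rejected
  rather than resampled.
* Frequency estimation requires ≥ 2 detected beats; ~10-s recordings
  bound its resolution at ±0.1 Hz.
* Mono-exponential uptake cannot represent biphasic uptake; a second
  component would require an explicit model extension.
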