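# cardiotox

Quantitative imaging and kinetics readouts for anthracycline
cardiotoxicity screens on human stem-cell-derived cardiomyocytes.

Screens of this kind expose cardiomyocyte monolayers and engineered heart
tissues (EHTs) to compounds such as doxorubicin, amrubicin and
aclarubicin, and read out damage through fluorescence microscopy and
transient recordings. This package implements the computational half of
such a platform as one tested R pipeline:

* **Myofibril integrity** from α-actinin micrographs: a 2D-FFT bandpass
  restricted to the sarcomere period band (1.2–2 μm), a fixed-threshold
  binary mask (threshold 21 on the 8-bit filtered image), z-line
  extraction, myofibril chain assembly, and six per-image structure
  metrics (sarcomere presence, fibril number, fibril orientation index,
  sarcomere width, fibril length, fraction of assigned z-lines),
  normalized to the experiment's timepoint 0.
* **Viability** as the coverage fraction of Calcein/GFP signal above a
  hard per-batch threshold, averaged over fields per well and normalized
  to baseline and vehicle control.
* **Calcium/force transient kinetics** from 70-fps videos or traces:
  beat frequency, time-to-peak, time-to-decay, amplitude (force of
  contraction for EHT traces), contraction/relaxation velocities, and
  the diastolic baseline load read from the minimum-intensity frame.
* **DNA damage** as γH2AX focus counts per DAPI-segmented nucleus:
  percent positive nuclei and mean dots per positive nucleus.
* **Drug uptake/washout**: least-squares fits of the saturating
  exponential `v(t) = v0 + (P − v0)(1 − e^(−kt))` and the washout decay
  `v(t) = B + (I0 − B)e^(−λt)`, with the time-to-background horizon
  `ln(20)/λ` (5% criterion) and exposure-to-saturation mapping
  `1 − e^(−k·t)`.
* **Synthetic-data generators** with exact ground truth for every stage
  (striated-cell scenes, coverage fields, transient traces, nuclei+foci
  image pairs, uptake samples), used throughout the test suite.

## Worked example

```r
library(cardiotox)

# render a striated scene with known truth, then recover it
scene <- make_sarcomere_image(n_fibrils = 3, spacing_um = c(1.4, 1.6, 1.8),
                              orientation_deg = c(10, 70, 130),
                              noise_sigma = 5, seed = 4)
res <- analyze_sarcomere_image(scene$image)
res$metrics
#>   sarcomere_presence_px fibril_number orientation_index sarcomere_width_um
#> 1                   457             3        0.07371715           1.566711
#>   fibril_length_um assigned_zline_fraction
#> 1         11.19214                       1
res$fibrils[, c("n_zlines", "axis_orientation_deg", "mean_spacing_um")]
#>   n_zlines axis_orientation_deg mean_spacing_um
#> 1        8             70.03180        1.593139
#> 2        8             10.52235        1.408792
#> 3        8            129.17169        1.794700
```

The three chains are recovered exactly (8 z-lines each), with spacings
within 0.01 μm and axis orientations within 0.9° of the generating
values; every z-line is assigned to a fibril, so the assigned fraction
is 1. The orientation index is low because the three fibrils point in
widely different directions.

```r
# uptake kinetics: fit and map an exposure regimen to saturation
fit <- fit_uptake(make_uptake_samples(P = 0.9, k = 0.02,
                                      noise_sigma = 0.02, seed = 1)$series)
fit
#> Saturating-exponential uptake fit
#>   plateau P        = 0.9058
#>   rate k           = 0.02012 /min
#>   half-saturation  = 34.5 min
#>   RSS              = 0.00287 on 13 points
#>   bootstrap 95% CI: P [0.8932, 0.9182], k [0.01914, 0.02117]
saturation_at(fit, 120)   # fraction of plateau after a 2-h incubation
#> [1] 0.9105329
```

A shell interface wrapping the same functions is installed at
`inst/cli/cardiotox` (`cardiotox simulate|sarcomere|viability|transients|
foci|uptake --key value ...`).

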