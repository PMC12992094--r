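---
title: "Methods: multi-round immunofluorescence quantification with quant4i"
author: "quant4i authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-round immunofluorescence quantification with quant4i}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

quant4i processes iterative indirect immunofluorescence (4i)
experiments: the same tissue field of view is stained, imaged and
eluted over several rounds, so that each round contributes a
multi-channel image stack of the same cells.  Inputs follow a strict
layout — one folder per round, identical file names across rounds, the
site (field of view) number as a trailing suffix (`example_1.tif`) —
and each stack is a single multi-page TIFF with page order equal to
channel order.  The acquisition convention does not record a
page-to-channel mapping beyond acquisition order, so page order *is*
channel order; this is an assumption, stated here once.

Intensities originate as 12- or 16-bit integers; internally everything
is floating point and nothing is clipped at zero after background
subtraction, so that downstream means remain unbiased.  Persisted
images (masks, crops) are clipped and rounded back to 16-bit.

Cell identity is defined once, by the nuclear mask of the reference
round (`primaryMaskRound`): all rounds are measured under that mask
after registration.  Masks computed for the other rounds serve quality
control (overlays, round-to-round concordance), never identity.

# Registration

The jitter between rounds is modelled as a rigid integer-pixel
translation — the physical situation is a stage that does not return to
exactly the same position, so rotation and deformation are out of
scope.  The estimator cross-correlates the mean-subtracted jitter
channel of each round against the reference round via the FFT over the
full circularly wrapped shift surface, after smoothing both with the
channel's `sigblur` circular-averaging radius.  Whether the original
workflow preprocesses the jitter channel before matching is not
documented; smoothing with the already-configured `sigblur` is this
package's choice and is visible in the configuration.

The global correlation argmax is located; if it lies outside the
±`maxjit` window the run stops with the error `Max jitter too high`.
Defining the error through the *global* peak (rather than treating a
window-boundary hit as an error) keeps every shift with |d| ≤ `maxjit`
recoverable while still failing loudly for true out-of-bound
displacements.  Correlation ties are broken toward the smaller
|dy| + |dx|, then lexicographically, for determinism.  Sub-pixel
refinement is deliberately absent: the displacement is integer-valued
by construction and keeping it integer preserves exact pixel identity
across rounds.

After estimation, all rounds are cropped to the intersection of the
shifted fields, so pixel (i, j) addresses the same physical location in
every round.

# Preprocessing

The per-channel order is fixed: camera (CMOS) background subtraction →
software binning (`postbin`, block mean) → smoothing (`sigblur`) →
background subtraction (`bgsubmethod`) → bleed-through correction →
measurement.  Smoothing is applied after cropping; disc averaging
commutes with cropping except within one radius of the border.

Background modes:

* `global nuclear` / `global cyto` subtract a single scalar: the
  `bgperctile`-th percentile (default 25) of pixels outside the
  nuclear (resp. cytoplasmic) mask, computed on an image downscaled by
  `compression` (default 4, block mean).  `signal_foreground = 1`
  additionally excludes bright foreground by an Otsu mask of the
  channel itself.  The configuration text ties `compression` to
  segmentation method names; those names only exist for
  `bgsubmethod`, so it is treated as a background-subtraction
  parameter.
* `tophat` subtracts the morphological opening with a flat disc of
  radius `2·nucr`.  The radius must exceed the nuclear radius so whole
  nuclei survive as foreground; the factor 2 is this package's choice.
* `semi-local nuclear` divides the downscaled masked image into an
  11×11 grid of blocks, takes the per-block background percentile and
  bilinearly upsamples it — "semi-local" behaviour at any image size.
* `none` is the identity.

Bleed-through is a linear mixing model: the corrected channel is
`target − slope·source − offset`, with per-round channel-pair matrices
supplied in the configuration.  Estimating the coefficients from data
is out of scope.  Correction is applied after background subtraction so
the offsets compose predictably.

EBImage's grayscale morphology binarises its input, so the flat-disc
grayscale erosion/dilation underlying the opening, top-hat and
related steps is implemented directly in the package (replicate-padded
min/max filtering over disc offsets).

# Nuclear segmentation

All threshold-family methods share: disc-average blur with
`blurradius` (default 3), a method-specific threshold, hole filling,
connected-component labelling.  Candidates are produced *before* the
area/solidity gate so the filter is observable on its own.

* `thresh` — Otsu's threshold, computed exactly on the empirical
  histogram (every distinct intensity is a candidate split), so it
  equals a brute-force inter-class-variance scan; ties go to the lowest
  split.  A constant image is degenerate and flagged.
* `single` / `double` / `multithresh` — threshold variants followed by
  watershed on the Euclidean distance transform.  `double` computes a
  second Otsu threshold over above-threshold pixels; since that upper
  mask is a subset of the first, the union step it prescribes is a
  no-op and the practical difference lies in `double marker`, where the
  bright cores seed a marker-controlled propagation.
* `concavity` — threshold at the knee of the cumulative intensity
  distribution (maximum deviation from the endpoint chord), a
  deterministic reading of "most convex and concave point of the
  distribution".
* `log` / `log contour` — scale-normalised Laplacian-of-Gaussian
  response at scale `nucr/√2` on log-scaled, max-normalised intensity;
  pixels with response below `blobthreshold` (default −0.02; more
  negative = stricter) are blob cores, optionally grown into an
  intensity-supported region by seeded propagation.
* `Nuc-Ecad boundary` — `thresh`, then concatenated nuclei are cut
  where the E-cadherin signal inside an object exceeds
  `split_mult` × the object's mean E-cadherin level (default 1).  The
  exact ridge statistic of the original implementation is not
  documented; the mean-baseline rule used here is validated against
  fixtures only.  Ridge pixels are reassigned to the nearest piece;
  pieces get fresh ids.  Raising `split_mult` removes ridge pixels
  monotonically, so the label count never increases with it.
* `Ecad boundary` — delegates wholly to membrane-based cell
  segmentation; centroids and areas then describe cells, not nuclei.

Watershed splitting delegates to EBImage's deterministic flooding;
plateau ties therefore follow the library's order rather than an
explicit lowest-id rule.  Objects touching the image border are kept —
after alignment cropping, border cells are common.  Holes are filled
before area measurement.

The gate removes objects outside [`debrisarea`, `boulderarea`] or with
solidity below `soliditythresh` (default 0.5, inside the recommended
0.3–0.8 band).  Solidity is object area over convex-hull *pixel* area
(lattice points inside the hull), which agrees with the area ratio a
pixel-counting oracle produces; the gate is idempotent.

# E-cadherin processing

Edges come from the Gaussian-smoothed (`Gaus_filter_sigma`) membrane
channel, by Canny (default) — Sobel gradients, non-maximum suppression,
hysteresis with the strong threshold set by Otsu on the nonzero
gradient magnitudes and the weak threshold at 0.4× strong — or by
Laplacian-of-Gaussian zero-crossings with an amplitude floor.  Both
return empty masks on flat images (an explicit relative floor guards
against FFT ripple).  The Canny threshold rule is parameter-free by
design and configurable.

The E-cad-positive area closes the edge mask with a disc of radius
`R_strel_edge`, fills holes with `Pixel_connectivity` (4 or 8), and
closes again with `R_strel_extended`.  Closings with discs are monotone
in the radius, and hole filling is monotone in the set, so the area
never shrinks as either radius grows — a property the tests check.
Cell segmentation labels the interior regions bounded by the closed
edges and removes regions below `Max_pixels`; the parameter's name says
maximum but its description says minimum, and the description wins.

A cell is E-cadherin positive when at least half of its nuclear pixels
(threshold configurable as `ecad_overlap`, boundary case positive) lie
inside the positive area.  No overlap fraction is prescribed anywhere;
0.5 is the package default.

# Quantification

The cytoring of nucleus i is the set of background pixels whose
Euclidean distance to i's mask lies in (`innerrad_cytoring`,
`outerrad_cytoring`] (defaults 1 and 5), excluding all nuclear pixels
and pixels nearer to a different nucleus.  Contested pixels go to the
nearest nucleus — whether the original resolves contested pixels by
distance or exclusion is unknown; nearest-nucleus assignment was
chosen, with ties to the lower id.  The construction uses one exact
Euclidean distance transform per label, so it agrees *exactly* with a
brute-force nearest-mask-pixel oracle.

Statistics: nuclear signal is the mean over the mask; the cytoring is
the median of pixels at or above `ringthresh`, missing when fewer than
`minringsize` pixels qualify.  The median guards the narrow ring
against bright neighbours; neither statistic is prescribed by the
protocol, both are documented here.

Puncta: white top-hat with a disc of radius `punctatopsize`; pixels at
or above `punctaThresh` form candidate components; each component is
assigned to the cell whose compartment (nucleus, or nucleus thickened
by `thickenradius` minus all nuclei when `cytopuncta = 1`) contains its
peak pixel.  Both the count and the integrated top-hat intensity are
emitted, because the output quantity is not fixed by the protocol.
`punctaThresh` is determined from the top-hat image background, as the
protocol's debug step instructs.

Local background (`localbg`) is the `bgperctile` percentile of
non-nuclear pixels in a square box of half-width `10·nucr` around the
cell centroid; the box size is a package choice.

The feature table has one row per reference-round cell and a fixed
column order: x, y (centroid, pixels), nuclear area (pixels), then per
round × channel the enabled measures (nuclear; cytoring; puncta count
and intensity; local background), then the E-cadherin flag.  Missing
values propagate as NA and are never zeroed.  On disk it is a CSV with
a plain-text header sidecar — a portable equivalent of the original
MATLAB container.

# Spatial analysis

The POI per cell is `nuc`, `cyto`, `nuc-cyto` or `cyto-nuc` over two
configured feature-table columns.  Profiles convert the row coordinate
to micrometres (`pixelsize`, µm/px) and aggregate into 20 µm bins
([k·w, (k+1)·w)); per occupied bin the mean and *population* SD are
reported.  Concordance between consecutive rounds is
100·|positive in both| / |positive in round N| (and the analogue over
negatives); it is undefined (NA) on an empty denominator and is not
symmetric in the two rounds.  The positivity rule behind published
concordance figures is not stated; the default here is an Otsu cut on
the per-round POI distribution, with a fixed threshold as the
alternative.

# The synthetic scene generator

`generateScene()` renders, in a fixed order, cells (a membrane lattice
with 2 px lines and optional gaps) → nuclei → puncta → bleed-through
mixing → background (constant + ramp + fixed camera pattern) → integer
jitter shift → additive Gaussian noise → 16-bit quantization, and
returns the full ground truth (centres, radii, applied shifts, mixing
coefficients, spot positions) plus the pre-noise and pre-mixing images
for exact oracles.

Deliberate realism choices: nuclei are radial-falloff plateaus
`A/(1 + (d/r)^10)` rather than hard discs — hard discs make watershed
trivially exact and hide bugs — and abutting nuclei compose by maximum,
as overlapping chromatin staining plateaus rather than adds.  Puncta
are Gaussian spots (σ = 1 px) at least 6 px apart inside the inner 70%
of the nuclear radius: foci that are closer merge into one
above-threshold component under any component-based counter, so the
generator produces scenes in which counting is well-posed.  Noise is
independent additive Gaussian; Poisson statistics, spatially correlated
noise, illumination vignetting, tissue autofluorescence, staining
heterogeneity and focus drift are *not* modelled.  Passing tests
therefore demonstrate algorithmic correctness against the stated model,
not robustness on real tissue.

Study conditions used by the validation suite (also the problem sizes):
isolated-nuclei scenes with 30 nuclei of radius 8 px on 400×400 fields;
jitter fields of 256×256 with shifts up to ±20 px and signal-to-noise
ratio 5 defined as nuclear amplitude over noise SD (3000/600); puncta
scenes with 11 nuclei of radius 16 px carrying 0–10 spots of amplitude
2000 (SNR 5 = 2000/400), counted with `punctatopsize = 3` and
`punctaThresh = 650` after 1 px smoothing; membrane lattices with 40 px
pitch; concatenated pairs at 1.5·r separation bisected by a 2 px line.

# Numerical choices and degenerate inputs

* Otsu is exact over unique intensities (two-level Otsu binned to 256
  levels above that); ties take the first maximum; constant images are
  flagged degenerate rather than erroring.
* Percentiles use R's default quantile interpolation (type 7).
* Block means define downscaling; bilinear interpolation at block
  centres defines upsampling.
* Distance assignment ties (rings, split pieces) go to the lower id.
* Empty masks, empty edge images and zero-cell tables flow through
  every stage and produce empty-but-well-formed outputs.
* All randomness lives in the generator and is seed-controlled; the
  pipeline itself is deterministic, so repeated runs are byte-identical
  and batch output equals serial per-site output.

# Limitations

Registration is translation-only and integer-valued.  The cytoring
assignment is geometric and ignores intensity.  Per-label distance
transforms make ring construction O(cells) transforms — exact, and
adequate at the field sizes above, but a bottleneck for fields with
thousands of cells.  The `double` threshold method is operationally
close to `single` (see above).  Real-tissue effects listed under the
generator are untested by construction.
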