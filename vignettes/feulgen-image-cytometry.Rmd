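---
title: "Feulgen DNA image cytometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feulgen DNA image cytometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feulgenICM)
```

## The measurement problem

Feulgen staining binds dye stoichiometrically to DNA, so the amount of
light a nucleus absorbs is proportional to its DNA content. In a
brightfield image the per-pixel optical density is

$$OD_i = -\log_{10}\!\left(\frac{IF_i}{IB_i}\right),$$

where $IF_i$ is the transmitted (foreground) intensity at pixel $i$ and
$IB_i$ the incident (blank-field) intensity at the same position. The
integrated optical density of a nucleus,

$$IOD = \sum_{i=1}^{n} OD_i,$$

is therefore a relative measure of its DNA content. Absolute content is
obtained against a reference population of normal cells whose DNA mass per
1C complement ($C_p$, picograms) is known:

$$C_s = \frac{IOD_s \times C_p}{IOD_p},$$

with $IOD_p$ the mean IOD of the reference. The package reports the
dimensionless ratio $IOD_s / IOD_p$ as **ploidy**, which places the
reference population at 1 by construction; for mussel haemocytes the
primary standard is $1C = 0.96$ pg. The package deliberately stops at the
ratio: whether "1" is haploid or diploid in genome-biology terms is an
interpretation the data alone cannot settle.

The intended use is the study of haemic neoplasia (HN) in mussels:
neoplastic haemocytes are grossly aneuploid, and histograms of per-nucleus
ploidy show discrete aneuploid populations (around 6.2n and 10.7n in
light disease, 7n in moderate, 7.8n plus a broad component near 31n in
heavy disease, the latter attributed to multinucleated giant cells whose
overlapping nuclei integrate as one object).

## The processing chain

`run_pipeline()` wires the stages together; each is exported on its own.

1. **Frame averaging** (`average_frames`): the mean of repeated exposures
   divides sensor noise by $\sqrt{k}$ (eight shots in the source
   protocol).
2. **Green channel** (`extract_green`): the Feulgen-DNA complex absorbs
   most strongly in the green; the other channels are discarded.
3. **Background correction** (`background_correct`): per-pixel division
   by a blank field removes illumination gradients exactly; a scalar
   (mean of a clear region) is accepted when no blank frame exists.
4. **Optical density** (`to_optical_density`): $-\log_{10} T$, clipped at
   `od_max = 3` — an 8-bit sensor cannot resolve transmittances below
   about $10^{-3}$ (one grey level), so larger ODs are not measurable and
   are reported at the ceiling.
5. **Segmentation** (`segment_nuclei`): Otsu threshold on the green
   intensity image (nuclei are the dark class), hole filling,
   deletion of components touching the frame edge, distance-transform
   watershed to separate touching nuclei, size filter, optional
   label-preserving dilation, optional exclusion mask.
6. **Morphometry** (`measure_all`): the 21 descriptors below.
7. **Densitometry** (`integrated_od`, `calibrate_reference`, `ploidy`,
   `ploidy_profile`): IOD per nucleus, ploidy against the reference
   calibrated from the images labelled `"normal"`, smoothed histograms,
   peak detection.
8. **Statistics** (`describe_features`, `two_group_test`, `ks_compare`,
   `multi_group_comparison`, `stepwise_lda`): the analysis battery.

### Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `pixel_size_um` | 0.45 | µm/px | the acquisition geometry of the source material; note its own caption elsewhere quotes 0.624 — the two are irreconcilable from the text, so the value is a configuration item and all measurements are reported in pixels |
| `od_max` | 3.0 | OD | 8-bit dynamic-range limit |
| `n_bins` | 256 | – | Otsu histogram resolution |
| `min_px`, `max_px` | 25, 300 | px | published single-nucleus size filter; the pipeline default raises `max_px` to 800 because neoplastic nuclei average >400 px² (see *Limitations*) |
| `min_distance` | 5 | px | merge radius for watershed seed cores |
| `seed_frac` | 0.75 | – | seed cores are the distance-transform regions above this fraction of the per-component maximum |
| `bin_width` | 0.2 | C-ratio | ploidy histogram resolution |
| `window` | 7 | bins | running-average smoothing, centred, shrinking at the edges |
| `min_prominence` | 0.05 | fraction of max | a "shallow but broad" high-ploidy shoulder at ~15% mixture weight must still be reported |
| `f_enter`, `f_remove` | 3.84, 2.71 | F | conventional stepwise thresholds |
| `Cp` | 0.96 | pg | primary standard, 1C of normal haemocytes |

### Watershed seeding

The textbook recipe — seeds at distance-transform maxima with a minimum
separation — oversplits elongated nuclei: an ellipse's distance ridge is
nearly flat, so it carries several spurious maxima farther apart than any
reasonable separation radius. Instead, seeds here are the connected
regions where the (3×3-smoothed) distance transform exceeds
`seed_frac` × the component's maximum. A single convex or elongated
nucleus keeps exactly one core for any fraction, because distance decays
monotonically from its medial ridge; two touching nuclei are split
whenever their neck is shallower than `seed_frac` of the lobe radius
(the canonical two-disc phantom, radius 10 and centres 16 px apart, has a
neck ratio of ~0.70, hence the 0.75 default). `min_distance` is kept as a
merge radius for cores inside the same component. Watershed ridge lines
are returned as background, so labels never share pixels.

## The 21 descriptors

Size measures (pixels): `Perimeter` (length of the closed polygon through
boundary-pixel centres, Moore-traced with 8-connectivity), `Area`
(shoelace area of that polygon), `MinR` (radius of the inscribed circle
centred at the pixel centre of mass, i.e. the nearest approach of the
centroid to the boundary polygon), `MaxR` (farthest boundary vertex from
the centroid), `Feret` (largest boundary-point distance, computed on the
convex hull), `Breadth` (boundary extent perpendicular to the Feret
chord — not the minimal width over all directions), `CHull` (hull
perimeter), `MBCRadius` (minimal enclosing circle radius, Welzl's
algorithm). Densitometric: `IOD`, `GrAverage` (= IOD / pixel count, in OD
units). Ratios: `AspRatio = Feret/Breadth`,
`Circularity = 4πA/P²`, `Roundness = 4A/(πFeret²)`,
`Compactness = sqrt(4A/π)/Feret`, `Solidity = A/ConvexArea`,
`Concavity = ConvexArea − A`, `Convexity = CHull/P`, `Shape = P²/A`,
`ModRatio = 2·MinR/Feret`, `Sphericity = MinR/MaxR`,
`Rectangularity = A/(Feret·Breadth)`.

Conventions worth spelling out:

* **Polygon, not pixel-count, area.** `Area` follows the boundary-centre
  polygon; the raw pixel count is kept in a separate `pixel_count`
  column and is what the size filter uses. This keeps `Solidity`,
  `Concavity` and `Convexity` internally consistent (hull and region
  share the vertex convention). For a digitised disc of radius $r$ the
  polygon area tracks $\pi (r - 1/2)^2$, so it differs from $\pi r^2$ by
  roughly $1/r$ — negligible for the nuclei of interest but visible on
  small phantoms.
* **Perimeter bias.** The polygon path length through boundary-pixel
  centres overestimates the perimeter of a smooth shape by a few percent
  (diagonal steps contribute $\sqrt 2$). A perfect digitised disc
  therefore has `Circularity` ≈ 0.87, not 1.0 — the same bias the
  original instrument shows (its round neoplastic nuclei average 0.81).
  Shape comparisons between groups measured with the same convention are
  unaffected; absolute circularities should not be read against the
  ideal-circle value of 1.
* **Degenerate regions** (< 3 boundary points): `Area` = pixel count,
  `Perimeter` = 0, every ratio `NA` — counts stay honest without
  dividing by zero.
* The algebraic identities `Shape × Circularity = 4π` and
  `Compactness² = Roundness` hold for every measured region and are
  asserted in the test suite, as is exact agreement of `Feret`,
  `Breadth`, `MBCRadius`, `Perimeter` and `Area` with brute-force
  $O(n^2)$/$O(n^3)$ oracles.

## Ploidy profiles and peak detection

Histograms use a fixed grid (bin width 0.2 C-ratio units over [0, 40])
so that profiles from different stages are directly comparable, and are
smoothed with a centred running average of size 7 (shrinking symmetrically
at the edges), preserving large-scale features while suppressing bin
noise. Peaks are local maxima of the smoothed curve with prominence at
least 5% of its maximum; prominence is measured against the highest
saddle towards higher terrain on either side.

The reported peak *location* is the raw-count centroid of the contiguous
bins within half a prominence of the peak top. The smoothed curve is used
to find peaks and delimit their support, but not to place them: near the
left edge of the histogram the shrinking smoothing window makes the
smoothed curve asymmetric, which would bias a smoothed-centroid (or
smoothed-mode) location of the 1n peak upward by a quarter bin or so. The
raw-count centroid is unbiased for symmetric components and recovers the
preset components at 1, 6.2, 10.7, 7, 7.8 and 31 within a few percent at
realistic sample sizes.

## Statistics

* **Two-group comparisons** use Welch's unequal-variance t by default
  (`var_equal = TRUE` recovers Student's). The source analysis says only
  "t test"; Welch is the safer default under the very unequal group
  variances seen here.
* **Multi-group comparisons** are one-way fixed-effects F tests per
  feature — the "general linear model" group comparison reduces to
  exactly this for a single categorical predictor. For two groups,
  F = t² (pooled t) holds and is tested.
* **Distribution shape** comparisons use the two-sample
  Kolmogorov–Smirnov D with asymptotic p.
* **Stepwise linear discriminant analysis** performs forward–backward
  selection minimising Wilks' Λ with partial-F thresholds 3.84 (enter)
  and 2.71 (remove) — the conventional defaults of the statistical
  package used for the original analysis, which reports none.
  Classification is Fisher's rule: nearest class mean in Mahalanobis
  distance under the pooled within-class covariance, equal priors.
  Confusion matrices are resubstitution by default (the way such tables
  are usually produced), with leave-one-out available (`cv = "loo"`).
  A singular pooled covariance receives a logged ridge.
* **No multiplicity correction** is applied by default across the 21
  features, mirroring the original reporting of raw P < 0.05; this
  inflates the family-wise error rate and should be borne in mind.

## The synthetic stated world

The generator exists so that every downstream stage is testable without
archival slides; its defaults are the conditions the source work states,
with gaps filled once and documented here.

What it emulates: dark Feulgen-stained nuclei on a bright background;
stain amount stoichiometric with DNA content (each nucleus's OD field is
normalised to integrate to `od_per_C × dna_content` exactly, so
Beer–Lambert conservation is exact before noise); transmitted intensity
`IF = IB · 10^(−OD)` with the full absorption on the green channel and
attenuated absorption on red and blue (the dye is magenta); linear
illumination gradients; additive Gaussian sensor noise clipped to
[0, 255]; two neoplastic morphotypes (A: ovoid, pleomorphic, vesicular,
boundary irregularity 0.16, aspect up to 1.9; B: round, larger, dense
chromatin texture); touching pairs; multinucleate clusters of 3–6
overlapping round lobes forming one connected blob under a single
ground-truth label (the rendering of the 31n component).

Chosen defaults, with reasons:

* **Stage mixtures** — peak positions are stated by the source; weights
  are not. Defaults: light 0.5/0.35/0.15 at 1/6.2/10.7n, moderate
  0.4/0.6 at 1/7n, heavy 0.3/0.55/0.15 at 1/7.8/31n. Component CV 0.08
  (no dispersion is published for the peaks).
* **`od_per_C = 19` OD·px** — makes a 1C nucleus of typical normal area
  (~113 px) average ~0.17 OD per pixel, matching the observed normal
  mean grey average; it also implies heavy-stage 31n clusters genuinely
  graze the 1-grey-level floor, which the renderer reports with a
  warning — the same saturation the source attributes to overlapping
  packed nuclei.
* **Geometry** — base radii 6.1 / 8.9 / 11.1 px for normal / A / B
  reproduce the published mean areas (117 / 250 / 390 px²).
* **Noise SD 2 grey levels, background 220** — a clean, well-exposed
  brightfield camera after 8-frame averaging; both are knobs, not claims.
* **Feature-level sampling** (`sample_feature_table`) draws from the
  published group means/SDs. Positive unbounded features use a
  moment-matched Gamma rather than a truncated Gaussian: truncating a
  Gaussian with 11% of its mass below zero (nuclear area, 117 ± 94)
  would bias the sample mean by several px², violating the very means
  the simulation must reproduce. Unit-interval ratios are clipped
  Gaussians; ordering constraints (MinR ≤ MaxR, Breadth ≤ Feret,
  Feret ≤ 2·MBCRadius ≤ 2·MaxR) are repaired after sampling. Some
  published B-cell SDs are evident typos (e.g. Circularity 0.58 ± 0.71);
  they are used verbatim and clipped at the valid range.

What it does **not** emulate: H&E staining, tissue context and
non-haemocyte nuclei, 3-D sectioning and out-of-focus light, chromatic
aberration, photorealistic chromatin texture. A green segmentation test
therefore establishes that the chain recovers well-separated elliptical
nuclei under the stated noise — not performance on real histology, where
debris, tissue nuclei and focus variation dominate the error budget.

## Numerical choices

* Otsu tie-break: the lowest bin edge among between-class-variance
  maximisers. On well-separated bimodal data the criterion is *exactly*
  flat across the empty gap between the modes, so the returned threshold
  sits just above the dark mode rather than mid-gap; any threshold on
  the plateau yields the same segmentation.
* OD floor `ε = 10^(−od_max)`; transmittance is clipped to (ε, 1] before
  the log.
* Welzl's minimal-circle recursion runs on convex-hull vertices only
  (tens of points), with exhaustive pair/triple search retained as the
  test oracle.
* Coordinates are 0-based, x right, y down, pixel centres at integers;
  all geometry uses double precision.
* Scene and run configurations serialise to JSON with 17 significant
  digits so that a restored specification re-renders bit-identically.

## Known limitations

* **Otsu on trimodal scenes.** Disease-stage scenes contain three
  intensity populations (background, faint 1n nuclei, dark aneuploid
  nuclei). A single Otsu threshold can land between the dark class and
  everything else and then drops part of the faint 1n population. The
  source workflow dealt with its analogue by manual editing; here the
  limitation is documented and the strict segmentation-recovery tests
  use single-population scenes.
* **Size filter conflict.** The published 25–300 px filter is
  incompatible with the published neoplastic mean area of 423 px²; both
  cannot be right for the same measure. `segment_nuclei` keeps the
  printed bounds as defaults, the pipeline raises `max_px` to 800, and
  both are configuration items.
* **Multinucleate clusters** are one ground-truth object but can be
  split by the watershed (or saturate densitometrically); their ploidy
  is by construction an artefact of overlap, as the source itself
  argues for the 31n peak.
* **A-cell pleomorphism** (irregularity 0.16) occasionally yields
  bilobed shapes whose distance transform carries two legitimate cores;
  such nuclei may be oversplit. At the default parameters this affects
  of the order of 1 nucleus in 40 on moderate scenes.
* Resubstitution classification rates are optimistic; use `cv = "loo"`
  for honest error estimates on small tables.
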