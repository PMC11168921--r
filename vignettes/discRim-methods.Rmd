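---
title: "discRim: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{discRim: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discRim)
options(discRim.verbose = FALSE)
```

# The measurement model

discRim quantifies where a nuclear mark sits within an epithelial
tissue section. Its central statistic is the reference-normalized
rim/centre ratio. Given a binary tissue mask, the **rim** is the set of
foreground pixels whose Euclidean distance to the nearest background
pixel is at most a fixed width $w$ (in pixels), and the **centre** is
the remaining foreground. With mark channel $M$ and normalization
channel $D$,

$$\mathrm{ratio} \;=\;
\frac{\sum_{\mathrm{rim}} M \,/\, \sum_{\mathrm{rim}} D}
     {\sum_{\mathrm{centre}} M \,/\, \sum_{\mathrm{centre}} D}.$$

The normalization is applied *per region* and the two normalized
quantities are then divided. This is the only reading of "integrated
intensities normalized to the reference, displayed as rim versus
centre" that yields a dimensionless quantity, and it makes the ratio
invariant to staining efficiency and to any global rescaling of either
channel — an invariance the test suite asserts directly.

Assumptions built into this model:

* a single connected, hole-free tissue region per analysed section;
* the mark scales with the reference within a region (DAPI for nuclear
  marks, since chromatin content sets the denominator; mitoGFP for
  TMRM, since mitochondrial mass does);
* measurements are 2-D, on single optical sections or sum projections —
  the rim band, all distances and all masks are per-section, never
  volumetric.

# Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| rim width, immunofluorescence | 10 | px | standard band width for histone-mark quantification |
| rim width, TMRM/mitoGFP | 13 | px | wider band used for membrane-potential imaging |
| distance bin edges | 5, 10 | µm | nuclei are scored as surface-facing (<5), intermediate (5–10) or interior (>10) |
| bin normalization reference | `<5` bin | — | interior values are expressed relative to the surface-facing mean |
| tissue smoothing $\sigma$ | 2 | px | suppresses shot noise before thresholding |
| nucleus smoothing $\sigma$ | 1 | px | preserves separation between adjacent nuclei |
| minimum nucleus area | 20 | px² | rejects noise specks below any plausible nucleus |
| watershed tolerance | 10 | a.u. | peaks separated by saddles shallower than this merge, so smoothed noise does not oversplit nuclei |
| ratiometric floor | 5 % of max ex405 | a.u. | masks pixels whose denominator is too dim for a stable ratio |
| ROUT Q | 0.01 | — | conventional 1 % false-discovery rate for outlier flagging |

Rim widths are deliberately specified in *pixels*, mirroring how such
bands are defined in practice; `partitionRimCentre(widthUm = ...)`
converts from micrometres via the pixel calibration, rounding half-up.

# Geometry conventions

Arrays are base-R 1-based with dimension order (z, y, x); all physical
distances are micrometres via `pixelSizeXY`. Distance-to-surface is the
Euclidean distance to the nearest *background pixel*, so a foreground
pixel touching the boundary carries 1 px, a 1-px-wide structure carries
1 px everywhere, and the image border does not count as background
(masks are expected to be surrounded by imaged background, as the
phantoms guarantee). The rim band uses the Euclidean distance transform
rather than square-structuring-element erosion: isotropic thickness
behaves correctly at high-curvature corners of the mask, and a fixed
numeric threshold can reproduce erosion behaviour if needed.

A nucleus's surface distance is taken at its *most outward-facing
pixel* — the minimum of the distance map over its pixels. The distance
to the nearest mitochondrion is the minimum pairwise pixel-centre
distance between the two objects (0 when they share pixels). With this
convention a single-pixel nucleus at (1, 1) and a single-pixel
mitochondrion offset by (3, 4) are exactly 5 px apart; objects in
pixel-adjacent contact score 1 px, which at typical calibrations is
well below any biologically meaningful distance.

Distance bins are half-open, $[0,5)$, $[5,10)$, $[10,\infty)$ µm: the
printed labels "<5", "5–10", ">10" force a convention only at the
edges, and the half-open choice (5 µm falls in "5–10") is declared and
tested rather than left to chance.

# Segmentation choices

Tissue masks default to a **two-threshold Otsu, lower cut**
(`"multiotsu_lo"`): DAPI sections contain three intensity populations
(slide background, cytoplasmic/tissue signal, bright nuclei), and
plain Otsu can land between tissue and nuclei, reducing the "tissue"
to the nuclei alone. The lower threshold of a three-class Otsu
separates slide from tissue regardless. Plain Otsu and fixed numeric
thresholds remain available, and externally drawn masks (e.g. manual
outlines) can be imported via `tissueMaskFromMatrix()`, since manual
outlining is how such masks are usually produced in practice.

Nucleus segmentation estimates its Otsu threshold *within* the tissue
mask when one is supplied, so the threshold separates nuclei from
cytoplasm rather than tissue from slide. Touching nuclei are split by
a watershed on the smoothed DAPI intensity.

# Statistics

All rank tests break ties by midranks. The Mann–Whitney p-value is
exact — full enumeration of rank assignments — when both groups have at
most 8 observations and no ties occur, otherwise the normal
approximation with tie and continuity correction is used (and logged).
The Wilcoxon signed-rank p-value is exact for up to 15 non-zero
differences by enumeration of all sign patterns on the midranks, which
remains valid under the symmetry null in the presence of ties. Both
exact paths are verified against independent brute-force enumeration
oracles in the test suite, and the Mann–Whitney approximation holds its
nominal type-I error (5 % ± 1.5 % over 2,000 null simulations at
n = 10 per group).

Dunn's pairwise comparisons use z statistics on pooled midranks with
the tie-corrected variance. The family-wise adjustment is Šídák
($p_\mathrm{adj} = 1-(1-p)^m$) by default, with Bonferroni and none as
options — the adjustment family behind "Dunn's multiple comparisons" is
not standardized, so the choice is surfaced as a parameter rather than
hidden.

The two-way ANOVA uses type-II sums of squares, computed from nested
model comparisons, because disc counts per condition are rarely
balanced; the implementation is cross-checked against `car::Anova` on
unbalanced data in the tests. Pairwise cell-mean comparisons within the
second factor use pooled-MSE t tests with Šídák adjustment over all
pairs computed. Degenerate noise-free inputs are reported with the
convention $SS = 0 \Rightarrow F = 0,\ p = 1$ (and a perfect fit with a
real effect as $F = \infty,\ p = 0$), so exact null fixtures behave
predictably.

ROUT outlier flagging is implemented for the one-sample case: residuals
from the median, scaled by a robust standard deviation (the 68.27th
percentile of absolute residuals inflated by $\sqrt{n/(n-1)}$), are
examined from the most extreme inwards and flagged while the two-sided
t probability stays below the stepwise FDR threshold
$Q\,(n-i+1)/n$. The procedure is deterministic and invariant under
affine transformation of the data.

# The phantom generator

The generator emulates exactly the spatial structures the analysis
assumes, with every generated quantity recorded as ground truth:

* **disc_xy** — an elliptical tissue region (160 × 160 px at
  0.5 µm/px) whose mark channel is enriched by a factor $R$ in the true
  rim band; the band is defined by the *same* Euclidean-distance rule
  as the segmentation module, so geometric and measured $R$ coincide by
  construction when the widths match. The mark field is generated
  proportional to the DAPI field (nuclear marks scale with chromatin
  content), which makes the DAPI-normalized ratio equal $R$ exactly in
  the noise-free limit even with textured DAPI. Nuclei are hard-core
  placed (rejection sampling with a bounded attempt budget) so the
  label-count ground truth is guaranteed; a reporter channel fills a
  configurable fraction of the tissue from one side.
* **cross_section** — a band epithelium (96 × 256 px) with nuclei whose
  most outward-facing pixel sits at requested surface distances
  (default 1–17 µm, populating all three bins), quantized to the pixel
  grid; the true nuclear mark mean follows a configurable monotone
  depth profile (default exponential decay with hi = 200, lo = 20,
  $\tau$ = 5 µm). Mitochondria are scattered as small labelled objects.
* **sensor** — a smooth positive 405 nm excitation dome with the
  488 nm channel equal to 405 times a true ratio field (uniform, or
  stepping by a factor — default 2 — in the rim band).

Noise is Poisson shot noise at a configurable photon scaling (default
1.0, i.e. ≈10 % CV at the base intensity of 100 counts) followed by
additive Gaussian read noise (default SD 5 counts); when any noise is
active, pixel values are rounded to non-negative integer counts, as a
real detector would produce. Both terms can be zeroed, in which case
the exact ideal field is emitted and construction identities hold to
floating-point precision. Generation is fully deterministic given the
spec (seed included) — byte-identical TIFFs across runs.

What the phantoms do **not** emulate: optical point-spread blur,
depth-dependent attenuation, uneven illumination, autofluorescence,
peripodial-versus-columnar layer structure, or irregular disc outlines.
Passing the phantom suite therefore demonstrates that the *measurement
machinery* is correct and noise-robust, not that segmentation defaults
will fit every real image — on real data the thresholds and manual-mask
import exist precisely because tissue appearance varies.

# Numerical and I/O details

* TIFF stacks are written channel-major with a JSON sidecar carrying
  channel roles, calibration and the intensity scale. The default
  16-bit mode stores integer detector counts exactly; the 32-bit mode
  stores values scaled by $1/65536$ with a quantization step of
  $65536/2^{32} \approx 1.5\times10^{-5}$ counts. Fiji-style resolution
  tags are honoured on read; explicit arguments override file metadata
  with a warning.
* Otsu thresholds are computed on 256-bin histograms over the observed
  intensity range.
* Empty compartments, empty nuclei sets and fully-invalid ratio maps
  are logged results, not errors; empty rim or centre regions and
  zero reference sums abort the ratio with a measurement error, since
  no meaningful value exists.
* When nuclei are binned across genotypes, normalization to the <5 µm
  bin is per-group by default (each genotype's own reference bin); a
  pooled reference is a deliberate, explicit alternative.

# Problem sizes in the validation suite

The test and acceptance runs use 160 × 160 px disc phantoms (20 seeds
per enrichment factor, $R \in \{1, 2, 3, 5\}$), 96 × 256 px
cross-sections with 12 nuclei, 64 × 64 px phantoms for exhaustive
pixel-level oracle comparisons, and 2,000 null simulations for the
type-I error calibration — sizes chosen so the full suite validates
every code path in well under a minute per module on one CPU while
keeping Monte-Carlo bands tight.

# Known limitations

* Strictly 2-D: no volumetric masks or 3-D distances.
* No image registration, deconvolution, bleaching or background
  correction (a constant-offset subtraction flag is the only
  concession); inputs are assumed to be calibrated, single-position
  confocal sections.
* Automated tissue segmentation assumes one dominant tissue piece per
  field; debris larger than the tissue would defeat the
  largest-component rule.
* The ROUT implementation covers the univariate location case only —
  the regression variant is out of scope.
* Proprietary microscope formats (LIF, CZI) are not read; convert to
  (OME-)TIFF first.
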