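# discRim

Quantification of spatial patterns of nuclear marks in epithelial tissue
sections — built around the biology of the *Drosophila* wing imaginal
disc, where histone acetylation marks such as H3K18ac and H4K8ac are
enriched in the outer rim of the disc and in nuclei close to the
outward-facing tissue surface.

The package is aimed at microscopists who quantify multi-channel
confocal images of whole-mount tissue and want the measurements behind
such figures to be scripted, parameterized and testable rather than
clicked together: tissue masks, fixed-width rim bands, normalized
intensity ratios, per-nucleus distance scoring, ratiometric sensor maps
and the accompanying statistics. Because raw microscope images are
rarely shareable, discRim also ships a synthetic phantom generator with
exact ground truth, so the entire pipeline can be validated end to end
on images whose correct answer is known.

## The core statistic

For a tissue mask split into a rim band **R** (all foreground pixels
within *w* pixels — Euclidean distance — of the tissue boundary;
*w* = 10 for immunofluorescence, 13 for TMRM) and the remaining centre
**C**, with mark channel *M* and a normalization channel *D* (DAPI for
nuclear marks, mitoGFP for TMRM):

```
ratio = ( Σ_R M / Σ_R D ) / ( Σ_C M / Σ_C D )
```

The ratio is dimensionless, invariant to staining efficiency and global
rescaling of either channel, and equals 1 for a spatially uniform mark.
Around it the package implements:

- reporter-defined (GFP/IFP) compartment restriction of the same ratio,
  and per-compartment total rim intensities;
- sum-intensity z-projections and projected integrated-intensity ratios
  (for cytoplasmic marks and FISH signals, normalized to DAPI);
- per-nucleus mean intensities with distance from the nucleus's most
  outward-facing pixel to the tissue surface, distance to the nearest
  mitochondrion, binning at <5 / 5–10 / >10 µm and normalization to the
  <5 µm bin average, plus per-replicate control normalization;
- dual-excitation ratiometric sensor maps (488 nm / 405 nm, with a
  denominator floor);
- the statistical layer: two-sided Mann–Whitney (exact by enumeration
  for small samples), Kruskal–Wallis with Dunn's multiple comparisons,
  two-way type-II ANOVA with Šídák's multiple comparisons, Wilcoxon
  signed-rank, Pearson correlation and ROUT outlier flagging.

## Worked example

```r
library(discRim)

## a synthetic disc section: true rim enrichment 3, realistic noise
ph <- makeDiscPhantom(phantomSpec("disc_xy", seed = 1, enrichmentR = 3))
st <- ph$stack
st
#> ImageStack 'phantom_disc_seed1': 3 channel(s), 160 x 160 px, 1 plane(s)
#>   pixel size: 0.5 um (xy), 1 um (z)
#>   channels: dapi[dapi], mark[mark], reporter[reporter]

tissue <- segmentTissue(getPlane(st, "dapi"))
part   <- partitionRimCentre(tissue, widthPx = 10)
part
#> RegionPartition (width 10 px): rim 4169 px, centre 12087 px

res <- rimCentreRatio(getPlane(st, "mark"), getPlane(st, "dapi"), part)
res[, c("disc_id", "compartment", "ratio", "width_px")]
#>   disc_id compartment   ratio width_px
#> 1    disc       whole 2.99474       10
```

The recovered rim/centre ratio (2.995) agrees with the generating
enrichment factor (3) to well within the shot-noise level. The same
phantom machinery drives the per-nucleus analysis — on a cross-section
phantom whose mark decays with surface distance:

```r
xs  <- makeCrossSectionPhantom(phantomSpec("cross_section", seed = 1))
tis <- segmentTissue(getPlane(xs$stack, "dapi"))
nuc <- segmentNuclei(getPlane(xs$stack, "dapi"), within = tis)
rec <- measureNuclei(nuc, list(mark = getPlane(xs$stack, "mark")))
rec <- annotateSurfaceDistance(rec, nuc, tis)
rec <- binAndNormalize(rec, "mark")
round(tapply(rec$normalized_intensity, rec$bin, mean)[c("<5", "5-10", ">10")], 3)
#>    <5  5-10   >10
#> 1.000 0.458 0.243
```

Nuclei nearest the surface carry the strongest signal; the bin means
decrease with depth, and the <5 µm bin averages 1 because it is the
normalization reference. `runPipeline()` chains these stages (and the
sensor and statistics stages) from a single JSON-style configuration;
`inst/scripts/discrim_pipeline.R` exposes the same thing on the shell.

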