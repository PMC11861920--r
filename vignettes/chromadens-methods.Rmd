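---
title: "Densitometric assessment of sperm chromatin integrity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Densitometric assessment of sperm chromatin integrity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromadens)
```

## The measurement problem

During spermiogenesis, histones are replaced by protamines and sperm
chromatin becomes highly compacted. Defective compaction ("decompaction")
is a recognized cause of subfertility in breeding bulls, yet the standard
flow-cytometric assay (SCSA) is impractical for many field and IVF
laboratories. Stain-based alternatives exploit the fact that decompacted
chromatin binds cationic dyes differently: in toluidine blue (TB) and
Feulgen (FR) stained smears, decompacted regions of the head stain *darker*,
while acridine orange (AO) fluoresces green on intact double-stranded DNA
and red on denatured DNA, and in transmission electron microscopy (TEM)
decompacted chromatin appears as electron-lucent ("clear") areas inside the
otherwise dense head section.

Visual scoring of these subtle intensity differences is subjective.
`chromadens` implements the computational analog: per-head densitometry
against an automatically chosen within-sample staining reference, followed
by a location-based classification of decompacted regions, plus the
statistical layer such studies use downstream (IVEP rates normalized to a
reference bull, correlations, odds ratios, Scott–Knott grouping).

## The TB/FR pipeline

1. **Normalization.** Images are reduced to a single channel (Rec.709
   luminance by default for RGB input) and rescaled to $[0,1]$ by the full
   bit-depth range. Higher = lighter = more compacted; every downstream
   threshold assumes this polarity. No percentile stretching is applied:
   the deficit criterion below is relative, so a global affine rescaling is
   harmless, whereas data-dependent stretching would change results between
   acquisitions.
2. **Segmentation.** Heads are darker than the background, so the
   foreground is the set of pixels below a histogram threshold (Otsu's
   between-class-variance maximizer over 256 bins by default, with a fixed
   override). 8-connected components are filtered by area
   (400–20 000 px at the study's ×100/×2 magnification), solidity
   (≥ 0.85) and moment eccentricity (≤ 0.95) to reject tails, debris and
   fused heads; border-touching components are rejected because their
   masks may be truncated. Each surviving mask loses its perimeter through
   one pass of morphological erosion (disk of radius 1, realized as the
   4-connected cross), which also smooths the contour.
3. **Reference selection.** The staining reference of a smear is built
   from its K = 10 lightest and most homogeneous heads: heads are ranked
   by mean intensity (descending) and coefficient of variation (ascending,
   population SD convention), and the K smallest equal-weight rank sums
   are selected; ties break toward the lighter head. The scalar reference
   is the mean of the selected heads' mean intensities — the simplest
   unbiased pooling of the K per-head values. Per-head statistics are
   computed on the post-erosion mask: the eroded mask is the quantity the
   rest of the pipeline consumes, and including perimeter pixels would mix
   background-adjacent partial-volume pixels into the reference. (The
   alternative, pre-erosion statistics, changes the reference by well
   under the deficit thresholds on our phantoms.)
4. **Deficit mapping.** For each head pixel $p$,
   $\mathrm{deficit}(p) = (I_{\mathrm{ref}} - I(p)) / I_{\mathrm{ref}}$.
   Pixels lighter than the reference keep their negative deficits. The
   continuous deficit field is smoothed with a truncated Gaussian
   ($\sigma = 2$ px, truncation radius 5 px, i.e. an 11×11 window,
   renormalized to sum 1). The convolution is restricted to the head mask
   with mask-normalized weights, so boundary pixels are never diluted by
   background. Smoothing the *continuous* field before thresholding is
   the standard denoising reading; smoothing a binary result instead would
   require an extra re-binarization level that nothing in the method
   specifies. (The alternative order is available via
   `altered_regions()` on an unsmoothed map.)
5. **Altered regions.** The smoothed deficit is thresholded at
   $\tau = 0.07$ for TB and $\tau = 0.04$ for FR — 7% and 4% below the
   sample reference. FR stains decompaction more weakly, hence its lower
   cutoff; on the same map the 4% set is always a superset of the 7% set.
   8-connected components smaller than `max(5, 0.5%)` of the head area are
   discarded as residual noise.
6. **Location taxonomy.** Principal axes come from the mask's second
   moments (length/width as $4\sqrt{\lambda}$, the exact full extents for
   a solid ellipse). The base is the broader terminal 25% of the major
   axis — the bovine head tapers toward the apex; circular heads fall back
   to a fixed deterministic sign and are flagged ambiguous. Mask pixels
   are ranked by projection and split into equal-count quartiles Q1 (base)
   … Q4 (apex); the axial band is the strip within `width/6` of the major
   axis. The decision list runs in fixed precedence
   N → TD → BAD → BHD → BD → CAD → DD:

   | rule | default |
   |---|---|
   | N: altered fraction below | `f_min = 0.02` |
   | TD: altered fraction at least | `0.75` |
   | BAD: altered coverage of both Q1 and Q4 at least | `0.25` |
   | BHD: share of altered pixels in basal half ≥ `0.80` and basal-half coverage ≥ | `0.40` |
   | BD: share of altered pixels in Q1 at least | `0.80` |
   | CAD: share of altered pixels in axial band at least | `0.80` |
   | DD | fallback |

   The taxonomy's semantics are location containment; the literature gives
   no quantitative cutoffs, so these are declared, config-exposed defaults
   of this implementation (`pattern_rules()`), not claims about any
   external source. The list is total and deterministic: every altered
   head matching no positive rule is dispersed decompaction (DD).

## TEM grading and AO calling

TEM polarity is inverted: condensed chromatin is dark, decompacted areas
are clear. Sections are segmented as dark components on the light field
with hole filling (clear regions would otherwise punch holes in the
mask). Clear pixels are those at or above an absolute normalized intensity
`clear_tau = 0.60`; components at most `small_spot_max_fraction = 0.02` of
the section area count as small spots, larger ones report their maximum
area fraction. Grading is closed-form and monotone in both inputs: G1 for
1–3 small spots; G2 for 4–6 spots or a clearer region up to ¼ of the head;
G3 for more than six spots or a region up to ½; G4 for a clear area of more
than half the head. Heads with no findings receive an explicit N0 grade,
reported separately so the G1–G4 percentages remain comparable with
grading schemes that have no normal class.

AO heads are segmented on the inverted luminance (fluorescent heads on a
dark field) and called on the original channels: with mean red $R$ and
mean green $G$ over the head mask, the head is denatured when
$R/(R+G) \ge 0.40$, the onset of yellow/orange (red overlapping green).
The boundary is inclusive, and one parameterized rule serves both the
confocal and epifluorescence acquisition routes.

## The phantom generator

Phantoms are statistical test doubles, not optical renderings: rasterized
elliptical heads (semi-axes a ∈ [20, 25], b ∈ [11, 14] px, tapered 25%
toward the apex so the base is detectable) placed without overlap on a
uniform background, with additive Gaussian noise and tail-like debris
filaments. For TB/FR the background is 0.92, heads 0.75, and stamped
regions are darkened by `deficit_depth` × head intensity; validation runs
use `deficit_depth = 0.15` and noise σ = 0.01, the regime the deficit
thresholds are designed for. Stamp templates mirror the taxonomy (a basal
cap for BD, the base-most 40% for BHD, an axial band for CAD, both-end
caps for BAD, a 90% cap for TD, one small off-axis blob per quartile for
DD); TEM phantoms stamp internal clear spots/ellipses, AO phantoms set the
red/green channels per state. Ground truth records the exact rasterized
masks and fractions. Generation is bitwise deterministic for a fixed seed
(R's Mersenne-Twister).

What phantoms do *not* emulate: point-spread blur, uneven illumination,
stain batch variation, overlapping or folded heads, and partial-volume
effects at head borders. Passing the phantom suites therefore demonstrates
the internal consistency of segmentation, densitometry and classification
under the stated noise model — not performance on real smears, which
requires calibration of the shape filters and rule cutoffs against
expert-scored images.

## Statistical layer

- **IVEP rates.** Cleavage = cleaved/oocytes, embryonic development =
  day-7 embryos/cleaved, blastocyst = blastocysts/oocytes, all in percent.
  Reference-bull normalization reports `100 × test/reference` at two
  decimals (round-half-even), cancelling plate-level variables. Note that
  published tables of this kind sometimes normalize unrounded internal
  rates; recomputation from printed two-decimal inputs can differ by
  ±0.01–0.02 in isolated cells, and this package always reports the value
  its actual inputs yield.
- **Pearson correlation** uses the exact t-transform
  $t = r\sqrt{(n-2)/(1-r^2)}$; exactly collinear input reports $p = 0$
  rather than a rounded small value.
- **Odds ratios** use the cross-product with the Woolf log-normal interval
  and the Haldane–Anscombe +0.5 correction when any cell is zero (flagged
  in the result) — standard, closed-form, reproducible.
- **Pairwise proportion comparisons** are pooled two-proportion z-tests,
  unadjusted by default with a Bonferroni option. This is a documented
  stand-in: the studies this layer mirrors do not name their procedure.
- **Scott–Knott** follows the canonical likelihood-ratio recursion: at
  each node of the sorted means, the split maximizing the between-group
  sum of squares $B_0$ is tested with
  $\lambda = \frac{\pi}{2(\pi-2)} B_0/\hat\sigma_0^2$ against
  $\chi^2_{\alpha}$ on $k/(\pi-2)$ degrees of freedom, where
  $\hat\sigma_0^2 = (\sum_i(\bar y_i - \bar y)^2 + \nu s^2_{\bar y})/(k+\nu)$
  pools the node's mean dispersion with the ANOVA error ($s^2_{\bar y} =$
  MSE/replicates, $\nu$ error df). The error mean square is supplied
  externally: the surrounding ANOVA and its assumption checks are routine
  and delegated to base R. The test is per-node and deliberately liberal:
  with a very small MSE even visually "tight" pairs split, because their
  gap is many standard errors of a mean — e.g. means (1.0, 1.1, 9.0, 9.2)
  form two groups at MSE = 0.05 (r = 5, ν = 20) but three at MSE = 0.01,
  where the 0.2 gap is ≈ 4.4 SE. Groups are always contiguous in
  sorted-mean order; α → 0 yields one group and α → 1 singletons.

## Numerical and implementation choices

- Pixel coordinates are 1-based `(row, col)`, origin top-left (R matrix
  convention).
- 8-connectivity everywhere components are formed (heads, altered regions,
  clear spots); `EBImage::bwlabel`'s 4-connected labels are merged across
  diagonal adjacencies with a union-find pass.
- Solidity uses the convex hull of pixel *corners*, so convex rasterized
  shapes score ≈ 1.
- `cv_intensity` uses the population (divisor n) standard deviation — a
  fixed, documented convention.
- Region-boundary outlines are traced on pixel-corner vertices with the
  interior on the left; `write_overlay()` whitens the interior boundary
  pixels and never touches pixels outside the outlines.
- Degenerate inputs raise classed conditions (`cd_*`) rather than
  returning sentinel values: constant images under Otsu, heads eroded to
  the empty set, collinear masks, unstained AO heads, zero-variance
  correlations, degenerate 2×2 tables.

## Validation problem sizes

The shipped test-suite and acceptance script exercise: 200 stamped heads
across eight 600×600 TB phantoms for category recovery (observed: 100%
at the default rules), six-head noise-free phantoms for exact count and
sub-pixel centroid recovery, 100 single-head phantoms for the τ-superset
property, a 110-point sweep of the TEM rule domain, 20-head AO phantoms,
and the closed-form statistical oracles. These sizes were chosen to give
stable rates from seeded runs while keeping a full run in well under a
minute.

## Known limitations

- No watershed splitting of fused heads and no learning-based
  segmentation; fused pairs are rejected, biasing very dense smears.
- No flat-field correction; uneven illumination will leak into deficits.
- Physical-unit areas require the user-supplied `pixel_size_um`; the
  magnification alone does not determine the pixel scale.
- The location-rule cutoffs are implementation defaults, to be
  recalibrated against expert scoring before use in a new laboratory.
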