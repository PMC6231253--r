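---
title: "Methods: quantifying leaf intercellular airspace from microCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying leaf intercellular airspace from microCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafspace)
```

## The measurement model

A reconstructed microCT stack of a leaf disc is a 3D grayscale image in which
air attenuates X-rays less than hydrated tissue, so intercellular airspace
appears dark. `leafspace` converts such a stack into three families of
quantities:

- **Porosity** — airspace volume as a percentage of leaf (mask) volume,
  computed as an exact voxel ratio (Eq. 1 below), plus its per-slice depth
  profile.
- **S_mes** — mesophyll surface area exposed to intercellular airspace per
  unit projected leaf area, from summed per-slice pore perimeters (Eq. 2),
  with the classical single-section stereological estimator (Eq. 3) as the 2D
  companion.
- **Channel diameters** — a local thickness map assigning to each air voxel
  the diameter of the largest sphere that fits in the airspace through it.

Axis convention: arrays are indexed `(z, y, x)` with slice 1 the adaxial
(upper) leaf surface. The voxel size is never guessed from file metadata; it
must be supplied (the phantoms use 0.00275 mm, a typical benchtop value).

## Segmentation

Segmentation is a fixed, deterministic chain:

1. `makeLeafMask` thresholds the stack (maximum entropy by default for the
   mask), fills holes per slice, keeps the largest 3D connected component and
   applies a morphological closing (radius 5 disc) so the mask spans the leaf
   including its internal airspace.
2. `autoThreshold` selects an airspace threshold on the 256-bin histogram
   (16-bit data are rebinned by integer division by 256; the raw threshold is
   the upper edge of the selected bin). Voxels at or below the raw threshold
   are airspace (`binarize`).
3. `extractAirspace` restricts the airspace to the mask.
4. `removeSmallParticles` deletes connected particles with equivalent
   spherical diameter $(6V/\pi)^{1/3}$ below 3x the voxel size — the smallest
   feature the scan can be trusted to resolve — first in the foreground then
   in the background (filling sub-resolution holes).

### Threshold methods

Three standard histogram criteria are provided, all operating on the same
256-bin histogram:

- **IsoData** (Ridler–Calvard): iterate the floor of the midpoint of the two
  class means to a fixed point.
- **Li** minimum cross-entropy: the histogram is placed on 1-offset bin
  values (avoiding $\log 0$) and the criterion
  $\eta(t) = -(S_b \ln\mu_b + S_f \ln\mu_f)$ is minimised **by exhaustive
  scan** over all 255 splits. Li's iterative scheme
  $\tau' = (\mu_f-\mu_b)/(\ln\mu_f - \ln\mu_b)$ is only an acceleration of
  this minimisation; on bimodal histograms with an empty inter-mode valley
  the criterion is nearly flat across the valley and the fixed point can sit
  tens of bins from the discrete argmin at a numerically indistinguishable
  objective value. Since 256 bins make the scan essentially free, the package
  uses the defining (global-minimum) form, with ties resolved toward the
  lower bin.
- **Maximum entropy** (Kapur): exhaustive argmax of the sum of the two class
  entropies.

The test suite validates each method against an independent brute-force scan
of its published objective on seeded random bimodal histograms.

## Perimeter and S_mes

Porosity (Eq. 1) and S_mes (Eq. 2) follow the standard microCT formulation:

$$\mathrm{porosity} = \frac{\sum_z A_{\mathrm{pores}}(z)}{\sum_z A_{\mathrm{mask}}(z)} \times 100,
\qquad
S_{\mathrm{mes}} = \frac{\sum_z P_{\mathrm{pores}}(z) \cdot \mathrm{RES}}{A_{\mathrm{leaf}}}$$

where RES is the voxel size and $A_{\mathrm{leaf}}$ is by default the mean
per-slice mask area (the projected leaf area; a "summed" alternative is
available). The perimeter rule is normative and exactly specified: each
8-connected pore boundary is traced through pixel centres (Moore
neighbourhood), accumulating 1 per axis step and $\sqrt2$ per diagonal step,
plus 4 for the closed contour (so a single pixel has perimeter 4 and any
$w \times h$ rectangle exactly $2w + 2h$); boundaries of enclosed solid
islands are added the same way. This corner-count rule is exact on
axis-aligned shapes but overestimates smooth curves — measured on digitised
discs the bias is +24% at $r = 3$ falling to about +8% for $r \ge 12$ — which
is the behaviour of the chain-code perimeter used throughout the microCT
literature this package follows, so values are comparable with published
S_mes numbers.

The corresponding 2D estimator (Eq. 3) from a single transverse section is

$$S_{\mathrm{mes}} = \frac{\sum P_{\mathrm{pores}}}{W} \times F$$

with $W$ the section width and $F = 1.42$ the classical curvature correction.
`analyzeSection` composes masking, 2D noise removal (equivalent circular
diameter $2\sqrt{A/\pi}$, 3x resolution) and this estimator.

### Crofton perimeter for stereology

For the *isotropic stereological identity* $S_V = (4/\pi) B_A$ (surface
density from boundary-length density on random sections), the corner-count
rule is the wrong pairing: its smooth-curve bias does not cancel against the
voxel-face surface estimator. The package therefore also provides
`croftonPerimeter`, the intercept-count (Crofton) boundary length
$B = (\pi/4) \cdot (\text{row} + \text{column transitions}) \cdot h$ — the
exact 2D analogue of the corrected voxel-face surface area, and nearly exact
on digitised discs against $2\pi(r + 1/2)$. The consistency test packs an
isotropic sphere phantom, measures $S_V$ from corrected voxel faces in 3D and
$(4/\pi) B_A$ from Crofton perimeters on 60 random sections, and the two
agree within a few percent (ratio 1.0005 at the validation seed).

## Local thickness

`localThickness` implements the Hildebrand–Ruegsegger definition: the value
at an air voxel is the diameter of the largest sphere entirely contained in
the airspace that covers that voxel. It is computed in C++ as

1. an exact squared Euclidean distance transform (Felzenszwalb–Huttenlocher
   separable parabolic envelopes) to the nearest solid voxel, with the volume
   padded by one solid layer so the outside counts as solid; and
2. sphere propagation in decreasing radius order with strict integer
   containment $|q - c|^2 < r^2$.

One numerical detail matters: the parabolic-envelope recursion evaluates
differences of sampled values, and seeding foreground with `Inf` produces
`Inf - Inf = NaN`, silently corrupting envelopes. Foreground is therefore
seeded with a large finite constant (`1e15`). The transform is validated
against an exhaustive brute-force oracle (nearest-solid search plus explicit
sphere containment) on random volumes, where the two agree exactly.

On digitised balls the map maximum is $2r$ within one voxel *when the ball
centre lies on a grid point* (odd bounding boxes); with half-integer centres
the largest integer-centred inscribed sphere is genuinely smaller, which is a
property of the discretisation, not the transform.

## Phantoms and validation design

Because no ground truth exists for real scans, validation rests on synthetic
phantoms with analytic truth:

- `generateLeafPhantom` builds a dicot-like (or monocot-like) leaf: epidermis,
  palisade layer with vertical cylindrical air channels, spongy layer with
  randomly packed spherical air pockets (random sequential addition), then
  renders grayscale with optional Gaussian noise and rendering specks. The
  truth object carries both analytic values (from the placed geometry) and
  discrete values (from the digitised volumes), including per-slice
  perimeters under the normative corner-count rule.
- `generateSpherePhantom` packs non-touching spheres for stereology tests.
  Random sequential packing saturates near 38% for touching monodisperse
  spheres and considerably lower with a clearance margin and in small
  volumes (edge effects), so the default target porosity is 0.25 at
  $128^3$–$208^3$; requesting an unreachable target raises a classed
  `leafspace_infeasible_packing` error rather than looping forever.
- `generateSectionPhantom` draws a 2D leaf band with elliptical holes for the
  stereological workflow; with no noise the section masks recover the drawn
  holes pixel-for-pixel when despeckling is disabled.

Problem sizes in the validation suite are the package's own choices,
balancing runtime against sampling variance: e.g. the $S_V$ consistency check
uses a $208^3$ volume (about 110 spheres) and 60 random sections, for which
the section-sampling standard error is comfortably inside the stated 10%
tolerance; smaller volumes or fewer sections leave the check dominated by
sampling noise rather than estimator quality.

All phantom generation is seed-deterministic and restores the caller's RNG
stream.

## Pipeline and provenance

`runPipeline(config, samples)` runs the chain over a batch, isolating
per-sample failures (a failing sample produces a warning naming it and an
entry in `failures`, never aborting the batch), and optionally writes a
fixed-header `metrics.csv`, a long-format `profiles.csv` and one JSON
provenance file per sample recording the threshold method and selected bin,
voxel size, ROIs and mask source. Configurations come from R lists or YAML
(`readRunConfig`); replicate ROIs are analysed independently and averaged.
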