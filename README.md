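# leafspace

Quantification of the three-dimensional intercellular airspace network of
plant leaves from laboratory X-ray computed microtomography (microCT) stacks.

## Background

The mesophyll of a leaf is laced with an interconnected network of
intercellular airspace through which CO2 diffuses from the stomata to the
chloroplast-bearing cell walls. Two quantities dominate models of that
diffusion path: the **porosity** (airspace volume as a fraction of leaf
volume) and **S_mes**, the mesophyll surface area exposed to intercellular
airspace per unit projected leaf area. Classically both were estimated
stereologically from a handful of stained 2D sections; benchtop microCT now
resolves the airspace in 3D at micron-scale voxels, and this package
implements the full image-analysis chain from reconstructed grayscale stack
to published metrics, together with the classical 2D estimator for
comparison.

The pipeline mirrors established microCT practice:

1. **Read** a reconstructed 8- or 16-bit TIFF/PNG stack (`readStack`); slice
   1 is the adaxial (upper) surface and the voxel size must be supplied
   explicitly.
2. **Mask** the leaf disc by thresholding, hole filling, largest-component
   selection and morphological closing (`makeLeafMask`).
3. **Threshold** the 256-bin intensity histogram with IsoData, Li minimum
   cross-entropy or Kapur maximum entropy (`autoThreshold`); air attenuates
   less than tissue, so the low side is airspace (`binarize`).
4. **Composite** the airspace with the mask (`extractAirspace`) and remove
   particles smaller than three times the scan resolution — below the
   instrument's trustworthy feature size — in foreground and background
   (`removeSmallParticles`).
5. **Measure** per slice with 8-connected component analysis
   (`analyzeStack`): porosity as the exact voxel ratio, S_mes from summed
   pore perimeters (a chain-code corner-count rule that is exact on
   axis-aligned rectangles), pore counts, and a depth-resolved porosity
   profile. A Hildebrand–Ruegsegger local thickness transform
   (`localThickness`) maps air-channel diameters as the largest inscribed
   sphere through each air voxel.
6. **2D stereology** (`analyzeSection`, `smes2d`) reproduces the classical
   estimate S_mes = (sum of airspace perimeters / section width) x F with
   the curvature correction factor F = 1.42, for comparison against the 3D
   measurement.

All segmentation steps are deterministic: the same stack and configuration
give bit-identical results.

## Worked example

The package ships a synthetic leaf phantom generator with analytic ground
truth, so the full pipeline can be exercised without data. A dicot-like
phantom has epidermis, a palisade layer with vertical air channels, and a
spongy layer packed with spherical air pockets:

```r
library(leafspace)

ph   <- generateLeafPhantom(dicotPhantomSpec(seed = 42, noiseSD = 12))
grid <- ph$grid
grid
#> VoxelGrid: 120 slices x 160 x 160, 8-bit, voxel 0.00275 mm

thr <- autoThreshold(grid, "isodata")
thr
#> ThresholdResult: method isodata, bin 105 (raw 105), airspace = low side

mask <- makeLeafMask(grid)
air  <- removeSmallParticles(extractAirspace(binarize(grid, thr), mask))

m <- leafMetrics(air, mask, sample_id = "leaf42", thicknessMap = TRUE)
m$record
#>   sample_id porosity_pct smes_mm2_per_mm2 pore_count leaf_thickness_mm
#> 1    leaf42     18.45031           8.1676       3802              0.33
#>   mean_channel_diameter_mm max_channel_diameter_mm
#> 1               0.03900212              0.04434242
```

The phantom's discrete ground-truth porosity is 18.44633%, so the recovered
value is accurate to 0.004 percentage points despite the added Gaussian
noise. The depth profile resolves the airspace gradient from the compact
palisade to the porous spongy layer:

```r
head(m$profile, 3)
#>   slice depth_mm  depth_norm porosity_pct
#> 1     1  0.00000 0.000000000            0
#> 2     2  0.00275 0.008403361            0
#> 3     3  0.00550 0.016806723            0
```

The classical 2D estimate from a single stained-section image:

```r
sec <- generateSectionPhantom(seed = 3, noiseSD = 8)
res <- analyzeSection(sec$image)
str(res)
#> List of 5
#>  $ porosity_pct      : num 8.77
#>  $ smes_2d           : num 2.27
#>  $ total_perimeter_mm: num 1.28
#>  $ correction_factor : num 1.42
#>  $ width_mm          : num 0.8
```

Batch processing of real stacks goes through the pipeline driver with a YAML
configuration (`readRunConfig` / `runPipeline`) or the command-line script in
`inst/scripts/leafspace.R`; outputs are a fixed-header `metrics.csv`,
per-slice `profiles.csv` and per-sample JSON provenance.

## License

MIT (see `LICENSE`).
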