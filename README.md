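# hepatovasc

3D image analysis of liver microvasculature in photoacoustic microscopy
(PAM) volumes: separation of wall-bearing **vessels** from **hepatic
sinusoids**, and quantitative morphometry of both compartments.

Liver PAM resolves the microvasculature label-free via hemoglobin
absorption, but mixes two structures with different biology in one
intensity volume: the dense mesh of 3–5 µm sinusoids in the shallow
tissue and the ≥ 20 µm vessels rising from deeper layers. Image-wide
statistics cross-contaminate (vessel signal inflates sinusoid radius and
density estimates; sinusoid clutter corrupts vessel counts). `hepatovasc`
implements a separation-first analysis chain for researchers quantifying
microvascular remodeling, e.g. across stages of fatty-liver disease:

1. **Enhancement** — per-slice percentile analysis (`I1`/`I99`) and
   monotone histogram matching to the widest-range reference slice,
   compensating depth attenuation.
2. **Vessel separation** — grayscale spherical erosion whose radius is
   selected from the trade-off of mean intensity difference
   `MID(r) = |mean(I_c) − mean(I)|` and intensity retention
   `IR(r) = ΣI_c / ΣI` (normalised curves cross near 0.5, default radius
   4 µm), followed by adaptive local-mean thresholding, median-volume
   component filtering, and extent restoration.
3. **Sinusoid separation** — subtraction of the scaled vessel mask,
   negative clipping, multi-scale Frangi-type Hessian tubularness,
   adaptive segmentation; sinusoid and vessel masks are disjoint by
   construction.
4. **Morphometry** — topology-preserving 3D thinning, centerline graph,
   cylinder-model metrics (length, volume, radius `√(V/πL)`,
   branch-weighted straightness), sinusoid density `D = V_S/(V − V_L)`,
   vessel counts.
5. **Branch analysis** — dead-end / crossing / complex classification and
   per-class box-counting fractal dimension
   `FD = −lim log N(L)/log L`.
6. **Coverage** — per-vessel sinusoidal canopy rate
   `R_i = Σ[V_i ∧ S′]/ΣV_i` (columnar overlay above the vessel's deepest
   layer `Z_max`), with high/low-coverage classification at 50%.
7. **Quality** — GLCM texture features (contrast, entropy, homogeneity)
   combined into a composite image-quality score normalised to 1.

A **synthetic phantom generator** with voxel-level ground truth (vessel
trunks + curved-walk sinusoid mesh, depth attenuation, noise, and
disease-stage presets for sinusoid rarefaction) makes the whole chain
testable end to end without any acquisition data.

## Worked example

```r
library(hepatovasc)

# a degraded phantom with ground truth (normal-stage sinusoid density 0.091)
ph <- generate_phantom(phantom_spec(shape = c(96, 128, 128), stage = "normal",
                                    seed = 11))
res <- run_pipeline(ph$intensity, pipeline_config())
res
#> <pipeline_result>
#>   erosion radius: 4 um
#>   vessel mask: 90078 voxels in 13 components
#>   sinusoid mask: 148783 voxels; density 0.1003
#>   morphometry: length 3.177e+04 um, volume 1.488e+05 um^3, radius 1.22 um, tortuosity 0.860
#> <branch_classification> 15782 branches: dead_end 40.9%, crossing 0.9%, complex 58.1%
#> <coverage_report> 13 vessels, mean rate 0.918, HC 100% / LC 0%

evaluate_separation(res$vessel_mask, res$sinusoid_mask,
                    ph$vessel_truth, ph$sinusoid_truth)
#> $vessel_dice   [1] 0.877
#> $sinusoid_dice [1] 0.725
```

The printed numbers mean: erosion at the 4 µm default suppressed the
sinusoid mesh; the vessel mask recovered the trunks (Dice 0.88 against
ground truth); the disjoint sinusoid mask (Dice 0.73) yields a density of
0.100 against a generative target of 0.091; the vessels are canopied by
the sinusoid mesh (mean coverage rate 0.92, all high-coverage), as
expected for the normal stage.

Paired pre/post or cross-stage comparisons use the larger-denominator
relative change, averaged per subject:

```r
ref <- separation_reference()          # bundled reference morphometry table
eu <- subset(ref, stage == "early" & !separated)
es <- subset(ref, stage == "early" & separated)
relative_change_table(eu$density, es$density)
#> <stage_comparison> n = 3 subjects: 46.48% +/- 3.97% (decrease)
```

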