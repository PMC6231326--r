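# mechquant

Image quantification for mechanotransduction assays: how organized a
cell's cytoskeletal fibers are, where a transcription factor sits
between nucleus and cytosol, and which knockdowns in an image-based
siRNA screen shift that localization.

The package is written for cell biologists running high-content or
confocal imaging experiments on mechanosensing (substrate stiffness,
micropatterns, stretch) who need the standard readouts of that field as
tested, scriptable functions rather than one-off macros.

## What it computes

**Multiscale nematic anisotropy.** Fiber orientations are defined
modulo 180°, so statistics live on the doubled angle. At each pixel the
fiber direction is the 90°-rotation of the intensity gradient; a
region's mean nematic tensor `Q = [[c, s], [s, -c]]/2` (with `c`, `s`
the weighted means of cos 2θ and sin 2θ) has eigenvalue difference
`sqrt(c² + s²)` — the anisotropy, 0 for isotropic content, 1 for
perfect alignment, identical to the nematic order parameter
`|mean(exp(2iθ))|` for unit weights. The multiscale score tiles the
image into N×N patches for N in {2^i} ∪ {3^i} (patches no smaller than
10×10 px), scores each patch, assigns every pixel the mean score of the
processed patches containing it, and averages over pixels. The
computation can be restricted to a segmentation mask.

**Nuclear/cytosolic (N:C) ratio.** Nuclei are segmented from the DNA
stain (Gaussian–Otsu–watershed with per-object half-maximum
refinement), QC-filtered (mitotic by intensity, aberrant by roundness
4πA/P², out-of-range area, image-border contact), and each cell's
marker signal is measured over the nucleus, a 4-px perinuclear
cytosolic ring, and the grown whole-cell region. Readouts:
`nc_ratio = nuclear mean / ring mean`, `nuclear_to_total`, and a
N / C / N-C localization class with a symmetric band around ratio 1.

**Screen Z-scores.** Per plate and replicate,
`Z = (x − control mean)/control SD` against non-targeting control
wells (sample SD, n−1); the hit statistic is the replicate-mean Z with
a strict `|mean Z| > 2.5` threshold, plus genotype-specificity
partitioning (WT-specific / KO-specific / shared).

**Assay statistics.** Exact Fisher enrichment of a gene set (one-sided
hypergeometric from log-binomials), dual-luciferase normalization
(firefly over secreted luciferase, fold change vs. a reference
condition), and collagen-gel contraction indices.

**Synthetic ground truth.** Generators for fibrous textures with a
planted von Mises orientation concentration, multicell fields with a
planted N:C ratio and planted QC defects, and screen plates with
planted hit effects — all pure functions of their seed, used by the
test suite to verify parameter *recovery*, not just execution.

## Worked example

```r
library(mechquant)

## fibrous texture with planted orientation concentration kappa = 4
g <- generate_fibers(kappa = 4, seed = 42)        # 512x512, 300 fibers
g$truth                                           # 0.865  planted order parameter
whole_image_anisotropy(g$image)                   # 0.850  recovered global order
multiscale_anisotropy(g$image)$global_score       # 0.858  multiscale score

## cell field with planted N:C ratio 2 and 30% planted QC defects
f <- generate_cell_field(nc_ratio_true = 2, frac_border = 0.1,
                         frac_mitotic = 0.1, frac_aberrant = 0.1, seed = 42)
q <- quantify_nc(f$hoechst, f$marker)
sum(q$records$qc_pass)                            # 35 of 50 cells pass QC
median(q$cells_df$nc_ratio, na.rm = TRUE)         # 2.00  planted ratio recovered
q$fractions                                       # N 100, C 0, NC 0 (ratio 2 => nuclear)

## simulated screen: two planted +/-4 sigma effects among 89 siRNAs
tab <- simulate_screen(planted_effects = c(siRNA_011 = 4, siRNA_042 = -4),
                       seed = 42)
z <- zscore_screen(tab)
z[z$is_hit, c("sirna", "mean_z", "direction")]
#      sirna    mean_z direction
#  siRNA_011  4.307304        up
#  siRNA_042 -4.203931      down

## gene-set enrichment, 2x2 table (in-set/selected counts)
fisher_enrichment(14, 47, 212, 5531)
# odds ratio 7.77, p = 5.45e-08 (one-sided, enrichment)
```

The whole-image anisotropy recovers the planted order parameter within
a few hundredths; the multiscale score additionally reflects local
(patch-level) organization. The N:C pipeline recovers the planted
ratio at its median and excludes the planted border/mitotic/aberrant
cells; the screen calls exactly the planted effects. The methods
vignette (`vignettes/mechquant-methods.Rmd`) documents every model,
parameter, and design choice.

A command-line entry point for shell pipelines is installed at
`system.file("cli", "mechquant", package = "mechquant")`, exposing
`anisotropy`, `ncratio`, `screen`, `enrich`, `luciferase`, `gel`, and
`simulate` subcommands; every run writes a JSON manifest (inputs with
digests, resolved parameters, seed, package version) next to its
outputs.

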