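# stainbench

Benchmarking classical stain normalization for H&E histology.

Sections cut from one tissue block and stained in different laboratories
come back in wildly different colours — stain composition, protocol and
scanner all vary — which degrades any downstream image analysis. *Stain
normalization* remaps an image's colours to match a reference slide while
preserving tissue structure. `stainbench` implements the four classical
methods and everything needed to compare them reproducibly on a
multi-laboratory panel:

* **Normalization** — histogram matching (256-level quantile LUT),
  Reinhard colour transfer in Ruderman's lαβ space, Macenko SVD stain
  estimation, and Vahadane sparse non-negative stain factorization, each
  applied whole-image against a whole-image reference.
* **Selection** — the reference-slide rule (red-to-blue mean intensity
  ratio closest to 1) and representative-sample selection (lαβ channel
  histograms → PCA → seeded k-means, k = 8, member nearest each centroid,
  with a within-cluster-sum-of-squares elbow diagnostic).
* **Evaluation** — histogram intersection, Pearson correlation, Euclidean
  distance and Jensen–Shannon divergence on lαβ channel histograms versus
  the reference; SSIM versus the original (structural integrity); and a
  Fréchet distance ‖μ₁−μ₂‖² + Tr(Σ₁+Σ₂−2(Σ₁Σ₂)^1/2) between tile feature
  clouds (self-contained seeded extractor; pluggable).
* **Synthetic panels** — a Beer–Lambert renderer that "sections" one
  seeded tissue morphology and stains it under per-lab stain matrices,
  log-normal over-/under-staining, smooth unevenness and background
  tints, retaining full ground truth.

The core model: stains mix linearly in optical density,
`od = −log10((I+1)/(I0+1))`, so a pixel is `od ≈ W c` with `W` the 3×2
unit-norm stain matrix (hematoxylin, eosin columns) and `c ≥ 0` the stain
concentrations. Macenko estimates `W` from angular percentiles in the
top-2 SVD plane of the tissue OD cloud; Vahadane solves
`min ½‖V − WH‖² + λ‖H‖₁` with nonnegativity and unit-ball stain columns
by exact alternating block solves (monotone objective, deterministic).

## Worked example

Generate an 8-lab panel from one shared morphology, pick the reference,
and benchmark all four methods:

```r
library(stainbench)

panel <- synthetic_panel(n_labs = 8, size = 128, seed = 1)
sel <- select_reference(panel$images)
sel$ratios
#> # A tibble: 8 × 2
#>   sample_id ratio
#>   <chr>     <dbl>
#> 1 lab_01    0.934
#> 2 lab_02    1.13
#> 3 lab_03    0.945
#> 4 lab_04    1.15
#> 5 lab_05    0.915
#> 6 lab_06    0.968
#> 7 lab_07    0.865
#> 8 lab_08    0.843
```

Lab 6's ratio (0.968) is closest to the colour-balanced value 1, so it
becomes the reference. Every other slide is normalized with every method
and scored:

```r
report <- run_benchmark(panel, config = benchmark_config(tile = 64, seed = 1))
glance(report)
#> # A tibble: 4 × 7
#>   method    intersection    pcc euclidean    js  ssim     fid
#>   <chr>            <dbl>  <dbl>     <dbl> <dbl> <dbl>   <dbl>
#> 1 histmatch        0.583 0.871      0.116 0.295 0.735 0.306
#> 2 macenko          0.727 0.463      0.235 0.188 0.529 0.00537
#> 3 reinhard         0.189 0.0223     0.342 0.726 0.929 0.537
#> 4 vahadane         0.701 0.458      0.239 0.197 0.530 0.00591

rb_convergence(report)
#> # A tibble: 4 × 4
#>   method    mad_before mad_after converged
#>   <chr>          <dbl>     <dbl> <lgl>
#> 1 histmatch      0.111    0.0320 TRUE
#> 2 macenko        0.111    0.0363 TRUE
#> 3 reinhard       0.111    0.0459 TRUE
#> 4 vahadane       0.111    0.0363 TRUE
```

Reading the tables: intersection/PCC near 1 and Euclidean/JS near 0 mean
the normalized colour histograms sit close to the reference's; SSIM near
1 means tissue structure survived; the Fréchet column is comparable only
within a run. `rb_convergence()` is the headline sanity check — every
method pulls the panel's mean |R/B − 1| down (here from 0.111 to
0.032–0.046), i.e. the colour spread of the panel collapses toward the
balanced line after normalization. `tidy(report)` returns per-sample
records, `autoplot(report)` draws the before/after ratio plot, and
`write_report(report, dir)` serializes the tables, plot and run metadata.

Single-pair use mirrors the pipeline:

```r
res <- normalize_stains(panel$images[[2]], panel$images[[6]], "macenko")
res
#> <stain_normalization> method 'macenko', 128 x 128 image
round(unclass(res$diagnostics$source_stains), 3)
#>   hematoxylin eosin
#> R       0.435 0.027
#> G       0.710 0.988
#> B       0.554 0.153
```

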