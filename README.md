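# ventseg

2D level set segmentation of dark, weakly bounded structures — built for
the brain ventricles on axial CT and T1 MRI slices, where enlargement of
the CSF-filled ventricles is a standard marker of cerebral atrophy and
the boundary mixes sharp segments with blurred, low-contrast ("weak")
ones that purely edge-driven contours leak through.

## The model

The contour is the zero level set of a field φ (inside-negative) that
descends a distance-regularized energy whose edge-based data terms are
replaced by edge-gated **region-scalable fitting** intensity terms:

    E(φ) = μ ∫ p(|∇φ|)  +  λ ∫ g (I − f₁)² M₁(φ)  +  α ∫ g (I − f₂)² M₂(φ)

* `p` — double-well potential with minima at |∇φ| = 0 and 1: keeps φ a
  signed distance function near the contour with **no re-initialization**
  (DRLSE).
* `g = 1/(1+|∇(G_σ∗I)|²)` — edge indicator, gating the data force where
  gradients already pin the contour.
* `f₁, f₂` — Gaussian-kernel local means of the image inside/outside the
  contour (RSF); the squared residuals `(I − fᵢ)²` let the contour stop
  at weak boundaries that `g` cannot see.

One explicit Euler step (fits recomputed every iteration):

    φ ← φ + Δt [ μ div(d_p(|∇φ|)∇φ) + δ_ε(φ) g (λe₁ − αe₂)
                 + c_w δ_ε(φ) div(g ∇φ/|∇φ|) ]

Defaults are the tuned values α=2, λ=1, ε=2, Δt=1.5, Gaussian kernel
σ=2.5 of size 15, μ=0.2/Δt.  An edge-only DRLSE baseline
(`method = "drlse"`) is included for head-to-head comparison, along with
a coordinate-wise grid-search tuner, the full metric battery (Dice,
Jaccard, sensitivity/specificity/accuracy in standard and as-printed
modes, PSNR, SSIM), ventricle/disk phantom generators, PNG/TIFF/NIfTI/
DICOM slice readers and a CLI.

## Worked example

```r
library(ventseg)

ph  <- make_ventricle_phantom()          # 128x128 slice-like phantom:
                                         # crescent pair at 60 on brain 120,
                                         # 60 deg weak arc, noise sd 4
fit <- run_segmentation(ph$image, ph$box, box_mode = "around")
fit
#> ventseg_fit (modified, box_mode=around): converged after 98 iterations
#>   foreground: 2477 of 16384 pixels

segmentation_report(fit$mask, ph$truth)
#> # A tibble: 1 × 8
#>    dice jaccard sensitivity specificity accuracy psnr_db  ssim definition_mode
#>   <dbl>   <dbl>       <dbl>       <dbl>    <dbl>   <dbl> <dbl> <chr>
#> 1 0.824   0.700       0.999       0.949    0.955    13.4 0.869 standard
```

The contour converges in ~100 iterations; sensitivity ≈ 1 (the
ventricles are fully recovered), and the 0.82 Dice reflects a thin halo
of false positives where the weak arc blurs the boundary.  On the sharp
64×64 disk phantom the same defaults reach Dice 0.98 in 43 iterations,
while the edge-only baseline with the same tuned parameters overruns
even sharp boundaries (its balloon term beats the λ-weighted geodesic
term) and loses the contour — exactly the failure the region terms fix:

```r
disk <- make_disk_phantom()
dice(run_segmentation(disk$image, disk$box, box_mode = "seed")$mask,
     disk$truth)
#> [1] 0.9807692
```

The `box` is the operator's rectangle: `box_mode = "around"` encloses
the target (clinical workflow; the box also bounds the search domain),
`box_mode = "seed"` grows a region from inside it.  A command-line
interface covering the same pipeline is installed at
`inst/cli/ventseg` (`phantom`, `segment`, `tune`, `evaluate`).

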