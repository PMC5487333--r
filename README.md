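# malsf — multi-atlas level set label fusion

`malsf` segments low-contrast structures (the motivating case is the thalamus
in T1-weighted brain MRI) by fusing propagated multi-atlas labels inside a
variational level-set framework. It is aimed at researchers in medical image
analysis who already have atlas labels registered into a target's coordinate
frame — registration itself is out of scope — and want a fusion step that uses
the target's intensities and produces a smooth, closed contour, together with
voting baselines and standard evaluation metrics.

## The model

A level set function φ (negative inside the structure, positive outside)
evolves to minimize

    E(φ) = α F(φ; φ1,…,φN) + β D(φ; I) + γ R(φ)

with three terms:

* **Label fusion** — `F(φ) = Σx Σi ωi(x) |φ(x) − φi(x)|²`, where φi are
  signed-distance level sets of the N propagated atlas labels and ωi(x) ≥ 0,
  Σi ωi(x) = 1 are voxelwise weights derived from local-similarity maps
  (uniform 1/N without them). Its minimizer is the pointwise weighted mean of
  the atlas level sets, which also serves as the initialization.
* **Image term** — the region-scalable fitting (RSF) energy: around every
  point y, intensities inside/outside the contour within a Gaussian window
  K_ρ are fit by local constants f1(y), f2(y), giving residual fields
  `ei(x) = ∫ Kρ(x−y) |I(x) − fi(y)|² dy` and the energy
  `D = Σx [λ1 e1 M1(φ) + λ2 e2 M2(φ)]` with memberships M1 = 1 − H_ε(φ),
  M2 = H_ε(φ) (smoothed Heaviside). This pulls the contour toward intensity
  boundaries even when atlas labels carry registration errors.
* **Regularity** — the contour length `R(φ) = Σx δ_ε(φ)|∇φ|`.

Gradient descent on E, plus a distance-regularization term
`μ(∇²φ − div(∇φ/|∇φ|))` that keeps φ close to a signed distance function,
gives the evolution

    ∂φ/∂t = −2α Σi ωi(φ − φi) + β δ_ε(φ)(λ1 e1 − λ2 e2)
            + υ δ_ε(φ) div(∇φ/|∇φ|) + μ(∇²φ − div(∇φ/|∇φ|))

The default coefficients are α = 0.1, β = 1, γ = 0.1, μ = 0.1, υ = 0.01,
λ1 = λ2 = 10⁻⁴. The methods vignette (`vignettes/malsf-methods.Rmd`) derives
the equation, explains every parameter and records the numerical choices.

## Worked example

Everything needed to try the package is generated in code: a 64×64
low-contrast phantom (intensity gap 20, boundary blur, noise σ 8) with 10
"propagated" atlas labels deformed by smooth random displacement fields.

```r
library(malsf)

fx  <- standard_fixture(seed = 0)        # image + truth + 10-atlas ensemble
res <- malsf_segment(fx$image, fx$ensemble)
res
#> <malsf_result> 695 voxels segmented after 123 iterations (converged)
#>   energy 1334 -> 1347 (fusion 1308, data 28.09, regularization 10.8)

m <- overlap_metrics(fx$truth, res$mask)
sprintf("SI %.4f  P %.4f  R %.4f  RO %.4f  HD %.2f",
        m$si, m$precision, m$recall, m$ro,
        hausdorff_distance(fx$truth, res$mask))
#> "SI 0.9949  P 0.9914  R 0.9986  RO 0.9899  HD 1.00"
```

The similarity index (SI, Dice) of 0.9949 against the ground truth edges out
plain majority voting of the same ten labels (0.99495 vs 0.99492 at this
seed), and the fused contour is no longer than the voted one — the level-set
evolution trades voxelwise votes for a smooth, closed boundary at sub-voxel
consensus. `res$energy_trace` holds the per-iteration energy components.

A command-line interface wraps the same functions for NIfTI volumes on disk:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "malsf.R", package = "malsf"))') \
    synth --out fixtures --seed 0
Rscript .../malsf.R segment --target fixtures/target.nii.gz \
    --labels fixtures/label_01.nii.gz,...,fixtures/label_10.nii.gz \
    --truth fixtures/truth.nii.gz --out outdir
Rscript .../malsf.R eval --auto outdir/segmentation.nii.gz --truth fixtures/truth.nii.gz
```

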