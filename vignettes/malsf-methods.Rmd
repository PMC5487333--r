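---
title: "Multi-atlas level set label fusion: model, numerics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-atlas level set label fusion: model, numerics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(malsf)
```

## The problem

Multi-atlas segmentation propagates manually labelled atlases into a target
image's coordinate frame via nonrigid registration and then *fuses* the
propagated labels into one segmentation. Voxelwise fusers such as majority
voting treat every voxel independently: they cannot exploit the target's own
intensities, cannot correct a systematic registration error shared by many
atlases, and can produce ragged, disconnected masks. For structures with weak
intensity contrast — the thalamus in T1-weighted MRI is the canonical example
— both failure modes matter.

`malsf` poses label fusion as an energy minimization over a level set
function $\varphi$ (negative inside the structure, positive outside, zero on
the contour):

$$E(\varphi) = \alpha F(\varphi;\varphi_1,\dots,\varphi_N)
             + \beta D(\varphi; I) + \gamma R(\varphi).$$

The three terms encode, in order, agreement with the atlas shape priors,
agreement with the target intensities, and contour regularity.

## The three energies

**Label fusion.** Each propagated binary label $L_i'$ is represented by its
signed Euclidean distance function $\varphi_i$ (`signed_distance()`), and

$$F(\varphi) = \sum_x \sum_{i=1}^N \omega_i(x)\,
              |\varphi(x) - \varphi_i(x)|^2,
  \qquad \omega_i(x) \ge 0,\ \ \textstyle\sum_i \omega_i(x) = 1 .$$

The weights come from voxelwise local-similarity maps (as produced by
registration packages) normalized by `normalize_weights()`; voxels where all
maps vanish fall back to $1/N$, as does the whole field when no maps are
supplied. $F$ is a convex quadratic in $\varphi$ whose minimizer is the
pointwise weighted mean $\bar\varphi = \sum_i \omega_i \varphi_i$ — working
with distance functions rather than binary votes is what buys sub-voxel
consensus and a meaningful notion of "between" atlas shapes.

**Image term (region-scalable fitting).** Around every point $y$ the
intensities inside and outside the contour within a Gaussian window
$K_\rho$ are approximated by local constants $f_1(y)$, $f_2(y)$. With the
smoothed Heaviside $H_\varepsilon(z) = \tfrac12[1 + \tfrac2\pi
\arctan(z/\varepsilon)]$ and memberships $M_1 = 1 - H_\varepsilon(\varphi)$
(inside), $M_2 = H_\varepsilon(\varphi)$, the optimal fits have the closed
form

$$f_i = \frac{K_\rho * (M_i(\varphi)\, I)}{K_\rho * M_i(\varphi)},$$

and the energy is $D = \sum_x [\lambda_1 e_1 M_1(\varphi) + \lambda_2 e_2
M_2(\varphi)]$ with residual fields $e_i(x) = \int K_\rho(x-y)\,
|I(x)-f_i(y)|^2\,dy$, evaluated through the expansion
$e_i = I^2 - 2I\,(K_\rho * f_i) + K_\rho * f_i^2$ (exact because the discrete
kernel has unit mass). The window scale $\rho$ makes the term *region
scalable*: small $\rho$ tolerates intensity inhomogeneity, large $\rho$
approaches a global two-phase (Chan–Vese-style) fit — in the limit the $f_i$
become the $H_\varepsilon$-weighted global means, a property the test suite
checks to $10^{-6}$.

**Regularity.** $R(\varphi) = \sum_x \delta_\varepsilon(\varphi)\,
|\nabla\varphi|$, the smoothed co-area expression for the length of the zero
level contour; $\delta_\varepsilon = H_\varepsilon'$ is the Cauchy kernel
$\tfrac1\pi \varepsilon/(\varepsilon^2 + z^2)$.

## The evolution equation and two sign/coefficient decisions

Gradient descent on $E$, augmented with the standard distance-regularization
penalty flow $\mu(\nabla^2\varphi - \mathrm{div}(\nabla\varphi /
|\nabla\varphi|))$ that keeps $|\nabla\varphi| \approx 1$ without periodic
reinitialization, gives `evolve_step()`:

$$\frac{\partial\varphi}{\partial t} =
   -2\alpha \sum_i \omega_i (\varphi - \varphi_i)
   + \beta\, \delta_\varepsilon(\varphi)(\lambda_1 e_1 - \lambda_2 e_2)
   + \upsilon\, \delta_\varepsilon(\varphi)\,
     \mathrm{div}\!\left(\frac{\nabla\varphi}{|\nabla\varphi|}\right)
   + \mu\left(\nabla^2\varphi - \mathrm{div}\!\left(
     \frac{\nabla\varphi}{|\nabla\varphi|}\right)\right).$$

Two points here were genuinely open and deserve a record:

* **Sign of the data force.** RSF formulations in the literature are usually
  written for the positive-inside convention ($M_1 = H(\varphi)$), where the
  data force is $-\delta_\varepsilon(\lambda_1 e_1 - \lambda_2 e_2)$. Under
  the negative-inside convention used here ($M_1 = 1 - H_\varepsilon$),
  differentiating $D$ gives $\partial D/\partial\varphi =
  \delta_\varepsilon(\lambda_2 e_2 - \lambda_1 e_1)$, so the descent
  direction flips to $+\delta_\varepsilon(\lambda_1 e_1 - \lambda_2 e_2)$.
  The package implements the descent direction: where the inside fit is
  locally worse than the outside fit, $\varphi$ rises and the voxel leaves
  the structure. Carrying the positive-inside sign over unchanged would
  *ascend* $D$ — the test suite verifies descent directly (an Euler step
  along `rsf_force()` never increases the energy) and that a data-term-only
  flow recovers a clean two-phase region.
* **Fusion force and coefficient mapping.** Operational statements of the
  evolution equation in the label-fusion setting often list only the data,
  curvature and distance-regularization forces. Without the analytic fusion
  gradient $-2\alpha\sum_i \omega_i(\varphi - \varphi_i)$, however, the
  atlas prior would act only through the initialization, making $\alpha F$
  inert during the flow; the package therefore includes the term by default
  and exposes `fusion_in_flow = FALSE` for the initialization-only variant.
  Similarly, the curvature flow is driven by $\upsilon$ alone while $\gamma$
  scales $R$ in energy reporting; `curvature_coeff_mode = "gamma_upsilon"`
  selects the alternative reading where the flow coefficient is
  $\gamma\upsilon$.

`malsf_segment()` initializes $\varphi$ at $\bar\varphi$ — the fusion term's
exact minimizer, so the flow starts from the pure shape-prior solution and
the image term refines it (`init = "majority"` starts from the signed
distance of the majority-vote mask instead) — and runs explicit Euler steps,
refitting $f_1, f_2$ from the current $\varphi$ each iteration (alternating
minimization). The output mask is the strict interior $\varphi < 0$.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| $\alpha$ | 0.1 | – | fusion (shape prior) strength |
| $\beta$ | 1 | – | image term strength |
| $\gamma$ | 0.1 | – | regularization weight in the reported energy |
| $\mu$ | 0.1 | – | distance-regularization strength |
| $\upsilon$ | 0.01 | – | curvature (length-shrinking) flow strength |
| $\lambda_1,\lambda_2$ | $10^{-4}$ | intensity$^{-2}$ | inside/outside residual weights |
| $\varepsilon$ | 1 | voxels | Heaviside/Dirac width |
| $\rho$ | 3 | voxels | fitting window scale |
| $\Delta t$ | 0.1 | – | explicit Euler step |
| `max_iters` | 200 | – | iteration cap |
| `tol` | $10^{-4}$ | – | relative energy change over a 5-iteration window |

The seven coefficients are the fixed working set for all experiments;
$\lambda_i$ are small because $e_i$ scales with squared intensity on the
0–255 range. $\varepsilon$ and $\rho$ follow common practice for
regularized-Heaviside level sets on unit-spaced grids: $\varepsilon$ of one
voxel localizes the Dirac to a ~2-voxel band, and $\rho = 3$ voxels is the
usual RSF neighbourhood; both are exposed in `fusion_params()` since $\rho$
controls the region scalability. $\Delta t = 0.1$ keeps the explicit scheme
comfortably inside the stability bounds of its stiffest parts (the linear
fusion relaxation, rate $2\alpha$, and the $\mu$-diffusion). `tol` uses a
5-iteration window so the slowly oscillating tail of the explicit scheme
does not trigger a premature stop. For parameter selection from labelled
training images, `tune_parameters()` grid-searches any subset of these,
scoring each candidate by mean similarity index and breaking exact ties by
grid order (deterministic).

## Numerical choices

* **Signed distances** use two exact separable (Felzenszwalb–Huttenlocher)
  Euclidean distance transforms: $\varphi = d(\cdot,\text{inside set}) -
  d(\cdot,\text{outside set})$ at voxel centres, in physical units. An
  inside voxel adjacent to the boundary gets $-1$ (unit spacing), its
  outside neighbour $+1$, and `signed_distance(m) == -signed_distance(1-m)`
  holds exactly.
* **Gaussian windows** are separable discrete kernels truncated at $3\rho$
  and renormalized *per voxel over the grid domain* (normalized
  convolution) — the discrete counterpart of restricting the RSF integrals
  to the image domain $\Omega$. Constants are therefore preserved exactly,
  $K*1 = 1$ everywhere including the border, and the truncation radius can
  be capped at the domain extent, which makes the large-$\rho$ limit exact
  and cheap.
* **Finite differences** are central with reflective padding (zero normal
  derivative at the border, no spurious boundary curvature); the gradient
  magnitude in $\mathrm{div}(\nabla\varphi/|\nabla\varphi|)$ is floored at
  $\eta = 10^{-8}$.
* **Degenerate inputs**: fitting denominators $K*M_i$ are floored at
  $10^{-10}$ (a locally absent phase yields a finite fit); an all-zero or
  all-one mask has no boundary and `signed_distance()` refuses it; an empty
  final mask is flagged with a warning rather than an error; a non-finite
  Euler update aborts with a divergence error naming the time step.
* **Metrics**: SI/precision/recall/relative-overlap use voxel counts with
  the ground truth as $A$ and the automatic mask as $B$; the Hausdorff
  distance is the max of the two directed max–min distances between
  *boundary* voxel sets (voxels with an opposite-valued face neighbour), in
  physical units. Voting ties go to background in both voting fusers.

## The synthetic study

No external data ship with the package; `make_phantom()` and
`make_atlas_ensemble()` generate everything the tests and the acceptance
script use. The phantom emulates the low-contrast regime that motivates the
method: a bean-shaped (non-convex) structure occupying ~13% of a 64×64 grid,
intensity gap 20 on the 0–255 scale (inside 120, outside 100), boundary blur
1.5 voxels, additive Gaussian noise $\sigma = 8$. Atlas labels are the truth
resampled through independent smooth random displacement fields — white
noise smoothed at 8 voxels, scaled to a 3-voxel peak, nearest-neighbour
resampled so labels stay binary — with 2% voxelwise label flips; this stands
in for independent registration errors across 10 atlases. Similarity maps
are Gaussian-smoothed agreement between each label and the ensemble
consensus, a documented stand-in for registration-derived similarity (no
atlas *images* exist in the fixture). Blur and displacement smoothness were
fixed once at values typical of T1 tissue interfaces and nonrigid
registration error correlation lengths; everything is deterministic given a
seed.

What the fixture does *not* emulate: intensity bias fields, partial-volume
mixtures, anatomically realistic shapes, and — most importantly —
*correlated* registration failures shared across atlases. Independent
zero-mean deformations average out well, so voxelwise voting is already
strong on this fixture and the margin by which the level-set fusion beats it
is small; on real data with systematic registration bias the image term has
more room to correct the consensus. Passing the desk-scale tests therefore
demonstrates correctness of the machinery and the qualitative ordering of
methods, not a clinical effect size.

Problem sizes throughout the test suite are chosen at desk scale — $64^2$
fixtures for end-to-end runs, $\le 12^2$ instances wherever a brute-force
oracle recomputes a quantity exactly, 200-iteration evolutions for the
descent checks — so the whole suite runs in about a minute.

## Known limitations

* Two-phase only: one structure against background per run (left/right
  structures are independent runs); no multi-label coupling.
* No narrowband or fast-marching acceleration; cost is proportional to grid
  size per iteration. The intended use is on a region of interest cropped to
  the label union (`roi_union()`, default margin 5 voxels).
* Anisotropic spacing is honoured in distances and finite differences, but
  the Gaussian window $\rho$ is isotropic in voxels.
* The explicit Euler scheme with the default $\Delta t$ is not
  unconditionally energy-monotone; the test suite asserts per-step descent
  within $10^{-3} E_0$ rather than strict monotonicity.
* Registration, bias-field correction and similarity-map computation are
  upstream of this package and must be supplied by the caller.
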