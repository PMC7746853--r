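---
title: "Methods: hybrid active contour segmentation with bilateral filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid active contour segmentation with bilateral filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acbf)
```

## The model

The package segments a single-channel image $I \in [0,1]^{H\times W}$ by
evolving a level-set field $\phi$ with the interior convention
$\phi<0$ inside the contour, $\phi>0$ outside, and the Heaviside
indicator $H(\phi)=\mathbf 1\{\phi\le 0\}$ ($\phi=0$ is assigned to the
interior so that interior area is exactly the pixel count
$\sum H(\phi)$). One evolution equation serves both phases:

$$\frac{\partial\phi}{\partial t} \;=\;
\Big[(1-|\alpha|)\,\big(I_{BF}-\tfrac{c_1+c_2}{2}\big) \;+\;
\alpha\,\kappa\Big]\,|\nabla\phi|,$$

where $I_{BF}$ is the bilateral-filtered image, $c_1,c_2$ are the mean
intensities inside and outside the current contour, $\kappa$ is a binary
stopping mask and $\alpha \in \{0,-1,+1\}$ is the phase switch:

* **Global phase, $\alpha=0$, $\kappa\equiv 1$.** The update reduces to
  the simplified two-phase piecewise-constant (Chan–Vese) force
  $I_{BF} - (c_1+c_2)/2$: a running two-class intensity threshold. The
  underlying assumption is that, after despeckling, lesion and
  background are approximately two homogeneous intensity classes. The
  original quadratic form
  $\lambda_1(I-c_1)^2-\lambda_2(I-c_2)^2$ is also implemented
  (`cv_step_original`) as a baseline; with unit weights the two models
  converge to the same two-class partition, which the test suite checks
  on bimodal phantoms.
* **Switch.** Convergence is declared when the contour length
  $\sum|\nabla H(\phi)|$ and the interior area are both stationary:
  $|\Delta L| \le \theta$ and $|\Delta A| \le \theta$ over several
  consecutive evaluations. The converged field then yields the binary
  stopping function $\kappa = H(\phi)$ (expanding) or $1-H(\phi)$
  (shrinking), and the mode is inferred by summing the converged $\phi$
  over the boundary pixels of the user's seed region: negative sum
  $\Rightarrow$ the seed sits inside the object (expand, $\alpha=-1$),
  positive sum $\Rightarrow$ the seed encloses it (shrink, $\alpha=+1$).
* **Local phase, $\alpha=\pm 1$.** The threshold force vanishes
  ($1-|\alpha|=0$) and the front, restarted at the seed, moves at unit
  speed only where $\kappa=1$. Because $\kappa$ is binary, the force is
  exactly zero beyond the stopping boundary, so the local phase cannot
  leak — the property that the gradient-based edge-stopping function
  $g = 1/(1+|\nabla(G_\sigma * I)|^2)$ (implemented as `esf_g` with a
  `gac_step` baseline) fails to provide on blurry speckled images.

Restarting the local front at the seed, rather than continuing from the
converged global field, is what makes the local phase *local*: the
global threshold partition contains every region of the target class,
while the seeded restart recovers only the component(s) the user marked.
It is also what gives the two-phase history its characteristic shape —
a spike in error length/area at the switch, then decay to zero.

## Parameters

All tunables live in `acbf_control()`:

| parameter | default | units | role |
|---|---|---|---|
| `sigma_s` | 3 | px | spatial width of the bilateral filter |
| `sigma_i` | 0.1 | intensity | range width; edges with step $\gg \sigma_i$ are preserved |
| `window_radius` | `ceiling(3*sigma_s)` | px | filter window truncation |
| `dt` | 10 | — | global-phase step (see numerics below) |
| `dt_local` | 1 | — | local-phase step |
| `theta` | 0 | px / px² | convergence tolerance; 0 is attainable because length and area are discrete on the binarised field |
| `check_interval` | 10 | iterations | spacing of convergence evaluations |
| `stable_checks` | 3 | evaluations | consecutive passes required, so convergence is not declared during an oscillation |
| `max_iter` | 2000 | iterations | per-phase safety cap |
| `polarity` | `"dark"` | — | interior captures the class below (`dark`) or above (`bright`) the running midpoint |
| `rd_coef` | 0.2 | — | diffusion coefficient of the regularisation pass |
| `use_bf` | `TRUE` | — | disable for the preprocessing ablation |

On $[0,1]$-normalised images, `sigma_i = 0.1` sits between the
within-region speckle scale and typical lesion contrast, which is the
regime in which the range kernel smooths grain but not boundaries.
Intensities are always normalised by the source bit-depth maximum on
load, so `sigma_i` is bit-depth independent.

## Numerics of the binary level set

The field is regularised every iteration by the reaction–diffusion pass
`rd_regularize`: binarise to $\pm 1$ by sign, then one explicit
diffusion step $\phi + 0.2\,\Delta\phi$ with the 5-point (4-neighbour)
Laplacian and Neumann (replicate) boundaries. Three consequences shape
every other numerical choice:

1. **Flip quantisation.** After the pass, a front pixel sits at
   $|\phi| \approx 0.6$ and the sign-binarisation discards any update
   that does not cross zero. A force $F$ therefore moves the front only
   when $\mathrm{d}t\cdot|F|\cdot|\nabla\phi| \gtrsim 0.6$ (with
   $|\nabla\phi|\approx 0.8$ at the front). The global threshold force
   is bounded by half the region contrast, so the global phase needs a
   large step — hence `dt = 10`. The local force has unit scale, and
   its step must stay *small* enough that nothing flips beyond the
   stopping boundary — hence `dt_local = 1`, at which the front
   provably halts at the $\kappa$ edge (the largest force outside
   $\kappa$ is zero). Explicit-scheme CFL limits do not apply: the
   re-binarisation clamps $\phi$ each iteration.
2. **Curvature by threshold dynamics.** Sign-thresholding followed by a
   diffusion step, re-thresholded on the next iteration, is a
   threshold-dynamics (Merriman–Bence–Osher) realisation of motion by
   mean curvature. The curvature motion of the divergence terms
   $\mathrm{div}(\nabla\phi/|\nabla\phi|)$ /
   $\mathrm{div}(\kappa\nabla\phi/|\nabla\phi|)$ is therefore carried by
   the regularisation pass itself, and no explicit curvature term
   appears in the updates. This is not merely economical: an explicit
   curvature term is stable only for steps around $0.25$, incompatible
   with the step sizes flip quantisation demands, and at those steps its
   discretisation noise (spurious $\pm0.5$ values at the shoulders of
   the gradient support of a near-binary field) fragments or ratchets
   the front. The diagnostic operator `curvature()` (central-difference
   $\mathrm{div}(\nabla\phi/|\nabla\phi|)$ with an $10^{-8}$
   gradient-magnitude floor) is still exported and oracle-tested against
   the analytic curvature of a circle's signed distance.
3. **Force normalisation.** Each region step rescales its data force by
   its sup-norm. A positive per-iteration rescaling only reparametrises
   evolution time — sign structure and fixed points are untouched — but
   it makes the flip threshold relative to image contrast rather than
   absolute. Without it, a large enclosing seed can start with
   $|{\rm background} - {\rm midpoint}|$ below the flip threshold and
   freeze; with it, seed placement is immaterial, which the suite
   verifies by requiring identical converged masks from an inside seed
   and an enclosing seed.

Two further discretisation choices: the edge-alignment component
$\nabla\kappa\cdot \hat n$ of the stopping divergence term is omitted —
on a pixel-aligned binary mask there is no sub-pixel edge to align to,
and under flip quantisation the term only dilates the result 1–2 px past
the stopping boundary (the `gac_step` baseline keeps its classical
$\nabla g\cdot\hat n$ attraction, meaningful for smooth $g$). And the
variational Dirac $\delta(\phi)$ is replaced by $|\nabla\phi|$ in all
evolutions, which confines motion to the front; a consequence worth
stating is that disconnected regions cannot nucleate away from the
front, so "seed outside the object" means an enclosing region, not a
disjoint one.

Degenerate inputs are errors, not silent results: an empty interior or
exterior during the global phase, an all-zero stopping function, a
full-frame stopping function, and an exactly balanced seed-boundary sum
(ambiguous mode) all abort with diagnostics. A non-convergent phase
returns its result flagged `converged = FALSE` (nonzero exit from the
CLI).

## The phantom generator

`phantom_spec()` / `render_phantom()` implement the additive transformed
speckle model $g = f + h * w$: a piecewise-constant clean image $f$
(background 0.55, lesion 0.25 by default — a hypoechoic target), plus
zero-mean Gaussian white noise $w$ convolved with a Gaussian PSF $h$
(sum-normalised, $\sigma = 1.5$ px), clipped to $[0,1]$. Lesion
boundaries are ellipses whose polar radius carries a seeded 2–5-harmonic
perturbation, emulating the irregular margins clinical reporting systems
describe; datasets jitter position, size, rotation and contrast under
one master seed with derived per-item seeds, so any suite is
reproducible from two integers.

The white-noise level defaults to $\sigma_w = 0.5$, leaving post-PSF
speckle of sd $\approx 0.094$ — about a third of the default lesion
contrast. This is a deliberate calibration: with the PSF sum-normalised
(which is what makes pixel noise variance decrease as the PSF widens,
a property the tests check), the speckle grain must be set at the level
where raw-image threshold classification visibly degrades
(per-pixel misclassification around 10%) while the filtered image
classifies cleanly, because that is the regime the method addresses and
the only one in which the filtering ablation measures anything.

What the phantoms emulate: two-class intensity structure, correlated
multiplicative-origin grain in its additive transformed form, irregular
star-shaped lesion margins, optional smooth inhomogeneity ramps,
multiple lesions. What they do not: beamforming physics, Rayleigh/Rician
amplitude statistics, attenuation shadows, heterogeneous internal echo
texture. Passing the phantom suite therefore demonstrates correctness
of the machinery and the claimed structural properties (threshold
consistency, initialisation insensitivity, mode selection, confinement
by the stopping function, the direction of the filtering benefit) — not
clinical-grade accuracy on real ultrasound.

## Validation layout

The test suite runs entirely on phantoms built in code. Problem sizes
were chosen to exercise every code path at desk scale: oracle equality
of the bilateral filter on 100 random images up to $16\times16$ against
a brute-force quadruple-loop reference ($10^{-12}$); model agreement
(simplified vs original) on twenty $32\times32$ bimodal phantoms;
field-exact phase equivalence of the hybrid and simplified updates on
random states; mode inference and area monotonicity on twenty default
phantoms per mode; and a 50-phantom two-arm benchmark at the default
$128\times128$ conditions for the confinement, single-switch and
recovery checks. `scripts/acceptance.R` recomputes the benchmark
quantities from scratch for any seed.

## Known limitations

* Seeds are manual; automatic initialisation is out of scope.
* The global phase assumes a meaningful two-class partition after
  filtering; strong inhomogeneity can bias the threshold (a polarity
  flag handles hyperechoic targets, not inhomogeneity).
* The stopping function is built once, at the first convergence; it is
  not rebuilt if the local phase degenerates.
* Front motion is capped at one pixel per iteration by construction, so
  runtime scales with lesion diameter.
* Dice is the only metric reported; boundary-distance metrics are not
  implemented.
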