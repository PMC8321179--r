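---
title: "Halo-free gradient-domain daltonisation: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Halo-free gradient-domain daltonisation: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daltonise)
```

## The problem and the model

A colour vision deficient (CVD) observer confuses colours that differ
along a particular direction of colour space. Given an image `u0` and a
simulation `s(u0)` of what the observer perceives, the lost information
is the difference image `d0 = u0 - s(u0)`. Daltonisation rotates this
invisible content into a visible colour direction.

### Observer model

The simulation used here is a severity-weighted matrix blend acting
directly on encoded sRGB values in $[0,1]$:
$$ s(u) = \alpha M u + (1-\alpha)\,u, $$
with $M$ one of two row-stochastic dichromat matrices (red–green or
blue–yellow) and $\alpha \in [0,1]$ the severity. Because $M$ has
non-negative entries and unit row sums, the blend maps the RGB cube into
itself and fixes the achromatic axis exactly; `simulate_cvd()` therefore
asserts rather than clips. All processing stays on encoded (non-linear)
sRGB values: the observer matrices are defined on them, and no
linearisation step is introduced anywhere in the pipeline. The observer
object carries its transform as a function, so an LMS-space dichromat
projection could be swapped in without touching the rest of the
pipeline; only the matrix backend ships.

### Colour basis

An *uncentred* PCA of the per-pixel `d0` vectors (dominant eigenvector of
the second-moment matrix $\sum_p d_p d_p^T$) gives the principal loss
direction `p1`. Uncentred, because `d0` measures displacement from the
simulation surface: the meaningful axis passes through the origin, and
centring would misbehave on images where most pixels lose nothing.
Gram–Schmidt against the grey axis then yields the orthonormal triplet
`el` (lightness), `ed` (lost difference), `ec = el x ed` (maximally
visible chroma).

Two sign conventions make the construction deterministic: the component
of `p1` largest in magnitude is made positive (first such component on
ties, compared with a `1e-9` slack so exact ties are broken by index, not
by round-off), and `ec` is the right-handed cross product, with
`flip_ec = TRUE` exposing the equally valid opposite hue.

### Grey axis: why the default is flat

Both `[1,1,1]` and the sRGB luminance weights are supported as the grey
axis. The default is the **flat** axis `[1,1,1]/sqrt(3)`. The choice
matters more than it first appears. With the flat axis, `ed` is a pure
opponent direction — `(R-G)/sqrt(2)` for red–green observers,
`(R+G-2B)/sqrt(6)` for blue–yellow — so axis-neutral colours (greys, and
any colour with `R = G` for the RG case) have zero projection and are
*exact fixed points* of the recolouring: only pixels that actually lose
information are recoloured. With the luminance axis, orthogonalising
`p1` against the luminance vector leaves a large achromatic component in
`ed`; every bright pixel then projects strongly onto `ed` and the whole
image — including neutral backgrounds that lose nothing — receives a
large uniform colour shift. In experiments with the synthetic suite this
global cast inverted the expected behaviour of the method comparison
(reintegration artefacts moved pixels *towards* the original, rewarding
exactly the halo behaviour the anisotropic variant is designed to
remove). The luminance axis remains available via
`grey_axis = "luminance"`.

### Simple daltonisation and the gradient tensor

The closed-form recolouring is
$$ u_s = g\!\left(u_0 + (u_0 \cdot e_d)\, e_c\right), $$
with `g` per-channel clamping to $[0,1]$ (the simplest projection onto
the gamut). `u_s` is a serviceable daltonisation on its own and the
initial value for the diffusion methods. The target gradient field is
$$ G = \nabla u_0 + (\nabla u_0 \cdot e_d)\, e_c, $$
the image gradient with its lost component rotated into the visible
direction (unit rotation weight; no scalar field is solved for). The
basis is computed once from `u0` and frozen: `G` and the diffusion
tensor never see the evolving image.

### Reintegration

Both diffusion methods run the explicit-Euler projected flow
$$ u \leftarrow g\!\left(u + \Delta t\, \nabla\!\cdot\!\left[D (\nabla u - G)\right]\right),
   \qquad u(t=0) = u_s, $$
with `D = I` (isotropic) or the frozen local linear anisotropic tensor.
`D` is built from the Di Zenzo multichannel structure tensor of the
original image, $S_{ij} = \sum_k \partial_i u_k\, \partial_j u_k$, by
mapping its eigenvalues through the diffusivity
$d(\lambda) = 1/(1+\kappa\lambda^2)$ while keeping its eigenvectors.
Across a strong edge ($\lambda$ large) diffusion is throttled towards
zero; along edges and in smooth regions it proceeds at full strength.
This is what removes halos: the clipped excess of `u_s` can no longer
bleed across object boundaries into regions that were never recoloured.

The structure-tensor definition in the source literature prints a double
sum over two channel indices; read literally it is the outer product of
channel-summed gradients. The standard Di Zenzo single sum over channels
is implemented as the default, and the literal variant is available as
`structure_tensor(img, literal_double_sum = TRUE)` for comparison; no
attempt is made to guess which was intended.

## Numerical choices

* **Discretisation.** Forward differences with Neumann (zero) boundary
  for the gradient; the divergence is constructed as the *exact*
  negative adjoint (backward differences with boundary rows), so
  $\langle \nabla u, p\rangle = -\langle u, \nabla\!\cdot p\rangle$
  holds to machine precision and the discrete energy
  $\sum \lVert \nabla u - G \rVert_F^2$ is non-increasing along the
  isotropic flow. The test suite checks both properties directly.
* **Stability.** With $d(\lambda) \le 1$ the explicit 2-D scheme is
  stable for $\Delta t \le 1/4$; the default is `dt = 0.24` and
  `solver_config()` rejects larger steps.
* **Stopping.** `max |du| / dt < tol` with `tol = 1e-4`, capped at
  `max_iter = 1000`. The solver reports iterations, convergence and the
  final update, and can record the energy trace.
* **kappa.** `kappa = 1e4` (units: inverse squared structure-tensor
  eigenvalue) puts the $d = 1/2$ transition at gradient magnitudes of
  about $0.1$ — edges of a few tens of 8-bit levels. Much weaker texture
  diffuses freely; strong chromatic edges are essentially frozen.
* **Gamut constraint.** Projected gradient descent: the image is clamped
  after every step, not only at the end.
* **Structure-tensor smoothing.** No Gaussian pre-smoothing by default
  (`smooth_sigma = 0`); a separable Gaussian is available when noisy
  inputs demand it.
* **Degeneracy.** If every pixel's `|d0|` is below `1e-6`, or the loss
  direction is achromatic (parallel to the grey axis within `1e-6` rad),
  the observer effectively loses nothing; every daltonisation entry
  point returns the input unchanged rather than erroring.
* **Wilcoxon with ties.** The paired comparison discards zero
  differences, and for up to 25 remaining pairs computes the *exact*
  two-sided signed-rank p-value by direct convolution over sign flips on
  doubled midranks — valid under tied magnitudes, where the textbook
  exact distribution does not apply (constant shifts between methods,
  common in grid comparisons, tie every magnitude). Above 25 pairs the
  normal approximation with continuity correction is used.

## The synthetic suite

`fixture_suite()` stands in for a set of colourful photographs with
dominant red–green and blue–yellow contrast. Its palettes are built by
construction, not by eye: an object colour and a background colour
separated along the *null direction* of the target dichromat matrix
(`[1,-1,0]` for RG, `[1,1,-1]` for BY), so the object/background
contrast is provably invisible to that observer — the suite's
confusability is a theorem, not an observation. The design mirrors what
makes real photographs hard for these algorithms:

* **Asymmetry.** The background is axis-neutral (plus a small random
  tint so observers of the other axis still see a little loss, as with
  real photographs); only the object is strongly recoloured. Halos are
  then pure damage: colour bleeding into pixels the method had no reason
  to touch.
* **Saturation.** Object colours graze the gamut boundary
  (margin 0.005), as in highly saturated imagery, so the recolouring
  clips and halo spill has no headroom.
* **Detail.** Ishihara-style plates use dense, radially shaded dots on a
  near-white paper canvas with per-dot lightness jitter (visible to
  everyone, uninformative about the numeral), so clipping destroys real
  structure that reintegration can recover. Texture fields pass
  two-octave smooth noise through a steep sigmoid: saturated patches
  with boundaries a few pixels wide and residual interior texture.
  Chroma edges and ramps stay as pure half-planes and linear blends —
  the clean cases for the solver's unit tests.

Default study conditions (chosen once): 14 images, 256 × 256 pixels,
half RG- and half BY-confusable with every kind occurring on both axes,
evaluated for four observers (RG/BY × α ∈ {1.0, 0.8}) under the default
solver configuration; the smaller grids in the unit tests (32–64 px,
reduced `max_iter`) exercise the same code paths at lower cost.

What the suite does **not** capture: natural image statistics (1/f
spectra, lighting, camera noise), adjacent saturated objects of
different hues, and the heterogeneity of a real photo collection. Two
consequences follow. First, passing tests show the algorithms behave as
designed on images with the assumed structure, not that they are
preferable on any particular photograph. Second, with only 14 synthetic
images the paired isotropic-vs-anisotropic comparison is underpowered:
the median orderings (simple worst on GPF; anisotropic at least as good
as isotropic on GPF and closer to the original on PSNR) are stable
across suite seeds, but which of the two Wilcoxon p-values crosses 0.05
varies with the seed — on the fixed suite used by the acceptance tests
the PSNR comparison is significant and the GPF one is not. A
significance level like the published one would require a larger and
more photograph-like image population.

## Known limitations

* The matrix observer model is a coarse approximation of dichromat
  vision (no LMS projection, no tritan-specific modelling); it is,
  however, exactly the model the evaluation machinery assumes, and the
  pipeline accepts any image-to-image simulation backend.
* Reintegration cost grows with image area; 1000 explicit steps on a
  256 × 256 image take on the order of a second with the compiled inner
  loop, but very large images would want a multigrid or implicit solver,
  which is out of scope.
* The gamut projection is per-channel clamping; perceptually uniform
  gamut mapping is out of scope.
* PSNR and GPF are proxy metrics; no perceptual difference metric or
  behavioural validation is included.
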