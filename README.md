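# daltonise

Halo-free gradient-domain daltonisation of colour images in R.

About 8% of men and 0.4% of women have a congenital colour vision
deficiency (CVD), most often on the red–green axis. *Daltonisation*
recolours an image so that chromatic detail such an observer cannot
distinguish is rotated into a colour direction they can see, at the cost
of introducing artificial colours. This package is for researchers and
tool builders in colour imaging who need a spatial (image-dependent)
daltonisation method that does not produce the halo artefacts of earlier
gradient-domain approaches, together with the machinery to evaluate it:
a parametrised CVD simulation, gamut-pixel-fraction (GPF) and PSNR
metrics, a paired Wilcoxon comparison harness, and a seeded synthetic
image generator so that everything runs without external data.

## Method

An observer is modelled by a severity-weighted matrix simulation acting
directly on encoded sRGB values in [0, 1],

    s(u) = α M u + (1 − α) u,

with `M` the red–green or blue–yellow dichromat matrix

    M_RG = [ 1/2 1/2  0 ]      M_BY = [ 1/2  0   1/2 ]
           [ 1/2 1/2  0 ]             [  0  1/2  1/2 ]
           [  0   0   1 ]             [ 1/4 1/4  1/2 ]

(`α = 0` colour normal, `0 < α < 1` anomalous trichromat, `α = 1`
dichromat). The lost information is `d0 = u0 − s(u0)`. An uncentred PCA
of `d0` gives the principal loss direction, from which Gram–Schmidt
against the grey axis builds the orthonormal colour triplet
`(e_l, e_d, e_c)`: lightness, lost difference, and maximally visible
chroma. Three methods are provided:

* **simple** — the closed-form recolouring
  `u_s = g(u0 + (u0·e_d) e_c)`, with `g` the gamut clip. Fast and
  halo-free, but clipping destroys detail in saturated regions.
* **isotropic** — gradient-domain reintegration of the recoloured
  gradient tensor `G = ∇u0 + (∇u0·e_d) e_c` by the explicit flow
  `∂u/∂t = ∇·(∇u − G)`, started from `u_s` and projected onto the gamut
  each step. Restores clipped detail but bleeds colour across strong
  edges (halos).
* **anisotropic** — the same flow through a diffusion tensor frozen from
  the original image, `∂u/∂t = ∇·[D(∇u − G)]`, where `D` shares the
  eigenvectors of the Di Zenzo structure tensor `S` with eigenvalues
  `d(λ) = 1/(1 + κλ²)`. Diffusion is throttled across strong edges, so
  detail is restored without halos.

Evaluation follows the method literature: GPF (the fraction of pixels
with a channel at 0 or 1 — a proxy for clipping-induced detail loss),
PSNR against the original (colour distortion), and a paired two-sided
Wilcoxon signed-rank test comparing the isotropic and anisotropic
variants over a test suite.

## Worked example

```r
library(daltonise)

img <- generate_fixture(fixture_spec(
  "ishihara_plate", size = c(128, 128),
  palette = confusable_palette("rg", background = c(0.5, 0.5, 0.45),
                               amplitude = 0.55),
  seed = 42))
obs <- cvd_observer("rg", 1)        # red-green dichromat
out <- daltonise(img, obs, method = "anisotropic")

attr(out, "diagnostics")$iterations
#> 317
gamut_pixel_fraction(daltonise(img, obs, method = "simple"))
#> 0.02716064
gamut_pixel_fraction(out)
#> 0.003234863
psnr(out, img)
#> 25.07 (dB)

build_basis(principal_difference_direction(lost_difference(img, obs)))
#> <direction_basis>
#>   el = [ 0.5774,  0.5774,  0.5774]
#>   ed = [ 0.7071, -0.7071,  0.0000]
#>   ec = [ 0.4082,  0.4082, -0.8165]
```

The plate hides a numeral drawn in colours a red–green dichromat cannot
tell apart; the anisotropic daltonisation converges in a few hundred
explicit steps, leaves an order of magnitude fewer pixels stuck on the
gamut boundary than the closed-form method (0.003 vs 0.027), and stays
close to the original (25 dB). The basis shows the red–green loss
direction being rotated into a blue–yellow direction.

A thin command-line front end is installed with the package
(`system.file("cli", "daltonise", package = "daltonise")`) with
subcommands `simulate`, `daltonise`, `metrics`, `fixtures` and
`evaluate`.

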