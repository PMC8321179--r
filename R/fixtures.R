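## Seeded synthetic test images with strong red-green or blue-yellow
## chromatic contrast.  Palettes are built by construction along the null
## directions of the dichromat matrices, so the contrast is mathematically
## guaranteed to vanish under the corresponding alpha = 1 simulation.

# evaluate `code` under a local RNG seeded with `seed`, restoring the
# caller's RNG state afterwards
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Confusable object/background colour pair for a CVD axis
#'
#' Two RGB colours separated along the null direction of the dichromatic
#' simulation matrix: `[1, -1, 0]/sqrt(2)` for the red-green matrix,
#' `[1, 1, -1]/sqrt(3)` for the blue-yellow one.  Both colours (and every
#' convex combination of them) map to the *same* colour under the
#' corresponding `alpha = 1` observer, so any detail drawn with this pair
#' is invisible to it.
#'
#' The pair is deliberately asymmetric, mirroring photographs with a
#' dominant confusable subject: row `b` is the `background` colour, which
#' is neutral with respect to the axis (red = green for `"rg"`; a grey for
#' `"by"`) and therefore nearly untouched by daltonisation, while row `a`
#' is the saturated object colour `background + amplitude * dir`.  The
#' amplitude is reduced if needed to keep the object colour within
#' `[margin, 1 - margin]`.
#'
#' @param axis `"rg"` or `"by"`.
#' @param background RGB triple of the background colour (default a mid
#'   grey); its red and green channels are averaged for `"rg"`, all three
#'   channels for `"by"`, to put it on the axis-neutral locus.
#' @param amplitude signed distance from the background to the object
#'   colour along the (unit) confusion direction; the sign selects e.g.
#'   red versus green objects.
#' @param margin minimum distance from the gamut boundary (default 0.03).
#' @return 2 x 3 matrix, rows `a` (object) and `b` (background).
#' @export
confusable_palette <- function(axis = c("rg", "by"),
                               background = c(0.5, 0.5, 0.5),
                               amplitude = 0.55, margin = 0.03) {
  axis <- match.arg(axis)
  dir <- if (axis == "rg") c(1, -1, 0) / sqrt(2) else c(1, 1, -1) / sqrt(3)
  background <- pmin(pmax(background, margin), 1 - margin)
  if (axis == "rg") {
    background[1:2] <- mean(background[1:2])
  } else {
    background[] <- mean(background)
  }
  d <- sign(amplitude) * dir
  # largest step keeping background + t*d inside [margin, 1-margin]
  room <- ifelse(d > 0, (1 - margin - background) / d,
                 ifelse(d < 0, (background - margin) / (-d), Inf))
  t <- min(abs(amplitude), room)
  rbind(a = pmin(pmax(background + t * d, margin), 1 - margin),
        b = background)
}

#' Synthetic image specification
#'
#' @param kind one of `"ishihara_plate"` (numeral spelled out in
#'   confusable-coloured dots), `"chroma_edge"` (two half-planes),
#'   `"chroma_ramp"` (linear blend), `"texture_field"` (smooth noise mapped
#'   onto the palette axis).
#' @param size `c(H, W)` in pixels.
#' @param palette 2 x 3 matrix of RGB rows (see [confusable_palette()]).
#' @param seed integer; the same spec always generates bit-identical
#'   pixels.
#' @return list of class `"fixture_spec"`.
#' @export
fixture_spec <- function(kind = c("ishihara_plate", "chroma_edge",
                                  "chroma_ramp", "texture_field"),
                         size = c(256L, 256L),
                         palette = confusable_palette("rg"),
                         seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(length(size) == 2L, all(size >= 1))
  palette <- as.matrix(palette)
  stopifnot(identical(dim(palette), c(2L, 3L)),
            all(palette >= 0), all(palette <= 1))
  structure(list(kind = kind, size = as.integer(size), palette = palette,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic test image
#'
#' Deterministic given the spec (seeded local RNG; the caller's RNG state
#' is untouched).
#'
#' @param spec a [fixture_spec()].
#' @return `H x W x 3` array in `[0, 1]`.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, switch(
    spec$kind,
    chroma_edge = fixture_chroma_edge(spec),
    chroma_ramp = fixture_chroma_ramp(spec),
    texture_field = fixture_texture_field(spec),
    ishihara_plate = fixture_ishihara(spec)
  ))
}

flat_image <- function(H, W, colour) {
  img <- array(0, c(H, W, 3L))
  for (k in 1:3) img[, , k] <- colour[k]
  img
}

# t in [0,1] (H x W) mixed along the palette segment a..b
mix_palette <- function(t, palette) {
  H <- nrow(t); W <- ncol(t)
  img <- array(0, c(H, W, 3L))
  for (k in 1:3)
    img[, , k] <- (1 - t) * palette["b", k] + t * palette["a", k]
  img
}

fixture_chroma_edge <- function(spec) {
  H <- spec$size[1L]; W <- spec$size[2L]
  t <- matrix(0, H, W)
  t[, seq_len(ceiling(W / 2))] <- 1  # left half colour a, right half b
  mix_palette(t, spec$palette)
}

fixture_chroma_ramp <- function(spec) {
  H <- spec$size[1L]; W <- spec$size[2L]
  t <- matrix(if (W > 1) (seq_len(W) - 1) / (W - 1) else 0.5,
              H, W, byrow = TRUE)
  mix_palette(1 - t, spec$palette)  # colour a on the left
}

fixture_texture_field <- function(spec) {
  H <- spec$size[1L]; W <- spec$size[2L]
  # two octaves of smooth noise mapped onto the confusable a..b axis
  # through a steep sigmoid: saturated object patches and background
  # separated by boundaries a few pixels wide (as in photographs), with a
  # residual smooth chromatic texture inside the patches
  coarse <- bilinear_upsample(matrix(stats::runif(9 * 9), 9, 9), H, W)
  fine <- bilinear_upsample(matrix(stats::runif(33 * 33), 33, 33), H, W)
  t <- 0.65 * coarse + 0.35 * fine
  t <- (t - min(t)) / max(max(t) - min(t), 1e-12)
  t <- 0.6 * stats::plogis(40 * (t - 0.5)) + 0.4 * t
  mix_palette(t, spec$palette)
}

bilinear_upsample <- function(m, H, W) {
  k1 <- nrow(m); k2 <- ncol(m)
  x <- if (H > 1) (seq_len(H) - 1) / (H - 1) * (k1 - 1) else 0
  y <- if (W > 1) (seq_len(W) - 1) / (W - 1) * (k2 - 1) else 0
  i0 <- pmin(floor(x), k1 - 2); fi <- x - i0
  j0 <- pmin(floor(y), k2 - 2); fj <- y - j0
  i0 <- i0 + 1; j0 <- j0 + 1  # 1-based
  out <- matrix(0, H, W)
  for (j in seq_len(W)) {
    c0 <- m[, j0[j]] * (1 - fj[j]) + m[, j0[j] + 1] * fj[j]
    out[, j] <- c0[i0] * (1 - fi) + c0[i0 + 1] * fi
  }
  out
}

# seven-segment numeral rendered as a logical mask in the central region
numeral_mask <- function(H, W, digit) {
  segs <- list(  # each segment: c(x0, y0, x1, y1) in [0,1]^2 (x right, y up)
    a = c(0.15, 0.90, 0.85, 1.00), b = c(0.75, 0.50, 0.90, 1.00),
    c = c(0.75, 0.00, 0.90, 0.50), d = c(0.15, 0.00, 0.85, 0.10),
    e = c(0.10, 0.00, 0.25, 0.50), f = c(0.10, 0.50, 0.25, 1.00),
    g = c(0.15, 0.45, 0.85, 0.55))
  on <- list(`0` = "abcdef", `1` = "bc", `2` = "abged", `3` = "abgcd",
             `4` = "fgbc", `5` = "afgcd", `6` = "afgedc", `7` = "abc",
             `8` = "abcdefg", `9` = "abcfgd")[[as.character(digit)]]
  # glyph occupies the central 50% x 30% of the image
  gx0 <- 0.35 * W; gx1 <- 0.65 * W
  gy0 <- 0.25 * H; gy1 <- 0.75 * H
  mask <- matrix(FALSE, H, W)
  for (s in strsplit(on, "")[[1L]]) {
    r <- segs[[s]]
    x0 <- gx0 + r[1] * (gx1 - gx0); x1 <- gx0 + r[3] * (gx1 - gx0)
    # image row index grows downwards; segment y grows upwards
    i0 <- max(1L, floor(gy1 - r[4] * (gy1 - gy0)))
    i1 <- min(H, ceiling(gy1 - r[2] * (gy1 - gy0)))
    j0 <- max(1L, floor(x0)); j1 <- min(W, ceiling(x1))
    mask[i0:i1, j0:j1] <- TRUE
  }
  mask
}

fixture_ishihara <- function(spec) {
  H <- spec$size[1L]; W <- spec$size[2L]
  pal <- spec$palette
  mask <- numeral_mask(H, W, sample(0:9, 1L))
  # light "paper" canvas: the background colour lifted towards white, as
  # on a printed plate, leaving little headroom above
  canvas <- pmin(pal["b", ] + 0.35, 0.96)
  img <- flat_image(H, W, canvas)
  r_min <- max(2, round(min(H, W) / 48))
  r_max <- max(r_min + 1, round(min(H, W) / 14))
  centres <- matrix(0, 0, 2L)
  radii <- numeric(0)
  fails <- 0L
  max_consecutive_fails <- 4000L
  while (fails < max_consecutive_fails) {
    r <- stats::runif(1, r_min, r_max)
    ci <- stats::runif(1, 1 + r, H - r)
    cj <- stats::runif(1, 1 + r, W - r)
    if (nrow(centres) > 0 &&
        any((centres[, 1] - ci)^2 + (centres[, 2] - cj)^2 <
            (radii + r + 1)^2)) {
      fails <- fails + 1L
      next
    }
    fails <- 0L
    centres <- rbind(centres, c(ci, cj))
    radii <- c(radii, r)
    inside <- mask[round(ci), round(cj)]
    # chromatic jitter along the confusable segment (invisible to the
    # target observer) plus the lightness jitter of real pseudoisochromatic
    # plates: visible to everyone, uninformative about the numeral
    t <- if (inside) stats::runif(1, 0.75, 1) else stats::runif(1, 0, 0.25)
    l <- stats::runif(1, -0.10, 0.10) / sqrt(3)
    colour <- t * pal["a", ] + (1 - t) * pal["b", ]
    shade <- stats::runif(1, 0.08, 0.18) / sqrt(3)  # printed-dot shading
    i <- max(1L, floor(ci - r)):min(H, ceiling(ci + r))
    j <- max(1L, floor(cj - r)):min(W, ceiling(cj + r))
    d2 <- outer((i - ci)^2, (j - cj)^2, `+`)
    hit <- d2 <= r^2
    # smooth radial lightness gradient inside the dot (bright centre)
    dome <- (1 - d2 / r^2)[hit]
    for (k in 1:3) {
      plane <- img[i, j, k]
      plane[hit] <- pmin(pmax(colour[k] + l + shade * dome, 0.02), 0.98)
      img[i, j, k] <- plane
    }
  }
  if (length(radii) < 12L)
    stop("dot packing failed (", length(radii),
         " dots placed); use a larger fixture size")
  img
}

#' Deterministic suite of synthetic test images
#'
#' `n` images cycling over the four fixture kinds, half with red-green and
#' half with blue-yellow confusable palettes (the axis pattern is phased
#' against the kind cycle so every kind occurs with both axes), with
#' per-image palette backgrounds and amplitudes drawn from a seeded RNG.
#' A small random tint is left on each background, so images built on one
#' confusion axis still carry a little information loss for observers of
#' the other axis, as real photographs do.  The palettes stay strictly
#' inside the gamut, so the images carry no boundary pixels before
#' daltonisation.
#'
#' @param n number of images (default 14).
#' @param seed integer master seed; the whole suite is bit-reproducible.
#' @return named list of `H x W x 3` arrays; each image carries its
#'   `"fixture_spec"` as attribute `"spec"` and its palette axis as
#'   attribute `"axis"`.
#' @param size `c(H, W)` of every image (default `c(256, 256)`).
#' @export
fixture_suite <- function(n = 14L, seed = 0L, size = c(256L, 256L)) {
  stopifnot(n >= 1)
  kinds <- c("ishihara_plate", "chroma_edge", "chroma_ramp", "texture_field")
  params <- with_seed(seed, lapply(seq_len(n), function(i) {
    list(background = stats::runif(3, 0.35, 0.65),
         tint = stats::runif(3, -0.04, 0.04),
         amplitude = sample(c(-1, 1), 1L) * stats::runif(1, 0.50, 0.62),
         seed = sample.int(.Machine$integer.max, 1L))
  }))
  out <- vector("list", n)
  names(out) <- sprintf("img%02d", seq_len(n))
  for (i in seq_len(n)) {
    # kind has period 4; phasing the axis parity by the cycle number makes
    # every kind occur with both axes (and n = 14 split 7 RG / 7 BY)
    axis <- if (((i - 1L) + (i - 1L) %/% 4L) %% 2L == 0L) "rg" else "by"
    # margin 0.005: saturated object colours graze the gamut boundary
    # (no boundary pixels before daltonisation, but no headroom either,
    # as in highly saturated photographs)
    pal <- confusable_palette(axis, background = params[[i]]$background,
                              amplitude = params[[i]]$amplitude,
                              margin = 0.005)
    pal["b", ] <- pmin(pmax(pal["b", ] + params[[i]]$tint, 0.03), 0.97)
    spec <- fixture_spec(kinds[(i - 1L) %% 4L + 1L], size = size,
                         palette = pal, seed = params[[i]]$seed)
    img <- generate_fixture(spec)
    attr(img, "spec") <- spec
    attr(img, "axis") <- axis
    out[[i]] <- img
  }
  out
}
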