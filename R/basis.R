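## Colour-direction analysis: the lost-information image, its principal
## direction, and the orthonormal (el, ed, ec) daltonisation basis.

degenerate_difference <- function(msg) {
  stop(structure(
    class = c("degenerate_difference", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# max pixel norm of d0 below which the observer is treated as colour normal
EPS_DEGENERATE <- 1e-6

#' Information lost to a CVD observer
#'
#' The lost-information image `d0 = img - simulate_cvd(img, observer)`:
#' the pixelwise colour displacement the modelled observer cannot see.
#' Zero for greyscale images and for `alpha = 0` observers.
#'
#' @inheritParams simulate_cvd
#' @return `H x W x 3` array of signed differences.
#' @export
lost_difference <- function(img, observer) {
  check_image(img)
  img - simulate_cvd(img, observer)
}

#' Principal direction of the lost difference
#'
#' First principal component of the per-pixel difference vectors, computed
#' from the uncentred 3x3 second-moment matrix `sum_p d0_p d0_p^T`: the
#' unit vector `p1` maximising `sum_p (d0_p . p1)^2`.  The moments are taken
#' about the origin rather than the mean because `d0` measures displacement
#' from the simulation surface; the axis through the origin is the
#' meaningful one, and most pixels of a typical image have `d0` near zero.
#'
#' Sign convention: the component of `p1` with the largest absolute value
#' is made positive (first such component on ties), so the direction is
#' deterministic.
#'
#' @param d0 `H x W x 3` array of lost differences (see [lost_difference()]).
#' @return unit 3-vector.
#' @section Degeneracy: if every pixel's `|d0|` is below `1e-6` the
#'   direction is undefined and a condition of class
#'   `"degenerate_difference"` is signalled; pipeline callers map this to
#'   "return the input image unchanged".
#' @export
principal_difference_direction <- function(d0) {
  check_image(d0)
  V <- matrix(d0, ncol = 3L)
  if (max(rowSums(V * V)) <= EPS_DEGENERATE^2)
    degenerate_difference("all lost-difference vectors are negligibly small")
  M2 <- crossprod(V)  # 3x3 second-moment matrix, uncentred
  p1 <- eigen(M2, symmetric = TRUE)$vectors[, 1L]
  fix_sign(p1 / sqrt(sum(p1^2)))
}

fix_sign <- function(v) {
  # first component whose magnitude is within round-off of the maximum,
  # so exact ties are broken by index rather than floating-point noise
  i <- which(abs(v) >= max(abs(v)) - 1e-9)[1L]
  if (v[i] < 0) -v else v
}

grey_axis_vector <- function(grey_axis = c("flat", "luminance")) {
  grey_axis <- match.arg(grey_axis)
  v <- if (grey_axis == "flat") c(1, 1, 1) else c(0.2126, 0.7152, 0.0722)
  v / sqrt(sum(v^2))
}

#' Orthonormal daltonisation basis
#'
#' Gram-Schmidt construction of the colour-space triplet:
#' `el` is the normalised grey axis (lightness direction), `ed` the
#' component of the principal lost-difference direction `p1` orthogonal to
#' `el` (the direction of information loss), and `ec = el x ed` the
#' remaining direction of maximally visible chroma change.  The cross
#' product fixes the handedness; either sign of `ec` yields equal-magnitude
#' visible contrast, so determinism is preferred and `flip_ec` exposes the
#' other solution.
#'
#' @param p1 unit 3-vector (see [principal_difference_direction()]).
#' @param grey_axis `"flat"` (`[1,1,1]/sqrt(3)`; default) or `"luminance"`
#'   (sRGB weights 0.2126, 0.7152, 0.0722, normalised).  With the flat
#'   axis, axis-neutral colours (red = green for a red-green observer;
#'   colours with blue equal to the red/green mean for a blue-yellow
#'   observer) project to zero on `ed` and are left untouched by the
#'   recolouring; the luminance axis leaves a large achromatic component
#'   in `ed`, so bright neutral regions are recoloured too.
#' @param flip_ec negate `ec` to recolour towards the opposite hue.
#' @return object of class `"direction_basis"`: list with unit vectors
#'   `el`, `ed`, `ec`, pairwise orthogonal to better than `1e-10`.
#' @section Degeneracy: if `p1` is parallel to the grey axis within an
#'   angular tolerance of `1e-6` rad the lost information is purely
#'   achromatic and a `"degenerate_difference"` condition is signalled.
#' @export
build_basis <- function(p1, grey_axis = c("flat", "luminance"),
                        flip_ec = FALSE) {
  el <- grey_axis_vector(grey_axis)
  p1 <- p1 / sqrt(sum(p1^2))
  r <- p1 - sum(p1 * el) * el
  nr <- sqrt(sum(r^2))  # |sin(angle between p1 and el)|
  if (nr < 1e-6)
    degenerate_difference("lost-difference direction is purely achromatic")
  ed <- r / nr
  ec <- c(el[2] * ed[3] - el[3] * ed[2],
          el[3] * ed[1] - el[1] * ed[3],
          el[1] * ed[2] - el[2] * ed[1])
  ec <- ec / sqrt(sum(ec^2))
  if (flip_ec) ec <- -ec
  structure(list(el = el, ed = ed, ec = ec), class = "direction_basis")
}

#' @export
print.direction_basis <- function(x, ...) {
  cat("<direction_basis>\n")
  for (nm in c("el", "ed", "ec"))
    cat(sprintf("  %s = [% .4f, % .4f, % .4f]\n",
                nm, x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  invisible(x)
}

observer_basis <- function(img, observer, grey_axis, flip_ec = FALSE) {
  d0 <- lost_difference(img, observer)
  p1 <- principal_difference_direction(d0)
  build_basis(p1, grey_axis, flip_ec)
}

#' Simple (closed-form) daltonisation
#'
#' Projects each pixel onto the lost-difference direction, rotates that
#' component into the maximally visible chroma direction, and clips to the
#' gamut:
#' \deqn{u_s = g\big(u_0 + (u_0 \cdot e_d)\, e_c\big).}
#' A usable daltonisation by itself (no halos, but the clipping destroys
#' detail in saturated regions) and the initial value for the diffusion
#' methods.  If the observer loses no information (greyscale input,
#' `alpha = 0`, or an achromatic loss direction) the image is returned
#' unchanged.
#'
#' @inheritParams simulate_cvd
#' @inheritParams build_basis
#' @return daltonised image in `[0, 1]`.
#' @export
simple_daltonise <- function(img, observer,
                             grey_axis = c("flat", "luminance"),
                             flip_ec = FALSE) {
  check_image(img)
  basis <- tryCatch(observer_basis(img, observer, grey_axis, flip_ec),
                    degenerate_difference = function(e) NULL)
  if (is.null(basis)) return(img)
  apply_simple_daltonise(img, basis)
}

apply_simple_daltonise <- function(img, basis) {
  proj <- img[, , 1] * basis$ed[1] + img[, , 2] * basis$ed[2] +
    img[, , 3] * basis$ed[3]
  out <- img
  for (k in 1:3) out[, , k] <- out[, , k] + proj * basis$ec[k]
  gamut_clip(out)
}

#' Spatial gradient of an image
#'
#' Forward differences `u[i+1,j] - u[i,j]` (rows, component `d1`) and
#' `u[i,j+1] - u[i,j]` (columns, component `d2`), with zeros on the last
#' row/column (Neumann boundary).  [divergence()] is the exact negative
#' adjoint of this operator, so the discrete gradient-descent energy is
#' dissipated by the diffusion iterations.
#'
#' @param img `H x W x 3` array (any values).
#' @return list of class `"gradient_field"` with arrays `d1`, `d2`
#'   (each `H x W x 3`, units: intensity per pixel).
#' @export
spatial_gradient <- function(img) {
  check_image(img)
  H <- dim(img)[1L]; W <- dim(img)[2L]
  d1 <- array(0, dim(img)); d2 <- array(0, dim(img))
  if (H > 1L)
    d1[-H, , ] <- img[-1L, , , drop = FALSE] - img[-H, , , drop = FALSE]
  if (W > 1L)
    d2[, -W, ] <- img[, -1L, , drop = FALSE] - img[, -W, , drop = FALSE]
  structure(list(d1 = d1, d2 = d2), class = "gradient_field")
}

#' Daltonised gradient tensor
#'
#' The recoloured target gradient field: for each spatial direction the
#' channel gradient's projection onto the lost direction `ed` is rotated
#' into the visible chroma direction `ec` and added back,
#' \deqn{G = \nabla u_0 + (\nabla u_0 \cdot e_d)\, e_c,}
#' where the dot product contracts the colour index.  Gradients orthogonal
#' to `ed` pass through unchanged.
#'
#' @param img `H x W x 3` array.
#' @param basis a [build_basis()] result.
#' @return `"gradient_field"` list with arrays `d1`, `d2`.
#' @export
modified_gradient <- function(img, basis) {
  g <- spatial_gradient(img)
  stopifnot(inherits(basis, "direction_basis"))
  for (comp in c("d1", "d2")) {
    gd <- g[[comp]]
    proj <- gd[, , 1] * basis$ed[1] + gd[, , 2] * basis$ed[2] +
      gd[, , 3] * basis$ed[3]
    for (k in 1:3) gd[, , k] <- gd[, , k] + proj * basis$ec[k]
    g[[comp]] <- gd
  }
  g
}

# Frobenius norm over space, channels and both gradient directions
gradient_norm <- function(g) {
  sqrt(sum(g$d1^2) + sum(g$d2^2))
}
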