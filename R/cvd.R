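#' Parametrised colour-vision-deficiency observer
#'
#' Builds an observer model for red-green ("rg") or blue-yellow ("by")
#' colour vision deficiency with severity `alpha` in `[0, 1]`:
#' `alpha = 0` is a colour-normal observer, `0 < alpha < 1` an anomalous
#' trichromat, `alpha = 1` a dichromat.  The dichromatic limits are fixed
#' row-stochastic matrices acting directly on encoded RGB,
#'
#' \deqn{M_{RG} = \begin{pmatrix} 1/2 & 1/2 & 0 \\ 1/2 & 1/2 & 0 \\
#'   0 & 0 & 1 \end{pmatrix}, \quad
#'   M_{BY} = \begin{pmatrix} 1/2 & 0 & 1/2 \\ 0 & 1/2 & 1/2 \\
#'   1/4 & 1/4 & 1/2 \end{pmatrix},}
#'
#' and the simulated colour is the blend \eqn{s(u) = \alpha M u +
#' (1-\alpha) u}.  Every row of both matrices sums to one, so the
#' achromatic axis is fixed for every observer and simulated images stay
#' inside the RGB gamut.
#'
#' The object carries a `simulate` function (image in, image out), so an
#' alternative simulation backend (e.g. an LMS-space dichromat projection)
#' can be substituted by constructing an object of class `"cvd_observer"`
#' with a different `simulate` member; every daltonisation routine only
#' calls that interface.
#'
#' @param kind `"rg"` or `"by"`.
#' @param alpha severity in `[0, 1]`.
#' @return object of class `"cvd_observer"` with members `kind`, `alpha`,
#'   `matrix` (the dichromatic 3x3 matrix) and `simulate`.
#' @examples
#' obs <- cvd_observer("rg", 1)
#' simulate_cvd(array(c(1, 0, 0), c(1, 1, 3)), obs)  # red -> mid yellow-grey
#' @export
cvd_observer <- function(kind = c("rg", "by"), alpha = 1) {
  kind <- match.arg(tolower(kind), c("rg", "by"))
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1)
    stop("alpha must be a single value in [0, 1]")
  M <- if (kind == "rg") {
    matrix(c(1 / 2, 1 / 2, 0,
             1 / 2, 1 / 2, 0,
             0,     0,     1), 3L, 3L, byrow = TRUE)
  } else {
    matrix(c(1 / 2, 0,     1 / 2,
             0,     1 / 2, 1 / 2,
             1 / 4, 1 / 4, 1 / 2), 3L, 3L, byrow = TRUE)
  }
  # effective per-pixel linear map of the blend s(u) = alpha M u + (1-alpha) u
  A <- alpha * M + (1 - alpha) * diag(3)
  obs <- list(
    kind = kind, alpha = alpha, matrix = M,
    simulate = function(img) apply_colour_matrix(img, A)
  )
  class(obs) <- "cvd_observer"
  obs
}

# right-multiply each pixel's RGB row-vector by t(A): v -> A %*% v
apply_colour_matrix <- function(img, A) {
  d <- dim(img)
  out <- matrix(img, ncol = 3L) %*% t(A)
  array(out, d)
}

#' Simulate the appearance of an image for a CVD observer
#'
#' Applies the observer's simulation transform pixelwise.  For the matrix
#' backend this is the convex blend \eqn{s(u) = \alpha M u + (1-\alpha) u},
#' which maps the gamut into itself, fixes greys exactly, and is the
#' identity at `alpha = 0`.
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @param observer a [cvd_observer()].
#' @return simulated image, same shape, values in `[0, 1]`.
#' @export
simulate_cvd <- function(img, observer) {
  check_image(img)
  stopifnot(inherits(observer, "cvd_observer"))
  observer$simulate(img)
}

#' @export
print.cvd_observer <- function(x, ...) {
  cat(sprintf("<cvd_observer> kind=%s alpha=%g\n", x$kind, x$alpha))
  invisible(x)
}
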