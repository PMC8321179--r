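## Quantitative evaluation: gamut pixel fraction, PSNR, and the paired
## nonparametric comparison used to contrast daltonisation methods.

#' Gamut pixel fraction (GPF)
#'
#' Fraction of pixels sitting on the RGB gamut boundary — a proxy for
#' clipping-induced detail loss.  A pixel counts if *any* of its three
#' channels lies within `1/510` (half an 8-bit quantum) of 0 or 1, so the
#' measure is robust to 8-bit round-trips.
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @param quantise if `TRUE`, measure on the 8-bit quantisation of the
#'   image rather than the floating-point values (default `FALSE`).
#' @return fraction in `[0, 1]`.
#' @export
gamut_pixel_fraction <- function(img, quantise = FALSE) {
  check_image(img)
  if (quantise) img <- floor(gamut_clip(img) * 255 + 0.5) / 255
  eps <- 1 / 510
  at_bound <- img <= eps | img >= 1 - eps
  on_boundary <- at_bound[, , 1] | at_bound[, , 2] | at_bound[, , 3]
  mean(on_boundary)
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = -10 log10(MSE)` in decibels, for images with peak value 1; the
#' MSE averages the squared difference over pixels and channels.  Identical
#' images give `Inf`.
#'
#' @param I,K `H x W x 3` arrays of the same shape, values in `[0, 1]`.
#' @return PSNR in dB.
#' @export
psnr <- function(I, K) {
  check_image(I); check_image(K)
  if (!identical(dim(I), dim(K))) stop("images must have the same shape")
  mse <- mean((I - K)^2)
  if (mse == 0) Inf else -10 * log10(mse)
}

#' Paired Wilcoxon signed-rank comparison
#'
#' Two-sided Wilcoxon signed-rank test on paired per-image metric values
#' (e.g. GPF of isotropic vs anisotropic daltonisation across a test set).
#' Zero differences are discarded; the test is exact when at most 25
#' non-zero untied differences remain, otherwise the normal approximation
#' (with continuity correction) is used.
#'
#' @param values_a,values_b equal-length numeric vectors (`>= 6` pairs),
#'   paired by image.
#' @return list with `p_value`, `median_a`, `median_b`, `n_pairs`,
#'   `n_nonzero`.
#' @export
paired_comparison <- function(values_a, values_b) {
  stopifnot(is.numeric(values_a), is.numeric(values_b))
  if (length(values_a) != length(values_b))
    stop("paired comparison requires equal-length vectors")
  if (length(values_a) < 6L)
    stop("paired comparison requires at least 6 pairs")
  d <- values_a - values_b
  d <- d[d != 0]
  if (length(d) == 0L)
    stop("degenerate paired comparison: all differences are zero")
  p <- if (length(d) <= 25L) {
    exact_signrank_p(d)
  } else {
    suppressWarnings(
      stats::wilcox.test(d, alternative = "two.sided", exact = FALSE,
                         correct = TRUE)$p.value)
  }
  list(p_value = unname(p),
       median_a = stats::median(values_a),
       median_b = stats::median(values_b),
       n_pairs = length(values_a),
       n_nonzero = length(d))
}

# exact two-sided signed-rank p-value, valid with tied |differences|:
# the null distribution of twice the positive-rank sum (an integer even
# with midranks) is built by direct convolution over the 2^n sign flips
exact_signrank_p <- function(d) {
  r <- rank(abs(d))
  w <- as.integer(round(2 * r))
  dist <- c(1)  # probabilities over 2*V = 0, 1, 2, ...
  for (wi in w) {
    grown <- c(dist, numeric(wi)) / 2
    grown[(wi + 1):(wi + length(dist))] <-
      grown[(wi + 1):(wi + length(dist))] + dist / 2
    dist <- grown
  }
  v2 <- as.integer(round(2 * sum(r[d > 0])))
  lower <- sum(dist[seq_len(v2 + 1L)])
  upper <- sum(dist[(v2 + 1L):length(dist)])
  min(1, 2 * min(lower, upper))
}
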