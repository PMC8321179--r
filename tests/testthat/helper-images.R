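# shared generators for random test images and fields

random_image <- function(h, w, seed = NULL, lo = 0, hi = 1) {
  if (!is.null(seed)) set.seed(seed)
  array(runif(h * w * 3, lo, hi), c(h, w, 3L))
}

grey_image <- function(h, w, value = 0.5) {
  array(value, c(h, w, 3L))
}

single_pixel <- function(rgb) {
  array(rgb, c(1L, 1L, 3L))
}

# vertical chroma edge: left half `left`, right half `right`
edge_image <- function(h, w, left, right) {
  img <- array(0, c(h, w, 3L))
  half <- ceiling(w / 2)
  for (k in 1:3) {
    img[, seq_len(half), k] <- left[k]
    img[, (half + 1):w, k] <- right[k]
  }
  img
}

frobenius <- function(g) sqrt(sum(g$d1^2) + sum(g$d2^2))
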