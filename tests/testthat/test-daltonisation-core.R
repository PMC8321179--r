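test_that("lost_difference isolates what the observer cannot see", {
  rg <- cvd_observer("rg", 1)
  expect_equal(drop(lost_difference(single_pixel(c(1, 0, 0)), rg)),
               c(0.5, -0.5, 0))
  expect_true(all(lost_difference(grey_image(5, 5, 0.7), rg) == 0))
  img <- random_image(5, 5, seed = 20)
  expect_true(all(lost_difference(img, cvd_observer("by", 0)) == 0))
})

test_that("principal difference direction matches a power-iteration oracle", {
  # rank-1 field with mixed signs recovers the generating axis
  set.seed(21)
  c_ <- matrix(rnorm(30), 6, 5)
  d0 <- array(0, c(6, 5, 3))
  d0[, , 1] <- c_; d0[, , 2] <- -c_
  expect_equal(principal_difference_direction(d0), c(1, -1, 0) / sqrt(2),
               tolerance = 1e-12)

  # dominated field: 100 pixels [1,0,0] + one tiny [0,0.01,0]
  d0 <- array(0, c(101, 1, 3))
  d0[1:100, 1, 1] <- 1
  d0[101, 1, 2] <- 0.01
  expect_equal(principal_difference_direction(d0), c(1, 0, 0),
               tolerance = 1e-3)

  # random fields against an independent dominant-eigenvector oracle
  for (s in 1:25) {
    set.seed(100 + s)
    d0 <- array(rnorm(8 * 7 * 3), c(8, 7, 3))
    M2 <- matrix(0, 3, 3)  # second moments accumulated long-hand
    for (i in 1:8) for (j in 1:7) {
      v <- d0[i, j, ]
      M2 <- M2 + v %o% v
    }
    w <- c(1, 1, 1) / sqrt(3)  # power iteration
    for (it in 1:500) {
      w <- M2 %*% w
      w <- w / sqrt(sum(w^2))
    }
    p1 <- principal_difference_direction(d0)
    expect_gt(abs(sum(p1 * w)), 1 - 1e-8)
  }
})

test_that("degenerate lost differences signal a classed condition", {
  expect_error(principal_difference_direction(array(0, c(4, 4, 3))),
               class = "degenerate_difference")
  expect_error(principal_difference_direction(array(1e-8, c(4, 4, 3))),
               class = "degenerate_difference")
})

test_that("the basis is an orthonormal right-handed triplet", {
  b <- build_basis(c(1, -1, 0) / sqrt(2), grey_axis = "flat")
  expect_equal(b$ed, c(1, -1, 0) / sqrt(2), tolerance = 1e-14)
  expect_equal(b$ec, c(1, 1, -2) / sqrt(6), tolerance = 1e-14)
  expect_equal(build_basis(c(1, -1, 0) / sqrt(2), grey_axis = "flat",
                           flip_ec = TRUE)$ec,
               -c(1, 1, -2) / sqrt(6), tolerance = 1e-14)

  set.seed(22)
  for (axis in c("flat", "luminance")) {
    for (s in 1:500) {
      p1 <- rnorm(3)
      p1 <- p1 / sqrt(sum(p1^2))
      b <- tryCatch(build_basis(p1, axis),
                    degenerate_difference = function(e) NULL)
      if (is.null(b)) next
      V <- cbind(b$el, b$ed, b$ec)
      expect_lt(max(abs(crossprod(V) - diag(3))), 1e-10)
    }
  }
  expect_error(build_basis(c(1, 1, 1) / sqrt(3), "flat"),
               class = "degenerate_difference")
})

test_that("simple daltonisation matches the closed-form hand example", {
  # [1,0,0] under an RG dichromat, flat grey axis:
  # ed = [1,-1,0]/sqrt(2), ec = [1,1,-2]/sqrt(6), projection 1/sqrt(2)
  out <- simple_daltonise(single_pixel(c(1, 0, 0)), cvd_observer("rg", 1),
                          grey_axis = "flat")
  expect_equal(drop(out), c(1, 1 / sqrt(12), 0), tolerance = 1e-12)
})

test_that("simple daltonisation is the identity without visible loss", {
  g <- grey_image(6, 6, 0.4)
  expect_identical(simple_daltonise(g, cvd_observer("rg", 1)), g)
  img <- random_image(6, 6, seed = 23)
  expect_identical(simple_daltonise(img, cvd_observer("by", 0)), img)
  # pixels orthogonal to ed are fixed points of the recolouring
  b <- build_basis(c(1, -1, 0) / sqrt(2), "flat")
  img_orth <- grey_image(4, 4, 0.3)
  img_orth[, , 3] <- 0.8  # el and [0,0,1]-[1,1,0]/2 span the ed-orthogonal
  proj <- apply(img_orth, c(1, 2), function(v) sum(v * b$ed))
  expect_lt(max(abs(proj)), 1e-12)
  expect_equal(daltonise:::apply_simple_daltonise(img_orth, b), img_orth)
})

test_that("spatial gradient uses forward differences with Neumann edges", {
  expect_true(all(spatial_gradient(grey_image(5, 7, 0.2))$d1 == 0))
  W <- 10
  ramp <- array(rep((seq_len(W) - 1) / W, each = 6), c(6, W, 3))
  g <- spatial_gradient(ramp)
  expect_equal(g$d2[, seq_len(W - 1), ], array(1 / W, c(6, W - 1, 3)),
               tolerance = 1e-14)
  expect_true(all(g$d2[, W, ] == 0))
  expect_true(all(g$d1 == 0))
})

test_that("modified gradient adds the rotated lost projection", {
  b <- build_basis(c(1, -1, 0) / sqrt(2), "flat")
  # gradients orthogonal to ed pass through
  img <- grey_image(5, 5, 0.2)
  img[, , 3] <- matrix(seq(0, 1, length.out = 25), 5, 5)
  gd <- modified_gradient(img, b)
  g0 <- spatial_gradient(img)
  expect_equal(gd$d1, g0$d1, tolerance = 1e-12)
  expect_equal(gd$d2, g0$d2, tolerance = 1e-12)

  # step edge [1,0,0] -> [0,1,0]: x-gradient [-1,1,0] gains -sqrt(2)*ec
  img <- edge_image(4, 6, c(1, 0, 0), c(0, 1, 0))
  gd <- modified_gradient(img, b)
  jump <- gd$d2[1, 3, ]
  expect_equal(jump, c(-1, 1, 0) - sqrt(2) * c(1, 1, -2) / sqrt(6),
               tolerance = 1e-12)

  # exact expansion: |G|^2 = |g|^2 + (g.ed)^2 + 2 (g.ed)(g.ec), pixelwise
  img <- random_image(7, 6, seed = 24)
  g0 <- spatial_gradient(img)
  gd <- modified_gradient(img, b)
  for (comp in c("d1", "d2")) {
    g <- g0[[comp]]
    ped <- g[, , 1] * b$ed[1] + g[, , 2] * b$ed[2] + g[, , 3] * b$ed[3]
    pec <- g[, , 1] * b$ec[1] + g[, , 2] * b$ec[2] + g[, , 3] * b$ec[3]
    lhs <- apply(gd[[comp]]^2, c(1, 2), sum)
    rhs <- apply(g^2, c(1, 2), sum) + ped^2 + 2 * ped * pec
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("recolouring raises the observer-visible edge strength", {
  img <- edge_image(16, 16, c(0.85, 0.15, 0.4), c(0.5, 0.5, 0.44))
  rg <- cvd_observer("rg", 1)
  us <- simple_daltonise(img, rg)
  before <- frobenius(spatial_gradient(simulate_cvd(img, rg)))
  after <- frobenius(spatial_gradient(simulate_cvd(us, rg)))
  expect_gt(after, before)
})
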