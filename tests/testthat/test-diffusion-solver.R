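test_that("structure tensor reproduces closed-form cases", {
  S <- structure_tensor(grey_image(6, 6, 0.3))
  expect_true(all(S$S11 == 0) && all(S$S12 == 0) && all(S$S22 == 0))

  # single-channel ramp of slope g down the rows
  g <- 0.04
  img <- array(0.2, c(8, 8, 3))
  img[, , 1] <- matrix(g * (1:8), 8, 8)
  S <- structure_tensor(img)
  expect_equal(S$S11[2:7, 2:7], matrix(g^2, 6, 6), tolerance = 1e-14)
  expect_true(all(S$S12 == 0) && all(S$S22 == 0))
})

test_that("literal double-sum variant is the channel-summed outer product", {
  img <- random_image(6, 5, seed = 30)
  g <- spatial_gradient(img)
  t1 <- apply(g$d1, c(1, 2), sum)
  t2 <- apply(g$d2, c(1, 2), sum)
  S <- structure_tensor(img, literal_double_sum = TRUE)
  expect_equal(S$S11, t1 * t1, tolerance = 1e-14)
  expect_equal(S$S12, t1 * t2, tolerance = 1e-14)
})

test_that("diffusivity follows d(lambda) = 1/(1 + kappa lambda^2)", {
  expect_identical(diffusivity(0, 1e4), 1)
  expect_equal(diffusivity(1e-2, 1e4), 0.5)   # kappa lambda^2 = 1
  lam <- seq(0, 2, by = 0.05)
  d <- diffusivity(lam, 50)
  expect_true(all(diff(d) < 0))
  expect_true(all(d > 0 & d <= 1))
  expect_error(diffusivity(-1e-6, 1e4), "negative")
})

test_that("diffusion tensor shares eigenvectors with S", {
  kappa <- 1e4
  # flat image: D is the identity
  D <- diffusion_tensor(structure_tensor(grey_image(4, 4, 0.1)), kappa)
  expect_true(all(D$D11 == 1) && all(D$D12 == 0) && all(D$D22 == 1))

  # axis-aligned rank-1 tensor
  g <- 0.1
  img <- array(0.2, c(6, 6, 3))
  img[, , 1] <- matrix(g * (1:6), 6, 6)
  D <- diffusion_tensor(structure_tensor(img), kappa)
  expect_equal(D$D11[3, 3], 1 / (1 + kappa * g^4), tolerance = 1e-12)
  expect_equal(D$D22[3, 3], 1, tolerance = 1e-12)

  # random images: per-pixel eigendecomposition oracle, commutation,
  # spectrum in (0, 1]
  img <- random_image(7, 6, seed = 31)
  S <- structure_tensor(img)
  D <- diffusion_tensor(S, kappa)
  for (i in 1:7) for (j in 1:6) {
    Sm <- matrix(c(S$S11[i, j], S$S12[i, j], S$S12[i, j], S$S22[i, j]), 2)
    Dm <- matrix(c(D$D11[i, j], D$D12[i, j], D$D12[i, j], D$D22[i, j]), 2)
    e <- eigen(Sm, symmetric = TRUE)
    Do <- e$vectors %*% diag(diffusivity(pmax(e$values, 0), kappa)) %*%
      t(e$vectors)
    expect_equal(Dm, Do, tolerance = 1e-10)
    expect_lt(max(abs(Dm %*% Sm - Sm %*% Dm)), 1e-10)
    ev <- eigen(Dm, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > 0 & ev <= 1 + 1e-12))
  }
})

test_that("divergence is the exact negative adjoint of the gradient", {
  expect_true(all(divergence(list(d1 = array(0, c(5, 4, 3)),
                                  d2 = array(0, c(5, 4, 3)))) == 0))
  set.seed(32)
  for (rep in 1:20) {
    u <- array(rnorm(8 * 6 * 3), c(8, 6, 3))
    p <- list(d1 = array(rnorm(8 * 6 * 3), c(8, 6, 3)),
              d2 = array(rnorm(8 * 6 * 3), c(8, 6, 3)))
    g <- spatial_gradient(u)
    lhs <- sum(g$d1 * p$d1) + sum(g$d2 * p$d2)
    rhs <- -sum(u * divergence(p))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
  expect_true(all(abs(divergence(spatial_gradient(grey_image(6, 6, 0.5))))
                  < 1e-15))
})

test_that("u0 is a fixed point when the target gradient is its own", {
  u0 <- random_image(10, 9, seed = 33, lo = 0.2, hi = 0.8)
  G <- spatial_gradient(u0)
  for (mode in c("isotropic", "anisotropic")) {
    res <- reintegrate(u0, G, mode = mode)
    expect_true(res$converged)
    expect_lte(res$iterations, 1L)
    expect_equal(res$image, u0, tolerance = 1e-15)
  }
})

test_that("isotropic reintegration matches a dense least-squares oracle", {
  H <- 16; W <- 16; n <- H * W
  # smooth interior-valued target so the gamut constraint stays inactive
  x <- outer(seq(0, 1, length.out = H), seq(0, 1, length.out = W),
             function(a, b) 0.5 + 0.18 * sin(2 * pi * a) * cos(2 * pi * b))
  v <- array(0, c(H, W, 3))
  v[, , 1] <- x; v[, , 2] <- 0.5 + 0.15 * (x - 0.5); v[, , 3] <- 1 - x
  G <- spatial_gradient(v)
  u0 <- grey_image(H, W, 0.5)
  res <- reintegrate(u0, G, mode = "isotropic", init = u0,
                     cfg = solver_config(dt = 0.24, tol = 1e-11,
                                         max_iter = 50000L))
  expect_true(res$converged)

  # dense forward-difference operator built long-hand
  idx <- function(i, j) (j - 1) * H + i
  A <- matrix(0, 2 * n, n)
  for (j in 1:W) for (i in 1:H) {
    if (i < H) { A[idx(i, j), idx(i + 1, j)] <- 1
                 A[idx(i, j), idx(i, j)] <- -1 }
    if (j < W) { A[n + idx(i, j), idx(i, j + 1)] <- 1
                 A[n + idx(i, j), idx(i, j)] <- -1 }
  }
  Ag <- MASS::ginv(A)
  for (k in 1:3) {
    gvec <- c(G$d1[, , k], G$d2[, , k])
    u_ls <- Ag %*% gvec
    u_ls <- u_ls + (mean(res$image[, , k]) - mean(u_ls))  # fix the constant
    expect_equal(as.numeric(res$image[, , k]), as.numeric(u_ls),
                 tolerance = 1e-6)
  }
})

test_that("residual energy decreases monotonically at dt = 0.24", {
  set.seed(34)
  u0 <- random_image(12, 12, lo = 0.35, hi = 0.65)
  v <- random_image(12, 12, lo = 0.4, hi = 0.6)
  G <- spatial_gradient(v)
  res <- reintegrate(u0, G, mode = "isotropic", init = u0,
                     cfg = solver_config(dt = 0.24, max_iter = 400L,
                                         record_energy = TRUE))
  expect_true(all(diff(res$energy) <= 1e-12))
})

test_that("the frozen-tensor update operator is linear", {
  ustar <- random_image(9, 8, seed = 35, lo = 0.4, hi = 0.6)
  G <- spatial_gradient(ustar)
  set.seed(36)
  delta <- array(rnorm(9 * 8 * 3, sd = 0.01), c(9, 8, 3))
  one_step <- function(init) {
    reintegrate(ustar, G, mode = "anisotropic", init = init,
                cfg = solver_config(tol = 1e-300, max_iter = 1L))$image
  }
  u1 <- one_step(ustar + delta)
  u2 <- one_step(ustar + 2 * delta)
  expect_equal(u2 - ustar, 2 * (u1 - ustar), tolerance = 1e-12)
})

test_that("non-finite updates raise an instability error naming dt", {
  u0 <- grey_image(6, 6, 0.5)
  G <- spatial_gradient(u0)
  G$d1[] <- Inf
  expect_error(reintegrate(u0, G, mode = "isotropic"), "dt")
})

test_that("solver configuration enforces the stability bound", {
  expect_error(solver_config(dt = 0.3), "0.25")
  expect_error(solver_config(kappa = -1))
  cfg <- solver_config()
  expect_equal(cfg$dt, 0.24)
  expect_equal(cfg$kappa, 1e4)
})

test_that("full pipeline is the identity on degenerate inputs", {
  g <- grey_image(8, 8, 0.6)
  expect_identical(daltonise(g, cvd_observer("rg", 1)), g,
                   ignore_attr = TRUE)
  img <- random_image(8, 8, seed = 37)
  expect_identical(daltonise(img, cvd_observer("by", 0)), img,
                   ignore_attr = TRUE)
})

test_that("anisotropic daltonisation recovers clipped detail on a plate", {
  pal <- confusable_palette("rg", background = c(0.5, 0.5, 0.45),
                            amplitude = 0.55)
  img <- generate_fixture(fixture_spec("ishihara_plate", size = c(128, 128),
                                       palette = pal, seed = 42))
  rg <- cvd_observer("rg", 1)
  us <- daltonise(img, rg, method = "simple")
  an <- daltonise(img, rg, method = "anisotropic")
  base <- frobenius(spatial_gradient(simulate_cvd(img, rg)))
  vis <- frobenius(spatial_gradient(simulate_cvd(an, rg)))
  expect_gt(vis, base)
  expect_lt(gamut_pixel_fraction(an), gamut_pixel_fraction(us))

  # on a pure chroma edge the visible contrast gain is large
  edge <- generate_fixture(fixture_spec("chroma_edge", size = c(64, 64),
                                        palette = pal, seed = 1))
  out <- daltonise(edge, rg, method = "anisotropic")
  r <- frobenius(spatial_gradient(simulate_cvd(out, rg))) /
    frobenius(spatial_gradient(simulate_cvd(edge, rg)))
  expect_gte(r, 1.2)
})
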