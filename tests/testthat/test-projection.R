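test_that("forward projection is linear and zero maps to zero", {
  g <- ct_geometry(24)
  z <- radon_forward(matrix(0, 32, 32), g)
  expect_true(all(z == 0))
  set.seed(21)
  x <- matrix(rnorm(32 * 32), 32); y <- matrix(rnorm(32 * 32), 32)
  a <- 0.7; b <- -1.3
  lhs <- unclass(radon_forward(a * x + b * y, g))
  rhs <- a * unclass(radon_forward(x, g)) + b * unclass(radon_forward(y, g))
  expect_lt(max(abs(lhs - rhs)), 1e-6 * max(abs(rhs)))
})

test_that("a centred disk projects identically at every angle", {
  g <- ct_geometry(36)
  sino <- unclass(radon_forward(disk_image(64), g))
  ref <- sino[, 1]
  for (j in 2:36) expect_lt(max(abs(sino[, j] - ref)), 0.02 * max(ref))
})

test_that("per-view detector sums conserve the image mass", {
  ph <- shepp_logan(64)
  sino <- radon_forward(ph, ct_geometry(60))
  mass <- sum(ph)
  expect_lt(max(abs(colSums(unclass(sino)) - mass)) / mass, 0.005)
})

test_that("backprojection is the exact adjoint of the forward projector", {
  set.seed(22)
  g <- ct_geometry(40)
  for (k in 1:20) {
    x <- matrix(rnorm(32 * 32), 32)
    s <- radon_forward(x, g)
    s2 <- ct_sinogram(matrix(rnorm(length(s)), nrow(s)), sino_geometry(s))
    lhs <- sum(unclass(s) * unclass(s2))
    rhs <- sum(x * radon_adjoint(s2, 32))
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-5)
  }
  expect_true(all(radon_adjoint(
    ct_sinogram(matrix(0, 32, 40), g), 32) == 0))
})

test_that("a single-view impulse backprojects to a stripe along the ray", {
  g <- ct_geometry(1, angles = 0)         # detector axis = x, rays along y
  s <- matrix(0, 32, 1); s[16, 1] <- 1
  img <- radon_adjoint(ct_sinogram(s, g), 32)
  # detector bin 16 (0-based 15) sits at column 16; the smear covers the
  # inscribed-circle extent of the ray, and no other column receives weight
  expect_true(all(img[, c(1:14, 18:32)] == 0))
  interior <- img[13:20, 16]
  expect_lt(diff(range(interior)), 1e-9)
  expect_gt(mean(interior), 0)
})

test_that("FBP reconstructs a dense-view phantom and is linear", {
  ph <- shepp_logan(64)
  sino <- radon_forward(ph, ct_geometry(360))
  rec <- fbp(sino)
  expect_gt(psnr(rec, ph), 25)
  # at least as good as an independently coded reference FBP, within 1 dB
  expect_gt(psnr(rec, ph), psnr(ref_fbp(sino), ph) - 1)
  expect_true(all(fbp(ct_sinogram(matrix(0, 64, 360),
                                  ct_geometry(360))) == 0))
  expect_error(fbp(sino, filter_name = "butterworth"), "unknown filter")
  for (fn in c("shepp-logan", "hann"))
    expect_gt(psnr(fbp(sino, fn), ph), 20)
})

test_that("FBP gradient equals the adjoint map (finite differences)", {
  set.seed(23)
  g <- ct_geometry(16, n_detectors = 16L)
  s0 <- matrix(rnorm(16 * 16), 16)
  R <- matrix(rnorm(256), 16)                 # random cotangent
  loss <- function(s) sum(fbp(ct_sinogram(s, g), size = 16) * R)
  grad <- fbp_adjoint(R, g)
  eps <- 1e-5
  for (idx in c(1L, 37L, 100L, 250L)) {
    sp <- s0; sp[idx] <- sp[idx] + eps
    sm <- s0; sm[idx] <- sm[idx] - eps
    num <- (loss(sp) - loss(sm)) / (2 * eps)
    expect_lt(abs(num - grad[idx]) / max(abs(num), 1e-8), 1e-3)
  }
})

test_that("uniform subsampling keeps every factor-th view", {
  sino <- ct_sinogram(matrix(rnorm(32 * 360), 32), ct_geometry(360))
  for (f in c(3L, 4L, 6L, 12L)) {
    sub <- subsample_views(sino, f)
    expect_identical(ncol(sub), 360L %/% f)
    expect_equal(unclass(sub)[, 1], unclass(sino)[, 1])
    expect_equal(sino_geometry(sub)$angles, seq(0, 359) [seq(1, 360, f)])
  }
  expect_equal(unclass(subsample_views(sino, 1)), unclass(sino))
  expect_error(subsample_views(sino, 7), "does not divide")
})

test_that("angular interpolation wraps the seam and preserves samples", {
  # two views at 0 and 180 interpolated onto four views
  g2 <- ct_geometry(2, n_detectors = 4L, angles = c(0, 180))
  g4 <- ct_geometry(4)
  sp <- ct_sinogram(cbind(c(1, 2, 3, 4), c(5, 6, 7, 8)), g2)
  out <- unclass(interpolate_views(sp, g4))
  expect_equal(out[, 1], c(1, 2, 3, 4))
  expect_equal(out[, 3], c(5, 6, 7, 8))
  expect_equal(out[, 2], (c(1, 2, 3, 4) + c(5, 6, 7, 8)) / 2)
  expect_equal(out[, 4], (c(5, 6, 7, 8) + c(1, 2, 3, 4)) / 2)
  # identity when nothing is missing
  full <- ct_sinogram(matrix(rnorm(16 * 8), 16), ct_geometry(8))
  expect_equal(unclass(interpolate_views(full, ct_geometry(8))),
               unclass(full))
  expect_error(interpolate_views(
    ct_sinogram(matrix(1, 4, 3), ct_geometry(3, angles = c(0, 10, 20))),
    ct_geometry(4)), "subset")
})

test_that("interpolation beats zero-filling by an order of magnitude", {
  g <- ct_geometry(96)
  full <- radon_forward(disk_image(64), g)
  sp <- subsample_views(full, 3)
  interp <- unclass(interpolate_views(sp, g))
  zerofill <- matrix(0, 64, 96)
  zerofill[, seq(1, 96, 3)] <- unclass(sp)
  mse_i <- mean((interp - unclass(full))^2)
  mse_z <- mean((zerofill - unclass(full))^2)
  expect_lt(mse_i * 10, mse_z)
})

test_that("FBP quality degrades monotonically with angular subsampling", {
  ph <- shepp_logan(64)
  sino <- radon_forward(ph, ct_geometry(360))
  ps <- vapply(c(1L, 3L, 4L, 6L, 12L),
               function(f) psnr(fbp(subsample_views(sino, f)), ph), 0)
  expect_true(all(diff(ps) <= 0))
  expect_gt(ps[1] - ps[5], 1)               # 360 vs 30 views
})

test_that("geometry and sinogram constructors validate their contracts", {
  expect_error(ct_geometry(0), ">= 1")
  expect_error(ct_geometry(3, angles = c(0, 0, 10)), "increasing")
  expect_error(ct_sinogram(matrix(1, 4, 5), ct_geometry(4)), "views")
  expect_error(radon_forward(matrix(1, 4, 6), ct_geometry(4)), "square")
})
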