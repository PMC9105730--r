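test_that("2x2 block transform matches the hand-derived subband values", {
  x <- matrix(c(1, 3, 2, 4), 2, 2)   # [[1,2],[3,4]] row-wise
  sb <- dwt2(x)
  expect_identical(drop(sb$CA), 10)
  expect_identical(drop(sb$CDh), 4)
  expect_identical(drop(sb$CDv), 2)
  expect_identical(drop(sb$CDd), 0)
  expect_equal(iwt2(sb), x)
})

test_that("constant images have pure approximation content", {
  sb <- dwt2(matrix(2.5, 8, 8))
  expect_true(all(sb$CA == 10))
  expect_true(all(sb$CDh == 0) && all(sb$CDv == 0) && all(sb$CDd == 0))
})

test_that("dwt2/iwt2 is a perfect-reconstruction pair on random images", {
  set.seed(11)
  for (k in 1:50) {
    d <- 2L * sample(4:32, 2)
    x <- matrix(rnorm(prod(d)), d[1], d[2])
    expect_lt(max(abs(iwt2(dwt2(x)) - x)), 1e-10)
  }
})

test_that("subband energy is four times the image energy", {
  set.seed(12)
  x <- matrix(rnorm(256), 16, 16)
  sb <- dwt2(x)
  e <- sum(sb$CA^2) + sum(sb$CDh^2) + sum(sb$CDv^2) + sum(sb$CDd^2)
  expect_equal(e, 4 * sum(x^2), tolerance = 1e-10)
})

test_that("transform agrees with an independent matrix-operator Haar", {
  set.seed(13)
  for (k in 1:50) {
    n <- 2L * sample(3:16, 1)
    x <- matrix(rnorm(n * n), n, n)
    sb <- dwt2(x)
    ref <- ref_haar2(x)
    for (nm in names(ref)) expect_equal(sb[[nm]], ref[[nm]], tolerance = 1e-12)
  }
})

test_that("transforms are linear maps", {
  set.seed(14)
  x <- matrix(rnorm(64), 8, 8); z <- matrix(rnorm(64), 8, 8)
  a <- 1.7; b <- -0.4
  sb1 <- dwt2(a * x + b * z); sb2 <- dwt2(x); sb3 <- dwt2(z)
  for (nm in c("CA", "CDh", "CDv", "CDd"))
    expect_equal(sb1[[nm]], a * sb2[[nm]] + b * sb3[[nm]], tolerance = 1e-10)
})

test_that("invalid shapes are rejected", {
  expect_error(dwt2(matrix(1, 3, 4)), "even")
  expect_error(iwt2(list(CA = matrix(1, 2, 2), CDh = matrix(1, 2, 2),
                         CDv = matrix(1, 2, 2), CDd = matrix(1, 1, 2))),
               "shape")
  expect_error(wpt_decompose(matrix(1, 12, 12), 3), "divisible")
})

test_that("wavelet packet tree has 4^L leaves and reconstructs exactly", {
  set.seed(15)
  x <- matrix(rnorm(64 * 64), 64, 64)
  tr2 <- wpt_decompose(x, 2)
  expect_length(tr2$leaves, 16L)
  expect_identical(dim(tr2$leaves[[1]]), c(16L, 16L))
  tr3 <- wpt_decompose(x, 3)
  expect_lt(max(abs(wpt_reconstruct(tr3) - x)), 1e-9)
  # one factor of 4 in energy per level
  e2 <- sum(vapply(tr2$leaves, function(l) sum(l^2), 0))
  expect_equal(e2, 16 * sum(x^2), tolerance = 1e-10)
})

test_that("channel-stacked transform inverts exactly and reduces to dwt2", {
  set.seed(16)
  f <- array(rnorm(8 * 16 * 16), c(16, 16, 8, 1))
  expect_lt(max(abs(iwt_stack(dwt_stack(f)) - f)), 1e-6)
  x <- matrix(rnorm(64), 8, 8)
  st <- dwt_stack(x)
  sb <- dwt2(x)
  expect_equal(st[, , 1, 1], sb$CA)
  expect_equal(st[, , 2, 1], sb$CDh)
  expect_equal(st[, , 3, 1], sb$CDv)
  expect_equal(st[, , 4, 1], sb$CDd)
  expect_error(dwt_stack(array(1, c(5, 6, 1, 1))), "even")
})

test_that("stacked-transform adjoints satisfy the dot-product identity", {
  set.seed(17)
  for (k in 1:10) {
    x <- array(rnorm(2 * 8 * 8), c(8, 8, 2, 1))
    y <- array(rnorm(2 * 4 * 4 * 4), c(4, 4, 8, 1))
    lhs <- sum(dwt_stack(x) * y)
    rhs <- sum(x * dualwave:::dwt_stack_adjoint(y))
    expect_equal(lhs, rhs, tolerance = 1e-10)
    lhs2 <- sum(iwt_stack(y) * x)
    rhs2 <- sum(y * dualwave:::iwt_stack_adjoint(x))
    expect_equal(lhs2, rhs2, tolerance = 1e-10)
  }
})
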