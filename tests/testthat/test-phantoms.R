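test_that("Shepp-Logan phantom honours its contracts", {
  ph <- shepp_logan(64)
  expect_identical(dim(ph), c(64L, 64L))
  expect_identical(ph[1, 1], 0)              # support is inside the ellipse
  expect_identical(ph[1, 64], 0)
  expect_true(all(ph >= 0 & ph <= 1))
  expect_gte(max(shepp_logan(128)), 0.999)   # skull rim reaches full scale
  expect_error(shepp_logan(63), "even")
  expect_error(shepp_logan(8), "even integer >= 16")
})

test_that("phantom mass matches an independent point-sampled rasterizer", {
  ph <- shepp_logan(64)
  ref <- ref_shepp_logan(64)
  expect_lt(abs(sum(ph) - sum(ref)) / sum(ref), 0.01)
})

test_that("random-ellipse phantoms are seed-deterministic", {
  sp <- phantom_spec(size = 64, n_ellipses = 5, seed = 7)
  expect_identical(random_ellipses(sp), random_ellipses(sp))
  sp8 <- phantom_spec(size = 64, n_ellipses = 5, seed = 8)
  expect_false(identical(random_ellipses(sp), random_ellipses(sp8)))
  expect_error(phantom_spec(n_ellipses = 0), ">= 1")
})

test_that("generated phantoms satisfy the image invariants across seeds", {
  for (seed in 1:100) {
    img <- random_ellipses(phantom_spec(size = 32, seed = seed))
    expect_true(all(is.finite(img)))
    expect_true(all(img >= 0 & img <= 1))
    expect_identical(dim(img), c(32L, 32L))
  }
})

test_that("phantom generation leaves the global RNG stream untouched", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(random_ellipses(phantom_spec(seed = 3)))
  expect_identical(runif(1), before)
})

test_that("paired datasets are aligned, subsampled and deterministic", {
  g <- ct_geometry(360)
  ds <- make_paired_dataset(3, phantom_spec(size = 32), g, 3, seed = 5)
  expect_length(ds, 3L)
  for (tr in ds) {
    expect_identical(ncol(tr$sparse), 120L)
    expect_identical(ncol(tr$full), 360L)
    expect_equal(unclass(tr$sparse),
                 unclass(subsample_views(tr$full, 3)))
    expect_equal(unclass(tr$full),
                 unclass(radon_forward(tr$image, g)))
  }
  ds2 <- make_paired_dataset(3, phantom_spec(size = 32), g, 3, seed = 5)
  expect_identical(lapply(ds, function(t) t$image),
                   lapply(ds2, function(t) t$image))
  expect_length(make_paired_dataset(0, phantom_spec(size = 32), g, 3), 0L)
  expect_error(make_paired_dataset(1, phantom_spec(size = 32), g, 7),
               "does not divide")
})

test_that("PNG round trip preserves images to quantization accuracy", {
  img <- random_ellipses(phantom_spec(size = 32, seed = 2))
  path <- tempfile(fileext = ".png")
  write_image_png(img, path)
  back <- read_image_png(path)
  expect_identical(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 1 / 255)
  unlink(path)
})
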