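test_that("the default architecture counts exactly 30 convolution layers", {
  expect_identical(count_conv_layers(build_mwcnn()), 30L)
  # the count is a property of the topology, not of the channel widths
  expect_identical(count_conv_layers(build_mwcnn(small_netspec())), 30L)
})

test_that("all builders accept one spec and preserve spatial shape", {
  set.seed(51)
  sp <- small_netspec()
  x <- array(rnorm(64 * 64), c(64, 64, 1, 2))
  for (m in list(build_mwcnn(sp), build_wcnn(sp),
                 build_unet(network_spec(channels = sp$channels,
                                         downsample = "pool")))) {
    out <- dualwave:::nn_forward(m, x, training = FALSE)$out
    expect_identical(dim(out), dim(x))
  }
})

test_that("WCNN is a single-resolution trunk behind one wavelet level", {
  m <- build_wcnn(small_netspec())
  types <- vapply(m$ops, function(op) op$type, "")
  expect_identical(sum(types == "dwt"), 1L)
  expect_identical(sum(types == "iwt"), 1L)
  expect_identical(which(types == "dwt"), 1L)
  expect_identical(which(types == "iwt"), length(types))
})

test_that("zero-initialized residual networks restore the identity", {
  set.seed(52)
  img <- matrix(runif(64 * 64), 64)
  for (m in list(build_mwcnn(small_netspec()),
                 build_wcnn(small_netspec()),
                 build_unet(network_spec(channels = c(4L, 6L, 8L),
                                         downsample = "pool")))) {
    expect_equal(restore(m, img), img, tolerance = 1e-12)
  }
})

test_that("restore preserves shape for divisible and padded inputs", {
  m <- build_mwcnn(small_netspec())
  for (n in c(64L, 36L, 128L)) {            # 36 exercises the reflect pad
    img <- matrix(runif(n * n), n)
    expect_identical(dim(restore(m, img)), c(n, n))
  }
})

test_that("every parameter receives gradient once the head is non-zero", {
  set.seed(53)
  for (m in list(build_mwcnn(small_netspec()),
                 build_unet(network_spec(channels = c(4L, 6L, 8L),
                                         downsample = "pool")))) {
    wn <- names(m$params)
    head_w <- wn[grepl("[.]w$", wn)]
    head_w <- head_w[length(head_w)]
    m$params[[head_w]] <- matrix(rnorm(length(m$params[[head_w]]), 0, 0.1),
                                 nrow(m$params[[head_w]]))
    x <- array(rnorm(16 * 16 * 2), c(16, 16, 1, 2))
    f <- dualwave:::nn_forward(m, x, training = TRUE)
    b <- dualwave:::nn_backward(m, f$caches,
                                array(rnorm(length(f$out)), dim(f$out)))
    expect_setequal(names(b$grads), names(m$params))
    dead <- vapply(b$grads, function(g) all(g == 0), TRUE)
    expect_false(any(dead), info = paste(names(dead)[dead], collapse = ", "))
  }
})

test_that("wavelet and pooling variants differ only in the resampling ops", {
  mw <- build_mwcnn(small_netspec())
  un <- build_unet(network_spec(channels = c(4L, 6L, 8L),
                                downsample = "pool"))
  expect_identical(count_conv_layers(mw), count_conv_layers(un))
  tw <- vapply(mw$ops, function(o) o$type, "")
  tu <- vapply(un$ops, function(o) o$type, "")
  expect_identical(sum(tw %in% c("dwt", "iwt")), 6L)
  expect_identical(sum(tu == "pool") + sum(tu == "tconv"), 6L)
})

test_that("a small residual model can be trained to strip a fixed artifact", {
  set.seed(54)
  x0 <- matrix(runif(256, 0.2, 0.8), 16)
  u <- (1:16) / 16
  t0 <- 0.3 * outer(sin(6 * u), cos(4 * u))       # artifact template
  degraded <- x0 + t0
  spec <- network_spec(levels = 1L, block_depth = 2L, channels = 32L)
  bd <- dualwave:::arch_builder(spec)
  dualwave:::push_conv(bd, 1L, 32L, bn = FALSE, relu = TRUE)
  dualwave:::push_conv(bd, 32L, 1L, bn = FALSE, relu = FALSE)
  model <- dualwave:::new_residual_model(spec, "toy", bd$ops, bd$params,
                                         bd$buffers)
  xin <- array(degraded, c(16, 16, 1, 1))
  target <- array(t0, c(16, 16, 1, 1))
  st <- dualwave:::adam_init(model$params)
  for (step in 1:500) {
    f <- dualwave:::nn_forward(model, xin, training = TRUE)
    b <- dualwave:::nn_backward(model, f$caches, f$out - target)
    a <- dualwave:::adam_step(model$params, b$grads, st, 2e-2)
    model$params <- a$params; st <- a$state
  }
  restored <- restore(model, degraded)
  expect_lt(mean((restored - x0)^2), 1e-3)
})

test_that("network specs validate their arguments", {
  expect_error(network_spec(levels = 0), ">= 1")
  expect_error(network_spec(channels = c(8, 16)), "one width per level")
  expect_error(build_mwcnn(network_spec(channels = c(4L, 6L, 8L),
                                        downsample = "pool")), "dwt")
})
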