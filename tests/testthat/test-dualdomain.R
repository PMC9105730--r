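make_tiny_ds <- function(n, seed, size = 32L, views = 48L, factor = 6L) {
  make_paired_dataset(n, phantom_spec(size = size), ct_geometry(views),
                      factor, seed = seed)
}

test_that("the residual L2 loss matches its definition", {
  a <- array(0, c(4, 4, 1, 1))
  b <- a; b[2, 3, 1, 1] <- 2                 # one pixel off by 2, N = 1
  expect_identical(l2_residual_loss(a, b), 2)
  expect_identical(l2_residual_loss(b, b), 0)
  one <- array(rnorm(32), c(4, 4, 1, 2))
  two <- array(rnorm(32), c(4, 4, 1, 2))
  doubled <- array(c(one, one), c(4, 4, 1, 4))
  target2 <- array(c(two, two), c(4, 4, 1, 4))
  expect_equal(l2_residual_loss(doubled, target2),
               l2_residual_loss(one, two), tolerance = 1e-12)
  expect_error(l2_residual_loss(one, array(0, c(4, 4, 1, 1))), "shapes")
})

test_that("joint loss is zero at the perfect-model fixed point and additive", {
  set.seed(61)
  ds <- make_tiny_ds(2, seed = 100)
  g <- attr(ds, "geometry"); g$n_detectors <- 32L
  rd <- build_mwcnn(small_netspec())         # zero residual head
  id <- build_mwcnn(small_netspec())
  y <- array(unclass(ds[[1]]$full), c(32, 48, 1, 1))
  rep0 <- joint_loss(y, y, rd, id, g, size = 32, scale = max(y))
  expect_lt(rep0$L_total, 1e-20)
  for (k in 1:10) {
    xs <- y + array(rnorm(length(y), 0, 0.1 * max(y)), dim(y))
    rep <- joint_loss(xs, y, rd, id, g, size = 32, scale = max(y))
    expect_identical(rep$L_total, rep$L_radon + rep$L_image)
    expect_gte(rep$L_radon, 0); expect_gte(rep$L_image, 0)
  }
})

test_that("image-domain loss reaches the sinogram network through the
           FBP bridge", {
  set.seed(62)
  ds <- make_tiny_ds(1, seed = 200, size = 16L, views = 16L, factor = 4L)
  g <- attr(ds, "geometry"); g$n_detectors <- 16L
  sp <- network_spec(levels = 2L, channels = c(4L, 8L))
  rd <- build_mwcnn(sp); id <- build_mwcnn(sp)
  # give both heads signal so gradients are not trivially zero
  for (nm in list(c("rd", "conv19.w"), c("id", "conv19.w"))) {
    m <- get(nm[1]); wn <- names(m$params)
    last <- wn[grepl("[.]w$", wn)]; last <- last[length(last)]
    m$params[[last]] <- matrix(rnorm(length(m$params[[last]]), 0, 0.05),
                               nrow(m$params[[last]]))
    assign(nm[1], m)
  }
  scale <- max(ds[[1]]$full)
  ctx <- dualwave:::bridge_ctx(g, 16L, scale, "ram-lak")
  xs <- array(unclass(interpolate_views(ds[[1]]$sparse, g)) / scale,
              c(16, 16, 1, 1))
  ys <- array(unclass(ds[[1]]$full) / scale, c(16, 16, 1, 1))
  ti <- array(dualwave:::bridge_fwd(ctx, ys[, , 1, 1]), c(16, 16, 1, 1))
  r <- dualwave:::dual_batch(rd, id, xs, ys, ti, ctx, training = TRUE,
                             backward = TRUE)
  # analytic gradient of L_total w.r.t. probed sinogram-network parameters
  # matches central differences (this is the end-to-end differentiability
  # of interpolation -> completion -> FBP -> restoration)
  probe <- c("conv01.w", "conv10.w")
  for (nm in probe) {
    i <- 2L; eps <- 1e-6
    f <- function(v) {
      rd2 <- rd; rd2$params[[nm]][i] <- v
      rr <- dualwave:::dual_batch(rd2, id, xs, ys, ti, ctx, training = TRUE)
      rr$L_total
    }
    num <- (f(rd$params[[nm]][i] + eps) - f(rd$params[[nm]][i] - eps)) /
      (2 * eps)
    ana <- r$grads_rd[[nm]][i]
    expect_lt(abs(num - ana) / max(abs(num), 1e-8), 1e-3)
  }
  # L_image alone moves rdnet parameters: with the radon term frozen the
  # image loss still responds to an rdnet perturbation
  g_im <- function(v) {
    rd2 <- rd; rd2$params[["conv01.w"]][2] <- v
    rr <- dualwave:::dual_batch(rd2, id, xs, ys, ti, ctx, training = TRUE)
    rr$L_image
  }
  v0 <- rd$params[["conv01.w"]][2]
  expect_gt(abs(g_im(v0 + 1e-3) - g_im(v0 - 1e-3)), 0)
})

test_that("training is seed-deterministic and reduces the joint loss", {
  ds <- make_tiny_ds(16, seed = 300)
  ts <- train_spec(epochs = 6L, seed = 9L)
  sp <- network_spec(channels = c(6L, 8L, 12L))
  m1 <- train_dual(ds, sp, sp, ts)
  m2 <- train_dual(ds, sp, sp, ts)
  expect_equal(m1$history$L_total[1], m2$history$L_total[1],
               tolerance = 1e-6)
  expect_identical(m1$history$val_psnr, m2$history$val_psnr)
  expect_lt(mean(tail(m1$history$L_total, 2)),
            mean(head(m1$history$L_total, 2)))
  expect_identical(nrow(m1$history), 6L)
  expect_error(train_dual(list()), "empty")
})

test_that("reconstruction degenerates to linear-interpolation FBP for
           untrained networks", {
  ds <- make_tiny_ds(2, seed = 400)
  model <- untrained_dual_model(ds)
  tr <- ds[[1]]
  rec <- reconstruct_dual(tr$sparse, model)
  base <- fbp(interpolate_views(tr$sparse, model$geometry), size = 32)
  expect_equal(rec, base, tolerance = 1e-10)
  expect_identical(dim(rec), dim(tr$image))
})

test_that("evaluation tables have one row per method with sane metrics", {
  ds <- make_tiny_ds(3, seed = 500)
  tab <- evaluate_methods(ds, list(gt = "gt", fbp = "fbp",
                                   linfbp = "linfbp"))
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$n, rep(3L, 3))
  gt_row <- tab[tab$method == "gt", ]
  expect_equal(gt_row$ssim_mean, 1, tolerance = 1e-12)
  expect_identical(gt_row$psnr_mean, Inf)
  expect_gt(tab$psnr_mean[tab$method == "linfbp"],
            tab$psnr_mean[tab$method == "fbp"])
})

test_that("direct FBP quality falls as the subsampling factor grows", {
  ps <- vapply(c(3L, 12L), function(f) {
    ds <- make_tiny_ds(3, seed = 600, factor = f)
    evaluate_methods(ds, list(fbp = "fbp"))$psnr_mean
  }, 0)
  expect_lt(ps[2], ps[1])
})
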