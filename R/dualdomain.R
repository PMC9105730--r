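#' Optimization hyper-parameters for joint training
#'
#' Defaults follow the standard recipe for this model family: Adam with
#' learning rate 1e-4, beta1 0.9, beta2 0.999, mini-batch 4, and a 10%
#' learning-rate decay every 20 epochs. The desk-scale default trains 20
#' epochs; 50 is the full-scale setting.
#'
#' @param lr Initial learning rate (> 0).
#' @param beta1,beta2 Adam moment decay rates.
#' @param batch_size Mini-batch size (>= 1).
#' @param lr_decay Multiplicative decay factor (default 0.9).
#' @param decay_every Epoch interval between decays (default 20).
#' @param epochs Training epochs.
#' @param seed Master seed: parameter init, shuffling, everything downstream.
#' @return An object of class `train_spec`.
#' @export
train_spec <- function(lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                       batch_size = 4L, lr_decay = 0.9, decay_every = 20L,
                       epochs = 20L, seed = 1L) {
  if (lr <= 0) stop("lr must be positive")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (epochs < 1L) stop("epochs must be >= 1")
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size), lr_decay = lr_decay,
                 decay_every = as.integer(decay_every),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_spec")
}

#' Mean residual L2 loss
#'
#' `sum((predicted - target)^2) / (2 N)` where `N` is the batch size (the
#' trailing dimension for 4D arrays, 1 for matrices): the residual-learning
#' training loss, with targets being artifact maps (degraded minus clean).
#'
#' @param predicted,target Numeric arrays of identical shape.
#' @return Non-negative scalar.
#' @export
l2_residual_loss <- function(predicted, target) {
  if (!identical(dim(predicted), dim(target)) ||
      length(predicted) != length(target))
    stop("l2_residual_loss() requires identical shapes")
  N <- if (length(dim(predicted)) == 4L) dim(predicted)[4L] else 1L
  sum((predicted - target)^2) / (2 * N)
}

# Bridge context: everything the differentiable FBP step needs.
bridge_ctx <- function(geometry, size, scale, filter_name) {
  list(geometry = geometry, size = size, scale = scale,
       filter_name = filter_name,
       angles_rad = geometry$angles * pi / 180)
}

bridge_fwd <- function(ctx, sino_norm) {
  filt <- fbp_filter_sinogram(sino_norm * ctx$scale, ctx$filter_name)
  (pi / ctx$geometry$n_views) *
    cpp_radon_adjoint(filt, ctx$angles_rad, ctx$size)
}

bridge_bwd <- function(ctx, dimg) {
  proj <- cpp_radon_forward(dimg, ctx$angles_rad, ctx$geometry$n_detectors)
  (pi / ctx$geometry$n_views) * ctx$scale *
    fbp_filter_sinogram(proj, ctx$filter_name)
}

# Forward (and optionally backward) pass of the hybrid model on one batch.
# xs, ys: (n_det, n_views, 1, N) normalized interpolated / full sinograms;
# t_imgs: (n, n, 1, N) FBP reconstructions of the full sinograms.
dual_batch <- function(rdnet, idnet, xs, ys, t_imgs, ctx, training,
                       backward = FALSE) {
  N <- dim(xs)[4L]
  if (!is.null(rdnet)) {
    fr <- nn_forward(rdnet, xs, training)
    completed <- xs - fr$out
  } else {
    fr <- NULL
    completed <- xs
  }
  L_radon <- sum((completed - ys)^2) / (2 * N)
  out <- list(L_radon = L_radon, L_image = 0, completed = completed)
  if (!is.null(idnet)) {
    imgs <- array(0, c(ctx$size, ctx$size, 1L, N))
    for (i in seq_len(N)) imgs[, , 1L, i] <- bridge_fwd(ctx, completed[, , 1L, i])
    fi <- nn_forward(idnet, imgs, training)
    restored <- imgs - fi$out
    out$L_image <- sum((restored - t_imgs)^2) / (2 * N)
    out$restored <- restored
  }
  out$L_total <- out$L_radon + out$L_image
  if (!backward) {
    if (!is.null(rdnet) && training) rdnet$buffers <- fr$buffers
    if (!is.null(idnet) && training) idnet$buffers <- fi$buffers
    out$rdnet <- rdnet; out$idnet <- idnet
    return(out)
  }
  grads_rd <- NULL; grads_id <- NULL
  dcomp <- (completed - ys) / N
  if (!is.null(idnet)) {
    dRest <- (restored - t_imgs) / N
    bi <- nn_backward(idnet, fi$caches, -dRest)
    grads_id <- bi$grads
    dimgs <- dRest + bi$dx
    if (!is.null(rdnet)) {
      for (i in seq_len(N))
        dcomp[, , 1L, i] <- dcomp[, , 1L, i] + bridge_bwd(ctx, dimgs[, , 1L, i])
    }
  }
  if (!is.null(rdnet)) {
    br <- nn_backward(rdnet, fr$caches, -dcomp)
    grads_rd <- br$grads
    rdnet$buffers <- fr$buffers
  }
  if (!is.null(idnet)) idnet$buffers <- fi$buffers
  out$grads_rd <- grads_rd; out$grads_id <- grads_id
  out$rdnet <- rdnet; out$idnet <- idnet
  out
}

#' Joint loss of the hybrid model on a batch
#'
#' Evaluates the end-to-end training objective
#' `L_total = L_radon + L_image`: the radon-domain term is the squared error
#' between the completed and true full-view sinograms (per-batch mean, factor
#' 1/2), and the image-domain term is the squared error between the restored
#' image and the FBP reconstruction of the true sinogram. The image term's
#' gradient flows through the differentiable FBP bridge into the sinogram
#' network, which is what makes the two stages trainable in the same cycle.
#'
#' @param x_sparse Interpolated sparse sinogram batch: a `ct_sinogram`, a
#'   matrix, or a 4D `(n_det, n_views, 1, N)` array, in physical units.
#' @param y_full Matching full sinogram batch.
#' @param rdnet,idnet `residual_model`s (either may be `NULL` to drop that
#'   stage).
#' @param geometry Full-view [ct_geometry()] with `n_detectors` set.
#' @param size Image side for the bridge.
#' @param scale Sinogram normalization scale (networks see values divided by
#'   this; the bridge restores physical units). Default 1.
#' @param filter_name FBP filter for the bridge.
#' @return An object of class `loss_report`: list with `L_radon`, `L_image`,
#'   `L_total` (exact sum).
#' @export
joint_loss <- function(x_sparse, y_full, rdnet, idnet, geometry, size,
                       scale = 1, filter_name = "ram-lak") {
  xs <- as_nhwc(unclass(x_sparse)) / scale
  ys <- as_nhwc(unclass(y_full)) / scale
  if (!identical(dim(xs), dim(ys))) stop("batch shapes must match")
  if (dim(xs)[2L] != geometry$n_views)
    stop("sinogram view count does not match the geometry")
  geometry$n_detectors <- dim(xs)[1L]
  ctx <- bridge_ctx(geometry, size, scale, filter_name)
  N <- dim(xs)[4L]
  t_imgs <- array(0, c(size, size, 1L, N))
  for (i in seq_len(N)) t_imgs[, , 1L, i] <- bridge_fwd(ctx, ys[, , 1L, i])
  r <- dual_batch(rdnet, idnet, xs, ys, t_imgs, ctx, training = FALSE)
  structure(list(L_radon = r$L_radon, L_image = r$L_image,
                 L_total = r$L_total), class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("<loss_report> L_radon %.6g + L_image %.6g = L_total %.6g\n",
              x$L_radon, x$L_image, x$L_total))
  invisible(x)
}

#' Train the hybrid-domain reconstruction model
#'
#' End-to-end joint optimization of the radon-domain completion network and
#' the image-domain restoration network on paired (sparse, full, reference)
#' triplets. Sparse sinograms are linearly interpolated to the full view
#' grid, min-max normalized by a single dataset-wide scale, completed by the
#' residual sinogram network, reconstructed by the differentiable FBP bridge
#' and restored by the residual image network; both networks are updated by
#' Adam on the joint loss every mini-batch. Because the final conv of each
#' network is zero-initialized, the untrained model coincides with the
#' linear-interpolation + FBP baseline and training improves from there.
#'
#' @param dataset A [make_paired_dataset()] result (or equivalent list of
#'   triplets with a `geometry` attribute).
#' @param netspec_rd,netspec_id [network_spec()]s for the two stages. The
#'   desk-scale default uses widths `c(8, 16, 32)`.
#' @param trainspec A [train_spec()].
#' @param domains `"dual"` (both stages), `"image"` (restoration network only,
#'   on FBP of the interpolated sinogram) or `"radon"` (completion network
#'   only).
#' @param filter_name FBP filter for the bridge.
#' @param valset Optional held-out triplet list for per-epoch validation
#'   PSNR; defaults to up to 4 training triplets.
#' @param verbose Print per-epoch losses.
#' @return An object of class `dualwave_model`: the two trained networks,
#'   the bridge configuration, and a per-epoch `history` data frame with
#'   columns `epoch`, `lr`, `L_radon`, `L_image`, `L_total`, `val_psnr`.
#' @export
train_dual <- function(dataset,
                       netspec_rd = network_spec(channels = c(8L, 16L, 32L)),
                       netspec_id = network_spec(channels = c(8L, 16L, 32L)),
                       trainspec = train_spec(),
                       domains = c("dual", "image", "radon"),
                       filter_name = "ram-lak", valset = NULL,
                       verbose = FALSE) {
  domains <- match.arg(domains)
  n <- length(dataset)
  if (n < 1L) stop("dataset is empty")
  geometry <- attr(dataset, "geometry")
  size <- nrow(dataset[[1L]]$image)
  geometry$n_detectors <- nrow(dataset[[1L]]$full)
  scale <- max(vapply(dataset, function(tr) max(tr$full), 0))
  if (scale <= 0) scale <- 1
  ctx <- bridge_ctx(geometry, size, scale, filter_name)

  # precompute normalized interpolated inputs, targets and FBP references
  xs_all <- array(0, c(geometry$n_detectors, geometry$n_views, 1L, n))
  ys_all <- xs_all
  t_imgs <- array(0, c(size, size, 1L, n))
  for (i in seq_len(n)) {
    tr <- dataset[[i]]
    xs_all[, , 1L, i] <- unclass(interpolate_views(tr$sparse, geometry)) / scale
    ys_all[, , 1L, i] <- unclass(tr$full) / scale
    t_imgs[, , 1L, i] <- bridge_fwd(ctx, ys_all[, , 1L, i])
  }
  if (domains == "image") {
    # the restoration network sees FBP of the interpolated sinogram directly
    in_imgs <- array(0, c(size, size, 1L, n))
    for (i in seq_len(n)) in_imgs[, , 1L, i] <- bridge_fwd(ctx, xs_all[, , 1L, i])
  }

  with_seed(trainspec$seed, {
    rdnet <- if (domains != "image") build_mwcnn_or(netspec_rd) else NULL
    idnet <- if (domains != "radon") build_mwcnn_or(netspec_id) else NULL
    st_rd <- if (!is.null(rdnet)) adam_init(rdnet$params)
    st_id <- if (!is.null(idnet)) adam_init(idnet$params)
    hist <- vector("list", trainspec$epochs)
    for (epoch in seq_len(trainspec$epochs)) {
      lr <- trainspec$lr *
        trainspec$lr_decay^((epoch - 1L) %/% trainspec$decay_every)
      ord <- sample.int(n)
      ep <- c(L_radon = 0, L_image = 0)
      nb <- 0L
      for (start in seq(1L, n, by = trainspec$batch_size)) {
        idx <- ord[start:min(start + trainspec$batch_size - 1L, n)]
        ys <- ys_all[, , , idx, drop = FALSE]
        ti <- t_imgs[, , , idx, drop = FALSE]
        if (domains == "image") {
          xi <- in_imgs[, , , idx, drop = FALSE]
          r <- image_only_batch(idnet, xi, ti, backward = TRUE)
          r$L_radon <- sum((xs_all[, , , idx, drop = FALSE] - ys)^2) /
            (2 * length(idx))
          r$L_total <- r$L_radon + r$L_image
        } else {
          xs <- xs_all[, , , idx, drop = FALSE]
          r <- dual_batch(rdnet, idnet, xs, ys, ti, ctx, training = TRUE,
                          backward = TRUE)
        }
        if (!is.null(r$rdnet)) rdnet <- r$rdnet
        if (!is.null(r$idnet)) idnet <- r$idnet
        if (!is.null(r$grads_rd)) {
          a <- adam_step(rdnet$params, r$grads_rd, st_rd, lr,
                         trainspec$beta1, trainspec$beta2)
          rdnet$params <- a$params; st_rd <- a$state
        }
        if (!is.null(r$grads_id)) {
          a <- adam_step(idnet$params, r$grads_id, st_id, lr,
                         trainspec$beta1, trainspec$beta2)
          idnet$params <- a$params; st_id <- a$state
        }
        ep <- ep + c(r$L_radon, r$L_image)
        nb <- nb + 1L
      }
      model <- new_dualwave_model(rdnet, idnet, geometry, scale, filter_name,
                                  domains, NULL, trainspec)
      vset <- if (is.null(valset)) dataset[seq_len(min(4L, n))] else valset
      vp <- mean(vapply(vset, function(tr)
        psnr(reconstruct_dual(tr$sparse, model), tr$image), 0))
      hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                  L_radon = ep[[1L]] / nb,
                                  L_image = ep[[2L]] / nb,
                                  L_total = sum(ep) / nb, val_psnr = vp)
      if (verbose)
        message(sprintf("epoch %3d  lr %.2e  L_radon %.5f  L_image %.5f  val %.2f dB",
                        epoch, lr, ep[[1L]] / nb, ep[[2L]] / nb, vp))
    }
    new_dualwave_model(rdnet, idnet, geometry, scale, filter_name, domains,
                       do.call(rbind, hist), trainspec)
  })
}

# Image-only training batch (no bridge backward needed).
image_only_batch <- function(idnet, xi, ti, backward = FALSE) {
  N <- dim(xi)[4L]
  fi <- nn_forward(idnet, xi, training = TRUE)
  restored <- xi - fi$out
  out <- list(L_image = sum((restored - ti)^2) / (2 * N), L_radon = 0)
  idnet$buffers <- fi$buffers
  if (backward) {
    dRest <- (restored - ti) / N
    bi <- nn_backward(idnet, fi$caches, -dRest)
    out$grads_id <- bi$grads
  }
  out$idnet <- idnet
  out
}

build_mwcnn_or <- function(spec) {
  arch <- if (is.null(spec$arch) || spec$arch == "auto") {
    if (spec$downsample == "pool") "unet" else "mwcnn"
  } else spec$arch
  switch(arch, mwcnn = build_mwcnn(spec), wcnn = build_wcnn(spec),
         unet = build_unet(spec))
}

new_dualwave_model <- function(rdnet, idnet, geometry, scale, filter_name,
                               domains, history, trainspec) {
  structure(list(rdnet = rdnet, idnet = idnet, geometry = geometry,
                 scale = scale, filter_name = filter_name, domains = domains,
                 history = history, trainspec = trainspec),
            class = "dualwave_model")
}

#' @export
print.dualwave_model <- function(x, ...) {
  cat("<dualwave_model> ", x$domains, " domain(s), ", x$geometry$n_views,
      " full views, sinogram scale ", signif(x$scale, 4), "\n", sep = "")
  if (!is.null(x$history))
    cat("  trained ", nrow(x$history), " epochs, final val PSNR ",
        sprintf("%.2f dB", x$history$val_psnr[nrow(x$history)]), "\n",
        sep = "")
  invisible(x)
}

#' Reconstruct an image from a sparse-view sinogram with a trained model
#'
#' Pipeline: linear view interpolation to the full geometry, residual
#' sinogram completion (if the model has a radon stage), FBP, residual image
#' restoration (if the model has an image stage). With untrained
#' (zero-residual) networks this degenerates exactly to the
#' linear-interpolation + FBP baseline.
#'
#' @param sparse A sparse-view [ct_sinogram()] whose angles are a subset of
#'   the model's full geometry.
#' @param model A `dualwave_model` from [train_dual()].
#' @return Square numeric matrix.
#' @export
reconstruct_dual <- function(sparse, model) {
  interp <- interpolate_views(sparse, model$geometry)
  completed <- unclass(interp) / model$scale
  if (!is.null(model$rdnet)) completed <- restore(model$rdnet, completed)
  ctx <- bridge_ctx(model$geometry, nrow(completed), model$scale,
                    model$filter_name)
  ctx$geometry$n_detectors <- nrow(completed)
  img <- bridge_fwd(ctx, completed)
  if (!is.null(model$idnet)) img <- restore(model$idnet, img)
  img
}

#' Evaluate reconstruction methods on a paired dataset
#'
#' Reconstructs every sparse sinogram in `dataset` with each method and
#' averages PSNR and SSIM against the reference phantom images.
#'
#' @param dataset A [make_paired_dataset()] result.
#' @param methods Named list; each element is `"gt"`, `"fbp"`, `"linfbp"`,
#'   `"sart"`, `"sarttv"`, a `dualwave_model`, or a function
#'   `(sparse_sinogram, full_geometry) -> image`. Unnamed character entries
#'   are named after themselves.
#' @param max_val Dynamic range for both metrics (default 1).
#' @param sarttv_params [sart_tv_params()] used by the `"sarttv"` shorthand.
#' @return `data.frame` with columns `method`, `factor`, `psnr_mean`,
#'   `ssim_mean`, `n`; one row per method.
#' @export
evaluate_methods <- function(dataset, methods, max_val = 1,
                             sarttv_params = sart_tv_params()) {
  if (length(dataset) < 1L) stop("dataset is empty")
  if (is.character(methods)) methods <- as.list(methods)
  nm <- names(methods)
  if (is.null(nm)) nm <- rep("", length(methods))
  for (i in seq_along(methods))
    if (nm[i] == "")
      nm[i] <- if (is.character(methods[[i]])) methods[[i]]
               else if (inherits(methods[[i]], "dualwave_model"))
                 paste0("dual_", methods[[i]]$domains)
               else paste0("method", i)
  geometry <- attr(dataset, "geometry")
  fct <- attr(dataset, "factor")
  size <- nrow(dataset[[1L]]$image)
  geometry$n_detectors <- nrow(dataset[[1L]]$full)
  rows <- vector("list", length(methods))
  for (mi in seq_along(methods)) {
    fun <- resolve_method(methods[[mi]], geometry, size, sarttv_params)
    ps <- ss <- numeric(length(dataset))
    for (i in seq_along(dataset)) {
      tr <- dataset[[i]]
      rec <- fun(tr$sparse, tr$image)
      ps[i] <- psnr(rec, tr$image, max_val)
      ss[i] <- ssim(rec, tr$image, ssim_consts(max_val))
    }
    rows[[mi]] <- data.frame(method = nm[mi], factor = fct,
                             psnr_mean = mean(ps), ssim_mean = mean(ss),
                             n = length(dataset))
  }
  do.call(rbind, rows)
}

resolve_method <- function(m, geometry, size, sarttv_params) {
  if (inherits(m, "dualwave_model"))
    return(function(sp, img) reconstruct_dual(sp, m))
  if (is.function(m))
    return(function(sp, img) m(sp, geometry))
  switch(m,
    gt = function(sp, img) img,
    fbp = function(sp, img) fbp(sp, size = size),
    linfbp = function(sp, img) fbp(interpolate_views(sp, geometry), size = size),
    sart = function(sp, img) sart(sp, size = size),
    sarttv = function(sp, img) sart_tv(sp, sarttv_params, size = size),
    stop("unknown method: ", m))
}
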