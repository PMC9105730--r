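#' Architecture specification for the restoration networks
#'
#' Shared by all three builders ([build_mwcnn()], [build_wcnn()],
#' [build_unet()]). The default instantiates the multi-level wavelet CNN:
#' three transform levels, CNN blocks of four 3x3 convolution layers between
#' transforms, element-sum encoder/decoder skips, and residual prediction
#' (the network outputs the artifact map, subtracted from its input by
#' [restore()]). With the defaults the builder realizes exactly 30
#' convolution layers: one input-lift conv, three encoder blocks of four,
#' a four-conv bottleneck, three decoder blocks of four, and one bare output
#' conv (no batch-norm, no rectifier).
#'
#' @param levels Transform/pooling depth (default 3).
#' @param block_depth Convolution layers per CNN block (default 4).
#' @param channels Feature widths per level, length `levels`
#'   (default `c(64, 128, 256)`). Training at desk scale typically uses
#'   smaller widths such as `c(8, 16, 32)`.
#' @param downsample `"dwt"` (lossless Haar stacking) or `"pool"` (2x2
#'   max-pool with transposed-conv upsampling, the U-Net ablation).
#' @param residual Predict the artifact residual (default `TRUE`).
#' @param in_channels Input channel count (default 1).
#' @param arch Which builder [train_dual()] should use for this spec:
#'   `"auto"` (multi-level wavelet net for `"dwt"`, U-Net for `"pool"`),
#'   `"mwcnn"`, `"wcnn"` or `"unet"`.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(levels = 3L, block_depth = 4L,
                         channels = c(64L, 128L, 256L),
                         downsample = c("dwt", "pool"),
                         residual = TRUE, in_channels = 1L,
                         arch = c("auto", "mwcnn", "wcnn", "unet")) {
  downsample <- match.arg(downsample)
  arch <- match.arg(arch)
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1")
  if (length(channels) != levels)
    stop("channels must have one width per level")
  if (block_depth < 2L) stop("block_depth must be >= 2")
  structure(list(levels = levels, block_depth = as.integer(block_depth),
                 kernel = 3L, channels = as.integer(channels),
                 skip = "sum", downsample = downsample,
                 residual = isTRUE(residual),
                 in_channels = as.integer(in_channels), arch = arch),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec> levels ", x$levels, ", block depth ", x$block_depth,
      ", channels [", paste(x$channels, collapse = ", "), "], ",
      x$downsample, " downsampling\n", sep = "")
  invisible(x)
}

new_residual_model <- function(spec, arch, ops, params, buffers) {
  structure(list(spec = spec, arch = arch, ops = ops, params = params,
                 buffers = buffers),
            class = "residual_model")
}

#' @export
print.residual_model <- function(x, ...) {
  cat("<residual_model> ", x$arch, ", ", count_conv_layers(x),
      " conv layers, ", format(sum(vapply(x$params, length, 0L)),
                               big.mark = ","),
      " parameters\n", sep = "")
  invisible(x)
}

# Helpers that accumulate ops + parameter initialization.
arch_builder <- function(spec) {
  env <- new.env(parent = emptyenv())
  env$ops <- list()
  env$params <- list()
  env$buffers <- list()
  env$k <- 0L
  env
}

push_conv <- function(bd, cin, cout, bn = TRUE, relu = TRUE, zero = FALSE) {
  bd$k <- bd$k + 1L
  name <- sprintf("conv%02d", bd$k)
  bd$params <- nn_init_conv(bd$params, name, cin, cout, zero = zero,
                            bias = !bn)
  if (bn) {
    r <- nn_init_bn(bd$params, bd$buffers, name, cout)
    bd$params <- r$params; bd$buffers <- r$buffers
  }
  bd$ops[[length(bd$ops) + 1L]] <-
    list(type = "conv", name = name, in_ch = cin, out_ch = cout,
         bn = bn, relu = relu)
}

push_op <- function(bd, type, tag = NULL, cin = NULL, cout = NULL) {
  op <- list(type = type)
  if (!is.null(tag)) op$tag <- tag
  if (type == "tconv") {
    bd$k <- bd$k + 1L
    op$name <- sprintf("tconv%02d", bd$k)
    op$in_ch <- cin; op$out_ch <- cout
    bd$params <- nn_init_tconv(bd$params, op$name, cin, cout)
  }
  bd$ops[[length(bd$ops) + 1L]] <- op
}

push_block <- function(bd, depth, cin, cout) {
  push_conv(bd, cin, cout)
  for (i in seq_len(depth - 1L)) push_conv(bd, cout, cout)
}

#' Build the multi-level wavelet CNN (MWCNN) residual model
#'
#' Encoder: repeated (CNN block, stacked Haar transform); four-conv
#' bottleneck; decoder: repeated (inverse transform, element-sum with the
#' matching encoder feature, CNN block); bare final conv producing the
#' single-channel artifact residual. The Haar stacking quadruples channels on
#' the way down and the inverse transform divides them on the way up, so no
#' spatial information is discarded anywhere (the ablation motivation for
#' replacing pooling). The final conv is zero-initialized, so an untrained
#' model is exactly the identity restoration.
#'
#' With the default [network_spec()] the builder asserts the documented count
#' of 30 convolution layers.
#'
#' @param spec A [network_spec()] with `downsample = "dwt"`.
#' @return A `residual_model`.
#' @export
build_mwcnn <- function(spec = network_spec()) {
  if (spec$downsample != "dwt")
    stop("build_mwcnn() requires downsample = 'dwt' (use build_unet for pooling)")
  L <- spec$levels; ch <- spec$channels; bdp <- spec$block_depth
  bd <- arch_builder(spec)
  push_conv(bd, spec$in_channels, ch[1L])                    # input lift
  # encoder
  for (l in seq_len(L)) {
    cin <- if (l == 1L) ch[1L] else 4L * ch[l - 1L]
    push_block(bd, bdp, cin, ch[l])
    push_op(bd, "save", tag = paste0("s", l))
    push_op(bd, "dwt")
  }
  # bottleneck: block at width ch[L], last conv lifts to 4*ch[L] for the IWT
  push_conv(bd, 4L * ch[L], ch[L])
  for (i in seq_len(bdp - 2L)) push_conv(bd, ch[L], ch[L])
  push_conv(bd, ch[L], 4L * ch[L])
  # decoder
  for (l in rev(seq_len(L))) {
    push_op(bd, "iwt")
    push_op(bd, "add", tag = paste0("s", l))
    cnext <- if (l > 1L) 4L * ch[l - 1L] else ch[1L]
    for (i in seq_len(bdp - 1L)) push_conv(bd, ch[l], ch[l])
    push_conv(bd, ch[l], cnext)
  }
  push_conv(bd, ch[1L], spec$in_channels, bn = FALSE, relu = FALSE,
            zero = TRUE)                                     # output conv
  model <- new_residual_model(spec, "mwcnn", bd$ops, bd$params, bd$buffers)
  if (spec$levels == 3L && spec$block_depth == 4L &&
      count_conv_layers(model) != 30L)
    stop("internal error: default MWCNN must count 30 conv layers")
  model
}

#' Build the one-level wavelet CNN (WCNN) ablation
#'
#' A single-resolution network: one stacked Haar transform at the input,
#' a convolutional trunk of `2 * levels` blocks at that one resolution, a
#' bare zero-initialized conv back to four channels, and the inverse
#' transform to full resolution. Uses `channels[1]` as trunk width.
#'
#' @param spec A [network_spec()].
#' @return A `residual_model`.
#' @export
build_wcnn <- function(spec = network_spec()) {
  ch <- spec$channels[1L]; bdp <- spec$block_depth
  bd <- arch_builder(spec)
  push_op(bd, "dwt")                                  # 1 -> 4 channels
  push_conv(bd, 4L * spec$in_channels, ch)
  for (b in seq_len(2L * spec$levels)) push_block(bd, bdp, ch, ch)
  push_conv(bd, ch, 4L * spec$in_channels, bn = FALSE, relu = FALSE,
            zero = TRUE)
  push_op(bd, "iwt")                                  # back to 1 channel
  new_residual_model(spec, "wcnn", bd$ops, bd$params, bd$buffers)
}

#' Build the pooling U-Net ablation
#'
#' Identical multi-level topology to [build_mwcnn()] but with 2x2 max-pool
#' downsampling and 2x2 stride-2 transposed-convolution upsampling in place
#' of the Haar transforms; conv-layer counts are otherwise the same, so the
#' comparison isolates the down/upsampling operators.
#'
#' @param spec A [network_spec()] (its `downsample` field is taken as
#'   `"pool"`).
#' @return A `residual_model`.
#' @export
build_unet <- function(spec = network_spec()) {
  L <- spec$levels; ch <- spec$channels; bdp <- spec$block_depth
  bd <- arch_builder(spec)
  push_conv(bd, spec$in_channels, ch[1L])
  for (l in seq_len(L)) {
    cin <- if (l == 1L) ch[1L] else ch[l - 1L]
    push_block(bd, bdp, cin, ch[l])
    push_op(bd, "save", tag = paste0("s", l))
    push_op(bd, "pool")
  }
  for (i in seq_len(bdp)) push_conv(bd, ch[L], ch[L])
  for (l in rev(seq_len(L))) {
    push_op(bd, "tconv", cin = ch[l], cout = ch[l])
    push_op(bd, "add", tag = paste0("s", l))
    cnext <- if (l > 1L) ch[l - 1L] else ch[1L]
    for (i in seq_len(bdp - 1L)) push_conv(bd, ch[l], ch[l])
    push_conv(bd, ch[l], cnext)
  }
  push_conv(bd, ch[1L], spec$in_channels, bn = FALSE, relu = FALSE,
            zero = TRUE)
  new_residual_model(spec, "unet", bd$ops, bd$params, bd$buffers)
}

#' Count convolution layers of a model
#'
#' The documented counting rule: the number of 3x3 convolution layers
#' (transposed-convolution upsamplers and parameter-free transforms are not
#' counted). The default MWCNN counts exactly 30.
#'
#' @param model A `residual_model`.
#' @return Integer layer count.
#' @export
count_conv_layers <- function(model) {
  sum(vapply(model$ops, function(op) op$type == "conv", TRUE))
}

# Reflect-pad a 4D activation on the bottom/right to multiples of 2^levels.
pad_to_multiple <- function(x, mult) {
  d <- dim(x)
  ph <- (mult - d[1L] %% mult) %% mult
  pw <- (mult - d[2L] %% mult) %% mult
  if (ph == 0L && pw == 0L) return(list(x = x, ph = 0L, pw = 0L))
  ri <- c(seq_len(d[1L]), d[1L] - seq_len(ph))
  ci <- c(seq_len(d[2L]), d[2L] - seq_len(pw))
  list(x = x[ri, ci, , , drop = FALSE], ph = ph, pw = pw)
}

#' Apply a residual model to a degraded image or sinogram
#'
#' Runs the network in evaluation mode (batch-norm uses running statistics)
#' and returns `input - predicted_residual`. Inputs whose dimensions are not
#' divisible by `2^levels` are reflect-padded on the bottom/right and the
#' output is cropped back, so any even-sized input is accepted.
#'
#' @param model A `residual_model`.
#' @param degraded Numeric matrix (image, or sinogram treated as an image).
#' @return Numeric matrix of the same dimension as `degraded`.
#' @export
restore <- function(model, degraded) {
  m <- as.matrix(degraded)
  x <- array(m, c(dim(m), 1L, 1L))
  mult <- 2L^model$spec$levels
  p <- pad_to_multiple(x, mult)
  res <- nn_forward(model, p$x, training = FALSE)$out
  res <- res[seq_len(nrow(m)), seq_len(ncol(m)), 1L, 1L]
  if (model$spec$residual) m - res else res
}
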