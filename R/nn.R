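# Minimal CNN engine used by the restoration networks: 3x3 reflect-padded
# convolution (C++ im2col + gemm), batch normalization, ReLU, 2x2 max-pool,
# 2x2 stride-2 transposed convolution, and the stacked Haar transforms from
# wavelet.R. Networks are flat op lists executed by nn_forward()/nn_backward()
# with explicit caches, so gradients are exact and checkable against finite
# differences.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# Broadcast a per-channel vector over an (H, W, C, N) array.
bc_ch <- function(v, d) array(rep(rep(v, each = d[1L] * d[2L]), d[4L]), d)

# Per-channel sum over (H, W, N).
ch_sum <- function(x) {
  d <- dim(x)
  rowSums(matrix(colSums(matrix(x, d[1L] * d[2L])), d[3L], d[4L]))
}

nn_init_conv <- function(params, name, cin, cout, zero = FALSE,
                         bias = TRUE) {
  fan_in <- 9 * cin
  w <- if (zero) matrix(0, 9 * cin, cout)
       else matrix(stats::rnorm(9 * cin * cout, 0, sqrt(2 / fan_in)),
                   9 * cin, cout)
  params[[paste0(name, ".w")]] <- w
  # a bias ahead of batch norm is cancelled by the mean subtraction, so it is
  # only allocated for bare convolutions
  if (bias) params[[paste0(name, ".b")]] <- numeric(cout)
  params
}

nn_init_bn <- function(params, buffers, name, c) {
  params[[paste0(name, ".g")]] <- rep(1, c)
  params[[paste0(name, ".be")]] <- numeric(c)
  buffers[[paste0(name, ".rm")]] <- numeric(c)
  buffers[[paste0(name, ".rv")]] <- rep(1, c)
  list(params = params, buffers = buffers)
}

# --- fused conv (+ optional BN + optional ReLU) ------------------------------

conv_layer_fwd <- function(op, params, buffers, x, training) {
  w <- params[[paste0(op$name, ".w")]]
  b <- params[[paste0(op$name, ".b")]]
  if (is.null(b)) b <- numeric(op$out_ch)
  z <- cpp_conv3_fwd(x, dim(x), w, b)
  cache <- list(x = x)
  out <- z
  if (isTRUE(op$bn)) {
    g <- params[[paste0(op$name, ".g")]]
    be <- params[[paste0(op$name, ".be")]]
    if (training) {
      st <- cpp_bn_stats(z, dim(z))
      mu <- as.numeric(st$mu); va <- as.numeric(st$var)
      buffers[[paste0(op$name, ".rm")]] <-
        BN_MOMENTUM * buffers[[paste0(op$name, ".rm")]] + (1 - BN_MOMENTUM) * mu
      buffers[[paste0(op$name, ".rv")]] <-
        BN_MOMENTUM * buffers[[paste0(op$name, ".rv")]] + (1 - BN_MOMENTUM) * va
    } else {
      mu <- buffers[[paste0(op$name, ".rm")]]
      va <- buffers[[paste0(op$name, ".rv")]]
    }
    istd <- 1 / sqrt(va + BN_EPS)
    r <- cpp_bn_fwd(z, dim(z), mu, istd, g, be, isTRUE(op$relu))
    out <- r$out
    cache$xhat <- r$xhat; cache$istd <- istd; cache$out <- out
  } else if (isTRUE(op$relu)) {
    mask <- out > 0
    out <- out * mask
    cache$mask <- mask
  }
  list(out = out, cache = cache, buffers = buffers)
}

conv_layer_bwd <- function(op, params, cache, dy) {
  grads <- list()
  if (isTRUE(op$bn)) {
    g <- params[[paste0(op$name, ".g")]]
    r <- cpp_bn_bwd(dy, dim(dy), cache$xhat, cache$out, g, cache$istd,
                    isTRUE(op$relu))
    grads[[paste0(op$name, ".g")]] <- as.numeric(r$dg)
    grads[[paste0(op$name, ".be")]] <- as.numeric(r$dbe)
    dy <- r$dz
  } else if (isTRUE(op$relu)) {
    dy <- dy * cache$mask
  }
  w <- params[[paste0(op$name, ".w")]]
  bw <- cpp_conv3_bwd(cache$x, dim(cache$x), w, dy)
  grads[[paste0(op$name, ".w")]] <- bw$dw
  if (!is.null(params[[paste0(op$name, ".b")]]))
    grads[[paste0(op$name, ".b")]] <- as.numeric(bw$db)
  list(dx = bw$dx, grads = grads)
}

# --- 2x2 max pooling ---------------------------------------------------------

pool_fwd <- function(x) {
  d <- dim(x)
  ri <- seq(1L, d[1L], by = 2L); ci <- seq(1L, d[2L], by = 2L)
  a <- x[ri, ci, , , drop = FALSE];      b <- x[ri + 1L, ci, , , drop = FALSE]
  cc <- x[ri, ci + 1L, , , drop = FALSE]; e <- x[ri + 1L, ci + 1L, , , drop = FALSE]
  out <- pmax(a, b, cc, e)
  wa <- out == a; wb <- (out == b) & !wa
  wc <- (out == cc) & !wa & !wb; we <- !(wa | wb | wc)
  list(out = out, cache = list(wa = wa, wb = wb, wc = wc, we = we, d = d))
}

pool_bwd <- function(cache, dy) {
  d <- cache$d
  dx <- array(0, d)
  ri <- seq(1L, d[1L], by = 2L); ci <- seq(1L, d[2L], by = 2L)
  dx[ri, ci, , ] <- dy * cache$wa
  dx[ri + 1L, ci, , ] <- dy * cache$wb
  dx[ri, ci + 1L, , ] <- dy * cache$wc
  dx[ri + 1L, ci + 1L, , ] <- dy * cache$we
  dx
}

# --- 2x2 stride-2 transposed convolution ------------------------------------
# Weight layout: (Cin) x (4 * Cout), column blocks ordered by the output
# position within each 2x2 cell: (r0,c0), (r1,c0), (r0,c1), (r1,c1).

nn_init_tconv <- function(params, name, cin, cout) {
  params[[paste0(name, ".w")]] <- matrix(
    stats::rnorm(cin * 4 * cout, 0, sqrt(2 / cin)), cin, 4 * cout)
  params[[paste0(name, ".b")]] <- numeric(cout)
  params
}

tconv_fwd <- function(op, params, x) {
  d <- dim(x)
  cout <- op$out_ch
  w <- params[[paste0(op$name, ".w")]]
  b <- params[[paste0(op$name, ".b")]]
  xm <- matrix(aperm(x, c(1L, 2L, 4L, 3L)), ncol = d[3L])   # (H*W*N) x Cin
  ym <- xm %*% w                                            # M x 4*Cout
  out <- array(0, c(2L * d[1L], 2L * d[2L], cout, d[4L]))
  ri <- seq(1L, 2L * d[1L], by = 2L); ci <- seq(1L, 2L * d[2L], by = 2L)
  put <- function(p) aperm(array(ym[, (p - 1L) * cout + seq_len(cout)] +
                                   rep(b, each = nrow(ym)),
                                 c(d[1L], d[2L], d[4L], cout)),
                           c(1L, 2L, 4L, 3L))
  out[ri, ci, , ]           <- put(1L)
  out[ri + 1L, ci, , ]      <- put(2L)
  out[ri, ci + 1L, , ]      <- put(3L)
  out[ri + 1L, ci + 1L, , ] <- put(4L)
  list(out = out, cache = list(xm = xm, d = d))
}

tconv_bwd <- function(op, params, cache, dy) {
  d <- cache$d
  cout <- op$out_ch
  w <- params[[paste0(op$name, ".w")]]
  ri <- seq(1L, 2L * d[1L], by = 2L); ci <- seq(1L, 2L * d[2L], by = 2L)
  grab <- function(block) matrix(aperm(block, c(1L, 2L, 4L, 3L)), ncol = cout)
  dym <- cbind(grab(dy[ri, ci, , , drop = FALSE]),
               grab(dy[ri + 1L, ci, , , drop = FALSE]),
               grab(dy[ri, ci + 1L, , , drop = FALSE]),
               grab(dy[ri + 1L, ci + 1L, , , drop = FALSE]))
  dxm <- dym %*% t(w)
  dx <- aperm(array(dxm, c(d[1L], d[2L], d[4L], d[3L])), c(1L, 2L, 4L, 3L))
  db <- rowSums(matrix(colSums(dym), cout, 4L))
  grads <- list()
  grads[[paste0(op$name, ".w")]] <- t(cache$xm) %*% dym
  grads[[paste0(op$name, ".b")]] <- as.numeric(db)
  list(dx = dx, grads = grads)
}

# --- network executor --------------------------------------------------------

nn_forward <- function(model, x, training = FALSE) {
  params <- model$params; buffers <- model$buffers
  saved <- list()
  caches <- vector("list", length(model$ops))
  for (i in seq_along(model$ops)) {
    op <- model$ops[[i]]
    caches[[i]] <- switch(op$type,
      conv = {
        r <- conv_layer_fwd(op, params, buffers, x, training)
        x <- r$out; buffers <- r$buffers; r$cache
      },
      dwt  = { x <- dwt_stack(x); NULL },
      iwt  = { x <- iwt_stack(x); NULL },
      pool = { r <- pool_fwd(x); x <- r$out; r$cache },
      tconv = { r <- tconv_fwd(op, params, x); x <- r$out; r$cache },
      save = { saved[[op$tag]] <- x; NULL },
      add  = { x <- x + saved[[op$tag]]; NULL },
      stop("unknown op type: ", op$type))
  }
  list(out = x, caches = caches, buffers = buffers)
}

nn_backward <- function(model, caches, dy) {
  params <- model$params
  grads <- list()
  slot <- list()
  for (i in rev(seq_along(model$ops))) {
    op <- model$ops[[i]]
    if (op$type == "conv") {
      r <- conv_layer_bwd(op, params, caches[[i]], dy)
      dy <- r$dx
      grads[names(r$grads)] <- r$grads
    } else if (op$type == "dwt") {
      dy <- dwt_stack_adjoint(dy)
    } else if (op$type == "iwt") {
      dy <- iwt_stack_adjoint(dy)
    } else if (op$type == "pool") {
      dy <- pool_bwd(caches[[i]], dy)
    } else if (op$type == "tconv") {
      r <- tconv_bwd(op, params, caches[[i]], dy)
      dy <- r$dx
      grads[names(r$grads)] <- r$grads
    } else if (op$type == "save") {
      if (!is.null(slot[[op$tag]])) dy <- dy + slot[[op$tag]]
    } else if (op$type == "add") {
      slot[[op$tag]] <- dy      # branch gradient joins at the matching save
    }
  }
  list(dx = dy, grads = grads)
}

# --- Adam --------------------------------------------------------------------

adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
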