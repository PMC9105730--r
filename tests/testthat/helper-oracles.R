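# Independent oracle implementations, deliberately coded along different
# routes than the package (matrix operators instead of index arithmetic,
# point sampling instead of supersampling, direct |f| ramp + pixel-driven
# backprojection instead of the package's kernel-filtered adjoint).

# One-level unnormalized Haar transform via explicit pairing matrices:
# L sums row pairs, D differences them; subbands are L x L', D x L', etc.
ref_haar2 <- function(x) {
  n <- nrow(x); m <- ncol(x)
  Lr <- matrix(0, n / 2, n); Dr <- Lr
  for (i in seq_len(n / 2)) {
    Lr[i, 2 * i - 1] <- 1; Lr[i, 2 * i] <- 1
    Dr[i, 2 * i - 1] <- -1; Dr[i, 2 * i] <- 1
  }
  Lc <- matrix(0, m / 2, m); Dc <- Lc
  for (j in seq_len(m / 2)) {
    Lc[j, 2 * j - 1] <- 1; Lc[j, 2 * j] <- 1
    Dc[j, 2 * j - 1] <- -1; Dc[j, 2 * j] <- 1
  }
  list(CA = Lr %*% x %*% t(Lc), CDh = Dr %*% x %*% t(Lc),
       CDv = Lr %*% x %*% t(Dc), CDd = Dr %*% x %*% t(Dc))
}

# Point-sampled (no anti-aliasing) rasterizer of the classical Shepp-Logan
# parameter table, written as nested loops.
ref_shepp_logan <- function(size) {
  e <- list(
    c(2.00, 0.69, 0.92, 0, 0, 0),
    c(-0.98, 0.6624, 0.8740, 0, -0.0184, 0),
    c(-0.02, 0.1100, 0.3100, 0.22, 0, -18),
    c(-0.02, 0.1600, 0.4100, -0.22, 0, 18),
    c(0.01, 0.2100, 0.2500, 0, 0.35, 0),
    c(0.01, 0.0460, 0.0460, 0, 0.1, 0),
    c(0.01, 0.0460, 0.0460, 0, -0.1, 0),
    c(0.01, 0.0460, 0.0230, -0.08, -0.605, 0),
    c(0.01, 0.0230, 0.0230, 0, -0.606, 0),
    c(0.01, 0.0230, 0.0460, 0.06, -0.605, 0))
  img <- matrix(0, size, size)
  for (r in seq_len(size)) {
    y <- 1 - (r - 0.5) / size * 2           # row 1 is the top, y near +1
    for (cc in seq_len(size)) {
      x <- (cc - 0.5) / size * 2 - 1
      v <- 0
      for (el in e) {
        phi <- el[6] * pi / 180
        xr <- (x - el[4]) * cos(phi) + (y - el[5]) * sin(phi)
        yr <- -(x - el[4]) * sin(phi) + (y - el[5]) * cos(phi)
        if ((xr / el[2])^2 + (yr / el[3])^2 <= 1) v <- v + el[1]
      }
      img[r, cc] <- v
    }
  }
  pmin(pmax(img / 2, 0), 1)
}

# Reference FBP: direct |f| frequency ramp and pixel-driven backprojection
# with linear detector interpolation.
ref_fbp <- function(sinogram) {
  g <- sino_geometry(sinogram)
  vals <- unclass(sinogram)
  nd <- nrow(vals)
  n_pad <- 2^ceiling(log2(2 * nd))
  freq <- c(seq(0, n_pad / 2), seq(n_pad / 2 - 1, 1)) / n_pad
  padded <- rbind(vals, matrix(0, n_pad - nd, ncol(vals)))
  filt <- Re(stats::mvfft(stats::mvfft(padded) * freq,
                          inverse = TRUE))[seq_len(nd), , drop = FALSE] / n_pad
  n <- nd
  cen <- (n - 1) / 2
  xs <- matrix(rep(0:(n - 1), each = n), n) - cen   # column coordinate
  ys <- matrix(rep(0:(n - 1), n), n) - cen          # row coordinate
  rec <- matrix(0, n, n)
  for (j in seq_len(g$n_views)) {
    th <- g$angles[j] * pi / 180
    t <- xs * cos(th) + ys * sin(th) + cen
    k0 <- floor(t); fr <- t - k0
    in0 <- k0 >= 0 & k0 < nd
    in1 <- k0 + 1 >= 0 & k0 + 1 < nd
    v0 <- matrix(0, n, n); v1 <- v0
    v0[in0] <- filt[k0[in0] + 1 + nd * (j - 1)]
    v1[in1] <- filt[k0[in1] + 2 + nd * (j - 1)]
    rec <- rec + (1 - fr) * v0 + fr * v1
  }
  rec * pi / g$n_views
}

# Small deterministic test phantom: centred disk with a two-pixel cosine
# edge taper (a hard pixel edge would alias and break rotational symmetry).
disk_image <- function(n, radius = 0.6, value = 1) {
  u <- (seq_len(n) - 0.5) / n * 2 - 1
  w <- 4 / n
  outer(u, u, function(a, b) {
    r <- sqrt(a^2 + b^2)
    value * pmin(pmax((radius + w / 2 - r) / w, 0), 1)
  })
}

small_netspec <- function(channels = c(4L, 6L, 8L), ...) {
  network_spec(channels = channels, ...)
}

# Untrained hybrid model wired for a dataset (zero residual networks).
untrained_dual_model <- function(dataset, netspec = small_netspec()) {
  geometry <- attr(dataset, "geometry")
  geometry$n_detectors <- nrow(dataset[[1L]]$full)
  scale <- max(vapply(dataset, function(tr) max(tr$full), 0))
  set.seed(7)
  dualwave:::new_dualwave_model(build_mwcnn(netspec), build_mwcnn(netspec),
                                geometry, scale, "ram-lak", "dual", NULL,
                                NULL)
}
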