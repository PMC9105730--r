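#' Peak signal-to-noise ratio
#'
#' `10 * log10(max_val^2 / MSE)`, in decibels. Identical images give `Inf`.
#'
#' @param x,y Numeric matrices of equal shape.
#' @param max_val Dynamic range of the reference (default 1 for \[0, 1\]
#'   images; use 255 for 8-bit scales).
#' @return PSNR in dB.
#' @export
psnr <- function(x, y, max_val = 1) {
  if (!identical(dim(as.matrix(x)), dim(as.matrix(y))))
    stop("psnr() requires equal shapes")
  if (max_val <= 0) stop("max_val must be positive")
  mse <- mean((as.numeric(x) - as.numeric(y))^2)
  if (mse == 0) return(Inf)
  10 * log10(max_val^2 / mse)
}

#' SSIM stabilizing constants
#'
#' The community-standard choices: `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`,
#' `C3 = C2 / 2` for dynamic range `L`, with an 11x11 Gaussian window of
#' sigma 1.5 (or a single global window covering the whole image).
#'
#' @param max_val Dynamic range `L` (default 1).
#' @param C1,C2,C3 Override the defaults.
#' @param window `"gaussian"` (11x11, sigma 1.5, mean-pooled) or `"global"`
#'   (whole-image moments, one window).
#' @return An object of class `ssim_consts`.
#' @export
ssim_consts <- function(max_val = 1, C1 = (0.01 * max_val)^2,
                        C2 = (0.03 * max_val)^2, C3 = C2 / 2,
                        window = c("gaussian", "global")) {
  window <- match.arg(window)
  if (any(c(C1, C2, C3) <= 0)) stop("SSIM constants must be positive")
  structure(list(max_val = max_val, C1 = C1, C2 = C2, C3 = C3,
                 window = window), class = "ssim_consts")
}

# Dense separable Gaussian blur operator with reflect padding.
gaussian_blur_op <- function(n, size = 11L, sigma = 1.5) {
  half <- (size - 1L) %/% 2L
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  g <- g / sum(g)
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- i + (-half:half)
    idx <- ifelse(idx < 1L, 2L - idx, idx)           # reflect
    idx <- ifelse(idx > n, 2L * n - idx, idx)
    for (k in seq_along(idx)) B[i, idx[k]] <- B[i, idx[k]] + g[k]
  }
  B
}

#' Structural similarity index
#'
#' The product of luminance, contrast and structure terms with unit
#' exponents:
#' \deqn{SSIM = \frac{2\mu_x\mu_y + C_1}{\mu_x^2+\mu_y^2+C_1}\cdot
#'              \frac{2\sigma_x\sigma_y + C_2}{\sigma_x^2+\sigma_y^2+C_2}\cdot
#'              \frac{\sigma_{xy} + C_3}{\sigma_x\sigma_y + C_3}.}
#' In the default `"gaussian"` mode the moments are local (11x11 Gaussian
#' window, sigma 1.5) and the map is mean-pooled; `"global"` evaluates the
#' raw formula once on whole-image moments, which is useful for checking the
#' closed form (e.g. the structure term of an image against its negation
#' tends to -1 as the constants tend to 0).
#'
#' @param x,y Numeric matrices of equal shape.
#' @param consts A [ssim_consts()] object.
#' @return SSIM value in \[-1, 1\].
#' @export
ssim <- function(x, y, consts = ssim_consts()) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!identical(dim(x), dim(y))) stop("ssim() requires equal shapes")
  C1 <- consts$C1; C2 <- consts$C2; C3 <- consts$C3
  if (consts$window == "global") {
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    cxy <- mean((x - mx) * (y - my))
    sx <- sqrt(vx); sy <- sqrt(vy)
    return(((2 * mx * my + C1) / (mx^2 + my^2 + C1)) *
           ((2 * sx * sy + C2) / (vx + vy + C2)) *
           ((cxy + C3) / (sx * sy + C3)))
  }
  Br <- gaussian_blur_op(nrow(x))
  Bc <- gaussian_blur_op(ncol(x))
  blur <- function(m) Br %*% m %*% t(Bc)
  mx <- blur(x); my <- blur(y)
  vx <- pmax(blur(x * x) - mx^2, 0)
  vy <- pmax(blur(y * y) - my^2, 0)
  cxy <- blur(x * y) - mx * my
  sx <- sqrt(vx); sy <- sqrt(vy)
  ssim_map <- ((2 * mx * my + C1) / (mx^2 + my^2 + C1)) *
              ((2 * sx * sy + C2) / (vx + vy + C2)) *
              ((cxy + C3) / (sx * sy + C3))
  mean(ssim_map)
}
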