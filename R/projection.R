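#' Parallel-beam acquisition geometry
#'
#' Describes a parallel-beam scan: `n_views` view angles uniformly spaced over
#' \[0, 360) degrees and `n_detectors` detector bins with one-image-pixel
#' spacing. The full-circle convention mirrors common CT simulation practice
#' even though parallel-beam data is 180-degree redundant.
#'
#' @param n_views Number of view angles (>= 1).
#' @param n_detectors Number of detector bins; defaults to the image side at
#'   projection time and must be at least the image side.
#' @param angles Optional explicit angle vector in degrees; defaults to the
#'   uniform grid `(0:(n_views-1)) * 360 / n_views`.
#' @return An object of class `ct_geometry`.
#' @export
ct_geometry <- function(n_views, n_detectors = NULL, angles = NULL) {
  n_views <- as.integer(n_views)
  if (n_views < 1L) stop("n_views must be >= 1")
  if (is.null(angles)) angles <- (seq_len(n_views) - 1) * 360 / n_views
  if (length(angles) != n_views) stop("length(angles) must equal n_views")
  if (n_views > 1L && any(diff(angles) <= 0))
    stop("angles must be strictly increasing")
  structure(list(n_views = n_views,
                 angles = as.numeric(angles),
                 n_detectors = if (is.null(n_detectors)) NULL
                               else as.integer(n_detectors),
                 detector_spacing = 1),
            class = "ct_geometry")
}

#' @export
print.ct_geometry <- function(x, ...) {
  cat("<ct_geometry> ", x$n_views, " views over [0,360), ",
      if (is.null(x$n_detectors)) "auto" else x$n_detectors,
      " detectors\n", sep = "")
  invisible(x)
}

#' Construct a sinogram object
#'
#' A sinogram is an `n_detectors x n_views` matrix of line integrals bound to
#' its [ct_geometry()]: rows index detector bins (rays), columns index view
#' angles.
#'
#' @param values Numeric matrix, `n_detectors x n_views`.
#' @param geometry A `ct_geometry` whose `n_views` matches `ncol(values)`.
#' @return An object of class `ct_sinogram` (a matrix with a `geometry`
#'   attribute).
#' @export
ct_sinogram <- function(values, geometry) {
  values <- as.matrix(values)
  if (!inherits(geometry, "ct_geometry")) stop("geometry must be a ct_geometry")
  if (ncol(values) != geometry$n_views)
    stop("sinogram has ", ncol(values), " columns but geometry declares ",
         geometry$n_views, " views")
  if (!all(is.finite(values))) stop("sinogram values must be finite")
  geometry$n_detectors <- nrow(values)
  structure(values, geometry = geometry, class = c("ct_sinogram", "matrix"))
}

#' @export
print.ct_sinogram <- function(x, ...) {
  g <- attr(x, "geometry")
  cat("<ct_sinogram> ", nrow(x), " detectors x ", g$n_views, " views\n",
      sep = "")
  invisible(x)
}

#' Geometry accessor
#' @param sinogram A `ct_sinogram`.
#' @return The bound `ct_geometry`.
#' @export
sino_geometry <- function(sinogram) attr(sinogram, "geometry")

check_image <- function(image) {
  image <- as.matrix(image)
  if (nrow(image) != ncol(image)) stop("image must be square")
  if (!all(is.finite(image))) stop("image must be finite")
  image
}

#' Parallel-beam forward projection (radon transform)
#'
#' Computes discrete line integrals of a square image along parallel rays at
#' every view angle of `geometry`, with unit sample spacing along each ray and
#' bilinear interpolation into the pixel grid. The operator is linear in the
#' image; its exact matrix transpose is [radon_adjoint()].
#'
#' @param image Square numeric matrix.
#' @param geometry A [ct_geometry()]. If `n_detectors` is unset it defaults to
#'   the image side.
#' @return A [ct_sinogram()] of dimension `n_detectors x n_views`.
#' @export
radon_forward <- function(image, geometry) {
  image <- check_image(image)
  n <- nrow(image)
  nd <- if (is.null(geometry$n_detectors)) n else geometry$n_detectors
  if (nd < n) stop("n_detectors must be at least the image side")
  vals <- cpp_radon_forward(image, geometry$angles * pi / 180, nd)
  geometry$n_detectors <- nd
  ct_sinogram(vals, geometry)
}

#' Unfiltered backprojection (exact adjoint of the forward projector)
#'
#' Applies the matrix transpose of [radon_forward()] as implemented: each
#' sinogram sample is smeared back along its ray with the same bilinear
#' weights used in the forward gather. Used by SART and by backpropagation
#' through the FBP bridge.
#'
#' @param sinogram A [ct_sinogram()].
#' @param size Image side; defaults to the detector count.
#' @return Square numeric matrix `size x size`.
#' @export
radon_adjoint <- function(sinogram, size = NULL) {
  g <- sino_geometry(sinogram)
  if (is.null(g)) stop("sinogram must carry a geometry")
  n <- if (is.null(size)) nrow(sinogram) else as.integer(size)
  if (nrow(sinogram) < n) stop("detector count smaller than image side")
  cpp_radon_adjoint(unclass(sinogram), g$angles * pi / 180, n)
}

# Frequency response of the ramp filter with optional apodizing window,
# following the standard band-limited spatial-domain construction
# (h[0] = 1/4, h[n] = -1/(pi n)^2 for odd n) so the DC term is handled
# correctly on a finite grid.
ramp_filter_response <- function(n_pad, filter_name) {
  h <- numeric(n_pad)
  h[1] <- 0.25
  k <- seq(1, n_pad / 2, by = 2)             # odd lags
  h[1 + k] <- -1 / (pi * k)^2
  h[n_pad + 1 - k] <- -1 / (pi * k)^2        # negative lags (circular layout)
  H <- Re(stats::fft(h))
  f <- c(seq(0, n_pad / 2), seq(n_pad / 2 - 1, 1)) / n_pad   # |freq|, cyc/sample
  w <- switch(filter_name,
    "ram-lak" = rep(1, n_pad),
    "shepp-logan" = { s <- pi * f; ifelse(f == 0, 1, sin(s) / s) },
    "hann" = 0.5 * (1 + cos(2 * pi * f)),
    stop("unknown filter name: ", filter_name,
         " (use 'ram-lak', 'shepp-logan' or 'hann')"))
  H * w
}

#' Filtered back-projection reconstruction
#'
#' Ramp-filters each view in the frequency domain (zero-padded to the next
#' power of two at least twice the detector count) and backprojects with the
#' adjoint operator, scaled by `pi / n_views` for full-circle data so a
#' dense-view reconstruction approximates the original image. Sparse-view
#' sinograms are handled by the same formula: the `pi / n_views` weight is
#' exactly the view-spacing scaling, so intensity is comparable across
#' subsampling factors. The whole map is linear in the sinogram;
#' [fbp_adjoint()] provides its transpose for backpropagation.
#'
#' @param sinogram A [ct_sinogram()].
#' @param filter_name One of `"ram-lak"` (default), `"shepp-logan"`, `"hann"`.
#' @param size Output image side; defaults to the detector count.
#' @return Square numeric matrix.
#' @export
fbp <- function(sinogram, filter_name = "ram-lak", size = NULL) {
  g <- sino_geometry(sinogram)
  if (is.null(g)) stop("sinogram must carry a geometry")
  filt <- fbp_filter_sinogram(unclass(sinogram), filter_name)
  n <- if (is.null(size)) nrow(sinogram) else as.integer(size)
  (pi / g$n_views) * cpp_radon_adjoint(filt, g$angles * pi / 180, n)
}

fbp_filter_sinogram <- function(vals, filter_name) {
  nd <- nrow(vals)
  n_pad <- 2^ceiling(log2(2 * nd))
  H <- ramp_filter_response(n_pad, filter_name)
  padded <- rbind(vals, matrix(0, n_pad - nd, ncol(vals)))
  spec <- stats::mvfft(padded) * H
  Re(stats::mvfft(spec, inverse = TRUE))[seq_len(nd), , drop = FALSE] / n_pad
}

#' Transpose of the FBP map
#'
#' Adjoint of [fbp()] with respect to the sinogram: forward-projects the
#' image-domain cotangent and applies the (symmetric) ramp filtering, scaled
#' by `pi / n_views`. This is what the training loop uses to propagate
#' image-domain loss gradients through the reconstruction bridge back into
#' the sinogram network.
#'
#' @param dimage Square numeric matrix (gradient w.r.t. the FBP output).
#' @param geometry The sinogram's [ct_geometry()] (with `n_detectors` set).
#' @param filter_name Filter used in the forward FBP.
#' @return Numeric matrix `n_detectors x n_views` (gradient w.r.t. sinogram).
#' @export
fbp_adjoint <- function(dimage, geometry, filter_name = "ram-lak") {
  proj <- cpp_radon_forward(as.matrix(dimage), geometry$angles * pi / 180,
                            geometry$n_detectors)
  (pi / geometry$n_views) * fbp_filter_sinogram(proj, filter_name)
}

#' Uniform angular subsampling of a sinogram
#'
#' Keeps every `factor`-th view column starting at the first, emulating
#' sparse-view acquisition; the bound geometry is updated accordingly.
#' A 360-view sinogram subsampled by factors 3, 4, 6 and 12 yields 120, 90,
#' 60 and 30 views.
#'
#' @param sinogram A [ct_sinogram()].
#' @param factor Positive integer dividing the view count.
#' @return A [ct_sinogram()] with `n_views / factor` columns.
#' @export
subsample_views <- function(sinogram, factor) {
  g <- sino_geometry(sinogram)
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  if (g$n_views %% factor != 0L)
    stop("factor ", factor, " does not divide n_views = ", g$n_views)
  keep <- seq(1L, g$n_views, by = factor)
  ct_sinogram(unclass(sinogram)[, keep, drop = FALSE],
              ct_geometry(length(keep), nrow(sinogram), g$angles[keep]))
}

#' Linear angular interpolation of a sparse sinogram
#'
#' Upsamples a sparse-view sinogram to a denser target geometry by linear
#' interpolation along the view-angle axis, per detector row, with circular
#' wrap across the 360/0 degree seam. Values at the sampled angles are
#' preserved exactly. This is the classical pre-completion step whose residual
#' error the radon-domain network learns to correct.
#'
#' @param sparse A [ct_sinogram()] whose angles are a subset of the target's.
#' @param target A [ct_geometry()] for the full view set.
#' @return A [ct_sinogram()] on `target`.
#' @export
interpolate_views <- function(sparse, target) {
  g <- sino_geometry(sparse)
  sa <- g$angles
  ta <- target$angles
  if (!all(sa %in% ta))
    stop("sparse angles must be a subset of the target angles")
  vals <- unclass(sparse)
  ext_a <- c(sa, sa[1L] + 360)               # circular wrap
  idx <- findInterval(ta, ext_a, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  nxt <- idx %% length(sa) + 1L              # wrap the right neighbour
  w <- (ta - ext_a[idx]) / (ext_a[idx + 1L] - ext_a[idx])
  out <- vals[, idx, drop = FALSE] * rep(1 - w, each = nrow(vals)) +
         vals[, nxt, drop = FALSE] * rep(w, each = nrow(vals))
  ct_sinogram(out, ct_geometry(target$n_views, nrow(vals), ta))
}
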