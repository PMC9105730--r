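#' Shepp-Logan head phantom
#'
#' Rasterizes the classical 10-ellipse Shepp-Logan head phantom on a square
#' grid mapped to \[-1, 1\]^2 and rescales the result to \[0, 1\] (the summed
#' ellipse intensities of the classical parameter table span \[0, 2\]).
#' Edges are anti-aliased by 4x4 area-fraction supersampling. The phantom's
#' support lies inside the inscribed circle, so no mass is clipped by the
#' projector's detector span.
#'
#' @param size Image side in pixels; even, at least 16.
#' @return `size x size` numeric matrix with values in \[0, 1\].
#' @export
shepp_logan <- function(size) {
  size <- as.integer(size)
  if (size < 16L || size %% 2L != 0L)
    stop("size must be an even integer >= 16")
  # columns: intensity, a (x half-axis), b (y half-axis), x0, y0, phi (deg)
  e <- matrix(c(
     2.00, 0.69,   0.92,   0,      0,      0,
    -0.98, 0.6624, 0.8740, 0,     -0.0184, 0,
    -0.02, 0.1100, 0.3100, 0.22,   0,     -18,
    -0.02, 0.1600, 0.4100, -0.22,  0,      18,
     0.01, 0.2100, 0.2500, 0,      0.35,   0,
     0.01, 0.0460, 0.0460, 0,      0.1,    0,
     0.01, 0.0460, 0.0460, 0,     -0.1,    0,
     0.01, 0.0460, 0.0230, -0.08, -0.605,  0,
     0.01, 0.0230, 0.0230, 0,     -0.606,  0,
     0.01, 0.0230, 0.0460, 0.06,  -0.605,  0), ncol = 6, byrow = TRUE)
  img <- rasterize_ellipses(size, e[, 1], e[, 4], e[, 5], e[, 2], e[, 3],
                            e[, 6] * pi / 180)
  img <- img / 2                     # classical intensities peak at 2
  pmin(pmax(img, 0), 1)
}

# Supersampled additive ellipse rasterizer shared by both phantom generators.
# Pixel (r, c) covers [-1,1]^2 coordinates; 4x4 subsamples per pixel give
# area-fraction anti-aliasing at the ellipse boundaries.
rasterize_ellipses <- function(size, intensity, x0, y0, a, b, phi_rad,
                               supersample = 4L) {
  ss <- supersample
  # subpixel centre coordinates in [-1, 1]
  u <- (seq_len(size * ss) - 0.5) / (size * ss) * 2 - 1
  X <- matrix(u, size * ss, size * ss, byrow = TRUE)
  Y <- matrix(rev(u), size * ss, size * ss)    # row 1 = top = y near +1
  img <- matrix(0, size * ss, size * ss)
  for (k in seq_along(intensity)) {
    ct <- cos(phi_rad[k]); st <- sin(phi_rad[k])
    xr <- (X - x0[k]) * ct + (Y - y0[k]) * st
    yr <- -(X - x0[k]) * st + (Y - y0[k]) * ct
    inside <- (xr / a[k])^2 + (yr / b[k])^2 <= 1
    img <- img + intensity[k] * inside
  }
  # box-average the supersampled grid down to size x size
  idx <- rep(seq_len(size), each = ss)
  rowsum(t(rowsum(img, idx)), idx) / (ss * ss)
}

#' Random-ellipse phantom specification
#'
#' Parameters of the synthetic phantom generator that stands in for real CT
#' slices: a handful of soft-edged ellipses with random centres, axes,
#' orientations and intensities, additively overlapped and clipped to
#' \[0, 1\] (mimicking overlapping tissue densities). All supports are kept
#' inside the inscribed circle so the projector sees the whole object.
#'
#' @param size Image side in pixels (even; divisible by `2^levels` of any
#'   network it will feed). Default 64.
#' @param n_ellipses Number of ellipses, or a length-2 range sampled per
#'   phantom. Default `c(5, 12)`.
#' @param intensity_range Ellipse intensity bounds inside \[0, 1\].
#'   Default `c(0.2, 1.0)`.
#' @param seed Integer seed; fully determines the phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 64L, n_ellipses = c(5L, 12L),
                         intensity_range = c(0.2, 1.0), seed = 1L) {
  size <- as.integer(size)
  if (size < 16L || size %% 2L != 0L) stop("size must be an even integer >= 16")
  if (any(n_ellipses < 1L)) stop("n_ellipses must be >= 1")
  if (length(n_ellipses) == 1L) n_ellipses <- rep(n_ellipses, 2L)
  if (intensity_range[1] < 0 || intensity_range[2] > 1 ||
      intensity_range[1] > intensity_range[2])
    stop("intensity_range must be an increasing range inside [0, 1]")
  structure(list(size = size, n_ellipses = as.integer(n_ellipses),
                 intensity_range = as.numeric(intensity_range),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> ", x$size, "x", x$size, ", ", x$n_ellipses[1], "-",
      x$n_ellipses[2], " ellipses, intensities [", x$intensity_range[1], ", ",
      x$intensity_range[2], "], seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Evaluate a function under a private RNG stream, restoring global state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Random-ellipse phantom
#'
#' Draws one phantom image from a [phantom_spec()]. Identical specs (including
#' the seed) produce bitwise-identical images.
#'
#' @param spec A [phantom_spec()].
#' @return `size x size` numeric matrix with values in \[0, 1\].
#' @export
random_ellipses <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  with_seed(spec$seed, {
    k <- if (spec$n_ellipses[1] == spec$n_ellipses[2]) spec$n_ellipses[1]
         else sample(spec$n_ellipses[1]:spec$n_ellipses[2], 1L)
    a <- stats::runif(k, 0.08, 0.45)
    b <- stats::runif(k, 0.08, 0.45)
    # keep |centre| + max axis inside radius 0.92 (inscribed-circle support)
    rmax <- pmax(a, b)
    rad <- stats::runif(k, 0, pmax(0, 0.92 - rmax))
    th <- stats::runif(k, 0, 2 * pi)
    x0 <- rad * cos(th); y0 <- rad * sin(th)
    phi <- stats::runif(k, 0, pi)
    inten <- stats::runif(k, spec$intensity_range[1], spec$intensity_range[2])
    img <- rasterize_ellipses(spec$size, inten, x0, y0, a, b, phi)
    pmin(pmax(img, 0), 1)
  })
}

#' Paired sparse/full sinogram training data
#'
#' Generates `n_images` random-ellipse phantoms and, for each, the full-view
#' sinogram (forward projection on `geometry`) and its `factor`-subsampled
#' sparse sinogram. The triplets are index-aligned and the whole set is a
#' deterministic function of `(spec, seed)`; per-image seeds are derived from
#' `seed` so datasets of different lengths share their leading phantoms.
#'
#' @param n_images Number of phantoms (>= 0).
#' @param spec A [phantom_spec()] (its own `seed` field is overridden by the
#'   derived per-image seeds).
#' @param geometry Full-view [ct_geometry()].
#' @param factor Subsampling factor; must divide `geometry$n_views`.
#' @param seed Master seed for the dataset.
#' @return An object of class `ct_dataset`: a list of triplet lists with
#'   elements `sparse` ([ct_sinogram()]), `full` ([ct_sinogram()]) and
#'   `image` (matrix), plus attributes `geometry` and `factor`.
#' @export
make_paired_dataset <- function(n_images, spec, geometry, factor, seed = 1L) {
  n_images <- as.integer(n_images)
  if (n_images < 0L) stop("n_images must be >= 0")
  factor <- as.integer(factor)
  if (geometry$n_views %% factor != 0L)
    stop("factor ", factor, " does not divide n_views = ", geometry$n_views)
  out <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    sp <- spec
    sp$seed <- as.integer((seed * 10007L + i) %% .Machine$integer.max)
    img <- random_ellipses(sp)
    full <- radon_forward(img, geometry)
    out[[i]] <- list(sparse = subsample_views(full, factor),
                     full = full, image = img)
  }
  structure(out, geometry = geometry, factor = factor, class = "ct_dataset")
}

#' @export
print.ct_dataset <- function(x, ...) {
  g <- attr(x, "geometry")
  cat("<ct_dataset> ", length(x), " triplets, ", g$n_views,
      " full views, subsampling factor ", attr(x, "factor"), "\n", sep = "")
  invisible(x)
}

#' Write an image as a 16-bit PNG preview
#'
#' Lossy convenience output: values are clipped to \[0, 1\] and quantized to
#' 16 bits. Use [saveRDS()]/[readRDS()] on the matrix itself (as the CLI does)
#' when exact values matter.
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(as.matrix(image), 0), 1), path)
  invisible(path)
}

#' Read a grayscale PNG as an image matrix
#' @param path PNG file path.
#' @return Numeric matrix in \[0, 1\] (first channel if multi-channel).
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}
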