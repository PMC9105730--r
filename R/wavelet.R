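#' One-level 2D Haar wavelet decomposition
#'
#' Decomposes an even-sized matrix into four subbands using the unnormalized
#' Haar filters with entries +/-1 applied to disjoint 2x2 blocks. For a block
#' \eqn{[[a, b], [c, d]]} (rows x columns) the subband coefficients are
#' \eqn{CA = a + b + c + d}, \eqn{CDh = -a - b + c + d},
#' \eqn{CDv = -a + b - c + d} and \eqn{CDd = a - b - c + d}. No normalization
#' is applied at this stage; the factor 1/4 lives entirely in [iwt2()], so the
#' pair is exactly biorthogonal (perfect reconstruction to machine precision)
#' and subband energy is four times the image energy.
#'
#' @param x Numeric matrix with both dimensions even.
#' @return An object of class `haar_subbands`: a list with matrices `CA`,
#'   `CDh`, `CDv`, `CDd`, each of dimension `dim(x) / 2`.
#' @seealso [iwt2()], [wpt_decompose()], [dwt_stack()]
#' @examples
#' sb <- dwt2(matrix(c(1, 3, 2, 4), 2, 2))
#' sb$CA   # 10
#' @export
dwt2 <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) %% 2L != 0L || ncol(x) %% 2L != 0L)
    stop("dwt2() requires even dimensions, got ", nrow(x), "x", ncol(x))
  ri <- seq(1L, nrow(x), by = 2L)
  ci <- seq(1L, ncol(x), by = 2L)
  a <- x[ri, ci, drop = FALSE]        # (2i-1, 2j-1)
  b <- x[ri, ci + 1L, drop = FALSE]   # (2i-1, 2j)
  c <- x[ri + 1L, ci, drop = FALSE]   # (2i,   2j-1)
  d <- x[ri + 1L, ci + 1L, drop = FALSE]
  structure(list(CA = a + b + c + d, CDh = -a - b + c + d,
                 CDv = -a + b - c + d, CDd = a - b - c + d),
            class = "haar_subbands")
}

#' One-level inverse Haar wavelet transform
#'
#' Exact inverse of [dwt2()]: reconstructs each 2x2 block from the four
#' subband coefficients, dividing by 4.
#'
#' @param sb A `haar_subbands` object, or a list with elements
#'   `CA`, `CDh`, `CDv`, `CDd` of identical dimension.
#' @return Numeric matrix of dimension `2 * dim(sb$CA)`.
#' @export
iwt2 <- function(sb) {
  x1 <- as.matrix(sb$CA); x2 <- as.matrix(sb$CDh)
  x3 <- as.matrix(sb$CDv); x4 <- as.matrix(sb$CDd)
  d <- dim(x1)
  if (!all(vapply(list(x2, x3, x4), function(m) identical(dim(m), d), TRUE)))
    stop("iwt2() subbands must share one shape")
  out <- matrix(0, 2L * d[1L], 2L * d[2L])
  ri <- seq(1L, nrow(out), by = 2L)
  ci <- seq(1L, ncol(out), by = 2L)
  out[ri, ci]           <- (x1 - x2 - x3 + x4) / 4
  out[ri, ci + 1L]      <- (x1 - x2 + x3 - x4) / 4
  out[ri + 1L, ci]      <- (x1 + x2 - x3 - x4) / 4
  out[ri + 1L, ci + 1L] <- (x1 + x2 + x3 + x4) / 4
  out
}

#' Multi-level wavelet-packet decomposition
#'
#' Applies [dwt2()] recursively to *all four* subbands at each level (a full
#' wavelet packet tree, not the pyramid that only splits the approximation).
#' Because the Haar pair here is exactly invertible, the decomposition is a
#' lossless change of representation: `4^levels` leaves, each
#' `dim(x) / 2^levels`, holding all of the image's information.
#'
#' @param x Numeric matrix; both dimensions divisible by `2^levels`.
#' @param levels Integer depth `L >= 1`.
#' @return An object of class `haar_wpt`: list with `levels`, `dim`, and
#'   `leaves`, a list of `4^levels` matrices ordered by filter path
#'   (at every level the four children appear in CA, CDh, CDv, CDd order).
#' @export
wpt_decompose <- function(x, levels) {
  x <- as.matrix(x)
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1")
  if (any(dim(x) %% 2L^levels != 0L))
    stop("image dimensions must be divisible by 2^levels")
  leaves <- list(x)
  for (l in seq_len(levels)) {
    nxt <- vector("list", 4L * length(leaves))
    for (i in seq_along(leaves)) {
      sb <- dwt2(leaves[[i]])
      nxt[[4L * i - 3L]] <- sb$CA
      nxt[[4L * i - 2L]] <- sb$CDh
      nxt[[4L * i - 1L]] <- sb$CDv
      nxt[[4L * i]]      <- sb$CDd
    }
    leaves <- nxt
  }
  structure(list(levels = levels, dim = dim(x), leaves = leaves),
            class = "haar_wpt")
}

#' Reconstruct an image from a wavelet-packet tree
#'
#' Exact inverse of [wpt_decompose()].
#'
#' @param tree A `haar_wpt` object.
#' @return Numeric matrix of dimension `tree$dim`.
#' @export
wpt_reconstruct <- function(tree) {
  leaves <- tree$leaves
  if (length(leaves) != 4L^tree$levels)
    stop("leaf count does not match 4^levels")
  for (l in seq_len(tree$levels)) {
    nxt <- vector("list", length(leaves) %/% 4L)
    for (i in seq_along(nxt)) {
      nxt[[i]] <- iwt2(list(CA  = leaves[[4L * i - 3L]],
                            CDh = leaves[[4L * i - 2L]],
                            CDv = leaves[[4L * i - 1L]],
                            CDd = leaves[[4L * i]]))
    }
    leaves <- nxt
  }
  leaves[[1L]]
}

#' Channel-stacked Haar transform for feature maps
#'
#' Applies [dwt2()] independently to every channel of a `H x W x C x N`
#' feature array and stacks the four subbands along the channel axis in fixed
#' block order `[CA | CDh | CDv | CDd]`, giving `H/2 x W/2 x 4C x N`. This is
#' the network's downsampling operator: invertible (nothing is discarded),
#' linear, and with a closed-form adjoint, so no learned parameters and no
#' gradient derivation for the filters are needed.
#'
#' A plain matrix or `H x W x C` array is promoted to the 4D layout.
#'
#' @param x Numeric array `H x W x C x N` (or matrix / 3D array), `H`, `W` even.
#' @return Numeric 4D array `H/2 x W/2 x 4C x N`.
#' @export
dwt_stack <- function(x) {
  x <- as_nhwc(x)
  d <- dim(x)
  if (d[1L] %% 2L != 0L || d[2L] %% 2L != 0L)
    stop("dwt_stack() requires even spatial dimensions")
  ri <- seq(1L, d[1L], by = 2L); ci <- seq(1L, d[2L], by = 2L)
  a <- x[ri, ci, , , drop = FALSE]
  b <- x[ri, ci + 1L, , , drop = FALSE]
  cc <- x[ri + 1L, ci, , , drop = FALSE]
  dd <- x[ri + 1L, ci + 1L, , , drop = FALSE]
  out <- array(0, c(d[1L] %/% 2L, d[2L] %/% 2L, 4L * d[3L], d[4L]))
  C <- d[3L]
  out[, , seq_len(C), ]            <-  a + b + cc + dd
  out[, , C + seq_len(C), ]        <- -a - b + cc + dd
  out[, , 2L * C + seq_len(C), ]   <- -a + b - cc + dd
  out[, , 3L * C + seq_len(C), ]   <-  a - b - cc + dd
  out
}

#' Inverse channel-stacked Haar transform
#'
#' Exact inverse of [dwt_stack()]: consumes a `h x w x 4C x N` array whose
#' channel blocks are `[CA | CDh | CDv | CDd]` and returns `2h x 2w x C x N`.
#'
#' @param x Numeric 4D array with channel count divisible by 4.
#' @return Numeric 4D array at doubled spatial resolution.
#' @export
iwt_stack <- function(x) {
  x <- as_nhwc(x)
  d <- dim(x)
  if (d[3L] %% 4L != 0L) stop("iwt_stack() needs a channel count divisible by 4")
  C <- d[3L] %/% 4L
  x1 <- x[, , seq_len(C), , drop = FALSE]
  x2 <- x[, , C + seq_len(C), , drop = FALSE]
  x3 <- x[, , 2L * C + seq_len(C), , drop = FALSE]
  x4 <- x[, , 3L * C + seq_len(C), , drop = FALSE]
  out <- array(0, c(2L * d[1L], 2L * d[2L], C, d[4L]))
  ri <- seq(1L, 2L * d[1L], by = 2L); ci <- seq(1L, 2L * d[2L], by = 2L)
  out[ri, ci, , ]           <- (x1 - x2 - x3 + x4) / 4
  out[ri, ci + 1L, , ]      <- (x1 - x2 + x3 - x4) / 4
  out[ri + 1L, ci, , ]      <- (x1 + x2 - x3 - x4) / 4
  out[ri + 1L, ci + 1L, , ] <- (x1 + x2 + x3 + x4) / 4
  out
}

# Adjoints of the stacked transforms (linear maps; used by backpropagation).
# The 4x4 block matrix M has orthogonal rows of squared norm 4, so
# t(M) = 4 * solve(M): the adjoint of dwt_stack is 4 * iwt_stack and the
# adjoint of iwt_stack is dwt_stack / 4.
dwt_stack_adjoint <- function(dy) 4 * iwt_stack(dy)
iwt_stack_adjoint <- function(dy) dwt_stack(dy) / 4

# Promote matrix / HxWxC array to the canonical H x W x C x N layout.
as_nhwc <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  else if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  else if (length(dim(x)) != 4L) stop("expected a 2D, 3D or 4D array")
  x
}
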