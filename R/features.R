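#' Global pooling of a feature matrix
#'
#' Collapses the spatial dimensions of an H x W x F activation volume to one
#' value per filter: the mean (average pooling) or the maximum (max pooling)
#' of each filter's H x W slice.
#'
#' @param fm H x W x F array.
#' @param mode \code{"average"} or \code{"max"}.
#' @return Numeric vector of length F.
#' @export
global_pool <- function(fm, mode = c("average", "max")) {
  mode <- match.arg(mode)
  stopifnot(length(dim(fm)) == 3)
  if (mode == "average") apply(fm, 3, mean) else apply(fm, 3, max)
}

#' Halve a feature matrix spatially by 2x2 average pooling
#'
#' Non-overlapping 2x2 windows with stride 2, averaged per filter. In the
#' intermediate pooling scheme this brings c3's feature matrix down to the
#' reference side shared with c4 (e.g. 52 -> 26 at a 416-pixel input).
#'
#' @param fm H x W x F array with even H and W.
#' @return (H/2) x (W/2) x F array.
#' @export
avg_pool2 <- function(fm) {
  d <- dim(fm)
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L) {
    stop("geometry error: spatial sides must be even, got ",
         d[1], " x ", d[2])
  }
  i1 <- seq(1L, d[1], 2L); i2 <- seq(2L, d[1], 2L)
  j1 <- seq(1L, d[2], 2L); j2 <- seq(2L, d[2], 2L)
  (fm[i1, j1, , drop = FALSE] + fm[i2, j1, , drop = FALSE] +
     fm[i1, j2, , drop = FALSE] + fm[i2, j2, , drop = FALSE]) / 4
}

#' Align a block's feature matrix to the intermediate-scheme reference side
#'
#' The intermediate pooling scheme standardises c3, c4 and c5 to a common
#' spatial side before padding and N x N pooling: the reference is c4's
#' post-pool side (S/16; 26 for a 416-pixel input). c3 (at twice the side) is
#' reduced by 2x2 average pooling with stride 2; c4 and c5-tapped-pre-pool
#' already have the reference side and pass through unchanged.
#'
#' @param fm Feature matrix from [extract_features()] (c3 post_pool, c4
#'   post_pool, or c5 pre_pool).
#' @param reference_side Target spatial side (default: the side of c4 for the
#'   input size implied by \code{fm}'s own geometry).
#' @return Feature matrix with spatial side \code{reference_side}.
#' @export
align_to_reference <- function(fm, reference_side = NULL) {
  d <- dim(fm)
  side <- d[1]
  if (is.null(reference_side)) {
    blk <- attr(fm, "block") %||% ""
    reference_side <- if (identical(blk, "c3")) side %/% 2L else side
  }
  if (side == reference_side) return(fm)
  if (side == 2L * reference_side) {
    out <- avg_pool2(fm)
    return(feature_matrix(out, attr(fm, "block") %||% NA_character_,
                          attr(fm, "tap_point") %||% NA_character_))
  }
  stop("geometry error: cannot align side ", side, " to reference side ",
       reference_side)
}

#' Zero-pad a feature matrix by a one-pixel border
#'
#' Adds a zero border on each spatial side (26 -> 28 at the 416-pixel
#' geometry), making the side divisible by the intermediate pooling levels
#' 2, 4, 7 and 14. Padding exists purely to make the window arithmetic exact;
#' it is never included in the N = 1 (global) average.
#'
#' @param fm H x W x F array.
#' @return (H+2) x (W+2) x F array whose interior equals \code{fm}.
#' @export
pad_border <- function(fm) {
  d <- dim(fm)
  stopifnot(length(d) == 3)
  out <- array(0, c(d[1] + 2L, d[2] + 2L, d[3]))
  out[1L + seq_len(d[1]), 1L + seq_len(d[2]), ] <- fm
  feature_matrix(out, attr(fm, "block") %||% NA_character_,
                 attr(fm, "tap_point") %||% NA_character_)
}

#' N x N spatial pooling of a padded feature matrix
#'
#' Pools non-overlapping (side/N) x (side/N) windows, per filter, down to an
#' N x N grid. At the 416-pixel geometry the padded side is 28, so the
#' admissible levels are N in {2, 4, 7, 14} (plus N = 28, no reduction, and
#' N = 1, plain global pooling of the unpadded matrix — both handled by the
#' feature-vector builder rather than here).
#'
#' @param fm side x side x F array with side divisible by \code{n}.
#' @param n Pooling level.
#' @param mode \code{"average"} or \code{"max"}.
#' @return n x n x F array.
#' @export
spatial_pool <- function(fm, n, mode = c("average", "max")) {
  mode <- match.arg(mode)
  d <- dim(fm)
  stopifnot(length(d) == 3, d[1] == d[2])
  if (n < 1L || d[1] %% n != 0L) {
    stop("config error: pooling level ", n, " does not divide side ", d[1])
  }
  win <- d[1] %/% n
  out <- array(0, c(n, n, d[3]))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      w <- fm[(i - 1L) * win + seq_len(win), (j - 1L) * win + seq_len(win), ,
              drop = FALSE]
      out[i, j, ] <- if (mode == "average") {
        colMeans(matrix(w, win * win, d[3]))
      } else {
        apply(w, 3, max)
      }
    }
  }
  out
}

#' Flatten a feature matrix to a one-dimensional feature vector
#'
#' Traversal order is fixed and documented: spatial positions in row-major
#' order (left-to-right, then top-to-bottom), with the filter index varying
#' fastest within each position. Any consistent order is equivalent for a
#' linear classifier, but caches, models and fused vectors must agree on one.
#'
#' @param fm N x N x F array.
#' @return Numeric vector of length N^2 * F.
#' @export
flatten_features <- function(fm) {
  d <- dim(fm)
  stopifnot(length(d) == 3)
  # aperm to (filter, col, row) then flatten column-major = filter fastest,
  # then column, then row: spatial row-major with depth innermost.
  as.vector(aperm(fm, c(3, 2, 1)))
}

#' Restore a flattened feature vector to its N x N x F matrix
#'
#' Inverse of [flatten_features()] given the original dimensions.
#'
#' @param v Numeric vector of length prod(dims).
#' @param dims Integer vector (N, N, F).
#' @return Array of dimension \code{dims}.
#' @export
unflatten_features <- function(v, dims) {
  stopifnot(length(v) == prod(dims))
  aperm(array(v, dims[c(3, 2, 1)]), c(3, 2, 1))
}

#' Fuse feature vectors by concatenation
#'
#' Concatenates per-block feature vectors from the same image, in the given
#' (ascending block) order. The fused length is the sum of the part lengths.
#'
#' @param vectors List of numeric vectors, ascending block order.
#' @return Single numeric vector.
#' @export
fuse_features <- function(vectors) {
  stopifnot(is.list(vectors), length(vectors) >= 1)
  unlist(vectors, use.names = FALSE)
}

#' Signed square root normalisation
#'
#' Elementwise sign(x) * sqrt(|x|). Compresses the dynamic range of feature
#' values, reducing the influence of rare large activations on the margin —
#' the single normalisation step applied before classification by default.
#'
#' @param v Numeric vector.
#' @return Numeric vector of the same length.
#' @export
signed_sqrt <- function(v) sign(v) * sqrt(abs(v))

#' L2 normalisation
#'
#' Scales a vector to unit Euclidean norm; the zero vector is returned
#' unchanged. Off by default in the feature pipeline (it tends to hurt the
#' linear classifier here) but available for completeness.
#'
#' @param v Numeric vector.
#' @return Numeric vector of the same length.
#' @export
l2_normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) v else v / n
}

#' Build a classifier-ready feature vector from block feature matrices
#'
#' Implements both feature paths. The \emph{global} path applies global
#' pooling (average or max) to each requested block's feature matrix and
#' fuses the resulting F-vectors. The \emph{intermediate} path aligns c3/c4/
#' c5(pre-pool) matrices to the common reference side, zero-pads the border,
#' applies N x N spatial pooling, flattens, and fuses; N = 1 means plain
#' global pooling of the unpadded matrix, and N = padded side means
#' flattening with no spatial reduction. Signed-square-root and l2
#' normalisation are applied (in that order, when enabled) once, after
#' fusion.
#'
#' @param fms Named list of feature matrices (ascending block order), as
#'   returned by [extract_features()].
#' @param level Pooling level N; 1 = global pooling.
#' @param mode Pooling operator, \code{"average"} (default) or \code{"max"}.
#' @param use_signed_sqrt Apply signed square root after fusion (default TRUE).
#' @param use_l2 Apply l2 normalisation after signed sqrt (default FALSE).
#' @return Numeric feature vector with a \code{provenance} attribute.
#' @export
feature_vector <- function(fms, level = 1L, mode = "average",
                           use_signed_sqrt = TRUE, use_l2 = FALSE) {
  stopifnot(is.list(fms), length(fms) >= 1)
  parts <- lapply(fms, function(fm) {
    if (level == 1L) {
      global_pool(fm, mode)   # plain global pooling; no alignment, no padding
    } else {
      padded <- pad_border(align_to_reference(fm))
      side <- dim(padded)[1]
      if (level == side) {
        flatten_features(padded)
      } else {
        flatten_features(spatial_pool(padded, level, mode))
      }
    }
  })
  v <- fuse_features(parts)
  if (use_signed_sqrt) v <- signed_sqrt(v)
  if (use_l2) v <- l2_normalize(v)
  attr(v, "provenance") <- list(blocks = names(fms), level = level,
                                mode = mode, signed_sqrt = use_signed_sqrt,
                                l2 = use_l2)
  v
}
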