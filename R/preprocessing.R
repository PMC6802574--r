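#' Resize specification
#'
#' Describes how a stored image becomes the fixed square backbone input.
#' \code{preserve_aspect} scales the image so its larger side equals
#' \code{target_side}, centres it, and fills the frame with random pixel
#' noise; \code{distort} resamples both dimensions independently to the
#' target, changing the aspect ratio.
#'
#' @param target_side Side of the square input in pixels. Must be >= 32 and
#'   divisible by 32 so each of the five pooling halvings lands on integers;
#'   the sizes explored by the sweep experiments are 128, 224, 320, 416, 512.
#' @param mode \code{"preserve_aspect"} or \code{"distort"}.
#' @param pad_seed Seed for the random padding noise (preserve_aspect only);
#'   the same seed gives bit-identical padding.
#' @return A \code{resize_spec} list.
#' @export
resize_spec <- function(target_side = 224L,
                        mode = c("preserve_aspect", "distort"),
                        pad_seed = 1L) {
  mode <- match.arg(mode)
  target_side <- as.integer(target_side)
  if (target_side < 32L || target_side %% 32L != 0L) {
    stop("config error: target_side must be >= 32 and divisible by 32, got ",
         target_side)
  }
  structure(list(target_side = target_side, mode = mode, pad_seed = pad_seed),
            class = "resize_spec")
}

bilinear_resize <- function(image, height, width) {
  img <- EBImage::Image(aperm(image, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(img, w = width, h = height, filter = "bilinear")
  aperm(EBImage::imageData(out), c(2, 1, 3))
}

#' Resize an image preserving aspect ratio, padding with random pixels
#'
#' The image is scaled so its larger dimension equals the target side and
#' centred in the square frame; every frame pixel outside the scaled content
#' is filled with an independent uniform random 8-bit value per pixel and
#' channel (scaled to \[0,1\]). Random filler is deliberately uninformative:
#' it prevents the padding itself from becoming a learnable cue, which a
#' constant border could be. With odd margins the extra pixel goes to the
#' bottom/right.
#'
#' @param image Numeric H x W x 3 array in \[0, 1\].
#' @param spec A [resize_spec()] with \code{mode = "preserve_aspect"}.
#' @return S x S x 3 array, S = \code{spec$target_side}.
#' @export
resize_preserve_aspect <- function(image, spec) {
  check_image_input(image)
  s <- spec$target_side
  h <- dim(image)[1]; w <- dim(image)[2]
  scale <- s / max(h, w)
  nh <- max(1L, as.integer(round(h * scale)))
  nw <- max(1L, as.integer(round(w * scale)))
  if (nh > s) nh <- s
  if (nw > s) nw <- s
  content <- bilinear_resize(image, nh, nw)
  out <- with_seed(spec$pad_seed, {
    array((sample.int(256L, s * s * 3L, replace = TRUE) - 1L) / 255,
          dim = c(s, s, 3L))
  })
  top <- (s - nh) %/% 2L
  left <- (s - nw) %/% 2L
  out[top + seq_len(nh), left + seq_len(nw), ] <- content
  out
}

#' Resize an image to a square, distorting aspect ratio
#'
#' Both dimensions are independently resampled (bilinear) to the target side;
#' no padding is added.
#'
#' @inheritParams resize_preserve_aspect
#' @return S x S x 3 array.
#' @export
resize_distort <- function(image, spec) {
  check_image_input(image)
  bilinear_resize(image, spec$target_side, spec$target_side)
}

#' Apply a resize specification
#'
#' Dispatches to [resize_preserve_aspect()] or [resize_distort()] according
#' to \code{spec$mode}.
#'
#' @inheritParams resize_preserve_aspect
#' @return S x S x 3 array.
#' @export
resize_image <- function(image, spec) {
  switch(spec$mode,
         preserve_aspect = resize_preserve_aspect(image, spec),
         distort = resize_distort(image, spec))
}

check_image_input <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3) {
    stop("input error: image must be an H x W x 3 array")
  }
  if (any(dim(image)[1:2] == 0)) stop("input error: zero-area image")
  invisible(image)
}

# Content region of an aspect-preserving resize: (rows, cols) index vectors
# of the centred scaled image inside the S x S frame. Exposed for tests and
# for padding-aware diagnostics.
content_region <- function(h, w, s) {
  scale <- s / max(h, w)
  nh <- min(s, max(1L, as.integer(round(h * scale))))
  nw <- min(s, max(1L, as.integer(round(w * scale))))
  top <- (s - nh) %/% 2L
  left <- (s - nw) %/% 2L
  list(rows = top + seq_len(nh), cols = left + seq_len(nw))
}
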