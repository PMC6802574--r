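#' Five-block backbone layout
#'
#' The backbone follows the VGG16 convolutional layout: five blocks of 3x3
#' convolutions (ReLU), each block ending in a 2x2 max-pooling layer that
#' halves the spatial extent. Filter depths per block are 64, 128, 256, 512
#' and 512, so an S x S input leaves block ck with side S / 2^k.
#'
#' @return A \code{backbone_spec} list with \code{filters_per_block} and the
#'   per-block downsampling factor.
#' @export
backbone_spec <- function() {
  structure(list(
    blocks = paste0("c", 1:5),
    filters_per_block = c(c1 = 64L, c2 = 128L, c3 = 256L, c4 = 512L, c5 = 512L),
    downsample_per_block = 2L
  ), class = "backbone_spec")
}

#' Spatial side and depth of a block's feature matrix
#'
#' @param s Square input side (divisible by 32).
#' @param block One of \code{"c1"} .. \code{"c5"}.
#' @param tap_point \code{"post_pool"} (after the block's max pooling, the
#'   default) or \code{"pre_pool"} (just before it, retaining twice the side).
#' @return Named vector \code{c(side =, depth =)}.
#' @export
block_geometry <- function(s, block, tap_point = c("post_pool", "pre_pool")) {
  tap_point <- match.arg(tap_point)
  spec <- backbone_spec()
  stopifnot(block %in% spec$blocks)
  k <- match(block, spec$blocks)
  if (s %% 32L != 0L) stop("config error: input side must be divisible by 32")
  side <- if (tap_point == "post_pool") s %/% 2L^k else s %/% 2L^(k - 1L)
  c(side = as.integer(side), depth = spec$filters_per_block[[block]])
}

# -- forward-pass primitives --------------------------------------------------

# 3x3 same-padding stride-1 convolution by im2col + matrix multiply.
# x: H x W x Cin; W arrays are (3, 3, Cin, Cout); returns H x W x Cout.
conv3x3 <- function(x, w, b) {
  h <- dim(x)[1]; wd <- dim(x)[2]; cin <- dim(x)[3]
  cout <- dim(w)[4]
  stopifnot(dim(w)[3] == cin)
  xp <- array(0, c(h + 2L, wd + 2L, cin))
  xp[1L + seq_len(h), 1L + seq_len(wd), ] <- x
  patches <- matrix(0, h * wd, 9L * cin)
  k <- 0L
  for (ch in seq_len(cin)) {
    for (dx in 0:2) {
      for (dy in 0:2) {
        k <- k + 1L
        patches[, k] <- xp[dy + seq_len(h), dx + seq_len(wd), ch]
      }
    }
  }
  out <- patches %*% matrix(w, 9L * cin, cout)
  out <- sweep(out, 2L, b, "+")
  array(out, c(h, wd, cout))
}

relu <- function(x) pmax(x, 0)

# 2x2 max pooling, stride 2.
maxpool2 <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]
  stopifnot(h %% 2L == 0L, w %% 2L == 0L)
  i1 <- seq(1L, h, 2L); i2 <- seq(2L, h, 2L)
  j1 <- seq(1L, w, 2L); j2 <- seq(2L, w, 2L)
  pmax(x[i1, j1, , drop = FALSE], x[i2, j1, , drop = FALSE],
       x[i1, j2, , drop = FALSE], x[i2, j2, , drop = FALSE])
}

# -- backbones ---------------------------------------------------------------

new_backbone <- function(kind, weights, conv_layers, input_transform) {
  structure(list(kind = kind, spec = backbone_spec(), weights = weights,
                 conv_layers = conv_layers, input_transform = input_transform),
            class = "deepident_backbone")
}

#' @export
print.deepident_backbone <- function(x, ...) {
  cat(sprintf("<%s backbone: 5 blocks, %s conv layer(s)/block, depths %s>\n",
              x$kind, paste(x$conv_layers, collapse = "/"),
              paste(x$spec$filters_per_block, collapse = "/")))
  invisible(x)
}

#' Deterministic fixture backbone
#'
#' A backbone with the same block and shape semantics as the VGG16 layout but
#' small fixed random weights (He-scaled Gaussian, one convolutional layer
#' per block), cheap enough for CPU test runs. Random convolutions preserve
#' colour and coarse texture statistics well enough that visually distinct
#' synthetic categories stay linearly separable, which is what the offline
#' integration tests rely on.
#'
#' @param seed Integer seed; the same seed gives identical weights and hence
#'   identical features.
#' @return A backbone usable with [extract_features()].
#' @export
make_fixture_backbone <- function(seed = 42L) {
  spec <- backbone_spec()
  depths <- c(3L, unname(spec$filters_per_block))
  weights <- with_seed(seed, {
    lapply(1:5, function(k) {
      cin <- depths[k]; cout <- depths[k + 1L]
      sd <- sqrt(2 / (9 * cin))
      list(list(W = array(stats::rnorm(9 * cin * cout, sd = sd),
                          c(3L, 3L, cin, cout)),
                b = rep(0, cout)))
    })
  })
  new_backbone("fixture", weights, conv_layers = rep(1L, 5),
               input_transform = function(x) x - 0.5)
}

#' Pretrained VGG16 backbone adapter
#'
#' Loads VGG16 ImageNet convolutional weights from an RDS container (a list
#' of five blocks, each a list of conv layers with \code{W} (3 x 3 x Cin x
#' Cout) and \code{b} arrays, in the published layer order). The adapter
#' applies the canonical input preprocessing those weights were trained with:
#' pixel values scaled to 0-255, channels reordered RGB -> BGR, and the
#' ImageNet channel means subtracted.
#'
#' @param weights_path Path to the RDS weight container.
#' @return A backbone usable with [extract_features()].
#' @export
vgg16_backbone <- function(weights_path) {
  if (missing(weights_path) || !file.exists(weights_path)) {
    stop("pretrained VGG16 weights not available",
         if (!missing(weights_path)) paste0(" at ", weights_path) else "",
         ". Convert the published ImageNet weights to the documented RDS ",
         "layout, or use make_fixture_backbone() for an offline test double.")
  }
  weights <- readRDS(weights_path)
  spec <- backbone_spec()
  depths <- c(3L, unname(spec$filters_per_block))
  conv_layers <- c(2L, 2L, 3L, 3L, 3L)
  stopifnot(length(weights) == 5L)
  for (k in 1:5) {
    stopifnot(length(weights[[k]]) == conv_layers[k])
    first <- weights[[k]][[1]]$W
    stopifnot(dim(first)[3] == depths[k], dim(first)[4] == depths[k + 1L])
  }
  imagenet_means <- c(103.939, 116.779, 123.68)   # B, G, R on 0-255 scale
  input_transform <- function(x) {
    x <- x * 255
    x <- x[, , c(3L, 2L, 1L), drop = FALSE]       # RGB -> BGR
    for (ch in 1:3) x[, , ch] <- x[, , ch] - imagenet_means[ch]
    x
  }
  new_backbone("vgg16", weights, conv_layers, input_transform)
}

#' Extract per-block convolutional feature matrices
#'
#' Runs a single forward pass through the backbone and returns the requested
#' blocks' activation volumes ("feature matrices"). Each block can be tapped
#' \code{post_pool} (the block output, side S / 2^k — the conventional
#' "bottleneck" tap for c5) or \code{pre_pool} (just before the block's final
#' max pooling, side S / 2^(k-1), used by the intermediate pooling scheme to
#' keep c5 at the same side as c4).
#'
#' @param backbone A backbone from [make_fixture_backbone()] or
#'   [vgg16_backbone()].
#' @param image S x S x 3 array, S divisible by 32.
#' @param blocks Character vector of blocks to return, subset of c1..c5.
#' @param tap_points Named character vector (or single value recycled) giving
#'   \code{"post_pool"} or \code{"pre_pool"} per requested block.
#' @return Named list of \code{feature_matrix} objects (arrays with
#'   \code{block} and \code{tap_point} attributes).
#' @export
extract_features <- function(backbone, image, blocks = "c5",
                             tap_points = "post_pool") {
  stopifnot(inherits(backbone, "deepident_backbone"))
  check_image_input(image)
  s <- dim(image)[1]
  if (dim(image)[2] != s) stop("config error: input must be square")
  if (s %% 32L != 0L) {
    stop("config error: input side must be divisible by 32, got ", s)
  }
  spec <- backbone$spec
  stopifnot(all(blocks %in% spec$blocks))
  if (is.null(names(tap_points))) {
    tap_points <- stats::setNames(rep(tap_points, length.out = length(blocks)),
                                  blocks)
  }
  stopifnot(all(tap_points %in% c("post_pool", "pre_pool")))
  x <- backbone$input_transform(image)
  out <- list()
  last <- max(match(blocks, spec$blocks))
  for (k in seq_len(last)) {
    blk <- spec$blocks[k]
    for (layer in backbone$weights[[k]]) {
      x <- relu(conv3x3(x, layer$W, layer$b))
    }
    if (blk %in% blocks && tap_points[[blk]] == "pre_pool") {
      out[[blk]] <- feature_matrix(x, blk, "pre_pool")
    }
    x <- maxpool2(x)
    if (blk %in% blocks && tap_points[[blk]] == "post_pool") {
      out[[blk]] <- feature_matrix(x, blk, "post_pool")
    }
  }
  out[blocks]
}

feature_matrix <- function(values, block, tap_point) {
  structure(values, block = block, tap_point = tap_point,
            class = c("feature_matrix", class(values)))
}
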