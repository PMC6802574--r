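#' Synthetic fixture dataset specification
#'
#' Describes a seeded synthetic specimen-image dataset. Each category has a
#' parametric motif (body hue, stripe frequency, and the count and size of
#' white spots on the body); each synthetic "specimen" is one motif instance
#' (a fixed spot layout) photographed several times with nuisance variation
#' in scale, position, rotation, background tone and noise, and image size.
#' \code{easy} specs separate categories by hue and gross motif; \code{hard}
#' specs share a single hue and differ only in spot statistics — quantity and
#' size of white spots — exercising fine-grained discrimination.
#'
#' @param n_categories Number of categories (>= 2).
#' @param images_per_category Images per category.
#' @param images_per_specimen Images of each synthetic specimen (default 4,
#'   matching the multiple-views-per-specimen structure that grouped folds
#'   must respect).
#' @param height_range,width_range Inclusive pixel bounds for stored image
#'   sizes; non-square draws exercise aspect handling.
#' @param difficulty \code{"easy"} or \code{"hard"}.
#' @param seed Integer seed; generation is a pure function of (spec, seed).
#' @return A \code{fixture_spec} list.
#' @export
fixture_spec <- function(n_categories = 4L, images_per_category = 12L,
                         images_per_specimen = 4L,
                         height_range = c(48L, 96L),
                         width_range = c(48L, 96L),
                         difficulty = c("easy", "hard"), seed = 1L) {
  difficulty <- match.arg(difficulty)
  stopifnot(n_categories >= 2, images_per_category >= 1,
            images_per_specimen >= 1,
            height_range[1] >= 16, width_range[1] >= 16)
  structure(list(n_categories = as.integer(n_categories),
                 images_per_category = as.integer(images_per_category),
                 images_per_specimen = as.integer(images_per_specimen),
                 height_range = as.integer(height_range),
                 width_range = as.integer(width_range),
                 difficulty = difficulty, seed = seed),
            class = "fixture_spec")
}

# Render one synthetic specimen image: elliptical striped body of the
# category hue on a noisy background, with the specimen's white spots.
# All randomness comes in through the arguments.
render_fixture_image <- function(h, w, body_rgb, stripe_freq, spots,
                                 spot_r, bg_level, noise, scale, angle,
                                 offset) {
  img <- array(pmin(pmax(bg_level + noise, 0), 1), c(h, w, 3L))
  yy <- matrix((seq_len(h) - 0.5) / h, h, w)
  xx <- matrix((seq_len(w) - 0.5) / w, h, w, byrow = TRUE)
  cy <- 0.5 + offset[1]; cx <- 0.5 + offset[2]
  u <- cos(angle) * (yy - cy) + sin(angle) * (xx - cx)
  v <- -sin(angle) * (yy - cy) + cos(angle) * (xx - cx)
  body <- (u / (0.38 * scale))^2 + (v / (0.28 * scale))^2 <= 1
  stripe <- 0.75 + 0.25 * sin(2 * pi * stripe_freq * u / scale)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[body] <- pmin(1, body_rgb[ch] * stripe[body])
    img[, , ch] <- plane
  }
  if (nrow(spots) > 0) {
    for (s in seq_len(nrow(spots))) {
      mask <- ((u - spots[s, 1] * scale)^2 + (v - spots[s, 2] * scale)^2) <=
        (spot_r * scale)^2
      mask <- mask & body
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[mask] <- 0.95
        img[, , ch] <- plane
      }
    }
  }
  img
}

#' Generate a synthetic labelled image dataset
#'
#' Writes PNG images and a manifest CSV (with \code{specimen_id}) under
#' \code{out_dir}. Deterministic: the same spec and seed reproduce the files
#' bit for bit.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Writable output directory (created if absent).
#' @return The generated \code{manifest} (paths point into \code{out_dir}).
#' @export
generate_image_dataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("I/O error: cannot create directory ", out_dir)
  probe <- file.path(out_dir, ".write_probe")
  if (!isTRUE(file.create(probe, showWarnings = FALSE))) {
    stop("I/O error: directory not writable: ", out_dir)
  }
  unlink(probe)
  rows <- with_seed(spec$seed, {
    n_cat <- spec$n_categories
    # category motif parameters
    if (spec$difficulty == "easy") {
      hues <- seq(0, 1 - 1 / n_cat, length.out = n_cat)
      spot_counts <- 1L + (seq_len(n_cat) - 1L) %% 4L
      spot_r <- rep(0.07, n_cat)
      stripe_freqs <- seq(2, 6, length.out = n_cat)
    } else {
      hues <- rep(0.08, n_cat)                       # one shared brown hue
      spot_counts <- 2L + 2L * (seq_len(n_cat) - 1L) # differ in spot count
      spot_r <- 0.05 + 0.015 * ((seq_len(n_cat) - 1L) %% 3L) # ... and size
      stripe_freqs <- rep(4, n_cat)
    }
    body_cols <- t(grDevices::col2rgb(grDevices::hsv(hues, 0.75, 0.75)) / 255)
    out <- list()
    for (ci in seq_len(n_cat)) {
      label <- sprintf("taxon_%02d", ci)
      n_spec <- ceiling(spec$images_per_category / spec$images_per_specimen)
      img_i <- 0L
      for (si in seq_len(n_spec)) {
        specimen_id <- sprintf("%s_sp%03d", label, si)
        k <- spot_counts[ci]
        spots <- cbind(stats::runif(k, -0.25, 0.25),
                       stats::runif(k, -0.2, 0.2))
        n_imgs <- min(spec$images_per_specimen,
                      spec$images_per_category - (si - 1L) * spec$images_per_specimen)
        for (ii in seq_len(n_imgs)) {
          img_i <- img_i + 1L
          h <- sample(spec$height_range[1]:spec$height_range[2], 1L)
          w <- sample(spec$width_range[1]:spec$width_range[2], 1L)
          img <- render_fixture_image(
            h, w, body_rgb = body_cols[ci, ],
            stripe_freq = stripe_freqs[ci], spots = spots,
            spot_r = spot_r[ci],
            bg_level = stats::runif(1, 0.1, 0.35),
            noise = array(stats::rnorm(h * w * 3, sd = 0.03), c(h, w, 3)),
            scale = stats::runif(1, 0.8, 1.15),
            angle = stats::runif(1, -0.4, 0.4),
            offset = stats::runif(2, -0.06, 0.06))
          fname <- sprintf("%s_img%03d.png", specimen_id, img_i)
          EBImage::writeImage(
            EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color"),
            file.path(out_dir, fname))
          out[[length(out) + 1L]] <- data.frame(
            path = fname, label = label, specimen_id = specimen_id)
        }
      }
    }
    do.call(rbind, out)
  })
  manifest <- as_manifest(rows, base_dir = NULL)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest$path <- file.path(out_dir, manifest$path)
  manifest
}

#' Generate a Gaussian feature test set
#'
#' Balanced K-class Gaussian clusters in d dimensions with controllable
#' separation: class means sit \code{separation} apart along orthogonal axes
#' and points have unit-variance isotropic noise. \code{separation} far above
#' 1 gives a linearly separable problem; 0 gives chance-level class
#' structure.
#'
#' @param n Total number of points (split as evenly as possible over classes).
#' @param d Feature dimension (>= K).
#' @param k Number of classes (>= 2).
#' @param separation Distance scale between class means.
#' @param seed Integer seed.
#' @return List with \code{features} (n x d) and \code{labels} (length n).
#' @export
generate_feature_testset <- function(n, d, k, separation, seed = 1L) {
  stopifnot(k >= 2, d >= k, n >= k)
  counts <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  labels <- rep(sprintf("class_%02d", seq_len(k)), counts)
  with_seed(seed, {
    means <- diag(k) * separation
    x <- matrix(stats::rnorm(n * d), n, d)
    for (i in seq_len(k)) {
      sel <- labels == sprintf("class_%02d", i)
      x[sel, seq_len(k)] <- x[sel, seq_len(k)] +
        matrix(means[i, ], sum(sel), k, byrow = TRUE)
    }
    list(features = x, labels = labels)
  })
}
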