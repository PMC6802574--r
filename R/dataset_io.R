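#' Read a dataset manifest
#'
#' A manifest is a UTF-8 CSV with header columns \code{path,label} and an
#' optional \code{specimen_id} column. Each row describes one labelled
#' specimen image; \code{specimen_id}, when present, marks images of the same
#' physical specimen so that grouped cross-validation can keep them in one
#' fold.
#'
#' @param path Path to the manifest CSV.
#' @param base_dir Directory that relative image paths are resolved against.
#'   Defaults to the manifest's own directory.
#' @return A \code{manifest} object: a data frame with columns \code{path},
#'   \code{label} and (if present in the file) \code{specimen_id}, plus a
#'   \code{categories} attribute holding the distinct labels in first-seen
#'   order.
#' @export
read_manifest <- function(path, base_dir = dirname(path)) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("path", "label")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("manifest format error: missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) stop("empty manifest: ", path, " has a header but no records")
  keep <- intersect(c("path", "label", "specimen_id"), names(df))
  df <- df[, keep, drop = FALSE]
  as_manifest(df, base_dir = base_dir)
}

#' Construct a manifest from a data frame
#'
#' @param df Data frame with columns \code{path}, \code{label} and optionally
#'   \code{specimen_id}.
#' @param base_dir Optional directory against which relative paths resolve.
#' @return A \code{manifest} object.
#' @export
as_manifest <- function(df, base_dir = NULL) {
  stopifnot(is.data.frame(df), all(c("path", "label") %in% names(df)))
  if (nrow(df) == 0) stop("empty manifest: no records")
  df$label <- as.character(df$label)
  df$path <- as.character(df$path)
  if (any(!nzchar(df$label))) stop("manifest format error: empty label")
  if (!is.null(base_dir)) {
    rel <- !grepl("^(/|[A-Za-z]:)", df$path)
    df$path[rel] <- file.path(base_dir, df$path[rel])
  }
  rownames(df) <- NULL
  structure(df,
            categories = unique(df$label),
            class = c("manifest", "data.frame"))
}

#' @export
print.manifest <- function(x, ...) {
  cats <- attr(x, "categories")
  cat(sprintf("manifest: %d images, %d categories\n", nrow(x), length(cats)))
  tab <- table(factor(x$label, levels = cats))
  cat(sprintf("  %s: %d\n", names(tab), as.integer(tab)), sep = "")
  if ("specimen_id" %in% names(x)) {
    cat(sprintf("  specimens: %d\n", length(unique(x$specimen_id))))
  }
  invisible(x)
}

#' Categories of a manifest
#' @param manifest A \code{manifest}.
#' @return Character vector of distinct labels in first-seen order.
#' @export
manifest_categories <- function(manifest) attr(manifest, "categories")

#' Write a manifest to CSV
#'
#' Inverse of [read_manifest()] on record content (paths are written as
#' stored, labels and specimen ids verbatim).
#'
#' @param manifest A \code{manifest}.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE,
                   quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Load an image as a height x width x 3 array
#'
#' Pixel values are in \[0, 1\]. Grayscale images are replicated to three
#' channels; an alpha channel, if present, is dropped. JPEG, PNG and TIFF are
#' supported through the EBImage decoders.
#'
#' @param path Image file path.
#' @return Numeric array of dimension height x width x 3.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("I/O error: cannot read image: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("I/O error: cannot read image: ",
                                           path, " (", conditionMessage(e), ")"))
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]   # drop alpha
  if (dim(a)[3] == 1) a <- array(rep(a, 3), dim = c(dim(a)[1:2], 3))
  # EBImage stores (x = width, y = height, channel); flip to H x W x 3
  aperm(a, c(2, 1, 3))
}

#' Average image dimensions of a dataset
#'
#' Reads every image named in the manifest and returns the arithmetic mean of
#' the stored heights and widths, rounded to the nearest integer. This is the
#' dataset-level geometry statistic that guides the choice of a common input
#' frame when aspect ratio is preserved.
#'
#' @param manifest A \code{manifest}.
#' @return Named integer vector \code{c(mean_height =, mean_width =)}.
#' @export
average_dimensions <- function(manifest) {
  dims <- vapply(manifest$path, function(p) dim(load_image(p))[1:2],
                 numeric(2))
  c(mean_height = round(mean(dims[1, ])), mean_width = round(mean(dims[2, ])))
}

#' Randomly subsample a manifest per category
#'
#' Draws at most \code{n_per_category} records per category, uniformly
#' without replacement; categories with fewer images keep all of them. Used
#' for accuracy-versus-sample-size experiments on subsampled datasets.
#'
#' @param manifest A \code{manifest}.
#' @param n_per_category Maximum records kept per category (>= 1).
#' @param seed Integer seed; the same seed always selects the same records.
#' @return A \code{manifest} with the selected records, in original order.
#' @export
subsample_per_category <- function(manifest, n_per_category, seed = 1L) {
  stopifnot(n_per_category >= 1)
  idx <- with_seed(seed, {
    unlist(lapply(manifest_categories(manifest), function(cat) {
      i <- which(manifest$label == cat)
      if (length(i) <= n_per_category) i else sort(sample(i, n_per_category))
    }))
  })
  idx <- sort(idx)
  out <- as.data.frame(manifest)[idx, , drop = FALSE]
  as_manifest(out)
}
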