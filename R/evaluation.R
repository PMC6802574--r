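#' Stratified k-fold plan
#'
#' Partitions the records into k folds by stratified random sampling: within
#' each category the (seeded) shuffled records are dealt to folds in turn, so
#' per-category counts differ by at most one across folds and any remainder
#' goes to the lowest-indexed folds. Every record lands in exactly one fold.
#'
#' @param manifest A \code{manifest} (or any data frame with a \code{label}
#'   column).
#' @param k Number of folds (>= 2), default 10.
#' @param seed Integer seed; the same seed always yields the same plan.
#' @return A \code{fold_plan}: integer fold id (1..k) per record, plus k,
#'   grouping mode and seed.
#' @export
stratified_folds <- function(manifest, k = 10L, seed = 1L) {
  stopifnot(k >= 2L)
  labels <- manifest$label
  counts <- table(labels)
  if (any(counts < k)) {
    warning("category count below k: ",
            paste(names(counts)[counts < k], collapse = ", "),
            " will be absent from some test folds")
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cat in unique(labels)) {
      idx <- which(labels == cat)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  new_fold_plan(fold, k, "none", seed)
}

#' Specimen-grouped stratified k-fold plan
#'
#' Like [stratified_folds()] but assigns whole specimens, not images: all
#' images sharing a \code{specimen_id} always land in the same fold, so no
#' specimen ever appears on both sides of a train/test split. Stratification
#' is best-effort at specimen granularity (specimen counts per category are
#' balanced across folds; image counts then follow approximately).
#'
#' @inheritParams stratified_folds
#' @return A \code{fold_plan} with \code{grouping = "by_specimen"}.
#' @export
grouped_folds <- function(manifest, k = 10L, seed = 1L) {
  stopifnot(k >= 2L)
  if (!"specimen_id" %in% names(manifest) || anyNA(manifest$specimen_id)) {
    stop("usage error: grouped folds require a specimen_id on every record")
  }
  spec_fold <- new.env(parent = emptyenv())
  with_seed(seed, {
    for (cat in unique(manifest$label)) {
      specs <- unique(manifest$specimen_id[manifest$label == cat])
      specs <- setdiff(specs, ls(spec_fold))
      if (length(specs) == 0) next
      specs <- specs[sample.int(length(specs))]
      f <- rep_len(seq_len(k), length(specs))
      for (i in seq_along(specs)) assign(as.character(specs[i]), f[i], spec_fold)
    }
  })
  fold <- vapply(as.character(manifest$specimen_id),
                 function(s) get(s, spec_fold), integer(1), USE.NAMES = FALSE)
  new_fold_plan(fold, k, "by_specimen", seed)
}

new_fold_plan <- function(fold, k, grouping, seed) {
  structure(list(fold = as.integer(fold), k = as.integer(k),
                 grouping = grouping, seed = seed),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold plan: %d records, k = %d, grouping = %s, seed = %s>\n",
              length(x$fold), x$k, x$grouping, x$seed))
  invisible(x)
}

#' Cross-validated evaluation of a feature matrix
#'
#' For each fold, trains the linear one-vs-rest classifier on the remaining
#' folds and predicts the held-out records; accuracies are the proportion of
#' predicted labels exactly matching the true labels, pooled over all folds
#' and reported per fold, per category, and as cumulative and per-rank top-k
#' correctness. Error rate is the complement of accuracy. A training split
#' that lacks a category entirely is recorded in the report and the fold is
#' still evaluated.
#'
#' @param x Numeric n x d feature matrix, rows aligned with \code{labels}.
#' @param labels Character vector of true category labels.
#' @param plan A \code{fold_plan} over the same records.
#' @param config A [classifier_config()].
#' @param top Maximum suggestion depth for top-k correctness (default 3,
#'   capped at the number of categories).
#' @return An \code{evaluation_report} list: \code{accuracy},
#'   \code{error_rate}, \code{per_fold}, \code{per_category},
#'   \code{top_k_cumulative}, \code{top_k_per_rank}, \code{confusion},
#'   \code{predictions}, \code{missing_in_training}.
#' @export
cross_validate <- function(x, labels, plan, config = classifier_config(),
                           top = 3L) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(inherits(plan, "fold_plan"), nrow(x) == length(labels),
            length(plan$fold) == length(labels))
  categories <- sort(unique(labels))
  top <- min(as.integer(top), length(categories))
  predicted <- character(length(labels))
  ranks <- rep(NA_integer_, length(labels))   # rank of true label in top list
  missing <- list()
  for (f in seq_len(plan$k)) {
    test <- plan$fold == f
    if (!any(test)) next
    train_labels <- labels[!test]
    absent <- setdiff(categories, unique(train_labels))
    if (length(absent) > 0) {
      missing[[length(missing) + 1L]] <-
        data.frame(fold = f, category = absent)
    }
    model <- train_classifier(x[!test, , drop = FALSE], train_labels, config)
    full <- top_k(model, x[test, , drop = FALSE], length(model$categories))
    predicted[test] <- vapply(full, `[`, character(1), 1L)
    ranks[test] <- vapply(seq_along(full), function(i) {
      r <- match(labels[test][i], full[[i]])
      if (is.na(r)) NA_integer_ else r
    }, integer(1))
  }
  correct <- predicted == labels
  per_fold <- vapply(seq_len(plan$k), function(f) {
    sel <- plan$fold == f
    if (!any(sel)) NA_real_ else mean(correct[sel])
  }, numeric(1))
  per_category <- do.call(rbind, lapply(categories, function(cat) {
    sel <- labels == cat
    data.frame(category = cat, n_images = sum(sel),
               accuracy = mean(correct[sel]))
  }))
  top_cum <- vapply(seq_len(top), function(j) mean(!is.na(ranks) & ranks <= j),
                    numeric(1))
  top_rank <- vapply(seq_len(top), function(j) mean(!is.na(ranks) & ranks == j),
                     numeric(1))
  names(top_cum) <- names(top_rank) <- paste0("top", seq_len(top))
  structure(list(
    accuracy = mean(correct),
    error_rate = 1 - mean(correct),
    per_fold = per_fold,
    per_category = per_category,
    top_k_cumulative = top_cum,
    top_k_per_rank = top_rank,
    confusion = table(truth = factor(labels, categories),
                      predicted = factor(predicted, categories)),
    predictions = data.frame(index = seq_along(labels), fold = plan$fold,
                             truth = labels, predicted = predicted,
                             rank_of_truth = ranks),
    missing_in_training = if (length(missing)) do.call(rbind, missing) else
      data.frame(fold = integer(), category = character()),
    n = length(labels)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation: n = %d, accuracy = %.4f, error rate = %.4f>\n",
              x$n, x$accuracy, x$error_rate))
  cat("  top-k correctness (cumulative):",
      paste(sprintf("%s = %.4f", names(x$top_k_cumulative),
                    x$top_k_cumulative), collapse = ", "), "\n")
  invisible(x)
}

#' Per-category accuracy against sample size
#'
#' One row per category with its image count and cross-validated accuracy,
#' the table behind accuracy-versus-sample-size scatter plots. With a
#' \code{by} column name (e.g. a genus column carried in the manifest), rows
#' are aggregated to that subgroup instead: subgroup image count and the
#' pooled accuracy of its images.
#'
#' @param report An \code{evaluation_report}.
#' @param manifest Optional manifest aligned with the evaluated records,
#'   needed only when \code{by} names one of its columns.
#' @param by Optional subgroup column name in \code{manifest}.
#' @return Data frame (category-or-subgroup, n_images, accuracy).
#' @export
accuracy_by_category <- function(report, manifest = NULL, by = NULL) {
  if (is.null(by)) return(report$per_category)
  stopifnot(!is.null(manifest), by %in% names(manifest),
            nrow(manifest) == report$n)
  grp <- as.character(manifest[[by]])
  correct <- report$predictions$truth == report$predictions$predicted
  out <- do.call(rbind, lapply(unique(grp), function(g) {
    sel <- grp == g
    data.frame(subgroup = g, n_images = sum(sel), accuracy = mean(correct[sel]))
  }))
  rownames(out) <- NULL
  out
}

#' Two-dimensional t-SNE embedding of feature vectors
#'
#' Exact (quadratic-time) t-distributed stochastic neighbour embedding:
#' per-point Gaussian bandwidths calibrated to the target perplexity by
#' bisection, symmetrised input affinities, Student-t low-dimensional kernel,
#' gradient descent with momentum and early exaggeration. Labels are never
#' used — the embedding is unsupervised and labels serve only to colour
#' plots afterwards. Intended for dataset-scale visualisation (hundreds to a
#' few thousand points).
#'
#' @param x Numeric n x d feature matrix, n >= 5.
#' @param seed Integer seed for the random initialisation.
#' @param perplexity Target perplexity (default 30, clamped to (n-1)/3).
#' @param n_iter Gradient-descent iterations (default 400).
#' @return n x 2 matrix of embedding coordinates.
#' @export
tsne_embed <- function(x, seed = 1L, perplexity = 30, n_iter = 400L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 5) stop("usage error: t-SNE needs at least 5 points, got ", n)
  perplexity <- min(perplexity, (n - 1) / 3)
  d2 <- as.matrix(stats::dist(x))^2
  p <- tsne_input_affinities(d2, perplexity)
  p <- (p + t(p)) / (2 * n)
  p <- pmax(p, 1e-12)
  exaggeration_until <- min(100L, n_iter %/% 4L)
  y <- with_seed(seed, matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  update <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  eta <- 100
  for (it in seq_len(n_iter)) {
    pp <- if (it <= exaggeration_until) p * 12 else p
    num <- 1 / (1 + as.matrix(stats::dist(y))^2)
    diag(num) <- 0
    q <- pmax(num / sum(num), 1e-12)
    l <- (pp - q) * num
    grad <- 4 * (diag(rowSums(l)) - l) %*% y
    momentum <- if (it <= 250) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(update), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    update <- momentum * update - eta * gains * grad
    y <- y + update
    y <- sweep(y, 2, colMeans(y))
  }
  y
}

# Per-row conditional affinities at the given perplexity: bisection on the
# Gaussian precision beta so that the entropy of each row matches
# log(perplexity).
tsne_input_affinities <- function(d2, perplexity) {
  n <- nrow(d2)
  target <- log(perplexity)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- d2[i, -i]
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { h <- 0; pr <- w } else {
        pr <- w / sw
        h <- -sum(pr[pr > 0] * log(pr[pr > 0]))
      }
      if (abs(h - target) < 1e-5) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    p[i, -i] <- pr
  }
  p
}
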