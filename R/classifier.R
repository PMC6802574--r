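#' Classifier configuration
#'
#' Settings for the linear one-vs-rest max-margin classifier. The defaults —
#' cost (regularisation constant) 1, convergence tolerance 1e-4, no feature
#' standardisation — are the package's documented defaults for a linear SVM
#' trained on pooled convolutional features; the feature module's
#' normalisation is the only scaling ever applied.
#'
#' @param cost Soft-margin cost C (> 0).
#' @param tolerance Solver convergence tolerance.
#' @param seed Seed recorded with the model (the quadratic-programming solve
#'   itself is deterministic given the data).
#' @return A \code{classifier_config} list.
#' @export
classifier_config <- function(cost = 1, tolerance = 1e-4, seed = 1L) {
  stopifnot(cost > 0, tolerance > 0)
  structure(list(cost = cost, tolerance = tolerance, seed = seed),
            class = "classifier_config")
}

#' Train a linear one-vs-rest classifier
#'
#' Fits one binary linear max-margin (SVM) score function per category
#' against the rest and stores the stacked weight vectors and biases. With K
#' categories this scales linearly in K, which is why one-vs-rest is
#' preferred over one-vs-one for taxon-rich datasets. The binary subproblems
#' are solved with the libsvm linear-kernel C-classifier (via e1071); the
#' one-vs-rest assembly, score orientation and ranking semantics are defined
#' here.
#'
#' @param x Numeric n x d feature matrix.
#' @param labels Character (or factor) vector of n category labels; at least
#'   two distinct categories, each with >= 1 example.
#' @param config A [classifier_config()].
#' @return A \code{linear_ovr} model: weight matrix (K x d), bias vector,
#'   category order (fixed at training), and the configuration.
#' @export
train_classifier <- function(x, labels, config = classifier_config()) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels), ncol(x) >= 1)
  if (anyNA(x) || any(!is.finite(x))) {
    stop("input error: feature matrix contains NA or non-finite values")
  }
  categories <- sort(unique(labels))
  if (length(categories) < 2) {
    stop("training error: need at least two categories, got ",
         length(categories))
  }
  d <- ncol(x)
  weights <- matrix(0, length(categories), d,
                    dimnames = list(categories, NULL))
  biases <- stats::setNames(rep(-Inf, length(categories)), categories)
  for (k in seq_along(categories)) {
    pos <- labels == categories[k]
    if (!any(pos)) next   # category absent from this training split
    y <- factor(ifelse(pos, "pos", "rest"), levels = c("pos", "rest"))
    fit <- with_seed(config$seed, {
      e1071::svm(x, y, kernel = "linear", cost = config$cost,
                 tolerance = config$tolerance, scale = FALSE, shrinking = TRUE)
    })
    w <- as.vector(t(fit$coefs) %*% fit$SV)
    b <- -fit$rho
    # libsvm orients the decision function by order of appearance in the
    # data; re-orient so the positive category always scores higher.
    score <- as.vector(x %*% w + b)
    if (mean(score[pos]) < mean(score[!pos])) {
      w <- -w; b <- -b
    }
    weights[k, ] <- w
    biases[k] <- b
  }
  structure(list(weights = weights, biases = biases, categories = categories,
                 config = config, n_features = d),
            class = "linear_ovr")
}

#' @export
print.linear_ovr <- function(x, ...) {
  cat(sprintf("<linear one-vs-rest model: %d categories, %d features>\n",
              length(x$categories), x$n_features))
  invisible(x)
}

#' Per-category decision scores
#'
#' Score of category k for sample i is w_k . x_i + b_k, the raw signed
#' margin of the k-th one-vs-rest score function. Raw scores, not
#' probabilities: the linear classifier provides no probability estimates,
#' and all ranking is done on these margins.
#'
#' @param model A \code{linear_ovr} model.
#' @param x Numeric n x d matrix (or a single length-d vector).
#' @return n x K numeric matrix with category column names.
#' @export
decision_scores <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != model$n_features) {
    stop("usage error: feature dimension ", ncol(x),
         " does not match model dimension ", model$n_features)
  }
  sweep(x %*% t(model$weights), 2, model$biases, "+")
}

#' Predict category labels
#'
#' The predicted category is the one with the highest decision score;
#' equivalently the first element of [top_k()] with k = 1.
#'
#' @inheritParams decision_scores
#' @return Character vector of predicted labels.
#' @export
predict_categories <- function(model, x) {
  vapply(top_k(model, x, 1L), `[`, character(1), 1L)
}

#' Top-k ranked category suggestions
#'
#' Categories sorted by descending decision score; exact ties are broken by
#' ascending category order (the model's fixed training order), so rankings
#' are fully deterministic.
#'
#' @inheritParams decision_scores
#' @param k Number of suggestions, 1 <= k <= number of categories.
#' @return List of length n; each element a character vector of k categories.
#' @export
top_k <- function(model, x, k = 3L) {
  if (k < 1L || k > length(model$categories)) {
    stop("usage error: k must be between 1 and ", length(model$categories))
  }
  scores <- decision_scores(model, x)
  lapply(seq_len(nrow(scores)), function(i) {
    ord <- order(-scores[i, ], seq_along(model$categories))
    model$categories[ord[seq_len(k)]]
  })
}

#' Save / load a trained model
#'
#' Serialises the model (weights, biases, category order, configuration and
#' any feature-pipeline provenance attached by the caller) to a single RDS
#' file.
#'
#' @param model A \code{linear_ovr} model.
#' @param path File path.
#' @return \code{path} (save) or the model (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "linear_ovr"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "linear_ovr"))
  model
}
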