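make_labels_manifest <- function(labels, specimen = NULL) {
  df <- data.frame(path = sprintf("img%03d.png", seq_along(labels)),
                   label = labels)
  if (!is.null(specimen)) df$specimen_id <- specimen
  as_manifest(df)
}

test_that("stratified folds balance per-category counts to within one", {
  m <- make_labels_manifest(rep(sprintf("t%02d", 1:10), each = 10))
  plan <- stratified_folds(m, k = 10, seed = 2)
  expect_equal(plan$k, 10)
  expect_equal(sort(unique(plan$fold)), 1:10)
  tab <- table(m$label, plan$fold)
  expect_true(all(tab == 1))   # 10 x 10: exactly one per category per fold

  m23 <- make_labels_manifest(c(rep("big", 23), rep("other", 40)))
  p23 <- stratified_folds(m23, k = 10, seed = 3)
  counts <- table(factor(p23$fold[m23$label == "big"], levels = 1:10))
  expect_true(all(counts %in% c(2, 3)))
  expect_identical(stratified_folds(m23, 10, 5)$fold,
                   stratified_folds(m23, 10, 5)$fold)
  expect_warning(stratified_folds(make_labels_manifest(c(rep("a", 3), rep("b", 20))),
                                  k = 10, seed = 1),
                 "below k")
})

test_that("grouped folds never split a specimen and balance specimens", {
  labels <- rep(sprintf("t%d", 1:2), each = 40)
  specimen <- paste0(labels, "_s", rep(rep(1:10, each = 4), 2))
  m <- make_labels_manifest(labels, specimen)
  plan <- grouped_folds(m, k = 5, seed = 4)
  # all images of one specimen share a fold
  by_spec <- tapply(plan$fold, m$specimen_id, function(f) length(unique(f)))
  expect_true(all(by_spec == 1))
  # no train/test specimen leakage in any split
  for (f in 1:5) {
    expect_length(intersect(m$specimen_id[plan$fold == f],
                            m$specimen_id[plan$fold != f]), 0)
  }
  # 10 specimens per category over 5 folds: 2 per fold
  spec_fold <- tapply(plan$fold, m$specimen_id, unique)
  spec_cat <- tapply(m$label, m$specimen_id, unique)
  expect_true(all(table(spec_cat, spec_fold) == 2))
  expect_error(grouped_folds(make_labels_manifest(c("a", "a", "b", "b")), 2),
               "usage error")
})

test_that("cross-validation: oracle features give perfect pooled accuracy", {
  labels <- rep(c("a", "b", "c"), each = 9)
  x <- diag(3)[match(labels, c("a", "b", "c")), ]   # one-hot label encoding
  m <- make_labels_manifest(labels)
  plan <- stratified_folds(m, k = 3, seed = 1)
  rep_ <- cross_validate(x, labels, plan)
  expect_equal(rep_$accuracy, 1)
  expect_equal(rep_$error_rate, 0)
  expect_true(all(rep_$per_fold == 1))
  expect_true(all(diag(rep_$confusion) == 9))
})

test_that("accuracy is the exact hand-counted fraction of matching labels", {
  labels <- rep(c("a", "b", "c", "d"), each = 12)
  x <- diag(4)[match(labels, c("a", "b", "c", "d")), ]
  # corrupt three category-a samples to the codes of b, c and d: with eleven
  # clean examples per category the corrupted points cannot flip training,
  # so exactly those three predictions are wrong, by hand count 45 of 48
  x[1, ] <- diag(4)[2, ]; x[2, ] <- diag(4)[3, ]; x[3, ] <- diag(4)[4, ]
  m <- make_labels_manifest(labels)
  plan <- stratified_folds(m, k = 4, seed = 2)
  rep_ <- cross_validate(x, labels, plan)
  expect_equal(rep_$predictions$predicted[1:3], c("b", "c", "d"))
  expect_true(all((rep_$predictions$truth ==
                     rep_$predictions$predicted)[-(1:3)]))
  expect_equal(rep_$accuracy, 45 / 48)
  expect_equal(rep_$error_rate, 3 / 48)
  # pooled accuracy equals a recount from the confusion table
  expect_equal(rep_$accuracy, sum(diag(rep_$confusion)) / sum(rep_$confusion))
  # and from the prediction table
  expect_equal(rep_$accuracy,
               mean(rep_$predictions$truth == rep_$predictions$predicted))
})

test_that("top-k correctness is monotone and consistent with ranks", {
  ts <- generate_feature_testset(n = 80, d = 4, k = 4, separation = 1.2,
                                 seed = 7)
  m <- make_labels_manifest(ts$labels)
  plan <- stratified_folds(m, k = 5, seed = 3)
  rep_ <- cross_validate(ts$features, ts$labels, plan)
  tk <- rep_$top_k_cumulative
  expect_true(all(diff(tk) >= 0))
  expect_equal(unname(tk[1]), rep_$accuracy)
  expect_equal(unname(cumsum(rep_$top_k_per_rank)), unname(tk))
})

test_that("report is invariant to record order under a fixed fold plan", {
  ts <- generate_feature_testset(n = 60, d = 3, k = 3, separation = 2, seed = 8)
  m <- make_labels_manifest(ts$labels)
  plan <- stratified_folds(m, k = 4, seed = 9)
  r1 <- cross_validate(ts$features, ts$labels, plan)
  perm <- sample(60)
  plan2 <- plan; plan2$fold <- plan$fold[perm]
  r2 <- cross_validate(ts$features[perm, ], ts$labels[perm], plan2)
  expect_equal(r2$accuracy, r1$accuracy)
  expect_equal(r2$confusion, r1$confusion)
})

test_that("a training split missing a category is recorded, fold still scored", {
  labels <- c(rep("a", 6), rep("b", 6), rep("rare", 2))
  x <- cbind(diag(3)[match(labels, c("a", "b", "rare")), ], rnorm(14, sd = .1))
  m <- make_labels_manifest(labels)
  plan <- suppressWarnings(stratified_folds(m, k = 2, seed = 1))
  # force both rare images into fold 1 so fold-1 training never sees "rare"
  plan$fold[labels == "rare"] <- 1L
  rep_ <- cross_validate(x, labels, plan)
  expect_true("rare" %in% rep_$missing_in_training$category)
  expect_false(anyNA(rep_$per_fold))
})

test_that("per-category table recounts the confusion matrix; subgroup roll-up works", {
  labels <- rep(c("a", "b"), each = 10)
  x <- diag(2)[match(labels, c("a", "b")), ]
  x[1, ] <- c(0, 1)    # one "a" miscoded
  m <- make_labels_manifest(labels)
  m$genus <- rep(c("g1", "g2"), 10)
  plan <- stratified_folds(m, k = 5, seed = 4)
  rep_ <- cross_validate(x, labels, plan)
  tab <- accuracy_by_category(rep_)
  expect_equal(tab$n_images, c(10, 10))
  expect_equal(sum(tab$n_images), rep_$n)
  recount <- vapply(tab$category, function(cat) {
    rep_$confusion[cat, cat] / sum(rep_$confusion[cat, ])
  }, numeric(1))
  expect_equal(tab$accuracy, unname(recount))
  sub <- accuracy_by_category(rep_, m, by = "genus")
  expect_equal(sum(sub$n_images), 20)
  expect_equal(nrow(sub), 2)
})

test_that("t-SNE embedding: shape, determinism, and cluster preservation", {
  ts <- generate_feature_testset(n = 60, d = 10, k = 2, separation = 25,
                                 seed = 11)
  y1 <- tsne_embed(ts$features, seed = 3)
  expect_equal(dim(y1), c(60, 2))
  expect_identical(y1, tsne_embed(ts$features, seed = 3))
  expect_false(identical(y1, tsne_embed(ts$features, seed = 4)))
  # far-separated clouds stay separated: nearest-neighbour label purity
  d <- as.matrix(dist(y1)); diag(d) <- Inf
  nn <- apply(d, 1, which.min)
  expect_gt(mean(ts$labels[nn] == ts$labels), 0.9)
  expect_error(tsne_embed(matrix(0, 3, 2)), "at least 5")
})
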