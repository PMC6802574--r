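test_that("global pooling: hand cases and constant invariance", {
  fm <- array(7, c(5, 5, 3))
  expect_equal(global_pool(fm, "average"), rep(7, 3))
  expect_equal(global_pool(fm, "max"), rep(7, 3))
  toy <- array(c(1, 3, 2, 4), c(2, 2, 1))   # [[1,2],[3,4]] row-major
  expect_equal(global_pool(toy, "average"), 2.5)
  expect_equal(global_pool(toy, "max"), 4)
})

test_that("pooling operators equal the brute-force window loop on random volumes", {
  set.seed(99)
  for (rep in 1:30) {
    fm <- random_volume(28, 2)
    for (n in c(2, 4, 7, 14)) {
      for (mode in c("average", "max")) {
        expect_equal(spatial_pool(fm, n, mode), brute_pool(fm, n, mode),
                     tolerance = 1e-9)
      }
    }
    fm2 <- random_volume(4, 2)
    expect_equal(avg_pool2(fm2), brute_pool(fm2, 2, "average"),
                 tolerance = 1e-9)
    expect_equal(global_pool(fm2, "average"),
                 as.vector(brute_pool(fm2, 1, "average")), tolerance = 1e-9)
    expect_equal(global_pool(fm2, "max"),
                 as.vector(brute_pool(fm2, 1, "max")), tolerance = 1e-9)
  }
})

test_that("2x2 average halving: checkerboard and identity-side behaviour", {
  side <- 52
  cb <- array(outer(1:side, 1:side, function(i, j) (i + j) %% 2), c(side, side, 1))
  expect_true(all(avg_pool2(cb) == 0.5))
  expect_error(avg_pool2(random_volume(5, 1)), "even")
})

test_that("alignment to the reference side: c3 halved, c4/c5 unchanged", {
  c3 <- deepident:::feature_matrix(random_volume(52, 2), "c3", "post_pool")
  a <- align_to_reference(c3)
  expect_equal(dim(a), c(26, 26, 2))
  expect_equal(unclass(a)[1, 1, ], apply(c3[1:2, 1:2, , drop = FALSE], 3, mean))
  c4 <- deepident:::feature_matrix(random_volume(26, 2), "c4", "post_pool")
  expect_identical(align_to_reference(c4), c4)
  expect_error(align_to_reference(random_volume(13, 1), 26), "geometry error")
})

test_that("zero border padding preserves interior, border and total sum", {
  fm <- random_volume(26, 3)
  p <- pad_border(fm)
  expect_equal(dim(p), c(28, 28, 3))
  expect_equal(unclass(p)[2:27, 2:27, ], fm)
  expect_equal(sum(p[c(1, 28), , ]) + sum(p[2:27, c(1, 28), ]), 0)
  expect_equal(sum(p), sum(fm))
})

test_that("flatten order is fixed, row-major with filter fastest, and invertible", {
  fm <- array(seq_len(2 * 2 * 3), c(2, 2, 3))
  v <- flatten_features(fm)
  # position (1,1) filters, then (1,2), then (2,1), then (2,2)
  expect_equal(v[1:3], fm[1, 1, ])
  expect_equal(v[4:6], fm[1, 2, ])
  expect_equal(v[7:9], fm[2, 1, ])
  expect_equal(unflatten_features(v, dim(fm)), fm)
  expect_equal(flatten_features(array(5:7, c(1, 1, 3))), 5:7)
  expect_equal(length(flatten_features(random_volume(7, 512))), 25088)
})

test_that("fusion concatenates in order with additive length", {
  v1 <- rnorm(256); v2 <- rnorm(512)
  expect_equal(length(fuse_features(list(v1, v2))), 768)
  expect_equal(fuse_features(list(v1, v2)), c(v1, v2))
  expect_equal(fuse_features(list(v1)), v1)
  depths <- backbone_spec()$filters_per_block
  vs <- lapply(depths, function(f) rnorm(f))
  expect_equal(length(fuse_features(vs)), sum(depths))
})

test_that("normalisation identities and degenerate conventions", {
  expect_equal(signed_sqrt(c(4, -9, 0)), c(2, -3, 0))
  expect_equal(signed_sqrt(rep(0, 5)), rep(0, 5))
  v <- rnorm(100)
  expect_equal(sign(signed_sqrt(v)), sign(v))
  expect_equal(l2_normalize(c(3, 4)), c(0.6, 0.8))
  expect_equal(l2_normalize(rep(0, 4)), rep(0, 4))
  for (i in 1:5) expect_equal(sqrt(sum(l2_normalize(rnorm(20))^2)), 1)
})

test_that("average pooling commutes with positive scaling; max with monotone maps", {
  fm <- random_volume(28, 2)
  expect_equal(spatial_pool(fm * 3.5, 7, "average"),
               spatial_pool(fm, 7, "average") * 3.5, tolerance = 1e-12)
  expect_equal(spatial_pool(exp(fm), 4, "max"),
               exp(spatial_pool(fm, 4, "max")), tolerance = 1e-12)
  expect_error(spatial_pool(fm, 5), "config error")
})

test_that("feature_vector: global path, intermediate path, and N=1 semantics", {
  c3 <- deepident:::feature_matrix(random_volume(8, 4), "c3", "post_pool")
  c4 <- deepident:::feature_matrix(random_volume(4, 6), "c4", "post_pool")
  fms <- list(c3 = c3, c4 = c4)
  v <- feature_vector(fms, level = 1, mode = "average", use_signed_sqrt = FALSE)
  # N=1 pools the raw (unpadded, unaligned) matrices
  expect_equal(as.vector(v), c(global_pool(c3, "average"),
                               global_pool(c4, "average")))
  # intermediate path: align c3 to 4, pad to 6, pool to 2x2
  v2 <- feature_vector(fms, level = 2, mode = "average",
                       use_signed_sqrt = FALSE)
  expect_length(v2, 2 * 2 * 4 + 2 * 2 * 6)
  want_c3 <- flatten_features(spatial_pool(pad_border(avg_pool2(c3)), 2,
                                           "average"))
  expect_equal(as.vector(v2)[1:16], want_c3)
  # level equal to the padded side means flatten with no spatial reduction
  v3 <- feature_vector(list(c4 = c4), level = 6, use_signed_sqrt = FALSE)
  expect_length(v3, 6 * 6 * 6)
  # signed sqrt applied once, after fusion
  v4 <- feature_vector(fms, level = 1, use_signed_sqrt = TRUE)
  expect_equal(as.vector(v4), signed_sqrt(as.vector(v)))
  expect_equal(attr(v4, "provenance")$blocks, c("c3", "c4"))
})
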