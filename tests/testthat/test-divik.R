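make_blobs <- function(n_per, centers, sd = 1, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
      rep(centers[i, ], each = n_per)
  }))
}

test_that("feature filtering keeps the informative mode", {
  set.seed(3)
  m <- cbind(matrix(rnorm(200 * 90, sd = 1), 200),
             matrix(rnorm(200 * 10, sd = 10), 200))
  expect_identical(filter_features(m, "none"), 1:100)
  sel <- filter_features(m, "variance_gmm")
  expect_setequal(sel, 91:100)
  const <- matrix(1, 50, 20)
  expect_warning(sel_const <- filter_features(const, "variance_gmm"),
                 "keeping all")
  expect_identical(sel_const, 1:20)
  # amplitude filter keeps high-mean features
  m2 <- cbind(matrix(rnorm(200 * 50, mean = 1000, sd = 1), 200),
              matrix(rnorm(200 * 50, mean = 1, sd = 1), 200))
  expect_setequal(filter_features(abs(m2), "amplitude_gmm"), 1:50)
})

test_that("choose_k finds planted cluster counts under both distances", {
  params_e <- divik_params(k_max = 5L, distance = "euclidean",
                           min_split_size = 10L, seed = 4L)
  # two well-separated blobs: separation 10 x blob SD
  x2 <- make_blobs(60, rbind(c(0, 0, 0), c(10, 10, 10)), sd = 1, seed = 5)
  res2 <- choose_k(x2, params_e)
  expect_equal(res2$k_best, 2L)
  # three orthogonal-profile populations under correlation distance
  params_c <- divik_params(k_max = 6L, distance = "correlation",
                           min_split_size = 10L, seed = 4L)
  protos <- rbind(c(10, 1, 1, 1, 10, 1), c(1, 10, 1, 10, 1, 1),
                  c(1, 1, 10, 1, 1, 10))
  x3 <- do.call(rbind, lapply(1:3, function(i) {
    matrix(rep(protos[i, ], each = 50), 50) + abs(matrix(rnorm(300, sd = .3), 50))
  }))
  res3 <- choose_k(x3, params_c)
  expect_equal(res3$k_best, 3L)
  truth <- rep(1:3, each = 50)
  expect_equal(adjusted_rand_index(res3$labels, truth), 1)
  # identical rows -> no structure
  expect_null(choose_k(matrix(1, 30, 4), params_e))
})

test_that("GAP decision accepts real splits and rejects single blobs", {
  # node sizes at or above the default min_split_size; 5 features
  hit_one <- 0L; hit_two <- 0L
  for (s in 1:20) {
    p1 <- divik_params(distance = "euclidean", min_split_size = 20L, seed = s)
    one <- make_blobs(300, matrix(0, 1, 5), sd = 1, seed = s + 100)
    c1 <- choose_k(one, p1)
    if (!should_split(one, c1, p1, seed = s)) hit_one <- hit_one + 1L
    two <- make_blobs(150, rbind(rep(0, 5), rep(10, 5)), sd = 1, seed = s + 200)
    c2 <- choose_k(two, p1)
    if (should_split(two, c2, p1, seed = s)) hit_two <- hit_two + 1L
  }
  expect_gte(hit_one, 18L)  # >= 0.9 frequency
  expect_gte(hit_two, 18L)
})

test_that("divik recovers planted structure and respects stop rules", {
  centers <- rbind(c(0, 0, 8, 0), c(8, 0, 0, 0), c(0, 8, 0, 8))
  x <- make_blobs(120, centers, sd = 1, seed = 7) + 10
  truth <- rep(1:3, each = 120)
  params <- divik_params(k_max = 5L, distance = "euclidean",
                         feature_filter = "none", min_split_size = 30L,
                         max_depth = 1L, seed = 11L)
  tree <- divik(x, params)
  l1 <- labels_at_level(tree, 1L)
  expect_gte(adjusted_rand_index(l1$labels, truth), 0.9)

  # homogeneous data: GAP rejects, K = 1
  set.seed(40)
  noise <- matrix(rnorm(300 * 5), 300)
  tree0 <- divik(noise, divik_params(distance = "euclidean",
                                     feature_filter = "none",
                                     min_split_size = 30L, seed = 2L))
  expect_equal(labels_at_level(tree0, 1L)$k, 1L)

  # determinism
  tree_b <- divik(x, params)
  expect_identical(tree$leaf_id, tree_b$leaf_id)

  # nodes smaller than min_split_size are never split
  small <- divik(x[1:25, ], params)
  expect_equal(labels_at_level(small, 1L)$k, 1L)

  expect_error(divik(matrix(numeric(0), 0, 3), params), "empty")
})

test_that("deeper levels refine shallower ones and order is irrelevant", {
  centers <- rbind(c(0, 0), c(12, 0), c(0, 12), c(12, 12))
  x <- make_blobs(80, centers, sd = 1, seed = 9)
  params <- divik_params(k_max = 6L, distance = "euclidean",
                         feature_filter = "none", min_split_size = 20L,
                         max_depth = 2L, seed = 3L)
  tree <- divik(x, params)
  l1 <- labels_at_level(tree, 1L)$labels
  l2 <- labels_at_level(tree, 2L)$labels
  # refinement: every level-2 cluster sits inside one level-1 cluster
  expect_true(all(tapply(l1, l2, function(v) length(unique(v))) == 1L))
  expect_gte(labels_at_level(tree, 2L)$k, labels_at_level(tree, 1L)$k)

  # permutation invariance up to renaming
  perm <- sample(nrow(x))
  tree_p <- divik(x[perm, ], params)
  expect_equal(adjusted_rand_index(tree_p$leaf_id, tree$leaf_id[perm]), 1)
})

test_that("label truncation and level flattening follow path semantics", {
  expect_equal(truncate_label("2.1.3", 2L), "2.1")
  expect_equal(truncate_label("2.1.3", 5L), "2.1.3")  # persistence
  fake <- structure(list(leaf_id = c("1.1", "1.2", "2"), n_pixels = 3L,
                         max_depth = 3L), class = "segmentation_tree")
  expect_equal(labels_at_level(fake, 1L)$labels, c("1", "1", "2"))
  expect_equal(labels_at_level(fake, 2L)$labels, c("1.1", "1.2", "2"))
  expect_equal(labels_at_level(fake, 3L)$labels, c("1.1", "1.2", "2"))
  expect_error(labels_at_level(fake, 4L), "level")
})
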