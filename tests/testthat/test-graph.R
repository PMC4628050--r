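test_that("edge weights follow the chosen dissimilarity mode", {
  img <- gray_image(matrix(c(40L, 100L, 7L, 7L), 2, 2))
  expect_equal(edge_weight(c(1, 1), c(1, 2), img), 60 - 27) # |40 - 7|
  expect_equal(edge_weight(c(1, 1), c(2, 1), img), 60)
  expect_equal(edge_weight(c(2, 2), c(1, 2), img), 0)
  expect_equal(edge_weight(c(1, 1), c(1, 2), img, "spatial_literal"), 1)
  expect_equal(edge_weight(c(1, 1), c(2, 2), img, "spatial_literal"), sqrt(2))
  expect_error(edge_weight(c(1, 1), c(1, 3), img), "neighbors")
})

test_that("graph has the exact edge count for each connectivity", {
  img <- gray_image(matrix(0:8, 3, 3))
  expect_equal(nrow(build_graph(img, 4)$edges), 12)
  expect_equal(nrow(build_graph(img, 8)$edges), 20)
  expect_equal(nrow(build_graph(gray_image(matrix(5L, 1, 1)), 8)$edges), 0)
  set.seed(9)
  for (rep in 1:5) {
    h <- sample(1:7, 1); w <- sample(1:7, 1)
    img <- random_gray_image(h, w)
    expect_equal(nrow(build_graph(img, 4)$edges), h * (w - 1) + w * (h - 1))
    expect_equal(nrow(build_graph(img, 8)$edges),
                 h * (w - 1) + w * (h - 1) + 2 * (h - 1) * (w - 1))
    e <- build_graph(img, 8)$edges
    expect_true(all(e$i < e$j))
    expect_false(any(duplicated(e[, c("i", "j")])))
    expect_true(all(e$w >= 0))
  }
})

test_that("edges sort ascending with deterministic tie-breaking", {
  img <- gray_image(matrix(c(0L, 0L, 0L, 0L), 2, 2))
  g <- sort_edges(build_graph(img, 4))
  # all weights equal: (i, j)-lexicographic order
  expect_true(all(diff(g$edges$i) >= 0))
  img2 <- gray_image(matrix(c(0L, 3L, 1L, 2L), 2, 2))
  g2 <- sort_edges(build_graph(img2, 4))
  expect_true(all(diff(g2$edges$w) >= 0))
})

test_that("merge criterion reproduces hand-computed decisions", {
  # two singletons: DT = k_scale, so any w <= k merges
  expect_true(merge_criterion(0, 0, 1, 1, w_current = 5, k_scale = 8))
  expect_false(merge_criterion(0, 0, 1, 1, w_current = 9, k_scale = 8))
  # DT = min(1 + 8/4, 0 + 8/1) = 3 < 5
  expect_false(merge_criterion(1, 0, 4, 1, w_current = 5, k_scale = 8))
  # zero-weight edges always merge
  expect_true(merge_criterion(0, 0, 10, 20, w_current = 0, k_scale = 0))
})

test_that("segmentation partitions the image and matches the replay oracle", {
  set.seed(10)
  for (rep in 1:60) {
    img <- random_gray_image(5, 5, levels = 0:40)
    k <- stats::runif(1, 0, 200)
    conn <- sample(c(4L, 8L), 1)
    seg <- segment(img, connectivity = conn, k_scale = k, min_size = 1)
    expect_equal(sum(seg$region_table$size), 25)
    expect_true(all(sort(unique(as.vector(seg$labels))) ==
                      seq_len(nrow(seg$region_table))))
    oracle <- oracle_replay(img, conn, k)
    expect_identical(canon_rowmajor(seg$labels), canon_rowmajor(oracle))
  }
})

test_that("limit scales give constant-intensity components and one region", {
  set.seed(11)
  for (rep in 1:10) {
    img <- random_gray_image(8, 8, levels = 0:4)
    seg0 <- segment(img, k_scale = 0, min_size = 1)
    ref <- bfs_constant_components(img$pixels, 8L)
    expect_identical(canon_rowmajor(seg0$labels), canon_rowmajor(ref))
    seg_inf <- segment(img, k_scale = 1e9, min_size = 1)
    expect_equal(nrow(seg_inf$region_table), 1)
  }
  # constant image: a single region at any scale
  seg_c <- segment(gray_image(matrix(42L, 6, 6)))
  expect_equal(nrow(seg_c$region_table), 1)
})

test_that("region count is non-increasing in the merge scale", {
  set.seed(12)
  for (rep in 1:8) {
    img <- random_gray_image(10, 10, levels = 0:60)
    counts <- sapply(c(0, 5, 20, 80, 320),
                     function(k) nrow(segment(img, k_scale = k,
                                              min_size = 1)$region_table))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("two constant halves separate at a small scale", {
  px <- cbind(matrix(10L, 8, 4), matrix(110L, 8, 4))
  seg <- segment(gray_image(px), k_scale = 1, min_size = 1)
  expect_equal(nrow(seg$region_table), 2)
  expect_identical(seg$labels[, 1:4], matrix(1L, 8, 4))
  expect_identical(seg$labels[, 5:8], matrix(2L, 8, 4))
})

test_that("segmentation is bit-for-bit deterministic", {
  set.seed(13)
  img <- random_gray_image(20, 20)
  a <- segment(img)
  b <- segment(img)
  expect_identical(a$labels, b$labels)
  expect_identical(a$region_table, b$region_table)
  expect_identical(a$k_scale, b$k_scale)
})

test_that("min_size cleanup leaves no undersized region", {
  set.seed(14)
  img <- random_gray_image(16, 16)
  seg <- segment(img, min_size = 10)
  expect_true(all(seg$region_table$size >= 10))
})
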