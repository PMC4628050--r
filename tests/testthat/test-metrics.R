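test_that("MSE and PSNR follow their closed forms", {
  a <- gray_image(matrix(100L, 4, 4))
  expect_equal(mse_psnr(a, a), list(mse = 0, psnr = Inf))
  b <- gray_image(matrix(101L, 4, 4))
  r <- mse_psnr(a, b)
  expect_equal(r$mse, 1)
  expect_equal(r$psnr, 20 * log10(255))
  z <- gray_image(matrix(0L, 2, 2))
  f <- gray_image(matrix(255L, 2, 2))
  expect_equal(mse_psnr(z, f), list(mse = 255^2, psnr = 0))
  expect_error(mse_psnr(a, gray_image(matrix(0L, 2, 8))), "shape")
})

test_that("NSD and ENL use the population convention", {
  img <- gray_image(matrix(c(0L, 0L, 2L, 2L), 2, 2))
  r <- nsd_enl(img, matrix(TRUE, 2, 2))
  expect_equal(r$nsd, 1)
  expect_equal(r$enl, 1)
  expect_equal(nsd_enl(gray_image(matrix(9L, 3, 3)), matrix(TRUE, 3, 3)),
               list(nsd = 0, enl = Inf))
  # intensity scaling: nsd scales, enl is invariant
  img2 <- gray_image(matrix(c(0L, 0L, 6L, 6L), 2, 2))
  r2 <- nsd_enl(img2, matrix(TRUE, 2, 2))
  expect_equal(r2$nsd, 3 * r$nsd)
  expect_equal(r2$enl, r$enl)
  expect_error(nsd_enl(img, matrix(FALSE, 2, 2)), "empty")
})

test_that("fuzziness measures vanish iff crisp and peak at P = 0.5", {
  crisp <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(index_of_fuzziness(crisp), 0)
  expect_equal(fuzzy_entropy(crisp), 0)
  half <- matrix(0.5, 2, 2)
  expect_equal(index_of_fuzziness(half), 1)
  expect_equal(fuzzy_entropy(half), 1)
  expect_equal(index_of_fuzziness(matrix(0.25, 2, 2)), 0.5)
  expect_equal(fuzzy_entropy(matrix(c(0.5, 0), 1, 2)), 0.5)
  set.seed(20)
  p <- matrix(runif(64), 8, 8)
  expect_true(index_of_fuzziness(p) > 0 && index_of_fuzziness(p) < 1)
  expect_true(fuzzy_entropy(p) > 0 && fuzzy_entropy(p) < 1)
})

test_that("target-to-background contrast behaves as specified", {
  px <- matrix(c(rep(c(0L, 4L), 8), rep(c(0L, 4L), 8)), 4, 8)
  target <- cbind(matrix(TRUE, 4, 4), matrix(FALSE, 4, 4))
  r <- target_background_contrast(gray_image(px), target)
  expect_equal(r$tbc_std, 0) # identically distributed halves
  expect_equal(r$tbc_entropy, 0)

  px2 <- cbind(matrix(200L, 4, 4), matrix(100L, 4, 4))
  r2 <- target_background_contrast(gray_image(px2), target)
  expect_equal(r2$tbc_std, 1e12) # zero-sigma sentinel cap
  expect_equal(r2$tbc_entropy, 0) # both entropies are zero

  # doubling the mean separation doubles the std-based measure
  mk <- function(hi) {
    v <- cbind(matrix(c(hi, hi + 2L), 4, 4), matrix(c(0L, 2L), 4, 4))
    target_background_contrast(gray_image(v), target)$tbc_std
  }
  expect_equal(mk(40L) / mk(20L), 2, tolerance = 1e-9)
  expect_error(target_background_contrast(gray_image(px2),
                                          matrix(TRUE, 4, 8)), "non-empty")
})

test_that("local refinement error is zero under refinement and asymmetric", {
  a <- matrix(c(1, 1, 2, 3), 2, 2)
  expect_equal(local_refinement_error(a, a)$mean, 0)
  set.seed(21)
  lab <- matrix(sample(1:5, 36, replace = TRUE), 6, 6)
  expect_equal(local_refinement_error(lab, lab)$mean, 0)
  # A strictly refines B
  b <- matrix(1, 6, 6)
  expect_equal(local_refinement_error(lab, b)$mean, 0)
  expect_true(local_refinement_error(b, lab)$mean > 0)
  # region {p, q} in A against {p} in B: error 1/2 at p
  a2 <- matrix(c(1, 1), 1, 2)
  b2 <- matrix(c(1, 2), 1, 2)
  expect_equal(local_refinement_error(a2, b2)$per_pixel[1, 1], 0.5)
})

test_that("overlap acceptance is IoU against the inclusive threshold", {
  m <- matrix(FALSE, 4, 4)
  m[1:2, 1:2] <- TRUE
  expect_true(overlap_accept(m, m))
  d <- matrix(FALSE, 4, 4); d[3:4, 3:4] <- TRUE
  expect_false(overlap_accept(m, d))
  expect_equal(attr(overlap_accept(m, d), "iou"), 0)
  # |A & B| = 3, |A | B| = 4: exactly 0.75 is accepted
  a <- matrix(FALSE, 2, 2); a[c(1, 2, 3)] <- TRUE
  b <- matrix(FALSE, 2, 2); b[c(1, 2, 4)] <- TRUE
  expect_equal(region_iou(a, b), 0.5)
  a2 <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  b2 <- matrix(TRUE, 2, 2)
  expect_equal(region_iou(a2, b2), 0.75)
  expect_true(overlap_accept(a2, b2, k = 0.75))
  expect_equal(region_dice(a2, b2), 6 / 7)
})

test_that("boundary edgels match to the published toy example", {
  a <- rbind(c(1, 1), c(1, 6))
  b <- rbind(c(1, 2))
  r <- edgel_match_f(a, b, d_max = 2)
  expect_equal(r$precision, 0.5)
  expect_equal(r$recall, 1)
  expect_equal(r$f_measure, 2 / 3)
  expect_equal(r$n_matched, 1L)

  m <- matrix(FALSE, 8, 8); m[3:6, 3:6] <- TRUE
  same <- edgel_match_f(m, m)
  expect_equal(same$precision, 1)
  expect_equal(same$recall, 1)
  expect_equal(same$f_measure, 1)
  expect_equal(same$mean_match_distance, 0)

  far_a <- matrix(FALSE, 12, 12); far_a[1:2, 1:2] <- TRUE
  far_b <- matrix(FALSE, 12, 12); far_b[10:12, 10:12] <- TRUE
  expect_equal(edgel_match_f(far_a, far_b, d_max = 2)$f_measure, 0)

  expect_warning(r0 <- edgel_match_f(matrix(FALSE, 3, 3), m[1:3, 1:3]),
                 "empty")
  expect_equal(r0$f_measure, 0)
})

test_that("assignment solver is exact against exhaustive enumeration", {
  set.seed(22)
  for (rep in 1:30) {
    nl <- sample(1:4, 1); nr <- sample(1:4, 1)
    npair <- sample(1:(nl * nr), 1)
    all_pairs <- expand.grid(l = seq_len(nl), r = seq_len(nr))
    pick <- all_pairs[sample(nrow(all_pairs), npair), ]
    pairs <- data.frame(l = pick$l, r = pick$r,
                        cost = round(runif(npair, 0, 10), 3))
    adj_r <- split(pairs$r, factor(pairs$l, levels = seq_len(nl)))
    adj_c <- split(pairs$cost, factor(pairs$l, levels = seq_len(nl)))
    got <- mammoseg:::min_cost_max_matching(nl, nr, adj_r, adj_c)
    ref <- brute_matching(pairs, nl, nr)
    expect_equal(sum(got$match_l > 0), ref$cardinality)
    expect_equal(got$total_cost, ref$cost, tolerance = 1e-9)
  }
})

test_that("edgel matching is symmetric up to swapping precision and recall", {
  set.seed(23)
  m1 <- matrix(runif(100) > 0.6, 10, 10)
  m2 <- matrix(runif(100) > 0.6, 10, 10)
  f12 <- suppressWarnings(edgel_match_f(m1, m2))
  f21 <- suppressWarnings(edgel_match_f(m2, m1))
  expect_equal(f12$precision, f21$recall)
  expect_equal(f12$recall, f21$precision)
  expect_equal(f12$f_measure, f21$f_measure)
})

test_that("confusion statistics and their sentinels", {
  r <- confusion_stats(list(tp = 9, fn = 1, tn = 89, fp = 1))
  expect_equal(r$sensitivity, 0.9)
  expect_equal(r$specificity, 89 / 90)
  expect_equal(r$ppv, 0.9)
  expect_equal(r$npv, 89 / 90)
  expect_equal(r$accuracy, 0.98)
  perfect <- confusion_stats(list(tp = 5, fn = 0, tn = 5, fp = 0))
  expect_true(all(unlist(perfect) == 1))
  expect_warning(u <- confusion_stats(list(tp = 0, fn = 0, tn = 5, fp = 5)),
                 "sensitivity")
  expect_true(is.na(u$sensitivity))

  pred <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  truth <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  cc <- confusion_counts(pred, truth)
  expect_equal(unclass(cc), list(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
})

test_that("AUC equals exhaustive pair counting", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(roc_auc(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  set.seed(24)
  for (rep in 1:50) {
    n <- sample(4:30, 1)
    scores <- sample(0:10, n, replace = TRUE)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(labels) || !any(labels)) next
    expect_equal(roc_auc(scores, labels), brute_auc(scores, labels))
  }
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "classes")
})
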