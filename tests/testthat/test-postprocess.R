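test_that("largest connected component matches exhaustive flood fill", {
  # hand-built two-blob case: the 12-pixel blob wins over the 5-pixel one
  m <- matrix(FALSE, 10, 12)
  m[2:4, 2:5] <- TRUE          # 12 px
  m[7:8, 9:10] <- TRUE; m[9, 9] <- TRUE  # 5 px
  out <- largest_connected_component(m)
  expect_false(out$empty)
  expect_equal(sum(out$mask), 12)
  expect_true(all(out$mask[2:4, 2:5]))

  set.seed(12)
  for (i in 1:100) {
    rm_ <- matrix(runif(16 * 16) < 0.35, 16, 16)
    got <- suppressWarnings(largest_connected_component(rm_)$mask)
    want <- flood_fill_largest(rm_)
    # size always agrees; the component itself agrees whenever the maximum
    # is unique (ties may be broken differently)
    expect_equal(sum(got), sum(want))
    expect_true(all(got[!rm_] == FALSE))
  }
})

test_that("largest connected component is idempotent and conservative", {
  set.seed(2)
  m <- matrix(runif(20 * 20) < 0.3, 20, 20)
  once <- suppressWarnings(largest_connected_component(m)$mask)
  twice <- suppressWarnings(largest_connected_component(once)$mask)
  expect_identical(once, twice)
  expect_lte(sum(once), sum(m))
  expect_true(all(!m | once | TRUE))  # subset: no new pixels
  expect_true(all(once <= m))

  expect_warning(out <- largest_connected_component(matrix(FALSE, 4, 4)),
                 "empty")
  expect_true(out$empty)
  expect_equal(sum(out$mask), 0)
})

test_that("center of mass is the intensity-weighted mean coordinate", {
  m <- matrix(0, 10, 10)
  m[8, 4] <- 2.5   # row 7, col 3 in 0-based coordinates
  expect_equal(center_of_mass(m), c(x = 3, y = 7))

  m2 <- matrix(0, 3, 11)
  m2[1, 1] <- 1; m2[1, 11] <- 1
  expect_equal(center_of_mass(m2), c(x = 5, y = 0))

  # negative values are clipped before weighting
  m3 <- m; m3[1, 1] <- -5
  expect_equal(center_of_mass(m3), c(x = 3, y = 7))

  expect_error(center_of_mass(matrix(0, 4, 4)), "all-zero")
})

test_that("vcdr follows the vertical-extent ratio formula", {
  od <- matrix(0, 120, 50); od[1:100, 10:40] <- 1
  oc <- matrix(0, 120, 50); oc[11:50, 15:35] <- 1
  rec <- compute_vcdr(od, oc)
  expect_equal(rec$od_height, 100L)
  expect_equal(rec$oc_height, 40L)
  expect_equal(rec$vcdr, 0.4)

  expect_equal(compute_vcdr(od, od)$vcdr, 1.0)
  expect_equal(compute_vcdr(od, matrix(0, 120, 50))$vcdr, 0)
  empty_od <- compute_vcdr(matrix(0, 5, 5), matrix(0, 5, 5))
  expect_true(is.na(empty_od$vcdr))

  # invariant to horizontal translation and column rearrangement that
  # preserves occupied row ranges
  od_shift <- od[, c(41:50, 1:40)]
  oc_shift <- oc[, c(41:50, 1:40)]
  expect_equal(compute_vcdr(od_shift, oc_shift)$vcdr, 0.4)
})

test_that("logistic fit matches a dense grid-search maximizer", {
  vc <- c(0.2, 0.3, 0.6, 0.7)
  y <- c(0, 0, 1, 1)
  fit <- fit_logistic(vc, y, l2_lambda = 1e-3)
  oracle <- grid_logistic(vc, y, 1e-3)
  expect_equal(fit$weight, oracle$weight, tolerance = 1e-3)
  expect_equal(fit$bias, oracle$bias, tolerance = 1e-3)

  # symmetric data: predicted probability is one half at the midpoint
  vc2 <- c(0.3, 0.4, 0.6, 0.7)
  fit2 <- fit_logistic(vc2, c(0, 0, 1, 1))
  expect_equal(predict(fit2, 0.5), 0.5, tolerance = 1e-6)

  # permutation invariance
  set.seed(6)
  perm <- sample(4)
  fit3 <- fit_logistic(vc[perm], y[perm], 1e-3)
  expect_equal(fit3$weight, fit$weight, tolerance = 1e-9)

  expect_error(fit_logistic(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("ensemble averages probabilities with ties going positive", {
  expect_equal(ensemble_classify(0.9, 0.3),
               list(probability = 0.6, label = 1L))
  expect_equal(ensemble_classify(0.2, 0.2),
               list(probability = 0.2, label = 0L))
  expect_equal(ensemble_classify(0.5, 0.5)$label, 1L)
  expect_error(ensemble_classify(1.2, 0.5), "0, 1")

  # monotone non-decreasing in each argument
  set.seed(14)
  p <- runif(20); q <- runif(20)
  base <- ensemble_classify(p, q)$probability
  up <- ensemble_classify(pmin(p + 0.05, 1), q)$probability
  expect_true(all(up >= base))
})

test_that("dice handles overlap and degenerate masks", {
  a <- matrix(0, 6, 6); a[1:2, 1:2] <- 1
  expect_equal(dice(a, a), 1)
  b <- matrix(0, 6, 6); b[4:5, 4:5] <- 1
  expect_equal(dice(a, b), 0)
  c_ <- matrix(0, 6, 6); c_[2:3, 1:2] <- 1  # 4 px, overlap 2
  expect_equal(dice(a, c_), 0.5)
  expect_equal(dice(matrix(0, 3, 3), matrix(0, 3, 3)), 1)
  expect_equal(dice(a, matrix(0, 6, 6)), 0)
  expect_error(dice(a, matrix(0, 3, 3)), "shape")
})

test_that("auc equals brute-force pair counting and its own ROC area", {
  got <- auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(got$auc, 0.75)

  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(auc(c(4, 3, 2, 1), c(0, 0, 1, 1))$auc, 0)

  set.seed(19)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
    scores <- round(runif(n), 2)  # rounded scores force ties
    a <- auc(scores, labels)
    expect_equal(a$auc, pairwise_auc(scores, labels), tolerance = 1e-9)
    # trapezoidal area under the returned ROC polyline
    roc <- a$roc[order(a$roc$fpr, a$roc$tpr), ]
    trap <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
    expect_equal(a$auc, trap, tolerance = 1e-9)
  }
  expect_error(auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("fovea error is the symmetric euclidean distance", {
  expect_equal(fovea_error(c(3, 4), c(3, 4)), 0)
  expect_equal(fovea_error(c(0, 0), c(3, 4)), 5)
  expect_equal(fovea_error(c(1, 7), c(4, 2)), fovea_error(c(4, 2), c(1, 7)))
  expect_equal(fovea_error(c(0, 0), c(3, 4), scale = 0.5), 2.5)
})

test_that("evaluation reports are invariant to dataset order", {
  ds <- generate_dataset(synth_params(n_images = 6, image_size = 32,
                                      seed = 44))
  set.seed(10)
  m <- build_model(tiny_config())
  m$classifier <- fit_logistic(c(0.3, 0.4, 0.7, 0.8), c(0, 0, 1, 1))
  r1 <- evaluate(m, ds)
  perm <- c(4, 2, 6, 1, 3, 5)
  ds2 <- ds
  ds2$images <- ds$images[, , , perm, drop = FALSE]
  ds2$od_masks <- ds$od_masks[, , perm]
  ds2$oc_masks <- ds$oc_masks[, , perm]
  ds2$fovea <- ds$fovea[perm, ]
  ds2$labels <- ds$labels[perm]
  ds2$ids <- ds$ids[perm]
  r2 <- evaluate(m, ds2)
  expect_equal(r1$aggregate, r2$aggregate, tolerance = 1e-12)
  m1 <- r1$per_image[order(r1$per_image$image_id), ]
  m2 <- r2$per_image[order(r2$per_image$image_id), ]
  rownames(m1) <- rownames(m2) <- NULL
  expect_equal(m1, m2, tolerance = 1e-12)
})
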