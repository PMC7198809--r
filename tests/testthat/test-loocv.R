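test_that("LOOCV produces one fold per subject, each left out once", {
  co <- toy_cohort(n_pat = 4, n_ctl = 4, grid = c(5, 5, 5), seed = 61)
  msk <- build_mask(co, threshold = 0.2)
  folds <- loocv_run(co, msk, k = 10)
  expect_length(folds$folds, 8L)
  expect_identical(vapply(folds$folds, `[[`, character(1), "left_out_subject"),
                   co$subject_ids)
  expect_identical(folds$true_labels, co$labels)
  expect_true(all(vapply(folds$folds, function(f)
    length(f$selected_features), integer(1)) == 10L))
})

test_that("fold statistics never depend on the left-out subject", {
  co <- toy_cohort(n_pat = 5, n_ctl = 5, grid = c(6, 6, 6), seed = 62,
                   noise_sd = 0.05)
  msk <- build_mask(co, threshold = 0.2)
  X <- volumes_to_matrix(co, msk)
  base <- loocv_run(X, k = 15, labels = co$labels)
  p <- 3L
  Xp <- X
  set.seed(63)
  Xp[p, ] <- Xp[p, ] + rnorm(ncol(X), sd = 0.05)  # perturb only the left-out row
  pert <- loocv_run(Xp, k = 15, labels = co$labels)
  expect_identical(pert$folds[[p]]$selected_features,
                   base$folds[[p]]$selected_features)
  expect_equal(pert$folds[[p]]$scaler, base$folds[[p]]$scaler)
  expect_equal(pert$folds[[p]]$w, base$folds[[p]]$w)
  expect_equal(pert$folds[[p]]$b, base$folds[[p]]$b)
  expect_false(isTRUE(all.equal(pert$folds[[p]]$decision_value,
                                base$folds[[p]]$decision_value)))
})

test_that("a strong planted effect is classified perfectly", {
  co <- toy_cohort(n_pat = 6, n_ctl = 6, grid = c(8, 8, 8), delta = -0.2,
                   noise_sd = 0.02, fwhm = 4, seed = 64,
                   effects = list(effect_spec(c(4, 4, 4), 2, -0.2)))
  msk <- build_mask(co, threshold = 0.2)
  folds <- loocv_run(co, msk, k = 20)
  expect_identical(folds$predicted_labels, as.integer(folds$true_labels))
})

test_that("undersized groups and out-of-range k raise the documented errors", {
  co <- toy_cohort(n_pat = 2, n_ctl = 6, grid = c(4, 4, 4), seed = 65)
  msk <- build_mask(co, threshold = 0.2)
  expect_error(loocv_run(co, msk, k = 5), "cohort-size error")
  co2 <- toy_cohort(n_pat = 4, n_ctl = 4, grid = c(4, 4, 4), seed = 66)
  msk2 <- build_mask(co2, threshold = 0.2)
  expect_error(loocv_run(co2, msk2, k = mask_size(msk2) + 1), "parameter error")
})

test_that("the feature-count grid is built and truncated as documented", {
  expect_identical(k_grid(20000, 100), seq.int(100L, 20000L, 100L))
  expect_length(k_grid(20000, 100), 200L)
  expect_identical(k_grid(300, 100), c(100L, 200L, 300L))
  expect_identical(k_grid(1000, 100, m = 567, truncate = TRUE),
                   c(100L, 200L, 300L, 400L, 500L))
  expect_error(k_grid(1000, 100, m = 567, truncate = FALSE), "parameter error")
  expect_error(k_grid(1000, 100, m = 80), "parameter error")
  expect_error(k_grid(50, 100), "parameter error")
})

test_that("sweep metrics equal confusion metrics of the per-k folds", {
  co <- toy_cohort(n_pat = 4, n_ctl = 4, grid = c(7, 7, 7), seed = 67,
                   noise_sd = 0.05)
  msk <- build_mask(co, threshold = 0.2)
  sw <- k_sweep(co, msk, k_max = 300, step = 100)
  expect_identical(sw$k_grid, c(100L, 200L, 300L))
  for (i in seq_along(sw$k_grid)) {
    cm <- confusion_metrics(sw$results[[i]]$true_labels,
                            sw$results[[i]]$predicted_labels)
    expect_identical(sw$metrics$accuracy[i], cm$accuracy)
    expect_identical(sw$metrics$sensitivity[i], cm$sensitivity)
    expect_identical(sw$metrics$specificity[i], cm$specificity)
    expect_length(sw$results[[i]]$folds, 8L)
  }
})

test_that("the plateau-midpoint rule picks the documented optima", {
  ks <- seq.int(100L, 20000L, 100L)
  acc <- rep(0.70, length(ks))
  acc[ks >= 1400 & ks <= 3400] <- 0.8333
  expect_identical(select_optimal_k(data.frame(k = ks, accuracy = acc)), 2400L)
  acc2 <- rep(0.6, length(ks)); acc2[ks == 500] <- 0.9
  expect_identical(select_optimal_k(data.frame(k = ks, accuracy = acc2)), 500L)
  acc3 <- rep(0.6, length(ks)); acc3[ks %in% c(100, 200)] <- 0.9
  expect_identical(select_optimal_k(data.frame(k = ks, accuracy = acc3)), 100L)
  # earliest run wins ties in run length
  acc4 <- rep(0.6, length(ks))
  acc4[ks %in% c(300, 400)] <- 0.9; acc4[ks %in% c(900, 1000)] <- 0.9
  expect_identical(select_optimal_k(data.frame(k = ks, accuracy = acc4)), 300L)
})

test_that("fold weight vectors average by scatter into full feature space", {
  co <- toy_cohort(n_pat = 3, n_ctl = 3, grid = c(4, 4, 4), seed = 68)
  msk <- build_mask(co, threshold = 0.2)
  m <- mask_size(msk)
  mkfold <- function(sel, w) list(left_out_subject = "s", true_label = 1,
                                  decision_value = 0, predicted_label = 1L,
                                  selected_features = sel, w = w, b = 0)
  same <- structure(list(folds = list(mkfold(c(2L, 5L), c(0.4, -0.2)),
                                      mkfold(c(2L, 5L), c(0.4, -0.2)))),
                    class = "loocv_folds")
  map <- average_weight_map(same, msk)
  expect_equal(attr(map, "weights")[c(2, 5)], c(0.4, -0.2))
  expect_equal(sum(attr(map, "weights") != 0), 2)
  mixed <- structure(list(folds = list(mkfold(c(1L, 2L), c(0.3, 0.1)),
                                      mkfold(c(2L, 3L), c(0.2, -0.4)))),
                    class = "loocv_folds")
  wbar <- attr(average_weight_map(mixed, msk), "weights")
  expect_equal(wbar[1], 0.3 / 2)          # selected by one fold of two
  expect_equal(wbar[2], (0.1 + 0.2) / 2)
  expect_equal(wbar[3], -0.4 / 2)
  nanmap <- average_weight_map(same, msk, fill = NaN)
  expect_true(all(is.nan(nanmap$values[-msk$linear_index])))
  bad <- structure(list(folds = list(mkfold(1L, 0.5), mkfold(c(1L, 2L), c(1, 2)))),
                   class = "loocv_folds")
  expect_error(average_weight_map(bad, msk), "dimension error")
})

test_that("patient-lower planted voxels get positive averaged weights", {
  co <- toy_cohort(n_pat = 5, n_ctl = 5, grid = c(6, 6, 6), delta = -0.2,
                   noise_sd = 0.02, seed = 69)
  msk <- build_mask(co, threshold = 0.2)
  folds <- loocv_run(co, msk, k = 20)
  map <- average_weight_map(folds, msk)
  center <- round(c(6, 6, 6) / 2)
  expect_gt(map$values[center[1], center[2], center[3]], 0)
})

test_that("null cohorts show no optimistic max-over-k accuracy", {
  co <- toy_cohort(n_pat = 8, n_ctl = 8, grid = c(8, 8, 8), seed = 70,
                   noise_sd = 0.1, effects = list())
  msk <- build_mask(co, threshold = 0.2)
  sw <- k_sweep(co, msk, k_max = 500, step = 100)
  upper <- 0.5 + 1.96 * sqrt(0.25 / 16)
  expect_lte(max(sw$metrics$accuracy), upper)
})
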