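test_that("confusion metrics reproduce the printed worked example", {
  truth <- c(rep(-1, 22), rep(1, 26))
  predicted <- c(rep(-1, 17), rep(1, 5),    # 17 of 22 patients detected
                 rep(1, 23), rep(-1, 3))    # 23 of 26 controls cleared
  cm <- confusion_metrics(truth, predicted)
  expect_equal(cm$accuracy, 40 / 48)
  expect_equal(round(100 * cm$accuracy, 2), 83.33)
  expect_equal(round(100 * cm$sensitivity, 2), 77.27)
  expect_equal(round(100 * cm$specificity, 2), 88.46)
  perfect <- confusion_metrics(truth, truth)
  expect_equal(c(perfect$accuracy, perfect$sensitivity, perfect$specificity),
               c(1, 1, 1))
})

test_that("confusion counts agree with a brute-force recount under label swaps", {
  set.seed(71)
  truth <- sample(c(-1, 1), 40, replace = TRUE)
  truth[1:2] <- c(-1, 1)
  predicted <- sample(c(-1, 1), 40, replace = TRUE)
  cm <- confusion_metrics(truth, predicted)
  recount <- function(t, p) c(tp = sum(t == -1 & p == -1), fn = sum(t == -1 & p == 1),
                              tn = sum(t == 1 & p == 1), fp = sum(t == 1 & p == -1))
  expect_identical(c(tp = cm$tp, fn = cm$fn, tn = cm$tn, fp = cm$fp),
                   recount(truth, predicted))
  sw <- confusion_metrics(-truth, -predicted)
  expect_identical(sw$tp, cm$tn)  # swapping both labels swaps the roles
  expect_identical(sw$fp, cm$fn)
  expect_equal(sw$accuracy, cm$accuracy)
})

test_that("ROC handles separation, ties and the worked pair example", {
  expect_equal(roc_curve(c(3, 2, -1, -2), c(1, 1, -1, -1))$auc, 1)
  expect_equal(roc_curve(rep(0.5, 6), rep(c(1, -1), 3))$auc, 0.5)
  r <- roc_curve(c(1.0, 0.2, 0.5, -1.0), c(1, 1, -1, -1))
  expect_equal(r$auc, 0.75)  # 3 of the 4 HC-patient pairs ordered correctly
  expect_error(roc_curve(1:3, c(1, 1, 1)), "class error")
})

test_that("trapezoidal AUC equals the pairwise rank statistic", {
  pairwise_auc <- function(values, truth) {
    hc <- values[truth > 0]; pat <- values[truth < 0]
    mean(outer(hc, pat, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(72)
  for (rep in 1:20) {
    n <- sample(6:20, 1)
    truth <- c(rep(1, 3), rep(-1, 3), sample(c(1, -1), n - 6, replace = TRUE))
    values <- round(rnorm(n), sample(0:2, 1))  # rounding forces ties
    expect_equal(roc_curve(values, truth)$auc, pairwise_auc(values, truth),
                 tolerance = 1e-12)
    # invariance under strictly increasing transforms
    expect_equal(roc_curve(exp(values), truth)$auc,
                 roc_curve(values, truth)$auc, tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(73)
  values <- rnorm(30)
  truth <- sample(c(1, -1), 30, replace = TRUE)
  truth[1:2] <- c(1, -1)
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = factor(truth, levels = c(-1, 1)), predictor = values,
    direction = "<", quiet = TRUE)))
  expect_equal(roc_curve(values, truth)$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("the permutation test follows the count/N rule deterministically", {
  co <- toy_cohort(n_pat = 4, n_ctl = 4, grid = c(5, 5, 5), delta = -0.3,
                   noise_sd = 0.02, seed = 74)
  msk <- build_mask(co, threshold = 0.2)
  pt <- permutation_test(co, msk, k = 10, n_perm = 30, seed = 99)
  expect_identical(pt$n_permutations, 30L)
  expect_length(pt$null_accuracies, 30L)
  expect_identical(pt$count_ge, sum(pt$null_accuracies >= pt$observed_accuracy))
  expect_equal(pt$p_value, pt$count_ge / 30)
  expect_equal(pt$p_value_unbiased, (pt$count_ge + 1) / 31)
  expect_gte(pt$p_value, 0); expect_lte(pt$p_value, 1)
  pt2 <- permutation_test(co, msk, k = 10, n_perm = 30, seed = 99)
  expect_identical(pt$null_accuracies, pt2$null_accuracies)
  # strong signal, one weaker permutation: the plug-in rule may return exactly 0
  one <- permutation_test(co, msk, k = 10, n_perm = 1, seed = 7)
  expect_identical(one$p_value,
                   as.numeric(one$null_accuracies[1] >= one$observed_accuracy))
})

test_that("spearman correlation matches the rank formula and edge cases", {
  expect_equal(score_correlation(1:5, c(2, 4, 6, 8, 10))$rho, 1)
  expect_equal(score_correlation(1:5, 5:1)$rho, -1)
  r <- score_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$rho, 0.8)  # 1 - 6*2 / (4*15)
  set.seed(75)
  x <- rnorm(12); y <- rnorm(12)
  d2 <- sum((rank(x) - rank(y))^2)
  expect_equal(score_correlation(x, y)$rho, 1 - 6 * d2 / (12 * (12^2 - 1)),
               tolerance = 1e-12)
  expect_error(score_correlation(rep(1, 5), 1:5), "undefined-correlation")
  expect_error(score_correlation(1:2, 1:2), "dimension error")
})

test_that("patient folds pair with clinical scores through the cohort", {
  co <- toy_cohort(n_pat = 6, n_ctl = 6, grid = c(6, 6, 6), seed = 76)
  msk <- build_mask(co, threshold = 0.2)
  folds <- loocv_run(co, msk, k = 20)
  r <- score_correlation(folds, co)
  expect_identical(r$n, 6L)
  manual <- score_correlation(folds$decision_values[co$labels < 0],
                              co$clinical_scores[co$labels < 0])
  expect_equal(r$rho, manual$rho)
})
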