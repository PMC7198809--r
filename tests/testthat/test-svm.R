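test_that("the hand-solvable 1-D instance is recovered exactly", {
  m <- train_linear_svm(matrix(c(-1, 1), ncol = 1), c(-1, 1), C = 1)
  expect_equal(as.numeric(m$w), 1, tolerance = 1e-8)
  expect_equal(m$b, 0, tolerance = 1e-8)
  expect_equal(m$alphas, c(0.5, 0.5), tolerance = 1e-8)
})

test_that("the scaler computes training-column statistics with an sd floor", {
  sc <- fit_scaler(cbind(c(1, 3)))
  expect_equal(sc$means, 2)
  expect_equal(sc$sds, sqrt(2))
  X <- cbind(a = c(1, 2, 3, 4), b = rep(5, 4))
  sc2 <- fit_scaler(X)
  expect_equal(sc2$sds[2], 1e-8)       # floored constant column
  Z <- apply_scaler(sc2, X)
  expect_equal(colMeans(Z), c(0, 0), ignore_attr = TRUE)
  expect_equal(sd(Z[, 1]), 1)
  expect_equal(Z[, 2], rep(0, 4), ignore_attr = TRUE)
  ident <- structure(list(means = c(0, 0), sds = c(1, 1)),
                     class = "feature_scaler")
  expect_equal(apply_scaler(ident, X), X)
  expect_equal(as.numeric(apply_scaler(sc2, matrix(sc2$means, 1))), c(0, 0))
  expect_error(apply_scaler(sc2, matrix(1, 2, 3)), "dimension error")
  expect_error(fit_scaler(matrix(1, 1, 2)), "dimension error")
})

test_that("SMO matches the brute-force QP oracle on random tiny instances", {
  checked <- 0L
  for (seed in 1:110) {
    n <- c(4:6, 8)[(seed %% 4) + 1]
    k <- (seed %% 3) + 1
    inst <- random_svm_instance(n, k, seed = 1000 + seed)
    C <- c(1, 1, 0.5, 2)[(seed %% 4) + 1]
    model <- train_linear_svm(inst$X, inst$y, C = C)
    oracle <- qp_dual_oracle(inst$X, inst$y, C = C)
    expect_false(is.null(oracle))
    expect_equal(model$objective, oracle$objective, tolerance = 1e-6)
    expect_equal(as.numeric(model$w), oracle$w, tolerance = 1e-6)
    expect_lt(kkt_violation(model), 1e-6)
    expect_equal(sum(model$alphas * model$train_labels), 0, tolerance = 1e-8)
    expect_true(all(model$alphas >= -1e-10 & model$alphas <= C + 1e-10))
    checked <- checked + 1L
  }
  expect_gte(checked, 100L)
})

test_that("the duality gap vanishes at the returned solution", {
  for (seed in 201:205) {
    inst <- random_svm_instance(8, 3, seed = seed)
    model <- train_linear_svm(inst$X, inst$y, C = 1)
    expect_equal(svm_primal_objective(model), model$objective,
                 tolerance = 1e-6)
  }
})

test_that("SMO agrees with an independent libsvm implementation", {
  skip_if_not_installed("e1071")
  for (seed in 301:305) {
    inst <- random_svm_instance(10, 3, seed = seed)
    ours <- train_linear_svm(inst$X, inst$y, C = 1)
    ref <- e1071::svm(inst$X, factor(inst$y), kernel = "linear", cost = 1,
                      scale = FALSE, tolerance = 1e-8)
    w_ref <- drop(crossprod(ref$SV, ref$coefs))
    # e1071 orients by the first factor level; align signs before comparing
    s <- sign(sum(w_ref * ours$w))
    expect_equal(as.numeric(ours$w), unname(s * w_ref), tolerance = 1e-4)
    expect_equal(ours$b, s * -ref$rho, tolerance = 1e-4)
  }
})

test_that("duplicating every training point leaves the separator unchanged", {
  set.seed(31)
  X <- rbind(matrix(rnorm(8, mean = -2), 4, 2), matrix(rnorm(8, mean = 2), 4, 2))
  y <- rep(c(-1, 1), each = 4)
  m1 <- train_linear_svm(X, y, C = 1)
  m2 <- train_linear_svm(rbind(X, X), c(y, y), C = 1)
  expect_equal(as.numeric(m2$w), as.numeric(m1$w), tolerance = 1e-5)
  expect_equal(m2$b, m1$b, tolerance = 1e-5)
})

test_that("primal and dual decision values agree", {
  inst <- random_svm_instance(8, 3, seed = 41)
  model <- train_linear_svm(inst$X, inst$y, C = 1)
  set.seed(42)
  for (rep in 1:5) {
    x <- rnorm(3)
    dual <- sum(model$alphas * model$train_labels *
                  (model$train_inputs %*% x)) + model$b
    expect_equal(decision_value(model, x), dual, tolerance = 1e-8)
  }
  expect_equal(decision_value(model, model$train_inputs),
               drop(model$train_inputs %*% model$w + model$b))
  w2 <- structure(list(w = c(1, -1), b = 0.5, alphas = 1, train_labels = 1,
                       train_inputs = matrix(0, 1, 2), C = 1),
                  class = "linear_svm")
  expect_equal(decision_value(w2, c(2, 1)), 1.5)
  expect_equal(decision_value(structure(list(w = c(1, -1), b = 0), class = "linear_svm"),
                              c(0, 0)), 0)
  expect_error(decision_value(model, c(1, 2)), "dimension error")
})

test_that("the label rule sends zero to the patient group", {
  expect_identical(predict_label(0.7), 1L)
  expect_identical(predict_label(-0.3), -1L)
  expect_identical(predict_label(0), -1L)
  expect_identical(predict_label(c(1, 0, -1)), c(1L, -1L, -1L))
  expect_error(predict_label(NaN), "numeric error")
})

test_that("degenerate SVM inputs are rejected", {
  X <- matrix(rnorm(8), 4, 2)
  expect_error(train_linear_svm(X, rep(1, 4)), "label error")
  expect_error(train_linear_svm(X, c(1, 1, -1, -1), C = 0), "parameter error")
  expect_error(train_linear_svm(X, c(1, -1)), "dimension error")
})

test_that("training is deterministic", {
  inst <- random_svm_instance(10, 3, seed = 51)
  m1 <- train_linear_svm(inst$X, inst$y)
  m2 <- train_linear_svm(inst$X, inst$y)
  expect_identical(m1$alphas, m2$alphas)
  expect_identical(m1$w, m2$w)
  expect_identical(m1$b, m2$b)
})
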