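#' Feature scaler (mean centering + unit-variance normalisation)
#'
#' Fitted on training rows only; the same statistics are then applied to the
#' left-out subject, so no test information leaks into the model.
#' "Normalisation" is z-scoring: each selected feature is divided by its
#' training-sample standard deviation, floored at `1e-8` so within-training
#' constant features map to zero instead of NaN.
#'
#' @param X Training matrix, (n-1) x k.
#' @return An object of class `feature_scaler` with `means` and `sds`.
#' @export
fit_scaler <- function(X) {
  if (!is.matrix(X) || nrow(X) < 2L || ncol(X) < 1L)
    stop("dimension error: need a matrix with >= 2 rows and >= 1 column",
         call. = FALSE)
  means <- colMeans(X)
  n <- nrow(X)
  sds <- sqrt(colSums((X - rep(means, each = n))^2) / (n - 1))
  sds <- pmax(sds, 1e-8)
  structure(list(means = unname(means), sds = unname(sds)),
            class = "feature_scaler")
}

#' @param scaler A `feature_scaler`.
#' @param X Matrix (or single row) with the same column count.
#' @rdname fit_scaler
#' @export
apply_scaler <- function(scaler, X) {
  stopifnot(inherits(scaler, "feature_scaler"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != length(scaler$means))
    stop("dimension error: column count does not match the fitted scaler",
         call. = FALSE)
  n <- nrow(X)
  (X - rep(scaler$means, each = n)) / rep(scaler$sds, each = n)
}

#' Train a soft-margin linear SVM
#'
#' Solves the dual problem
#' `max sum(alpha) - 0.5 * sum_ij alpha_i alpha_j y_i y_j <x_i, x_j>`
#' subject to `0 <= alpha <= C` and `sum(alpha * y) = 0`, by deterministic
#' sequential minimal optimization (maximal-violating-pair selection, no
#' randomised initialisation: identical input yields an identical model).
#' The weight vector is `w = sum_j alpha_j y_j x_j` and the bias is averaged
#' over margin support vectors (`0 < alpha < C`), falling back to the
#' KKT-interval midpoint when every multiplier sits at a bound.
#'
#' The misclassification penalty defaults to `C = 1`, the conventional fixed
#' setting for high-dimensional linear neuroimaging classifiers.
#'
#' @param X Scaled training matrix, one row per subject.
#' @param y Labels in `{+1, -1}` (HC = `+1`, patient = `-1`).
#' @param C Penalty parameter (`> 0`).
#' @param tol Working-set violation tolerance of the solver.
#' @param max_iter Iteration cap; exceeding it raises a convergence error.
#' @return An object of class `linear_svm` with fields `alphas`,
#'   `train_labels`, `train_inputs`, `w`, `b`, `C`, `objective`,
#'   `iterations`.
#' @export
train_linear_svm <- function(X, y, C = 1, tol = 1e-8, max_iter = 200000L) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  y <- as.numeric(y)
  if (length(y) != nrow(X))
    stop("dimension error: one label per training row required", call. = FALSE)
  if (!all(y %in% c(-1, 1)) || length(unique(y)) != 2L)
    stop("label error: need both classes coded +1/-1", call. = FALSE)
  if (!is.numeric(C) || C <= 0) stop("parameter error: C must be > 0", call. = FALSE)
  K <- tcrossprod(X)
  fit <- smo_solve(K, y, C, tol, as.integer(max_iter))
  if (!fit$converged && fit$iterations >= max_iter)
    stop("convergence error: SMO did not converge within the iteration cap",
         call. = FALSE)
  w <- drop(crossprod(X, fit$alpha * y))
  structure(list(alphas = fit$alpha, train_labels = y, train_inputs = X,
                 w = w, b = fit$b, C = C, objective = fit$objective,
                 iterations = fit$iterations),
            class = "linear_svm")
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("<linear_svm> %d features, %d training points, C = %g\n",
              length(x$w), length(x$alphas), x$C))
  cat(sprintf("  support vectors: %d (|alpha| > 1e-8), b = %.4g\n",
              sum(x$alphas > 1e-8), x$b))
  invisible(x)
}

#' SVM decision value
#'
#' `f(x) = <w, x> + b`; identical (within solver tolerance) to the dual form
#' `sum_j alpha_j y_j <x_j, x> + b`.
#'
#' @param model A `linear_svm`.
#' @param x Length-k vector or a matrix with k columns (one value per row).
#' @return Numeric decision value(s).
#' @export
decision_value <- function(model, x) {
  stopifnot(inherits(model, "linear_svm"))
  if (is.null(dim(x))) {
    if (length(x) != length(model$w))
      stop("dimension error: input length does not match the weight vector",
           call. = FALSE)
    return(sum(model$w * x) + model$b)
  }
  if (ncol(x) != length(model$w))
    stop("dimension error: input width does not match the weight vector",
         call. = FALSE)
  drop(x %*% model$w + model$b)
}

#' Label rule for decision values
#'
#' A positive decision value assigns the healthy-control group (`+1`,
#' "label 1"); zero or negative assigns the patient group (`-1`, "label 2") —
#' zero falls to the patient side by the "otherwise" branch of the rule.
#'
#' @param value Numeric decision value(s); must be finite.
#' @return Integer group code(s), `+1` or `-1`.
#' @export
predict_label <- function(value) {
  if (any(!is.finite(value)))
    stop("numeric error: non-finite decision value", call. = FALSE)
  ifelse(value > 0, 1L, -1L)
}

#' @param object A `linear_svm`.
#' @param newdata Matrix (or vector) of already-scaled feature rows.
#' @param type `"label"` for group codes, `"decision"` for raw values.
#' @param ... Unused.
#' @rdname train_linear_svm
#' @export
predict.linear_svm <- function(object, newdata,
                               type = c("label", "decision"), ...) {
  type <- match.arg(type)
  v <- decision_value(object, newdata)
  if (type == "decision") v else predict_label(v)
}
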