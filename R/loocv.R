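#' Nested leave-one-out cross-validation at a fixed feature count
#'
#' For each of the n subjects in turn: the remaining n-1 rows form the
#' training set; Fisher scores, the descending ranking, the top-k selection,
#' the feature scaler and the linear SVM (penalty `C`) are all computed from
#' those training rows only; the left-out row is then scaled with the training
#' statistics and scored. Every fold statistic is therefore a pure function of
#' its n-1 training rows — no test information leaks into ranking, scaling or
#' the model.
#'
#' @param cohort A [fa_cohort()], or an n x m feature matrix (then pass
#'   `labels`).
#' @param mask A [voxel_mask()] (ignored when `cohort` is already a matrix).
#' @param k Number of top-ranked features per fold, `1 <= k <= m`.
#' @param C SVM penalty.
#' @param labels Group codes when `cohort` is a matrix.
#' @return An object of class `loocv_folds`: per-fold records (left-out id,
#'   true/predicted label, decision value, selected feature indices, scaler,
#'   `w`, `b`) plus flat vectors of truths, decision values and predictions.
#' @export
loocv_run <- function(cohort, mask = NULL, k, C = 1, labels = NULL) {
  if (inherits(cohort, "fa_cohort")) {
    X <- volumes_to_matrix(cohort, mask)
    y <- cohort$labels
    ids <- cohort$subject_ids
  } else {
    X <- cohort
    y <- encode_labels(labels)
    ids <- rownames(X)
    if (is.null(ids)) ids <- sprintf("sub%03d", seq_len(nrow(X)))
  }
  check_loocv_inputs(X, y, k)
  n <- nrow(X)
  folds <- vector("list", n)
  for (p in seq_len(n)) {
    tr <- seq_len(n)[-p]
    ft <- fit_fold(X, y, tr, k, C)
    xs <- (X[p, ft$selected] - ft$scaler$means) / ft$scaler$sds
    dv <- sum(ft$model$w * xs) + ft$model$b
    folds[[p]] <- list(left_out_subject = ids[p], true_label = y[p],
                       decision_value = dv, predicted_label = predict_label(dv),
                       selected_features = ft$selected, scaler = ft$scaler,
                       w = ft$model$w, b = ft$model$b)
  }
  structure(list(folds = folds, k = as.integer(k), subject_ids = ids,
                 true_labels = y,
                 decision_values = vapply(folds, `[[`, numeric(1), "decision_value"),
                 predicted_labels = vapply(folds, `[[`, integer(1), "predicted_label")),
            class = "loocv_folds")
}

check_loocv_inputs <- function(X, y, k) {
  if (min(sum(y > 0), sum(y < 0)) < 3L)
    stop("cohort-size error: each group needs >= 3 subjects so every training split keeps >= 2 per group",
         call. = FALSE)
  if (k < 1 || k > ncol(X))
    stop(sprintf("parameter error: k must lie in [1, %d]", ncol(X)),
         call. = FALSE)
  invisible(TRUE)
}

# One training fit: ranking, selection, scaling, SVM — training rows only.
fit_fold <- function(X, y, tr, k, C) {
  fs <- fisher_scores(X[tr, , drop = FALSE], y[tr])
  sel <- fs$ranking[seq_len(k)]
  Xs <- X[tr, sel, drop = FALSE]
  sc <- fit_scaler(Xs)
  model <- train_linear_svm(apply_scaler(sc, Xs), y[tr], C = C)
  list(selected = sel, scaler = sc, model = model)
}

# Lean LOOCV accuracy used by the permutation test: no per-fold records.
loocv_accuracy <- function(X, y, k, C = 1) {
  n <- nrow(X)
  correct <- 0L
  for (p in seq_len(n)) {
    tr <- seq_len(n)[-p]
    ft <- fit_fold(X, y, tr, k, C)
    xs <- (X[p, ft$selected] - ft$scaler$means) / ft$scaler$sds
    dv <- sum(ft$model$w * xs) + ft$model$b
    if ((dv > 0 && y[p] > 0) || (dv <= 0 && y[p] < 0)) correct <- correct + 1L
  }
  correct / n
}

#' @export
print.loocv_folds <- function(x, ...) {
  cat(sprintf("<loocv_folds> n = %d folds, k = %d features, accuracy %.4f\n",
              length(x$folds), x$k,
              mean(x$predicted_labels == x$true_labels)))
  invisible(x)
}

#' Feature-count sweep over the LOOCV
#'
#' Runs [loocv_run()] for every k on the grid `{step, 2*step, ..., k_max}`
#' (the conventional grid is step 100 up to 20,000, i.e. 200 cycles) and
#' collects per-k accuracy, sensitivity and specificity.
#'
#' @inheritParams loocv_run
#' @param k_max Largest feature count on the grid.
#' @param step Grid step (default 100).
#' @param truncate When `TRUE` (default) a `k_max` exceeding the mask's m is
#'   truncated to the largest grid point `<= m`; when `FALSE` that is an
#'   error.
#' @return An object of class `fa_sweep`: `k_grid`, per-k `results`
#'   (`loocv_folds`), and a `metrics` data frame.
#' @export
k_sweep <- function(cohort, mask = NULL, k_max = 20000L, step = 100L, C = 1,
                    labels = NULL, truncate = TRUE) {
  if (inherits(cohort, "fa_cohort")) {
    X <- volumes_to_matrix(cohort, mask)
    y <- cohort$labels
  } else {
    X <- cohort
    y <- encode_labels(labels)
  }
  ks <- k_grid(k_max, step, m = ncol(X), truncate = truncate)
  results <- lapply(ks, function(k) loocv_run(X, k = k, C = C, labels = y))
  metrics <- do.call(rbind, lapply(seq_along(ks), function(i) {
    cm <- confusion_metrics(results[[i]]$true_labels,
                            results[[i]]$predicted_labels)
    data.frame(k = ks[i], accuracy = cm$accuracy, sensitivity = cm$sensitivity,
               specificity = cm$specificity)
  }))
  structure(list(k_grid = ks, results = results, metrics = metrics,
                 n = nrow(X)), class = "fa_sweep")
}

#' The feature-count grid
#'
#' `{step, 2*step, ..., k_max}`; with the conventional `k_max = 20000`,
#' `step = 100` this is the 200-point grid `k = t * 100`.
#'
#' @param k_max Largest feature count.
#' @param step Grid step (`>= 1`).
#' @param m Optional feature-space size; grid points above `m` are dropped
#'   (`truncate = TRUE`) or rejected (`truncate = FALSE`).
#' @param truncate See [k_sweep()].
#' @return Strictly increasing integer vector.
#' @export
k_grid <- function(k_max, step = 100L, m = NULL, truncate = TRUE) {
  step <- as.integer(step); k_max <- as.integer(k_max)
  if (step < 1L || k_max < step)
    stop("parameter error: need step >= 1 and k_max >= step", call. = FALSE)
  if (!is.null(m) && k_max > m) {
    if (!truncate)
      stop(sprintf("parameter error: k_max = %d exceeds m = %d features",
                   k_max, m), call. = FALSE)
    k_max <- as.integer((m %/% step) * step)
    if (k_max < step)
      stop(sprintf("parameter error: fewer than `step` = %d features in the mask",
                   step), call. = FALSE)
  }
  seq.int(step, k_max, by = step)
}

#' @export
print.fa_sweep <- function(x, ...) {
  best <- x$metrics[which.max(x$metrics$accuracy), ]
  cat(sprintf("<fa_sweep> %d grid points (k = %d..%d), n = %d subjects\n",
              length(x$k_grid), min(x$k_grid), max(x$k_grid), x$n))
  cat(sprintf("  best accuracy %.4f at k = %d; plateau-midpoint optimum k = %d\n",
              best$accuracy, best$k, select_optimal_k(x)))
  invisible(x)
}

#' Plateau-midpoint selection of the optimal feature count
#'
#' Finds the maximal accuracy on the sweep, takes the longest contiguous run
#' of grid points attaining it (earliest run on ties), and returns the run's
#' midpoint snapped down to the grid. A run spanning k = 1,400..3,400 on a
#' step-100 grid therefore yields 2,400, the middle of the plateau.
#'
#' @param sweep An `fa_sweep`, or any data frame with `k` and `accuracy`
#'   columns (k strictly increasing).
#' @return The optimal k (integer).
#' @export
select_optimal_k <- function(sweep) {
  df <- if (inherits(sweep, "fa_sweep")) sweep$metrics else as.data.frame(sweep)
  if (!all(c("k", "accuracy") %in% names(df)) || nrow(df) == 0L)
    stop("need a non-empty sweep with `k` and `accuracy`", call. = FALSE)
  ks <- df$k
  acc <- df$accuracy
  is_max <- acc >= max(acc) - 1e-12
  r <- rle(is_max)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  best <- cand[which.max(r$lengths[cand])]      # longest run, earliest on ties
  k_lo <- ks[starts[best]]; k_hi <- ks[ends[best]]
  mid <- (k_lo + k_hi) / 2
  as.integer(max(ks[ks <= mid]))
}

#' Average discriminative weight map over LOOCV folds
#'
#' Each fold's weight vector is scattered to its own selected voxel positions
#' in the full m-dimensional feature space (zeros elsewhere), the full-length
#' vectors are averaged over folds, and the average is back-projected through
#' [matrix_to_volume()]. Because the per-fold SVMs are trained on z-scored
#' features, the map lives in standardized-FA units; a positive map value
#' means the patients' FA at that voxel is lower than the controls' (the
#' voxel votes "control-like" for high FA).
#'
#' @param folds A `loocv_folds` object (all folds share one k).
#' @param mask The [voxel_mask()] defining the feature space.
#' @param fill Out-of-mask fill value for the map volume.
#' @return A [scalar_volume()]; the full-length averaged weight vector is
#'   attached as attribute `"weights"`.
#' @export
average_weight_map <- function(folds, mask, fill = 0) {
  stopifnot(inherits(folds, "loocv_folds"), inherits(mask, "voxel_mask"))
  m <- mask_size(mask)
  kk <- vapply(folds$folds, function(f) length(f$w), integer(1))
  if (length(unique(kk)) != 1L)
    stop("dimension error: folds have inconsistent k", call. = FALSE)
  acc <- numeric(m)
  for (f in folds$folds) acc[f$selected_features] <- acc[f$selected_features] + f$w
  wbar <- acc / length(folds$folds)
  vol <- matrix_to_volume(wbar, mask, fill = fill)
  attr(vol, "weights") <- wbar
  vol
}
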