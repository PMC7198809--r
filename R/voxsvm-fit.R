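#' Voxel-wise linear-SVM discrimination of a two-group cohort
#'
#' The top-level fitting function. Given a cohort of registered scalar
#' volumes it (i) builds (or accepts) the analysis mask, (ii) extracts the
#' n x m feature matrix, (iii) sweeps the nested leave-one-out
#' cross-validation over the feature-count grid, (iv) picks the optimal k by
#' the plateau-midpoint rule, (v) computes confusion metrics, the ROC/AUC of
#' the decision values and — when clinical scores are present — their
#' Spearman correlation with the patients' decision values, (vi) averages the
#' per-fold weight vectors into a discriminative map with its cluster report,
#' and (vii) refits a final model on all subjects at the optimal k for use on
#' new volumes via [predict.voxsvm()].
#'
#' Statistical significance of the accuracy is not part of the fit: run
#' [permutation_test()] at `fit$k_opt` for that.
#'
#' @param cohort A [fa_cohort()].
#' @param mask Optional [voxel_mask()]; by default built from the cohort with
#'   [build_mask()] at `mask_threshold`.
#' @param mask_threshold Mean-value threshold for the default mask.
#' @param k_max,k_step Feature-count grid (default step 100 up to 20,000,
#'   truncated to the mask size).
#' @param C SVM penalty (default 1).
#' @param map_fraction Per-sign threshold fraction for the cluster report.
#' @param min_cluster Minimum reported cluster size in voxels.
#' @return An object of class `voxsvm`.
#' @seealso [summary.voxsvm()], [coef.voxsvm()], [predict.voxsvm()],
#'   [plot.voxsvm()]
#' @export
voxsvm <- function(cohort, mask = NULL, mask_threshold = 0.2,
                   k_max = 20000L, k_step = 100L, C = 1,
                   map_fraction = 0.10, min_cluster = 20L) {
  stopifnot(inherits(cohort, "fa_cohort"))
  if (is.null(mask)) mask <- build_mask(cohort, mask_threshold)
  X <- volumes_to_matrix(cohort, mask)
  y <- cohort$labels
  sweep <- k_sweep(X, k_max = k_max, step = k_step, C = C, labels = y,
                   truncate = TRUE)
  k_opt <- select_optimal_k(sweep)
  folds <- sweep$results[[match(k_opt, sweep$k_grid)]]
  metrics <- confusion_metrics(folds$true_labels, folds$predicted_labels)
  roc <- roc_curve(folds$decision_values, folds$true_labels)
  spear <- if (any(!is.na(cohort$clinical_scores)))
    score_correlation(folds, cohort) else NULL
  map <- average_weight_map(folds, mask)
  clusters <- cluster_table(map, fraction = map_fraction, min_size = min_cluster)

  # final model on the full cohort at k_opt, for predicting new subjects
  fs <- fisher_scores(X, y)
  sel <- select_top_k(fs, k_opt)
  sc <- fit_scaler(X[, sel, drop = FALSE])
  final <- train_linear_svm(apply_scaler(sc, X[, sel, drop = FALSE]), y, C = C)

  structure(list(call = match.call(), cohort = cohort, mask = mask,
                 sweep = sweep, k_opt = k_opt, folds = folds,
                 metrics = metrics, roc = roc, spearman = spear,
                 weight_map = map, clusters = clusters,
                 final_model = list(selected = sel, scaler = sc, model = final),
                 C = C, map_fraction = map_fraction, min_cluster = min_cluster),
            class = "voxsvm")
}

#' @export
print.voxsvm <- function(x, ...) {
  cat("Voxel-wise linear SVM classification\n")
  cat(sprintf("  %d subjects (%d HC, %d patients), %d mask voxels\n",
              length(x$cohort$volumes), sum(x$cohort$labels > 0),
              sum(x$cohort$labels < 0), mask_size(x$mask)))
  cat(sprintf("  optimal k = %d (grid %d..%d, step %d)\n", x$k_opt,
              min(x$sweep$k_grid), max(x$sweep$k_grid),
              x$sweep$k_grid[2] - x$sweep$k_grid[1]))
  cat("  LOOCV: "); print(x$metrics)
  cat(sprintf("  AUC = %.3f\n", x$roc$auc))
  invisible(x)
}

#' Summary of a fitted voxel-wise SVM classifier
#'
#' @param object A `voxsvm` fit.
#' @param ... Unused.
#' @export
summary.voxsvm <- function(object, ...) {
  print(object)
  if (!is.null(object$spearman))
    cat(sprintf("  decision value vs clinical score: rho = %.3f, p = %.3g (n = %d patients)\n",
                object$spearman$rho, object$spearman$p_value, object$spearman$n))
  cat(sprintf("  discriminative map: %d clusters >= %d voxels at %.0f%% per-sign threshold\n",
              nrow(object$clusters), object$min_cluster, 100 * object$map_fraction))
  if (nrow(object$clusters) > 0) print(object$clusters)
  invisible(object)
}

#' Averaged discriminative weights of a fit
#'
#' @param object A `voxsvm` fit.
#' @param as_volume Return the back-projected [scalar_volume()] map instead
#'   of the length-m weight vector.
#' @param ... Unused.
#' @export
coef.voxsvm <- function(object, as_volume = FALSE, ...) {
  if (as_volume) object$weight_map else attr(object$weight_map, "weights")
}

#' @export
fitted.voxsvm <- function(object, ...) {
  structure(object$folds$decision_values, names = object$folds$subject_ids)
}

#' Classify new volumes with a fitted voxel-wise SVM
#'
#' Applies the final full-cohort model (features, scaler and SVM refitted on
#' all training subjects at the optimal k) to new registered volumes on the
#' training grid.
#'
#' @param object A `voxsvm` fit.
#' @param newdata A [fa_cohort()], list of [scalar_volume()]s, or an n x m
#'   feature matrix extracted with the fit's mask.
#' @param type `"label"` for group codes (+1 HC / -1 patient),
#'   `"decision"` for raw decision values.
#' @param ... Unused.
#' @export
predict.voxsvm <- function(object, newdata, type = c("label", "decision"), ...) {
  type <- match.arg(type)
  X <- if (is.matrix(newdata)) newdata else volumes_to_matrix(newdata, object$mask)
  fm <- object$final_model
  Xs <- apply_scaler(fm$scaler, X[, fm$selected, drop = FALSE])
  v <- decision_value(fm$model, Xs)
  names(v) <- rownames(X)
  if (type == "decision") v else predict_label(v)
}

#' Diagnostic plots for a voxel-wise SVM fit
#'
#' `type = "sweep"` draws LOOCV accuracy against the number of selected
#' features with the optimal k marked; `type = "roc"` draws the ROC curve of
#' the decision values.
#'
#' @param x A `voxsvm` fit.
#' @param type `"sweep"` or `"roc"`.
#' @param ... Passed to the underlying plot call.
#' @export
plot.voxsvm <- function(x, type = c("sweep", "roc"), ...) {
  type <- match.arg(type)
  if (type == "sweep") {
    graphics::plot(x$sweep$metrics$k, 100 * x$sweep$metrics$accuracy,
                   type = "l", xlab = "selected features k",
                   ylab = "LOOCV accuracy (%)", ...)
    graphics::abline(v = x$k_opt, lty = 2, col = "grey40")
    graphics::mtext(sprintf("k_opt = %d", x$k_opt), side = 3, adj = 1, cex = 0.8)
  } else {
    graphics::plot(x$roc$points$fpr, x$roc$points$tpr, type = "l",
                   xlab = "1 - specificity", ylab = "sensitivity",
                   xlim = c(0, 1), ylim = c(0, 1), ...)
    graphics::abline(0, 1, lty = 3, col = "grey60")
    graphics::mtext(sprintf("AUC = %.3f", x$roc$auc), side = 3, adj = 1, cex = 0.8)
  }
  invisible(x)
}
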