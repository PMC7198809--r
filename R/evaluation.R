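#' Confusion-matrix metrics
#'
#' The patient group (`-1`, "label 2") is the positive class: sensitivity is
#' the fraction of patients detected, specificity the fraction of controls
#' cleared.
#'
#' @param truth True group codes (`+1` HC / `-1` patient, or any encoding
#'   accepted by the cohort constructor).
#' @param predicted Predicted group codes, same encoding.
#' @return An object of class `confusion_metrics`: counts `tp`, `fn`, `tn`,
#'   `fp` and proportions `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(truth, predicted) {
  truth <- encode_labels(truth); predicted <- encode_labels(predicted)
  if (length(truth) == 0L || length(truth) != length(predicted))
    stop("dimension error: need matching non-empty truth/prediction vectors",
         call. = FALSE)
  if (length(unique(truth)) != 2L)
    stop("class error: both classes must be present in the truths", call. = FALSE)
  tp <- sum(truth < 0 & predicted < 0)
  fn <- sum(truth < 0 & predicted > 0)
  tn <- sum(truth > 0 & predicted > 0)
  fp <- sum(truth > 0 & predicted < 0)
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 accuracy = (tp + tn) / length(truth),
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp)),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.2f%% (%d/%d), sensitivity %.2f%% (%d/%d), specificity %.2f%% (%d/%d)\n",
              100 * x$accuracy, x$tp + x$tn, x$tp + x$fn + x$tn + x$fp,
              100 * x$sensitivity, x$tp, x$tp + x$fn,
              100 * x$specificity, x$tn, x$tn + x$fp))
  invisible(x)
}

#' ROC curve and AUC from decision values
#'
#' Decision values are oriented so that healthy controls score high (the sign
#' rule of the classifier). The curve sweeps a threshold over the unique
#' values (rule: value >= threshold is called HC); the AUC is the trapezoidal
#' area, which equals the rank statistic — the probability that a random
#' control's value exceeds a random patient's, ties counted 1/2.
#'
#' @param values Numeric decision values.
#' @param truth True group codes.
#' @return An object of class `roc_curve` with a `points` data frame
#'   (`threshold`, `tpr` = HC detection rate, `fpr` = patient false-call
#'   rate) and `auc`.
#' @export
roc_curve <- function(values, truth) {
  truth <- encode_labels(truth)
  if (length(values) != length(truth))
    stop("dimension error: one truth per value required", call. = FALSE)
  n_hc <- sum(truth > 0); n_pat <- sum(truth < 0)
  if (n_hc == 0L || n_pat == 0L)
    stop("class error: both classes must be present", call. = FALSE)
  thr <- sort(unique(values), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(values >= t & truth > 0) / n_hc, numeric(1))
  fpr <- vapply(thr, function(t) sum(values >= t & truth < 0) / n_pat, numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), tpr = c(0, tpr), fpr = c(0, fpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d thresholds, AUC = %.3f\n", nrow(x$points) - 1L, x$auc))
  invisible(x)
}

#' Permutation test of LOOCV classification accuracy
#'
#' Builds the empirical null of the accuracy by shuffling the group labels
#' over all subjects and re-running the full leakage-free LOOCV at the fixed
#' feature count `k` — Fisher ranking, selection and scaling are recomputed
#' under the permuted labels inside every fold. The p-value is the paper-
#' style plug-in estimate `count(null >= observed) / n_perm` (which can be
#' zero); the positively biased but never-zero estimate
#' `(count + 1) / (n_perm + 1)` is reported alongside as `p_value_unbiased`.
#'
#' @param cohort A [fa_cohort()] or feature matrix (then pass `labels`).
#' @param mask A [voxel_mask()] when `cohort` is a cohort.
#' @param k Fixed feature count (typically the sweep optimum).
#' @param n_perm Number of permutations (`>= 1`; 10,000 for publication-grade
#'   inference, a few hundred for calibration experiments).
#' @param seed Optional RNG seed for the permutation stream (independent of
#'   any cohort-generation stream).
#' @param C SVM penalty.
#' @param labels Group codes when `cohort` is a matrix.
#' @return An object of class `permutation_result`: `observed_accuracy`,
#'   `null_accuracies`, `count_ge`, `p_value`, `p_value_unbiased`,
#'   `n_permutations`.
#' @export
permutation_test <- function(cohort, mask = NULL, k, n_perm = 1000L,
                             seed = NULL, C = 1, labels = NULL) {
  if (inherits(cohort, "fa_cohort")) {
    X <- volumes_to_matrix(cohort, mask)
    y <- cohort$labels
  } else {
    X <- cohort
    y <- encode_labels(labels)
  }
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("parameter error: n_perm must be >= 1", call. = FALSE)
  check_loocv_inputs(X, y, k)
  observed <- loocv_accuracy(X, y, k, C)
  if (!is.null(seed)) set.seed(seed)
  null_acc <- numeric(n_perm)
  for (b in seq_len(n_perm))
    null_acc[b] <- loocv_accuracy(X, sample(y), k, C)
  count_ge <- sum(null_acc >= observed)
  structure(list(n_permutations = n_perm, observed_accuracy = observed,
                 null_accuracies = null_acc, count_ge = count_ge,
                 p_value = count_ge / n_perm,
                 p_value_unbiased = (count_ge + 1) / (n_perm + 1)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed accuracy %.4f, %d permutations\n",
              x$observed_accuracy, x$n_permutations))
  cat(sprintf("  p = %d/%d = %.4g  [(count+1)/(N+1) = %.4g]\n",
              x$count_ge, x$n_permutations, x$p_value, x$p_value_unbiased))
  invisible(x)
}

#' Spearman correlation of patient decision values with clinical scores
#'
#' Rank correlation (Pearson correlation of mid-ranks, average ranks on ties)
#' between the patients' SVM decision values and their clinical severity
#' scores, with the large-sample t-approximation p-value. Computed on
#' patients only — controls carry no severity score.
#'
#' @param decision_values Patient decision values (or a `loocv_folds`, from
#'   which patient folds are taken when `scores` is a [fa_cohort()]).
#' @param scores Patient clinical scores, same length/order.
#' @return List with `rho`, `p_value` and `n`.
#' @export
score_correlation <- function(decision_values, scores) {
  if (inherits(decision_values, "loocv_folds") && inherits(scores, "fa_cohort")) {
    stopifnot(identical(decision_values$subject_ids, scores$subject_ids))
    pat <- scores$labels < 0
    decision_values <- decision_values$decision_values[pat]
    scores <- scores$clinical_scores[pat]
  }
  x <- as.numeric(decision_values); y <- as.numeric(scores)
  if (length(x) != length(y) || length(x) < 3L)
    stop("dimension error: need >= 3 paired observations", call. = FALSE)
  if (var(rank(x)) == 0 || var(rank(y)) == 0)
    stop("undefined-correlation error: zero rank variance", call. = FALSE)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
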