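#' Fisher scores for two-group feature ranking
#'
#' For feature q with group means `m1` (HC), `m2` (patient), grand mean `g`
#' and unbiased within-group sample variances `s1sq`, `s2sq`:
#'
#'   `F(q) = ((m1 - g)^2 + (m2 - g)^2) / (s1sq + s2sq)`
#'
#' The numerator measures interclass separation, the denominator intraclass
#' variance; larger scores mean more discriminative features. Scores are
#' computed on raw (unscaled) training rows — centering/normalisation is
#' applied only to the selected features, downstream. Degenerate features
#' follow the limit of the ratio: zero numerator and denominator give 0, a
#' positive numerator over a zero denominator gives `Inf` (a perfectly
#' separating within-group-constant feature ranks first).
#'
#' @param X n x m numeric feature matrix (training rows only).
#' @param labels Group codes (`+1` HC / `-1` patient; see [encode_labels]
#'   conventions), both groups with at least 2 members.
#' @return An object of class `fisher_scores` with fields `scores` (length m)
#'   and `ranking` (permutation of `1:m`, descending score, ties broken by
#'   ascending feature index).
#' @export
fisher_scores <- function(X, labels) {
  y <- encode_labels(labels)
  if (length(y) != nrow(X))
    stop("dimension error: one label per row required", call. = FALSE)
  i1 <- y > 0; i2 <- y < 0
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L)
    stop("cohort-size error: both groups need >= 2 members for Fisher scores",
         call. = FALSE)
  X1 <- X[i1, , drop = FALSE]; X2 <- X[i2, , drop = FALSE]
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  g  <- (n1 * m1 + n2 * m2) / (n1 + n2)
  v1 <- colSums((X1 - rep(m1, each = n1))^2) / (n1 - 1)
  v2 <- colSums((X2 - rep(m2, each = n2))^2) / (n2 - 1)
  num <- (m1 - g)^2 + (m2 - g)^2
  den <- v1 + v2
  f <- num / den
  zero_den <- den == 0
  f[zero_den & num == 0] <- 0
  f[zero_den & num > 0] <- Inf
  structure(list(scores = unname(f),
                 ranking = order(-f, seq_along(f))),
            class = "fisher_scores")
}

#' @export
print.fisher_scores <- function(x, ...) {
  cat(sprintf("<fisher_scores> %d features, top score %.4g (feature %d)\n",
              length(x$scores), x$scores[x$ranking[1]], x$ranking[1]))
  invisible(x)
}

#' Descending-score feature ranking
#'
#' @param scores A `fisher_scores` object.
#' @return Permutation of `1:m`: feature indices in non-increasing score
#'   order, ties broken by ascending index (stable, platform independent).
#' @export
rank_features <- function(scores) {
  stopifnot(inherits(scores, "fisher_scores"))
  scores$ranking
}

#' Top-k feature selection
#'
#' @param ranking Permutation from [rank_features()] (or a `fisher_scores`).
#' @param k Number of features to keep, `1 <= k <= m`.
#' @return The first `k` entries of the ranking, order preserved.
#' @export
select_top_k <- function(ranking, k) {
  if (inherits(ranking, "fisher_scores")) ranking <- ranking$ranking
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > length(ranking))
    stop(sprintf("parameter error: k must lie in [1, %d]", length(ranking)),
         call. = FALSE)
  ranking[seq_len(as.integer(k))]
}
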