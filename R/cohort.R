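#' Cohort of registered scalar volumes
#'
#' Aligned per-subject volumes, two-group labels and optional clinical severity
#' scores. Group labels use the sign convention of the classifier: healthy
#' controls (HC) are `+1`, patients are `-1`, so a positive SVM decision value
#' reads "control-like". Clinical scores (e.g. ALSFRS-R) are defined for every
#' patient and `NA` for controls.
#'
#' @param volumes List of [scalar_volume()]s, one per subject, common grid.
#' @param labels Integer/numeric vector of `+1` (HC) / `-1` (patient), or a
#'   character vector of `"HC"` / `"patient"`.
#' @param subject_ids Character vector of unique subject identifiers.
#' @param clinical_scores Numeric vector, `NA` for controls; may be omitted
#'   when no clinical score is available.
#' @return An object of class `fa_cohort`.
#' @export
fa_cohort <- function(volumes, labels, subject_ids = NULL, clinical_scores = NULL) {
  n <- length(volumes)
  if (is.null(subject_ids)) subject_ids <- sprintf("sub%03d", seq_len(n))
  labels <- encode_labels(labels)
  if (length(labels) != n || length(subject_ids) != n)
    stop("volumes, labels and subject_ids must have one entry per subject",
         call. = FALSE)
  if (anyDuplicated(subject_ids)) stop("subject ids must be unique", call. = FALSE)
  stopifnot(all(vapply(volumes, inherits, logical(1), "scalar_volume")))
  if (!same_grid(volumes))
    stop("geometry error: cohort volumes are not on a common grid", call. = FALSE)
  if (length(unique(labels)) != 2L)
    stop("labels must contain both groups", call. = FALSE)
  if (is.null(clinical_scores)) {
    clinical_scores <- rep(NA_real_, n)
  } else {
    clinical_scores <- as.numeric(clinical_scores)
    if (length(clinical_scores) != n)
      stop("clinical_scores must have one entry per subject", call. = FALSE)
    if (anyNA(clinical_scores[labels < 0]))
      stop("clinical_scores must be defined for every patient", call. = FALSE)
  }
  structure(list(subject_ids = as.character(subject_ids),
                 volumes = volumes, labels = labels,
                 clinical_scores = clinical_scores),
            class = "fa_cohort")
}

# Accept +1/-1, 1/2 ("label 1" = HC, "label 2" = patient) or "HC"/"patient".
encode_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    lab <- tolower(as.character(labels))
    out <- ifelse(lab %in% c("hc", "control", "healthy"), 1,
                  ifelse(lab %in% c("patient", "als", "case"), -1, NA))
    if (anyNA(out)) stop("unrecognised group label", call. = FALSE)
    return(as.numeric(out))
  }
  labels <- as.numeric(labels)
  if (all(labels %in% c(1, 2))) return(ifelse(labels == 1, 1, -1))
  if (all(labels %in% c(-1, 1))) return(labels)
  stop("labels must be +1/-1, 1/2, or 'HC'/'patient'", call. = FALSE)
}

group_name <- function(label) ifelse(label > 0, "HC", "patient")

#' @export
print.fa_cohort <- function(x, ...) {
  d <- dim(x$volumes[[1]]$values)
  cat(sprintf("<fa_cohort> %d subjects (%d HC, %d patients), grid %d x %d x %d\n",
              length(x$volumes), sum(x$labels > 0), sum(x$labels < 0),
              d[1], d[2], d[3]))
  if (any(!is.na(x$clinical_scores)))
    cat(sprintf("  clinical scores: mean %.1f, sd %.1f (patients)\n",
                mean(x$clinical_scores[x$labels < 0]),
                sd(x$clinical_scores[x$labels < 0])))
  invisible(x)
}

#' @export
length.fa_cohort <- function(x) length(x$volumes)
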