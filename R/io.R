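#' Read / write scalar volumes as NIfTI-1
#'
#' Thin wrappers around RNifti. Volumes are written as float64 so that a
#' write/read round trip reproduces the values bit-exactly. `pixdim` is stored
#' as float32 in the NIfTI header, so prefer exactly representable voxel sizes
#' when exact geometry round trips matter.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a [scalar_volume()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  vs <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  affine <- if (!is.null(attr(xf, "code")) && attr(xf, "code") > 0)
    matrix(as.numeric(xf), 4, 4) else NULL
  scalar_volume(vals, vs, affine)
}

#' @param volume A [scalar_volume()].
#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "scalar_volume"))
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$voxel_size
  if (!is.null(volume$affine))
    RNifti::qform(img) <- structure(volume$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Write an analysis mask as an integer {0,1} NIfTI volume
#'
#' @param mask A [voxel_mask()].
#' @param path Output path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voxel_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$mask), dim = dim(mask$mask)))
  RNifti::pixdim(img) <- mask$voxel_size
  if (!is.null(mask$affine))
    RNifti::qform(img) <- structure(mask$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Write a cohort to a directory
#'
#' One NIfTI file per subject (`<subject_id>.nii.gz`) plus a tab-separated
#' metadata table `cohort.tsv` with header
#' `subject_id<TAB>group<TAB>clinical_score`; the group column holds `HC` or
#' `patient`, and the clinical-score field is empty for controls.
#'
#' @param cohort A [fa_cohort()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @seealso [read_cohort()] for the inverse.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fa_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort$volumes))
    write_volume(cohort$volumes[[i]],
                 file.path(dir, paste0(cohort$subject_ids[i], ".nii.gz")))
  score <- ifelse(is.na(cohort$clinical_scores), "",
                  formatC(cohort$clinical_scores, digits = 17, format = "g"))
  lines <- c("subject_id\tgroup\tclinical_score",
             paste(cohort$subject_ids, group_name(cohort$labels), score,
                   sep = "\t"))
  writeLines(lines, file.path(dir, "cohort.tsv"))
  invisible(dir)
}

#' Read a cohort from a directory
#'
#' Expects the layout produced by [write_cohort()]: a `cohort.tsv` table and
#' one `<subject_id>.nii.gz` (or `.nii`) volume per row.
#'
#' @param dir Directory path.
#' @return A [fa_cohort()].
#' @export
read_cohort <- function(dir) {
  tsv <- file.path(dir, "cohort.tsv")
  if (!file.exists(tsv)) stop("I/O error: no cohort.tsv in ", dir, call. = FALSE)
  tab <- read.delim(tsv, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric"))
  volumes <- lapply(tab$subject_id, function(id) {
    for (ext in c(".nii.gz", ".nii")) {
      p <- file.path(dir, paste0(id, ext))
      if (file.exists(p)) return(read_volume(p))
    }
    stop("I/O error: no volume found for subject ", id, call. = FALSE)
  })
  fa_cohort(volumes, labels = tab$group, subject_ids = tab$subject_id,
            clinical_scores = tab$clinical_score)
}

#' Serialize an SVM model (and optional scaler) to JSON
#'
#' Audit/export format carrying the dual coefficients, weight vector, bias and
#' penalty so a discriminative map can be reconstructed outside R.
#'
#' @param model A `linear_svm` model from [train_linear_svm()].
#' @param scaler Optional `feature_scaler` from [fit_scaler()].
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @export
svm_to_json <- function(model, scaler = NULL, path = NULL) {
  stopifnot(inherits(model, "linear_svm"))
  obj <- list(alphas = model$alphas, train_labels = model$train_labels,
              w = as.numeric(model$w), b = model$b, C = model$C)
  if (!is.null(scaler)) obj$scaler <- list(means = scaler$means, sds = scaler$sds)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
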