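#' Build an analysis mask from a cohort of volumes
#'
#' The analysis mask selects the voxels that enter the feature matrix. The
#' standard convention for white-matter analyses is adopted: a voxel is kept
#' when its across-subject mean value exceeds `threshold` (default 0.2 FA).
#'
#' The in-mask voxels are enumerated in ascending column-major linear index
#' order (first coordinate fastest), R's native array order. This scan order
#' fixes the feature <-> voxel correspondence used by [volumes_to_matrix()],
#' [matrix_to_volume()] and every downstream report, and is stable across runs
#' and platforms.
#'
#' @param volumes List of [scalar_volume()]s on a common grid (or a
#'   [fa_cohort()], whose volumes are used).
#' @param threshold Mean-value threshold (strict `>`).
#' @return An object of class `voxel_mask` with fields `mask` (logical array),
#'   `index_map` (m x 3 integer matrix of 1-based voxel coordinates),
#'   `linear_index` (column-major linear indices), `voxel_size`, `affine`.
#' @export
build_mask <- function(volumes, threshold = 0.2) {
  if (inherits(volumes, "fa_cohort")) volumes <- volumes$volumes
  if (length(volumes) < 1L) stop("need at least one volume", call. = FALSE)
  stopifnot(all(vapply(volumes, inherits, logical(1), "scalar_volume")))
  if (!same_grid(volumes))
    stop("geometry error: volumes are not on a common grid", call. = FALSE)
  mean_vol <- Reduce(`+`, lapply(volumes, `[[`, "values")) / length(volumes)
  keep <- mean_vol > threshold
  lin <- which(keep)
  if (length(lin) == 0L)
    stop("empty mask: no voxel has mean value above the threshold", call. = FALSE)
  structure(list(mask = keep,
                 index_map = arrayInd(lin, dim(keep)),
                 linear_index = lin,
                 voxel_size = volumes[[1]]$voxel_size,
                 affine = volumes[[1]]$affine),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<voxel_mask> %d of %d voxels in mask (grid %d x %d x %d)\n",
              length(x$linear_index), prod(d), d[1], d[2], d[3]))
  invisible(x)
}

mask_size <- function(mask) length(mask$linear_index)

#' Extract the cohort feature matrix
#'
#' Flattens every subject's masked voxel values into one row of the n x m
#' feature matrix; column q corresponds to `mask$index_map[q, ]`.
#'
#' @param cohort A [fa_cohort()] (or plain list of [scalar_volume()]s).
#' @param mask A [voxel_mask()] on the same grid.
#' @return n x m numeric matrix with subject ids as row names.
#' @export
volumes_to_matrix <- function(cohort, mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  volumes <- if (inherits(cohort, "fa_cohort")) cohort$volumes else cohort
  ids <- if (inherits(cohort, "fa_cohort")) cohort$subject_ids else names(volumes)
  d <- dim(mask$mask)
  ok <- vapply(volumes, function(v) identical(dim(v$values), d), logical(1))
  if (!all(ok))
    stop("geometry error: volume grid does not match the mask grid", call. = FALSE)
  m <- mask_size(mask)
  X <- matrix(vapply(volumes, function(v) v$values[mask$linear_index],
                     numeric(m)),
              nrow = length(volumes), ncol = m, byrow = TRUE)
  rownames(X) <- ids
  X
}

#' Back-project a feature vector into a volume
#'
#' Inverse of [volumes_to_matrix()] for a single length-m vector: the value of
#' voxel `mask$index_map[q, ]` is `x[q]`, out-of-mask voxels get `fill`
#' (use `NaN` to flag them for map writers).
#'
#' @param x Numeric vector of length m.
#' @param mask A [voxel_mask()].
#' @param fill Out-of-mask value (default 0).
#' @return A [scalar_volume()] on the mask grid.
#' @export
matrix_to_volume <- function(x, mask, fill = 0) {
  stopifnot(inherits(mask, "voxel_mask"))
  m <- mask_size(mask)
  if (length(x) != m)
    stop(sprintf("dimension error: vector length %d, mask has %d voxels",
                 length(x), m), call. = FALSE)
  vals <- array(as.numeric(fill), dim = dim(mask$mask))
  vals[mask$linear_index] <- x
  out <- structure(list(values = vals, voxel_size = mask$voxel_size,
                        affine = mask$affine), class = "scalar_volume")
  out
}
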