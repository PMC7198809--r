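#' Planted group effect
#'
#' A spherical region where the patient group's mean value is shifted by
#' `delta` (negative = patient FA reduced, the dominant direction in motor
#' pathway findings; positive = patient FA increased).
#'
#' @param center Integer voxel triple (1-based), sphere centre.
#' @param radius Sphere radius in voxels (Euclidean, `>= 1`).
#' @param delta Signed shift in FA units, `|delta| < 1`.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(center, radius, delta) {
  center <- as.integer(round(center))
  if (length(center) != 3L) stop("geometry error: center must be a voxel triple",
                                 call. = FALSE)
  if (!is.numeric(radius) || length(radius) != 1L || radius < 1)
    stop("geometry error: radius must be >= 1 voxel", call. = FALSE)
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      abs(delta) >= 1)
    stop("parameter error: |delta| must be < 1 FA unit", call. = FALSE)
  structure(list(center = center, radius = as.numeric(radius),
                 delta = as.numeric(delta)), class = "effect_spec")
}

# Column-major linear indices of the integer ball |v - center| <= radius.
sphere_indices <- function(center, radius, grid_shape) {
  r <- floor(radius)
  rng <- lapply(1:3, function(ax) (center[ax] - r):(center[ax] + r))
  g <- as.matrix(expand.grid(rng))
  d2 <- rowSums((g - matrix(center, nrow(g), 3, byrow = TRUE))^2)
  g <- g[d2 <= radius^2, , drop = FALSE]
  if (any(g < 1L) || any(g > matrix(grid_shape, nrow(g), 3, byrow = TRUE)))
    stop("geometry error: effect sphere extends outside the grid", call. = FALSE)
  g[, 1] + (g[, 2] - 1L) * grid_shape[1] + (g[, 3] - 1L) * grid_shape[1] * grid_shape[2]
}

#' Default planted effects for the synthetic cohort
#'
#' Thirteen spheres — ten where the patient group's FA is reduced and three
#' where it is increased, mirroring the 10-vs-3 split of discriminative
#' regions typical of ALS white-matter findings. Centres are placed at fixed
#' relative positions in the central portion of the grid; deltas span roughly
#' one to three times the post-smoothing voxel noise level of the default
#' generator settings.
#'
#' @param grid_shape Integer voxel triple.
#' @return List of [effect_spec()]s.
#' @export
default_effects <- function(grid_shape = c(48L, 48L, 48L)) {
  rel <- rbind(
    c(.30, .35, .60), c(.65, .40, .62), c(.45, .55, .70), c(.38, .62, .45),
    c(.60, .60, .35), c(.50, .30, .40), c(.30, .55, .30), c(.68, .30, .45),
    c(.55, .45, .55), c(.35, .45, .38),
    c(.62, .68, .55), c(.30, .68, .62), c(.68, .55, .68))
  delta <- c(-0.035, -0.030, -0.030, -0.025, -0.025, -0.020, -0.020,
             -0.015, -0.015, -0.012, 0.030, 0.020, 0.015)
  radius <- c(3, 2, 4, 2, 3, 2, 3, 2, 2, 2, 2, 3, 2)
  lapply(seq_along(delta), function(i) {
    effect_spec(round(rel[i, ] * grid_shape), radius[i], delta[i])
  })
}

#' Synthetic cohort parameters
#'
#' Defaults reproduce the study design this generator emulates: 22 patients
#' vs 26 healthy controls, FA-like volumes smoothed at 6 mm FWHM on a 2 mm
#' grid, a white-matter-like baseline FA of 0.45, and an ALSFRS-R-like
#' clinical score with mean ~40 and sd ~7 for patients. Disease severity is a
#' per-patient multiplier `~ N(1, 0.3)` (clamped to [0.1, 1.9]) that scales
#' every planted `delta` and drives the clinical score
#' `score = score_intercept + score_slope * multiplier + N(0, score_noise_sd)`,
#' so with a negative slope a more severe patient has a lower score and — at
#' the planted voxels — lower FA, making the decision-value/score correlation
#' recoverable by construction.
#'
#' @param n_patients,n_controls Group sizes (each `>= 2`).
#' @param grid_shape Integer voxel triple.
#' @param voxel_size Voxel edge lengths in mm.
#' @param baseline_mean Baseline FA in (0, 1).
#' @param noise_sd Standard deviation of the i.i.d. voxel noise added before
#'   smoothing (FA units, `> 0`).
#' @param smooth_fwhm Gaussian smoothing FWHM in mm (0 disables smoothing).
#' @param effects List of [effect_spec()]s (may be empty for null cohorts).
#' @param score_intercept,score_slope,score_noise_sd Clinical-score model.
#' @param seed Integer RNG seed; fixed seed implies bit-identical cohorts.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 22L, n_controls = 26L,
                          grid_shape = c(48L, 48L, 48L),
                          voxel_size = c(2, 2, 2),
                          baseline_mean = 0.45, noise_sd = 0.1,
                          smooth_fwhm = 6,
                          effects = default_effects(grid_shape),
                          score_intercept = 55, score_slope = -15,
                          score_noise_sd = 4, seed = 1L) {
  n_patients <- as.integer(n_patients); n_controls <- as.integer(n_controls)
  if (n_patients < 2L || n_controls < 2L)
    stop("parameter error: both groups need at least 2 subjects", call. = FALSE)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("geometry error: grid_shape must be a positive voxel triple", call. = FALSE)
  if (!is.numeric(baseline_mean) || baseline_mean <= 0 || baseline_mean >= 1)
    stop("parameter error: baseline_mean must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("parameter error: noise_sd must be positive", call. = FALSE)
  if (smooth_fwhm < 0) stop("parameter error: smooth_fwhm must be >= 0", call. = FALSE)
  effects <- lapply(effects, function(e) {
    if (!inherits(e, "effect_spec")) e <- do.call(effect_spec, e)
    sphere_indices(e$center, e$radius, grid_shape)  # validates geometry
    e
  })
  structure(list(n_patients = n_patients, n_controls = n_controls,
                 grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
                 baseline_mean = baseline_mean, noise_sd = noise_sd,
                 smooth_fwhm = smooth_fwhm, effects = effects,
                 score_intercept = score_intercept, score_slope = score_slope,
                 score_noise_sd = score_noise_sd, seed = as.integer(seed)),
            class = "cohort_params")
}

#' Read cohort parameters from a YAML file
#'
#' The YAML keys mirror the arguments of [cohort_params()]; `effects` is a
#' list of mappings with `center`, `radius`, `delta`.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's value.
#' @return A [cohort_params()] object.
#' @export
cohort_params_from_yaml <- function(path, seed = NULL) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(cfg$effects))
    cfg$effects <- lapply(cfg$effects, function(e)
      effect_spec(unlist(e$center), e$radius, e$delta))
  do.call(cohort_params, cfg)
}

#' Generate a synthetic cohort
#'
#' Each subject volume is `baseline_mean` plus i.i.d. Gaussian voxel noise,
#' Gaussian-smoothed at `smooth_fwhm` (giving the spatially correlated noise
#' structure of smoothed FA maps); for patients each planted sphere then adds
#' `multiplier * delta`, and finally values are clipped to [0, 1]. One RNG
#' stream is seeded from `params$seed`; per-subject sub-seeds are drawn from
#' it first, so the generator is fully deterministic.
#'
#' @param params A [cohort_params()] object.
#' @return A [fa_cohort()]; patients carry clinical scores, controls `NA`.
#'   The per-patient severity multipliers are attached as attribute
#'   `"multipliers"`.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  np <- params$n_patients; nc <- params$n_controls
  n <- np + nc
  set.seed(params$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  mult <- pmin(pmax(rnorm(np, mean = 1, sd = 0.3), 0.1), 1.9)
  scores <- params$score_intercept + params$score_slope * mult +
    rnorm(np, 0, params$score_noise_sd)
  eff_idx <- lapply(params$effects, function(e)
    sphere_indices(e$center, e$radius, params$grid_shape))
  eff_delta <- vapply(params$effects, `[[`, numeric(1), "delta")

  make_volume <- function(i, patient) {
    set.seed(sub_seeds[i])
    vals <- array(params$baseline_mean +
                    rnorm(prod(params$grid_shape), 0, params$noise_sd),
                  dim = params$grid_shape)
    vol <- scalar_volume(vals, params$voxel_size)
    if (params$smooth_fwhm > 0) vol <- gaussian_smooth(vol, params$smooth_fwhm)
    if (patient && length(eff_idx)) {
      for (j in seq_along(eff_idx))
        vol$values[eff_idx[[j]]] <- vol$values[eff_idx[[j]]] + mult[i] * eff_delta[j]
    }
    vol$values[] <- pmin(pmax(vol$values, 0), 1)
    vol
  }

  volumes <- c(lapply(seq_len(np), make_volume, patient = TRUE),
               lapply(np + seq_len(nc), make_volume, patient = FALSE))
  cohort <- fa_cohort(volumes,
                      labels = c(rep(-1, np), rep(1, nc)),
                      subject_ids = c(sprintf("pat%03d", seq_len(np)),
                                      sprintf("ctl%03d", seq_len(nc))),
                      clinical_scores = c(scores, rep(NA_real_, nc)))
  attr(cohort, "multipliers") <- mult
  attr(cohort, "params") <- params
  cohort
}
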