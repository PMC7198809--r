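# Independent oracles used to check the package implementations.

# Brute-force soft-margin SVM dual solver: enumerate every active-set
# assignment (each point at 0, at C, or free), solve the KKT linear system for
# the free multipliers, keep KKT-feasible solutions and return the one with
# the largest dual objective. Exact for small n; independent of the SMO path.
qp_dual_oracle <- function(X, y, C = 1, tol = 1e-7) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  n <- nrow(X)
  K <- tcrossprod(X)
  Q <- (y %o% y) * K
  best <- NULL
  states <- expand.grid(rep(list(0:2), n))  # 0 = at 0, 1 = at C, 2 = free
  for (r in seq_len(nrow(states))) {
    st <- as.integer(states[r, ])
    free <- which(st == 2L); atC <- which(st == 1L)
    alpha <- numeric(n)
    alpha[atC] <- C
    if (length(free) > 0) {
      A <- rbind(cbind(Q[free, free, drop = FALSE], y[free]),
                 c(y[free], 0))
      contrib <- if (length(atC)) rowSums(Q[free, atC, drop = FALSE]) * C
                 else numeric(length(free))
      rhs <- c(rep(1, length(free)) - contrib, -sum(y[atC]) * C)
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      alpha[free] <- sol[seq_along(free)]
      lambda <- sol[length(sol)]
      if (any(alpha[free] < -tol) || any(alpha[free] > C + tol)) next
    } else {
      if (abs(sum(y * alpha)) > tol) next
      # any lambda in the feasible interval will do
      g <- drop(Q %*% alpha) - 1
      lo <- -Inf; hi <- Inf
      for (i in seq_len(n)) {
        mu_slope <- y[i]
        if (st[i] == 0L) {         # need g_i + lambda*y_i >= 0
          if (mu_slope > 0) lo <- max(lo, -g[i]) else hi <- min(hi, g[i])
        } else {                   # at C: need g_i + lambda*y_i <= 0
          if (mu_slope > 0) hi <- min(hi, -g[i]) else lo <- max(lo, g[i])
        }
      }
      if (lo > hi + tol) next
      lambda <- (max(lo, min(hi, 0)))
    }
    g <- drop(Q %*% alpha) - 1
    kkt <- g + lambda * y
    ok <- TRUE
    for (i in seq_len(n)) {
      if (st[i] == 0L && kkt[i] < -tol) ok <- FALSE
      if (st[i] == 1L && kkt[i] > tol) ok <- FALSE
      if (st[i] == 2L && abs(kkt[i]) > 1e-6) ok <- FALSE
    }
    if (!ok) next
    obj <- sum(alpha) - 0.5 * drop(alpha %*% Q %*% alpha)
    if (is.null(best) || obj > best$objective + 1e-12)
      best <- list(alpha = alpha, objective = obj,
                   w = drop(crossprod(X, alpha * y)))
  }
  best
}

# KKT residual check of a trained model on its own training data.
kkt_violation <- function(model, tol_alpha = 1e-8) {
  f <- decision_value(model, model$train_inputs)
  yf <- model$train_labels * f
  a <- model$alphas; C <- model$C
  worst <- 0
  for (j in seq_along(a)) {
    if (a[j] < tol_alpha) worst <- max(worst, 1 - yf[j])            # yf >= 1
    else if (a[j] > C - tol_alpha) worst <- max(worst, yf[j] - 1)   # yf <= 1
    else worst <- max(worst, abs(yf[j] - 1))
  }
  worst
}

svm_primal_objective <- function(model) {
  xi <- pmax(0, 1 - model$train_labels *
               decision_value(model, model$train_inputs))
  0.5 * sum(model$w^2) + model$C * sum(xi)
}

random_svm_instance <- function(n, k, seed) {
  set.seed(seed)
  repeat {
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) == 2L) break
  }
  list(X = matrix(rnorm(n * k), n, k), y = y)
}

# Stack-based flood fill: independent connected-component labelling.
flood_fill_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- voxsvm:::neighbour_offsets(connectivity)
  labels <- array(0L, d)
  cur <- 0L
  for (start in which(mask)) {
    if (labels[start] > 0L) next
    cur <- cur + 1L
    stack <- start
    labels[start] <- cur
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      vc <- arrayInd(v, d)
      for (t in seq_len(nrow(offs))) {
        nb <- vc + offs[t, ]
        if (any(nb < 1L) || any(nb > d)) next
        lin <- nb[1] + (nb[2] - 1L) * d[1] + (nb[3] - 1L) * d[1] * d[2]
        if (mask[lin] && labels[lin] == 0L) {
          labels[lin] <- cur
          stack <- c(stack, lin)
        }
      }
    }
  }
  labels
}

# Same partition? Compare as sets of voxel sets.
same_partition <- function(lab1, lab2) {
  s1 <- unname(split(which(lab1 > 0), lab1[lab1 > 0]))
  s2 <- unname(split(which(lab2 > 0), lab2[lab2 > 0]))
  key <- function(s) sort(vapply(s, function(v) paste(sort(v), collapse = ","),
                                 character(1)))
  identical(key(s1), key(s2))
}

# Direct (loop-based) separable Gaussian convolution with half-sample
# reflection, written independently of the package's matrix implementation.
naive_gauss_smooth <- function(a, sigma) {
  refl <- function(j, n) {
    while (j < 1L || j > n) {
      if (j < 1L) j <- 1L - j
      if (j > n) j <- 2L * n + 1L - j
    }
    j
  }
  conv1 <- function(v, s) {
    n <- length(v)
    r <- max(1L, as.integer(ceiling(4 * s)))
    w <- exp(-(-r:r)^2 / (2 * s^2)); w <- w / sum(w)
    out <- numeric(n)
    for (i in seq_len(n)) {
      acc <- 0
      for (t in -r:r) acc <- acc + w[t + r + 1L] * v[refl(i + t, n)]
      out[i] <- acc
    }
    out
  }
  d <- dim(a)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) a[x, y, ] <- conv1(a[x, y, ], sigma[3])
  for (x in seq_len(d[1])) for (z in seq_len(d[3])) a[x, , z] <- conv1(a[x, , z], sigma[2])
  for (y in seq_len(d[2])) for (z in seq_len(d[3])) a[, y, z] <- conv1(a[, y, z], sigma[1])
  a
}

# Tiny cohort helper used across files.
toy_cohort <- function(n_pat = 5, n_ctl = 5, grid = c(6, 6, 6), delta = -0.2,
                       noise_sd = 0.02, fwhm = 0, seed = 1,
                       effects = list(effect_spec(round(grid / 2), 1.5, delta))) {
  simulate_cohort(cohort_params(
    n_patients = n_pat, n_controls = n_ctl, grid_shape = grid,
    voxel_size = c(2, 2, 2), baseline_mean = 0.5, noise_sd = noise_sd,
    smooth_fwhm = fwhm, effects = effects, seed = seed))
}
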