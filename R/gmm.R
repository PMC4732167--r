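# Diagonal-covariance Gaussian mixture fitting by EM, used for the per-state
# emission models. Deliberately small and fixed-seed: k-means initialization,
# responsibility EM with a per-channel variance floor, relative log-likelihood
# convergence.

# Log density of each row of X (N x D) under each mixture component:
# returns N x M matrix of log(w_m) + log N(x | mu_m, diag(var_m)).
gmm_component_logdens <- function(X, weights, means, vars) {
  N <- nrow(X); M <- nrow(means)
  X2 <- X^2
  out <- matrix(0, N, M)
  for (m in seq_len(M)) {
    iv <- 1 / vars[m, ]
    const <- -0.5 * sum(log(2 * pi * vars[m, ])) + log(weights[m])
    out[, m] <- const - 0.5 *
      (X2 %*% iv - 2 * (X %*% (means[m, ] * iv)) + sum(means[m, ]^2 * iv))
  }
  out
}

row_max <- function(m) {
  out <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) out <- pmax(out, m[, j])
  out
}

# Per-observation mixture log density (N-vector).
gmm_logdens <- function(X, weights, means, vars) {
  lc <- gmm_component_logdens(X, weights, means, vars)
  m <- row_max(lc)
  m + log(rowSums(exp(lc - m)))
}

# Fit an M-component diagonal GMM. Variance floor: floor_frac times the
# per-channel variance of the training frames (never below .Machine eps).
fit_diag_gmm <- function(X, M = 3, max_iter = 200, tol = 1e-6,
                         floor_frac = 1e-6, seed = 0L) {
  N <- nrow(X); D <- ncol(X)
  if (N < 3 * D) {
    stop("insufficient frames for ", M, "-mode GMM: ", N, " frames of ",
         D, " channels", call. = FALSE)
  }
  vfloor <- pmax(floor_frac * apply(X, 2, var), 1e-12)

  init <- with_fixed_seed(seed, {
    # k-means init on (at most) a fixed-size subsample: the centers only seed
    # EM, which then sees every frame
    Xi <- if (N > 8192L) X[sample.int(N, 8192L), , drop = FALSE] else X
    uni <- unique(Xi)
    if (nrow(uni) < M) {
      # fewer distinct frames than components: duplicate centers, EM will
      # collapse weights as needed
      uni[rep(seq_len(nrow(uni)), length.out = M), , drop = FALSE]
    } else {
      stats::kmeans(Xi, centers = M, nstart = 5, iter.max = 50)$centers
    }
  })
  means <- matrix(init, M, D)
  vars <- matrix(rep(pmax(apply(X, 2, var), vfloor), each = M), M, D)
  weights <- rep(1 / M, M)

  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    lc <- gmm_component_logdens(X, weights, means, vars)
    mx <- row_max(lc)
    pr <- exp(lc - mx)
    rs <- rowSums(pr)
    ll <- sum(mx + log(rs))
    resp <- pr / rs
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-10)
    weights <- nk / N
    means <- crossprod(resp, X) / nk
    vars <- crossprod(resp, X^2) / nk - means^2
    vars <- sweep(vars, 2, vfloor, pmax)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  weights <- weights / sum(weights)
  # report the log-likelihood of the returned (post-update) parameters
  ll <- sum(gmm_logdens(X, weights, means, vars))
  list(weights = weights, means = means, vars = vars,
       loglik = ll, iterations = iter, variance_floor = vfloor)
}
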