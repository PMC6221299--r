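# Shared fixtures: small landscapes/rivers for fast tests, a pure-covariate
# strata generator for estimator-only checks, and brute-force oracles.

# average-rank Spearman correlation, written out by hand as an oracle
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

with_seed_test <- function(seed, code) {
  set.seed(seed)
  code
}

small_landscape <- function(seed = 1L, extent = c(4000, 4000), clusters = 6L) {
  generate_landscape(landscape_config(
    extent_m = extent, structure_clusters = clusters, seed = seed
  ))
}

small_river <- function(seed = 1L, extent = c(4000, 4000)) {
  generate_river(
    river_config(bridge_spacing_m = 1500, sinuosity_amp_m = 300,
                 sinuosity_wavelength_m = 3000, seed = seed),
    extent_m = extent
  )
}

# strata with iid Gaussian covariates and softmax-chosen used rows: the
# conditional-logit DGP stripped of all spatial structure. One cluster per
# `cluster_of` entry (default: each stratum its own cluster).
gauss_strata <- function(n_strata, S, beta, seed = 1L, cluster_of = NULL) {
  set.seed(seed)
  p <- length(beta)
  n <- n_strata * S
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  sid <- rep(seq_len(n_strata), each = S)
  lp <- drop(X %*% beta)
  used <- integer(n)
  for (s in seq_len(n_strata)) {
    ii <- which(sid == s)
    w <- exp(lp[ii] - max(lp[ii]))
    used[ii[sample.int(S, 1, prob = w)]] <- 1L
  }
  cl <- if (is.null(cluster_of)) sid else cluster_of[sid]
  out <- data.frame(stratum_id = sid, cluster_id = cl, is_used = used,
                    period = "diurnal")
  out <- cbind(out, as.data.frame(X))
  structure(out, covariates = colnames(X), M = S - 1L, radius_m = NA,
            seed = seed, standardization = NULL,
            class = c("strata_set", "data.frame"))
}

# O(n^2) loop oracle for the conditional log-likelihood, gradient and
# cluster sandwich; deliberately naive
oracle_cll <- function(beta, X, sid, used) {
  ll <- 0
  grad <- numeric(ncol(X))
  for (s in unique(sid)) {
    ii <- which(sid == s)
    num <- exp(drop(X[ii, , drop = FALSE] %*% beta))
    den <- sum(num)
    iu <- ii[used[ii] == 1L]
    ll <- ll + as.numeric(X[iu, , drop = FALSE] %*% beta) - log(den)
    xbar <- numeric(ncol(X))
    for (k in seq_along(ii)) xbar <- xbar + num[k] / den * X[ii[k], ]
    grad <- grad + X[iu, ] - xbar
  }
  list(ll = ll, gradient = grad)
}

oracle_sandwich <- function(fit, X, sid, used, cl) {
  p <- length(fit$coefficients)
  eta <- drop(X %*% fit$coefficients)
  U <- matrix(0, length(unique(cl)), p)
  rownames(U) <- as.character(unique(cl))
  for (s in unique(sid)) {
    ii <- which(sid == s)
    w <- exp(eta[ii] - max(eta[ii]))
    w <- w / sum(w)
    score_s <- numeric(p)
    for (k in seq_along(ii)) {
      score_s <- score_s + (used[ii[k]] - w[k]) * X[ii[k], ]
    }
    cc <- as.character(cl[ii[1]])
    U[cc, ] <- U[cc, ] + score_s
  }
  g <- nrow(U)
  B <- matrix(0, p, p)
  for (c1 in seq_len(g)) B <- B + U[c1, ] %o% U[c1, ]
  B <- B * g / (g - 1)
  fit$naive_vcov %*% B %*% fit$naive_vcov
}
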