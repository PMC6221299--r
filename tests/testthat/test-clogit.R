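test_that("uniform probabilities give -log(stratum size) per stratum", {
  S <- gauss_strata(1, 51, beta = c(0.5, -0.5), seed = 1)
  X <- build_model_matrix(S, ~ x1 + x2)
  ll <- conditional_loglik(c(0, 0), X, S$stratum_id, S$is_used)
  expect_equal(as.numeric(ll), -log(51), tolerance = 1e-12)
})

test_that("the conditional likelihood is invariant to per-stratum covariate shifts", {
  S <- gauss_strata(6, 8, beta = c(1, -0.7), seed = 2)
  X <- build_model_matrix(S, ~ x1 + x2)
  beta <- c(0.4, 0.2)
  ll0 <- as.numeric(conditional_loglik(beta, X, S$stratum_id, S$is_used))
  Xs <- X
  Xs[S$stratum_id == 3L, ] <- Xs[S$stratum_id == 3L, ] + 5
  lls <- as.numeric(conditional_loglik(beta, Xs, S$stratum_id, S$is_used))
  expect_equal(lls, ll0, tolerance = 1e-10)

  f0 <- craneRSF:::fit_clogit_xy(X, S$stratum_id, S$is_used, S$cluster_id)
  fs <- craneRSF:::fit_clogit_xy(Xs, S$stratum_id, S$is_used, S$cluster_id)
  expect_equal(fs$coefficients, f0$coefficients, tolerance = 1e-8)
})

test_that("likelihood, gradient and sandwich match brute-force loop oracles", {
  for (seed in 1:5) {
    n_strata <- 7 + (seed %% 4)                 # 7..10 strata of size 4..6
    S <- gauss_strata(n_strata, S = 4 + (seed %% 3), beta = c(0.5, -0.3, 0.1),
                      seed = seed, cluster_of = rep(1:2, length.out = n_strata))
    X <- build_model_matrix(S, ~ x1 + x2 + x3)
    beta <- rnorm(3, 0, 0.5)
    got <- conditional_loglik(beta, X, S$stratum_id, S$is_used,
                              derivatives = TRUE)
    want <- oracle_cll(beta, X, S$stratum_id, S$is_used)
    expect_equal(as.numeric(got), want$ll, tolerance = 1e-10)
    expect_equal(attr(got, "gradient"), want$gradient, tolerance = 1e-10)

    fit <- craneRSF:::fit_clogit_xy(X, S$stratum_id, S$is_used, S$cluster_id)
    V <- oracle_sandwich(fit, X, S$stratum_id, S$is_used, S$cluster_id)
    expect_equal(unname(fit$robust_vcov), unname(V), tolerance = 1e-12)
  }
})

test_that("hessian matches central finite differences of the gradient", {
  S <- gauss_strata(5, 6, beta = c(0.5, -1), seed = 3)
  X <- build_model_matrix(S, ~ x1 + x2)
  beta <- c(0.3, -0.4)
  g <- function(b) attr(conditional_loglik(b, X, S$stratum_id, S$is_used,
                                           derivatives = TRUE), "gradient")
  H <- attr(conditional_loglik(beta, X, S$stratum_id, S$is_used,
                               derivatives = TRUE), "hessian")
  eps <- 1e-6
  for (j in 1:2) {
    e <- c(0, 0); e[j] <- eps
    expect_equal(H[, j], (g(beta + e) - g(beta - e)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("tiny-instance estimate matches a dense likelihood grid search", {
  S <- gauss_strata(8, 5, beta = c(0.6, -0.4), seed = 5)
  X <- build_model_matrix(S, ~ x1 + x2)
  fit <- craneRSF:::fit_clogit_xy(X, S$stratum_id, S$is_used, S$cluster_id)
  expect_lt(max(abs(fit$coefficients)), 3)     # interior maximum
  ll_at <- function(b1, b2) {
    as.numeric(conditional_loglik(c(b1, b2), X, S$stratum_id, S$is_used))
  }
  ## coarse grid over a bounded box, then a fine grid around the maximum
  g1 <- seq(-4, 4, by = 0.05)
  coarse <- outer(g1, g1, Vectorize(ll_at))
  i <- which(coarse == max(coarse), arr.ind = TRUE)[1, ]
  c1 <- g1[i[1]]; c2 <- g1[i[2]]
  f1 <- seq(c1 - 0.06, c1 + 0.06, by = 5e-4)
  f2 <- seq(c2 - 0.06, c2 + 0.06, by = 5e-4)
  fine <- outer(f1, f2, Vectorize(ll_at))
  j <- which(fine == max(fine), arr.ind = TRUE)[1, ]
  expect_equal(unname(fit$coefficients), c(f1[j[1]], f2[j[2]]),
               tolerance = 1e-3)
})

test_that("the score vanishes at every converged estimate", {
  for (seed in 1:3) {
    S <- gauss_strata(30, 6, beta = c(0.5, -0.5), seed = seed)
    X <- build_model_matrix(S, ~ x1 + x2)
    fit <- craneRSF:::fit_clogit_xy(X, S$stratum_id, S$is_used, S$cluster_id)
    expect_true(fit$converged)
    g <- attr(conditional_loglik(fit$coefficients, X, S$stratum_id, S$is_used,
                                 derivatives = TRUE), "gradient")
    expect_lt(max(abs(g)), 1e-8)
  }
})

test_that("unidentifiable and degenerate designs are rejected with diagnostics", {
  S <- gauss_strata(5, 6, beta = c(0.5), seed = 7)
  ## a covariate constant within every stratum
  S$xc <- rep(seq_len(5), each = 6)
  expect_error(fit_clogit(S, ~ x1 + xc), "constant within every stratum")
  ## exact duplicate column
  S$xdup <- S$x1
  expect_error(fit_clogit(S, ~ x1 + xdup), "rank deficient")
  ## separation: the used row always has the strictly largest covariate
  S2 <- gauss_strata(20, 4, beta = c(0), seed = 8)
  ord <- order(S2$stratum_id, -S2$is_used)
  S2 <- S2[ord, ]
  S2$xsep <- ifelse(S2$is_used == 1L, 10, rnorm(nrow(S2)))
  expect_error(fit_clogit(S2, ~ xsep), "separation|unbounded")
})

test_that("duplicating every cluster leaves the estimate unchanged", {
  S <- gauss_strata(12, 5, beta = c(0.7, -0.2), seed = 9,
                    cluster_of = rep(1:3, each = 4))
  f1 <- fit_clogit(S, ~ x1 + x2)
  S2 <- S
  S2$stratum_id <- S2$stratum_id + 100L
  S2$cluster_id <- paste0(S2$cluster_id, "_copy")
  Sd <- rbind(as.data.frame(S), as.data.frame(S2))
  attributes(Sd)$covariates <- attr(S, "covariates")
  class(Sd) <- c("strata_set", "data.frame")
  f2 <- fit_clogit(Sd, ~ x1 + x2)
  expect_equal(f2$coefficients, f1$coefficients, tolerance = 1e-7)
})

test_that("robust and naive standard errors agree under independent clusters", {
  ## every stratum its own cluster, correctly specified model
  set.seed(42)
  ratios <- replicate(200, {
    seed <- sample.int(1e6, 1)
    S <- gauss_strata(80, 6, beta = c(0.6, -0.4), seed = seed)
    f <- fit_clogit(S, ~ x1 + x2)
    mean(sqrt(diag(f$robust_vcov)) / sqrt(diag(f$naive_vcov)))
  })
  expect_lt(abs(mean(ratios) - 1), 0.15)
})

test_that("estimates and cluster variance line up with package survival", {
  skip_if_not_installed("survival")
  L <- small_landscape()
  S <- simulate_strata(L, truth = true_model(), period = "diurnal",
                       n_clusters = 8, strata_per_cluster = 25, seed = 7)
  f <- fit_clogit(S, ~ ownership + dens500 + dist_structure_km)
  d <- as.data.frame(S)
  cf <- survival::coxph(
    survival::Surv(rep(1, nrow(d)), is_used) ~ ownership + dens500 +
      dist_structure_km + survival::strata(stratum_id),
    data = d, ties = "breslow", cluster = cluster_id, robust = TRUE
  )
  expect_equal(unname(f$coefficients), unname(coef(cf)), tolerance = 1e-6)
  g <- length(unique(S$cluster_id))
  expect_equal(unname(diag(f$robust_vcov)),
               unname(diag(vcov(cf))) * g / (g - 1), tolerance = 1e-6)
  expect_equal(unname(diag(f$naive_vcov)), unname(diag(cf$naive.var)),
               tolerance = 1e-6)
})

test_that("QIC reduces to the AIC-like limit when the sandwich equals the naive", {
  S <- gauss_strata(40, 6, beta = c(0.5, -0.5, 0.2), seed = 10)
  f <- fit_clogit(S, ~ x1 + x2 + x3)
  f$robust_vcov <- f$naive_vcov
  expect_equal(qic(f), -2 * f$loglik + 2 * 3, tolerance = 1e-10)
})

test_that("VIF follows the closed form and flags collinear columns", {
  set.seed(4)
  n <- 4000
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  S <- data.frame(x1 = x1, x2 = x2)
  v <- vif_screen(S, ~ x1 + x2, threshold = 5)
  expect_true(all(abs(v$vif - 1) < 0.05))
  expect_length(v$flagged, 0)

  rho <- 0.9
  x3 <- rho * x1 + sqrt(1 - rho^2) * rnorm(n)
  S2 <- data.frame(x1 = x1, x3 = x3)
  v2 <- vif_screen(S2, ~ x1 + x3, threshold = 5)
  expect_equal(unname(v2$vif), rep(1 / (1 - cor(x1, x3)^2), 2), tolerance = 1e-9)
  expect_true(abs(v2$vif[["x1"]] - 5.26) < 0.75)
  expect_setequal(v2$flagged, c("x1", "x3"))

  S3 <- data.frame(x1 = x1, xdup = x1)
  v3 <- vif_screen(S3, ~ x1 + xdup, threshold = 5)
  expect_true(all(is.infinite(v3$vif)))
})
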