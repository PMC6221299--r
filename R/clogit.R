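#' Conditional logistic log-likelihood for matched sets
#'
#' The conditional likelihood of a matched used--available design: within
#' each stratum (one used plus its availables), the probability that the
#' used row is the one observed is the softmax of the linear predictors, so
#'
#' \deqn{\ell(\beta) = \sum_s \left[ x_{u(s)}'\beta -
#'   \log \sum_{j \in s} e^{x_j'\beta} \right].}
#'
#' The gradient is the summed difference between the used row's covariates
#' and the stratum's softmax-weighted mean covariates; the Hessian is minus
#' the summed softmax-weighted covariance. Stratum intercepts cancel, so
#' per-stratum covariate shifts leave the likelihood unchanged.
#'
#' @param beta coefficient vector
#' @param X design matrix (rows = design rows)
#' @param stratum stratum id per row
#' @param used 0/1 used indicator per row (exactly one 1 per stratum)
#' @param derivatives if `TRUE`, also return gradient and Hessian
#' @return the log-likelihood, with attributes `gradient` and `hessian` when
#'   requested
#' @export
conditional_loglik <- function(beta, X, stratum, used, derivatives = FALSE) {
  if (!all(is.finite(X))) stop("non-finite covariates in design matrix")
  sid <- match(stratum, unique(stratum))
  cll_core(beta, X, sid, used, derivatives)
}

## hot loop: sid must be a dense integer stratum index (1..ns, any order)
cll_core <- function(beta, X, sid, used, derivatives = FALSE) {
  eta <- X %*% beta
  ## centre by the stratum maximum only when exp() could overflow
  if (max(abs(eta)) > 500) {
    smax <- as.numeric(tapply(eta, sid, max))
    e <- exp(eta - smax[sid])
    denom <- as.numeric(rowsum(e, sid, reorder = TRUE)[, 1L])
    lse <- log(denom) + smax
  } else {
    e <- exp(eta)
    denom <- as.numeric(rowsum(e, sid, reorder = TRUE)[, 1L])
    lse <- log(denom)
  }
  ll <- sum(eta[used == 1L]) - sum(lse)
  if (!derivatives) return(ll)
  w <- as.numeric(e) / denom[sid]
  resid <- (used == 1L) - w
  grad <- drop(crossprod(X, resid))
  Xbar <- rowsum(w * X, sid, reorder = FALSE)     # per-stratum weighted mean
  H <- -(crossprod(X, w * X) - crossprod(Xbar))
  structure(ll, gradient = grad, hessian = H)
}

## column is constant within every stratum -> not identified
constant_within_strata <- function(X, stratum) {
  vapply(seq_len(ncol(X)), function(j) {
    rng <- tapply(X[, j], stratum, function(v) diff(range(v)))
    all(rng < 1e-12)
  }, TRUE)
}

#' Fit a conditional logistic regression to a strata set
#'
#' Newton--Raphson maximization of the matched-set conditional likelihood
#' with step-halving, treating strata as independent (the GEE independence
#' working model). Inference uses the cluster-robust sandwich: score
#' contributions are summed within each cluster (individual bird), so
#' within-individual dependence among strata inflates the standard errors
#' rather than biasing them. The Quasi-likelihood under Independence
#' Criterion (QIC, Pan 2001 form) is computed from the independence
#' quasi-likelihood and the trace of (naive information x robust
#' covariance).
#'
#' @param strata a `strata_set` from [build_strata()] or [simulate_strata()]
#' @param formula RHS model formula over the strata covariates
#' @param init optional starting coefficients (default 0)
#' @param tol convergence tolerance on the maximum absolute score
#' @param max_iter maximum Newton iterations
#' @return a `crane_clogit` fit: `coefficients`, `naive_vcov`,
#'   `robust_vcov`, `loglik`, `qic`, `converged`, `iterations`, `n_strata`,
#'   `n_clusters`, `formula`, plus the fitting frame needed for prediction
#' @export
fit_clogit <- function(strata, formula, init = NULL, tol = 1e-8,
                       max_iter = 50L) {
  X <- build_model_matrix(strata, formula)
  fit_clogit_xy(
    X, strata$stratum_id, strata$is_used, strata$cluster_id,
    init = init, tol = tol, max_iter = max_iter, formula = formula,
    standardization = attr(strata, "standardization")
  )
}

## matrix-level fitter; exported pieces wrap this
fit_clogit_xy <- function(X, stratum, used, cluster, init = NULL,
                          tol = 1e-8, max_iter = 50L, formula = NULL,
                          standardization = NULL) {
  if (any(rowsum(used, stratum)[, 1L] != 1L)) {
    stop("every stratum must contain exactly one used row")
  }
  const <- constant_within_strata(X, stratum)
  if (any(const)) {
    stop("covariate(s) constant within every stratum cannot be identified ",
         "by the conditional likelihood: ",
         paste(colnames(X)[const], collapse = ", "))
  }
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient (exactly collinear columns)")
  }
  if (!all(is.finite(X))) stop("non-finite covariates in design matrix")
  p <- ncol(X)
  sid <- match(stratum, unique(stratum))
  beta <- if (is.null(init)) rep(0, p) else init
  ll <- cll_core(beta, X, sid, used, derivatives = TRUE)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    g <- attr(ll, "gradient")
    H <- attr(ll, "hessian")
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(-H, g), error = function(e) {
      stop("singular information matrix at iteration ", iter,
           " (possible separation)")
    })
    lam <- 1
    for (h in seq_len(10L)) {
      cand <- beta + lam * step
      ll_cand <- cll_core(cand, X, sid, used, derivatives = FALSE)
      ## scale-aware: near the optimum the true improvement is below the
      ## floating-point resolution of ll, and the full step must be accepted
      if (ll_cand > as.numeric(ll) - (abs(as.numeric(ll)) + 1) * 1e-10) break
      lam <- lam / 2
    }
    beta <- cand
    ll <- cll_core(beta, X, sid, used, derivatives = TRUE)
    if (any(abs(beta) > 500)) {
      j <- which.max(abs(beta))
      stop("likelihood appears unbounded (separation) in covariate: ",
           colnames(X)[j])
    }
    if (max(abs(attr(ll, "gradient"))) < tol) { converged <- TRUE; break }
  }
  names(beta) <- colnames(X)
  if (converged) {
    ## a perfectly predicted design (every used row carries essentially the
    ## whole stratum mass) means the likelihood is unbounded: the score
    ## saturates numerically but the MLE does not exist
    eta_f <- drop(X %*% beta)
    e_f <- exp(eta_f - as.numeric(tapply(eta_f, sid, max))[sid])
    w_used <- e_f[used == 1L] /
      as.numeric(rowsum(e_f, sid, reorder = TRUE)[, 1L])
    if (all(w_used > 1 - 1e-7)) {
      j <- which.max(abs(beta))
      stop("likelihood appears unbounded (separation): the fit predicts ",
           "every used row perfectly; largest coefficient: ", colnames(X)[j])
    }
  }
  A <- -attr(ll, "hessian")                      # naive information
  naive_vcov <- solve(A)
  dimnames(naive_vcov) <- list(colnames(X), colnames(X))

  fit <- structure(
    list(
      coefficients = beta,
      naive_vcov = naive_vcov,
      loglik = as.numeric(ll),
      converged = converged,
      iterations = iter,
      n_strata = length(unique(stratum)),
      n_clusters = length(unique(cluster)),
      formula = formula,
      qic_variant = "Pan2001-independence",
      standardization = standardization,
      X = X, stratum = stratum, used = used, cluster = cluster
    ),
    class = "crane_clogit"
  )
  fit$robust_vcov <- robust_vcov(fit)
  fit$qic <- qic(fit)
  fit
}

#' Cluster-robust sandwich covariance of a fit
#'
#' \eqn{A^{-1} B A^{-1}} with \eqn{A} the observed information at the
#' estimate and \eqn{B = \frac{g}{g-1}\sum_c U_c U_c'}, where \eqn{U_c} sums
#' the per-stratum score contributions over the strata of cluster \eqn{c}
#' and \eqn{g} is the number of clusters (the small-sample factor
#' \eqn{g/(g-1)} is applied).
#'
#' @param fit a `crane_clogit`
#' @param cluster optional replacement cluster labels per design row
#' @return robust covariance matrix
#' @export
robust_vcov <- function(fit, cluster = NULL) {
  if (!fit$converged) stop("robust variance requires a converged fit")
  cl <- if (is.null(cluster)) fit$cluster else cluster
  g <- length(unique(cl))
  if (g < 2L) stop("cluster sandwich undefined with fewer than 2 clusters")
  eta <- drop(fit$X %*% fit$coefficients)
  sid <- match(fit$stratum, unique(fit$stratum))
  smax <- as.numeric(tapply(eta, sid, max))
  e <- exp(eta - smax[sid])
  w <- e / as.numeric(rowsum(e, sid)[, 1L])[sid]
  resid <- (fit$used == 1L) - w
  U <- rowsum(resid * fit$X, cl)                 # per-cluster score sums
  B <- crossprod(U) * g / (g - 1)
  Ainv <- fit$naive_vcov
  V <- Ainv %*% B %*% Ainv
  (V + t(V)) / 2
}

#' Quasi-likelihood under Independence Criterion
#'
#' \eqn{QIC = -2 Q(\hat\beta) + 2\,\mathrm{tr}(\hat A \hat V_r)} with
#' \eqn{Q} the independence conditional log-quasi-likelihood, \eqn{\hat A}
#' the naive information and \eqn{\hat V_r} the cluster-robust covariance.
#' When the model is correctly specified and clustering is ignorable the
#' trace approaches the parameter count and QIC reduces to AIC.
#'
#' @param fit a `crane_clogit`
#' @return QIC value
#' @export
qic <- function(fit) {
  if (!fit$converged) stop("QIC requires a converged fit")
  A <- solve(fit$naive_vcov)
  -2 * fit$loglik + 2 * sum(diag(A %*% fit$robust_vcov))
}

#' Variance inflation factor screen
#'
#' Computes \eqn{VIF_k = 1/(1 - R^2_k)} from regressing each design-matrix
#' column on the others over all design rows (one-hot columns are screened
#' individually). Columns at or above the threshold are flagged for
#' exclusion from the model in which they co-occur; exact collinearity
#' reports an infinite VIF.
#'
#' @param strata a `strata_set` or data.frame of covariates
#' @param formula RHS model formula
#' @param threshold flag columns with VIF at or above this value
#' @return list with `vif` (named), `flagged` (character), `keep` (character)
#' @export
vif_screen <- function(strata, formula,
                       threshold = study_constants()$vif_threshold) {
  X <- build_model_matrix(strata, formula)
  if (ncol(X) < 2L) stop("VIF screening needs at least 2 covariates")
  vif <- vapply(seq_len(ncol(X)), function(j) {
    y <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.fit(Z, y)
    ssr <- sum(fit$residuals^2)
    sst <- sum((y - mean(y))^2)
    if (sst == 0) return(Inf)
    if (ssr / sst < 1e-12) Inf else 1 / (ssr / sst)
  }, 1)
  names(vif) <- colnames(X)
  flagged <- names(vif)[vif >= threshold]
  list(vif = vif, flagged = flagged, keep = setdiff(names(vif), flagged))
}

#' @export
print.crane_clogit <- function(x, ...) {
  se <- sqrt(diag(x$robust_vcov))
  z <- x$coefficients / se
  tab <- data.frame(
    estimate = round(x$coefficients, 4),
    robust_se = round(se, 4),
    z = round(z, 2),
    p = signif(2 * stats::pnorm(-abs(z)), 3)
  )
  cat(sprintf(
    "Conditional logistic fit: %d strata, %d clusters, %s\n",
    x$n_strata, x$n_clusters,
    if (x$converged) sprintf("converged in %d iterations", x$iterations)
    else "NOT converged"
  ))
  print(tab)
  cat(sprintf("Quasi-loglik %.3f, QIC %.3f\n", x$loglik, x$qic))
  invisible(x)
}

#' @export
coef.crane_clogit <- function(object, ...) object$coefficients

#' @export
vcov.crane_clogit <- function(object, type = c("robust", "naive"), ...) {
  type <- match.arg(type)
  if (type == "robust") object$robust_vcov else object$naive_vcov
}

#' @export
logLik.crane_clogit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients), class = "logLik")
}

#' Serialize a fit to JSON
#' @param fit a `crane_clogit`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fit_json <- function(fit, path) {
  se <- sqrt(diag(fit$robust_vcov))
  obj <- list(
    coefficients = as.list(fit$coefficients),
    robust_se = as.list(stats::setNames(se, names(fit$coefficients))),
    naive_se = as.list(stats::setNames(sqrt(diag(fit$naive_vcov)),
                                       names(fit$coefficients))),
    loglik = fit$loglik, qic = fit$qic,
    converged = fit$converged, iterations = fit$iterations,
    n_strata = fit$n_strata, n_clusters = fit$n_clusters,
    qic_variant = fit$qic_variant,
    formula = if (!is.null(fit$formula)) deparse(fit$formula) else NULL
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
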