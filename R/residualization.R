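# First stage of the two-stage residual analysis: per-species PCA of
# environmental covariates, a zero-inflated Poisson regression on retained
# axes plus fixed covariates, response-residual extraction, and the Mantel
# spatial-autocorrelation check.

#' Per-species principal component analysis of environmental covariates
#'
#' Covariates are standardized to zero mean and unit variance before the
#' decomposition; axes are ordered by decreasing variance and the retained
#' set is those axes whose variance fraction strictly exceeds `retention`.
#' Constant covariates are dropped with a warning before decomposition.
#'
#' @param covariate_matrix Numeric matrix or data.frame, rows = sites.
#' @param retention Variance-fraction retention threshold (strict `>`).
#' @return An object of class `pca_result`: `loadings` (covariates x axes),
#'   `scores` (rows x axes), `variance_fraction`, `retained_axes`.
#' @export
species_pca <- function(covariate_matrix, retention = 0.10) {
  X <- as.matrix(covariate_matrix)
  if (nrow(X) < 2 || ncol(X) < 2) stop("need >= 2 rows and >= 2 covariates")
  sds <- apply(X, 2, stats::sd)
  if (all(sds == 0)) stop("all covariates are constant")
  if (any(sds == 0)) {
    warning("dropping constant covariates: ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    loadings = pc$rotation,
    scores = pc$x,
    variance_fraction = vf,
    retained_axes = which(vf > retention),
    center = pc$center, scale = pc$scale
  ), class = "pca_result")
}

# Negative ZIP log-likelihood and analytic gradient. Parameters:
# par = (gamma, beta): gamma = logit(pi) (intercept-only inflation part),
# beta = count-part coefficients on X (log link). lgamma(y+1) is used so
# non-integer site-averaged densities are tolerated.
zip_negloglik <- function(par, y, X) {
  gamma <- par[1]; beta <- par[-1]
  eta <- drop(X %*% beta)
  eta <- pmin(eta, 30)  # guard overflow
  lambda <- exp(eta)
  p <- stats::plogis(gamma)
  is0 <- y == 0
  ll <- numeric(length(y))
  ll[is0] <- log(p + (1 - p) * exp(-lambda[is0]))
  ll[!is0] <- log1p(-p) + y[!is0] * eta[!is0] - lambda[!is0] -
    lgamma(y[!is0] + 1)
  -sum(ll)
}

zip_negloglik_grad <- function(par, y, X) {
  gamma <- par[1]; beta <- par[-1]
  eta <- pmin(drop(X %*% beta), 30)
  lambda <- exp(eta)
  p <- stats::plogis(gamma)
  q <- 1 - p
  is0 <- y == 0
  g_gamma <- numeric(length(y))
  w_beta <- numeric(length(y))
  if (any(is0)) {
    a <- p + q * exp(-lambda[is0])
    g_gamma[is0] <- p * q * (1 - exp(-lambda[is0])) / a
    w_beta[is0] <- -q * exp(-lambda[is0]) * lambda[is0] / a
  }
  if (any(!is0)) {
    g_gamma[!is0] <- -p
    w_beta[!is0] <- y[!is0] - lambda[!is0]
  }
  -c(sum(g_gamma), drop(crossprod(X, w_beta)))
}

# Build a full-rank design matrix with intercept from a data.frame/matrix;
# zero-variance and aliased columns are dropped (recorded in `dropped`).
build_design <- function(design) {
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0 | !is.finite(sds)]
  X <- X[, sds > 0 & is.finite(sds), drop = FALSE]
  X <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- c(dropped, colnames(X)[-keep])
    X <- X[, keep, drop = FALSE]
  }
  list(X = X, dropped = dropped)
}

#' Fit a zero-inflated Poisson regression
#'
#' Maximizes the ZIP log-likelihood `P(0) = pi + (1 - pi) e^{-lambda}`,
#' `P(y > 0) = (1 - pi) Poisson(y; lambda)` with a log link on `lambda` and
#' an intercept-only logit link on `pi`, by BFGS with analytic gradient.
#' Zero-variance or aliased design columns are dropped to keep the design
#' full rank. On optimizer failure the species is routed to a plain Poisson
#' GLM fallback with a warning.
#'
#' @param abundance Non-negative counts (site-averaged densities allowed).
#' @param design Data.frame or matrix of covariates (no intercept column);
#'   typically retained PCA scores plus depth, protection and sampling
#'   intensity.
#' @param max_iter Maximum BFGS iterations.
#' @return An object of class `zip_fit`: `coefficients` (`count`,
#'   `inflation`), `pi`, `loglik`, `loglik_init`, `converged`, `fallback`,
#'   `vcov`, fitted `lambda` and `mu = (1 - pi) lambda`, and the design used.
#' @export
fit_zip <- function(abundance, design, max_iter = 500) {
  y <- as.numeric(abundance)
  if (any(y < 0)) stop("abundance must be non-negative")
  if (!any(y == 0) || !any(y > 0)) {
    stop("response must contain at least one zero and one positive count")
  }
  bd <- build_design(design)
  X <- bd$X
  # Poisson init for the count part; moment-style init for the inflation part
  pois <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson()))
  beta0 <- pois$coefficients
  beta0[!is.finite(beta0)] <- 0
  mu0 <- exp(pmin(drop(X %*% beta0), 30))
  p0_obs <- mean(y == 0)
  p0_pois <- mean(exp(-mu0))
  pi0 <- min(0.9, max(0.02, (p0_obs - p0_pois) / max(1e-6, 1 - p0_pois)))
  par0 <- c(stats::qlogis(pi0), beta0)
  ll_init <- -zip_negloglik(par0, y, X)
  opt <- tryCatch(
    stats::optim(par0, zip_negloglik, zip_negloglik_grad, y = y, X = X,
                 method = "BFGS", hessian = TRUE,
                 control = list(maxit = max_iter, reltol = 1e-10)),
    error = function(e) NULL
  )
  ok <- !is.null(opt) && opt$convergence == 0 && is.finite(opt$value)
  if (!ok) {
    warning("ZIP fit did not converge; falling back to Poisson GLM")
    return(poisson_fallback(y, X, bd$dropped))
  }
  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  gamma <- opt$par[1]
  beta <- opt$par[-1]
  names(beta) <- colnames(X)
  lambda <- exp(pmin(drop(X %*% beta), 30))
  pi_hat <- stats::plogis(gamma)
  structure(list(
    coefficients = list(count = beta, inflation = c(logit_pi = gamma)),
    pi = pi_hat,
    loglik = -opt$value,
    loglik_init = ll_init,
    converged = TRUE,
    fallback = FALSE,
    vcov = vc,
    lambda = lambda,
    mu = (1 - pi_hat) * lambda,
    X = X,
    dropped = bd$dropped
  ), class = "zip_fit")
}

# Plain Poisson GLM wrapped as a zip_fit (pi = 0), used when the ZIP
# optimizer fails (separation / non-convergence).
poisson_fallback <- function(y, X, dropped) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson()))
  beta <- fit$coefficients
  names(beta) <- colnames(X)
  lambda <- exp(pmin(drop(X %*% beta), 30))
  structure(list(
    coefficients = list(count = beta, inflation = c(logit_pi = -Inf)),
    pi = 0,
    loglik = sum(stats::dpois(round(y), lambda, log = TRUE)),
    loglik_init = NA_real_,
    converged = fit$converged,
    fallback = TRUE,
    vcov = NULL,
    lambda = lambda,
    mu = lambda,
    X = X,
    dropped = dropped
  ), class = "zip_fit")
}

#' @export
print.zip_fit <- function(x, ...) {
  cat("Zero-inflated Poisson fit",
      if (x$fallback) "(Poisson fallback)" else "", "\n")
  cat("  pi =", format(x$pi, digits = 3),
      " logLik =", format(x$loglik, digits = 6),
      " converged:", x$converged, "\n")
  cat("  count coefficients:\n")
  print(x$coefficients$count, ...)
  invisible(x)
}

#' Extract response residuals from a first-stage fit
#'
#' Residuals on the count scale: `y - mu_hat` with
#' `mu_hat = (1 - pi_hat) * lambda_hat`.
#'
#' @param fit A [fit_zip()] result.
#' @param frame The modelling frame the fit was computed on (supplies `sst`
#'   and `abundance`).
#' @return A data.frame of class `residual_series` with columns `sst` and
#'   `residual`, one row per frame row.
#' @export
extract_residuals <- function(fit, frame) {
  if (!inherits(fit, "zip_fit")) stop("`fit` must be a zip_fit")
  if (nrow(frame) != length(fit$mu)) {
    stop("frame does not match the fitted model rows")
  }
  out <- data.frame(sst = frame$sst,
                    residual = frame$abundance - fit$mu)
  class(out) <- c("residual_series", "data.frame")
  out
}

# All permutations of 1..n (small n only), for the exhaustive Mantel mode.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1)))
  }
  out
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower triangles, with significance from random
#' permutations of one matrix's rows and columns:
#' `p = (1 + #\{permuted r >= observed r\}) / (n_perm + 1)`. With
#' `exact = TRUE` (matrices up to 7 x 7) the permutation distribution is
#' enumerated exhaustively and `p` is the fraction of all `n!` permutations
#' (identity included) with `r >= observed`.
#'
#' @param geo_dist,resid_dist Square symmetric matrices of equal dimension
#'   (>= 3).
#' @param n_perm Number of random permutations.
#' @param seed Integer seed for the permutations.
#' @param exact Enumerate all permutations instead of sampling.
#' @return List with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(geo_dist, resid_dist, n_perm = 999, seed = 1,
                        exact = FALSE) {
  A <- as.matrix(geo_dist); B <- as.matrix(resid_dist)
  n <- nrow(A)
  if (!all(dim(A) == dim(B)) || nrow(A) != ncol(A)) {
    stop("matrices must be square and of matching dimension")
  }
  if (n < 3) stop("need matrices of dimension >= 3")
  lt <- lower.tri(A)
  a <- A[lt]
  r_obs <- stats::cor(a, B[lt])
  if (exact) {
    if (n > 7) stop("exact enumeration supported only for n <= 7")
    perms <- all_permutations(n)
    r_perm <- apply(perms, 1, function(ix) stats::cor(a, B[ix, ix][lt]))
    return(list(r = r_obs, p = mean(r_perm >= r_obs), n_perm = nrow(perms)))
  }
  r_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      ix <- sample.int(n)
      stats::cor(a, B[ix, ix][lt])
    }, numeric(1))
  })
  list(r = r_obs, p = (1 + sum(r_perm >= r_obs)) / (n_perm + 1),
       n_perm = n_perm)
}

# Assemble the first-stage design for one frame: retained PCA scores of the
# environmental covariates plus depth, protection and sampling intensity
# (constants dropped later by build_design), then fit and extract residuals.
residualize_frame <- function(frame, retention = 0.10) {
  env_cols <- grep("^env_", names(frame), value = TRUE)
  pca <- NULL
  design <- data.frame(row.names = seq_len(nrow(frame)))
  if (length(env_cols) >= 2) {
    pca <- species_pca(frame[, env_cols, drop = FALSE], retention = retention)
    if (length(pca$retained_axes)) {
      sc <- pca$scores[, pca$retained_axes, drop = FALSE]
      colnames(sc) <- paste0("PC", pca$retained_axes)
      design <- cbind(design, as.data.frame(sc))
    }
  }
  for (v in c("depth", "protection", "sampling_intensity")) {
    if (v %in% names(frame)) design[[v]] <- frame[[v]]
  }
  fit <- tryCatch(fit_zip(frame$abundance, design),
                  error = function(e) NULL)
  if (is.null(fit)) {
    bd <- build_design(design)
    fit <- poisson_fallback(frame$abundance, bd$X, bd$dropped)
  }
  list(fit = fit, pca = pca, residuals = extract_residuals(fit, frame))
}
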