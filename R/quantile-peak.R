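# Second stage: the 80th-quantile penalized spline of residual abundance
# against temperature, bootstrapped over absence subsets; thermal-optimum
# extraction, the permutation test of the temperature effect, the four-way
# shape classification and the category-proportions chi-square test.

# Smoothed pinball (check) loss: rho_tau(r) = 0.5 * (|r| + (2 tau - 1) r),
# with |r| ~ sqrt(r^2 + eps^2). Mean loss (not sum) is used so the objective
# is invariant to uniform duplication of observations.
pinball_smooth <- function(r, tau, eps) {
  0.5 * ((2 * tau - 1) * r + sqrt(r^2 + eps^2))
}

pinball_loss <- function(r, tau) {
  mean(r * (tau - (r < 0)))
}

# Fit penalized quantile spline coefficients for fixed lambda by BFGS on the
# smoothed objective, warm-started from penalized least squares and polished
# with a ten-fold smaller eps.
fit_pinball_beta <- function(X, y, S, tau, lambda, eps) {
  n <- length(y)
  ridge <- 1e-8 * diag(ncol(X))
  beta <- tryCatch(
    solve(crossprod(X) / n + lambda * S + ridge, crossprod(X, y) / n),
    error = function(e) rep(0, ncol(X))
  )
  obj <- function(b, e) {
    r <- y - drop(X %*% b)
    mean(pinball_smooth(r, tau, e)) + lambda * drop(crossprod(b, S %*% b))
  }
  grd <- function(b, e) {
    r <- y - drop(X %*% b)
    d <- 0.5 * ((2 * tau - 1) + r / sqrt(r^2 + e^2))
    drop(-crossprod(X, d) / n) + 2 * lambda * drop(S %*% b)
  }
  for (e in c(eps, eps / 10)) {
    op <- stats::optim(beta, obj, grd, e = e, method = "BFGS",
                       control = list(maxit = 200, reltol = 1e-12))
    beta <- op$par
  }
  drop(beta)
}

#' Fit an 80th-quantile penalized regression spline
#'
#' Minimizes the mean pinball (check) loss at level `tau` over a cubic
#' regression spline of temperature with basis dimension `basis_dim`, plus a
#' second-derivative roughness penalty. The smoothing parameter is chosen by
#' k-fold (k = 5) cross-validated pinball loss over a fixed log-spaced grid;
#' ties go to the smallest smoothing parameter.
#'
#' @param residuals A `residual_series` (columns `sst`, `residual`) or any
#'   data.frame with those columns.
#' @param tau Quantile level in (0, 1).
#' @param basis_dim Spline basis dimension; the default of 4 keeps curves
#'   robust to outliers and limited in non-linearity.
#' @param lambda Optional fixed smoothing parameter; skips cross-validation.
#' @param lambda_grid Log-spaced candidate smoothing parameters.
#' @param cv_folds Number of cross-validation folds.
#' @param grid_n Number of prediction grid points over the sampled range.
#' @param seed Seed for the fold assignment.
#' @return An object of class `quantile_curve`: `grid`, `fitted`, `tau`,
#'   `basis_dim`, `smoothing_parameter`, plus the basis object and
#'   coefficients for prediction.
#' @export
fit_quantile_spline <- function(residuals, tau = 0.8, basis_dim = 4,
                                lambda = NULL,
                                lambda_grid = 10^seq(-5, 2, length.out = 8),
                                cv_folds = 5, grid_n = 200, seed = 1) {
  x <- residuals$sst
  y <- residuals$residual
  n <- length(y)
  if (n < 2 * basis_dim) stop("need at least 2 * basis_dim observations")
  if (diff(range(x)) <= 0) stop("temperature range must be positive")
  if (tau <= 0 || tau >= 1) stop("`tau` must lie in (0, 1)")
  sm <- mgcv::smoothCon(mgcv::s(sst, k = basis_dim, bs = "cr"),
                        data = data.frame(sst = x), knots = NULL,
                        absorb.cons = FALSE)[[1]]
  X <- sm$X
  S <- sm$S[[1]] / max(sm$S[[1]])   # unit-scaled penalty
  # smoothing width of the softened check loss; the mean absolute deviation
  # from the median is invariant under duplication of the sample
  eps <- max(1e-6, 1e-3 * mean(abs(y - stats::median(y))))
  if (is.null(lambda)) {
    folds <- with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
    cv <- vapply(lambda_grid, function(lam) {
      loss <- 0
      for (f in seq_len(cv_folds)) {
        tr <- folds != f
        if (sum(tr) < basis_dim + 1) next
        b <- fit_pinball_beta(X[tr, , drop = FALSE], y[tr], S, tau, lam, eps)
        r <- y[!tr] - drop(X[!tr, , drop = FALSE] %*% b)
        loss <- loss + sum(r * (tau - (r < 0)))
      }
      loss
    }, numeric(1))
    lambda <- lambda_grid[which.min(cv)]  # first minimum = smallest lambda
  }
  beta <- fit_pinball_beta(X, y, S, tau, lambda, eps)
  grid <- seq(min(x), max(x), length.out = grid_n)
  Xg <- mgcv::PredictMat(sm, data.frame(sst = grid))
  structure(list(
    grid = grid,
    fitted = drop(Xg %*% beta),
    tau = tau,
    basis_dim = basis_dim,
    smoothing_parameter = lambda,
    smooth = sm,
    beta = beta
  ), class = "quantile_curve")
}

#' Predict from a fitted quantile curve
#'
#' @param object A `quantile_curve`.
#' @param newtemp Temperatures at which to evaluate the curve.
#' @param ... Unused.
#' @return Numeric vector of fitted quantile values.
#' @export
predict.quantile_curve <- function(object, newtemp, ...) {
  if (!is.null(object$smooth)) {
    Xg <- mgcv::PredictMat(object$smooth, data.frame(sst = newtemp))
    drop(Xg %*% object$beta)
  } else {
    stats::approx(object$grid, object$fitted, xout = newtemp, rule = 2)$y
  }
}

#' @export
print.quantile_curve <- function(x, ...) {
  cat("Quantile curve (tau =", x$tau, ", k =", x$basis_dim,
      ", lambda =", format(x$smoothing_parameter, digits = 3), ")\n")
  cat("  grid:", length(x$grid), "points over [",
      format(min(x$grid), digits = 4), ",",
      format(max(x$grid), digits = 4), "] C\n")
  invisible(x)
}

#' Bootstrap the thermal optimum over absence subsets
#'
#' For each replicate, absences are rebalanced with a fresh child seed, the
#' first-stage residualization is rerun, the quantile spline is refit and
#' predicted on a common grid. The aggregated curve is the pointwise mean of
#' replicate curves and the thermal optimum is its grid argmax (ties broken
#' at the lowest temperature). If absences do not outnumber presences, a
#' single fit is performed. The smoothing parameter is cross-validated on
#' the first replicate and reused for the rest.
#'
#' @param frame A filtered per-species modelling frame.
#' @param n_boot Number of absence-subset replicates.
#' @param tau,basis_dim Quantile-spline settings.
#' @param seed Master seed.
#' @param residualize Run the first-stage covariate model (two-stage
#'   analysis); if `FALSE`, the spline is fit to raw abundance (one-stage).
#' @param retention PCA variance-fraction retention threshold.
#' @return An object of class `topt_estimate`: `topt`, `curve` (aggregated
#'   `quantile_curve`), `n_boot`, `per_boot_topt`, `per_boot_curves`,
#'   `residuals` (last replicate's residual series).
#' @export
bootstrap_topt <- function(frame, n_boot = 25, tau = 0.8, basis_dim = 4,
                           seed = 1, residualize = TRUE, retention = 0.10) {
  if (n_boot < 1) stop("`n_boot` must be >= 1")
  n_pres <- sum(!frame$is_absence)
  n_abs <- sum(frame$is_absence)
  reps <- if (n_abs > n_pres) n_boot else 1L
  grid <- seq(min(frame$sst), max(frame$sst), length.out = 200)
  curves <- matrix(NA_real_, nrow = reps, ncol = length(grid))
  topts <- rep(NA_real_, reps)
  lambda <- NULL
  last_res <- NULL
  ok <- logical(reps)
  for (b in seq_len(reps)) {
    fr <- if (n_abs > n_pres) {
      balance_absences(frame, seed = child_seed(seed, b))
    } else {
      frame
    }
    res <- tryCatch({
      series <- if (residualize) {
        residualize_frame(fr, retention = retention)$residuals
      } else {
        data.frame(sst = fr$sst, residual = fr$abundance)
      }
      qc <- fit_quantile_spline(series, tau = tau, basis_dim = basis_dim,
                                lambda = lambda,
                                seed = child_seed(seed, 1000 + b))
      list(series = series, qc = qc)
    }, error = function(e) NULL)
    if (is.null(res)) next
    ok[b] <- TRUE
    if (is.null(lambda)) lambda <- res$qc$smoothing_parameter
    curves[b, ] <- predict(res$qc, grid)
    topts[b] <- grid[which.max(curves[b, ])]
    last_res <- res$series
  }
  if (!any(ok)) stop("all bootstrap replicates failed for this species")
  agg <- colMeans(curves[ok, , drop = FALSE])
  curve <- structure(list(grid = grid, fitted = agg, tau = tau,
                          basis_dim = basis_dim,
                          smoothing_parameter = lambda,
                          smooth = NULL, beta = NULL),
                     class = "quantile_curve")
  structure(list(
    topt = grid[which.max(agg)],  # which.max returns the first (lowest T) tie
    curve = curve,
    n_boot = sum(ok),
    per_boot_topt = topts[ok],
    per_boot_curves = curves[ok, , drop = FALSE],
    residuals = last_res
  ), class = "topt_estimate")
}

#' @export
print.topt_estimate <- function(x, ...) {
  cat("Thermal optimum estimate: Topt =", format(x$topt, digits = 4),
      "C over", x$n_boot, "bootstrap replicate(s)\n")
  if (x$n_boot > 1) {
    cat("  per-replicate Topt range: [",
        format(min(x$per_boot_topt), digits = 4), ",",
        format(max(x$per_boot_topt), digits = 4), "]\n")
  }
  invisible(x)
}

#' Permutation test of the temperature effect on maximum abundance
#'
#' Test statistic: reduction in mean pinball loss of the smooth quantile fit
#' relative to the constant tau-quantile fit. The null distribution is built
#' by permuting temperatures against residuals and refitting with the
#' observed smoothing parameter; `p = (1 + #\{null >= observed\}) /
#' (n_perm + 1)`.
#'
#' @param residuals A `residual_series`.
#' @param curve The fitted `quantile_curve` for the observed data.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `statistic` and `p`.
#' @export
temperature_effect_test <- function(residuals, curve, n_perm = 199,
                                    seed = 1) {
  y <- residuals$residual
  x <- residuals$sst
  tau <- curve$tau
  qconst <- stats::quantile(y, tau, type = 7, names = FALSE)
  loss_const <- pinball_loss(y - qconst, tau)
  loss_fit <- pinball_loss(y - predict(curve, x), tau)
  stat <- max(0, loss_const - loss_fit)
  lam <- curve$smoothing_parameter
  null_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      xp <- sample(x)
      qc <- fit_quantile_spline(data.frame(sst = xp, residual = y),
                                tau = tau, basis_dim = curve$basis_dim,
                                lambda = lam)
      max(0, loss_const - pinball_loss(y - predict(qc, xp), tau))
    }, numeric(1))
  })
  list(statistic = stat,
       p = (1 + sum(null_stats >= stat)) / (n_perm + 1))
}

#' Classify the shape of a thermal-abundance distribution
#'
#' The aggregated curve is shifted so its minimum is zero (residual curves
#' can be negative; the relative-abundance scale presumes non-negativity).
#' With `M` the shifted maximum, `r_cool` and `r_warm` are the shifted curve
#' values at the cool and warm thermal edges as fractions of `M`. Labels:
#' `no_trend` if both fractions are at or above the threshold,
#' `abundant_centre` if both fall below it, `warm_skewed` if only the warm
#' edge stays high, `cool_skewed` if only the cool edge stays high. Edges
#' outside the curve's grid span are clamped to the grid ends.
#'
#' @param curve A `quantile_curve` (or list with `grid`, `fitted`).
#' @param tmin,tmax Cool and warm thermal edges (degrees C), `tmin < tmax`.
#' @param threshold Edge-drop threshold as a fraction of maximum.
#' @param quiet Suppress clamping/degenerate-curve messages.
#' @return An object of class `shape_class`: `label`,
#'   `rel_abund_cool_edge`, `rel_abund_warm_edge`, `threshold`.
#' @export
classify_shape <- function(curve, tmin, tmax, threshold = 0.75,
                           quiet = FALSE) {
  if (!(tmin < tmax)) stop("`tmin` must be < `tmax`")
  g <- curve$grid
  if (tmin < min(g) || tmax > max(g)) {
    if (!quiet) message("thermal edges clamped to the curve grid span")
    tmin <- max(tmin, min(g))
    tmax <- min(tmax, max(g))
  }
  v <- curve$fitted - min(curve$fitted)
  M <- max(v)
  if (M == 0) {
    if (!quiet) warning("flat zero curve; classifying as no_trend")
    out <- list(label = "no_trend", rel_abund_cool_edge = 1,
                rel_abund_warm_edge = 1, threshold = threshold)
    class(out) <- "shape_class"
    return(out)
  }
  r_cool <- stats::approx(g, v, xout = tmin, rule = 2)$y / M
  r_warm <- stats::approx(g, v, xout = tmax, rule = 2)$y / M
  label <- if (r_cool >= threshold && r_warm >= threshold) {
    "no_trend"
  } else if (r_cool < threshold && r_warm < threshold) {
    "abundant_centre"
  } else if (r_warm >= threshold) {
    "warm_skewed"
  } else {
    "cool_skewed"
  }
  structure(list(label = label, rel_abund_cool_edge = r_cool,
                 rel_abund_warm_edge = r_warm, threshold = threshold),
            class = "shape_class")
}

#' @export
print.shape_class <- function(x, ...) {
  cat("Shape:", x$label, "(threshold", x$threshold, ")\n")
  cat("  edge fractions of maximum: cool =",
      format(x$rel_abund_cool_edge, digits = 3), ", warm =",
      format(x$rel_abund_warm_edge, digits = 3), "\n")
  invisible(x)
}

#' Chi-square goodness-of-fit test of shape-category proportions
#'
#' Pearson chi-square of observed category counts against a uniform
#' expectation of `n_total / 4` per category (df = 3). Accepts either a
#' vector of labels or a numeric vector of four category counts; counts
#' implied by rounded printed percentages need not sum to `n_total`, hence
#' the separate argument.
#'
#' @param x Character/factor vector of shape labels, or numeric length-4
#'   counts.
#' @param n_total Total number of species behind the counts; defaults to
#'   `sum(observed)`.
#' @return List with `chi2`, `df`, `p`, `observed`, `expected`.
#' @export
shape_proportions_test <- function(x, n_total = NULL) {
  levels4 <- c("no_trend", "abundant_centre", "warm_skewed", "cool_skewed")
  observed <- if (is.numeric(x)) {
    if (length(x) != 4) stop("numeric input must give four category counts")
    x
  } else {
    as.numeric(table(factor(as.character(x), levels = levels4)))
  }
  if (is.null(n_total)) n_total <- sum(observed)
  expected <- rep(n_total / 4, 4)
  chi2 <- sum((observed - expected)^2 / expected)
  list(chi2 = chi2, df = 3L,
       p = stats::pchisq(chi2, df = 3, lower.tail = FALSE),
       observed = observed, expected = expected)
}
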