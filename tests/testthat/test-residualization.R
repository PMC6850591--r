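# First-stage residualization: PCA retention, the zero-inflated Poisson
# likelihood, response residuals, and the Mantel permutation test.

test_that("PCA retains axes strictly above the variance threshold", {
  # two perfectly correlated covariates: one axis carries everything
  x <- rnorm(100)
  p <- species_pca(cbind(a = x, b = 2 * x + 1))
  expect_equal(p$variance_fraction[1], 1, tolerance = 1e-12)
  expect_identical(p$retained_axes, 1L)
  # orthogonal columns split variance evenly; the retention threshold cuts
  # exactly at the stated fraction
  H <- stats::contr.helmert(5)  # 5 x 4, mutually orthogonal, zero-sum
  p2 <- species_pca(H, retention = 0.2501)
  expect_equal(p2$variance_fraction, rep(0.25, 4), tolerance = 1e-9)
  expect_length(p2$retained_axes, 0)
  p3 <- species_pca(H, retention = 0.2499)
  expect_length(p3$retained_axes, 4)
})

test_that("independent equal-variance covariates split variance evenly", {
  set.seed(20)
  X <- matrix(rnorm(10000 * 5), ncol = 5)
  p <- species_pca(X, retention = 0.10)
  expect_true(all(p$variance_fraction >= 0.15 & p$variance_fraction <= 0.25))
  expect_length(p$retained_axes, 5)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-9)
})

test_that("PCA drops constant covariates and reconstructs its input", {
  set.seed(21)
  X <- cbind(a = rnorm(50), b = rnorm(50), c = rep(3, 50))
  expect_warning(p <- species_pca(X), "constant")
  expect_equal(ncol(p$loadings), 2L)
  expect_error(species_pca(cbind(a = rep(1, 10), b = rep(2, 10))),
               "constant")
  # full-rank reconstruction of the standardized matrix
  X2 <- matrix(rnorm(200), ncol = 4)
  p2 <- species_pca(X2)
  expect_equal(p2$scores %*% t(p2$loadings), scale(X2),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("ZIP estimates recover simulation truth within 3 SE", {
  set.seed(3)
  x <- rnorm(5000)
  lam <- exp(1 + 0.5 * x)
  y <- ifelse(runif(5000) < 0.3, 0, rpois(5000, lam))
  fit <- fit_zip(y, data.frame(x = x))
  expect_true(fit$converged)
  expect_false(fit$fallback)
  est <- c(fit$coefficients$inflation, fit$coefficients$count)
  se <- sqrt(diag(fit$vcov))
  truth <- c(qlogis(0.3), 1, 0.5)
  expect_true(all(abs(est - truth) / se < 3))
  # the optimizer never worsened the objective it monitors
  expect_gte(fit$loglik, fit$loglik_init)
})

test_that("with no structural zeros the ZIP collapses to plain Poisson", {
  set.seed(4)
  x <- rnorm(3000)
  y <- rpois(3000, exp(0.5 + 0.8 * x))
  y[1] <- 0L  # ensure a sampling zero exists
  fit <- fit_zip(y, data.frame(x = x))
  glmfit <- glm(y ~ x, family = poisson)
  expect_lt(fit$pi, 0.02)
  expect_equal(unname(fit$coefficients$count), unname(coef(glmfit)),
               tolerance = 0.02)
  # nesting: the covariate model cannot have lower likelihood than the
  # intercept-only ZIP
  fit0 <- fit_zip(y, data.frame(z = rep(c(0, 1), length.out = 3000) * 0 +
                                  rnorm(3000) * 1e-8))
  expect_gte(fit$loglik, fit0$loglik - 1e-6)
})

test_that("responses without both zeros and positives are rejected", {
  expect_error(fit_zip(rep(1:3, 10), data.frame(x = rnorm(30))), "zero")
  expect_error(fit_zip(rep(0, 30), data.frame(x = rnorm(30))), "positive")
})

test_that("response residuals equal y minus (1 - pi) lambda", {
  set.seed(5)
  fr <- make_frame(n_pres = 150, n_abs = 150, seed = 5)
  out <- thermoniche:::residualize_frame(fr)
  fit <- out$fit
  r <- out$residuals
  expect_equal(nrow(r), nrow(fr))
  # hand-computed mu for three rows
  for (i in c(1, 50, 200)) {
    eta <- sum(fit$coefficients$count * fit$X[i, ])
    mu_hand <- unname((1 - fit$pi) * exp(eta))
    expect_equal(r$residual[i], fr$abundance[i] - mu_hand, tolerance = 1e-8)
  }
  # approximately centred: the ZIP score equations do not force the response
  # residuals to sum to zero exactly, only near it
  expect_lt(abs(sum(r$residual)), 0.02 * nrow(fr) * mean(fr$abundance))
  # perfect fit: mu equal to y gives all-zero residuals
  fake <- structure(list(mu = fr$abundance, pi = 0), class = "zip_fit")
  expect_equal(extract_residuals(fake, fr)$residual, rep(0, nrow(fr)))
})

test_that("residualization does not manufacture temperature signal", {
  # counts independent of every covariate and of temperature
  set.seed(6)
  n <- 2000
  fr <- data.frame(site_id = sprintf("r%04d", 1:n), species_id = "spX",
                   count = ifelse(runif(n) < 0.3, 0L, rpois(n, 4)),
                   sst = runif(n, 5, 30), depth = runif(n, 2, 20),
                   protection = sample(0:3, n, TRUE),
                   env_1 = rnorm(n), env_2 = rnorm(n), env_3 = rnorm(n),
                   stringsAsFactors = FALSE)
  fr$is_absence <- fr$count == 0
  fr$abundance <- fr$count
  fr$sampling_intensity <- 1
  out <- thermoniche:::residualize_frame(fr)
  expect_lt(abs(cor(out$residuals$residual, fr$sst)), 0.05)
})

test_that("Mantel r and p behave on identical and enumerable matrices", {
  set.seed(7)
  pts <- matrix(rnorm(20), ncol = 2)
  d <- as.matrix(dist(pts))
  res <- mantel_test(d, d, n_perm = 999, seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 1000)
  expect_error(mantel_test(d, d[1:5, 1:5]), "dimension")
  # 4 x 4 exhaustive enumeration against an in-test oracle
  A <- as.matrix(dist(matrix(rnorm(8), ncol = 2)))
  B <- as.matrix(dist(matrix(rnorm(8), ncol = 2)))
  res4 <- mantel_test(A, B, exact = TRUE)
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- as.matrix(perms[apply(perms, 1, function(p) length(unique(p)) == 4), ])
  lt <- lower.tri(A)
  r_all <- apply(perms, 1, function(ix) cor(A[lt], B[ix, ix][lt]))
  expect_equal(res4$n_perm, 24L)
  expect_equal(res4$p, mean(r_all >= res4$r))
})

test_that("Mantel statistic agrees with the vegan implementation", {
  set.seed(8)
  A <- as.matrix(dist(matrix(rnorm(24), ncol = 2)))
  B <- as.matrix(dist(matrix(rnorm(24), ncol = 2)))
  ours <- mantel_test(A, B, n_perm = 99, seed = 1)
  ref <- vegan::mantel(A, B, permutations = 99)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-10)
})
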