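# Axis standardization, binned maxima, the split-Gaussian likelihood and
# sampler, Gelman-Rubin diagnostics and R-squared summaries.

make_profile <- function(topt = 20, smin = 2, smax = 2) {
  data.frame(species_id = "spX", topt = topt, sigma_min = smin,
             sigma_max = smax, stringsAsFactors = FALSE)
}

test_that("standardization centres, scales and bounds abundance", {
  fr <- data.frame(sst = c(20, 22, 18, 25), abundance = c(4, 8, 2, 1),
                   is_absence = FALSE)
  pts <- standardize_abundance(fr, make_profile(topt = 20, smin = 1, smax = 3))
  expect_equal(pts$t_std[1], 0)                 # at the optimum
  expect_equal(pts$t_std[2], 1.0)               # 2 C / mean(1, 3)
  expect_equal(max(pts$a_std), 1)               # maximum record maps to 1
  expect_true(all(pts$a_std >= 0 & pts$a_std <= 1))
  # absences are excluded
  fr2 <- rbind(fr, data.frame(sst = 30, abundance = 0, is_absence = TRUE))
  expect_equal(nrow(standardize_abundance(fr2, make_profile())), 4L)
  expect_error(standardize_abundance(fr, make_profile(smin = 0, smax = 0)),
               "sigma")
  # invariance to affine rescaling of counts
  fr3 <- fr; fr3$abundance <- fr$abundance * 17
  expect_equal(standardize_abundance(fr3, make_profile())$a_std,
               standardize_abundance(fr, make_profile())$a_std)
})

test_that("binning is half-open, anchored at zero, with type-7 quantiles", {
  pts <- data.frame(species_id = "a", t_std = c(0.05, 0.1, 0.149), a_std = c(0.2, 0.5, 0.9))
  b <- bin_q99(pts)
  # 0.1 sits exactly on a boundary and joins the right-hand bin
  expect_equal(sort(unique(b$bin_centre)), c(0.05, 0.15))
  expect_equal(b$q99[b$bin_centre == 0.05], 0.2)
  # single point in a bin is its own quantile
  one <- bin_q99(data.frame(species_id = "a", t_std = -0.31, a_std = 0.4))
  expect_equal(one$q99, 0.4)
  expect_equal(one$bin_centre, -0.35)
  # 200 iid uniforms in one bin: the 99th percentile sits near the top
  set.seed(25)
  u <- data.frame(species_id = "a", t_std = runif(200, 0, 0.0999),
                  a_std = runif(200))
  expect_gte(bin_q99(u)$q99, 0.95)
  # per-species separation
  two <- bin_q99(data.frame(species_id = c("a", "b"), t_std = c(0.01, 0.01),
                            a_std = c(0.3, 0.7)))
  expect_equal(nrow(two), 2L)
})

test_that("split-Gaussian likelihood matches hand computation", {
  d <- data.frame(bin_centre = c(-1, 0, 2), q99 = c(0.3, 0.55, 0.2))
  par <- c(0.55, 0, 1, 2, 0.05)
  m <- c(0.55 * exp(-1), 0.55, 0.55 * exp(-1))  # sides at one sigma
  expect_equal(split_gaussian_loglik(par, d),
               sum(dnorm(d$q99, m, 0.05, log = TRUE)))
  # the mean at the optimum is c, and c * e^-1 one sigma above
  expect_equal(thermoniche:::split_gaussian_mean(0, 0.55, 0, 1, 2), 0.55)
  expect_equal(thermoniche:::split_gaussian_mean(2, 0.55, 0, 1, 2),
               0.55 * exp(-1))
  expect_identical(split_gaussian_loglik(c(-0.1, 0, 1, 2, 0.05), d), -Inf)
  expect_identical(split_gaussian_loglik(c(0.5, 0, 0, 2, 0.05), d), -Inf)
  # likelihood at truth beats perturbed parameters on ample data
  set.seed(26)
  t <- runif(400, -4, 4)
  mm <- ifelse(t < 0, 0.55 * exp(-t^2), 0.55 * exp(-(t / 2)^2))
  dd <- data.frame(bin_centre = t, q99 = mm + rnorm(400, 0, 0.05))
  truth <- c(0.55, 0, 1, 2, 0.05)
  expect_gt(split_gaussian_loglik(truth, dd),
            split_gaussian_loglik(truth + c(0.1, 0.3, 0.4, -0.5, 0.02), dd))
})

test_that("Gelman-Rubin follows the potential-scale-reduction formula", {
  expect_error(gelman_rubin(list(matrix(rnorm(100)))), "2 chains")
  # identical nonconstant chains: B = 0 so Rhat = sqrt((n-1)/n)
  ch <- matrix(rnorm(200), ncol = 2)
  rh <- gelman_rubin(list(ch, ch, ch))
  expect_equal(unname(rh), rep(sqrt(99 / 100), 2))
  # far-separated chains blow up
  set.seed(27)
  rh2 <- gelman_rubin(list(matrix(rnorm(1000), ncol = 1),
                           matrix(rnorm(1000, 5), ncol = 1)))
  expect_gt(rh2, 1.5)
  # iid chains from one distribution converge
  rh3 <- gelman_rubin(lapply(1:4, function(i) matrix(rnorm(5000), ncol = 1)))
  expect_lt(rh3, 1.01)
})

test_that("sampler keeps the prescribed number of thinned draws", {
  set.seed(28)
  t <- runif(120, -3, 3)
  m <- ifelse(t < 0, 0.5 * exp(-(t / 1.5)^2), 0.5 * exp(-(t / 1.5)^2))
  d <- data.frame(species_id = "x", bin_centre = t,
                  q99 = m + rnorm(120, 0, 0.05))
  # runs this short may legitimately fail the convergence bar; the fit must
  # then flag itself rather than stay silent
  fit <- suppressWarnings(
    fit_split_gaussian(d, chains = 2, iterations = 2000, burn_in = 500,
                       thin = 5, seed = 30)
  )
  per_chain <- floor((fit$settings$iterations - 500) / 5)
  expect_true(all(vapply(fit$chains, nrow, 0L) == per_chain))
  expect_true(all(c("c", "topt_std", "sigma_min_std", "sigma_max_std",
                    "error_sd", "tskew") %in% colnames(fit$draws)))
  expect_error(fit_split_gaussian(d[d$bin_centre > 0, ], seed = 1), "both sides")
  expect_error(fit_split_gaussian(d[1:10, ], seed = 1), "20 binned")
})

test_that("symmetric truth yields a skew interval covering zero", {
  set.seed(29)
  t <- runif(300, -3.5, 3.5)
  m <- 0.55 * exp(-(t / 1.5)^2)
  d <- data.frame(species_id = "x", bin_centre = t,
                  q99 = m + rnorm(300, 0, 0.05))
  fit <- fit_split_gaussian(d, seed = 31)
  ts <- fit$summary[fit$summary$parameter == "tskew", ]
  expect_lt(ts$q2.5, 0)
  expect_gt(ts$q97.5, 0)
  expect_true(all(fit$rhat < 1.01))
})

test_that("R-squared summaries separate point and bin-mean scales", {
  # perfect noiseless data: both R2 are 1
  t <- seq(-3, 3, by = 0.1) + 0.05
  m <- ifelse(t < 0, 0.6 * exp(-t^2), 0.6 * exp(-(t / 2)^2))
  d <- data.frame(species_id = "x", bin_centre = t, q99 = m)
  fake <- list(draws = matrix(rep(c(0.6, 0, 1, 2, 0.05, 1), each = 2), nrow = 2,
                              dimnames = list(NULL, c("c", "topt_std",
                                                      "sigma_min_std",
                                                      "sigma_max_std",
                                                      "error_sd", "tskew"))))
  r2 <- fit_r2(fake, d)
  expect_equal(r2$r2_points, 1, tolerance = 1e-12)
  expect_equal(r2$r2_binned_means, 1, tolerance = 1e-12)
  # between-species scatter deflates the point-level R2 only
  set.seed(30)
  d2 <- do.call(rbind, lapply(1:12, function(s) {
    off <- runif(1, -0.25, 0.25)
    data.frame(species_id = paste0("s", s), bin_centre = t,
               q99 = pmax(0, m + off + rnorm(length(t), 0, 0.02)))
  }))
  r2h <- fit_r2(fake, d2)
  expect_gt(r2h$r2_binned_means, r2h$r2_points)
})
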