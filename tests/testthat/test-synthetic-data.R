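# Synthetic survey generator: argument checking, determinism, and agreement
# of simulated counts with the generative split-Gaussian / zero-inflation
# model.

test_that("site generation validates arguments and boundary sizes", {
  expect_error(generate_sites(0), "n_sites")
  expect_error(generate_sites(10, sst_range = c(20, 20)), "sst_range")
  expect_error(generate_sites(10, covariate_sst_correlation = 1.5))
  one <- generate_sites(1, seed = 3)
  expect_equal(nrow(one), 1L)
})

test_that("site tables satisfy their invariants", {
  s <- generate_sites(800, seed = 4)
  expect_false(any(duplicated(s$site_id)))
  expect_true(all(s$sst >= 5 & s$sst <= 30))
  expect_true(all(s$coral_cover + s$macroalgae_cover <= 100))
  # coral/macroalgae transition crosses near 23 C
  cool <- s$sst < 20
  warm <- s$sst > 26
  expect_true(mean(s$coral_cover[cool] < s$macroalgae_cover[cool]) > 0.95)
  expect_true(mean(s$coral_cover[warm] > s$macroalgae_cover[warm]) > 0.95)
})

test_that("covariates carry the requested rank correlation with sst", {
  s <- generate_sites(1000, covariate_sst_correlation = 0.6, seed = 1)
  rho <- cor(s$env_1, s$sst, method = "spearman")
  expect_gte(rho, 0.5)
  expect_lte(rho, 0.7)
  rho8 <- cor(s$env_8, s$sst, method = "spearman")
  expect_gte(rho8, 0.5)
  expect_lte(rho8, 0.7)
})

test_that("generators are bit-identical under a fixed seed", {
  expect_identical(generate_sites(200, seed = 9), generate_sites(200, seed = 9))
  expect_identical(generate_species(20, seed = 9), generate_species(20, seed = 9))
  s <- generate_sites(50, seed = 1)
  sp <- generate_species(5, seed = 2)
  expect_identical(simulate_surveys(s, sp, seed = 3),
                   simulate_surveys(s, sp, seed = 3))
  expect_false(identical(simulate_surveys(s, sp, seed = 3),
                         simulate_surveys(s, sp, seed = 4)))
})

test_that("species truth respects guild mix and skew scenarios", {
  expect_error(generate_species(0), "n_species")
  expect_error(generate_species(10, skew_scenario = "bogus"))
  sp <- generate_species(50, guild_mix = 0.5, seed = 5)
  expect_equal(sum(sp$true_Topt > 23), 25L)
  sym <- generate_species(20, skew_scenario = "symmetric", seed = 6)
  expect_equal(sym$true_sigma_min, sym$true_sigma_max)
  warm <- generate_species(20, skew_scenario = "warm_skew", seed = 7)
  expect_true(all(warm$true_sigma_max - warm$true_sigma_min < 0))
  cool <- generate_species(20, skew_scenario = "cool_skew", seed = 7)
  expect_true(all(cool$true_sigma_max - cool$true_sigma_min > 0))
  expect_true(all(sp$true_sigma_min > 0 & sp$true_sigma_max > 0))
  expect_true(all(sp$zero_inflation_pi >= 0 & sp$zero_inflation_pi < 1))
})

test_that("simulated counts are non-negative integers flagged as absences", {
  s <- generate_sites(300, seed = 1)
  sp <- generate_species(4, seed = 2)
  rec <- simulate_surveys(s, sp, seed = 3)
  expect_true(is.integer(rec$count))
  expect_true(all(rec$count >= 0))
  expect_identical(rec$is_absence, rec$count == 0L)
  expect_error(simulate_surveys(s[0, ], sp, seed = 1), "non-empty")
  expect_error(simulate_surveys(s, sp[0, ], seed = 1), "non-empty")
})

test_that("mean simulated count follows the split-Gaussian mean structure", {
  # 10 000 replicate sites at the optimum, no zero inflation, no habitat
  # preference: the Monte-Carlo mean matches peak_lambda within 2%
  tr <- make_truth(topt = 20, peak_lambda = 12, pi = 0, pref = 0)
  at_opt <- make_sites(rep(20, 10000))
  rec <- simulate_surveys(at_opt, tr, seed = 11)
  expect_lt(abs(mean(rec$count) - 12) / 12, 0.02)
  # one scale parameter above the optimum the mean falls to peak * e^-1
  at_sig <- make_sites(rep(22, 10000))
  rec2 <- simulate_surveys(at_sig, tr, seed = 12)
  expect_lt(abs(mean(rec2$count) - 12 * exp(-1)), 3 * sqrt(12 * exp(-1) / 10000))
})

test_that("heavy zero inflation produces mostly absences", {
  tr <- make_truth(topt = 20, peak_lambda = 12, pi = 0.99)
  s <- make_sites(rep(20, 5000))
  rec <- simulate_surveys(s, tr, seed = 13)
  expect_gte(mean(rec$is_absence), 0.95)
})

test_that("normalized count means track the thermal performance curve", {
  # mean / ((1 - pi) * peak) converges to exp(-((T - Topt)/sigma_side)^2),
  # checked at five temperatures with 10 000 replicates each
  tr <- make_truth(topt = 20, sigma_min = 2, sigma_max = 3,
                   peak_lambda = 10, pi = 0.3, pref = 0)
  for (temp in c(16, 18, 20, 22, 26)) {
    sig <- if (temp < 20) 2 else 3
    expected <- exp(-((temp - 20) / sig)^2)
    s <- make_sites(rep(temp, 10000))
    rec <- simulate_surveys(s, tr, seed = 100 + temp)
    norm_mean <- mean(rec$count) / (0.7 * 10)
    mc_se <- sd(rec$count) / (0.7 * 10) / sqrt(10000)
    expect_lt(abs(norm_mean - expected), 3 * mc_se + 1e-9)
  }
})

test_that("realised truth marks truncated optima and habitat shifts", {
  sites <- generate_sites(1500, seed = 21)
  # optimum beyond the warm end of the gradient: realised optimum clamps
  # near the gradient top and the intended class is warm-skewed
  tr <- make_truth(topt = 31, sigma_min = 3.5, sigma_max = 2, pi = 0.2)
  rt <- realised_truth(tr, sites)
  expect_lt(rt$topt_curve, 30.5)
  expect_identical(rt$shape, "warm_skewed")
  expect_lt(rt$tskew, 0)
  # clearly peaked temperate species: intended abundant-centre, small skew
  tr2 <- make_truth(topt = 10, sigma_min = 2.4, sigma_max = 2.4, pi = 0.2)
  rt2 <- realised_truth(tr2, sites)
  expect_identical(rt2$shape, "abundant_centre")
  expect_lt(abs(rt2$tskew), 0.5)
  # a broad niche spanning the whole gradient is flat at the procedure's
  # resolution: intended no-trend
  tr3 <- make_truth(topt = 17, sigma_min = 2.4, sigma_max = 2.4, pi = 0.2)
  expect_identical(realised_truth(tr3, sites)$shape, "no_trend")
})
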