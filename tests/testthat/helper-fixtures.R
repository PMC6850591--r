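# Shared fixture builders; everything is generated in code at test time.

# Minimal site table with the columns simulate_surveys() and the prep stage
# expect, at arbitrary temperatures.
make_sites <- function(sst, lat = NULL, lon = NULL, coral = 50, macro = 30) {
  n <- length(sst)
  data.frame(
    site_id = sprintf("T%04d", seq_len(n)),
    latitude = if (is.null(lat)) seq(0, 10, length.out = n) else lat,
    longitude = if (is.null(lon)) rep(150, n) else lon,
    sst = sst,
    depth = rep(10, n),
    protection = rep(1L, n),
    coral_cover = rep(coral, n)[seq_len(n)],
    macroalgae_cover = rep(macro, n)[seq_len(n)],
    stringsAsFactors = FALSE
  )
}

# One-row species-truth table with overridable fields.
make_truth <- function(topt = 20, sigma_min = 2, sigma_max = 2,
                       peak_lambda = 10, pi = 0, pref = 0) {
  data.frame(
    species_id = "spX", order = "O1", family = "F1", genus = "G1",
    guild_truth = if (topt < 23) "temperate" else "tropical",
    scenario = "symmetric",
    true_Topt = topt, true_sigma_min = sigma_min, true_sigma_max = sigma_max,
    peak_lambda = peak_lambda, zero_inflation_pi = pi, habitat_pref = pref,
    stringsAsFactors = FALSE
  )
}

# A ready-made per-species modelling frame: presences drawn in proportion to
# occupancy of a split-Gaussian niche, absences uniform over the span, with
# a few environmental covariates.
make_frame <- function(n_pres = 400, n_abs = 400, topt = 20, sigma = 2,
                       peak = 10, span = NULL, seed = 1, n_env = 3) {
  if (is.null(span)) span <- c(topt - 3 * sigma - 4, topt + 3 * sigma + 4)
  set.seed(seed)
  xs <- runif(20000, span[1], span[2])
  lam <- peak * exp(-((xs - topt) / sigma)^2)
  pres_x <- sample(xs, n_pres, prob = 1 - exp(-lam), replace = TRUE)
  pres_y <- vapply(pres_x, function(x) {
    repeat {
      v <- rpois(1, peak * exp(-((x - topt) / sigma)^2))
      if (v > 0) return(v)
    }
  }, numeric(1))
  abs_x <- runif(n_abs, span[1], span[2])
  n <- n_pres + n_abs
  fr <- data.frame(
    site_id = sprintf("F%05d", seq_len(n)),
    species_id = "spX",
    count = c(pres_y, rep(0, n_abs)),
    is_absence = rep(c(FALSE, TRUE), c(n_pres, n_abs)),
    sst = c(pres_x, abs_x),
    depth = runif(n, 2, 20),
    protection = sample(0:3, n, replace = TRUE),
    coral_cover = runif(n, 0, 60),
    macroalgae_cover = runif(n, 0, 40),
    stringsAsFactors = FALSE
  )
  for (j in seq_len(n_env)) fr[[paste0("env_", j)]] <- rnorm(n)
  fr$abundance <- fr$count
  fr$sampling_intensity <- length(unique(fr$site_id)) / diff(range(fr$sst))
  fr
}

# Independent reference quantile (linear interpolation between order
# statistics, the type-7 convention) written out longhand.
ref_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[pmin(lo + 1, n)] - x[lo])
}

# Synthetic thermal-profiles table for the skew regression: a linear
# skew-vs-optimum relationship with optional genus-level random intercepts.
make_profiles <- function(n = 200, beta_topt = -0.5, sd_resid = 1,
                          genus_sd = 0, seed = 1, guild = "tropical") {
  set.seed(seed)
  orders <- paste0("O", rep_len(1:4, n))
  families <- paste0(orders, "_F", rep_len(1:3, n))
  genera <- paste0(families, "_G", rep_len(1:2, n))
  topt <- runif(n, 10, 28)
  coral <- rnorm(n, 0, 10)
  macro <- rnorm(n, 0, 10)
  g_eff <- if (genus_sd > 0) {
    fx <- rnorm(length(unique(genera)), 0, genus_sd)
    fx[match(genera, unique(genera))]
  } else 0
  data.frame(
    species_id = sprintf("p%03d", 1:n),
    order = orders, family = families, genus = genera,
    guild = guild, topt = topt, coral_assoc = coral,
    macroalgae_assoc = macro,
    tskew = 2 + beta_topt * topt + 0.02 * coral + g_eff +
      rnorm(n, 0, sd_resid),
    stringsAsFactors = FALSE
  )
}
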