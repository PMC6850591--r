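# Synthetic survey generator: sites along a sea-surface-temperature gradient,
# species with split-Gaussian thermal performance and zero-inflated counts,
# and ground-truth bookkeeping for recovery tests.

#' Generate a synthetic site table
#'
#' Sites span a sea-surface-temperature (SST) gradient with environmental
#' covariates partially rank-correlated with SST, and a coral-to-macroalgae
#' habitat transition crossing near 23 degrees C (coral cover rises, and
#' macroalgae cover falls, sigmoidally with SST; their sum never exceeds 100).
#' Latitude decreases with SST so that the 10-degree absence buffer used
#' downstream is meaningful in degree space.
#'
#' @param n_sites Number of sites (>= 1).
#' @param sst_range Length-2 numeric, min < max, degrees C.
#' @param covariate_sst_correlation Target rank correlation in `[0, 1]`
#'   between each environmental covariate and SST.
#' @param n_covariates Number of continuous environmental covariate columns.
#' @param seed Integer seed; the output is bit-identical for a fixed seed.
#' @return A data.frame with columns `site_id`, `latitude`, `longitude`,
#'   `sst`, `depth`, `protection`, `coral_cover`, `macroalgae_cover` and
#'   `env_1 ... env_<n_covariates>`.
#' @export
generate_sites <- function(n_sites, sst_range = c(5, 30),
                           covariate_sst_correlation = 0.6,
                           n_covariates = 8, seed = 1) {
  if (!is.numeric(n_sites) || length(n_sites) != 1 || n_sites < 1) {
    stop("`n_sites` must be a single integer >= 1")
  }
  if (length(sst_range) != 2 || !(sst_range[1] < sst_range[2])) {
    stop("`sst_range` must be (min, max) with min < max")
  }
  if (covariate_sst_correlation < 0 || covariate_sst_correlation > 1) {
    stop("`covariate_sst_correlation` must lie in [0, 1]")
  }
  n_sites <- as.integer(n_sites)
  with_seed(seed, {
    sst <- stats::runif(n_sites, sst_range[1], sst_range[2])
    # crude meridional structure: warm sites at low latitude
    lat <- (sst_range[2] - sst) * 60 / diff(sst_range) +
      stats::rnorm(n_sites, 0, 1.5)
    lon <- stats::runif(n_sites, 150, 160)
    # Gaussian-copula covariates: Pearson correlation r on normal scores gives
    # Spearman rho = (6/pi) asin(r/2), close to r for moderate values.
    z_sst <- stats::qnorm(rank(sst, ties.method = "first") / (n_sites + 1))
    r <- covariate_sst_correlation
    env <- vapply(seq_len(n_covariates), function(j) {
      r * z_sst + sqrt(max(0, 1 - r^2)) * stats::rnorm(n_sites)
    }, numeric(n_sites))
    env <- matrix(env, nrow = n_sites)
    colnames(env) <- paste0("env_", seq_len(n_covariates))
    avail <- pmin(100, pmax(0, stats::rnorm(n_sites, 70, 10)))
    coral_frac <- stats::plogis((sst - 23) / 1.5)
    out <- data.frame(
      site_id = sprintf("S%05d", seq_len(n_sites)),
      latitude = lat,
      longitude = lon,
      sst = sst,
      depth = round(stats::runif(n_sites, 2, 20), 1),
      protection = sample(0:3, n_sites, replace = TRUE,
                          prob = c(0.5, 0.2, 0.2, 0.1)),
      coral_cover = avail * coral_frac,
      macroalgae_cover = avail * (1 - coral_frac),
      stringsAsFactors = FALSE
    )
    cbind(out, as.data.frame(env))
  })
}

#' Generate synthetic species with ground-truth thermal performance
#'
#' Each species carries the true parameters of its split-Gaussian thermal
#' performance curve: thermal optimum `true_Topt`, scale parameters below and
#' above the optimum (`true_sigma_min`, `true_sigma_max`), expected count at
#' the optimum (`peak_lambda`, log-normal across species), zero-inflation
#' probability and a signed coral-vs-macroalgae habitat preference. Tropical
#' species have `true_Topt` > 23 C and a coral preference; temperate species
#' the reverse. Skew scenarios:
#' \describe{
#'   \item{symmetric}{`sigma_min == sigma_max`; optima placed centrally
#'     within the guild band, so the curve drops at both realised edges.}
#'   \item{warm_skew}{`sigma_min > sigma_max` (generator-side
#'     `T_skew = sigma_max - sigma_min < 0`); optima pushed toward the warm
#'     end of the gradient so warm edges are truncated.}
#'   \item{cool_skew}{`sigma_min < sigma_max`; optima near the cool end of
#'     the guild band.}
#'   \item{mixed}{round-robin over the three shapes above.}
#' }
#'
#' @param n_species Number of species (>= 1).
#' @param guild_mix Fraction of species that are tropical, in `[0, 1]`.
#' @param skew_scenario One of `"symmetric"`, `"warm_skew"`, `"cool_skew"`,
#'   `"mixed"`.
#' @param seed Integer seed.
#' @param sst_range Gradient bounds used to place truncated optima.
#' @return A data.frame, one row per species, with taxonomy labels
#'   (`order`, `family`, `genus`), truth columns and the per-species scenario.
#' @export
generate_species <- function(n_species, guild_mix = 0.5,
                             skew_scenario = c("mixed", "symmetric",
                                               "warm_skew", "cool_skew"),
                             seed = 1, sst_range = c(5, 30)) {
  if (!is.numeric(n_species) || length(n_species) != 1 || n_species < 1) {
    stop("`n_species` must be a single integer >= 1")
  }
  if (guild_mix < 0 || guild_mix > 1) stop("`guild_mix` must lie in [0, 1]")
  skew_scenario <- match.arg(skew_scenario)
  n_species <- as.integer(n_species)
  with_seed(seed, {
    n_trop <- round(n_species * guild_mix)
    guild <- rep(c("tropical", "temperate"),
                 c(n_trop, n_species - n_trop))
    scenario <- if (skew_scenario == "mixed") {
      rep_len(c("symmetric", "warm_skew", "cool_skew"), n_species)
    } else {
      rep(skew_scenario, n_species)
    }
    lo <- sst_range[1]; hi <- sst_range[2]
    topt <- numeric(n_species)
    for (i in seq_len(n_species)) {
      topt[i] <- if (guild[i] == "tropical") {
        switch(scenario[i],
               warm_skew = stats::runif(1, hi - 2.5, hi + 1),
               cool_skew = stats::runif(1, 23.2, 25.5),
               symmetric = stats::runif(1, 24, hi - 3))
      } else {
        switch(scenario[i],
               warm_skew = stats::runif(1, 20, 22.8),
               cool_skew = stats::runif(1, lo + 0.5, lo + 4),
               symmetric = stats::runif(1, lo + 6, 20))
      }
    }
    # realised thermal breadths of reef fishes: total ranges ~ 9-14 C, i.e.
    # sigma ~ 2-4 C; skewed species get a 1.45 / 0.7 long/short-side split
    # (|T_skew| ~ 1.6-2.7 C, matching observed skew magnitudes)
    base_sigma <- stats::runif(n_species, 2.2, 3.6)
    sig_min <- ifelse(scenario == "warm_skew", base_sigma * 1.45,
                      ifelse(scenario == "cool_skew", base_sigma * 0.7,
                             base_sigma))
    sig_max <- ifelse(scenario == "warm_skew", base_sigma * 0.7,
                      ifelse(scenario == "cool_skew", base_sigma * 1.45,
                             base_sigma))
    pref <- ifelse(guild == "tropical", 1, -1) * stats::runif(n_species, 0.1, 0.6)
    orders <- paste0("Order", rep_len(1:4, n_species))
    families <- paste0(orders, "_Fam", rep_len(1:3, n_species))
    genera <- paste0(families, "_Gen", rep_len(1:2, n_species))
    data.frame(
      species_id = sprintf("sp%04d", seq_len(n_species)),
      order = orders, family = families, genus = genera,
      guild_truth = guild,
      scenario = scenario,
      true_Topt = topt,
      true_sigma_min = sig_min,
      true_sigma_max = sig_max,
      peak_lambda = stats::rlnorm(n_species, log(12), 0.4),
      zero_inflation_pi = stats::runif(n_species, 0.15, 0.4),
      habitat_pref = pref,
      stringsAsFactors = FALSE
    )
  })
}

# Split-Gaussian mean count at temperature sst for one species truth row,
# including the habitat multiplier. Exponent as printed in the performance
# model: exp(-((T - Topt)/sigma_side)^2), no 1/2 factor.
true_lambda <- function(truth, sst, coral_cover, macroalgae_cover) {
  sigma <- ifelse(sst < truth$true_Topt, truth$true_sigma_min,
                  truth$true_sigma_max)
  hab <- exp(truth$habitat_pref * (coral_cover - macroalgae_cover) / 100)
  truth$peak_lambda * exp(-((sst - truth$true_Topt) / sigma)^2) * hab
}

#' Simulate zero-inflated survey counts
#'
#' For every species x site pair, the count is 0 with probability
#' `zero_inflation_pi`, else Poisson with mean
#' `peak_lambda * exp(-((sst - Topt)/sigma_side)^2) * habitat multiplier`,
#' where `sigma_side` is `true_sigma_min` below the optimum and
#' `true_sigma_max` above, and the habitat multiplier is
#' `exp(habitat_pref * (coral_cover - macroalgae_cover)/100)`.
#' Zero counts are flagged as absences.
#'
#' @param sites Site table from [generate_sites()].
#' @param species Species truth table from [generate_species()].
#' @param seed Integer seed.
#' @return A data.frame of survey records: `site_id`, `species_id`, `count`
#'   (integer >= 0), `is_absence`.
#' @export
simulate_surveys <- function(sites, species, seed = 1) {
  if (is.null(sites) || nrow(sites) == 0) stop("`sites` must be non-empty")
  if (is.null(species) || nrow(species) == 0) stop("`species` must be non-empty")
  with_seed(seed, {
    n_sites <- nrow(sites)
    out <- vector("list", nrow(species))
    for (i in seq_len(nrow(species))) {
      tr <- species[i, ]
      lam <- true_lambda(tr, sites$sst, sites$coral_cover,
                         sites$macroalgae_cover)
      structural_zero <- stats::runif(n_sites) < tr$zero_inflation_pi
      count <- ifelse(structural_zero, 0L, stats::rpois(n_sites, lam))
      out[[i]] <- data.frame(
        site_id = sites$site_id,
        species_id = tr$species_id,
        count = as.integer(count),
        is_absence = count == 0L,
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
}

#' Generator-intended shape class for a synthetic species
#'
#' The population target of the categorical shape procedure for a synthetic
#' species: the noiseless true mean curve (including the expected habitat
#' multiplier) is projected onto the same basis-dimension-4 cubic regression
#' spline the estimator uses — the class is defined at the procedure's
#' resolution, so sharply asymmetric curves whose short side cannot drop
#' within 4 degrees of freedom are intended-skewed, exactly as an
#' infinite-data run of the estimator would label them. Thermal edges come
#' from the occupancy-probability weighted temperature distribution over the
#' supplied sites; the spline span mimics the modelling frame (presence
#' range widened by the absence buffer's temperature reach, clipped to the
#' gradient). Used as truth in end-to-end recovery tests.
#'
#' @param truth One row of a [generate_species()] table.
#' @param sites Site table the species is surveyed over.
#' @param threshold Edge-drop threshold (fraction of maximum).
#' @param basis_dim Spline basis dimension of the estimator being targeted.
#' @param buffer_reach_C Temperature span the absence buffer adds on each
#'   side of the presence range.
#' @return Character label: one of `"no_trend"`, `"abundant_centre"`,
#'   `"warm_skewed"`, `"cool_skewed"`.
#' @export
intended_shape <- function(truth, sites, threshold = 0.75, basis_dim = 4,
                           buffer_reach_C = 4) {
  realised_truth(truth, sites, threshold = threshold,
                 basis_dim = basis_dim,
                 buffer_reach_C = buffer_reach_C)$shape
}

#' Realised-niche ground truth for a synthetic species
#'
#' The generator-side estimand of the full pipeline for one species: the
#' noiseless true mean curve (habitat multiplier included) evaluated over
#' the realised survey span, its occupancy-weighted thermal edges, and the
#' niche geometry these imply. Gradient truncation (optima near or beyond
#' the warmest / coolest surveyed water) is therefore part of the truth, as
#' it is in the realised niche the pipeline measures. `topt_curve` is the
#' argmax of the raw true curve; `topt_target` and `shape` come from the
#' curve's projection onto the estimator's own spline basis (its
#' population-level target).
#'
#' @param truth One row of a [generate_species()] table.
#' @param sites Site table the species is surveyed over.
#' @param threshold Edge-drop threshold for the shape label.
#' @param basis_dim Spline basis dimension of the estimator being targeted.
#' @param buffer_reach_C Temperature span the absence buffer adds on each
#'   side of the presence range.
#' @return List with `topt_curve`, `topt_target`, `tmin`, `tmax`,
#'   `sigma_min`, `sigma_max`, `tskew` (from `topt_target`), `shape`.
#' @export
realised_truth <- function(truth, sites, threshold = 0.75, basis_dim = 4,
                           buffer_reach_C = 4) {
  lam <- true_lambda(truth, sites$sst, sites$coral_cover,
                     sites$macroalgae_cover)
  p_occ <- (1 - truth$zero_inflation_pi) * (1 - exp(-lam))
  keep <- p_occ >= 1e-3
  if (!any(keep)) {
    return(list(topt_curve = NA_real_, topt_target = NA_real_,
                tmin = NA_real_, tmax = NA_real_, sigma_min = NA_real_,
                sigma_max = NA_real_, tskew = NA_real_, shape = "no_trend"))
  }
  sst <- sites$sst[keep]
  w <- p_occ[keep]
  o <- order(sst)
  sst <- sst[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  edges <- stats::approx(cw, sst, xout = c(0.025, 0.975), rule = 2)$y
  span <- c(max(min(sites$sst), min(sst) - buffer_reach_C),
            min(max(sites$sst), max(sst) + buffer_reach_C))
  grid <- seq(span[1], span[2], length.out = 200)
  sig <- ifelse(grid < truth$true_Topt, truth$true_sigma_min,
                truth$true_sigma_max)
  # expected habitat multiplier along the gradient (mean habitat availability)
  hab <- exp(truth$habitat_pref * 70 *
               (2 * stats::plogis((grid - 23) / 1.5) - 1) / 100)
  curve_true <- exp(-((grid - truth$true_Topt) / sig)^2) * hab
  sm <- mgcv::smoothCon(mgcv::s(sst, k = basis_dim, bs = "cr"),
                        data = data.frame(sst = grid), knots = NULL,
                        absorb.cons = FALSE)[[1]]
  beta <- stats::lm.fit(sm$X, curve_true)$coefficients
  proj <- drop(sm$X %*% beta)
  topt_target <- grid[which.max(proj)]
  cls <- classify_shape(list(grid = grid, fitted = proj),
                        tmin = edges[1], tmax = edges[2],
                        threshold = threshold, quiet = TRUE)
  sig_t <- sigmas_from_edges(topt_target, edges[1], edges[2])
  list(topt_curve = grid[which.max(curve_true)],
       topt_target = topt_target,
       tmin = edges[1], tmax = edges[2],
       sigma_min = unname(sig_t["sigma_min"]),
       sigma_max = unname(sig_t["sigma_max"]),
       tskew = unname(sig_t["sigma_max"] - sig_t["sigma_min"]),
       shape = cls$label)
}

#' Write a synthetic dataset to plain-text CSV files
#'
#' Convenience wrapper emitting `sites.csv`, `surveys.csv` and `truth.csv`
#' in `out_dir`, for use by external harnesses.
#'
#' @param sites,species,records Outputs of the generator functions.
#' @param out_dir Directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_synthetic_dataset <- function(sites, species, records, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("sites.csv", "truth.csv", "surveys.csv"))
  utils::write.csv(sites, paths[1], row.names = FALSE)
  utils::write.csv(species, paths[2], row.names = FALSE)
  utils::write.csv(records, paths[3], row.names = FALSE)
  invisible(paths)
}
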