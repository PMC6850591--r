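# End-to-end pipeline: raw survey records -> per-species thermal profiles
# (optimum, edges, sigmas, skew, guild, habitat associations, shape classes).

#' Run the per-species thermal-abundance pipeline
#'
#' From raw survey records and a site table: derives buffer-based absences,
#' builds and filters per-species modelling frames, bootstraps the
#' 80th-quantile residual-abundance curve over absence subsets to estimate
#' each species' thermal optimum, derives realised-niche geometry (edges,
#' split-Gaussian sigmas, skew, guild) and habitat associations, and
#' classifies the thermal-abundance distribution shape at the 0.75 and 0.50
#' thresholds.
#'
#' @param records Survey records (`site_id`, `species_id`, `count`);
#'   presences suffice, absences are derived.
#' @param sites Site table from [generate_sites()] or equivalent.
#' @param n_boot Bootstrap replicates over absence subsets.
#' @param tau,basis_dim Quantile-spline settings.
#' @param buffer_radius_deg Absence buffer radius in degrees.
#' @param min_records,min_thermal_range_C Species eligibility filters.
#' @param residualize Two-stage (TRUE) or one-stage (FALSE) analysis.
#' @param guild_cutoff Guild boundary in degrees C.
#' @param z Normal z-score for converting edges to sigma parameters.
#' @param seed Master seed.
#' @return List with `profiles` (one row per retained species: `species_id`,
#'   `topt`, `tmin`, `tmax`, `sigma_min`, `sigma_max`, `tskew`, `guild`,
#'   `coral_assoc`, `macroalgae_assoc`, `shape`, `shape_50`, edge
#'   fractions, taxonomy if present), `estimates` (per-species
#'   `topt_estimate` objects), `frames` (the filtered modelling frames).
#' @export
run_thermal_pipeline <- function(records, sites, n_boot = 25, tau = 0.8,
                                 basis_dim = 4, buffer_radius_deg = 10,
                                 min_records = 30, min_thermal_range_C = 3,
                                 residualize = TRUE, guild_cutoff = 23,
                                 z = 1.96, seed = 1) {
  pres <- records[records$count > 0, , drop = FALSE]
  recs <- derive_absences(pres, sites, buffer_radius_deg = buffer_radius_deg)
  frames <- filter_species(build_frames(recs, sites),
                           min_records = min_records,
                           min_thermal_range_C = min_thermal_range_C)
  if (!length(frames)) {
    return(list(profiles = NULL, estimates = list(), frames = frames))
  }
  estimates <- list()
  rows <- list()
  for (sp in names(frames)) {
    fr <- frames[[sp]]
    est <- tryCatch(
      bootstrap_topt(fr, n_boot = n_boot, tau = tau, basis_dim = basis_dim,
                     seed = child_seed(seed, match(sp, names(frames))),
                     residualize = residualize),
      error = function(e) NULL
    )
    if (is.null(est)) {
      warning("species ", sp, " excluded: no bootstrap replicate converged")
      next
    }
    pres_sst <- fr$sst[!fr$is_absence]
    edges <- thermal_edges(pres_sst)
    sig <- sigmas_from_edges(est$topt, edges["tmin"], edges["tmax"], z = z)
    shape75 <- classify_shape(est$curve, edges["tmin"], edges["tmax"],
                              threshold = 0.75, quiet = TRUE)
    shape50 <- classify_shape(est$curve, edges["tmin"], edges["tmax"],
                              threshold = 0.50, quiet = TRUE)
    estimates[[sp]] <- est
    rows[[sp]] <- data.frame(
      species_id = sp,
      topt = est$topt,
      tmin = unname(edges["tmin"]), tmax = unname(edges["tmax"]),
      sigma_min = unname(sig["sigma_min"]),
      sigma_max = unname(sig["sigma_max"]),
      tskew = tskew(sig["sigma_min"], sig["sigma_max"]),
      guild = assign_guild(est$topt, cutoff = guild_cutoff),
      coral_assoc = habitat_association(fr, "coral_cover"),
      macroalgae_assoc = habitat_association(fr, "macroalgae_cover"),
      shape = shape75$label,
      shape_50 = shape50$label,
      rel_abund_cool_edge = shape75$rel_abund_cool_edge,
      rel_abund_warm_edge = shape75$rel_abund_warm_edge,
      stringsAsFactors = FALSE
    )
  }
  profiles <- do.call(rbind, rows)
  rownames(profiles) <- NULL
  list(profiles = profiles, estimates = estimates, frames = frames)
}

#' Pooled split-Gaussian analysis over a fitted community
#'
#' Standardizes every species onto common axes using its fitted profile,
#' bins the 99th-percentile maxima and fits the split-Gaussian performance
#' model, separately per guild when requested.
#'
#' @param pipeline A [run_thermal_pipeline()] result.
#' @param guild `"all"`, `"tropical"` or `"temperate"`.
#' @param seed Master seed for the sampler.
#' @param ... Passed to [fit_split_gaussian()].
#' @return List with `posterior`, `binned`, `r2`, `n_species`.
#' @export
pooled_shape_analysis <- function(pipeline, guild = "all", seed = 1, ...) {
  prof <- pipeline$profiles
  if (guild != "all") prof <- prof[prof$guild == guild, , drop = FALSE]
  pts <- list()
  for (i in seq_len(nrow(prof))) {
    p <- prof[i, ]
    fr <- pipeline$frames[[p$species_id]]
    pts[[i]] <- tryCatch(standardize_abundance(fr, p),
                         error = function(e) NULL)
  }
  pts <- do.call(rbind, pts)
  binned <- bin_q99(pts)
  posterior <- fit_split_gaussian(binned, seed = seed, ...)
  list(posterior = posterior, binned = binned,
       r2 = fit_r2(posterior, binned),
       n_species = length(unique(pts$species_id)))
}
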