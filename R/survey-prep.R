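# Survey preparation: absence construction within a degree-space buffer,
# species eligibility filters, absence balancing and the sampling-intensity
# covariate.

#' Derive absences within a circular degree-space buffer
#'
#' For each species, zero-count records are added at surveyed sites where the
#' species was not recorded but was present somewhere within
#' `buffer_radius_deg` degrees (planar Euclidean distance on latitude /
#' longitude). These are not true absences: they mark sites at which local
#' abundance was too low for detection in a standardised survey. Species with
#' no presences anywhere are dropped with a warning. Running the function on
#' its own output adds nothing (idempotent).
#'
#' @param records Survey records (`site_id`, `species_id`, `count`).
#' @param sites Site table with `site_id`, `latitude`, `longitude`.
#' @param buffer_radius_deg Buffer radius in degrees (> 0).
#' @return Records with derived zero-count rows appended and `is_absence`
#'   set from `count == 0`.
#' @export
derive_absences <- function(records, sites, buffer_radius_deg = 10) {
  if (buffer_radius_deg <= 0) stop("`buffer_radius_deg` must be > 0")
  if (!all(c("latitude", "longitude") %in% names(sites))) {
    stop("`sites` must carry latitude/longitude coordinates")
  }
  site_idx <- match(records$site_id, sites$site_id)
  if (anyNA(site_idx)) stop("records reference unknown site_id values")
  no_presence <- setdiff(unique(records$species_id),
                         unique(records$species_id[records$count > 0]))
  if (length(no_presence)) {
    warning("dropping species with no presences: ",
            paste(no_presence, collapse = ", "))
    records <- records[!records$species_id %in% no_presence, , drop = FALSE]
  }
  out <- vector("list", length(unique(records$species_id)))
  sp_ids <- unique(records$species_id)
  for (k in seq_along(sp_ids)) {
    sp <- sp_ids[k]
    rec <- records[records$species_id == sp, , drop = FALSE]
    pres_sites <- unique(rec$site_id[rec$count > 0])
    recorded <- unique(rec$site_id)
    cand <- sites[!sites$site_id %in% recorded, , drop = FALSE]
    if (nrow(cand)) {
      ps <- sites[match(pres_sites, sites$site_id), , drop = FALSE]
      d2 <- outer(cand$latitude, ps$latitude, "-")^2 +
        outer(cand$longitude, ps$longitude, "-")^2
      within <- apply(d2 <= buffer_radius_deg^2, 1, any)
      add <- cand$site_id[within]
    } else {
      add <- character(0)
    }
    base <- data.frame(site_id = rec$site_id, species_id = sp,
                       count = rec$count, stringsAsFactors = FALSE)
    if (length(add)) {
      base <- rbind(base, data.frame(site_id = add, species_id = sp,
                                     count = 0L, stringsAsFactors = FALSE))
    }
    out[[k]] <- base
  }
  res <- do.call(rbind, out)
  res$is_absence <- res$count == 0
  rownames(res) <- NULL
  res
}

#' Build per-species modelling frames
#'
#' Joins site covariates onto survey records and attaches the per-species
#' sampling-intensity covariate, returning one data.frame per species.
#'
#' @param records Records including derived absences.
#' @param sites Site table.
#' @return Named list of per-species frames with columns `site_id`, `sst`,
#'   `latitude`, `longitude`, `depth`, `protection`, habitat covers, the
#'   environmental covariates, `sampling_intensity`, `abundance`,
#'   `is_absence`.
#' @export
build_frames <- function(records, sites) {
  idx <- match(records$site_id, sites$site_id)
  if (anyNA(idx)) stop("records reference unknown site_id values")
  joined <- cbind(records, sites[idx, setdiff(names(sites), "site_id"),
                                 drop = FALSE])
  joined$abundance <- joined$count
  frames <- split(joined, joined$species_id)
  lapply(frames, function(fr) {
    rownames(fr) <- NULL
    fr$sampling_intensity <- if (length(unique(fr$sst)) >= 2) {
      sampling_intensity(fr)
    } else {
      NA_real_
    }
    fr
  })
}

#' Filter species by data adequacy
#'
#' Retains species with at least `min_records` presence rows and an observed
#' thermal range (max - min SST over presences) of at least
#' `min_thermal_range_C`. Both thresholds are inclusive; species falling
#' below either are deemed to have inadequate data.
#'
#' @param frames List of per-species frames from [build_frames()].
#' @param min_records Minimum number of presence rows.
#' @param min_thermal_range_C Minimum presence SST range in degrees C.
#' @return The retained subset of `frames` (possibly empty).
#' @export
filter_species <- function(frames, min_records = 30, min_thermal_range_C = 3) {
  keep <- vapply(frames, function(fr) {
    pres <- fr[!fr$is_absence, , drop = FALSE]
    nrow(pres) >= min_records &&
      diff(range(pres$sst)) >= min_thermal_range_C
  }, logical(1))
  frames[keep]
}

#' Balance absences against presences
#'
#' If a frame holds more absences than presences, a uniform random subset of
#' absences of size equal to the presence count is kept (sampling without
#' replacement); otherwise the frame is returned unchanged. Presence rows are
#' never altered.
#'
#' @param frame A per-species modelling frame.
#' @param seed Integer seed (deterministic subset for a fixed seed).
#' @return The balanced frame.
#' @export
balance_absences <- function(frame, seed = 1) {
  pres <- frame[!frame$is_absence, , drop = FALSE]
  abs_rows <- frame[frame$is_absence, , drop = FALSE]
  if (nrow(abs_rows) <= nrow(pres)) return(frame)
  keep <- with_seed(seed, sample.int(nrow(abs_rows), nrow(pres)))
  out <- rbind(pres, abs_rows[sort(keep), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Sampling intensity of a species' frame
#'
#' Number of distinct survey sites per degree of temperature across the rows
#' of the frame supplied.
#'
#' @param frame A per-species frame with `site_id` and `sst`.
#' @return Sites per degree C.
#' @export
sampling_intensity <- function(frame) {
  rng <- diff(range(frame$sst))
  if (rng <= 0) stop("zero thermal range: frame should have been filtered")
  length(unique(frame$site_id)) / rng
}
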