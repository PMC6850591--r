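# Realised-niche geometry per species: thermal edges, split-Gaussian scale
# parameters, the skew statistic, guild assignment and habitat-association
# scores.

#' Thermal distribution edges
#'
#' The cool and warm edges are the 2.5th and 97.5th empirical quantiles of
#' temperatures at occupied sites, using the linear-interpolation convention
#' (R quantile type 7) held fixed across the package.
#'
#' @param presence_temperatures Temperatures (degrees C) of presence records.
#' @return Named numeric vector `c(tmin, tmax)`.
#' @export
thermal_edges <- function(presence_temperatures) {
  x <- presence_temperatures[is.finite(presence_temperatures)]
  if (length(unique(x)) < 2) stop("need at least 2 distinct temperatures")
  q <- stats::quantile(x, c(0.025, 0.975), type = 7, names = FALSE)
  c(tmin = q[1], tmax = q[2])
}

#' Split-Gaussian scale parameters from thermal edges
#'
#' `sigma_min = |topt - tmin| / z` and `sigma_max = |tmax - topt| / z`,
#' treating the edges as the 95th-percentile bounds of a normal distribution
#' centred on the optimum (`z = 1.96`). Magnitudes are used so that a
#' centred optimum gives zero skew and an optimum near the warm edge gives
#' negative skew. An optimum outside `[tmin, tmax]` is clamped to the nearer
#' edge, making the corresponding sigma zero.
#'
#' @param topt Thermal optimum (degrees C).
#' @param tmin,tmax Thermal edges, `tmin <= tmax`.
#' @param z Normal z-score mapping edge distance to a standard deviation.
#' @return Named numeric vector `c(sigma_min, sigma_max)`.
#' @export
sigmas_from_edges <- function(topt, tmin, tmax, z = 1.96) {
  topt <- unname(topt); tmin <- unname(tmin); tmax <- unname(tmax)
  if (!(tmin <= tmax)) stop("`tmin` must be <= `tmax`")
  if (topt < tmin || topt > tmax) {
    topt <- if (topt < tmin) tmin else tmax
  }
  c(sigma_min = abs(topt - tmin) / z, sigma_max = abs(tmax - topt) / z)
}

#' Thermal-abundance distribution skew
#'
#' `T_skew = sigma_max - sigma_min`: negative means warm-skewed (optimum
#' nearer the warm edge), positive cool-skewed, zero exactly centred.
#'
#' @param sigma_min,sigma_max Non-negative scale parameters.
#' @return The skew in degrees C.
#' @export
tskew <- function(sigma_min, sigma_max) {
  if (any(sigma_min < 0) || any(sigma_max < 0)) stop("sigmas must be >= 0")
  sigma_max - sigma_min
}

#' Assign a thermal guild
#'
#' Temperate when the thermal optimum is below the cutoff, tropical
#' otherwise (ties at exactly the cutoff go to tropical).
#'
#' @param topt Thermal optimum (degrees C).
#' @param cutoff Guild boundary, 23 degrees C by default.
#' @return `"temperate"` or `"tropical"` (vectorised).
#' @export
assign_guild <- function(topt, cutoff = 23) {
  ifelse(topt < cutoff, "temperate", "tropical")
}

#' Species habitat-association score
#'
#' Abundance-weighted mean habitat cover across presence sites minus the
#' unweighted mean cover across all sites in the species' frame; positive
#' values indicate association with that habitat.
#'
#' @param frame A per-species modelling frame.
#' @param cover_col Name of the cover column (e.g. `"coral_cover"`).
#' @return The association score (percentage points), or `NA` if the cover
#'   column is missing.
#' @export
habitat_association <- function(frame, cover_col) {
  if (!cover_col %in% names(frame)) return(NA_real_)
  pres <- frame[!frame$is_absence, , drop = FALSE]
  if (nrow(pres) == 0 || sum(pres$abundance) == 0) return(NA_real_)
  stats::weighted.mean(pres[[cover_col]], w = pres$abundance) -
    mean(frame[[cover_col]])
}
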