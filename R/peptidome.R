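# Peak-list processing: migration-time calibration, housekeeping
# normalization, and catalogue matching of CE-MS detections.

#' Relative cluster width of the CE electropherogram
#'
#' CE peak widths grow with migration time through analyte diffusion. The
#' matching window therefore widens linearly over the electropherogram,
#' from 2% of the migration time at 19 min to 5% at 45 min; times outside
#' that range are clamped. The value is the *full* relative window: a
#' detection at time t matches catalogue time t_p when
#' `|t - t_p| <= cluster_width(t_p) * t_p / 2`.
#'
#' @param cemt_min migration time(s), minutes
#' @return relative window width(s) in `[0.02, 0.05]`
#' @export
cluster_width <- function(cemt_min) {
  t <- clamp(cemt_min, 19, 45)
  0.02 + (0.05 - 0.02) * (t - 19) / (45 - 19)
}

# Match profile detections to reference peptides by mass (strict ppm) and a
# coarse time window; one detection per reference, nearest mass wins.
# Returns indices into profile$detections per reference row (NA = no match).
match_reference_peaks <- function(detections, reference, mass_tol_ppm, time_window_min) {
  vapply(seq_len(nrow(reference)), function(j) {
    mp <- reference$mass_da[j]
    ppm <- abs(detections$mass_da - mp) / mp * 1e6
    ok <- ppm < mass_tol_ppm &
      abs(detections$cemt_min - reference$cemt_min[j]) <= time_window_min
    if (!any(ok)) return(NA_integer_)
    which(ok)[which.min(ppm[ok])]
  }, integer(1))
}

#' Calibrate migration times against a reference catalogue
#'
#' Anchors the profile to the reference timeline: detections are matched to
#' reference peptides by mass, and a locally weighted regression (tricube
#' weights, local-linear, one robustness iteration) of reference time on
#' observed time is fitted on the anchor pairs, then applied to every
#' detection. The maximum absolute anchor residual is recorded and must be
#' below 0.35 min; a violation flags the profile rather than failing it.
#'
#' @param profile list with `sample_id` and `detections`
#'   (mass_da, cemt_min, amplitude)
#' @param reference catalogue data.frame with mass_da and cemt_min
#' @param span local-regression span as a fraction of anchors
#' @param mass_tol_ppm anchor mass tolerance (ppm, strict)
#' @param time_window_min coarse anchor time window (min)
#' @param max_residual_min admissible post-calibration anchor deviation
#' @return the profile with calibrated `cemt_min` and attributes
#'   `n_anchors`, `max_residual`, `calibration_flag`
#' @export
calibrate_migration_time <- function(profile, reference, span = 0.3,
                                     mass_tol_ppm = 50, time_window_min = 2,
                                     max_residual_min = 0.35) {
  det <- profile$detections
  idx <- match_reference_peaks(det, reference, mass_tol_ppm, time_window_min)
  anchors <- which(!is.na(idx))
  if (length(anchors) < 10) {
    stop(errorCondition(
      sprintf("calibration failed for %s: only %d reference anchors matched (>= 10 required)",
              profile$sample_id, length(anchors)),
      n_anchors = length(anchors), class = "acs_calibration_error"))
  }
  obs <- det$cemt_min[idx[anchors]]
  ref <- reference$cemt_min[anchors]
  do_fit <- function(o, r) {
    # span must leave at least 3 points in each local neighbourhood
    eff_span <- max(span, 3.5 / length(o))
    stats::loess(r ~ o, span = eff_span, degree = 1, family = "symmetric",
                 control = stats::loess.control(surface = "direct",
                                                iterations = 2))
  }
  fit <- do_fit(obs, ref)
  resid <- abs(stats::predict(fit, newdata = data.frame(o = obs)) - ref)
  # a mass-only anchor match can pair a detection with the wrong peptide
  # several minutes away; reject gross outlier anchors and refit
  cut <- max(0.35, 6 * stats::mad(resid))
  keep <- resid <= cut
  if (any(!keep) && sum(keep) >= 10) {
    obs <- obs[keep]; ref <- ref[keep]
    anchors <- anchors[keep]
    fit <- do_fit(obs, ref)
    resid <- abs(stats::predict(fit, newdata = data.frame(o = obs)) - ref)
  }
  calibrated <- stats::predict(fit, newdata = data.frame(o = det$cemt_min))
  max_resid <- max(resid)
  flagged <- max_resid >= max_residual_min
  if (flagged) {
    warning(sprintf("calibration residual %.3f min >= %.2f min for %s; profile flagged",
                    max_resid, max_residual_min, profile$sample_id))
  }
  det$cemt_min <- as.numeric(calibrated)
  profile$detections <- det
  attr(profile, "n_anchors") <- length(anchors)
  attr(profile, "max_residual") <- max_resid
  attr(profile, "calibration_flag") <- flagged
  profile
}

#' Normalize amplitudes to housekeeping peptides
#'
#' Corrects urine dilution and analytical intensity variance: housekeeping
#' peptides (stable excretion across subjects) detected in the profile are
#' regressed, without intercept, observed amplitude on reference amplitude;
#' the slope is the per-sample scale factor and all amplitudes are divided
#' by it. `method = "median_ratio"` uses the median observed/reference
#' ratio instead.
#'
#' @param profile list with `detections` (mass_da, cemt_min, amplitude)
#' @param reference catalogue with `is_housekeeping` flags and
#'   `ref_amplitude` for the housekeeping rows
#' @param mass_tol_ppm,time_window_min matching tolerances for locating the
#'   housekeeping peptides in the profile
#' @param method scale-factor estimator
#' @return profile with rescaled amplitudes; attribute `scale_factor`
#' @export
normalize_amplitudes <- function(profile, reference,
                                 mass_tol_ppm = 50, time_window_min = 2,
                                 method = c("regression", "median_ratio")) {
  method <- match.arg(method)
  hk <- reference[reference$is_housekeeping, , drop = FALSE]
  det <- profile$detections
  idx <- match_reference_peaks(det, hk, mass_tol_ppm, time_window_min)
  found <- which(!is.na(idx))
  if (length(found) < 3) {
    stop(errorCondition(
      sprintf("normalization failed for %s: %d housekeeping peptides detected (>= 3 required)",
              profile$sample_id, length(found)),
      class = "acs_normalization_error"))
  }
  obs <- det$amplitude[idx[found]]
  ref <- hk$ref_amplitude[found]
  scale <- switch(method,
                  regression = sum(ref * obs) / sum(ref^2),
                  median_ratio = stats::median(obs / ref))
  if (!is.finite(scale) || scale <= 0) {
    stop(errorCondition(sprintf("non-positive normalization factor for %s", profile$sample_id),
                        class = "acs_normalization_error"))
  }
  det$amplitude <- det$amplitude / scale
  profile$detections <- det
  attr(profile, "scale_factor") <- scale
  profile
}

#' Match calibrated profiles to the peptide catalogue
#'
#' Clusters detections across samples onto catalogue peptides: a detection
#' of observed mass m and time t is eligible for catalogue peptide p when
#' the mass deviation is strictly below `mass_tol_ppm` parts per million of
#' the catalogue mass and `|t - t_p| <= cluster_width(t_p) * t_p / 2`.
#' Among eligible peptides the smallest ppm deviation wins, ties broken by
#' smaller time deviation, then lower peptide id. Several detections of one
#' peptide within a sample are summed. Unmatched detections are counted per
#' sample, and an empty profile yields a zero row with a warning.
#'
#' @param profiles list of calibrated, normalized profiles
#' @param reference peptide catalogue (peptide_id, mass_da, cemt_min)
#' @param mass_tol_ppm mass tolerance, ppm (strict inequality)
#' @return numeric matrix samples x peptides (0 = undetected) with
#'   attribute `unmatched` (per-sample counts)
#' @export
match_to_catalog <- function(profiles, reference, mass_tol_ppm = 50) {
  ord <- order(reference$mass_da, reference$peptide_id)
  ref <- reference[ord, , drop = FALSE]
  masses <- ref$mass_da
  half_win <- cluster_width(ref$cemt_min) * ref$cemt_min / 2
  tol <- mass_tol_ppm * 1e-6

  out <- matrix(0, nrow = length(profiles), ncol = nrow(reference),
                dimnames = list(vapply(profiles, `[[`, "", "sample_id"),
                                reference$peptide_id))
  unmatched <- integer(length(profiles))
  for (s in seq_along(profiles)) {
    det <- profiles[[s]]$detections
    if (is.null(det) || nrow(det) == 0) {
      warning(sprintf("empty profile for sample %s", profiles[[s]]$sample_id))
      next
    }
    # candidate catalogue range per detection: |m - m_p| < tol * m_p
    lo <- findInterval(det$mass_da / (1 + tol), masses) + 1L
    hi <- findInterval(det$mass_da / (1 - tol), masses)
    for (i in seq_len(nrow(det))) {
      if (lo[i] > hi[i]) { unmatched[s] <- unmatched[s] + 1L; next }
      cand <- lo[i]:hi[i]
      ppm <- abs(det$mass_da[i] - masses[cand]) / masses[cand] * 1e6
      dt <- abs(det$cemt_min[i] - ref$cemt_min[cand])
      ok <- ppm < mass_tol_ppm & dt <= half_win[cand]
      if (!any(ok)) { unmatched[s] <- unmatched[s] + 1L; next }
      cand <- cand[ok]; ppm <- ppm[ok]; dt <- dt[ok]
      pick <- order(ppm, dt, ref$peptide_id[cand])[1]
      col <- match(ref$peptide_id[cand[pick]], reference$peptide_id)
      out[s, col] <- out[s, col] + det$amplitude[i]
    }
  }
  attr(out, "unmatched") <- unmatched
  out
}

#' Process raw profiles into a normalized amplitude matrix
#'
#' Applies calibration, housekeeping normalization, and catalogue matching
#' in sequence — the full peak-list processing stage.
#' @inheritParams match_to_catalog
#' @param calibrate apply migration-time calibration (skip when profiles
#'   are already on the reference timeline)
#' @param ... passed to [normalize_amplitudes()]
#' @return amplitude matrix as from [match_to_catalog()]
#' @export
process_profiles <- function(profiles, reference, mass_tol_ppm = 50,
                             calibrate = TRUE, ...) {
  prepped <- lapply(profiles, function(p) {
    if (calibrate) p <- calibrate_migration_time(p, reference, mass_tol_ppm = mass_tol_ppm)
    normalize_amplitudes(p, reference, mass_tol_ppm = mass_tol_ppm, ...)
  })
  match_to_catalog(prepped, reference, mass_tol_ppm = mass_tol_ppm)
}
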