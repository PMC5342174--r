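# Synthetic peptidome cohorts.
#
# The generator emulates the data layout of a multi-centre urinary CE-MS
# study: a peptide catalogue (mass, migration time), per-sample peak lists
# with detection dropout and urine-dilution scaling, case/control labels
# with censored time-to-event outcomes, and clinical covariates including a
# Framingham-style 10-year risk score. Planted differential excretion on a
# known biomarker subset gives every downstream stage a recoverable truth.

#' Simulation configuration for a synthetic peptidome cohort
#'
#' Defaults reflect the study design the pipeline targets: 126 cases with an
#' ACS event within five years of urine sampling and 126 event-free
#' controls, roughly two thousand catalogued peptides of which 75 carry a
#' planted case/control excretion difference, and 29 housekeeping peptides
#' detected in every sample and used for dilution normalization.
#'
#' @param n_cases,n_controls cohort sizes (cases carry an event in follow-up)
#' @param n_peptides catalogue size
#' @param n_true_biomarkers number of peptides with planted differential
#'   excretion (never housekeeping)
#' @param log2_effect_mean,log2_effect_sd magnitude distribution of the
#'   planted case-vs-control shift on the log2 amplitude scale; each
#'   biomarker's sign is random (urinary markers go both ways)
#' @param base_log_amplitude_sd within-group biological + analytical
#'   spread of detected log2 amplitudes
#' @param housekeeping_log_sd log2 amplitude spread of the housekeeping
#'   peptides, which are selected for small relative standard deviation;
#'   their stability is what makes dilution normalization work
#' @param detect_freq_range range the per-peptide control-group detection
#'   frequency is drawn from (Bernoulli dropout per sample)
#' @param biomarker_detect_freq detection frequency of the planted
#'   biomarkers in controls (NA: drawn from `detect_freq_range` like any
#'   other peptide). Plantable biomarkers are typically high-frequency —
#'   the discovery filter only considers peptides seen in at least 70% of
#'   one group
#' @param case_freq_shift additive shift of the detection frequency in the
#'   case group, applied to planted biomarkers only, capped at 1
#' @param mass_range_da,cemt_range_min uniform ranges for catalogue mass
#'   (Da) and mean CE migration time (min, within the 19-45 min window)
#' @param mass_jitter_ppm half-width of the uniform per-detection relative
#'   mass error; must stay below the 50 ppm matching tolerance
#' @param cemt_jitter_fraction per-detection migration-time jitter as a
#'   fraction of the half cluster width at the catalogue time; must be <= 1
#'   so generated detections are matchable by construction
#' @param n_housekeeping housekeeping peptides, detected in every sample
#' @param follow_up_years administrative censoring horizon
#' @param baseline_hazard event hazard (per year) at true risk 0
#' @param risk_sd standard deviation of the latent per-subject log relative
#'   risk; 0 gives a homogeneous-hazard cohort
#' @param censor_rate rate (per year) of random loss to follow-up
#' @param dilution_range range of the per-sample multiplicative urine
#'   dilution factor, drawn log-uniformly
#' @param case_age_shift mean extra years of age for cases
#' @param seed integer seed; all generator randomness derives from it
#' @return a validated `sim_config` list
#' @export
sim_config <- function(n_cases = 126L, n_controls = 126L,
                       n_peptides = 2042L, n_true_biomarkers = 75L,
                       log2_effect_mean = 1.0, log2_effect_sd = 0.25,
                       base_log_amplitude_sd = 1.0,
                       housekeeping_log_sd = 0.1,
                       detect_freq_range = c(0.35, 0.95),
                       biomarker_detect_freq = 0.9,
                       case_freq_shift = 0.10,
                       mass_range_da = c(800, 15000),
                       cemt_range_min = c(19, 45),
                       mass_jitter_ppm = 15,
                       cemt_jitter_fraction = 0.2,
                       n_housekeeping = 29L,
                       follow_up_years = 5,
                       baseline_hazard = 0.10,
                       risk_sd = 1.0,
                       censor_rate = 0.02,
                       dilution_range = c(0.5, 2),
                       case_age_shift = 4,
                       seed = 1L) {
  cfg <- list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              n_peptides = as.integer(n_peptides),
              n_true_biomarkers = as.integer(n_true_biomarkers),
              log2_effect_mean = log2_effect_mean, log2_effect_sd = log2_effect_sd,
              base_log_amplitude_sd = base_log_amplitude_sd,
              housekeeping_log_sd = housekeeping_log_sd,
              detect_freq_range = detect_freq_range,
              biomarker_detect_freq = biomarker_detect_freq,
              case_freq_shift = case_freq_shift,
              mass_range_da = mass_range_da, cemt_range_min = cemt_range_min,
              mass_jitter_ppm = mass_jitter_ppm,
              cemt_jitter_fraction = cemt_jitter_fraction,
              n_housekeeping = as.integer(n_housekeeping),
              follow_up_years = follow_up_years,
              baseline_hazard = baseline_hazard, risk_sd = risk_sd,
              censor_rate = censor_rate,
              dilution_range = dilution_range,
              case_age_shift = case_age_shift,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  pos_int <- function(field) {
    if (is.na(cfg[[field]]) || cfg[[field]] < 0) config_error(field, "must be a non-negative count")
  }
  for (f in c("n_cases", "n_controls", "n_peptides", "n_true_biomarkers", "n_housekeeping")) pos_int(f)
  if (cfg$n_true_biomarkers > cfg$n_peptides)
    config_error("n_true_biomarkers", "exceeds n_peptides")
  if (cfg$n_housekeeping > cfg$n_peptides)
    config_error("n_housekeeping", "exceeds n_peptides")
  if (cfg$n_true_biomarkers + cfg$n_housekeeping > cfg$n_peptides)
    config_error("n_true_biomarkers", "plus n_housekeeping exceeds n_peptides (sets must be disjoint)")
  fr <- cfg$detect_freq_range
  if (length(fr) != 2 || any(fr < 0) || any(fr > 1) || fr[1] > fr[2])
    config_error("detect_freq_range", "must be an ordered pair of fractions in [0,1]")
  if (!is.na(cfg$biomarker_detect_freq) &&
      (cfg$biomarker_detect_freq < 0 || cfg$biomarker_detect_freq > 1))
    config_error("biomarker_detect_freq", "must be a fraction in [0,1] (or NA)")
  if (cfg$case_freq_shift < 0 || cfg$case_freq_shift > 1)
    config_error("case_freq_shift", "must be a fraction in [0,1]")
  ct <- cfg$cemt_range_min
  if (length(ct) != 2 || ct[1] < 19 || ct[2] > 45 || ct[1] > ct[2])
    config_error("cemt_range_min", "must lie within [19, 45] minutes")
  if (cfg$mass_range_da[1] <= 0 || cfg$mass_range_da[1] > cfg$mass_range_da[2])
    config_error("mass_range_da", "must be an ordered positive pair")
  if (cfg$mass_jitter_ppm < 0 || cfg$mass_jitter_ppm >= 50)
    config_error("mass_jitter_ppm", "must be in [0, 50) so detections stay inside the 50 ppm matching tolerance")
  if (cfg$cemt_jitter_fraction < 0 || cfg$cemt_jitter_fraction > 1)
    config_error("cemt_jitter_fraction", "must be in [0, 1] so detections stay inside the cluster-width window")
  if (cfg$baseline_hazard < 0) config_error("baseline_hazard", "must be >= 0")
  if (cfg$censor_rate < 0) config_error("censor_rate", "must be >= 0")
  if (cfg$follow_up_years <= 0) config_error("follow_up_years", "must be > 0")
  if (cfg$risk_sd < 0) config_error("risk_sd", "must be >= 0")
  if (any(cfg$dilution_range <= 0) || cfg$dilution_range[1] > cfg$dilution_range[2])
    config_error("dilution_range", "must be an ordered positive pair")
  invisible(cfg)
}

#' Generate the peptide catalogue
#'
#' Draws `n_peptides` catalogue entries with uniform masses and migration
#' times, flags disjoint housekeeping and true-biomarker subsets, assigns
#' each peptide a baseline log2 amplitude and a control-group detection
#' frequency, and plants a signed log2 excretion effect on the biomarkers.
#' Housekeeping peptides have effect 0 and detection frequency 1.
#'
#' Randomness: the catalogue uses stream `seed`; the cohort and profiles use
#' `seed + 1` and `seed + 2`, so each stage is reproducible in isolation.
#'
#' @param config a [sim_config()]
#' @return data.frame with one row per peptide
#' @export
generate_catalog <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_peptides
  ids <- sprintf("pep%05d", seq_len(n))
  mass <- sort(stats::runif(n, config$mass_range_da[1], config$mass_range_da[2]))
  cemt <- stats::runif(n, config$cemt_range_min[1], config$cemt_range_min[2])
  base_log2 <- stats::runif(n, 10, 16)

  idx <- sample.int(n, config$n_housekeeping + config$n_true_biomarkers)
  hk <- rep(FALSE, n); hk[idx[seq_len(config$n_housekeeping)]] <- TRUE
  bm <- rep(FALSE, n)
  if (config$n_true_biomarkers > 0) {
    bm[idx[config$n_housekeeping + seq_len(config$n_true_biomarkers)]] <- TRUE
  }

  effect <- numeric(n)
  if (any(bm)) {
    mag <- abs(stats::rnorm(sum(bm), config$log2_effect_mean, config$log2_effect_sd))
    effect[bm] <- mag * sample(c(-1, 1), sum(bm), replace = TRUE)
  }

  freq_control <- stats::runif(n, config$detect_freq_range[1], config$detect_freq_range[2])
  freq_control[hk] <- 1
  if (!is.na(config$biomarker_detect_freq)) {
    freq_control[bm] <- config$biomarker_detect_freq
  }
  freq_case <- freq_control
  freq_case[bm] <- pmin(1, freq_case[bm] + config$case_freq_shift)

  data.frame(peptide_id = ids, mass_da = mass, cemt_min = cemt,
             is_housekeeping = hk, is_true_biomarker = bm,
             true_log2_effect = effect,
             base_log2_amplitude = base_log2,
             ref_amplitude = 2^base_log2,
             freq_control = freq_control, freq_case = freq_case,
             stringsAsFactors = FALSE)
}

#' Generate cohort records and per-sample ground truth
#'
#' Subjects are drawn with a latent log relative risk `r ~ N(0, risk_sd^2)`,
#' an exponential event time with hazard `baseline_hazard * exp(r)`, an
#' independent exponential censoring time, and administrative censoring at
#' `follow_up_years`. Sampling continues until the case and control quotas
#' are filled: a case is a subject whose event precedes both censoring
#' mechanisms; anyone else is an event-free control. Clinical covariates are
#' drawn with case shifts patterned on the demographics of ACS cohorts
#' (older, more hypertension/diabetes/cardiac history, lower eGFR and HDL),
#' and the synthetic Framingham score (FCVRS) is a noisy logistic transform
#' of the true risk, so it carries real but imperfect prognostic signal.
#'
#' @param config a [sim_config()]
#' @param catalog output of [generate_catalog()] (recorded for lineage only)
#' @return list with `cohort` (one row per sample) and `truth`
#'   (latent risk and uncensored times per sample)
#' @export
generate_cohort <- function(config, catalog) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  n_target <- config$n_cases + config$n_controls
  max_draws <- max(1000L * n_target, 100000L)

  risk <- numeric(0); ev_time <- numeric(0); cs_time <- numeric(0); is_case <- logical(0)
  drawn <- 0L
  batch <- max(2L * n_target, 64L)
  while ((sum(is_case) < config$n_cases || sum(!is_case) < config$n_controls) &&
         drawn < max_draws) {
    r <- stats::rnorm(batch, 0, config$risk_sd)
    h <- config$baseline_hazard * exp(r)
    te <- ifelse(h > 0, stats::rexp(batch, pmax(h, .Machine$double.xmin)), Inf)
    tc <- if (config$censor_rate > 0) stats::rexp(batch, config$censor_rate) else rep(Inf, batch)
    case <- te <= pmin(tc, config$follow_up_years)
    risk <- c(risk, r); ev_time <- c(ev_time, te); cs_time <- c(cs_time, tc)
    is_case <- c(is_case, case)
    drawn <- drawn + batch
  }
  if (sum(is_case) < config$n_cases)
    config_error("baseline_hazard", sprintf(
      "infeasible: only %d events in %d draws; cannot fill %d cases",
      sum(is_case), drawn, config$n_cases))
  if (sum(!is_case) < config$n_controls)
    config_error("censor_rate", "infeasible: cannot fill control quota")

  keep <- c(which(is_case)[seq_len(config$n_cases)],
            which(!is_case)[seq_len(config$n_controls)])
  risk <- risk[keep]; ev_time <- ev_time[keep]; cs_time <- cs_time[keep]
  case <- is_case[keep]
  n <- length(keep)

  obs_time <- ifelse(case, ev_time, pmin(cs_time, config$follow_up_years))
  event <- as.integer(case)

  centre <- sample(c("AUSDIA", "FLEMEN", "CACTI", "HACVD"), n, replace = TRUE,
                   prob = c(0.86, 0.06, 0.03, 0.05))
  sex <- ifelse(stats::runif(n) < 0.35, "F", "M")
  age <- round(stats::rnorm(n, 64, 11) + 2.5 * risk + config$case_age_shift * case)
  age <- clamp(age, 30, 95)
  sbp <- round(stats::rnorm(n, 136, 19) + 5 * case + 3 * risk)
  dbp <- round(stats::rnorm(n, 72, 12) + 4 * case)
  bmi <- round(stats::rnorm(n, 26, 4) + 1.5 * case, 1)
  smoker <- as.integer(stats::runif(n) < (0.10 + 0.12 * case))
  chol <- round(stats::rnorm(n, 6.0, 1.2), 1)
  hdl <- round(pmax(0.4, stats::rnorm(n, 1.5, 0.35) - 0.2 * case), 2)
  egfr <- round(pmax(15, stats::rnorm(n, 72, 13) - 3 * case - 3 * risk))
  diabetes <- as.integer(stats::runif(n) < (0.13 + 0.16 * case))
  hypertension <- as.integer(stats::runif(n) < (0.45 + 0.24 * case))
  hist_cvd <- as.integer(stats::runif(n) < (0.07 + 0.16 * case))
  fcvrs <- clamp(stats::plogis(-1.4 + 1.1 * risk + 0.012 * (age - 64) +
                                 stats::rnorm(n, 0, 0.6)), 0, 1)
  cad238 <- round(0.5 * risk + 0.4 * case + stats::rnorm(n, 0, 0.6), 4)

  ord <- sample.int(n)  # shuffle so cases/controls are interleaved
  sid <- sprintf("s%04d", seq_len(n))
  cohort <- data.frame(sample_id = sid, study = centre[ord],
                       label = ifelse(case[ord], "case", "control"),
                       time_years = round(obs_time[ord], 4),
                       event = event[ord],
                       age = age[ord], sex = sex[ord],
                       sbp = sbp[ord], dbp = dbp[ord], bmi = bmi[ord],
                       smoker = smoker[ord], chol = chol[ord], hdl = hdl[ord],
                       egfr = egfr[ord], diabetes = diabetes[ord],
                       hypertension = hypertension[ord], hist_cvd = hist_cvd[ord],
                       fcvrs = round(fcvrs[ord], 4), cad238 = cad238[ord],
                       stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = sid, true_risk = risk[ord],
                      event_time = ev_time[ord], censor_time = pmin(cs_time[ord], config$follow_up_years),
                      stringsAsFactors = FALSE)
  list(cohort = cohort, truth = truth)
}

#' Generate raw CE-MS peak-list profiles for a cohort
#'
#' For every sample, each catalogued peptide is detected independently with
#' its group-specific frequency (housekeeping peptides always). Detected
#' log2 amplitudes are Gaussian around the peptide baseline, shifted by the
#' planted effect in cases; every amplitude in a sample is multiplied by one
#' log-uniform dilution factor, which housekeeping normalization must undo.
#' Observed coordinates carry uniform mass jitter (ppm) and migration-time
#' jitter bounded by a fraction of the half cluster width, so profiles are
#' matchable back to the catalogue by construction.
#'
#' @param config a [sim_config()]
#' @param catalog output of [generate_catalog()]
#' @param cohort cohort data.frame from [generate_cohort()]
#' @return list of profiles; each has `sample_id`, `dilution`, and a
#'   `detections` data.frame (mass_da, cemt_min, amplitude, peptide_id —
#'   the id is generator truth, not visible to the matcher)
#' @export
generate_profiles <- function(config, catalog, cohort) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  case <- as_case_flag(cohort$label)
  halfwidth <- cluster_width(catalog$cemt_min) * catalog$cemt_min / 2
  lapply(seq_len(nrow(cohort)), function(i) {
    freq <- if (case[i]) catalog$freq_case else catalog$freq_control
    det <- stats::runif(nrow(catalog)) < freq
    k <- sum(det)
    dil <- exp(stats::runif(1, log(config$dilution_range[1]), log(config$dilution_range[2])))
    mu <- catalog$base_log2_amplitude[det] +
      if (case[i]) catalog$true_log2_effect[det] else 0
    sdv <- ifelse(catalog$is_housekeeping[det], config$housekeeping_log_sd,
                  config$base_log_amplitude_sd)
    amp <- 2^(mu + stats::rnorm(k, 0, sdv)) * dil
    mass <- catalog$mass_da[det] *
      (1 + stats::runif(k, -1, 1) * config$mass_jitter_ppm * 1e-6)
    cemt <- catalog$cemt_min[det] +
      stats::runif(k, -1, 1) * config$cemt_jitter_fraction * halfwidth[det]
    list(sample_id = cohort$sample_id[i], dilution = dil,
         detections = data.frame(mass_da = mass, cemt_min = cemt,
                                 amplitude = amp,
                                 peptide_id = catalog$peptide_id[det],
                                 stringsAsFactors = FALSE))
  })
}

#' Split a cohort into discovery and validation sets with matched controls
#'
#' Cases are assigned to discovery at random in the given ratio (the rest
#' validate). Within each split, every case is greedily paired with an
#' unused control of the same sex whose age differs by at most
#' `match_age_window` years, nearest age first (ties to the lower sample
#' id). Cases with no eligible control are reported, never dropped
#' silently.
#'
#' @param cohort cohort data.frame (needs sample_id, label, age, sex)
#' @param ratio fraction of cases assigned to discovery (default 2/3)
#' @param match_age_window maximum case-control age difference, years
#' @param seed integer seed for the random case split
#' @return list with `discovery` / `validation` (character sample ids,
#'   cases then matched controls), `pairs` (data.frame of case_id,
#'   control_id, split), and `unmatched` (case ids with no usable control)
#' @export
split_discovery_validation <- function(cohort, ratio = 2 / 3,
                                       match_age_window = 5, seed = 1L) {
  case <- as_case_flag(cohort$label)
  if (!any(case) || all(case)) stop("cohort must contain both cases and controls")
  set.seed(seed)
  case_ids <- cohort$sample_id[case]
  n_disc <- round(ratio * length(case_ids))
  disc_cases <- sort(sample(case_ids, n_disc))
  valid_cases <- sort(setdiff(case_ids, disc_cases))

  ctrl <- cohort[!case, , drop = FALSE]
  used <- character(0)
  match_one <- function(cid) {
    crow <- cohort[cohort$sample_id == cid, ]
    elig <- ctrl[ctrl$sex == crow$sex &
                   abs(ctrl$age - crow$age) <= match_age_window &
                   !(ctrl$sample_id %in% used), , drop = FALSE]
    if (nrow(elig) == 0) return(NA_character_)
    elig <- elig[order(abs(elig$age - crow$age), elig$sample_id), , drop = FALSE]
    elig$sample_id[1]
  }
  pairs <- data.frame(case_id = character(0), control_id = character(0),
                      split = character(0), stringsAsFactors = FALSE)
  unmatched <- character(0)
  for (split in c("discovery", "validation")) {
    ids <- if (split == "discovery") disc_cases else valid_cases
    for (cid in ids) {
      m <- match_one(cid)
      if (is.na(m)) {
        unmatched <- c(unmatched, cid)
      } else {
        used <- c(used, m)
        pairs <- rbind(pairs, data.frame(case_id = cid, control_id = m,
                                         split = split, stringsAsFactors = FALSE))
      }
    }
  }
  dp <- pairs[pairs$split == "discovery", ]
  vp <- pairs[pairs$split == "validation", ]
  list(discovery = c(dp$case_id, dp$control_id),
       validation = c(vp$case_id, vp$control_id),
       pairs = pairs, unmatched = unmatched,
       n_discovery_cases = length(disc_cases),
       n_validation_cases = length(valid_cases))
}

#' Generate a complete synthetic study bundle
#'
#' Convenience wrapper chaining catalogue, cohort, and profile generation.
#' @param config a [sim_config()]
#' @return list with `config`, `catalog`, `cohort`, `truth`, `profiles`
#' @export
generate_bundle <- function(config) {
  catalog <- generate_catalog(config)
  ct <- generate_cohort(config, catalog)
  profiles <- generate_profiles(config, catalog, ct$cohort)
  list(config = config, catalog = catalog, cohort = ct$cohort,
       truth = ct$truth, profiles = profiles)
}
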