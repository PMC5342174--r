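# Synthetic-cohort generator: counting contracts, determinism, outcome
# model calibration, and the statistical structure downstream stages rely
# on.

test_that("catalogue honours counts, disjointness, and the null model", {
  cfg <- sim_config(n_peptides = 100, n_true_biomarkers = 10,
                    n_housekeeping = 5, seed = 1)
  cat1 <- generate_catalog(cfg)
  expect_equal(nrow(cat1), 100)
  expect_equal(sum(cat1$is_true_biomarker), 10)
  expect_equal(sum(cat1$is_housekeeping), 5)
  expect_false(any(cat1$is_housekeeping & cat1$is_true_biomarker))
  expect_false(anyDuplicated(cat1$peptide_id) > 0)
  expect_true(all(cat1$mass_da > 0))
  expect_true(all(cat1$true_log2_effect[cat1$is_housekeeping] == 0))
  expect_true(all(cat1$true_log2_effect[!cat1$is_true_biomarker] == 0))
  expect_true(all(cat1$mass_da >= cfg$mass_range_da[1] &
                    cat1$mass_da <= cfg$mass_range_da[2]))
  expect_true(all(cat1$cemt_min >= 19 & cat1$cemt_min <= 45))

  # same seed: byte-identical
  expect_identical(cat1, generate_catalog(cfg))

  # null model: no biomarkers, no effects
  null_cat <- generate_catalog(sim_config(n_peptides = 100,
                                          n_true_biomarkers = 0, seed = 2))
  expect_true(all(null_cat$true_log2_effect == 0))
})

test_that("invalid configurations name the offending field", {
  expect_error(sim_config(n_true_biomarkers = 200, n_peptides = 100),
               "n_true_biomarkers")
  expect_error(sim_config(cemt_range_min = c(10, 45)), "cemt_range_min")
  expect_error(sim_config(mass_jitter_ppm = 60), "mass_jitter_ppm")
  expect_error(sim_config(detect_freq_range = c(0.9, 0.2)), "detect_freq_range")
  expect_error(sim_config(cemt_jitter_fraction = 1.5), "cemt_jitter_fraction")
})

test_that("cohort meets quotas with consistent outcomes", {
  cfg <- sim_config(n_cases = 84, n_controls = 84, n_peptides = 50,
                    n_true_biomarkers = 5, n_housekeeping = 5, seed = 3)
  ct <- generate_cohort(cfg, generate_catalog(cfg))
  expect_equal(nrow(ct$cohort), 168)
  expect_equal(sum(ct$cohort$event), 84)
  expect_equal(sum(ct$cohort$label == "case"), 84)
  expect_true(all(ct$cohort$time_years[ct$cohort$event == 1] <= cfg$follow_up_years))
  expect_true(all(ct$cohort$time_years >= 0))
  expect_true(all(ct$cohort$fcvrs >= 0 & ct$cohort$fcvrs <= 1))
  # observed time = min(event, censoring, follow-up)
  merged <- merge(ct$cohort, ct$truth, by = "sample_id")
  expect_true(all(abs(merged$time_years -
                        round(pmin(merged$event_time, merged$censor_time), 4)) < 1e-6))
  # determinism
  ct2 <- generate_cohort(cfg, generate_catalog(cfg))
  expect_identical(ct, ct2)
})

test_that("zero baseline hazard is reported as infeasible", {
  cfg <- sim_config(n_cases = 5, n_controls = 5, n_peptides = 30,
                    n_true_biomarkers = 2, n_housekeeping = 3,
                    baseline_hazard = 0, seed = 1)
  expect_error(generate_cohort(cfg, generate_catalog(cfg)), "infeasible")
})

test_that("event times follow the truncated exponential under a homogeneous hazard", {
  h <- 0.3; fu <- 5
  cfg <- sim_config(n_cases = 10000, n_controls = 10, n_peptides = 30,
                    n_true_biomarkers = 2, n_housekeeping = 3,
                    baseline_hazard = h, risk_sd = 0, censor_rate = 0,
                    follow_up_years = fu, seed = 11)
  ct <- generate_cohort(cfg, generate_catalog(cfg))
  times <- ct$cohort$time_years[ct$cohort$event == 1]
  # closed-form mean of Exp(h) truncated to events before follow-up
  expected <- 1 / h - fu * exp(-h * fu) / (1 - exp(-h * fu))
  mc_se <- stats::sd(times) / sqrt(length(times))
  expect_lt(abs(mean(times) - expected), 4 * mc_se)
})

test_that("profiles respect detection, jitter, and dilution contracts", {
  cfg <- tiny_config(detect_freq_range = c(1, 1), case_freq_shift = 0,
                     mass_jitter_ppm = 0, cemt_jitter_fraction = 0,
                     dilution_range = c(1, 1))
  b <- generate_bundle(cfg)
  # every peptide present at exact catalogue coordinates
  for (p in b$profiles[1:3]) {
    expect_equal(nrow(p$detections), nrow(b$catalog))
    ord <- match(b$catalog$peptide_id, p$detections$peptide_id)
    expect_equal(p$detections$mass_da[ord], b$catalog$mass_da)
    expect_equal(p$detections$cemt_min[ord], b$catalog$cemt_min)
  }

  # jitter stays within the declared bounds
  cfg2 <- tiny_config(mass_jitter_ppm = 10, cemt_jitter_fraction = 0.5)
  b2 <- generate_bundle(cfg2)
  for (p in b2$profiles[1:3]) {
    i <- match(p$detections$peptide_id, b2$catalog$peptide_id)
    ppm <- abs(p$detections$mass_da - b2$catalog$mass_da[i]) /
      b2$catalog$mass_da[i] * 1e6
    expect_true(all(ppm <= 10 + 1e-9))
    half <- cluster_width(b2$catalog$cemt_min[i]) * b2$catalog$cemt_min[i] / 2
    expect_true(all(abs(p$detections$cemt_min - b2$catalog$cemt_min[i]) <=
                      0.5 * half + 1e-12))
  }
})

test_that("a planted +1 log2 effect doubles the case/control amplitude ratio", {
  cfg <- sim_config(n_cases = 300, n_controls = 300, n_peptides = 12,
                    n_true_biomarkers = 4, n_housekeeping = 4,
                    log2_effect_mean = 1, log2_effect_sd = 0,
                    biomarker_detect_freq = 1, case_freq_shift = 0,
                    detect_freq_range = c(1, 1), dilution_range = c(1, 1),
                    base_log_amplitude_sd = 0.5, seed = 5)
  b <- generate_bundle(cfg)
  case <- b$cohort$label == "case"
  bm <- which(b$catalog$is_true_biomarker)
  for (j in bm) {
    id <- b$catalog$peptide_id[j]
    amps <- t(vapply(b$profiles, function(p) {
      k <- match(id, p$detections$peptide_id)
      c(p$detections$amplitude[k])
    }, numeric(1)))
    ratio <- mean(amps[case]) / mean(amps[!case])
    expected <- 2^b$catalog$true_log2_effect[j]
    expect_lt(abs(log2(ratio) - log2(expected)), 0.35)
  }
})

test_that("with no planted structure, case and control amplitudes agree in law", {
  pvals <- vapply(1:5, function(s) {
    cfg <- sim_config(n_cases = 40, n_controls = 40, n_peptides = 20,
                      n_true_biomarkers = 0, n_housekeeping = 5,
                      detect_freq_range = c(1, 1), case_freq_shift = 0,
                      dilution_range = c(1, 1), seed = 100 + s)
    b <- generate_bundle(cfg)
    case <- b$cohort$label == "case"
    amp_of <- function(p) log2(p$detections$amplitude)
    x <- unlist(lapply(b$profiles[case], amp_of))
    y <- unlist(lapply(b$profiles[!case], amp_of))
    suppressWarnings(stats::ks.test(x, y)$p.value)
  }, numeric(1))
  # null p-values should not pile up at zero
  expect_gt(max(pvals), 0.1)
  expect_lt(sum(pvals < 0.01), 3)
})

test_that("discovery/validation split assigns 2/3 of cases and matches controls", {
  cfg <- sim_config(n_cases = 126, n_controls = 126, n_peptides = 30,
                    n_true_biomarkers = 2, n_housekeeping = 3, seed = 9)
  ct <- generate_cohort(cfg, generate_catalog(cfg))
  sp <- split_discovery_validation(ct$cohort, ratio = 2 / 3,
                                   match_age_window = 5, seed = 21)
  expect_equal(sp$n_discovery_cases, 84)
  expect_equal(sp$n_validation_cases, 42)
  expect_length(intersect(sp$discovery, sp$validation), 0)
  # every matched pair respects sex and the age window
  rn <- ct$cohort; rownames(rn) <- rn$sample_id
  for (k in seq_len(nrow(sp$pairs))) {
    ca <- rn[sp$pairs$case_id[k], ]; co <- rn[sp$pairs$control_id[k], ]
    expect_identical(ca$sex, co$sex)
    expect_lte(abs(ca$age - co$age), 5)
    expect_identical(co$label, "control")
  }
  expect_false(anyDuplicated(sp$pairs$control_id) > 0)
  expect_equal(length(sp$unmatched) + nrow(sp$pairs), 126)
})

test_that("cases with no eligible control are reported unmatched", {
  cohort <- data.frame(sample_id = sprintf("x%02d", 1:8),
                       label = rep(c("case", "control"), each = 4),
                       age = rep(50, 8),
                       sex = rep(c("M", "F"), each = 4),
                       stringsAsFactors = FALSE)
  sp <- split_discovery_validation(cohort, ratio = 0.5, seed = 1)
  expect_equal(sort(sp$unmatched), sort(cohort$sample_id[1:4]))
  expect_equal(nrow(sp$pairs), 0)
})

test_that("a uniquely matchable pairing is recovered", {
  # each case has exactly one control within the age window and sex
  cohort <- data.frame(
    sample_id = c("c1", "c2", "c3", "k1", "k2", "k3"),
    label = rep(c("case", "control"), each = 3),
    age = c(40, 60, 80, 41, 59, 78),
    sex = "M", stringsAsFactors = FALSE)
  sp <- split_discovery_validation(cohort, ratio = 1, match_age_window = 5,
                                   seed = 4)
  got <- sp$pairs[order(sp$pairs$case_id), c("case_id", "control_id")]
  expect_equal(got$control_id, c("k1", "k2", "k3"))
  expect_length(sp$unmatched, 0)
})
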