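# End-to-end orchestration and bundle I/O. TSV dialect: tab-separated,
# UTF-8, header row, empty cell = missing.

#' Write a study bundle as plain-text tables
#'
#' Four TSV files (cohort classification, amplitude matrix with peptide
#' columns, peptide catalogue, clinical covariates) plus a JSON truth file
#' for tests. Round-trips through [read_bundle()].
#'
#' @param bundle list with `cohort`, `catalog`, optionally `matrix` and
#'   `truth`
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cohort = file.path(dir, "cohort.tsv"),
             catalog = file.path(dir, "catalog.tsv"),
             clinical = file.path(dir, "clinical.tsv"))
  class_cols <- c("sample_id", "study", "label", "time_years", "event")
  utils::write.table(bundle$cohort[, class_cols], paths["cohort"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  clin_cols <- setdiff(names(bundle$cohort), c("study", "label", "time_years", "event"))
  utils::write.table(bundle$cohort[, clin_cols], paths["clinical"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$catalog, paths["catalog"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$matrix)) {
    paths["matrix"] <- file.path(dir, "matrix.tsv")
    m <- data.frame(sample_id = rownames(bundle$matrix), bundle$matrix,
                    check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(m, paths["matrix"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(bundle$truth)) {
    paths["truth"] <- file.path(dir, "truth.json")
    jsonlite::write_json(bundle$truth, paths["truth"], digits = NA, pretty = TRUE)
  }
  invisible(paths)
}

#' Read and validate a study bundle
#'
#' Reads the TSV tables written by [write_bundle()] and cross-checks them:
#' matrix rows must be known samples, amplitudes non-negative, ids unique.
#'
#' @param dir directory holding cohort.tsv, catalog.tsv, clinical.tsv and
#'   optionally matrix.tsv
#' @return list with `cohort` (classification joined with clinical),
#'   `catalog`, and `matrix` (or NULL)
#' @export
read_bundle <- function(dir) {
  rd <- function(f) utils::read.delim(file.path(dir, f), sep = "\t",
                                      check.names = FALSE,
                                      stringsAsFactors = FALSE)
  need <- function(df, cols, file) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      stop(sprintf("%s: missing column(s) %s", file, paste(miss, collapse = ", ")))
    }
  }
  cls <- rd("cohort.tsv")
  need(cls, c("sample_id", "label", "time_years", "event"), "cohort.tsv")
  if (anyDuplicated(cls$sample_id)) {
    stop(sprintf("cohort.tsv: duplicate sample id '%s'",
                 cls$sample_id[duplicated(cls$sample_id)][1]))
  }
  clin <- rd("clinical.tsv")
  need(clin, "sample_id", "clinical.tsv")
  orphan <- setdiff(clin$sample_id, cls$sample_id)
  if (length(orphan) > 0) {
    stop(sprintf("clinical.tsv: unknown sample id '%s'", orphan[1]))
  }
  cohort <- merge(cls, clin, by = "sample_id", sort = FALSE)
  catalog <- rd("catalog.tsv")
  need(catalog, c("peptide_id", "mass_da", "cemt_min"), "catalog.tsv")
  if (anyDuplicated(catalog$peptide_id)) stop("catalog.tsv: duplicate peptide id")

  mat <- NULL
  if (file.exists(file.path(dir, "matrix.tsv"))) {
    m <- rd("matrix.tsv")
    need(m, "sample_id", "matrix.tsv")
    orphan <- setdiff(m$sample_id, cls$sample_id)
    if (length(orphan) > 0) {
      stop(sprintf("matrix.tsv: unknown sample id '%s'", orphan[1]))
    }
    mat <- as.matrix(m[, -1, drop = FALSE])
    rownames(mat) <- m$sample_id
    if (any(mat < 0)) stop("matrix.tsv: negative amplitude")
  }
  list(cohort = cohort, catalog = catalog, matrix = mat)
}

md5_of <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, version = 2)
  unname(tools::md5sum(f))
}

#' Run the full prognostic pipeline on a synthetic (or provided) bundle
#'
#' Orchestrates simulate -> process -> split -> discover -> train -> score
#' -> composite -> evaluate. All fitting (panel selection, SVM, composite
#' weights, thresholds) happens on the discovery split only; the validation
#' split is scored and evaluated blind, with the manifest asserting zero
#' sample overlap between the two.
#'
#' @param config list of run settings: `sim` (a [sim_config()]) or
#'   `bundle_dir` to read; `freq_min`, `alpha`, `C`, `gamma`,
#'   `split_ratio`, `match_age_window`, `categories`, `seed`; optional
#'   `out_dir` to write tables
#' @return list with per-stage results and a `manifest` (config hash,
#'   package version, stage checksums, timings, warnings)
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(list(freq_min = 0.70, alpha = 0.05,
                                C = 1638.4, gamma = 0.000256,
                                split_ratio = 2 / 3, match_age_window = 5,
                                categories = c(0.10, 0.20), seed = 1L,
                                calibrate = TRUE),
                           config)
  warnings_log <- character(0)
  timings <- c()
  manifest_stage <- list()
  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stage_error(name, conditionMessage(e))
      }),
      warning = function(w) {
        warnings_log <<- c(warnings_log, sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    timings[name] <<- proc.time()[["elapsed"]] - t0
    manifest_stage[[name]] <<- md5_of(res)
    res
  }

  bundle <- run_stage("simulate", {
    if (!is.null(cfg$bundle_dir)) {
      b <- read_bundle(cfg$bundle_dir)
      list(cohort = b$cohort, catalog = b$catalog, matrix = b$matrix)
    } else {
      sim <- if (is.null(cfg$sim)) sim_config(seed = cfg$seed) else cfg$sim
      generate_bundle(sim)
    }
  })

  mat <- run_stage("process", {
    if (!is.null(bundle$matrix)) bundle$matrix
    else process_profiles(bundle$profiles, bundle$catalog,
                          calibrate = isTRUE(cfg$calibrate))
  })

  split <- run_stage("split", split_discovery_validation(
    bundle$cohort, ratio = cfg$split_ratio,
    match_age_window = cfg$match_age_window, seed = cfg$seed))

  cohort <- bundle$cohort
  rownames(cohort) <- cohort$sample_id
  disc <- split$discovery
  valid <- split$validation
  if (length(intersect(disc, valid)) > 0) {
    stage_error("split", "discovery/validation overlap")
  }

  # housekeeping peptides are normalization references, not biomarker
  # candidates: normalization pins their values by construction
  candidate_cols <- colnames(mat)
  if ("is_housekeeping" %in% names(bundle$catalog)) {
    hk_ids <- bundle$catalog$peptide_id[bundle$catalog$is_housekeeping]
    candidate_cols <- setdiff(candidate_cols, hk_ids)
  }
  panel <- run_stage("discover", discover_panel(
    mat[disc, candidate_cols, drop = FALSE], cohort[disc, "label"],
    freq_min = cfg$freq_min, alpha = cfg$alpha))
  if (panel$n_selected == 0) stage_error("discover", "empty biomarker panel")

  model <- run_stage("train", {
    feats <- feature_transform(mat[disc, , drop = FALSE], panel$records$peptide_id)
    train_pattern(feats, cohort[disc, "label"], C = cfg$C, gamma = cfg$gamma,
                  seed = cfg$seed)
  })

  scores <- run_stage("score", {
    feats <- feature_transform(mat, panel$records$peptide_id)
    score_samples(model, feats)
  })

  comp <- run_stage("composite", {
    w <- fit_composite_weights(scores[disc], cohort[disc, "cad238"],
                               cohort[disc, "age"], cohort[disc, "label"])
    all_scores <- composite_score(scores, cohort[names(scores), "cad238"],
                                  cohort[names(scores), "age"], w$weights)
    list(weights = w, scores = all_scores)
  })

  evaluation <- run_stage("evaluate", {
    thr <- youden_threshold(scores[disc], cohort[disc, "label"])
    cthr <- youden_threshold(comp$scores[disc], cohort[disc, "label"])
    v <- cohort[valid, ]
    vs <- scores[valid]
    vc <- comp$scores[valid]
    flag <- factor(ifelse(vs > thr$threshold, "above", "below"),
                   levels = c("below", "above"))
    cox_cov <- data.frame(pattern_pos = as.integer(vs > thr$threshold),
                          age = v$age, egfr = v$egfr,
                          diabetes = v$diabetes, hypertension = v$hypertension,
                          hist_cvd = v$hist_cvd)
    # a small validation split can leave a covariate constant; drop it
    cox_cov <- cox_cov[, vapply(cox_cov, function(x) length(unique(x)) > 1,
                                logical(1)), drop = FALSE]
    models <- nested_logistic_models(v$label, v$study, v$fcvrs,
                                     pattern_score = vs, composite = vc)
    list(threshold = thr, composite_threshold = cthr,
         pattern = list(
           diagnostics = diagnostic_summary(vs, v$label, thr$threshold),
           auc = roc_auc(vs, v$label)$auc,
           harrell = harrell_c(vs, v$time_years, v$event),
           km = km_estimate(v$time_years, v$event, flag),
           cox = stepwise_cox(v$time_years, v$event, cox_cov)),
         composite = list(
           diagnostics = diagnostic_summary(vc, v$label, cthr$threshold),
           auc = roc_auc(vc, v$label)$auc,
           harrell = harrell_c(vc, v$time_years, v$event)),
         reclassification = list(
           model2_vs_1 = idi_nri(models$p1, models$p2, v$label, cfg$categories),
           model3_vs_1 = idi_nri(models$p1, models$p3, v$label, cfg$categories)))
  })

  manifest <- list(config_hash = md5_of(cfg),
                   package_version = as.character(utils::packageVersion("acspredict")),
                   stage_checksums = manifest_stage,
                   timings = timings,
                   n_discovery = length(disc), n_validation = length(valid),
                   split_overlap = length(intersect(disc, valid)),
                   leakage_guard = identical(sort(model$train_ids), sort(disc)),
                   warnings = warnings_log)

  result <- list(bundle = bundle, matrix = mat, split = split, panel = panel,
                 model = model, scores = scores, composite = comp,
                 evaluation = evaluation, manifest = manifest)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_bundle(list(cohort = bundle$cohort, catalog = bundle$catalog,
                      matrix = mat, truth = bundle$truth), cfg$out_dir)
    utils::write.table(panel$records, file.path(cfg$out_dir, "panel.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(sample_id = names(scores),
                                  pattern_score = unname(scores),
                                  composite_score = unname(comp$scores)),
                       file.path(cfg$out_dir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  result
}
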