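#!/usr/bin/env Rscript
# Stage 5: blinded prognostic evaluation on the validation split.
#
# Thresholds are fixed on the discovery split (Youden), then the
# validation samples are assessed: sensitivity/specificity with exact
# binomial intervals, positive likelihood ratio, ROC AUC, Harrell's c on
# the censored outcomes, Kaplan-Meier curves and stepwise Cox for the
# dichotomized score, and IDI/NRI of the risk models over the Framingham
# baseline. Writes results/evaluation.json and the KM/Cox tables.

library(acspredict)

b <- read_bundle("results/bundle")
sp <- read.delim("results/split.tsv")
sc <- read.delim("results/scores.tsv")
rownames(b$cohort) <- b$cohort$sample_id
scores <- setNames(sc$pattern_score, sc$sample_id)
comp <- setNames(sc$composite_score, sc$sample_id)
disc <- sp$sample_id[sp$split == "discovery"]
valid <- sp$sample_id[sp$split == "validation"]
v <- b$cohort[valid, ]

thr <- youden_threshold(scores[disc], b$cohort[disc, "label"])
cthr <- youden_threshold(comp[disc], b$cohort[disc, "label"])
cat(sprintf("thresholds fixed on discovery: pattern %.4f (J=%.2f), composite %.3f\n",
            thr$threshold, thr$J, cthr$threshold))

d_pat <- diagnostic_summary(scores[valid], v$label, thr$threshold)
d_cmp <- diagnostic_summary(comp[valid], v$label, cthr$threshold)
cat("validation, pattern score:   "); print(d_pat)
cat("validation, composite score: "); print(d_cmp)

hc <- harrell_c(scores[valid], v$time_years, v$event)
cat(sprintf("Harrell c (pattern, censored): %.3f (%.3f-%.3f)\n",
            hc$c, hc$ci[1], hc$ci[2]))

flag <- factor(ifelse(scores[valid] > thr$threshold, "above", "below"),
               levels = c("below", "above"))
km <- km_estimate(v$time_years, v$event, flag)
write.table(km, "results/km_curve.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

covs <- data.frame(pattern_pos = as.integer(scores[valid] > thr$threshold),
                   age = v$age, egfr = v$egfr, diabetes = v$diabetes,
                   hypertension = v$hypertension, hist_cvd = v$hist_cvd)
covs <- covs[, vapply(covs, function(x) length(unique(x)) > 1, logical(1))]
sw <- stepwise_cox(v$time_years, v$event, covs)
write.table(sw$fit$table, "results/cox_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("stepwise Cox retained:", paste(sw$retained, collapse = ", "), "\n")
if ("pattern_pos" %in% sw$fit$table$term) {
  r <- sw$fit$table[sw$fit$table$term == "pattern_pos", ]
  cat(sprintf("adjusted HR for a positive pattern score: %.2f (%.2f-%.2f), P=%.4g\n",
              r$hr, r$lo, r$hi, r$p))
}

nm <- nested_logistic_models(v$label, v$study, v$fcvrs,
                             pattern_score = scores[valid], composite = comp[valid])
r21 <- idi_nri(nm$p1, nm$p2, v$label)
r31 <- idi_nri(nm$p1, nm$p3, v$label)
cat("model 2 vs 1 (add pattern):   "); print(r21)
cat("model 3 vs 1 (add composite): "); print(r31)

report <- list(
  pattern = list(threshold = thr$threshold,
                 sensitivity = d_pat$sensitivity, sensitivity_ci = d_pat$sensitivity_ci,
                 specificity = d_pat$specificity, specificity_ci = d_pat$specificity_ci,
                 plr = d_pat$plr, auc = roc_auc(scores[valid], v$label)$auc,
                 harrell_c = hc$c, harrell_ci = hc$ci),
  composite = list(threshold = cthr$threshold,
                   sensitivity = d_cmp$sensitivity, specificity = d_cmp$specificity,
                   plr = d_cmp$plr, auc = roc_auc(comp[valid], v$label)$auc),
  reclassification = list(
    model2_vs_1 = list(idi = r21$idi, idi_se = r21$idi_se, idi_p = r21$idi_p,
                       nri = r21$nri, nri_se = r21$nri_se, nri_p = r21$nri_p),
    model3_vs_1 = list(idi = r31$idi, idi_se = r31$idi_se, idi_p = r31$idi_p,
                       nri = r31$nri, nri_se = r31$nri_se, nri_p = r31$nri_p)))
jsonlite::write_json(report, "results/evaluation.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat("wrote results/evaluation.json\n")
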