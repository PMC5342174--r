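#!/usr/bin/env Rscript
# Stage 3: biomarker discovery on the discovery split.
#
# Splits the cohort 2/3 : 1/3 with age- and sex-matched controls, then on
# the discovery samples screens every non-housekeeping peptide: detection
# frequency >= 70% in at least one group, two-sided Wilcoxon rank-sum
# p-value, Benjamini-Hochberg adjustment (< 0.05), and the signed
# differential-excretion ratio. Writes results/panel.tsv and
# results/split.tsv.

library(acspredict)

dir <- "results/bundle"
b <- read_bundle(dir)
sp <- split_discovery_validation(b$cohort, ratio = 2 / 3,
                                 match_age_window = 5, seed = 1L)
write.table(data.frame(sample_id = c(sp$discovery, sp$validation),
                       split = rep(c("discovery", "validation"),
                                   c(length(sp$discovery), length(sp$validation)))),
            "results/split.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

rownames(b$cohort) <- b$cohort$sample_id
hk <- b$catalog$peptide_id[b$catalog$is_housekeeping]
m_disc <- b$matrix[sp$discovery, setdiff(colnames(b$matrix), hk)]
panel <- discover_panel(m_disc, b$cohort[sp$discovery, "label"])
write.table(panel$records, "results/panel.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

print(panel)
cat(sprintf("split: %d discovery / %d validation samples, %d unmatched cases\n",
            length(sp$discovery), length(sp$validation), length(sp$unmatched)))
truth <- b$catalog$peptide_id[b$catalog$is_true_biomarker]
cat(sprintf("planted-biomarker recall: %.2f; strongest DE: %+.2f\n",
            mean(truth %in% panel$records$peptide_id),
            panel$records$differential_excretion[
              which.max(abs(panel$records$differential_excretion))]))
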