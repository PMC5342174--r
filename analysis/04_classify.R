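#!/usr/bin/env Rscript
# Stage 4: pattern and composite scoring.
#
# Trains the RBF-kernel SVM pattern on the discovery split's log2
# intensities of the panel peptides (C = 1638.4, gamma = 0.000256), scores
# every sample by signed distance to the separating hyperplane, fits the
# composite weights (pattern score, CAD pattern score, age) by logistic
# regression on the discovery split, and writes results/scores.tsv.

library(acspredict)

b <- read_bundle("results/bundle")
sp <- read.delim("results/split.tsv")
panel <- read.delim("results/panel.tsv")
rownames(b$cohort) <- b$cohort$sample_id
disc <- sp$sample_id[sp$split == "discovery"]

feats <- feature_transform(b$matrix, panel$peptide_id)
model <- train_pattern(feats[disc, , drop = FALSE],
                       b$cohort[disc, "label"], seed = 1L)
print(model)

scores <- score_samples(model, feats)
cw <- fit_composite_weights(scores[disc], b$cohort[disc, "cad238"],
                            b$cohort[disc, "age"], b$cohort[disc, "label"])
cat(sprintf("composite weights (logistic, discovery): pattern %.3f, cad %.3f, age %.3f\n",
            cw$weights$w_pattern, cw$weights$w_cad, cw$weights$w_age))
comp <- composite_score(scores, b$cohort[names(scores), "cad238"],
                        b$cohort[names(scores), "age"], cw$weights)

write.table(data.frame(sample_id = names(scores),
                       pattern_score = unname(scores),
                       composite_score = unname(comp)),
            "results/scores.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("scored %d samples -> results/scores.tsv\n", length(scores)))
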