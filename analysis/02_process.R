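#!/usr/bin/env Rscript
# Stage 2: peak-list processing.
#
# Calibrates each sample's migration times against the catalogue by
# locally weighted regression, normalizes amplitudes to the housekeeping
# peptides (urine dilution correction), and clusters detections onto
# catalogue peptides (<50 ppm mass deviation, 2-5% time windows).
# Writes the sample x peptide amplitude matrix into results/bundle/.

library(acspredict)

dir <- "results/bundle"
catalog <- read.delim(file.path(dir, "catalog.tsv"))
long <- read.delim(file.path(dir, "profiles.tsv"))
profiles <- lapply(split(long, long$sample_id), function(d) {
  list(sample_id = d$sample_id[1],
       detections = d[, c("mass_da", "cemt_min", "amplitude")])
})

mat <- process_profiles(profiles, catalog)
write.table(data.frame(sample_id = rownames(mat), mat, check.names = FALSE),
            file.path(dir, "matrix.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("matrix: %d samples x %d peptides; %.1f%% of cells detected\n",
            nrow(mat), ncol(mat), 100 * mean(mat > 0)))
cat(sprintf("unmatched detections: %d of %d\n",
            sum(attr(mat, "unmatched")), nrow(long)))
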