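#!/usr/bin/env Rscript
# Stage 2 — subject-centered standardization and temporal smoothing.
#
# Builds the two analysis views from the simulated cohort: per-subject
# z-scores (unsmoothed; feeds network mapping) and the 3-day moving average
# of those z-scores (feeds correlation tracking and classification).

library(dailycyto)

cohort <- read_cohort("results/cohort.csv")
views <- build_analysis_views(cohort, window = 3)

write.csv(views$unsmoothed, "results/view_unsmoothed.csv", row.names = FALSE)
write.csv(views$smoothed, "results/view_smoothed.csv", row.names = FALSE)

degenerate <- unique(views$smoothed$subject_id[is.na(views$smoothed$fatigue_mean)])
cat(sprintf("Processed %d series per subject (3 fatigue variants + %d analytes).\n",
            3 + length(analyte_columns(cohort)), length(analyte_columns(cohort))))
cat(sprintf("Degenerate (constant-fatigue) subjects propagated as NA: %s\n",
            if (length(degenerate)) paste(degenerate, collapse = ", ") else "none"))
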