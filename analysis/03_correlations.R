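#!/usr/bin/env Rscript
# Stage 3 — leptin-fatigue tracking and demographic comparisons.
#
# Per-subject correlations of smoothed leptin with AM/PM/mean fatigue (the
# participant tracking table), the pooled within-group correlations over all
# subject-days, and the BMI / leptin group statistics.

library(dailycyto)

cohort <- read_cohort("results/cohort.csv")
profiles <- read.csv("results/profiles.csv")
views <- build_analysis_views(cohort, window = 3)

tracking <- per_subject_tracking(views$smoothed, "leptin")
write.csv(tracking, "results/tracking_leptin.csv", row.names = FALSE)

pooled <- rbind(pooled_group_correlation(views$smoothed, "patient"),
                pooled_group_correlation(views$smoothed, "control"))
demo <- covariate_stats(profiles, cohort)
jsonlite::write_json(list(pooled = pooled, demographics = demo),
                     "results/correlations.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

sig <- subset(tracking, group == "patient" & !is.na(p_mean) & p_mean < 0.05)
cat(sprintf("Patients with significant mean-fatigue leptin tracking: %d of %d (%s)\n",
            nrow(sig), sum(tracking$group == "patient"),
            paste(sig$subject_id, collapse = ", ")))
cat(sprintf("Pooled leptin-fatigue r: patients %.3f (n = %d), controls %.3f (n = %d)\n",
            pooled$r[1], pooled$n[1], pooled$r[2], pooled$n[2]))
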