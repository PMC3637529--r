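#!/usr/bin/env Rscript
# Stage 1 — simulate the default daily-monitoring cohort.
#
# 10 patients + 10 controls, 25 consecutive days, a 51-analyte serum panel and
# twice-daily VAS fatigue reports; 6 patients carry a planted leptin-fatigue
# coupling and 29 cytokines form a leptin-coupled nest. Writes the cohort,
# the subject profiles and the planted truth under results/.

library(dailycyto)

seed <- as.integer(Sys.getenv("DAILYCYTO_SEED", "20260929"))
dir.create("results", showWarnings = FALSE)

cfg <- cohort_config(seed = seed)
cohort <- generate_cohort(cfg)
profiles <- subject_profiles(cfg)

write_cohort(cohort, "results/cohort.csv")
write.csv(profiles, "results/profiles.csv", row.names = FALSE)
write.csv(planted_truth(cfg), "results/planted_truth.csv", row.names = FALSE)

cat(sprintf("Simulated %d subject-day records (%d subjects x %d days).\n",
            nrow(cohort), nrow(profiles), cfg$n_days))
cat(sprintf("Responders: %s\n",
            paste(profiles$subject_id[profiles$is_responder], collapse = ", ")))
cat(sprintf("Zero-fatigue controls: %s\n",
            paste(profiles$subject_id[profiles$zero_fatigue], collapse = ", ")))
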