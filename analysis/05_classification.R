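#!/usr/bin/env Rscript
# Stage 5 — extreme-day classification experiment.
#
# Labels each subject's 9 most and 9 least severe fatigue days, excludes
# ambiguous scores, trains the linear SVM (C = 1) on the patient cases with
# stratified 10-fold cross-validation (day-level, as in the original design,
# and subject-grouped for a leakage-free estimate), then transfers the frozen
# patient model to the control cases.

library(dailycyto)

cohort <- read_cohort("results/cohort.csv")
views <- build_analysis_views(cohort, window = 3)
seed <- as.integer(Sys.getenv("DAILYCYTO_SEED", "20260929"))

ds_p <- extreme_day_dataset(views$smoothed, "patient", k = 9)
ds_c <- extreme_day_dataset(views$smoothed, "control", k = 9)
cat(sprintf("Patient cases: %d (pre-exclusion %d); control cases: %d\n",
            nrow(ds_p$cases), ds_p$n_pre_exclusion, nrow(ds_c$cases)))

cv <- cross_validate(ds_p, folds = 10, seed = derive_seed(seed, "cv"))
cv_g <- cross_validate(ds_p, folds = 10, seed = derive_seed(seed, "cv"),
                       grouped = TRUE)
fit <- train_linear_classifier(ds_p, cost = 1)
transfer <- transfer_evaluate(fit, ds_c)

write.csv(cv$folds, "results/cv_folds.csv", row.names = FALSE)
jsonlite::write_json(
  list(cv_day_level = unclass(cv)[c("accuracy", "recall_low", "recall_high", "n")],
       cv_grouped = unclass(cv_g)[c("accuracy", "recall_low", "recall_high", "n")],
       transfer = unclass(transfer)[c("accuracy", "recall_low", "recall_high", "n")],
       exclusions = list(patient = ds_p$exclusion_log,
                         control = ds_c$exclusion_log)),
  "results/classification.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("Day-level CV accuracy:   %.1f%% (n = %d)\n", cv$accuracy, cv$n))
cat(sprintf("Subject-grouped CV:      %.1f%% (n = %d)\n", cv_g$accuracy, cv_g$n))
cat(sprintf("Patient->control transfer: %.1f%% (low recall %.1f%%, high recall %.1f%%)\n",
            transfer$accuracy, transfer$recall_low, transfer$recall_high))
cat("Note: day-level folds leak temporal neighbours; the grouped estimate is honest.\n")
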