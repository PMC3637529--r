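#' Run the full daily-monitoring analysis end-to-end
#'
#' Orchestrates simulate, preprocess, correlate, network and classify over one
#' configuration, writing every stage output plus a run manifest to `out_dir`.
#' All randomness derives from the configuration seed (fanned out per stage
#' with [derive_seed()]), so a manifest fully determines a re-run's outputs.
#'
#' Stage outputs written: the cohort, subject profiles and planted-truth CSVs;
#' the per-participant tracking table (`table2.csv`); pooled correlations and
#' demographic comparisons (JSON); per-group FDR-thresholded networks
#' (GraphML + TSV edge list + layout CSV); the classification experiment
#' (within-patient cross-validation and the patient-to-control transfer test,
#' JSON); and `manifest.json`.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if absent).
#' @param window Moving-average window (odd days).
#' @param fdr_q Target false-discovery rate for the network.
#' @param cost SVM cost parameter C.
#' @param folds Cross-validation folds.
#' @param k_extreme Extreme days per class per subject.
#' @param grouped_cv Assign whole subjects to CV folds.
#' @param permutation_p Use circular-shift permutation p-values for tracking
#'   and pooled correlations.
#' @return Invisibly, a list with every in-memory stage result and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir,
                         window = 3, fdr_q = 0.01, cost = 1, folds = 10,
                         k_extreme = 9, grouped_cv = FALSE,
                         permutation_p = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(out_dir, ...)
  written <- character(0)
  emit <- function(p) { written <<- c(written, p); p }

  # -- simulate ---------------------------------------------------------------
  cohort <- generate_cohort(config)
  profiles <- subject_profiles(config)
  truth <- planted_truth(config)
  write_cohort(cohort, emit(path("cohort.csv")))
  write.csv(profiles, emit(path("profiles.csv")), row.names = FALSE)
  write.csv(truth, emit(path("planted_truth.csv")), row.names = FALSE)
  message("simulate: ", nrow(cohort), " subject-day records, ",
          nrow(profiles), " subjects")

  # -- preprocess -------------------------------------------------------------
  views <- build_analysis_views(cohort, window = window)

  # -- correlate --------------------------------------------------------------
  tracking <- per_subject_tracking(views$smoothed, "leptin",
                                   permutation = permutation_p)
  write.csv(tracking, emit(path("table2.csv")), row.names = FALSE)
  pooled <- dplyr::bind_rows(lapply(c("patient", "control"), function(g)
    pooled_group_correlation(views$smoothed, g, "leptin", "mean",
                             permutation = permutation_p)))
  demo <- covariate_stats(profiles, cohort)
  jsonlite::write_json(list(pooled = pooled, demographics = demo),
                       emit(path("correlations.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("correlate: pooled patient r = ",
          signif(pooled$r[pooled$group == "patient"], 3),
          " over n = ", pooled$n[pooled$group == "patient"], " days")

  # -- network ----------------------------------------------------------------
  networks <- list()
  for (g in c("patient", "control")) {
    pm <- pairwise_matrix(views$unsmoothed, g)
    net <- build_network(pm, q = fdr_q)
    coords <- fr_layout(net, seed = derive_seed(config$seed, "layout"))
    write_network_graphml(net, emit(path(paste0("network_", g, ".graphml"))))
    write_edge_list(net, emit(path(paste0("network_", g, "_edges.tsv"))))
    write_layout_csv(coords, emit(path(paste0("network_", g, "_layout.csv"))))
    networks[[g]] <- net
    message("network (", g, "): ", nrow(net$edges), " edges at FDR q = ",
            fdr_q, "; leptin degree ", net$leptin_degree)
  }

  # -- classify ---------------------------------------------------------------
  ds_patient <- extreme_day_dataset(views$smoothed, "patient", k = k_extreme)
  ds_control <- extreme_day_dataset(views$smoothed, "control", k = k_extreme)
  cv <- cross_validate(ds_patient, folds = folds,
                       seed = derive_seed(config$seed, "cv"), cost = cost,
                       grouped = grouped_cv)
  model <- train_linear_classifier(ds_patient, cost = cost)
  transfer <- transfer_evaluate(model, ds_control)
  write.csv(cv$folds, emit(path("cv_folds.csv")), row.names = FALSE)
  write.csv(ds_patient$cases[, c("subject_id", "day", "score", "label")],
            emit(path("cases_patient.csv")), row.names = FALSE)
  jsonlite::write_json(
    list(cv = unclass(cv)[c("accuracy", "recall_low", "recall_high", "n")],
         transfer = unclass(transfer)[c("accuracy", "recall_low",
                                        "recall_high", "n")],
         exclusions = list(patient = ds_patient$exclusion_log,
                           control = ds_control$exclusion_log)),
    emit(path("classification.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("classify: CV accuracy ", round(cv$accuracy, 1), "% (n = ", cv$n,
          "); transfer accuracy ", round(transfer$accuracy, 1),
          "% (n = ", transfer$n, ")")

  # -- manifest ---------------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("dailycyto")),
    config = unclass(config),
    flags = list(window = window, fdr_q = fdr_q, cost = cost, folds = folds,
                 k_extreme = k_extreme, grouped_cv = grouped_cv,
                 permutation_p = permutation_p,
                 fatigue_variant = "mean", fdr_procedure = "benjamini-hochberg",
                 cv_mode = if (grouped_cv) "subject-grouped" else
                   "day-level stratified"),
    derived_seeds = list(
      profiles = derive_seed(config$seed, "profiles"),
      days = derive_seed(config$seed, "days"),
      layout = derive_seed(config$seed, "layout"),
      cv = derive_seed(config$seed, "cv")),
    file_digests = as.list(tools::md5sum(sort(written)))
  )
  jsonlite::write_json(manifest, path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, profiles = profiles, truth = truth,
                 views = views, tracking = tracking, pooled = pooled,
                 demographics = demo, networks = networks,
                 dataset_patient = ds_patient, dataset_control = ds_control,
                 cv = cv, model = model, transfer = transfer,
                 manifest = manifest))
}
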