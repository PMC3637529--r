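#' Pearson correlation with degenerate-input handling
#'
#' Product-moment correlation between two daily series after pairwise removal
#' of missing days, with a two-sided p-value from the t-distribution on
#' `n - 2` degrees of freedom. Degenerate inputs (fewer than 3 complete pairs,
#' or zero variance in either series) yield an all-`NA` result rather than an
#' error, mirroring how subjects with constant fatigue appear as `NA` rows in
#' the tracking table.
#'
#' The t-based p-value ignores autocorrelation, which matches how smoothed
#' daily series are conventionally tested but is anti-conservative on them;
#' `permutation = TRUE` replaces it with an exact circular-shift permutation
#' p-value (all `n - 1` nonzero rotations of `y`), which preserves each
#' series' autocorrelation under the null.
#'
#' @param x,y Numeric series of equal length.
#' @param permutation Use the circular-shift permutation p-value instead of
#'   the t-based one.
#' @return One-row tibble: `r`, `p`, `n` (complete pairs), `sig_05`,
#'   `sig_01`.
#' @examples
#' pearson_cor(1:4, c(2, 1, 4, 3))
#' @export
pearson_cor <- function(x, y, permutation = FALSE) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  na_result <- tibble::tibble(r = NA_real_, p = NA_real_, n = n,
                              sig_05 = NA, sig_01 = NA)
  if (n < 3) return(na_result)
  xs <- x[ok]; ys <- y[ok]
  if (sd(xs) == 0 || sd(ys) == 0) return(na_result)
  ct <- stats::cor.test(xs, ys, method = "pearson")
  r <- unname(ct$estimate)
  p <- if (permutation) circular_shift_p(xs, ys) else ct$p.value
  tibble::tibble(r = r, p = p, n = n, sig_05 = p < 0.05, sig_01 = p < 0.01)
}

# Exact permutation p-value over all nonzero circular shifts of y.
circular_shift_p <- function(x, y) {
  n <- length(y)
  r_obs <- abs(cor(x, y))
  shifts <- vapply(seq_len(n - 1), function(s) {
    abs(cor(x, y[c((s + 1):n, 1:s)]))
  }, numeric(1))
  (1 + sum(shifts >= r_obs - 1e-12)) / n
}

star_flag <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Per-subject tracking of one analyte against fatigue
#'
#' For each subject, correlates the analyte's processed series with the three
#' fatigue variants (AM, PM, mean), producing the per-participant tracking
#' table with significance stars (`*` p < 0.05, `**` p < 0.01). Subjects with
#' degenerate (constant) fatigue yield `NA` rows. Intended to be run on the
#' smoothed view; any analysis view is accepted, which also supports null
#' calibration on unsmoothed data.
#'
#' @param view An `analysis_view` from [build_analysis_views()].
#' @param analyte Analyte name present in the view.
#' @param permutation Passed to [pearson_cor()].
#' @return Tibble with one row per subject: `subject_id`, `group`, then for
#'   each variant `v` in am/pm/mean the columns `r_<v>`, `p_<v>`, `star_<v>`,
#'   plus `n` complete pairs for the mean variant.
#' @export
per_subject_tracking <- function(view, analyte = "leptin",
                                 permutation = FALSE) {
  stopifnot(inherits(view, "analysis_view"))
  if (!analyte %in% attr(view, "analyte_names"))
    stop("unknown analyte: ", analyte)
  subs <- split(view, factor(view$subject_id, levels = unique(view$subject_id)))
  rows <- lapply(subs, function(sv) {
    out <- tibble::tibble(subject_id = sv$subject_id[1], group = sv$group[1])
    for (v in c("am", "pm", "mean")) {
      res <- pearson_cor(sv[[analyte]], sv[[paste0("fatigue_", v)]],
                         permutation = permutation)
      out[[paste0("r_", v)]] <- res$r
      out[[paste0("p_", v)]] <- res$p
      out[[paste0("star_", v)]] <- star_flag(res$p)
      if (v == "mean") out$n <- res$n
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Pooled within-group correlation across subject-days
#'
#' Concatenates the subject-centered series of every subject in a group and
#' correlates the analyte against a fatigue variant over all pooled
#' subject-days. Because each series is already centered per subject, the
#' pooled coefficient reflects within-person fluctuation only. Degenerate
#' subjects contribute `NA` fatigue values that are dropped pairwise; `n` in
#' the result counts complete pairs, `n_days` all pooled subject-days.
#'
#' @param view An `analysis_view`.
#' @param group `"patient"` or `"control"`.
#' @param analyte Analyte name.
#' @param fatigue_variant One of `"am"`, `"pm"`, `"mean"`.
#' @param permutation Passed to [pearson_cor()].
#' @return One-row tibble: `group`, `r`, `p`, `n`, `n_days`, `sig_05`,
#'   `sig_01`.
#' @export
pooled_group_correlation <- function(view, group, analyte = "leptin",
                                     fatigue_variant = "mean",
                                     permutation = FALSE) {
  stopifnot(inherits(view, "analysis_view"))
  fatigue_variant <- match.arg(fatigue_variant, c("am", "pm", "mean"))
  sel <- view[view$group == group, ]
  if (nrow(sel) == 0) stop("no subjects in group: ", group)
  if (!analyte %in% attr(view, "analyte_names"))
    stop("unknown analyte: ", analyte)
  res <- pearson_cor(sel[[analyte]], sel[[paste0("fatigue_", fatigue_variant)]],
                     permutation = permutation)
  tibble::tibble(group = group, res, n_days = nrow(sel))
}

#' Demographic and baseline group comparisons
#'
#' Reproduces the cohort-description statistics: within each group, the
#' Pearson correlation of BMI with subject-mean raw leptin; and two-sample
#' pooled-variance (classic Student) t-tests comparing patients with controls
#' on BMI and on subject-mean leptin. The t statistics are signed
#' patients-minus-controls. Groups with fewer than two subjects give `NA`
#' statistics.
#'
#' @param profiles Subject profile table (needs `subject_id`, `group`, `bmi`).
#' @param cohort Cohort tibble with a `leptin` column.
#' @return List with `bmi_leptin` (per-group r, p, n) and `group_tests`
#'   (per-variable t, df, p and group means).
#' @export
covariate_stats <- function(profiles, cohort) {
  subj_lep <- cohort |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(mean_leptin = mean(.data$leptin), .groups = "drop")
  tab <- dplyr::inner_join(profiles, subj_lep, by = "subject_id")

  bmi_leptin <- tab |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(d, key) {
      pearson_cor(d$bmi, d$mean_leptin)[, c("r", "p", "n")]
    }) |>
    dplyr::ungroup()

  pooled_t <- function(variable) {
    x <- tab[[variable]][tab$group == "patient"]
    y <- tab[[variable]][tab$group == "control"]
    if (length(x) < 2 || length(y) < 2)
      return(tibble::tibble(variable = variable, t = NA_real_, df = NA_real_,
                            p = NA_real_, mean_patient = NA_real_,
                            mean_control = NA_real_))
    tt <- stats::t.test(x, y, var.equal = TRUE)
    tibble::tibble(variable = variable, t = unname(tt$statistic),
                   df = unname(tt$parameter), p = tt$p.value,
                   mean_patient = mean(x), mean_control = mean(y))
  }
  list(bmi_leptin = bmi_leptin,
       group_tests = dplyr::bind_rows(pooled_t("bmi"), pooled_t("mean_leptin")))
}
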