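#' Label a subject's most and least severe fatigue days
#'
#' Ranks one subject's daily fatigue scores by a stable sort on
#' (score, day index) and labels the top `k` days `"high"` and the bottom `k`
#' days `"low"`; middle days are dropped. Ties that straddle the k-th rank are
#' resolved deterministically by the day index, so repeated runs select the
#' same days.
#'
#' @param scores Numeric daily fatigue scores for one subject (the ranking
#'   variable; the pipeline uses the smoothed mean-fatigue series).
#' @param k Days per class.
#' @return Tibble with `day`, `score`, `label` (2k rows), or, for a constant
#'   or unusable series, a zero-row tibble with attribute
#'   `dropped_reason`.
#' @examples
#' label_extreme_days(c(5, 1, 9, 7, 3, 8, 2, 6, 4, 10), k = 3)
#' @export
label_extreme_days <- function(scores, k = 9) {
  stopifnot(is.numeric(scores), k >= 1)
  days <- seq_along(scores)
  empty <- tibble::tibble(day = integer(0), score = numeric(0),
                          label = character(0))
  usable <- !is.na(scores)
  if (sum(usable) < 2 * k) {
    attr(empty, "dropped_reason") <- "fewer than 2k usable fatigue scores"
    return(empty)
  }
  if (sd(scores[usable]) == 0) {
    attr(empty, "dropped_reason") <- "constant fatigue: all days ambiguous"
    return(empty)
  }
  d <- days[usable]
  s <- scores[usable]
  ord <- order(s, d)                # stable: ties broken by day index
  low <- ord[seq_len(k)]
  high <- ord[seq(length(ord) - k + 1, length(ord))]
  out <- tibble::tibble(
    day = c(d[low], d[high]),
    score = c(s[low], s[high]),
    label = rep(c("low", "high"), each = k)
  )
  out[order(out$day), ]
}

#' Remove days with scores present in both extreme sets
#'
#' Applies the ambiguity rule to a labeled-day table: within each subject, any
#' fatigue score value that occurs in both the high and the low set makes
#' every day carrying that value ambiguous, and all such days are removed from
#' both sets. Subjects left with no cases are removed entirely. Every removal
#' is recorded in the exclusion log.
#'
#' @param labeled Tibble with `subject_id`, `day`, `score`, `label` (the
#'   per-subject output of [label_extreme_days()], row-bound).
#' @return List: `cases` (retained labeled days) and `log` (tibble
#'   `subject_id`, `day`, `reason`).
#' @export
exclude_ambiguous <- function(labeled) {
  stopifnot(all(c("subject_id", "day", "score", "label") %in% names(labeled)))
  log <- tibble::tibble(subject_id = character(0), day = integer(0),
                        reason = character(0))
  keep <- rep(TRUE, nrow(labeled))
  for (sid in unique(labeled$subject_id)) {
    idx <- which(labeled$subject_id == sid)
    sub <- labeled[idx, ]
    shared <- intersect(sub$score[sub$label == "high"],
                        sub$score[sub$label == "low"])
    bad <- sub$score %in% shared
    if (any(bad)) {
      keep[idx[bad]] <- FALSE
      log <- dplyr::bind_rows(log, tibble::tibble(
        subject_id = sid, day = as.integer(sub$day[bad]),
        reason = "score value present in both high and low sets"))
    }
    if (all(bad)) {
      log <- dplyr::bind_rows(log, tibble::tibble(
        subject_id = sid, day = NA_integer_,
        reason = "no unambiguous days; subject removed"))
    }
  }
  list(cases = labeled[keep, ], log = log)
}

#' Assemble the extreme-day classification dataset
#'
#' Builds the labeled case table for one group from the smoothed analysis
#' view: per subject, days are ranked on the smoothed mean-fatigue series,
#' the `k` most and `k` least severe days are labeled, ambiguous scores are
#' excluded, and each retained day carries its 51-analyte smoothed z feature
#' vector. Subjects with constant fatigue (e.g. all-zero reporters)
#' contribute no cases and are logged.
#'
#' @param view The smoothed `analysis_view`.
#' @param group `"patient"` or `"control"`.
#' @param k Days per class per subject.
#' @return Object of class `extreme_day_dataset`: list with `cases` (tibble:
#'   `subject_id`, `day`, `score`, `label`, one column per analyte),
#'   `exclusion_log`, `feature_names`, `k`, `group`, and `n_pre_exclusion`
#'   (labeled cases before the ambiguity rule).
#' @export
extreme_day_dataset <- function(view, group, k = 9) {
  stopifnot(inherits(view, "analysis_view"))
  analytes <- attr(view, "analyte_names")
  sel <- view[view$group == group, ]
  if (nrow(sel) == 0) stop("no subjects in group: ", group)

  labeled <- list()
  log <- tibble::tibble(subject_id = character(0), day = integer(0),
                        reason = character(0))
  for (sid in unique(sel$subject_id)) {
    sub <- sel[sel$subject_id == sid, ]
    lab <- label_extreme_days(sub$fatigue_mean, k = k)
    if (nrow(lab) == 0) {
      log <- dplyr::bind_rows(log, tibble::tibble(
        subject_id = sid, day = NA_integer_,
        reason = attr(lab, "dropped_reason")))
      next
    }
    lab$subject_id <- sid
    labeled[[sid]] <- lab[, c("subject_id", "day", "score", "label")]
  }
  labeled <- dplyr::bind_rows(labeled)
  n_pre <- nrow(labeled)
  excl <- if (n_pre > 0) exclude_ambiguous(labeled)
          else list(cases = labeled, log = log[0, ])
  cases <- dplyr::inner_join(
    excl$cases, sel[, c("subject_id", "day", analytes)],
    by = c("subject_id", "day"))
  structure(list(cases = cases,
                 exclusion_log = dplyr::bind_rows(log, excl$log),
                 feature_names = analytes, k = k, group = group,
                 n_pre_exclusion = n_pre),
            class = "extreme_day_dataset")
}

#' @export
print.extreme_day_dataset <- function(x, ...) {
  cat("<extreme_day_dataset> group: ", x$group, "; ",
      nrow(x$cases), " cases (", sum(x$cases$label == "low"), " low / ",
      sum(x$cases$label == "high"), " high; k = ", x$k, "); ",
      nrow(x$exclusion_log), " exclusion-log entries\n", sep = "")
  invisible(x)
}

case_matrix <- function(dataset) {
  x <- as.matrix(dataset$cases[, dataset$feature_names])
  rownames(x) <- paste(dataset$cases$subject_id, dataset$cases$day, sep = ":")
  x
}

#' Train the linear support vector machine
#'
#' Fits a linear soft-margin SVM (L2-penalized hinge loss with an unpenalized
#' bias) at cost `C` on the extreme-day cases, consuming the smoothed
#' subject-z-scored features as provided (no further scaling). The fit is
#' deterministic for a given dataset.
#'
#' @param dataset An `extreme_day_dataset` (or a list with `cases` and
#'   `feature_names` in the same shape).
#' @param cost Soft-margin cost parameter C.
#' @return Object of class `linear_svm`: `weights` (named vector), `bias`,
#'   `levels`, `feature_names`, `cost`, and the underlying fit.
#' @export
train_linear_classifier <- function(dataset, cost = 1) {
  y <- factor(dataset$cases$label, levels = c("low", "high"))
  if (nlevels(droplevels(y)) < 2)
    stop("both classes must be present to train")
  x <- case_matrix(dataset)
  fit <- e1071::svm(x = x, y = y, kernel = "linear", cost = cost,
                    scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  names(w) <- colnames(x)
  structure(list(weights = w, bias = -fit$rho, levels = levels(y),
                 feature_names = dataset$feature_names, cost = cost,
                 fit = fit),
            class = "linear_svm")
}

#' @export
predict.linear_svm <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.null(newdata$cases))
    newdata <- case_matrix(newdata)
  if (!identical(colnames(newdata), object$feature_names))
    stop("feature mismatch: new data must carry the training features, ",
         "in order")
  predict(object$fit, newdata)
}

#' Summarize predictions against true labels
#'
#' @param truth,pred Character or factor labels (`"low"` / `"high"`).
#' @param folds Optional fold-assignment tibble to attach.
#' @param seed Optional seed to record.
#' @return Object of class `evaluation_report`: `accuracy`, `recall_low`,
#'   `recall_high` (all percentages), `n`, `n_low`, `n_high`, plus any fold
#'   assignments and seed.
#' @export
classification_report <- function(truth, pred, folds = NULL, seed = NULL) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  structure(list(
    accuracy = 100 * mean(pred == truth),
    recall_low = 100 * mean(pred[truth == "low"] == "low"),
    recall_high = 100 * mean(pred[truth == "high"] == "high"),
    n = length(truth),
    n_low = sum(truth == "low"),
    n_high = sum(truth == "high"),
    folds = folds,
    seed = seed
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> accuracy %.1f%% (n = %d); recall: low %.1f%%, high %.1f%%\n",
    x$accuracy, x$n, x$recall_low, x$recall_high))
  invisible(x)
}

#' Stratified k-fold cross-validation of the linear classifier
#'
#' Assigns cases to folds stratified by class under a fixed seed (or, in
#' grouped mode, assigns whole subjects to folds so no subject spans a
#' train/test boundary), trains on each training split and pools the held-out
#' predictions into one report. Grouped mode removes the within-subject
#' leakage that day-level assignment permits when adjacent smoothed days fall
#' in different folds.
#'
#' @param dataset An `extreme_day_dataset`.
#' @param folds Number of folds.
#' @param seed Integer seed for fold assignment.
#' @param cost Passed to [train_linear_classifier()].
#' @param grouped Assign whole subjects to folds instead of individual cases.
#' @return An `evaluation_report` with per-case fold assignments attached.
#' @export
cross_validate <- function(dataset, folds = 10, seed = 1L, cost = 1,
                           grouped = FALSE) {
  cases <- dataset$cases
  n <- nrow(cases)
  if (folds > n) stop("more folds than cases")
  set.seed(as.integer(seed))
  fold_id <- integer(n)
  if (grouped) {
    subs <- sample(unique(cases$subject_id))
    sub_fold <- setNames(rep(seq_len(folds), length.out = length(subs)), subs)
    fold_id <- unname(sub_fold[cases$subject_id])
  } else {
    for (cl in c("low", "high")) {
      idx <- which(cases$label == cl)
      fold_id[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
  }
  pred <- character(n)
  for (f in sort(unique(fold_id))) {
    test <- fold_id == f
    train <- list(cases = cases[!test, ],
                  feature_names = dataset$feature_names)
    fit <- train_linear_classifier(train, cost = cost)
    x_test <- as.matrix(cases[test, dataset$feature_names])
    pred[test] <- as.character(predict(fit$fit, x_test))
  }
  classification_report(
    cases$label, pred,
    folds = tibble::tibble(subject_id = cases$subject_id, day = cases$day,
                           label = cases$label, fold = fold_id),
    seed = seed)
}

#' Evaluate a frozen model on another cohort's dataset
#'
#' Applies an already-trained linear classifier, unchanged, to the extreme-day
#' dataset of a different cohort (the transfer test: does the model trained on
#' patients predict fatigue extremes in controls?). Feature names must align
#' exactly.
#'
#' @param fit A `linear_svm`.
#' @param dataset An `extreme_day_dataset` from the other cohort.
#' @return An `evaluation_report`.
#' @export
transfer_evaluate <- function(fit, dataset) {
  if (!identical(fit$feature_names, dataset$feature_names))
    stop("feature mismatch between model and dataset")
  pred <- predict(fit, case_matrix(dataset))
  classification_report(dataset$cases$label, pred)
}
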