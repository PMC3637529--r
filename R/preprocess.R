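#' Analyte columns of a cohort table
#'
#' Every column that is not part of the study design (`subject_id`, `group`,
#' `day`, the two VAS reports, and the simulator's `.latent_fatigue`
#' diagnostic) is treated as an analyte.
#'
#' @param cohort A cohort tibble.
#' @return Character vector of analyte column names.
#' @export
analyte_columns <- function(cohort) {
  setdiff(names(cohort),
          c("subject_id", "group", "day", "am_fatigue", "pm_fatigue",
            ".latent_fatigue"))
}

#' Subject-centered z-score standardization
#'
#' Centers and scales one subject's daily series to mean 0 and sample standard
#' deviation 1 (n - 1 denominator), so pooled analyses reflect within-person
#' fluctuation rather than baseline differences between subjects. A
#' zero-variance (or all-missing) series is degenerate: the result is all `NA`
#' and carries attribute `degenerate = TRUE`, which propagates downstream as
#' missing values rather than an error.
#'
#' @param series Numeric vector of daily values for one subject.
#' @return Standardized numeric vector of the same length, with attribute
#'   `degenerate`.
#' @examples
#' subject_center_zscore(c(2, 4, 6))
#' @export
subject_center_zscore <- function(series) {
  stopifnot(is.numeric(series))
  ok <- !is.na(series)
  if (sum(ok) < 3) {
    out <- rep(NA_real_, length(series))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  s <- sd(series[ok])
  if (!is.finite(s) || s == 0) {
    out <- rep(NA_real_, length(series))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (series - mean(series[ok])) / s
  attr(out, "degenerate") <- FALSE
  out
}

#' Centered moving average with shrinking edges
#'
#' Temporal smoothing by a centered `window`-day moving average. At the
#' boundaries the window shrinks so that output length equals input length:
#' for a 3-day window the first and last elements average two values. Missing
#' values propagate (no `na.rm`), so degenerate series stay all-`NA`.
#'
#' @param series Numeric vector.
#' @param window Odd window length, at least 1 and at most `length(series)`.
#' @return Numeric vector, same length as `series`.
#' @examples
#' moving_average(c(1, 2, 3, 4, 5), 3)
#' @export
moving_average <- function(series, window = 3) {
  stopifnot(is.numeric(series))
  n <- length(series)
  if (window %% 2 == 0) stop("window must be odd")
  if (window < 1 || window > n) stop("window must be in [1, length(series)]")
  half <- (window - 1) / 2
  # Cumulative-sum sliding mean; NA anywhere in a window yields NA.
  cs <- c(0, cumsum(series))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Aggregate morning and evening fatigue reports
#'
#' Builds the three fatigue variants used throughout the analysis from the raw
#' VAS reports: AM, PM, and their daily mean. When exactly one report exists
#' on a day, the mean variant equals the available report; when both are
#' missing it is `NA`.
#'
#' @param am,pm Numeric VAS series of equal length.
#' @return A tibble with columns `am`, `pm`, `mean`.
#' @examples
#' aggregate_fatigue(c(10, 20), c(30, 40))
#' @export
aggregate_fatigue <- function(am, pm) {
  stopifnot(length(am) == length(pm))
  m <- rowMeans(cbind(am, pm), na.rm = TRUE)
  m[is.na(am) & is.na(pm)] <- NA_real_
  tibble::tibble(am = am, pm = pm, mean = m)
}

process_subject <- function(sub, analytes, window, smooth) {
  fat <- aggregate_fatigue(sub$am_fatigue, sub$pm_fatigue)
  vars <- c(fatigue_am = "am", fatigue_pm = "pm", fatigue_mean = "mean")
  out <- sub[, c("subject_id", "group", "day")]
  for (v in names(vars)) {
    z <- subject_center_zscore(fat[[vars[[v]]]])
    out[[v]] <- if (smooth && !attr(z, "degenerate"))
      moving_average(as.numeric(z), window) else as.numeric(z)
  }
  for (a in analytes) {
    z <- subject_center_zscore(sub[[a]])
    out[[a]] <- if (smooth && !attr(z, "degenerate"))
      moving_average(as.numeric(z), window) else as.numeric(z)
  }
  out
}

#' Build the smoothed and unsmoothed analysis views
#'
#' Applies the preprocessing pipeline per subject and variable, in the fixed
#' order standardize-then-smooth: every analyte and every fatigue variant is
#' subject-centered to z-scores; the smoothed view additionally applies the
#' centered moving average. Smoothed series are deliberately not
#' re-standardized. The two views serve different consumers: correlation
#' tracking and classification use the smoothed view; network mapping is
#' restricted to the unsmoothed view (enforced by [pairwise_matrix()]).
#'
#' @param cohort A cohort tibble (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param window Moving-average window (odd), default 3 days.
#' @return A list with elements `smoothed` and `unsmoothed`; each is a tibble
#'   of class `analysis_view` with columns `subject_id`, `group`, `day`,
#'   `fatigue_am`, `fatigue_pm`, `fatigue_mean`, and one column per analyte,
#'   all on the per-subject z scale. Attributes: `smoothed` (logical),
#'   `analyte_names`, `window`.
#' @export
build_analysis_views <- function(cohort, window = 3) {
  analytes <- analyte_columns(cohort)
  subs <- split(cohort, factor(cohort$subject_id,
                               levels = unique(cohort$subject_id)))
  make_view <- function(smooth) {
    view <- dplyr::bind_rows(
      lapply(subs, process_subject, analytes = analytes,
             window = window, smooth = smooth))
    attr(view, "smoothed") <- smooth
    attr(view, "analyte_names") <- analytes
    attr(view, "window") <- if (smooth) window else NA_integer_
    class(view) <- c("analysis_view", class(view))
    view
  }
  list(smoothed = make_view(TRUE), unsmoothed = make_view(FALSE))
}

#' @export
print.analysis_view <- function(x, ...) {
  cat("<analysis_view> ",
      if (isTRUE(attr(x, "smoothed")))
        paste0("z-scored + ", attr(x, "window"), "-day moving average")
      else "z-scored (unsmoothed)",
      "; ", length(unique(x$subject_id)), " subjects x ",
      nrow(x) / max(1, length(unique(x$subject_id))), " days, ",
      length(attr(x, "analyte_names")), " analytes\n", sep = "")
  NextMethod()
}

is_smoothed_view <- function(view) {
  isTRUE(attr(view, "smoothed"))
}
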