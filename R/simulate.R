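#' @importFrom stats rnorm runif rbinom sd cor quantile median pt p.adjust
#'   cor.test t.test setNames
#' @importFrom utils write.csv read.csv write.table
#' @importFrom graphics plot
#' @importFrom rlang .data
NULL

# Subject-level model draws shared by generate_cohort() and planted_truth().
# Seeded independently of the day-level noise so the truth table can be
# reproduced without simulating any trajectories.
draw_subject_model <- function(config) {
  validate_config(config)
  set.seed(derive_seed(config$seed, "profiles"))

  n_p <- config$n_patients
  n_c <- config$n_controls
  n_s <- n_p + n_c
  ids <- c(sprintf("P%02d", seq_len(n_p)), sprintf("C%02d", seq_len(n_c)))
  group <- rep(c("patient", "control"), c(n_p, n_c))

  # Demographics loosely matched between groups, as in a matched-control design.
  age <- round(pmin(pmax(rnorm(n_s, 53, 8), 29), 62))
  bmi <- round(pmin(pmax(rnorm(n_s, 26, 5.5), 18), 42), 1)

  responder_idx <- if (config$n_responders > 0) {
    sample(seq_len(n_p), config$n_responders)
  } else integer(0)
  is_responder <- seq_len(n_s) %in% responder_idx
  planted_r <- numeric(n_s)
  planted_r[responder_idx] <-
    runif(config$n_responders, config$coupling_range[1], config$coupling_range[2])

  zero_idx <- if (config$n_zero_fatigue_controls > 0) {
    n_p + sample(seq_len(n_c), config$n_zero_fatigue_controls)
  } else integer(0)
  zero_fatigue <- seq_len(n_s) %in% zero_idx

  # Analyte grand means on the log-MFI scale, then per-subject baselines.
  analyte_means <- runif(config$n_analytes, log(100), log(5000))
  names(analyte_means) <- config$analyte_names
  baselines <- matrix(
    rnorm(n_s * config$n_analytes, 0, config$between_subject_sd),
    nrow = n_s, dimnames = list(ids, config$analyte_names)
  )
  baselines <- sweep(baselines, 2, analyte_means, "+")
  baselines[, "leptin"] <- baselines[, "leptin"] +
    config$bmi_leptin_slope * (bmi - 26)

  nest_analytes <- setdiff(config$analyte_names, "leptin")[
    seq_len(config$nest_size)]
  nest_weights <- if (config$nest_size > 0) {
    runif(config$nest_size, config$nest_weight_range[1],
          config$nest_weight_range[2])
  } else numeric(0)
  names(nest_weights) <- nest_analytes

  profiles <- tibble::tibble(
    subject_id = ids, group = group, age = age, bmi = bmi,
    is_responder = is_responder, planted_r = planted_r,
    zero_fatigue = zero_fatigue
  )
  list(profiles = profiles, baselines = baselines,
       analyte_means = analyte_means, nest_weights = nest_weights)
}

#' Generate a synthetic daily-monitoring cohort
#'
#' Simulates a cohort under the generative model the downstream analysis
#' assumes. Per subject, a latent fatigue process follows a stationary lag-1
#' autoregression around the group baseline; morning and evening VAS reports
#' are the latent value plus/minus a time-of-day offset plus report noise,
#' clipped to `[0, 100]` and rounded to the integer resolution of a VAS
#' slider. Log-leptin is a BMI-dependent baseline plus a coupling term
#' `b * z(t)` in the standardized latent fatigue plus daily noise, with `b`
#' solved in closed form so the model-implied correlation of log-leptin with
#' latent fatigue equals the subject's `planted_r`:
#' `b = r * sigma_eps / sqrt(1 - r^2)` for unit-variance `z(t)`. Each "nest"
#' cytokine loads on the standardized leptin latent signal with its own
#' weight; remaining cytokines are independent log-normal noise. All analytes
#' are exponentiated to a positive, right-skewed median-fluorescence-like
#' scale.
#'
#' Deterministic for a fixed configuration (including its seed).
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per subject x day: `subject_id`, `group`,
#'   `day`, `am_fatigue`, `pm_fatigue`, one column per analyte, and
#'   `.latent_fatigue` (the simulation's latent ground truth, kept for
#'   diagnostics and ignored by the analysis). Attributes: `analyte_names`,
#'   `profiles` (the subject table, see [planted_truth()]), `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 7))
#' dim(cohort)
#' @export
generate_cohort <- function(config) {
  model <- draw_subject_model(config)
  profiles <- model$profiles
  set.seed(derive_seed(config$seed, "days"))

  n_days <- config$n_days
  phi <- config$ar_coefficient
  sigma_f <- config$fatigue_sd
  sigma_eps <- sqrt(config$leptin_noise_sd^2 + config$diurnal_sd^2)
  analytes <- config$analyte_names
  nest_w <- model$nest_weights

  rows <- vector("list", nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    p <- profiles[i, ]
    mu_g <- if (p$group == "patient") config$fatigue_baseline_patient
            else config$fatigue_baseline_control

    # Stationary AR(1) latent fatigue.
    f <- numeric(n_days)
    f[1] <- mu_g + rnorm(1, 0, sigma_f)
    innov_sd <- sigma_f * sqrt(1 - phi^2)
    for (t in 2:n_days) f[t] <- mu_g + phi * (f[t - 1] - mu_g) +
        rnorm(1, 0, innov_sd)
    z_f <- (f - mu_g) / sigma_f

    vas_noise <- matrix(rnorm(2 * n_days, 0, config$vas_noise_sd), ncol = 2)
    am <- round(pmin(pmax(f - config$ampm_offset / 2 + vas_noise[, 1], 0), 100))
    pm <- round(pmin(pmax(f + config$ampm_offset / 2 + vas_noise[, 2], 0), 100))
    if (p$zero_fatigue) am <- pm <- rep(0, n_days)

    b <- p$planted_r * sigma_eps / sqrt(1 - p$planted_r^2)
    lep_eps <- rnorm(n_days, 0, sigma_eps)
    lep_centered <- b * z_f + lep_eps
    log_lep <- model$baselines[i, "leptin"] + lep_centered
    s_lep <- sqrt(b^2 + sigma_eps^2)
    lambda <- if (s_lep > 0) lep_centered / s_lep else rep(0, n_days)

    vals <- matrix(NA_real_, nrow = n_days, ncol = length(analytes),
                   dimnames = list(NULL, analytes))
    vals[, "leptin"] <- log_lep
    for (a in setdiff(analytes, "leptin")) {
      load <- if (a %in% names(nest_w)) nest_w[[a]] * lambda else 0
      vals[, a] <- model$baselines[i, a] + load +
        rnorm(n_days, 0, config$analyte_noise_sd)
    }

    rows[[i]] <- tibble::tibble(
      subject_id = p$subject_id, group = p$group, day = seq_len(n_days),
      am_fatigue = am, pm_fatigue = pm
    ) |>
      dplyr::bind_cols(tibble::as_tibble(exp(vals))) |>
      dplyr::mutate(.latent_fatigue = f)
  }

  cohort <- dplyr::bind_rows(rows)
  attr(cohort, "analyte_names") <- analytes
  attr(cohort, "profiles") <- profiles
  attr(cohort, "config") <- config
  cohort
}

#' Ground-truth coupling table for a configuration
#'
#' Reproduces the subject-level draws of [generate_cohort()] for the same
#' configuration and seed without simulating trajectories: which patients are
#' responders and each subject's planted log-leptin-fatigue correlation
#' (0 for non-responders and all controls).
#'
#' @param config A [cohort_config()].
#' @return Tibble with `subject_id`, `group`, `is_responder`, `planted_r`.
#' @export
planted_truth <- function(config) {
  draw_subject_model(config)$profiles[
    , c("subject_id", "group", "is_responder", "planted_r")]
}

#' Subject profile table for a configuration
#'
#' Demographics and simulation flags for every subject: age, BMI, responder
#' status, planted coupling, and the zero-fatigue flag.
#'
#' @param config A [cohort_config()].
#' @return Tibble with one row per subject.
#' @export
subject_profiles <- function(config) {
  draw_subject_model(config)$profiles
}

#' Write or read a cohort as CSV
#'
#' The on-disk layout is the long format of the cohort table: one row per
#' subject x day, analyte columns named. `read_cohort()` restores the
#' `analyte_names` attribute by treating every column other than the design
#' columns as an analyte.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   a cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- tibble::as_tibble(read.csv(path, check.names = FALSE))
  attr(cohort, "analyte_names") <- analyte_columns(cohort)
  cohort
}
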