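#' Default 51-plex analyte panel names
#'
#' Returns the analyte labels used by the synthetic cohort generator: leptin
#' first, followed by 50 cytokines, chemokines and growth factors typical of a
#' bead-based human 51-plex serum panel.
#'
#' @return Character vector of length 51; the first element is `"leptin"`.
#' @export
default_analyte_names <- function() {
  c(
    "leptin",
    "GMCSF", "MCSF", "TGFa", "IFNa", "IFNb", "ICAM1", "MCP3", "IL6", "IL10",
    "IL12P40", "TNFb", "TRAIL", "VEGF",
    "IL1a", "IL1b", "IL1RA", "IL2", "IL4", "IL5", "IL7", "IL8", "IL12P70",
    "IL13", "IL15", "IL17A", "IL17F", "IL21", "IL22", "IL23",
    "IFNg", "TNFa", "GCSF", "EGF", "FGFb", "HGF", "NGF", "PDGFbb", "SCF",
    "CD40L", "CTACK", "ENA78", "Eotaxin", "GRO-a", "IP10", "MCP1", "MIG",
    "MIP1a", "MIP1b", "RANTES", "Resistin"
  )
}

#' Configure a synthetic daily-monitoring cohort
#'
#' Bundles every design parameter and effect size of the generative model into
#' a validated configuration object. Defaults mirror a 10-patient / 10-control,
#' 25-day, 51-analyte design with twice-daily 0-100 VAS fatigue reports, six
#' "responder" patients whose serum leptin tracks fatigue, a 29-cytokine block
#' ("nest") coupled to leptin, and two controls reporting zero fatigue on every
#' day.
#'
#' Units and scales: analytes are simulated on a log-normal
#' median-fluorescence-like scale and all analyte couplings act on the log
#' scale; fatigue is a 0-100 visual analogue scale; `coupling_range` is the
#' interval from which each responder's target correlation between log-leptin
#' and latent fatigue is drawn.
#'
#' @param n_patients,n_controls Number of subjects per group.
#' @param n_days Days of observation per subject.
#' @param analyte_names Analyte labels; must contain `"leptin"`.
#' @param n_responders Number of patients with a planted leptin-fatigue
#'   coupling.
#' @param coupling_range Length-2 interval in (-1, 1): target per-subject
#'   correlations of log-leptin with the latent fatigue process for responders.
#' @param nest_size Number of cytokines (besides leptin) coupled to the leptin
#'   latent signal.
#' @param nest_weight_range Length-2 interval of log-scale nest coupling
#'   weights.
#' @param ar_coefficient Lag-1 autocorrelation of the latent fatigue process,
#'   in `[0, 1)`.
#' @param fatigue_baseline_patient,fatigue_baseline_control Group means of the
#'   latent fatigue process (VAS units).
#' @param fatigue_sd Stationary standard deviation of latent fatigue (VAS
#'   units).
#' @param vas_noise_sd Report noise added to each AM/PM VAS report (VAS units).
#' @param ampm_offset Evening-minus-morning fatigue offset (VAS units); PM
#'   reports sit `ampm_offset / 2` above the latent value, AM the same amount
#'   below.
#' @param analyte_noise_sd Log-scale daily noise of each cytokine.
#' @param leptin_noise_sd Log-scale daily noise of leptin excluding the
#'   diurnal-window term.
#' @param diurnal_sd Log-scale noise for leptin attributable to imperfect
#'   control of the daily blood-draw window.
#' @param between_subject_sd Log-scale SD of per-subject analyte baselines.
#' @param bmi_leptin_slope Increase in baseline log-leptin per BMI unit.
#' @param n_zero_fatigue_controls Controls reporting exactly 0 fatigue on all
#'   days (exercises degenerate-series and exclusion paths downstream).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#'
#' @return An object of class `cohort_config` (a named list).
#' @examples
#' cfg <- cohort_config(seed = 1)
#' cfg$n_patients
#' @export
cohort_config <- function(n_patients = 10,
                          n_controls = 10,
                          n_days = 25,
                          analyte_names = default_analyte_names(),
                          n_responders = 6,
                          coupling_range = c(0.40, 0.75),
                          nest_size = 29,
                          nest_weight_range = c(0.16, 0.33),
                          ar_coefficient = 0.6,
                          fatigue_baseline_patient = 55,
                          fatigue_baseline_control = 10,
                          fatigue_sd = 15,
                          vas_noise_sd = 5,
                          ampm_offset = 6,
                          analyte_noise_sd = 0.5,
                          leptin_noise_sd = 0.35,
                          diurnal_sd = 0.25,
                          between_subject_sd = 0.30,
                          bmi_leptin_slope = 0.08,
                          n_zero_fatigue_controls = 2,
                          seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    n_controls = as.integer(n_controls),
    n_days = as.integer(n_days),
    analyte_names = as.character(analyte_names),
    n_analytes = length(analyte_names),
    n_responders = as.integer(n_responders),
    coupling_range = as.numeric(coupling_range),
    nest_size = as.integer(nest_size),
    nest_weight_range = as.numeric(nest_weight_range),
    ar_coefficient = as.numeric(ar_coefficient),
    fatigue_baseline_patient = as.numeric(fatigue_baseline_patient),
    fatigue_baseline_control = as.numeric(fatigue_baseline_control),
    fatigue_sd = as.numeric(fatigue_sd),
    vas_noise_sd = as.numeric(vas_noise_sd),
    ampm_offset = as.numeric(ampm_offset),
    analyte_noise_sd = as.numeric(analyte_noise_sd),
    leptin_noise_sd = as.numeric(leptin_noise_sd),
    diurnal_sd = as.numeric(diurnal_sd),
    between_subject_sd = as.numeric(between_subject_sd),
    bmi_leptin_slope = as.numeric(bmi_leptin_slope),
    n_zero_fatigue_controls = as.integer(n_zero_fatigue_controls),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_config(cfg)
  cfg
}

#' Fully null cohort configuration
#'
#' Convenience constructor for calibration studies: no responders, no
#' leptin-coupled cytokine nest, and no BMI-leptin coupling, so every analyte
#' is independent of fatigue and (marginally) of every other analyte.
#'
#' @param ... Overrides passed on to [cohort_config()].
#' @return A `cohort_config`.
#' @export
null_cohort_config <- function(...) {
  cohort_config(n_responders = 0, nest_size = 0, bmi_leptin_slope = 0, ...)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> ",
      x$n_patients, " patients + ", x$n_controls, " controls x ",
      x$n_days, " days, ", x$n_analytes, " analytes\n",
      "  responders: ", x$n_responders,
      " (target r in [", x$coupling_range[1], ", ", x$coupling_range[2], "])",
      "; nest size: ", x$nest_size,
      "; seed: ", x$seed, "\n", sep = "")
  invisible(x)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (!"leptin" %in% cfg$analyte_names)
    stop("analyte_names must include 'leptin'")
  if (anyDuplicated(cfg$analyte_names))
    stop("analyte_names must be unique")
  if (cfg$n_responders > cfg$n_patients)
    stop("n_responders must not exceed n_patients")
  if (cfg$nest_size > cfg$n_analytes - 1L)
    stop("nest_size must not exceed n_analytes - 1")
  if (cfg$n_zero_fatigue_controls > cfg$n_controls)
    stop("n_zero_fatigue_controls must not exceed n_controls")
  if (cfg$ar_coefficient < 0 || cfg$ar_coefficient >= 1)
    stop("ar_coefficient must lie in [0, 1)")
  sds <- c(cfg$fatigue_sd, cfg$vas_noise_sd, cfg$analyte_noise_sd,
           cfg$leptin_noise_sd, cfg$diurnal_sd, cfg$between_subject_sd)
  if (any(sds < 0)) stop("all sd parameters must be >= 0")
  if (length(cfg$coupling_range) != 2 ||
      any(abs(cfg$coupling_range) >= 1))
    stop("coupling_range must be two values strictly inside (-1, 1)")
  if (diff(cfg$coupling_range) < 0) stop("coupling_range must be increasing")
  if (length(cfg$nest_weight_range) != 2 ||
      diff(cfg$nest_weight_range) < 0)
    stop("nest_weight_range must be an increasing length-2 interval")
  # A nonzero target correlation is unattainable when leptin carries no noise:
  # log-leptin would be an exact affine function of latent fatigue (r = +/-1).
  leptin_total_noise <- sqrt(cfg$leptin_noise_sd^2 + cfg$diurnal_sd^2)
  if (leptin_total_noise == 0 && cfg$n_responders > 0 &&
      any(cfg$coupling_range != 0))
    stop("planted couplings in (0, 1) are unattainable with zero leptin noise")
  invisible(cfg)
}

#' Derive a stage-specific seed from the master seed
#'
#' Fans the single configuration seed out to independent per-stage seeds via a
#' stable string hash, so pipeline stages can be re-run in isolation and still
#' reproduce bit-for-bit.
#'
#' @param seed Integer master seed.
#' @param stage Character stage label (e.g. `"profiles"`, `"days"`, `"cv"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(length(stage) == 1L, is.character(stage))
  h <- 0
  for (cp in utf8ToInt(stage)) h <- (h * 131 + cp) %% 2147482951
  as.integer((as.numeric(seed) %% 2147482951 * 2654435 + h) %% 2147482951)
}
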