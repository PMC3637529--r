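#' Published cohort covariates
#'
#' The age and BMI covariates of the 20-woman study cohort (participants 1-10:
#' chronic fatigue syndrome patients; 11-20: healthy controls) as printed in
#' the study's demographics table, at the printed one-decimal precision.
#' Bundled so design-determined statistics (group means, pooled-variance
#' t-tests) can be recomputed without external data.
#'
#' @return Tibble with `participant`, `group`, `age` (years), `bmi` (kg/m2).
#' @examples
#' mean(table1_covariates()$age[table1_covariates()$group == "control"])
#' @export
table1_covariates <- function() {
  tibble::tibble(
    participant = 1:20,
    group = rep(c("patient", "control"), each = 10),
    age = c(54, 53, 53, 47, 61, 60, 51, 29, 55, 62,
            57, 48, 51, 58, 52, 50, 44, 47, 61, 62),
    bmi = c(18, 31.6, 25.2, 25.9, 35.7, 20.6, 23.3, 27.5, 20.4, 42,
            33.1, 23, 21.3, 25.1, 19.7, 20.5, 25.5, 31.6, 24, 24.5)
  )
}
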