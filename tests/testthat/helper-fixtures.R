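# Small cohort configuration for unit tests: full design depth (10 + 10
# subjects, 25 days) but a 12-analyte panel so cohorts generate in
# milliseconds. Acceptance tests use the full 51-analyte default instead.
tiny_config <- function(seed = 1, ...) {
  cohort_config(
    analyte_names = c("leptin", paste0("cyto", sprintf("%02d", 1:11))),
    nest_size = 6,
    seed = seed,
    ...
  )
}

tiny_null_config <- function(seed = 1, ...) {
  cohort_config(
    analyte_names = c("leptin", paste0("cyto", sprintf("%02d", 1:11))),
    n_responders = 0, nest_size = 0, bmi_leptin_slope = 0,
    seed = seed, ...
  )
}

# Independent loop oracle for the centered shrinking-window moving average.
moving_average_oracle <- function(x, window) {
  half <- (window - 1) / 2
  n <- length(x)
  sapply(seq_len(n), function(t) {
    idx <- max(1, t - half):min(n, t + half)
    mean(x[idx])
  })
}

# Brute-force Benjamini-Hochberg over all candidate ranks k.
bh_oracle <- function(p, q) {
  m <- length(p)
  sp <- sort(p)
  ks <- which(sp <= seq_len(m) * q / m)
  if (length(ks) == 0) return(list(threshold = NA_real_, rejected = rep(FALSE, m)))
  thr <- sp[max(ks)]
  list(threshold = thr, rejected = p <= thr)
}

# Exhaustive oracle for extreme-day selection under the stated tie-break:
# stable ascending sort on (score, day); bottom k low, top k high.
extreme_oracle <- function(scores, k) {
  d <- seq_along(scores)
  ord <- order(scores, d)
  list(low = sort(d[ord[seq_len(k)]]),
       high = sort(d[ord[seq(length(ord) - k + 1, length(ord))]]))
}
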