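# Shared fixtures: small cohorts and count tables built in code.

# eight-cell grouped data for a G x E interaction from four counts per stratum
grouped_ge <- function(e1_case_gg, e1_case_car, e1_ctl_gg, e1_ctl_car,
                       e0_case_gg, e0_case_car, e0_ctl_gg, e0_ctl_car) {
  ge_strata_data(two_by_two(e1_case_car, e1_case_gg, e1_ctl_car, e1_ctl_gg),
                 two_by_two(e0_case_car, e0_case_gg, e0_ctl_car, e0_ctl_gg))
}

# expand grouped count rows to one row per subject
expand_grouped <- function(d, weight = "n") {
  d[rep(seq_len(nrow(d)), d[[weight]]), setdiff(names(d), weight),
    drop = FALSE]
}

small_cohort <- function(n = 300, seed = 42, ...) {
  simulate_cohort(cohort_config(n_cases = n, n_controls = n, seed = seed,
                                ...))
}

# deterministic toy data where one factor predicts the outcome perfectly
perfect_predictor_data <- function(n_per_cell = 20) {
  data.frame(
    status_case = rep(c(1L, 0L), each = 2 * n_per_cell),
    signal = rep(c(1L, 1L, 0L, 0L), each = n_per_cell),
    noise1 = rep(c(0L, 1L), 2 * n_per_cell),
    noise2 = rep(c(0L, 1L, 1L, 0L), each = n_per_cell))
}
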