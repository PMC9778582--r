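# In-code fixtures: record builders and small generator presets.

mk_records <- function(dates, patient_id = "P1", birth = "1950-06-15",
                       sex = "M", atc = "G04CA02", drug = "tamsulosin",
                       n_packages = 1L, ddd = 30) {
  k <- length(dates)
  data.frame(
    patient_id = rep_len(patient_id, k),
    birth_date = rep_len(as.Date(birth), k),
    sex = rep_len(sex, k),
    dispensation_date = as.Date(dates),
    atc_code = rep_len(atc, k),
    drug_name = rep_len(drug, k),
    n_packages = rep_len(as.integer(n_packages), k),
    ddd_per_package = rep_len(ddd, k),
    stringsAsFactors = FALSE
  )
}

# numeric-day supply spans for episode hand-traces
mk_spans <- function(days, durations = 30, key = "tamsulosin") {
  data.frame(key = key, start = days,
             duration_days = rep_len(durations, length(days)),
             stringsAsFactors = FALSE)
}

# a patient whose monthly refills run from `start` for `n_fills` months
refill_dates <- function(start, n_fills, step = 30) {
  as.Date(start) + step * (0:(n_fills - 1))
}

# single-drug profile used wherever tests need analytic control over the
# latent distribution and the supply grid
single_profile <- function(median_days = 300, ddd = 10, jitter = 0) {
  data.frame(
    drug_name = "tamsulosin", atc_code = "G04CA02", class = "AB",
    ddd_per_package = ddd, dist = "exponential", median_days = median_days,
    shape = NA_real_, refill_jitter_sd = jitter, market_share = 1,
    stringsAsFactors = FALSE
  )
}

clean_params <- function(n, seed, ...) {
  args <- list(
    n_patients = n, seed = seed,
    class_mix = c(ab_only = 1, fiveari_only = 0, both = 0),
    switch_prob = 0, death_rate_annual = 0,
    frac_occasional = 0, frac_underage = 0,
    frac_washout_users = 0, frac_short_history = 0
  )
  do.call(simulation_params, utils::modifyList(args, list(...)))
}

jitterfree_profiles <- function() {
  p <- default_drug_profiles()
  p$refill_jitter_sd <- 0
  p
}
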