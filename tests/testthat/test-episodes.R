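cfg <- study_config()

test_that("supply duration is packages times DDD content", {
  expect_equal(supply_duration(data.frame(n_packages = 1, ddd_per_package = 30)), 30)
  expect_equal(supply_duration(data.frame(n_packages = 2, ddd_per_package = 30)), 60)
  expect_equal(supply_duration(data.frame(n_packages = 1, ddd_per_package = 28)), 28)
  expect_error(supply_duration(data.frame(n_packages = 0, ddd_per_package = 30)),
               "non-positive")
})

test_that("grace period scales the supply duration", {
  expect_equal(grace_period(30, 1.5), 45)
  expect_equal(grace_period(28, 1.5), 42)
  expect_equal(grace_period(30, 1.0), 30)
  expect_error(grace_period(30, 0), "> 0")
})

test_that("hand-traced refill patterns split into the expected episodes", {
  # 40-day gap within the 45-day grace: one episode, supply to day 70
  eps <- build_episodes(mk_spans(c(0, 40)), cfg)
  expect_equal(nrow(eps), 1)
  expect_equal(eps$supply_end, 70)
  expect_equal(eps$n_dispensations, 2L)

  # 50-day gap beyond grace: two episodes, first ends at its supply end
  eps <- build_episodes(mk_spans(c(0, 50)), cfg)
  expect_equal(nrow(eps), 2)
  expect_equal(eps$supply_end[1], 30)
  expect_equal(eps$terminated_by[1], "gap")
  expect_equal(eps$episode_start[2], 50)

  # early refill at day 10 stockpiles: supply carried to day 60
  eps <- build_episodes(mk_spans(c(0, 10)), cfg)
  expect_equal(nrow(eps), 1)
  expect_equal(eps$supply_end, 60)
})

test_that("unsorted spans are an error, not silently sorted", {
  expect_error(build_episodes(mk_spans(c(40, 0)), cfg), "sorted")
})

test_that("same-day fills of one key merge into a single span", {
  recs <- mk_records(c("2018-04-05", "2018-04-05", "2018-05-06"))
  spans <- make_supply_spans(recs, "drug", cfg)
  expect_equal(nrow(spans), 2)
  expect_equal(spans$duration_days[1], 60)
})

test_that("every dispensation lands in exactly one episode", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(2:15, 1)
    days <- sort(sample(0:400, n))
    spans <- mk_spans(days, durations = sample(c(28, 30, 60), n, replace = TRUE))
    eps <- build_episodes(spans, cfg)
    expect_equal(sum(eps$n_dispensations), n)
    expect_true(all(diff(eps$episode_start) > 0))
  }
})

test_that("discontinuation observations follow the gap/death/censor rules", {
  # one 30-day fill, nothing after: event at supply end
  eps <- build_episodes(mk_spans(0), cfg)
  td <- time_to_discontinuation(eps, cfg)
  expect_equal(td$time_days, 30L)
  expect_equal(td$event, 1L)

  # refills every 30 days through day 360: persistent at the horizon
  eps <- build_episodes(mk_spans(seq(0, 360, 30)), cfg)
  td <- time_to_discontinuation(eps, cfg)
  expect_equal(td$time_days, 365L)
  expect_equal(td$event, 0L)

  # death at day 100 while supplied: death is non-persistence
  eps <- build_episodes(mk_spans(seq(0, 90, 30)), cfg, death_date = 100)
  td <- time_to_discontinuation(eps, cfg, death_date = 100)
  expect_equal(td$time_days, 100L)
  expect_equal(td$event, 1L)
  expect_equal(td$cause, "death")

  # gap before death: the earlier cause wins
  eps <- build_episodes(mk_spans(c(0, 200)), cfg, death_date = 250)
  td <- time_to_discontinuation(eps, cfg, death_date = 250)
  expect_equal(td$time_days, 30L)
  expect_equal(td$cause, "gap")

  expect_error(time_to_discontinuation(build_episodes(mk_spans(0), cfg)[0, ], cfg),
               "no episodes")
})

test_that("supply-end anchoring is an equivalent gap rule without stockpiling", {
  cfg_se <- study_config(gap_anchor = "supply_end")
  expect_equal(nrow(build_episodes(mk_spans(c(0, 40)), cfg_se)), 1)
  expect_equal(nrow(build_episodes(mk_spans(c(0, 50)), cfg_se)), 2)
})

test_that("stockpiling carry-over can be capped", {
  cfg_cap <- study_config(stockpile_cap = 0)
  eps <- build_episodes(mk_spans(c(0, 10)), cfg_cap)
  expect_equal(eps$supply_end, 40)  # no carry-over: 10 + 30
})

test_that("event times are monotone in the grace multiplier", {
  set.seed(55)
  ds <- generate_dataset(simulation_params(n_patients = 150, seed = 55))
  sel <- select_cohort(ds$records, ds$deaths, cfg)
  sweep <- lapply(c(1.0, 1.25, 1.5, 2.0), function(m) {
    obs <- persistence_observations(ds$records, sel$cohort,
                                    study_config(grace_multiplier = m), "drug")
    obs[order(obs$patient_id, obs$key), ]
  })
  for (i in 2:4) {
    expect_equal(sweep[[i]]$patient_id, sweep[[1]]$patient_id)
    expect_true(all(sweep[[i]]$time_days >= sweep[[i - 1]]$time_days))
    expect_lte(sum(sweep[[i]]$event), sum(sweep[[i - 1]]$event))
  }
})

test_that("class-level persistence dominates the member drugs' persistence", {
  ds <- generate_dataset(simulation_params(n_patients = 250, seed = 61,
                                           switch_prob = 0.6))
  sel <- select_cohort(ds$records, ds$deaths, cfg)
  obs_c <- persistence_observations(ds$records, sel$cohort, cfg, "class")
  obs_d <- persistence_observations(ds$records, sel$cohort, cfg, "drug")
  drug_class <- setNames(study_drugs()$class, study_drugs()$drug_name)
  obs_d$class <- drug_class[obs_d$key]
  best_drug <- aggregate(time_days ~ patient_id + class, obs_d, max)
  merged <- merge(obs_c, best_drug,
                  by.x = c("patient_id", "key"),
                  by.y = c("patient_id", "class"),
                  suffixes = c("_class", "_drug"))
  expect_gt(nrow(merged), 0)
  expect_true(all(merged$time_days_class >= merged$time_days_drug))
})

test_that("jitter-free drug-level event times equal the truth's supply end", {
  ds <- generate_dataset(clean_params(200, seed = 71), single_profile(100, 10))
  sel <- select_cohort(ds$records, ds$deaths, cfg)
  obs <- persistence_observations(ds$records, sel$cohort, cfg, "drug")
  truth <- ds$truth[ds$truth$patient_id %in% sel$cohort$patient_id, ]
  m <- merge(obs, truth, by.x = c("patient_id", "key"),
             by.y = c("patient_id", "drug_name"))
  expect_equal(nrow(m), nrow(obs))
  exp_end <- 10 * ceiling(m$true_discontinuation_day / 10)
  censored <- exp_end + grace_period(10, cfg$grace_multiplier) > cfg$followup_days
  expect_equal(m$event == 0, censored)
  expect_equal(m$time_days[!censored], exp_end[!censored])
})
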