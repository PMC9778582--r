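cfg <- study_config()

test_that("age groups use completed years and half-open bins", {
  expect_equal(assign_age_group(as.Date("1948-04-01"), cfg$reference_date),
               "70-79")
  expect_equal(assign_age_group(as.Date("1948-04-02"), cfg$reference_date),
               "60-69")
  expect_equal(assign_age_group(as.Date("1923-01-01"), cfg$reference_date),
               "90-100")
  expect_warning(
    out <- assign_age_group(as.Date("1910-01-01"), cfg$reference_date),
    "out_of_range")
  expect_equal(out, "out_of_range")
  expect_error(assign_age_group(as.Date("1990-01-01"), cfg$reference_date),
               "below the first")
})

test_that("each exclusion rule fires on its hand-built patient", {
  hist <- function(pid, birth) {
    mk_records("2016-05-01", patient_id = pid, birth = birth,
               atc = "C10AA05", drug = "atorvastatin", ddd = 28)
  }
  recs <- rbind(
    # under-age despite 5 fills
    mk_records(refill_dates("2018-04-10", 5), "A", birth = "1978-04-15"),
    hist("A", "1978-04-15"),
    # wash-out fill in February 2018, then fills from May
    mk_records(c("2018-02-10", refill_dates("2018-05-03", 4)), "B",
               birth = "1950-01-01"),
    hist("B", "1950-01-01"),
    # exactly one study fill in follow-up
    mk_records("2018-04-20", "C", birth = "1945-03-03"),
    hist("C", "1945-03-03"),
    # first-ever database record only 100 days before index
    mk_records(refill_dates("2018-06-01", 4), "D", birth = "1942-07-07"),
    mk_records("2018-02-21", "D", birth = "1942-07-07",
               atc = "C10AA05", drug = "atorvastatin", ddd = 28),
    # study fills only before the wash-out window: no index fill
    mk_records(refill_dates("2017-05-01", 3), "E", birth = "1949-09-09"),
    hist("E", "1949-09-09"),
    # eligible chronic user
    mk_records(refill_dates("2018-04-05", 6), "F", birth = "1940-02-02"),
    hist("F", "1940-02-02")
  )
  sel <- select_cohort(recs, config = cfg)
  status <- setNames(sel$ledger$by_patient$status, sel$ledger$by_patient$patient_id)
  expect_equal(status[["A"]], "under_age")
  expect_equal(status[["B"]], "washout_user")
  expect_equal(status[["C"]], "occasional")
  expect_equal(status[["D"]], "short_history")
  expect_equal(status[["E"]], "no_index_fill")
  expect_equal(status[["F"]], "eligible")
  expect_equal(sel$cohort$patient_id, "F")
  expect_equal(sel$cohort$index_date, as.Date("2018-04-05"))
  expect_equal(sel$cohort$followup_end, as.Date("2018-04-05") + 365)
  # ledger conservation
  expect_equal(sum(sel$ledger$counts$n), 6)
})

test_that("wash-out exclusion outranks occasional in the fixed order", {
  recs <- rbind(
    mk_records(c("2018-03-15", "2018-04-20"), "W", birth = "1950-01-01"),
    mk_records("2016-01-01", "W", birth = "1950-01-01",
               atc = "C10AA05", drug = "atorvastatin", ddd = 28)
  )
  sel <- select_cohort(recs, config = cfg)
  expect_equal(sel$ledger$by_patient$status, "washout_user")
})

test_that("a death during follow-up does not exclude the patient", {
  recs <- rbind(
    mk_records(refill_dates("2018-04-05", 3), "G", birth = "1940-02-02"),
    mk_records("2016-05-01", "G", birth = "1940-02-02",
               atc = "C10AA05", drug = "atorvastatin", ddd = 28)
  )
  deaths <- data.frame(patient_id = "G", death_date = as.Date("2018-08-01"))
  sel <- select_cohort(recs, deaths, cfg)
  expect_equal(nrow(sel$cohort), 1)
  expect_true(sel$cohort$died_in_followup)
})

test_that("an empty record set yields an empty cohort and zeroed ledger", {
  sel <- select_cohort(mk_records(character(0)), config = cfg)
  expect_equal(nrow(sel$cohort), 0)
  expect_equal(sum(sel$ledger$counts$n), 0)
})

test_that("jitter-free synthetic statuses are reproduced with zero discordance", {
  ds <- generate_dataset(simulation_params(n_patients = 600, seed = 41),
                         jitterfree_profiles())
  sel <- select_cohort(ds$records, ds$deaths, study_config())
  truth_status <- ds$truth[!duplicated(ds$truth$patient_id),
                           c("patient_id", "eligibility_status")]
  merged <- merge(sel$ledger$by_patient, truth_status, by = "patient_id")
  expect_equal(nrow(merged), nrow(truth_status))
  expect_equal(merged$status, merged$eligibility_status)
})

test_that("cohort summaries report paper-style rounded percentages", {
  ds <- generate_dataset(simulation_params(n_patients = 800, seed = 8))
  sel <- select_cohort(ds$records, ds$deaths, cfg)
  s <- summarize_cohort(sel$cohort)
  expect_equal(s$n, nrow(sel$cohort))
  # percentages per partition sum to 100 +/- 0.1 after rounding
  expect_lt(abs(sum(s$age_table$pct) - 100), 0.1 + 1e-9)
  expect_equal(sum(s$age_table$n), s$n)
  # exposure to both classes is at most each single-class exposure
  exp_tab <- setNames(s$exposure_table$n, s$exposure_table$category)
  expect_lte(exp_tab[["both_classes"]], exp_tab[["at_least_one_ab"]])
  expect_lte(exp_tab[["both_classes"]], exp_tab[["at_least_one_5ari"]])
  # age medians by class bracket the overall median
  expect_true(all(s$age_by_class$n > 0))
})

test_that("a single-member cohort is its own median with zero-width IQR", {
  recs <- rbind(
    mk_records(refill_dates("2018-04-05", 3), "H", birth = "1948-01-01"),
    mk_records("2016-05-01", "H", birth = "1948-01-01",
               atc = "C10AA05", drug = "atorvastatin", ddd = 28)
  )
  s <- summarize_cohort(select_cohort(recs, config = cfg)$cohort)
  expect_equal(s$median_age, 70)
  expect_equal(diff(s$age_iqr), 0)
})

test_that("rank-sum test handles symmetry, separation and ties", {
  same <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$z, 0)
  expect_equal(same$p_two_sided, 1)
  sep <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(sep$statistic, 3)  # minimum possible rank sum
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
  # agreement with the tie-corrected normal approximation in stats
  a <- c(70, 71, 71, 73, 75, 78, 64, 71)
  b <- c(75, 75, 76, 78, 81, 68, 74)
  expect_equal(wilcoxon_rank_sum(a, b)$p_two_sided,
               wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
})

test_that("rank-sum p agrees with a permutation oracle at n = 30", {
  set.seed(77)
  a <- rnorm(30, 70, 8)
  b <- rnorm(30, 73, 8)
  approx_p <- wilcoxon_rank_sum(a, b)$p_two_sided
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[1:30])
  mu <- 30 * 61 / 2
  perm <- replicate(50000, sum(r[sample.int(60, 30)]))
  perm_p <- mean(abs(perm - mu) >= abs(w_obs - mu))
  expect_lt(abs(approx_p - perm_p), 0.01)
})

test_that("rank-sum test is invariant under common monotone transforms", {
  set.seed(5)
  a <- rexp(25); b <- rexp(20, 0.7)
  base <- wilcoxon_rank_sum(a, b)
  logged <- wilcoxon_rank_sum(log(a), log(b))
  expect_equal(base$statistic, logged$statistic)
  expect_equal(base$p_two_sided, logged$p_two_sided)
})
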