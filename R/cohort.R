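# New-user cohort selection and descriptive summaries.
#
# Eligibility: men aged >= 40 completed years at the reference date, first
# study-drug fill inside the index period (the index date), no study-drug fill
# in the wash-out window (new users), at least one year of database history
# before index, and at least 2 distinct study-drug dispensation dates during
# follow-up (chronic use). Men who die during follow-up are retained: death is
# a cause of non-persistence, not an exclusion.

EXCLUSION_STATUSES <- c("eligible", "under_age", "washout_user",
                        "short_history", "no_index_fill", "occasional")

#' Assign age groups from configurable edges
#'
#' Completed-years age is binned into half-open intervals `[e_i, e_{i+1})`
#' labelled `"e_i-(e_{i+1}-1)"` (e.g. `"70-79"`).
#'
#' @param birth_date Date vector.
#' @param reference_date single Date at which age is computed.
#' @param edges strictly increasing integer edges.
#' @return character vector of group labels; ages at or above the last edge
#'   get `"out_of_range"` with a warning, ages below the first edge are an
#'   error.
#' @export
assign_age_group <- function(birth_date, reference_date,
                             edges = study_config()$age_group_edges) {
  age <- completed_years(birth_date, reference_date)
  if (any(age < edges[1]))
    stop("age below the first age-group edge (", edges[1], ")")
  labels <- paste0(utils::head(edges, -1), "-", utils::tail(edges, -1) - 1)
  idx <- findInterval(age, edges)
  out <- ifelse(idx >= length(edges), "out_of_range", labels[idx])
  if (any(out == "out_of_range"))
    warning("age(s) at or above the last edge assigned to 'out_of_range'")
  out
}

age_group_labels <- function(config) {
  e <- config$age_group_edges
  paste0(utils::head(e, -1), "-", utils::tail(e, -1) - 1)
}

#' Select the study cohort and account for every exclusion
#'
#' Applies the eligibility procedure to validated dispensing records. Every
#' male patient with at least one study-drug record receives exactly one final
#' status, assigned in the fixed order `under_age` -> `washout_user` ->
#' `short_history` -> `no_index_fill` -> `occasional` -> `eligible`, so the
#' exclusion ledger is reproducible. Database history is judged on records of
#' any ATC code; all other rules look at study drugs only.
#'
#' @param records validated dispensing records (all ATC codes).
#' @param deaths optional data.frame (`patient_id`, `death_date`).
#' @param config a [study_config()] object.
#' @return list with `cohort` (one row per eligible man: demographics, index
#'   date, follow-up end, death, and list-columns `drugs_prescribed` /
#'   `classes_prescribed` over the follow-up window) and `ledger` (per-status
#'   counts plus the per-patient status table).
#' @export
select_cohort <- function(records, deaths = NULL, config = study_config()) {
  rec_class <- classify_atc(records$atc_code, config$class_map)
  study <- records[!is.na(rec_class) & records$sex == "M", , drop = FALSE]

  empty_ledger <- list(
    counts = data.frame(status = EXCLUSION_STATUSES,
                        n = integer(length(EXCLUSION_STATUSES))),
    by_patient = data.frame(patient_id = character(), status = character())
  )
  if (nrow(study) == 0)
    return(list(cohort = empty_cohort(config), ledger = empty_ledger))

  death_lookup <- if (!is.null(deaths) && nrow(deaths)) {
    stats::setNames(deaths$death_date, deaths$patient_id)
  } else stats::setNames(as.Date(character()), character())

  first_any <- vapply(split(as.numeric(records$dispensation_date),
                            records$patient_id), min, 0)
  study_idx <- split(seq_len(nrow(study)), study$patient_id)
  pids <- names(study_idx)

  status <- character(length(pids))
  members <- vector("list", length(pids))

  for (j in seq_along(pids)) {
    pid <- pids[j]
    rows <- study[study_idx[[j]], , drop = FALSE]
    birth <- rows$birth_date[1]
    age <- completed_years(birth, config$reference_date)

    if (age < config$min_age_years) { status[j] <- "under_age"; next }
    if (any(rows$dispensation_date >= config$washout_start &
              rows$dispensation_date < config$washout_end)) {
      status[j] <- "washout_user"; next
    }
    in_index <- rows$dispensation_date >= config$index_start &
      rows$dispensation_date < config$index_end
    if (!any(in_index)) { status[j] <- "no_index_fill"; next }
    index_date <- min(rows$dispensation_date[in_index])
    earliest <- as.Date(first_any[[pid]], origin = "1970-01-01")
    if (earliest > index_date - config$min_history_days) {
      status[j] <- "short_history"; next
    }
    followup_end <- index_date + config$followup_days
    fu <- rows[rows$dispensation_date >= index_date &
                 rows$dispensation_date < followup_end, , drop = FALSE]
    enough <- if (config$per_drug_prescriptions) {
      any(tapply(as.numeric(fu$dispensation_date), fu$drug_name,
                 function(d) length(unique(d))) >= config$min_prescriptions)
    } else {
      length(unique(fu$dispensation_date)) >= config$min_prescriptions
    }
    if (!enough) { status[j] <- "occasional"; next }

    status[j] <- "eligible"
    death_date <- if (pid %in% names(death_lookup)) death_lookup[[pid]] else as.Date(NA)
    drugs <- sort(unique(fu$drug_name))
    classes <- sort(unique(classify_atc(fu$atc_code, config$class_map)))
    members[[j]] <- data.frame(
      patient_id = pid,
      birth_date = birth,
      age_at_reference = age,
      age_group = assign_age_group(birth, config$reference_date,
                                   config$age_group_edges),
      young_old = ifelse(age >= config$young_old_cut,
                         paste0(">=", config$young_old_cut),
                         paste0("<", config$young_old_cut)),
      index_date = index_date,
      followup_end = followup_end,
      death_date = death_date,
      died_in_followup = !is.na(death_date) && death_date >= index_date &&
        death_date < followup_end,
      stringsAsFactors = FALSE
    )
    members[[j]]$drugs_prescribed <- I(list(drugs))
    members[[j]]$classes_prescribed <- I(list(classes))
  }

  cohort <- do.call(rbind, members[!vapply(members, is.null, TRUE)])
  if (is.null(cohort)) cohort <- empty_cohort(config)
  rownames(cohort) <- NULL
  cohort$age_group <- factor(cohort$age_group, levels = age_group_labels(config))

  counts <- data.frame(
    status = EXCLUSION_STATUSES,
    n = as.integer(table(factor(status, levels = EXCLUSION_STATUSES)))
  )
  ledger <- list(counts = counts,
                 by_patient = data.frame(patient_id = pids, status = status,
                                         stringsAsFactors = FALSE))
  list(cohort = cohort, ledger = ledger)
}

empty_cohort <- function(config) {
  data.frame(
    patient_id = character(), birth_date = as.Date(character()),
    age_at_reference = integer(),
    age_group = factor(character(), levels = age_group_labels(config)),
    young_old = character(),
    index_date = as.Date(character()), followup_end = as.Date(character()),
    death_date = as.Date(character()), died_in_followup = logical(),
    drugs_prescribed = I(list()), classes_prescribed = I(list())
  )
}

has_class <- function(cohort, label) {
  vapply(cohort$classes_prescribed, function(z) label %in% z, TRUE)
}

#' Summarize a cohort (study-population descriptives)
#'
#' Produces the age-group distribution, median age with IQR (overall, per
#' class, per drug), exposure counts (at least one AB, at least one 5ARI,
#' both classes) and deaths during follow-up. All percentages use the cohort
#' size as denominator and are rounded half away from zero to one decimal.
#'
#' @param cohort cohort data.frame from [select_cohort()].
#' @return list with `n`, `median_age`, `age_iqr`, `age_table`,
#'   `exposure_table`, `age_by_class`, `age_by_drug`.
#' @export
summarize_cohort <- function(cohort) {
  if (nrow(cohort) == 0) stop("cannot summarize an empty cohort")
  n <- nrow(cohort)
  ages <- cohort$age_at_reference

  age_tab <- as.data.frame(table(cohort$age_group), stringsAsFactors = FALSE)
  names(age_tab) <- c("age_group", "n")
  age_tab$pct <- percentage(age_tab$n, n)

  ab <- has_class(cohort, "AB")
  ari <- has_class(cohort, "5ARI")
  exposure <- data.frame(
    category = c("at_least_one_ab", "at_least_one_5ari", "both_classes",
                 "died_in_followup"),
    n = c(sum(ab), sum(ari), sum(ab & ari), sum(cohort$died_in_followup))
  )
  exposure$pct <- percentage(exposure$n, n)

  med_iqr <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    c(q1 = q[1], median = q[2], q3 = q[3])
  }

  by_class <- do.call(rbind, lapply(c("AB", "5ARI"), function(cl) {
    sel <- ages[has_class(cohort, cl)]
    if (!length(sel)) return(NULL)
    data.frame(class = cl, n = length(sel), t(med_iqr(sel)))
  }))

  all_drugs <- sort(unique(unlist(cohort$drugs_prescribed)))
  by_drug <- do.call(rbind, lapply(all_drugs, function(dr) {
    sel <- ages[vapply(cohort$drugs_prescribed, function(z) dr %in% z, TRUE)]
    data.frame(drug = dr, n = length(sel), pct = percentage(length(sel), n),
               t(med_iqr(sel)))
  }))

  list(
    n = n,
    median_age = stats::median(ages),
    age_iqr = unname(stats::quantile(ages, c(0.25, 0.75), type = 7)),
    age_table = age_tab,
    exposure_table = exposure,
    age_by_class = by_class,
    age_by_drug = by_drug
  )
}

#' Wilcoxon rank-sum test (normal approximation)
#'
#' Two-sided rank-sum test with midranks for ties, tie-corrected variance and
#' a continuity correction, as used to compare the ages of men prescribed the
#' two drug classes.
#'
#' @param sample_a,sample_b numeric vectors (both non-empty).
#' @return list with `statistic` (rank sum of `sample_a`), `z`, `p_two_sided`,
#'   `n_a`, `n_b`.
#' @export
wilcoxon_rank_sum <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b))
    stop("both samples must be non-empty")
  n1 <- length(sample_a)
  n2 <- length(sample_b)
  pooled <- c(sample_a, sample_b)
  N <- n1 + n2
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  v <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (v <= 0) {
    z <- 0
  } else {
    d <- W - mu
    z <- sign(d) * max(0, abs(d) - 0.5) / sqrt(v)
  }
  list(statistic = W, z = z, p_two_sided = min(1, 2 * stats::pnorm(-abs(z))),
       n_a = n1, n_b = n2)
}
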