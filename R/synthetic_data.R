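# Synthetic pharmacy-claims generator with known ground truth.
#
# Discontinuation behaviour is simulated at the episode level: each (patient,
# drug) carries a latent intended treatment span drawn from the drug profile's
# time-to-discontinuation distribution, and refills are noisy observations of
# that span. Switching draws a new drug within the same class with a fresh
# latent span starting where the previous drug's supply ends, so class-level
# persistence is preserved across switches. Death truncates all refills.

#' Default drug profiles for the seven study drugs
#'
#' Market shares within each class follow the per-drug exposure counts of the
#' study population (e.g. tamsulosin 2057 of 4022 AB users), and the latent
#' median times to discontinuation follow the per-drug survival medians
#' (alfuzosin 278 d, silodosin 120 d, tamsulosin 101 d, doxazosin 81 d,
#' terazosin 28 d; dutasteride 272 d, finasteride 97 d). Packages hold 30 DDD
#' (one month of once-daily therapy) and refill dates get a 2-day jitter.
#'
#' @return data.frame, one row per drug, columns `drug_name`, `atc_code`,
#'   `class`, `ddd_per_package`, `dist`, `median_days`, `shape`,
#'   `refill_jitter_sd`, `market_share`.
#' @export
default_drug_profiles <- function() {
  d <- study_drugs()
  d$ddd_per_package <- 30
  d$dist <- "exponential"
  d$median_days <- c(278, 81, 120, 101, 28, 97, 272)
  d$shape <- NA_real_
  d$refill_jitter_sd <- 2
  n_exposed <- c(584, 88, 1074, 2057, 219, 416, 1064)
  d$market_share <- n_exposed / ave(n_exposed, d$class, FUN = sum)
  validate_profiles(d)
  d
}

validate_profiles <- function(profiles) {
  req <- c("drug_name", "atc_code", "class", "ddd_per_package", "dist",
           "median_days", "refill_jitter_sd", "market_share")
  missing <- setdiff(req, names(profiles))
  if (length(missing))
    stop("drug profiles missing column(s): ", paste(missing, collapse = ", "))
  if (any(profiles$median_days <= 0)) stop("median_days must be > 0")
  if (any(profiles$ddd_per_package <= 0)) stop("ddd_per_package must be > 0")
  if (any(profiles$refill_jitter_sd < 0)) stop("refill_jitter_sd must be >= 0")
  share_sums <- tapply(profiles$market_share, profiles$class, sum)
  if (any(abs(share_sums - 1) > 1e-6))
    stop("market shares must sum to 1 within each class")
  invisible(profiles)
}

#' Simulation parameters
#'
#' Defaults emulate the study population: the age distribution follows the
#' published age-group counts (2.3/12.2/28.5/35.6/19.4/1.9% from 40-49 to
#' 90-100 years), the class mix follows the exposure counts (AB only /
#' 5ARI only / both classes), and the annual death probability is 3.2%.
#' Contaminant fractions inject the subpopulations that cohort selection must
#' exclude: occasional users (exactly one fill), under-age men, men with a
#' fill inside the wash-out window, and men with short database history.
#'
#' @param n_patients number of patients to simulate.
#' @param seed integer RNG seed; identical inputs give identical outputs.
#' @param age_dist named probability vector over age-group labels.
#' @param class_mix probabilities of `ab_only`, `fiveari_only`, `both`.
#' @param switch_prob probability of a within-class switch at the end of each
#'   treatment episode.
#' @param death_rate_annual probability of death during follow-up.
#' @param frac_occasional fraction with exactly one study-drug fill.
#' @param frac_underage fraction aged below the study age gate.
#' @param frac_washout_users fraction with a fill inside the wash-out window.
#' @param frac_short_history fraction whose first database record is less
#'   than the required history window before index.
#' @return object of class `simulation_params`.
#' @export
simulation_params <- function(n_patients = 5000,
                              seed = 1,
                              age_dist = c("40-49" = 100, "50-59" = 525,
                                           "60-69" = 1229, "70-79" = 1533,
                                           "80-89" = 838, "90-100" = 84),
                              class_mix = c(ab_only = 2802, fiveari_only = 936,
                                            both = 471),
                              switch_prob = 0.2,
                              death_rate_annual = 0.032,
                              frac_occasional = 0.15,
                              frac_underage = 0.05,
                              frac_washout_users = 0.05,
                              frac_short_history = 0.05) {
  p <- list(
    n_patients = as.integer(n_patients),
    seed = as.integer(seed),
    age_dist = age_dist / sum(age_dist),
    class_mix = class_mix / sum(class_mix),
    switch_prob = as.numeric(switch_prob),
    death_rate_annual = as.numeric(death_rate_annual),
    frac_occasional = as.numeric(frac_occasional),
    frac_underage = as.numeric(frac_underage),
    frac_washout_users = as.numeric(frac_washout_users),
    frac_short_history = as.numeric(frac_short_history)
  )
  if (p$n_patients < 1) stop("n_patients must be >= 1")
  probs <- c(p$switch_prob, p$death_rate_annual, p$frac_occasional,
             p$frac_underage, p$frac_washout_users, p$frac_short_history)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  frac_sum <- p$frac_occasional + p$frac_underage + p$frac_washout_users +
    p$frac_short_history
  if (frac_sum > 1)
    stop("infeasible mix: contaminant fractions sum to more than 1")
  if (!setequal(names(p$class_mix), c("ab_only", "fiveari_only", "both")))
    stop("class_mix must be named ab_only, fiveari_only, both")
  class(p) <- "simulation_params"
  p
}

# Draw one latent time-to-discontinuation from a profile row.
sample_latent_span <- function(profile) {
  if (profile$dist == "exponential") {
    stats::rexp(1, rate = log(2) / profile$median_days)
  } else if (profile$dist == "weibull") {
    shape <- profile$shape
    if (!is.finite(shape) || shape <= 0) stop("weibull profile needs shape > 0")
    stats::rweibull(1, shape = shape,
                    scale = profile$median_days / log(2)^(1 / shape))
  } else {
    stop("unknown discontinuation distribution: ", profile$dist)
  }
}

#' Sample a refill sequence for one latent treatment span
#'
#' Fills start at day 0 and successive fills are spaced one package-supply
#' apart plus zero-mean integer jitter; refilling continues while the next
#' fill date falls before the true discontinuation day, so jitter-free
#' reconstruction recovers a supply end of `ddd * ceiling(t / ddd)`.
#'
#' @param profile one drug-profile row.
#' @param true_discontinuation_day latent span length in days (> 0).
#' @param jitter_sd overrides the profile's `refill_jitter_sd` if non-`NULL`.
#' @param config study configuration (for the grace bound in the jitter check).
#' @param warn if `TRUE`, warn when the jitter SD makes a refill gap exceed
#'   the grace period with probability above 10% (ground truth then no longer
#'   recoverable from the records).
#' @return integer vector of fill-day offsets, starting at 0.
#' @export
sample_refill_sequence <- function(profile, true_discontinuation_day,
                                   jitter_sd = NULL, config = study_config(),
                                   warn = TRUE) {
  if (true_discontinuation_day <= 0)
    stop("true_discontinuation_day must be > 0")
  ddd <- profile$ddd_per_package
  sd <- jitter_sd %||% profile$refill_jitter_sd
  if (warn && sd > 0) {
    p_exceed <- stats::pnorm(-(config$grace_multiplier - 1) * ddd / sd)
    if (p_exceed > 0.1)
      warning("refill jitter SD ", sd, " exceeds the grace bound with ",
              "probability ", signif(p_exceed, 3),
              "; ground truth is no longer recoverable")
  }
  days <- 0
  last <- 0
  repeat {
    gap <- ddd + if (sd > 0) round(stats::rnorm(1, 0, sd)) else 0
    gap <- max(1, gap)
    nxt <- last + gap
    if (nxt >= true_discontinuation_day) break
    days <- c(days, nxt)
    last <- nxt
  }
  as.integer(days)
}

#' Generate a synthetic dispensing dataset with ground truth
#'
#' Produces dispensing records (study drugs plus a background statin record
#' that provides database history), death records, and a truth table giving,
#' per patient and drug, the latent time to discontinuation and the patient's
#' eligibility status (`eligible`, `occasional`, `under_age`, `washout_user`,
#' `short_history`). Truth statuses describe the emitted records: a patient
#' drawn as eligible whose refills end up with fewer than the chronic-use
#' minimum of distinct fill dates in follow-up (a very short latent span, or
#' death-truncated refills) is labelled `occasional`, which is what cohort
#' selection must conclude from the data. Output is deterministic given the
#' seed.
#'
#' @param params a [simulation_params()] object.
#' @param profiles drug profile table, see [default_drug_profiles()].
#' @param config a [study_config()] object.
#' @return list with `records`, `deaths`, `truth` data.frames.
#' @export
generate_dataset <- function(params = simulation_params(),
                             profiles = default_drug_profiles(),
                             config = study_config()) {
  stopifnot(inherits(params, "simulation_params"))
  validate_profiles(profiles)
  set.seed(params$seed)
  n <- params$n_patients

  edges <- config$age_group_edges
  group_labels <- paste0(utils::head(edges, -1), "-", utils::tail(edges, -1) - 1)
  age_dist <- params$age_dist
  if (!all(names(age_dist) %in% group_labels))
    stop("age_dist names must match the configured age-group labels")

  frac <- c(occasional = params$frac_occasional,
            under_age = params$frac_underage,
            washout_user = params$frac_washout_users,
            short_history = params$frac_short_history)
  statuses <- sample(c(names(frac), "eligible"), n, replace = TRUE,
                     prob = c(frac, 1 - sum(frac)))

  index_len <- days_between(config$index_start, config$index_end)
  washout_len <- days_between(config$washout_start, config$washout_end)
  mix_names <- c("ab_only", "fiveari_only", "both")

  rec_acc <- vector("list", n)
  truth_acc <- vector("list", n)
  death_acc <- vector("list", n)

  for (i in seq_len(n)) {
    pid <- sprintf("P%06d", i)
    st <- statuses[i]

    if (st == "under_age") {
      age <- sample(30:(config$min_age_years - 1), 1)
    } else {
      grp <- sample(names(age_dist), 1, prob = age_dist)
      lo <- edges[match(grp, group_labels)]
      hi <- edges[match(grp, group_labels) + 1] - 1
      age <- sample(lo:hi, 1)
    }
    birth <- add_years(config$reference_date, -age) - sample(0:364, 1)
    index_date <- config$index_start + (sample.int(index_len, 1) - 1)

    death_date <- if (stats::runif(1) < params$death_rate_annual) {
      index_date + sample.int(config$followup_days, 1)
    } else as.Date(NA)

    # background (non-study) record providing database history
    hist_offset <- if (st == "short_history") sample(30:(config$min_history_days - 5), 1)
                   else sample((config$min_history_days + 35):1200, 1)
    fills <- data.frame(date = index_date - hist_offset,
                        profile_row = NA_integer_,
                        stringsAsFactors = FALSE)

    pick_drug <- function(class, exclude = NULL) {
      rows <- which(profiles$class == class & !(profiles$drug_name %in% exclude))
      if (length(rows) == 1) return(rows)
      sample(rows, 1, prob = profiles$market_share[rows])
    }

    truth_rows <- list()
    add_chain <- function(class) {
      # chain of within-class episodes; each switch starts a fresh latent span
      start_off <- 0
      drug_row <- pick_drug(class)
      repeat {
        prof <- profiles[drug_row, ]
        t_disc <- sample_latent_span(prof)
        offs <- sample_refill_sequence(prof, t_disc, config = config, warn = FALSE)
        cap <- start_off + config$followup_days + 2 * prof$ddd_per_package
        offs <- offs[start_off + offs <= cap]
        fills <<- rbind(fills, data.frame(date = index_date + start_off + offs,
                                          profile_row = drug_row))
        truth_rows[[length(truth_rows) + 1]] <<- data.frame(
          patient_id = pid, drug_name = prof$drug_name,
          start_day = start_off, true_discontinuation_day = t_disc,
          stringsAsFactors = FALSE)
        supply_end_off <- start_off + offs[length(offs)] + prof$ddd_per_package
        can_switch <- sum(profiles$class == class) > 1 &&
          supply_end_off < config$followup_days
        if (can_switch && stats::runif(1) < params$switch_prob) {
          drug_row <- pick_drug(class, exclude = prof$drug_name)
          start_off <- supply_end_off
        } else break
      }
    }

    if (st == "occasional") {
      cls <- sample(mix_names, 1, prob = params$class_mix)
      drug_row <- pick_drug(if (cls == "fiveari_only") "5ARI" else "AB")
      fills <- rbind(fills, data.frame(date = index_date, profile_row = drug_row))
      truth_rows[[1]] <- data.frame(
        patient_id = pid, drug_name = profiles$drug_name[drug_row],
        start_day = 0, true_discontinuation_day = NA_real_,
        stringsAsFactors = FALSE)
    } else {
      cls <- sample(mix_names, 1, prob = params$class_mix)
      if (cls %in% c("ab_only", "both")) add_chain("AB")
      if (cls %in% c("fiveari_only", "both")) add_chain("5ARI")
      if (st == "washout_user") {
        wo_date <- config$washout_start + (sample.int(washout_len, 1) - 1)
        first_study <- which(!is.na(fills$profile_row))[1]
        fills <- rbind(fills, data.frame(date = wo_date,
                                         profile_row = fills$profile_row[first_study]))
      }
    }

    if (!is.na(death_date)) fills <- fills[fills$date < death_date, , drop = FALSE]

    study_dates <- fills$date[!is.na(fills$profile_row)]
    in_window <- study_dates[study_dates >= index_date &
                               study_dates < index_date + config$followup_days]
    if (st == "eligible" &&
        length(unique(in_window)) < config$min_prescriptions) {
      st <- "occasional"
    }
    if (length(study_dates) == 0) next  # death erased every study fill

    truth <- do.call(rbind, truth_rows)
    truth$eligibility_status <- st
    truth$index_date <- index_date
    truth_acc[[i]] <- truth

    is_bg <- is.na(fills$profile_row)
    rec_acc[[i]] <- data.frame(
      patient_id = pid,
      birth_date = birth,
      sex = "M",
      dispensation_date = fills$date,
      atc_code = ifelse(is_bg, "C10AA05", profiles$atc_code[fills$profile_row]),
      drug_name = ifelse(is_bg, "atorvastatin", profiles$drug_name[fills$profile_row]),
      n_packages = 1L,
      ddd_per_package = ifelse(is_bg, 28, profiles$ddd_per_package[fills$profile_row]),
      stringsAsFactors = FALSE
    )
    if (!is.na(death_date))
      death_acc[[i]] <- data.frame(patient_id = pid, death_date = death_date,
                                   stringsAsFactors = FALSE)
  }

  records <- do.call(rbind, rec_acc[!vapply(rec_acc, is.null, TRUE)])
  records <- records[order(records$patient_id, records$dispensation_date,
                           records$atc_code), ]
  rownames(records) <- NULL
  deaths <- do.call(rbind, death_acc[!vapply(death_acc, is.null, TRUE)])
  if (is.null(deaths))
    deaths <- data.frame(patient_id = character(), death_date = as.Date(character()))
  rownames(deaths) <- NULL
  truth <- do.call(rbind, truth_acc[!vapply(truth_acc, is.null, TRUE)])
  rownames(truth) <- NULL

  list(records = records, deaths = deaths, truth = truth)
}

#' Write a generated dataset to a directory
#'
#' Emits `records.csv`, `deaths.csv` and `truth.csv` in the package's CSV
#' dialect.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dispensing_records(dataset$records, file.path(dir, "records.csv"))
  write_death_records(dataset$deaths, file.path(dir, "deaths.csv"))
  truth <- dataset$truth
  truth$index_date <- format(truth$index_date, "%Y-%m-%d")
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
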