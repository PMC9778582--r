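# Treatment-episode construction under the grace-period rule, and conversion
# of first episodes into time-to-discontinuation observations.
#
# A treatment episode is a maximal run of dispensations in which every new
# fill arrives within the grace period of the previous one. The grace period
# is a multiple (default 1.5) of the previous dispensation's supply duration,
# so products with different package sizes get proportionally longer leeway.
# Early refills stockpile: a fill arriving before the previous supply is
# exhausted starts counting from the previous supply end.

#' Days of drug supply in each dispensation
#'
#' One DDD covers one day of standard maintenance therapy, so the supply
#' duration is the dispensed DDD total: packages times DDD per package.
#'
#' @param records data.frame with `n_packages` and `ddd_per_package`.
#' @return numeric vector of supply durations in days.
#' @export
supply_duration <- function(records) {
  out <- records$n_packages * records$ddd_per_package
  if (any(!is.finite(out) | out <= 0))
    stop("non-positive supply duration")
  out
}

#' Grace period for a dispensation
#'
#' @param duration_days supply duration(s) in days (> 0).
#' @param multiplier grace multiplier (> 0), default 1.5.
#' @return numeric vector: `multiplier * duration_days`.
#' @export
grace_period <- function(duration_days, multiplier = 1.5) {
  if (any(multiplier <= 0)) stop("grace multiplier must be > 0")
  if (any(duration_days <= 0)) stop("duration_days must be > 0")
  multiplier * duration_days
}

#' Build supply spans from dispensing records
#'
#' Keeps study-drug fills, keys them by drug name or pharmacological class,
#' and merges same-day dispensations of the same key into one span with the
#' summed duration.
#'
#' @param records validated dispensing records.
#' @param level `"drug"` or `"class"` grouping.
#' @param config a [study_config()] object.
#' @return data.frame (`patient_id`, `key`, `start`, `duration_days`) sorted
#'   by patient, key and start date.
#' @export
make_supply_spans <- function(records, level = c("drug", "class"),
                              config = study_config()) {
  level <- match.arg(level)
  cls <- classify_atc(records$atc_code, config$class_map)
  keep <- !is.na(cls)
  df <- data.frame(
    patient_id = records$patient_id[keep],
    key = if (level == "drug") records$drug_name[keep] else cls[keep],
    start = records$dispensation_date[keep],
    duration_days = supply_duration(records[keep, , drop = FALSE]),
    stringsAsFactors = FALSE
  )
  agg <- stats::aggregate(duration_days ~ patient_id + key + start, df, sum)
  agg <- agg[order(agg$patient_id, agg$key, agg$start), ]
  rownames(agg) <- NULL
  agg
}

#' Build treatment episodes for one patient
#'
#' Scans each key's spans in date order. A fill at date `d` continues the
#' current episode iff its gap from the previous fill is within the grace
#' period of the previous dispensation (with `gap_anchor = "fill"`, the gap
#' is `d` minus the previous dispensation date; with `"supply_end"`, `d`
#' minus the previous supply end, against the grace allowance beyond the
#' supply). Otherwise the episode closes with `terminated_by = "gap"` and a
#' new one opens at `d`. An early refill's effective start is the previous
#' supply end (stockpiling carry-over, capped at `stockpile_cap` days of
#' oversupply).
#'
#' @param spans one patient's spans (`key`, `start`, `duration_days`), sorted
#'   by start date within key; unsorted input is an error, not silently
#'   sorted.
#' @param config a [study_config()] object.
#' @param death_date optional death date; a final episode whose supply covers
#'   it is terminated by `"death"`.
#' @param followup_end optional follow-up end; when supplied, a final episode
#'   whose supply end plus its last grace period reaches it is
#'   `"censored_alive"`.
#' @return data.frame of episodes: `key`, `episode_start`, `supply_end`,
#'   `n_dispensations`, `last_fill`, `last_duration`, `terminated_by`.
#' @export
build_episodes <- function(spans, config = study_config(),
                           death_date = NULL, followup_end = NULL) {
  if (!nrow(spans)) stop("no spans to build episodes from")
  out <- list()
  for (k in unique(spans$key)) {
    s <- spans[spans$key == k, , drop = FALSE]
    if (is.unsorted(as.numeric(s$start), strictly = FALSE))
      stop("spans must be sorted by start date within key '", k, "'")
    ep_start <- s$start[1]
    supply_end <- s$start[1] + ceiling(s$duration_days[1])
    last_fill <- s$start[1]
    last_dur <- s$duration_days[1]
    n_disp <- 1L
    close <- function(term) {
      out[[length(out) + 1]] <<- data.frame(
        key = k, episode_start = ep_start, supply_end = supply_end,
        n_dispensations = n_disp, last_fill = last_fill,
        last_duration = last_dur, terminated_by = term,
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(s))[-1]) {
      d <- s$start[i]
      within_grace <- if (config$gap_anchor == "fill") {
        as.numeric(d - last_fill) <= grace_period(last_dur, config$grace_multiplier)
      } else {
        as.numeric(d - supply_end) <=
          (config$grace_multiplier - 1) * last_dur
      }
      if (within_grace) {
        carry <- min(supply_end, d + config$stockpile_cap)
        eff_start <- if (as.numeric(carry - d) > 0) carry else d
        supply_end <- eff_start + ceiling(s$duration_days[i])
        last_fill <- d
        last_dur <- s$duration_days[i]
        n_disp <- n_disp + 1L
      } else {
        close("gap")
        ep_start <- d
        supply_end <- d + ceiling(s$duration_days[i])
        last_fill <- d
        last_dur <- s$duration_days[i]
        n_disp <- 1L
      }
    }
    fu_end <- followup_end %||% (s$start[1] + config$followup_days)
    term <- if (!is.null(death_date) && !is.na(death_date) &&
                  death_date >= ep_start && death_date <= supply_end) {
      "death"
    } else if (as.numeric(supply_end - fu_end) +
                 grace_period(last_dur, config$grace_multiplier) > 0) {
      "censored_alive"
    } else {
      "gap"
    }
    close(term)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Time to first discontinuation from a patient's episodes
#'
#' Persistence is the time from the first episode's start (the index fill for
#' that key) to the first discontinuation. The first episode yields an event
#' if it closes with a gap before the follow-up horizon (time = supply end
#' minus episode start) or if the patient dies while supplied (time = death
#' minus episode start); it is censored at `followup_days` if its supply end
#' plus its last grace period extends past the horizon. Whichever of gap and
#' death comes first wins.
#'
#' @param episodes episodes of one (patient, key), from [build_episodes()].
#' @param config a [study_config()] object.
#' @param death_date optional death date.
#' @return list with `time_days` (integer in `[0, followup_days]`), `event`
#'   (1 discontinued / 0 censored) and `cause` (`"gap"`, `"death"` or
#'   `"censored"`).
#' @export
time_to_discontinuation <- function(episodes, config = study_config(),
                                    death_date = NULL) {
  if (!nrow(episodes)) stop("no episodes")
  first <- episodes[1, ]
  s <- first$episode_start
  horizon <- config$followup_days

  t_gap <- if (nrow(episodes) > 1) {
    as.numeric(first$supply_end - s)  # a later fill fell beyond the grace period
  } else if (as.numeric(first$supply_end - s) +
               grace_period(first$last_duration, config$grace_multiplier) <=
               horizon) {
    as.numeric(first$supply_end - s)
  } else {
    Inf
  }
  t_death <- if (!is.null(death_date) && !is.na(death_date) &&
                   death_date >= s &&
                   as.numeric(death_date - first$supply_end) <= 0) {
    as.numeric(death_date - s)
  } else {
    Inf
  }
  t <- min(t_gap, t_death)
  if (t >= horizon) {
    list(time_days = as.integer(horizon), event = 0L, cause = "censored")
  } else {
    list(time_days = as.integer(t), event = 1L,
         cause = if (t_death <= t_gap) "death" else "gap")
  }
}

#' Persistence observations for a whole cohort
#'
#' For every cohort member and every key (drug or class) the member filled
#' during follow-up, builds the episodes from that key's first fill onward
#' and emits one time-to-discontinuation observation. Each key is followed
#' for `followup_days` from its own first fill; drug-level observations use
#' that drug's fills only, so a within-class switcher discontinues drug A and
#' contributes to drug B from B's first fill.
#'
#' @param records validated dispensing records.
#' @param cohort cohort data.frame from [select_cohort()].
#' @param config a [study_config()] object.
#' @param level `"class"` or `"drug"`.
#' @return data.frame: `patient_id`, `level`, `key`, `time_days`, `event`,
#'   `cause`, `age_group`, `young_old`.
#' @export
persistence_observations <- function(records, cohort,
                                     config = study_config(),
                                     level = c("class", "drug")) {
  level <- match.arg(level)
  spans <- make_supply_spans(records, level, config)
  span_idx <- split(seq_len(nrow(spans)), spans$patient_id)

  rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$patient_id[i]
    idx <- span_idx[[pid]]
    if (is.null(idx)) next
    sp <- spans[idx, , drop = FALSE]
    sp <- sp[sp$start >= cohort$index_date[i], , drop = FALSE]
    if (!nrow(sp)) next
    death <- cohort$death_date[i]
    obs <- lapply(unique(sp$key), function(k) {
      ks <- sp[sp$key == k, , drop = FALSE]
      horizon_end <- ks$start[1] + config$followup_days
      ks <- ks[ks$start < horizon_end, , drop = FALSE]
      eps <- build_episodes(ks, config, death_date = death,
                            followup_end = horizon_end)
      td <- time_to_discontinuation(eps, config, death_date = death)
      data.frame(patient_id = pid, level = level, key = k,
                 time_days = td$time_days, event = td$event, cause = td$cause,
                 age_group = as.character(cohort$age_group[i]),
                 young_old = cohort$young_old[i], stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, obs)
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(res) <- NULL
  res
}
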