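# Dispensing-record I/O and study configuration.
#
# A dispensing record is one pharmacy dispensation event reimbursed by the
# health system: who received what drug, when, and how many Defined Daily
# Doses (DDDs) the dispensed packages contain. DDD content is the link between
# a dispensation and days of drug supply.

RECORD_COLUMNS <- c(
  "patient_id", "birth_date", "sex", "dispensation_date",
  "atc_code", "drug_name", "n_packages", "ddd_per_package"
)

ATC7_REGEX <- "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"

#' The seven study drugs
#'
#' Alpha-1-adrenoceptor antagonists (class AB) and steroid 5-alpha-reductase
#' inhibitors (class 5ARI) used to treat BPH/BPO-associated lower urinary
#' tract symptoms, with their ATC codes. Doxazosin is classified under the
#' cardiovascular chapter (C02CA04) by the WHO but is an AB in this indication.
#'
#' @return data.frame with columns `drug_name`, `atc_code`, `class`.
#' @export
study_drugs <- function() {
  data.frame(
    drug_name = c("alfuzosin", "doxazosin", "silodosin", "tamsulosin",
                  "terazosin", "finasteride", "dutasteride"),
    atc_code  = c("G04CA01", "C02CA04", "G04CA04", "G04CA02",
                  "G04CA03", "G04CB01", "G04CB02"),
    class     = c(rep("AB", 5), rep("5ARI", 2)),
    stringsAsFactors = FALSE
  )
}

#' Default ATC class map
#'
#' Maps ATC code prefixes to pharmacological class labels; matching is by
#' longest prefix, so a full-code entry overrides a chapter prefix.
#'
#' @return named character vector (names are ATC prefixes, values class labels).
#' @export
default_class_map <- function() {
  c("G04CA" = "AB", "G04CB" = "5ARI", "C02CA04" = "AB")
}

#' Classify ATC codes into study drug classes
#'
#' @param atc_code character vector of ATC codes.
#' @param class_map named character vector of prefix -> class label.
#' @return character vector of class labels, `NA` where no prefix matches.
#' @export
classify_atc <- function(atc_code, class_map = default_class_map()) {
  out <- rep(NA_character_, length(atc_code))
  for (k in names(class_map)[order(-nchar(names(class_map)))]) {
    hit <- is.na(out) & startsWith(as.character(atc_code), k)
    out[hit] <- unname(class_map[[k]])
  }
  out
}

#' Study configuration
#'
#' All tunable parameters of the persistence analysis. Defaults encode the
#' study design: men aged >= 40 years on 1 April 2018, a wash-out period
#' 1 January - 31 March 2018 to restrict to new users, 365 days of required
#' database history and of follow-up, at least 2 dispensations for chronic
#' use, and a grace period of 1.5 times each dispensation's supply duration.
#' All intervals are half-open `[start, end)` and durations are day counts.
#'
#' @param reference_date date at which age is evaluated.
#' @param min_age_years minimum age in completed years.
#' @param index_start,index_end index period (first-fill window), half-open.
#' @param washout_start,washout_end wash-out window, half-open; `washout_end`
#'   must equal `index_start`.
#' @param min_history_days required days of database history before index.
#' @param followup_days follow-up horizon per subject (days).
#' @param min_prescriptions minimum distinct dispensation dates for chronic use.
#' @param per_drug_prescriptions if `TRUE`, the chronic-use threshold is
#'   applied per drug rather than per subject.
#' @param grace_multiplier grace period as a multiple of the supply duration.
#' @param gap_anchor `"fill"` (default) measures refill gaps between
#'   dispensation dates; `"supply_end"` measures them from the end of supply.
#' @param stockpile_cap maximum days of forward-carried oversupply (default
#'   `Inf`, i.e. uncapped stockpiling).
#' @param class_map named prefix -> class label map, see [default_class_map()].
#' @param age_group_edges strictly increasing integer edges for age groups.
#' @param young_old_cut age (years) separating younger from older men.
#' @return object of class `study_config` (a validated list).
#' @export
study_config <- function(reference_date = "2018-04-01",
                         min_age_years = 40,
                         index_start = "2018-04-01",
                         index_end = "2019-04-01",
                         washout_start = "2018-01-01",
                         washout_end = "2018-04-01",
                         min_history_days = 365,
                         followup_days = 365,
                         min_prescriptions = 2,
                         per_drug_prescriptions = FALSE,
                         grace_multiplier = 1.5,
                         gap_anchor = c("fill", "supply_end"),
                         stockpile_cap = Inf,
                         class_map = default_class_map(),
                         age_group_edges = c(40, 50, 60, 70, 80, 90, 101),
                         young_old_cut = 70) {
  cfg <- list(
    reference_date = as.Date(reference_date),
    min_age_years = as.integer(min_age_years),
    index_start = as.Date(index_start),
    index_end = as.Date(index_end),
    washout_start = as.Date(washout_start),
    washout_end = as.Date(washout_end),
    min_history_days = as.integer(min_history_days),
    followup_days = as.integer(followup_days),
    min_prescriptions = as.integer(min_prescriptions),
    per_drug_prescriptions = isTRUE(per_drug_prescriptions),
    grace_multiplier = as.numeric(grace_multiplier),
    gap_anchor = match.arg(gap_anchor),
    stockpile_cap = as.numeric(stockpile_cap),
    class_map = class_map,
    age_group_edges = as.integer(age_group_edges),
    young_old_cut = as.integer(young_old_cut)
  )
  validate_config(cfg)
  class(cfg) <- "study_config"
  cfg
}

validate_config <- function(cfg) {
  if (is.na(cfg$grace_multiplier) || cfg$grace_multiplier <= 0)
    stop("grace_multiplier must be > 0")
  if (is.na(cfg$min_age_years) || cfg$min_age_years < 0)
    stop("min_age_years must be >= 0")
  if (cfg$index_start != cfg$washout_end)
    stop("index_start must equal washout_end (contiguous wash-out and index periods)")
  if (cfg$index_end <= cfg$index_start) stop("index period must be non-empty")
  if (cfg$washout_end <= cfg$washout_start) stop("wash-out window must be non-empty")
  edges <- cfg$age_group_edges
  if (length(edges) < 2 || any(diff(edges) <= 0))
    stop("age_group_edges must be strictly increasing with at least two edges")
  if (cfg$followup_days < 1) stop("followup_days must be >= 1")
  if (cfg$min_prescriptions < 1) stop("min_prescriptions must be >= 1")
  if (cfg$min_history_days < 0) stop("min_history_days must be >= 0")
  if (!length(cfg$class_map) || is.null(names(cfg$class_map)))
    stop("class_map must be a named vector")
  invisible(cfg)
}

#' Load a study configuration from a YAML file
#'
#' Keys absent from the file take the defaults of [study_config()]; unknown
#' keys are an error. An empty file yields the full default configuration.
#'
#' @param path path to a YAML document with `study_config` keys.
#' @return a `study_config` object.
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(study_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(vals$class_map)) vals$class_map <- unlist(vals$class_map)
  do.call(study_config, vals)
}

#' Validate dispensing records
#'
#' Checks every row against the record invariants. Malformed rows are not
#' silently dropped: they are returned in a rejects report with the reason
#' for rejection.
#'
#' @param df data.frame with the columns named in the record schema
#'   (`patient_id`, `birth_date`, `sex`, `dispensation_date`, `atc_code`,
#'   `drug_name`, `n_packages`, `ddd_per_package`).
#' @return list with `records` (typed, valid rows) and `rejects` (raw rows
#'   plus a `reason` column).
#' @export
validate_records <- function(df) {
  missing <- setdiff(RECORD_COLUMNS, names(df))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  df <- df[, RECORD_COLUMNS, drop = FALSE]

  n <- nrow(df)
  reason <- rep(NA_character_, n)
  flag <- function(bad, why) reason[is.na(reason) & bad] <<- why

  pid <- as.character(df$patient_id)
  flag(is.na(pid) | !nzchar(pid), "missing patient id")
  birth <- parse_iso_date(df$birth_date)
  flag(is.na(birth), "unparseable birth date")
  disp <- parse_iso_date(df$dispensation_date)
  flag(is.na(disp), "unparseable dispensation date")
  sex <- as.character(df$sex)
  flag(!sex %in% c("M", "F"), "invalid sex code")
  npk <- suppressWarnings(as.numeric(df$n_packages))
  flag(!is.finite(npk) | npk < 1 | npk %% 1 != 0, "non-positive package count")
  ddd <- suppressWarnings(as.numeric(df$ddd_per_package))
  flag(!is.finite(ddd) | ddd <= 0, "non-positive DDD per package")
  flag(!is.na(birth) & !is.na(disp) & disp < birth, "dispensation precedes birth date")
  atc <- as.character(df$atc_code)
  flag(is.na(atc) | !nzchar(atc) |
         (nchar(atc) == 7 & !grepl(ATC7_REGEX, atc)), "malformed ATC code")

  ok <- is.na(reason)
  records <- data.frame(
    patient_id = pid[ok],
    birth_date = birth[ok],
    sex = sex[ok],
    dispensation_date = disp[ok],
    atc_code = atc[ok],
    drug_name = as.character(df$drug_name)[ok],
    n_packages = as.integer(npk[ok]),
    ddd_per_package = ddd[ok],
    stringsAsFactors = FALSE
  )
  rownames(records) <- NULL
  rejects <- cbind(df[!ok, , drop = FALSE], reason = reason[!ok])
  rownames(rejects) <- NULL
  list(records = records, rejects = rejects)
}

#' Read dispensing records from CSV
#'
#' Comma-separated, UTF-8, ISO-8601 dates; `.gz` paths are read transparently.
#' Rows violating record invariants are collected in the rejects report.
#'
#' @param path CSV file with a header naming the record schema columns.
#' @return list with `records` and `rejects`, see [validate_records()].
#' @export
read_dispensing_records <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_records(raw)
}

#' Write dispensing records to CSV
#'
#' Canonical column order and ISO-8601 dates, so that a write -> read round
#' trip reproduces the record sequence exactly. `.gz` paths are compressed.
#'
#' @param records validated record data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dispensing_records <- function(records, path) {
  out <- records[, RECORD_COLUMNS]
  out$birth_date <- format(out$birth_date, "%Y-%m-%d")
  out$dispensation_date <- format(out$dispensation_date, "%Y-%m-%d")
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "w")
    on.exit(close(con))
    utils::write.csv(out, con, row.names = FALSE)
  } else {
    utils::write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read death records from CSV
#'
#' Optional companion table (`patient_id`, `death_date`) so that death can be
#' treated as a cause of non-persistence.
#'
#' @param path CSV file.
#' @return data.frame with `patient_id` (character) and `death_date` (Date).
#' @export
read_death_records <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(c("patient_id", "death_date"), names(raw))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  dd <- parse_iso_date(raw$death_date)
  if (anyNA(dd)) stop("unparseable death date(s) in ", path)
  data.frame(patient_id = as.character(raw$patient_id), death_date = dd,
             stringsAsFactors = FALSE)
}

#' Write death records to CSV
#'
#' @param deaths data.frame with `patient_id` and `death_date`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_death_records <- function(deaths, path) {
  out <- data.frame(patient_id = deaths$patient_id,
                    death_date = format(deaths$death_date, "%Y-%m-%d"))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
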