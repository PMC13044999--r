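# Seeded synthetic PDMS fixture with injected documentation pathologies and
# retained ground truth.
#
# The generator emulates the transaction-oriented, denormalized layout of an
# ICU patient-data-management system: patients, cases (with perioperative
# timestamps on the case record), bed occupancy, observations (vitals plus
# point-of-care analytes with a specimen context), medication records
# documented heterogeneously as volume / dose / rate WITHOUT explicit
# concentrations, fragmented therapy interval records, and internal drug and
# variable catalogs. All stored timestamps are UTC ISO-8601 at second
# resolution. The hidden truth (episodes, infusion rates, identity map,
# conflicted cases) is retained so downstream reconstruction can be scored.

DEVICE_TYPES <- c("ECMO", "dialysis", "microaxial_pump", "IABP")

#' Configuration for the synthetic PDMS generator
#'
#' Defaults are the study conditions the fixture emulates: 266 medication
#' records per case on average (the observed drugs-per-case density of a
#' transformation-heavy ICU extraction), a 30% chance that a therapy record
#' lacks its end timestamp, a 50% chance of duplicate "reverification"
#' entries for an ongoing therapy, and a case-to-multiple-patient identifier
#' inconsistency rate of 1/1838.
#'
#' @param n_cases Number of ICU cases (>= 1).
#' @param seed Integer seed; identical config + seed gives an identical
#'   fixture.
#' @param p_missing_end Probability that a therapy record's end timestamp is
#'   absent.
#' @param p_reverify Probability that a therapy receives additional
#'   overlapping reverification records.
#' @param mean_drug_events_per_case Mean medication records per case.
#' @param p_case_patient_conflict Probability that a case maps to more than
#'   one patient identifier; the generator realizes exactly
#'   `round(n_cases * p)` conflicted cases.
#' @param date_range Closed interval of calendar dates (length-2 character or
#'   Date) within which admissions start.
#' @return An object of class `pdms_synthetic_config`.
#' @export
synthetic_config <- function(n_cases = 100L,
                             seed = 1L,
                             p_missing_end = 0.3,
                             p_reverify = 0.5,
                             mean_drug_events_per_case = 266,
                             p_case_patient_conflict = 1 / 1838,
                             date_range = c("2024-01-01", "2024-06-30")) {
  probs <- c(p_missing_end = p_missing_end, p_reverify = p_reverify,
             p_case_patient_conflict = p_case_patient_conflict)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    pdms_error("pdms_configuration_error", "probabilities must lie in [0, 1]")
  }
  if (!is.finite(n_cases) || n_cases < 1) {
    pdms_error("pdms_configuration_error", "n_cases must be >= 1")
  }
  if (!is.finite(mean_drug_events_per_case) || mean_drug_events_per_case <= 0) {
    pdms_error("pdms_configuration_error",
               "mean_drug_events_per_case must be positive")
  }
  date_range <- as.Date(date_range)
  if (length(date_range) != 2L || any(is.na(date_range)) ||
      date_range[1L] > date_range[2L]) {
    pdms_error("pdms_configuration_error", "date_range must be a valid closed interval")
  }
  structure(
    list(n_cases = as.integer(n_cases), seed = as.integer(seed),
         p_missing_end = p_missing_end, p_reverify = p_reverify,
         mean_drug_events_per_case = mean_drug_events_per_case,
         p_case_patient_conflict = p_case_patient_conflict,
         date_range = date_range),
    class = "pdms_synthetic_config"
  )
}

with_preserved_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rsec <- function(n, from, to) {
  # random whole-second instants between two POSIXct bounds
  as.POSIXct(round(stats::runif(n, as.numeric(from), as.numeric(to))),
             origin = "1970-01-01", tz = "UTC")
}

.load_csv <- function(name) {
  utils::read.csv(system.file("extdata", name, package = "pdmsetl"),
                  stringsAsFactors = FALSE, encoding = "UTF-8")
}

#' Inject documentation pathologies into raw therapy records
#'
#' Emulates the two documentation pathologies of interval-based therapy
#' records: with probability `p_missing_end` a record loses its end
#' timestamp, and with probability `p_reverify` one or two additional
#' overlapping "reverification" records for the same treatment are appended
#' (sharing the possibly-nulled end). Ground-truth linkage is preserved via
#' the `episode_id` column. Uses the current RNG state; seed before calling
#' for reproducibility.
#'
#' @param records Data frame with columns `record_id`, `case_id`,
#'   `device_type`, `start_ts`, `end_ts` (`POSIXct`, UTC) and `episode_id`.
#' @param config A [synthetic_config()].
#' @return Data frame of the same columns plus `missing_end` (end nulled on
#'   this originally documented record) and `is_reverify`.
#' @export
inject_pathologies <- function(records, config) {
  n <- nrow(records)
  records$missing_end <- FALSE
  records$is_reverify <- FALSE
  if (n == 0L) return(records)
  # coverage upper bound used to place reverification times
  upper <- ifelse(is.na(records$end_ts),
                  as.numeric(records$start_ts) + 24 * 3600,
                  as.numeric(records$end_ts))
  drop_end <- stats::runif(n) < config$p_missing_end
  records$missing_end <- drop_end & !is.na(records$end_ts)
  records$end_ts[records$missing_end] <- NA
  reverify <- stats::runif(n) < config$p_reverify
  extra <- list()
  for (i in which(reverify)) {
    k <- 1L + stats::rbinom(1L, 1L, 0.3)
    t <- rsec(k, records$start_ts[i] + 1, upper[i] - 1)
    dup <- records[rep(i, k), , drop = FALSE]
    dup$start_ts <- t
    dup$is_reverify <- TRUE
    dup$missing_end <- FALSE
    extra[[length(extra) + 1L]] <- dup
  }
  if (length(extra)) {
    records <- rbind(records, do.call(rbind, extra))
  }
  records$record_id <- sprintf("T%06d", seq_len(nrow(records)))
  rownames(records) <- NULL
  records
}

# ---- generator internals ----------------------------------------------------

.gen_patients_cases <- function(config) {
  n_cases <- config$n_cases
  n_twice <- min(round(0.08 * n_cases), floor(n_cases / 2))
  n_patients <- n_cases - n_twice
  first <- c("Anna", "Ben", "Clara", "David", "Emma", "Felix", "Greta",
             "Henrik", "Ida", "Jonas", "Katharina", "Lukas", "Marie",
             "Niklas", "Olga", "Paul", "Ronja", "Stefan", "Theresa", "Viktor")
  last <- c("Bauer", "Fischer", "Hoffmann", "Keller", "Lang", "Meyer",
            "Neumann", "Richter", "Schmidt", "Vogel", "Wagner", "Weber",
            "Winkler", "Wolf", "Zimmermann")
  patients <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n_patients)),
    name = paste(sample(first, n_patients, replace = TRUE),
                 sample(last, n_patients, replace = TRUE)),
    date_of_birth = as.character(as.Date("1935-01-01") +
      sample.int(as.integer(as.Date("2006-01-01") - as.Date("1935-01-01")),
                 n_patients, replace = TRUE)),
    sex = sample(c("f", "m", "d"), n_patients, replace = TRUE,
                 prob = c(0.48, 0.50, 0.02)),
    stringsAsFactors = FALSE
  )
  range_start <- as.POSIXct(paste0(config$date_range[1L], " 00:00:00"), tz = "UTC")
  range_end <- as.POSIXct(paste0(config$date_range[2L], " 23:59:59"), tz = "UTC")
  # patients 1..n_twice get two cases; admission windows per patient are
  # generated sequentially with a positive gap, so they can never overlap
  owner <- c(seq_len(n_patients), seq_len(n_twice))
  cases <- vector("list", length(owner))
  next_free <- rep(as.numeric(range_start), n_patients)
  ord <- order(owner)  # second visits processed after first visits
  for (idx in ord) {
    p <- owner[idx]
    adm <- next_free[p] +
      stats::runif(1, 0, max(1, as.numeric(range_end) - next_free[p]) * 0.5)
    los <- pmin(pmax(stats::rexp(1, 1 / 5), 0.5), 30) * 86400
    dis <- adm + los
    next_free[p] <- dis + stats::runif(1, 2, 60) * 86400
    cases[[idx]] <- data.frame(patient_id = patients$patient_id[p],
                               admission = round(adm), discharge = round(dis))
  }
  cases <- do.call(rbind, cases)
  cases <- cases[order(cases$admission), , drop = FALSE]
  cases$case_id <- sprintf("C%06d", seq_len(nrow(cases)))
  # ~5% of cases are still on the unit (no discharge yet); only admissible
  # for a patient's chronologically last case
  last_case <- !duplicated(cases$patient_id, fromLast = TRUE)
  ongoing <- last_case & stats::runif(nrow(cases)) < 0.05
  cases$ongoing <- ongoing
  cases$discharge[ongoing] <- NA
  # perioperative (operating room) interval shortly after admission
  or_start <- cases$admission + round(stats::runif(nrow(cases), 1, 6) * 3600)
  or_end <- or_start + round(stats::runif(nrow(cases), 1, 4) * 3600)
  cases$or_start <- or_start
  cases$or_end <- or_end
  cases$ward <- sample(c("ICU-1", "ICU-2", "ICU-3"), nrow(cases), replace = TRUE)
  list(patients = patients, cases = cases)
}

.gen_occupancy <- function(cases) {
  rows <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    a <- cases$admission[i]
    d <- if (cases$ongoing[i]) NA_real_ else cases$discharge[i]
    split <- !is.na(d) && stats::runif(1) < 0.3
    if (split) {
      m <- round(a + stats::runif(1, 0.2, 0.8) * (d - a))
      rows[[i]] <- data.frame(case_id = cases$case_id[i],
                              start = c(a, m), end = c(m, d))
    } else {
      rows[[i]] <- data.frame(case_id = cases$case_id[i], start = a, end = d)
    }
  }
  occ <- do.call(rbind, rows)
  occ$bed_id <- sprintf("B%03d", sample.int(60, nrow(occ), replace = TRUE))
  occ
}

.gen_observations <- function(cases, varcat) {
  gen_one <- function(case, a, d, var, n, rfun, context = NA_character_) {
    d <- if (is.na(d)) a + 86400 else d
    data.frame(case_id = case, variable_id = var$variable_id,
               value = round(rfun(n), 2), unit = var$unit,
               ts = round(stats::runif(n, a, d)),
               context = context, stringsAsFactors = FALSE)
  }
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  dists <- list(
    HR   = function(n) clip(stats::rnorm(n, 85, 15), 40, 160),
    MAP  = function(n) clip(stats::rnorm(n, 75, 12), 40, 130),
    SPO2 = function(n) clip(stats::rnorm(n, 96, 2), 85, 100),
    TEMP = function(n) clip(stats::rnorm(n, 37, 0.6), 35, 40),
    LACT = function(n) clip(stats::rexp(n, 1 / 1.8) + 0.4, 0.4, 12),
    PH   = function(n) clip(stats::rnorm(n, 7.38, 0.05), 7.1, 7.6)
  )
  out <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    per_case <- lapply(seq_len(nrow(varcat)), function(j) {
      var <- varcat[j, ]
      poc <- var$poc == 1
      n <- if (poc) 6L else 10L
      ctx <- if (poc) sample(c("arterial", "venous"), n, replace = TRUE,
                             prob = c(0.7, 0.3)) else NA_character_
      gen_one(cases$case_id[i], cases$admission[i], cases$discharge[i],
              var, n, dists[[var$variable_id]], ctx)
    })
    out[[i]] <- do.call(rbind, per_case)
  }
  obs <- do.call(rbind, out)
  obs$obs_id <- sprintf("O%07d", seq_len(nrow(obs)))
  obs
}

.gen_medications <- function(cases, drugcat, config) {
  counts <- stats::rpois(nrow(cases), config$mean_drug_events_per_case)
  idx <- rep(seq_len(nrow(cases)), counts)
  n <- length(idx)
  if (n == 0L) {
    empty <- data.frame(record_id = character(0), case_id = character(0),
                        drug_id = character(0), doc_format = character(0),
                        value = numeric(0), unit = character(0),
                        start = numeric(0), end = numeric(0))
    return(list(records = empty, true_rates = empty))
  }
  case_id <- cases$case_id[idx]
  a <- cases$admission[idx]
  d <- ifelse(is.na(cases$discharge[idx]), a + 86400, cases$discharge[idx])
  di <- sample.int(nrow(drugcat), n, replace = TRUE)
  doc_format <- sample(c("volume", "dose", "rate"), n, replace = TRUE)
  conc <- drugcat$amount[di] / drugcat$volume_ml[di]
  std_unit <- drugcat$standard_unit[di]
  is_mass <- sub("/h$", "", std_unit) == "mg"
  infusion <- doc_format != "dose"
  # infusions: a true rate over a closed sub-interval of the stay
  dur_h <- stats::runif(n, 0.5, 24)
  start <- round(a + stats::runif(n) * pmax(d - a - dur_h * 3600, 1))
  end <- round(pmin(start + dur_h * 3600, d))
  end <- pmax(end, start + 600)  # at least 10 minutes
  rate <- stats::runif(n, drugcat$rate_min[di], drugcat$rate_max[di])
  # boluses: an amount at one instant, documented in a random same-dimension unit
  amount <- stats::runif(n, drugcat$bolus_min[di], drugcat$bolus_max[di])
  alt_unit <- ifelse(is_mass,
                     ifelse(stats::runif(n) < 0.3, "ug", "mg"),
                     ifelse(stats::runif(n) < 0.3, "IU", "U"))
  base_unit <- ifelse(is_mass, "mg", "U")
  amount_doc <- ifelse(alt_unit == "ug", amount * 1000, amount)
  value <- numeric(n)
  unit <- character(n)
  vol <- doc_format == "volume"
  rat <- doc_format == "rate"
  dos <- doc_format == "dose"
  value[rat] <- rate[rat] / conc[rat]                # mL/h
  unit[rat] <- "mL/h"
  dur_hours <- (end - start) / 3600
  value[vol] <- rate[vol] * dur_hours[vol] / conc[vol]  # mL over the interval
  unit[vol] <- "mL"
  value[dos] <- amount_doc[dos]
  unit[dos] <- alt_unit[dos]
  start[dos] <- round(stats::runif(sum(dos), a[dos], d[dos]))
  end[dos] <- NA
  records <- data.frame(
    record_id = sprintf("M%07d", seq_len(n)),
    case_id = case_id, drug_id = drugcat$drug_id[di],
    doc_format = doc_format, value = value, unit = unit,
    start = start, end = end, stringsAsFactors = FALSE
  )
  true_rates <- data.frame(
    case_id = case_id[infusion],
    drug_id = drugcat$drug_id[di][infusion],
    ingredient = drugcat$ingredient[di][infusion],
    start = start[infusion], end = end[infusion],
    rate = rate[infusion], unit = std_unit[infusion],
    stringsAsFactors = FALSE
  )
  true_bolus <- data.frame(
    case_id = case_id[dos], drug_id = drugcat$drug_id[di][dos],
    ingredient = drugcat$ingredient[di][dos],
    ts = start[dos], amount = amount[dos], unit = base_unit[dos],
    stringsAsFactors = FALSE
  )
  list(records = records, true_rates = true_rates, true_boluses = true_bolus)
}

.gen_therapies <- function(cases, occupancy, config) {
  eps <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    if (stats::runif(1) >= 0.4) next
    devs <- sample(DEVICE_TYPES, sample(1:2, 1))
    occ <- occupancy[occupancy$case_id == cases$case_id[i], , drop = FALSE]
    per_dev <- lapply(devs, function(dev) {
      k <- sample.int(nrow(occ), 1L)
      os <- occ$start[k]
      oe <- if (is.na(occ$end[k])) NA_real_ else occ$end[k]
      eff_end <- if (is.na(oe)) os + 30 * 86400 else oe
      s <- round(os + stats::runif(1, 0, 0.5) * (eff_end - os))
      dur <- stats::runif(1, 6, 96) * 3600
      e <- round(min(s + max(dur, 3600), eff_end))
      data.frame(case_id = cases$case_id[i], device_type = dev,
                 start = s,
                 end = if (is.na(oe)) NA_real_ else e,
                 stringsAsFactors = FALSE)
    })
    eps[[i]] <- do.call(rbind, per_dev)
  }
  eps <- do.call(rbind, eps)
  if (is.null(eps)) {
    eps <- data.frame(case_id = character(0), device_type = character(0),
                      start = numeric(0), end = numeric(0))
  }
  eps$episode_id <- sprintf("E%05d", seq_len(max(nrow(eps), 0L)))[seq_len(nrow(eps))]
  eps
}

#' Generate a synthetic PDMS fixture with ground truth
#'
#' Creates a single-file SQLite database with the tables `patients`, `cases`,
#' `bed_occupancy`, `observations`, `medication_records`, `therapy_records`,
#' `drug_catalog` and `variable_catalog`, applies the configured
#' documentation pathologies, writes the hidden truth as JSON next to the
#' fixture, and returns a read-only handle plus the [GroundTruth] object.
#'
#' A therapy whose end timestamp is dropped is, in the emulated world, a
#' therapy that kept running until the enclosing bed-occupancy interval
#' closed (staff never terminate a record for a therapy still active at
#' transfer): its true episode end is the occupancy end, or remains open when
#' the bed is still occupied.
#'
#' @param config A [synthetic_config()].
#' @param path Filesystem path for the SQLite fixture file.
#' @return List with `handle` (read-only [connect_readonly()] handle),
#'   `ground_truth` (class `pdms_ground_truth`: `true_episodes`,
#'   `true_rates`, `true_boluses`, `identity_map`, `conflicted_cases`),
#'   `path` and `ground_truth_path`.
#' @export
generate_fixture <- function(config, path) {
  if (!inherits(config, "pdms_synthetic_config")) {
    pdms_error("pdms_configuration_error", "config must be a pdms_synthetic_config")
  }
  if (!dir.exists(dirname(path)) || file.access(dirname(path), 2L) != 0L) {
    pdms_error("pdms_io_error", sprintf("path not writable: %s", path))
  }
  drugcat <- .load_csv("drug_catalog.csv")
  varcat <- .load_csv("variable_catalog.csv")
  with_preserved_rng(config$seed, {
    pc <- .gen_patients_cases(config)
    occupancy <- .gen_occupancy(pc$cases)
    obs <- .gen_observations(pc$cases, varcat)
    meds <- .gen_medications(pc$cases, drugcat, config)
    episodes <- .gen_therapies(pc$cases, occupancy, config)

    records <- data.frame(
      record_id = sprintf("T%06d", seq_len(nrow(episodes)))[seq_len(nrow(episodes))],
      case_id = episodes$case_id, device_type = episodes$device_type,
      start_ts = as.POSIXct(episodes$start, origin = "1970-01-01", tz = "UTC"),
      end_ts = as.POSIXct(episodes$end, origin = "1970-01-01", tz = "UTC"),
      episode_id = episodes$episode_id, stringsAsFactors = FALSE
    )
    records <- inject_pathologies(records, config)

    # truth adjustment for the missing-end pathology: the therapy truly ran
    # until its bed-occupancy interval ended (open occupancy -> ongoing)
    nulled <- records$episode_id[records$missing_end]
    for (ep in nulled) {
      j <- which(episodes$episode_id == ep)
      occ <- occupancy[occupancy$case_id == episodes$case_id[j], , drop = FALSE]
      k <- which(occ$start <= episodes$start[j] &
                   (is.na(occ$end) | episodes$start[j] < occ$end))
      episodes$end[j] <- if (length(k) && !is.na(occ$end[k[1L]])) {
        occ$end[k[1L]]
      } else NA_real_
    }

    # identifier-inconsistency pathology: a deterministic number of cases
    # additionally appears under a second ("ghost") patient identifier
    n_conf <- round(config$n_cases * config$p_case_patient_conflict)
    conflicted <- character(0)
    patients <- pc$patients
    cases_tbl <- pc$cases
    extra_case_rows <- NULL
    if (n_conf > 0L) {
      conflicted <- sort(sample(cases_tbl$case_id, n_conf))
      ghost <- data.frame(
        patient_id = sprintf("P9%04d", seq_len(n_conf)),
        name = paste("Ghost", sprintf("Duplicate%02d", seq_len(n_conf))),
        date_of_birth = "1970-01-01", sex = "d", stringsAsFactors = FALSE
      )
      patients <- rbind(patients, ghost)
      extra_case_rows <- cases_tbl[match(conflicted, cases_tbl$case_id), , drop = FALSE]
      extra_case_rows$patient_id <- ghost$patient_id
    }

    iso <- function(x) {
      format_utc(as.POSIXct(x, origin = "1970-01-01", tz = "UTC"))
    }
    cases_out <- data.frame(
      case_id = cases_tbl$case_id, patient_id = cases_tbl$patient_id,
      admission_ts = iso(cases_tbl$admission),
      discharge_ts = iso(cases_tbl$discharge),
      ward = cases_tbl$ward,
      or_start_ts = iso(cases_tbl$or_start), or_end_ts = iso(cases_tbl$or_end),
      stringsAsFactors = FALSE
    )
    if (!is.null(extra_case_rows)) {
      extra_out <- data.frame(
        case_id = extra_case_rows$case_id, patient_id = extra_case_rows$patient_id,
        admission_ts = iso(extra_case_rows$admission),
        discharge_ts = iso(extra_case_rows$discharge),
        ward = extra_case_rows$ward,
        or_start_ts = iso(extra_case_rows$or_start),
        or_end_ts = iso(extra_case_rows$or_end),
        stringsAsFactors = FALSE
      )
      cases_out <- rbind(cases_out, extra_out)
    }
    occupancy_out <- data.frame(
      case_id = occupancy$case_id, bed_id = occupancy$bed_id,
      start_ts = iso(occupancy$start), end_ts = iso(occupancy$end),
      stringsAsFactors = FALSE
    )
    obs_out <- data.frame(
      obs_id = obs$obs_id, case_id = obs$case_id,
      variable_id = obs$variable_id, value = obs$value, unit = obs$unit,
      ts = iso(obs$ts), context = obs$context, stringsAsFactors = FALSE
    )
    meds_out <- data.frame(
      record_id = meds$records$record_id, case_id = meds$records$case_id,
      drug_id = meds$records$drug_id, doc_format = meds$records$doc_format,
      value = meds$records$value, unit = meds$records$unit,
      start_ts = iso(meds$records$start), end_ts = iso(meds$records$end),
      stringsAsFactors = FALSE
    )
    therapy_out <- data.frame(
      record_id = records$record_id, case_id = records$case_id,
      device_type = records$device_type,
      start_ts = format_utc(records$start_ts), end_ts = format_utc(records$end_ts),
      stringsAsFactors = FALSE
    )
    therapy_out <- therapy_out[order(therapy_out$case_id,
                                     therapy_out$device_type,
                                     therapy_out$start_ts,
                                     therapy_out$record_id), , drop = FALSE]

    if (file.exists(path)) file.remove(path)
    con <- DBI::dbConnect(RSQLite::SQLite(), path)
    on.exit(DBI::dbDisconnect(con), add = TRUE)
    DBI::dbWriteTable(con, "patients", patients)
    DBI::dbWriteTable(con, "cases", cases_out)
    DBI::dbWriteTable(con, "bed_occupancy", occupancy_out)
    DBI::dbWriteTable(con, "observations", obs_out)
    DBI::dbWriteTable(con, "medication_records", meds_out)
    DBI::dbWriteTable(con, "therapy_records", therapy_out)
    DBI::dbWriteTable(con, "drug_catalog",
                      drugcat[, c("drug_id", "ingredient", "amount",
                                  "amount_unit", "volume_ml", "standard_unit")])
    DBI::dbWriteTable(con, "variable_catalog", varcat)
    DBI::dbDisconnect(con)
    on.exit(NULL)

    gt <- structure(list(
      true_episodes = data.frame(
        case_id = episodes$case_id, device_type = episodes$device_type,
        start = iso(episodes$start), end = iso(episodes$end),
        stringsAsFactors = FALSE
      ),
      true_rates = data.frame(
        case_id = meds$true_rates$case_id, drug_id = meds$true_rates$drug_id,
        ingredient = meds$true_rates$ingredient,
        start = iso(meds$true_rates$start), end = iso(meds$true_rates$end),
        rate = meds$true_rates$rate, unit = meds$true_rates$unit,
        stringsAsFactors = FALSE
      ),
      true_boluses = data.frame(
        case_id = meds$true_boluses$case_id,
        drug_id = meds$true_boluses$drug_id,
        ingredient = meds$true_boluses$ingredient,
        ts = iso(meds$true_boluses$ts), amount = meds$true_boluses$amount,
        unit = meds$true_boluses$unit, stringsAsFactors = FALSE
      ),
      identity_map = data.frame(case_id = pc$cases$case_id,
                                patient_id = pc$cases$patient_id,
                                stringsAsFactors = FALSE),
      conflicted_cases = conflicted
    ), class = "pdms_ground_truth")

    gt_path <- paste0(path, ".ground_truth.json")
    jsonlite::write_json(unclass(gt), gt_path, dataframe = "columns",
                         na = "null", digits = NA, pretty = FALSE)
    list(handle = connect_readonly(path), ground_truth = gt,
         path = path, ground_truth_path = gt_path)
  })
}

#' Read a previously generated ground-truth JSON file
#'
#' @param path Path to a `*.ground_truth.json` file written by
#'   [generate_fixture()].
#' @return A `pdms_ground_truth` object.
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  raw$conflicted_cases <- as.character(unlist(raw$conflicted_cases))
  for (nm in c("true_episodes", "true_rates", "true_boluses", "identity_map")) {
    raw[[nm]] <- as.data.frame(raw[[nm]], stringsAsFactors = FALSE)
  }
  structure(raw, class = "pdms_ground_truth")
}
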