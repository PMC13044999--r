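# Demographics and observation extraction with content-aware filtering, plus
# source data-quality checks (identifier consistency, admission-window
# overlap). Direct identifiers (name, date of birth) never leave this layer:
# age is derived at extraction time and the date of birth is discarded before
# any export. Intervals use half-open [start, end) semantics throughout, so
# abutting windows never count as overlapping.

#' Age in completed years at a reference date
#'
#' Calendar arithmetic: the age increments on the birthday, not after a fixed
#' number of days.
#'
#' @param dob Date of birth (`Date` or `"YYYY-MM-DD"`).
#' @param on Reference date.
#' @return Integer vector of completed years.
#' @export
age_in_years <- function(dob, on) {
  dob <- as.Date(dob)
  on <- as.Date(on)
  dob_lt <- as.POSIXlt(dob)
  on_lt <- as.POSIXlt(on)
  age <- on_lt$year - dob_lt$year
  before_birthday <- (on_lt$mon < dob_lt$mon) |
    (on_lt$mon == dob_lt$mon & on_lt$mday < dob_lt$mday)
  as.integer(age - before_birthday)
}

#' Extract demographics: one row per matched case
#'
#' Joins the (denormalized, possibly duplicated) case rows with the patient
#' registry, derives age at admission from the date of birth, converts
#' timestamps to local CET/CEST representation, and drops all direct
#' identifiers. A case appearing under several patient identifiers (a source
#' inconsistency) still yields exactly one row: the first patient record in
#' source order is used; such cases are surfaced by
#' [check_case_patient_consistency()], not silently multiplied.
#'
#' @param handle A `pdms_source`.
#' @param case_ids Identifier vector; unmatched ids yield no rows.
#' @param chunk_size Batch bound for source queries.
#' @return Data frame with columns `case_id`, `admission_ts`,
#'   `discharge_ts` (local ISO-8601), `age_at_admission`, `sex`, `ward`.
#' @export
extract_demographics <- function(handle, case_ids, chunk_size = 500L) {
  cases <- fetch_by_case_ids(handle, "cases", case_ids, chunk_size)
  if (nrow(cases) == 0L) {
    return(data.frame(case_id = character(0), admission_ts = character(0),
                      discharge_ts = character(0),
                      age_at_admission = integer(0), sex = character(0),
                      ward = character(0), stringsAsFactors = FALSE))
  }
  cases <- cases[!duplicated(cases$case_id), , drop = FALSE]
  pat <- fetch_by_case_ids(handle, "patients", unique(cases$patient_id),
                           chunk_size, id_column = "patient_id")
  m <- match(cases$patient_id, pat$patient_id)
  adm_date <- as.Date(substr(cases$admission_ts, 1L, 10L))
  out <- data.frame(
    case_id = cases$case_id,
    admission_ts = to_local(cases$admission_ts),
    discharge_ts = to_local(cases$discharge_ts),
    age_at_admission = age_in_years(pat$date_of_birth[m], adm_date),
    sex = pat$sex[m],
    ward = cases$ward,
    stringsAsFactors = FALSE
  )
  out[order(out$case_id), , drop = FALSE]
}

#' Extract observations (vitals and point-of-care results)
#'
#' Catalog plausibility bounds are attached as `lower`/`upper` columns so
#' the observations contract can enforce them per variable.
#'
#' @param handle A `pdms_source`.
#' @param case_ids Identifier vector.
#' @param chunk_size Batch bound.
#' @return Data frame with `case_id`, `variable_id`, `value`, `unit`, `ts`
#'   (local), `context`, `lower`, `upper`.
#' @export
extract_observations <- function(handle, case_ids, chunk_size = 500L) {
  obs <- fetch_by_case_ids(handle, "observations", case_ids, chunk_size)
  cat <- fetch_table(handle, "variable_catalog")
  m <- match(obs$variable_id, cat$variable_id)
  data.frame(
    case_id = obs$case_id, variable_id = obs$variable_id,
    value = obs$value, unit = obs$unit, ts = to_local(obs$ts),
    context = obs$context, lower = cat$lower[m], upper = cat$upper[m],
    stringsAsFactors = FALSE
  )
}

#' Content-aware filtering of point-of-care results
#'
#' Retains only rows matching the analyte identity AND the context predicate
#' (e.g. a specimen-type marker such as "arterial"); relative row order is
#' preserved and the operation is a pure subset.
#'
#' @param rows Candidate observation rows (need `variable_id`; the predicate
#'   sees the whole data frame).
#' @param variable_ids Analyte identifiers to keep.
#' @param predicate Either a character scalar matched against the `context`
#'   column, or a function `rows -> logical vector`. `NULL` keeps all
#'   contexts.
#' @param catalog Optional variable catalog; when supplied, every requested
#'   variable must be cataloged.
#' @return Filtered data frame.
#' @export
filter_poc_results <- function(rows, variable_ids, predicate = NULL,
                               catalog = NULL) {
  if (!is.null(catalog)) {
    missing <- setdiff(variable_ids, catalog$variable_id)
    if (length(missing)) {
      pdms_error("pdms_catalog_error",
                 sprintf("uncataloged variable(s): %s",
                         paste(missing, collapse = ", ")))
    }
  }
  keep <- rows$variable_id %in% variable_ids
  if (is.character(predicate)) {
    keep <- keep & !is.na(rows$context) & rows$context %in% predicate
  } else if (is.function(predicate)) {
    keep <- keep & predicate(rows) %in% TRUE
  }
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Check whether cases map to a single patient identifier
#'
#' Scans the case table for case numbers appearing under more than one
#' distinct patient identifier — a rare but real source inconsistency.
#'
#' @param handle A `pdms_source`.
#' @param case_ids Identifier vector to audit.
#' @param chunk_size Batch bound.
#' @return An object of class `pdms_quality_findings` with
#'   `n_cases_checked`, `multi_patient_cases`, `multi_patient_rate`,
#'   `overlapping_admissions`.
#' @export
check_case_patient_consistency <- function(handle, case_ids,
                                           chunk_size = 500L) {
  rows <- fetch_by_case_ids(handle, "cases", case_ids, chunk_size)
  counts <- tapply(rows$patient_id, rows$case_id,
                   function(p) length(unique(p)))
  multi <- sort(names(counts)[counts > 1L])
  n_checked <- length(unique(as.character(case_ids)))
  structure(list(
    n_cases_checked = n_checked,
    multi_patient_cases = multi,
    multi_patient_rate = length(multi) / max(n_checked, 1L),
    overlapping_admissions = data.frame(case_a = character(0),
                                        case_b = character(0))
  ), class = "pdms_quality_findings")
}

#' Detect overlapping admission windows per patient
#'
#' All pairs of same-patient case windows with a positive-length intersection
#' under half-open semantics are reported; windows missing either timestamp
#' are skipped and counted as unchecked.
#'
#' @param case_windows Data frame with `case_id`, `patient_id`,
#'   `admission_ts`, `discharge_ts` (UTC or local ISO-8601).
#' @return A `pdms_quality_findings` with the overlapping pairs, plus
#'   `n_skipped` (windows with incomplete timestamps).
#' @export
check_admission_overlaps <- function(case_windows) {
  s <- as.numeric(parse_utc(case_windows$admission_ts))
  e <- as.numeric(parse_utc(case_windows$discharge_ts))
  complete <- !is.na(s) & !is.na(e)
  cw <- case_windows[complete, , drop = FALSE]
  s <- s[complete]; e <- e[complete]
  pairs <- list()
  for (p in unique(cw$patient_id)) {
    i <- which(cw$patient_id == p)
    if (length(i) < 2L) next
    for (a in seq_along(i)[-length(i)]) {
      for (b in (a + 1L):length(i)) {
        ia <- i[a]; ib <- i[b]
        # half-open [s, e): positive-length intersection required
        if (max(s[ia], s[ib]) < min(e[ia], e[ib])) {
          pairs[[length(pairs) + 1L]] <-
            data.frame(case_a = cw$case_id[ia], case_b = cw$case_id[ib],
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  overlaps <- if (length(pairs)) do.call(rbind, pairs) else {
    data.frame(case_a = character(0), case_b = character(0))
  }
  structure(list(
    n_cases_checked = sum(complete),
    n_skipped = sum(!complete),
    multi_patient_cases = character(0),
    multi_patient_rate = 0,
    overlapping_admissions = overlaps
  ), class = "pdms_quality_findings")
}

#' @export
print.pdms_quality_findings <- function(x, ...) {
  cat(sprintf("<quality findings: %d cases checked, %d multi-patient (%.3f%%), %d overlapping pairs>\n",
              x$n_cases_checked, length(x$multi_patient_cases),
              100 * x$multi_patient_rate, nrow(x$overlapping_admissions)))
  invisible(x)
}
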