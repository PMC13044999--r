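# Medication concentration reconstruction and dose-rate standardization —
# the transformation-heaviest domain. Source records document drug
# administration as a volume, a dose, or a pump rate, without explicit
# concentrations; concentrations are reconstructed from mixture definitions
# in the internal drug catalog (ingredient amount / diluent volume) and used
# to express every administration as either a bolus amount (mg or U) or an
# infusion rate (mg/h or U/h), keyed by ingredient. Mass and activity are
# never mixed within an ingredient.

#' Load mixture definitions (drug catalog)
#'
#' @param source Either a `pdms_source` handle (reads the fixture's
#'   `drug_catalog` table), a path to a catalog CSV, or `NULL` for the
#'   packaged catalog. Columns: `drug_id`, `ingredient`, `amount`,
#'   `amount_unit`, `volume_ml`, `standard_unit`.
#' @return Data frame of mixture definitions.
#' @export
load_drug_catalog <- function(source = NULL) {
  cat <- if (inherits(source, "pdms_source")) {
    fetch_table(source, "drug_catalog")
  } else if (is.character(source)) {
    utils::read.csv(source, stringsAsFactors = FALSE, encoding = "UTF-8")
  } else {
    .load_csv("drug_catalog.csv")
  }
  need <- c("drug_id", "ingredient", "amount", "amount_unit", "volume_ml",
            "standard_unit")
  if (!all(need %in% names(cat))) {
    pdms_error("pdms_catalog_error",
               "drug catalog must have columns drug_id, ingredient, amount, amount_unit, volume_ml, standard_unit")
  }
  cat[need]
}

#' Reconstruct a drug concentration from its mixture definition
#'
#' @param ingredient_amount Amount of active ingredient (mg or U); zero is
#'   legal (placebo mixture).
#' @param diluent_volume Diluent volume in mL (> 0).
#' @return Concentration in mg/mL or U/mL.
#' @export
reconstruct_concentration <- function(ingredient_amount, diluent_volume) {
  if (any(!is.finite(diluent_volume) | diluent_volume <= 0)) {
    pdms_error("pdms_value_error", "diluent volume must be positive")
  }
  if (any(!is.finite(ingredient_amount) | ingredient_amount < 0)) {
    pdms_error("pdms_value_error", "ingredient amount must be >= 0")
  }
  ingredient_amount / diluent_volume
}

#' Standardize a batch of raw medication records
#'
#' Resolves each record's drug against the mixture catalog, reconstructs the
#' concentration, and emits standardized events: `rate`-documented records
#' become infusions with `rate = value[mL/h] x concentration`;
#' `volume`-documented records are interpreted as evenly infused over their
#' documented interval (`rate = value[mL] x concentration / duration[h]`);
#' `dose`-documented records become boluses with the amount converted to the
#' drug's standard unit. Unresolvable records (unknown drug, volume without
#' a usable interval, unknown documentation format) are never silently
#' dropped: they are routed to the `failures` table.
#'
#' @param raw Data frame of raw records: `record_id`, `case_id`, `drug_id`,
#'   `doc_format`, `value`, `unit`, `start_ts`, `end_ts` (UTC ISO strings or
#'   `POSIXct`).
#' @param catalog Mixture definitions from [load_drug_catalog()].
#' @return `list(events, failures)`; `events` has `case_id`, `ingredient`,
#'   `kind` (`bolus`/`infusion`), `value` (amount or rate), `unit`
#'   (`mg`, `U`, `mg/h`, `U/h`), `start_ts`, `end_ts` (local ISO-8601).
#' @export
standardize_medications <- function(raw, catalog = load_drug_catalog()) {
  n <- nrow(raw)
  empty_events <- data.frame(
    case_id = character(0), ingredient = character(0), kind = character(0),
    value = numeric(0), unit = character(0), start_ts = character(0),
    end_ts = character(0), stringsAsFactors = FALSE
  )
  empty_fail <- data.frame(record_id = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  if (n == 0L) return(list(events = empty_events, failures = empty_fail))

  m <- match(raw$drug_id, catalog$drug_id)
  conc <- rep(NA_real_, n)
  known <- !is.na(m)
  conc[known] <- reconstruct_concentration(catalog$amount[m[known]],
                                           catalog$volume_ml[m[known]])
  std_unit <- catalog$standard_unit[m]           # mg/h or U/h
  base_unit <- sub("/h$", "", std_unit)          # mg or U

  start <- parse_utc(raw$start_ts)
  end <- parse_utc(raw$end_ts)
  dur_h <- as.numeric(end - start, units = "hours")

  reason <- rep(NA_character_, n)
  reason[!known] <- "unknown drug_id"
  fmt_ok <- raw$doc_format %in% c("volume", "dose", "rate")
  reason[is.na(reason) & !fmt_ok] <- "unknown documentation format"
  bad_vol <- raw$doc_format == "volume" & (is.na(dur_h) | dur_h <= 0)
  reason[is.na(reason) & bad_vol] <- "volume record without usable interval"
  bad_rate <- raw$doc_format == "rate" & (is.na(dur_h) | dur_h <= 0)
  reason[is.na(reason) & bad_rate] <- "rate record without usable interval"

  ok <- is.na(reason)
  value <- rep(NA_real_, n)
  unit <- rep(NA_character_, n)
  kind <- rep(NA_character_, n)
  is_rate <- ok & raw$doc_format == "rate"
  is_vol <- ok & raw$doc_format == "volume"
  is_dose <- ok & raw$doc_format == "dose"
  value[is_rate] <- raw$value[is_rate] * conc[is_rate]
  value[is_vol] <- raw$value[is_vol] * conc[is_vol] / dur_h[is_vol]
  unit[is_rate | is_vol] <- std_unit[is_rate | is_vol]
  kind[is_rate | is_vol] <- "infusion"
  # boluses: convert the documented amount to the drug's standard base unit;
  # a cross-dimension documentation (e.g. mL for a dose) is a failure
  for (i in which(is_dose)) {
    v <- tryCatch(convert_unit(raw$value[i], raw$unit[i], base_unit[i]),
                  pdms_error = function(e) NA_real_)
    if (is.na(v)) {
      reason[i] <- sprintf("dose unit '%s' not convertible to %s",
                           raw$unit[i], base_unit[i])
      is_dose[i] <- FALSE
    } else {
      value[i] <- v
      unit[i] <- base_unit[i]
      kind[i] <- "bolus"
    }
  }
  ok <- is.na(reason)

  events <- data.frame(
    case_id = raw$case_id[ok], ingredient = catalog$ingredient[m[ok]],
    kind = kind[ok], value = value[ok], unit = unit[ok],
    start_ts = to_local(start[ok]),
    end_ts = ifelse(kind[ok] == "bolus", to_local(start[ok]),
                    to_local(end[ok])),
    stringsAsFactors = FALSE
  )
  failures <- data.frame(record_id = as.character(raw$record_id)[!ok],
                         reason = reason[!ok], stringsAsFactors = FALSE)
  rownames(events) <- rownames(failures) <- NULL
  list(events = events, failures = failures)
}

#' Standardize a single raw medication record
#'
#' Strict single-record variant of [standardize_medications()]: an
#' unresolvable record raises an error instead of being routed to a failure
#' table.
#'
#' @param raw One-row data frame (see [standardize_medications()]).
#' @param catalog Mixture definitions.
#' @return One-row standardized event data frame.
#' @export
standardize_record <- function(raw, catalog = load_drug_catalog()) {
  res <- standardize_medications(as.data.frame(raw, stringsAsFactors = FALSE),
                                 catalog)
  if (nrow(res$failures)) {
    cls <- if (grepl("drug_id", res$failures$reason[1L])) {
      "pdms_catalog_error"
    } else "pdms_unresolvable_record_error"
    pdms_error(cls, res$failures$reason[1L])
  }
  res$events
}

#' Aggregate standardized medication events over a time window
#'
#' A bolus contributes its amount when its timestamp falls inside the
#' half-open window; an infusion contributes `rate x overlap duration`.
#' Totals are keyed by (ingredient, unit); mass (mg) and activity (U) never
#' collapse into one total.
#'
#' @param events Standardized events from [standardize_medications()].
#' @param window_start,window_end Window bounds (ISO-8601 strings or
#'   `POSIXct`), `window_start < window_end`.
#' @return Data frame `ingredient`, `unit` (mg or U), `total`, sorted by
#'   ingredient.
#' @export
aggregate_window <- function(events, window_start, window_end) {
  ws <- as.numeric(parse_utc(window_start))
  we <- as.numeric(parse_utc(window_end))
  if (!is.finite(ws) || !is.finite(we) || ws >= we) {
    pdms_error("pdms_value_error", "window start must precede window end")
  }
  if (nrow(events) == 0L) {
    return(data.frame(ingredient = character(0), unit = character(0),
                      total = numeric(0), stringsAsFactors = FALSE))
  }
  s <- as.numeric(parse_utc(events$start_ts))
  e <- as.numeric(parse_utc(events$end_ts))
  contrib <- numeric(nrow(events))
  bol <- events$kind == "bolus"
  contrib[bol] <- ifelse(s[bol] >= ws & s[bol] < we, events$value[bol], 0)
  inf <- events$kind == "infusion"
  overlap_h <- pmax(0, (pmin(e[inf], we) - pmax(s[inf], ws))) / 3600
  contrib[inf] <- events$value[inf] * overlap_h
  base_unit <- sub("/h$", "", events$unit)
  key <- paste(events$ingredient, base_unit, sep = "\r")
  totals <- tapply(contrib, key, sum)
  parts <- strsplit(names(totals), "\r", fixed = TRUE)
  out <- data.frame(
    ingredient = vapply(parts, `[[`, character(1L), 1L),
    unit = vapply(parts, `[[`, character(1L), 2L),
    total = as.numeric(totals), stringsAsFactors = FALSE
  )
  out <- out[order(out$ingredient, out$unit), , drop = FALSE]
  rownames(out) <- NULL
  out
}
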