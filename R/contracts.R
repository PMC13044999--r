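# Schema contracts: per-domain output specifications (fields, semantic types,
# plausibility bounds, cross-field predicates) with failure accounting.
# Contracts live as human-editable JSON under inst/extdata/contracts/ and are
# enforced on every exported batch; a record fails on the FIRST violated rule
# (required -> type -> plausibility -> cross-field, in declared order), giving
# a stable, cheap failure accounting. Failed records are excluded from export
# but fully listed in the report.

TIMESTAMP_RE <- "^[0-9]{4}-[0-9]{2}-[0-9]{2}T[0-9]{2}:[0-9]{2}:[0-9]{2}(Z|[+-][0-9]{2}:[0-9]{2})$"

#' Construct a schema contract
#'
#' @param name Domain identifier.
#' @param fields Data frame (or list coercible to one) with columns `name`,
#'   `type` (one of `character`, `numeric`, `integer`, `logical`,
#'   `timestamp`), `required` (logical).
#' @param plausibility List of rules, each either a closed numeric interval
#'   `list(field=, min=, max=)` or an enumerated set `list(field=, allowed=)`.
#' @param cross_field List of predicates; supported rules are
#'   `list(name=, rule="le", left=, right=)` (left <= right where both
#'   present) and `list(name=, rule="between", field=, low=, high=)`
#'   (field within `[low, high]` where bounds present).
#' @return An object of class `pdms_contract`.
#' @export
schema_contract <- function(name, fields, plausibility = list(),
                            cross_field = list()) {
  fields <- as.data.frame(fields, stringsAsFactors = FALSE)
  if (!all(c("name", "type", "required") %in% names(fields))) {
    pdms_error("pdms_configuration_error",
               "contract fields need columns name, type, required")
  }
  if (anyDuplicated(fields$name)) {
    pdms_error("pdms_configuration_error",
               sprintf("contract '%s': duplicate field names", name))
  }
  ok_types <- c("character", "numeric", "integer", "logical", "timestamp")
  if (!all(fields$type %in% ok_types)) {
    pdms_error("pdms_configuration_error",
               sprintf("contract '%s': unknown field type", name))
  }
  plausibility <- lapply(plausibility, as.list)
  for (rule in plausibility) {
    if (is.null(rule$field) || !(rule$field %in% fields$name)) {
      pdms_error("pdms_configuration_error",
                 sprintf("contract '%s': plausibility rule targets undeclared field",
                         name))
    }
  }
  cross_field <- lapply(cross_field, as.list)
  structure(list(name = name, fields = fields,
                 plausibility = plausibility, cross_field = cross_field),
            class = "pdms_contract")
}

#' Load a packaged (or external) schema contract
#'
#' @param name Contract name; one of the packaged domains
#'   (`demographics`, `observations`, `drugs`, `therapy`, `or_times`,
#'   `drug_windows`) unless `path` is given.
#' @param path Optional path to a contract JSON file.
#' @return A `pdms_contract`.
#' @export
load_contract <- function(name, path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "contracts", paste0(name, ".json"),
                        package = "pdmsetl")
    if (!nzchar(path)) {
      pdms_error("pdms_configuration_error",
                 sprintf("no packaged contract named '%s'", name))
    }
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  plaus <- raw$plausibility
  if (is.data.frame(plaus)) {
    plaus <- lapply(seq_len(nrow(plaus)), function(i) {
      r <- as.list(plaus[i, , drop = FALSE])
      r <- lapply(r, function(v) if (is.list(v)) v[[1L]] else v)
      r[!vapply(r, function(v) all(is.na(v)) && !is.character(v), logical(1L))]
    })
  } else if (is.null(plaus)) plaus <- list()
  cross <- raw$cross_field
  if (is.data.frame(cross)) {
    cross <- lapply(seq_len(nrow(cross)), function(i) as.list(cross[i, ]))
  } else if (is.null(cross)) cross <- list()
  schema_contract(raw$name, raw$fields, plaus, cross)
}

# coerce one column to the contract's semantic type; returns list(values,
# bad) where bad marks entries that could not be coerced
coerce_field <- function(x, type) {
  switch(type,
    character = {
      v <- as.character(x)
      list(values = v, bad = rep(FALSE, length(v)))
    },
    numeric = {
      v <- suppressWarnings(as.numeric(x))
      list(values = v, bad = !is.na(x) & is.na(v))
    },
    integer = {
      v <- suppressWarnings(as.numeric(x))
      bad <- (!is.na(x) & is.na(v)) | (!is.na(v) & v != round(v))
      list(values = v, bad = bad)
    },
    logical = {
      v <- as.logical(x)
      list(values = v, bad = !is.na(x) & is.na(v))
    },
    timestamp = {
      v <- as.character(x)
      bad <- !is.na(v) & !grepl(TIMESTAMP_RE, v)
      list(values = v, bad = bad)
    }
  )
}

.ts_or_num <- function(x) {
  if (is.character(x)) as.numeric(parse_utc(x)) else as.numeric(x)
}

# evaluate all rules over a batch; returns character vector: NA where valid,
# else the name of the first violated rule
first_violation <- function(df, contract) {
  n <- nrow(df)
  viol <- rep(NA_character_, n)
  mark <- function(bad, label) {
    hit <- is.na(viol) & bad %in% TRUE
    viol[hit] <<- label
  }
  # 1. required presence + type conformance, in declared field order
  for (i in seq_len(nrow(contract$fields))) {
    f <- contract$fields[i, ]
    if (!f$name %in% names(df)) {
      if (isTRUE(f$required)) mark(rep(TRUE, n), paste0("required: ", f$name))
      next
    }
    col <- coerce_field(df[[f$name]], f$type)
    if (isTRUE(f$required)) mark(is.na(col$values), paste0("required: ", f$name))
    mark(col$bad, paste0("type: ", f$name))
    df[[f$name]] <- col$values
  }
  # 2. plausibility bounds / enumerations, in declared order
  for (rule in contract$plausibility) {
    x <- df[[rule$field]]
    if (is.null(x)) next
    if (!is.null(rule$allowed)) {
      bad <- !is.na(x) & !(x %in% rule$allowed)
    } else {
      xv <- suppressWarnings(as.numeric(x))
      bad <- !is.na(xv) & (xv < rule$min | xv > rule$max)
    }
    mark(bad, paste0("plausibility: ", rule$field))
  }
  # 3. cross-field predicates
  for (rule in contract$cross_field) {
    bad <- switch(rule$rule,
      le = {
        l <- .ts_or_num(df[[rule$left]]); r <- .ts_or_num(df[[rule$right]])
        !is.na(l) & !is.na(r) & l > r
      },
      between = {
        x <- .ts_or_num(df[[rule$field]])
        lo <- .ts_or_num(df[[rule$low]]); hi <- .ts_or_num(df[[rule$high]])
        (!is.na(x) & !is.na(lo) & x < lo) | (!is.na(x) & !is.na(hi) & x > hi)
      },
      pdms_error("pdms_configuration_error",
                 sprintf("unknown cross-field rule '%s'", rule$rule))
    )
    mark(bad, paste0("cross_field: ", rule$name))
  }
  viol
}

#' Validate a single record against a contract
#'
#' @param record One-row data frame or named list.
#' @param contract A `pdms_contract`.
#' @return The type-coerced record (one-row data frame) if valid; otherwise a
#'   failure descriptor `list(valid = FALSE, rule = <first violated rule>)`.
#' @export
validate_record <- function(record, contract) {
  if (!inherits(contract, "pdms_contract")) {
    pdms_error("pdms_configuration_error", "contract must be a pdms_contract")
  }
  df <- as.data.frame(record, stringsAsFactors = FALSE)
  res <- validate_batch(df, contract)
  if (res$report$n_failed > 0L) {
    return(list(valid = FALSE, rule = res$report$failures$rule[1L]))
  }
  res$valid
}

#' Validate a batch of candidate output rows
#'
#' Applies the contract to every row; valid rows are returned type-coerced
#' and in their original order, failures are counted and listed.
#'
#' @param records Data frame of candidate rows.
#' @param contract A `pdms_contract`.
#' @return `list(valid = <data frame>, report = <pdms_validation_report>)`
#'   where the report carries `n_input`, `n_valid`, `n_failed`,
#'   `failure_rate` (= `n_failed / max(n_input, 1)`) and a `failures` data
#'   frame of (row locator, rule).
#' @export
validate_batch <- function(records, contract) {
  if (!inherits(contract, "pdms_contract")) {
    pdms_error("pdms_configuration_error", "contract must be a pdms_contract")
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  n <- nrow(records)
  viol <- if (n) first_violation(records, contract) else character(0)
  ok <- is.na(viol)
  valid <- records[ok, , drop = FALSE]
  # return coerced values for the valid rows
  for (i in seq_len(nrow(contract$fields))) {
    f <- contract$fields[i, ]
    if (f$name %in% names(valid)) {
      valid[[f$name]] <- coerce_field(valid[[f$name]], f$type)$values
    }
  }
  rownames(valid) <- NULL
  failures <- data.frame(row = which(!ok),
                         rule = viol[!ok],
                         stringsAsFactors = FALSE)
  report <- structure(
    list(name = contract$name,
         n_input = n,
         n_valid = sum(ok),
         n_failed = sum(!ok),
         failure_rate = sum(!ok) / max(n, 1L),
         failures = failures),
    class = "pdms_validation_report"
  )
  list(valid = valid, report = report)
}

#' @export
print.pdms_validation_report <- function(x, ...) {
  cat(sprintf("<validation report '%s': %d input, %d valid, %d failed (%.2f%%)>\n",
              x$name, x$n_input, x$n_valid, x$n_failed, 100 * x$failure_rate))
  invisible(x)
}
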