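# Orchestration: a resource registry, predefined multi-domain extraction
# templates, and analysis-ready export. Every resource run follows one flow:
# fetch (chunked) -> transform -> pseudonymize -> validate against the
# domain's schema contract -> export -> audit. The contract describes the
# de-identified output model, so pseudonyms (never raw identifiers) are what
# gets validated and exported. Row order in exports is a total sort over all
# columns starting with (case_pseudonym, domain timestamp), which makes
# artifacts byte-identical across chunk sizes and runs.

#' Pipeline configuration
#'
#' @param salt A [salt_config()] or the salt string itself (secrets should
#'   come from the environment, never from files in the repository).
#' @param out_dir Directory for export artifacts and the audit log.
#' @param format Export format, `"csv"` or `"parquet"`.
#' @param chunk_size Identifier batch bound for source queries.
#' @param gap_tolerance Therapy merge gap tolerance (minutes); scalar or
#'   named per-device vector with a `"default"` entry.
#' @param roles Actor-to-template role map (see [load_roles()]).
#' @param audit_sink Path of the JSON-lines audit log (default
#'   `<out_dir>/audit.jsonl`).
#' @param id_sample_size Number of hashed case ids sampled into each audit
#'   record.
#' @return An object of class `pdms_config`.
#' @export
pdms_config <- function(salt, out_dir, format = c("csv", "parquet"),
                        chunk_size = 500L, gap_tolerance = 60,
                        roles = load_roles(), audit_sink = NULL,
                        id_sample_size = 5L) {
  format <- match.arg(format)
  if (is.character(salt)) salt <- salt_config(salt)
  if (!inherits(salt, "pdms_salt_config")) {
    pdms_error("pdms_configuration_error", "a salt must be configured")
  }
  if (is.null(audit_sink)) audit_sink <- file.path(out_dir, "audit.jsonl")
  structure(list(salt = salt, out_dir = out_dir, format = format,
                 chunk_size = as.integer(chunk_size),
                 gap_tolerance = gap_tolerance, roles = roles,
                 audit_sink = audit_sink,
                 id_sample_size = as.integer(id_sample_size)),
            class = "pdms_config")
}

# ---- registry ---------------------------------------------------------------

#' Create an empty resource registry
#' @return An environment-backed registry of class `pdms_registry`.
#' @export
new_registry <- function() {
  structure(new.env(parent = emptyenv()), class = "pdms_registry")
}

#' Register an extraction resource
#'
#' @param registry A [new_registry()].
#' @param name Unique resource name.
#' @param extractor Function `(handle, case_ids, cfg) -> data.frame` with a
#'   `case_id` column.
#' @param contract Name of the schema contract validating the resource's
#'   output (see [load_contract()]).
#' @param export_name File stem of the export artifact (defaults to `name`).
#' @param sort_by Column(s) defining the domain sort order after the
#'   pseudonym.
#' @return The registry, invisibly.
#' @export
register_resource <- function(registry, name, extractor, contract,
                              export_name = name, sort_by = character(0)) {
  stopifnot(inherits(registry, "pdms_registry"), is.function(extractor))
  if (!is.null(registry[[name]])) {
    pdms_error("pdms_registration_error",
               sprintf("resource '%s' is already registered", name))
  }
  registry[[name]] <- list(name = name, extractor = extractor,
                           contract = contract, export_name = export_name,
                           sort_by = sort_by)
  invisible(registry)
}

#' Resolve a registered resource by name
#' @param registry A `pdms_registry`.
#' @param name Resource name.
#' @return The resource definition list.
#' @export
resolve_resource <- function(registry, name) {
  defn <- registry[[name]]
  if (is.null(defn)) {
    pdms_error("pdms_lookup_error", sprintf("unknown resource '%s'", name))
  }
  defn
}

# ---- built-in resource extractors -------------------------------------------

.extract_drugs <- function(handle, case_ids, cfg) {
  raw <- fetch_by_case_ids(handle, "medication_records", case_ids,
                           cfg$chunk_size)
  catalog <- load_drug_catalog(handle)
  std <- standardize_medications(raw, catalog)
  out <- std$events
  attr(out, "n_unresolved") <- nrow(std$failures)
  out
}

.extract_or_times <- function(handle, case_ids, cfg) {
  cases <- fetch_by_case_ids(handle, "cases", case_ids, cfg$chunk_size)
  cases <- cases[!duplicated(cases$case_id), , drop = FALSE]
  data.frame(case_id = cases$case_id,
             or_start = to_local(cases$or_start_ts),
             or_end = to_local(cases$or_end_ts), stringsAsFactors = FALSE)
}

.extract_drug_windows <- function(handle, case_ids, cfg) {
  events <- .extract_drugs(handle, case_ids, cfg)
  windows <- .extract_or_times(handle, case_ids, cfg)
  by_case <- split(seq_len(nrow(events)), events$case_id)
  per_case <- lapply(seq_len(nrow(windows)), function(i) {
    idx <- by_case[[windows$case_id[i]]]
    if (is.null(idx)) return(NULL)
    ev <- events[idx, , drop = FALSE]
    agg <- aggregate_window(ev, windows$or_start[i], windows$or_end[i])
    if (nrow(agg) == 0L) return(NULL)
    data.frame(case_id = windows$case_id[i], ingredient = agg$ingredient,
               unit = agg$unit, total = agg$total,
               window_start = windows$or_start[i],
               window_end = windows$or_end[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_case)
  if (is.null(out)) {
    out <- data.frame(case_id = character(0), ingredient = character(0),
                      unit = character(0), total = numeric(0),
                      window_start = character(0), window_end = character(0),
                      stringsAsFactors = FALSE)
  }
  out
}

.extract_therapy <- function(handle, case_ids, cfg) {
  records <- fetch_by_case_ids(handle, "therapy_records", case_ids,
                               cfg$chunk_size)
  occupancy <- fetch_by_case_ids(handle, "bed_occupancy", case_ids,
                                 cfg$chunk_size)
  eps <- reconstruct_episodes(records, occupancy, cfg$gap_tolerance)
  data.frame(case_id = eps$case_id, device_type = eps$device_type,
             start_ts = to_local(eps$start_ts), end_ts = to_local(eps$end_ts),
             end_inferred = eps$end_inferred, ongoing = eps$ongoing,
             n_source_records = eps$n_source_records, stringsAsFactors = FALSE)
}

#' The default resource registry
#'
#' Registers the built-in resources: `demographics`, `observations`,
#' `drugs`, `or_times`, `drug_windows` and `therapy`.
#'
#' @return A populated `pdms_registry`.
#' @export
default_registry <- function() {
  reg <- new_registry()
  register_resource(reg, "demographics",
    function(handle, ids, cfg) extract_demographics(handle, ids, cfg$chunk_size),
    contract = "demographics", sort_by = "admission_ts")
  register_resource(reg, "observations",
    function(handle, ids, cfg) extract_observations(handle, ids, cfg$chunk_size),
    contract = "observations", sort_by = c("variable_id", "ts"))
  register_resource(reg, "drugs", .extract_drugs,
    contract = "drugs", sort_by = c("ingredient", "start_ts"))
  register_resource(reg, "or_times", .extract_or_times,
    contract = "or_times", sort_by = "or_start")
  register_resource(reg, "drug_windows", .extract_drug_windows,
    contract = "drug_windows", sort_by = c("ingredient", "window_start"))
  register_resource(reg, "therapy", .extract_therapy,
    contract = "therapy", sort_by = c("device_type", "start_ts"))
  reg
}

#' Predefined extraction templates
#'
#' `demographics` covers the plain demographic workflow; `periop_study` is
#' the multi-domain perioperative pipeline (demographics, standardized
#' drugs, operating-room timestamps, and per-ingredient drug totals within
#' each case's operating-room window); `icu_course` adds reconstructed
#' device-therapy episodes and observations.
#'
#' @param name Template name.
#' @return `list(name, resources)`.
#' @export
get_template <- function(name) {
  templates <- list(
    demographics = c("demographics"),
    periop_study = c("demographics", "drugs", "or_times", "drug_windows"),
    icu_course = c("demographics", "observations", "drugs", "therapy")
  )
  if (!name %in% names(templates)) {
    pdms_error("pdms_lookup_error", sprintf("unknown template '%s'", name))
  }
  list(name = name, resources = templates[[name]])
}

# ---- export -----------------------------------------------------------------

#' Export a validated table as CSV or Parquet
#'
#' CSV: header row, comma delimiter, quoted character fields, UTF-8, empty
#' string for missing values, ISO-8601 timestamps. Parquet: typed columns
#' via arrow. Re-reading reproduces the table.
#'
#' @param rows Data frame of validated rows.
#' @param format `"csv"` or `"parquet"`.
#' @param path Output file path.
#' @return An object of class `pdms_export_artifact` (fields `path`,
#'   `format`, `n_rows`, `columns`).
#' @export
export_table <- function(rows, format = c("csv", "parquet"), path) {
  format <- match.arg(format)
  if (!dir.exists(dirname(path)) || file.access(dirname(path), 2L) != 0L) {
    pdms_error("pdms_io_error", sprintf("export path not writable: %s", path))
  }
  if (format == "csv") {
    utils::write.csv(rows, path, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
  } else {
    arrow::write_parquet(rows, path)
  }
  structure(list(path = path, format = format, n_rows = nrow(rows),
                 columns = names(rows)),
            class = "pdms_export_artifact")
}

#' Read back an export artifact
#' @param artifact A `pdms_export_artifact` (or a path plus `format`).
#' @param format Format when `artifact` is a bare path.
#' @return Data frame.
#' @export
read_export <- function(artifact, format = NULL) {
  if (inherits(artifact, "pdms_export_artifact")) {
    path <- artifact$path; format <- artifact$format
  } else path <- artifact
  if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  } else {
    as.data.frame(arrow::read_parquet(path))
  }
}

# total, reproducible row order: pseudonym, then domain sort keys, then all
# remaining columns as tie-breakers
.sort_rows <- function(df, sort_by) {
  if (nrow(df) == 0L) return(df)
  keys <- c("case_pseudonym", sort_by,
            setdiff(names(df), c("case_pseudonym", sort_by)))
  keys <- keys[keys %in% names(df)]
  ord <- do.call(order, c(unname(as.list(df[keys])), list(method = "radix")))
  out <- df[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run a predefined extraction template
#'
#' Authorization and salt configuration are checked before any source
#' access; the audit sink is opened before any export. Each resource is then
#' fetched (in identifier chunks), transformed, pseudonymized, validated
#' against its schema contract, exported, and audited with its exported row
#' count and runtime. A failure in one resource marks the run `partial` but
#' still writes that resource's audit entry (outcome `error`) and completes
#' the independent resources.
#'
#' @param template Template name or `list(name, resources)` (see
#'   [get_template()]).
#' @param handle A `pdms_source`.
#' @param case_ids Identifier vector (one case number per element).
#' @param actor User label (mandatory).
#' @param purpose Free-text purpose (mandatory).
#' @param cfg A [pdms_config()].
#' @param registry Resource registry (default [default_registry()]).
#' @return `list(artifacts, audit, reports, outcome)`.
#' @export
run_template <- function(template, handle, case_ids, actor, purpose, cfg,
                         registry = default_registry()) {
  if (missing(actor) || !nzchar(actor)) {
    pdms_error("pdms_configuration_error", "actor is mandatory")
  }
  if (missing(purpose) || !nzchar(purpose)) {
    pdms_error("pdms_configuration_error", "purpose is mandatory")
  }
  if (!inherits(cfg, "pdms_config")) {
    pdms_error("pdms_configuration_error", "cfg must be a pdms_config")
  }
  if (is.character(template)) template <- get_template(template)
  if (!dir.exists(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  }

  # governance gates: authorization and auditability come before any access
  auth_err <- tryCatch({
    authorize_actor(actor, template$name, cfg$roles)
    NULL
  }, pdms_authorization_error = function(e) e)
  now <- Sys.time()
  if (!is.null(auth_err)) {
    rec <- audit_record(
      actor = actor, purpose = purpose, resource = template$name,
      parameters = list(error = conditionMessage(auth_err)),
      n_cases_requested = length(unique(case_ids)), n_rows_exported = 0L,
      started_at = now, finished_at = Sys.time(), outcome = "error"
    )
    write_audit(rec, cfg$audit_sink)
    pdms_error("pdms_authorization_error", conditionMessage(auth_err))
  }

  ids <- unique(as.character(case_ids))
  id_sample <- pseudonymize(utils::head(ids, cfg$id_sample_size), cfg$salt)
  artifacts <- list(); audit <- list(); reports <- list()
  outcome <- "success"

  for (res_name in template$resources) {
    defn <- resolve_resource(registry, res_name)
    started <- Sys.time()
    result <- tryCatch({
      rows <- defn$extractor(handle, ids, cfg)
      n_unresolved <- attr(rows, "n_unresolved")
      # pseudonymize the linkage identifier, then validate the output model
      rows$case_pseudonym <- pseudonymize(rows$case_id, cfg$salt)
      rows$case_id <- NULL
      rows <- rows[, c("case_pseudonym",
                       setdiff(names(rows), "case_pseudonym")), drop = FALSE]
      contract <- load_contract(defn$contract)
      vb <- validate_batch(rows, contract)
      rows <- .sort_rows(vb$valid, defn$sort_by)
      ext <- if (cfg$format == "csv") "csv" else "parquet"
      path <- file.path(cfg$out_dir, paste0(defn$export_name, ".", ext))
      artifact <- export_table(rows, cfg$format, path)
      params <- list(template = template$name, resource = res_name,
                     case_ids = ids, chunk_size = cfg$chunk_size,
                     format = cfg$format,
                     n_validation_failed = vb$report$n_failed)
      if (!is.null(n_unresolved)) params$n_unresolved <- n_unresolved
      rec <- audit_record(
        actor = actor, purpose = purpose, resource = res_name,
        parameters = redact_parameters(params, cfg$salt),
        n_cases_requested = length(ids),
        n_rows_exported = artifact$n_rows,
        started_at = started, finished_at = Sys.time(),
        id_sample = id_sample, outcome = "success"
      )
      write_audit(rec, cfg$audit_sink)
      list(artifact = artifact, rec = rec, report = vb$report)
    }, error = function(e) {
      rec <- audit_record(
        actor = actor, purpose = purpose, resource = res_name,
        parameters = list(error = conditionMessage(e)),
        n_cases_requested = length(ids), n_rows_exported = 0L,
        started_at = started, finished_at = Sys.time(),
        id_sample = id_sample, outcome = "error"
      )
      write_audit(rec, cfg$audit_sink)
      list(error = e, rec = rec)
    })
    if (!is.null(result$error)) {
      outcome <- "partial"
      audit[[res_name]] <- result$rec
    } else {
      artifacts[[res_name]] <- result$artifact
      audit[[res_name]] <- result$rec
      reports[[res_name]] <- result$report
    }
  }
  list(artifacts = artifacts, audit = audit, reports = reports,
       outcome = outcome)
}
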