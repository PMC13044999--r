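# Salted irreversible pseudonymization and structured audit logging.
#
# Identifiers are replaced with keyed digests (HMAC-SHA-256, salt as key)
# rather than plain salt||id concatenation: the keyed construction gives the
# stated irreversibility property with a standard primitive. The salt is a
# run-time secret (environment/config); it is never written to exports, logs
# or audit records, and pseudonyms are not linkable across different salts.

#' Salt configuration for pseudonymization
#'
#' @param salt Secret character string, at least 16 bytes. Defaults to the
#'   `PDMSETL_SALT` environment variable.
#' @param digest_algorithm Digest algorithm name (default `"sha256"`).
#' @param output_length Number of hex characters retained (default 64, the
#'   full SHA-256 digest).
#' @return An object of class `pdms_salt_config`.
#' @export
salt_config <- function(salt = Sys.getenv("PDMSETL_SALT"),
                        digest_algorithm = "sha256",
                        output_length = 64L) {
  if (is.null(salt) || !nzchar(salt)) {
    pdms_error("pdms_configuration_error",
               "no salt configured: set PDMSETL_SALT or pass `salt`")
  }
  if (nchar(salt, type = "bytes") < 16L) {
    pdms_error("pdms_configuration_error", "salt must be at least 16 bytes")
  }
  structure(
    list(salt = salt, digest_algorithm = digest_algorithm,
         output_length = as.integer(output_length)),
    class = "pdms_salt_config"
  )
}

#' @export
print.pdms_salt_config <- function(x, ...) {
  # never echo the salt itself
  cat(sprintf("<pdms_salt_config: %s, %d hex chars, salt of %d bytes (hidden)>\n",
              x$digest_algorithm, x$output_length,
              nchar(x$salt, type = "bytes")))
  invisible(x)
}

#' Pseudonymize identifiers by salted irreversible hashing
#'
#' Deterministic for a given (identifier, salt) pair, so the same case keeps
#' the same pseudonym across all domains of a run and cross-domain linkage
#' remains possible in pseudonymized space; different salts yield unrelated
#' pseudonyms.
#'
#' @param identifier Character vector of identifiers; empty strings are
#'   rejected, `NA` passes through as `NA`.
#' @param cfg A [salt_config()].
#' @return Character vector of lowercase hex digests.
#' @export
pseudonymize <- function(identifier, cfg) {
  if (!inherits(cfg, "pdms_salt_config")) {
    pdms_error("pdms_configuration_error", "cfg must be a pdms_salt_config")
  }
  identifier <- as.character(identifier)
  if (any(!is.na(identifier) & !nzchar(identifier))) {
    pdms_error("pdms_value_error", "cannot pseudonymize an empty identifier")
  }
  out <- rep(NA_character_, length(identifier))
  todo <- which(!is.na(identifier))
  if (length(todo)) {
    # hash unique values once; identifier lists are highly repetitive
    uniq <- unique(identifier[todo])
    dig <- vapply(uniq, function(id) {
      digest::hmac(cfg$salt, id, algo = cfg$digest_algorithm)
    }, character(1L), USE.NAMES = FALSE)
    dig <- substr(dig, 1L, cfg$output_length)
    out[todo] <- dig[match(identifier[todo], uniq)]
  }
  out
}

#' Redact sensitive values in a parameter map
#'
#' Values under keys classified as sensitive are replaced element-wise by
#' pseudonyms; all other entries pass through verbatim. The key set is never
#' changed, so audit records stay structurally complete.
#'
#' @param params Named list of extraction parameters.
#' @param cfg A [salt_config()].
#' @param sensitive_keys Keys whose values are identifiers (default
#'   `c("case_ids", "patient_ids", "id_sample")`).
#' @return Named list with sensitive values pseudonymized.
#' @export
redact_parameters <- function(params, cfg,
                              sensitive_keys = c("case_ids", "patient_ids",
                                                 "id_sample")) {
  stopifnot(is.list(params))
  if (length(params) == 0L) return(params)
  for (key in intersect(names(params), sensitive_keys)) {
    params[[key]] <- pseudonymize(as.character(params[[key]]), cfg)
  }
  params
}

#' Construct an audit record
#'
#' One record documents one extraction event: actor, purpose, resource,
#' redacted parameters, row counts and runtime. Raw identifiers must never
#' appear; the caller passes already-redacted parameters and a hashed
#' identifier sample.
#'
#' @param actor User label.
#' @param purpose Free-text purpose of the extraction.
#' @param resource Resource name.
#' @param parameters Redacted named list (see [redact_parameters()]).
#' @param n_cases_requested,n_rows_exported Counts.
#' @param started_at,finished_at `POSIXct` instants (UTC).
#' @param id_sample Character vector of hashed case identifiers (a small
#'   sample for traceability).
#' @param outcome One of `"success"`, `"partial"`, `"error"`.
#' @param event_id Unique identifier; derived from content and time if omitted.
#' @return An object of class `pdms_audit_record` (named list).
#' @export
audit_record <- function(actor, purpose, resource, parameters = list(),
                         n_cases_requested, n_rows_exported,
                         started_at, finished_at,
                         id_sample = character(0),
                         outcome = c("success", "partial", "error"),
                         event_id = NULL) {
  outcome <- match.arg(outcome)
  if (is.null(event_id)) {
    event_id <- digest::digest(list(actor, resource, as.numeric(started_at),
                                    stats::runif(1)), algo = "sha1")
  }
  rec <- list(
    event_id = event_id,
    actor = actor,
    purpose = purpose,
    resource = resource,
    parameters = parameters,
    n_cases_requested = as.integer(n_cases_requested),
    n_rows_exported = as.integer(n_rows_exported),
    started_at = to_local(started_at),
    finished_at = to_local(finished_at),
    runtime_s = round(as.numeric(difftime(finished_at, started_at,
                                          units = "secs")), 3),
    id_sample = as.character(id_sample),
    outcome = outcome
  )
  class(rec) <- "pdms_audit_record"
  rec
}

#' Append an audit record to a JSON-lines sink
#'
#' One JSON object per line; the sink is append-only within a run. The sink
#' is opened (and the I/O error raised) before any export proceeds, so a run
#' that cannot be audited cannot export.
#'
#' @param record A [audit_record()].
#' @param sink Path to the JSON-lines audit log.
#' @return The serialized line, invisibly.
#' @export
write_audit <- function(record, sink) {
  stopifnot(inherits(record, "pdms_audit_record"))
  dir <- dirname(sink)
  if (!dir.exists(dir) || file.access(dir, 2L) != 0L) {
    pdms_error("pdms_io_error", sprintf("audit sink not writable: %s", sink))
  }
  line <- jsonlite::toJSON(unclass(record), auto_unbox = TRUE, null = "null",
                           digits = NA)
  con <- file(sink, open = "a", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(line, con)
  invisible(as.character(line))
}

#' Read an audit log
#'
#' @param sink Path to a JSON-lines audit log.
#' @return List of audit records (named lists).
#' @export
read_audit <- function(sink) {
  if (!file.exists(sink)) {
    pdms_error("pdms_io_error", sprintf("audit log not found: %s", sink))
  }
  lines <- readLines(sink, encoding = "UTF-8")
  lapply(lines[nzchar(lines)], jsonlite::fromJSON, simplifyVector = TRUE)
}

# ---- role-based template authorization --------------------------------------

#' Load the actor-to-template role map
#'
#' A static config mapping each actor to the extraction templates they may
#' run; `"*"` grants all templates. Fine-grained institutional user
#' management is front-end scope; this is its enforcement hook.
#'
#' @param path Optional path to a roles JSON file; defaults to the packaged
#'   example roles.
#' @return Named list actor -> character vector of permitted templates.
#' @export
load_roles <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "roles.json", package = "pdmsetl")
  }
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Check whether an actor may run a template
#'
#' @param actor User label.
#' @param template Template name.
#' @param roles Role map from [load_roles()].
#' @return `TRUE` invisibly, or raises an authorization error.
#' @export
authorize_actor <- function(actor, template, roles = load_roles()) {
  allowed <- roles[[actor]]
  if (is.null(allowed) || !(("*" %in% allowed) || template %in% allowed)) {
    pdms_error("pdms_authorization_error",
               sprintf("actor '%s' is not authorized for template '%s'",
                       actor, template))
  }
  invisible(TRUE)
}
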