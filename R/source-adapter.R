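# Read-only access to the relational PDMS source. All site-specific query
# logic is confined to this layer: porting the toolkit to a different PDMS
# schema means reimplementing these fetchers only. Identifier lists are
# chunked into bounded batches so queries never exceed relational parameter
# limits; results are multiset-equal for every chunk size.

#' Open a read-only handle to a relational PDMS source
#'
#' The connection is opened with the SQLite read-only flag, so any write
#' attempt fails at the database level; the adapter additionally refuses to
#' issue non-SELECT statements.
#'
#' @param uri Path to the SQLite fixture/source file.
#' @return An object of class `pdms_source` (fields `con`, `uri`,
#'   `read_only`, `dialect`).
#' @export
connect_readonly <- function(uri) {
  if (!file.exists(uri)) {
    pdms_error("pdms_connection_error", sprintf("source not reachable: %s", uri))
  }
  con <- tryCatch(
    DBI::dbConnect(RSQLite::SQLite(), uri, flags = RSQLite::SQLITE_RO),
    error = function(e) {
      pdms_error("pdms_connection_error",
                 sprintf("cannot open source %s: %s", uri, conditionMessage(e)))
    }
  )
  structure(list(con = con, uri = uri, read_only = TRUE, dialect = "sqlite"),
            class = "pdms_source")
}

#' Close a source handle
#' @param handle A `pdms_source`.
#' @export
disconnect <- function(handle) {
  stopifnot(inherits(handle, "pdms_source"))
  DBI::dbDisconnect(handle$con)
  invisible(NULL)
}

#' List tables available through a handle
#' @param handle A `pdms_source`.
#' @return Character vector of table names.
#' @export
source_tables <- function(handle) {
  stopifnot(inherits(handle, "pdms_source"))
  DBI::dbListTables(handle$con)
}

#' Run a SELECT query through a read-only handle
#'
#' Non-SELECT statements are rejected with a read-only violation before they
#' reach the database.
#'
#' @param handle A `pdms_source`.
#' @param sql SQL text (must be a SELECT).
#' @param params Optional list of positional parameters.
#' @return Data frame of results.
#' @export
source_query <- function(handle, sql, params = NULL) {
  stopifnot(inherits(handle, "pdms_source"))
  if (!grepl("^\\s*select\\b", sql, ignore.case = TRUE)) {
    pdms_error("pdms_readonly_error",
               "only SELECT statements are permitted through a read-only handle")
  }
  DBI::dbGetQuery(handle$con, sql, params = params)
}

#' Split an identifier list into bounded, order-preserving batches
#'
#' The concatenation of the returned chunks equals the input list; every
#' chunk holds at most `chunk_size` identifiers; an empty input yields an
#' empty plan.
#'
#' @param ids Identifier vector.
#' @param chunk_size Positive integer batch bound (default 500, safely below
#'   common relational parameter limits).
#' @return An object of class `pdms_batch_plan` (fields `chunk_size`,
#'   `chunks`).
#' @export
chunk_ids <- function(ids, chunk_size = 500L) {
  if (!is.finite(chunk_size) || chunk_size < 1) {
    pdms_error("pdms_value_error", "chunk_size must be >= 1")
  }
  chunk_size <- as.integer(chunk_size)
  chunks <- if (length(ids) == 0L) {
    list()
  } else {
    unname(split(ids, ceiling(seq_along(ids) / chunk_size)))
  }
  structure(list(chunk_size = chunk_size, chunks = chunks),
            class = "pdms_batch_plan")
}

#' Fetch rows for a set of case identifiers, in bounded batches
#'
#' Requested identifiers are deduplicated (set semantics: each source row is
#' returned once, regardless of how often its case id was requested), split
#' into chunks of at most `chunk_size`, and fetched with parameterized `IN`
#' queries. The resulting row multiset is independent of `chunk_size`;
#' column names arrive unchanged from the source.
#'
#' @param handle A `pdms_source`.
#' @param table Source table name.
#' @param case_ids Identifier vector.
#' @param chunk_size Positive integer batch bound.
#' @param id_column Name of the identifier column (default `"case_id"`).
#' @return Data frame of matched rows (empty, with source columns, when no
#'   id matches).
#' @export
fetch_by_case_ids <- function(handle, table, case_ids, chunk_size = 500L,
                              id_column = "case_id") {
  stopifnot(inherits(handle, "pdms_source"))
  if (!DBI::dbExistsTable(handle$con, table)) {
    pdms_error("pdms_schema_error", sprintf("unknown table: %s", table))
  }
  ids <- unique(as.character(case_ids))
  plan <- chunk_ids(ids, chunk_size)
  pieces <- lapply(plan$chunks, function(chunk) {
    ph <- paste(rep("?", length(chunk)), collapse = ", ")
    sql <- sprintf("SELECT * FROM %s WHERE %s IN (%s)",
                   DBI::dbQuoteIdentifier(handle$con, table),
                   DBI::dbQuoteIdentifier(handle$con, id_column), ph)
    DBI::dbGetQuery(handle$con, sql, params = as.list(chunk))
  })
  if (length(pieces) == 0L) {
    return(DBI::dbGetQuery(handle$con,
      sprintf("SELECT * FROM %s WHERE 1 = 0",
              DBI::dbQuoteIdentifier(handle$con, table))))
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Read a whole source table
#'
#' @param handle A `pdms_source`.
#' @param table Table name.
#' @return Data frame.
#' @export
fetch_table <- function(handle, table) {
  stopifnot(inherits(handle, "pdms_source"))
  if (!DBI::dbExistsTable(handle$con, table)) {
    pdms_error("pdms_schema_error", sprintf("unknown table: %s", table))
  }
  DBI::dbReadTable(handle$con, table)
}
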