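# Reconstruction of continuous therapy/device episodes from fragmented,
# partially unterminated interval records.
#
# Two documentation pathologies drive this module: reverification of an
# ongoing therapy always produces additional records for one continuous
# intervention, and end timestamps are frequently absent. Records for one
# (case, device) are therefore merged when they overlap, abut, or are
# separated by no more than a configurable gap tolerance; an open-ended
# record is treated as superseded by any later record of the same group.
# Remaining open episodes are closed against bed occupancy: if the occupancy
# interval enclosing the episode start has ended, the therapy cannot have
# outlived it, so its end is inferred from the occupancy end; if the bed is
# still occupied the therapy is flagged as truly ongoing.

#' Merge fragmented therapy records of one (case, device) group
#'
#' Records are sorted by start; a record joins the current episode iff its
#' start lies within `gap_tolerance` of the episode's running coverage. An
#' open-ended (missing end) record extends coverage indefinitely, so it
#' absorbs every later record of the group. The merged episode starts at the
#' earliest contributing start; its end is the latest documented end, unless
#' an open contributor starts at or after that end, in which case the
#' episode end is unresolved (`NA`) and left to occupancy-based inference.
#'
#' @param records Data frame with `record_id`, `case_id`, `device_type`,
#'   `start_ts`, `end_ts` (`POSIXct` UTC or UTC ISO-8601 strings; `end_ts`
#'   may be `NA`). All rows must share one (case, device).
#' @param gap_tolerance Maximum documentation gap (minutes) bridged within
#'   one episode (default 60).
#' @return Data frame of provisional episodes: `case_id`, `device_type`,
#'   `start_ts`, `end_ts` (`POSIXct`, `NA` when unresolved),
#'   `n_source_records`, `source_records` (";"-joined record ids).
#' @export
merge_records <- function(records, gap_tolerance = 60) {
  if (gap_tolerance < 0) {
    pdms_error("pdms_value_error", "gap_tolerance must be >= 0")
  }
  if (nrow(records) == 0L) {
    return(data.frame(case_id = character(0), device_type = character(0),
                      start_ts = as.POSIXct(character(0), tz = "UTC"),
                      end_ts = as.POSIXct(character(0), tz = "UTC"),
                      n_source_records = integer(0),
                      source_records = character(0), stringsAsFactors = FALSE))
  }
  if (length(unique(records$case_id)) > 1L ||
      length(unique(records$device_type)) > 1L) {
    pdms_error("pdms_grouping_error",
               "merge_records expects records of a single (case, device) group")
  }
  start <- as.numeric(parse_utc(records$start_ts))
  end <- as.numeric(parse_utc(records$end_ts))
  if (any(!is.na(end) & end < start)) {
    pdms_error("pdms_value_error", "record end_ts before start_ts")
  }
  tol <- gap_tolerance * 60
  ord <- order(start, end, method = "radix")
  start <- start[ord]; end <- end[ord]
  rid <- as.character(records$record_id)[ord]
  # sweep: coverage is +Inf once an open record contributes
  groups <- integer(length(start))
  g <- 0L
  cover <- -Inf
  for (i in seq_along(start)) {
    if (g == 0L || start[i] > cover + tol) g <- g + 1L
    groups[i] <- g
    cover <- max(cover, if (is.na(end[i])) Inf else end[i])
  }
  eps <- lapply(split(seq_along(start), groups), function(i) {
    doc_ends <- end[i][!is.na(end[i])]
    open_starts <- start[i][is.na(end[i])]
    ep_end <- if (length(doc_ends) == 0L) {
      NA_real_
    } else {
      m <- max(doc_ends)
      # an open record starting at/after the last documented end means the
      # therapy was re-documented as ongoing: end stays unresolved
      if (length(open_starts) && any(open_starts >= m)) NA_real_ else m
    }
    data.frame(case_id = records$case_id[1L],
               device_type = records$device_type[1L],
               start_ts = min(start[i]), end_ts = ep_end,
               n_source_records = length(i),
               source_records = paste(rid[i], collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, eps)
  out$start_ts <- as.POSIXct(out$start_ts, origin = "1970-01-01", tz = "UTC")
  out$end_ts <- as.POSIXct(out$end_ts, origin = "1970-01-01", tz = "UTC")
  rownames(out) <- NULL
  out
}

#' Infer missing episode end times from bed occupancy
#'
#' For an episode without a resolved end, the occupancy interval containing
#' the episode start decides: a closed occupancy bounds the therapy
#' (`end := occupancy end`, `end_inferred = TRUE`); an open occupancy marks
#' the therapy as truly ongoing. Documented ends are authoritative and pass
#' through untouched. An episode starting outside every occupancy interval
#' is retained but flagged as an orphan (with a warning).
#'
#' @param episodes Provisional episodes from [merge_records()].
#' @param occupancy Data frame with `case_id`, `start_ts`, `end_ts`
#'   (`POSIXct` UTC or ISO strings; open intervals have `NA` end).
#' @return Data frame of episodes with `end_inferred`, `ongoing`, `orphan`
#'   flags added.
#' @export
infer_end_times <- function(episodes, occupancy) {
  n <- nrow(episodes)
  episodes$end_inferred <- rep(FALSE, n)
  episodes$ongoing <- rep(FALSE, n)
  episodes$orphan <- rep(FALSE, n)
  if (n == 0L) return(episodes)
  os <- as.numeric(parse_utc(occupancy$start_ts))
  oe <- as.numeric(parse_utc(occupancy$end_ts))
  es <- as.numeric(episodes$start_ts)
  for (i in seq_len(n)) {
    if (!is.na(episodes$end_ts[i])) next
    j <- which(occupancy$case_id == episodes$case_id[i] &
                 os <= es[i] & (is.na(oe) | es[i] < oe))
    if (length(j) == 0L) {
      warning(sprintf("episode for case %s (%s) starts outside all occupancy intervals",
                      episodes$case_id[i], episodes$device_type[i]),
              call. = FALSE)
      episodes$orphan[i] <- TRUE
      next
    }
    j <- j[1L]  # occupancy intervals per case are non-overlapping
    if (is.na(oe[j])) {
      episodes$ongoing[i] <- TRUE
    } else {
      episodes$end_ts[i] <- as.POSIXct(oe[j], origin = "1970-01-01", tz = "UTC")
      episodes$end_inferred[i] <- TRUE
    }
  }
  episodes
}

#' Reconstruct continuous therapy episodes
#'
#' Groups raw therapy records by (case, device), merges fragments with
#' [merge_records()], closes unresolved ends with [infer_end_times()], and
#' returns episodes sorted by (case, device, start).
#'
#' @param records Raw therapy records (`record_id`, `case_id`,
#'   `device_type`, `start_ts`, `end_ts`).
#' @param occupancy Bed-occupancy intervals (`case_id`, `start_ts`,
#'   `end_ts`).
#' @param gap_tolerance Gap tolerance in minutes (default 60); may be a
#'   named vector giving per-device tolerances with a `"default"` entry.
#' @return Data frame of `TherapyEpisode` rows.
#' @export
reconstruct_episodes <- function(records, occupancy, gap_tolerance = 60) {
  if (nrow(records) == 0L) {
    out <- merge_records(records, 60)
    out$end_inferred <- logical(0); out$ongoing <- logical(0)
    out$orphan <- logical(0)
    return(out)
  }
  tol_for <- function(device) {
    if (length(gap_tolerance) == 1L && is.null(names(gap_tolerance))) {
      return(as.numeric(gap_tolerance))
    }
    if (device %in% names(gap_tolerance)) return(as.numeric(gap_tolerance[[device]]))
    if ("default" %in% names(gap_tolerance)) return(as.numeric(gap_tolerance[["default"]]))
    60
  }
  key <- paste(records$case_id, records$device_type, sep = "\r")
  merged <- lapply(split(seq_len(nrow(records)), key), function(i) {
    grp <- records[i, , drop = FALSE]
    merge_records(grp, tol_for(grp$device_type[1L]))
  })
  merged <- do.call(rbind, merged)
  out <- infer_end_times(merged, occupancy)
  out <- out[order(out$case_id, out$device_type, out$start_ts), , drop = FALSE]
  rownames(out) <- NULL
  out
}
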