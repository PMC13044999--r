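# Shared test helpers: fixture builders, a brute-force episode oracle, and a
# fixed test salt. Fixtures are generated in code at test time; nothing is
# stored on disk between runs.

TEST_SALT <- "unit-test-salt-0123456789abcdef"

# memoised fixture generation: several test blocks share one fixture config
.fixture_cache <- new.env(parent = emptyenv())

make_fixture <- function(n_cases = 30, seed = 101, ...) {
  key <- paste(n_cases, seed, paste(deparse(list(...)), collapse = ""),
               sep = "|")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  dir <- tempfile("fixture")
  dir.create(dir)
  cfg <- synthetic_config(n_cases = n_cases, seed = seed, ...)
  fx <- generate_fixture(cfg, file.path(dir, "pdms.sqlite"))
  .fixture_cache[[key]] <- fx
  fx
}

test_pipeline_config <- function(out_dir = tempfile("out"), ...) {
  pdms_config(salt = TEST_SALT, out_dir = out_dir, ...)
}

utc <- function(x) as.POSIXct(x, tz = "UTC")

therapy_rec <- function(start, end, case_id = "C1", device = "ECMO",
                        id = NULL) {
  n <- length(start)
  data.frame(
    record_id = if (is.null(id)) sprintf("R%02d", seq_len(n)) else id,
    case_id = case_id, device_type = device,
    start_ts = utc(start),
    end_ts = as.POSIXct(ifelse(is.na(end), NA, as.numeric(utc(end))),
                        origin = "1970-01-01", tz = "UTC"),
    stringsAsFactors = FALSE
  )
}

# ---- independent brute-force merge + inference oracle -----------------------
# Connected components of the pairwise "overlap/abut/within-gap" relation on
# intervals (open ends treated as +Inf), computed by explicit transitive
# closure; the episode end rule is re-derived from the definition, not shared
# with the implementation.
oracle_merge <- function(start, end, tol_minutes) {
  n <- length(start)
  if (n == 0L) return(data.frame(start = numeric(0), end = numeric(0),
                                 n = integer(0)))
  tol <- tol_minutes * 60
  s <- as.numeric(start)
  ee <- ifelse(is.na(end), Inf, as.numeric(end))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- (s[j] <= ee[i] + tol) && (s[i] <= ee[j] + tol)
    }
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (adj[i, k] && adj[k, j]) adj[i, j] <- TRUE
      }
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1L
      comp[adj[i, ]] <- cid
    }
  }
  out <- lapply(seq_len(cid), function(cc) {
    i <- which(comp == cc)
    doc <- as.numeric(end[i])[!is.na(end[i])]
    open_s <- s[i][is.na(end[i])]
    ep_end <- if (!length(doc)) {
      NA_real_
    } else if (length(open_s) && any(open_s >= max(doc))) {
      NA_real_
    } else max(doc)
    data.frame(start = min(s[i]), end = ep_end, n = length(i))
  })
  out <- do.call(rbind, out)
  out[order(out$start), , drop = FALSE]
}

oracle_infer <- function(eps, occ_start, occ_end) {
  # one occupancy interval; NA occ_end = still occupied
  for (i in seq_len(nrow(eps))) {
    if (is.na(eps$end[i])) {
      if (!is.na(occ_end)) eps$end[i] <- as.numeric(occ_end)
    }
  }
  eps
}

random_therapy_instance <- function(n_max = 12L) {
  n <- sample.int(n_max, 1L)
  base <- utc("2024-02-01 00:00:00")
  s <- as.numeric(base) + sample.int(72 * 60, n, replace = TRUE) * 60
  dur <- sample.int(24 * 60, n, replace = TRUE) * 60
  e <- s + dur
  e[stats::runif(n) < 0.3] <- NA
  therapy_rec(as.POSIXct(s, origin = "1970-01-01", tz = "UTC"),
              as.POSIXct(e, origin = "1970-01-01", tz = "UTC"))
}
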