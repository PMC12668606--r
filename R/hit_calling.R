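# Threshold-based hit evaluation, Scoring_Stats.csv bookkeeping, and radar
# normalization -- the computational core behind live campaign monitoring.

#' Build a threshold set
#'
#' @param specs data.frame with columns name, orientation
#'   ("lower_is_better"/"higher_is_better"), threshold, enabled
#' @return a `threshold_set`
#' @export
threshold_set <- function(specs) {
  stopifnot(is.data.frame(specs),
            all(c("name", "orientation", "threshold", "enabled") %in%
                names(specs)))
  if (anyDuplicated(specs$name)) stop("metric names must be unique",
                                      call. = FALSE)
  if (!all(specs$orientation %in% c("lower_is_better", "higher_is_better"))) {
    stop("orientation must be lower_is_better or higher_is_better",
         call. = FALSE)
  }
  if (any(specs$enabled & !is.finite(specs$threshold))) {
    stop("enabled metrics need finite thresholds", call. = FALSE)
  }
  structure(specs, class = c("threshold_set", "data.frame"))
}

#' Default hit thresholds
#'
#' The two standard in silico hit criteria are enabled: pLDDT_binder > 80
#' and PAE_interaction < 10 (strict inequalities). CUTRE ships disabled as
#' an optional extra filter.
#'
#' @return a `threshold_set`
#' @export
default_thresholds <- function() {
  threshold_set(data.frame(
    name = c("plddt_binder", "pae_interaction", "cutre"),
    orientation = c("higher_is_better", "lower_is_better", "lower_is_better"),
    threshold = c(80, 10, 10),
    enabled = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE))
}

#' Construct one design's score record
#'
#' @param design_id unique design identifier
#' @param batch_id batch identifier
#' @param metrics named numeric vector/list of metric values
#' @param binder_length binder length, residues
#' @param topology topology class label ("" when not assessed)
#' @param filter_reason rejection reason for filtered designs ("" otherwise)
#' @param strategy one of "standard", "partial_diffusion",
#'   "sequence_diversity"
#' @param thresholds a `threshold_set` used to stamp `is_hit`
#' @param timestamp optional ISO-8601 string (empty by default so score
#'   tables reproduce bit-identically under a fixed seed)
#' @return a `score_record`
#' @export
score_record <- function(design_id, batch_id, metrics, binder_length = NA,
                         topology = "", filter_reason = "",
                         strategy = "standard",
                         thresholds = default_thresholds(),
                         timestamp = "") {
  metrics <- as.list(metrics)
  rec <- structure(list(design_id = design_id, batch_id = batch_id,
                        binder_length = binder_length, metrics = metrics,
                        topology = topology, filter_reason = filter_reason,
                        strategy = strategy, timestamp = timestamp),
                   class = "score_record")
  rec$is_hit <- if (nzchar(filter_reason)) FALSE else
    evaluate_hit(rec, thresholds)
  rec
}

#' Evaluate the hit criteria for one record
#'
#' A design is a hit iff every enabled metric satisfies its strict
#' inequality: value > threshold for higher-is-better metrics, value <
#' threshold for lower-is-better. Values exactly at a threshold fail.
#'
#' @param record a `score_record` (or a bare named list/vector of metrics)
#' @param thresholds a `threshold_set`
#' @return logical
#' @export
evaluate_hit <- function(record, thresholds = default_thresholds()) {
  metrics <- if (inherits(record, "score_record")) record$metrics
             else as.list(record)
  enabled <- thresholds[thresholds$enabled, , drop = FALSE]
  for (k in seq_len(nrow(enabled))) {
    v <- metrics[[enabled$name[k]]]
    if (is.null(v) || is.na(v)) {
      stop("enabled metric '", enabled$name[k], "' missing from record",
           call. = FALSE)
    }
    ok <- if (enabled$orientation[k] == "higher_is_better") {
      v > enabled$threshold[k]
    } else {
      v < enabled$threshold[k]
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Normalize metrics against their thresholds for radar display
#'
#' Higher-is-better metrics map to value/threshold; lower-is-better to
#' threshold/value (with the value clamped below by `eps`), so a ratio of at
#' least 1 means the metric passes (up to the strict boundary).
#'
#' @param record a `score_record` or named metric list
#' @param thresholds a `threshold_set`
#' @param eps lower clamp for lower-is-better values
#' @return named numeric vector of ratios over the enabled metrics
#' @export
normalize_for_radar <- function(record, thresholds = default_thresholds(),
                                eps = 1e-9) {
  metrics <- if (inherits(record, "score_record")) record$metrics
             else as.list(record)
  enabled <- thresholds[thresholds$enabled, , drop = FALSE]
  if (any(enabled$threshold == 0)) {
    stop("zero threshold cannot be normalized", call. = FALSE)
  }
  out <- numeric(nrow(enabled))
  for (k in seq_len(nrow(enabled))) {
    v <- metrics[[enabled$name[k]]]
    out[k] <- if (enabled$orientation[k] == "higher_is_better") {
      v / enabled$threshold[k]
    } else {
      enabled$threshold[k] / max(v, eps)
    }
  }
  setNames(out, enabled$name)
}

# ---- Scoring_Stats.csv ----------------------------------------------------

SCORES_SCHEMA_COMMENT <- "#binderscreen-scores-v1"
SCORES_FIXED_COLS <- c("design_id", "batch_id", "strategy", "binder_length",
                       "topology", "filter_reason", "is_hit", "timestamp")
SCORES_CORE_METRICS <- c("plddt_binder", "pae_interaction", "cutre")

records_to_frame <- function(records) {
  extra <- setdiff(unique(unlist(lapply(records, function(r) names(r$metrics)))),
                   SCORES_CORE_METRICS)
  mcols <- c(SCORES_CORE_METRICS, sort(extra))
  rows <- lapply(records, function(r) {
    vals <- lapply(mcols, function(m) {
      v <- r$metrics[[m]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    })
    names(vals) <- mcols
    c(list(design_id = r$design_id, batch_id = r$batch_id,
           strategy = r$strategy,
           binder_length = as.numeric(r$binder_length),
           topology = r$topology, filter_reason = r$filter_reason),
      vals,
      list(is_hit = r$is_hit, timestamp = r$timestamp))
  })
  do.call(rbind, lapply(rows, function(x) as.data.frame(x, stringsAsFactors = FALSE)))
}

format_csv_field <- function(x) {
  if (is.numeric(x)) {
    out <- ifelse(is.na(x), "", formatC(x, format = "g", digits = 17))
  } else if (is.logical(x)) {
    out <- ifelse(x, "TRUE", "FALSE")
  } else {
    out <- as.character(x)
    out[is.na(out)] <- ""
    need <- grepl('[",\n]', out)
    out[need] <- paste0('"', gsub('"', '""', out[need]), '"')
  }
  out
}

# cooperative lock so concurrent batch writers never interleave rows;
# dir.create is atomic on POSIX filesystems
with_file_lock <- function(path, expr, timeout = 30) {
  lock <- paste0(path, ".lock")
  t0 <- Sys.time()
  while (!dir.create(lock, showWarnings = FALSE)) {
    if (as.numeric(Sys.time() - t0, units = "secs") > timeout) {
      stop("timed out waiting for lock on ", path, call. = FALSE)
    }
    Sys.sleep(0.05)
  }
  on.exit(unlink(lock, recursive = TRUE))
  force(expr)
}

#' Append score records to the campaign CSV
#'
#' Writes RFC-4180 CSV (UTF-8, "." decimal) with a schema-version comment
#' line and a fixed header; rows are appended whole under a file lock, so
#' concurrent batch writers never interleave partial rows. Rereading the
#' file recovers every numeric field at full precision. Missing metric
#' values serialize as empty cells. An existing file with a different
#' header is refused.
#'
#' @param path CSV path (conventionally `Scoring_Stats.csv`)
#' @param records list of `score_record`s
#' @return number of data rows written, invisibly
#' @export
append_scores <- function(path, records) {
  if (!length(records)) return(invisible(0L))
  df <- records_to_frame(records)
  header <- paste(names(df), collapse = ",")
  body <- do.call(paste, c(lapply(df, format_csv_field), sep = ","))
  with_file_lock(path, {
    if (file.exists(path)) {
      first <- readLines(path, n = 2)
      if (length(first) < 2 || first[1] != SCORES_SCHEMA_COMMENT ||
          first[2] != header) {
        stop("existing score file header does not match schema", call. = FALSE)
      }
      con <- file(path, open = "a", encoding = "UTF-8")
    } else {
      con <- file(path, open = "w", encoding = "UTF-8")
      writeLines(c(SCORES_SCHEMA_COMMENT, header), con)
    }
    writeLines(body, con)
    close(con)
  })
  invisible(length(body))
}

#' Read a campaign score CSV back into records
#'
#' @param path CSV path written by [append_scores()]
#' @return list(frame = data.frame, records = list of `score_record`)
#' @export
read_scores <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                 colClasses = NA)
  fixed <- intersect(SCORES_FIXED_COLS, names(df))
  mcols <- setdiff(names(df), fixed)
  records <- lapply(seq_len(nrow(df)), function(i) {
    metrics <- as.list(df[i, mcols, drop = FALSE])
    metrics <- metrics[!vapply(metrics, function(v) is.na(v), logical(1))]
    rec <- structure(list(design_id = df$design_id[i],
                          batch_id = df$batch_id[i],
                          binder_length = df$binder_length[i],
                          metrics = lapply(metrics, as.numeric),
                          topology = as.character(df$topology[i] %||% ""),
                          filter_reason = as.character(df$filter_reason[i] %||% ""),
                          strategy = df$strategy[i],
                          timestamp = as.character(df$timestamp[i] %||% "")),
                     class = "score_record")
    rec$is_hit <- as.logical(df$is_hit[i])
    rec
  })
  list(frame = df, records = records)
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0) b
  else if (length(a) == 1 && is.na(a)) b
  else a
}

#' Filter records by the hit criteria
#'
#' @param records list of `score_record`s
#' @param thresholds a `threshold_set`
#' @return list(hits, n_hits, success_rate) where success_rate = hits/total
#'   (0 for empty input)
#' @export
filter_records <- function(records, thresholds = default_thresholds()) {
  if (!length(records)) {
    return(list(hits = list(), n_hits = 0L, success_rate = 0))
  }
  pass <- vapply(records, function(r) {
    if (nzchar(r$filter_reason)) return(FALSE)
    evaluate_hit(r, thresholds)
  }, logical(1))
  list(hits = records[pass], n_hits = sum(pass),
       success_rate = sum(pass) / length(records))
}
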