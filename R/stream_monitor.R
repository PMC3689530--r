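#' Per-frame hit flags
#'
#' A frame is a hit when its strong-spot count meets the threshold
#' (default 16, the conventional cutoff for serial femtosecond
#' crystallography monitoring).
#'
#' @param records data.frame with at least a column `n_spots` (and
#'   typically `timestamp`, `frame_id`).
#' @param threshold Minimum spot count for a hit (default 16, >= 0).
#' @return Logical vector aligned with the records.
#' @export
hit_flags <- function(records, threshold = 16) {
  stopifnot(threshold >= 0)
  if (nrow(records) == 0) return(logical(0))
  if (any(records$n_spots < 0)) stop("spot counts must be non-negative")
  records$n_spots >= threshold
}

#' Sliding-window hit rate
#'
#' For each record at time t, the rate is the fraction of hits among the
#' records with timestamps in the causal window `(t - window, t]`
#' (default 5 s).  The window always contains the record itself, so the
#' rate is defined at every record; the denominator is the observed frame
#' count in the window, not a nominal cadence.
#'
#' @param records data.frame with columns `timestamp` (seconds, non-
#'   decreasing) and `n_spots`.
#' @param threshold Hit threshold (default 16).
#' @param window Window length in seconds (default 5, > 0).
#' @return data.frame with columns `window_end_time`, `hit_fraction`.
#' @export
sliding_hit_rate <- function(records, threshold = 16, window = 5) {
  stopifnot(window > 0)
  if (nrow(records) == 0) {
    return(data.frame(window_end_time = numeric(0), hit_fraction = numeric(0)))
  }
  ts <- records$timestamp
  bad <- which(diff(ts) < 0)
  if (length(bad)) {
    stop(sprintf("timestamps must be non-decreasing; record %d precedes record %d",
                 bad[1] + 1, bad[1]))
  }
  flags <- hit_flags(records, threshold)
  cum_n <- seq_along(ts)
  cum_h <- cumsum(flags)
  # first index with timestamp > t - window (window is (t - window, t])
  lo <- findInterval(ts - window, ts) + 1
  n_in <- cum_n - (lo - 1)
  h_in <- cum_h - c(0, cum_h)[lo]
  data.frame(window_end_time = ts, hit_fraction = h_in / n_in)
}

#' Build a hit series from frame records
#'
#' Bundles records, hit flags and the sliding-window rate curve.
#'
#' @inheritParams sliding_hit_rate
#' @return Object of class `hit_series` with `records` (including a `hit`
#'   column), `threshold`, `window` and `rates`.
#' @export
hit_series <- function(records, threshold = 16, window = 5) {
  records <- as.data.frame(records)
  records$hit <- hit_flags(records, threshold)
  structure(list(records = records, threshold = threshold, window = window,
                 rates = sliding_hit_rate(records, threshold, window)),
            class = "hit_series")
}

#' @export
print.hit_series <- function(x, ...) {
  s <- run_summary(x)
  cat(sprintf("Hit series: %d frame(s), %d hit(s) (fraction %.4f), threshold %d, window %g s\n",
              s$n_frames, s$n_hits, s$fraction, x$threshold, x$window))
  invisible(x)
}

#' Run summary of a hit series
#'
#' Totals over the stream: frame count, hit count and overall hit fraction,
#' with a per-run breakdown when the records carry a `run_id` column.
#' Totals are additive under stream concatenation.
#'
#' @param series A [hit_series()] (or a records data.frame, in which case
#'   the default threshold applies).
#' @param threshold Used only when `series` is a plain data.frame.
#' @return List: `n_frames`, `n_hits`, `fraction` (NaN for an empty
#'   stream), and `per_run` data.frame when run ids are present.
#' @export
run_summary <- function(series, threshold = 16) {
  rec <- if (inherits(series, "hit_series")) series$records
         else {
           d <- as.data.frame(series)
           d$hit <- hit_flags(d, threshold)
           d
         }
  out <- list(n_frames = nrow(rec), n_hits = sum(rec$hit),
              fraction = if (nrow(rec)) sum(rec$hit) / nrow(rec) else NaN)
  if (!is.null(rec$run_id)) {
    per <- stats::aggregate(hit ~ run_id, rec,
                            function(h) c(n = length(h), hits = sum(h)))
    out$per_run <- data.frame(run_id = per$run_id,
                              n_frames = per$hit[, "n"],
                              n_hits = per$hit[, "hits"])
  }
  out
}

#' Merge chunked hit-series summaries
#'
#' Processing contract for parallel monitoring: a stream split into
#' contiguous chunks, summarized independently and merged, must equal the
#' serial summary.  Rates are window-local, so they are recomputed on the
#' concatenated records.
#'
#' @param chunks List of record data.frames (contiguous pieces, in order).
#' @param threshold,window As in [hit_series()].
#' @return A [hit_series()] over the concatenated records.
#' @export
merge_hit_chunks <- function(chunks, threshold = 16, window = 5) {
  hit_series(do.call(rbind, lapply(chunks, as.data.frame)),
             threshold = threshold, window = window)
}

#' Read frame records from TSV/CSV
#'
#' Accepts a delimited file with columns `timestamp`, `frame_id`, `n_spots`
#' (header required; tab or comma separated).
#'
#' @param path Input path.
#' @return data.frame of frame records.
#' @export
read_frame_records <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep)
  need <- c("timestamp", "frame_id", "n_spots")
  if (!all(need %in% names(df))) {
    stop("frame records need columns: ", paste(need, collapse = ", "))
  }
  df
}
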