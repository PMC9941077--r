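#' Surgical event log of a session
#'
#' Needle-entry and thread-cut times per stitch. A stitch is completed when
#' its thread-cut time is present; uncompleted stitches keep their
#' needle-entry time but have `NA` thread cut. Events of successive stitches
#' must be ordered and non-overlapping.
#'
#' @param stitch_index stitch indices, unique and ascending.
#' @param needle_entry_s needle entry times, seconds.
#' @param thread_cut_s thread cut times, seconds; `NA` when uncompleted.
#' @param required_stitches number of stitches the task requires.
#' @return An `event_log` data frame with attribute `required_stitches`.
#' @export
event_log <- function(stitch_index, needle_entry_s, thread_cut_s,
                      required_stitches = 3L) {
  n <- length(stitch_index)
  if (n == 0L) stop_bad("event log must contain at least one needle entry")
  if (length(needle_entry_s) != n || length(thread_cut_s) != n)
    stop_bad("event columns must have equal length")
  if (anyDuplicated(stitch_index) ||
      (n > 1L && is.unsorted(stitch_index, strictly = TRUE)))
    stop_bad("stitch indices must be unique and ascending")
  check_number(required_stitches, "required_stitches", lower = 1, integer = TRUE)
  if (any(!is.finite(needle_entry_s)))
    stop_bad("needle entry times must be finite")
  bad <- !is.na(thread_cut_s) & thread_cut_s <= needle_entry_s
  if (any(bad)) stop_bad("thread cut must come after needle entry")
  last_evt <- ifelse(is.na(thread_cut_s), needle_entry_s, thread_cut_s)
  if (n > 1L && any(needle_entry_s[-1L] < last_evt[-n]))
    stop_bad("events of successive stitches must be ordered and non-overlapping")
  structure(data.frame(stitch_index = as.integer(stitch_index),
                       needle_entry_s = as.numeric(needle_entry_s),
                       thread_cut_s = as.numeric(thread_cut_s)),
            required_stitches = as.integer(required_stitches),
            class = c("event_log", "data.frame"))
}

as_event_log <- function(df, required = attr(df, "required_stitches") %||% 3L) {
  event_log(df$stitch_index, df$needle_entry_s, df$thread_cut_s, required)
}

n_completed <- function(log) sum(!is.na(log$thread_cut_s))

#' Time to realize one stitch
#'
#' Thread cut minus needle entry for a completed stitch, in seconds.
#'
#' @param log an [event_log()].
#' @param k stitch index.
#' @return Seconds.
#' @export
per_stitch_time <- function(log, k) {
  i <- match(k, log$stitch_index)
  if (is.na(i)) stop_bad(sprintf("no events for stitch %s", k))
  if (is.na(log$thread_cut_s[i]))
    stop_bad(sprintf("stitch %d is uncompleted; its time is undefined", log$stitch_index[i]))
  log$thread_cut_s[i] - log$needle_entry_s[i]
}

#' Total session time with the uncompleted-stitch penalty
#'
#' Raw total is the span from the first needle entry to the last thread cut.
#' Each required stitch left uncompleted adds a fixed penalty (300 s by
#' default) to the penalized total, so a premature termination is never
#' mistaken for a fast achievement. When no stitch was completed at all the
#' raw total falls back to the span up to the last recorded event and the
#' summary is flagged.
#'
#' @param log an [event_log()].
#' @param penalty_s penalty per uncompleted stitch, seconds.
#' @return A `time_summary` list: `total_raw_s`, `total_penalized_s`,
#'   `per_stitch_s` (named, completed stitches only), `intermediate_s`,
#'   `n_completed`, `n_uncompleted`, `raw_flagged`.
#' @export
total_time <- function(log, penalty_s = 300) {
  log <- as_event_log(log)
  check_number(penalty_s, "penalty_s", lower = 0)
  required <- attr(log, "required_stitches")
  done <- which(!is.na(log$thread_cut_s))
  first_entry <- log$needle_entry_s[1L]
  flagged <- length(done) == 0L
  raw <- if (flagged) {
    max(log$needle_entry_s, log$thread_cut_s, na.rm = TRUE) - first_entry
  } else {
    max(log$thread_cut_s[done]) - first_entry
  }
  n_done <- length(done)
  n_un <- max(required - n_done, 0L)
  ps <- vapply(log$stitch_index[done],
               function(k) per_stitch_time(log, k), numeric(1))
  names(ps) <- log$stitch_index[done]
  structure(list(
    total_raw_s = raw,
    total_penalized_s = raw + penalty_s * n_un,
    per_stitch_s = ps,
    intermediate_s = if (n_done >= 2L) suppressWarnings(intermediate_time(log))
                     else NA_real_,
    n_completed = n_done,
    n_uncompleted = n_un,
    raw_flagged = flagged
  ), class = "time_summary")
}

#' @export
print.time_summary <- function(x, ...) {
  cat(sprintf("<time_summary> raw %.1f s, penalized %.1f s (%d/%d+%d stitches completed)\n",
              x$total_raw_s, x$total_penalized_s, x$n_completed,
              x$n_completed, x$n_uncompleted))
  invisible(x)
}

#' Mean intermediate time between stitches
#'
#' Mean gap from one stitch's thread cut to the next stitch's needle entry,
#' over consecutive pairs of completed stitches. Gaps that involve an
#' uncompleted stitch have no defined endpoint and are excluded.
#'
#' @param log an [event_log()].
#' @return Seconds; `NA` (with a warning) when fewer than two completed
#'   stitches leave no gap to measure.
#' @export
intermediate_time <- function(log) {
  log <- as_event_log(log)
  done <- which(!is.na(log$thread_cut_s))
  gaps <- numeric(0)
  if (length(done) >= 2L) {
    for (j in seq_len(length(done) - 1L)) {
      a <- done[j]; b <- done[j + 1L]
      if (log$stitch_index[b] - log$stitch_index[a] == 1L)
        gaps <- c(gaps, log$needle_entry_s[b] - log$thread_cut_s[a])
    }
  }
  if (!length(gaps)) {
    warning("fewer than two consecutive completed stitches; intermediate time undefined",
            call. = FALSE)
    return(NA_real_)
  }
  mean(gaps)
}
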