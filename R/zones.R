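#' Two-circle zone partition of the microscope field of view
#'
#' The working area under the microscope is split into three zones by two
#' concentric circles: zone 1 is the corneal surface (inner circle), zone 2
#' the surface of the mounting base excluding the cornea (annulus between the
#' two circles), and zone 3 everything outside the base. Points exactly on a
#' boundary belong to the inner zone, so zone 1 is topologically closed.
#'
#' @param center numeric length-2, circle center (same units as the trace).
#' @param r_cornea radius of the cornea circle (zone 1 boundary).
#' @param r_base radius of the mounting-base circle (zone 2 outer boundary);
#'   must exceed `r_cornea`.
#' @param units coordinate units tag, `"mm"` or `"px"`.
#' @return A `zone_config` object.
#' @examples
#' z <- zone_config(center = c(0, 0), r_cornea = 5.5, r_base = 9.5)
#' attribute_zone(0, 0, z)        # 1: on the cornea
#' attribute_zone(7, 0, z)        # 2: on the base
#' attribute_zone(20, 0, z)       # 3: outside
#' @export
zone_config <- function(center = c(0, 0), r_cornea = 5.5, r_base = 9.5,
                        units = "mm") {
  if (!is.numeric(center) || length(center) != 2L || any(!is.finite(center)))
    stop_bad("'center' must be two finite numbers")
  check_number(r_cornea, "r_cornea", lower = 0)
  check_number(r_base, "r_base", lower = 0)
  if (r_cornea <= 0) stop_bad("'r_cornea' must be positive")
  if (r_base <= r_cornea) stop_bad("'r_base' must exceed 'r_cornea'")
  units <- match.arg(units, c("mm", "px"))
  structure(list(center = as.numeric(center), r_cornea = r_cornea,
                 r_base = r_base, units = units),
            class = "zone_config")
}

#' @export
print.zone_config <- function(x, ...) {
  cat(sprintf("<zone_config> center (%g, %g) %s, cornea r = %g, base r = %g\n",
              x$center[1], x$center[2], x$units, x$r_cornea, x$r_base))
  invisible(x)
}

#' Time-stamped instrument positions
#'
#' An ordered trace of 2-D instrument positions with a visibility flag.
#' When several tools are visible in a frame the trace carries one position
#' per sample: the innermost tool (a tool on the cornea dominates).
#' Invisible samples may have `NA` coordinates.
#'
#' @param t sample times in seconds, strictly increasing.
#' @param x,y coordinates; must be finite wherever `visible` is `TRUE`.
#' @param visible logical visibility flag per sample.
#' @return A `tool_trace` data frame with columns `t_s`, `x`, `y`, `visible`.
#' @export
tool_trace <- function(t, x, y, visible = rep(TRUE, length(t))) {
  n <- length(t)
  if (n == 0L) stop_bad("trace must contain at least one sample")
  if (length(x) != n || length(y) != n || length(visible) != n)
    stop_bad("trace columns must have equal length")
  if (any(!is.finite(t))) stop_bad("trace times must be finite")
  if (is.unsorted(t, strictly = TRUE))
    stop_bad("trace times must be strictly increasing")
  visible <- as.logical(visible)
  if (any(is.na(visible))) stop_bad("'visible' must not contain NA")
  bad <- visible & (!is.finite(x) | !is.finite(y))
  if (any(bad))
    stop_bad(sprintf("non-finite coordinates on %d visible sample(s)", sum(bad)))
  structure(data.frame(t_s = as.numeric(t), x = as.numeric(x),
                       y = as.numeric(y), visible = visible),
            class = c("tool_trace", "data.frame"))
}

as_tool_trace <- function(df) {
  tool_trace(df$t_s, df$x, df$y, df$visible)
}

#' Attribute an instrument position to a zone
#'
#' Maps positions to zones 1/2/3 by distance from the zone center, with
#' boundary distances belonging to the inner zone. Samples flagged invisible
#' are allocated zone 3 regardless of coordinates: a tool that is not in the
#' field of view is by definition outside the mounting base.
#'
#' @param x,y coordinates (vectorized); ignored where `visible` is `FALSE`.
#' @param zones a [zone_config()].
#' @param visible logical, recycled to the length of `x`.
#' @return Integer vector of zones in `{1, 2, 3}`.
#' @export
attribute_zone <- function(x, y, zones, visible = TRUE) {
  stopifnot(inherits(zones, "zone_config"))
  n <- length(x)
  if (length(y) != n) stop_bad("'x' and 'y' must have equal length")
  visible <- rep_len(as.logical(visible), n)
  if (any(visible & (!is.finite(x) | !is.finite(y))))
    stop_bad("non-finite coordinates on a visible sample")
  zone <- rep.int(3L, n)
  vis <- which(visible)
  if (length(vis)) {
    d <- sqrt((x[vis] - zones$center[1])^2 + (y[vis] - zones$center[2])^2)
    zone[vis] <- ifelse(d <= zones$r_cornea, 1L,
                        ifelse(d <= zones$r_base, 2L, 3L))
  }
  zone
}

#' Resample a trace at a fixed rate
#'
#' Takes the nearest-in-time input sample at each tick `t0, t0 + 1/rate, ...`
#' up to the last trace time (both endpoints included), where `t0` is the
#' first trace time. Ties between two equally near samples are broken toward
#' the earlier sample. Output timestamps are the tick times. Video-derived
#' traces are conventionally resampled at 1 Hz.
#'
#' @param trace a [tool_trace()].
#' @param rate_hz sampling rate in Hz, positive.
#' @return A `tool_trace` sampled at the tick times.
#' @export
sample_trace <- function(trace, rate_hz = 1) {
  trace <- as_tool_trace(trace)
  check_number(rate_hz, "rate_hz")
  if (rate_hz <= 0) stop_bad("'rate_hz' must be positive")
  t0 <- trace$t_s[1]
  span <- trace$t_s[nrow(trace)] - t0
  ticks <- t0 + seq(0, span, by = 1 / rate_hz)
  # nearest neighbour via the sorted times; ties go to the earlier sample
  n <- nrow(trace)
  lo <- pmax(findInterval(ticks, trace$t_s), 1L)
  hi <- pmin(lo + 1L, n)
  idx <- ifelse(ticks - trace$t_s[lo] <= trace$t_s[hi] - ticks, lo, hi)
  structure(data.frame(t_s = ticks, x = trace$x[idx], y = trace$y[idx],
                       visible = trace$visible[idx]),
            class = c("tool_trace", "data.frame"))
}

#' Zone timeline of a trace
#'
#' Resamples the trace at `rate_hz` and attributes each retained sample to a
#' zone; the timeline is what zone-transition plots display.
#'
#' @inheritParams sample_trace
#' @param zones a [zone_config()].
#' @return A data frame with columns `t_s` and `zone`.
#' @export
zone_timeline <- function(trace, zones, rate_hz = 1) {
  s <- sample_trace(trace, rate_hz)
  data.frame(t_s = s$t_s,
             zone = attribute_zone(s$x, s$y, zones, s$visible))
}

#' Summarize zone occupancy and transitions
#'
#' Computes the fraction of samples spent in each zone, the full 3x3 table of
#' consecutive-sample transitions (diagonal = stays), and the back-and-forth
#' count between zones 1 and 2 (number of direct 1->2 plus 2->1 moves), both
#' raw and per minute of timeline span.
#'
#' @param timeline a data frame with columns `t_s`, `zone` as produced by
#'   [zone_timeline()].
#' @return A `zone_summary` list with elements `fraction_zone` (length 3),
#'   `transitions` (3x3 count matrix), `n_samples`, `back_and_forth_12`,
#'   `back_and_forth_12_per_min`.
#' @export
summarize_zones <- function(timeline) {
  if (is.null(timeline$zone) || nrow(timeline) == 0L)
    stop_bad("timeline must be non-empty with a 'zone' column")
  z <- as.integer(timeline$zone)
  if (any(!z %in% 1:3)) stop_bad("zones must be in {1, 2, 3}")
  n <- length(z)
  frac <- tabulate(z, nbins = 3L) / n
  trans <- matrix(0L, 3, 3, dimnames = list(from = 1:3, to = 1:3))
  if (n > 1L) {
    a <- z[-n]; b <- z[-1L]
    for (k in seq_len(n - 1L)) trans[a[k], b[k]] <- trans[a[k], b[k]] + 1L
  }
  bf <- if (n > 1L) sum((z[-n] == 1L & z[-1L] == 2L) |
                        (z[-n] == 2L & z[-1L] == 1L)) else 0L
  span_min <- if (n > 1L) (timeline$t_s[n] - timeline$t_s[1]) / 60 else NA_real_
  structure(list(
    fraction_zone = frac,
    transitions = trans,
    n_samples = n,
    back_and_forth_12 = as.integer(bf),
    back_and_forth_12_per_min = if (isTRUE(span_min > 0)) bf / span_min else NA_real_
  ), class = "zone_summary")
}

#' @export
print.zone_summary <- function(x, ...) {
  cat(sprintf("<zone_summary> %d samples; %% time in zone 1/2/3: %s; 1<->2 moves: %d\n",
              x$n_samples,
              paste(sprintf("%.1f", 100 * x$fraction_zone), collapse = "/"),
              x$back_and_forth_12))
  invisible(x)
}

#' Locate the instrument in a grayscale frame
#'
#' Thresholds the frame, discards the faint zone-circle annotation band, and
#' returns the intensity-weighted centroid of the largest above-threshold
#' connected component, or `NULL` when no instrument is visible. The default
#' threshold is Otsu's automatic threshold, floored at `annotation_max` so the
#' drawn zone circles (rendered well below that intensity) never register as
#' an instrument; pass `threshold` to override, mirroring the human-assisted
#' attribution the workflow automates.
#'
#' @param frame numeric matrix in `[0, 1]`, indexed `[x, y]` (x right, y down).
#' @param threshold manual intensity threshold, or `NULL` for automatic.
#' @param annotation_max highest intensity used by faint annotations; pixels
#'   at or below it are never part of the instrument.
#' @return Numeric length-2 centroid `(x, y)` in pixel coordinates (1-based),
#'   or `NULL` if no blob is found.
#' @export
detect_instrument <- function(frame, threshold = NULL, annotation_max = 0.3) {
  if (!is.matrix(frame) || length(frame) == 0L)
    stop_bad("'frame' must be a non-empty numeric matrix")
  if (is.null(threshold)) {
    threshold <- tryCatch(
      EBImage::otsu(EBImage::Image(frame), range = c(0, 1)),
      error = function(e) annotation_max)
  }
  thr <- max(threshold, annotation_max)
  mask <- frame > thr
  if (!any(mask)) return(NULL)
  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(lab[lab > 0])
  keep <- which.max(areas)
  sel <- lab == keep
  w <- frame * sel
  ix <- row(frame); iy <- col(frame)
  tot <- sum(w)
  c(x = sum(ix * w) / tot, y = sum(iy * w) / tot)
}
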