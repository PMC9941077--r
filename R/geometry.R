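#' Stitch endpoint set from an end-of-session photograph
#'
#' Holds the entry/exit endpoints and completion status of the stitches
#' placed during one session, as digitized from the picture of the cornea
#' acquired when the session ends. Uncompleted stitches have no final
#' endpoints and are excluded from all geometry.
#'
#' @param index stitch indices, unique and ascending.
#' @param entry_x,entry_y,exit_x,exit_y endpoint coordinates.
#' @param completed logical per stitch.
#' @param units `"mm"` or `"px"`.
#' @param mm_per_px calibration scale, required when `units = "px"`.
#' @return A `stitch_set` data frame with attributes `units`, `mm_per_px`.
#' @export
stitch_set <- function(index, entry_x, entry_y, exit_x, exit_y,
                       completed = rep(TRUE, length(index)),
                       units = "mm", mm_per_px = NA_real_) {
  units <- match.arg(units, c("mm", "px"))
  n <- length(index)
  lens <- c(length(entry_x), length(entry_y), length(exit_x),
            length(exit_y), length(completed))
  if (any(lens != n)) stop_bad("stitch columns must have equal length")
  if (anyDuplicated(index) || (n > 1L && is.unsorted(index, strictly = TRUE)))
    stop_bad("stitch indices must be unique and ascending")
  completed <- as.logical(completed)
  same <- completed & entry_x == exit_x & entry_y == exit_y
  if (any(same, na.rm = TRUE))
    stop_bad("a completed stitch must have distinct entry and exit points")
  df <- data.frame(index = as.integer(index),
                   entry_x = as.numeric(entry_x), entry_y = as.numeric(entry_y),
                   exit_x = as.numeric(exit_x), exit_y = as.numeric(exit_y),
                   completed = completed)
  structure(df, units = units, mm_per_px = mm_per_px,
            class = c("stitch_set", "data.frame"))
}

as_stitch_set <- function(df, units = attr(df, "units") %||% "mm",
                          mm_per_px = attr(df, "mm_per_px") %||% NA_real_) {
  stitch_set(df$index, df$entry_x, df$entry_y, df$exit_x, df$exit_y,
             df$completed, units = units, mm_per_px = mm_per_px)
}

#' Calibrate a stitch set to millimetres
#'
#' Pixel coordinates are multiplied by `mm_per_px`; millimetre input is
#' returned unchanged (idempotent).
#'
#' @param set a [stitch_set()].
#' @return The set in mm.
#' @export
calibrate <- function(set) {
  stopifnot(inherits(set, "stitch_set"))
  if (attr(set, "units") == "mm") return(set)
  s <- attr(set, "mm_per_px")
  if (!is.numeric(s) || is.na(s) || s <= 0)
    stop_bad("pixel-unit stitches require a positive 'mm_per_px' scale")
  cols <- c("entry_x", "entry_y", "exit_x", "exit_y")
  set[cols] <- lapply(set[cols], function(v) v * s)
  attr(set, "units") <- "mm"
  attr(set, "mm_per_px") <- NA_real_
  set
}

one_stitch <- function(set, k) {
  i <- match(k, set$index)
  if (is.na(i)) stop_bad(sprintf("no stitch with index %s", k))
  set[i, , drop = FALSE]
}

#' Length of a completed stitch
#'
#' Euclidean distance between entry and exit points. A well-formed corneal
#' stitch is about 2 mm long; see [quality_deviation()].
#'
#' @param set a calibrated [stitch_set()].
#' @param k stitch index.
#' @return Length in the set's units.
#' @export
stitch_length <- function(set, k) {
  s <- one_stitch(set, k)
  if (!s$completed)
    stop_bad(sprintf("stitch %d is uncompleted and has no geometry", s$index))
  sqrt((s$exit_x - s$entry_x)^2 + (s$exit_y - s$entry_y)^2)
}

#' Length ratios with respect to the first stitch
#'
#' `ratio_k = length_k / length_1` for every completed stitch `k >= 2`.
#' Ratios above 1 indicate stitches growing over the course of the session,
#' below 1 shrinking. Undefined (empty, with a warning flag attribute) when
#' stitch 1 is absent or uncompleted.
#'
#' @param set a calibrated [stitch_set()].
#' @return Named numeric vector of ratios; attribute `defined` is `FALSE`
#'   when stitch 1 is unavailable.
#' @export
length_ratios <- function(set) {
  stopifnot(inherits(set, "stitch_set"))
  i1 <- match(1L, set$index)
  if (is.na(i1) || !set$completed[i1]) {
    return(structure(numeric(0), defined = FALSE))
  }
  l1 <- stitch_length(set, 1L)
  ks <- set$index[set$completed & set$index >= 2L]
  r <- vapply(ks, function(k) stitch_length(set, k) / l1, numeric(1))
  structure(stats::setNames(r, ks), defined = TRUE)
}

#' Distance between two successive stitches
#'
#' Euclidean distance between the stitch midpoints; both stitches must be
#' completed and have consecutive indices. Spacing of about 1 mm between
#' stitches closing a 4 mm wound is considered satisfactory.
#'
#' @param set a calibrated [stitch_set()].
#' @param a,b consecutive stitch indices.
#' @return Distance in the set's units.
#' @export
inter_stitch_distance <- function(set, a, b) {
  if (abs(a - b) != 1L) stop_bad("stitches must have consecutive indices")
  sa <- one_stitch(set, a); sb <- one_stitch(set, b)
  if (!sa$completed || !sb$completed)
    stop_bad("both stitches must be completed")
  ma <- c((sa$entry_x + sa$exit_x) / 2, (sa$entry_y + sa$exit_y) / 2)
  mb <- c((sb$entry_x + sb$exit_x) / 2, (sb$entry_y + sb$exit_y) / 2)
  sqrt(sum((ma - mb)^2))
}

#' Angle between two successive stitches
#'
#' Acute angle in degrees between the undirected stitch directions, in
#' `[0, 90]`: 0 for parallel stitches, 90 for perpendicular ones. Computed
#' from `|cos(theta)|` of the normalized direction vectors, so swapping a
#' stitch's endpoints leaves the angle unchanged.
#'
#' @inheritParams inter_stitch_distance
#' @return Angle in degrees.
#' @export
inter_stitch_angle <- function(set, a, b) {
  if (abs(a - b) != 1L) stop_bad("stitches must have consecutive indices")
  sa <- one_stitch(set, a); sb <- one_stitch(set, b)
  if (!sa$completed || !sb$completed)
    stop_bad("both stitches must be completed")
  va <- c(sa$exit_x - sa$entry_x, sa$exit_y - sa$entry_y)
  vb <- c(sb$exit_x - sb$entry_x, sb$exit_y - sb$entry_y)
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) stop_bad("degenerate zero-length stitch")
  cosang <- min(1, abs(sum(va * vb)) / (na * nb))
  acos(cosang) * 180 / pi
}

#' Deviation from the reference stitch geometry
#'
#' Absolute deviations of every completed stitch length from the reference
#' length (2 mm, the accepted size of a suitable corneal stitch) and of
#' every successive-pair spacing from the reference spacing (1 mm).
#'
#' @param set a calibrated [stitch_set()].
#' @param ref_length_mm,ref_spacing_mm reference geometry in mm.
#' @return List with `length_dev`, `spacing_dev` and their means.
#' @export
quality_deviation <- function(set, ref_length_mm = 2, ref_spacing_mm = 1) {
  g <- summarize_geometry(set)
  ld <- abs(g$length_mm - ref_length_mm)
  sd_ <- abs(g$distance_mm - ref_spacing_mm)
  list(length_dev = ld, spacing_dev = sd_,
       mean_length_dev = if (length(ld)) mean(ld) else NA_real_,
       mean_spacing_dev = if (length(sd_)) mean(sd_) else NA_real_)
}

#' Summarize stitch geometry
#'
#' Aggregates the four geometry criteria over completed stitches: per-stitch
#' lengths, length ratios with respect to stitch 1, and midpoint distance
#' and acute angle for each pair of successive completed stitches.
#' Uncompleted stitches contribute to none of them.
#'
#' @param set a [stitch_set()]; pixel sets are calibrated first.
#' @return A `geometry_summary` list with `length_mm` (named by stitch),
#'   `length_ratio`, `distance_mm`, `angle_deg` (named by pair), and
#'   `n_completed`.
#' @export
summarize_geometry <- function(set) {
  set <- calibrate(as_stitch_set(set))
  done <- set$index[set$completed]
  lens <- vapply(done, function(k) stitch_length(set, k), numeric(1))
  names(lens) <- done
  pairs <- if (length(done) >= 2L) {
    cand <- cbind(done[-length(done)], done[-1L])
    cand[cand[, 2] - cand[, 1] == 1L, , drop = FALSE]
  } else matrix(numeric(0), 0, 2)
  dist <- vapply(seq_len(nrow(pairs)), function(i)
    inter_stitch_distance(set, pairs[i, 1], pairs[i, 2]), numeric(1))
  ang <- vapply(seq_len(nrow(pairs)), function(i)
    inter_stitch_angle(set, pairs[i, 1], pairs[i, 2]), numeric(1))
  pn <- if (nrow(pairs)) paste(pairs[, 1], pairs[, 2], sep = "-") else character(0)
  ratios <- length_ratios(set)
  structure(list(
    length_mm = lens,
    length_ratio = stats::setNames(as.numeric(ratios), names(ratios)),
    distance_mm = stats::setNames(as.numeric(dist), pn),
    angle_deg = stats::setNames(as.numeric(ang), pn),
    n_completed = length(done)
  ), class = "geometry_summary")
}

#' @export
print.geometry_summary <- function(x, ...) {
  cat(sprintf("<geometry_summary> %d completed stitch(es)\n", x$n_completed))
  if (length(x$length_mm))
    cat("  lengths (mm):", paste(sprintf("%.2f", x$length_mm), collapse = ", "), "\n")
  if (length(x$length_ratio))
    cat("  ratios vs stitch 1:", paste(sprintf("%.2f", x$length_ratio), collapse = ", "), "\n")
  if (length(x$distance_mm))
    cat("  midpoint distances (mm):", paste(sprintf("%.2f", x$distance_mm), collapse = ", "), "\n")
  if (length(x$angle_deg))
    cat("  angles (deg):", paste(sprintf("%.1f", x$angle_deg), collapse = ", "), "\n")
  invisible(x)
}
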