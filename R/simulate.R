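#' Simulate one suturing session
#'
#' Generates a complete synthetic session with the statistical structure the
#' downstream analyses assume: per-stitch completion is Bernoulli in the
#' profile's completion probability; per-stitch durations and inter-stitch
#' gaps are log-normal with the stated medians; the instrument trace is the
#' fixed-rate sampling of a continuous-time 3-state zone process (positions
#' drawn uniformly inside the corresponding zone region when in zones 1/2,
#' flagged invisible in zone 3); stitch endpoints follow the ideal template
#' (evenly spaced along the wound, perpendicular to it) perturbed by the
#' profile's drift, spacing and angle-jitter parameters; two raters' rubric
#' sheets are integer-rounded truncated-normal item draws; and a RULA
#' posture consistent with the profile's grand mode is emitted. The same
#' `(profile, scenario, seed)` triple always yields the identical session.
#'
#' @param profile a [group_profile()].
#' @param scenario a [scenario_config()].
#' @param seed integer seed.
#' @param participant participant identifier.
#' @param session session index (1-based).
#' @param streams character vector of streams to generate, any of
#'   `"trace"`, `"stitches"`, `"events"`, `"scores"`; the full set by
#'   default. Dropping `"trace"` is useful in large calibration runs where
#'   only event/score statistics are needed.
#' @return A `session_record` list: `participant`, `group`, `session`,
#'   `trace`, `stitches`, `events`, `zhang` (list of sheets), `rula` (list
#'   of postures), `meta` (scenario and wound geometry).
#' @export
simulate_session <- function(profile, scenario = scenario_config(), seed = 1L,
                             participant = "p01", session = 1L,
                             streams = c("trace", "stitches", "events",
                                         "scores")) {
  stopifnot(inherits(profile, "group_profile"),
            inherits(scenario, "scenario_config"))
  check_number(seed, "seed", integer = TRUE)
  streams <- match.arg(streams, several.ok = TRUE)
  with_seed(seed, {
    n <- scenario$n_stitches_required
    completed <- stats::runif(n) < profile$completion_prob
    dur <- stats::rlnorm(n, log(profile$stitch_time_median_s),
                         profile$stitch_time_log_sd)
    gap <- stats::rlnorm(n, log(profile$gap_time_median_s),
                         profile$gap_time_log_sd)

    entry <- numeric(n); cut <- rep(NA_real_, n)
    t <- 0
    for (k in seq_len(n)) {
      entry[k] <- t
      if (completed[k]) cut[k] <- t + dur[k]
      t <- t + dur[k] + gap[k]            # attempt time elapses either way
    }
    session_end <- if (completed[n]) cut[n] else entry[n] + dur[n]
    events <- event_log(seq_len(n), entry, cut, required_stitches = n)

    stitches <- simulate_stitches(profile, scenario, completed)
    trace <- if ("trace" %in% streams) {
      simulate_trace(profile$zone_rates, session_end, scenario$sampling_hz,
                     scenario$zones)
    } else NULL
    scores <- if ("scores" %in% streams) {
      list(
        zhang = lapply(c("rater1", "rater2"), function(r)
          zhang_sheet(r, draw_items(profile$zhang_item_mean,
                                    profile$zhang_item_sd, 12L))),
        rula = list(rula_posture_for_grand(profile$rula_grand_mode))
      )
    } else list(zhang = NULL, rula = NULL)

    structure(list(
      participant = as.character(participant),
      group = profile$group_label,
      session = as.integer(session),
      trace = trace,
      stitches = stitches,
      events = events,
      zhang = scores$zhang,
      rula = scores$rula,
      meta = list(schema_version = 1L,
                  scenario = scenario,
                  wound_endpoints = scenario$wound_endpoints,
                  seed = as.integer(seed))
    ), class = "session_record")
  })
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record> %s (%s) session %d: %d/%d stitches completed%s\n",
              x$participant, x$group, x$session, n_completed(x$events),
              attr(x$events, "required_stitches"),
              if (is.null(x$trace)) "" else
                sprintf(", %d trace samples", nrow(x$trace))))
  invisible(x)
}

# Integer-rounded truncated-normal item draws on the rubric scale.
draw_items <- function(mean, sd, k) {
  pmin(pmax(round(stats::rnorm(k, mean, sd)), 1L), 5L)
}

# Stitch endpoints: midpoints laid along the wound axis with normally
# perturbed gaps (centered on the wound), directions perpendicular to the
# wound rotated by the angle jitter, lengths mean * drift^(k-1) plus noise.
simulate_stitches <- function(profile, scenario, completed) {
  n <- length(completed)
  th <- scenario$wound_orientation_deg * pi / 180
  u <- c(cos(th), sin(th))                 # along the wound
  gaps <- stats::rnorm(max(n - 1L, 0L), profile$spacing_mm,
                       profile$spacing_sd_mm)
  pos <- c(0, cumsum(gaps))
  pos <- pos - mean(range(pos))            # centered on the wound
  len <- pmax((profile$stitch_length_mm +
                 stats::rnorm(n, 0, profile$stitch_length_sd_mm)), 0.05) *
    profile$length_drift^(seq_len(n) - 1L)
  phi <- stats::rnorm(n, 0, profile$angle_jitter_deg_sd) * pi / 180
  ex <- ey <- xx <- xy <- numeric(n)
  for (k in seq_len(n)) {
    mid <- scenario$wound_center + u * pos[k]
    a <- th + pi / 2 + phi[k]              # perpendicular, jittered
    d <- c(cos(a), sin(a))
    ex[k] <- mid[1] - d[1] * len[k] / 2; ey[k] <- mid[2] - d[2] * len[k] / 2
    xx[k] <- mid[1] + d[1] * len[k] / 2; xy[k] <- mid[2] + d[2] * len[k] / 2
  }
  stitch_set(seq_len(n), ex, ey, xx, xy, completed, units = "mm")
}

#' Simulate the zone process of an instrument trace
#'
#' Runs a continuous-time 3-state Markov process with the given rate matrix
#' from zone 1 over `[0, duration_s]` and samples it at `rate_hz`. Zone 1/2
#' samples get positions drawn uniformly in the corresponding region of the
#' zone partition; zone 3 samples are invisible.
#'
#' @param rates 3x3 transition-rate matrix (events/s), diagonal ignored.
#' @param duration_s process duration, seconds.
#' @param rate_hz sampling rate, Hz.
#' @param zones a [zone_config()].
#' @param init initial state in `{1, 2, 3}`.
#' @return A [tool_trace()].
#' @export
simulate_trace <- function(rates, duration_s, rate_hz = 1,
                           zones = zone_config(), init = 1L) {
  check_number(duration_s, "duration_s", lower = 0)
  jump_t <- 0; state <- as.integer(init)
  times <- 0; states <- state
  repeat {
    out <- rates[state, ]; out[state] <- 0
    r <- sum(out)
    if (r <= 0) break
    jump_t <- jump_t + stats::rexp(1, r)
    if (jump_t > duration_s) break
    state <- sample.int(3L, 1L, prob = out)
    times <- c(times, jump_t); states <- c(states, state)
  }
  ticks <- seq(0, duration_s, by = 1 / rate_hz)
  z <- states[findInterval(ticks, times)]
  x <- y <- rep(NA_real_, length(ticks))
  vis <- z != 3L
  n1 <- sum(z == 1L); n2 <- sum(z == 2L)
  if (n1) {
    rad <- zones$r_cornea * sqrt(stats::runif(n1))
    ang <- stats::runif(n1, 0, 2 * pi)
    x[z == 1L] <- zones$center[1] + rad * cos(ang)
    y[z == 1L] <- zones$center[2] + rad * sin(ang)
  }
  if (n2) {
    rad <- sqrt(stats::runif(n2, zones$r_cornea^2, zones$r_base^2))
    ang <- stats::runif(n2, 0, 2 * pi)
    x[z == 2L] <- zones$center[1] + rad * cos(ang)
    y[z == 2L] <- zones$center[2] + rad * sin(ang)
  }
  tool_trace(ticks, x, y, vis)
}

#' Simulate a cohort of sessions
#'
#' One call per participant-session, with per-session seeds derived from the
#' master seed by a fixed counter scheme, so the cohort is reproducible as a
#' whole while sessions stay mutually independent. The default shape mirrors
#' a three-group study with 5/8/11 participants and three sessions each.
#'
#' @param profiles list of [group_profile()] objects, one per group.
#' @param n_per_group participants per group; recycled over `profiles`.
#' @param sessions_per_participant sessions per participant.
#' @param seed master integer seed.
#' @param scenario a [scenario_config()] shared by all sessions.
#' @param streams passed to [simulate_session()].
#' @return List of `session_record` objects.
#' @export
simulate_cohort <- function(profiles = default_profiles(),
                            n_per_group = c(5L, 8L, 11L),
                            sessions_per_participant = 3L,
                            seed = 1L,
                            scenario = scenario_config(),
                            streams = c("trace", "stitches", "events",
                                        "scores")) {
  if (!length(profiles)) stop_bad("'profiles' must not be empty")
  lapply(profiles, function(p) stopifnot(inherits(p, "group_profile")))
  n_per_group <- rep_len(as.integer(n_per_group), length(profiles))
  if (any(n_per_group < 1L)) stop_bad("'n_per_group' must be >= 1")
  check_number(sessions_per_participant, "sessions_per_participant",
               lower = 1, integer = TRUE)
  out <- list(); counter <- 0L
  for (g in seq_along(profiles)) {
    prof <- profiles[[g]]
    for (i in seq_len(n_per_group[g])) {
      pid <- sprintf("%s_%02d", prof$group_label, i)
      for (s in seq_len(sessions_per_participant)) {
        counter <- counter + 1L
        out[[length(out) + 1L]] <- simulate_session(
          prof, scenario, seed = derive_seed(seed, counter),
          participant = pid, session = s, streams = streams)
      }
    }
  }
  out
}

#' Render a trace as synthetic microscope frames
#'
#' One grayscale frame per trace sample: a bright Gaussian instrument blob
#' at the sample position when visible, over a dark background with the two
#' zone circles drawn faintly (intensity 0.2, below the annotation cutoff of
#' [detect_instrument()]). Frames are matrices indexed `[x, y]` (x right,
#' y down) with the zone center at the image center.
#'
#' @param trace a [tool_trace()].
#' @param zones a [zone_config()] in mm.
#' @param image_size_px side of the square frame; by default just large
#'   enough to hold the base circle plus a 2 mm margin.
#' @param mm_per_px scale, mm per pixel (> 0).
#' @return List of frames with attributes `mm_per_px`, `center_px` (pixel
#'   coordinates of the zone center), `t_s` (sample times) and `zones`.
#' @export
render_frames <- function(trace, zones, image_size_px = NULL,
                          mm_per_px = 0.1) {
  trace <- as_tool_trace(trace)
  stopifnot(inherits(zones, "zone_config"))
  check_number(mm_per_px, "mm_per_px")
  if (mm_per_px <= 0) stop_bad("'mm_per_px' must be positive")
  image_size_px <- image_size_px %||%
    ceiling(2 * (zones$r_base + 2) / mm_per_px)
  check_number(image_size_px, "image_size_px", lower = 1, integer = TRUE)
  if (image_size_px * mm_per_px < 2 * zones$r_base)
    stop_bad("image too small to contain the mounting-base circle")
  ctr <- (image_size_px + 1) / 2
  bg <- matrix(0, image_size_px, image_size_px)
  rad_px <- sqrt((row(bg) - ctr)^2 + (col(bg) - ctr)^2)
  for (r in c(zones$r_cornea, zones$r_base) / mm_per_px)
    bg[abs(rad_px - r) <= 0.6] <- 0.2
  sigma <- 1.5; half <- 5L
  frames <- vector("list", nrow(trace))
  for (i in seq_len(nrow(trace))) {
    f <- bg
    if (trace$visible[i]) {
      cx <- (trace$x[i] - zones$center[1]) / mm_per_px + ctr
      cy <- (trace$y[i] - zones$center[2]) / mm_per_px + ctr
      xs <- max(1L, floor(cx) - half):min(image_size_px, ceiling(cx) + half)
      ys <- max(1L, floor(cy) - half):min(image_size_px, ceiling(cy) + half)
      blob <- exp(-(outer((xs - cx)^2, (ys - cy)^2, "+")) / (2 * sigma^2))
      f[xs, ys] <- pmin(f[xs, ys] + blob, 1)
    }
    frames[[i]] <- f
  }
  structure(frames, mm_per_px = mm_per_px, center_px = c(ctr, ctr),
            t_s = trace$t_s, zones = zones, class = "rendered_frames")
}

#' Recover a trace from rendered frames
#'
#' Applies [detect_instrument()] to each frame and maps detected centroids
#' back to trace coordinates using the frames' scale and center metadata.
#'
#' @param frames a [render_frames()] result.
#' @param threshold optional manual threshold for [detect_instrument()].
#' @return A [tool_trace()]; frames without a detectable blob become
#'   invisible samples.
#' @export
frames_to_trace <- function(frames, threshold = NULL) {
  stopifnot(inherits(frames, "rendered_frames"))
  s <- attr(frames, "mm_per_px"); ctr <- attr(frames, "center_px")
  zc <- attr(frames, "zones")$center
  xy <- lapply(frames, detect_instrument, threshold = threshold)
  vis <- !vapply(xy, is.null, logical(1))
  x <- y <- rep(NA_real_, length(frames))
  x[vis] <- vapply(xy[vis], function(p) (p[1] - ctr[1]) * s + zc[1], numeric(1))
  y[vis] <- vapply(xy[vis], function(p) (p[2] - ctr[2]) * s + zc[2], numeric(1))
  tool_trace(attr(frames, "t_s"), x, y, vis)
}
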