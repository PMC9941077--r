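#' Skill-group profile for the session generator
#'
#' Bundles the statistical structure of one experience group: per-stitch
#' completion probability, log-normal per-stitch durations and inter-stitch
#' gaps, a continuous-time 3-state transition-rate table driving the zone
#' process of the instrument trace, stitch-geometry parameters (mean length,
#' multiplicative length drift per successive stitch, spacing, angle jitter),
#' and rater-score parameters (rubric item mean/sd, RULA grand mode).
#'
#' @param group_label `"senior"`, `"junior"` or `"novice"`.
#' @param stitch_time_median_s median time to realize one stitch, seconds.
#' @param stitch_time_log_sd log-scale sd of the per-stitch duration.
#' @param completion_prob per-stitch completion probability in `[0, 1]`.
#' @param gap_time_median_s median gap between two stitches, seconds.
#' @param gap_time_log_sd log-scale sd of the gap.
#' @param zone_rates 3x3 transition-rate matrix (events/s) of the zone
#'   process; the diagonal is ignored.
#' @param stitch_length_mm,stitch_length_sd_mm stitch length mean and sd, mm.
#' @param length_drift multiplicative length factor per successive stitch
#'   (above 1: stitches grow over the session; below 1: they shrink).
#' @param angle_jitter_deg_sd sd of the per-stitch direction jitter, degrees.
#' @param spacing_mm,spacing_sd_mm inter-stitch spacing mean and sd, mm.
#' @param zhang_item_mean,zhang_item_sd rubric item score mean (in `[1, 5]`)
#'   and sd.
#' @param rula_grand_mode modal RULA grand score, integer 1-7.
#' @return A `group_profile` list.
#' @seealso [default_profiles()] for the calibrated study groups.
#' @export
group_profile <- function(group_label,
                          stitch_time_median_s,
                          stitch_time_log_sd,
                          completion_prob,
                          gap_time_median_s,
                          gap_time_log_sd,
                          zone_rates,
                          stitch_length_mm,
                          stitch_length_sd_mm,
                          length_drift,
                          angle_jitter_deg_sd,
                          spacing_mm,
                          spacing_sd_mm,
                          zhang_item_mean,
                          zhang_item_sd,
                          rula_grand_mode) {
  group_label <- match.arg(group_label, c("senior", "junior", "novice"))
  check_number(stitch_time_median_s, "stitch_time_median_s", lower = 0)
  check_number(stitch_time_log_sd, "stitch_time_log_sd", lower = 0)
  check_number(completion_prob, "completion_prob", lower = 0, upper = 1)
  check_number(gap_time_median_s, "gap_time_median_s", lower = 0)
  check_number(gap_time_log_sd, "gap_time_log_sd", lower = 0)
  if (!is.matrix(zone_rates) || !all(dim(zone_rates) == c(3, 3)) ||
      any(!is.finite(zone_rates)) || any(zone_rates[row(zone_rates) != col(zone_rates)] < 0))
    stop_bad("'zone_rates' must be a finite 3x3 matrix with non-negative off-diagonal rates")
  check_number(stitch_length_mm, "stitch_length_mm", lower = 0)
  check_number(stitch_length_sd_mm, "stitch_length_sd_mm", lower = 0)
  check_number(length_drift, "length_drift", lower = 0)
  check_number(angle_jitter_deg_sd, "angle_jitter_deg_sd", lower = 0)
  check_number(spacing_mm, "spacing_mm", lower = 0)
  check_number(spacing_sd_mm, "spacing_sd_mm", lower = 0)
  check_number(zhang_item_mean, "zhang_item_mean", lower = 1, upper = 5)
  check_number(zhang_item_sd, "zhang_item_sd", lower = 0)
  check_number(rula_grand_mode, "rula_grand_mode", lower = 1, upper = 7,
               integer = TRUE)
  structure(list(
    group_label = group_label,
    stitch_time_median_s = stitch_time_median_s,
    stitch_time_log_sd = stitch_time_log_sd,
    completion_prob = completion_prob,
    gap_time_median_s = gap_time_median_s,
    gap_time_log_sd = gap_time_log_sd,
    zone_rates = zone_rates,
    stitch_length_mm = stitch_length_mm,
    stitch_length_sd_mm = stitch_length_sd_mm,
    length_drift = length_drift,
    angle_jitter_deg_sd = angle_jitter_deg_sd,
    spacing_mm = spacing_mm,
    spacing_sd_mm = spacing_sd_mm,
    zhang_item_mean = zhang_item_mean,
    zhang_item_sd = zhang_item_sd,
    rula_grand_mode = rula_grand_mode
  ), class = "group_profile")
}

# Reversible 3-state rate matrix with stationary occupancy `pi` and
# symmetric flow intensities c12/c13/c23 (events/s): q_ij = c_ij / pi_i.
rates_from_occupancy <- function(pi, c12, c13, c23) {
  stopifnot(length(pi) == 3, abs(sum(pi) - 1) < 1e-9, all(pi > 0))
  q <- matrix(0, 3, 3)
  q[1, 2] <- c12 / pi[1]; q[2, 1] <- c12 / pi[2]
  q[1, 3] <- c13 / pi[1]; q[3, 1] <- c13 / pi[3]
  q[2, 3] <- c23 / pi[2]; q[3, 2] <- c23 / pi[3]
  q
}

#' Default skill-group profiles
#'
#' Profiles for the senior, junior and novice groups, calibrated to the
#' published group medians of the corneal wound-closure task: per-stitch
#' time medians on the minute scale ordered senior < junior < novice; length
#' drift above 1 for seniors (stitches grow over the session) and below 1
#' for novices; zone-1 occupancy near 69% for seniors versus 55-61% for the
#' others, with few 1<->2 transitions for seniors and many for novices;
#' rubric item means giving total scores near 58 / 50 / 36; RULA grand mode
#' 3 in every group.
#'
#' @return Named list of three [group_profile()] objects
#'   (`senior`, `junior`, `novice`).
#' @export
default_profiles <- function() {
  list(
    senior = group_profile(
      "senior",
      stitch_time_median_s = 108, stitch_time_log_sd = 0.30,
      completion_prob = 1,
      gap_time_median_s = 67, gap_time_log_sd = 0.35,
      zone_rates = rates_from_occupancy(c(0.692, 0.185, 0.123),
                                        c12 = 0.005, c13 = 0.008, c23 = 0.004),
      stitch_length_mm = 1.1, stitch_length_sd_mm = 0.15,
      length_drift = 1.10, angle_jitter_deg_sd = 3,
      spacing_mm = 0.95, spacing_sd_mm = 0.12,
      zhang_item_mean = 4.85, zhang_item_sd = 0.30,
      rula_grand_mode = 3L),
    junior = group_profile(
      "junior",
      stitch_time_median_s = 134, stitch_time_log_sd = 0.35,
      completion_prob = 1,
      gap_time_median_s = 57, gap_time_log_sd = 0.35,
      zone_rates = rates_from_occupancy(c(0.547, 0.272, 0.181),
                                        c12 = 0.015, c13 = 0.010, c23 = 0.008),
      stitch_length_mm = 0.90, stitch_length_sd_mm = 0.20,
      length_drift = 1.03, angle_jitter_deg_sd = 6,
      spacing_mm = 0.80, spacing_sd_mm = 0.15,
      zhang_item_mean = 4.21, zhang_item_sd = 0.60,
      rula_grand_mode = 3L),
    novice = group_profile(
      "novice",
      stitch_time_median_s = 185, stitch_time_log_sd = 0.45,
      completion_prob = 0.90,
      gap_time_median_s = 78, gap_time_log_sd = 0.45,
      zone_rates = rates_from_occupancy(c(0.610, 0.234, 0.156),
                                        c12 = 0.030, c13 = 0.012, c23 = 0.010),
      stitch_length_mm = 1.15, stitch_length_sd_mm = 0.25,
      length_drift = 0.88, angle_jitter_deg_sd = 7,
      spacing_mm = 0.88, spacing_sd_mm = 0.20,
      zhang_item_mean = 3.00, zhang_item_sd = 0.90,
      rula_grand_mode = 3L)
  )
}

#' Scenario of the suturing task
#'
#' Geometry and acquisition parameters of one training scenario: a linear
#' penetrating corneal wound of given length (4 mm by default) to be closed
#' with a given number of stitches (3 by default, each with 3 thread loops),
#' centered and oriented within the zone partition, with the trace sampled
#' at a fixed rate (1 Hz by default).
#'
#' @param wound_length_mm wound length, mm (> 0).
#' @param wound_center 2-D wound center, mm; zone center by default.
#' @param wound_orientation_deg wound direction, degrees from the x axis.
#' @param n_stitches_required required number of stitches (>= 1).
#' @param loops_per_stitch thread loops per stitch (metadata only).
#' @param zones a [zone_config()].
#' @param sampling_hz trace sampling rate, Hz.
#' @return A `scenario_config` list; `wound_endpoints` is a 2x2 matrix with
#'   one endpoint per row.
#' @export
scenario_config <- function(wound_length_mm = 4,
                            wound_center = NULL,
                            wound_orientation_deg = 0,
                            n_stitches_required = 3L,
                            loops_per_stitch = 3L,
                            zones = zone_config(),
                            sampling_hz = 1) {
  check_number(wound_length_mm, "wound_length_mm")
  if (wound_length_mm <= 0) stop_bad("'wound_length_mm' must be positive")
  check_number(n_stitches_required, "n_stitches_required", lower = 1,
               integer = TRUE)
  check_number(sampling_hz, "sampling_hz")
  if (sampling_hz <= 0) stop_bad("'sampling_hz' must be positive")
  stopifnot(inherits(zones, "zone_config"))
  wound_center <- wound_center %||% zones$center
  if (!is.numeric(wound_center) || length(wound_center) != 2L ||
      any(!is.finite(wound_center)))
    stop_bad("'wound_center' must be two finite numbers")
  th <- wound_orientation_deg * pi / 180
  u <- c(cos(th), sin(th))
  ends <- rbind(wound_center - u * wound_length_mm / 2,
                wound_center + u * wound_length_mm / 2)
  dimnames(ends) <- list(c("start", "end"), c("x", "y"))
  structure(list(
    wound_length_mm = wound_length_mm,
    wound_center = as.numeric(wound_center),
    wound_orientation_deg = wound_orientation_deg,
    wound_endpoints = ends,
    n_stitches_required = as.integer(n_stitches_required),
    loops_per_stitch = as.integer(loops_per_stitch),
    zones = zones,
    sampling_hz = sampling_hz
  ), class = "scenario_config")
}
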