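#' Per-session metric summaries
#'
#' Computes every assessment metric for one session: rubric total averaged
#' over raters, RULA grand score, total/per-stitch/intermediate times in
#' minutes (with the uncompleted-stitch penalty), zone occupancy
#' percentages and 1<->2 back-and-forth count from the trace, and the four
#' geometry criteria. Streams absent from the record yield `NA` (scalars)
#' or empty vectors (pooled geometry measurements), never an error.
#'
#' @param session a `session_record`.
#' @param penalty_s penalty per uncompleted stitch, seconds.
#' @param rate_hz zone-timeline sampling rate, Hz.
#' @param zones a [zone_config()]; defaults to the session's own scenario
#'   config when present, else the package default.
#' @return A `session_metrics` list of scalars and measurement vectors.
#' @export
session_metrics <- function(session, penalty_s = 300, rate_hz = 1,
                            zones = NULL) {
  stopifnot(inherits(session, "session_record"))
  zones <- zones %||% session$meta$scenario$zones %||% zone_config()
  ts <- if (!is.null(session$events)) total_time(session$events, penalty_s)
  required <- if (!is.null(session$events))
    attr(session$events, "required_stitches") else 3L
  per_stitch_min <- stats::setNames(rep(NA_real_, required),
                                    paste0("stitch_", seq_len(required)))
  if (!is.null(ts))
    for (k in names(ts$per_stitch_s))
      per_stitch_min[paste0("stitch_", k)] <- ts$per_stitch_s[[k]] / 60

  zs <- if (!is.null(session$trace))
    summarize_zones(zone_timeline(session$trace, zones, rate_hz))
  gs <- if (!is.null(session$stitches)) summarize_geometry(session$stitches)

  list(
    zhang = if (length(session$zhang)) aggregate_raters(session$zhang)
            else NA_real_,
    rula = if (length(session$rula))
      stats::median(vapply(session$rula,
                           function(p) rula_grand(p)$grand, numeric(1)))
      else NA_real_,
    total_penalized_min = if (!is.null(ts)) ts$total_penalized_s / 60 else NA_real_,
    total_raw_min = if (!is.null(ts)) ts$total_raw_s / 60 else NA_real_,
    per_stitch_min = per_stitch_min,
    intermediate_min = if (!is.null(ts) && !is.na(ts$intermediate_s))
      ts$intermediate_s / 60 else NA_real_,
    zone_pct = if (!is.null(zs)) 100 * zs$fraction_zone else rep(NA_real_, 3),
    back_and_forth_12 = if (!is.null(zs)) zs$back_and_forth_12 else NA_integer_,
    length_mm = if (!is.null(gs)) unname(gs$length_mm) else numeric(0),
    length_ratio = if (!is.null(gs)) unname(gs$length_ratio) else numeric(0),
    distance_mm = if (!is.null(gs)) unname(gs$distance_mm) else numeric(0),
    angle_deg = if (!is.null(gs)) unname(gs$angle_deg) else numeric(0),
    n_completed = if (!is.null(ts)) ts$n_completed else NA_integer_,
    required = required
  )
}

#' Achievement counts per group
#'
#' Number of sessions in each group that completed 0, 1, ... up to the
#' required number of stitches.
#'
#' @param cohort list of `session_record` objects.
#' @return Integer matrix, groups x (required + 1) completion levels.
#' @export
count_achievement <- function(cohort) {
  groups <- canonical_groups(vapply(cohort, `[[`, character(1), "group"))
  req <- max(vapply(cohort, function(s)
    attr(s$events, "required_stitches"), integer(1)))
  m <- matrix(0L, length(groups), req + 1L,
              dimnames = list(group = groups, completed = 0:req))
  for (s in cohort) {
    k <- n_completed(s$events)
    m[s$group, as.character(k)] <- m[s$group, as.character(k)] + 1L
  }
  m
}

# Fixed experience-group ordering so reports do not depend on session order.
canonical_groups <- function(labels) {
  u <- unique(labels)
  c(intersect(c("senior", "junior", "novice"), u),
    sort(setdiff(u, c("senior", "junior", "novice"))))
}

report_metric_defs <- function(required = 3L) {
  defs <- list(
    list(id = "zhang_score", label = "Zhang score (/60)", unit = "points",
         type = "scalar", field = "zhang"),
    list(id = "rula_score", label = "RULA score (1-7)", unit = "grand score",
         type = "scalar", field = "rula"),
    list(id = "total_time_penalized", label = "Total time with penalties",
         unit = "min", type = "scalar", field = "total_penalized_min"),
    list(id = "total_time_raw", label = "Total time without penalties",
         unit = "min", type = "scalar", field = "total_raw_min"))
  for (k in seq_len(required))
    defs[[length(defs) + 1L]] <-
      list(id = paste0("stitch_", k, "_time"), label = paste("Stitch", k),
           unit = "min", type = "stitch", k = k)
  defs <- c(defs, list(
    list(id = "intermediate_time", label = "Intermediate time", unit = "min",
         type = "scalar", field = "intermediate_min"),
    list(id = "zone_1_pct", label = "Zone 1", unit = "% time", type = "zone", k = 1),
    list(id = "zone_2_pct", label = "Zone 2", unit = "% time", type = "zone", k = 2),
    list(id = "zone_3_pct", label = "Zone 3", unit = "% time", type = "zone", k = 3),
    list(id = "stitch_length", label = "Length of each stitch", unit = "mm",
         type = "pooled", field = "length_mm"),
    list(id = "length_ratio", label = "Length ratio with respect to stitch 1",
         unit = "ratio", type = "pooled", field = "length_ratio"),
    list(id = "inter_stitch_distance",
         label = "Distance between successive stitches", unit = "mm",
         type = "pooled", field = "distance_mm"),
    list(id = "inter_stitch_angle", label = "Angle between successive stitches",
         unit = "deg", type = "pooled", field = "angle_deg")))
  defs
}

metric_values <- function(metrics_list, def) {
  vals <- switch(def$type,
    scalar = vapply(metrics_list, function(m) m[[def$field]], numeric(1)),
    stitch = vapply(metrics_list, function(m)
      if (def$k <= length(m$per_stitch_min)) m$per_stitch_min[[def$k]]
      else NA_real_, numeric(1)),
    zone = vapply(metrics_list, function(m) m$zone_pct[def$k], numeric(1)),
    pooled = unlist(lapply(metrics_list, `[[`, def$field)))
  vals[!is.na(vals)]
}

#' Group-comparison report over a cohort
#'
#' Applies the session-selection policy, computes every metric per session,
#' and produces one row per metric with per-group median and IQR, the
#' Kruskal-Wallis H and p across groups, and a significance flag at the 0.05
#' level, plus an achievement row backed by per-group completion counts.
#' Geometry rows pool individual measurements (each stitch, each successive
#' pair) across a group's sessions; all other rows use one value per
#' session. No correction for multiple comparisons is applied across rows.
#'
#' @param cohort list of `session_record` objects.
#' @param policy session-selection policy, see [select_sessions()].
#' @param penalty_s,rate_hz passed to [session_metrics()].
#' @param pairwise if `TRUE`, adds two-sided Mann-Whitney p-values for every
#'   group pair to each row's entry in `$pairwise`.
#' @param alpha significance level for the flag.
#' @return A `comparison_report` list: `rows` (data frame), `achievement`
#'   (count matrix), `n_sessions` (per group), `pairwise` (optional),
#'   `policy`.
#' @export
build_report <- function(cohort, policy = "paper", penalty_s = 300,
                         rate_hz = 1, pairwise = FALSE, alpha = 0.05) {
  if (!length(cohort)) stop_bad("empty cohort")
  sel <- select_sessions(cohort, policy)
  groups <- canonical_groups(vapply(sel, `[[`, character(1), "group"))
  metrics <- lapply(sel, session_metrics, penalty_s = penalty_s,
                    rate_hz = rate_hz)
  by_group <- lapply(groups, function(g)
    metrics[vapply(sel, `[[`, character(1), "group") == g])
  names(by_group) <- groups
  required <- max(vapply(metrics, `[[`, integer(1), "required"))
  defs <- report_metric_defs(required)

  rows <- list(); pw <- list()
  for (def in defs) {
    gv <- lapply(by_group, metric_values, def = def)
    nonempty <- lengths(gv) > 0
    stat <- if (sum(nonempty) >= 2L) kruskal_wallis(gv[nonempty]) else NULL
    row <- data.frame(metric = def$id, label = def$label, unit = def$unit,
                      stringsAsFactors = FALSE)
    for (g in groups) {
      mi <- if (length(gv[[g]])) median_iqr(gv[[g]])
            else c(median = NA_real_, q1 = NA_real_, q3 = NA_real_)
      row[[paste0(g, "_median")]] <- mi[["median"]]
      row[[paste0(g, "_q1")]] <- mi[["q1"]]
      row[[paste0(g, "_q3")]] <- mi[["q3"]]
      row[[paste0(g, "_n")]] <- length(gv[[g]])
    }
    row$H <- if (is.null(stat)) NA_real_ else stat$H
    row$p <- if (is.null(stat)) NA_real_ else stat$p
    row$significant <- !is.na(row$p) & row$p < alpha
    row$flagged <- any(!nonempty)
    rows[[def$id]] <- row
    if (pairwise && sum(nonempty) >= 2L) {
      cmb <- utils::combn(groups[nonempty], 2, simplify = FALSE)
      pw[[def$id]] <- do.call(rbind, lapply(cmb, function(pr) {
        mw <- mann_whitney(gv[[pr[1]]], gv[[pr[2]]])
        data.frame(metric = def$id, group_a = pr[1], group_b = pr[2],
                   U = mw$U, p = mw$p, stringsAsFactors = FALSE)
      }))
    }
  }

  ach <- count_achievement(sel)
  ach_row <- data.frame(metric = "achievement",
                        label = "Achieved stitches", unit = "sessions",
                        stringsAsFactors = FALSE)
  for (g in groups) {
    ach_row[[paste0(g, "_median")]] <- NA_real_
    ach_row[[paste0(g, "_q1")]] <- NA_real_
    ach_row[[paste0(g, "_q3")]] <- NA_real_
    ach_row[[paste0(g, "_n")]] <- sum(ach[g, ])
  }
  ach_row$H <- NA_real_; ach_row$p <- NA_real_
  ach_row$significant <- FALSE; ach_row$flagged <- FALSE
  rows[["achievement"]] <- ach_row

  n_sessions <- vapply(groups, function(g)
    sum(vapply(sel, `[[`, character(1), "group") == g), integer(1))
  structure(list(
    rows = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    achievement = ach,
    n_sessions = stats::setNames(n_sessions, groups),
    pairwise = if (pairwise) do.call(rbind, pw) else NULL,
    policy = policy,
    alpha = alpha
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, digits = 3, ...) {
  cat(sprintf("<comparison_report> policy '%s'; sessions per group: %s\n",
              x$policy,
              paste(names(x$n_sessions), x$n_sessions, sep = "=",
                    collapse = ", ")))
  df <- x$rows
  med_cols <- grep("_median$", names(df), value = TRUE)
  show <- df[, c("label", "unit", med_cols, "p", "significant")]
  for (cc in c(med_cols, "p")) show[[cc]] <- signif(show[[cc]], digits)
  print(show, row.names = FALSE)
  cat("\nAchieved stitches (sessions):\n")
  print(x$achievement)
  invisible(x)
}
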