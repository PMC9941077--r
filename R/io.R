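# Session directory layout (schema_version 1):
#   trace.csv    t_s,x_mm,y_mm,visible   (visible 0/1; empty coords when 0)
#   stitches.csv stitch_index,entry_x_mm,entry_y_mm,exit_x_mm,exit_y_mm,completed
#   events.csv   stitch_index,needle_entry_s,thread_cut_s
#   zhang.csv    rater,item_1..item_N
#   rula.csv     upper_arm,...,force_b   (one row per observation)
#   meta.yaml    group, participant, session, scenario, zone config
# Coordinates use the image convention: x right, y down, origin at the
# field-of-view top-left; the zone center is carried in the config. All
# numeric fields use a fixed %.6f format with a '.' decimal point so that
# write -> read -> write is byte-identical.

fmt_num <- function(x) {
  out <- sprintf("%.6f", x)
  out[is.na(x)] <- ""
  out
}

write_csv_raw <- function(df, path) {
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(df, sep = ",")))
  writeLines(lines, path)
}

#' Write a session to a directory
#'
#' Serializes every stream the record carries into the documented per-file
#' CSV/YAML layout; absent streams produce no file. Writing is canonical:
#' writing a freshly read session reproduces the files byte for byte.
#'
#' @param session a `session_record`.
#' @param dir target directory (created if needed).
#' @param frames if `TRUE` and the session has a trace, also renders
#'   synthetic frames to `frames/frame_%06d.png` with a `timestamps.csv`.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, frames = FALSE) {
  stopifnot(inherits(session, "session_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(session$trace)) {
    tr <- session$trace
    write_csv_raw(data.frame(t_s = fmt_num(tr$t_s), x_mm = fmt_num(tr$x),
                             y_mm = fmt_num(tr$y),
                             visible = as.integer(tr$visible)),
                  file.path(dir, "trace.csv"))
  }
  if (!is.null(session$stitches)) {
    st <- session$stitches
    write_csv_raw(data.frame(stitch_index = st$index,
                             entry_x_mm = fmt_num(st$entry_x),
                             entry_y_mm = fmt_num(st$entry_y),
                             exit_x_mm = fmt_num(st$exit_x),
                             exit_y_mm = fmt_num(st$exit_y),
                             completed = as.integer(st$completed)),
                  file.path(dir, "stitches.csv"))
  }
  if (!is.null(session$events)) {
    ev <- session$events
    write_csv_raw(data.frame(stitch_index = ev$stitch_index,
                             needle_entry_s = fmt_num(ev$needle_entry_s),
                             thread_cut_s = fmt_num(ev$thread_cut_s)),
                  file.path(dir, "events.csv"))
  }
  if (length(session$zhang)) {
    sheets <- do.call(rbind, lapply(session$zhang, function(s)
      data.frame(rater = s$rater,
                 t(stats::setNames(as.integer(s$item_scores),
                                   paste0("item_", seq_along(s$item_scores)))),
                 stringsAsFactors = FALSE)))
    write_csv_raw(sheets, file.path(dir, "zhang.csv"))
  }
  if (length(session$rula)) {
    obs <- do.call(rbind, lapply(session$rula, function(p)
      as.data.frame(unclass(p))))
    write_csv_raw(obs, file.path(dir, "rula.csv"))
  }
  sc <- session$meta$scenario
  meta <- list(
    schema_version = 1L,
    participant = session$participant,
    group = session$group,
    session = session$session,
    seed = session$meta$seed,
    required_stitches = if (!is.null(session$events))
      attr(session$events, "required_stitches") else sc$n_stitches_required,
    scenario = list(
      wound_length_mm = sc$wound_length_mm,
      wound_center = as.numeric(sc$wound_center),
      wound_orientation_deg = sc$wound_orientation_deg,
      n_stitches_required = sc$n_stitches_required,
      loops_per_stitch = sc$loops_per_stitch,
      sampling_hz = sc$sampling_hz),
    zone_config = list(
      center = as.numeric(sc$zones$center),
      r_cornea = sc$zones$r_cornea,
      r_base = sc$zones$r_base,
      units = sc$zones$units))
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"), precision = 15)
  if (frames && !is.null(session$trace)) {
    fdir <- file.path(dir, "frames")
    dir.create(fdir, showWarnings = FALSE)
    fr <- render_frames(session$trace, sc$zones)
    for (i in seq_along(fr))
      png::writePNG(t(fr[[i]]), file.path(fdir, sprintf("frame_%06d.png", i)))
    write_csv_raw(data.frame(frame = seq_along(fr),
                             t_s = fmt_num(attr(fr, "t_s"))),
                  file.path(fdir, "timestamps.csv"))
  }
  invisible(dir)
}

read_csv_opt <- function(path) {
  if (!file.exists(path)) return(NULL)
  tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
           error = function(e)
             stop_bad(sprintf("malformed CSV %s: %s", path, conditionMessage(e))))
}

#' Read a session directory
#'
#' Loads `meta.yaml` plus whichever data streams are present; missing
#' optional streams are flagged absent (`NULL` in the record), while a
#' malformed file or an invariant violation (e.g. non-monotone trace times)
#' raises a validation error naming the file.
#'
#' @param dir session directory containing at least `meta.yaml`.
#' @return A `session_record`.
#' @export
read_session <- function(dir) {
  mf <- file.path(dir, "meta.yaml")
  if (!file.exists(mf)) stop_bad(sprintf("no meta.yaml in %s", dir))
  meta <- tryCatch(yaml::read_yaml(mf), error = function(e)
    stop_bad(sprintf("malformed YAML %s: %s", mf, conditionMessage(e))))
  zc <- meta$zone_config
  zones <- zone_config(center = unlist(zc$center), r_cornea = zc$r_cornea,
                       r_base = zc$r_base, units = zc$units %||% "mm")
  sc <- meta$scenario
  scenario <- scenario_config(
    wound_length_mm = sc$wound_length_mm,
    wound_center = unlist(sc$wound_center),
    wound_orientation_deg = sc$wound_orientation_deg,
    n_stitches_required = sc$n_stitches_required,
    loops_per_stitch = sc$loops_per_stitch,
    zones = zones, sampling_hz = sc$sampling_hz)

  tr <- read_csv_opt(file.path(dir, "trace.csv"))
  trace <- if (!is.null(tr))
    tryCatch(tool_trace(tr$t_s, tr$x_mm, tr$y_mm, tr$visible == 1L),
             error = function(e)
               stop_bad(sprintf("invalid trace.csv in %s: %s", dir,
                                conditionMessage(e))))
  st <- read_csv_opt(file.path(dir, "stitches.csv"))
  stitches <- if (!is.null(st))
    stitch_set(st$stitch_index, st$entry_x_mm, st$entry_y_mm,
               st$exit_x_mm, st$exit_y_mm, st$completed == 1L, units = "mm")
  ev <- read_csv_opt(file.path(dir, "events.csv"))
  events <- if (!is.null(ev))
    event_log(ev$stitch_index, ev$needle_entry_s, ev$thread_cut_s,
              meta$required_stitches %||% 3L)
  zh <- read_csv_opt(file.path(dir, "zhang.csv"))
  zhang <- if (!is.null(zh))
    lapply(seq_len(nrow(zh)), function(i)
      zhang_sheet(zh$rater[i], as.integer(zh[i, -1])))
  ru <- read_csv_opt(file.path(dir, "rula.csv"))
  rula <- if (!is.null(ru))
    lapply(seq_len(nrow(ru)), function(i) do.call(rula_posture, as.list(ru[i, ])))

  structure(list(
    participant = meta$participant, group = meta$group,
    session = meta$session,
    trace = trace, stitches = stitches, events = events,
    zhang = zhang, rula = rula,
    meta = list(schema_version = meta$schema_version,
                scenario = scenario,
                wound_endpoints = scenario$wound_endpoints,
                seed = meta$seed)
  ), class = "session_record")
}

#' Write a cohort and its manifest
#'
#' Writes each session to `<dir>/<participant>_s<session>/` and a
#' `cohort.yaml` manifest listing the session directories and group labels.
#'
#' @param cohort list of `session_record` objects.
#' @param dir cohort directory.
#' @param frames passed to [write_session()].
#' @return Path of the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir, frames = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cohort, function(s) {
    sub <- sprintf("%s_s%d", s$participant, s$session)
    write_session(s, file.path(dir, sub), frames = frames)
    list(dir = sub, group = s$group)
  })
  mf <- file.path(dir, "cohort.yaml")
  yaml::write_yaml(list(schema_version = 1L, sessions = entries), mf)
  invisible(mf)
}

#' Read a cohort manifest
#'
#' @param manifest path to a `cohort.yaml` manifest.
#' @return List of `session_record` objects.
#' @export
read_cohort <- function(manifest) {
  m <- yaml::read_yaml(manifest)
  base <- dirname(manifest)
  lapply(m$sessions, function(e) read_session(file.path(base, e$dir)))
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
}

#' Run the full assessment pipeline over a cohort
#'
#' Reads the manifest (or takes an in-memory cohort), writes per-session
#' artifacts (`timeline.csv`, `zone_summary.json`, `geometry.json`,
#' `time_summary.json`, `scores.json`) under `out_dir/sessions/`, then the
#' cohort-level report as `report.csv`, `report.md` and `report.json`.
#' A failing session is recorded in the error ledger (`errors.json`) and
#' skipped; the report covers the remaining sessions.
#'
#' @param manifest path to a `cohort.yaml`, or a list of `session_record`s.
#' @param out_dir output directory.
#' @param policy,penalty_s,rate_hz,pairwise passed to [build_report()].
#' @return The `comparison_report`, invisibly, with attribute `errors`
#'   (named list of failure messages, empty when all sessions succeeded).
#' @export
run_pipeline <- function(manifest, out_dir, policy = "paper",
                         penalty_s = 300, rate_hz = 1, pairwise = FALSE) {
  errors <- list(); kept <- list()
  cohort <- manifest
  if (is.character(manifest)) {
    m <- yaml::read_yaml(manifest)
    base <- dirname(manifest)
    cohort <- list()
    for (e in m$sessions) {
      s <- tryCatch(read_session(file.path(base, e$dir)),
                    error = function(err) conditionMessage(err))
      if (is.character(s)) {
        errors[[e$dir]] <- s
        message(sprintf("session %s failed to load: %s", e$dir, s))
      } else cohort[[length(cohort) + 1L]] <- s
    }
  }
  dir.create(file.path(out_dir, "sessions"), recursive = TRUE,
             showWarnings = FALSE)
  for (s in cohort) {
    sid <- sprintf("%s_s%d", s$participant, s$session)
    res <- tryCatch({
      sdir <- file.path(out_dir, "sessions", sid)
      dir.create(sdir, showWarnings = FALSE)
      zones <- s$meta$scenario$zones
      if (!is.null(s$trace)) {
        tl <- zone_timeline(s$trace, zones, rate_hz)
        write_csv_raw(data.frame(t_s = fmt_num(tl$t_s), zone = tl$zone),
                      file.path(sdir, "timeline.csv"))
        zs <- summarize_zones(tl)
        write_json_file(list(fraction_zone = zs$fraction_zone,
                             transitions = zs$transitions,
                             n_samples = zs$n_samples,
                             back_and_forth_12 = zs$back_and_forth_12,
                             back_and_forth_12_per_min = zs$back_and_forth_12_per_min),
                        file.path(sdir, "zone_summary.json"))
      }
      if (!is.null(s$stitches)) {
        gs <- summarize_geometry(s$stitches)
        write_json_file(gs[c("length_mm", "length_ratio", "distance_mm",
                             "angle_deg", "n_completed")],
                        file.path(sdir, "geometry.json"))
      }
      if (!is.null(s$events)) {
        ts <- total_time(s$events, penalty_s)
        write_json_file(ts[c("total_raw_s", "total_penalized_s",
                             "per_stitch_s", "intermediate_s", "n_completed",
                             "n_uncompleted", "raw_flagged")],
                        file.path(sdir, "time_summary.json"))
      }
      if (length(s$zhang) || length(s$rula)) {
        totals <- vapply(s$zhang %||% list(), zhang_total, numeric(1))
        write_json_file(list(
          zhang_totals = as.list(stats::setNames(
            totals, vapply(s$zhang %||% list(), `[[`, character(1), "rater"))),
          zhang_mean = if (length(s$zhang)) aggregate_raters(s$zhang) else NULL,
          rula_grand = if (length(s$rula))
            vapply(s$rula, function(p) rula_grand(p)$grand, numeric(1))
            else NULL),
          file.path(sdir, "scores.json"))
      }
      TRUE
    }, error = function(e) conditionMessage(e))
    if (isTRUE(res)) kept[[length(kept) + 1L]] <- s
    else {
      errors[[sid]] <- res
      message(sprintf("session %s failed: %s", sid, res))
    }
  }
  report <- build_report(kept, policy = policy, penalty_s = penalty_s,
                         rate_hz = rate_hz, pairwise = pairwise)
  write_report(report, out_dir)
  if (length(errors)) write_json_file(errors, file.path(out_dir, "errors.json"))
  attr(report, "errors") <- errors
  invisible(report)
}

#' Write a comparison report to disk
#'
#' @param report a `comparison_report`.
#' @param out_dir output directory; writes `report.csv`, `report.md`,
#'   `report.json`.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "comparison_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  df <- report$rows
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  out <- df
  out[num] <- lapply(df[num], fmt_num)
  write_csv_raw(out, file.path(out_dir, "report.csv"))
  write_json_file(list(policy = report$policy, alpha = report$alpha,
                       n_sessions = as.list(report$n_sessions),
                       rows = df, achievement = report$achievement,
                       pairwise = report$pairwise),
                  file.path(out_dir, "report.json"))
  md <- c(sprintf("# Group comparison report (policy: %s)", report$policy), "",
          sprintf("Sessions per group: %s",
                  paste(names(report$n_sessions), report$n_sessions,
                        sep = " = ", collapse = ", ")), "")
  groups <- names(report$n_sessions)
  hdr <- paste0("| Metric | Unit | ",
                paste(sprintf("%s median (IQR)", groups), collapse = " | "),
                " | p | sig |")
  md <- c(md, hdr,
          paste0("|", paste(rep("---", length(groups) + 4), collapse = "|"), "|"))
  for (i in seq_len(nrow(df))) {
    cells <- vapply(groups, function(g) {
      m <- df[[paste0(g, "_median")]][i]
      if (is.na(m)) "-" else sprintf("%.3g (%.3g-%.3g)", m,
                                     df[[paste0(g, "_q1")]][i],
                                     df[[paste0(g, "_q3")]][i])
    }, character(1))
    md <- c(md, paste0("| ", df$label[i], " | ", df$unit[i], " | ",
                       paste(cells, collapse = " | "), " | ",
                       ifelse(is.na(df$p[i]), "-", sprintf("%.3g", df$p[i])),
                       " | ", ifelse(df$significant[i], "*", ""), " |"))
  }
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' Export a zone timeline step plot
#'
#' Writes a PNG step plot of zone (1-3) against time, plus the timeline CSV
#' next to it.
#'
#' @param timeline data frame with `t_s`, `zone`.
#' @param out output PNG path; the CSV replaces the extension with `.csv`.
#' @return `out`, invisibly.
#' @export
export_timeline_plot <- function(timeline, out) {
  if (!nrow(timeline)) stop_bad("empty timeline")
  grDevices::png(out, width = 900, height = 300)
  on.exit(grDevices::dev.off())
  graphics::plot(timeline$t_s, timeline$zone, type = "s", ylim = c(0.5, 3.5),
                 yaxt = "n", xlab = "time (s)", ylab = "zone",
                 main = "Instrument zone over time")
  graphics::axis(2, at = 1:3)
  csv <- sub("\\.[^.]*$", ".csv", out)
  write_csv_raw(data.frame(t_s = fmt_num(timeline$t_s), zone = timeline$zone),
                csv)
  invisible(out)
}
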