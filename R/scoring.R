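#' Load a suturing-quality rubric definition
#'
#' The rubric is a data file, not hard-coded: the default is the 12-item
#' modification of the Zhang corneal-suturing scale (each item 1-5, total
#' 12-60), and a file with any item count (for example the original 15-item
#' scale) can be supplied instead.
#'
#' @param path YAML rubric file; `NULL` for the packaged default.
#' @return A `zhang_rubric` list with `name`, `items`, `scale_min`,
#'   `scale_max`.
#' @export
zhang_rubric <- function(path = NULL) {
  path <- path %||% system.file("extdata", "zhang_rubric_12.yaml",
                                package = "suturemetrics", mustWork = TRUE)
  r <- yaml::read_yaml(path)
  if (is.null(r$items) || !length(r$items))
    stop_bad("rubric file must list at least one item")
  structure(list(name = r$name %||% basename(path),
                 items = as.character(unlist(r$items)),
                 scale_min = as.integer(r$scale_min %||% 1L),
                 scale_max = as.integer(r$scale_max %||% 5L)),
            class = "zhang_rubric")
}

#' One rater's rubric score sheet
#'
#' @param rater rater identifier.
#' @param item_scores integer scores, one per rubric item, each within the
#'   rubric's scale.
#' @param rubric a [zhang_rubric()]; the packaged 12-item default when `NULL`.
#' @return A `zhang_sheet` list.
#' @export
zhang_sheet <- function(rater, item_scores, rubric = NULL) {
  rubric <- rubric %||% zhang_rubric()
  k <- length(rubric$items)
  if (length(item_scores) != k)
    stop_bad(sprintf("expected %d item scores, got %d", k, length(item_scores)))
  if (any(!is.finite(item_scores)) ||
      any(item_scores != round(item_scores)) ||
      any(item_scores < rubric$scale_min | item_scores > rubric$scale_max))
    stop_bad(sprintf("item scores must be integers in [%d, %d]",
                     rubric$scale_min, rubric$scale_max))
  structure(list(rater = as.character(rater),
                 item_scores = stats::setNames(as.integer(item_scores),
                                               rubric$items),
                 rubric = rubric),
            class = "zhang_sheet")
}

#' Total rubric score of one sheet
#'
#' Sum of the item scores; with the default 12-item rubric the range is
#' 12 (all items at 1) to 60 (all items at 5).
#'
#' @param sheet a [zhang_sheet()].
#' @return Integer total.
#' @export
zhang_total <- function(sheet) {
  stopifnot(inherits(sheet, "zhang_sheet"))
  sum(sheet$item_scores)
}

#' Aggregate rubric totals across raters
#'
#' Unrounded arithmetic mean of the per-rater totals (the blinded raters'
#' consensus value used for group statistics).
#'
#' @param sheets list of [zhang_sheet()] objects, at least one.
#' @return Numeric mean total.
#' @export
aggregate_raters <- function(sheets) {
  if (!length(sheets)) stop_bad("at least one score sheet is required")
  mean(vapply(sheets, zhang_total, numeric(1)))
}

# ---- RULA -----------------------------------------------------------------

#' Load the RULA lookup tables
#'
#' The three posture lookup tables of the Rapid Upper Limb Assessment
#' instrument, shipped as editable CSV fixtures transcribed from the
#' published instrument and guarded by md5 checksums: an edited fixture
#' raises a warning so silent drift is visible.
#'
#' @param dir directory holding `table_a.csv`, `table_b.csv`, `table_c.csv`
#'   and `checksums.txt`; `NULL` for the packaged fixtures.
#' @return A `rula_tables` list of three data frames.
#' @export
rula_tables <- function(dir = NULL) {
  dir <- dir %||% system.file("extdata", "rula", package = "suturemetrics",
                              mustWork = TRUE)
  files <- c("table_a.csv", "table_b.csv", "table_c.csv")
  paths <- file.path(dir, files)
  if (any(!file.exists(paths))) stop_bad("missing RULA table file(s)")
  sums_file <- file.path(dir, "checksums.txt")
  if (file.exists(sums_file)) {
    want <- utils::read.table(sums_file, col.names = c("md5", "file"),
                              stringsAsFactors = FALSE)
    have <- tools::md5sum(paths)
    for (i in seq_along(files)) {
      w <- want$md5[match(files[i], want$file)]
      if (!is.na(w) && w != unname(have[i]))
        warning(sprintf("RULA fixture %s does not match its recorded checksum",
                        files[i]), call. = FALSE)
    }
  }
  tabs <- lapply(paths, utils::read.csv)
  names(tabs) <- c("A", "B", "C")
  structure(tabs, class = "rula_tables")
}

#' A RULA posture observation
#'
#' Field ranges follow the published instrument: upper arm 1-6, lower arm
#' 1-3, wrist 1-4, wrist twist 1-2, neck 1-6, trunk 1-6, legs 1-2; muscle-use
#' additions 0-1 and force/load additions 0-3 for each of the arm-wrist (a)
#' and neck-trunk-legs (b) sides.
#'
#' @param upper_arm,lower_arm,wrist,wrist_twist arm and wrist posture scores.
#' @param neck,trunk,legs neck, trunk and leg posture scores.
#' @param muscle_use_a,force_a,muscle_use_b,force_b use and load additions.
#' @return A `rula_posture` list.
#' @export
rula_posture <- function(upper_arm = 1, lower_arm = 1, wrist = 1,
                         wrist_twist = 1, neck = 1, trunk = 1, legs = 1,
                         muscle_use_a = 0, force_a = 0,
                         muscle_use_b = 0, force_b = 0) {
  p <- list(upper_arm = upper_arm, lower_arm = lower_arm, wrist = wrist,
            wrist_twist = wrist_twist, neck = neck, trunk = trunk,
            legs = legs, muscle_use_a = muscle_use_a, force_a = force_a,
            muscle_use_b = muscle_use_b, force_b = force_b)
  lims <- rula_field_ranges()
  for (f in names(lims))
    check_number(p[[f]], f, lower = lims[[f]][1], upper = lims[[f]][2],
                 integer = TRUE)
  structure(lapply(p, as.integer), class = "rula_posture")
}

rula_field_ranges <- function() {
  list(upper_arm = c(1, 6), lower_arm = c(1, 3), wrist = c(1, 4),
       wrist_twist = c(1, 2), neck = c(1, 6), trunk = c(1, 6),
       legs = c(1, 2), muscle_use_a = c(0, 1), force_a = c(0, 3),
       muscle_use_b = c(0, 1), force_b = c(0, 3))
}

lookup_score <- function(tab, ...) {
  keys <- list(...)
  sel <- rep(TRUE, nrow(tab))
  for (k in names(keys)) sel <- sel & tab[[k]] == keys[[k]]
  s <- tab$score[sel]
  if (length(s) != 1L) stop_bad("RULA table lookup failed (corrupt fixture?)")
  s
}

#' RULA grand score of a posture
#'
#' Score A is looked up from Table A (arm and wrist), score B from Table B
#' (neck, trunk, legs); muscle-use and force additions give scores C and D,
#' which Table C combines into the grand score on the published 1-7 scale.
#' Scores C and D beyond the table bounds saturate at the last row/column.
#'
#' @param posture a [rula_posture()].
#' @param tables a [rula_tables()] set; packaged fixtures when `NULL`.
#' @return A `rula_result` list: `score_a`, `score_b`, `score_c`, `score_d`,
#'   `grand`.
#' @export
rula_grand <- function(posture, tables = NULL) {
  stopifnot(inherits(posture, "rula_posture"))
  tables <- tables %||% rula_tables()
  a <- lookup_score(tables$A, upper_arm = posture$upper_arm,
                    lower_arm = posture$lower_arm, wrist = posture$wrist,
                    wrist_twist = posture$wrist_twist)
  b <- lookup_score(tables$B, neck = posture$neck, trunk = posture$trunk,
                    legs = posture$legs)
  sc <- a + posture$muscle_use_a + posture$force_a
  sd_ <- b + posture$muscle_use_b + posture$force_b
  grand <- lookup_score(tables$C,
                        score_c = min(sc, max(tables$C$score_c)),
                        score_d = min(sd_, max(tables$C$score_d)))
  structure(list(score_a = a, score_b = b, score_c = sc, score_d = sd_,
                 grand = as.integer(grand)),
            class = "rula_result")
}

#' @export
print.rula_result <- function(x, ...) {
  cat(sprintf("<rula_result> A=%d B=%d C=%d D=%d grand=%d (1-7)\n",
              x$score_a, x$score_b, x$score_c, x$score_d, x$grand))
  invisible(x)
}

#' Grand scores for a grid of postures
#'
#' Vectorized RULA evaluation over a data frame of posture fields (missing
#' muscle-use/force columns default to 0). Convenient for exhaustive sweeps
#' of the posture grid, e.g. monotonicity audits of the lookup tables.
#'
#' @param grid data frame with the posture columns of [rula_posture()].
#' @param tables a [rula_tables()] set; packaged fixtures when `NULL`.
#' @return Integer vector of grand scores, one per row of `grid`.
#' @export
rula_grand_grid <- function(grid, tables = NULL) {
  tables <- tables %||% rula_tables()
  z <- function(col) if (is.null(grid[[col]])) 0L else grid[[col]]
  A <- tables$A; B <- tables$B; C <- tables$C
  a <- A$score[match(paste(grid$upper_arm, grid$lower_arm, grid$wrist,
                           grid$wrist_twist),
                     paste(A$upper_arm, A$lower_arm, A$wrist, A$wrist_twist))]
  b <- B$score[match(paste(grid$neck, grid$trunk, grid$legs),
                     paste(B$neck, B$trunk, B$legs))]
  if (anyNA(a) || anyNA(b)) stop_bad("posture fields outside the RULA tables")
  sc <- pmin(a + z("muscle_use_a") + z("force_a"), max(C$score_c))
  sd_ <- pmin(b + z("muscle_use_b") + z("force_b"), max(C$score_d))
  C$score[match(paste(sc, sd_), paste(C$score_c, C$score_d))]
}

.rula_cache <- new.env(parent = emptyenv())

# First (lexicographically smallest) posture whose grand score equals g;
# used by the session generator to emit postures consistent with a target
# grand score. Cached for the packaged tables.
rula_posture_for_grand <- function(g, tables = NULL) {
  check_number(g, "g", lower = 1, upper = 7, integer = TRUE)
  use_cache <- is.null(tables)
  if (use_cache && !is.null(.rula_cache$by_grand))
    return(.rula_cache$by_grand[[g]])
  tables <- tables %||% rula_tables()
  grid <- expand.grid(legs = 1:2, trunk = 1:6, neck = 1:6,
                      wrist_twist = 1:2, wrist = 1:4, lower_arm = 1:3,
                      upper_arm = 1:6)
  grid <- grid[order(grid$upper_arm, grid$lower_arm, grid$wrist,
                     grid$wrist_twist, grid$neck, grid$trunk, grid$legs), ]
  grand <- rula_grand_grid(grid, tables)
  reps <- lapply(1:7, function(gg) {
    i <- which(grand == gg)[1L]
    if (is.na(i)) stop_bad(sprintf("no posture attains grand score %d", gg))
    do.call(rula_posture, as.list(grid[i, ]))
  })
  if (use_cache) .rula_cache$by_grand <- reps
  reps[[g]]
}
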