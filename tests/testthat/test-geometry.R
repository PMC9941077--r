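test_that("calibration converts pixel sets to mm and is idempotent", {
  px <- stitch_set(1L, 0, 0, 100, 0, units = "px", mm_per_px = 0.01)
  mm <- calibrate(px)
  expect_equal(stitch_length(mm, 1), 1.0)
  expect_equal(attr(mm, "units"), "mm")
  expect_identical(calibrate(mm), mm)
  # round trip mm -> px -> mm
  set.seed(21)
  s <- random_stitch_set()
  back <- calibrate(stitch_set(s$index, s$entry_x / 0.0125, s$entry_y / 0.0125,
                               s$exit_x / 0.0125, s$exit_y / 0.0125,
                               units = "px", mm_per_px = 0.0125))
  expect_equal(back$entry_x, s$entry_x, tolerance = 1e-12)
  expect_error(calibrate(stitch_set(1L, 0, 0, 1, 0, units = "px")), "mm_per_px")
})

test_that("stitch lengths and ratios follow the endpoint arithmetic", {
  s <- stitch_set(1:3, c(0, 0, 0), c(0, 0, 0), c(0, 3, 0), c(2, 4, 2))
  expect_equal(stitch_length(s, 1), 2)
  expect_equal(stitch_length(s, 2), 5)    # 3-4-5 triangle
  r <- length_ratios(s)
  expect_equal(as.vector(r), c(2.5, 1))
  # growing-stitch pattern: lengths (1, 1.16, 1.16) -> ratios (1.16, 1.16)
  g <- stitch_set(1:3, c(0, 2, 4), c(0, 0, 0), c(0, 2, 4), c(1, 1.16, 1.16))
  expect_equal(as.vector(length_ratios(g)), c(1.16, 1.16))
  h <- stitch_set(1:2, c(0, 1), c(0, 0), c(0, 1), c(2, 1))
  expect_equal(as.vector(length_ratios(h)), 0.5)
  # stitch 1 uncompleted -> ratios undefined and flagged
  u <- stitch_set(1:2, c(0, 1), c(0, 0), c(0, 1), c(2, 1),
                  completed = c(FALSE, TRUE))
  expect_false(attr(length_ratios(u), "defined"))
  expect_error(stitch_length(u, 1), "uncompleted")
})

test_that("inter-stitch distance is the midpoint distance of consecutive completed pairs", {
  s <- stitch_set(1:2, c(0, 1), c(-1, -1), c(0, 1), c(1, 1))
  expect_equal(inter_stitch_distance(s, 1, 2), 1)
  ident <- stitch_set(1:2, c(0, 0), c(0, 0), c(1, 1), c(1, 1))
  expect_equal(inter_stitch_distance(ident, 1, 2), 0)
  expect_error(inter_stitch_distance(ideal_template(), 1, 3), "consecutive")
  # randomized pairs equal direct midpoint arithmetic
  set.seed(22)
  for (i in 1:50) {
    r <- random_stitch_set(2)
    ma <- c((r$entry_x[1] + r$exit_x[1]) / 2, (r$entry_y[1] + r$exit_y[1]) / 2)
    mb <- c((r$entry_x[2] + r$exit_x[2]) / 2, (r$entry_y[2] + r$exit_y[2]) / 2)
    expect_equal(inter_stitch_distance(r, 1, 2), sqrt(sum((ma - mb)^2)))
  }
})

test_that("inter-stitch angle is the acute angle between undirected segments", {
  mk <- function(v1, v2) stitch_set(1:2, c(0, 5), c(0, 0),
                                    c(v1[1], 5 + v2[1]), c(v1[2], v2[2]))
  expect_equal(inter_stitch_angle(mk(c(0, 1), c(0, 1)), 1, 2), 0)
  expect_equal(inter_stitch_angle(mk(c(0, 1), c(1, 1)), 1, 2), 45)
  expect_equal(inter_stitch_angle(mk(c(0, 1), c(1, 0)), 1, 2), 90)
  # symmetry and endpoint-swap invariance
  set.seed(23)
  for (i in 1:30) {
    r <- random_stitch_set(2)
    a12 <- inter_stitch_angle(r, 1, 2)
    expect_equal(inter_stitch_angle(r, 2, 1), a12)
    sw <- stitch_set(1:2, c(r$exit_x[1], r$entry_x[2]),
                     c(r$exit_y[1], r$entry_y[2]),
                     c(r$entry_x[1], r$exit_x[2]),
                     c(r$entry_y[1], r$exit_y[2]))
    expect_equal(inter_stitch_angle(sw, 1, 2), a12)
    expect_gte(a12, 0); expect_lte(a12, 90)
    expect_equal(inter_stitch_distance(r, 1, 2), inter_stitch_distance(r, 2, 1))
  }
})

test_that("quality deviation measures departure from the 2 mm / 1 mm reference", {
  q0 <- quality_deviation(ideal_template())
  expect_equal(q0$mean_length_dev, 0)
  expect_equal(q0$mean_spacing_dev, 0)
  one <- stitch_set(1L, 0, 0, 0, 1)
  q1 <- quality_deviation(one)
  expect_equal(q1$mean_length_dev, 1)
  expect_true(is.na(q1$mean_spacing_dev))
  set.seed(24)
  r <- random_stitch_set(3)
  g <- summarize_geometry(r)
  q <- quality_deviation(r)
  expect_equal(unname(q$length_dev), unname(abs(g$length_mm - 2)))
  expect_equal(unname(q$spacing_dev), unname(abs(g$distance_mm - 1)))
})

test_that("geometry summary aggregates the four criteria over completed stitches", {
  g <- summarize_geometry(ideal_template())
  expect_equal(unname(g$length_mm), c(2, 2, 2))
  expect_equal(unname(g$length_ratio), c(1, 1))
  expect_equal(unname(g$distance_mm), c(1, 1))
  expect_equal(unname(g$angle_deg), c(0, 0))
  # only stitch 1 completed: no pairwise metrics
  solo <- stitch_set(1:3, c(-1, 0, 1), c(-1, -1, -1), c(-1, 0, 1), c(1, 1, 1),
                     completed = c(TRUE, FALSE, FALSE))
  gs <- summarize_geometry(solo)
  expect_equal(length(gs$length_mm), 1L)
  expect_length(gs$length_ratio, 0)
  expect_length(gs$distance_mm, 0)
  expect_equal(gs$n_completed, 1L)
})

test_that("geometry is rigid-motion invariant and scale covariant", {
  set.seed(25)
  for (i in 1:40) {
    s <- random_stitch_set(3)
    g <- summarize_geometry(s)
    th <- runif(1, 0, 2 * pi); dx <- rnorm(1, sd = 10); dy <- rnorm(1, sd = 10)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    tf <- function(x, y) sweep(cbind(x, y) %*% t(R), 2, c(-dx, -dy))
    e <- tf(s$entry_x, s$entry_y); x <- tf(s$exit_x, s$exit_y)
    gm <- summarize_geometry(stitch_set(1:3, e[, 1], e[, 2], x[, 1], x[, 2]))
    for (f in c("length_mm", "length_ratio", "distance_mm", "angle_deg"))
      expect_equal(gm[[f]], g[[f]], tolerance = 1e-9)
    cc <- runif(1, 0.1, 10)
    gc_ <- summarize_geometry(stitch_set(1:3, s$entry_x * cc, s$entry_y * cc,
                                         s$exit_x * cc, s$exit_y * cc))
    expect_equal(gc_$length_mm, g$length_mm * cc, tolerance = 1e-9)
    expect_equal(gc_$distance_mm, g$distance_mm * cc, tolerance = 1e-9)
    expect_equal(gc_$length_ratio, g$length_ratio, tolerance = 1e-9)
    expect_equal(gc_$angle_deg, g$angle_deg, tolerance = 1e-9)
  }
})
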