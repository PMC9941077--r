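test_that("session generation honors completion probability and determinism", {
  p <- default_profiles()$senior
  s1 <- simulate_session(p, seed = 5)
  s2 <- simulate_session(p, seed = 5)
  expect_identical(s1, s2)
  expect_false(identical(s1, simulate_session(p, seed = 6)))
  # completion_prob = 1 -> every required stitch completed
  expect_equal(sum(!is.na(s1$events$thread_cut_s)), 3L)
  # completion_prob = 0 -> none
  p0 <- p; p0$completion_prob <- 0
  s0 <- simulate_session(p0, seed = 5)
  expect_equal(sum(!is.na(s0$events$thread_cut_s)), 0L)
})

test_that("an absorbing zone process keeps the trace on the cornea", {
  tr <- simulate_trace(matrix(0, 3, 3), duration_s = 60, zones = make_zones())
  expect_true(all(tr$visible))
  d <- sqrt(tr$x^2 + tr$y^2)
  expect_true(all(d <= 5.5))
})

test_that("per-stitch durations are log-normal with the profile median", {
  p <- default_profiles()$senior
  draws <- unlist(lapply(1:1200, function(i) {
    s <- simulate_session(p, seed = i, streams = c("events", "stitches"))
    vapply(1:3, function(k) per_stitch_time(s$events, k), numeric(1))
  }))
  expect_gt(length(draws), 3000)
  med_min <- median(draws) / 60
  expect_lt(abs(med_min - p$stitch_time_median_s / 60),
            0.1 * p$stitch_time_median_s / 60)
})

test_that("cohorts have the documented shape and are reproducible", {
  profs <- default_profiles()
  small <- simulate_cohort(profs, n_per_group = 1, sessions_per_participant = 3,
                           seed = 2, streams = "events")
  expect_length(small, 9L)
  ids <- vapply(small, function(s) paste(s$participant, s$session), "")
  expect_false(anyDuplicated(ids) > 0)
  full <- simulate_cohort(seed = 3, streams = "events")
  expect_length(full, 72L)   # 5 + 8 + 11 participants, three sessions each
  # same seed -> byte-identical serialized cohorts
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(n_per_group = 1, sessions_per_participant = 1,
                               seed = 9), d1)
  write_cohort(simulate_cohort(n_per_group = 1, sessions_per_participant = 1,
                               seed = 9), d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})

test_that("zeroed jitter reproduces the ideal stitch template exactly", {
  p <- default_profiles()$senior
  p$stitch_length_sd_mm <- 0; p$spacing_sd_mm <- 0; p$angle_jitter_deg_sd <- 0
  s <- simulate_session(p, seed = 11)
  g <- summarize_geometry(s$stitches)
  expect_equal(unname(g$length_mm),
               p$stitch_length_mm * p$length_drift^(0:2), tolerance = 1e-9)
  expect_equal(unname(g$distance_mm), rep(p$spacing_mm, 2), tolerance = 1e-9)
  expect_equal(unname(g$angle_deg), c(0, 0), tolerance = 1e-9)
})

test_that("symmetric zone rates converge to uniform occupancy", {
  q <- matrix(0.05, 3, 3); diag(q) <- 0
  tr <- simulate_trace(q, duration_s = 9999, rate_hz = 1, zones = make_zones())
  tl <- zone_timeline(tr, make_zones())
  occ <- summarize_zones(tl)$fraction_zone
  expect_equal(occ, rep(1 / 3, 3), tolerance = 0.05 * 3)  # +-0.05 absolute
  expect_true(all(abs(occ - 1 / 3) <= 0.05))
})

test_that("default profiles encode the monotone group structure", {
  p <- default_profiles()
  expect_lt(p$senior$stitch_time_median_s, p$junior$stitch_time_median_s)
  expect_lt(p$junior$stitch_time_median_s, p$novice$stitch_time_median_s)
  expect_gt(p$senior$zhang_item_mean, p$junior$zhang_item_mean)
  expect_gt(p$junior$zhang_item_mean, p$novice$zhang_item_mean)
  expect_gt(p$senior$length_drift, 1)
  expect_lt(p$novice$length_drift, 1)
})

test_that("rendered frames round-trip through detection to the true zones", {
  z <- make_zones()
  # blob at the zone center lands at the image center within a pixel
  tr0 <- tool_trace(0, 0, 0)
  fr0 <- render_frames(tr0, z)
  ctr <- attr(fr0, "center_px")
  p0 <- detect_instrument(fr0[[1]])
  expect_lt(max(abs(p0 - ctr)), 1)
  # invisible sample renders no blob
  fr3 <- render_frames(tool_trace(0, NA, NA, visible = FALSE), z)
  expect_null(detect_instrument(fr3[[1]]))
  # 100-sample round trip reproduces the generating zones exactly
  set.seed(51)
  n <- 100
  vis <- runif(n) > 0.2
  x <- ifelse(vis, runif(n, -9, 9), NA)
  y <- ifelse(vis, runif(n, -9, 9), NA)
  tr <- tool_trace(seq_len(n), x, y, vis)
  dec <- frames_to_trace(render_frames(tr, z))
  expect_identical(dec$visible, tr$visible)
  expect_lt(max(abs(dec$x - tr$x), na.rm = TRUE), 0.05)  # mm
  expect_lt(max(abs(dec$y - tr$y), na.rm = TRUE), 0.05)
  truth <- attribute_zone(tr$x, tr$y, z, tr$visible)
  got <- attribute_zone(dec$x, dec$y, z, dec$visible)
  # centroid quantization may flip samples sitting exactly on a circle
  expect_gte(mean(got == truth), 0.99)
  expect_error(render_frames(tr0, z, image_size_px = 50, mm_per_px = 0.1),
               "too small")
})
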