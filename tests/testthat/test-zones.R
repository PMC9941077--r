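test_that("zone attribution follows the two-circle partition with inclusive boundaries", {
  z <- make_zones()
  expect_identical(attribute_zone(0, 0, z), 1L)
  expect_identical(attribute_zone(5.5, 0, z), 1L)   # exactly on the cornea circle
  expect_identical(attribute_zone(7, 0, z), 2L)
  expect_identical(attribute_zone(9.5, 0, z), 2L)   # exactly on the base circle
  expect_identical(attribute_zone(20, 0, z), 3L)
  # an invisible tool is allocated zone 3 whatever the coordinates claim
  expect_identical(attribute_zone(0, 0, z, visible = FALSE), 3L)
  expect_identical(attribute_zone(NA_real_, NA_real_, z, visible = FALSE), 3L)
  expect_error(attribute_zone(NA_real_, 0, z, visible = TRUE), "non-finite")
})

test_that("zone attribution matches the brute-force distance oracle and is scale invariant", {
  set.seed(11)
  z <- make_zones()
  n <- 500
  x <- runif(n, -15, 15); y <- runif(n, -15, 15)
  vis <- runif(n) > 0.1
  got <- attribute_zone(x, y, z, vis)
  expect_identical(got, oracle_zone(x, y, vis, z))
  for (c_ in c(0.01, 3, 1000)) {
    zs <- zone_config(z$center * c_, z$r_cornea * c_, z$r_base * c_)
    expect_identical(attribute_zone(x * c_, y * c_, zs, vis), got)
  }
})

test_that("enlarging the cornea circle never demotes a visible sample out of zone 1", {
  set.seed(12)
  x <- runif(300, -12, 12); y <- runif(300, -12, 12)
  z1 <- zone_config(c(0, 0), 4, 9.5)
  z2 <- zone_config(c(0, 0), 6, 9.5)
  a1 <- attribute_zone(x, y, z1)
  a2 <- attribute_zone(x, y, z2)
  expect_true(all(a2[a1 == 1L] == 1L))
})

test_that("trace resampling hits every tick with the nearest sample", {
  # 10 s at 30 samples/s, 1 Hz -> 11 ticks, both endpoints included
  t <- seq(0, 10, by = 1 / 30)
  tr <- tool_trace(t, x = t, y = -t)
  s <- sample_trace(tr, 1)
  expect_equal(s$t_s, 0:10)
  expect_equal(nrow(s), 11L)
  # already at the requested rate -> identity
  tr1 <- tool_trace(0:9, x = 1:10, y = 1:10)
  expect_equal(sample_trace(tr1, 1), tr1, ignore_attr = TRUE)
  # irregular trace: each output equals the sample minimizing |t - tick|
  set.seed(13)
  tt <- sort(runif(80, 0, 20)); tt <- tt[!duplicated(tt)]
  tr2 <- tool_trace(tt, x = seq_along(tt), y = seq_along(tt))
  s2 <- sample_trace(tr2, 2)
  for (i in seq_len(nrow(s2))) {
    d <- abs(tt - s2$t_s[i])
    expect_equal(s2$x[i], which(d == min(d))[1])
  }
})

test_that("zone timeline composes sampling and attribution", {
  z <- make_zones()
  tr <- tool_trace(0:5, rep(0, 6), rep(0, 6))
  expect_equal(zone_timeline(tr, z)$zone, rep(1L, 6))
  # alternating visible-at-center / invisible
  tr2 <- tool_trace(0:5, rep(c(0, NA), 3), rep(c(0, NA), 3),
                    visible = rep(c(TRUE, FALSE), 3))
  expect_equal(zone_timeline(tr2, z)$zone, rep(c(1L, 3L), 3))
  set.seed(14)
  n <- 1000
  tr3 <- tool_trace(seq_len(n), runif(n, -12, 12), runif(n, -12, 12),
                    visible = runif(n) > 0.15)
  tl <- zone_timeline(tr3, z)
  expect_identical(tl$zone, oracle_zone(tr3$x, tr3$y, tr3$visible, z))
})

test_that("zone summary counts fractions, transitions and 1<->2 moves exactly", {
  tl <- function(z) data.frame(t_s = seq_along(z) - 1, zone = z)
  s1 <- summarize_zones(tl(rep(1L, 7)))
  expect_equal(s1$fraction_zone, c(1, 0, 0))
  expect_equal(sum(s1$transitions[row(s1$transitions) != col(s1$transitions)]), 0)
  s2 <- summarize_zones(tl(c(1, 2, 1, 2, 1)))
  expect_equal(s2$fraction_zone, c(0.6, 0.4, 0))
  expect_equal(s2$back_and_forth_12, 4L)
  # random timeline against exhaustive pair counting
  set.seed(15)
  z <- sample(1:3, 400, replace = TRUE)
  s3 <- summarize_zones(tl(z))
  trans <- matrix(0L, 3, 3)
  bf <- 0L
  for (i in seq_len(length(z) - 1)) {
    trans[z[i], z[i + 1]] <- trans[z[i], z[i + 1]] + 1L
    if ((z[i] == 1 && z[i + 1] == 2) || (z[i] == 2 && z[i + 1] == 1))
      bf <- bf + 1L
  }
  expect_equal(unname(unclass(s3$transitions)), trans)
  expect_equal(s3$back_and_forth_12, bf)
  expect_equal(tabulate(z, 3) / length(z), s3$fraction_zone)
  # conservation invariants
  expect_equal(sum(s3$fraction_zone), 1)
  expect_equal(sum(s3$transitions), length(z) - 1L)
})

test_that("instrument detection finds the largest blob and ignores annotations", {
  f <- matrix(0, 60, 60)
  # faint annotation ring must never register
  f[abs(sqrt((row(f) - 30)^2 + (col(f) - 30)^2) - 20) < 1] <- 0.2
  expect_null(detect_instrument(f))
  # one blob
  f[18:22, 38:42] <- 1
  p <- detect_instrument(f)
  expect_equal(unname(p), c(20, 40), tolerance = 1e-9)
  # add a smaller, brighter blob: the larger one wins
  f[50:51, 50:51] <- 1
  p2 <- detect_instrument(f)
  expect_equal(unname(p2), c(20, 40), tolerance = 1e-9)
  expect_error(detect_instrument(matrix(numeric(0), 0, 0)), "non-empty")
})
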