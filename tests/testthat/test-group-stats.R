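test_that("session selection pools novices and keeps first sessions elsewhere", {
  coh <- simulate_cohort(seed = 4, streams = "events")
  sel <- select_sessions(coh, "paper")
  groups <- vapply(sel, `[[`, character(1), "group")
  expect_equal(sum(groups == "senior"), 5L)
  expect_equal(sum(groups == "junior"), 8L)
  expect_equal(sum(groups == "novice"), 33L)   # 11 participants x 3 sessions
  expect_length(select_sessions(coh, "first"), 24L)
  expect_identical(select_sessions(coh, "all"), coh)
  expect_error(select_sessions(coh, "latest"))
})

test_that("median and IQR follow the linear-interpolation convention", {
  expect_equal(median_iqr(1:5), c(median = 3, q1 = 2, q3 = 4))
  expect_equal(median_iqr(7), c(median = 7, q1 = 7, q3 = 7))
  set.seed(61)
  for (i in 1:20) {
    v <- rnorm(sample(2:30, 1))
    got <- median_iqr(v)
    # sort-and-interpolate oracle (type-7 plotting positions)
    s <- sort(v); n <- length(s)
    ip <- function(p) {
      h <- (n - 1) * p + 1
      s[floor(h)] + (h - floor(h)) * (s[min(floor(h) + 1, n)] - s[floor(h)])
    }
    expect_equal(unname(got), c(ip(0.5), ip(0.25), ip(0.75)))
  }
  expect_error(median_iqr(numeric(0)), "at least one")
})

test_that("Kruskal-Wallis H matches independent rank arithmetic", {
  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  res <- kruskal_wallis(g)
  expect_equal(res$H, 7.2)                       # perfectly separated ranks
  expect_equal(res$H, oracle_kw_H(g))
  expect_equal(res$method, "exact")              # n = 9 takes the exact path
  expect_equal(res$p, 6 / 1680)                  # 3! orderings of the blocks
  # permuting group order changes nothing
  res2 <- kruskal_wallis(g[c(2, 3, 1)])
  expect_equal(res2$H, res$H)
  expect_equal(res2$p, res$p)
  # identical groups -> H = 0, p = 1
  same <- kruskal_wallis(list(c(2, 2), c(2, 2)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
})

test_that("the chi-square path agrees with the reference implementation", {
  set.seed(62)
  g <- list(rnorm(15), rnorm(15, 0.5), rnorm(15, 1))
  res <- kruskal_wallis(g)
  expect_equal(res$method, "chisq")
  ref <- stats::kruskal.test(unlist(g), rep(1:3, each = 15))
  expect_equal(res$H, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
  # ties are rank-corrected the same way
  gt <- list(c(1, 2, 2, 3, 8, 9, 10, 1, 4, 4, 7), c(2, 3, 3, 5, 5, 6, 6, 2, 9, 9, 1))
  rest <- kruskal_wallis(gt, method = "chisq")
  reft <- stats::kruskal.test(unlist(gt), rep(1:2, times = lengths(gt)))
  expect_equal(rest$H, unname(reft$statistic))
})

test_that("small-sample tests match brute-force permutation nulls within 0.01", {
  set.seed(63)
  for (i in 1:6) {
    sizes <- sample(2:4, 3, replace = TRUE)
    while (sum(sizes) > 10) sizes <- sample(2:4, 3, replace = TRUE)
    g <- split(sample(1000, sum(sizes)), rep(1:3, times = sizes))
    expect_lt(abs(kruskal_wallis(g)$p - oracle_kw_perm_p(g)), 0.01)
  }
  for (i in 1:6) {
    na <- sample(3:5, 1); nb <- sample(3:5, 1)
    x <- sample(1000, na + nb)
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    expect_lt(abs(mann_whitney(a, b)$p - oracle_mw_perm_p(a, b)), 0.01)
  }
})

test_that("Mann-Whitney follows the exact small-sample conventions", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- mann_whitney(a, b)
  expect_equal(res$U, 0)              # no (a, b) pair with a > b
  expect_equal(res$p, 0.1)            # 2 of the 20 splits are as extreme
  # swapping the samples mirrors U and keeps p
  sw <- mann_whitney(b, a)
  expect_equal(sw$U, length(a) * length(b) - res$U)
  expect_equal(sw$p, res$p)
  # identical samples are as null as it gets
  same <- mann_whitney(c(1, 1, 2), c(1, 1, 2))
  expect_gte(same$p, 0.95)
})

test_that("achievement counting tallies sessions per completion level", {
  coh <- simulate_cohort(n_per_group = 2, sessions_per_participant = 2,
                         seed = 8, streams = "events")
  m <- count_achievement(coh)
  expect_equal(dim(m), c(3L, 4L))
  expect_equal(sum(m), length(coh))
  # brute-force tally
  for (s in coh) {
    k <- sum(!is.na(s$events$thread_cut_s))
    expect_gte(m[s$group, as.character(k)], 1L)
  }
  expect_equal(unname(rowSums(m)),
               as.vector(table(vapply(coh, `[[`, character(1), "group"))[rownames(m)]))
  # all-complete cohorts land entirely in the last column
  senior_only <- coh[vapply(coh, `[[`, character(1), "group") == "senior"]
  ms <- count_achievement(senior_only)
  expect_equal(unname(ms["senior", "3"]), length(senior_only))
})

test_that("the comparison report has one row per metric and flags significance", {
  coh <- simulate_cohort(n_per_group = c(2, 2, 2), sessions_per_participant = 1,
                         seed = 10)
  rep <- build_report(coh, policy = "all")
  expect_s3_class(rep, "comparison_report")
  expect_equal(nrow(rep$rows), 16L)
  expect_true(all(rep$rows$p >= 0 & rep$rows$p <= 1, na.rm = TRUE))
  # IQR brackets the median wherever defined
  for (g in c("senior", "junior", "novice")) {
    ok <- !is.na(rep$rows[[paste0(g, "_median")]])
    expect_true(all(rep$rows[[paste0(g, "_q1")]][ok] <=
                      rep$rows[[paste0(g, "_median")]][ok]))
    expect_true(all(rep$rows[[paste0(g, "_median")]][ok] <=
                      rep$rows[[paste0(g, "_q3")]][ok]))
  }
  # a cohort of identical values across groups cannot be significant
  base <- simulate_session(default_profiles()$senior, seed = 77)
  clones <- lapply(c("senior", "junior", "novice"), function(g) {
    s <- base; s$group <- g; s$participant <- paste0(g, "_01"); s
  })
  rep0 <- build_report(clones, policy = "all")
  expect_true(all(rep0$rows$p[!is.na(rep0$rows$p)] == 1))
  med <- rep0$rows[, c("senior_median", "junior_median", "novice_median")]
  expect_true(all(apply(med, 1, function(r) all(is.na(r)) ||
                          max(r) - min(r) == 0)))
  # report invariant to session ordering
  rep_shuf <- build_report(rev(clones), policy = "all")
  expect_equal(rep_shuf$rows, rep0$rows)
})
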