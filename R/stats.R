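#' Apply a session-selection policy to a cohort
#'
#' The study policy (`"paper"` is named `"pooled_novice"` here as well)
#' pools all sessions of novice participants — who gain no outside practice
#' between sessions — while keeping only the first session of junior and
#' senior participants, whose between-session practice would otherwise
#' contaminate a cross-sectional comparison. Policies `"first"` (first
#' session of everyone) and `"all"` (identity) are also available.
#'
#' @param cohort list of `session_record` objects.
#' @param policy `"paper"`, `"first"` or `"all"`.
#' @return Filtered list of sessions.
#' @export
select_sessions <- function(cohort, policy = c("paper", "first", "all")) {
  policy <- match.arg(policy)
  keep <- vapply(cohort, function(s) {
    switch(policy,
           all = TRUE,
           first = s$session == 1L,
           paper = s$group == "novice" || s$session == 1L)
  }, logical(1))
  cohort[keep]
}

#' Median and interquartile range
#'
#' Median with first and third quartiles by the linear-interpolation
#' convention (`stats::quantile` type 7, the R default).
#'
#' @param values numeric, at least one value.
#' @return Named numeric vector `(median, q1, q3)`.
#' @export
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop_bad("at least one non-missing value is required")
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

# Tie-corrected Kruskal-Wallis H for a list of numeric groups.
kw_statistic <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr == 0) return(0)  # all values identical
  H / corr
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic. For small problems (total n at most
#' `exact_n_max`) the p-value is by default the exact permutation tail:
#' every assignment of the observations to the group sizes is enumerated
#' and `p = P(H* >= H)` under that null. Larger problems use the chi-square
#' approximation with `k - 1` degrees of freedom (as common software does).
#' When every value is identical across all groups, `H = 0` and `p = 1`.
#'
#' @param groups list of at least two non-empty numeric vectors.
#' @param method `"auto"` (exact when feasible), `"exact"`, or `"chisq"`.
#' @param exact_n_max largest total n for which `"auto"` enumerates.
#' @return List with `H`, `p`, `df`, `method`.
#' @export
kruskal_wallis <- function(groups, method = c("auto", "exact", "chisq"),
                           exact_n_max = 10L) {
  method <- match.arg(method)
  if (length(groups) < 2L || any(lengths(groups) == 0L))
    stop_bad("at least two non-empty groups are required")
  ns <- lengths(groups)
  n <- sum(ns)
  H <- kw_statistic(groups)
  use_exact <- method == "exact" || (method == "auto" && n <= exact_n_max)
  if (use_exact) {
    x <- unlist(groups, use.names = FALSE)
    Hs <- enumerate_kw(x, ns)
    p <- mean(Hs >= H - 1e-9)
    list(H = H, p = p, df = length(groups) - 1L, method = "exact")
  } else {
    p <- if (H == 0) 1 else stats::pchisq(H, length(groups) - 1L,
                                          lower.tail = FALSE)
    list(H = H, p = min(p, 1), df = length(groups) - 1L, method = "chisq")
  }
}

# All H statistics over the distinct assignments of x to the group sizes.
enumerate_kw <- function(x, ns) {
  assign_rec <- function(pool, sizes) {
    if (length(sizes) == 1L) return(list(list(pool)))
    first <- utils::combn(seq_along(pool), sizes[1], simplify = FALSE)
    out <- list()
    for (sel in first) {
      rest <- assign_rec(pool[-sel], sizes[-1])
      out <- c(out, lapply(rest, function(r) c(list(pool[sel]), r)))
    }
    out
  }
  parts <- assign_rec(x, ns)
  vapply(parts, kw_statistic, numeric(1))
}

#' Mann-Whitney U test between two groups
#'
#' Two-sided rank-sum test. Small untied samples get the exact null
#' distribution; otherwise the normal approximation with tie and continuity
#' correction is used (the standard switch-over of `stats::wilcox.test`,
#' which performs the computation).
#'
#' @param a,b non-empty numeric vectors.
#' @return List with `U` (number of `(a, b)` pairs with `a > b`), `p`,
#'   `method`.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop_bad("both samples must be non-empty")
  exact <- length(a) < 50 && length(b) < 50 &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  p <- wt$p.value
  if (is.na(p)) p <- 1  # identical constant samples
  list(U = unname(wt$statistic), p = min(p, 1),
       method = if (exact) "exact" else "normal-approx")
}
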