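# Shared fixtures and independent oracles. Oracles deliberately recompute
# quantities from first principles (plain loops, distance formulas, rank
# arithmetic) rather than calling the code paths they check.

make_zones <- function() zone_config(center = c(0, 0), r_cornea = 5.5,
                                     r_base = 9.5)

# Ideal three-stitch template: 2 mm stitches perpendicular to a horizontal
# wound, midpoints 1 mm apart on the x axis.
ideal_template <- function() {
  stitch_set(1:3,
             entry_x = c(-1, 0, 1), entry_y = c(-1, -1, -1),
             exit_x = c(-1, 0, 1), exit_y = c(1, 1, 1))
}

random_stitch_set <- function(n = 3) {
  repeat {
    m <- matrix(stats::rnorm(n * 4, sd = 2), n, 4)
    if (all(m[, 1] != m[, 3] | m[, 2] != m[, 4])) break
  }
  stitch_set(seq_len(n), m[, 1], m[, 2], m[, 3], m[, 4])
}

# Brute-force zone attribution: explicit distance comparison per point.
oracle_zone <- function(x, y, visible, zones) {
  n <- length(x)
  out <- integer(n)
  for (i in seq_len(n)) {
    if (!visible[i]) { out[i] <- 3L; next }
    d <- sqrt((x[i] - zones$center[1])^2 + (y[i] - zones$center[2])^2)
    out[i] <- if (d <= zones$r_cornea) 1L else if (d <= zones$r_base) 2L else 3L
  }
  out
}

# Independent tie-corrected Kruskal-Wallis H from the textbook formula.
oracle_kw_H <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x); r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(vapply(split(r, g), function(ri) sum(ri)^2 / length(ri), 1)) -
    3 * (N + 1)
  tie <- table(x)
  H / (1 - sum(tie^3 - tie) / (N^3 - N))
}

# Exact permutation tail probability of H by full enumeration of group
# assignments (distinct from the package's internal enumeration code).
oracle_kw_perm_p <- function(groups) {
  ns <- lengths(groups); x <- unlist(groups)
  Hobs <- oracle_kw_H(groups)
  hit <- 0; tot <- 0
  sel1 <- utils::combn(sum(ns), ns[1], simplify = FALSE)
  for (s1 in sel1) {
    rest <- setdiff(seq_len(sum(ns)), s1)
    sel2 <- utils::combn(length(rest), ns[2], simplify = FALSE)
    for (i2 in sel2) {
      s2 <- rest[i2]; s3 <- setdiff(rest, s2)
      gs <- list(x[s1], x[s2])
      if (length(s3)) gs <- c(gs, list(x[s3]))
      tot <- tot + 1
      if (oracle_kw_H(gs) >= Hobs - 1e-9) hit <- hit + 1
    }
  }
  hit / tot
}

# Exact two-sided Mann-Whitney p by full enumeration of the splits.
oracle_mw_perm_p <- function(a, b) {
  x <- c(a, b); na <- length(a)
  Uobs <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  nb <- length(b); mid <- na * nb / 2
  hit <- 0; tot <- 0
  for (s in utils::combn(length(x), na, simplify = FALSE)) {
    aa <- x[s]; bb <- x[-s]
    U <- sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
    tot <- tot + 1
    if (abs(U - mid) >= abs(Uobs - mid) - 1e-9) hit <- hit + 1
  }
  hit / tot
}

# A small deterministic event log: all three stitches completed.
complete_log <- function() {
  event_log(1:3,
            needle_entry_s = c(0, 150, 300),
            thread_cut_s = c(100, 240, 414))
}
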