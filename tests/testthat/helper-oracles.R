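# Independent brute-force oracles.  These deliberately use the slowest,
# most literal formulation of each operation so they share no code path
# with the implementation they check.

# does interval (s1, e1) overlap (s2, e2) by at least `min` bp?
# (0-based half-open)
bp_overlap <- function(s1, e1, s2, e2) {
  max(0, min(e1, e2) - max(s1, s2))
}

# for each interval of `a`, TRUE if it overlaps any interval of `b`
# on the same chromosome by >= min_overlap bp  -- O(n * m) scan
oracle_overlaps_any <- function(a, b, min_overlap = 1) {
  vapply(seq_len(nrow(a)), function(i) {
    any(vapply(seq_len(nrow(b)), function(j) {
      a$chrom[i] == b$chrom[j] &&
        bp_overlap(a$start[i], a$end[i], b$start[j], b$end[j]) >= min_overlap
    }, logical(1)))
  }, logical(1))
}

# exhaustive closest-feature scan with the package's distance convention
oracle_closest <- function(query, subjects) {
  vapply(seq_len(nrow(query)), function(i) {
    same <- subjects[subjects$chrom == query$chrom[i], ]
    if (!nrow(same)) return(NA_real_)
    p <- query$pos[i]
    min(vapply(seq_len(nrow(same)), function(j) {
      if (p >= same$start[j] && p < same$end[j]) 0
      else max(same$start[j] - p, p - (same$end[j] - 1))
    }, numeric(1)))
  }, numeric(1))
}

# Benjamini-Hochberg by explicit sort and cumulative minimum
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# P(X >= i) for X ~ Hypergeom(N population, r marked, K drawn),
# by full enumeration of all C(N, K) draws (N <= 12)
oracle_hyper_tail <- function(i, N, K, r) {
  draws <- utils::combn(N, K)
  mean(apply(draws, 2, function(d) sum(d <= r) >= i))
}

# two-group log-rank by hand O/E tabulation over event times, plus
# the O/E hazard ratio (group2 vs group1)
oracle_logrank <- function(time, event, group) {
  group <- as.integer(factor(group))
  o <- e <- v <- 0
  obs <- exp_ <- c(0, 0)
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n1 <- sum(at_risk & group == 1); n2 <- sum(at_risk & group == 2)
    d1 <- sum(time == t & event == 1 & group == 1)
    d2 <- sum(time == t & event == 1 & group == 2)
    d <- d1 + d2; n <- n1 + n2
    obs <- obs + c(d1, d2)
    exp_ <- exp_ + d * c(n1, n2) / n
    if (n > 1) v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chisq <- (obs[1] - exp_[1])^2 / v
  list(chisq = chisq,
       hr = (obs[2] / exp_[2]) / (obs[1] / exp_[1]),
       obs = obs, exp = exp_)
}

# product-limit survival estimate evaluated just after each event time
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (k in seq_along(ts)) {
    n <- sum(time >= ts[k])
    d <- sum(time == ts[k] & event == 1)
    s <- s * (1 - d / n)
    out[k] <- s
  }
  tibble::tibble(time = ts, surv = out)
}

# best agreement between cluster labels and truth over all relabelings
best_permutation_agreement <- function(labels, truth) {
  k <- max(labels, truth)
  perms <- combinat_perms(seq_len(k))
  best <- 0
  for (p in perms) best <- max(best, mean(p[labels] == truth))
  best
}

combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# random non-degenerate peak tibble for property tests
random_peaks <- function(n, seed, chroms = c("chr1", "chr2"), max_pos = 1e4,
                         width_range = c(10, 300)) {
  withr::with_seed(seed, {
    start <- floor(runif(n, 0, max_pos))
    width <- floor(runif(n, width_range[1], width_range[2]))
    tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                   start = start, end = start + width,
                   name = sprintf("p%03d", seq_len(n)),
                   score = 0, strand = ".") |>
      dplyr::arrange(chrom, start)
  })
}
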