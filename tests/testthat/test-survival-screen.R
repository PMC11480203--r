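# Signature scoring, stratification, KM curves, log-rank/HR, dual screen.

toy_cohort <- function(expr_mat, time = NULL, event = NULL) {
  n <- nrow(expr_mat)
  if (is.null(time)) time <- rep(1, n)
  if (is.null(event)) event <- rep(1L, n)
  dplyr::bind_cols(
    tibble::tibble(patient = paste0("p", seq_len(n)),
                   time = time, event = event),
    tibble::as_tibble(expr_mat)
  )
}

test_that("signature scores are means of within-cohort z-scores", {
  m <- cbind(gA = c(1, 2, 3), gB = c(10, 10, 40))
  cohort <- toy_cohort(m)
  # single-gene signature equals that gene's z-score
  s1 <- signature_score(cohort, "gA")
  expect_equal(s1$score, as.numeric(scale(m[, "gA"])))
  # two-gene signature equals the hand-computed mean of z-scores
  s2 <- signature_score(cohort, c("gA", "gB"))
  expect_equal(s2$score, rowMeans(scale(m)))
  # location shifts of one gene do not change scores
  cohort2 <- dplyr::mutate(cohort, gB = gB + 100)
  expect_equal(signature_score(cohort2, c("gA", "gB"))$score, s2$score)
  expect_warning(signature_score(cohort, c("gA", "missing")), "absent")
  expect_error(signature_score(cohort, "missing"),
               class = "cooccupy_bad_input")
})

test_that("median split sends ties low and rejects degenerate scores", {
  sc <- tibble::tibble(score = c(1, 2, 3, 4))
  st <- stratify_median(sc)
  expect_equal(as.character(st$stratum), c("low", "low", "high", "high"))
  st3 <- stratify_median(tibble::tibble(score = c(1, 2, 3, 2.5)))
  expect_equal(sum(st3$stratum == "high"), 2)
  # odd n: the median value itself goes low
  st_odd <- stratify_median(tibble::tibble(score = c(1, 2, 3, 2, 5)))
  expect_equal(as.character(st_odd$stratum)[st_odd$score == 2],
               c("low", "low"))
  expect_error(stratify_median(tibble::tibble(score = rep(1, 5))),
               class = "cooccupy_no_split")
  expect_error(stratify_median(tibble::tibble(score = 1:3)),
               class = "cooccupy_bad_input")
})

test_that("KM curves match hand product-limit computation", {
  d <- tibble::tibble(time = c(1, 2), event = c(1L, 1L))
  km <- km_estimate(d)
  expect_equal(km$estimate[km$time == 1], 0.5)
  expect_equal(km$estimate[km$time == 2], 0)
  # all censored: flat at 1, with a warning
  expect_warning(km0 <- km_estimate(tibble::tibble(time = 1:4,
                                                   event = rep(0L, 4))),
                 "flat")
  expect_true(all(km0$estimate == 1))
  # censoring after the last event leaves the curve unchanged
  d2 <- tibble::tibble(time = c(1, 2, 5), event = c(1L, 1L, 0L))
  km2 <- km_estimate(d2)
  expect_equal(km2$estimate[km2$time %in% c(1, 2)], c(2 / 3, 1 / 3))
  ok <- oracle_km(d2$time, d2$event)
  expect_equal(km2$estimate[match(ok$time, km2$time)], ok$surv)
  # curves are bounded and nonincreasing
  withr::with_seed(2, {
    d3 <- tibble::tibble(time = rexp(50, 0.2),
                         event = rbinom(50, 1, 0.7))
  })
  km3 <- km_estimate(d3)
  expect_true(all(km3$estimate >= 0 & km3$estimate <= 1))
  expect_true(all(diff(km3$estimate) <= 1e-12))
})

test_that("log-rank statistic and O/E hazard ratio match hand tabulation", {
  d <- tibble::tibble(time = c(1, 2, 3, 4), event = rep(1L, 4),
                      stratum = factor(c("A", "A", "B", "B"),
                                       levels = c("A", "B")))
  got <- logrank_hr(d)
  hand <- oracle_logrank(d$time, d$event, d$stratum)
  expect_equal(got$statistic, hand$chisq)
  expect_equal(got$hr, hand$hr)
  # swapping labels inverts the HR, preserves the statistic
  d_sw <- dplyr::mutate(d, stratum = factor(ifelse(stratum == "A", "B", "A"),
                                            levels = c("A", "B")))
  got_sw <- logrank_hr(d_sw)
  expect_equal(got_sw$statistic, got$statistic)
  expect_equal(got_sw$hr, 1 / got$hr)
  # identical event patterns in both groups: statistic 0, HR 1
  d_eq <- tibble::tibble(time = rep(c(1, 2, 3), 2), event = rep(1L, 6),
                         stratum = rep(c("A", "B"), each = 3))
  expect_equal(logrank_hr(d_eq)$statistic, 0)
  expect_equal(logrank_hr(d_eq)$hr, 1)
  expect_error(logrank_hr(dplyr::mutate(d, stratum = "A")),
               class = "cooccupy_bad_input")
})

test_that("log-rank p-values are uniform under the null", {
  pvals <- vapply(1:500, function(k) {
    withr::with_seed(4000 + k, {
      d <- tibble::tibble(time = rexp(100, 0.1),
                          event = rbinom(100, 1, 0.8),
                          stratum = rep(c("low", "high"), each = 50))
    })
    logrank_hr(d)$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("random hand-generated log-rank cases always match the oracle", {
  for (k in 1:10) {
    withr::with_seed(k, {
      n <- 40
      d <- tibble::tibble(time = sample(1:20, n, TRUE),
                          event = rbinom(n, 1, 0.7),
                          stratum = sample(c("A", "B"), n, TRUE))
    })
    if (sum(d$event) == 0 || length(unique(d$stratum)) < 2) next
    got <- logrank_hr(d)
    hand <- oracle_logrank(d$time, d$event, d$stratum)
    expect_equal(got$statistic, hand$chisq, tolerance = 1e-8)
    expect_equal(got$hr, hand$hr, tolerance = 1e-8)
  }
})

test_that("the dual screen is exact under identical signatures and records failures", {
  cfg <- sim_config(seed = 13, n_cohorts = 2, cohort_size = 120)
  ch <- simulate_cohort(cfg)
  same <- dual_signature_screen(ch$cohorts, ch$signatures$sig1,
                                ch$signatures$sig1)
  expect_equal(same$hr_sig1, same$hr_sig2)
  expect_equal(same$p_sig1, same$p_sig2)
  # a cohort with constant expression fails its split but not the screen
  broken <- ch$cohorts
  broken[broken$cohort == "cohort_2", ch$signatures$sig1] <- 0
  res <- dual_signature_screen(broken, ch$signatures$sig1,
                               ch$signatures$sig2)
  expect_true(is.na(res$hr_sig1[res$cohort == "cohort_2"]))
  expect_match(res$note[res$cohort == "cohort_2"], "sig1")
  expect_false(any(is.na(res$hr_sig2)))
})
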