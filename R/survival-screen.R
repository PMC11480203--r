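#' Per-patient signature score
#'
#' Z-scores each signature gene across the patients of a cohort, then
#' averages the z-scores per patient.  Adding a constant to any gene's
#' expression therefore leaves the scores unchanged.  Genes absent from the
#' cohort are dropped with a warning; it is an error if none remain.
#'
#' @param cohort Tibble with one row per patient, columns `patient`, `time`,
#'   `event`, and one column per gene.
#' @param genes Character vector of signature genes.
#' @return Tibble (`patient`, `time`, `event`, `score`).
#' @export
signature_score <- function(cohort, genes) {
  assert_columns(cohort, c("patient", "time", "event"), "cohort")
  present <- intersect(genes, names(cohort))
  if (!length(present)) {
    abort("none of the signature genes are present in the cohort.",
          class = "cooccupy_bad_input")
  }
  if (length(present) < length(genes)) {
    warn(sprintf("%d signature gene(s) absent from the cohort.",
                 length(genes) - length(present)))
  }
  m <- as.matrix(cohort[present])
  z <- scale(m)
  z[, attr(z, "scaled:scale") == 0] <- 0  # constant genes carry no signal
  tibble(patient = cohort$patient, time = cohort$time,
         event = cohort$event, score = rowMeans(z))
}

#' Median split of signature scores
#'
#' Labels patients `high` when their score strictly exceeds the cohort
#' median; ties at the median go to `low`.  Errors when fewer than 4
#' patients are available or when the split leaves a stratum empty (e.g.
#' constant scores).
#'
#' @param scores Tibble from [signature_score()] (needs a `score` column).
#' @return `scores` with an appended `stratum` factor (`low`/`high`).
#' @export
stratify_median <- function(scores) {
  assert_columns(scores, "score", "scores")
  if (nrow(scores) < 4) {
    abort("need at least 4 patients to stratify.",
          class = "cooccupy_bad_input")
  }
  med <- median(scores$score)
  stratum <- ifelse(scores$score > med, "high", "low")
  if (length(unique(stratum)) < 2) {
    abort("scores do not split at the median (constant or degenerate).",
          class = "cooccupy_no_split")
  }
  mutate(scores, stratum = factor(stratum, levels = c("low", "high")))
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimates per stratum via [survival::survfit()], returned
#' as a tidy step-function table.  With zero events the curve is flat at 1
#' and a warning is raised.
#'
#' @param data Tibble with `time`, `event` (0/1) and optionally `stratum`.
#' @return Tibble with `time`, `n.risk`, `n.event`, `n.censor`, `estimate`
#'   and, when stratified, `strata`.
#' @export
km_estimate <- function(data) {
  assert_columns(data, c("time", "event"), "data")
  if (sum(data$event) == 0) {
    warn("no events observed: survival curve is flat at 1.")
  }
  fml <- if ("stratum" %in% names(data)) {
    survival::Surv(time, event) ~ stratum
  } else {
    survival::Surv(time, event) ~ 1
  }
  fit <- survival::survfit(fml, data = data)
  broom::tidy(fit)
}

#' Two-group log-rank test with an O/E hazard ratio
#'
#' Standard two-group log-rank test ([survival::survdiff()]) with the hazard
#' ratio estimated from the observed/expected event tables as
#' `(O_high / E_high) / (O_low / E_low)` — i.e. the second stratum level
#' relative to the first.  Swapping the group labels inverts the HR and
#' leaves the statistic unchanged.  With zero events the result is flagged
#' not computable instead of erroring.
#'
#' @param data Tibble with `time`, `event`, and a two-level `stratum`.
#' @return One-row tibble: `statistic` (chi-square, 1 df), `p_value`, `hr`,
#'   `n_low`, `n_high`, `events`, `computable`.
#' @export
logrank_hr <- function(data) {
  assert_columns(data, c("time", "event", "stratum"), "data")
  grp <- factor(data$stratum)
  if (nlevels(grp) != 2 || any(table(grp) == 0)) {
    abort("`stratum` must have two nonempty levels.",
          class = "cooccupy_bad_input")
  }
  tab <- table(grp)
  if (sum(data$event) == 0) {
    return(tibble(statistic = NA_real_, p_value = NA_real_, hr = NA_real_,
                  n_low = as.integer(tab[1]), n_high = as.integer(tab[2]),
                  events = 0L, computable = FALSE))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp,
                           data = tibble(time = data$time,
                                         event = data$event, grp = grp))
  hr <- (sd$obs[2] / sd$exp[2]) / (sd$obs[1] / sd$exp[1])
  tibble(statistic = sd$chisq,
         p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE),
         hr = hr,
         n_low = as.integer(tab[1]), n_high = as.integer(tab[2]),
         events = as.integer(sum(data$event)), computable = TRUE)
}

#' Dual-gene-signature survival screen across cohorts
#'
#' For every cohort: score patients on both signatures, median-split each
#' score, and run the log-rank/HR readout for both splits.  A cohort is
#' flagged when the signature-1 split is significant (`p < alpha`); the
#' signature-2 flag is reported alongside as the specificity control.  The
#' paired hazard ratios are the scatter coordinates of the screen readout.
#' Cohort-level failures (e.g. degenerate splits) are recorded in `note`
#' and the screen continues.
#'
#' @param cohorts Tibble with columns `cohort`, `patient`, `time`, `event`
#'   and one column per gene (all cohorts stacked).
#' @param sig1,sig2 Character vectors of signature genes.
#' @param alpha Significance level for the flags (default 0.05).
#' @return A `dual_screen` tibble: per cohort `hr_sig1`, `p_sig1`,
#'   `hr_sig2`, `p_sig2`, `sig1_flag`, `sig2_flag`, `n`, `note`.
#' @export
dual_signature_screen <- function(cohorts, sig1, sig2, alpha = 0.05) {
  assert_columns(cohorts, c("cohort", "patient", "time", "event"), "cohorts")
  one_sig <- function(data, genes) {
    signature_score(data, genes) |>
      stratify_median() |>
      logrank_hr()
  }
  res <- map(split(cohorts, cohorts$cohort), function(data) {
    row <- tibble(cohort = data$cohort[1], hr_sig1 = NA_real_,
                  p_sig1 = NA_real_, hr_sig2 = NA_real_, p_sig2 = NA_real_,
                  sig1_flag = FALSE, sig2_flag = FALSE,
                  n = nrow(data), note = NA_character_)
    r1 <- tryCatch(one_sig(data, sig1), error = function(e) conditionMessage(e))
    r2 <- tryCatch(one_sig(data, sig2), error = function(e) conditionMessage(e))
    if (is.character(r1)) {
      row$note <- paste("sig1:", r1)
    } else {
      row$hr_sig1 <- r1$hr; row$p_sig1 <- r1$p_value
      row$sig1_flag <- isTRUE(r1$computable && r1$p_value < alpha)
    }
    if (is.character(r2)) {
      row$note <- paste(stats::na.omit(c(row$note, paste("sig2:", r2))),
                        collapse = "; ")
    } else {
      row$hr_sig2 <- r2$hr; row$p_sig2 <- r2$p_value
      row$sig2_flag <- isTRUE(r2$computable && r2$p_value < alpha)
    }
    row
  }) |> list_rbind()
  class(res) <- c("dual_screen", class(res))
  attr(res, "alpha") <- alpha
  res
}

#' @describeIn dual_signature_screen Scatter of per-cohort hazard ratios
#'   (signature 1 vs signature 2), flagged cohorts highlighted.
#' @param object A `dual_screen` result.
#' @param ... Unused.
#' @method autoplot dual_screen
#' @export
autoplot.dual_screen <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$hr_sig2, y = .data$hr_sig1,
                               colour = .data$sig1_flag)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey70") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$cohort),
                       vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey40")) +
    ggplot2::labs(x = "hazard ratio (signature 2 split)",
                  y = "hazard ratio (signature 1 split)",
                  colour = "signature 1\nsignificant") +
    ggplot2::theme_minimal()
}
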