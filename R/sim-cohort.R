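#' Simulate survival cohorts whose hazard tracks one gene signature
#'
#' Builds `n_cohorts` patient cohorts.  Each patient has two independent
#' latent activity scores; signature-1 genes express the first, signature-2
#' genes the second (plus noise), and background genes are pure noise.  In
#' the cohorts listed in `effect_cohorts`, event times are exponential with
#' rate `baseline_hazard * hazard_ratio^(high signature-1 activity)`; in all
#' other cohorts (and always for signature 2) the hazard is flat, so a
#' correctly working screen flags signature 1 in the affected cohorts only.
#' Censoring is independent of the event process.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   * `cohorts`: tibble with `cohort`, `patient`, `time`, `event`, and one
#'     column per gene;
#'   * `signatures`: list of character vectors `sig1`, `sig2`;
#'   * `truth`: tibble (`cohort`, `hazard_ratio`) of planted effects.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$hazard_ratio <= 0) {
    abort("`hazard_ratio` must be positive.",
          class = "cooccupy_invalid_config")
  }
  ns <- config$n_signature_genes
  sig1 <- sprintf("S1_%03d", seq_len(ns))
  sig2 <- sprintf("S2_%03d", seq_len(ns))
  bg <- sprintf("BG_%03d", seq_len(ns))

  with_seed(sub_seed(config$seed, 4), {
    cohorts <- map(seq_len(config$n_cohorts), function(k) {
      n <- config$cohort_size
      a1 <- rnorm(n); a2 <- rnorm(n)
      expr <- cbind(
        matrix(a1, n, ns) + matrix(rnorm(n * ns, sd = 0.5), n),
        matrix(a2, n, ns) + matrix(rnorm(n * ns, sd = 0.5), n),
        matrix(rnorm(n * ns), n)
      )
      colnames(expr) <- c(sig1, sig2, bg)
      hr_k <- if (k %in% config$effect_cohorts) config$hazard_ratio else 1
      rate <- config$baseline_hazard * hr_k^(a1 > 0)
      ev_time <- rexp(n, rate)
      if (config$censor_frac >= 1) {
        time <- runif(n, 0, 1 / config$baseline_hazard)
        event <- rep(0L, n)
      } else if (config$censor_frac <= 0) {
        time <- ev_time
        event <- rep(1L, n)
      } else {
        cens_rate <- config$baseline_hazard *
          config$censor_frac / (1 - config$censor_frac)
        c_time <- rexp(n, cens_rate)
        time <- pmin(ev_time, c_time)
        event <- as.integer(ev_time <= c_time)
      }
      bind_cols(
        tibble(cohort = paste0("cohort_", k),
               patient = sprintf("c%d_p%04d", k, seq_len(n)),
               time = time, event = event),
        as_tibble(expr)
      )
    }) |> list_rbind()

    list(
      cohorts = cohorts,
      signatures = list(sig1 = sig1, sig2 = sig2),
      truth = tibble(
        cohort = paste0("cohort_", seq_len(config$n_cohorts)),
        hazard_ratio = ifelse(seq_len(config$n_cohorts) %in%
                                config$effect_cohorts,
                              config$hazard_ratio, 1)
      )
    )
  })
}
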