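#' Simulate condition-dependent binding counts with spike-in tallies
#'
#' Draws negative-binomial read counts over a set of regions for two
#' conditions (`OFF`, `ON`) with `n_replicates` each.  A planted subset of
#' regions has its ON-condition mean shifted by `diff_log2fc` log2 units; an
#' optional `global_shift` scales every ON mean, emulating a genome-wide
#' occupancy gain that is invisible after per-sample depth normalization but
#' recoverable through the spike-in.  Samples are depth-normalized at
#' generation (library composition determines what fraction of reads each
#' region receives), and each sample receives a spike-in read tally drawn so
#' that the true composition is restored by [scaling_factor()]
#' multiplication.
#'
#' @param peaks A peak/region table with at least `name` (used as region id);
#'   typically the `truth` element of [simulate_peak_landscape()].
#' @param config A [sim_config()].
#' @return A list with elements
#'   * `counts`: wide tibble, `region` plus one column per sample;
#'   * `design`: tibble (`sample`, `condition`, `replicate`);
#'   * `tallies`: tibble (`sample`, `reads_target_lt120`, `reads_spike`);
#'   * `truth`: tibble (`region`, `is_diff`, `log2fc`).
#' @export
simulate_binding_counts <- function(peaks, config) {
  stopifnot(inherits(config, "sim_config"))
  assert_columns(peaks, "name", "peaks")
  if (config$dispersion < 0) {
    abort("`dispersion` must be nonnegative.",
          class = "cooccupy_invalid_config")
  }
  if (config$n_replicates < 2) {
    abort("at least 2 replicates per condition are required.",
          class = "cooccupy_invalid_config")
  }
  regions <- unique(peaks$name)
  n_regions <- length(regions)
  n_diff <- min(config$n_diff_regions, n_regions)

  with_seed(sub_seed(config$seed, 2), {
    mu0 <- rlnorm(n_regions, meanlog = log(config$region_depth), sdlog = 0.5)
    diff_idx <- sample.int(n_regions, n_diff)
    effect <- rep(0, n_regions)
    effect[diff_idx] <- config$diff_log2fc
    mu_on <- mu0 * 2^effect * config$global_shift

    design <- tidyr::expand_grid(condition = c("OFF", "ON"),
                                 replicate = seq_len(config$n_replicates)) |>
      mutate(sample = paste0(.data$condition, "_rep", .data$replicate)) |>
      select("sample", "condition", "replicate")

    # Library composition: a sample sequences a fixed read budget, so the
    # per-region expectation is the region's share of total true occupancy.
    comp <- c(OFF = 1, ON = sum(mu_on) / sum(mu0))
    depth <- rlnorm(nrow(design), 0, config$depth_sdlog)

    draw <- function(mu) {
      if (config$dispersion == 0) rpois(length(mu), mu)
      else rnbinom(length(mu), size = 1 / config$dispersion, mu = mu)
    }
    counts_mat <- vapply(seq_len(nrow(design)), function(s) {
      mu <- (if (design$condition[s] == "ON") mu_on else mu0) /
        comp[[design$condition[s]]] * depth[s]
      draw(mu)
    }, numeric(n_regions))
    colnames(counts_mat) <- design$sample

    tallies <- tibble(
      sample = design$sample,
      reads_target_lt120 = colSums(counts_mat),
      reads_spike = rpois(nrow(design),
                          config$spike_base * depth /
                            comp[design$condition])
    )

    list(
      counts = bind_cols(tibble(region = regions), as_tibble(counts_mat)),
      design = design,
      tallies = tallies,
      truth = tibble(region = regions,
                     is_diff = seq_len(n_regions) %in% diff_idx,
                     log2fc = effect)
    )
  })
}
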