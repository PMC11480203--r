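#' Simulate a two-factor peak landscape with planted co-occupancy categories
#'
#' Places non-overlapping binding sites on the synthetic genome and assigns
#' each to one of three planted categories: `joint` (bound by both factors),
#' `factorA_only`, or `factorB_only`.  Each factor then receives
#' `n_replicates` replicate peak sets containing the joint sites plus its
#' exclusive sites, with per-replicate coordinate jitter bounded by
#' `replicate_jitter`.  A configured fraction of sites carries an AP-1-motif
#' flag (a boolean annotation, not a sequence scan).  Transcription start
#' sites are simulated alongside, so distance analyses have a reference
#' point set.
#'
#' @param genome A genome tibble from [make_genome()].
#' @param config A [sim_config()].
#' @return A list with elements
#'   * `peaks`: tibble of all replicate peaks with columns `chrom`, `start`,
#'     `end`, `name`, `score`, `strand`, `tf` (`"A"`/`"B"`), `replicate`,
#'     `category`, `motif`;
#'   * `tss`: tibble of reference points (`chrom`, `pos`, `gene`, `strand`);
#'   * `truth`: one row per planted site (`name`, `chrom`, `start`, `end`,
#'     `category`, `motif`).
#' @examples
#' cfg <- sim_config(seed = 1, n_joint = 20, n_factor_a = 10, n_factor_b = 10)
#' land <- simulate_peak_landscape(make_genome(cfg), cfg)
#' dplyr::count(land$truth, category)
#' @export
simulate_peak_landscape <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  assert_columns(genome, c("chrom", "length"), "genome")
  n_sites <- config$n_joint + config$n_factor_a + config$n_factor_b
  slot <- max(10 * config$peak_width,
              config$peak_width + 4 * config$replicate_jitter)
  slots_per_chrom <- pmax(floor(genome$length / slot), 0)
  if (sum(slots_per_chrom) < n_sites) {
    abort("requested peak mass exceeds genome capacity.",
          class = "cooccupy_invalid_config")
  }

  with_seed(sub_seed(config$seed, 1), {
    slot_chrom <- rep(genome$chrom, slots_per_chrom)
    slot_start <- unlist(map(slots_per_chrom, function(k) slot * (seq_len(k) - 1)),
                         use.names = FALSE)
    pick <- sort(sample.int(length(slot_chrom), n_sites))
    # leave jitter headroom at the slot edge
    start <- slot_start[pick] + 2 * config$replicate_jitter
    truth <- tibble(
      name = sprintf("site_%04d", seq_len(n_sites)),
      chrom = slot_chrom[pick],
      start = start,
      end = start + config$peak_width,
      category = sample(rep(c("joint", "factorA_only", "factorB_only"),
                            times = c(config$n_joint, config$n_factor_a,
                                      config$n_factor_b))),
      motif = runif(n_sites) < config$motif_fraction
    ) |>
      arrange(.data$chrom, .data$start)

    reps <- seq_len(config$n_replicates)
    peaks <- tidyr::expand_grid(tf = c("A", "B"), replicate = reps) |>
      pmap(function(tf, replicate) {
        keep <- truth$category %in%
          c("joint", if (tf == "A") "factorA_only" else "factorB_only")
        sites <- truth[keep, ]
        jit <- if (config$replicate_jitter > 0) {
          sample(seq(-config$replicate_jitter, config$replicate_jitter),
                 nrow(sites), replace = TRUE)
        } else 0L
        tibble(chrom = sites$chrom,
               start = sites$start + jit,
               end = sites$end + jit,
               name = sites$name,
               score = round(runif(nrow(sites), 10, 1000), 1),
               strand = ".",
               tf = tf, replicate = replicate,
               category = sites$category, motif = sites$motif)
      }) |>
      list_rbind() |>
      arrange(.data$tf, .data$replicate, .data$chrom, .data$start)

    tss_chrom <- sample(genome$chrom, config$n_tss, replace = TRUE,
                        prob = genome$length / sum(genome$length))
    tss <- tibble(
      chrom = tss_chrom,
      pos = floor(runif(config$n_tss, 0,
                        genome$length[match(tss_chrom, genome$chrom)])),
      gene = sprintf("gene_%04d", seq_len(config$n_tss)),
      strand = sample(c("+", "-"), config$n_tss, replace = TRUE)
    ) |>
      arrange(.data$chrom, .data$pos)

    list(peaks = peaks, tss = tss, truth = truth)
  })
}
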