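#' Simulate a CRISPR-activation screen with planted enriched genes
#'
#' Baseline sgRNA abundances are log-normal; after selection, the sgRNAs of
#' planted hit genes (all of them, or a configured fraction per gene) are
#' multiplied by `hit_enrichment` before log-normal selection noise is
#' applied.  Counts are reported for a `baseline` and a `selected` sample.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   * `counts`: tibble (`sgrna`, `gene`, `baseline`, `selected`);
#'   * `lib_sizes`: named numeric, total reads per sample;
#'   * `truth`: tibble (`gene`, `is_hit`, `enrichment`).
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- as.integer(config$sgrnas_per_gene)
  if (k < 1) {
    abort("every gene needs at least one sgRNA.",
          class = "cooccupy_invalid_config")
  }
  n_genes <- as.integer(config$n_screen_genes)
  genes <- sprintf("G%04d", seq_len(n_genes))

  with_seed(sub_seed(config$seed, 5), {
    hit_genes <- sample(genes, min(config$n_hit_genes, n_genes))
    tab <- tidyr::expand_grid(gene = genes, sg = seq_len(k)) |>
      mutate(sgrna = paste0(.data$gene, "_sg", .data$sg))
    n <- nrow(tab)
    abundance <- rlnorm(n, meanlog = log(200), sdlog = 1)
    responds <- tab$gene %in% hit_genes &
      runif(n) < config$hit_sgrna_fraction
    enrich <- ifelse(responds, config$hit_enrichment, 1)
    baseline <- round(abundance *
                        rlnorm(n, 0, config$screen_noise_sd))
    selected <- round(abundance * enrich *
                        rlnorm(n, 0, config$screen_noise_sd))
    counts <- tibble(sgrna = tab$sgrna, gene = tab$gene,
                     baseline = baseline, selected = selected)
    list(
      counts = counts,
      lib_sizes = c(baseline = sum(baseline), selected = sum(selected)),
      truth = tibble(gene = genes,
                     is_hit = genes %in% hit_genes,
                     enrichment = ifelse(genes %in% hit_genes,
                                         config$hit_enrichment, 1))
    )
  })
}
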