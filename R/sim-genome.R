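#' Build the synthetic genome
#'
#' Constructs the chromosome table that anchors all simulated coordinates.
#' A stand-in for real genome assemblies at desk scale.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `chrom` and `length` (bp).
#' @examples
#' make_genome(sim_config(seed = 1))
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- as.integer(config$n_chromosomes)
  if (n < 1) {
    abort("configuration requests zero chromosomes.",
          class = "cooccupy_invalid_config")
  }
  n_sites <- config$n_joint + config$n_factor_a + config$n_factor_b
  if (n * config$chromosome_length < 10 * n_sites * config$peak_width) {
    abort("genome too small: total length must be at least 10x the requested peak mass.",
          class = "cooccupy_invalid_config")
  }
  tibble(chrom = paste0("chr", seq_len(n)),
         length = rep(as.numeric(config$chromosome_length), n))
}
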