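#' Simulation configuration
#'
#' Builds the single configuration object consumed by every synthetic-data
#' generator in the package.  The defaults define the desk-scale study
#' conditions the whole test suite runs under: 2 chromosomes of 1 Mb, 1,000
#' transcription-factor peaks split across co-occupancy categories, 434
#' top-induced genes in three planted clusters, 3 patient cohorts of 500, and
#' a 1,000-gene activation screen with 3 sgRNAs per gene.
#'
#' @param seed Integer seed; every generator derives its sub-streams from it.
#' @param n_chromosomes,chromosome_length Genome shape (lengths in bp).
#' @param n_tss Number of simulated transcription start sites.
#' @param peak_width Width of every simulated peak, bp.
#' @param n_joint,n_factor_a,n_factor_b Peak counts per planted co-occupancy
#'   category: sites bound by both factors, and by each factor exclusively.
#' @param motif_fraction Probability that a peak carries the AP-1-motif flag
#'   (a boolean annotation; no sequence scanning is simulated).
#' @param replicate_jitter Maximum absolute per-replicate shift of peak
#'   coordinates, bp.
#' @param n_replicates Replicates per factor (peaks) and per condition
#'   (binding counts, expression).
#' @param region_depth Mean sequencing depth per region (reads), baseline
#'   condition.
#' @param dispersion Negative-binomial dispersion (1/size) of region counts;
#'   0 gives Poisson counts.
#' @param n_diff_regions Number of regions with a planted binding change.
#' @param diff_log2fc Planted log2 effect at differential regions (ON vs OFF).
#' @param global_shift Multiplicative global occupancy shift in the ON
#'   condition (1 = no composition change); recovered via the spike-in.
#' @param spike_base Expected spike-in read count at unit depth.
#' @param depth_sdlog Log-normal sd of per-sample depth factors (libraries
#'   are assumed sequenced to closely matched depth: the spike-in scaling
#'   factor cancels depth only in the factor, not in the raw counts).
#' @param n_genes Total genes in the expression simulation (induced +
#'   background).
#' @param cluster_sizes Sizes of the three planted clusters of top-induced
#'   genes (sums to 434 by default, the size of the selected gene set the
#'   clustering operates on).
#' @param expr_noise_sd Gaussian noise sd around cluster archetypes
#'   (z-score units).
#' @param expr_groups Names of the four condition groups (empty-vector /
#'   JUN-overexpression crossed with induction OFF/ON).
#' @param n_cohorts,cohort_size Survival-screen cohorts and patients each.
#' @param n_signature_genes Genes per survival signature.
#' @param baseline_hazard Exponential event rate in the low-score stratum,
#'   per time unit.
#' @param hazard_ratio Planted hazard ratio for high signature-1 activity in
#'   the affected cohort(s).
#' @param effect_cohorts Indices of cohorts whose hazard depends on
#'   signature 1 (others are null).
#' @param censor_frac Approximate fraction of patients censored; 1 censors
#'   everyone.
#' @param n_screen_genes,sgrnas_per_gene,n_hit_genes Screen shape.
#' @param hit_enrichment Fold enrichment of hit-gene sgRNAs after selection.
#' @param hit_sgrna_fraction Fraction of a hit gene's sgRNAs that respond.
#' @param screen_noise_sd Log-normal sd of selection noise per sgRNA.
#' @param ... Overrides are also accepted as a named list via [modifyList()].
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$n_joint
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chromosome_length = 1e6,
                       n_tss = 500L,
                       peak_width = 200L,
                       n_joint = 400L,
                       n_factor_a = 300L,
                       n_factor_b = 300L,
                       motif_fraction = 0.4,
                       replicate_jitter = 10L,
                       n_replicates = 3L,
                       region_depth = 100,
                       dispersion = 0.05,
                       n_diff_regions = 100L,
                       diff_log2fc = 2,
                       global_shift = 1,
                       spike_base = 1e5,
                       depth_sdlog = 0.02,
                       n_genes = 2000L,
                       cluster_sizes = c(150L, 150L, 134L),
                       expr_noise_sd = 0.25,
                       expr_groups = c("ev_OFF", "ev_ON",
                                       "JUNoe_OFF", "JUNoe_ON"),
                       n_cohorts = 3L,
                       cohort_size = 500L,
                       n_signature_genes = 25L,
                       baseline_hazard = 0.1,
                       hazard_ratio = 2,
                       effect_cohorts = 1L,
                       censor_frac = 0.3,
                       n_screen_genes = 1000L,
                       sgrnas_per_gene = 3L,
                       n_hit_genes = 20L,
                       hit_enrichment = 8,
                       hit_sgrna_fraction = 1,
                       screen_noise_sd = 0.3,
                       ...) {
  cfg <- c(as.list(environment()), list(...))
  cfg$... <- NULL
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  assert_scalar_number(cfg$seed, "seed", lower = 0, upper = 2^31 - 1)
  assert_scalar_number(cfg$n_chromosomes, "n_chromosomes", lower = 0)
  assert_scalar_number(cfg$chromosome_length, "chromosome_length",
                       lower = 0, strict_lower = TRUE)
  for (nm in c("n_tss", "peak_width", "n_joint", "n_factor_a", "n_factor_b",
               "replicate_jitter", "n_diff_regions", "n_genes", "n_cohorts",
               "cohort_size", "n_signature_genes", "n_screen_genes",
               "n_hit_genes")) {
    assert_scalar_number(cfg[[nm]], nm, lower = 0)
  }
  assert_scalar_number(cfg$n_replicates, "n_replicates", lower = 1)
  assert_scalar_number(cfg$sgrnas_per_gene, "sgrnas_per_gene", lower = 1)
  assert_scalar_number(cfg$motif_fraction, "motif_fraction", 0, 1)
  assert_scalar_number(cfg$hit_sgrna_fraction, "hit_sgrna_fraction", 0, 1)
  assert_scalar_number(cfg$censor_frac, "censor_frac", 0, 1)
  assert_scalar_number(cfg$dispersion, "dispersion", lower = 0)
  assert_scalar_number(cfg$hazard_ratio, "hazard_ratio",
                       lower = 0, strict_lower = TRUE)
  assert_scalar_number(cfg$baseline_hazard, "baseline_hazard",
                       lower = 0, strict_lower = TRUE)
  assert_scalar_number(cfg$global_shift, "global_shift",
                       lower = 0, strict_lower = TRUE)
  assert_scalar_number(cfg$hit_enrichment, "hit_enrichment",
                       lower = 0, strict_lower = TRUE)
  if (!is.numeric(cfg$cluster_sizes) || length(cfg$cluster_sizes) < 1 ||
      any(cfg$cluster_sizes < 0)) {
    abort("`cluster_sizes` must be nonnegative counts.",
          class = "cooccupy_invalid_config")
  }
  if (length(cfg$expr_groups) < 4) {
    abort("at least 4 condition groups are required (two factors crossed with OFF/ON).",
          class = "cooccupy_invalid_config")
  }
  if (sum(cfg$cluster_sizes) > cfg$n_genes) {
    abort("`cluster_sizes` exceed `n_genes`.",
          class = "cooccupy_invalid_config")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  seed:", x$seed, "\n")
  cat("  genome:", x$n_chromosomes, "chromosome(s) x",
      format(x$chromosome_length, big.mark = ","), "bp\n")
  cat("  peaks:", x$n_joint, "joint +", x$n_factor_a, "A-only +",
      x$n_factor_b, "B-only;", x$n_replicates, "replicates\n")
  cat("  expression:", sum(x$cluster_sizes), "induced genes in",
      length(x$cluster_sizes), "clusters of", x$n_genes, "total\n")
  cat("  cohorts:", x$n_cohorts, "x", x$cohort_size,
      "patients; HR", x$hazard_ratio, "\n")
  cat("  screen:", x$n_screen_genes, "genes x", x$sgrnas_per_gene,
      "sgRNAs;", x$n_hit_genes, "hits at", x$hit_enrichment, "fold\n")
  invisible(x)
}
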