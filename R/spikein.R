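#' Spike-in scaling factors from alignment tallies
#'
#' Computes, per sample, the scaling factor
#' `reads_target_lt120 / reads_spike`: reads mapped to the target genome
#' with short (sub-nucleosomal, < 120 bp) inserts over reads mapped to the
#' exogenous spike-in genome.  Samples that lose global signal recover fewer
#' target reads per spike-in read, so multiplying raw counts by this factor
#' restores true composition differences between conditions.
#'
#' @param tallies Tibble with columns `reads_target_lt120` and `reads_spike`
#'   (plus any id columns, preserved).
#' @return `tallies` with an appended `scaling_factor` column.
#' @examples
#' scaling_factor(tibble::tibble(sample = "s1",
#'                               reads_target_lt120 = 1000,
#'                               reads_spike = 100))
#' @export
scaling_factor <- function(tallies) {
  assert_columns(tallies, c("reads_target_lt120", "reads_spike"), "tallies")
  if (any(tallies$reads_target_lt120 < 0 | tallies$reads_spike < 0)) {
    abort("read tallies must be nonnegative.", class = "cooccupy_bad_input")
  }
  if (any(tallies$reads_spike == 0)) {
    abort("spike-in failed: zero spike-in reads in at least one sample.",
          class = "cooccupy_spikein_error")
  }
  mutate(tallies,
         scaling_factor = .data$reads_target_lt120 / .data$reads_spike)
}

#' Spike-in normalize a region count table
#'
#' Multiplies each sample column of a wide region-by-sample count table by
#' that sample's spike-in scaling factor.  Linear in the raw counts.
#'
#' @param counts Wide tibble: `region` plus one numeric column per sample.
#' @param tallies Tibble with `sample`, `reads_target_lt120`, `reads_spike`
#'   covering every sample column of `counts`.
#' @return `counts` with each sample column scaled.
#' @export
normalize_counts <- function(counts, tallies) {
  assert_columns(counts, "region", "counts")
  assert_columns(tallies, c("sample", "reads_target_lt120", "reads_spike"),
                 "tallies")
  samples <- sample_columns(counts, "region")
  missing <- setdiff(samples, tallies$sample)
  if (length(missing)) {
    abort(sprintf("no spike-in tally for sample(s): %s",
                  paste(missing, collapse = ", ")),
          class = "cooccupy_bad_input")
  }
  sf <- scaling_factor(tallies)
  fac <- setNames(sf$scaling_factor, sf$sample)
  out <- counts
  for (s in samples) out[[s]] <- out[[s]] * fac[[s]]
  out
}
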