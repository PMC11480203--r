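# Genomic interval algebra on peak tibbles.  Coordinates are 0-based
# half-open throughout; overlap queries are delegated to
# GenomicRanges::findOverlaps after conversion to 1-based closed ranges.

peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1, end = peaks$end)
  )
}

#' Replicate-conservative peak set
#'
#' Retains the intervals of the first peak set that overlap (by at least
#' `min_overlap` bp) at least one interval in *every* other set — the
#' "occurring in all replicates" rule used to build conservative peak sets
#' from replicated profiling experiments.
#'
#' @param sets A list of two or more peak tibbles (`chrom`, `start`, `end`,
#'   ...).  The first set is the reference whose rows are returned.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return The filtered first set, original columns preserved.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
#' b <- tibble::tibble(chrom = "chr1", start = 50, end = 150)
#' intersect_replicates(list(a, b))
#' @export
intersect_replicates <- function(sets, min_overlap = 1) {
  if (!is.list(sets) || length(sets) < 2) {
    abort("`sets` must be a list of at least two peak tables.",
          class = "cooccupy_bad_input")
  }
  purrr::walk(sets, assert_columns, c("chrom", "start", "end"), "each peak set")
  ref <- sets[[1]]
  gr_ref <- peaks_to_granges(ref)
  keep <- rep(TRUE, nrow(ref))
  for (other in sets[-1]) {
    hits <- GenomicRanges::findOverlaps(gr_ref, peaks_to_granges(other),
                                        minoverlap = min_overlap)
    keep <- keep & seq_len(nrow(ref)) %in% S4Vectors::queryHits(hits)
  }
  ref[keep, ]
}

#' Categorize reference peaks by multi-set overlap, with Venn counts
#'
#' Labels every interval of the first (reference) set by the exact subset of
#' the other sets it overlaps, and tabulates Venn-region counts over the
#' merged union of all sets (single-linkage merge, >= `min_overlap` bp).
#'
#' @param sets A *named* list of 2--4 peak tibbles; the first is the
#'   reference.
#' @param min_overlap Minimum overlap in bp for set membership (default 1).
#' @return A list with
#'   * `labels`: the reference set plus a `category` column — the
#'     intersection label (set names joined by `"&"`), or the reference
#'     name alone for exclusive intervals;
#'   * `venn`: tibble (`combination`, `n`) whose counts sum to the number of
#'     distinct merged intervals.
#' @export
categorize_overlap <- function(sets, min_overlap = 1) {
  if (!is.list(sets) || length(sets) < 2 || length(sets) > 4) {
    abort("`sets` must be a named list of 2-4 peak tables.",
          class = "cooccupy_bad_input")
  }
  nms <- names(sets)
  if (is.null(nms) || any(!nzchar(nms)) || anyDuplicated(nms)) {
    abort("`sets` must have unique non-empty names.",
          class = "cooccupy_bad_input")
  }
  purrr::walk(sets, assert_columns, c("chrom", "start", "end"), "each peak set")
  grs <- map(sets, peaks_to_granges)

  ref <- sets[[1]]
  memb <- vapply(seq_along(sets)[-1], function(j) {
    hits <- GenomicRanges::findOverlaps(grs[[1]], grs[[j]],
                                        minoverlap = min_overlap)
    seq_len(nrow(ref)) %in% S4Vectors::queryHits(hits)
  }, logical(nrow(ref)))
  memb <- matrix(memb, nrow = nrow(ref))
  category <- vapply(seq_len(nrow(ref)), function(i) {
    paste(c(nms[1], nms[-1][memb[i, ]]), collapse = "&")
  }, character(1))

  merged <- GenomicRanges::reduce(do.call(c, unname(grs)),
                                  min.gapwidth = 0L)
  in_set <- vapply(grs, function(g) {
    hits <- GenomicRanges::findOverlaps(merged, g, minoverlap = min_overlap)
    seq_along(merged) %in% S4Vectors::queryHits(hits)
  }, logical(length(merged)))
  in_set <- matrix(in_set, nrow = length(merged))
  combination <- vapply(seq_len(length(merged)), function(i) {
    paste(nms[in_set[i, ]], collapse = "&")
  }, character(1))
  venn <- tibble(combination = combination) |>
    count(.data$combination, name = "n")

  labels <- as_tibble(ref)
  labels[["category"]] <- category  # overwrite any annotation of that name
  list(labels = labels, venn = venn)
}

#' Distance from reference points to the closest interval
#'
#' For every query point (e.g., a TSS), finds the nearest subject interval on
#' the same chromosome and its distance in bp.  A point inside an interval
#' has distance 0; otherwise the distance is measured to the nearest
#' *included* base of the half-open interval, i.e. `start - pos` on the left
#' and `pos - (end - 1)` on the right, so a point at 100 is 1 bp from
#' `[0, 100)`.  Ties are broken by the leftmost subject start; strand is
#' ignored.  Queries on chromosomes absent from the subjects get `NA`.
#'
#' @param query Tibble of points with columns `chrom`, `pos` (plus optional
#'   ids, preserved).
#' @param subjects Peak tibble (`chrom`, `start`, `end`, optional `name`).
#' @return `query` plus columns `nearest` (subject name or row index),
#'   `nearest_start`, `nearest_end`, `distance`.
#' @export
closest_distance <- function(query, subjects) {
  assert_columns(query, c("chrom", "pos"), "query")
  assert_columns(subjects, c("chrom", "start", "end"), "subjects")
  if (!nrow(query) || !nrow(subjects)) {
    abort("`query` and `subjects` must be nonempty.",
          class = "cooccupy_bad_input")
  }
  subj_name <- if ("name" %in% names(subjects)) subjects$name
               else as.character(seq_len(nrow(subjects)))
  res <- as_tibble(query)
  res$nearest <- NA_character_
  res$nearest_start <- NA_real_
  res$nearest_end <- NA_real_
  res$distance <- NA_real_
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- which(subjects$chrom == ch)
    if (!length(si)) next
    ord <- order(subjects$start[si])
    s_start <- subjects$start[si][ord]
    s_end <- subjects$end[si][ord]
    s_name <- subj_name[si][ord]
    for (i in qi) {
      p <- query$pos[i]
      d <- ifelse(p >= s_start & p < s_end, 0,
                  pmax(s_start - p, p - (s_end - 1)))
      j <- which.min(d)  # first minimum = leftmost start after ordering
      res$nearest[i] <- s_name[j]
      res$nearest_start[i] <- s_start[j]
      res$nearest_end[i] <- s_end[j]
      res$distance[i] <- d[j]
    }
  }
  res
}

#' Random same-size peak subsets
#'
#' Draws `n_draws` uniform without-replacement subsets of `size` intervals
#' from a pool — the construction behind the permutation null of
#' [efdr_test()], where observed category peak sets are compared against
#' random same-size sets taken from the remaining categories.
#'
#' @param pool Peak tibble to sample from.
#' @param size Number of intervals per draw; must not exceed `nrow(pool)`.
#' @param n_draws Number of draws.
#' @param seed Integer seed; the draw sequence is reproducible.
#' @return A list of `n_draws` peak tibbles, each sorted by (chrom, start).
#' @export
sample_random_subsets <- function(pool, size, n_draws, seed = 1L) {
  assert_columns(pool, c("chrom", "start", "end"), "pool")
  if (size > nrow(pool)) {
    abort("`size` exceeds the pool size.", class = "cooccupy_bad_input")
  }
  with_seed(seed, {
    map(seq_len(n_draws), function(i) {
      pool[sort(sample.int(nrow(pool), size)), ] |>
        arrange(.data$chrom, .data$start)
    })
  })
}
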