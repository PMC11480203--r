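#' Read a BED file into a peak table
#'
#' Accepts BED3 to BED6.  Coordinates are 0-based half-open, as in the BED
#' standard.  `track`, `browser` and `#` comment lines are skipped.  Input is
#' sorted by (chrom, start, end, name) on read; duplicate
#' (chrom, start, end, name) records are dropped with a warning.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.  Missing name/score/strand fields become `NA`/`NA`/`"."`.
#' @seealso [write_bed()]
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  name = character(), score = numeric(), strand = character()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- nf < 3
  if (any(bad)) {
    abort(sprintf("malformed BED line %d: fewer than 3 fields.",
                  idx[which(bad)[1]]),
          class = "cooccupy_parse_error")
  }
  get <- function(i) vapply(fields, function(f) {
    if (length(f) >= i) f[[i]] else NA_character_
  }, character(1))
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  bad <- is.na(start) | is.na(end)
  if (any(bad)) {
    abort(sprintf("malformed BED line %d: non-numeric coordinates.",
                  idx[which(bad)[1]]),
          class = "cooccupy_parse_error")
  }
  bad <- start < 0 | end < 0
  if (any(bad)) {
    abort(sprintf("malformed BED line %d: negative coordinate.",
                  idx[which(bad)[1]]),
          class = "cooccupy_parse_error")
  }
  bad <- start >= end
  if (any(bad)) {
    abort(sprintf("malformed BED line %d: start >= end.",
                  idx[which(bad)[1]]),
          class = "cooccupy_parse_error")
  }
  name <- get(4)
  name[name == "."] <- NA_character_
  score_raw <- get(5)
  score <- suppressWarnings(as.numeric(ifelse(score_raw == ".",
                                              NA_character_, score_raw)))
  strand <- get(6)
  strand[is.na(strand)] <- "."
  bad <- !strand %in% c("+", "-", ".")
  if (any(bad)) {
    abort(sprintf("malformed BED line %d: invalid strand.",
                  idx[which(bad)[1]]),
          class = "cooccupy_parse_error")
  }
  out <- tibble(chrom = get(1), start = start, end = end,
                name = name, score = score, strand = strand) |>
    arrange(.data$chrom, .data$start, .data$end, .data$name)
  dup <- duplicated(out[c("chrom", "start", "end", "name")])
  if (any(dup)) {
    warn(sprintf("dropped %d duplicate interval(s).", sum(dup)))
    out <- out[!dup, ]
  }
  out
}

#' Write a peak table as BED6
#'
#' Inverse of [read_bed()]: missing names and scores are written as `"."`,
#' missing strands as `"."`, and coordinates are emitted as integers where
#' possible.  Output is sorted in the same canonical order as [read_bed()]
#' produces, so `write_bed(read_bed(f))` round-trips.
#'
#' @param peaks A peak tibble (`chrom`, `start`, `end`, optional `name`,
#'   `score`, `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  assert_columns(peaks, c("chrom", "start", "end"), "peaks")
  name <- if ("name" %in% names(peaks)) peaks$name else NA_character_
  score <- if ("score" %in% names(peaks)) peaks$score else NA_real_
  strand <- if ("strand" %in% names(peaks)) peaks$strand else "."
  out <- tibble(chrom = peaks$chrom,
                start = format(peaks$start, scientific = FALSE, trim = TRUE),
                end = format(peaks$end, scientific = FALSE, trim = TRUE),
                name = ifelse(is.na(name), ".", name),
                score = ifelse(is.na(score), ".", as.character(score)),
                strand = ifelse(is.na(strand) | strand == "", ".", strand))
  readr::write_tsv(out, path, col_names = FALSE, escape = "none")
  invisible(path)
}
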