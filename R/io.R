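#' Read a per-bp recombination rate track
#'
#' Rate tracks are 4-column whitespace-separated text files
#' (`chrom start end rate`), the interval format emitted by LD-based
#' recombination inference. Rates are per-bp, per-generation crossover
#' probabilities. Coordinates are 0-based half-open. Intervals may tile or
#' partially cover each linkage group but must not overlap.
#'
#' @param path Path to the track file.
#' @param layout Optional [genome_layout()]; when given, intervals are checked
#'   against linkage-group lengths.
#'
#' @return A tibble with columns `lg`, `start`, `end`, `rate`, sorted by
#'   `lg` then `start`.
#' @seealso [write_rate_track()], [read_bed()]
#' @export
read_rate_track <- function(path, layout = NULL) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(lg = character(), start = numeric(), end = numeric(),
                  rate = numeric()))
  }
  parts <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(parts)
  if (any(nf < 4)) {
    abort(sprintf("rate track parse error at line %d: expected 4 fields",
                  which(nf < 4)[1]))
  }
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  rate <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 4L)))
  bad <- which(is.na(start) | is.na(end) | is.na(rate))
  if (length(bad)) {
    abort(sprintf("rate track parse error at line %d: non-numeric field",
                  bad[1]))
  }
  x <- tibble(lg = vapply(parts, `[[`, "", 1L), start = start, end = end,
              rate = rate) %>% arrange(.data$lg, .data$start)
  validate_intervals(x, layout, value_col = "rate", require_nonneg = TRUE,
                     allow_overlap = FALSE, what = "rate track")
  x
}

#' Write a rate track to file
#'
#' Inverse of [read_rate_track()]: rates are written with enough significant
#' digits (15) that a write/read round trip preserves them.
#'
#' @param track Tibble with columns `lg`, `start`, `end`, `rate`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rate_track <- function(track, path) {
  validate_intervals(track, value_col = "rate", require_nonneg = TRUE,
                     allow_overlap = FALSE, what = "rate track")
  lines <- sprintf("%s\t%d\t%d\t%.15g", track$lg, as.integer(track$start),
                   as.integer(track$end), track$rate)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read and write BED intervals
#'
#' Standard 3+ column BED: 0-based half-open coordinates, optional fourth
#' `name` column. Used for genes, CpG islands, repeats and masks.
#'
#' @param path File path.
#' @param layout Optional [genome_layout()] to validate coordinates against.
#' @return `read_bed()`: a tibble with columns `lg`, `start`, `end` and,
#'   when present in the file, `name`.
#' @export
read_bed <- function(path, layout = NULL) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(lg = character(), start = numeric(), end = numeric()))
  }
  parts <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(parts)
  if (any(nf < 3)) {
    abort(sprintf("BED parse error at line %d: expected >= 3 fields",
                  which(nf < 3)[1]))
  }
  x <- tibble(
    lg = vapply(parts, `[[`, "", 1L),
    start = as.numeric(vapply(parts, `[[`, "", 2L)),
    end = as.numeric(vapply(parts, `[[`, "", 3L))
  )
  if (all(nf >= 4)) x$name <- vapply(parts, `[[`, "", 4L)
  validate_intervals(x, layout, what = "BED")
  arrange(x, .data$lg, .data$start)
}

#' @rdname read_bed
#' @param x Tibble of intervals (`lg`, `start`, `end`, optionally `name`).
#' @return `write_bed()`: `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x, what = "BED")
  if ("name" %in% names(x)) {
    lines <- sprintf("%s\t%d\t%d\t%s", x$lg, as.integer(x$start),
                     as.integer(x$end), x$name)
  } else {
    lines <- sprintf("%s\t%d\t%d", x$lg, as.integer(x$start),
                     as.integer(x$end))
  }
  readr::write_lines(lines, path)
  invisible(path)
}
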