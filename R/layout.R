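#' Describe the linkage groups of an assembly
#'
#' A genome layout is the minimal description of the sequence the analysis
#' runs on: one row per linkage group (LG) with its assembled length and
#' whether it is an autosome. All interval data (rate tracks, annotations,
#' windows) are validated against a layout.
#'
#' @param lg Character vector of unique linkage-group identifiers.
#' @param length_bp Integer-valued vector of assembled lengths in bp (>= 1).
#' @param is_autosome Logical vector; defaults to all `TRUE`.
#'
#' @return A tibble with columns `lg`, `length_bp`, `is_autosome`.
#' @examples
#' genome_layout(c("lg1", "lg2"), c(50e6, 10e6))
#' @export
genome_layout <- function(lg, length_bp, is_autosome = rep(TRUE, length(lg))) {
  lg <- as.character(lg)
  if (anyDuplicated(lg)) abort("linkage-group ids must be unique")
  length_bp <- as.numeric(length_bp)
  if (any(!is.finite(length_bp)) || any(length_bp < 1)) {
    abort("linkage-group lengths must be positive")
  }
  if (length(is_autosome) != length(lg)) {
    abort("`is_autosome` must match `lg` in length")
  }
  tibble(lg = lg, length_bp = length_bp, is_autosome = as.logical(is_autosome))
}

# Internal: check a tibble of intervals (lg, start, end, ...) against a layout.
# BED convention throughout: 0-based, half-open [start, end).
validate_intervals <- function(x, layout = NULL, value_col = NULL,
                               require_nonneg = FALSE, allow_overlap = TRUE,
                               what = "interval set") {
  need <- c("lg", "start", "end")
  if (!all(need %in% names(x))) {
    abort(paste0(what, " needs columns lg, start, end"))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(!is.finite(x$start)) || any(!is.finite(x$end))) {
    abort(paste0(what, ": non-finite coordinates"))
  }
  if (any(x$start < 0)) abort(paste0(what, ": negative start coordinate"))
  bad <- which(x$start >= x$end)
  if (length(bad)) {
    abort(sprintf("%s: start >= end at row %d", what, bad[1]))
  }
  if (!is.null(value_col) && require_nonneg) {
    v <- x[[value_col]]
    if (any(!is.finite(v)) || any(v < 0)) {
      abort(paste0(what, ": values must be finite and non-negative"))
    }
  }
  if (!is.null(layout)) {
    ln <- setNames(layout$length_bp, layout$lg)
    unknown <- setdiff(unique(x$lg), names(ln))
    if (length(unknown)) {
      abort(paste0(what, ": unknown linkage group ", unknown[1]))
    }
    if (any(x$end > ln[x$lg])) {
      abort(paste0(what, ": interval beyond linkage-group length"))
    }
  }
  if (!allow_overlap) {
    ord <- order(x$lg, x$start)
    xs <- x[ord, ]
    same <- xs$lg[-1] == xs$lg[-nrow(xs)]
    if (any(same & xs$start[-1] < xs$end[-nrow(xs)])) {
      abort(paste0(what, ": overlapping intervals"))
    }
  }
  invisible(x)
}

# Internal: per-lg lengths as a named vector
lg_lengths <- function(layout) setNames(layout$length_bp, layout$lg)
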