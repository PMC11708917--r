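#' Haldane's mapping function
#'
#' Converts between recombination probability and additive map distance under
#' the assumption of no crossover interference: `d = -50 * log(1 - 2p)` cM,
#' with inverse `p = (1 - exp(-d/50)) / 2`.
#'
#' @param p Recombination probability, `0 <= p < 0.5`.
#' @param d Map distance in cM, `d >= 0`.
#' @return `haldane_cm()`: map distance in cM; `haldane_p()`: recombination
#'   probability. Both are vectorised and mutual inverses.
#' @examples
#' haldane_cm(0.25) # -50 * log(0.5)
#' haldane_p(50)    # (1 - exp(-1)) / 2
#' @export
haldane_cm <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 0.5)) {
    abort("recombination probability must lie in [0, 0.5)")
  }
  -50 * log1p(-2 * p)
}

#' @rdname haldane_cm
#' @export
haldane_p <- function(d) {
  if (any(!is.finite(d)) || any(d < 0)) abort("map distance must be >= 0")
  (1 - exp(-d / 50)) / 2
}

#' Build sex-specific genetic maps from crossover events
#'
#' Estimates a genetic map from a table of crossover (CO) breakpoints observed
#' in transmitted gametes, the raw material of pedigree linkage mapping. For
#' each adjacent pair of markers, the recombination fraction `c` is the
#' proportion of meioses carrying an odd number of COs between the two
#' markers (an even number is undetectable from segregation, so double COs
#' within one interval do not inflate the map). Interval distance is `100 * c`
#' cM (`mode = "direct"`) or Haldane's `-50 * log(1 - 2c)`
#' (`mode = "haldane"`); cumulative positions start at 0 at the first marker.
#'
#' Maps are returned per sex (from meioses of that sex) and sex-averaged,
#' where the sex-averaged map is built from the pooled male + female meioses.
#'
#' @param cos Crossover table: tibble with columns `meiosis`, `sex`
#'   (`"M"`/`"F"`), `lg`, `pos` (0-based breakpoint bp).
#' @param markers Marker grid: tibble with columns `lg`, `pos` (bp, sorted
#'   and unique within lg).
#' @param n_meioses Number of meioses observed per sex: either a single
#'   number (same for both sexes) or a named vector like `c(M = 175, F =
#'   175)`. Meioses without COs never appear in `cos`, so the total cannot be
#'   inferred from the table.
#' @param mode `"direct"` (default) or `"haldane"`.
#' @return A tibble with columns `lg`, `pos` and cumulative cM columns
#'   `cm_male`, `cm_female` (for sexes present) and `cm_avg`, with the number
#'   of pooled meioses in attribute `n_meioses`.
#' @export
build_map <- function(cos, markers, n_meioses, mode = c("direct", "haldane")) {
  mode <- match.arg(mode)
  stopifnot(all(c("meiosis", "sex", "lg", "pos") %in% names(cos)),
            all(c("lg", "pos") %in% names(markers)))
  if (any(n_meioses <= 0)) abort("n_meioses must be positive")
  sexes <- sort(unique(as.character(cos$sex)))
  if (!all(sexes %in% c("M", "F"))) abort("sex must be 'M' or 'F'")
  if (is.null(names(n_meioses))) {
    n_meioses <- setNames(rep(n_meioses[1], length(sexes)), sexes)
  }
  if (!all(sexes %in% names(n_meioses))) {
    abort("n_meioses must name every sex present in `cos`")
  }

  markers <- markers %>% arrange(.data$lg, .data$pos)
  if (any(markers %>% group_by(.data$lg) %>%
            summarise(dup = anyDuplicated(.data$pos) > 0) %>% pull(dup))) {
    abort("duplicate marker positions within a linkage group")
  }

  cm_for <- function(co_sub, n) {
    purrr::map_dfr(split(markers, markers$lg), function(mk) {
      s <- mk$pos
      m <- length(s)
      out <- tibble(lg = mk$lg[1], pos = s, cm = 0)
      if (m < 2) return(out)
      co_lg <- co_sub[co_sub$lg == mk$lg[1], ]
      if (nrow(co_lg) > 0) {
        # interval i covers [s_i, s_{i+1}); COs outside the span are dropped
        itv <- findInterval(co_lg$pos, s)
        keep <- itv >= 1 & itv <= m - 1
        odd <- tibble(meiosis = co_lg$meiosis[keep], itv = itv[keep]) %>%
          dplyr::count(.data$meiosis, .data$itv) %>%
          filter(.data$n %% 2 == 1) %>%
          dplyr::count(.data$itv)
        n_odd <- numeric(m - 1)
        n_odd[odd$itv] <- odd$n
        c_hat <- n_odd / n
        d <- if (mode == "direct") 100 * c_hat else {
          if (any(c_hat >= 0.5)) {
            abort(paste0("recombination fraction >= 0.5 under haldane mode; ",
                         "use a denser marker grid"))
          }
          haldane_cm(c_hat)
        }
        out$cm <- cumsum(c(0, d))
      }
      out
    })
  }

  res <- NULL
  for (sx in sexes) {
    m <- cm_for(cos[cos$sex == sx, ], n_meioses[[sx]])
    col <- if (sx == "M") "cm_male" else "cm_female"
    names(m)[names(m) == "cm"] <- col
    res <- if (is.null(res)) m else left_join(res, m, by = c("lg", "pos"))
  }
  n_pool <- if (length(sexes)) sum(n_meioses[sexes]) else sum(n_meioses)
  pooled <- cm_for(cos, n_pool)
  names(pooled)[names(pooled) == "cm"] <- "cm_avg"
  res <- if (is.null(res)) pooled else left_join(res, pooled,
                                                 by = c("lg", "pos"))
  attr(res, "n_meioses") <- n_pool
  res
}

#' Trim unreliable map ends
#'
#' Markers erroneously placed at the extremities of a linkage group inflate
#' the map through spurious jumps in genetic position. Working inward from
#' each end, any marker within the terminal `window_markers` markers that is
#' separated from its inner neighbour by more than `max_jump` cM is removed
#' together with everything outside it; the scan repeats until no offending
#' jump remains in the terminal window. Interior jumps are untouched.
#' Cumulative positions are re-anchored so each retained map starts at 0.
#'
#' @param map Genetic map tibble from [build_map()].
#' @param max_jump Maximum tolerated neighbour separation in the terminal
#'   region, in cM (default 2).
#' @param window_markers Number of markers from each end scanned for jumps
#'   (default 100).
#' @param sex Which cM column drives the trimming: `"avg"` (default),
#'   `"male"` or `"female"`.
#' @return The trimmed map, same columns as `map`.
#' @export
trim_map_ends <- function(map, max_jump = 2, window_markers = 100,
                          sex = "avg") {
  col <- paste0("cm_", sex)
  if (!col %in% names(map)) abort(paste0("no column ", col, " in map"))
  cm_cols <- grep("^cm_", names(map), value = TRUE)
  out <- purrr::map_dfr(split(map, map$lg), function(mk) {
    mk <- arrange(mk, .data$pos)
    repeat {
      m <- nrow(mk)
      if (m < 2) break
      gaps <- diff(mk[[col]])
      w <- min(window_markers, m - 1)
      # gap i separates markers i and i+1
      left_bad <- which(gaps[seq_len(w)] > max_jump)
      right_idx <- seq(m - w, m - 1)
      right_bad <- right_idx[gaps[right_idx] > max_jump]
      if (length(left_bad) == 0 && length(right_bad) == 0) break
      keep <- rep(TRUE, m)
      if (length(left_bad)) keep[seq_len(max(left_bad))] <- FALSE
      if (length(right_bad)) keep[seq(min(right_bad) + 1, m)] <- FALSE
      if (!any(keep)) abort("map end trimming removed all markers")
      mk <- mk[keep, ]
    }
    for (cc in cm_cols) mk[[cc]] <- mk[[cc]] - mk[[cc]][1]
    mk
  })
  attr(out, "n_meioses") <- attr(map, "n_meioses")
  out
}

#' Interpolate equidistant pseudomarkers
#'
#' Real markers are irregularly spaced, which biases statistics computed over
#' marker pairs. This places pseudomarkers on a regular grid (every `spacing`
#' bp from the start of the sequence, plus the sequence end) and assigns each
#' a genetic position by linear interpolation between the two flanking true
#' markers:
#' `D_b = [(s_{a+1} - s_b) D_a + (s_b - s_a) D_{a+1}] / (s_{a+1} - s_a)`.
#' Pseudomarkers outside the marker span take the nearest terminal genetic
#' position (no genetic information exists beyond the span).
#'
#' @param map Genetic map tibble from [build_map()] (>= 2 markers per lg).
#' @param layout [genome_layout()] supplying sequence ends.
#' @param spacing Pseudomarker spacing in bp (default 10 kb).
#' @return Tibble with `lg`, `pos` and interpolated `cm_*` columns.
#' @export
interpolate_pseudomarkers <- function(map, layout, spacing = 10000) {
  cm_cols <- grep("^cm_", names(map), value = TRUE)
  ln <- lg_lengths(layout)
  purrr::map_dfr(split(map, map$lg), function(mk) {
    mk <- arrange(mk, .data$pos)
    if (nrow(mk) < 2) abort("need >= 2 markers per linkage group")
    if (anyDuplicated(mk$pos)) abort("duplicate marker positions")
    L <- ln[[mk$lg[1]]]
    grid <- unique(c(seq(0, L, by = spacing), L))
    out <- tibble(lg = mk$lg[1], pos = grid)
    for (cc in cm_cols) {
      out[[cc]] <- approx(mk$pos, mk[[cc]], xout = grid, rule = 2)$y
    }
    out
  })
}
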