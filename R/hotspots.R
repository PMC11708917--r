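#' Lorenz curves and Gini coefficients of a recombination landscape
#'
#' Quantifies how unevenly recombination is spread along each linkage group.
#' Complete windows are ordered by decreasing recombination rate and the
#' cumulative fraction of genetic length is plotted against the cumulative
#' fraction of sequence; the Gini coefficient is twice the area between this
#' Lorenz curve and the identity line (0 = perfectly even landscape, 1 = all
#' recombination in one window). Also reported is the sequence fraction that
#' contains 80% of the genetic length. A pooled genome-wide curve is
#' included under `lg = "genome"`. Incomplete (trailing) windows are
#' excluded because their unequal support would distort the sequence axis;
#' an all-zero linkage group has an undefined Gini and is flagged.
#'
#' @param windows Window tibble (typically 10 kb) from
#'   [windows_from_track()].
#' @return A list of class `recland_lorenz` with `curve` (tibble `lg`,
#'   `frac_seq`, `frac_cm`, including the (0,0) anchor) and `gini` (tibble
#'   `lg`, `gini`, `frac_seq_80`, `undefined`).
#' @export
lorenz_gini <- function(windows) {
  w <- windows[windows$complete, ]
  groups <- split(w, w$lg)
  if (any(vapply(groups, nrow, 0L) < 2)) {
    abort("need >= 2 complete windows per linkage group")
  }
  groups <- c(groups, list(genome = w %>% mutate(lg = "genome")))
  res <- purrr::map(groups, function(x) {
    v <- sort(x$cm, decreasing = TRUE)
    n <- length(v)
    tot <- sum(v)
    if (tot == 0) {
      return(list(curve = tibble(lg = x$lg[1], frac_seq = c(0, seq_len(n) / n),
                                 frac_cm = NA_real_),
                  gini = tibble(lg = x$lg[1], gini = NA_real_,
                                frac_seq_80 = NA_real_, undefined = TRUE)))
    }
    frac_seq <- c(0, seq_len(n) / n)
    frac_cm <- c(0, cumsum(v) / tot)
    # trapezoid area under the curve; curve lies above the diagonal
    area <- sum((frac_cm[-1] + frac_cm[-(n + 1)]) / 2 * diff(frac_seq))
    list(curve = tibble(lg = x$lg[1], frac_seq = frac_seq, frac_cm = frac_cm),
         gini = tibble(lg = x$lg[1], gini = 2 * (area - 0.5),
                       frac_seq_80 = frac_seq[which(frac_cm >= 0.8)[1]],
                       undefined = FALSE))
  })
  structure(list(curve = bind_rows(purrr::map(res, "curve")),
                 gini = bind_rows(purrr::map(res, "gini"))),
            class = "recland_lorenz")
}

#' @export
print.recland_lorenz <- function(x, ...) {
  g <- x$gini$gini[x$gini$lg == "genome"]
  cat(sprintf("Lorenz/Gini summary over %d linkage groups; pooled Gini %.3f\n",
              nrow(x$gini) - 1, g))
  invisible(x)
}

#' @export
tidy.recland_lorenz <- function(x, ...) x$gini

#' Genome-mean-fold hotspot and coldspot calls
#'
#' Broad-scale annotation of 10 kb windows against the genome-average
#' recombination rate: hotspots are windows with *more than* `hot_fold`
#' times the average, coldspots windows with less than `1 / cold_fold` of
#' the average, and a stricter "global hotspot" set has *at least*
#' `alt_hot_fold` times the average (the strict/inclusive boundaries follow
#' the "more than" vs "at least" definitions of the two sets).
#'
#' @param windows Window tibble with `cm_per_mb`.
#' @param mean_rate Genome-average rate in cM/Mb (see [genome_mean_rate()]);
#'   must be > 0.
#' @param hot_fold,cold_fold,alt_hot_fold Fold thresholds (defaults 5, 5,
#'   10).
#' @return Tibble of calls: `lg`, `start`, `end`, `cm_per_mb`, `fold`
#'   (rate / mean) and `kind` (`"hotspot"`, `"coldspot"`,
#'   `"global_hotspot_10x"`). A window can appear in both the fold-5 and the
#'   fold-10 definition sets.
#' @export
call_global <- function(windows, mean_rate, hot_fold = 5, cold_fold = 5,
                        alt_hot_fold = 10) {
  if (!is.finite(mean_rate) || mean_rate <= 0) {
    abort("mean_rate must be positive")
  }
  base <- windows %>%
    mutate(fold = .data$cm_per_mb / mean_rate) %>%
    select("lg", "start", "end", "cm_per_mb", "fold")
  bind_rows(
    base %>% filter(.data$fold > hot_fold) %>% mutate(kind = "hotspot"),
    base %>% filter(.data$fold < 1 / cold_fold) %>%
      mutate(kind = "coldspot"),
    base %>% filter(.data$fold >= alt_hot_fold) %>%
      mutate(kind = "global_hotspot_10x")
  ) %>% arrange(.data$kind, .data$lg, .data$start)
}

#' Relative recombination rate in 80 kb (RRR80)
#'
#' The local-hotspot statistic: each focal window's rate divided by the mean
#' rate of the flanking windows within `flank_bp` upstream and `flank_bp`
#' downstream (focal window excluded). Near linkage-group ends the statistic
#' is computed when at least half of the full flank is available, otherwise
#' it is `NA`; a zero flank mean also yields `NA`.
#'
#' @param windows Complete fixed-size window tibble (typically 1 kb) from
#'   [windows_from_track()].
#' @param flank_bp Flank span on each side in bp (default 40 kb, i.e. 80 kb
#'   around).
#' @return `windows` with an added `rrr80` column (`NA` for incomplete
#'   windows).
#' @export
rrr80 <- function(windows, flank_bp = 40000) {
  size <- max(windows$end - windows$start)
  k <- as.integer(flank_bp / size)
  out <- purrr::map_dfr(split(windows, windows$lg), function(w) {
    w <- arrange(w, .data$start)
    r <- ifelse(w$complete, w$cm_per_mb, NA_real_)
    n <- length(r)
    cs <- c(0, cumsum(ifelse(is.na(r), 0, r)))
    cn <- c(0, cumsum(!is.na(r)))
    i <- seq_len(n)
    lo <- pmax(i - k, 1)
    hi <- pmin(i + k, n)
    fsum <- cs[hi + 1] - cs[lo] - ifelse(is.na(r), 0, r)
    fcnt <- cn[hi + 1] - cn[lo] - !is.na(r)
    fmean <- ifelse(fcnt > 0, fsum / fcnt, NA_real_)
    w$rrr80 <- ifelse(!is.na(r) & fcnt >= k & !is.na(fmean) & fmean > 0,
                      r / fmean, NA_real_)
    w
  })
  arrange(out, .data$lg, .data$start)
}

#' Local (RRR80) hotspot calls
#'
#' Fine-scale hotspot annotation on 1 kb windows. Candidate windows must
#' have `rrr80 >= rrr80_min`, a recombination rate between `rate_lo` and
#' `rate_hi` cM/Mb (LD-based inference has poor power outside this range),
#' and at most `max_repeat_bp` of annotated repeats. Runs of at least
#' `min_run` consecutive candidate windows are emitted as hotspots; an
#' isolated candidate is not called.
#'
#' @param windows Window tibble carrying `rrr80` (see [rrr80()]) and
#'   `repeat_bp` (see [window_covariates()]; treated as 0 when absent).
#' @param rrr80_min Minimum relative rate (default 5).
#' @param min_run Minimum run length in windows (default 2).
#' @param rate_lo,rate_hi Allowed rate range in cM/Mb (defaults 1 and 10).
#' @param max_repeat_bp Maximum repeat overlap per window (default 500).
#' @param inclusive Use `rrr80 >= rrr80_min` (default) rather than strict
#'   `>`.
#' @return A list with `windows` (hotspot windows with `run_id`) and `runs`
#'   (merged runs: `lg`, `start`, `end`, `n_windows`).
#' @export
call_local <- function(windows, rrr80_min = 5, min_run = 2, rate_lo = 1,
                       rate_hi = 10, max_repeat_bp = 500, inclusive = TRUE) {
  if (!"rrr80" %in% names(windows)) abort("run rrr80() first")
  rep_bp <- if ("repeat_bp" %in% names(windows)) windows$repeat_bp else 0
  size <- max(windows$end - windows$start)
  ok_rrr <- if (inclusive) windows$rrr80 >= rrr80_min else
    windows$rrr80 > rrr80_min
  cand <- !is.na(windows$rrr80) & ok_rrr &
    windows$cm_per_mb >= rate_lo & windows$cm_per_mb <= rate_hi &
    rep_bp <= max_repeat_bp
  w <- windows %>% mutate(.cand = cand) %>% arrange(.data$lg, .data$start)
  # consecutive = same lg, abutting windows, both candidates
  brk <- c(TRUE, w$lg[-1] != w$lg[-nrow(w)] |
             w$start[-1] != w$end[-nrow(w)] | !w$.cand[-1] | !w$.cand[-nrow(w)])
  run <- cumsum(brk)
  w$run_id <- ifelse(w$.cand, run, NA_integer_)
  if (!any(w$.cand)) {
    empty <- w[0, ] %>% select(-".cand")
    return(list(windows = empty,
                runs = tibble(lg = character(), start = numeric(),
                              end = numeric(), n_windows = integer())))
  }
  runs <- w %>% filter(.data$.cand) %>%
    group_by(.data$run_id) %>%
    summarise(lg = .data$lg[1], start = min(.data$start),
              end = max(.data$end), n_windows = dplyr::n(),
              .groups = "drop") %>%
    filter(.data$n_windows >= min_run)
  hot <- w %>% filter(.data$run_id %in% runs$run_id) %>% select(-".cand")
  list(windows = hot, runs = runs %>% select("lg", "start", "end",
                                             "n_windows"))
}

#' Recombination profile around genomic elements
#'
#' Mean relative recombination rate as a function of distance from a set of
#' elements (TSS-containing windows or windows fully spanned by a CpG
#' island). For each element the rates of the windows at offsets
#' `-span .. +span` are divided by the element's 80 kb flank mean (its RRR80
#' denominator) and the curves are averaged over elements. A peak at offset
#' 0 indicates recombination concentrated on the elements.
#'
#' @param windows Complete fixed-size window tibble (typically 1 kb).
#' @param elements Element positions: tibble with `lg` and `pos` (bp; the
#'   window containing `pos` is the focal window).
#' @param span Maximum offset in bp (default 40 kb).
#' @param flank_bp Flank used for the normalising mean (default 40 kb each
#'   side, focal excluded).
#' @return Tibble with `offset_bp`, `mean_rel` and `n` (elements
#'   contributing at that offset).
#' @export
element_profile <- function(windows, elements, span = 40000,
                            flank_bp = 40000) {
  if (nrow(elements) == 0) abort("no elements supplied")
  size <- max(windows$end - windows$start)
  k_span <- as.integer(span / size)
  wf <- rrr80(windows, flank_bp)
  acc <- purrr::map_dfr(split(wf, wf$lg), function(w) {
    w <- arrange(w, .data$start)
    el <- elements[elements$lg == w$lg[1], ]
    if (nrow(el) == 0) return(NULL)
    idx <- match((el$pos %/% size) * size, w$start)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0) return(NULL)
    r <- ifelse(w$complete, w$cm_per_mb, NA_real_)
    fmean <- ifelse(is.na(w$rrr80), NA_real_, r / w$rrr80)
    purrr::map_dfr(seq(-k_span, k_span), function(o) {
      j <- idx + o
      valid <- j >= 1 & j <= nrow(w) & !is.na(fmean[idx])
      rel <- r[j[valid]] / fmean[idx[valid]]
      tibble(offset_bp = o * size, sum_rel = sum(rel, na.rm = TRUE),
             n = sum(!is.na(rel)))
    })
  })
  acc %>% group_by(.data$offset_bp) %>%
    summarise(mean_rel = sum(.data$sum_rel) / sum(.data$n),
              n = sum(.data$n), .groups = "drop")
}
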