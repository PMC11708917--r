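#' Aggregate a rate track into fixed-size windows
#'
#' Converts a per-bp recombination probability track into a windowed genetic
#' map. Each track interval of length `len` and rate `r` carries a
#' recombination probability `p = r * len`, translated to map distance with
#' Haldane's function `d = -50 log(1 - 2p)`; the interval's centimorgans are
#' then distributed over the windows it overlaps pro rata by bp. Because
#' Haldane's function is applied once per track interval (the unit the rate
#' was estimated on) and its centimorgans split linearly, window maps are
#' exactly additive across scales: summing 1 kb windows reproduces the 1 Mb
#' windows and the genome total is invariant under window size.
#'
#' Windows tile each linkage group from position 0; a trailing window
#' shorter than `size` is kept, its `cm_per_mb` normalised by its true
#' length, and flagged `complete = FALSE`.
#'
#' @param track Rate-track tibble (`lg`, `start`, `end`, `rate`).
#' @param layout [genome_layout()].
#' @param size Window size in bp (1 kb, 10 kb, 100 kb and 1 Mb in typical
#'   use).
#' @return Window tibble: `lg`, `start`, `end`, `cm`, `cm_per_mb`,
#'   `complete`.
#' @export
windows_from_track <- function(track, layout, size) {
  validate_intervals(track, layout, value_col = "rate", require_nonneg = TRUE,
                     allow_overlap = FALSE, what = "rate track")
  ln <- lg_lengths(layout)
  tiles <- purrr::map_dfr(seq_len(nrow(layout)), function(i) {
    starts <- seq(0, layout$length_bp[i] - 1, by = size)
    tibble(lg = layout$lg[i], start = starts,
           end = pmin(starts + size, layout$length_bp[i]))
  })
  if (nrow(track) > 0) {
    len <- track$end - track$start
    p <- track$rate * len
    if (any(p >= 0.5)) {
      abort("track interval with recombination probability >= 0.5")
    }
    d <- haldane_cm(p)
    w0 <- track$start %/% size
    w1 <- (track$end - 1) %/% size
    n_w <- w1 - w0 + 1
    idx <- rep(seq_len(nrow(track)), n_w)
    wi <- w0[idx] + sequence(n_w) - 1
    ps <- pmax(track$start[idx], wi * size)
    pe <- pmin(track$end[idx], (wi + 1) * size)
    shares <- tibble(lg = track$lg[idx], start = wi * size,
                     cm = d[idx] * (pe - ps) / len[idx]) %>%
      group_by(.data$lg, .data$start) %>%
      summarise(cm = sum(.data$cm), .groups = "drop")
    tiles <- left_join(tiles, shares, by = c("lg", "start"))
    tiles$cm[is.na(tiles$cm)] <- 0
  } else {
    tiles$cm <- 0
  }
  tiles %>%
    mutate(cm_per_mb = .data$cm / ((.data$end - .data$start) / 1e6),
           complete = (.data$end - .data$start) == size) %>%
    arrange(.data$lg, .data$start)
}

#' Genome-average recombination rate
#'
#' Total autosomal genetic length divided by total autosomal assembled
#' length, in cM/Mb; the reference for fold-based hotspot and coldspot
#' thresholds.
#'
#' @param windows Window tibble from [windows_from_track()].
#' @param layout [genome_layout()].
#' @return A single number (cM/Mb).
#' @export
genome_mean_rate <- function(windows, layout) {
  auto <- layout$lg[layout$is_autosome]
  w <- windows[windows$lg %in% auto, ]
  if (nrow(w) == 0) abort("no autosomal windows")
  sum(w$cm) / (sum(layout$length_bp[layout$lg %in% unique(w$lg)]) / 1e6)
}

#' Scale an LD-based landscape to the linkage map
#'
#' LD-based inference estimates the population rate rho = 4 Ne r, so its
#' genetic lengths are confounded by effective population size. Scaling
#' forces, for each linkage group separately, the LD-derived total genetic
#' length to equal the pedigree linkage-map length: every window's (or
#' interval's) centimorgans are multiplied by
#' `f_k = linkage cM of lg k / LD cM of lg k`.
#'
#' @param x A window tibble (with `cm`) or a rate track (with `rate`).
#' @param map Genetic map from [build_map()] covering the same linkage
#'   groups.
#' @param sex Which map column supplies the target lengths (default
#'   `"avg"`).
#' @return `x` with centimorgans (and rates, for a track) rescaled; the
#'   per-lg factors are attached as attribute `"scale_factors"` (tibble
#'   `lg`, `f`).
#' @export
scale_to_linkage <- function(x, map, sex = "avg") {
  col <- paste0("cm_", sex)
  if (!col %in% names(map)) abort(paste0("no column ", col, " in map"))
  link <- map %>% group_by(.data$lg) %>%
    summarise(link_cm = max(.data[[col]]) - min(.data[[col]]),
              .groups = "drop")
  if ("rate" %in% names(x)) {
    len <- x$end - x$start
    d <- haldane_cm(x$rate * len)
    ld <- tibble(lg = x$lg, d = d) %>% group_by(.data$lg) %>%
      summarise(ld_cm = sum(.data$d), .groups = "drop")
    fs <- scale_factors(link, ld)
    f <- unname(setNames(fs$f, fs$lg)[x$lg])
    x$rate <- haldane_p(f * d) / len
  } else if ("cm" %in% names(x)) {
    ld <- x %>% group_by(.data$lg) %>%
      summarise(ld_cm = sum(.data$cm), .groups = "drop")
    fs <- scale_factors(link, ld)
    f <- unname(setNames(fs$f, fs$lg)[x$lg])
    x$cm <- x$cm * f
    if ("cm_per_mb" %in% names(x)) x$cm_per_mb <- x$cm_per_mb * f
  } else {
    abort("`x` must be a rate track or a window table")
  }
  attr(x, "scale_factors") <- fs
  x
}

# Internal: per-lg scale factors with validation
scale_factors <- function(link, ld) {
  fs <- left_join(ld, link, by = "lg")
  if (any(is.na(fs$link_cm))) {
    abort("linkage map does not cover every linkage group in the track")
  }
  if (any(fs$ld_cm == 0 & fs$link_cm > 0)) {
    abort("LD-derived length is 0 on a linkage group with positive linkage length")
  }
  fs$f <- ifelse(fs$ld_cm == 0, 1, fs$link_cm / fs$ld_cm)
  fs[, c("lg", "f")]
}

#' Annotate windows with genomic covariates
#'
#' Adds to a window table the covariates used to characterise hotspots and
#' coldspots: GC fraction over unmasked bases, nucleotide diversity
#' (mask-corrected), gene count, TSS and CpG-island flags, and repeat and
#' mask overlap.
#'
#' Nucleotide diversity per window is
#' `pi = sum(2 p (1 - p)) * 2n/(2n - 1) / unmasked bp` over the polymorphic
#' sites in the window (`p` the alternate allele frequency, `n` the number
#' of diploid individuals; the `2n/(2n-1)` factor is the small-sample
#' correction of heterozygosity). A fully masked window gets `pi = NA`
#' rather than 0.
#'
#' @param windows Window tibble from [windows_from_track()].
#' @param fasta Optional FASTA path or named character vector for GC
#'   content.
#' @param genes,cgi,repeats,mask Optional interval tibbles
#'   (`lg`, `start`, `end`).
#' @param tss Optional TSS point tibble (`lg`, `pos`).
#' @param sites Optional polymorphic-site tibble (`lg`, `pos`, `p`).
#' @param n_diploids Number of diploid individuals behind `sites`.
#' @return `windows` with added columns among `gc_fraction`, `pi`,
#'   `n_genes`, `has_tss`, `full_cgi`, `repeat_bp`, `masked_bp`.
#' @export
window_covariates <- function(windows, fasta = NULL, genes = NULL,
                              tss = NULL, cgi = NULL, repeats = NULL,
                              mask = NULL, sites = NULL, n_diploids = NULL) {
  size <- max(windows$end - windows$start)
  key <- function(lg, start) paste(lg, start)
  wkey <- key(windows$lg, windows$start)
  wlen <- windows$end - windows$start

  overlap_bp <- function(feat) {
    if (is.null(feat) || nrow(feat) == 0) return(numeric(length(wkey)))
    sh <- expand_to_windows(feat, size)
    v <- sh %>% group_by(.data$lg, .data$start) %>%
      summarise(bp = sum(.data$bp), .groups = "drop")
    out <- numeric(length(wkey))
    m <- match(key(v$lg, v$start), wkey)
    out[m[!is.na(m)]] <- v$bp[!is.na(m)]
    out
  }

  windows$masked_bp <- overlap_bp(mask)
  windows$masked_bp <- pmin(windows$masked_bp, wlen)
  if (!is.null(repeats)) windows$repeat_bp <- overlap_bp(repeats)

  if (!is.null(genes)) {
    sh <- expand_to_windows(genes, size)
    v <- sh %>% dplyr::count(.data$lg, .data$start)
    windows$n_genes <- 0L
    m <- match(key(v$lg, v$start), wkey)
    windows$n_genes[m[!is.na(m)]] <- v$n[!is.na(m)]
  }
  if (!is.null(tss)) {
    tkey <- key(tss$lg, (tss$pos %/% size) * size)
    windows$has_tss <- wkey %in% tkey
  }
  if (!is.null(cgi) && nrow(cgi) > 0) {
    # windows fully contained in a CpG island
    full <- purrr::map_dfr(seq_len(nrow(cgi)), function(i) {
      w_first <- ceiling(cgi$start[i] / size)
      w_last <- floor(cgi$end[i] / size) - 1
      if (w_last < w_first) return(NULL)
      tibble(lg = cgi$lg[i], start = seq(w_first, w_last) * size)
    })
    windows$full_cgi <- wkey %in% key(full$lg, full$start) &
      wlen == size
  } else if (!is.null(cgi)) {
    windows$full_cgi <- FALSE
  }

  if (!is.null(fasta)) {
    seqs <- load_sequences(fasta)
    if (!is.null(mask) && nrow(mask) > 0) {
      for (i in seq_len(nrow(mask))) {
        s <- seqs[[mask$lg[i]]]
        substr(s, mask$start[i] + 1, mask$end[i]) <-
          strrep("N", mask$end[i] - mask$start[i])
        seqs[[mask$lg[i]]] <- s
      }
    }
    windows$gc_fraction <- NA_real_
    for (id in unique(windows$lg)) {
      if (!id %in% names(seqs)) next
      sel <- windows$lg == id
      v <- Biostrings::Views(Biostrings::DNAString(seqs[[id]]),
                             start = windows$start[sel] + 1,
                             end = windows$end[sel])
      af <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
      tot <- rowSums(af)
      windows$gc_fraction[sel] <-
        ifelse(tot == 0, NA_real_, (af[, "C"] + af[, "G"]) / tot)
    }
  }

  if (!is.null(sites)) {
    if (is.null(n_diploids)) abort("`n_diploids` is required with `sites`")
    corr <- 2 * n_diploids / (2 * n_diploids - 1)
    h <- 2 * sites$p * (1 - sites$p) * corr
    v <- tibble(lg = sites$lg, start = (sites$pos %/% size) * size, h = h) %>%
      group_by(.data$lg, .data$start) %>%
      summarise(h = sum(.data$h), .groups = "drop")
    hsum <- numeric(length(wkey))
    m <- match(key(v$lg, v$start), wkey)
    hsum[m[!is.na(m)]] <- v$h[!is.na(m)]
    unmasked <- wlen - windows$masked_bp
    windows$pi <- ifelse(unmasked > 0, hsum / unmasked, NA_real_)
  }
  windows
}

# Internal: split features at window boundaries; returns (lg, start of
# window, bp of overlap) one row per feature x window
expand_to_windows <- function(feat, size) {
  w0 <- feat$start %/% size
  w1 <- (feat$end - 1) %/% size
  n_w <- w1 - w0 + 1
  idx <- rep(seq_len(nrow(feat)), n_w)
  wi <- w0[idx] + sequence(n_w) - 1
  ps <- pmax(feat$start[idx], wi * size)
  pe <- pmin(feat$end[idx], (wi + 1) * size)
  tibble(lg = feat$lg[idx], start = wi * size, bp = pe - ps)
}

#' Regression of genetic on physical length
#'
#' Under one obligate crossover per chromosome, every linkage group is
#' expected to be at least 50 cM long regardless of physical size, with
#' additional crossovers accruing with length: an ordinary least-squares fit
#' of genetic length (cM) on physical length (Mb) therefore has an
#' interpretable intercept (the obligate-crossover floor, ~50 cM) and slope
#' (extra cM per Mb).
#'
#' @param map Genetic map from [build_map()].
#' @param layout [genome_layout()]; needs >= 3 linkage groups in the map.
#' @param sex Map column to use (default `"avg"`).
#' @return An object of class `recland_lenreg`; see [tidy.recland_lenreg()]
#'   and [glance.recland_lenreg()].
#' @export
length_regression <- function(map, layout, sex = "avg") {
  col <- paste0("cm_", sex)
  if (!col %in% names(map)) abort(paste0("no column ", col, " in map"))
  dat <- map %>% group_by(.data$lg) %>%
    summarise(cm = max(.data[[col]]) - min(.data[[col]]),
              .groups = "drop") %>%
    left_join(layout, by = "lg") %>%
    mutate(mb = .data$length_bp / 1e6)
  if (nrow(dat) < 3) abort("need >= 3 linkage groups for the regression")
  fit <- lm(cm ~ mb, data = dat)
  structure(list(fit = fit, data = dat), class = "recland_lenreg")
}

#' @export
print.recland_lenreg <- function(x, ...) {
  cf <- stats::coef(x$fit)
  cat(sprintf(
    "Genetic ~ physical length OLS on %d LGs: intercept %.3g cM, slope %.3g cM/Mb\n",
    nrow(x$data), cf[1], cf[2]))
  invisible(x)
}

#' Tidy and summarise a length regression
#'
#' Broom-style accessors: `tidy()` returns one row per coefficient with 95%
#' t-based confidence intervals, `glance()` a one-row model summary.
#'
#' @param x A `recland_lenreg` object from [length_regression()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.recland_lenreg <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  ci <- stats::confint(x$fit, level = 0.95)
  tibble(term = c("intercept", "slope"),
         estimate = unname(sm[, 1]), std.error = unname(sm[, 2]),
         statistic = unname(sm[, 3]), p.value = unname(sm[, 4]),
         conf.low = unname(ci[, 1]), conf.high = unname(ci[, 2]))
}

#' @rdname tidy.recland_lenreg
#' @export
glance.recland_lenreg <- function(x, ...) {
  sm <- summary(x$fit)
  tibble(r.squared = sm$r.squared, sigma = sm$sigma,
         statistic = unname(sm$fstatistic[1]),
         p.value = unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                                    sm$fstatistic[3], lower.tail = FALSE)),
         nobs = nrow(x$data))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
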