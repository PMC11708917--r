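#' Parameters for the synthetic recombination landscape
#'
#' Bundles every knob of the generator with defaults that emulate an
#' avian-like genome: tens of linkage groups spanning a few to ~90 Mb, a
#' log-normal background recombination rate averaging roughly 2 cM/Mb,
#' kb-scale hotspots preferentially sitting on TSSs/CpG islands, 1-2
#' crossovers per chromosome per meiosis with sex-specific telomere-biased
#' placement, diversity coupled to recombination, and multiplicative noise
#' for population replicates.
#'
#' @param seed Integer seed; identical parameters + seed give identical
#'   output.
#' @param layout [genome_layout()]; default 8 LGs of 5-90 Mb.
#' @param n_meioses_per_sex Meioses simulated per sex (default 100).
#' @param obligate One guaranteed crossover per LG per meiosis (default
#'   `TRUE`).
#' @param extra_co_rate Expected additional crossovers per Morgan of
#'   (gamete-level) map length beyond the obligate one (default 0.5).
#' @param placement_telo_weight Named per-sex mixture weight (`M`, `F`) of
#'   the telomere-biased U-shaped placement density (a symmetric
#'   Beta(0.5, 0.5) on relative position) versus uniform.
#' @param background_meanlog,background_sdlog Log-normal parameters of the
#'   per-bp background rate, drawn per 100 kb segment.
#' @param segment_bp Background segment size in bp (default 100 kb).
#' @param hotspot_density Hotspots per Mb (default 0.5).
#' @param hotspot_width Hotspot width in bp (default 2 kb, aligned to 1 kb
#'   boundaries).
#' @param hotspot_intensity Length-2 range of fold-increase over the local
#'   background (default 10-50).
#' @param frac_at_tss_cgi Fraction of hotspots centred on a TSS or CpG
#'   island (default 0.8).
#' @param genes_per_mb,cgi_per_mb Annotation densities (defaults 10 and
#'   10).
#' @param repeat_fraction Fraction of sequence annotated as repeats
#'   (default 0.1).
#' @param div_intercept,div_slope,div_noise_sd Diversity model: windowed
#'   `log(pi) = div_intercept + div_slope * log(rate) + N(0, div_noise_sd)`;
#'   defaults give pi ~ 0.004 at the average rate with a positive coupling.
#' @param n_diploids Diploid sample size behind the allele-frequency table
#'   (default 10).
#' @param replicate_noise_sd Log-scale sd of the multiplicative noise used
#'   for population replicates (default 0.3).
#' @return A list of class `recland_sim_params`.
#' @export
sim_params <- function(seed = 1,
                       layout = genome_layout(
                         paste0("lg", 1:8),
                         c(90, 60, 40, 25, 15, 10, 7, 5) * 1e6),
                       n_meioses_per_sex = 100,
                       obligate = TRUE,
                       extra_co_rate = 0.5,
                       placement_telo_weight = c(M = 0.6, F = 0.3),
                       background_meanlog = log(1.6e-8),
                       background_sdlog = 0.6,
                       segment_bp = 100000,
                       hotspot_density = 0.5,
                       hotspot_width = 2000,
                       hotspot_intensity = c(10, 50),
                       frac_at_tss_cgi = 0.8,
                       genes_per_mb = 10,
                       cgi_per_mb = 10,
                       repeat_fraction = 0.1,
                       div_intercept = -0.25,
                       div_slope = 0.3,
                       div_noise_sd = 0.3,
                       n_diploids = 10,
                       replicate_noise_sd = 0.3) {
  p <- as.list(environment())
  if (any(p$placement_telo_weight < 0) || any(p$placement_telo_weight > 1)) {
    abort("placement mixture weights must lie in [0, 1]")
  }
  if (length(p$hotspot_intensity) == 1) {
    p$hotspot_intensity <- rep(p$hotspot_intensity, 2)
  }
  if (any(p$hotspot_intensity < 1)) {
    abort("hotspot intensity is a fold over background, must be >= 1")
  }
  structure(p, class = "recland_sim_params")
}

#' Simulate a true recombination landscape with annotations
#'
#' Generates the ground truth every downstream stage is tested against: a
#' piecewise-constant per-bp rate track (log-normal background per segment,
#' with planted kb-scale hotspots multiplying the local background by a
#' drawn intensity), plus consistent annotations (genes with TSSs, CpG
#' islands, repeats). A stated fraction of hotspots is centred on a TSS or
#' CpG island, emulating the concentration of crossovers at accessible
#' chromatin in species lacking PRDM9. The planted hotspot list is
#' recorded so recovery can be scored.
#'
#' @param params [sim_params()].
#' @return A list of class `recland_truth` with elements `track`,
#'   `hotspots` (`lg`, `start`, `end`, `intensity`, `on_element`), `genes`,
#'   `tss`, `cgi`, `repeats` and `params`.
#' @export
simulate_landscape <- function(params) {
  stopifnot(inherits(params, "recland_sim_params"))
  set.seed(params$seed)
  layout <- params$layout
  align <- 1000

  res <- purrr::map(seq_len(nrow(layout)), function(i) {
    id <- layout$lg[i]
    L <- layout$length_bp[i]

    # background segments
    starts <- seq(0, L - 1, by = params$segment_bp)
    bg <- tibble(lg = id, start = starts, end = pmin(starts +
                   params$segment_bp, L),
                 rate = rlnorm(length(starts), params$background_meanlog,
                               params$background_sdlog))

    # annotations
    n_genes <- rpois(1, params$genes_per_mb * L / 1e6)
    gene_start <- sort(sample.int(max(L - 60000, 1), n_genes))
    gene_len <- round(runif(n_genes, 5000, 50000))
    genes <- tibble(lg = id, start = gene_start,
                    end = pmin(gene_start + gene_len, L),
                    name = paste0(id, "_g", seq_len(n_genes)))
    tss <- tibble(lg = id, pos = genes$start)
    n_cgi <- rpois(1, params$cgi_per_mb * L / 1e6)
    cgi_start <- (sample.int(max(L %/% align - 3, 1), n_cgi)) * align
    cgi <- tibble(lg = id, start = cgi_start,
                  end = pmin(cgi_start + round(runif(n_cgi, 1500, 3000)), L))
    n_rep <- round(params$repeat_fraction * L / 1000)
    rep_start <- sample.int(max(L - 1000, 1), n_rep)
    repeats <- merge_adjacent(
      tibble(lg = id, start = rep_start, end = pmin(rep_start + 1000, L)) %>%
        arrange(.data$start))

    # hotspots: centred on elements with probability frac_at_tss_cgi,
    # aligned to 1 kb boundaries, non-overlapping
    n_hot <- rpois(1, params$hotspot_density * L / 1e6)
    if (n_hot * params$hotspot_width > L / 2) {
      abort("hotspot density too high for linkage-group length")
    }
    hw <- params$hotspot_width
    elements <- c(tss$pos, floor((cgi$start + cgi$end) / 2))
    on_el <- runif(n_hot) < params$frac_at_tss_cgi & length(elements) > 0
    centre <- numeric(n_hot)
    if (any(on_el)) {
      centre[on_el] <- sample(elements, sum(on_el), replace = TRUE)
    }
    centre[!on_el] <- runif(sum(!on_el), hw, L - hw)
    hstart <- pmax(0, pmin(round(centre / align) * align - hw / 2, L - hw))
    hot <- tibble(lg = id, start = hstart, end = hstart + hw,
                  intensity = runif(n_hot, params$hotspot_intensity[1],
                                    params$hotspot_intensity[2]),
                  on_element = on_el) %>%
      arrange(.data$start) %>%
      filter(c(TRUE, .data$start[-1] >= .data$end[-dplyr::n()]))

    list(track = overlay_hotspots(bg, hot), hotspots = hot, genes = genes,
         tss = tss, cgi = cgi, repeats = repeats)
  })

  structure(list(
    track = bind_rows(purrr::map(res, "track")),
    hotspots = bind_rows(purrr::map(res, "hotspots")),
    genes = bind_rows(purrr::map(res, "genes")),
    tss = bind_rows(purrr::map(res, "tss")),
    cgi = bind_rows(purrr::map(res, "cgi")),
    repeats = bind_rows(purrr::map(res, "repeats")),
    params = params
  ), class = "recland_truth")
}

# Internal: multiply background rate by hotspot intensity inside hotspot
# intervals, splitting intervals at hotspot boundaries (single lg).
overlay_hotspots <- function(bg, hot) {
  if (nrow(hot) == 0) return(bg)
  cuts <- sort(unique(c(bg$start, bg$end, hot$start, hot$end)))
  s <- cuts[-length(cuts)]
  e <- cuts[-1]
  seg_rate <- bg$rate[findInterval(s, bg$start)]
  hidx <- findInterval(s, hot$start)
  in_hot <- hidx >= 1 & s < hot$end[pmax(hidx, 1)]
  mult <- ifelse(in_hot, hot$intensity[pmax(hidx, 1)], 1)
  tibble(lg = bg$lg[1], start = s, end = e, rate = seg_rate * mult)
}

#' @export
print.recland_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic landscape: %d LGs, %.1f Mb, %d planted hotspots (seed %d)\n",
    nrow(x$params$layout), sum(x$params$layout$length_bp) / 1e6,
    nrow(x$hotspots), x$params$seed))
  invisible(x)
}

#' Simulate crossover tables from a true landscape
#'
#' Draws, for each meiosis, sex and linkage group, the crossovers of the
#' bivalent: one obligate crossover (when `obligate`) plus a
#' Poisson(`extra_co_rate` x map length in Morgans) number of additional,
#' independent crossovers (no interference). Positions are sampled from the
#' per-sex placement density -- a mixture of a symmetric U-shaped
#' Beta(0.5, 0.5) telomere-biased density and a uniform density on relative
#' position -- multiplied by the true rate track and renormalised, so the
#' pedigree crossovers and the LD landscape are mutually consistent.
#'
#' With `transmit = TRUE` (default) each bivalent crossover is recorded in
#' the transmitted gamete independently with probability 1/2 (two of four
#' chromatids are recombinant), which is what segregation data observe and
#' what makes an obligate crossover correspond to a 50 cM map. Set
#' `transmit = FALSE` to record every bivalent crossover.
#'
#' @param truth `recland_truth` from [simulate_landscape()], or a rate
#'   track.
#' @param params [sim_params()].
#' @param transmit Apply the 1/2 chromatid transmission thinning (default
#'   `TRUE`).
#' @return Crossover tibble (`meiosis`, `sex`, `lg`, `pos`) ready for
#'   [build_map()]. Meiosis ids are unique within sex.
#' @export
simulate_meioses <- function(truth, params, transmit = TRUE) {
  track <- if (inherits(truth, "recland_truth")) truth$track else truth
  set.seed(params$seed + 1L)
  layout <- params$layout
  n <- params$n_meioses_per_sex

  purrr::map_dfr(c("M", "F"), function(sx) {
    w_telo <- params$placement_telo_weight[[sx]]
    purrr::map_dfr(seq_len(nrow(layout)), function(i) {
      id <- layout$lg[i]
      L <- layout$length_bp[i]
      tr <- track[track$lg == id, ]
      if (nrow(tr) == 0) abort("truth track does not cover the layout")
      # discretise to <= 10 kb pieces for the placement weighting
      pieces <- split_at_grid(tr, 10000)
      mid <- (pieces$start + pieces$end) / 2 / L
      dens <- w_telo * dbeta(mid, 0.5, 0.5) + (1 - w_telo)
      wgt <- pieces$rate * (pieces$end - pieces$start) * dens
      if (sum(wgt) <= 0) wgt <- pieces$end - pieces$start
      morgans <- sum(tr$rate * (tr$end - tr$start))
      n_extra <- rpois(n, params$extra_co_rate * morgans)
      n_co <- (if (params$obligate) 1L else 0L) + n_extra
      tot <- sum(n_co)
      if (tot == 0) return(NULL)
      piece <- sample.int(length(wgt), tot, replace = TRUE, prob = wgt)
      pos <- pieces$start[piece] +
        runif(tot) * (pieces$end[piece] - pieces$start[piece])
      keep <- if (transmit) runif(tot) < 0.5 else rep(TRUE, tot)
      tibble(meiosis = paste0(sx, rep(seq_len(n), n_co)),
             sex = sx, lg = id, pos = floor(pos))[keep, ]
    })
  })
}

# Internal: split track intervals at multiples of `grid` bp (single lg)
split_at_grid <- function(tr, grid) {
  w0 <- tr$start %/% grid
  w1 <- (tr$end - 1) %/% grid
  n_w <- w1 - w0 + 1
  idx <- rep(seq_len(nrow(tr)), n_w)
  wi <- w0[idx] + sequence(n_w) - 1
  tibble(lg = tr$lg[idx],
         start = pmax(tr$start[idx], wi * grid),
         end = pmin(tr$end[idx], (wi + 1) * grid),
         rate = tr$rate[idx])
}

#' Simulate diversity coupled to recombination
#'
#' Produces a per-site allele-frequency table whose windowed nucleotide
#' diversity follows `log(pi) = a + b * log(rate) + N(0, sd)` on 10 kb
#' windows: regions of high recombination carry more segregating sites, the
#' pattern created by linked selection and GC-biased gene conversion. The
#' model value of pi per window (`pi_model`) is returned alongside the
#' sites so the monotone rate-diversity relationship can be checked without
#' site-sampling noise.
#'
#' @param truth `recland_truth` or rate track.
#' @param params [sim_params()].
#' @param window_bp Window size of the diversity model (default 10 kb).
#' @return List with `sites` (tibble `lg`, `pos`, `p`) and `windows`
#'   (tibble `lg`, `start`, `end`, `rate`, `pi_model`).
#' @export
simulate_diversity <- function(truth, params, window_bp = 10000) {
  track <- if (inherits(truth, "recland_truth")) truth$track else truth
  set.seed(params$seed + 2L)
  layout <- params$layout
  w <- windows_from_track(track, layout, window_bp) %>%
    filter(.data$complete) %>%
    mutate(rate = .data$cm_per_mb * 1e-8) # back to per-bp probability
  eps <- rnorm(nrow(w), 0, params$div_noise_sd)
  pi_model <- exp(params$div_intercept +
                    params$div_slope * log(pmax(w$rate, 1e-12)) + eps)
  # expected per-site heterozygosity for p ~ U(0.05, 0.95), with the
  # 2n/(2n-1) small-sample correction applied downstream
  mean_h <- 0.365 * 2 * params$n_diploids / (2 * params$n_diploids - 1)
  n_sites <- round(pi_model * window_bp / mean_h)
  sites <- purrr::map_dfr(which(n_sites > 0), function(i) {
    tibble(lg = w$lg[i],
           pos = w$start[i] + sort(sample.int(window_bp, min(n_sites[i],
                                                             window_bp))),
           p = runif(min(n_sites[i], window_bp), 0.05, 0.95))
  })
  list(sites = sites,
       windows = tibble(lg = w$lg, start = w$start, end = w$end,
                        rate = w$rate, pi_model = pi_model))
}

#' Perturb a rate track with replicate noise
#'
#' Emulates the statistical noise of LD-based inference re-run on another
#' sample of the same population: the track is segmented into `block_bp`
#' blocks (estimation error is locally correlated) and each block's rate is
#' multiplied by an independent log-normal factor `exp(N(0, noise_sd^2))`,
#' which preserves the expectation of the log rate.
#'
#' @param truth `recland_truth` or rate track.
#' @param noise_sd Log-scale standard deviation; 0 returns the track
#'   unchanged.
#' @param seed Integer seed.
#' @param block_bp Noise block size in bp (default 10 kb).
#' @return A rate track tibble.
#' @export
perturb_track <- function(truth, noise_sd, seed = 1, block_bp = 10000) {
  track <- if (inherits(truth, "recland_truth")) truth$track else truth
  if (noise_sd == 0) return(track)
  set.seed(seed)
  out <- purrr::map_dfr(split(track, track$lg), function(tr) {
    tr <- arrange(tr, .data$start)
    pieces <- split_at_grid(tr, block_bp)
    blk <- pieces$start %/% block_bp
    fac <- exp(rnorm(max(blk) + 1, 0, noise_sd))
    pieces$rate <- pieces$rate * fac[blk + 1]
    pieces
  })
  arrange(out, .data$lg, .data$start)
}
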