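#' Multi-scale correlation of recombination landscapes
#'
#' Pairwise Pearson correlations of windowed recombination rates between
#' populations, computed at several window sizes. Rates are heavy-tailed,
#' so correlations are taken on `log10(cm_per_mb + epsilon)` over pairwise
#' complete windows. Broad-scale windows average out estimation noise, so
#' correlations typically decrease as the window size shrinks.
#'
#' @param pops Named list of rate tracks (tibbles `lg`, `start`, `end`,
#'   `rate`) on a shared layout; >= 2 populations.
#' @param layout [genome_layout()].
#' @param sizes Window sizes in bp (default 1 kb and 100 kb).
#' @param epsilon Pseudocount added before the log transform (default 1e-6
#'   cM/Mb).
#' @return Tibble with `size`, `pop_a`, `pop_b`, `r` for all unordered
#'   pairs.
#' @export
multiscale_correlation <- function(pops, layout, sizes = c(1000, 100000),
                                   epsilon = 1e-6) {
  if (length(pops) < 2) abort("need >= 2 populations")
  if (is.null(names(pops)) || any(!nzchar(names(pops)))) {
    abort("populations must be named")
  }
  purrr::map_dfr(sizes, function(sz) {
    mats <- purrr::map(pops, function(tr) {
      w <- windows_from_track(tr, layout, sz)
      w <- w[w$complete, ]
      log10(w$cm_per_mb + epsilon)
    })
    nm <- names(pops)
    pairs <- utils::combn(nm, 2)
    purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      tibble(size = sz, pop_a = a, pop_b = b,
             r = cor(mats[[a]], mats[[b]], use = "pairwise.complete.obs"))
    })
  })
}

#' Pseudoreplicate populations from a true landscape
#'
#' Emulates re-estimating the landscape from independent subsamples of one
#' population: each replicate is the true track with independent
#' block-level multiplicative log-normal noise (see [perturb_track()]).
#' Replicate-to-replicate spread provides the sampling-noise envelope used
#' when judging whether another population's landscape differs.
#'
#' @param truth A rate track or a `recland_truth` object.
#' @param n_reps Number of replicates (default 5).
#' @param noise_sd Log-scale standard deviation of the noise.
#' @param seed Integer seed; replicate `i` uses `seed + i`.
#' @return Named list of rate tracks (`rep1` ... `repN`).
#' @export
make_pseudoreplicates <- function(truth, n_reps = 5, noise_sd, seed = 1) {
  reps <- purrr::map(seq_len(n_reps), function(i) {
    perturb_track(truth, noise_sd, seed = seed + i)
  })
  names(reps) <- paste0("rep", seq_len(n_reps))
  reps
}

#' Hotspot sharing across populations
#'
#' Evaluates whether hotspots called in one (focal) population are also hot
#' in others. For each population, the mean RRR80-style relative rate is
#' computed over the focal hotspot windows at offsets up to `span`: each
#' hotspot window's offset rates are divided by that population's own 80 kb
#' flank mean at the hotspot, then averaged over hotspots. A shared hotspot
#' set shows a peak at offset 0 in every population; comparing a
#' population's curve with the envelope of pseudoreplicate curves separates
#' landscape differences from sampling noise (see [sharing_envelope()]).
#'
#' @param hotspots Focal hotspot windows: tibble with `lg`, `start` (their
#'   1 kb window starts), e.g. `call_local(...)$windows`.
#' @param pops Named list of rate tracks.
#' @param layout [genome_layout()].
#' @param size Window size in bp (default 1000).
#' @param span Maximum offset in bp (default 40 kb).
#' @param flank_bp Flank for the normalising mean (default 40 kb each side).
#' @return Tibble with `pop`, `offset_bp`, `mean_rel`, `n`.
#' @export
hotspot_sharing <- function(hotspots, pops, layout, size = 1000,
                            span = 40000, flank_bp = 40000) {
  if (nrow(hotspots) == 0) abort("empty hotspot set")
  elements <- tibble(lg = hotspots$lg, pos = hotspots$start + size / 2)
  purrr::map_dfr(names(pops), function(nm) {
    w <- windows_from_track(pops[[nm]], layout, size)
    element_profile(w, elements, span = span, flank_bp = flank_bp) %>%
      mutate(pop = nm) %>%
      select("pop", "offset_bp", "mean_rel", "n")
  })
}

#' Pseudoreplicate envelope test at offset 0
#'
#' A population is "outside the envelope" when its mean relative rate at
#' the hotspot windows (offset 0) falls outside the min-max range of the
#' pseudoreplicate curves. This is a heuristic noise envelope (matching the
#' use of a handful of subsample replicates), not a formal confidence
#' interval.
#'
#' @param sharing Output of [hotspot_sharing()] containing both replicate
#'   populations (names starting with `rep_prefix`) and test populations.
#' @param rep_prefix Prefix identifying replicate curves (default `"rep"`).
#' @return Tibble with `pop`, `value` (offset-0 mean relative rate),
#'   `env_lo`, `env_hi`, `outside`.
#' @export
sharing_envelope <- function(sharing, rep_prefix = "rep") {
  at0 <- sharing %>% filter(.data$offset_bp == 0)
  is_rep <- startsWith(at0$pop, rep_prefix)
  if (!any(is_rep)) abort("no replicate curves found")
  lo <- min(at0$mean_rel[is_rep])
  hi <- max(at0$mean_rel[is_rep])
  at0 %>% filter(!is_rep) %>%
    mutate(value = .data$mean_rel, env_lo = lo, env_hi = hi,
           outside = .data$value < lo | .data$value > hi) %>%
    select("pop", "value", "env_lo", "env_hi", "outside")
}
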