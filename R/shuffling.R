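#' Crossover placement density along chromosomes
#'
#' Summarises where crossovers fall relative to chromosome ends, the signal
#' behind sex differences in crossover placement (heterochiasmy in placement
#' rather than in map length). Each crossover at position `x` on a linkage
#' group of length `L` is mapped to its relative distance from the nearest
#' end, `min(x, L - x) / L * 100` (% of LG length, in `[0, 50]`), and a
#' per-sex histogram normalised to total mass 1 is returned.
#'
#' @param cos Crossover table (`meiosis`, `sex`, `lg`, `pos`).
#' @param layout [genome_layout()].
#' @param n_bins Number of equal bins over `[0, 50]`% (default 50).
#' @return Tibble with columns `sex`, `bin_lo`, `bin_hi`, `mid`, `density`
#'   (per-sex densities sum to 1).
#' @export
placement_density <- function(cos, layout, n_bins = 50) {
  if (nrow(cos) == 0) abort("empty crossover table")
  ln <- lg_lengths(layout)
  rel <- relative_end_distance(cos$pos, ln[cos$lg])
  breaks <- seq(0, 50, length.out = n_bins + 1)
  bin <- pmin(findInterval(rel, breaks, rightmost.closed = TRUE), n_bins)
  tibble(sex = as.character(cos$sex), bin = bin) %>%
    dplyr::count(.data$sex, .data$bin) %>%
    group_by(.data$sex) %>%
    mutate(density = .data$n / sum(.data$n)) %>%
    ungroup() %>%
    tidyr::complete(sex = unique(cos$sex), bin = seq_len(n_bins),
                    fill = list(n = 0L, density = 0)) %>%
    mutate(bin_lo = breaks[.data$bin], bin_hi = breaks[.data$bin + 1],
           mid = (.data$bin_lo + .data$bin_hi) / 2) %>%
    select("sex", "bin_lo", "bin_hi", "mid", "density")
}

# Internal: relative distance from nearest lg end in % of length
relative_end_distance <- function(pos, L) pmin(pos, L - pos) / L * 100

#' Two-sample Kolmogorov-Smirnov comparison with permutation p-value
#'
#' `D = sup |ECDF_a - ECDF_b|`, with significance assessed by permuting the
#' pooled sample labels, so no asymptotic assumptions or tie corrections are
#' needed. Used to compare male and female crossover placement
#' distributions.
#'
#' @param a,b Numeric samples (non-empty).
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Optional integer seed for the permutations.
#' @return A list with `D`, `p_value` (permutation, with the +1 correction),
#'   and `n_perm`.
#' @export
ks_D <- function(a, b, n_perm = 10000, seed = NULL) {
  if (length(a) == 0 || length(b) == 0) abort("both samples must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  D <- ks_stat(a, b)
  pooled <- c(a, b)
  na <- length(a)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pooled), na)
    if (ks_stat(pooled[idx], pooled[-idx]) >= D) exceed <- exceed + 1L
  }
  list(D = D, p_value = (exceed + 1) / (n_perm + 1), n_perm = n_perm)
}

# Internal: KS D by an ECDF sweep over the pooled support
ks_stat <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(ecdf(a)(pts) - ecdf(b)(pts)))
}

#' Intrachromosomal allele shuffling
#'
#' A crossover in the middle of a chromosome shuffles more allele pairs than
#' a distal one, so two maps of equal length can differ in how effectively
#' they recombine. For each linkage group, the map is resampled at
#' equidistant pseudomarkers and the mean over all pseudomarker pairs of
#' their map separation is computed: in `"haldane_prob"` mode each pairwise
#' separation `d` (cM) is first converted to a recombination probability
#' `haldane_p(d)` (bounded by 0.5, appropriate for maps longer than 50 cM);
#' in `"morgan_linear"` mode the raw separation in Morgans (`d / 100`) is
#' averaged. The per-LG mean is weighted by the squared fraction of genome
#' length on that LG, `w_k = (L_k / sum(L))^2`, the probability that two
#' random loci both fall on LG `k`; the weighted sum over LGs is the total
#' intrachromosomal shuffling rate.
#'
#' The pairwise mean uses an O(n) prefix-sum identity on the sorted genetic
#' positions rather than enumerating all pairs.
#'
#' @param map Genetic map from [build_map()].
#' @param layout [genome_layout()] (assembled lengths supply the weights).
#' @param spacing Pseudomarker spacing in bp (default 10 kb).
#' @param mode `"haldane_prob"` (default) or `"morgan_linear"`.
#' @param sexes Which cM columns to evaluate; defaults to all present.
#' @return Tibble with one row per (lg, sex): `g_bar` (mean pairwise
#'   shuffling), `weight`, and `r_intra = g_bar * weight`. Total shuffling
#'   per sex is `sum(r_intra)` over LGs (see [shuffling_total()]).
#' @export
r_intra <- function(map, layout, spacing = 10000,
                    mode = c("haldane_prob", "morgan_linear"),
                    sexes = NULL) {
  mode <- match.arg(mode)
  cm_cols <- grep("^cm_", names(map), value = TRUE)
  if (!is.null(sexes)) {
    cm_cols <- intersect(paste0("cm_", sexes), cm_cols)
  }
  pm <- interpolate_pseudomarkers(map, layout, spacing)
  lgs <- unique(pm$lg)
  Ltot <- sum(lg_lengths(layout)[lgs])
  purrr::map_dfr(split(pm, pm$lg), function(x) {
    if (nrow(x) < 2) abort("need >= 2 pseudomarkers per linkage group")
    w <- (lg_lengths(layout)[[x$lg[1]]] / Ltot)^2
    purrr::map_dfr(cm_cols, function(cc) {
      g <- if (mode == "morgan_linear") {
        pairwise_mean_linear(x[[cc]]) / 100
      } else {
        pairwise_mean_haldane(x[[cc]])
      }
      tibble(lg = x$lg[1], sex = sub("^cm_", "", cc), g_bar = g,
             weight = w, r_intra = g * w)
    })
  })
}

#' @rdname r_intra
#' @param result Output of [r_intra()].
#' @return `shuffling_total()`: tibble with `sex` and `r_intra_total`.
#' @export
shuffling_total <- function(result) {
  result %>% group_by(.data$sex) %>%
    summarise(r_intra_total = sum(.data$r_intra), .groups = "drop")
}

# Internal: mean over unordered pairs of |x_i - x_j|, O(n log n).
# For sorted x: sum_{i<j}(x_j - x_i) = sum_i (2i - n - 1) x_(i).
pairwise_mean_linear <- function(x) {
  n <- length(x)
  if (n < 2) abort("need >= 2 values")
  x <- sort(x)
  i <- seq_len(n)
  sum((2 * i - n - 1) * x) / (n * (n - 1) / 2)
}

# Internal: mean over unordered pairs of haldane_p(|x_i - x_j|).
# haldane_p(d) = (1 - exp(-d/50))/2, and for sorted x
# sum_{i<j} exp(-(x_j - x_i)/50) accumulates via a prefix sum of exp(x_i/50).
pairwise_mean_haldane <- function(x) {
  n <- length(x)
  if (n < 2) abort("need >= 2 values")
  x <- sort(x)
  # stabilise the exponentials around the midpoint of the map
  x0 <- x - median(x)
  e_pos <- exp(x0 / 50)
  e_neg <- exp(-x0 / 50)
  pref <- cumsum(e_pos)
  s <- sum(e_neg[-1] * pref[-n])
  n_pairs <- n * (n - 1) / 2
  (1 - s / n_pairs) / 2
}

#' Male/female shuffling ratio per linkage group
#'
#' @param result Output of [r_intra()] containing both sexes.
#' @return Tibble with `lg`, `ratio` (`male r_intra / female r_intra`) and
#'   `undefined` flag where the female value is 0.
#' @export
shuffling_ratio <- function(result) {
  wide <- result %>% select("lg", "sex", "r_intra") %>%
    tidyr::pivot_wider(names_from = "sex", values_from = "r_intra")
  if (!all(c("male", "female") %in% names(wide))) {
    abort("result must contain both male and female components")
  }
  wide %>%
    mutate(undefined = .data$female == 0,
           ratio = ifelse(.data$undefined, NA_real_,
                          .data$male / .data$female)) %>%
    select("lg", "ratio", "undefined")
}
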