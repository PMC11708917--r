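# Shared fixtures and independent oracles used across the test files.

tiny_layout <- function() genome_layout(c("lg1", "lg2"), c(10e6, 5e6))

# a flat track covering a layout at a constant per-bp rate
flat_track <- function(layout, rate = 1e-8) {
  tibble::tibble(lg = layout$lg, start = 0, end = layout$length_bp,
                 rate = rate)
}

random_sequence <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# O(n^2) oracles ------------------------------------------------------------

# Gini as normalised mean absolute difference between all value pairs
gini_mad_oracle <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# brute-force mean over unordered pairs of |x_i - x_j|
pairwise_mean_oracle <- function(x, f = identity) {
  d <- abs(outer(x, x, "-"))
  mean(f(d[upper.tri(d)]))
}

# direct linear interpolation of genetic position, clamped at the ends
interp_oracle <- function(s, D, s_b) {
  vapply(s_b, function(b) {
    if (b <= s[1]) return(D[1])
    if (b >= s[length(s)]) return(D[length(D)])
    a <- max(which(s <= b))
    if (s[a] == b) return(D[a])
    (s[a + 1] - b) / (s[a + 1] - s[a]) * D[a] +
      (b - s[a]) / (s[a + 1] - s[a]) * D[a + 1]
  }, 0)
}

# crossover table with one uniformly placed CO per meiosis on one lg
uniform_cos <- function(n, L, sex = "M", lg = "lg1", seed = 1) {
  set.seed(seed)
  tibble::tibble(meiosis = paste0(sex, seq_len(n)), sex = sex, lg = lg,
                 pos = floor(runif(n, 0, L)))
}

# evenly spaced marker grid including both sequence ends
marker_grid <- function(L, n, lg = "lg1") {
  tibble::tibble(lg = lg, pos = round(seq(0, L, length.out = n)))
}
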