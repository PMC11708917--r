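test_that("windowed cM follows Haldane on the interval probability", {
  lay <- genome_layout("lg1", 10000)
  tr <- tibble::tibble(lg = "lg1", start = 0, end = 10000, rate = 1e-8)
  w <- windows_from_track(tr, lay, 10000)
  expect_equal(w$cm, -50 * log(1 - 2e-4), tolerance = 1e-12)
  expect_equal(w$cm_per_mb, w$cm / 0.01, tolerance = 1e-12)

  # zero rate -> zero map
  w0 <- windows_from_track(dplyr::mutate(tr, rate = 0), lay, 1000)
  expect_true(all(w0$cm == 0))

  # an interval straddling two windows equally splits its cM in half
  lay2 <- genome_layout("lg1", 20000)
  tr2 <- tibble::tibble(lg = "lg1", start = 5000, end = 15000, rate = 1e-8)
  w2 <- windows_from_track(tr2, lay2, 10000)
  expect_equal(w2$cm[1], w2$cm[2], tolerance = 1e-9)
  expect_equal(sum(w2$cm), -50 * log(1 - 2e-4), tolerance = 1e-12)

  # pathological probability rejected
  expect_error(
    windows_from_track(dplyr::mutate(tr, rate = 1e-4), lay, 1000),
    ">= 0.5")
})

test_that("window aggregation is exactly additive across scales", {
  lay <- tiny_layout()
  p <- sim_params(seed = 2, layout = lay, hotspot_density = 1)
  tl <- simulate_landscape(p)
  w1k <- windows_from_track(tl$track, lay, 1000)
  w1m <- windows_from_track(tl$track, lay, 1e6)
  expect_equal(sum(w1k$cm), sum(w1m$cm), tolerance = 1e-9)
  # every 1 Mb window equals the sum of its thousand 1 kb windows
  agg <- w1k %>%
    dplyr::group_by(lg, mb = start %/% 1e6) %>%
    dplyr::summarise(cm = sum(cm), .groups = "drop") %>%
    dplyr::arrange(lg, mb)
  expect_equal(agg$cm, dplyr::arrange(w1m, lg, start)$cm, tolerance = 1e-9)
})

test_that("trailing partial windows are kept and length-normalised", {
  lay <- genome_layout("lg1", 10500)
  tr <- tibble::tibble(lg = "lg1", start = 0, end = 10500, rate = 1e-8)
  w <- windows_from_track(tr, lay, 1000)
  expect_equal(nrow(w), 11)
  expect_false(w$complete[11])
  expect_equal(w$end[11] - w$start[11], 500)
  expect_equal(w$cm_per_mb[11], w$cm[11] / (500 / 1e6))
})

test_that("scaling matches LD-derived lengths to the linkage map", {
  lay <- tiny_layout()
  tr <- flat_track(lay, 2e-8)
  mk <- tibble::tibble(lg = rep(c("lg1", "lg2"), each = 2),
                       pos = c(0, 10e6, 0, 5e6),
                       cm_avg = c(0, 50, 0, 60))
  w <- windows_from_track(tr, lay, 1e6)
  sw <- scale_to_linkage(w, mk)
  per_lg <- sw %>% dplyr::group_by(lg) %>%
    dplyr::summarise(cm = sum(cm))
  expect_equal(per_lg$cm, c(50, 60), tolerance = 1e-6)

  # equal totals leave the windows untouched
  ld_tot <- w %>% dplyr::group_by(lg) %>% dplyr::summarise(cm = sum(cm))
  mk2 <- tibble::tibble(lg = rep(c("lg1", "lg2"), each = 2),
                        pos = c(0, 10e6, 0, 5e6),
                        cm_avg = c(0, ld_tot$cm[1], 0, ld_tot$cm[2]))
  sw2 <- scale_to_linkage(w, mk2)
  expect_equal(sw2$cm, w$cm, tolerance = 1e-9)

  # scaling a track rescales per-interval cM so totals match the map
  st <- scale_to_linkage(tr, mk)
  swt <- windows_from_track(st, lay, 1e6) %>%
    dplyr::group_by(lg) %>% dplyr::summarise(cm = sum(cm))
  expect_equal(swt$cm, c(50, 60), tolerance = 1e-6)

  # a zero LD landscape cannot be scaled to a positive linkage length
  expect_error(scale_to_linkage(dplyr::mutate(w, cm = 0), mk), "positive")
})

test_that("window covariates compute GC, diversity and annotations", {
  lay <- genome_layout("lg1", 2000)
  tr <- tibble::tibble(lg = "lg1", start = 0, end = 2000, rate = 1e-8)
  w <- windows_from_track(tr, lay, 1000)

  g <- c(lg1 = paste0(strrep("GC", 500), strrep("AT", 500)))
  wc <- window_covariates(w, fasta = g)
  expect_equal(wc$gc_fraction, c(1, 0))

  # one SNP at p = 0.5, 10 diploids, 1 kb unmasked
  sites <- tibble::tibble(lg = "lg1", pos = 100, p = 0.5)
  wc2 <- window_covariates(w, sites = sites, n_diploids = 10)
  expect_equal(wc2$pi[1], 0.5 * (20 / 19) / 1000, tolerance = 1e-12)

  # masking half the window doubles the estimate
  mask <- tibble::tibble(lg = "lg1", start = 500, end = 1000)
  wc3 <- window_covariates(w, sites = sites, n_diploids = 10, mask = mask)
  expect_equal(wc3$pi[1], 2 * wc2$pi[1], tolerance = 1e-12)
  expect_equal(wc3$masked_bp, c(500, 0))

  # a fully masked window has undefined diversity, not zero
  mask_all <- tibble::tibble(lg = "lg1", start = 0, end = 1000)
  wc4 <- window_covariates(w, sites = sites, n_diploids = 10,
                           mask = mask_all)
  expect_true(is.na(wc4$pi[1]))

  # annotation flags
  genes <- tibble::tibble(lg = "lg1", start = 500, end = 1500)
  tss <- tibble::tibble(lg = "lg1", pos = 500)
  cgi <- tibble::tibble(lg = "lg1", start = 900, end = 2000)
  repeats <- tibble::tibble(lg = "lg1", start = 0, end = 600)
  wc5 <- window_covariates(w, genes = genes, tss = tss, cgi = cgi,
                           repeats = repeats)
  expect_equal(wc5$n_genes, c(1, 1))
  expect_equal(wc5$has_tss, c(TRUE, FALSE))
  expect_equal(wc5$full_cgi, c(FALSE, TRUE))
  expect_equal(wc5$repeat_bp, c(600, 0))
})

test_that("length regression recovers a noiseless linear relation", {
  lay <- genome_layout(paste0("lg", 1:6), c(90, 60, 40, 25, 15, 10) * 1e6)
  mk <- purrr::map_dfr(seq_len(6), function(i) {
    tibble::tibble(lg = lay$lg[i], pos = c(0, lay$length_bp[i]),
                   cm_avg = c(0, 50 + 0.4 * lay$length_bp[i] / 1e6))
  })
  fit <- length_regression(mk, lay)
  td <- suppressWarnings(tidy(fit)) # a noiseless fit upsets summary.lm
  expect_equal(td$estimate[td$term == "intercept"], 50, tolerance = 1e-9)
  expect_equal(td$estimate[td$term == "slope"], 0.4, tolerance = 1e-9)
  expect_lt(td$conf.high[2] - td$conf.low[2], 1e-6)
  expect_equal(suppressWarnings(glance(fit))$nobs, 6)

  expect_error(length_regression(mk[mk$lg %in% c("lg1", "lg2"), ], lay),
               ">= 3")
})

test_that("permuted genetic lengths give a null slope", {
  lay <- genome_layout(paste0("lg", 1:10),
                       seq(5e6, 90e6, length.out = 10))
  base_cm <- 50 + 0.4 * lay$length_bp / 1e6
  covered <- 0
  set.seed(77)
  for (i in 1:50) {
    cm <- sample(base_cm)
    mk <- purrr::map_dfr(seq_len(10), function(j) {
      tibble::tibble(lg = lay$lg[j], pos = c(0, lay$length_bp[j]),
                     cm_avg = c(0, cm[j]))
    })
    td <- tidy(length_regression(mk, lay))
    if (td$conf.low[2] <= 0 && td$conf.high[2] >= 0) covered <- covered + 1
  }
  expect_gte(covered / 50, 0.9)
})
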