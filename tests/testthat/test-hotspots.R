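make_windows <- function(cm, size = 10000, lg = "lg1") {
  n <- length(cm)
  tibble::tibble(lg = lg, start = (seq_len(n) - 1) * size,
                 end = seq_len(n) * size, cm = cm,
                 cm_per_mb = cm / (size / 1e6), complete = TRUE)
}

test_that("Gini matches closed forms and the mean-difference oracle", {
  # equal windows: perfectly even landscape
  lz <- lorenz_gini(make_windows(rep(2, 10)))
  expect_equal(lz$gini$gini, rep(0, nrow(lz$gini)), tolerance = 1e-12)

  # all recombination in one window of n = 10: (n-1)/n
  lz1 <- lorenz_gini(make_windows(c(5, rep(0, 9))))
  expect_equal(lz1$gini$gini[lz1$gini$lg == "lg1"], 0.9, tolerance = 1e-12)

  # oracle equivalence on random tables
  set.seed(19)
  for (i in 1:100) {
    cm <- stats::rexp(sample(10:200, 1))
    lz <- lorenz_gini(make_windows(cm))
    expect_equal(lz$gini$gini[1], gini_mad_oracle(cm), tolerance = 1e-9)
  }

  # an all-zero lg is flagged undefined
  lz0 <- lorenz_gini(dplyr::bind_rows(make_windows(rep(0, 5)),
                                      make_windows(stats::rexp(5), lg = "lg2")))
  expect_true(lz0$gini$undefined[lz0$gini$lg == "lg1"])
  expect_true(is.na(lz0$gini$gini[lz0$gini$lg == "lg1"]))
})

test_that("Gini is scale-invariant and respects Pigou-Dalton transfers", {
  set.seed(23)
  cm <- stats::rexp(50)
  g <- function(x) lorenz_gini(make_windows(x))$gini$gini[1]
  expect_equal(g(cm), g(cm * 7.3), tolerance = 1e-12)

  # moving mass from a low to a high window increases inequality
  lo <- which.min(cm); hi <- which.max(cm)
  cm2 <- cm
  d <- cm[lo] / 2
  cm2[lo] <- cm2[lo] - d
  cm2[hi] <- cm2[hi] + d
  expect_gt(g(cm2), g(cm))
})

test_that("landscape concentration drives the Gini coefficient", {
  # uniform small lg vs a large lg with recombination concentrated
  # near its ends: the concentrated landscape is more unequal
  uniform <- make_windows(rep(1, 50))
  n <- 500
  conc <- c(stats::rexp(50, 1 / 10), rep(0.05, n - 100),
            stats::rexp(50, 1 / 10))
  concentrated <- make_windows(conc, lg = "lg2")
  lz <- lorenz_gini(dplyr::bind_rows(uniform, concentrated))
  g <- setNames(lz$gini$gini, lz$gini$lg)
  expect_lt(g[["lg1"]], g[["lg2"]])
})

test_that("80% of recombination fraction is reported from the curve", {
  lz <- lorenz_gini(make_windows(c(8, 1, 1, rep(0, 7))))
  expect_equal(lz$gini$frac_seq_80[1], 0.1)
})

test_that("global hotspot and coldspot thresholds follow their wording", {
  # mean 2: the 5x threshold is 10, the 10x threshold 20
  w <- make_windows(c(10.1, 10.0, 20.0, 0.39, 0.41) / 100)
  calls <- call_global(w, mean_rate = 2)
  kinds <- function(k) sort(calls$start[calls$kind == k])
  # strict > for the 5x hotspot: 10.1 qualifies, exactly 10.0 does not
  expect_equal(kinds("hotspot"), w$start[c(1, 3)])
  # inclusive >= for the 10x global set: exactly 20.0 qualifies
  expect_equal(kinds("global_hotspot_10x"), w$start[3])
  # coldspot: rate < mean / 5 = 0.4
  expect_equal(kinds("coldspot"), w$start[4])
  expect_error(call_global(w, mean_rate = 0), "positive")
})

test_that("RRR80 is the focal rate over the flanking mean", {
  # flat landscape: RRR80 = 1 wherever defined
  flat <- make_windows(rep(1, 200), size = 1000)
  r <- rrr80(flat)
  expect_true(all(abs(r$rrr80[!is.na(r$rrr80)] - 1) < 1e-12))

  # focal 6 with flanks of 1 -> RRR80 = 6 x (small flank correction)
  cm <- rep(0.001, 200); cm[100] <- 0.006
  r2 <- rrr80(make_windows(cm, size = 1000))
  expect_equal(r2$rrr80[100], 6, tolerance = 1e-12)

  # at the lg start only the downstream flank exists: defined with
  # exactly half the flank windows, by the require-half rule
  expect_false(is.na(r2$rrr80[1]))
  # with fewer than half the flank windows the statistic is undefined
  short <- rrr80(make_windows(rep(0.001, 30), size = 1000))
  expect_true(all(is.na(short$rrr80))) # at most 29 < 40 flank windows

  # zero flank is flagged undefined rather than divided
  cm0 <- rep(0, 200); cm0[100] <- 0.006
  r3 <- rrr80(make_windows(cm0, size = 1000))
  expect_true(is.na(r3$rrr80[100]))
})

test_that("local hotspot calls need runs, rate band and repeat filter", {
  cm <- rep(0.001, 300) # 1 cM/Mb background
  cm[150:151] <- 0.006  # two consecutive windows at 6 cM/Mb
  w <- make_windows(cm, size = 1000)
  w$repeat_bp <- 0
  cl <- call_local(rrr80(w))
  expect_equal(nrow(cl$runs), 1)
  expect_equal(cl$runs$n_windows, 2)
  expect_equal(cl$runs$start, w$start[150])
  expect_equal(cl$runs$end, w$end[151])

  # an isolated qualifying window is not a hotspot
  cm1 <- rep(0.001, 300); cm1[150] <- 0.006
  w1 <- make_windows(cm1, size = 1000); w1$repeat_bp <- 0
  expect_equal(nrow(call_local(rrr80(w1))$runs), 0)

  # a repeat-rich window breaks the run
  w2 <- w
  w2$repeat_bp[151] <- 600
  expect_equal(nrow(call_local(rrr80(w2))$runs), 0)

  # windows above the rate ceiling are excluded
  cm3 <- rep(0.001, 300); cm3[150:151] <- 0.012 # 12 cM/Mb
  w3 <- make_windows(cm3, size = 1000); w3$repeat_bp <- 0
  expect_equal(nrow(call_local(rrr80(w3))$runs), 0)
})

test_that("element profiles are flat on flat tracks and peak on hotspots", {
  flat <- make_windows(rep(0.001, 300), size = 1000)
  el <- tibble::tibble(lg = "lg1", pos = c(100500, 200500))
  pr <- element_profile(flat, el)
  expect_true(all(abs(pr$mean_rel - 1) < 1e-12))

  cm <- rep(0.001, 300); cm[100:101] <- 0.01
  hot <- make_windows(cm, size = 1000)
  pr2 <- element_profile(hot, tibble::tibble(lg = "lg1", pos = 100500))
  peak <- pr2$mean_rel[pr2$offset_bp == 0]
  away <- pr2$mean_rel[abs(pr2$offset_bp) == 20000]
  expect_gt(peak / max(away), 2)
})

test_that("planted hotspots on elements shape the mean profile", {
  lay <- genome_layout("lg1", 20e6)
  p <- sim_params(seed = 26, layout = lay, hotspot_density = 5,
                  genes_per_mb = 3, cgi_per_mb = 3, frac_at_tss_cgi = 1,
                  background_meanlog = log(4e-9), background_sdlog = 0.3,
                  hotspot_intensity = c(10, 10))
  tl <- simulate_landscape(p)
  w <- windows_from_track(tl$track, lay, 1000)
  pr <- element_profile(w, tl$tss)
  peak <- pr$mean_rel[pr$offset_bp == 0]
  away <- pr$mean_rel[abs(pr$offset_bp) == 20000]
  expect_gt(peak / max(away), 2)

  # with hotspots placed away from elements the profile is flat
  p0 <- sim_params(seed = 26, layout = lay, hotspot_density = 5,
                   genes_per_mb = 25, frac_at_tss_cgi = 0,
                   background_meanlog = log(4e-9), background_sdlog = 0.3,
                   hotspot_intensity = c(10, 10))
  tl0 <- simulate_landscape(p0)
  w0 <- windows_from_track(tl0$track, lay, 1000)
  pr0 <- element_profile(w0, tl0$tss)
  expect_lt(max(pr0$mean_rel) / min(pr0$mean_rel), 1.3)
})
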