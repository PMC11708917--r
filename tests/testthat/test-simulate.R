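test_that("generators are deterministic under a fixed seed", {
  lay <- tiny_layout()
  p <- sim_params(seed = 4, layout = lay, n_meioses_per_sex = 20)
  t1 <- simulate_landscape(p)
  t2 <- simulate_landscape(p)
  expect_equal(t1$track, t2$track)
  expect_equal(t1$hotspots, t2$hotspots)
  expect_equal(simulate_meioses(t1, p), simulate_meioses(t2, p))
  expect_equal(perturb_track(t1, 0.5, seed = 9),
               perturb_track(t1, 0.5, seed = 9))
})

test_that("landscape honours degenerate hotspot settings", {
  lay <- tiny_layout()
  p0 <- sim_params(seed = 6, layout = lay, hotspot_density = 0)
  t0 <- simulate_landscape(p0)
  expect_equal(nrow(t0$hotspots), 0)
  # with no hotspots the track is exactly the background segmentation
  expect_true(all(diff(t0$track$start[t0$track$lg == "lg1"]) ==
                    p0$segment_bp))

  # unit intensity leaves the marginal rate distribution unchanged
  p1 <- sim_params(seed = 6, layout = lay, hotspot_density = 1,
                   hotspot_intensity = c(1, 1))
  t1 <- simulate_landscape(p1)
  ks <- suppressWarnings(
    stats::ks.test(t1$track$rate, t0$track$rate))
  expect_gt(ks$p.value, 0.01)
})

test_that("obligate crossovers are conserved at the bivalent level", {
  lay <- genome_layout("lg1", 10e6)
  p <- sim_params(seed = 8, layout = lay, n_meioses_per_sex = 500,
                  extra_co_rate = 0)
  cos <- simulate_meioses(flat_track(lay), p, transmit = FALSE)
  expect_equal(nrow(cos), 1000) # exactly one CO per meiosis per lg
  # with transmission thinning about half the COs are observed
  cos_t <- simulate_meioses(flat_track(lay), p, transmit = TRUE)
  expect_lt(abs(nrow(cos_t) - 500), 4 * sqrt(1000 * 0.25))
})

test_that("uniform placement gives a centred mean position", {
  lay <- genome_layout("lg1", 50e6)
  p <- sim_params(seed = 10, layout = lay, n_meioses_per_sex = 5000,
                  extra_co_rate = 0,
                  placement_telo_weight = c(M = 0, F = 0))
  cos <- simulate_meioses(flat_track(lay), p, transmit = FALSE)
  se <- 50e6 / sqrt(12) / sqrt(nrow(cos))
  expect_lt(abs(mean(cos$pos) - 25e6), 3 * se)
})

test_that("distinct per-sex placement mixtures are detectable", {
  lay <- genome_layout("lg1", 50e6)
  p <- sim_params(seed = 12, layout = lay, n_meioses_per_sex = 5000,
                  extra_co_rate = 0,
                  placement_telo_weight = c(M = 0.8, F = 0.2))
  cos <- simulate_meioses(flat_track(lay), p, transmit = FALSE)
  rel <- function(sx) {
    x <- cos$pos[cos$sex == sx]
    pmin(x, 50e6 - x) / 50e6
  }
  res <- ks_D(rel("M"), rel("F"), n_perm = 199, seed = 3)
  expect_gt(res$D, 0.05)
  expect_lt(res$p_value, 0.01)
})

test_that("empirical crossover density converges to the truth track", {
  lay <- genome_layout("lg1", 10e6)
  p <- sim_params(seed = 14, layout = lay, n_meioses_per_sex = 25000,
                  extra_co_rate = 0, hotspot_density = 2,
                  placement_telo_weight = c(M = 0, F = 0))
  tl <- simulate_landscape(p)
  cos <- simulate_meioses(tl, p, transmit = FALSE)
  emp <- table(cut(cos$pos, seq(0, 10e6, by = 1e5)))
  w <- windows_from_track(tl$track, lay, 1e5)
  expect_gt(cor(as.numeric(emp), w$cm), 0.9)
})

test_that("replicate noise scales correlation loss monotonically", {
  lay <- genome_layout("lg1", 10e6)
  p <- sim_params(seed = 16, layout = lay, hotspot_density = 1)
  tl <- simulate_landscape(p)
  expect_equal(perturb_track(tl, 0, seed = 1), tl$track)

  w_true <- windows_from_track(tl$track, lay, 1000)$cm
  r_at <- function(sd) {
    w <- windows_from_track(perturb_track(tl, sd, seed = 20), lay, 1000)$cm
    cor(w, w_true)
  }
  r_small <- r_at(0.1); r_mid <- r_at(0.5); r_big <- r_at(1.5)
  expect_gt(r_small, r_mid)
  expect_gt(r_mid, r_big)

  # same noise level, different seeds: distinct tracks, same marginal law
  a <- perturb_track(tl, 0.5, seed = 31)
  b <- perturb_track(tl, 0.5, seed = 32)
  expect_gt(max(abs(a$rate - b$rate)), 0)
  ks <- suppressWarnings(stats::ks.test(log(a$rate), log(b$rate)))
  expect_gt(ks$p.value, 0.01)
})

test_that("diversity couples to recombination as parameterised", {
  lay <- genome_layout("lg1", 20e6)
  # b = 0: no coupling
  p0 <- sim_params(seed = 18, layout = lay, div_slope = 0,
                   hotspot_density = 1)
  tl <- simulate_landscape(p0)
  d0 <- simulate_diversity(tl, p0)
  expect_lt(abs(cor(log(d0$windows$pi_model), log(d0$windows$rate))), 0.05)

  # b > 0: positive window-level coupling
  p1 <- sim_params(seed = 18, layout = lay, div_slope = 0.4,
                   hotspot_density = 1)
  d1 <- simulate_diversity(tl, p1)
  expect_gt(cor(log(d1$windows$pi_model), log(d1$windows$rate)), 0.3)

  # zero noise: pi is a deterministic monotone transform of rate
  p2 <- sim_params(seed = 18, layout = lay, div_slope = 0.4,
                   div_noise_sd = 0, hotspot_density = 1)
  d2 <- simulate_diversity(tl, p2)
  expect_equal(cor(d2$windows$pi_model, d2$windows$rate,
                   method = "spearman"), 1, tolerance = 1e-9)

  # the site table reproduces the model diversity through the estimator
  w <- windows_from_track(tl$track, lay, 10000)
  wc <- window_covariates(w, sites = d1$sites, n_diploids = p1$n_diploids)
  ok <- wc$complete & wc$pi > 0
  expect_gt(cor(log(wc$pi[ok]),
                log(d1$windows$pi_model[match(
                  paste(wc$lg, wc$start)[ok],
                  paste(d1$windows$lg, d1$windows$start))])), 0.9)
})
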