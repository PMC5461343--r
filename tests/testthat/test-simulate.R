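test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 7)
  a <- simulate_stations(cfg)
  b <- simulate_stations(cfg)
  expect_identical(a, b)
  ca <- simulate_community(a$stations, cfg)
  cb <- simulate_community(b$stations, cfg)
  expect_identical(ca, cb)
  qa <- withr::with_seed(7, simulate_qpcr(c(s1 = 1e5, s2 = 1e3),
                                          noise_sd = 0.2))
  qb <- withr::with_seed(7, simulate_qpcr(c(s1 = 1e5, s2 = 1e3),
                                          noise_sd = 0.2))
  expect_identical(qa, qb)
})

test_that("degenerate noise collapses nutrients onto their configured means", {
  cfg <- sim_config(
    seed = 1, sst_noise_sd = 0,
    salinity_mean_sd = c(35.2, 0),
    nutrient_lognormal_params = list(nh3 = c(0.06, 0), sio4 = c(0.85, 0),
                                     po4 = c(0.02, 0), nox = c(0.04, 0))
  )
  st <- simulate_stations(cfg)$stations
  expect_equal(st$nh3_um, rep(0.06, 10))
  expect_equal(st$po4_um, rep(0.02, 10))
  expect_equal(st$salinity_psu, rep(35.2, 10))
})

test_that("moment-matched lognormals reproduce the configured moments at large n", {
  # detection-limit censoring off so the raw draws are observable
  cfg <- sim_config(n_stations = 10000, seed = 123, true_rates = c(3, 68),
                    nutrient_detection_limit = 0)
  st <- simulate_stations(cfg)$stations
  expect_lt(abs(mean(st$po4_um) - 0.02), 3 * 0.01 / sqrt(1e4))
  expect_lt(abs(mean(st$sio4_um) - 0.85), 3 * 0.47 / sqrt(1e4))
  expect_equal(sd(st$po4_um), 0.01, tolerance = 0.05)
  expect_equal(sd(st$sio4_um), 0.47, tolerance = 0.05)
  # with the limit on, sub-limit draws display as 0.00 and carry the flag
  cfg2 <- sim_config(n_stations = 2000, seed = 9)
  st2 <- simulate_stations(cfg2)$stations
  expect_true(any(st2$po4_below_detection))
  expect_true(all(st2$po4_um[st2$po4_below_detection] == 0))
  expect_true(all(st2$po4_um[!st2$po4_below_detection] >= 0.01))
})

test_that("nutrient forcing shapes the expected community composition", {
  base <- tibble::tibble(
    station = c("low", "high"),
    po4_um = c(0.001, 0.001),
    nox_um = c(0.005, 0.15),
    nh3_um = c(0.005, 0.05)
  )
  cfg0 <- sim_config(trichodesmium_dinsensitivity = 0)
  g0 <- expected_group_proportions(base, cfg0)
  expect_equal(g0$cluster_ib[1], g0$cluster_ib[2])
  cfg_steep <- sim_config(trichodesmium_dinsensitivity = 5)
  g <- expected_group_proportions(base, cfg_steep)
  expect_gt(g$cluster_ib[g$station == "low"],
            g$cluster_ib[g$station == "high"])
  # heterotrophs move the other way
  expect_lt(g$cluster_ig[g$station == "low"],
            g$cluster_ig[g$station == "high"])
  expect_equal(g$cluster_ib + g$cluster_ig + g$cluster_iii, c(1, 1))
  expect_error(expected_group_proportions(base[, -2], cfg0), "po4")
})

test_that("empirical community means match the logistic model within MC error", {
  cfg <- sim_config(seed = 31, read_depth_range = c(2000, 2000))
  st <- simulate_stations(cfg)$stations
  truth <- simulate_community(st, cfg)$truth
  sims <- vapply(1:50, function(i) {
    cfg_i <- cfg
    cfg_i$seed <- 1000 + i
    com <- simulate_community(st, cfg_i)
    m <- otu_matrix(com$otu_table)
    ib <- com$taxonomy$otu_id[com$taxonomy$cluster == "IB"]
    rowSums(m[, ib, drop = FALSE]) / rowSums(m)
  }, numeric(nrow(st)))
  emp <- rowMeans(sims)
  mc_se <- apply(sims, 1, sd) / sqrt(ncol(sims))
  expected <- truth$group_proportions$cluster_ib
  expect_true(all(abs(emp - expected) < 4 * mc_se + 0.01))
})

test_that("OTU table rows sum to their drawn depths with full taxonomy cover", {
  cfg <- sim_config(seed = 2)
  st <- simulate_stations(cfg)$stations
  com <- simulate_community(st, cfg)
  m <- otu_matrix(com$otu_table)
  expect_equal(unname(rowSums(m)), com$truth$read_depths)
  expect_setequal(colnames(m), com$taxonomy$otu_id)
  expect_true(all(com$taxonomy$cluster %in% c("IB", "IG", "III")))
  props <- com$truth$otu_proportions
  expect_equal(unname(rowSums(props)), rep(1, nrow(st)), tolerance = 1e-12)
})

test_that("forward incubation matches the mixing model and its noise-free limits", {
  setup <- tracer_setup()
  pair <- simulate_incubation(0, setup, pn0 = 500, dt = 1, noise_sd = 0)
  expect_equal(pair$atom_pct_15n[pair$timepoint == "Tf"], 0.3663)
  pair68 <- simulate_incubation(68, setup, pn0 = 500, dt = 1, noise_sd = 0)
  a_n2 <- pair68$a_n2[1]
  expect_equal(pair68$atom_pct_15n[pair68$timepoint == "Tf"],
               (500 * 0.3663 + 68 * a_n2) / 568, tolerance = 1e-12)
  expect_equal(pair68$pn_nmol_l, c(500, 568))
  expect_error(simulate_incubation(10, setup, pn0 = 500, dt = 0))
})

test_that("simulated qPCR plates obey the log-linear response", {
  plate <- withr::with_seed(1, simulate_qpcr(c(s1 = 1e5), efficiency = 1,
                                             noise_sd = 0))
  std <- plate[!is.na(plate$known_copies), ]
  # perfect doubling: exactly -1/log10(2) cycles per decade
  fit <- lm(cq ~ log10(known_copies), data = std)
  expect_equal(unname(coef(fit)[2]), -1 / log10(2), tolerance = 1e-12)
  # halving template adds exactly one cycle at efficiency 1
  p2 <- withr::with_seed(1, simulate_qpcr(c(s1 = 1e5, s2 = 5e4),
                                          efficiency = 1, noise_sd = 0))
  cqs <- p2$cq[is.na(p2$known_copies)]
  expect_equal(unname(cqs[2] - cqs[1]), 1, tolerance = 1e-12)
  # zero template never amplifies
  p0 <- withr::with_seed(1, simulate_qpcr(c(s1 = 0), noise_sd = 0))
  expect_true(is.na(p0$cq[is.na(p0$known_copies)]))
  expect_error(simulate_qpcr(c(s1 = 1e4), efficiency = 1.5))
})
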