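test_that("standardize_log produces unit-variance log10 predictors", {
  env <- tibble::tibble(station = c("a", "b", "c"), po4 = c(0.01, 0.1, 1))
  out <- standardize_log(env)
  expect_equal(out$po4, c(-1, 0, 1))  # z-scores of log10 = (-2, -1, 0)
  expect_equal(mean(out$po4), 0, tolerance = 1e-12)
  expect_equal(sd(out$po4), 1, tolerance = 1e-12)
  expect_error(standardize_log(tibble::tibble(station = c("a", "b"),
                                              x = c(2, 2))), "constant")
  # below-detection zeros get half-minimum pseudocounts, recorded
  env0 <- tibble::tibble(station = c("a", "b", "c"), nox = c(0, 0.02, 0.08))
  out0 <- standardize_log(env0)
  expect_equal(attr(out0, "zero_handling")[["nox"]], 0.01)
  expect_true(all(is.finite(out0$nox)))
})

test_that("Gower centering matches the closed form and centers exactly", {
  d <- matrix(c(0, 0.6, 0.6, 0), 2, 2)
  g <- gower_center(d)
  expect_equal(g, matrix(c(0.09, -0.09, -0.09, 0.09), 2, 2))
  expect_equal(gower_center(matrix(0, 3, 3)), matrix(0, 3, 3))
  set.seed(4)
  y <- matrix(rnorm(30), 10)
  dd <- as.matrix(dist(y))
  gg <- gower_center(dd)
  expect_true(all(abs(rowSums(gg)) < 1e-10))
  expect_true(all(abs(colSums(gg)) < 1e-10))
  expect_error(gower_center(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("pseudo-F equals the classical regression F in the Euclidean case", {
  set.seed(10)
  for (i in 1:20) {
    n <- sample(6:12, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    g <- gower_center(euclid_dist(y))
    pf <- pseudo_f(g, x)
    f_classical <- summary(lm(y ~ x))$fstatistic[["value"]]
    expect_equal(pf$pseudo_f, f_classical, tolerance = 1e-8)
    expect_equal(pf$prop_explained, summary(lm(y ~ x))$r.squared,
                 tolerance = 1e-8)
  }
})

test_that("pseudo-F handles orthogonal predictors, bounds and rank checks", {
  # response orthogonal to the predictor explains nothing
  x <- c(-1, 1, -1, 1, -1, 1)
  y <- c(-1, -1, 1, 1, 0, 0)  # centered, orthogonal to x
  g <- gower_center(euclid_dist(y))
  expect_equal(pseudo_f(g, x)$prop_explained, 0, tolerance = 1e-12)
  set.seed(2)
  for (i in 1:10) {
    tbl <- random_otu_table(n_samples = 6)
    g <- gower_center(bray_curtis(tbl))
    p <- pseudo_f(g, rnorm(6))$prop_explained
    expect_gte(p, 0)
    expect_lte(p, 1)
  }
  expect_error(pseudo_f(g, cbind(1:6, 2 * (1:6))), "rank")
  expect_error(pseudo_f(gower_center(euclid_dist(rnorm(3))),
                        cbind(rnorm(3), rnorm(3))), "few")
})

test_that("marginal tests agree with pseudo_f and with vegan's adonis2", {
  cfg <- sim_config(seed = 5)
  st <- simulate_stations(cfg)$stations
  com <- simulate_community(st, cfg)
  bc <- bray_curtis(com$otu_table)
  st <- add_din(st)
  env <- standardize_log(st[, c("station", "po4_um", "din_um")])
  fit <- distlm(bc, env, n_perm = 999, seed = 42)
  res <- tidy(fit)
  g <- gower_center(bc)
  for (i in seq_len(nrow(res))) {
    expect_equal(res$pseudo_f[i],
                 pseudo_f(g, env[[res$term[i]]])$pseudo_f,
                 tolerance = 1e-10)
  }
  # independent oracle: adonis2 computes the same marginal statistic
  ad <- vegan::adonis2(stats::as.dist(unclass(bc)) ~ po4,
                       data = data.frame(po4 = env$po4_um),
                       permutations = 99)
  expect_equal(res$pseudo_f[res$term == "po4_um"], ad$F[1], tolerance = 1e-8)
  expect_equal(res$prop_explained[res$term == "po4_um"], ad$R2[1],
               tolerance = 1e-8)
})

test_that("permutation p-values are seeded, add-one and duplicate-invariant", {
  cfg <- sim_config(seed = 8)
  st <- simulate_stations(cfg)$stations
  com <- simulate_community(st, cfg)
  bc <- bray_curtis(com$otu_table)
  env <- standardize_log(st[, c("station", "po4_um")])
  env$po4_copy <- env$po4_um
  fit1 <- distlm(bc, env, predictors = c("po4_um", "po4_copy"),
                 n_perm = 499, seed = 7)
  fit2 <- distlm(bc, env, predictors = c("po4_um", "po4_copy"),
                 n_perm = 499, seed = 7)
  expect_identical(tidy(fit1), tidy(fit2))
  r <- tidy(fit1)
  expect_equal(r$p_value[1], r$p_value[2])
  expect_equal(r$pseudo_f[1], r$pseudo_f[2])
  expect_gte(min(r$p_value), 1 / 500)  # add-one estimator floor
  gl <- glance(fit1)
  expect_equal(gl$n_perm, 499)
  expect_equal(gl$n, nrow(st))
})

test_that("pearson screen reproduces cor.test exactly", {
  ab <- tibble::tibble(a1 = c(1, 2, 3, 4), a2 = c(4, 3, 2, 1))
  env <- tibble::tibble(e1 = c(1, 3, 2, 4), e2 = c(1, 2, 3, 4))
  res <- pearson_screen(ab, env)
  r11 <- res[res$abundance == "a1" & res$predictor == "e1", ]
  expect_equal(r11$r, 0.8)
  ct <- cor.test(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r11$p_value, ct$p.value)
  expect_equal(res[res$abundance == "a1" & res$predictor == "e2", ]$r, 1)
  expect_equal(res[res$abundance == "a2" & res$predictor == "e2", ]$r, -1)
  expect_error(pearson_screen(tibble::tibble(a = c(1, 1, 1)),
                              tibble::tibble(e = c(1, 2, 3))), "variance")
})
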