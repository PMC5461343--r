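test_that("low-abundance filter uses a strict < threshold on OTU totals", {
  tbl <- toy_otu_table()  # totals 49, 50, 500
  out <- filter_low_abundance(tbl, min_total = 50)
  expect_setequal(setdiff(names(out), "sample_id"), c("otu_b", "otu_c"))
  expect_identical(filter_low_abundance(tbl, min_total = 0), tbl)
  expect_warning(empty <- filter_low_abundance(tbl, min_total = 1e6),
                 "below")
  expect_equal(ncol(empty), 1)
  expect_warning(
    filter_low_abundance(tibble::tibble(sample_id = c("a", "b"),
                                        x = c(100, 0), y = c(0, 5)),
                         min_total = 50),
    "emptied"
  )
})

test_that("rarefaction conserves depth, keeps full samples and is seeded", {
  tbl <- random_otu_table(n_samples = 4, n_otus = 6, depth = 300)
  out <- rarefy_counts(tbl, depth = 100, seed = 11)
  expect_true(all(rowSums(otu_matrix(out)) == 100))
  expect_identical(out, rarefy_counts(tbl, depth = 100, seed = 11))
  # a sample already at depth is returned unchanged
  same <- rarefy_counts(tbl, depth = 300, seed = 5)
  expect_equal(otu_matrix(same), otu_matrix(tbl))
  # shallow samples are dropped with a warning
  tbl$otu01[1] <- 0
  shallow_sum <- sum(otu_matrix(tbl)[1, ])
  expect_warning(drop <- rarefy_counts(tbl, depth = shallow_sum + 1, seed = 2),
                 "dropping")
  expect_equal(nrow(drop), 3)
  expect_error(rarefy_counts(tbl, depth = 0))
})

test_that("rarefied counts match the hypergeometric expectation", {
  tbl <- tibble::tibble(sample_id = "s", a = 60, b = 30, c = 10)
  depth <- 40
  draws <- vapply(seq_len(10000), function(i) {
    as.numeric(otu_matrix(rarefy_counts(tbl, depth = depth, seed = i))[1, ])
  }, numeric(3))
  emp <- rowMeans(draws)
  expected <- depth * c(60, 30, 10) / 100
  mc_se <- apply(draws, 1, sd) / sqrt(ncol(draws))
  expect_true(all(abs(emp - expected) < 4 * mc_se + 1e-9))
})

test_that("Shannon diversity hits its closed-form anchors", {
  uni <- tibble::tibble(sample_id = "u", a = 5, b = 5, c = 5, d = 5)
  expect_equal(shannon_diversity(uni)$shannon, log(4))
  single <- tibble::tibble(sample_id = "m", a = 12)
  expect_equal(shannon_diversity(single)$shannon, 0)
  mix <- tibble::tibble(sample_id = "x", a = 5, b = 3, c = 2)
  expect_equal(shannon_diversity(mix)$shannon, 1.0297, tolerance = 1e-4)
  expect_equal(shannon_diversity(mix, base = 2)$shannon,
               1.0297 / log(2), tolerance = 1e-4)
  expect_error(shannon_diversity(tibble::tibble(sample_id = "z", a = 0)))
})

test_that("Shannon is permutation-invariant and maximized by uniformity", {
  set.seed(99)
  for (i in 1:10) {
    tbl <- random_otu_table(n_samples = 3, n_otus = 7)
    m <- otu_matrix(tbl)
    perm <- m[, sample(ncol(m)), drop = FALSE]
    expect_equal(shannon_diversity(tbl)$shannon,
                 shannon_diversity(otu_tibble(perm))$shannon)
    s <- ncol(m)
    expect_true(all(shannon_diversity(tbl)$shannon <= log(s) + 1e-12))
  }
})

test_that("relative abundances normalize rows and honor the <1% boundary", {
  one <- tibble::tibble(sample_id = "s", a = 7)
  expect_equal(relative_abundance(one)$a, 1)
  tbl <- tibble::tibble(sample_id = "s", a = 30, b = 69, c = 1)
  out <- relative_abundance(tbl, other_threshold = 0.01)
  expect_false("Other" %in% names(out))  # 1% is not < 1%
  out2 <- relative_abundance(
    tibble::tibble(sample_id = "s", a = 300, b = 695, c = 5),
    other_threshold = 0.01)
  expect_true("Other" %in% names(out2))
  four <- relative_abundance(tibble::tibble(sample_id = "s", a = 27, b = 26,
                                            c = 17, d = 30))
  expect_equal(unlist(four[1, -1], use.names = FALSE),
               c(0.27, 0.26, 0.17, 0.30))
  set.seed(3)
  rnd <- relative_abundance(random_otu_table())
  expect_equal(unname(rowSums(as.matrix(rnd[-1]))), rep(1, nrow(rnd)),
               tolerance = 1e-12)
  expect_error(relative_abundance(tibble::tibble(sample_id = "s", a = 0)))
})

test_that("Bray-Curtis matches hand values and the manual formula", {
  ident <- tibble::tibble(sample_id = c("a", "b"), x = c(3, 3), y = c(7, 7))
  expect_equal(as.numeric(bray_curtis(ident, "none")[1, 2]), 0)
  disj <- tibble::tibble(sample_id = c("a", "b"), x = c(1, 0), y = c(0, 1))
  expect_equal(as.numeric(bray_curtis(disj, "none")[1, 2]), 1)
  sq <- tibble::tibble(sample_id = c("a", "b"), x = c(4, 1), y = c(0, 0))
  expect_equal(as.numeric(bray_curtis(sq, "sqrt")[1, 2]), 1 / 3)
  # manual-formula oracle on random tables, plus symmetry / diagonal / range
  set.seed(7)
  for (i in 1:5) {
    tbl <- random_otu_table(n_samples = 4, n_otus = 6)
    m <- sqrt(otu_matrix(tbl))
    d <- unclass(bray_curtis(tbl, "sqrt"))
    for (a in 1:3) for (b in (a + 1):4) {
      expect_equal(d[a, b], sum(abs(m[a, ] - m[b, ])) / sum(m[a, ] + m[b, ]),
                   tolerance = 1e-12)
    }
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 1))
  }
  expect_error(bray_curtis(tibble::tibble(sample_id = "a", x = 1)))
})

test_that("filter-then-rarefy differs from rarefy-then-filter on a constructed table", {
  tbl <- tibble::tibble(
    sample_id = c("deep", "shallow"),
    rare = c(50, 0),        # passes the <50 filter only before rarefaction
    filler = c(9950, 100)
  )
  fr <- rarefy_counts(filter_low_abundance(tbl, 50), depth = 100, seed = 1)
  rf <- suppressWarnings(
    filter_low_abundance(rarefy_counts(tbl, depth = 100, seed = 1), 50))
  expect_true("rare" %in% names(fr))
  expect_false("rare" %in% names(rf))
})
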