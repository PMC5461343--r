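# Small in-code fixtures shared across the suite.

toy_otu_table <- function() {
  # OTU totals 49, 50, 500 across two samples
  tibble::tibble(
    sample_id = c("s1", "s2"),
    otu_a = c(20, 29),
    otu_b = c(25, 25),
    otu_c = c(100, 400)
  )
}

random_otu_table <- function(n_samples = 5, n_otus = 8, depth = 200) {
  m <- t(vapply(seq_len(n_samples), function(i) {
    as.integer(rmultinom(1, depth, rgamma(n_otus, 1)))
  }, integer(n_otus)))
  colnames(m) <- sprintf("otu%02d", seq_len(n_otus))
  rownames(m) <- sprintf("s%02d", seq_len(n_samples))
  tibble::as_tibble(m, rownames = "sample_id")
}

# Euclidean distance matrix over a single response vector: the case where
# the pseudo-F reduces exactly to the classical regression F.
euclid_dist <- function(y) {
  as.matrix(stats::dist(matrix(y, ncol = 1)))
}

perfect_standards <- function(slope = -1 / log10(2), intercept = 38,
                              decades = 2:7) {
  tibble::tibble(copies = 10^decades, cq = intercept + slope * decades)
}
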