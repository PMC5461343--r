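#' Remove low-abundance OTUs from a count table
#'
#' Drops OTUs whose total count summed across all samples falls below
#' `min_total` (strict `<`, so an OTU with exactly `min_total` reads is
#' kept). Samples are never dropped, but samples emptied by the filter are
#' flagged with a warning. Removing rare OTUs before rarefaction is the
#' conventional hygiene order for amplicon surveys.
#'
#' @param otu_tbl Wide OTU tibble: `sample_id` column plus one integer count
#'   column per OTU.
#' @param min_total Minimum summed count for an OTU to be retained
#'   (default 50).
#' @return Filtered OTU tibble.
#' @examples
#' tbl <- tibble::tibble(sample_id = c("a", "b"),
#'                       otu1 = c(20, 29), otu2 = c(25, 25), otu3 = c(0, 400))
#' filter_low_abundance(tbl)  # otu1 (total 49) removed; otu2 (50) kept
#' @export
filter_low_abundance <- function(otu_tbl, min_total = 50) {
  m <- otu_matrix(otu_tbl)
  keep <- colSums(m) >= min_total
  if (!any(keep)) {
    warn("all OTUs fall below `min_total`; returning an empty table")
  }
  out <- m[, keep, drop = FALSE]
  emptied <- rowSums(m) > 0 & rowSums(out) == 0
  if (any(emptied)) {
    warn(sprintf("filtering emptied sample(s): %s",
                 paste(rownames(m)[emptied], collapse = ", ")))
  }
  otu_tibble(out)
}

#' Rarefy samples to a common read depth
#'
#' Subsamples each sample's reads without replacement (one multivariate
#' hypergeometric draw per sample) to exactly `depth` reads, removing the
#' between-sample depth differences that inflate richness in deeper samples.
#' Samples with fewer than `depth` reads are dropped with a warning. A single
#' draw is used rather than an average over repeated rarefactions, matching
#' the usual single-table workflow; results are deterministic given `seed`.
#'
#' @inheritParams filter_low_abundance
#' @param depth Target reads per sample; `"auto"` uses the minimum sample
#'   sum.
#' @param seed Integer seed for the subsampling draw.
#' @return Rarefied OTU tibble with attributes `depth` and `seed`.
#' @export
rarefy_counts <- function(otu_tbl, depth = "auto", seed = 1) {
  m <- otu_matrix(otu_tbl)
  sums <- rowSums(m)
  if (identical(depth, "auto")) depth <- min(sums)
  check_number(depth, "depth", lower = 1)
  keep <- sums >= depth
  if (!all(keep)) {
    warn(sprintf("dropping sample(s) shallower than depth %d: %s",
                 as.integer(depth),
                 paste(rownames(m)[!keep], collapse = ", ")))
  }
  m <- m[keep, , drop = FALSE]
  out <- withr::with_seed(seed, withCallingHandlers(
    vegan::rrarefy(m, sample = depth),
    # vegan advises when a table has no low counts; irrelevant here since
    # integrality is already enforced upstream
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  res <- otu_tibble(out)
  attr(res, "depth") <- depth
  attr(res, "seed") <- seed
  res
}

#' Shannon diversity per sample
#'
#' `H' = -sum(p_i log(p_i))` over the positive relative abundances of each
#' sample. Natural log by default (the PRIMER convention); the base is
#' recorded on the output because reported H' values are not comparable
#' across bases.
#'
#' @inheritParams filter_low_abundance
#' @param base Logarithm base (default `exp(1)`).
#' @return Tibble with `sample_id`, `shannon`, `richness`; attribute
#'   `log_base`.
#' @examples
#' tbl <- tibble::tibble(sample_id = "s", a = 5, b = 3, c = 2)
#' shannon_diversity(tbl)  # 1.0297
#' @export
shannon_diversity <- function(otu_tbl, base = exp(1)) {
  m <- otu_matrix(otu_tbl)
  if (any(rowSums(m) == 0)) abort("all-zero sample: diversity undefined")
  res <- tibble::tibble(
    sample_id = rownames(m),
    shannon = as.numeric(vegan::diversity(m, index = "shannon", base = base)),
    richness = as.integer(rowSums(m > 0))
  )
  attr(res, "log_base") <- base
  res
}

#' Relative abundance profiles
#'
#' Per-sample proportions, optionally collapsing OTUs whose share of the
#' pooled dataset falls strictly below `other_threshold` into a single
#' `Other` column (the usual treatment for stacked community bar charts).
#'
#' @inheritParams filter_low_abundance
#' @param other_threshold Proportion of total pooled sequences below which an
#'   OTU is grouped as `Other` (strict `<`); `NULL` disables grouping.
#' @return Tibble of proportions; rows sum to 1.
#' @export
relative_abundance <- function(otu_tbl, other_threshold = NULL) {
  m <- otu_matrix(otu_tbl)
  sums <- rowSums(m)
  if (any(sums == 0)) abort("zero-sum sample: proportions undefined")
  if (!is.null(other_threshold)) {
    pooled <- colSums(m) / sum(m)
    minor <- pooled < other_threshold
    if (any(minor)) {
      other <- rowSums(m[, minor, drop = FALSE])
      m <- cbind(m[, !minor, drop = FALSE], Other = other)
    }
  }
  otu_tibble(m / rowSums(m))
}

#' Bray-Curtis dissimilarity on (optionally transformed) counts
#'
#' Computes pairwise Bray-Curtis dissimilarity
#' `d(x, y) = sum|x'_i - y'_i| / sum(x'_i + y'_i)` on transformed abundances
#' `x' = f(x)`. A square-root transform (the default, following the standard
#' PRIMER workflow) tempers the influence of dominant OTUs; note the
#' transform is applied to the abundances, not to the dissimilarities.
#'
#' @inheritParams filter_low_abundance
#' @param transform One of `"sqrt"`, `"fourth_root"`, `"none"`.
#' @return A `dissimilarity_matrix`: a symmetric numeric matrix with zero
#'   diagonal, sample ids as dimnames and a `transform` attribute.
#' @examples
#' tbl <- tibble::tibble(sample_id = c("a", "b"), x = c(4, 1), y = c(0, 0))
#' bray_curtis(tbl, transform = "sqrt")  # d = 1/3
#' @export
bray_curtis <- function(otu_tbl, transform = c("sqrt", "fourth_root", "none")) {
  transform <- match.arg(transform)
  m <- otu_matrix(otu_tbl)
  if (nrow(m) < 2) abort("need at least two samples")
  mt <- switch(transform, none = m, sqrt = sqrt(m), fourth_root = m^0.25)
  d <- as.matrix(vegan::vegdist(mt, method = "bray"))
  new_dissimilarity_matrix(d, transform)
}

#' @keywords internal
new_dissimilarity_matrix <- function(d, transform = "none") {
  stopifnot(is.matrix(d), isSymmetric(unname(d)))
  diag(d) <- 0
  structure(d, transform = transform, class = c("dissimilarity_matrix",
                                                "matrix", "array"))
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat(sprintf("Bray-Curtis-type dissimilarity matrix (%d samples, %s transform)\n",
              nrow(x), attr(x, "transform")))
  print(round(unclass(x), 4), ...)
  invisible(x)
}

#' @rdname bray_curtis
#' @param x A `dissimilarity_matrix`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.dissimilarity_matrix <- function(x, ...) {
  ids <- rownames(x)
  pairs <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(
    sample_a = ids[pairs[, 1]],
    sample_b = ids[pairs[, 2]],
    dissimilarity = x[pairs]
  )
}
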