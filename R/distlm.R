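#' Log-transform and standardize environmental predictors
#'
#' Prepares an environmental table for distance-based linear modeling:
#' each numeric column is log10-transformed and then centered and scaled to
#' unit (sample) standard deviation. Columns containing zeros (e.g. nutrient
#' values below detection reported as 0.00) receive a pseudocount of half the
#' column's minimum positive value before the log; the pseudocount used is
#' recorded in the `zero_handling` attribute.
#'
#' @param env_tbl Tibble of station covariates; an id column named
#'   `station` or `sample_id` is carried through untransformed.
#' @param predictors Character vector of columns to transform (default: all
#'   numeric columns except the id).
#' @return Tibble of standardized predictors (each column mean 0, sd 1) with
#'   attributes `zero_handling` (named pseudocounts) and `predictors`.
#' @examples
#' env <- tibble::tibble(station = c("a", "b", "c"), po4 = c(0.01, 0.1, 1))
#' standardize_log(env)
#' @export
standardize_log <- function(env_tbl, predictors = NULL) {
  id_col <- intersect(c("station", "sample_id"), names(env_tbl))[1]
  if (is.null(predictors)) {
    predictors <- setdiff(names(env_tbl)[vapply(env_tbl, is.numeric, TRUE)],
                          id_col)
  }
  missing_cols <- setdiff(predictors, names(env_tbl))
  if (length(missing_cols) > 0) {
    abort(sprintf("predictor column(s) not found: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  pseudo <- setNames(numeric(length(predictors)), predictors)
  out <- env_tbl[c(if (!is.na(id_col)) id_col, predictors)]
  for (p in predictors) {
    x <- env_tbl[[p]]
    if (anyNA(x)) abort(sprintf("missing values in predictor `%s`", p))
    if (any(x < 0)) abort(sprintf("negative values in predictor `%s`", p))
    if (any(x == 0)) {
      pos <- x[x > 0]
      if (length(pos) == 0) abort(sprintf("predictor `%s` is all zero", p))
      pseudo[p] <- min(pos) / 2
      x <- x + pseudo[p]
    }
    lx <- log10(x)
    s <- sd(lx)
    if (!is.finite(s) || s == 0) {
      abort(sprintf("predictor `%s` is constant after log transform", p))
    }
    out[[p]] <- (lx - mean(lx)) / s
  }
  attr(out, "zero_handling") <- pseudo
  attr(out, "predictors") <- predictors
  out
}

#' Gower-center a dissimilarity matrix
#'
#' Double-centering of the squared dissimilarities: `A = -d_ij^2 / 2`,
#' `G = (I - 11'/n) A (I - 11'/n)`. G is the inner-product (Gower) matrix
#' whose total trace partitions into explained and residual components under
#' a hat-matrix projection; every row and column of G sums to zero.
#'
#' @param d A `dissimilarity_matrix` or symmetric zero-diagonal matrix.
#' @return Centered inner-product matrix (plain matrix, dimnames kept).
#' @export
gower_center <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) abort("dissimilarity matrix must be symmetric")
  n <- nrow(d)
  a <- -0.5 * d^2
  centered <- sweep(a, 1, rowMeans(a))
  centered <- sweep(centered, 2, colMeans(centered))
  dimnames(centered) <- dimnames(d)
  centered
}

#' Pseudo-F statistic for a distance-based linear model
#'
#' McArdle-Anderson trace statistic: with `H` the hat matrix of the design
#' `[1, X]` and `G` the Gower-centered matrix,
#' \deqn{F = \frac{tr(HGH)/q}{tr((I-H)G(I-H))/(n-q-1)}}
#' with `q` predictors. The proportion of community variation explained is
#' `tr(HGH)/tr(G)`. When `G` derives from Euclidean distances on a single
#' response this reduces exactly to the classical regression F.
#'
#' @param g Gower-centered matrix from [gower_center()].
#' @param x Numeric matrix (or vector) of predictors, rows matching `g`.
#' @return One-row tibble: `pseudo_f`, `prop_explained`, `df1`, `df2`.
#' @export
pseudo_f <- function(g, x) {
  x <- as.matrix(x)
  n <- nrow(g)
  if (nrow(x) != n) abort("predictor rows must match the distance matrix")
  design <- cbind(1, x)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) abort("rank-deficient predictor matrix")
  q <- qrd$rank - 1
  if (n - q - 1 < 1) abort("too few samples for the requested predictors")
  qmat <- qr.Q(qrd)[, seq_len(qrd$rank), drop = FALSE]
  # H = Q Q'; idempotency gives tr(HGH) = tr(GH) = sum((G Q) * Q)
  tr_gh <- sum((g %*% qmat) * qmat)
  tr_g <- sum(diag(g))
  f <- (tr_gh / q) / ((tr_g - tr_gh) / (n - q - 1))
  tibble::tibble(
    pseudo_f = f,
    prop_explained = tr_gh / tr_g,
    df1 = q,
    df2 = n - q - 1
  )
}

#' Marginal distance-based linear model with permutation tests
#'
#' Tests each predictor alone against a community dissimilarity matrix: the
#' observed pseudo-F is compared with its distribution under simultaneous
#' row/column permutation of the Gower matrix (equivalent to permuting the
#' raw observations), and the p-value uses the add-one estimator
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`. The same permutation set is
#' applied to every predictor so identical predictors receive identical
#' p-values.
#'
#' @param d A `dissimilarity_matrix` (or symmetric matrix) over samples.
#' @param env_std Standardized predictor tibble from [standardize_log()]
#'   (an id column is ignored).
#' @param predictors Columns of `env_std` to test (default: the
#'   `predictors` attribute, else all numeric columns).
#' @param n_perm Number of permutations (default 9999, the PRIMER
#'   convention).
#' @param seed Integer seed making the permutation draw reproducible.
#' @return A `distlm` object; see [tidy.distlm()] and [glance.distlm()].
#' @export
distlm <- function(d, env_std, predictors = NULL, n_perm = 9999, seed = 1) {
  check_number(n_perm, "n_perm", lower = 99)
  g <- gower_center(d)
  n <- nrow(g)
  if (n < 4) warn("fewer than 4 samples: permutation tests are weak")
  id_col <- intersect(c("station", "sample_id"), names(env_std))[1]
  if (is.null(predictors)) {
    predictors <- attr(env_std, "predictors")
    if (is.null(predictors)) {
      predictors <- setdiff(names(env_std)[vapply(env_std, is.numeric, TRUE)],
                            id_col)
    }
  }
  if (!is.na(id_col) && !is.null(rownames(g))) {
    ord <- match(rownames(g), as.character(env_std[[id_col]]))
    if (anyNA(ord)) abort("sample ids in `d` and `env_std` do not match")
    env_std <- env_std[ord, ]
  }
  if (nrow(env_std) != n) abort("predictor rows must match the distance matrix")

  perms <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  })
  tr_g <- sum(diag(g))
  res <- purrr::map_dfr(predictors, function(p) {
    x <- env_std[[p]]
    if (sd(x) == 0) abort(sprintf("predictor `%s` has zero variance", p))
    u <- x - mean(x)
    u <- u / sqrt(sum(u^2))
    # single predictor: tr(GH) = u'Gu since row/col sums of G are zero
    qf_obs <- sum(u * (g %*% u))
    f_obs <- qf_obs / ((tr_g - qf_obs) / (n - 2))
    up <- matrix(u[perms], nrow = n)
    qf_perm <- colSums((g %*% up) * up)
    f_perm <- qf_perm / ((tr_g - qf_perm) / (n - 2))
    tibble::tibble(
      term = p,
      pseudo_f = f_obs,
      prop_explained = qf_obs / tr_g,
      p_value = (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
    )
  })
  structure(
    list(results = res, n = n, n_perm = n_perm, seed = seed,
         transform = attr(d, "transform")),
    class = "distlm"
  )
}

#' @export
print.distlm <- function(x, ...) {
  cat(sprintf(
    "Distance-based linear model: marginal tests (%d samples, %d permutations)\n",
    x$n, x$n_perm))
  print(as.data.frame(x$results), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidy a distLM fit
#'
#' @param x A `distlm` object.
#' @param ... Unused.
#' @return Tibble with one row per tested predictor: `term`, `pseudo_f`,
#'   `prop_explained`, `p_value`.
#' @exportS3Method generics::tidy
tidy.distlm <- function(x, ...) x$results

#' One-row summary of a distLM fit
#'
#' @param x A `distlm` object.
#' @param ... Unused.
#' @return Tibble with `n`, `n_perm`, `seed`, `n_significant` (p < 0.05).
#' @exportS3Method generics::glance
glance.distlm <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_perm = x$n_perm,
    seed = x$seed,
    n_significant = sum(x$results$p_value < 0.05)
  )
}

#' Pearson correlation screen between two sets of variables
#'
#' All pairwise Pearson correlations between the numeric columns of an
#' abundance table and an environmental table, with two-sided p-values from
#' the t distribution on n - 2 degrees of freedom. Rows with missing values
#' are dropped pairwise and the n actually used is reported.
#'
#' @param abund_tbl,env_tbl Tibbles sharing row order (or a common
#'   `station`/`sample_id` column used to align them).
#' @return Tibble: `abundance`, `predictor`, `r`, `p_value`, `n`.
#' @export
pearson_screen <- function(abund_tbl, env_tbl) {
  id_col <- intersect(intersect(c("station", "sample_id"), names(abund_tbl)),
                      names(env_tbl))[1]
  if (!is.na(id_col)) {
    ord <- match(as.character(abund_tbl[[id_col]]),
                 as.character(env_tbl[[id_col]]))
    if (anyNA(ord)) abort("sample ids do not match between tables")
    env_tbl <- env_tbl[ord, ]
  }
  a_cols <- setdiff(names(abund_tbl)[vapply(abund_tbl, is.numeric, TRUE)],
                    id_col)
  e_cols <- setdiff(names(env_tbl)[vapply(env_tbl, is.numeric, TRUE)], id_col)
  grid <- tidyr::expand_grid(abundance = a_cols, predictor = e_cols)
  purrr::pmap_dfr(grid, function(abundance, predictor) {
    x <- abund_tbl[[abundance]]
    y <- env_tbl[[predictor]]
    ok <- complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3) abort("need at least 3 paired observations")
    if (sd(x) == 0 || sd(y) == 0) {
      abort(sprintf("zero-variance column in pair (%s, %s)",
                    abundance, predictor))
    }
    r <- cor(x, y)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    tibble::tibble(abundance = abundance, predictor = predictor, r = r,
                   p_value = 2 * pt(-abs(tstat), df = n - 2), n = n)
  })
}
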