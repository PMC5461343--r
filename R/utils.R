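#' Round half away from zero to a number of significant figures
#'
#' Base R's `signif()` rounds half to even; printed values in field reports
#' conventionally round half away from zero, so reported quantities (trace
#' moles, contamination bounds, release endpoints) use this helper.
#'
#' @param x Numeric vector.
#' @param digits Significant figures (default 2).
#' @return Numeric vector rounded half away from zero.
#' @keywords internal
signif_away <- function(x, digits = 2) {
  out <- x
  nz <- is.finite(x) & x != 0
  if (any(nz)) {
    mag <- floor(log10(abs(x[nz]))) - digits + 1
    scaled <- abs(x[nz]) / 10^mag
    # add a hair of slack so representation error does not pull .5 down
    out[nz] <- sign(x[nz]) * floor(scaled + 0.5 + 1e-9) * 10^mag
  }
  out
}

#' Convert a wide OTU count tibble to an integer matrix
#'
#' The package's tabular convention for OTU tables is one `sample_id` column
#' followed by one numeric column per OTU.
#'
#' @param otu_tbl Wide OTU tibble.
#' @return Integer matrix, samples in rows (named), OTUs in columns.
#' @keywords internal
otu_matrix <- function(otu_tbl) {
  stopifnot(is.data.frame(otu_tbl))
  if (!"sample_id" %in% names(otu_tbl)) {
    abort("OTU table must have a `sample_id` column.")
  }
  m <- as.matrix(otu_tbl[setdiff(names(otu_tbl), "sample_id")])
  if (!is.numeric(m)) abort("OTU count columns must be numeric.")
  if (any(m < 0) || any(m != round(m))) {
    abort("OTU counts must be non-negative integers.")
  }
  rownames(m) <- as.character(otu_tbl$sample_id)
  storage.mode(m) <- "double"
  m
}

#' @keywords internal
otu_tibble <- function(m) {
  tibble::as_tibble(m, rownames = "sample_id")
}

#' @keywords internal
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero_len = FALSE) {
  if (!is.numeric(x) || (!allow_zero_len && length(x) == 0) || anyNA(x)) {
    abort(sprintf("`%s` must be a non-missing numeric value.", name))
  }
  if (any(x < lower) || any(x > upper)) {
    abort(sprintf("`%s` must lie in [%s, %s].", name, format(lower),
                  format(upper)))
  }
  invisible(x)
}
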