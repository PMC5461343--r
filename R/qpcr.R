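#' Fit a qPCR standard curve
#'
#' Ordinary least squares of quantification cycle (Cq) on log10 standard
#' copies. The slope of the fitted line gives the per-cycle amplification
#' gain: `efficiency = (10^(-1/slope) - 1) x 100`, so a perfect-doubling
#' assay loses exactly `1/log10(2) = 3.3219` cycles per decade and reads
#' 100% efficiency.
#'
#' @param standards Tibble with columns `copies` (known copies per reaction)
#'   and `cq` (cycles); technical replicates are ordinary extra rows.
#' @param target Optional assay name carried into the result.
#' @param cq_limit Quantification-cycle limit of the assay (cycles, default
#'   35.5): samples beyond it are reported below the limit of
#'   quantification.
#' @return A `qpcr_curve` object with slope (cycles per decade), intercept
#'   (Cq at one copy), R-squared, efficiency (%), `cq_limit` and the implied
#'   `copies_limit`.
#' @examples
#' std <- tibble::tibble(copies = 10^(2:7), cq = 38 - 3.3219 * (2:7))
#' fit_standard_curve(std)
#' @export
fit_standard_curve <- function(standards, target = "assay", cq_limit = 35.5) {
  if (!all(c("copies", "cq") %in% names(standards))) {
    abort("`standards` needs `copies` and `cq` columns")
  }
  standards <- standards |> dplyr::filter(!is.na(.data$cq))
  if (length(unique(standards$copies)) < 3) {
    abort("need at least 3 distinct standard concentrations")
  }
  check_number(standards$copies, "copies", lower = 1e-12)
  fit <- lm(cq ~ log10(copies), data = standards)
  slope <- unname(coef(fit)[2])
  if (slope >= 0) abort("positive standard-curve slope: Cq must fall with copies")
  intercept <- unname(coef(fit)[1])
  structure(
    list(
      target = target,
      slope = slope,
      intercept = intercept,
      r_squared = summary(fit)$r.squared,
      efficiency = (10^(-1 / slope) - 1) * 100,
      cq_limit = cq_limit,
      copies_limit = 10^((cq_limit - intercept) / slope),
      n_standards = nrow(standards)
    ),
    class = "qpcr_curve"
  )
}

#' @export
print.qpcr_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve [%s]\n", x$target))
  cat(sprintf("  Cq = %.4f %+.4f x log10(copies);  R^2 = %.4f\n",
              x$intercept, x$slope, x$r_squared))
  cat(sprintf("  efficiency %.2f%%;  Cq limit %.1f (~%.1f copies/rxn)\n",
              x$efficiency, x$cq_limit, x$copies_limit))
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param x A `qpcr_curve`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.qpcr_curve <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname fit_standard_curve
#' @exportS3Method generics::glance
glance.qpcr_curve <- function(x, ...) {
  tibble::tibble(
    target = x$target,
    slope = x$slope,
    intercept = x$intercept,
    r_squared = x$r_squared,
    efficiency_pct = x$efficiency,
    cq_limit = x$cq_limit,
    copies_limit = x$copies_limit,
    n_standards = x$n_standards
  )
}

#' Copies per reaction from measured Cq values
#'
#' Inverts the standard curve, `copies = 10^((Cq - intercept)/slope)`, for
#' each technical replicate and averages. Replicates beyond the assay's Cq
#' limit are below the limit of quantification and are reported as 0 with a
#' `below_loq` flag (the convention for presence detected but not
#' quantifiable); samples with no Cq at all are non-detects (`NA`).
#'
#' @param cq Numeric vector of technical-replicate Cq values (NA =
#'   no amplification).
#' @param curve A `qpcr_curve`.
#' @return One-row tibble: `copies_per_rxn`, `below_loq`, `non_detect`,
#'   `n_replicates`.
#' @export
quantify_qpcr <- function(cq, curve) {
  stopifnot(inherits(curve, "qpcr_curve"))
  cq <- cq[!is.na(cq)]
  if (length(cq) == 0) {
    return(tibble::tibble(copies_per_rxn = NA_real_, below_loq = FALSE,
                          non_detect = TRUE, n_replicates = 0L))
  }
  mean_cq <- mean(cq)
  if (mean_cq > curve$cq_limit) {
    return(tibble::tibble(copies_per_rxn = 0, below_loq = TRUE,
                          non_detect = FALSE, n_replicates = length(cq)))
  }
  copies <- mean(10^((cq - curve$intercept) / curve$slope))
  tibble::tibble(copies_per_rxn = copies, below_loq = FALSE,
                 non_detect = FALSE, n_replicates = length(cq))
}

#' Convert copies per reaction to copies per liter of seawater
#'
#' Chains the dilution and volume bookkeeping back to the water sample:
#' `copies_rxn x dilution x (elution/template) / volume_filtered`. With the
#' common protocol (1/5 dilution, 5 uL of template from a 100 uL elution) a
#' reaction samples 1/100 of the filter's DNA.
#'
#' @param copies_per_rxn Copies in one reaction.
#' @param dilution_factor Template dilution applied before loading
#'   (default 5, i.e. 1/5 dilution).
#' @param template_volume_ul Diluted template loaded per reaction (uL,
#'   default 5).
#' @param elution_volume_ul DNA elution volume (uL, default 100 — a nominal
#'   extraction-kit value; supply the true value when known).
#' @param volume_filtered_l Seawater volume filtered (L).
#' @return Copies per liter; vectorised.
#' @examples
#' copies_per_liter(100, 5, 5, 100, 2)  # 5000
#' @export
copies_per_liter <- function(copies_per_rxn, dilution_factor = 5,
                             template_volume_ul = 5,
                             elution_volume_ul = 100,
                             volume_filtered_l) {
  check_number(dilution_factor, "dilution_factor", lower = 1e-12)
  check_number(template_volume_ul, "template_volume_ul", lower = 1e-12)
  check_number(elution_volume_ul, "elution_volume_ul", lower = 1e-12)
  check_number(volume_filtered_l, "volume_filtered_l", lower = 1e-12)
  copies_per_rxn * dilution_factor *
    (elution_volume_ul / template_volume_ul) / volume_filtered_l
}

#' Quantify all samples on a qPCR plate
#'
#' Table-level driver: fits one standard curve per target from the rows
#' carrying `known_copies`, then quantifies every sample row (grouping
#' technical replicates by sample and target) and converts to copies per
#' liter.
#'
#' @param plate Tibble with columns `sample_id`, `target`, `cq`,
#'   `known_copies` (NA for samples), `dilution_factor`,
#'   `template_volume_ul`, `elution_volume_ul`, `volume_filtered_l`.
#' @param cq_limit Assay quantification limit (cycles).
#' @return List with `curves` (tibble of per-target curve diagnostics) and
#'   `quantities` (tibble of per-sample copies per reaction and per liter,
#'   with flags).
#' @export
quantify_plate <- function(plate, cq_limit = 35.5) {
  needed <- c("sample_id", "target", "cq", "known_copies",
              "dilution_factor", "template_volume_ul", "elution_volume_ul",
              "volume_filtered_l")
  missing_cols <- setdiff(needed, names(plate))
  if (length(missing_cols) > 0) {
    abort(sprintf("plate table lacks columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  curves <- plate |>
    dplyr::filter(!is.na(.data$known_copies)) |>
    dplyr::group_by(.data$target) |>
    dplyr::group_map(function(rows, key) {
      fit_standard_curve(
        tibble::tibble(copies = rows$known_copies, cq = rows$cq),
        target = key$target, cq_limit = cq_limit
      )
    })
  names(curves) <- vapply(curves, function(cv) cv$target, character(1))

  quantities <- plate |>
    dplyr::filter(is.na(.data$known_copies)) |>
    dplyr::group_by(.data$sample_id, .data$target,
                    .data$dilution_factor, .data$template_volume_ul,
                    .data$elution_volume_ul, .data$volume_filtered_l) |>
    dplyr::group_modify(function(rows, key) {
      quantify_qpcr(rows$cq, curves[[key$target]])
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      copies_per_l = dplyr::if_else(
        .data$non_detect, NA_real_,
        copies_per_liter(.data$copies_per_rxn, .data$dilution_factor,
                         .data$template_volume_ul, .data$elution_volume_ul,
                         .data$volume_filtered_l))
    )
  list(
    curves = purrr::map_dfr(curves, glance),
    quantities = quantities,
    curve_objects = curves
  )
}
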