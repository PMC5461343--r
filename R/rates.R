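#' Particulate nitrogen concentration from a filter
#'
#' Converts the mass of particulate nitrogen (PN) retained on a filter to a
#' volumetric concentration, flagging filters below the elemental-analyzer
#' detection limit of 15 ug N per filter.
#'
#' @param mass_ug_n PN mass on the filter (ug N).
#' @param volume_l Volume of seawater filtered (L).
#' @param detection_limit_ug Per-filter detection limit (ug N), default 15.
#' @return Tibble with `pn_nmol_l` (nmol N L-1) and `below_detection`.
#' @examples
#' pn_concentration(15, 4)       # 267.7 nmol L-1 at the detection boundary
#' pn_concentration(14.0067, 1)  # exactly 1000 nmol L-1
#' @export
pn_concentration <- function(mass_ug_n, volume_l,
                             detection_limit_ug = PN_DETECTION_LIMIT_UG) {
  check_number(mass_ug_n, "mass_ug_n", lower = 0)
  check_number(volume_l, "volume_l", lower = 1e-12)
  tibble::tibble(
    pn_nmol_l = mass_ug_n / MOLAR_MASS_N * 1000 / volume_l,
    below_detection = mass_ug_n < detection_limit_ug
  )
}

#' Volumetric N2-fixation rate by isotope mass balance
#'
#' Final-point mass balance for a 15N2 tracer incubation: the fraction of the
#' final particulate nitrogen pool built from the enriched N2 source over the
#' incubation is
#' \deqn{rate = \frac{A_{PNf} - A_{PN0}}{A_{N2} - A_{PN0}} \cdot
#'       \frac{PN_f}{\Delta t}}
#' where `a_pn0` and `a_pnf` are the 15N atom% of PN at the start and end,
#' `a_n2` is the (dissolution-corrected) atom% of the dissolved N2 source,
#' `pn_f` the final PN concentration and `dt` the incubation duration.
#' Negative rates — possible under measurement noise — are clamped to zero
#' and flagged.
#'
#' @param a_pn0 Initial PN 15N content (atom%); natural abundance if no T0
#'   filter was measured.
#' @param a_pnf Final PN 15N content (atom%).
#' @param a_n2 Source-pool enrichment A_N2 (atom%), from
#'   [corrected_enrichment()].
#' @param pn_f Final PN concentration (nmol N L-1).
#' @param dt Incubation duration (d).
#' @return Tibble with `rate_nmol_n_l_d` and `clamped_negative`.
#' @examples
#' n2_fixation_rate(0.3663, 1.0324, 5.93, 568, 1)  # ~68 nmol N L-1 d-1
#' @export
n2_fixation_rate <- function(a_pn0, a_pnf, a_n2, pn_f, dt) {
  check_number(a_pn0, "a_pn0", lower = 0, upper = 100)
  check_number(a_pnf, "a_pnf", lower = 0, upper = 100)
  check_number(a_n2, "a_n2", lower = 0, upper = 100)
  check_number(pn_f, "pn_f", lower = 0)
  check_number(dt, "dt", lower = 1e-12)
  if (any(a_n2 <= a_pn0)) {
    abort(paste("source enrichment `a_n2` must exceed the initial PN atom%",
                "`a_pn0`; the tracer signal is uninterpretable otherwise"))
  }
  raw <- (a_pnf - a_pn0) / (a_n2 - a_pn0) * pn_f / dt
  tibble::tibble(
    rate_nmol_n_l_d = pmax(raw, 0),
    clamped_negative = raw < 0
  )
}

#' Compute per-replicate rates from an incubation filter table
#'
#' Table-level driver for [n2_fixation_rate()]. The incubation table holds
#' one row per filter with a `timepoint` of `"T0"` (natural-abundance filter)
#' or `"Tf"` (post-incubation filter). For each station the T0 atom% (mean
#' across T0 filters) sets `a_pn0`; stations with no T0 filter fall back to
#' the natural-abundance constant 0.3663 atom%.
#'
#' @param incubations Tibble with columns `station`, `replicate`, `timepoint`,
#'   `volume_filtered_l`, `pn_mass_ug`, `atom_pct_15n`, `duration_d`
#'   (Tf rows).
#' @param a_n2 Source enrichment (atom%), scalar or one value per station
#'   (named by station).
#' @param natural_abundance Fallback initial atom% when a station lacks T0
#'   filters.
#' @return Tibble, one row per Tf filter: station, replicate, pn
#'   concentration, rate and flags.
#' @export
calculate_rates <- function(incubations, a_n2,
                            natural_abundance = NAT_ABUND_15N) {
  needed <- c("station", "replicate", "timepoint", "volume_filtered_l",
              "pn_mass_ug", "atom_pct_15n")
  missing_cols <- setdiff(needed, names(incubations))
  if (length(missing_cols) > 0) {
    abort(sprintf("incubation table lacks columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  t0 <- incubations |>
    dplyr::filter(.data$timepoint == "T0") |>
    dplyr::group_by(.data$station) |>
    dplyr::summarise(a_pn0 = mean(.data$atom_pct_15n), .groups = "drop")

  a_n2_tbl <- if (length(a_n2) == 1 && is.null(names(a_n2))) {
    tibble::tibble(station = unique(incubations$station), a_n2 = a_n2)
  } else {
    tibble::tibble(station = names(a_n2), a_n2 = unname(a_n2))
  }

  tf <- incubations |>
    dplyr::select(-dplyr::any_of(c("a_n2", "a_pn0"))) |>
    dplyr::filter(.data$timepoint == "Tf") |>
    dplyr::left_join(t0, by = "station") |>
    dplyr::left_join(a_n2_tbl, by = "station") |>
    dplyr::mutate(a_pn0 = dplyr::coalesce(.data$a_pn0, .env$natural_abundance))
  pn <- pn_concentration(tf$pn_mass_ug, tf$volume_filtered_l)
  rate <- n2_fixation_rate(tf$a_pn0, tf$atom_pct_15n, tf$a_n2,
                           pn$pn_nmol_l, tf$duration_d)
  tibble::tibble(
    station = tf$station,
    replicate = tf$replicate,
    pn_nmol_l = pn$pn_nmol_l,
    below_detection = pn$below_detection,
    rate_nmol_n_l_d = rate$rate_nmol_n_l_d,
    clamped_negative = rate$clamped_negative
  )
}

#' Summarise replicate rates per site
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of the
#' replicate rates at each station. A site is flagged below detection only
#' when all of its replicates are; single-replicate sites report `NA` sd.
#' Rates from the bubble method are reported as qualitative throughout
#' because the incomplete dissolution correction is itself approximate.
#'
#' @param rates Tibble from [calculate_rates()] (needs `station`,
#'   `rate_nmol_n_l_d`, optionally `below_detection`).
#' @return Tibble: one row per station with `mean_rate`, `sd_rate`,
#'   `n_replicates`, `below_detection`, `qualitative`.
#' @export
site_summary <- function(rates) {
  if (nrow(rates) == 0) abort("no replicate rates to summarise")
  if (!"below_detection" %in% names(rates)) {
    rates$below_detection <- FALSE
  }
  rates |>
    dplyr::group_by(.data$station) |>
    dplyr::summarise(
      mean_rate = mean(.data$rate_nmol_n_l_d),
      sd_rate = if (dplyr::n() > 1) sd(.data$rate_nmol_n_l_d) else NA_real_,
      n_replicates = dplyr::n(),
      below_detection = all(.data$below_detection),
      .groups = "drop"
    ) |>
    dplyr::mutate(qualitative = TRUE)
}

#' @keywords internal
round_release <- function(x) {
  ifelse(abs(x) < 1, round(x, 1), signif_away(x, 2))
}

#' Diazotroph-derived dissolved nitrogen release range
#'
#' Field measurements on mixed diazotroph communities place dissolved N
#' release at 16-30% of gross community N2 fixation. Applying those fractions
#' to the low and high ends of the measured rate range bounds the potential
#' release flux. Endpoints are rounded to the conventional reporting
#' precision (1 decimal below 1, 2 significant figures above).
#'
#' @param rate_low,rate_high Rate extremes (nmol N L-1 d-1).
#' @param f_low,f_high Release fractions (default 0.16 and 0.30).
#' @return Tibble with raw and rounded `low`/`high` endpoints
#'   (nmol N L-1 d-1).
#' @examples
#' ddn_release(2.6, 68)  # 0.4 to 20 nmol N L-1 d-1
#' @export
ddn_release <- function(rate_low, rate_high, f_low = 0.16, f_high = 0.30) {
  check_number(rate_low, "rate_low", lower = 0)
  check_number(rate_high, "rate_high", lower = 0)
  check_number(f_low, "f_low", lower = 0, upper = 1)
  check_number(f_high, "f_high", lower = 0, upper = 1)
  if (f_low > f_high) abort("`f_low` must not exceed `f_high`")
  low <- rate_low * f_low
  high <- rate_high * f_high
  tibble::tibble(
    low_raw = low, high_raw = high,
    low = round_release(low), high = round_release(high)
  )
}

#' Carbon fixation supportable by an N2-fixation rate
#'
#' Converts a nitrogen-fixation rate to the phytoplankton carbon fixation it
#' could stoichiometrically support at a given molar C:N ratio (Redfield
#' 106:16 by default): 1 nmol N supports `c_to_n` nmol C, i.e.
#' `c_to_n x 12.011e-3` ug C.
#'
#' @param rate_nmol_n_l_d N2-fixation rate (nmol N L-1 d-1).
#' @param c_to_n Molar C:N ratio (default 106/16).
#' @return Supportable carbon fixation (ug C L-1 d-1); vectorised.
#' @examples
#' c_fixation_support(50)  # ~3.98 ug C L-1 d-1
#' @export
c_fixation_support <- function(rate_nmol_n_l_d, c_to_n = REDFIELD_C_TO_N) {
  check_number(rate_nmol_n_l_d, "rate_nmol_n_l_d", lower = 0)
  check_number(c_to_n, "c_to_n", lower = 1e-12)
  rate_nmol_n_l_d * c_to_n * MOLAR_MASS_C * 1e-3
}
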