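#' Configuration for the forward simulator
#'
#' Collects every knob of the synthetic-data generator. Defaults describe a
#' winter Great Barrier Reef-style survey: 10 stations spanning ~12-23 degS,
#' SST falling linearly with southern latitude over 21.2-26.3 degC, salinity
#' 35.2 +/- 0.2 PSU, and oligotrophic nutrients drawn from moment-matched
#' lognormals (NH3 0.06 +/- 0.06, SiO4 0.85 +/- 0.47, PO4 0.02 +/- 0.01,
#' NOx 0.04 +/- 0.03 uM — printed sds of the order of the means imply
#' right-skewed, non-negative distributions, hence lognormal rather than
#' truncated normal). True fixation rates span 3-68 nmol N L-1 d-1 with six
#' of ten sites at or above 30 and three at or below 9.
#'
#' @param n_stations Number of stations (>= 2).
#' @param seed Base seed; each simulate_* step uses a fixed offset from it so
#'   the sub-streams are independent.
#' @param sst_range SST at the northern and southern ends of the transect
#'   (degC): SST is linear in latitude plus noise.
#' @param sst_noise_sd SST noise around the latitude trend (degC).
#' @param salinity_mean_sd Mean and sd of salinity (PSU).
#' @param nutrient_lognormal_params Named list of `c(mean, sd)` (uM) per
#'   nutrient; lognormal parameters are derived by method of moments.
#' @param nutrient_detection_limit Analyzer detection limit (uM): draws below
#'   it are emitted as 0.00 and flagged.
#' @param chla_mean_sd Chlorophyll a mean and sd (ug L-1).
#' @param n_otus Number of OTUs in the simulated community.
#' @param dirichlet_concentration Overdispersion of the Dirichlet-multinomial
#'   count model (larger = closer to multinomial); default 50, moderate
#'   overdispersion typical of amplicon data.
#' @param read_depth_range Per-sample read depth drawn uniformly from this
#'   range.
#' @param trichodesmium_dinsensitivity Logistic slope of the
#'   Trichodesmium-group expected proportion on standardized (PO4 + DIN);
#'   positive = cyanobacterial dominance where nutrients are low.
#' @param trichodesmium_baseline Logistic intercept: the Trichodesmium-group
#'   expected proportion at average nutrient levels.
#' @param heterotroph_split Fraction of the non-cyanobacterial community in
#'   the gamma-proteobacterial (vs delta-proteobacterial) group.
#' @param qpcr_true_efficiency True amplification efficiency in (0.5, 1.1].
#' @param qpcr_intercept True Cq at a single copy per reaction (cycles).
#' @param qpcr_cq_noise_sd Cq measurement noise (cycles).
#' @param isotope_noise_sd Mass-spectrometer atom% noise (atom%).
#' @param true_rates True per-station fixation rates (nmol N L-1 d-1),
#'   recycled to `n_stations`.
#' @param pn0_nmol_l Background particulate-N concentration (nmol N L-1).
#' @param incubation_duration_d Incubation length (d).
#' @param tracer [tracer_setup()] used in incubation forward runs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_stations = 10,
                       seed = 1,
                       sst_range = c(26.3, 21.2),
                       sst_noise_sd = 0.4,
                       salinity_mean_sd = c(35.2, 0.2),
                       nutrient_lognormal_params = list(
                         nh3 = c(0.06, 0.06),
                         sio4 = c(0.85, 0.47),
                         po4 = c(0.02, 0.01),
                         nox = c(0.04, 0.03)
                       ),
                       nutrient_detection_limit = 0.01,
                       chla_mean_sd = c(0.34, 0.15),
                       n_otus = 92,
                       dirichlet_concentration = 50,
                       read_depth_range = c(1394, 7939),
                       trichodesmium_dinsensitivity = 2,
                       trichodesmium_baseline = 0.4,
                       heterotroph_split = 0.6,
                       qpcr_true_efficiency = 0.966,
                       qpcr_intercept = 38,
                       qpcr_cq_noise_sd = 0.15,
                       isotope_noise_sd = 0.02,
                       true_rates = c(3, 5, 9, 30, 35, 40, 45, 50, 55, 68),
                       pn0_nmol_l = 500,
                       incubation_duration_d = 1,
                       tracer = tracer_setup()) {
  check_number(n_stations, "n_stations", lower = 2)
  check_number(seed, "seed")
  stopifnot(length(sst_range) == 2, length(salinity_mean_sd) == 2)
  check_number(sst_noise_sd, "sst_noise_sd", lower = 0)
  check_number(salinity_mean_sd[2], "salinity sd", lower = 0)
  for (nut in names(nutrient_lognormal_params)) {
    p <- nutrient_lognormal_params[[nut]]
    if (length(p) != 2 || p[1] <= 0 || p[2] < 0) {
      abort(sprintf("nutrient `%s` needs c(mean > 0, sd >= 0)", nut))
    }
  }
  check_number(n_otus, "n_otus", lower = 3)
  check_number(dirichlet_concentration, "dirichlet_concentration",
               lower = 1e-6)
  check_number(read_depth_range, "read_depth_range", lower = 1)
  if (qpcr_true_efficiency <= 0.5 || qpcr_true_efficiency > 1.1) {
    abort("`qpcr_true_efficiency` must lie in (0.5, 1.1]")
  }
  check_number(qpcr_cq_noise_sd, "qpcr_cq_noise_sd", lower = 0)
  check_number(isotope_noise_sd, "isotope_noise_sd", lower = 0)
  check_number(true_rates, "true_rates", lower = 0)
  stopifnot(inherits(tracer, "tracer_setup"))
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation config: %d stations, %d OTUs, seed %d\n",
              x$n_stations, x$n_otus, x$seed))
  cat(sprintf("  nutrient forcing slope %.2f; qPCR efficiency %.3f\n",
              x$trichodesmium_dinsensitivity, x$qpcr_true_efficiency))
  invisible(x)
}

#' Read a simulator configuration from a YAML file
#'
#' Every key of [sim_config()] can be overridden; `tracer` may be given as a
#' nested mapping of [tracer_setup()] arguments.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$tracer)) {
    raw$tracer <- do.call(tracer_setup, raw$tracer)
  }
  if (!is.null(raw$nutrient_lognormal_params)) {
    raw$nutrient_lognormal_params <-
      lapply(raw$nutrient_lognormal_params, as.numeric)
  }
  do.call(sim_config, raw)
}

# lognormal parameters matched to a target mean/sd by method of moments
#' @keywords internal
lognormal_params <- function(mean, sd) {
  if (sd == 0) return(c(mu = log(mean), sigma = 0))
  sigma2 <- log(1 + (sd / mean)^2)
  c(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}
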