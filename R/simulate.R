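# Seed offsets giving each simulator stage its own reproducible sub-stream.
SEED_OFFSET <- c(stations = 0L, community = 1000L, incubation = 2000L,
                 qpcr = 3000L)

#' Simulate a station environment table
#'
#' Draws one row per station: latitude/longitude along a reef transect, SST
#' linear in latitude plus noise, Gaussian salinity, lognormal chlorophyll a
#' and flow-cytometry counts, and nutrient concentrations from lognormal
#' distributions moment-matched to the configured mean/sd. Nutrient draws
#' below the detection limit are emitted as 0.00 with a companion
#' `<nutrient>_below_detection` flag, as an autoanalyzer would report them.
#'
#' @param config A [sim_config()].
#' @return List with `stations` (tibble) and `truth` (list holding the exact
#'   per-station SST trend and configured nutrient moments).
#' @examples
#' sim <- simulate_stations(sim_config(seed = 7))
#' sim$stations
#' @export
simulate_stations <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_stations
  withr::with_seed(config$seed + SEED_OFFSET[["stations"]], {
    lat <- seq(12.13, 23.01, length.out = n)
    lon <- seq(143.5, 150.5, length.out = n) + rnorm(n, 0, 0.3)
    slope <- (config$sst_range[2] - config$sst_range[1]) /
      (max(lat) - min(lat))
    sst_trend <- config$sst_range[1] + slope * (lat - min(lat))
    sst <- sst_trend + rnorm(n, 0, config$sst_noise_sd)
    salinity <- rnorm(n, config$salinity_mean_sd[1],
                      config$salinity_mean_sd[2])
    chla_p <- lognormal_params(config$chla_mean_sd[1], config$chla_mean_sd[2])
    chla <- rlnorm(n, chla_p["mu"], chla_p["sigma"])

    nutrients <- purrr::imap(config$nutrient_lognormal_params, function(ms, nm) {
      p <- lognormal_params(ms[1], ms[2])
      pmax(rlnorm(n, p["mu"], p["sigma"]), 0)
    })

    counts <- list(
      total_bacteria = rlnorm(n, log(8e5), 0.5),
      synechococcus = rlnorm(n, log(8e4), 0.7),
      prochlorococcus = rlnorm(n, log(7e4), 0.6),
      picoeukaryotes = rlnorm(n, log(6e3), 0.6)
    )

    stations <- tibble::tibble(
      station = sprintf("ST%02d", seq_len(n)),
      latitude_s = lat,
      longitude_e = lon,
      bottom_depth_m = round(rlnorm(n, log(50), 0.8)),
      sst_c = sst,
      salinity_psu = salinity,
      chla_ug_l = chla
    )
    for (nm in names(nutrients)) {
      x <- nutrients[[nm]]
      bdl <- x < config$nutrient_detection_limit
      stations[[paste0(nm, "_um")]] <- ifelse(bdl, 0, x)
      stations[[paste0(nm, "_below_detection")]] <- bdl
    }
    for (nm in names(counts)) {
      stations[[paste0(nm, "_cells_ml")]] <- round(counts[[nm]])
    }
    list(
      stations = stations,
      truth = list(
        sst_trend = sst_trend,
        nutrient_moments = config$nutrient_lognormal_params,
        true_rates = rep_len(config$true_rates, n)
      )
    )
  })
}

#' Dissolved inorganic nitrogen
#'
#' DIN is the sum of the oxidised (NOx = nitrate + nitrite) and reduced
#' (ammonia) inorganic pools.
#'
#' @param stations Station tibble with `nox_um` and `nh3_um`.
#' @return Input with a `din_um` column appended.
#' @export
add_din <- function(stations) {
  if (!all(c("nox_um", "nh3_um") %in% names(stations))) {
    abort("station table needs `nox_um` and `nh3_um` columns")
  }
  dplyr::mutate(stations, din_um = .data$nox_um + .data$nh3_um)
}

#' @keywords internal
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Expected group proportions under the nutrient-forcing model
#'
#' The Trichodesmium-dominated cyanobacterial group (nifH Cluster IB) has
#' expected proportion `plogis(qlogis(baseline) - slope * z)` where `z` is
#' the standardized (PO4 + DIN) concentration, so cyanobacterial dominance
#' falls as inorganic nutrients rise; the heterotrophic gamma- (Cluster IG)
#' and delta-proteobacterial (Cluster III) groups share the remainder in a
#' fixed ratio and therefore increase with nutrients.
#'
#' @param stations Station tibble (needs `po4_um`, `nox_um`, `nh3_um`).
#' @param config A [sim_config()].
#' @return Tibble: station, z_nutrient and the three expected group
#'   proportions.
#' @export
expected_group_proportions <- function(stations, config = sim_config()) {
  if (!"po4_um" %in% names(stations)) {
    abort("station table needs a `po4_um` column")
  }
  stations <- add_din(stations)
  s <- stations$po4_um + stations$din_um
  z <- if (sd(s) > 0) (s - mean(s)) / sd(s) else rep(0, length(s))
  p_cyano <- plogis(qlogis(config$trichodesmium_baseline) -
                      config$trichodesmium_dinsensitivity * z)
  tibble::tibble(
    station = stations$station,
    z_nutrient = z,
    cluster_ib = p_cyano,
    cluster_ig = (1 - p_cyano) * config$heterotroph_split,
    cluster_iii = (1 - p_cyano) * (1 - config$heterotroph_split)
  )
}

#' Simulate a nifH OTU count table with taxonomy
#'
#' Forward model: expected group proportions from
#' [expected_group_proportions()], fixed within-group OTU weights drawn once
#' per run, per-sample composition from a Dirichlet with concentration
#' `dirichlet_concentration x expected proportions`, counts multinomial at a
#' uniformly drawn read depth. The taxonomy sidecar labels each OTU with its
#' nifH cluster, a nearest cultivated taxon and an amino-acid identity.
#'
#' @param stations Station tibble from [simulate_stations()].
#' @param config A [sim_config()].
#' @return List with `otu_table` (wide tibble), `taxonomy` (tibble) and
#'   `truth` (expected group and OTU proportions, read depths).
#' @export
simulate_community <- function(stations, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  groups <- expected_group_proportions(stations, config)
  n <- nrow(stations)
  n_otus <- config$n_otus
  withr::with_seed(config$seed + SEED_OFFSET[["community"]], {
    n_ib <- max(1, round(n_otus * 0.35))
    n_ig <- max(1, round(n_otus * 0.38))
    n_iii <- max(1, n_otus - n_ib - n_ig)
    cluster <- rep(c("IB", "IG", "III"), c(n_ib, n_ig, n_iii))
    taxon_pool <- list(
      IB = c("Trichodesmium erythraeum", "Leptolyngbya sp.",
             "Candidatus Atelocyanobacterium thalassa"),
      IG = c("Pseudomonas stutzeri", "Gamma A clade bacterium"),
      III = c("Desulfovibrio sp.", "Desulfobacter sp.")
    )
    taxonomy <- tibble::tibble(
      otu_id = sprintf("OTU%04d", seq_len(n_ib + n_ig + n_iii)),
      cluster = cluster,
      nearest_taxon = vapply(cluster, function(cl) {
        sample(taxon_pool[[cl]], 1)
      }, character(1)),
      aai_percent = round(runif(length(cluster), 85, 100), 1)
    )
    # geometric-flavoured within-group weights, fixed for the whole run
    weights <- lapply(c(IB = n_ib, IG = n_ig, III = n_iii), function(k) {
      rdirichlet1(rep(0.7, k) * 0.7^(seq_len(k) - 1) * k)
    })

    expected <- matrix(0, nrow = n, ncol = length(cluster),
                       dimnames = list(stations$station, taxonomy$otu_id))
    for (i in seq_len(n)) {
      expected[i, cluster == "IB"] <- groups$cluster_ib[i] * weights$IB
      expected[i, cluster == "IG"] <- groups$cluster_ig[i] * weights$IG
      expected[i, cluster == "III"] <- groups$cluster_iii[i] * weights$III
    }

    depths <- sample(seq(config$read_depth_range[1],
                         config$read_depth_range[2]), n, replace = TRUE)
    counts <- matrix(0L, nrow = n, ncol = ncol(expected),
                     dimnames = dimnames(expected))
    for (i in seq_len(n)) {
      p <- rdirichlet1(config$dirichlet_concentration * expected[i, ])
      counts[i, ] <- as.integer(rmultinom(1, depths[i], p))
    }

    list(
      otu_table = otu_tibble(counts),
      taxonomy = taxonomy,
      truth = list(
        group_proportions = groups,
        otu_proportions = expected,
        read_depths = depths,
        sensitivity_slope = config$trichodesmium_dinsensitivity
      )
    )
  })
}

#' Forward-simulate one tracer incubation
#'
#' Inverse of the isotope mass balance used by [n2_fixation_rate()]: given a
#' true fixation rate, the final PN pool is `pn0 + rate x dt` and its atom%
#' is the source-weighted mixture
#' `(pn0 x A0 + rate x dt x A_N2) / PN_f`, where `A_N2` is the
#' dissolution-corrected source enrichment from the tracer chain. Gaussian
#' noise of sd `noise_sd` is added to both measured atom% values; with
#' `noise_sd = 0` the pair inverts exactly under the rate calculator.
#'
#' @param true_rate True fixation rate (nmol N L-1 d-1).
#' @param setup A [tracer_setup()].
#' @param pn0 Initial PN concentration (nmol N L-1).
#' @param dt Incubation duration (d).
#' @param noise_sd Atom% measurement noise (atom%).
#' @param temperature_c,salinity Incubation water conditions used for the
#'   enrichment calculation.
#' @param volume_filtered_l Volume filtered per timepoint (L).
#' @return Tibble with a T0 and a Tf row (`timepoint`, `volume_filtered_l`,
#'   `pn_mass_ug`, `pn_nmol_l`, `atom_pct_15n`, `duration_d`, `a_n2`).
#' @examples
#' simulate_incubation(68, pn0 = 500, dt = 1, noise_sd = 0)
#' @export
simulate_incubation <- function(true_rate, setup = tracer_setup(),
                                pn0 = 500, dt = 1, noise_sd = 0,
                                temperature_c = 24.6, salinity = 35.2,
                                volume_filtered_l = 4) {
  check_number(true_rate, "true_rate", lower = 0)
  check_number(pn0, "pn0", lower = 1e-12)
  check_number(dt, "dt", lower = 1e-12)
  check_number(noise_sd, "noise_sd", lower = 0)
  a0 <- setup$natural_abundance
  a_n2 <- corrected_enrichment(
    theoretical_enrichment(setup, temperature_c, salinity), setup)
  pn_f <- pn0 + true_rate * dt
  a_pn_f <- (pn0 * a0 + true_rate * dt * a_n2) / pn_f
  atom <- c(a0, a_pn_f) + rnorm(2, 0, noise_sd)
  pn <- c(pn0, pn_f)
  tibble::tibble(
    timepoint = c("T0", "Tf"),
    volume_filtered_l = volume_filtered_l,
    pn_mass_ug = pn * MOLAR_MASS_N / 1000 * volume_filtered_l,
    pn_nmol_l = pn,
    atom_pct_15n = atom,
    duration_d = c(NA_real_, dt),
    a_n2 = a_n2
  )
}

#' Simulate a qPCR plate
#'
#' Log-linear response model: `Cq = intercept + slope x log10(copies per
#' reaction)` with `slope = -1/log10(1 + efficiency)`, plus Gaussian cycle
#' noise. The plate carries a 10^2-10^7 standard series (triplicate) and the
#' requested samples; samples whose expected Cq exceeds the cycle ceiling
#' (40) come back as non-detects (`NA` Cq), and zero-copy samples never
#' amplify.
#'
#' @param true_copies_per_l Named (by sample) vector of true gene copies per
#'   liter.
#' @param efficiency True amplification efficiency in (0, 1.1].
#' @param intercept True Cq at one copy per reaction (cycles).
#' @param noise_sd Cq noise (cycles).
#' @param target Assay label.
#' @param dilution_factor,template_volume_ul,elution_volume_ul,volume_filtered_l
#'   Volume bookkeeping, as in [copies_per_liter()].
#' @param max_cycles Thermocycler cycle ceiling (default 40).
#' @return Plate tibble in the layout [quantify_plate()] consumes.
#' @export
simulate_qpcr <- function(true_copies_per_l, efficiency = 0.966,
                          intercept = 38, noise_sd = 0, target = "assay",
                          dilution_factor = 5, template_volume_ul = 5,
                          elution_volume_ul = 100, volume_filtered_l = 2,
                          max_cycles = 40) {
  if (efficiency <= 0 || efficiency > 1.1) {
    abort("`efficiency` must lie in (0, 1.1]")
  }
  check_number(true_copies_per_l, "true_copies_per_l", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  slope <- -1 / log10(1 + efficiency)
  ids <- names(true_copies_per_l)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_along(true_copies_per_l))

  std_copies <- rep(10^(2:7), each = 3)
  standards <- tibble::tibble(
    sample_id = sprintf("STD_%d", seq_along(std_copies)),
    target = target,
    cq = intercept + slope * log10(std_copies) +
      rnorm(length(std_copies), 0, noise_sd),
    known_copies = std_copies,
    dilution_factor = dilution_factor,
    template_volume_ul = template_volume_ul,
    elution_volume_ul = elution_volume_ul,
    volume_filtered_l = NA_real_
  )

  copies_rxn <- true_copies_per_l * volume_filtered_l /
    (dilution_factor * elution_volume_ul / template_volume_ul)
  cq <- ifelse(
    copies_rxn > 0,
    intercept + slope * log10(copies_rxn) +
      rnorm(length(copies_rxn), 0, noise_sd),
    NA_real_
  )
  cq[!is.na(cq) & cq > max_cycles] <- NA_real_
  samples <- tibble::tibble(
    sample_id = ids,
    target = target,
    cq = cq,
    known_copies = NA_real_,
    dilution_factor = dilution_factor,
    template_volume_ul = template_volume_ul,
    elution_volume_ul = elution_volume_ul,
    volume_filtered_l = volume_filtered_l
  )
  dplyr::bind_rows(standards, samples)
}
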