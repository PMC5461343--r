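#' @keywords internal
format_fixed <- function(df, digits = 6) {
  df[] <- lapply(df, function(col) {
    if (is.double(col)) signif(col, digits) else col
  })
  df
}

#' @keywords internal
write_stage_csv <- function(df, path, digits = 6) {
  write.csv(format_fixed(as.data.frame(df), digits), path, row.names = FALSE,
            quote = FALSE, eol = "\n")
  path
}

#' Run the full synthetic-survey pipeline
#'
#' Executes every stage in order on simulated data with known ground truth:
#' station environment, tracer enrichment, triplicate incubations and
#' fixation rates, OTU community hygiene and diversity, distance-based
#' linear modeling of community-nutrient relationships, and qPCR absolute
#' quantification of the two focal taxa. All stage outputs are written as
#' fixed-precision CSV/TSV under `out_dir` together with a JSON run manifest
#' (config snapshot, seed, file digests, collected warnings) and a
#' full-precision JSON sidecar of the key result tables.
#'
#' @param config A [sim_config()], or a path to a YAML file for
#'   [read_sim_config()].
#' @param out_dir Output directory (created if missing).
#' @param seed Optional override of the config seed.
#' @param n_perm Permutations for the distLM stage (default 9999).
#' @param quiet Suppress the stage log.
#' @return Invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, seed = NULL,
                         n_perm = 9999, quiet = FALSE) {
  if (is.character(config)) config <- read_sim_config(config)
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  warnings_log <- character()
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  say("stage 1/6: stations")
  st <- simulate_stations(config)
  stations <- add_din(st$stations)

  say("stage 2/6: tracer enrichment")
  enr <- enrichment_summary(config$tracer, stations$sst_c,
                            stations$salinity_psu) |>
    dplyr::mutate(station = stations$station, .before = 1)

  say("stage 3/6: incubations and rates")
  incubations <- withr::with_seed(
    config$seed + SEED_OFFSET[["incubation"]],
    purrr::map2_dfr(st$truth$true_rates, stations$station, function(r, id) {
      purrr::map_dfr(1:3, function(rep) {
        simulate_incubation(
          r, config$tracer, pn0 = config$pn0_nmol_l,
          dt = config$incubation_duration_d,
          noise_sd = config$isotope_noise_sd,
          temperature_c = stations$sst_c[stations$station == id],
          salinity = stations$salinity_psu[stations$station == id]
        ) |>
          dplyr::mutate(station = id, replicate = rep, .before = 1)
      })
    })
  )
  a_n2 <- setNames(enr$corrected_atom_pct, enr$station)
  rates <- collect(calculate_rates(incubations, a_n2))
  sites <- site_summary(rates)
  ddn <- ddn_release(min(sites$mean_rate), max(sites$mean_rate))
  carbon <- c_fixation_support(range(sites$mean_rate))

  say("stage 4/6: community analytics")
  com <- simulate_community(stations, config)
  filtered <- collect(filter_low_abundance(com$otu_table))
  rarefied <- collect(rarefy_counts(filtered, depth = "auto",
                                    seed = config$seed))
  diversity <- shannon_diversity(rarefied)
  rel <- relative_abundance(rarefied, other_threshold = 0.01)
  bc <- bray_curtis(rarefied, transform = "sqrt")

  say("stage 5/6: distance-based linear model (%d permutations)", n_perm)
  env_cols <- c("po4_um", "din_um", "sst_c", "salinity_psu", "sio4_um",
                "chla_ug_l")
  env_std <- standardize_log(
    stations[stations$station %in% rownames(bc), c("station", env_cols)])
  dlm <- distlm(bc, env_std, n_perm = n_perm, seed = config$seed)

  say("stage 6/6: qPCR quantification")
  groups <- com$truth$group_proportions
  qpcr_plate <- withr::with_seed(config$seed + SEED_OFFSET[["qpcr"]], {
    tricho <- simulate_qpcr(
      setNames(groups$cluster_ib * 5e5, groups$station),
      efficiency = config$qpcr_true_efficiency,
      intercept = config$qpcr_intercept,
      noise_sd = config$qpcr_cq_noise_sd, target = "trichodesmium")
    gammaa <- simulate_qpcr(
      setNames(groups$cluster_ig * 2e3, groups$station),
      efficiency = config$qpcr_true_efficiency,
      intercept = config$qpcr_intercept,
      noise_sd = config$qpcr_cq_noise_sd, target = "gamma_a")
    dplyr::bind_rows(tricho, gammaa)
  })
  quant <- quantify_plate(qpcr_plate)

  say("writing outputs to %s", out_dir)
  paths <- c(
    stations = write_stage_csv(stations, file.path(out_dir, "stations.csv")),
    enrichment = write_stage_csv(enr, file.path(out_dir, "enrichment.csv")),
    incubations = write_stage_csv(incubations,
                                  file.path(out_dir, "incubations.csv")),
    rates = write_stage_csv(rates, file.path(out_dir, "rates.csv")),
    site_rates = write_stage_csv(sites, file.path(out_dir, "site_rates.csv")),
    diversity = write_stage_csv(diversity,
                                file.path(out_dir, "diversity.csv")),
    distlm = write_stage_csv(tidy(dlm), file.path(out_dir, "distlm.csv")),
    qpcr_plate = write_stage_csv(qpcr_plate, file.path(out_dir, "qpcr.csv")),
    qpcr_quant = write_stage_csv(quant$quantities,
                                 file.path(out_dir, "qpcr_quant.csv")),
    qpcr_curves = write_stage_csv(quant$curves,
                                  file.path(out_dir, "qpcr_curves.csv"))
  )
  otu_path <- file.path(out_dir, "otu_table.tsv")
  otu_out <- as.data.frame(t(otu_matrix(com$otu_table)))
  utils::write.table(cbind(otu_id = rownames(otu_out), otu_out), otu_path,
                     sep = "\t", row.names = FALSE, quote = FALSE, eol = "\n")
  tax_path <- file.path(out_dir, "taxonomy.tsv")
  utils::write.table(as.data.frame(com$taxonomy), tax_path, sep = "\t",
                     row.names = FALSE, quote = FALSE, eol = "\n")
  paths <- c(paths, otu_table = otu_path, taxonomy = tax_path)

  jsonlite::write_json(
    list(site_rates = sites, ddn_release = ddn,
         carbon_support_ug_c_l_d = carbon, distlm = tidy(dlm),
         qpcr = quant$quantities, diversity = diversity),
    file.path(out_dir, "full_precision.json"),
    auto_unbox = TRUE, digits = NA, na = "null"
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("diazoflux")),
    seed = config$seed,
    n_perm = n_perm,
    config = config[setdiff(names(config), "tracer")],
    tracer = unclass(config$tracer),
    files = as.list(tools::md5sum(unname(paths))),
    warnings = warnings_log
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  if (!quiet) {
    message(sprintf(
      "summary: %d stations | mean rate %.1f +/- %.1f nmol N L-1 d-1 | DDN %.3g-%.3g | %d OTUs after filtering | %d distLM predictor(s) p < 0.05",
      nrow(stations), mean(sites$mean_rate), sd(sites$mean_rate),
      ddn$low, ddn$high, ncol(filtered) - 1,
      sum(tidy(dlm)$p_value < 0.05)))
  }
  invisible(list(
    config = config, stations = stations, enrichment = enr,
    incubations = incubations, rates = rates, site_rates = sites,
    ddn_release = ddn, carbon_support = carbon, community = com,
    filtered = filtered, rarefied = rarefied, diversity = diversity,
    relative_abundance = rel, bray_curtis = bc, distlm = dlm,
    qpcr_plate = qpcr_plate, qpcr = quant, manifest = manifest,
    paths = paths
  ))
}

#' Validate pipeline input tables
#'
#' Schema and plausibility checks over the four tabular inputs: required
#' columns, physical ranges (salinity 0-42 PSU, atom% 0-100, non-negative
#' volumes and counts) and sample-id cross-references between tables.
#' Nothing is thrown: the report lists every failure with its table and
#' context.
#'
#' @param stations,incubations,otu_table,qpcr Input tibbles; any may be
#'   `NULL` to skip its checks.
#' @return Tibble with columns `table`, `check`, `ok`, `detail`.
#' @export
validate_tables <- function(stations = NULL, incubations = NULL,
                            otu_table = NULL, qpcr = NULL) {
  report <- list()
  add <- function(tbl, check, ok, detail = "") {
    report[[length(report) + 1]] <<-
      tibble::tibble(table = tbl, check = check, ok = ok, detail = detail)
  }
  need <- function(df, cols, tbl) {
    miss <- setdiff(cols, names(df))
    add(tbl, "required columns", length(miss) == 0,
        if (length(miss)) paste("missing:", paste(miss, collapse = ", "))
        else "")
    length(miss) == 0
  }
  if (!is.null(stations)) {
    if (need(stations, c("station", "sst_c", "salinity_psu", "po4_um",
                         "nox_um", "nh3_um", "sio4_um"), "stations")) {
      bad_sal <- stations$salinity_psu < 0 | stations$salinity_psu > 42
      add("stations", "salinity in [0, 42] PSU", !any(bad_sal),
          if (any(bad_sal)) sprintf("%d row(s) out of range", sum(bad_sal))
          else "")
      bad_sst <- stations$sst_c < -2 | stations$sst_c > 40
      add("stations", "SST in [-2, 40] degC", !any(bad_sst),
          if (any(bad_sst)) sprintf("%d row(s) out of range", sum(bad_sst))
          else "")
      nut_cols <- intersect(c("po4_um", "nox_um", "nh3_um", "sio4_um"),
                            names(stations))
      bad_nut <- vapply(nut_cols, function(cc) any(stations[[cc]] < 0), TRUE)
      add("stations", "nutrients non-negative", !any(bad_nut),
          if (any(bad_nut)) paste(nut_cols[bad_nut], collapse = ", ") else "")
    }
  }
  if (!is.null(incubations)) {
    if (need(incubations, c("station", "replicate", "timepoint",
                            "volume_filtered_l", "pn_mass_ug",
                            "atom_pct_15n"), "incubations")) {
      bad_at <- incubations$atom_pct_15n <= 0 | incubations$atom_pct_15n >= 100
      add("incubations", "atom% in (0, 100)", !any(bad_at),
          if (any(bad_at)) sprintf("%d row(s) out of range", sum(bad_at))
          else "")
      bad_tp <- !incubations$timepoint %in% c("T0", "Tf")
      add("incubations", "timepoint is T0 or Tf", !any(bad_tp),
          if (any(bad_tp)) sprintf("%d bad row(s)", sum(bad_tp)) else "")
      add("incubations", "volumes positive",
          all(incubations$volume_filtered_l > 0), "")
      if (!is.null(stations)) {
        orphans <- setdiff(incubations$station, stations$station)
        add("incubations", "stations cross-reference", length(orphans) == 0,
            if (length(orphans)) paste("unknown:",
                                       paste(orphans, collapse = ", "))
            else "")
      }
    }
  }
  if (!is.null(otu_table)) {
    if (need(otu_table, "sample_id", "otu_table")) {
      m <- try(otu_matrix(otu_table), silent = TRUE)
      add("otu_table", "integer non-negative counts", !inherits(m, "try-error"),
          if (inherits(m, "try-error")) "non-integer or negative counts"
          else "")
      if (!is.null(stations) && !inherits(m, "try-error")) {
        orphans <- setdiff(rownames(m), stations$station)
        add("otu_table", "stations cross-reference", length(orphans) == 0,
            if (length(orphans)) paste("unknown:",
                                       paste(orphans, collapse = ", "))
            else "")
      }
    }
  }
  if (!is.null(qpcr)) {
    if (need(qpcr, c("sample_id", "target", "cq", "known_copies"), "qpcr")) {
      bad_cq <- !is.na(qpcr$cq) & qpcr$cq <= 0
      add("qpcr", "Cq positive or non-detect", !any(bad_cq),
          if (any(bad_cq)) sprintf("%d bad row(s)", sum(bad_cq)) else "")
      std <- qpcr[!is.na(qpcr$known_copies), ]
      add("qpcr", "standards present", nrow(std) > 0, "")
    }
  }
  dplyr::bind_rows(report)
}
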