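#' Describe the tracer geometry of a 15N2 bubble incubation
#'
#' Bundles the injection volume, isotopic purity, bottle volume and the
#' dissolution-correction convention of a bubble-method incubation. The
#' defaults describe the common field protocol: 3 mL of 98 atom% 15N2 gas
#' injected into a 4 L bottle, with the effective enrichment taken as 75% of
#' the theoretical complete-dissolution value because an injected bubble does
#' not fully equilibrate over a ~24 h incubation.
#'
#' @param injection_volume_ml Volume of 15N2 gas injected (mL).
#' @param tracer_purity Isotopic purity of the tracer (atom% 15N).
#' @param bottle_volume_l Incubation bottle volume (L).
#' @param correction_factor Fraction of the theoretical enrichment actually
#'   realised (dimensionless, in (0, 1]).
#' @param gas_molar_volume One of `"STP_0C"` (22,414 mL mol-1) or `"lab_25C"`
#'   (24,465 mL mol-1): the convention used to convert the injected gas
#'   volume to moles.
#' @param natural_abundance Natural 15N abundance (atom%), default 0.3663.
#' @param density_kg_l Seawater density used to convert the per-kg N2
#'   solubility to a per-bottle inventory (kg L-1).
#' @return A list of class `tracer_setup`.
#' @examples
#' tracer_setup()
#' tracer_setup(gas_molar_volume = "lab_25C")
#' @export
tracer_setup <- function(injection_volume_ml = 3,
                         tracer_purity = 98,
                         bottle_volume_l = 4,
                         correction_factor = 0.75,
                         gas_molar_volume = c("STP_0C", "lab_25C"),
                         natural_abundance = NAT_ABUND_15N,
                         density_kg_l = 1.0235) {
  gas_molar_volume <- match.arg(gas_molar_volume)
  check_number(injection_volume_ml, "injection_volume_ml", lower = 0)
  check_number(tracer_purity, "tracer_purity", lower = 1e-12, upper = 100)
  check_number(bottle_volume_l, "bottle_volume_l", lower = 1e-12)
  check_number(correction_factor, "correction_factor", lower = 1e-12, upper = 1)
  check_number(natural_abundance, "natural_abundance", lower = 0, upper = 100)
  check_number(density_kg_l, "density_kg_l", lower = 0.9, upper = 1.1)
  structure(
    list(
      injection_volume_ml = injection_volume_ml,
      tracer_purity = tracer_purity,
      bottle_volume_l = bottle_volume_l,
      correction_factor = correction_factor,
      gas_molar_volume = gas_molar_volume,
      natural_abundance = natural_abundance,
      density_kg_l = density_kg_l
    ),
    class = "tracer_setup"
  )
}

#' @export
print.tracer_setup <- function(x, ...) {
  cat("15N2 bubble tracer setup\n")
  cat(sprintf("  injection: %.3g mL at %.4g atom%% 15N\n",
              x$injection_volume_ml, x$tracer_purity))
  cat(sprintf("  bottle: %.3g L; dissolution correction: %.3g\n",
              x$bottle_volume_l, x$correction_factor))
  cat(sprintf("  gas molar volume: %s; natural abundance: %.4f atom%%\n",
              x$gas_molar_volume, x$natural_abundance))
  invisible(x)
}

#' @keywords internal
gas_molar_volume_ml <- function(setup) {
  switch(setup$gas_molar_volume,
         STP_0C = STP_MOLAR_VOLUME_ML,
         lab_25C = LAB_MOLAR_VOLUME_ML)
}

#' Equilibrium N2 solubility in seawater
#'
#' Hamme & Emerson (2004) fit for dissolved N2 at equilibrium with a moist
#' atmosphere: a polynomial in scaled temperature
#' `Ts = ln((298.15 - T)/(273.15 + T))` with a linear salinity interaction,
#' returning micromoles of N2 per kilogram of seawater. The fit reproduces its
#' published check value (500.885 umol kg-1 at 10 degC, S = 35).
#'
#' @param temperature_c Water temperature (degC), in \[-2, 40\].
#' @param salinity Practical salinity (PSU), in \[0, 42\].
#' @return Equilibrium N2 concentration (umol kg-1); vectorised.
#' @examples
#' n2_solubility(10, 35)    # 500.885
#' n2_solubility(24.6, 35.2)
#' @export
n2_solubility <- function(temperature_c, salinity) {
  check_number(temperature_c, "temperature_c", lower = -2, upper = 40)
  check_number(salinity, "salinity", lower = 0, upper = 42)
  ts <- log((298.15 - temperature_c) / (273.15 + temperature_c))
  exp(6.42931 + 2.92704 * ts + 4.32531 * ts^2 + 4.69149 * ts^3 +
        salinity * (-7.44129e-3 - 8.02566e-3 * ts - 1.46775e-2 * ts^2))
}

#' Moles of tracer gas injected
#'
#' Converts the injected gas volume to moles of N2 under the setup's molar
#' volume convention, and to moles of N atoms (twice the N2 moles). Under the
#' STP convention a 3 mL injection is 1.34e-4 mol N2, i.e. 2.7e-4 mol N atoms.
#'
#' @param setup A [tracer_setup()].
#' @return One-row tibble with `mol_n2` and `mol_n_atoms`.
#' @examples
#' injected_tracer_moles(tracer_setup())
#' @export
injected_tracer_moles <- function(setup = tracer_setup()) {
  stopifnot(inherits(setup, "tracer_setup"))
  mol_n2 <- setup$injection_volume_ml / gas_molar_volume_ml(setup)
  tibble::tibble(mol_n2 = mol_n2, mol_n_atoms = 2 * mol_n2)
}

#' Theoretical 15N enrichment assuming complete bubble dissolution
#'
#' Two-pool isotope mixing between the injected tracer and the ambient
#' dissolved N2 inventory of the bottle:
#' \deqn{A_{theo} = \frac{A_{tracer} n_{tracer} + A_0 n_{ambient}}
#'                       {n_{tracer} + n_{ambient}}}
#' with all pools in moles of N2 (the factor 2 for atoms cancels),
#' `n_ambient = solubility x density x bottle volume` and `A_0` the natural
#' abundance. The result necessarily lies between natural abundance and the
#' tracer purity.
#'
#' @inheritParams n2_solubility
#' @param setup A [tracer_setup()].
#' @return Theoretical enrichment (atom% 15N).
#' @examples
#' theoretical_enrichment(tracer_setup(), 24.6, 35.2)  # ~7.9 atom%
#' @export
theoretical_enrichment <- function(setup = tracer_setup(),
                                   temperature_c, salinity) {
  stopifnot(inherits(setup, "tracer_setup"))
  sol <- n2_solubility(temperature_c, salinity)  # umol kg-1
  n_ambient <- sol * 1e-6 * setup$density_kg_l * setup$bottle_volume_l
  n_tracer <- setup$injection_volume_ml / gas_molar_volume_ml(setup)
  (setup$tracer_purity * n_tracer + setup$natural_abundance * n_ambient) /
    (n_tracer + n_ambient)
}

#' Dissolution-corrected 15N enrichment
#'
#' Scales the theoretical complete-dissolution enrichment by the setup's
#' correction factor (default 0.75) to account for incomplete bubble
#' equilibration. The result is the `a_n2` source term used by
#' [n2_fixation_rate()].
#'
#' @param theoretical Theoretical enrichment (atom%).
#' @param setup A [tracer_setup()].
#' @return Corrected enrichment A_N2 (atom%).
#' @export
corrected_enrichment <- function(theoretical, setup = tracer_setup()) {
  stopifnot(inherits(setup, "tracer_setup"))
  check_number(theoretical, "theoretical", lower = 0, upper = 100)
  if (any(theoretical < setup$natural_abundance)) {
    abort("theoretical enrichment below natural abundance is uninterpretable")
  }
  out <- setup$correction_factor * theoretical
  if (any(out < setup$natural_abundance)) {
    warn(paste("corrected enrichment fell below natural abundance;",
               "the tracer signal is unresolvable"))
  }
  out
}

#' 15N contamination bound for a tracer addition
#'
#' Commercial 15N2 stocks can carry dissolved 15N-labelled nitrate, ammonium
#' and nitrous oxide. Given the per-mole contaminant loads of a stock, the
#' worst-case 15N added alongside a trace addition is the product of the
#' tracer moles and the summed contaminant concentrations.
#'
#' @param trace_moles Moles of tracer the contaminant load is referenced to.
#' @param conc_no3,conc_nh4,conc_n2o Contaminant concentrations
#'   (umol of 15N per mole of tracer). Defaults are the reported mean loads
#'   for affected commercial stocks: 298, 818 and 61 umol/mole.
#' @return One-row tibble: `mol_15n` (mol of contaminant 15N),
#'   `ratio_to_trace` (dimensionless), and `mol_15n_2sf` rounded half away
#'   from zero to 2 significant figures for reporting.
#' @examples
#' contamination_15n(2.7e-4)
#' @export
contamination_15n <- function(trace_moles,
                              conc_no3 = 298, conc_nh4 = 818, conc_n2o = 61) {
  check_number(trace_moles, "trace_moles", lower = 0)
  check_number(conc_no3, "conc_no3", lower = 0)
  check_number(conc_nh4, "conc_nh4", lower = 0)
  check_number(conc_n2o, "conc_n2o", lower = 0)
  total <- (conc_no3 + conc_nh4 + conc_n2o) * 1e-6
  mol <- trace_moles * total
  tibble::tibble(
    mol_15n = mol,
    ratio_to_trace = total,
    mol_15n_2sf = signif_away(mol, 2)
  )
}

#' Full enrichment summary for one incubation condition
#'
#' Convenience wrapper running the whole tracer chain — dissolved N2
#' inventory, injected moles, theoretical and corrected enrichment, and the
#' 15N contamination bound — for one temperature/salinity condition.
#'
#' @inheritParams theoretical_enrichment
#' @return One-row tibble with columns `temperature_c`, `salinity`,
#'   `dissolved_n2_umol_kg`, `ambient_mol_n2`, `tracer_mol_n2`,
#'   `tracer_mol_n_atoms`, `theoretical_atom_pct`, `corrected_atom_pct`,
#'   `contamination_mol_15n`.
#' @examples
#' enrichment_summary(tracer_setup(), 24.6, 35.2)
#' @export
enrichment_summary <- function(setup = tracer_setup(),
                               temperature_c, salinity) {
  sol <- n2_solubility(temperature_c, salinity)
  tr <- injected_tracer_moles(setup)
  theo <- theoretical_enrichment(setup, temperature_c, salinity)
  corr <- corrected_enrichment(theo, setup)
  contam <- contamination_15n(tr$mol_n_atoms)
  tibble::tibble(
    temperature_c = temperature_c,
    salinity = salinity,
    dissolved_n2_umol_kg = sol,
    ambient_mol_n2 = sol * 1e-6 * setup$density_kg_l * setup$bottle_volume_l,
    tracer_mol_n2 = tr$mol_n2,
    tracer_mol_n_atoms = tr$mol_n_atoms,
    theoretical_atom_pct = theo,
    corrected_atom_pct = corr,
    contamination_mol_15n = contam$mol_15n
  )
}
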