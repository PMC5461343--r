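---
title: "Methods: tracer mass balance, community analytics and the forward simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracer mass balance, community analytics and the forward simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diazoflux)
```

`diazoflux` implements the quantitative core of a pelagic nitrogen-fixation
survey built around the ¹⁵N₂ "bubble" tracer method and *nifH* amplicon
community profiling. This vignette explains the models behind each stage,
the parameters that matter and their defaults, the design choices that were
genuinely open, and what the synthetic-data tests do — and do not — show
about real field data.

## The ¹⁵N₂ bubble tracer model

An incubation bottle of volume $V_b$ (default 4 L) is filled bubble-free
with seawater and injected with a small volume $V_g$ (default 3 mL) of
¹⁵N₂ gas of isotopic purity $A_{tracer}$ (default 98 atom%). If the bubble
dissolved completely, the dissolved N₂ pool would be a two-source mixture
of the tracer and the ambient dissolved N₂ inventory:

$$A_{theo} = \frac{A_{tracer}\, n_{tracer} + A_0\, n_{ambient}}
                  {n_{tracer} + n_{ambient}},$$

with $A_0 = 0.3663$ atom% the natural ¹⁵N abundance. The moles of tracer
are $n_{tracer} = V_g / V_m$; the molar volume convention defaults to STP
(0 °C, 22 414 mL mol⁻¹), with an ideal-gas 25 °C option
(24 465 mL mol⁻¹). Under the STP convention a 3 mL injection is
$1.34\times10^{-4}$ mol N₂, i.e. $2.7\times10^{-4}$ mol of N atoms; both
quantities are reported because published trace-addition figures are
sometimes labelled as one while computed as the other, and the package
deliberately reproduces the atoms-at-STP arithmetic while exposing both.

The ambient inventory $n_{ambient}$ comes from the Hamme & Emerson (2004)
N₂ solubility fit — the de facto standard for N₂ in seawater — as a
polynomial in scaled temperature with a linear salinity interaction,
validated in the test suite against the publication's check value
(500.885 µmol kg⁻¹ at 10 °C, S = 35). Solubility in µmol kg⁻¹ is converted
to a per-bottle inventory with a fixed default density of 1.0235 kg L⁻¹;
a full equation of state is deliberately out of scope, and the density is
configurable where that approximation matters. At warm reef conditions
(24.6 °C, 35.2 PSU) the theoretical enrichment computes to ≈7.9 atom%.

A freshly injected bubble does not fully equilibrate over a ~24 h
incubation, so the enrichment actually experienced by the cells is lower
than $A_{theo}$. The package applies a fixed dissolution-correction factor
(default 0.75) to give the working source enrichment $A_{N_2}$. This is the
standard first-order correction for the bubble method; it is the reason all
derived rates are labelled *qualitative* in the outputs. Kinetic,
time-resolved bubble equilibration is a non-goal.

Commercial ¹⁵N₂ stocks can carry ¹⁵N-labelled nitrate, ammonium and N₂O.
`contamination_15n()` multiplies the trace addition by per-mole contaminant
loads (defaults 298, 818 and 61 µmol per mole of tracer, the reported mean
loads for affected stocks) to bound the worst-case contaminant ¹⁵N; for the
default setup the bound is $3.2\times10^{-7}$ mol, three orders of
magnitude below the tracer itself. Whether those loads are referenced to
moles of ¹⁵N₂ or of ¹⁵N atoms is not standardised in the literature; the
package follows the convention of multiplying by the trace addition as
reported (atoms), which is the conservative reading.

## Isotope mass balance for fixation rates

Rates use the final-point Montoya-style mass balance on the particulate
nitrogen (PN) pool:

$$\text{rate} = \frac{A_{PN_f} - A_{PN_0}}{A_{N_2} - A_{PN_0}}
                \cdot \frac{PN_f}{\Delta t}.$$

$A_{PN_0}$ defaults to the station's measured T0 filter when present and to
the natural-abundance constant otherwise. $PN_f$ (not a T0/Tf average) is
used, consistent with the final-point formulation. Filters below the
elemental-analyzer detection limit of 15 µg N are flagged; a site is flagged
only if all its replicates are. Negative computed rates — which arise only
through measurement noise — are clamped to zero and flagged rather than
propagated, because a negative fixation rate is not physically
interpretable and field reports list non-negative qualitative rates.

Two derived quantities are exposed. `ddn_release()` applies release
fractions (defaults 16–30%, the reported range for mixed natural
communities) to the rate extremes; endpoints are rounded to 1 decimal below
1 and two significant figures above, the conventional reporting precision.
`c_fixation_support()` converts a nitrogen rate to the carbon fixation it
could support at a molar C:N of 106:16 (Redfield), so 50 nmol N L⁻¹ d⁻¹
supports ≈4 µg C L⁻¹ d⁻¹. Note that published carbon-support ranges do not
always back-convert exactly to the printed rate extremes at Redfield
stoichiometry; the function is therefore exposed with explicit arguments
rather than hard-wired endpoints.

## Community analytics

OTU tables are wide tibbles (one `sample_id` column plus integer OTU
counts). The hygiene order is filter-then-rarefy: OTUs with fewer than 50
reads summed over all samples are removed first (strict `<`, so a total of
exactly 50 survives), then every sample is subsampled without replacement
to a common depth, by default the minimum sample sum. The order matters —
the suite demonstrates non-commutativity on a constructed table — and
filter-first is the convention this workflow follows. Rarefaction is a
single multivariate-hypergeometric draw per sample (no averaging over
repeated draws), with the seed recorded on the output; the expectation
$\mathbb{E}[c'_{ij}] = \text{depth}\cdot c_{ij}/C_i$ is verified in the
suite over 10⁴ draws.

Shannon diversity uses the natural log by default (the PRIMER convention;
base 2 available), recorded in the output metadata because H′ values are
not comparable across bases. "Square-root transformed Bray–Curtis
dissimilarity" is read as Bray–Curtis computed **on square-root transformed
abundances** — the standard PRIMER workflow — not as the square root of the
dissimilarities; `transform = "none"` and `"fourth_root"` are also
available, and the transform is tagged on the matrix. Bray–Curtis,
Shannon and rarefaction delegate to `vegan` (`vegdist`, `diversity`,
`rrarefy`) behind the package's tabular interfaces.

## Distance-based linear modeling

Environmental predictors are log10-transformed and standardized to zero
mean and unit sd. Zeros (below-detection values reported as 0.00) receive a
pseudocount of half the column's minimum positive value, recorded in the
output metadata; columns without zeros are logged as-is. DIN is constructed
as NOₓ + NH₃ before transformation.

The test statistic is the McArdle–Anderson pseudo-F on the Gower-centered
matrix $G$ of the squared dissimilarities,
$F = \frac{\mathrm{tr}(HGH)/q}{\mathrm{tr}((I-H)G(I-H))/(n-q-1)}$ with $H$
the hat matrix of $[1, X]$. For marginal (single-predictor) tests the
statistic reduces to a quadratic form $u^\top G u$ in the standardized
predictor, which is how the permutation loop is computed; the general
hat-matrix form is exported as `pseudo_f()` and the two are cross-checked
in the suite, along with exact agreement with classical regression F in the
Euclidean case and with `vegan::adonis2` as an independent oracle.

Only marginal tests are implemented: the motivating analysis reports
marginal significance of individual nutrients, and sequential/AIC model
selection is a non-goal. Significance uses simultaneous row/column
permutation of $G$ (equivalent to permuting raw observations) with the
add-one estimator $p = (1 + \#\{F_\pi \ge F\})/(1 + n_{perm})$, which can
never return zero. The default is 9 999 permutations (PRIMER convention);
one shared permutation set serves all predictors so duplicated predictors
get identical p-values. Pearson screening of qPCR abundances against
environment uses the exact t-distribution p-value on $n-2$ df with
pairwise-complete observations.

## qPCR absolute quantification

The standard curve is ordinary least squares of Cq on log10 copies over a
10²–10⁷ standard series; efficiency is $(10^{-1/\text{slope}} - 1)\times
100$, so −3.3219 cycles per decade is exactly 100%. Samples are inverted
through the curve per technical replicate and averaged. Replicates whose
mean Cq exceeds the assay's quantification limit (default 35.5 cycles,
within the typical 35–36-of-40 window, equivalent to roughly 5–6 copies per
reaction) are *detected below LOQ* and reported as 0 with a flag — the
plotting convention for box plots with "no box"; samples with no
amplification at all are non-detects (`NA`). Copies per liter chain the
volume bookkeeping: `copies_rxn × dilution × (elution/template) /
volume_filtered`. The DNA elution volume is rarely printed in field
reports; it is a required input with a documented default of 100 µL
(nominal for common water DNA kits) and should be supplied when known.

## The forward simulator

The generator exists so that every downstream stage can be tested against
known ground truth. Its defaults describe the study conditions of a winter
tropical-reef survey:

* **Stations (n = 10).** Latitude spans ~12–23 °S; SST is linear in
  latitude from 26.3 to 21.2 °C plus 0.4 °C noise; salinity is
  N(35.2, 0.2²) PSU; chlorophyll a is lognormal with mean 0.34 and sd
  0.15 µg L⁻¹.
* **Nutrients.** NH₃ 0.06 ± 0.06, SiO₄ 0.85 ± 0.47, PO₄ 0.02 ± 0.01 and
  NOₓ 0.04 ± 0.03 µM, drawn from lognormals matched to those moments by
  method of moments. Lognormal (rather than truncated normal) because sds
  of the order of the means imply right skew on a non-negative support.
  Draws below the 0.01 µM analyzer detection limit are emitted as 0.00
  with a flag, as an autoanalyzer reports them.
* **Community (92 OTUs).** OTUs belong to three *nifH* groups — Cluster IB
  cyanobacteria (*Trichodesmium*-like), Cluster IG γ-proteobacteria and
  Cluster III δ-proteobacteria. The expected Cluster IB share is a
  decreasing logistic in standardized (PO₄ + DIN) with slope 2 and
  baseline 0.4 — a forcing strong enough to be detectable at n = 10, which
  is the regime the method is used in; heterotrophs share the remainder
  60:40. Within-group OTU weights are a geometric-flavoured Dirichlet draw
  fixed once per run. Counts are Dirichlet-multinomial with concentration
  50 (moderate amplicon-style overdispersion) at depths uniform on
  [1394, 7939].
* **Incubations.** The forward model is the exact inverse of the rate
  equation: $PN_f = PN_0 + r\,\Delta t$ and
  $A_{PN_f} = (PN_0 A_0 + r\,\Delta t\, A_{N_2})/PN_f$, with Gaussian
  atom% noise (default sd 0.02 atom%). True rates default to
  {3, 5, 9, 30, 35, 40, 45, 50, 55, 68} nmol N L⁻¹ d⁻¹ — extremes,
  mean (≈34) and the 6-high/3-low site split chosen to mirror the field
  regime the method targets. The replicate noise magnitude is a free
  parameter: field reports print per-site sds but not a generative noise
  model, so no calibration is claimed.
* **qPCR.** Cq = intercept + slope·log10(copies/rxn) with
  slope = −1/log10(1+E), true efficiency 0.966, intercept 38 cycles, Cq
  noise 0.15 cycles, 40-cycle ceiling.

Seeding: one base seed with fixed per-stage offsets (stations 0, community
1000, incubations 2000, qPCR 3000), so regenerating one stage does not
reshuffle the draws of another.

**What the simulator does not emulate.** Raw reads and their error models
(chimeras, homopolymer errors), primer bias, compositional artefacts of
PCR, spatial autocorrelation between stations, time-of-day effects on
fixation, and isotope dilution by DON release during the incubation. A
green suite therefore demonstrates that the *computational* chain is
correct and well-calibrated under its own assumptions — not that those
assumptions hold in any particular ocean.

## Numerical choices and degenerate inputs

* Reported 2-significant-figure values round half away from zero, matching
  how printed field numbers are rounded; internal computation is never
  rounded.
* `corrected_enrichment()` warns (rather than errors) if the corrected
  value falls below natural abundance; `n2_fixation_rate()` errors when
  $A_{N_2} \le A_{PN_0}$ because the mass balance is then uninterpretable.
* All-zero samples are errors for diversity and relative abundance;
  samples emptied by the OTU filter are kept but flagged.
* Constant predictor columns are rejected before standardization; with
  fewer than 4 samples the permutation test warns that it is weak.
* Pipeline CSVs are written at 6 significant digits so file digests are
  stable across platforms; a full-precision JSON sidecar carries the exact
  values.

## Problem sizes used by the shipped checks

The test suite and acceptance script run entirely on simulated data at
desk scale: surveys of 10 stations × 92 OTUs, 999–9 999 permutations per
distLM test, 500 null surveys for the type-I error check, 200 forced
surveys for power, 10⁴ replicate incubations for estimator bias and 10⁴
rarefaction draws for the hypergeometric check. These sizes give
Monte-Carlo error comfortably below the tolerances asserted while keeping
a full run in minutes on a single core.

## Known limitations

* The dissolution correction is a fixed scalar; true bubble equilibration
  depends on time, temperature and agitation, so rates are qualitative by
  construction.
* Marginal distLM tests do not control for correlated predictors; a
  predictor can be marginally significant purely through correlation with
  the true driver.
* The below-LOQ-as-zero qPCR convention biases means low at sites where a
  target hovers near its quantification limit; the flags are carried so
  users can treat such values as censored instead.
* Single-draw rarefaction adds sampling noise to diversity estimates;
  repeated-draw averaging would reduce it but would no longer match the
  single-table convention this workflow mirrors.
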