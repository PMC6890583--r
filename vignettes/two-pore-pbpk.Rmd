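---
title: "A whole-body two-pore PBPK model for therapeutic proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A whole-body two-pore PBPK model for therapeutic proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protpbpk)
```

## What the model does

`protpbpk` implements a mechanistic whole-body physiologically based
pharmacokinetic (PBPK) model for therapeutic proteins — cytokines, hormones,
albumin, fusion proteins and monoclonal antibodies — in an average human.
Its central claim is that a single drug property, the hydrodynamic radius
$R_s$, together with generic human physiology, is enough to predict how a
protein distributes between plasma and the interstitial fluid of each organ
and how fast it is absorbed after a subcutaneous (SC) injection. Plasma
clearance, the blood/plasma concentration ratio and the SC bioavailability
remain empirical inputs; nothing else is drug-specific.

Each of 13 tissues (adipose, bone, brain, gut, heart, kidney, liver, lung,
muscle, pancreas, skin, spleen, and the SC dosing site) is a pair of
well-mixed compartments, vascular and interstitial, joined by two exchange
routes:

* **convection** — fluid filters across the capillary wall at the tissue
  lymph flow $L_{org}$, carrying solute attenuated by the average vascular
  reflection coefficient $\sigma_{av}$, and returns to the venous blood
  through a common central-lymph compartment (lymph itself is
  non-restrictive, $\sigma_L = 0$);
* **diffusion** — solute crosses through two discrete populations of
  cylindrical endothelial pores (small and large), with
  permeability–surface-area products $PS_s, PS_l$ whose driving gradient is
  attenuated by the Péclet factor $Pe/(e^{Pe}-1)$ of each pathway.

The vascular balance of a generic tissue is

$$V_{v}\frac{dC_v}{dt} = Q\,C_{in} - (Q-L)C_v - L(1-\sigma_{av})C_v -
\left(PS_s\frac{Pe_s}{e^{Pe_s}-1} + PS_l\frac{Pe_l}{e^{Pe_l}-1}\right)(C_v - C_i)$$

with the matching interstitial balance receiving the filtered and diffused
solute and losing $L\,C_i$ to the lymph. Venous blood collects tissue
outflows and the total lymph return; the lung is perfused by the full
cardiac output from venous blood and feeds arterial blood; elimination acts
on arterial blood at rate $CL_p/BP$. The liver additionally receives the
venous outflows of gut, spleen and pancreas, so its vascular inflow is
hepatic artery plus portal drainage. The system is linear with constant
coefficients; the package assembles it once as a rate matrix
(`build_rate_matrix()`) and integrates it with `deSolve`.

## System physiology

`tissue_table()` ships the per-tissue volumes, vascular and
extracellular-water fractions, blood-flow and lymph-flow percentages, pore
radii and small/large pore number ratios; `build_physiology()` derives
vascular volume $V_v = V_{tot} f_{vasc}$, interstitial volume
$V_i = V_{tot} f_{EW} - V_v$, flows, and the venous/arterial blood volumes
(2/3 : 1/3 split of the blood not residing in tissue vascular spaces). The
reference individual weighs 80.7 kg with cardiac output 356 L/h and total
lymph flow 0.00386 L/h/kg.

Design choices where the source physiology left room:

* **Total blood volume** (5.760 L) is back-derived so the 2/3 : 1/3 split
  reproduces the tabulated venous (2.33 L) and arterial (1.165 L) volumes.
* **Liver flow convention.** The tissue table allocates 25.5% of cardiac
  output to the liver while the hepatic artery figure of 19% circulates in
  parts of the source literature. The default treats 25.5% as *total* liver
  perfusion, with the hepatic artery carrying the difference from the
  portal inflow (gut + spleen + pancreas, 18%); this is the only reading
  that keeps every arterial draw non-negative and closes the flow balance.
  The literal 19% hepatic-artery reading over-allocates cardiac output
  (draws sum to 104%) and is therefore rejected with an informative error
  when selected via `liver_flow_convention = "ha-19"`.
* **Bypass compartment.** Residual cardiac output (~7.5%) and lymph flow
  (~5%) are routed through a zero-volume vascular pass-through: solute goes
  from arterial to venous blood untouched while the bypass lymph joins the
  central lymph as solute-free filtrate. It exists purely to close the
  whole-body flow balance and has no interstitial exchange and no
  distribution volume.
* **SC-site interstitial volume.** The volume rule gives 2.865 mL from the
  5 mL site; the rounded literature estimate is 3 mL. The default keeps the
  single consistent volume rule, with
  `sc_site_vi_override_mL = 3.0` available to use the rounded value.
* **Spleen and bone** have no exiting lymph vessels and are modelled as
  well-stirred: $PS_s = PS_l = 0.1$ L/h with both Péclet factors pinned to
  1, so they equilibrate rapidly with plasma.

## Two-pore transport and the PS closure

For a solute of radius $R_s$ in a pore of radius $r$ (ratio
$\alpha = R_s/r$) the package uses the classical hindered-transport
polynomials: partition coefficient $\Phi = (1-\alpha)^2$, restricted
diffusion via the Renkin polynomial
$\Phi\,(1 - 2.104\alpha + 2.09\alpha^3 - 0.95\alpha^5)$, and osmotic
reflection coefficient $\sigma = 1 - \Phi(2-\Phi)(1-\alpha^2/3)$ (Curry
form), all clamped to $[0,1]$; a solute at least as large as the pore is
completely excluded ($\Phi = H = 0$, $\sigma = 1$). Fractional hydraulic
conductances follow Poiseuille $r^4$ weighting, and
$\sigma_{av} = \alpha_S\sigma_s + \alpha_L\sigma_l$.

Absolute $PS$ magnitudes are not identifiable from the published tissue
table, so the package closes them from the hydraulics: the total pore
conductance of a tissue is the one required to carry its lymph flow under a
single effective net filtration pressure $\Delta P_{net}$,
$L_{pS} = L_{org}/\Delta P_{net}$; the pore-area-to-diffusion-length ratio
of each pathway is $(A_0/\Delta x)_j = \alpha_j L_{pS}\, 8\eta / r_j^2$ and
$PS_j = (A_0/\Delta x)_j D_{free} H_j$ with $D_{free}$ from Stokes–Einstein
(310 K, water viscosity $6.913\times10^{-4}$ Pa s). The pathway fluid flux
in the Péclet number is $J_j = \alpha_j L_{org}$ — transcapillary
filtration equals lymph return at steady state. An optional isogravimetric
circular flux (large-pore filtration balanced by small-pore reabsorption)
can be switched on; it only perturbs the Péclet numbers and is off by
default because the mass balances drive net convection by lymph flow alone.

Two deliberate details of the closure:

* **Anchoring.** The conductance is anchored to the *standard* lymph flow.
  Pore area is anatomy: when the lymph-flow sensitivity analysis scales
  flows (or sets them to zero), the pores neither widen nor close. This
  also keeps the steady-state tissue ratios genuinely (if weakly) sensitive
  to lymph flow rather than exactly invariant by construction.
* **Choice of $\Delta P_{net}$.** The steady-state interstitial/plasma
  ratio of the liver for an albumin-sized probe ($R_s = 3.55$ nm, no
  clearance) is the published anchor value, 0.87. Under the Curry
  reflection form this ratio is bounded below by
  $1-\sigma_{av,liver} = 0.876$ (the vanishing-diffusion limit), so the
  anchor cannot be hit exactly by any pressure; the bound itself sits
  within the anchor's reported in-vivo range (0.78–1.00).
  `calibrate_filtration_pressure()` exposes the full ratio-vs-pressure
  surface. The default, fixed once and not refitted, is 1333 Pa (10 mmHg)
  — a physiologically sensible net filtration pressure that brings the
  liver ratio to 0.884 (within 1.6% of the anchor) while keeping diffusive
  exchange active for small proteins; pushing the pressure higher would
  creep another ~0.008 closer to the anchor at the cost of progressively
  switching diffusion off for every solute, which the model's treatment of
  small proteins cannot afford.

## The SC dosing site

The site is an ordinary tissue of the model (5 mL, skin-like pore geometry:
small pores 5 nm, large pores 20 nm, 500:1). Its lymph flow and
interstitial volume derive from imaging studies of radiolabelled IgG and
albumin depots: the depot is assumed spherical (`depot_volume()`, computed
on the unrounded radius), and because IgG is too large for the skin pores,
its fractional loss rate K equals lymph flow over depot volume
(`lymph_flow_from_k()`). Subject-weighted means across the studies
(`sc_weighted_means()`) give 3.25 mL, 0.110 %/min and 0.00226 mL/min; the
albumin study reports no K and enters the volume mean only — the one
weighting scheme that reproduces all three printed means simultaneously. A
separately circulating average IgG loss rate of 0.0009725 min⁻¹ is not
reproducible by any weighting of the study table and is therefore exposed
only as a recorded constant (`igg_fractional_loss_rate_per_min()`), never
as a computed output.

An SC dose enters as a bolus into the site's interstitium with initial
concentration $\text{dose}\times F / V_{i,sc}$; all other compartments
start at zero. The depot volume does not deplete, and no empirical lag time
is added.

## Simulation and numerical choices

* Stiff integration via `deSolve::lsoda`, relative tolerance $10^{-8}$,
  absolute $10^{-12}$ mg/L (configurable in `sim_config()`); linear or
  logarithmic output grids. Trajectories are checked non-negative to
  solver tolerance.
* Reported plasma concentration is venous blood over BP — clinical samples
  are venous, and the elimination term references plasma through
  $CL_p/BP$.
* Steady-state tissue ratios (`steady_state_ci_cp()`) come from the exact
  stationary space of the rate matrix (QR solve of the singular system plus
  a total-mass normalisation) rather than from long integration; the two
  agree to ~$10^{-12}$, and the per-tissue closed form
  $C_i/C_v = (L(1-\sigma_{av}) + PS_{eff})/(L + PS_{eff})$ matches the
  whole-system solve up to the small vascular–plasma gradients sustained by
  lymph filtration (order $L/Q \approx 10^{-3}$).
* Peak summaries (`pk_summary()`) refine the grid maximum by a quadratic
  through its neighbours, making Cmax/tmax stable under grid halving
  (<0.1% / <1%).
* Péclet factors use `expm1` and are continuously extended to 1 at 0 and 0
  at infinity, so closed pathways ($PS = 0$) never divide by zero.

## Observables

* `percent_remaining_sc()` references the bioavailable depot amount
  (dose × F), since only that fraction is placed in the depot; radiolabel
  comparisons reference the total dose and differ by the factor F.
* `percent_absorbed_via_lymph()` splits the *gross* efflux from the SC
  interstitium: lymph carries $L\,C_i$, pores carry $PS_{eff} C_i$. Both
  integrands share $C_i$, so the split equals $L/(L+PS_{eff})$ — bounded in
  [0, 100], independent of the horizon, non-decreasing in $R_s$, and
  exactly 100% once both SC pore radii are exceeded. A net-flux definition
  (subtracting recirculation back-flux, which is tracked separately in
  `sim$fluxes$influx`) was rejected: for a non-eliminated protein the
  equilibrium circulation makes the net pore flux drift negative linearly
  in time, so a net-based percentage exceeds 100 and depends on how long
  the system is left running.
* `fold_error_stats()` implements the prediction-accuracy bands (mean
  ratio, 0.80–1.25-fold and 2-fold counts, maximum fold deviation).

## Drug library, units, and the synthetic overlay

`protein_studies()` ships the 54-study SC validation table (12 proteins,
8–150 kDa) with each dose in its recorded unit. `build_drug_library()`
resolves per-kg doses against the 80.7 kg reference individual and per-m²
doses against a default body surface area of 1.9 m² (a representative
adult value; the source tables do not print one). Doses recorded in mIU or
percent-of-dose are deliberately *not* converted: the model is linear, so
simulating in the native activity unit yields concentrations in the
matching unit (mIU/L, % dose). `iu_to_mg()` applies the printed specific
activities (e.g. 4×10⁶ IU/mg, 160 000 IU/mg) where mass conversions are
wanted; where different factors are printed for different studies of the
same protein they are applied per-row without reconciliation.

The quantitative validation scenarios additionally need per-drug plasma
clearance and bioavailability. The package ships
`inst/extdata/drug_params_synthetic.tsv`, a *synthetic* overlay holding
literature-typical estimates for Etanercept (CL_p 0.072 L/h, F 0.58) and
IGF-1 (CL_p 1.40 L/h ≈ 0.29 mL/min/kg at 80.7 kg, F 1.0), both with
BP = 1 (the blood pool treated as plasma in the absence of red-cell
partitioning data). These are stand-ins assembled for this package, not a
published parameter table; proteins without overlay values load with
flagged placeholders and are excluded from quantitative validation.
`mw_to_rs()` (a log–log power law fitted to the library's eleven unique
MW–radius pairs) is a convenience only — a measured radius always takes
precedence.

## What the hypothetical panel does and does not show

The validation surfaces use `hypothetical_panel()`: non-eliminated
(CL_p = 0), fully bioavailable unit-dose proteins with radii 1–11 nm and
BP = 1. This emulates the tracer experiments behind the steady-state
lymph/plasma ratio compilations, where the measured lymph leaving a tissue
is used as a surrogate of its interstitial fluid. Passing the panel shows
that the size dependence of distribution and of the lymphatic absorption
share behaves correctly *within the model's assumptions*; it says nothing
about processes the model deliberately omits — FcRn-mediated transcytosis
and recycling, target-mediated disposition, nonlinear clearance,
charge/pI-dependent interstitial interactions, injection-site lag times,
depot geometry changes, or between-subject variability. Bioavailability is
an input, never a prediction. Observed clinical concentration profiles were
digitised from figures in the original work and are excluded here by
policy, so population-level accuracy statistics are exercised only against
the *published* per-study fold errors carried in the study table.

## Problem sizes used by the shipped tests

The test suite and acceptance script run entirely from code: steady states
are solved algebraically (29 states) and confirmed by integration to
$10^5$ h; SC scenarios use 150–2000 output points over horizons of 10 h to
30 000 h; the lymph-flow sensitivity sweep uses scales {0.1, 1, 10} on
logarithmic grids of 400–600 points. These sizes keep every check
deterministic and fast while spanning the dynamic range of the model
(depot turnover ~23 h; slowest tissue equilibration at 0.1× lymph flow
~10⁴ h).

## Known limitations

* The absolute PS closure rests on a single global filtration pressure;
  tissue-specific deviations surface as bias in the per-tissue ratios
  (brain, with its near-closed small pores, is most sensitive).
* The exact liver anchor of 0.87 is unattainable under the adopted
  reflection polynomial (floor 0.876); the shipped value is 0.884.
* Predicted absorption is known to run slightly fast for large proteins
  (no lag time, no FcRn), consistent with the general underprediction of
  tmax reported for models of this class.
* Dose–response is strictly linear; saturation phenomena
  (dose-dependent bioavailability, TMDD) are out of scope.

## A worked steady-state example

```{r steady-state}
phys <- build_physiology()
probe <- drug_properties("albumin-sized", Rs = 3.55, CL_p = 0, BP = 1, F = 1)
round(steady_state_ci_cp(probe, phys), 3)
```

```{r etanercept}
lib <- build_drug_library()
sim <- simulate_pbpk(lib[["Etanercept"]]$drug, dose_event("sc", 25), phys,
                     sim = sim_config(t_end = 500, n_points = 2000))
pk_summary(sim)
percent_absorbed_via_lymph(sim)
```
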