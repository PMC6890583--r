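Package: protpbpk
Title: Whole-Body Two-Pore PBPK Modelling of Therapeutic Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A mechanistic whole-body physiologically based pharmacokinetic
    (PBPK) model for therapeutic proteins in humans. Tissue distribution and
    the rate of subcutaneous absorption are predicted from protein
    hydrodynamic radius alone, using a two-pore description of transcapillary
    exchange (size-dependent convection and diffusion through small and large
    endothelial pores) coupled to whole-body lymph and blood circulation.
    Includes the packaged human system physiology, derivation of the
    subcutaneous dosing-site lymph flow and interstitial volume from
    radiolabelled IgG depot data, a stiff linear ODE simulator for
    intravenous and subcutaneous bolus dosing, steady-state
    interstitial-to-plasma concentration ratios, and post-processing into
    Cmax, tmax, fold-error and lymphatic-absorption summaries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
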