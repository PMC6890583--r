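# Shared model objects for the test suite. The physiology build is cheap but
# used everywhere; construct it once.
base_phys <- build_physiology()

# Tissue table with the lymph percentages rescaled to sum to 100, so that no
# residual lymph is routed through the bypass. Used by stationarity tests
# whose closed-form expectation assumes every lymph stream carries solute.
no_bypass_lymph_table <- function() {
  tab <- tissue_table()
  tab$pct_lymph <- tab$pct_lymph / sum(tab$pct_lymph) * 100
  tab
}

# Non-eliminated probe protein for distribution studies.
probe_drug <- function(rs, ...) {
  drug_properties(sprintf("probe_Rs_%g", rs), Rs = rs, CL_p = 0, BP = 1,
                  F = 1, ...)
}
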