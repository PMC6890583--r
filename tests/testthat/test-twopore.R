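test_that("molecular-weight power law recovers the tabulated radii", {
  expect_equal(mw_to_rs(67), 3.55, tolerance = 0.05)
  expect_equal(mw_to_rs(150), 5.08, tolerance = 0.05)
  mw <- seq(5, 200, by = 5)
  expect_true(all(diff(mw_to_rs(mw)) > 0))
  expect_error(mw_to_rs(-1), "positive")
})

test_that("Stokes-Einstein diffusion coefficient scales inversely with radius", {
  cfg <- two_pore_config()
  expect_equal(stokes_einstein_d(3.55, cfg), 9.26e-11, tolerance = 0.005)
  expect_equal(stokes_einstein_d(2, cfg) / stokes_einstein_d(4, cfg), 2,
               tolerance = 1e-12)
  expect_error(stokes_einstein_d(0), "positive")
})

test_that("pore hindrance factors cover the unhindered and excluded limits", {
  h0 <- pore_hindrance(0, 5)
  expect_equal(h0$phi, 1)
  expect_equal(h0$H_diff, 1)
  expect_equal(h0$sigma, 0)
  hx <- pore_hindrance(10, 9) # solute larger than the pore
  expect_equal(hx$sigma, 1)
  expect_equal(hx$H_diff, 0)
  expect_equal(hx$phi, 0)
  expect_equal(pore_hindrance(2.5, 5)$phi, 0.25)
})

test_that("fractional hydraulic conductances follow the r^4 weighting", {
  fc <- fractional_conductance(9, 33, 46)
  expect_equal(fc$alpha_L, 33^4 / (46 * 9^4 + 33^4), tolerance = 1e-12)
  expect_equal(fc$alpha_L, 0.797, tolerance = 1e-3)
  expect_equal(fc$alpha_S + fc$alpha_L, 1)
  # dominance limits
  expect_lt(fractional_conductance(9, 33, 1e12)$alpha_L, 1e-6)
  sym <- fractional_conductance(10, 10, 1)
  expect_equal(sym$alpha_S, 0.5)
  expect_equal(sym$alpha_L, 0.5)
})

test_that("Peclet attenuation factor matches its series limit and bounds", {
  expect_identical(peclet_factor(0), 1)
  expect_identical(peclet_factor(Inf), 0)
  expect_equal(peclet_factor(1), 1 / (exp(1) - 1), tolerance = 1e-12)
  # independent oracle: truncated exponential series for (e^x - 1)/x
  series_factor <- function(x) {
    terms <- vapply(0:60, function(k) x^k / factorial(k + 1), numeric(1))
    1 / sum(terms)
  }
  for (pe in c(1e-12, 1e-6, 1, 10)) {
    expect_equal(peclet_factor(pe), series_factor(pe), tolerance = 1e-9)
  }
  pe <- c(0.01, 0.1, 1, 5, 20)
  expect_true(all(diff(peclet_factor(pe)) < 0))
  expect_true(all(peclet_factor(pe) > 0 & peclet_factor(pe) <= 1))
})

test_that("well-stirred tissues get fixed PS and unit Peclet factors", {
  for (t in c("spleen", "bone")) {
    row <- base_phys$tissues[base_phys$tissues$tissue == t, ]
    tr <- tissue_transport(row, probe_drug(3.55))
    expect_equal(tr$PS_s, 0.1)
    expect_equal(tr$PS_l, 0.1)
    expect_equal(peclet_factor(tr$Pe_s), 1)
    expect_equal(peclet_factor(tr$Pe_l), 1)
  }
})

test_that("a pathway is shut completely once the solute exceeds its pore radius", {
  lung <- base_phys$tissues[base_phys$tissues$tissue == "lung", ]
  tr <- tissue_transport(lung, probe_drug(10)) # r_small = 9 nm
  expect_identical(tr$PS_s, 0)
  expect_equal(tr$sigma_s, 1)
  expect_gt(tr$PS_l, 0) # large pores (25 nm) stay open
})

test_that("transport parameters vary monotonically with solute size", {
  rs_grid <- c(0.25, 0.5, 1, 2, 3.55, 5, 7, 9, 11, 15, 25)
  trs <- lapply(rs_grid, function(rs) drug_transport(base_phys, probe_drug(rs)))
  for (k in seq_len(nrow(base_phys$tissues))) {
    sig <- vapply(trs, function(tr) tr$sigma_av[k], numeric(1))
    ps_s <- vapply(trs, function(tr) tr$PS_s[k], numeric(1))
    ps_l <- vapply(trs, function(tr) tr$PS_l[k], numeric(1))
    ps_eff <- vapply(trs, function(tr) tr$PS_eff[k], numeric(1))
    expect_true(all(sig >= 0 & sig <= 1))
    expect_true(all(diff(sig) >= -1e-12))
    if (!base_phys$tissues$well_stirred[k]) {
      expect_true(all(diff(ps_s) <= 1e-12))
      expect_true(all(diff(ps_l) <= 1e-12))
      expect_true(all(diff(ps_eff) <= 1e-12))
      r_s <- base_phys$tissues$r_small[k]
      expect_true(all(ps_s[rs_grid >= r_s] == 0))
      r_l <- base_phys$tissues$r_large[k]
      expect_true(all(ps_l[rs_grid >= r_l] == 0))
    }
  }
  # unhindered limit: a point solute is not reflected
  tr0 <- drug_transport(base_phys, probe_drug(1e-9))
  expect_true(all(tr0$sigma_av < 1e-6))
})

test_that("the isogravimetric option only perturbs Peclet numbers and is off by default", {
  cfg_off <- two_pore_config()
  cfg_on <- two_pore_config(include_isogravimetric_flow = TRUE,
                            J_iso_fraction = 0.5)
  tr_off <- drug_transport(base_phys, probe_drug(3), cfg_off)
  tr_on <- drug_transport(base_phys, probe_drug(3), cfg_on)
  expect_equal(tr_on$PS_s, tr_off$PS_s)
  expect_equal(tr_on$sigma_av, tr_off$sigma_av)
  free <- !tr_off$well_stirred & base_phys$tissues$L_org > 0
  expect_true(all(tr_on$Pe_l[free] > tr_off$Pe_l[free]))
})
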