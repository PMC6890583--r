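test_that("the zero state is stationary and dimensions are enforced", {
  drug <- probe_drug(3.55)
  tr <- drug_transport(base_phys, drug)
  n <- 2 * nrow(base_phys$tissues) + 3
  expect_equal(pbpk_rhs(numeric(n), base_phys, tr, drug), numeric(n),
               ignore_attr = TRUE)
  expect_error(pbpk_rhs(numeric(n - 1), base_phys, tr, drug), "length")
})

test_that("a uniform state is stationary when nothing is reflected anywhere", {
  # requires all lymph streams to carry solute: rescale lymph percentages so
  # the bypass (which filters solute out of its lymph) receives none
  phys <- build_physiology(table = no_bypass_lymph_table())
  drug <- probe_drug(3.55)
  tr <- drug_transport(phys, drug)
  tr$sigma_av <- 0
  M <- build_rate_matrix(phys, tr, CL_p = 0, BP = 1)
  y <- rep(2.5, nrow(M))
  expect_lt(max(abs(M %*% y)), 1e-9)
})

test_that("mass is conserved without elimination and the eliminated mass closes the balance", {
  drug <- drug_properties("p", Rs = 4, CL_p = 0, BP = 1, F = 0.7)
  sim <- simulate_pbpk(drug, dose_event("sc", 10), base_phys,
                       sim = sim_config(t_end = 2000, n_points = 400))
  amt <- total_amount(sim)
  expect_lt(max(abs(amt - 10 * 0.7)) / (10 * 0.7), 1e-6)

  # with clearance: augment the rate matrix with an eliminated-mass
  # accumulator and require amount + eliminated = dose
  CL_p <- 2; BP <- 0.8
  tr <- drug_transport(base_phys, drug)
  M <- build_rate_matrix(base_phys, tr, CL_p = CL_p, BP = BP)
  Ma <- cbind(rbind(M, 0), 0)
  Ma[nrow(Ma), match("C_ab", rownames(M))] <- CL_p / BP
  y0 <- numeric(nrow(Ma))
  y0[match("C_vb", rownames(M))] <- 5 / base_phys$V_vb
  out <- deSolve::ode(y0, seq(0, 300, length.out = 61),
                      function(t, y, p) list(drop(p %*% y)), Ma,
                      rtol = 1e-10, atol = 1e-13)
  vols <- c(base_phys$tissues$V_v, base_phys$tissues$V_i,
            base_phys$V_LN, base_phys$V_vb, base_phys$V_ab)
  amt <- out[, -1][, seq_along(vols)] %*% vols
  elim <- out[, ncol(out)]
  expect_true(all(diff(amt) < 0))
  expect_lt(max(abs(amt + elim - 5)) / 5, 1e-6)
})

test_that("SC bolus initial conditions follow dose x F / V_i at the site", {
  phys <- build_physiology(sc_site_vi_override_mL = 3.0)
  drug <- drug_properties("p", Rs = 5, CL_p = 0, BP = 1, F = 0.5)
  sim <- simulate_pbpk(drug, dose_event("sc", 1), phys,
                       sim = sim_config(t_end = 10, n_points = 20))
  expect_equal(unname(sim$conc[1, "Ci_sc_site"]), 1 * 0.5 / 0.003,
               tolerance = 1e-12) # 166.7 mg/L
  others <- setdiff(colnames(sim$conc), "Ci_sc_site")
  expect_true(all(sim$conc[1, others] == 0))
})

test_that("the system is linear: doubling the dose doubles every concentration", {
  drug <- drug_properties("p", Rs = 2.5, CL_p = 0.5, BP = 1, F = 0.6)
  s1 <- simulate_pbpk(drug, dose_event("sc", 5), base_phys,
                      sim = sim_config(t_end = 100, n_points = 200))
  s2 <- simulate_pbpk(drug, dose_event("sc", 10), base_phys,
                      sim = sim_config(t_end = 100, n_points = 200))
  expect_equal(2 * s1$conc, s2$conc, tolerance = 1e-7)
})

test_that("later dose events superpose onto the trajectory", {
  drug <- drug_properties("p", Rs = 3, CL_p = 0, BP = 1, F = 0.8)
  doses <- list(dose_event("sc", 2), dose_event("iv", 1, time = 50))
  sim <- simulate_pbpk(drug, doses, base_phys,
                       sim = sim_config(t_end = 200, n_points = 400))
  amt <- total_amount(sim)
  pre <- sim$time < 50; post <- sim$time > 50
  expect_lt(max(abs(amt[pre] - 2 * 0.8)), 1e-6)
  expect_lt(max(abs(amt[post] - (2 * 0.8 + 1))), 1e-5)
})

test_that("steady-state ratios match long-time integration and the local closed form", {
  for (rs in c(1, 3.55, 5, 11)) {
    drug <- probe_drug(rs)
    ss <- steady_state_ci_cp(drug, base_phys)
    sim <- simulate_pbpk(drug, dose_event("iv", 1), base_phys,
                         sim = c(0, 1e4, 1e5))
    cp <- sim$conc[3, "C_vb"]
    num <- sim$conc[3, paste0("Ci_", base_phys$tissues$tissue)] / cp
    expect_lt(max(abs(ss - num)), 1e-4)
    # local interstitial/vascular closed form vs the whole-system solve
    tr <- drug_transport(base_phys, drug)
    r_local <- ci_cv_ratio(tr, base_phys$tissues$L_org)
    st <- attr(ss, "state")
    r_system <- st[paste0("Ci_", base_phys$tissues$tissue)] /
      st[paste0("Cv_", base_phys$tissues$tissue)]
    expect_equal(unname(r_local), unname(r_system), tolerance = 1e-8)
  }
})

test_that("steady-state limiting cases behave as the pore picture demands", {
  # well-stirred tissues with no lymph equilibrate with plasma
  ss <- steady_state_ci_cp(probe_drug(3.55), base_phys)
  expect_equal(unname(ss["spleen"]), 1, tolerance = 2e-3)
  expect_equal(unname(ss["bone"]), 1, tolerance = 2e-3)
  # a solute larger than both pores in a drained tissue is washed out
  ss21 <- steady_state_ci_cp(probe_drug(21), base_phys)
  expect_lt(unname(ss21["adipose"]), 1e-10) # pores 7/20 nm, lymph > 0
  # no steady state exists under elimination
  expect_error(steady_state_ci_cp(
    drug_properties("p", Rs = 3, CL_p = 1, BP = 1, F = 1), base_phys),
    "CL_p = 0")
})

test_that("steady-state Ci/Cp decreases with solute size in every tissue", {
  rs_grid <- c(1, 2, 3, 4, 5, 7, 9, 11)
  mat <- vapply(rs_grid,
                function(rs) steady_state_ci_cp(probe_drug(rs), base_phys),
                numeric(nrow(base_phys$tissues)))
  for (k in seq_len(nrow(mat))) {
    if (base_phys$tissues$well_stirred[k]) {
      # pinned at equilibration with plasma, up to O(L/Q) circulation effects
      expect_true(all(abs(mat[k, ] - 1) < 1e-4))
    } else {
      expect_true(all(diff(mat[k, ]) <= 1e-9),
                  label = paste("monotone Ci/Cp for",
                                base_phys$tissues$tissue[k]))
    }
  }
})

test_that("plasma t_max after SC dosing is invariant to dose and bioavailability", {
  tmax_of <- function(dose, f) {
    drug <- drug_properties("p", Rs = 2.38, CL_p = 1, BP = 1, F = f)
    sim <- simulate_pbpk(drug, dose_event("sc", dose), base_phys,
                         sim = sim_config(t_end = 48, n_points = 600))
    pk_summary(sim)$t_max
  }
  t1 <- tmax_of(1, 1); t2 <- tmax_of(10, 1); t3 <- tmax_of(1, 0.3)
  expect_equal(t1, t2, tolerance = 1e-6)
  expect_equal(t1, t3, tolerance = 1e-6)
})

test_that("trajectories stay non-negative and the grid must increase", {
  drug <- probe_drug(5)
  sim <- simulate_pbpk(drug, dose_event("sc", 1), base_phys,
                       sim = sim_config(t_end = 5000, n_points = 300,
                                        log_grid = TRUE))
  nm <- c(paste0("Cv_", base_phys$tissues$tissue),
          paste0("Ci_", base_phys$tissues$tissue), "C_LN", "C_vb", "C_ab")
  expect_gt(min(sim$conc[, nm]), -1e-10)
  expect_error(simulate_pbpk(drug, dose_event("sc", 1), base_phys,
                             sim = c(0, 10, 5)), "increasing")
})

test_that("interstitial t_max shortens monotonically as lymph flow is scaled up", {
  sens <- sensitivity_lymph_scale(scales = c(0.1, 1, 10), rs_nm = 5,
                                  t_end = 3e4, n_points = 400)
  for (t in c("muscle", "skin", "gut", "heart")) {
    sub <- sens[sens$tissue == t, ]
    sub <- sub[order(sub$scale), ]
    expect_true(all(sub$interior_peak))
    expect_true(all(diff(sub$t_max_interstitial) < 0),
                label = paste("t_max decreasing in lymph scale for", t))
  }
  # scale = 1 reproduces the unscaled physiology bit-identically
  expect_identical(build_physiology(lymph_scale = 1), build_physiology())
  expect_error(sensitivity_lymph_scale(scales = 0), "positive")
})

test_that("steady-state ratios are less sensitive to lymph scale than interstitial t_max", {
  sens <- sensitivity_lymph_scale(scales = c(0.1, 1, 10), rs_nm = 3,
                                  t_end = 3e4, n_points = 400)
  rel_spread <- function(x) (max(x) - min(x)) / mean(x)
  for (t in c("muscle", "skin", "gut")) {
    sub <- sens[sens$tissue == t, ]
    expect_lt(rel_spread(sub$ss_ci_cp), rel_spread(sub$t_max_interstitial))
  }
})
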