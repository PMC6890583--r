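# Whole-body ODE system: vascular and interstitial mass balances per tissue,
# central lymph, venous and arterial blood, with a bypass pass-through
# closing the flow balance. The system is linear with constant coefficients,
# so it is assembled once as a rate matrix.

state_names <- function(phys, fluxes = FALSE) {
  tn <- phys$tissues$tissue
  nm <- c(paste0("Cv_", tn), paste0("Ci_", tn), "C_LN", "C_vb", "C_ab")
  if (fluxes) nm <- c(nm, "F_lymph_sc", "F_pore_sc", "F_influx_sc")
  nm
}

state_volumes <- function(phys) {
  c(phys$tissues$V_v, phys$tissues$V_i, phys$V_LN, phys$V_vb, phys$V_ab)
}

#' Assemble the linear rate matrix of the whole-body model
#'
#' Builds the constant matrix M such that dC/dt = M C for the concentration
#' state vector (per-tissue vascular and interstitial concentrations, then
#' central lymph, venous blood and arterial blood). Generic tissues receive
#' arterial blood; the lung receives the full cardiac output from venous
#' blood; the liver receives the hepatic artery plus the venous outflows of
#' gut, spleen and pancreas; elimination acts on arterial blood at rate
#' CL_p / BP. The bypass passes arterial solute straight to venous blood
#' while its lymph flow joins the central lymph as solute-free filtrate.
#'
#' When `fluxes = TRUE` three extra rows accumulate, in amount units, the
#' solute leaving the SC-site interstitium via lymph (L * Ci) and via the
#' endothelial pores (the gross diffusive efflux PS_eff * Ci), plus the
#' gross influx from the SC vascular space ((L (1 - sigma_av) + PS_eff) *
#' Cv); gross efflux minus influx gives the net pore exchange.
#'
#' @param phys A [build_physiology()] object.
#' @param transport A [drug_transport()] table for the same physiology.
#' @param CL_p Plasma clearance, L/h.
#' @param BP Blood/plasma concentration ratio.
#' @param fluxes Append SC-site flux accounting rows.
#' @return A square matrix with state names as dimnames.
#' @export
build_rate_matrix <- function(phys, transport, CL_p = 0, BP = 1,
                              fluxes = FALSE) {
  tis <- phys$tissues
  if (!identical(tis$tissue, transport$tissue)) {
    stop("transport table does not match the physiology tissue order")
  }
  n <- nrow(tis)
  nm <- state_names(phys, fluxes = fluxes)
  nst <- length(nm)
  M <- matrix(0, nst, nst, dimnames = list(nm, nm))

  iv <- function(t) match(paste0("Cv_", t), nm)
  ii <- function(t) match(paste0("Ci_", t), nm)
  i_LN <- match("C_LN", nm); i_vb <- match("C_vb", nm); i_ab <- match("C_ab", nm)

  ps_eff <- transport$PS_s * peclet_factor(transport$Pe_s) +
    transport$PS_l * peclet_factor(transport$Pe_l)

  for (k in seq_len(n)) {
    t <- tis$tissue[k]
    Vv <- tis$V_v[k]; Vi <- tis$V_i[k]
    L <- tis$L_org[k]; Qin <- tis$Q_in[k]
    sig <- transport$sigma_av[k]; ps <- ps_eff[k]

    # vascular inflow
    if (t == "lung") {
      M[iv(t), i_vb] <- M[iv(t), i_vb] + phys$Q_c / Vv
    } else if (t == "liver") {
      M[iv(t), i_ab] <- M[iv(t), i_ab] + tis$Q_art[k] / Vv
      for (p in PORTAL_TISSUES) {
        kp <- match(p, tis$tissue)
        M[iv(t), iv(p)] <- M[iv(t), iv(p)] +
          (tis$Q_in[kp] - tis$L_org[kp]) / Vv
      }
    } else {
      M[iv(t), i_ab] <- M[iv(t), i_ab] + tis$Q_art[k] / Vv
    }
    # vascular outflow, lymph filtration, pore exchange
    M[iv(t), iv(t)] <- M[iv(t), iv(t)] -
      ((Qin - L) + L * (1 - sig) + ps) / Vv
    M[iv(t), ii(t)] <- M[iv(t), ii(t)] + ps / Vv

    # interstitial balance (lymph reflection coefficient is zero)
    M[ii(t), iv(t)] <- M[ii(t), iv(t)] + (L * (1 - sig) + ps) / Vi
    M[ii(t), ii(t)] <- M[ii(t), ii(t)] - (ps + L) / Vi

    # lymph collection
    M[i_LN, ii(t)] <- M[i_LN, ii(t)] + L / phys$V_LN

    # venous return (lung and splanchnic tissues drain elsewhere)
    if (!(t %in% c("lung", PORTAL_TISSUES))) {
      M[i_vb, iv(t)] <- M[i_vb, iv(t)] + (Qin - L) / phys$V_vb
    }
  }

  M[i_LN, i_LN] <- -phys$L_total / phys$V_LN
  M[i_vb, i_LN] <- phys$L_total / phys$V_vb
  M[i_vb, i_ab] <- M[i_vb, i_ab] + phys$bypass$Q / phys$V_vb
  M[i_vb, i_vb] <- M[i_vb, i_vb] - phys$Q_c / phys$V_vb

  L_lung <- tis$L_org[tis$tissue == "lung"]
  M[i_ab, iv("lung")] <- (phys$Q_c - L_lung) / phys$V_ab
  M[i_ab, i_ab] <- -((phys$Q_c - L_lung) + CL_p / BP) / phys$V_ab

  if (fluxes) {
    k <- match("sc_site", tis$tissue)
    i_fl <- match("F_lymph_sc", nm)
    i_fp <- match("F_pore_sc", nm)
    i_fi <- match("F_influx_sc", nm)
    L <- tis$L_org[k]; sig <- transport$sigma_av[k]; ps <- ps_eff[k]
    M[i_fl, ii("sc_site")] <- L
    M[i_fp, ii("sc_site")] <- ps
    M[i_fi, iv("sc_site")] <- ps + L * (1 - sig)
  }
  M
}

#' Derivative of the whole-body state
#'
#' Thin evaluation of the assembled mass balances: given a named (or
#' correctly ordered) concentration state vector, returns its time
#' derivative. Exposed mainly for testing conservation and stationarity
#' properties; the integrator consumes the rate matrix directly.
#'
#' @param state Numeric state vector matching [build_rate_matrix()] order.
#' @param phys,transport,drug Model components; `drug` supplies CL_p and BP.
#' @return Numeric derivative vector of the same length.
#' @export
pbpk_rhs <- function(state, phys, transport, drug) {
  M <- build_rate_matrix(phys, transport, CL_p = drug$CL_p, BP = drug$BP)
  if (length(state) != nrow(M)) {
    stop("state has length ", length(state), ", expected ", nrow(M))
  }
  drop(M %*% state)
}

#' Simulation configuration
#'
#' @param t_end End of the simulation horizon, h.
#' @param n_points Number of output points (plus t = 0).
#' @param log_grid Use a logarithmically spaced output grid (recommended for
#'   horizons spanning several orders of magnitude).
#' @param rtol,atol Relative / absolute solver tolerances.
#' @param method `deSolve` integration method.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(t_end = 500, n_points = 1000, log_grid = FALSE,
                       rtol = 1e-8, atol = 1e-12, method = "lsoda") {
  stopifnot(t_end > 0, n_points >= 10)
  structure(list(t_end = t_end, n_points = n_points, log_grid = log_grid,
                 rtol = rtol, atol = atol, method = method),
            class = "sim_config")
}

sim_times <- function(sim) {
  if (sim$log_grid) {
    c(0, 10^seq(log10(sim$t_end) - 5, log10(sim$t_end),
                length.out = sim$n_points))
  } else {
    seq(0, sim$t_end, length.out = sim$n_points + 1)
  }
}

#' Simulate the whole-body model for a dosing scenario
#'
#' Subcutaneous boluses enter the SC-site interstitium as an initial (or
#' event-time) concentration step of amount * F / V_i,sc; intravenous
#' boluses enter venous blood as amount / V_vb. All other compartments start
#' at zero. The reported plasma concentration is the venous blood
#' concentration divided by the blood/plasma ratio. Cumulative solute efflux
#' from the SC interstitium via lymph and (net) via the pores is integrated
#' alongside the state.
#'
#' @param drug A [drug_properties()] object.
#' @param doses A [dose_event()] or list of them.
#' @param phys A [build_physiology()] object.
#' @param config A [two_pore_config()].
#' @param sim A [sim_config()], or a numeric vector of output times
#'   (starting at 0).
#' @return An object of class `pbpk_sim` with elements `time`, `conc`
#'   (time-by-state matrix), `plasma`, `fluxes` (SC lymph / pore cumulative
#'   amounts), `depot_amount` and the inputs.
#' @export
simulate_pbpk <- function(drug, doses, phys = build_physiology(),
                          config = two_pore_config(), sim = sim_config()) {
  if (inherits(doses, "dose_event")) doses <- list(doses)
  stopifnot(length(doses) >= 1,
            all(vapply(doses, inherits, TRUE, "dose_event")))
  times <- if (is.numeric(sim)) sim else sim_times(sim)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("output time grid must be strictly increasing")
  }
  rtol <- if (is.numeric(sim)) 1e-8 else sim$rtol
  atol <- if (is.numeric(sim)) 1e-12 else sim$atol
  method <- if (is.numeric(sim)) "lsoda" else sim$method

  transport <- drug_transport(phys, drug, config)
  M <- build_rate_matrix(phys, transport, CL_p = drug$CL_p, BP = drug$BP,
                         fluxes = TRUE)
  nm <- rownames(M)
  y0 <- stats::setNames(numeric(nrow(M)), nm)

  Vi_sc <- phys$tissues$V_i[phys$tissues$tissue == "sc_site"]
  dose_target <- function(d) {
    switch(d$route,
           sc = list(var = "Ci_sc_site", value = d$amount * drug$F / Vi_sc),
           iv = list(var = "C_vb", value = d$amount / phys$V_vb))
  }
  ev <- NULL
  for (d in doses) {
    tgt <- dose_target(d)
    if (d$time == 0) {
      y0[tgt$var] <- y0[tgt$var] + tgt$value
    } else {
      ev <- rbind(ev, data.frame(var = tgt$var, time = d$time,
                                 value = tgt$value, method = "add"))
    }
  }

  func <- function(t, y, p) list(drop(p %*% y))
  out <- deSolve::ode(y = y0, times = times, func = func, parms = M,
                      method = method, rtol = rtol, atol = atol,
                      events = if (!is.null(ev)) list(data = ev))
  if (attr(out, "istate")[1] < 0) {
    stop("ODE solver failed to converge; the system is stiff - consider ",
         "method = 'lsoda'/'bdf' and looser output spacing")
  }
  conc <- out[, nm, drop = FALSE]
  conc_states <- state_names(phys, fluxes = FALSE)
  neg <- min(conc[, conc_states])
  if (neg < -1e-8 * max(abs(conc[, conc_states]))) {
    stop("negative concentrations beyond solver tolerance (min ", neg, ")")
  }

  depot_amount <- sum(vapply(doses, function(d)
    if (d$route == "sc") d$amount * drug$F else 0, numeric(1)))

  structure(list(
    time = out[, "time"],
    conc = conc,
    plasma = conc[, "C_vb"] / drug$BP,
    fluxes = list(lymph = conc[, "F_lymph_sc"],
                  pore = conc[, "F_pore_sc"],
                  influx = conc[, "F_influx_sc"]),
    depot_amount = depot_amount,
    doses = doses, drug = drug, phys = phys, config = config
  ), class = "pbpk_sim")
}

#' @export
print.pbpk_sim <- function(x, ...) {
  cat(sprintf("<pbpk_sim> %s, %d dose(s), horizon %.4g h, %d time points\n",
              x$drug$name, length(x$doses), max(x$time), length(x$time)))
  cat(sprintf("  peak plasma %.4g at %.4g h (grid values)\n",
              max(x$plasma), x$time[which.max(x$plasma)]))
  invisible(x)
}

#' Total amount of drug in the system over time
#'
#' Sum of compartment volume times concentration over all compartments.
#' Conserved (to solver tolerance) when plasma clearance is zero.
#'
#' @param sim A [simulate_pbpk()] result.
#' @return Numeric vector of amounts per output time.
#' @export
total_amount <- function(sim) {
  vols <- state_volumes(sim$phys)
  nm <- state_names(sim$phys)
  drop(sim$conc[, nm, drop = FALSE] %*% vols)
}

#' Tidy long-format concentrations
#'
#' @param sim A [simulate_pbpk()] result.
#' @return data.frame with columns time, compartment, concentration.
#' @export
as_tidy_conc <- function(sim) {
  nm <- state_names(sim$phys)
  data.frame(
    time = rep(sim$time, times = length(nm)),
    compartment = rep(nm, each = length(sim$time)),
    concentration = as.vector(sim$conc[, nm])
  )
}

#' Steady-state interstitial-to-plasma concentration ratios
#'
#' For a non-eliminated drug (CL_p must be zero; with elimination no steady
#' state exists) the linear system has a one-dimensional stationary space.
#' The stationary concentrations are obtained algebraically by solving the
#' rate matrix together with a total-mass normalisation, and the ratio
#' C_i,org / C_plasma is reported per tissue with plasma = C_vb / BP.
#'
#' The per-tissue closed form Ci/Cv = (L (1 - sigma_av) + PS_eff) /
#' (L + PS_eff) (see [ci_cv_ratio()]) agrees with these whole-system ratios
#' up to the small vascular-to-plasma concentration gradients sustained by
#' lymph filtration.
#'
#' @param drug A [drug_properties()] with CL_p = 0.
#' @param phys A [build_physiology()] object.
#' @param config A [two_pore_config()].
#' @return Named numeric vector of Ci/Cp ratios per tissue, with the full
#'   stationary concentration vector as attribute `state`.
#' @export
steady_state_ci_cp <- function(drug, phys = build_physiology(),
                               config = two_pore_config()) {
  if (drug$CL_p != 0) {
    stop("steady-state ratios require CL_p = 0 (no steady state exists ",
         "under elimination)")
  }
  transport <- drug_transport(phys, drug, config)
  M <- build_rate_matrix(phys, transport, CL_p = 0, BP = drug$BP)
  vols <- state_volumes(phys)
  A <- rbind(M, vols)
  b <- c(numeric(nrow(M)), 1)
  x <- qr.solve(A, b)
  names(x) <- rownames(M)
  cp <- x["C_vb"] / drug$BP
  tn <- phys$tissues$tissue
  ratios <- x[paste0("Ci_", tn)] / cp
  names(ratios) <- tn
  attr(ratios, "state") <- x
  ratios
}

#' Lymph-flow sensitivity analysis
#'
#' Scales every lymph flow by each factor in `scales`, administers a unit
#' intravenous bolus of a non-eliminated protein for each hydrodynamic
#' radius in `rs_nm`, and records per tissue the time of maximum
#' interstitial concentration and the steady-state Ci/Cp ratio. Interstitial
#' concentrations under a venous bolus rise, overshoot while the
#' central pool is still draining, and relax to the steady state; tissues
#' whose equilibration is slower than the central redistribution show no
#' interior maximum inside the horizon, flagged by `interior_peak`.
#'
#' @param scales Positive lymph-flow scale factors.
#' @param rs_nm Hydrodynamic radii of the hypothetical proteins, nm.
#' @param phys_args Extra arguments passed to [build_physiology()].
#' @param config A [two_pore_config()].
#' @param t_end Simulation horizon, h.
#' @param n_points Output grid size (logarithmic grid).
#' @return data.frame with columns scale, rs_nm, tissue, t_max_interstitial,
#'   interior_peak, ss_ci_cp.
#' @export
sensitivity_lymph_scale <- function(scales = c(0.1, 1, 10),
                                    rs_nm = c(1, 3, 5, 7),
                                    phys_args = list(),
                                    config = two_pore_config(),
                                    t_end = 3e4, n_points = 600) {
  if (any(scales <= 0)) stop("lymph-flow scale factors must be positive")
  if (any(rs_nm <= 0)) stop("hydrodynamic radii must be positive")
  out <- list()
  for (s in scales) {
    phys <- do.call(build_physiology, c(phys_args, list(lymph_scale = s)))
    for (rs in rs_nm) {
      drug <- drug_properties(sprintf("panel_Rs_%g", rs), Rs = rs,
                              CL_p = 0, BP = 1, F = 1)
      simc <- sim_config(t_end = t_end, n_points = n_points, log_grid = TRUE)
      sim <- simulate_pbpk(drug, dose_event("iv", 1), phys = phys,
                           config = config, sim = simc)
      ss <- steady_state_ci_cp(drug, phys, config)
      for (t in phys$tissues$tissue) {
        ci <- sim$conc[, paste0("Ci_", t)]
        pk <- refine_peak(sim$time, ci)
        out[[length(out) + 1]] <- data.frame(
          scale = s, rs_nm = rs, tissue = t,
          t_max_interstitial = pk$t_max,
          interior_peak = pk$interior,
          ss_ci_cp = unname(ss[t]))
      }
    }
  }
  do.call(rbind, out)
}
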