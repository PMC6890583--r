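# Post-processing of simulations into reported pharmacokinetic quantities.

# Quadratic refinement of a discrete maximum: fit a parabola through the
# grid maximum and its neighbours (non-uniform spacing handled exactly).
refine_peak <- function(time, value) {
  i <- which.max(value)
  interior <- i > 1 && i < length(value)
  if (!interior) {
    return(list(t_max = time[i], c_max = value[i], interior = FALSE))
  }
  t0 <- time[i - 1]; t1 <- time[i]; t2 <- time[i + 1]
  y0 <- value[i - 1]; y1 <- value[i]; y2 <- value[i + 1]
  # Lagrange parabola derivative root
  d1 <- (y1 - y0) / (t1 - t0)
  d2 <- (y2 - y1) / (t2 - t1)
  curv <- (d2 - d1) / (t2 - t0)
  if (curv >= 0) {
    return(list(t_max = t1, c_max = y1, interior = TRUE))
  }
  tm <- (t0 + t1) / 2 - d1 / (2 * curv)
  tm <- min(max(tm, t0), t2)
  # Newton-form evaluation of the interpolating parabola at tm
  cm <- y0 + d1 * (tm - t0) + curv * (tm - t0) * (tm - t1)
  list(t_max = tm, c_max = max(cm, y1), interior = TRUE)
}

#' Peak plasma concentration and time of peak
#'
#' Cmax is the maximum of the simulated plasma profile, refined by quadratic
#' interpolation through the grid maximum and its two neighbours; t_max is
#' the abscissa of the refined peak. Deterministic for a fixed grid. When
#' observed values are supplied the prediction accuracy is expressed as the
#' fold error predicted / observed.
#'
#' @param sim A [simulate_pbpk()] result.
#' @param observed_cmax,observed_tmax Optional observed values.
#' @return A list of class `pk_summary` with `cmax`, `t_max` and, when
#'   observed values are given, `fold_error_cmax` / `fold_error_tmax`.
#' @export
pk_summary <- function(sim, observed_cmax = NULL, observed_tmax = NULL) {
  prof <- sim$plasma
  if (length(prof) == 0) stop("empty plasma profile")
  if (max(prof) <= 0) {
    stop("all-zero plasma profile: t_max is undefined")
  }
  pk <- refine_peak(sim$time, prof)
  out <- list(cmax = pk$c_max, t_max = pk$t_max, interior = pk$interior)
  if (!is.null(observed_cmax)) {
    if (observed_cmax <= 0) stop("observed Cmax must be positive")
    out$fold_error_cmax <- out$cmax / observed_cmax
  }
  if (!is.null(observed_tmax)) {
    if (observed_tmax <= 0) stop("observed t_max must be positive")
    out$fold_error_tmax <- out$t_max / observed_tmax
  }
  class(out) <- "pk_summary"
  out
}

#' @export
print.pk_summary <- function(x, ...) {
  cat(sprintf("<pk_summary> Cmax %.4g at t_max %.4g h\n", x$cmax, x$t_max))
  if (!is.null(x$fold_error_cmax))
    cat(sprintf("  fold error Cmax %.3g\n", x$fold_error_cmax))
  if (!is.null(x$fold_error_tmax))
    cat(sprintf("  fold error t_max %.3g\n", x$fold_error_tmax))
  invisible(x)
}

#' Fold-error summary statistics for predicted/observed pairs
#'
#' The fold error of a prediction is the ratio predicted / observed. The
#' summary reports the arithmetic mean ratio, the number of predictions
#' within 0.80-1.25-fold and within 2-fold (ratio in [0.5, 2]) of the
#' observations, and the maximum fold deviation max(ratio, 1/ratio).
#'
#' @param predicted Predicted values, or ready-made ratios when `observed`
#'   is omitted.
#' @param observed Observed values (same length), optional.
#' @return A list with `ratios`, `mean_ratio`, `n`, `n_within_0.8_1.25`,
#'   `n_within_2fold`, `max_fold_deviation`.
#' @export
fold_error_stats <- function(predicted, observed = NULL) {
  ratios <- if (is.null(observed)) predicted else {
    if (length(predicted) != length(observed)) {
      stop("predicted and observed must have the same length")
    }
    if (any(observed <= 0)) stop("observed values must be positive")
    predicted / observed
  }
  if (length(ratios) == 0) stop("no values supplied")
  if (any(ratios <= 0)) stop("fold errors must be positive")
  list(
    ratios = ratios,
    mean_ratio = mean(ratios),
    n = length(ratios),
    n_within_0.8_1.25 = sum(ratios >= 0.80 & ratios <= 1.25),
    n_within_2fold = sum(ratios >= 0.5 & ratios <= 2),
    max_fold_deviation = max(pmax(ratios, 1 / ratios))
  )
}

#' Percentage of the SC dose remaining at the dosing site
#'
#' Amount in the SC interstitial space at time t as a percentage of the
#' initial depot amount. The depot amount is the bioavailable dose
#' (dose x F), since only that fraction is placed in the depot; radiolabel
#' studies reference the total injected dose, which differs by the factor F.
#'
#' @param sim A [simulate_pbpk()] result of an SC dosing scenario.
#' @param t Time(s), h, at which to evaluate (linear interpolation on the
#'   output grid).
#' @return Percentages (one per element of `t`).
#' @export
percent_remaining_sc <- function(sim, t) {
  if (sim$depot_amount <= 0) {
    stop("not an SC dosing scenario (no depot amount)")
  }
  Vi_sc <- sim$phys$tissues$V_i[sim$phys$tissues$tissue == "sc_site"]
  amt <- sim$conc[, "Ci_sc_site"] * Vi_sc
  100 * stats::approx(sim$time, amt, xout = t, rule = 2)$y / sim$depot_amount
}

#' Percentage of SC absorption occurring via the lymphatics
#'
#' Cumulative solute efflux from the SC interstitium via lymph divided by
#' total efflux (lymph plus the diffusive efflux through the endothelial
#' pores), evaluated at the end of the simulation horizon, as a percentage.
#' Both efflux integrands are proportional to the SC interstitial
#' concentration, so the split is the local partition L / (L + PS_eff):
#' bounded in [0, 100], independent of the horizon, non-decreasing in
#' solute size, and exactly 100% for a protein larger than both SC pore
#' radii (pores closed, lymph the only exit). Back-flux from systemic
#' recirculation is tracked separately (`sim$fluxes$influx`) and does not
#' enter the split, which would otherwise depend on how long the system is
#' left to recirculate.
#'
#' @param sim A [simulate_pbpk()] result of an SC dosing scenario.
#' @return Percentage in [0, 100].
#' @export
percent_absorbed_via_lymph <- function(sim) {
  if (sim$depot_amount <= 0) {
    stop("not an SC dosing scenario (no depot amount)")
  }
  n <- length(sim$time)
  lymph <- sim$fluxes$lymph[n]
  pore <- sim$fluxes$pore[n]
  total <- lymph + pore
  if (total <= 0) stop("zero total efflux from the SC site: fraction undefined")
  100 * lymph / total
}
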