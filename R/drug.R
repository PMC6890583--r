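# Drug-specific parameters.

#' Drug (therapeutic protein) properties
#'
#' The hydrodynamic radius Rs is the only drug property that determines
#' transcapillary transport; plasma clearance, blood/plasma ratio and
#' subcutaneous bioavailability govern disposition and dosing. When Rs is
#' not supplied it is estimated from molecular weight with [mw_to_rs()]; a
#' supplied Rs always takes precedence.
#'
#' @param name Drug name.
#' @param Rs Hydrodynamic radius, nm.
#' @param MW Molecular weight, kDa (used to estimate Rs when absent).
#' @param CL_p Plasma clearance, L/h (>= 0).
#' @param BP Blood/plasma concentration ratio (> 0).
#' @param F Subcutaneous bioavailability, fraction in (0, 1].
#' @param pI Isoelectric point (metadata only; charge is not modelled).
#' @return An object of class `drug_properties`.
#' @export
drug_properties <- function(name, Rs = NULL, MW = NULL, CL_p = 0, BP = 1,
                            F = 1, pI = NA_real_) {
  if (is.null(Rs)) {
    if (is.null(MW)) stop("supply either Rs or MW")
    Rs <- mw_to_rs(MW)
  }
  if (!(is.numeric(Rs) && length(Rs) == 1 && Rs > 0)) {
    stop("Rs must be a single positive number")
  }
  if (CL_p < 0) stop("CL_p must be non-negative")
  if (BP <= 0) stop("BP must be positive")
  if (!(F > 0 && F <= 1)) stop("F must lie in (0, 1]")
  structure(list(name = name, Rs = Rs, MW = if (is.null(MW)) NA_real_ else MW,
                 CL_p = CL_p, BP = BP, F = F, pI = pI),
            class = "drug_properties")
}

#' @export
print.drug_properties <- function(x, ...) {
  cat(sprintf("<drug_properties> %s: Rs %.3g nm, CL_p %.3g L/h, BP %.3g, F %.3g\n",
              x$name, x$Rs, x$CL_p, x$BP, x$F))
  invisible(x)
}

#' Dose event
#'
#' @param route `"sc"` (bolus into the SC-site interstitial space, scaled by
#'   bioavailability) or `"iv"` (bolus into venous blood).
#' @param amount Dose amount (mg, or any linear activity unit carried
#'   through unchanged).
#' @param time Dosing time, h.
#' @return An object of class `dose_event`.
#' @export
dose_event <- function(route = c("sc", "iv"), amount, time = 0) {
  route <- match.arg(route)
  if (amount < 0) stop("dose amount must be non-negative")
  if (time < 0) stop("dose time must be non-negative")
  structure(list(route = route, amount = amount, time = time),
            class = "dose_event")
}
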