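# Whole-body system physiology: tissue volumes, blood and lymph flows.

#' Packaged tissue-level system parameters
#'
#' Reads the tissue table shipped with the package: whole-organ volume,
#' fraction of vascular space, fraction of extracellular water, percentage of
#' cardiac output, percentage of total lymph flow, the two endothelial pore
#' radii and the small-pore/large-pore number ratio for the 12 exchanging
#' tissues plus the subcutaneous (SC) dosing site. Spleen and bone carry a
#' well-stirred flag: they have no exiting lymph vessels and are modelled as
#' rapidly equilibrating compartments.
#'
#' @param path Optional path to an alternative tab-separated table with the
#'   same columns.
#' @return A data.frame with one row per tissue.
#' @export
tissue_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "system_params.tsv", package = "protpbpk",
                        mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("tissue", "V_total", "f_vasc", "f_EW", "pct_CO", "pct_lymph",
                "r_small", "r_large", "n_small_per_large", "well_stirred")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("tissue table lacks columns: ", paste(missing, collapse = ", "))
  }
  validate_tissue_table(tab)
  tab
}

validate_tissue_table <- function(tab) {
  with(tab, {
    bad <- tissue[!(f_EW > 0 & f_EW <= 1)]
    if (length(bad)) stop("f_EW outside (0, 1] for: ", paste(bad, collapse = ", "))
    bad <- tissue[!(f_vasc > 0 & f_vasc < f_EW)]
    if (length(bad)) {
      stop("fraction of vascular space must satisfy 0 < f_vasc < f_EW ",
           "(otherwise interstitial volume is non-positive); violated for: ",
           paste(bad, collapse = ", "))
    }
    bad <- tissue[r_small > r_large]
    if (length(bad)) stop("r_small > r_large for: ", paste(bad, collapse = ", "))
    bad <- tissue[n_small_per_large < 1]
    if (length(bad)) stop("n_small_per_large < 1 for: ", paste(bad, collapse = ", "))
    bad <- tissue[pct_CO < 0 | pct_CO > 100 | pct_lymph < 0 | pct_lymph > 100]
    if (length(bad)) stop("percentages outside [0, 100] for: ", paste(bad, collapse = ", "))
    for (t in c("spleen", "bone")) {
      if (t %in% tissue && tab$pct_lymph[tab$tissue == t] != 0) {
        stop(t, " must have zero lymph flow (no exiting lymph vessels)")
      }
    }
  })
  invisible(tab)
}

# Tissues whose venous outflow drains into the liver vascular space.
PORTAL_TISSUES <- c("gut", "spleen", "pancreas")

MANDATORY_TISSUES <- c("adipose", "bone", "brain", "gut", "heart", "kidney",
                       "liver", "lung", "muscle", "pancreas", "skin",
                       "spleen", "sc_site")

#' Default whole-body configuration constants
#'
#' Body weight, cardiac output and total lymph flow of the reference
#' individual, together with the total blood volume. The total blood volume
#' is not an independent measurement: it is fixed so that the residual-blood
#' split (2/3 venous : 1/3 arterial) reproduces the packaged venous and
#' arterial blood volumes of 2.33 L and 1.165 L given the summed tissue
#' vascular volumes.
#'
#' @return Named list of configuration constants.
#' @export
physiology_defaults <- function() {
  list(
    body_weight_kg = 80.7,
    cardiac_output_L_per_h = 356,
    total_lymph_flow_L_per_h_per_kg = 0.00386,
    total_blood_volume_L = 5.760223,
    central_lymph_volume_L = 0.312,
    liver_flow_convention = "total-25.5",
    sc_site_vi_override_mL = NULL,
    body_surface_area_m2 = 1.9
  )
}

#' Build the whole-body physiology object
#'
#' Derives, for every tissue, the vascular volume (V_v = V_total * f_vasc),
#' the interstitial volume (V_i = V_total * f_EW - V_v), the blood flow and
#' the lymph flow, and closes the whole-body mass/flow balance with a bypass
#' compartment that absorbs the residual cardiac output and lymph flow. The
#' bypass is a pure vascular pass-through: blood enters at the arterial
#' concentration and returns to venous blood, its lymph flow joins the
#' central lymph as solute-free filtrate, and it has no interstitial
#' exchange.
#'
#' Venous and arterial blood volumes split the blood volume not residing in
#' tissue vascular spaces 2/3 : 1/3.
#'
#' The liver receives both a hepatic-artery inflow and the venous outflows of
#' gut, spleen and pancreas. Under the default convention
#' (\code{"total-25.5"}) total liver perfusion is 25.5\% of cardiac output
#' and the hepatic artery carries the difference between that and the portal
#' inflow. The alternative \code{"ha-19"} reads the hepatic artery flow
#' literally as 19\% of cardiac output; that reading over-allocates the
#' cardiac output (arterial draws then exceed 100\%) and is rejected with an
#' informative error.
#'
#' @param table Tissue table, see [tissue_table()].
#' @param body_weight Body weight, kg.
#' @param Q_c Cardiac output, L/h.
#' @param L_total_per_kg Total lymph flow, L/h/kg.
#' @param total_blood_volume Total blood volume, L.
#' @param V_LN Central lymph compartment volume, L.
#' @param liver_flow_convention `"total-25.5"` (default) or `"ha-19"`.
#' @param sc_site_vi_override_mL Optional replacement for the SC-site
#'   interstitial volume, in mL (e.g. 3.0 to use the rounded literature
#'   estimate instead of the value implied by the volume fractions).
#' @param lymph_scale Non-negative scalar multiplying every lymph flow
#'   (including total lymph flow); 1 leaves the standard physiology
#'   untouched. Used by the lymph-flow sensitivity analysis.
#' @return An object of class `pbpk_physiology`.
#' @export
build_physiology <- function(table = tissue_table(),
                             body_weight = physiology_defaults()$body_weight_kg,
                             Q_c = physiology_defaults()$cardiac_output_L_per_h,
                             L_total_per_kg = physiology_defaults()$total_lymph_flow_L_per_h_per_kg,
                             total_blood_volume = physiology_defaults()$total_blood_volume_L,
                             V_LN = physiology_defaults()$central_lymph_volume_L,
                             liver_flow_convention = c("total-25.5", "ha-19"),
                             sc_site_vi_override_mL = NULL,
                             lymph_scale = 1) {
  liver_flow_convention <- match.arg(liver_flow_convention)
  validate_tissue_table(table)
  missing <- setdiff(MANDATORY_TISSUES, table$tissue)
  if (length(missing) > 0) {
    stop("missing mandatory tissue(s): ", paste(missing, collapse = ", "))
  }
  if (lymph_scale < 0) stop("lymph_scale must be non-negative")

  tis <- table
  tis$V_v <- tis$V_total * tis$f_vasc
  tis$V_i <- tis$V_total * tis$f_EW - tis$V_v
  bad <- tis$tissue[tis$V_i <= 0]
  if (length(bad)) stop("non-positive interstitial volume for: ", paste(bad, collapse = ", "))

  if (!is.null(sc_site_vi_override_mL)) {
    stopifnot(sc_site_vi_override_mL > 0)
    tis$V_i[tis$tissue == "sc_site"] <- sc_site_vi_override_mL / 1000
  }

  L_total <- L_total_per_kg * body_weight * lymph_scale
  # standard (unscaled) lymph flow: the pore-conductance closure is anchored
  # to it, since pore geometry does not change when flow is perturbed
  tis$L_org_std <- tis$pct_lymph / 100 * L_total_per_kg * body_weight
  tis$L_org <- tis$L_org_std * lymph_scale

  # Total perfusion per tissue; for the lung this is the full cardiac output.
  tis$Q_org <- tis$pct_CO / 100 * Q_c

  portal_Q <- sum(tis$Q_org[tis$tissue %in% PORTAL_TISSUES])
  portal_L <- sum(tis$L_org[tis$tissue %in% PORTAL_TISSUES])
  liver_total_Q <- tis$Q_org[tis$tissue == "liver"]
  if (liver_flow_convention == "total-25.5") {
    Q_ha <- liver_total_Q - portal_Q
  } else {
    Q_ha <- 0.19 * Q_c
    liver_total_Q <- Q_ha + portal_Q
    tis$Q_org[tis$tissue == "liver"] <- liver_total_Q
  }
  if (Q_ha <= 0) stop("hepatic artery flow is non-positive under this convention")

  # Arterial draw per tissue (what leaves the arterial blood compartment);
  # for the liver this is the hepatic artery only, and the lung draws from
  # venous blood, not arterial.
  tis$Q_art <- tis$Q_org
  tis$Q_art[tis$tissue == "liver"] <- Q_ha
  tis$Q_art[tis$tissue == "lung"] <- 0

  # Blood inflow per tissue (for the liver, artery plus portal venous inflow).
  tis$Q_in <- tis$Q_org
  tis$Q_in[tis$tissue == "liver"] <- Q_ha + portal_Q - portal_L

  bad <- tis$tissue[tis$L_org > tis$Q_in]
  if (length(bad)) {
    stop("lymph flow exceeds blood inflow for: ", paste(bad, collapse = ", "))
  }

  V_vb <- (total_blood_volume - sum(tis$V_v)) * 2 / 3
  V_ab <- (total_blood_volume - sum(tis$V_v)) * 1 / 3
  if (V_vb <= 0) stop("total blood volume smaller than summed tissue vascular volumes")

  L_lung <- tis$L_org[tis$tissue == "lung"]
  arterial_draws <- sum(tis$Q_art)
  Q_bypass <- (Q_c - L_lung) - arterial_draws
  if (Q_bypass < 0) {
    stop("arterial flow over-allocated (bypass blood flow would be negative, ",
         signif(Q_bypass, 4), " L/h); the liver flow convention '",
         liver_flow_convention, "' cannot close the flow balance")
  }
  L_bypass <- L_total - sum(tis$L_org)
  if (L_bypass < 0) stop("tissue lymph flows exceed total lymph flow")

  V_residual <- body_weight - sum(tis$V_total) - total_blood_volume - V_LN

  structure(list(
    tissues = tis,
    body_weight = body_weight,
    Q_c = Q_c,
    L_total = L_total,
    L_total_per_kg = L_total_per_kg,
    total_blood_volume = total_blood_volume,
    V_vb = V_vb,
    V_ab = V_ab,
    V_LN = V_LN,
    bypass = list(Q = Q_bypass, L = L_bypass, V_residual = V_residual),
    liver_flow_convention = liver_flow_convention,
    lymph_scale = lymph_scale
  ), class = "pbpk_physiology")
}

#' @export
print.pbpk_physiology <- function(x, ...) {
  cat("Whole-body PBPK physiology\n")
  cat(sprintf("  body weight      %.1f kg\n", x$body_weight))
  cat(sprintf("  cardiac output   %.0f L/h\n", x$Q_c))
  cat(sprintf("  total lymph flow %.6f L/h (scale %.3g)\n", x$L_total, x$lymph_scale))
  cat(sprintf("  blood volumes    venous %.3f L, arterial %.3f L (total %.3f L)\n",
              x$V_vb, x$V_ab, x$total_blood_volume))
  cat(sprintf("  bypass           Q %.2f L/h, L %.5f L/h\n", x$bypass$Q, x$bypass$L))
  cat(sprintf("  %d tissues (liver convention: %s)\n",
              nrow(x$tissues), x$liver_flow_convention))
  invisible(x)
}

tissue_row <- function(phys, tissue) {
  i <- match(tissue, phys$tissues$tissue)
  if (is.na(i)) stop("unknown tissue: ", tissue)
  phys$tissues[i, , drop = FALSE]
}
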