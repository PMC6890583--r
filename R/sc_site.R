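# Calibration of the subcutaneous dosing site from radiolabelled depot data:
# spherical depot volume from injection diameter, lymph flow from the
# fractional drainage rate, and subject-weighted means.

#' Packaged SC depot studies
#'
#' The radiolabelled IgG / albumin depot observations used to size the SC
#' dosing site: number of subjects, depot diameter and, where reported, the
#' fractional drainage rate K (%/min). The albumin study reports no K.
#'
#' @param path Optional path to an alternative tab-separated table.
#' @return data.frame with one row per study.
#' @export
depot_studies <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "sc_depot_studies.tsv",
                        package = "protpbpk", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protein", "n_subjects", "diameter_cm", "K_pct_per_min")
                %in% names(tab)))
  if (any(tab$diameter_cm <= 0)) stop("depot diameters must be positive")
  if (any(tab$n_subjects < 1)) stop("subject counts must be >= 1")
  if (any(!is.na(tab$K_pct_per_min) & tab$K_pct_per_min < 0)) {
    stop("drainage rates must be non-negative")
  }
  tab
}

#' Spherical depot volume from injection diameter
#'
#' Assumes the dose distributes into a sphere; the volume is computed on the
#' unrounded radius diameter / 2.
#'
#' @param diameter_cm Depot diameter, cm.
#' @return Volume, mL.
#' @export
depot_volume <- function(diameter_cm) {
  if (any(diameter_cm <= 0)) stop("diameter must be positive")
  (4 / 3) * pi * (diameter_cm / 2)^3
}

#' SC-site lymph flow from the fractional drainage rate
#'
#' The drainage rate constant of a protein too large to cross the
#' endothelial pores equals lymph flow over depot volume, so
#' lymph flow = (K / 100) * volume.
#'
#' @param K_pct_per_min Fractional loss rate, percent per minute.
#' @param volume_mL Depot volume, mL.
#' @return Lymph flow, mL/min.
#' @export
lymph_flow_from_k <- function(K_pct_per_min, volume_mL) {
  if (any(K_pct_per_min < 0)) stop("K must be non-negative")
  if (any(volume_mL <= 0)) stop("volume must be positive")
  K_pct_per_min / 100 * volume_mL
}

#' Subject-weighted means of the depot calibration statistics
#'
#' Arithmetic means weighted by the number of subjects per study. Studies
#' with no reported drainage rate contribute to the volume mean only.
#'
#' @param studies A [depot_studies()] table.
#' @return List with `volume_mL`, `K_pct_per_min`, `lymph_flow_mL_per_min`
#'   and a per-study table of the derived quantities.
#' @export
sc_weighted_means <- function(studies = depot_studies()) {
  if (nrow(studies) == 0) stop("no studies supplied")
  studies$volume_mL <- depot_volume(studies$diameter_cm)
  has_k <- !is.na(studies$K_pct_per_min)
  studies$lymph_flow_mL_per_min <- NA_real_
  studies$lymph_flow_mL_per_min[has_k] <-
    lymph_flow_from_k(studies$K_pct_per_min[has_k], studies$volume_mL[has_k])
  wmean <- function(x, w) sum(x * w) / sum(w)
  if (!any(has_k)) stop("no study reports a drainage rate")
  list(
    volume_mL = wmean(studies$volume_mL, studies$n_subjects),
    K_pct_per_min = wmean(studies$K_pct_per_min[has_k],
                          studies$n_subjects[has_k]),
    lymph_flow_mL_per_min = wmean(studies$lymph_flow_mL_per_min[has_k],
                                  studies$n_subjects[has_k]),
    studies = studies
  )
}

#' Recorded average fractional IgG loss rate
#'
#' The literature-averaged fractional rate of radiolabelled IgG loss from
#' the SC site, 0.0009725 per minute, is carried as a recorded constant:
#' no weighting of the per-study drainage rates in [depot_studies()]
#' reproduces it, so it is not a computed output of this package.
#'
#' @return The constant, per minute.
#' @export
igg_fractional_loss_rate_per_min <- function() 0.0009725
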