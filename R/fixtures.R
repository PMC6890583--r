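# Packaged drug library and scenario generation.

#' Packaged protein study table
#'
#' One row per study/dose level of the subcutaneous validation dataset:
#' protein identity (molecular weight, hydrodynamic radius, isoelectric
#' point), the administered dose with its unit, and the model-predicted
#' peak concentration / time of peak together with their published fold
#' errors (predicted/observed).
#'
#' @param path Optional path to an alternative tab-separated table.
#' @return data.frame with one row per study.
#' @export
protein_studies <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "protein_studies.tsv",
                        package = "protpbpk", mustWork = TRUE)
  }
  utils::read.delim(path, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
}

#' Synthetic per-drug disposition parameter overlay
#'
#' Plasma clearance, blood/plasma ratio and SC bioavailability for the
#' quantitative validation scenarios. These values are literature-typical
#' estimates assembled for this package (see the file header of
#' `drug_params_synthetic.tsv`); they are synthetic stand-ins, not a
#' published reference table. Its absence degrades validation coverage but
#' never breaks the library build.
#'
#' @param path Optional path to an alternative overlay table.
#' @return data.frame with columns protein, CL_p, BP, F; or NULL when the
#'   file is absent.
#' @export
drug_overlay <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "drug_params_synthetic.tsv",
                        package = "protpbpk")
  }
  if (path == "" || !file.exists(path)) return(NULL)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Convert an international-unit dose to mass
#'
#' @param iu Dose in IU.
#' @param iu_per_mg Specific activity, IU/mg.
#' @return Dose, mg.
#' @export
iu_to_mg <- function(iu, iu_per_mg) {
  stopifnot(iu >= 0, iu_per_mg > 0)
  iu / iu_per_mg
}

#' Resolve a study dose record to an absolute amount
#'
#' Per-kg doses multiply by body weight; per-m2 doses multiply by body
#' surface area; doses recorded in milli-international units (or percent of
#' dose) are kept in their native activity unit, which the linear model
#' carries through so that simulated concentrations come out in the matching
#' unit (e.g. mIU/L).
#'
#' @param dose Dose value as recorded.
#' @param unit One of `"mg"`, `"mg_per_kg"`, `"mg_per_m2"`, `"mIU"`,
#'   `"mIU_per_kg"`, `"pct_dose"`.
#' @param body_weight Body weight, kg.
#' @param bsa Body surface area, m^2.
#' @return List with `amount`, `amount_unit` (`"mg"`, `"mIU"` or
#'   `"pct_dose"`) and `conc_unit`.
#' @export
resolve_dose <- function(dose, unit, body_weight = 80.7, bsa = 1.9) {
  switch(unit,
    mg = list(amount = dose, amount_unit = "mg", conc_unit = "mg_per_L"),
    mg_per_kg = list(amount = dose * body_weight, amount_unit = "mg",
                     conc_unit = "mg_per_L"),
    mg_per_m2 = list(amount = dose * bsa, amount_unit = "mg",
                     conc_unit = "mg_per_L"),
    mIU = list(amount = dose, amount_unit = "mIU", conc_unit = "mIU_per_L"),
    mIU_per_kg = list(amount = dose * body_weight, amount_unit = "mIU",
                      conc_unit = "mIU_per_L"),
    pct_dose = list(amount = dose, amount_unit = "pct_dose",
                    conc_unit = "pct_dose"),
    stop("unknown dose unit '", unit, "'")
  )
}

#' Build the drug library from the packaged study table
#'
#' Groups the study table by protein, attaches the disposition overlay where
#' available, resolves every dose to an absolute amount, and flags records
#' that lack clearance/bioavailability as incomplete (they load, but are
#' excluded from quantitative validation).
#'
#' @param studies A [protein_studies()] table.
#' @param overlay A [drug_overlay()] table (or NULL).
#' @param body_weight Body weight used for per-kg doses, kg.
#' @param bsa Body surface area used for per-m2 doses, m^2.
#' @return A list of class `drug_library`: per-protein records each holding
#'   a [drug_properties()] object (placeholder CL_p = 0, BP = 1, F = 1 when
#'   incomplete), a `complete` flag and the per-study dose table.
#' @export
build_drug_library <- function(studies = protein_studies(),
                               overlay = drug_overlay(),
                               body_weight = physiology_defaults()$body_weight_kg,
                               bsa = physiology_defaults()$body_surface_area_m2) {
  bad <- setdiff(unique(studies$dose_unit),
                 c("mg", "mg_per_kg", "mg_per_m2", "mIU", "mIU_per_kg",
                   "pct_dose"))
  if (length(bad)) {
    rows <- studies$protein[studies$dose_unit %in% bad]
    stop("unknown dose unit(s) ", paste(bad, collapse = ", "),
         " in record(s): ", paste(unique(rows), collapse = ", "))
  }
  lib <- lapply(split(studies, studies$protein), function(d) {
    p <- d$protein[1]
    ov <- if (!is.null(overlay) && p %in% overlay$protein) {
      overlay[overlay$protein == p, , drop = FALSE]
    } else NULL
    complete <- !is.null(ov)
    drug <- drug_properties(
      name = p, Rs = d$rs_nm[1], MW = d$mw_kda[1],
      CL_p = if (complete) ov$CL_p else 0,
      BP = if (complete) ov$BP else 1,
      F = if (complete) ov$F else 1,
      pI = d$pI[1])
    res <- lapply(seq_len(nrow(d)), function(i) {
      resolve_dose(d$dose[i], d$dose_unit[i], body_weight, bsa)
    })
    d$amount <- vapply(res, `[[`, numeric(1), "amount")
    d$amount_unit <- vapply(res, `[[`, character(1), "amount_unit")
    list(drug = drug, complete = complete, studies = d)
  })
  structure(lib[order(match(names(lib), unique(studies$protein)))],
            class = "drug_library")
}

#' @export
print.drug_library <- function(x, ...) {
  n_st <- sum(vapply(x, function(r) nrow(r$studies), integer(1)))
  cat(sprintf("<drug_library> %d proteins, %d studies/dose levels\n",
              length(x), n_st))
  for (r in x) {
    cat(sprintf("  %-14s Rs %.3g nm, %2d studies%s\n", r$drug$name,
                r$drug$Rs, nrow(r$studies),
                if (r$complete) "" else "  [incomplete: placeholder CL_p/F]"))
  }
  invisible(x)
}

#' Hypothetical protein panel
#'
#' Non-eliminated unit-dose proteins spanning a range of hydrodynamic radii,
#' used for the steady-state distribution and SC-sweep validation surfaces.
#'
#' @param rs_nm Hydrodynamic radii, nm (default 1-11 in 1 nm steps).
#' @param dose_amount Unit dose, mg.
#' @return List of scenarios, each with a [drug_properties()] (CL_p = 0,
#'   F = 1, BP = 1) and a unit SC dose event.
#' @export
hypothetical_panel <- function(rs_nm = 1:11, dose_amount = 1) {
  if (any(rs_nm <= 0)) stop("hydrodynamic radii must be positive")
  lapply(rs_nm, function(rs) {
    list(drug = drug_properties(sprintf("panel_Rs_%g", rs), Rs = rs,
                                CL_p = 0, BP = 1, F = 1),
         dose = dose_event("sc", dose_amount))
  })
}
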