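# Per-interval indirect-calorimetry computations. Four equations drive the
# whole analysis:
#   RER = VCO2 / VO2
#   CV  = 3.815 + 1.232 * RER            (Lusk calorific value, kcal per L O2)
#   EE  = CV * VO2                        (VO2 in L/kg/hr -> kcal/kg/hr)
#   carbohydrate oxidation = 4.585*VCO2 - 3.226*VO2
#   lipid oxidation        = 1.695*VO2  - 1.701*VCO2   (Frayn-type forms)

ox_coef <- matrix(c(-3.226, 4.585,    # carb  row:  (vo2, vco2)
                    1.695, -1.701),   # lipid row
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("carb", "lipid"), c("vo2", "vco2")))

#' Respiratory exchange ratio
#'
#' @param vo2,vco2 Gas volumes (same units); `vo2` must be positive.
#' @return `vco2 / vo2`, elementwise.
#' @export
#' @examples
#' compute_rer(5, 5)
compute_rer <- function(vo2, vco2) {
  if (any(vo2 <= 0)) abort("vo2 must be > 0 to form RER")
  vco2 / vo2
}

#' Lusk calorific value
#'
#' kcal released per liter of O2 consumed: `3.815 + 1.232 * RER`.
#'
#' @param rer Respiratory exchange ratio.
#' @return Calorific value, kcal per L O2.
#' @export
#' @examples
#' compute_cv(0.90)
compute_cv <- function(rer) {
  if (any(!is.finite(rer))) abort("rer must be finite")
  3.815 + 1.232 * rer
}

#' Energy expenditure (metabolic rate)
#'
#' Product of the calorific value and oxygen consumption. Gas channels are
#' stored in ml/kg/hr, so VO2 is converted to L/kg/hr first.
#'
#' @param cv Calorific value, kcal per L O2.
#' @param vo2 Oxygen consumption, ml/kg/hr.
#' @return Energy expenditure, kcal/kg/hr.
#' @export
#' @examples
#' compute_ee(compute_cv(0.90), 3860)
compute_ee <- function(cv, vo2) {
  cv * (vo2 / 1000)
}

#' Carbohydrate and lipid oxidation rates
#'
#' Evaluates the two linear oxidation forms
#' `carb = 4.585*VCO2 - 3.226*VO2` and `lipid = 1.695*VO2 - 1.701*VCO2`.
#' Inputs are expected on the oxidation scale (L/kg/hr in this pipeline; see
#' the methods vignette for the unit convention). Negative values are
#' reported as computed, never clamped; their count is returned in the
#' `n_negative` attribute.
#'
#' @param vo2,vco2 Gas volumes on the oxidation scale.
#' @return Tibble with columns `carb_ox` and `lipid_ox` (nominal g/min).
#' @export
#' @examples
#' compute_substrate_oxidation(6.278, 5.697)
compute_substrate_oxidation <- function(vo2, vco2) {
  carb <- ox_coef["carb", "vo2"] * vo2 + ox_coef["carb", "vco2"] * vco2
  lipid <- ox_coef["lipid", "vo2"] * vo2 + ox_coef["lipid", "vco2"] * vco2
  out <- tibble(carb_ox = carb, lipid_ox = lipid)
  attr(out, "n_negative") <- sum(carb < 0) + sum(lipid < 0)
  out
}

#' Invert the substrate-oxidation equations
#'
#' Exact 2x2 linear solve recovering (VO2, VCO2) from (carbohydrate, lipid)
#' oxidation rates; the round trip through
#' [compute_substrate_oxidation()] is exact to numerical precision. Used as a
#' consistency check between printed oxidation rates and printed RER.
#'
#' @param carb_ox,lipid_ox Oxidation rates.
#' @return Tibble with columns `vo2` and `vco2`.
#' @export
#' @examples
#' invert_substrate_oxidation(5.87, 0.95)
invert_substrate_oxidation <- function(carb_ox, lipid_ox) {
  sol <- solve(ox_coef, rbind(carb_ox, lipid_ox))
  tibble(vo2 = as.numeric(sol["vo2", ]), vco2 = as.numeric(sol["vco2", ]))
}

#' Derive the full per-interval metabolic series from a gas trace
#'
#' Computes RER, calorific value, energy expenditure and the two substrate
#' oxidation channels for every interval of a calorimetry trace.
#'
#' @param trace A `calorimetry_trace` (see [read_trace_csv()] or
#'   [generate_calorimetry_trace()]).
#' @return A `metabolic_series` tibble: the trace's identity and timestamp
#'   columns plus `rer`, `cv`, `ee`, `carb_ox`, `lipid_ox`.
#' @export
#' @examples
#' tr <- generate_calorimetry_trace(builtin_presets()$baseline, seed = 1)
#' derive_metabolic_series(tr)
derive_metabolic_series <- function(trace) {
  trace <- validate_calorimetry_trace(trace)
  bad <- which(trace$vo2 <= 0)
  if (length(bad)) {
    abort(paste0("vo2 <= 0 at interval(s) ", paste(head(bad, 5), collapse = ", ")))
  }
  rer <- compute_rer(trace$vo2, trace$vco2)
  cv <- compute_cv(rer)
  ee <- compute_ee(cv, trace$vo2)
  ox <- compute_substrate_oxidation(trace$vo2 / 1000, trace$vco2 / 1000)
  out <- dplyr::bind_cols(
    dplyr::select(trace, dplyr::any_of(c("subject_id", "group", "timepoint",
                                         "timestamp"))),
    tibble(rer = rer, cv = cv, ee = ee),
    ox
  )
  attr(out, "interval_width") <- attr(trace, "interval_width") %||% 4
  class(out) <- c("metabolic_series", class(tibble()))
  out
}
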