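#' Water-use efficiency
#'
#' `WUE = Y / (P_e + I + SW)`: economic yield per unit of total applied water
#' — irrigation, effective rainfall and soil-water depletion from the root
#' zone. With yield in kg/ha and water in m3/ha the result is kg/m3.
#'
#' @param yield Economic yield `Y` (kg/ha).
#' @param irrigation Irrigation water `I` (m3/ha).
#' @param effective_rainfall Effective rainfall `P_e` (m3/ha, default 0).
#' @param soil_depletion Soil-water depletion `SW` (m3/ha, default 0).
#' @return WUE in kg/m3. Vectorized.
#' @examples
#' water_use_efficiency(5000, 800, 100, 100)  # 5 kg/m3
#' @export
water_use_efficiency <- function(yield, irrigation, effective_rainfall = 0,
                                 soil_depletion = 0) {
  denom <- irrigation + effective_rainfall + soil_depletion
  if (any(yield < 0) || any(irrigation < 0) || any(effective_rainfall < 0) ||
      any(soil_depletion < 0)) {
    stop("water-balance components must be non-negative")
  }
  if (any(denom <= 0)) stop("total applied water must be positive")
  yield / denom
}

#' Irrigation application efficiency
#'
#' `AE = D_z / D_app * 100`: the share of the applied depth stored in the
#' root zone, in percent. Warns when the stored depth exceeds the applied
#' depth (physically suspect input).
#'
#' @param d_z Average depth stored in the root zone (mm).
#' @param d_app Average depth applied to the irrigated area (mm), positive.
#' @return Application efficiency in percent. Vectorized.
#' @examples
#' application_efficiency(57.5, 74.3)
#' @export
application_efficiency <- function(d_z, d_app) {
  if (any(d_app <= 0)) stop("`d_app` must be positive")
  if (any(d_z < 0)) stop("`d_z` must be non-negative")
  if (any(d_z > d_app)) {
    warning("stored depth exceeds applied depth for some events")
  }
  d_z / d_app * 100
}

#' Applied irrigation depth
#'
#' `D_app = V / A`; one liter per square meter is one millimeter of depth.
#'
#' @param volume_l Inlet volume (liters).
#' @param area_m2 Irrigated area (square meters), positive.
#' @return Applied depth in mm. Vectorized.
#' @examples
#' applied_depth(1000, 10)  # 100 mm
#' applied_depth(8.61 * 93 * 60, 1000)
#' @export
applied_depth <- function(volume_l, area_m2) {
  if (any(area_m2 <= 0)) stop("`area_m2` must be positive")
  if (any(volume_l < 0)) stop("`volume_l` must be non-negative")
  volume_l / area_m2
}

#' Daily water requirement under shaded-strip irrigation
#'
#' In a narrow-strip layout only the canopy-shaded strip transpires, so the
#' daily requirement scales the crop evapotranspiration by the shading
#' factor: `R_r = ET_c * (h_s + 0.15 (1 - h_s))`. For mature orchard trees
#' the shading fraction is typically 0.5–0.7; values outside that window are
#' allowed but flagged with a warning.
#'
#' @param et_c Maximum daily crop evapotranspiration (mm/day, non-negative).
#' @param h_s Canopy shading fraction in `[0, 1]`.
#' @return Daily requirement in mm/day. Vectorized.
#' @examples
#' nsi_daily_requirement(5, 0.6)  # 3.3 mm/day
#' @export
nsi_daily_requirement <- function(et_c, h_s) {
  if (any(h_s < 0) || any(h_s > 1)) stop("`h_s` must lie in [0, 1]")
  if (any(et_c < 0)) stop("`et_c` must be non-negative")
  if (any(h_s < 0.5 | h_s > 0.7)) {
    warning("shading fraction outside the typical 0.5-0.7 window for trees")
  }
  et_c * (h_s + 0.15 * (1 - h_s))
}

#' Compare irrigation treatments against a reference
#'
#' Computes, for every non-reference treatment: the WUE advantage of the
#' reference (`WUE_ref - WUE_other`, kg/m3), the yield increase of the
#' reference relative to its own yield (`(Y_ref - Y_other) / Y_ref * 100`),
#' and — when per-event data are supplied — the mean application efficiency
#' per treatment and the relative mean-AE increase
#' (`(AE_ref - AE_other) / AE_ref * 100`).
#'
#' @param summaries Data frame with columns `treatment`, `yield_kg_ha`,
#'   `wue_kg_m3` (e.g. [load_fixture]`("table5_summary")`).
#' @param events Optional data frame with columns `treatment` and `AE_pct`
#'   (e.g. [load_fixture]`("table4_events")`).
#' @param reference Treatment label used as the reference (default `"NSI"`).
#' @return An object of class `treatment_comparison`: data frame with one row
#'   per non-reference treatment and columns `treatment`, `wue_diff_kg_m3`,
#'   `yield_increase_pct`, `mean_ae_pct`, `ae_increase_pct` (the last two
#'   `NA` without event data), plus attributes `reference`,
#'   `reference_mean_ae`.
#' @examples
#' compare_treatments(load_fixture("table5_summary"),
#'                    load_fixture("table4_events"))
#' @export
compare_treatments <- function(summaries, events = NULL, reference = "NSI") {
  req <- c("treatment", "yield_kg_ha", "wue_kg_m3")
  missing <- setdiff(req, names(summaries))
  if (length(missing)) {
    stop("`summaries` lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!reference %in% summaries$treatment) {
    stop("reference treatment '", reference, "' not present")
  }
  ref <- summaries[summaries$treatment == reference, ]
  others <- summaries[summaries$treatment != reference, , drop = FALSE]
  mean_ae <- function(tr) {
    if (is.null(events)) return(NA_real_)
    if (!all(c("treatment", "AE_pct") %in% names(events))) {
      warning("`events` lacks treatment/AE_pct columns; AE comparison omitted")
      return(NA_real_)
    }
    vals <- events$AE_pct[events$treatment == tr]
    if (!length(vals)) return(NA_real_)
    mean(vals)
  }
  ref_ae <- mean_ae(reference)
  out <- data.frame(
    treatment = others$treatment,
    wue_diff_kg_m3 = ref$wue_kg_m3 - others$wue_kg_m3,
    yield_increase_pct =
      (ref$yield_kg_ha - others$yield_kg_ha) / ref$yield_kg_ha * 100,
    mean_ae_pct = vapply(others$treatment, mean_ae, numeric(1)),
    stringsAsFactors = FALSE
  )
  out$ae_increase_pct <- (ref_ae - out$mean_ae_pct) / ref_ae * 100
  attr(out, "reference") <- reference
  attr(out, "reference_mean_ae") <- ref_ae
  class(out) <- c("treatment_comparison", "data.frame")
  out
}

#' @export
print.treatment_comparison <- function(x, ...) {
  cat("Treatment comparison (reference: ", attr(x, "reference"), ")\n",
      sep = "")
  if (!is.na(attr(x, "reference_mean_ae"))) {
    cat(sprintf("  reference mean AE: %.2f%%\n", attr(x, "reference_mean_ae")))
  }
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Classify a coefficient of variation
#'
#' Field-variability convention: below 15% the variable shows low changes,
#' from 15 to 35% (boundaries included) moderate changes, above 35% great
#' changes.
#'
#' @param cv Coefficient(s) of variation in percent, non-negative.
#' @return Character vector with levels `"low"`, `"moderate"`, `"great"`.
#' @examples
#' classify_cv(c(10, 15, 40))
#' @export
classify_cv <- function(cv) {
  if (any(cv < 0)) stop("`cv` must be non-negative")
  ifelse(cv < 15, "low", ifelse(cv <= 35, "moderate", "great"))
}
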