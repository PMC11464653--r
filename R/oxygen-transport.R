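#' Physiological constants for oxygen-transport calculations
#'
#' Hemoglobin O2 binding capacity (mL/g), dissolved-O2 solubility
#' (mL/dL/mmHg), barometric pressure, water vapor pressure (mmHg),
#' respiratory quotient and assumed end-capillary saturation. All
#' configurable; the record travels with every derived result.
#'
#' @param k1 binding capacity (mL O2 per g Hb).
#' @param k2 dissolved coefficient (mL O2/dL/mmHg).
#' @param pb barometric pressure (mmHg). @param ph2o water vapor pressure
#'   (mmHg). @param rq respiratory quotient. @param sc_o2 end-capillary
#'   saturation (fraction).
#' @return named list of constants.
#' @export
o2_constants <- function(k1 = 1.34, k2 = 0.003, pb = 760, ph2o = 47,
                         rq = 0.8, sc_o2 = 1.0) {
  list(k1 = k1, k2 = k2, pb = pb, ph2o = ph2o, rq = rq, sc_o2 = sc_o2)
}

#' Blood oxygen content
#'
#' `content = k1 x Hb x SO2 + k2 x PO2` (mL O2/dL).
#'
#' @param hb hemoglobin (g/dL). @param so2 saturation (fraction, 0-1).
#' @param po2 partial pressure (mmHg).
#' @param constants an [o2_constants()] record.
#' @return oxygen content (mL/dL).
#' @export
o2_content <- function(hb, so2, po2, constants = o2_constants()) {
  if (any(hb <= 0)) stop("`hb` must be positive")
  if (any(so2 < 0 | so2 > 1)) stop("`so2` must lie in [0, 1]")
  if (any(po2 < 0)) stop("`po2` must be non-negative")
  constants$k1 * hb * so2 + constants$k2 * po2
}

#' End-capillary oxygen content via the alveolar gas equation
#'
#' `PAO2 = FiO2 x (Pb - PH2O) - PaCO2/RQ`; end-capillary blood is assumed
#' fully saturated (ScO2 = 1 by default), so
#' `CcO2 = k1 x Hb x ScO2 + k2 x PAO2`.
#'
#' @param fio2 inspired oxygen fraction (0, 1].
#' @param paco2 arterial CO2 tension (mmHg).
#' @param hb hemoglobin (g/dL).
#' @param constants an [o2_constants()] record.
#' @return end-capillary content (mL/dL), attribute `pao2_alv` (mmHg).
#' @export
capillary_content <- function(fio2, paco2, hb, constants = o2_constants()) {
  if (any(fio2 <= 0 | fio2 > 1)) stop("`fio2` must lie in (0, 1]")
  if (any(paco2 <= 0)) stop("`paco2` must be positive")
  pao2_alv <- fio2 * (constants$pb - constants$ph2o) - paco2 / constants$rq
  if (any(pao2_alv <= 0)) stop("alveolar PO2 is not positive: check FiO2 and PaCO2")
  cc <- o2_content(hb, constants$sc_o2, pao2_alv, constants)
  attr(cc, "pao2_alv") <- pao2_alv
  cc
}

#' Berggren venous-admixture shunt fraction
#'
#' `Qs/Qt = (CcO2 - CaO2) / (CcO2 - CvO2)`. Values outside [0, 1]
#' (possible with inconsistent measured panels) are clipped and flagged.
#'
#' @param cc_o2,ca_o2,cv_o2 end-capillary, arterial and mixed-venous
#'   oxygen contents (mL/dL).
#' @return shunt fraction in [0, 1]; attribute `clipped` marks clipping.
#' @export
shunt_fraction <- function(cc_o2, ca_o2, cv_o2) {
  if (any(cc_o2 <= cv_o2)) {
    stop("CcO2 must exceed CvO2: shunt denominator is not positive")
  }
  raw <- (cc_o2 - ca_o2) / (cc_o2 - cv_o2)
  out <- clamp(raw, 0, 1)
  attr(out, "clipped") <- any(raw < 0 | raw > 1)
  out
}

#' Oxygen delivery
#'
#' `DO2 = CO x CaO2 x 10` (mL/min), the factor 10 bridging content per dL
#' to cardiac output per L.
#'
#' @param co cardiac output (L/min). @param ca_o2 arterial content (mL/dL).
#' @return DO2 (mL/min).
#' @export
oxygen_delivery <- function(co, ca_o2) {
  if (any(co <= 0)) stop("`co` must be positive")
  if (any(ca_o2 < 0)) stop("`ca_o2` must be non-negative")
  co * ca_o2 * 10
}

#' Oxygen uptake (Fick)
#'
#' `VO2 = CO x (CaO2 - CvO2) x 10` (mL/min). A negative arterio-venous
#' difference is returned with an implausibility flag rather than an error.
#'
#' @param co cardiac output (L/min).
#' @param ca_o2,cv_o2 arterial and mixed-venous contents (mL/dL).
#' @return VO2 (mL/min); attribute `implausible` if negative.
#' @export
oxygen_uptake <- function(co, ca_o2, cv_o2) {
  if (any(co <= 0)) stop("`co` must be positive")
  v <- co * (ca_o2 - cv_o2) * 10
  attr(v, "implausible") <- any(v < 0)
  v
}

#' Blood-gas panel container
#'
#' @param pao2,paco2,pvo2,pvco2 arterial/mixed-venous tensions (mmHg).
#' @param sao2,svo2 saturations (fraction). @param hb hemoglobin (g/dL).
#' @param fio2 inspired O2 fraction. @param lactate mmol/L (pass-through).
#' @param timepoint label.
#' @return An object of class `bloodgas_panel`.
#' @export
bloodgas_panel <- function(pao2, paco2, pvo2, pvco2, sao2, svo2, hb, fio2,
                           lactate = NA_real_, timepoint = "baseline") {
  if (any(c(sao2, svo2) < 0 | c(sao2, svo2) > 1)) stop("saturations must lie in [0, 1]")
  if (any(c(pao2, paco2, pvo2, pvco2) <= 0)) stop("partial pressures must be positive")
  if (hb <= 0) stop("`hb` must be positive")
  structure(list(pao2 = pao2, paco2 = paco2, pvo2 = pvo2, pvco2 = pvco2,
                 sao2 = sao2, svo2 = svo2, hb = hb, fio2 = fio2,
                 lactate = lactate, timepoint = timepoint),
            class = "bloodgas_panel")
}

#' Full oxygen-transport panel
#'
#' Computes arterial, mixed-venous and end-capillary contents, DO2, VO2
#' and the Berggren shunt from a blood-gas panel and thermodilution
#' cardiac output; the constants record is embedded in the result.
#'
#' @param panel a [bloodgas_panel()].
#' @param co cardiac output (L/min).
#' @param constants an [o2_constants()] record.
#' @return An object of class `o2_transport`.
#' @export
transport_panel <- function(panel, co, constants = o2_constants()) {
  stopifnot(inherits(panel, "bloodgas_panel"))
  ca <- o2_content(panel$hb, panel$sao2, panel$pao2, constants)
  cv <- o2_content(panel$hb, panel$svo2, panel$pvo2, constants)
  cc <- capillary_content(panel$fio2, panel$paco2, panel$hb, constants)
  qs <- shunt_fraction(as.numeric(cc), ca, cv)
  structure(list(
    timepoint = panel$timepoint,
    ca_o2 = ca, cv_o2 = cv, cc_o2 = as.numeric(cc),
    do2 = oxygen_delivery(co, ca),
    vo2 = as.numeric(oxygen_uptake(co, ca, cv)),
    qs_qt = as.numeric(qs), qs_qt_clipped = attr(qs, "clipped"),
    co_lmin = co, constants = constants
  ), class = "o2_transport")
}

#' @export
print.o2_transport <- function(x, ...) {
  cat(sprintf(paste0("<o2_transport> [%s] CaO2 %.2f CvO2 %.2f CcO2 %.2f mL/dL\n",
    "  DO2 %.0f VO2 %.0f mL/min  Qs/Qt %.3f\n"),
    x$timepoint, x$ca_o2, x$cv_o2, x$cc_o2, x$do2, x$vo2, x$qs_qt))
  invisible(x)
}
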