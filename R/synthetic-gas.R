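#' Parameters for the venous-admixture blood-gas generator
#'
#' Forward model inverted exactly by the Berggren equation: given a true
#' shunt fraction, cardiac output, hemoglobin, FiO2 and true VO2, the two
#' linear relations `CaO2 = Qs/Qt x CvO2 + (1 - Qs/Qt) x CcO2` and
#' `CvO2 = CaO2 - VO2/(10 x CO)` have a closed-form solution; the emitted
#' panel's saturations and tensions are chosen so the contents reproduce
#' that solution exactly at zero noise.
#'
#' @param qs_qt true shunt fraction (0-1).
#' @param co cardiac output (L/min). @param hb hemoglobin (g/dL).
#' @param fio2 inspired O2 fraction. @param vo2 true oxygen uptake
#'   (mL/min). @param paco2 arterial CO2 tension (mmHg).
#' @param constants an [o2_constants()] record.
#' @param noise_sd named noise SDs for emitted values: `so2` (fraction)
#'   and `po2` (mmHg).
#' @param timepoint label. @param seed RNG seed.
#' @return An object of class `gas_exchange_params`.
#' @export
gas_exchange_params <- function(qs_qt = 0.3, co = 2, hb = 9, fio2 = 1.0,
                                vo2 = 60, paco2 = 40,
                                constants = o2_constants(),
                                noise_sd = c(so2 = 0, po2 = 0),
                                timepoint = "cpr", seed = 1L) {
  if (qs_qt < 0 || qs_qt > 1) stop("`qs_qt` must lie in [0, 1]")
  stop_if_not_scalar_pos(co, "co"); stop_if_not_scalar_pos(hb, "hb")
  if (vo2 < 0) stop("`vo2` must be non-negative")
  structure(list(qs_qt = qs_qt, co = co, hb = hb, fio2 = fio2, vo2 = vo2,
                 paco2 = paco2, constants = constants, noise_sd = noise_sd,
                 timepoint = timepoint, seed = as.integer(seed)),
            class = "gas_exchange_params")
}

# choose (SO2, PO2) reproducing a target content exactly: prefer a plausible
# PO2, push the remainder into saturation; overflow beyond SO2 = 1 goes back
# into dissolved O2
so2_po2_for_content <- function(content, hb, po2_nominal, po2_max, constants) {
  k1 <- constants$k1; k2 <- constants$k2
  so2 <- (content - k2 * po2_nominal) / (k1 * hb)
  po2 <- po2_nominal
  if (so2 > 1) {
    so2 <- 1
    po2 <- (content - k1 * hb) / k2
    if (po2 > po2_max + 1e-9) stop("content infeasible at full saturation and alveolar PO2")
    po2 <- min(po2, po2_max)
  } else if (so2 < 0) {
    so2 <- 0
    po2 <- content / k2
  }
  list(so2 = so2, po2 = po2)
}

#' Generate a blood-gas panel from the venous-admixture forward model
#'
#' @param params a [gas_exchange_params()].
#' @return list with `panel` ([bloodgas_panel()]), `reference` (the exact
#'   contents and derived DO2/VO2 implied by the truth) and `truth`
#'   (class `gas_truth`: the generating shunt, CO, VO2, seed).
#' @export
gen_bloodgas_panel <- function(params) {
  stopifnot(inherits(params, "gas_exchange_params"))
  p <- params
  cc <- capillary_content(p$fio2, p$paco2, p$hb, p$constants)
  pao2_alv <- attr(cc, "pao2_alv")
  cc <- as.numeric(cc)
  v_drop <- p$vo2 / (10 * p$co)
  if (p$qs_qt >= 1) {
    if (p$vo2 > 0) stop("VO2 must be zero at complete shunt: no oxygen is being added")
    ca <- cc - v_drop # v_drop = 0
  } else {
    ca <- cc - p$qs_qt * v_drop / (1 - p$qs_qt)
  }
  cv <- ca - v_drop
  if (cv <= 0) stop("infeasible VO2: mixed-venous content would be non-positive")

  art <- so2_po2_for_content(ca, p$hb, po2_nominal = min(100, pao2_alv),
                             po2_max = pao2_alv, constants = p$constants)
  ven <- so2_po2_for_content(cv, p$hb, po2_nominal = 40,
                             po2_max = pao2_alv, constants = p$constants)

  noisy <- with_seed(p$seed, {
    ns <- p$noise_sd
    list(sao2 = clamp(art$so2 + rnorm(1, 0, ns[["so2"]]), 0, 1),
         svo2 = clamp(ven$so2 + rnorm(1, 0, ns[["so2"]]), 0, 1),
         pao2 = max(1, art$po2 + rnorm(1, 0, ns[["po2"]])),
         pvo2 = max(1, ven$po2 + rnorm(1, 0, ns[["po2"]])))
  })
  panel <- bloodgas_panel(pao2 = noisy$pao2, paco2 = p$paco2,
                          pvo2 = noisy$pvo2, pvco2 = p$paco2 + 6,
                          sao2 = noisy$sao2, svo2 = noisy$svo2,
                          hb = p$hb, fio2 = p$fio2, timepoint = p$timepoint)
  reference <- list(cc_o2 = cc, ca_o2 = ca, cv_o2 = cv,
                    do2 = oxygen_delivery(p$co, ca),
                    vo2 = p$vo2, pao2_alv = pao2_alv)
  truth <- structure(list(qs_qt = p$qs_qt, co = p$co, vo2 = p$vo2,
                          do2 = reference$do2, seed = p$seed),
                     class = "gas_truth")
  list(panel = panel, reference = reference, truth = truth)
}
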