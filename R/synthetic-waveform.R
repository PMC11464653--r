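#' Parameters for synthetic CPR pressure waveforms
#'
#' Models the study conditions during resuscitation: volume-controlled
#' ventilation (tidal volume 500 mL, 10 breaths/min, I:E 1:1, ZEEP)
#' unsynchronized with continuous chest compressions (102/min, raised-cosine
#' pulse with 50% duty cycle, amplitude expressed directly in cmH2O of
#' esophageal pressure). Esophageal pressure is the sum of a baseline
#' offset, the volume/chest-wall-compliance term and the compression pulse
#' train; airway pressure adds the resistive and lung-elastic terms during
#' flow and settles exponentially to plateau values during occlusions.
#'
#' @param duration_s trace length (s); extended if epochs/occlusions need it.
#' @param fs sampling rate (Hz); must exceed 20x the compression frequency.
#' @param cc_rate compression rate (per min). @param cc_amp compression
#'   esophageal-pressure amplitude (cmH2O). @param duty compression duty
#'   cycle (fraction of the cycle in compression).
#' @param vent_rate ventilation rate (breaths/min). @param vt tidal volume
#'   (mL). @param ie inspiratory:expiratory time ratio. @param peep
#'   applied PEEP (cmH2O).
#' @param r_aw airway resistance (cmH2O.s/L).
#' @param cl,ccw lung and chest-wall compliance (mL/cmH2O).
#' @param pes_ee end-expiratory esophageal pressure offset (cmH2O).
#' @param epochs data.frame(label, start_s, end_s, kind, cc_amp) with kind
#'   in baseline/cc_mechanical/cc_manual/post_rosc; compression amplitude
#'   may vary per epoch.
#' @param occlusions data.frame(start_s, duration_s, kind, compressions)
#'   with kind in insp/exp and durations >= 5 s; `compressions = TRUE`
#'   marks the catheter-placement occlusion test.
#' @param transmission fraction of the compression pulse appearing on Paw
#'   during occlusions (1 = full transmission).
#' @param vascular if TRUE, emit aortic/right-atrial channels (mmHg).
#' @param ao_dia,ao_pulse,ra_base,ra_pulse vascular waveform parameters
#'   (mmHg): diastolic aortic level, aortic compression pulse, right-atrial
#'   baseline and pulse.
#' @param noise_sd additive Gaussian noise SD on the pressure channels
#'   (cmH2O). @param seed RNG seed.
#' @return An object of class `waveform_params`.
#' @export
waveform_params <- function(duration_s = 60, fs = 100, cc_rate = 102,
                            cc_amp = 12, duty = 0.5, vent_rate = 10, vt = 500,
                            ie = 1, peep = 0, r_aw = 10, cl = 50, ccw = 100,
                            pes_ee = 5, epochs = NULL, occlusions = NULL,
                            transmission = 1, vascular = FALSE, ao_dia = 25,
                            ao_pulse = 35, ra_base = 10, ra_pulse = 30,
                            noise_sd = 0.2, seed = 1L) {
  stop_if_not_scalar_pos(fs, "fs"); stop_if_not_scalar_pos(cc_rate, "cc_rate")
  stop_if_not_scalar_pos(vent_rate, "vent_rate")
  stop_if_not_scalar_pos(cl, "cl"); stop_if_not_scalar_pos(ccw, "ccw")
  if (fs < 20 * cc_rate / 60) {
    stop(sprintf("sampling rate %.1f Hz is below 20x the compression frequency (%.1f Hz): aliasing",
                 fs, cc_rate / 60))
  }
  if (!is.null(occlusions) && any(occlusions$duration_s < 5)) {
    stop("occlusion maneuvers must last at least 5 s")
  }
  if (is.null(epochs)) {
    epochs <- data.frame(label = "cc1", start_s = 0, end_s = duration_s,
                         kind = "cc_mechanical", cc_amp = cc_amp,
                         stringsAsFactors = FALSE)
  }
  if (is.null(epochs$cc_amp)) epochs$cc_amp <- cc_amp
  structure(list(duration_s = max(duration_s, max(epochs$end_s),
                                  if (!is.null(occlusions))
                                    max(occlusions$start_s + occlusions$duration_s)
                                  else 0),
                 fs = fs, cc_rate = cc_rate, cc_amp = cc_amp, duty = duty,
                 vent_rate = vent_rate, vt = vt, ie = ie, peep = peep,
                 r_aw = r_aw, cl = cl, ccw = ccw, pes_ee = pes_ee,
                 epochs = epochs, occlusions = occlusions,
                 transmission = transmission, vascular = vascular,
                 ao_dia = ao_dia, ao_pulse = ao_pulse, ra_base = ra_base,
                 ra_pulse = ra_pulse, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "waveform_params")
}

#' Pressure trace container
#'
#' @param data data.frame with columns `time_s`, `paw_cmh2o`, `pes_cmh2o`
#'   and optionally `pao_mmhg`, `pra_mmhg`; uniform sampling.
#' @param fs sampling rate (Hz).
#' @param annotations data.frame(label, start_s, end_s, kind) with kind in
#'   baseline, cc_mechanical, cc_manual, occlusion_insp, occlusion_exp,
#'   post_rosc.
#' @return An object of class `pressure_trace`.
#' @export
pressure_trace <- function(data, fs, annotations) {
  need <- c("time_s", "paw_cmh2o", "pes_cmh2o")
  if (!all(need %in% names(data))) {
    stop("trace needs columns time_s, paw_cmh2o, pes_cmh2o")
  }
  if (any(!is.finite(data$paw_cmh2o)) || any(!is.finite(data$pes_cmh2o))) {
    stop("pressures must be finite")
  }
  if (nrow(data) > 2L && diff(range(diff(data$time_s))) > 1e-6 / fs) {
    stop("sampling must be uniform")
  }
  if (!is.null(annotations) && nrow(annotations) &&
      (min(annotations$start_s) < data$time_s[1] - 1e-9 ||
       max(annotations$end_s) > data$time_s[nrow(data)] + 1 / fs + 1e-9)) {
    stop("annotations fall outside the trace span")
  }
  structure(list(data = data, fs = fs, annotations = annotations),
            class = "pressure_trace")
}

# raised-cosine pulse train; phase in cycles, duty = compression fraction
cc_pulse <- function(t, rate_per_min, duty, phase = 0) {
  tau <- (t * rate_per_min / 60 + phase) %% 1
  ifelse(tau < duty, 0.5 * (1 - cos(2 * pi * tau / duty)), 0)
}

#' Generate synchronized Paw/Pes (and optional vascular) CPR traces
#'
#' Constructs the ventilation volume signal, superimposes the unsynchronized
#' compression pulse train, derives the two pressure channels from the
#' two-compartment (lung + chest wall) linear model, inserts occlusion
#' plateaus with exponential settling, and returns the trace together with
#' a `waveform_truth` record: the true compliances, the derived
#' `crs = cl*ccw/(cl+ccw)`, exact plateau values and the exact per-cycle
#' esophageal pressure swings of the noiseless trace per epoch.
#'
#' @param params a [waveform_params()].
#' @return list with `trace` ([pressure_trace()]) and `truth`.
#' @export
gen_pressure_traces <- function(params) {
  stopifnot(inherits(params, "waveform_params"))
  p <- params
  n <- round(p$duration_s * p$fs)
  t <- (seq_len(n) - 1) / p$fs
  t_cycle <- 60 / p$vent_rate
  ti <- t_cycle * p$ie / (1 + p$ie)
  te <- t_cycle - ti

  draws <- with_seed(p$seed, list(
    phase_cc = runif(1), phase_vent = runif(1),
    noise_paw = rnorm(n, 0, p$noise_sd), noise_pes = rnorm(n, 0, p$noise_sd)
  ))

  # ventilation volume above FRC (mL): linear inflation/deflation
  tau_v <- (t / t_cycle + draws$phase_vent) %% 1
  v <- ifelse(tau_v < ti / t_cycle, p$vt * tau_v * t_cycle / ti,
              p$vt * pmax(0, 1 - (tau_v * t_cycle - ti) / te))
  flow <- ifelse(tau_v < ti / t_cycle, p$vt / ti,
                 ifelse(tau_v * t_cycle - ti < te, -p$vt / te, 0)) / 1000 # L/s

  # per-sample compression amplitude from epochs (0 outside CC epochs)
  amp <- rep(0, n)
  for (i in seq_len(nrow(p$epochs))) {
    e <- p$epochs[i, ]
    if (e$kind %in% c("cc_mechanical", "cc_manual")) {
      amp[t >= e$start_s & t < e$end_s] <- e$cc_amp
    }
  }
  occ_kind <- rep("", n)
  occ_t0 <- rep(NA_real_, n)
  if (!is.null(p$occlusions)) {
    for (i in seq_len(nrow(p$occlusions))) {
      o <- p$occlusions[i, ]
      sel <- t >= o$start_s & t < o$start_s + o$duration_s
      occ_kind[sel] <- o$kind
      occ_t0[sel] <- o$start_s
      amp[sel] <- if (isTRUE(o$compressions)) p$cc_amp else 0
    }
  }
  pulse <- cc_pulse(t, p$cc_rate, p$duty, draws$phase_cc) * amp

  crs <- p$cl * p$ccw / (p$cl + p$ccw)
  # occlusions override the ventilation state
  is_occ <- occ_kind != ""
  v[is_occ] <- ifelse(occ_kind[is_occ] == "insp", p$vt, 0)
  flow[is_occ] <- 0
  pes0 <- p$pes_ee + v / p$ccw + pulse
  paw0 <- p$peep + v / crs + p$r_aw * flow + pulse * p$transmission
  # exponential settling of the resistive component into the plateau
  settle <- is_occ
  if (any(settle)) {
    dt_occ <- t[settle] - occ_t0[settle]
    res0 <- ifelse(occ_kind[settle] == "insp", p$r_aw * p$vt / ti / 1000,
                   -p$r_aw * p$vt / te / 1000)
    paw0[settle] <- paw0[settle] + res0 * exp(-dt_occ / 0.25)
  }

  paw <- paw0 + draws$noise_paw
  pes <- pes0 + draws$noise_pes
  data <- data.frame(time_s = t, paw_cmh2o = paw, pes_cmh2o = pes)
  if (p$vascular) {
    ao_pulse <- cc_pulse(t, p$cc_rate, p$duty, draws$phase_cc) *
      ifelse(amp > 0, p$ao_pulse, 0)
    data$pao_mmhg <- p$ao_dia + ao_pulse
    data$pra_mmhg <- p$ra_base + cc_pulse(t, p$cc_rate, p$duty, draws$phase_cc) *
      ifelse(amp > 0, p$ra_pulse, 0)
  }

  ann <- p$epochs[, c("label", "start_s", "end_s", "kind")]
  if (!is.null(p$occlusions)) {
    occ_ann <- data.frame(label = paste0("occ_", seq_len(nrow(p$occlusions))),
                          start_s = p$occlusions$start_s,
                          end_s = p$occlusions$start_s + p$occlusions$duration_s,
                          kind = paste0("occlusion_", p$occlusions$kind),
                          stringsAsFactors = FALSE)
    ann <- rbind(ann, occ_ann)
  }
  trace <- pressure_trace(data, p$fs, ann)

  truth <- waveform_truth(p, t, pes0, amp, draws$phase_cc, crs, ti, te)
  list(trace = trace, truth = truth)
}

# exact per-cycle Pes swings of the noiseless trace, grouped by CC epoch
waveform_truth <- function(p, t, pes0, amp, phase_cc, crs, ti, te) {
  cyc <- floor(t * p$cc_rate / 60 + phase_cc) # compression cycle index
  epoch_swings <- list()
  for (i in seq_len(nrow(p$epochs))) {
    e <- p$epochs[i, ]
    if (!e$kind %in% c("cc_mechanical", "cc_manual")) next
    sel <- t >= e$start_s & t < e$end_s & amp > 0
    if (!any(sel)) next
    full <- names(which(table(cyc[sel]) >= 0.9 * p$fs * 60 / p$cc_rate))
    sw <- vapply(full, function(k) {
      s <- sel & cyc == as.numeric(k)
      max(pes0[s]) - min(pes0[s])
    }, numeric(1))
    epoch_swings[[e$label]] <- list(kind = e$kind, swings = unname(sw),
                                    mean_swing = mean(sw))
  }
  structure(list(
    cl = p$cl, ccw = p$ccw, crs = crs,
    plateau = list(paw_insp = p$peep + p$vt / crs, paw_exp = p$peep,
                   pes_insp = p$pes_ee + p$vt / p$ccw, pes_exp = p$pes_ee),
    cc_rate = p$cc_rate, epoch_swings = epoch_swings, seed = p$seed
  ), class = "waveform_truth")
}
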