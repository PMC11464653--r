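#' Esophageal catheter occlusion test
#'
#' Validates catheter placement from chest compressions applied during an
#' airway occlusion: the ratio of the esophageal to the airway
#' peak-to-trough pressure swing should be close to unity (acceptable
#' interval 0.8 to 1.2). The first `skip_s` seconds of the window are
#' discarded so the post-occlusion resistive settling does not enter the
#' swing.
#'
#' @param trace a [pressure_trace()].
#' @param window length-2 numeric, occlusion window (s).
#' @param skip_s initial settling time excluded from the window (s).
#' @return list with `ratio`, `valid`, `dpes`, `dpaw`.
#' @export
occlusion_test <- function(trace, window, skip_s = 1) {
  d <- trace$data
  sel <- d$time_s >= window[1] + skip_s & d$time_s <= window[2]
  if (sum(sel) < 2L) stop("occlusion window contains no samples")
  dpaw <- diff(range(d$paw_cmh2o[sel]))
  dpes <- diff(range(d$pes_cmh2o[sel]))
  if (dpaw < 1) stop("airway swing below 1 cmH2O: no compression detected in the occlusion window")
  ratio <- dpes / dpaw
  list(ratio = ratio, valid = ratio >= 0.8 && ratio <= 1.2,
       dpes = dpes, dpaw = dpaw)
}

# peak prominence: height above the higher of the two bracketing minima,
# where brackets run to the nearest higher sample on each side
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    left <- x[seq_len(p)]
    higher_l <- which(left > x[p])
    lmin <- min(left[seq(if (length(higher_l)) max(higher_l) else 1L, p)])
    right <- x[p:length(x)]
    higher_r <- which(right > x[p])
    rmin <- min(right[seq_len(if (length(higher_r)) min(higher_r) else length(right))])
    x[p] - max(lmin, rmin)
  }, numeric(1))
}

#' Detect chest-compression cycles on the esophageal pressure channel
#'
#' Band-passes Pes with a zero-phase 0.5-5 Hz Butterworth filter (keeps
#' the ~1.7 Hz compressions, rejects the 0.17 Hz ventilation), finds peaks
#' above a prominence threshold, and returns trough-to-trough cycle
#' windows. A detected rate outside 50-150/min sets `rate_warning`.
#'
#' @param trace a [pressure_trace()].
#' @param epoch length-2 numeric window (s), e.g. one 5-min CC epoch.
#' @param band band-pass corner frequencies (Hz).
#' @param min_prominence absolute prominence floor (cmH2O); the effective
#'   threshold is the larger of this and `prominence_frac` x the IQR-based
#'   swing of the band-passed signal.
#' @param prominence_frac relative prominence threshold (default 0.25).
#' @return data.frame (class `cc_cycles`) with `start_s`, `end_s`,
#'   `peak_s` per cycle; attributes `rate_per_min`, `rate_warning`.
#' @export
detect_cc_cycles <- function(trace, epoch, band = c(0.5, 5),
                             min_prominence = 1, prominence_frac = 0.25) {
  d <- trace$data
  sel <- which(d$time_s >= epoch[1] & d$time_s < epoch[2])
  if (length(sel) < 10L) stop("epoch contains too few samples")
  fs <- trace$fs
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  bp <- signal::filtfilt(bf, d$pes_cmh2o[sel])
  thr <- max(min_prominence, prominence_frac * diff(stats::quantile(bp, c(0.25, 0.75))) * 2)
  cand <- which(diff(sign(diff(bp))) == -2) + 1L
  if (length(cand) == 0L) stop("no compression cycles detected in epoch")
  prom <- peak_prominence(bp, cand)
  pk <- cand[prom >= thr]
  # enforce a refractory distance of half the minimum plausible period (150/min)
  min_dist <- round(fs * 60 / 150 / 2)
  if (length(pk) > 1L) {
    keep <- pk[1L]
    for (p in pk[-1L]) {
      if (p - keep[length(keep)] >= min_dist) keep <- c(keep, p)
      else if (bp[p] > bp[keep[length(keep)]]) keep[length(keep)] <- p
    }
    pk <- keep
  }
  if (length(pk) < 2L) stop("fewer than two compression peaks: cannot delimit cycles")
  t_pk <- d$time_s[sel][pk]
  # trough between consecutive peaks bounds each cycle; the outermost
  # cycles are closed by the epoch edges
  troughs <- vapply(seq_len(length(pk) - 1L), function(i) {
    seg <- pk[i]:pk[i + 1L]
    d$time_s[sel][seg[which.min(bp[seg])]]
  }, numeric(1))
  bounds <- c(d$time_s[sel][1L], troughs, d$time_s[sel][length(sel)])
  cycles <- data.frame(start_s = bounds[-length(bounds)],
                       end_s = bounds[-1L],
                       peak_s = t_pk)
  rate <- 60 / stats::median(diff(t_pk))
  if (rate < 50) {
    # slower than any CPR compression protocol: these "peaks" are
    # ventilation or artifact, not compressions
    stop(sprintf("no compression cycles detected in epoch (apparent rate %.0f/min)",
                 rate))
  }
  attr(cycles, "rate_per_min") <- rate
  attr(cycles, "rate_warning") <- rate > 150
  class(cycles) <- c("cc_cycles", "data.frame")
  cycles
}

#' Per-cycle esophageal pressure statistics
#'
#' For each detected compression cycle, the minimum, maximum and swing
#' (max - min) of raw Pes; per-epoch aggregate = mean of per-cycle swings
#' (the reported delta-Pes).
#'
#' @param trace a [pressure_trace()].
#' @param cycles output of [detect_cc_cycles()].
#' @param epochs data.frame(label, start_s, end_s, kind); cycles are
#'   assigned to epochs by their peak time. May be NULL for a single pool.
#' @param smooth_hz low-pass corner (Hz) applied zero-phase to Pes before
#'   taking per-cycle extrema, so broadband sensor noise does not bias the
#'   min/max; generous relative to the ~1.7 Hz compression pulse. `NULL`
#'   disables smoothing.
#' @return An object of class `cc_cycle_stats`: list with `cycles`
#'   (per-cycle data.frame) and `epochs` (label, kind, n_cycles,
#'   mean_swing, mean_min, mean_max).
#' @export
pes_swing_stats <- function(trace, cycles, epochs = NULL, smooth_hz = 10) {
  if (is.null(cycles) || nrow(cycles) == 0L) stop("empty cycle list")
  d <- trace$data
  pes_all <- d$pes_cmh2o
  if (!is.null(smooth_hz) && smooth_hz < trace$fs / 2) {
    lf <- signal::butter(2, smooth_hz / (trace$fs / 2), type = "low")
    pes_all <- signal::filtfilt(lf, pes_all)
  }
  per <- do.call(rbind, lapply(seq_len(nrow(cycles)), function(i) {
    s <- d$time_s >= cycles$start_s[i] & d$time_s < cycles$end_s[i]
    pes <- pes_all[s]
    data.frame(peak_s = cycles$peak_s[i], pes_min = min(pes),
               pes_max = max(pes), swing = max(pes) - min(pes))
  }))
  if (any(per$swing < 0)) stop("negative swing: corrupted cycles")
  if (is.null(epochs)) {
    epochs <- data.frame(label = "all", start_s = min(per$peak_s),
                         end_s = max(per$peak_s) + 1e-9, kind = "cc_mechanical",
                         stringsAsFactors = FALSE)
  }
  agg <- do.call(rbind, lapply(seq_len(nrow(epochs)), function(i) {
    e <- epochs[i, ]
    s <- per$peak_s >= e$start_s & per$peak_s < e$end_s
    data.frame(label = e$label, kind = e$kind, n_cycles = sum(s),
               mean_swing = if (any(s)) mean(per$swing[s]) else NA_real_,
               mean_min = if (any(s)) mean(per$pes_min[s]) else NA_real_,
               mean_max = if (any(s)) mean(per$pes_max[s]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(cycles = per, epochs = agg), class = "cc_cycle_stats")
}

#' Occlusion plateau pressures
#'
#' Mean Paw and Pes over the last stable stretch of an occlusion window of
#' at least 5 s. Stability is judged on consecutive `tail_s`-long blocks:
#' the plateau is the final `tail_s` seconds provided the block-to-block
#' drift is below `settle_thresh` (cmH2O/s) for both channels.
#'
#' @param trace a [pressure_trace()].
#' @param window length-2 numeric occlusion window (s), span >= 5 s.
#' @param tail_s averaging tail (s). @param settle_thresh drift threshold
#'   (cmH2O/s).
#' @return list with `paw_plateau`, `pes_plateau` (cmH2O).
#' @export
plateau_values <- function(trace, window, tail_s = 0.5, settle_thresh = 0.5) {
  if (diff(window) < 5) stop("occlusion window must span at least 5 s")
  d <- trace$data
  block_mean <- function(ch, w) {
    s <- d$time_s >= w[1] & d$time_s < w[2]
    if (!any(s)) stop("plateau window contains no samples")
    mean(ch[s])
  }
  last <- c(window[2] - tail_s, window[2])
  prev <- last - tail_s
  for (ch_name in c("paw_cmh2o", "pes_cmh2o")) {
    ch <- d[[ch_name]]
    drift <- abs(block_mean(ch, last) - block_mean(ch, prev)) / tail_s
    if (drift > settle_thresh) {
      stop(sprintf("%s has not settled (drift %.2f cmH2O/s > %.2f): no stable plateau",
                   ch_name, drift, settle_thresh))
    }
  }
  list(paw_plateau = block_mean(d$paw_cmh2o, last),
       pes_plateau = block_mean(d$pes_cmh2o, last))
}

#' Partitioned respiratory mechanics from an occlusion pair
#'
#' From inspiratory and expiratory occlusion plateaus: driving pressure of
#' the respiratory system `DPrs = Pplat - PEEPtot`, of the chest wall
#' `DPcw = Pes_insp - Pes_exp`, and of the lung (transpulmonary)
#' `DPL = DPrs - DPcw`; compliances are `VT / DP` per partition, so
#' `1/Crs = 1/CL + 1/Ccw` holds identically.
#'
#' @param trace a [pressure_trace()].
#' @param insp_window,exp_window occlusion windows (s), no compressions.
#' @param vt tidal volume used for the breath preceding the occlusions (mL).
#' @param ... passed to [plateau_values()].
#' @return An object of class `mechanics_panel`.
#' @export
partitioned_mechanics <- function(trace, insp_window, exp_window, vt, ...) {
  stop_if_not_scalar_pos(vt, "vt")
  pi_ <- plateau_values(trace, insp_window, ...)
  pe <- plateau_values(trace, exp_window, ...)
  dprs <- pi_$paw_plateau - pe$paw_plateau
  dpcw <- pi_$pes_plateau - pe$pes_plateau
  dpl <- dprs - dpcw
  if (dprs <= 0) stop("respiratory-system driving pressure is not positive")
  if (dpcw <= 0) stop("chest-wall driving pressure is not positive")
  if (dpl <= 0) stop("lung driving pressure is not positive")
  panel <- list(
    vt_ml = vt,
    pplat_cmh2o = pi_$paw_plateau, peep_tot_cmh2o = pe$paw_plateau,
    pes_insp_cmh2o = pi_$pes_plateau, pes_exp_cmh2o = pe$pes_plateau,
    dp_rs = dprs, dp_l = dpl, dp_cw = dpcw,
    crs = vt / dprs, cl = vt / dpl, ccw = vt / dpcw,
    units = c(pressure = "cmH2O", compliance = "mL/cmH2O", volume = "mL")
  )
  # series-compliance identity, exact by construction
  stopifnot(abs(1 / panel$crs - (1 / panel$cl + 1 / panel$ccw)) < 1e-9)
  structure(panel, class = "mechanics_panel")
}

#' @export
print.mechanics_panel <- function(x, ...) {
  cat(sprintf(paste0("<mechanics_panel> VT %.0f mL\n",
    "  DPrs %.2f  DPL %.2f  DPcw %.2f cmH2O\n",
    "  Crs %.1f  CL %.1f  Ccw %.1f mL/cmH2O\n"),
    x$vt_ml, x$dp_rs, x$dp_l, x$dp_cw, x$crs, x$cl, x$ccw))
  invisible(x)
}

#' Coronary perfusion pressure per compression cycle
#'
#' CPP is the difference between time-coincident diastolic aortic and
#' right-atrial pressure; during chest compressions the diastolic instant
#' is taken as the aortic minimum in the decompression phase of each
#' cycle.
#'
#' @param trace a [pressure_trace()] carrying `pao_mmhg` and `pra_mmhg`.
#' @param cycles output of [detect_cc_cycles()].
#' @param decomp_frac fraction of the cycle after which the decompression
#'   phase is searched (default 0.5, the device duty cycle).
#' @return data.frame with `peak_s`, `cpp_mmhg`; attribute `mean_cpp`.
#' @export
coronary_perfusion_pressure <- function(trace, cycles, decomp_frac = 0.5) {
  d <- trace$data
  if (is.null(d$pao_mmhg) || is.null(d$pra_mmhg)) {
    stop("trace lacks aortic and/or right-atrial channels")
  }
  out <- do.call(rbind, lapply(seq_len(nrow(cycles)), function(i) {
    t0 <- cycles$start_s[i] + decomp_frac * (cycles$end_s[i] - cycles$start_s[i])
    s <- which(d$time_s >= t0 & d$time_s < cycles$end_s[i])
    if (length(s) == 0L) return(NULL)
    j <- s[which.min(d$pao_mmhg[s])]
    data.frame(peak_s = cycles$peak_s[i],
               cpp_mmhg = d$pao_mmhg[j] - d$pra_mmhg[j])
  }))
  attr(out, "mean_cpp") <- mean(out$cpp_mmhg)
  out
}
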