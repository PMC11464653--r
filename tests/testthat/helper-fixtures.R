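# independent per-voxel loop oracle for the aeration report: explicit
# scalar arithmetic, no shared code path with quantify()
naive_quantify <- function(ct, mask) {
  d <- dim(ct$hu)
  vox_ml <- prod(ct$spacing) / 1000
  n <- 0L; gas <- 0; wt <- 0; husum <- 0
  counts <- c(hyper = 0L, normal = 0L, poor = 0L, non = 0L, oor = 0L)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!mask$mask[i, j, k]) next
    hu <- ct$hu[i, j, k]
    n <- n + 1L
    husum <- husum + hu
    g <- -min(max(hu, -1000), 0) / 1000
    tfrac <- 1 + min(max(hu, -1000), 100) / 1000
    if (tfrac > 1) tfrac <- 1
    gas <- gas + g
    wt <- wt + tfrac
    lab <- if (hu < -1000 || hu > 100) "oor"
      else if (hu < -900.5) "hyper"
      else if (hu < -500.5) "normal"
      else if (hu < -100.5) "poor"
      else "non"
    counts[lab] <- counts[lab] + 1L
  }
  n_in <- sum(counts[c("hyper", "normal", "poor", "non")])
  list(volume_ml = n * vox_ml, gas_ml = gas * vox_ml, weight_g = wt * vox_ml,
       mean_hu = husum / n,
       f_hyper = counts[["hyper"]] / n_in, f_normal = counts[["normal"]] / n_in,
       f_poor = counts[["poor"]] / n_in, f_non = counts[["non"]] / n_in)
}

# box-mask CT with an arbitrary HU field: exercises analytic cases where
# the ellipsoid phantom would be awkward
box_ct <- function(hu_fun, shape = c(12L, 15L, 8L), spacing = c(2, 2, 2)) {
  hu <- array(0, shape)
  for (k in seq_len(shape[3])) for (j in seq_len(shape[2])) for (i in seq_len(shape[1])) {
    hu[i, j, k] <- hu_fun(i, j, k)
  }
  list(ct = ct_volume(hu, spacing = spacing),
       mask = lung_mask(array(TRUE, shape)))
}

# short single-epoch CC trace with an occlusion pair appended
make_cc_trace <- function(cc_amp = 12, cl = 50, ccw = 100, noise_sd = 0,
                          duration = 60, seed = 1, cc_rate = 102, ...) {
  ep <- data.frame(label = "e1", start_s = 0, end_s = duration,
                   kind = "cc_mechanical", cc_amp = cc_amp,
                   stringsAsFactors = FALSE)
  occ <- data.frame(start_s = duration + c(5, 15), duration_s = c(6, 6),
                    kind = c("insp", "exp"), compressions = FALSE)
  gen_pressure_traces(waveform_params(
    duration_s = duration + 25, cc_rate = cc_rate, cc_amp = cc_amp, cl = cl,
    ccw = ccw, epochs = ep, occlusions = occ, noise_sd = noise_sd,
    seed = seed, ...))
}
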