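#' Cohort timeline configuration
#'
#' Mirrors the experimental protocol: baseline CT and mechanics, 25 min of
#' CPR split into five 5-min epochs alternating mechanical and manual
#' compressions (mechanical first), mixed-venous panels at minutes 15
#' (mechanical) and 20 (manual), then post-ROSC CT, mechanics and a
#' post-ROSC panel.
#'
#' @param epoch_s length of each CC epoch (s); 300 s in the emulated
#'   protocol, shorter values keep exploratory runs fast.
#' @param n_epochs number of CC epochs (default 5).
#' @param fs waveform sampling rate (Hz).
#' @param ct_shape,ct_spacing phantom grid for the CT scans.
#' @param vt tidal volume during CPR (mL).
#' @return list of timeline settings.
#' @export
cohort_timeline <- function(epoch_s = 300, n_epochs = 5L, fs = 100,
                            ct_shape = c(48L, 44L, 36L), ct_spacing = c(3, 3, 3),
                            vt = 500) {
  list(epoch_s = epoch_s, n_epochs = n_epochs, fs = fs,
       ct_shape = ct_shape, ct_spacing = ct_spacing, vt = vt)
}

#' Generate a synthetic multi-animal cohort
#'
#' Each animal carries a latent edema-severity score (evenly spread over
#' the cohort) that jointly drives the post-CPR CT edema shift, the
#' compression esophageal-pressure amplitude (mechanical epochs stronger
#' than manual), the post-CPR fall in lung compliance, the shunt fraction,
#' the wet-to-dry ratio and the histology airspace loss — so downstream
#' cross-modality associations are positive by construction. All per-animal
#' generator truths are retained.
#'
#' @param n_animals number of animals (>= 1).
#' @param timeline a [cohort_timeline()].
#' @param seed RNG seed.
#' @param edema_range HU edema-shift range mapped onto severity 0-1;
#'   `c(0, 0)` generates a CRALE-free cohort.
#' @return An object of class `crale_cohort`: list of per-animal bundles.
#' @export
gen_cohort <- function(n_animals = 5L, timeline = cohort_timeline(), seed = 1L,
                       edema_range = c(150, 300)) {
  if (n_animals < 1L) stop("`n_animals` must be >= 1")
  tl <- timeline
  severity <- if (n_animals == 1L) 1 else seq(0.15, 1, length.out = n_animals)
  sub_seeds <- with_seed(seed, sample.int(2^20, n_animals * 8))
  animals <- lapply(seq_len(n_animals), function(i) {
    sv <- severity[i]
    seeds <- sub_seeds[(i - 1L) * 8L + 1:8]
    # mild anatomical variability; kept small so the constructed
    # severity-driven contrasts dominate the cohort associations
    biom <- with_seed(seeds[7], list(body_kg = stats::rnorm(1, 33, 4),
                                     base_hu = stats::rnorm(1, -549, 8),
                                     size = stats::rnorm(1, 1, 0.008)))
    body_kg <- biom$body_kg
    semi <- rbind(c(0.48, 0.42, 0.19), c(0.48, 0.42, 0.19)) *
      clamp(biom$size, 0.97, 1.03) # keeps the ellipsoids inside the grid

    base_ct <- gen_ct_phantom(phantom_ct_params(
      shape = tl$ct_shape, spacing = tl$ct_spacing, base_hu = biom$base_hu,
      vd_slope = 190, edema_shift = 0, noise_sd = 5,
      lung_semiaxes = semi, seed = seeds[1]))
    edema <- edema_range[1] + sv * diff(edema_range)
    post_ct <- gen_ct_phantom(phantom_ct_params(
      shape = tl$ct_shape, spacing = tl$ct_spacing, base_hu = biom$base_hu,
      vd_slope = 190 + 220 * sv, edema_shift = edema, noise_sd = 5,
      lung_semiaxes = semi, seed = seeds[2]))

    # CC epochs alternate mechanical/manual; amplitude grows with severity
    # and with time, mechanical stronger than manual
    kinds <- rep(c("cc_mechanical", "cc_manual"), length.out = tl$n_epochs)
    amp_mech <- 8 + 10 * sv
    ep <- data.frame(
      start_s = (seq_len(tl$n_epochs) - 1L) * tl$epoch_s,
      end_s = seq_len(tl$n_epochs) * tl$epoch_s,
      kind = kinds,
      cc_amp = ifelse(kinds == "cc_mechanical", amp_mech, 0.75 * amp_mech) *
        (1 + 0.05 * (seq_len(tl$n_epochs) - 1L)),
      stringsAsFactors = FALSE)
    ep$label <- paste0("epoch", seq_len(tl$n_epochs), "_", ep$kind)
    cc_end <- max(ep$end_s)

    cl_base <- 50; ccw <- 100
    cl_post <- cl_base * (1 - 0.55 * sv)
    occ_post <- data.frame(start_s = cc_end + c(5, 15), duration_s = c(6, 6),
                           kind = c("insp", "exp"), compressions = FALSE)
    wave <- gen_pressure_traces(waveform_params(
      duration_s = cc_end + 30, fs = tl$fs, cc_amp = amp_mech,
      vt = tl$vt, cl = cl_post, ccw = ccw, epochs = ep,
      occlusions = occ_post, vascular = TRUE, noise_sd = 0.2,
      seed = seeds[3]))
    occ_base <- data.frame(start_s = c(5, 15), duration_s = c(6, 6),
                           kind = c("insp", "exp"), compressions = FALSE)
    wave_base <- gen_pressure_traces(waveform_params(
      duration_s = 30, fs = tl$fs, cc_amp = 0,
      epochs = data.frame(label = "baseline", start_s = 0, end_s = 30,
                          kind = "baseline", cc_amp = 0),
      vt = tl$vt, cl = cl_base, ccw = ccw, occlusions = occ_base,
      noise_sd = 0.2, seed = seeds[4]))

    shunt_mech <- clamp(0.15 + 0.35 * sv, 0, 0.9)
    gas <- list(
      min15 = gen_bloodgas_panel(gas_exchange_params(
        qs_qt = shunt_mech, co = 1.9, hb = 9, fio2 = 1, vo2 = 55,
        timepoint = "cpr_min15_mechanical", seed = seeds[5])),
      min20 = gen_bloodgas_panel(gas_exchange_params(
        qs_qt = clamp(shunt_mech - 0.07, 0, 0.9), co = 1.4, hb = 9, fio2 = 1,
        vo2 = 50, timepoint = "cpr_min20_manual", seed = seeds[5] + 1L)),
      post_rosc = gen_bloodgas_panel(gas_exchange_params(
        qs_qt = clamp(0.08 + 0.25 * sv, 0, 0.9), co = 3.5, hb = 9.5,
        fio2 = 0.3, vo2 = 180, timepoint = "post_rosc", seed = seeds[5] + 2L)))

    airspace <- clamp(0.65 - 0.30 * sv, 0.05, 1)
    hem <- clamp(0.02 + 0.14 * sv, 0, 0.5)
    rest <- 1 - airspace - hem
    histo <- gen_histology_image(
      width = 256L, height = 256L,
      truth = histology_truth(airspace = airspace, acinar = rest * 0.72,
                              nonacinar = rest * 0.28, hemorrhage = hem),
      texture_scale = 8, seed = seeds[6])

    necropsy <- with_seed(seeds[8], list(
      exvivo_weight_g = post_ct$truth$weight_g * stats::rnorm(1, 1.02, 0.03),
      wet_g = 10, dry_g = 10 / (5.2 + 2.4 * sv + stats::rnorm(1, 0, 0.1)),
      body_kg = body_kg))

    list(id = sprintf("pig%02d", i), severity = sv,
         baseline_ct = base_ct, post_ct = post_ct,
         wave_base = wave_base, wave_cpr = wave,
         occ_base = occ_base, occ_post = occ_post, epochs = ep,
         gas = gas, histology = histo, necropsy = necropsy,
         cl_base = cl_base, cl_post = cl_post, ccw = ccw)
  })
  structure(list(animals = animals, timeline = tl, seed = as.integer(seed),
                 edema_range = edema_range),
            class = "crale_cohort")
}
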