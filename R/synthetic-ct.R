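#' Parameters for the synthetic lung CT phantom
#'
#' The phantom places two ellipsoidal lungs in a thorax-like background
#' (-1000 HU air outside the body, a +40 HU soft-tissue rim inside it) and
#' fills them with a ventro-dorsal linear density profile plus an optional
#' uniform edema shift and Gaussian HU noise. Defaults reproduce the
#' baseline supine-pig regime: mean density near -549 HU with a modest
#' gravitational gradient; an edema shift of ~225 HU moves the mean into
#' the post-resuscitation -324 HU regime.
#'
#' @param shape integer length-3 grid size (cranio-caudal, ventro-dorsal,
#'   left-right voxels).
#' @param spacing voxel size in mm per axis.
#' @param base_hu mean density of the noiseless profile (HU).
#' @param vd_slope density increase from the most ventral to the most
#'   dorsal mask voxel (HU per unit normalized depth); >= 0 makes the
#'   dependent lung denser.
#' @param edema_shift uniform density increase (HU, >= 0).
#' @param noise_sd additive Gaussian noise SD (HU).
#' @param lung_centers 2 x 3 matrix of ellipsoid centres (fraction of grid
#'   extent per axis).
#' @param lung_semiaxes 2 x 3 matrix of semi-axes (fraction of grid extent).
#' @param seed RNG seed.
#' @return An object of class `phantom_ct_params`.
#' @export
phantom_ct_params <- function(shape = c(48L, 44L, 36L), spacing = c(3, 3, 3),
                              base_hu = -549, vd_slope = 190, edema_shift = 0,
                              noise_sd = 5,
                              lung_centers = rbind(c(0.5, 0.52, 0.30),
                                                   c(0.5, 0.52, 0.70)),
                              lung_semiaxes = rbind(c(0.48, 0.42, 0.19),
                                                    c(0.48, 0.42, 0.19)),
                              seed = 1L) {
  if (any(shape <= 0)) stop("grid shape must be positive")
  if (edema_shift < 0) stop("`edema_shift` must be >= 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 base_hu = base_hu, vd_slope = vd_slope,
                 edema_shift = edema_shift, noise_sd = noise_sd,
                 lung_centers = lung_centers, lung_semiaxes = lung_semiaxes,
                 seed = as.integer(seed)),
            class = "phantom_ct_params")
}

#' Generate a synthetic lung CT phantom with exact ground truth
#'
#' Builds the CT volume, its lung mask and a `phantom_truth` record holding
#' the exact lung volume, gas volume, weight, per-band mean densities and
#' compartment fractions, all computed from the noiseless generating field
#' before noise is added. In-mask values are clipped to [-1000, +100] HU.
#'
#' @param params a [phantom_ct_params()].
#' @return list with elements `ct` ([ct_volume()]), `mask` ([lung_mask()])
#'   and `truth` (class `phantom_truth`).
#' @export
gen_ct_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_ct_params"))
  d <- params$shape
  ext <- d * params$spacing
  axname <- c("cranio-caudal", "ventro-dorsal", "left-right")
  for (l in 1:2) {
    ctr <- params$lung_centers[l, ] * ext
    sa <- params$lung_semiaxes[l, ] * ext
    bad <- which(ctr - sa < 0 | ctr + sa > ext)
    if (length(bad)) {
      stop(sprintf("lung %d ellipsoid overlaps the grid boundary on the %s axis",
                   l, axname[bad[1]]))
    }
  }
  # voxel-centre coordinates (mm)
  x1 <- (seq_len(d[1]) - 0.5) * params$spacing[1]
  x2 <- (seq_len(d[2]) - 0.5) * params$spacing[2]
  x3 <- (seq_len(d[3]) - 0.5) * params$spacing[3]
  in_ellipsoid <- function(ctr, sa) {
    q1 <- ((x1 - ctr[1]) / sa[1])^2
    q2 <- ((x2 - ctr[2]) / sa[2])^2
    q3 <- ((x3 - ctr[3]) / sa[3])^2
    outer(outer(q1, q2, `+`), q3, `+`) <= 1
  }
  mask <- in_ellipsoid(params$lung_centers[1, ] * ext,
                       params$lung_semiaxes[1, ] * ext) |
          in_ellipsoid(params$lung_centers[2, ] * ext,
                       params$lung_semiaxes[2, ] * ext)
  if (!any(mask)) stop("phantom lungs contain no voxels; enlarge the grid")
  body <- in_ellipsoid(c(0.5, 0.5, 0.5) * ext, c(0.49, 0.49, 0.49) * ext)

  # normalized ventro-dorsal depth over the whole-lung bounding extent
  vd_rows <- which(apply(mask, 2L, any))
  depth_row <- rep(0, d[2])
  if (length(vd_rows) > 1L) {
    depth_row[vd_rows] <- (vd_rows - min(vd_rows)) / (max(vd_rows) - min(vd_rows))
  }
  depth <- array(depth_row[slice.index(mask, 2L)], d)

  field <- params$base_hu - params$vd_slope / 2 + params$vd_slope * depth +
    params$edema_shift
  noiseless <- array(-1000, d)
  noiseless[body] <- 40
  noiseless[mask] <- clamp(field[mask], -1000, 100)

  hu <- noiseless
  if (params$noise_sd > 0) {
    noise <- with_seed(params$seed, rnorm(sum(mask), 0, params$noise_sd))
    hu[mask] <- clamp(noiseless[mask] + noise, -1000, 100)
  }

  ct <- ct_volume(hu, spacing = params$spacing)
  lm <- lung_mask(mask, provenance = "synthetic")
  truth <- phantom_truth(ct_volume(noiseless, spacing = params$spacing), lm, params)
  list(ct = ct, mask = lm, truth = truth)
}

# exact quantities from the noiseless generating field
phantom_truth <- function(ct0, mask, params) {
  hu <- ct0$hu[mask$mask]
  vox_ml <- voxel_volume_ml(ct0)
  gt <- voxel_gas_tissue(hu)
  lab <- classify_hu(hu)
  prof <- gravitational_profile(ct0, mask)
  structure(list(
    lung_volume_ml = length(hu) * vox_ml,
    gas_volume_ml = sum(gt$gas) * vox_ml,
    weight_g = sum(gt$tissue) * vox_ml,
    mean_hu = mean(hu),
    band_mean_hu = stats::setNames(prof$mean_hu, prof$band),
    f_hyper = mean(lab == "hyper"), f_normal = mean(lab == "normal"),
    f_poor = mean(lab == "poor"), f_non = mean(lab == "non"),
    seed = params$seed
  ), class = "phantom_truth")
}
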