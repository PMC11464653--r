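#' Classify Hounsfield units into aeration compartments
#'
#' Standard quantitative-CT aeration compartments: hyper-aerated
#' (-1000 to -901 HU), normally aerated (-900 to -501 HU), poorly aerated
#' (-500 to -101 HU) and non-aerated (-100 to +100 HU). The printed integer
#' ranges leave sub-integer values undefined; internally the bins are
#' half-open at the midpoints (-900.5, -500.5, -100.5) so a voxel at
#' -900.5 falls in the normally-aerated class while every integer HU value
#' lands exactly where the printed ranges put it. Values outside
#' [-1000, +100] are labelled `out_of_range`.
#'
#' @param hu numeric vector of attenuation values (HU); must be finite.
#' @return character vector in
#'   `c("hyper", "normal", "poor", "non", "out_of_range")`.
#' @export
classify_hu <- function(hu) {
  if (length(hu) == 0L) return(character(0))
  if (any(!is.finite(hu))) stop("`hu` contains non-finite values")
  out <- rep("out_of_range", length(hu))
  out[hu >= -1000 & hu < -900.5] <- "hyper"
  out[hu >= -900.5 & hu < -500.5] <- "normal"
  out[hu >= -500.5 & hu < -100.5] <- "poor"
  out[hu >= -100.5 & hu <= 100] <- "non"
  out
}

#' Voxel gas and tissue fractions
#'
#' Linear gas/tissue decomposition of CT attenuation: a voxel at -1000 HU
#' is pure gas, a voxel at 0 HU pure tissue of density 1 g/mL. HU is
#' clipped to [-1000, 0] for the gas fraction (`-hu/1000`); the tissue
#' fraction is `1 + hu/1000` on HU clipped to [-1000, +100], capped at 1
#' so voxels denser than water count as pure tissue.
#'
#' @param hu numeric vector (HU), finite.
#' @return list with numeric vectors `gas` and `tissue`.
#' @export
voxel_gas_tissue <- function(hu) {
  if (any(!is.finite(hu))) stop("`hu` contains non-finite values")
  gas <- -clamp(hu, -1000, 0) / 1000
  tissue <- pmin(1 + clamp(hu, -1000, 100) / 1000, 1)
  list(gas = gas, tissue = tissue)
}

#' Mean lung density
#'
#' Average density of all cranio-caudal lung slices normalized by the
#' in-mask area of each slice: `sum(slice mean x slice area)/sum(area)`.
#' With uniform voxel dimensions this equals the plain in-mask voxel mean;
#' the equivalence is asserted.
#'
#' @param ct a [ct_volume()].
#' @param mask a [lung_mask()].
#' @return mean lung density (HU).
#' @export
mean_lung_density <- function(ct, mask) {
  check_congruent(ct, mask)
  cc <- ct$axes[["cc"]]
  hu_m <- ct$hu
  hu_m[!mask$mask] <- NA_real_
  slice_sum <- apply(hu_m, cc, sum, na.rm = TRUE)
  slice_n <- apply(mask$mask, cc, sum)
  keep <- slice_n > 0
  if (!any(keep)) stop("lung mask is empty")
  area <- slice_n[keep] # uniform in-plane spacing: voxel count is proportional to area
  smean <- slice_sum[keep] / slice_n[keep]
  out <- sum(smean * area) / sum(area)
  plain <- mean(ct$hu[mask$mask])
  stopifnot(abs(out - plain) <= 1e-6 * max(1, abs(plain)))
  out
}

#' Quantitative CT aeration report
#'
#' Computes lung volume (voxel count times voxel volume), gas volume and
#' weight from the voxel gas/tissue decomposition, area-normalized mean
#' density, aeration-compartment fractions and the CRALE flag
#' (mean density >= -500 HU). Compartment fractions are taken over
#' in-range voxels; in-mask voxels outside [-1000, +100] HU are counted
#' separately and enter weight/gas via clipping.
#'
#' @param ct a [ct_volume()].
#' @param mask a [lung_mask()].
#' @return An object of class `aeration_report`: a list with
#'   `volume_ml`, `gas_ml`, `weight_g`, `mean_hu`, `f_hyper`, `f_normal`,
#'   `f_poor`, `f_non`, `crale`, `n_voxels`, `n_out_of_range`.
#' @export
quantify <- function(ct, mask) {
  check_congruent(ct, mask)
  hu <- ct$hu[mask$mask]
  if (length(hu) == 0L) stop("lung mask is empty")
  vox_ml <- voxel_volume_ml(ct)
  gt <- voxel_gas_tissue(hu)
  lab <- classify_hu(hu)
  in_range <- lab != "out_of_range"
  n_in <- sum(in_range)
  frac <- function(l) if (n_in > 0) sum(lab == l) / n_in else NA_real_
  rep <- list(
    volume_ml = length(hu) * vox_ml,
    gas_ml = sum(gt$gas) * vox_ml,
    weight_g = sum(gt$tissue) * vox_ml * 1.0,
    mean_hu = mean_lung_density(ct, mask),
    f_hyper = frac("hyper"),
    f_normal = frac("normal"),
    f_poor = frac("poor"),
    f_non = frac("non"),
    n_voxels = length(hu),
    n_out_of_range = length(hu) - n_in
  )
  rep$crale <- detect_crale(rep)
  structure(rep, class = "aeration_report")
}

#' @export
print.aeration_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<aeration_report> volume %.1f mL, gas %.1f mL, weight %.1f g, mean %.0f HU%s\n",
    "  compartments: hyper %.1f%% normal %.1f%% poor %.1f%% non %.1f%%\n"),
    x$volume_ml, x$gas_ml, x$weight_g, x$mean_hu,
    if (isTRUE(x$crale)) " [CRALE]" else "",
    100 * x$f_hyper, 100 * x$f_normal, 100 * x$f_poor, 100 * x$f_non))
  invisible(x)
}

#' CRALE criterion
#'
#' CPR-associated lung edema is identified by a mean lung density of
#' -500 HU or more (inclusive).
#'
#' @param report an `aeration_report`, or anything with a `mean_hu` field.
#' @return logical flag.
#' @export
detect_crale <- function(report) {
  mu <- report$mean_hu
  if (is.null(mu) || !is.finite(mu)) stop("report lacks a finite mean density")
  mu >= -500
}

#' Gravitational (sterno-vertebral) density profile
#'
#' In each cranio-caudal slice the in-mask ventro-dorsal extent is split
#' into three bands of equal height (ventral, ventro-dorsal, dorsal);
#' voxels are pooled across slices per band. A slice thinner than three
#' rows contributes only to the bands it spans.
#'
#' @param ct a [ct_volume()].
#' @param mask a [lung_mask()].
#' @param n_bands number of bands (default 3).
#' @return An object of class `gravitational_profile`: a data.frame with one
#'   row per band (`band`, `mean_hu`, `n_voxels`, `f_hyper`, `f_normal`,
#'   `f_poor`, `f_non`), with the boundary definition stored as an attribute.
#' @export
gravitational_profile <- function(ct, mask, n_bands = 3L) {
  check_congruent(ct, mask)
  stop_if_not_scalar_pos(n_bands, "n_bands")
  cc <- ct$axes[["cc"]]; vd <- ct$axes[["vd"]]
  # reorder so slices are the 3rd axis and vd the 1st: band index per voxel
  perm <- c(vd, setdiff(1:3, c(vd, cc)), cc)
  hu <- aperm(ct$hu, perm)
  m <- aperm(mask$mask, perm)
  d <- dim(m)
  band <- array(NA_integer_, d)
  for (s in seq_len(d[3])) {
    ms <- m[, , s]
    rows <- which(apply(ms, 1L, any))
    if (length(rows) == 0L) next
    rmin <- min(rows); rmax <- max(rows)
    h <- rmax - rmin + 1L
    # continuous thirds of the bounding extent; remainder rows fall where
    # the row-centre lands
    b <- pmin(n_bands, floor((seq(rmin, rmax) - rmin + 0.5) / h * n_bands) + 1L)
    idx <- rep(NA_integer_, d[1]); idx[rmin:rmax] <- b
    band[, , s] <- array(idx, dim = d[1:2])
  }
  band[!m] <- NA_integer_
  labels <- if (n_bands == 3L) c("ventral", "ventro-dorsal", "dorsal")
            else paste0("band", seq_len(n_bands))
  out <- do.call(rbind, lapply(seq_len(n_bands), function(b) {
    sel <- !is.na(band) & band == b
    huv <- hu[sel]
    lab <- classify_hu(huv)
    n_in <- sum(lab != "out_of_range")
    data.frame(band = labels[b],
               mean_hu = if (length(huv)) mean(huv) else NA_real_,
               n_voxels = length(huv),
               f_hyper = if (n_in) sum(lab == "hyper") / n_in else NA_real_,
               f_normal = if (n_in) sum(lab == "normal") / n_in else NA_real_,
               f_poor = if (n_in) sum(lab == "poor") / n_in else NA_real_,
               f_non = if (n_in) sum(lab == "non") / n_in else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (sum(out$n_voxels) != sum(m)) stop("band voxel counts do not partition the mask")
  attr(out, "band_definition") <-
    "per-slice in-mask ventro-dorsal bounding extent split into equal-height thirds"
  class(out) <- c("gravitational_profile", "data.frame")
  out
}

#' Ventro-dorsal density gradient
#'
#' `(ventral HU - dorsal HU) / ventral HU x 100`, applied to signed HU:
#' with negative ventral density, a denser (less negative) dorsal region
#' yields a positive percentage.
#'
#' @param profile a [gravitational_profile()] (first band ventral, last dorsal).
#' @return gradient in percent.
#' @export
ventrodorsal_gradient <- function(profile) {
  v <- profile$mean_hu[1L]
  d <- profile$mean_hu[nrow(profile)]
  if (!is.finite(v) || v == 0) stop("ventral band mean density is zero or undefined")
  (v - d) / v * 100
}

#' Select slices for ten-slice analysis
#'
#' The most cranial and most caudal mask-containing slices plus `n - 2`
#' evenly spaced slices between them. Fractional positions round half
#' toward the cranial end; duplicates created by rounding are replaced by
#' the nearest unused in-span indices.
#'
#' @param mask a [lung_mask()].
#' @param n number of slices (default 10).
#' @param cc_axis array axis holding the cranio-caudal direction.
#' @return sorted integer vector of `n` distinct slice indices.
#' @export
select_slices <- function(mask, n = 10L, cc_axis = 1L) {
  if (!inherits(mask, "lung_mask")) stop("`mask` must be a lung_mask")
  stop_if_not_scalar_pos(n, "n")
  n <- as.integer(n)
  occ <- which(apply(mask$mask, cc_axis, any))
  lo <- min(occ); hi <- max(occ)
  span <- hi - lo + 1L
  if (span < n) {
    stop(sprintf("mask spans %d slices, fewer than n = %d; use a smaller n", span, n))
  }
  pos <- lo + (hi - lo) * (seq_len(n) - 1) / (n - 1)
  idx <- ceiling(pos - 0.5) # round, halves toward the cranial (lower-index) end
  idx <- unique(as.integer(idx))
  cand <- setdiff(lo:hi, idx)
  while (length(idx) < n) { # backfill nearest unused indices after collapses
    want <- n - length(idx)
    d <- vapply(cand, function(i) min(abs(i - idx)), numeric(1))
    take <- cand[order(d)][seq_len(want)]
    idx <- unique(c(idx, take))
    cand <- setdiff(cand, take)
  }
  sort(idx)
}

#' Per-slice aeration reports
#'
#' Runs [quantify()] on single cranio-caudal slices, for use with
#' [extrapolate_whole_lung()].
#'
#' @param ct a [ct_volume()]; @param mask a [lung_mask()].
#' @param slices slice indices along the cranio-caudal axis.
#' @return list with `reports` (list of `aeration_report`), `positions_mm`
#'   (slice-centre positions) and `thickness_mm`.
#' @export
quantify_slices <- function(ct, mask, slices) {
  check_congruent(ct, mask)
  cc <- ct$axes[["cc"]]
  dz <- ct$spacing[cc]
  reports <- lapply(slices, function(s) {
    keep <- array(FALSE, dim(mask$mask))
    idx <- slice.index(keep, cc) == s
    keep[idx & mask$mask] <- TRUE
    if (!any(keep)) stop(sprintf("slice %d contains no mask", s))
    quantify(ct, lung_mask(keep, provenance = mask$provenance))
  })
  list(reports = reports, positions_mm = (slices - 0.5) * dz, thickness_mm = dz)
}

#' Whole-lung extrapolation from sampled slices
#'
#' Per-slice linear densities (mL gas per mm, g per mm, mL volume per mm)
#' are interpolated linearly between the sampled slice positions and
#' integrated by the trapezoid rule over the full cranio-caudal mask span,
#' extending the end segments linearly to the span boundaries (clamped at
#' zero). Exact when the per-slice quantities vary linearly between
#' samples. Mean density is the volume-weighted combination of slice means.
#'
#' @param slice_reports list of per-slice `aeration_report`s.
#' @param positions_mm slice-centre positions (strictly increasing).
#' @param thickness_mm slice thickness (mm).
#' @param span_mm length-2 numeric, outer cranio-caudal limits of the mask
#'   (defaults to half a slice beyond the outermost sampled centres).
#' @return An `aeration_report` estimate for the whole lung.
#' @export
extrapolate_whole_lung <- function(slice_reports, positions_mm, thickness_mm,
                                   span_mm = NULL) {
  if (length(slice_reports) < 2L) stop("need at least 2 sampled slices")
  if (any(diff(positions_mm) <= 0)) stop("slice positions must be strictly increasing")
  if (is.null(span_mm)) {
    span_mm <- c(min(positions_mm) - thickness_mm / 2,
                 max(positions_mm) + thickness_mm / 2)
  }
  if (min(positions_mm) < span_mm[1] || max(positions_mm) > span_mm[2]) {
    stop("sampled slice positions fall outside the stated span")
  }
  get <- function(f) vapply(slice_reports, `[[`, numeric(1), f) / thickness_mm
  lin_ext <- function(x, y, clamp0 = TRUE) { # linear end-segment extrapolation
    ends <- function(x0, x1, y0, y1, xt) {
      v <- y1 + (y1 - y0) / (x1 - x0) * (xt - x1)
      if (clamp0) max(0, v) else v # physical quantities cannot go negative
    }
    n <- length(x)
    xs <- c(span_mm[1], x, span_mm[2])
    ys <- c(ends(x[2], x[1], y[2], y[1], span_mm[1]), y,
            ends(x[n - 1], x[n], y[n - 1], y[n], span_mm[2]))
    list(x = xs, y = ys)
  }
  integ <- function(f) {
    e <- lin_ext(positions_mm, get(f))
    trapz(e$x, e$y)
  }
  vol <- integ("volume_ml")
  gas <- integ("gas_ml")
  wt <- integ("weight_g")
  # volume-weighted mean HU: integrate slice mean x slice linear volume
  mu_lin <- get("volume_ml") * vapply(slice_reports, `[[`, numeric(1), "mean_hu")
  e <- lin_ext(positions_mm, mu_lin, clamp0 = FALSE)
  mu <- trapz(e$x, e$y) / vol
  wfr <- function(f) {
    w <- get("volume_ml")
    sum(w * vapply(slice_reports, `[[`, numeric(1), f)) / sum(w)
  }
  rep <- list(volume_ml = vol, gas_ml = gas, weight_g = wt, mean_hu = mu,
              f_hyper = wfr("f_hyper"), f_normal = wfr("f_normal"),
              f_poor = wfr("f_poor"), f_non = wfr("f_non"),
              n_voxels = sum(vapply(slice_reports, `[[`, numeric(1), "n_voxels")),
              n_out_of_range = sum(vapply(slice_reports, `[[`, numeric(1),
                                          "n_out_of_range")))
  rep$crale <- detect_crale(rep)
  structure(rep, class = "aeration_report")
}
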