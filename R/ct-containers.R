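#' CT volume container
#'
#' Wraps a 3-D Hounsfield-unit array together with its voxel spacing and an
#' explicit declaration of which array axis plays which anatomical role.
#' The analysis code never assumes an orientation: the cranio-caudal axis
#' defines "slices" and the ventro-dorsal axis defines the gravitational
#' direction (index increasing toward dorsal, i.e. toward the dependent
#' lung in dorsal recumbency).
#'
#' @param hu 3-D numeric array of attenuation values (HU).
#' @param spacing numeric length-3, voxel edge length in mm per array axis.
#' @param axes named integer vector mapping the roles `cc` (cranio-caudal),
#'   `vd` (ventro-dorsal) and `lr` (left-right) to array axis indices;
#'   must be a permutation of 1:3.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(hu, spacing = c(1, 1, 1), axes = c(cc = 1L, vd = 2L, lr = 3L)) {
  if (!is.array(hu) || length(dim(hu)) != 3L) stop("`hu` must be a 3-D array")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive voxel sizes (mm)")
  }
  axes <- axes[c("cc", "vd", "lr")]
  if (any(is.na(axes)) || !setequal(axes, 1:3)) {
    stop("`axes` must map roles cc, vd, lr to a permutation of array axes 1:3")
  }
  structure(list(hu = hu, spacing = as.numeric(spacing),
                 axes = vapply(axes, as.integer, integer(1))),
            class = "ct_volume")
}

#' Lung mask container
#'
#' @param mask logical 3-D array, congruent with its CT volume.
#' @param provenance `"manual"` or `"synthetic"`.
#' @param vessels_excluded,effusion_excluded segmentation-policy flags:
#'   whether main vessels/bronchi and pleural effusion were excluded when
#'   the mask was drawn.
#' @return An object of class `lung_mask`.
#' @export
lung_mask <- function(mask, provenance = c("synthetic", "manual"),
                      vessels_excluded = TRUE, effusion_excluded = TRUE) {
  if (!is.array(mask) || length(dim(mask)) != 3L) stop("`mask` must be a 3-D array")
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stop("lung mask is empty")
  structure(list(mask = mask, provenance = match.arg(provenance),
                 vessels_excluded = isTRUE(vessels_excluded),
                 effusion_excluded = isTRUE(effusion_excluded)),
            class = "lung_mask")
}

check_congruent <- function(ct, mask) {
  if (!inherits(ct, "ct_volume")) stop("`ct` must be a ct_volume")
  if (!inherits(mask, "lung_mask")) stop("`mask` must be a lung_mask")
  if (!identical(dim(ct$hu), dim(mask$mask))) {
    stop("CT volume and lung mask have different shapes")
  }
  invisible(TRUE)
}

voxel_volume_ml <- function(ct) prod(ct$spacing) / 1000

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing %s mm, axes cc=%d vd=%d lr=%d\n",
              paste(dim(x$hu), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              x$axes[["cc"]], x$axes[["vd"]], x$axes[["lr"]]))
  invisible(x)
}

#' @export
print.lung_mask <- function(x, ...) {
  cat(sprintf("<lung_mask> %s voxels, %d in mask (%s)\n",
              paste(dim(x$mask), collapse = "x"), sum(x$mask), x$provenance))
  invisible(x)
}
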