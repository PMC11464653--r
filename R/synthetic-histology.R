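#' True per-class area fractions for a synthetic histology image
#'
#' @param airspace,acinar,nonacinar,hemorrhage area fractions; must be
#'   non-negative and sum to 1.
#' @return An object of class `histology_truth`.
#' @export
histology_truth <- function(airspace = 0.41, acinar = 0.31, nonacinar = 0.15,
                            hemorrhage = 0.13) {
  f <- c(airspace = airspace, acinar_tissue = acinar,
         nonacinar_tissue = nonacinar, hemorrhage = hemorrhage)
  if (any(f < 0)) stop("requested class fractions must be non-negative")
  if (abs(sum(f) - 1) > 1e-8) stop("class fractions must sum to 1")
  structure(list(fractions = f), class = "histology_truth")
}

# bilinear upsampling of a coarse matrix to (nr, nc)
upsample_bilinear <- function(m, nr, nc) {
  ry <- seq(1, nrow(m), length.out = nr)
  rx <- seq(1, ncol(m), length.out = nc)
  y0 <- pmin(floor(ry), nrow(m) - 1L); fy <- ry - y0
  x0 <- pmin(floor(rx), ncol(m) - 1L); fx <- rx - x0
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x0 + 1L, drop = FALSE]
  c_ <- m[y0 + 1L, x0, drop = FALSE]; d <- m[y0 + 1L, x0 + 1L, drop = FALSE]
  wy <- matrix(fy, nr, nc); wx <- matrix(fx, nr, nc, byrow = TRUE)
  a * (1 - wy) * (1 - wx) + b * (1 - wy) * wx + c_ * wy * (1 - wx) + d * wy * wx
}

#' Generate a synthetic histology label image
#'
#' Thresholds a smooth Gaussian random field (coarse iid noise bilinearly
#' upsampled, correlation length ~ `texture_scale` pixels) at the
#' empirical quantiles of the requested class fractions, giving contiguous
#' blobs per class. The realized pixel fractions — not the requested ones —
#' are recorded back into the returned truth.
#'
#' @param width,height image size (pixels).
#' @param truth a [histology_truth()] with requested fractions.
#' @param texture_scale blob length scale (pixels).
#' @param seed RNG seed.
#' @return list with `image` (integer matrix, codes per
#'   [histology_legend()]), `legend`, `truth` (realized fractions) and
#'   `requested` (the input fractions).
#' @export
gen_histology_image <- function(width = 512L, height = 512L, truth,
                                texture_scale = 8, seed = 1L) {
  stopifnot(inherits(truth, "histology_truth"))
  f <- truth$fractions
  coarse_r <- max(2L, ceiling(height / texture_scale) + 1L)
  coarse_c <- max(2L, ceiling(width / texture_scale) + 1L)
  field <- with_seed(seed, matrix(rnorm(coarse_r * coarse_c), coarse_r, coarse_c))
  field <- upsample_bilinear(field, height, width)
  # quantile thresholds realize the requested fractions up to ties
  qs <- cumsum(f)[-length(f)]
  thr <- stats::quantile(field, probs = pmin(qs, 1), names = FALSE, type = 1)
  img <- matrix(1L, height, width)
  for (k in seq_along(thr)) img[field > thr[k]] <- k + 1L
  # classes requested at fraction 0 can capture no pixels only if their
  # threshold interval is empty; quantile ties may leak a pixel, reassign
  for (k in which(f == 0)) img[img == k] <- if (k > 1L) k - 1L else k + 1L
  legend <- histology_legend()
  realized <- vapply(legend, function(code) mean(img == code), numeric(1))
  out_truth <- structure(list(fractions = realized), class = "histology_truth")
  list(image = img, legend = legend, truth = out_truth, requested = f,
       seed = as.integer(seed))
}
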