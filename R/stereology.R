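#' Histology class legend
#'
#' Integer class map used for label images: 1 airspace, 2 acinar tissue,
#' 3 non-acinar tissue, 4 hemorrhage.
#'
#' @return named integer vector.
#' @export
histology_legend <- function() {
  c(airspace = 1L, acinar_tissue = 2L, nonacinar_tissue = 3L, hemorrhage = 4L)
}

#' Overlay a point-counting grid
#'
#' A centered sqrt(n) x sqrt(n) regular lattice with margin equal to half
#' the pitch, in continuous 0-based image coordinates; deterministic for
#' given dimensions. A `random` offset mode (uniform translation within
#' one pitch) is available for unbiased stereology.
#'
#' @param width,height image dimensions (pixels).
#' @param n_points number of grid points; must be a perfect square.
#' @param offset `"center"` (default) or `"random"`.
#' @param seed RNG seed for the random offset.
#' @return data.frame with continuous coordinates `x`, `y` and 1-based
#'   pixel indices `col`, `row`.
#' @export
overlay_grid <- function(width, height, n_points = 100L, offset = "center",
                         seed = 1L) {
  s <- sqrt(n_points)
  if (s != floor(s)) stop(sprintf("n_points = %d is not a perfect square", n_points))
  s <- as.integer(s)
  if (width < s || height < s) stop("image is smaller than the grid pitch")
  px <- width / s; py <- height / s
  if (identical(offset, "random")) {
    o <- with_seed(seed, runif(2))
    ox <- o[1] * px; oy <- o[2] * py
  } else {
    ox <- px / 2; oy <- py / 2
  }
  g <- expand.grid(ix = seq_len(s) - 1L, iy = seq_len(s) - 1L)
  x <- g$ix * px + ox
  y <- g$iy * py + oy
  data.frame(x = x, y = y,
             col = pmin(as.integer(floor(x)) + 1L, as.integer(width)),
             row = pmin(as.integer(floor(y)) + 1L, as.integer(height)))
}

#' Point (touch) count on a histology label image
#'
#' Records the class under each grid intersection and derives per-class
#' percentages and the alveolar-tissue percentage.
#'
#' @param image integer matrix (rows = y, cols = x) of class labels.
#' @param grid output of [overlay_grid()].
#' @param legend named integer vector mapping class names to codes.
#' @return An object of class `point_count_result`: list with `counts`,
#'   `percent` (named, sums to 100), `total`, `alveolar_tissue_percent`,
#'   `grid`.
#' @export
point_count <- function(image, grid, legend = histology_legend()) {
  if (max(grid$row) > nrow(image) || max(grid$col) > ncol(image)) {
    stop("grid falls outside the image")
  }
  cls <- image[cbind(grid$row, grid$col)]
  unknown <- setdiff(unique(cls), legend)
  if (length(unknown)) {
    stop(sprintf("legend is missing class code(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  counts <- vapply(legend, function(code) sum(cls == code), integer(1))
  total <- nrow(grid)
  stopifnot(sum(counts) == total)
  res <- structure(list(counts = counts, total = total,
                        percent = 100 * counts / total, grid = grid),
                   class = "point_count_result")
  res$alveolar_tissue_percent <- alveolar_tissue_percent(res)
  res
}

#' Alveolar-tissue percentage
#'
#' Non-acinar tissue subtracted from the overall tissue count:
#' `(tissue points - nonacinar points) / total x 100`. Overall tissue is
#' acinar + non-acinar; hemorrhage is reported as its own class and is
#' excluded from tissue unless `include_hemorrhage = TRUE`.
#'
#' @param result a [point_count()] result.
#' @param include_hemorrhage count hemorrhage points as tissue.
#' @return percentage of alveolar (acinar) tissue.
#' @export
alveolar_tissue_percent <- function(result, include_hemorrhage = FALSE) {
  ct <- result$counts
  tissue <- ct[["acinar_tissue"]] + ct[["nonacinar_tissue"]] +
    if (include_hemorrhage) ct[["hemorrhage"]] else 0L
  (tissue - ct[["nonacinar_tissue"]]) / result$total * 100
}

#' Lung wet-to-dry weight ratio
#'
#' @param wet_g,dry_g wet and desiccated sample mass (g).
#' @return wet/dry ratio.
#' @export
wet_to_dry <- function(wet_g, dry_g) {
  if (any(dry_g <= 0)) stop("dry mass must be positive")
  if (any(wet_g < dry_g)) stop("wet mass cannot be below dry mass")
  wet_g / dry_g
}

#' Lung-to-body weight ratio
#'
#' @param lung_g lung mass (g). @param body_kg body mass (kg).
#' @return ratio in g/kg.
#' @export
lung_body_ratio <- function(lung_g, body_kg) {
  if (any(lung_g <= 0) || any(body_kg <= 0)) stop("masses must be positive")
  lung_g / body_kg
}

#' Sample non-overlapping fields of view
#'
#' Seeded uniform sampling of `n` non-overlapping rectangular windows,
#' emulating random field selection on a slide.
#'
#' @param width,height slide dimensions (pixels).
#' @param field_w,field_h field dimensions (pixels).
#' @param n number of fields. @param seed RNG seed.
#' @return data.frame with 1-based corner `x0`, `y0` per field.
#' @export
sample_fields <- function(width, height, field_w, field_h, n = 2L, seed = 1L) {
  if (field_w > width || field_h > height) stop("field larger than slide")
  with_seed(seed, {
    picked <- data.frame(x0 = integer(0), y0 = integer(0))
    tries <- 0L
    while (nrow(picked) < n) {
      if ((tries <- tries + 1L) > 1000L) stop("could not place non-overlapping fields")
      x0 <- sample.int(width - field_w + 1L, 1L)
      y0 <- sample.int(height - field_h + 1L, 1L)
      overlaps <- any(abs(picked$x0 - x0) < field_w & abs(picked$y0 - y0) < field_h)
      if (!overlaps) picked <- rbind(picked, data.frame(x0 = x0, y0 = y0))
    }
    picked
  })
}
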