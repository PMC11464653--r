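#' Write a CT phantom as NIfTI with a JSON truth sidecar
#'
#' @param phantom a [gen_ct_phantom()] result.
#' @param dir output directory. @param prefix file-name prefix.
#' @return named character vector of written paths, invisibly.
#' @export
write_ct_nifti <- function(phantom, dir, prefix = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ct_path <- file.path(dir, paste0(prefix, "_ct.nii.gz"))
  mask_path <- file.path(dir, paste0(prefix, "_mask.nii.gz"))
  truth_path <- file.path(dir, paste0(prefix, "_truth.json"))
  img <- RNifti::asNifti(phantom$ct$hu)
  RNifti::pixdim(img) <- phantom$ct$spacing
  RNifti::writeNifti(img, ct_path)
  msk <- RNifti::asNifti(array(as.integer(phantom$mask$mask),
                               dim(phantom$mask$mask)))
  RNifti::pixdim(msk) <- phantom$ct$spacing
  RNifti::writeNifti(msk, mask_path)
  tr <- unclass(phantom$truth)
  tr$band_mean_hu <- as.list(tr$band_mean_hu)
  jsonlite::write_json(tr, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(ct = ct_path, mask = mask_path, truth = truth_path))
}

#' Read a CT volume and lung mask from NIfTI files
#'
#' @param ct_path,mask_path NIfTI file paths (same grid).
#' @param axes axis-role declaration, see [ct_volume()].
#' @return list with `ct` ([ct_volume()]) and `mask` ([lung_mask()]).
#' @export
read_ct_nifti <- function(ct_path, mask_path,
                          axes = c(cc = 1L, vd = 2L, lr = 3L)) {
  img <- RNifti::readNifti(ct_path)
  msk <- RNifti::readNifti(mask_path)
  spacing <- RNifti::pixdim(img)[1:3]
  ct <- ct_volume(array(as.numeric(img), dim(img)), spacing = spacing, axes = axes)
  mask <- lung_mask(array(as.numeric(msk) > 0.5, dim(msk)), provenance = "manual")
  check_congruent(ct, mask)
  list(ct = ct, mask = mask)
}

#' Write a pressure trace and its annotations as CSV
#'
#' @param trace a [pressure_trace()].
#' @param trace_path,annotation_path output CSV paths.
#' @return the paths, invisibly.
#' @export
write_trace_csv <- function(trace, trace_path, annotation_path) {
  utils::write.csv(trace$data, trace_path, row.names = FALSE)
  utils::write.csv(trace$annotations, annotation_path, row.names = FALSE)
  invisible(c(trace = trace_path, annotations = annotation_path))
}

#' Read a pressure trace and its annotations from CSV
#'
#' @param trace_path,annotation_path CSV paths written by
#'   [write_trace_csv()].
#' @return a [pressure_trace()].
#' @export
read_trace_csv <- function(trace_path, annotation_path) {
  d <- utils::read.csv(trace_path)
  ann <- utils::read.csv(annotation_path)
  fs <- 1 / stats::median(diff(d$time_s))
  pressure_trace(d, fs = fs, annotations = ann)
}

#' Write a histology label image as PNG with a JSON legend
#'
#' Class codes are stored in the 8-bit gray channel directly
#' (code / 255).
#'
#' @param histo a [gen_histology_image()] result.
#' @param image_path,legend_path output paths.
#' @return the paths, invisibly.
#' @export
write_histology_png <- function(histo, image_path, legend_path) {
  png::writePNG(histo$image / 255, image_path)
  jsonlite::write_json(as.list(histo$legend), legend_path, auto_unbox = TRUE)
  invisible(c(image = image_path, legend = legend_path))
}

#' Read a histology label image and legend
#'
#' @param image_path,legend_path paths written by [write_histology_png()].
#' @return list with integer `image` matrix and named integer `legend`.
#' @export
read_histology_png <- function(image_path, legend_path) {
  img <- png::readPNG(image_path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  lg <- jsonlite::read_json(legend_path, simplifyVector = TRUE)
  list(image = matrix(as.integer(round(img * 255)), nrow(img), ncol(img)),
       legend = vapply(lg, as.integer, integer(1)))
}
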