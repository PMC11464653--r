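#' Pearson correlation with least-squares fit
#'
#' Pearson's r with the two-sided p from the t transform and the
#' least-squares line, for the cross-modality associations (lung weight vs
#' compliance, delta-Pes vs lung weight, CT vs ex-vivo weight, weight vs
#' wet-to-dry).
#'
#' @param x,y numeric vectors of equal length >= 3, finite.
#' @param names optional length-2 character, variable names.
#' @return An object of class `association`: list with `pair`, `r`, `p`,
#'   `slope`, `intercept`, `n`.
#' @export
correlate <- function(x, y, names = c(deparse(substitute(x)),
                                      deparse(substitute(y)))) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in input series")
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  structure(list(pair = names, r = unname(ct$estimate), p = ct$p.value,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]), n = length(x)),
            class = "association")
}

#' @export
print.association <- function(x, ...) {
  cat(sprintf("<association> %s vs %s: r = %.3f, p = %.3g, n = %d\n",
              x$pair[1], x$pair[2], x$r, x$p, x$n))
  invisible(x)
}

#' Paired baseline-to-post change
#'
#' Summary of within-subject change with a paired t-test (default) or
#' Wilcoxon signed-rank test; the test used is recorded. With zero
#' within-pair variance the difference is reported with `p = NA` (the test
#' statistic is undefined), or `p = 1` for identical series by convention.
#'
#' @param baseline,post paired numeric vectors.
#' @param test `"t"` or `"wilcoxon"`.
#' @return list with means, SDs, `mean_diff`, `sd_diff`, `p`, `test`, `n`.
#' @export
paired_change <- function(baseline, post, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  if (length(baseline) != length(post)) stop("series must be paired")
  if (length(baseline) < 2L) stop("need at least 2 pairs")
  d <- post - baseline
  p <- if (all(d == 0)) {
    1 # identical series: no evidence of change
  } else if (stats::sd(d) == 0) {
    NA_real_ # constant nonzero shift: t statistic undefined
  } else if (test == "t") {
    stats::t.test(post, baseline, paired = TRUE)$p.value
  } else {
    stats::wilcox.test(post, baseline, paired = TRUE, exact = FALSE)$p.value
  }
  list(mean_baseline = mean(baseline), sd_baseline = stats::sd(baseline),
       mean_post = mean(post), sd_post = stats::sd(post),
       mean_diff = mean(d), sd_diff = stats::sd(d), p = p,
       test = if (test == "t") "paired t" else "Wilcoxon signed-rank",
       n = length(d))
}

#' Run the full per-animal analysis pipeline on a cohort
#'
#' For every animal: quantitative CT at baseline and post-CPR (aeration
#' report, gravitational profile, ventro-dorsal gradient, CRALE flag),
#' partitioned mechanics from the baseline and post occlusion pairs,
#' per-epoch delta-Pes from compression-cycle detection, oxygen transport
#' at the mixed-venous timepoints, stereology on the histology image and
#' the necropsy ratios. Assembles a per-animal table and the
#' cross-modality associations.
#'
#' @param cohort a [gen_cohort()] bundle.
#' @return An object of class `cohort_report`: list with `records`
#'   (data.frame, one row per animal), `associations` (named list of
#'   [correlate()] results) and `paired` (baseline-vs-post summaries).
#' @export
run_pipeline <- function(cohort) {
  stopifnot(inherits(cohort, "crale_cohort"))
  vt <- cohort$timeline$vt
  rows <- lapply(cohort$animals, function(a) {
    base_rep <- quantify(a$baseline_ct$ct, a$baseline_ct$mask)
    post_rep <- quantify(a$post_ct$ct, a$post_ct$mask)
    base_prof <- gravitational_profile(a$baseline_ct$ct, a$baseline_ct$mask)
    post_prof <- gravitational_profile(a$post_ct$ct, a$post_ct$mask)

    mech_base <- partitioned_mechanics(
      a$wave_base$trace,
      insp_window = c(a$occ_base$start_s[1], a$occ_base$start_s[1] + a$occ_base$duration_s[1]),
      exp_window = c(a$occ_base$start_s[2], a$occ_base$start_s[2] + a$occ_base$duration_s[2]),
      vt = vt)
    mech_post <- partitioned_mechanics(
      a$wave_cpr$trace,
      insp_window = c(a$occ_post$start_s[1], a$occ_post$start_s[1] + a$occ_post$duration_s[1]),
      exp_window = c(a$occ_post$start_s[2], a$occ_post$start_s[2] + a$occ_post$duration_s[2]),
      vt = vt)

    epoch_stats <- do.call(rbind, lapply(seq_len(nrow(a$epochs)), function(i) {
      e <- a$epochs[i, ]
      cyc <- detect_cc_cycles(a$wave_cpr$trace, c(e$start_s, e$end_s))
      st <- pes_swing_stats(a$wave_cpr$trace, cyc, a$epochs[i, , drop = FALSE])
      st$epochs
    }))
    dpes_mean <- mean(epoch_stats$mean_swing)

    o2 <- lapply(a$gas, function(g) transport_panel(g$panel, co = g$truth$co))

    grid <- overlay_grid(ncol(a$histology$image), nrow(a$histology$image))
    pc <- point_count(a$histology$image, grid, a$histology$legend)

    w2d <- wet_to_dry(a$necropsy$wet_g, a$necropsy$dry_g)

    data.frame(
      id = a$id, severity = a$severity,
      weight_base_g = base_rep$weight_g, weight_post_g = post_rep$weight_g,
      gas_base_ml = base_rep$gas_ml, gas_post_ml = post_rep$gas_ml,
      mean_hu_base = base_rep$mean_hu, mean_hu_post = post_rep$mean_hu,
      crale_base = base_rep$crale, crale_post = post_rep$crale,
      gradient_base_pct = ventrodorsal_gradient(base_prof),
      gradient_post_pct = ventrodorsal_gradient(post_prof),
      crs_base = mech_base$crs, crs_post = mech_post$crs,
      cl_base = mech_base$cl, cl_post = mech_post$cl,
      ccw_base = mech_base$ccw, ccw_post = mech_post$ccw,
      dpes_mean_cmh2o = dpes_mean,
      qs_qt_min15 = o2$min15$qs_qt, qs_qt_min20 = o2$min20$qs_qt,
      do2_min15 = o2$min15$do2, do2_min20 = o2$min20$do2,
      airspace_pct = pc$percent[["airspace"]],
      alveolar_tissue_pct = pc$alveolar_tissue_percent,
      hemorrhage_pct = pc$percent[["hemorrhage"]],
      exvivo_weight_g = a$necropsy$exvivo_weight_g,
      wet_to_dry = w2d,
      lung_body_g_kg = lung_body_ratio(a$necropsy$exvivo_weight_g,
                                       a$necropsy$body_kg),
      stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rows)

  assoc <- if (nrow(records) < 3L) list() else list(
    weight_vs_crs = correlate(records$weight_post_g, records$crs_post,
                              names = c("lung weight (g)", "Crs (mL/cmH2O)")),
    dpes_vs_weight = correlate(records$dpes_mean_cmh2o, records$weight_post_g,
                               names = c("delta-Pes (cmH2O)", "lung weight (g)")),
    ct_vs_exvivo_weight = correlate(records$weight_post_g, records$exvivo_weight_g,
                                    names = c("CT weight (g)", "ex-vivo weight (g)")),
    weight_vs_wet_to_dry = correlate(records$weight_post_g, records$wet_to_dry,
                                     names = c("lung weight (g)", "wet-to-dry"))
  )
  paired <- list(
    weight = paired_change(records$weight_base_g, records$weight_post_g),
    gas_volume = paired_change(records$gas_base_ml, records$gas_post_ml),
    crs = paired_change(records$crs_base, records$crs_post),
    cl = paired_change(records$cl_base, records$cl_post),
    ccw = paired_change(records$ccw_base, records$ccw_post)
  )
  structure(list(records = records, associations = assoc, paired = paired,
                 n_crale_post = sum(records$crale_post),
                 n_crale_base = sum(records$crale_base),
                 schema_version = "1.0"),
            class = "cohort_report")
}

#' Write a cohort report to disk
#'
#' Emits `records.csv`, `report.json` and a plain-text `summary.txt`.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_report <- function(report, dir) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(schema_version = report$schema_version,
         n_crale_post = report$n_crale_post,
         n_crale_base = report$n_crale_base,
         associations = lapply(report$associations, unclass),
         paired = report$paired),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  txt <- c(
    sprintf("Cohort of %d animals", nrow(report$records)),
    sprintf("CRALE flagged post-CPR: %d/%d (baseline: %d)",
            report$n_crale_post, nrow(report$records), report$n_crale_base),
    vapply(report$associations, function(a)
      sprintf("%s vs %s: r = %.3f (p = %.3g, n = %d)",
              a$pair[1], a$pair[2], a$r, a$p, a$n), character(1)))
  writeLines(txt, file.path(dir, "summary.txt"))
  invisible(dir)
}
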