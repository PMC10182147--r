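#' Pipeline run configuration
#'
#' Bundles all stage parameters of the phantom-to-report pipeline. Defaults
#' carry the protocol constants: match IoU threshold 0.1, bone threshold
#' 120 HU, FP/c evaluation points 0.125..8, operating FP/c ceiling 2.0,
#' two-sided exact CIs at alpha 0.05.
#'
#' @param n_cases number of phantom cases to simulate.
#' @param phantom a [phantom_config()] (per-case seeds are derived from
#'   `seed`, overriding the phantom's own).
#' @param norm a [normalization_params()].
#' @param air_threshold_hu,min_component_voxels lung segmentation
#'   parameters, see [segment_lungs()].
#' @param crop_margin_slices extra slices kept around the lung z-range so
#'   that upper-abdominal structures remain in the detector's view.
#' @param bone_hu_threshold region-map bone threshold (strictly above).
#' @param detector `"reference"` or `"external-json"`.
#' @param external_predictions path to a predictions JSON when
#'   `detector = "external-json"`.
#' @param detector_params,patch_size,stride,merge_iou detection stage
#'   parameters, see [detect_lesions()].
#' @param iou_threshold prediction-to-lesion match threshold.
#' @param fpc_points FROC evaluation points.
#' @param max_fpc operating-threshold policy ceiling.
#' @param alpha CI significance level.
#' @param out_dir optional directory for intermediates and the report.
#' @param seed master seed; one fixed seed reproduces the whole run
#'   byte-identically.
#' @return an object of class `run_config`.
#' @export
run_config <- function(n_cases = 10,
                       phantom = phantom_config(),
                       norm = normalization_params(),
                       air_threshold_hu = -400,
                       min_component_voxels = 500,
                       crop_margin_slices = 12,
                       bone_hu_threshold = 120,
                       detector = c("reference", "external-json"),
                       external_predictions = NULL,
                       detector_params = list(suv_zscore_min = 3,
                                              min_voxels = 3,
                                              max_voxels = Inf),
                       patch_size = c(32, 96, 96),
                       stride = c(16, 96, 96),
                       merge_iou = 0.5,
                       iou_threshold = 0.1,
                       fpc_points = c(0.125, 0.25, 0.5, 1, 2, 4, 8),
                       max_fpc = 2.0,
                       alpha = 0.05,
                       out_dir = NULL,
                       seed = 1L) {
  detector <- match.arg(detector)
  stop_if_not(n_cases >= 1, "n_cases must be at least 1")
  stop_if_not(iou_threshold >= 0 && max_fpc > 0 && alpha > 0 && alpha < 1,
              "evaluation parameters out of range")
  if (detector == "external-json") {
    stop_if_not(!is.null(external_predictions) &&
                  file.exists(external_predictions),
                "external predictions file not found: %s",
                external_predictions %||% "<missing>")
  }
  structure(list(n_cases = n_cases, phantom = phantom, norm = norm,
                 air_threshold_hu = air_threshold_hu,
                 min_component_voxels = min_component_voxels,
                 crop_margin_slices = crop_margin_slices,
                 bone_hu_threshold = bone_hu_threshold,
                 detector = detector,
                 external_predictions = external_predictions,
                 detector_params = detector_params,
                 patch_size = patch_size, stride = stride,
                 merge_iou = merge_iou,
                 iou_threshold = iou_threshold, fpc_points = fpc_points,
                 max_fpc = max_fpc, alpha = alpha,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, case, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed for case %s: %s", name, case,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full phantom-to-report pipeline
#'
#' Executes simulate -> preprocess -> regions -> detect -> evaluate ->
#' report over a cohort of seeded phantoms: lung segmentation and z-axis
#' cropping, patch-wise detection on the cropped pair, mapping of the
#' predictions back to original coordinates, five-region label maps,
#' FROC analysis with the operating-threshold policy, per-category
#' sensitivities with exact CIs, FP/c with and without double annotations,
#' TNM attribution of detected lesions, FP-cause and FN-category tables.
#' A fixed seed yields an identical report.
#'
#' @param config a [run_config()].
#' @return an object of class `study_report`.
#' @export
run_pipeline <- function(config) {
  stop_if_not(inherits(config, "run_config"), "config must be a run_config")
  set.seed(config$seed)
  case_seeds <- sample.int(.Machine$integer.max - 1, config$n_cases)
  ext_preds <- if (config$detector == "external-json")
    import_external_predictions(config$external_predictions) else NULL

  cases <- vector("list", config$n_cases)
  for (i in seq_len(config$n_cases)) {
    pcfg <- config$phantom
    pcfg$seed <- case_seeds[i]
    ph <- stage("simulate", i, generate_phantom(pcfg))
    lung <- stage("preprocess", i,
                  segment_lungs(ph$ct, config$air_threshold_hu,
                                config$min_component_voxels))
    cropped <- stage("preprocess", i,
                     crop_to_lung_slices(ph$ct, ph$pet, lung,
                                         config$crop_margin_slices))
    ct_norm <- stage("preprocess", i,
                     clip_and_normalize(cropped$ct, config$norm))
    regions <- stage("regions", i,
                     build_region_map(ph$ct, lung, config$bone_hu_threshold))
    preds <- if (config$detector == "reference") {
      stage("detect", i,
            detect_lesions(cropped$ct, cropped$pet,
                           patch_size = config$patch_size,
                           stride = config$stride,
                           params = config$detector_params,
                           merge_iou = config$merge_iou))
    } else {
      stop_if_not(i <= length(ext_preds),
                  "no external predictions for case %d", i)
      shift_boxes_z(ext_preds[[i]], -cropped$z_offset)
    }
    preds <- shift_boxes_z(preds, cropped$z_offset)
    gts <- ph$truth$lesions
    gts$id <- seq_len(nrow(gts))
    if (!is.null(config$out_dir)) {
      case_dir <- file.path(config$out_dir, sprintf("case_%03d", i))
      write_phantom(ph, case_dir)
      write_nifti(regions$labels, file.path(case_dir, "regions.nii.gz"),
                  spacing_mm = ph$ct$spacing_mm, datatype = "int32")
      write_nifti(ct_norm, file.path(case_dir, "ct_normalized.nii.gz"),
                  spacing_mm = cropped$ct$spacing_mm)
      jsonlite::write_json(
        list(z_offset = cropped$z_offset, n_slices = cropped$n_slices,
             predictions = preds),
        file.path(case_dir, "predictions.json"),
        dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    cases[[i]] <- list(phantom_seed = case_seeds[i], preds = preds,
                       gts = gts, regions = regions,
                       hotspots = ph$truth$hotspots,
                       z_offset = cropped$z_offset)
  }

  preds_per_case <- lapply(cases, `[[`, "preds")
  gts_per_case <- lapply(cases, `[[`, "gts")
  regions_per_case <- lapply(cases, `[[`, "regions")
  hotspots_per_case <- lapply(cases, `[[`, "hotspots")

  report <- stage("evaluate", "all", evaluate_cohort(
    preds_per_case, gts_per_case, regions_per_case, hotspots_per_case,
    iou_threshold = config$iou_threshold, fpc_points = config$fpc_points,
    max_fpc = config$max_fpc, alpha = config$alpha))
  report$seed <- config$seed
  report$cases <- cases

  if (!is.null(config$out_dir)) {
    stage("report", "all", write_study_report(report, config$out_dir))
  }
  report
}

#' Evaluate a cohort of predictions against ground truth
#'
#' The evaluation protocol on its own: FROC over all observed scores, the
#' operating threshold at the FP/c ceiling, sensitivities with exact CIs
#' overall and per category, FP/c with and without double annotations, TNM
#' attribution of detected lesions through the region maps, FP-cause and
#' FN-category tables.
#'
#' @param preds_per_case,gts_per_case lists of data frames, one per case.
#' @param regions_per_case list of [build_region_map()] results (`NULL` to
#'   skip attribution and FP causes).
#' @param hotspots_per_case optional list of hotspot truth data frames.
#' @param iou_threshold,fpc_points,max_fpc,alpha protocol parameters.
#' @return an object of class `study_report`.
#' @export
evaluate_cohort <- function(preds_per_case, gts_per_case,
                            regions_per_case = NULL,
                            hotspots_per_case = NULL,
                            iou_threshold = 0.1,
                            fpc_points = c(0.125, 0.25, 0.5, 1, 2, 4, 8),
                            max_fpc = 2.0, alpha = 0.05) {
  n_cases <- length(gts_per_case)
  froc_all <- froc(preds_per_case, gts_per_case, fpc_points, iou_threshold)
  thr <- if (length(froc_all$thresholds) > 0)
    operating_threshold(froc_all, max_fpc) else 0

  sets <- mapply(function(p, g)
    match_predictions(p, g, iou_threshold, score_threshold = thr),
    preds_per_case, gts_per_case, SIMPLIFY = FALSE)

  categories <- c("T", "N", "M")
  gt_cats <- unlist(lapply(gts_per_case, function(g) g$category))
  collapsed <- ifelse(grepl("^T", gt_cats), "T", gt_cats)
  sens <- list(overall = sensitivity_by_category(sets, NULL, alpha))
  froc_by_cat <- list()
  for (cat in categories) {
    if (sum(collapsed == cat) > 0) {
      sens[[cat]] <- sensitivity_by_category(sets, cat, alpha)
      froc_by_cat[[cat]] <- froc(preds_per_case, gts_per_case, fpc_points,
                                 iou_threshold, category = cat)
    }
  }

  attribution <- NULL
  fp_causes <- NULL
  if (!is.null(regions_per_case)) {
    assigned <- character(0)
    truth_lab <- character(0)
    for (i in seq_len(n_cases)) {
      tps <- sets[[i]]$tps
      if (nrow(tps) == 0) next
      att <- attribute_lesions(tps[, box_cols], regions_per_case[[i]])
      assigned <- c(assigned, att$assigned_class)
      truth_lab <- c(truth_lab, tps$gt_category)
    }
    if (length(assigned) > 0) {
      attribution <- tnm_attribution_accuracy(assigned, truth_lab)
    }
    fp_causes <- attribute_fp_causes(sets, regions_per_case,
                                     hotspots_per_case)
  }

  structure(list(n_cases = n_cases,
                 n_lesions = length(gt_cats),
                 operating_threshold = thr,
                 sensitivity = sens,
                 fp_per_case = fp_per_case(sets, n_cases),
                 fp_per_case_excl_double =
                   fp_per_case(sets, n_cases, exclude_double = TRUE),
                 froc = froc_all,
                 froc_by_category = froc_by_cat,
                 tnm_attribution = attribution,
                 fp_causes = fp_causes,
                 fn_breakdown = fn_breakdown(sets),
                 match_sets = sets),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d cases, %d lesions\n", x$n_cases, x$n_lesions))
  cat(sprintf("  operating threshold: %.3f (FP/c %.2f; %.2f excluding double annotations)\n",
              x$operating_threshold, x$fp_per_case, x$fp_per_case_excl_double))
  for (nm in names(x$sensitivity)) {
    s <- x$sensitivity[[nm]]
    cat(sprintf("  sensitivity %-8s %5.1f%% (95%% CI: %.1f-%.1f%%, n = %d/%d)\n",
                nm, s$percent, round_half_up(100 * s$ci$lower, 1),
                round_half_up(100 * s$ci$upper, 1), s$k, s$n))
  }
  cat(sprintf("  FROC score (all lesions): %.3f\n", x$froc$froc_score))
  if (!is.null(x$tnm_attribution)) {
    cat(sprintf("  TNM attribution accuracy: %.1f%% (%d/%d)\n",
                x$tnm_attribution$percent, x$tnm_attribution$n_correct,
                x$tnm_attribution$n_total))
  }
  invisible(x)
}

report_as_list <- function(report) {
  ci_list <- function(s) list(
    percent = s$percent, k = s$k, n = s$n,
    ci_lower_percent = round_half_up(100 * s$ci$lower, 1),
    ci_upper_percent = round_half_up(100 * s$ci$upper, 1))
  list(n_cases = report$n_cases,
       n_lesions = report$n_lesions,
       seed = report$seed,
       operating_threshold = report$operating_threshold,
       sensitivity = lapply(report$sensitivity, ci_list),
       fp_per_case = report$fp_per_case,
       fp_per_case_excl_double = report$fp_per_case_excl_double,
       froc_score = report$froc$froc_score,
       froc_score_by_category = lapply(report$froc_by_category,
                                       `[[`, "froc_score"),
       tpr_at_fpc_points = stats::setNames(
         as.list(report$froc$tpr_at_points), report$froc$fpc_points),
       tnm_attribution = if (!is.null(report$tnm_attribution)) list(
         percent = report$tnm_attribution$percent,
         n_correct = report$tnm_attribution$n_correct,
         n_total = report$tnm_attribution$n_total,
         confusion = as.data.frame(report$tnm_attribution$confusion)),
       fp_causes = if (!is.null(report$fp_causes)) report$fp_causes$table,
       fn_breakdown = report$fn_breakdown)
}

#' Write a study report to disk
#'
#' `report.json` (summary metrics), `froc_points.csv` (threshold, TPR,
#' FP/c), and `fp_causes.csv` (cause table).
#'
#' @param report a `study_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_as_list(report), file.path(dir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.csv(data.frame(threshold = report$froc$thresholds,
                              tpr = report$froc$tpr,
                              fp_per_case = report$froc$fpc),
                   file.path(dir, "froc_points.csv"), row.names = FALSE)
  if (!is.null(report$fp_causes)) {
    utils::write.csv(report$fp_causes$table, file.path(dir, "fp_causes.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Export and import predictions as JSON
#'
#' The interchange schema is a list of cases, each with a `case_id` and a
#' list of predictions `{z0, y0, x0, z1, y1, x1, score}` in original-volume
#' voxel coordinates, so that boxes produced by any external detector can
#' be evaluated by this harness. Import validates the schema, box validity
#' (`max > min` per axis), score range and (optionally) the volume extent.
#'
#' @param preds_per_case list of prediction data frames.
#' @param path JSON file path.
#' @return `import_external_predictions`: a list of validated prediction
#'   data frames, one per case, ordered by `case_id`.
#' @export
export_predictions <- function(preds_per_case, path) {
  cases <- lapply(seq_along(preds_per_case), function(i)
    list(case_id = i,
         predictions = preds_per_case[[i]][, c(box_cols, "score")]))
  jsonlite::write_json(list(cases = cases), path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname export_predictions
#' @param extent optional volume shape (nz, ny, nx) each box must fit.
#' @export
import_external_predictions <- function(path, extent = NULL) {
  stop_if_not(file.exists(path), "predictions file not found: %s", path)
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  stop_if_not(!is.null(obj$cases), "predictions JSON must contain 'cases'")
  cases <- obj$cases
  ids <- cases$case_id
  stop_if_not(!is.null(ids), "every case needs a case_id")
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    p <- cases$predictions[[i]]
    if (is.null(p) || length(p) == 0) {
      out[[order(ids)[i]]] <- empty_boxes(score = TRUE)
      next
    }
    stop_if_not(all(c(box_cols, "score") %in% names(p)),
                "case %s: predictions need %s and score", ids[i],
                paste(box_cols, collapse = ", "))
    validate_boxes(p, extent = extent)
    out[[which(order(ids) == i)]] <- p[, c(box_cols, "score")]
  }
  out
}
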