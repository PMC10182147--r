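#' Match predictions to ground-truth lesions
#'
#' Greedy matching in descending score order at a fixed IoU threshold: each
#' prediction matches the still-unmatched ground-truth lesion of highest
#' IoU, provided that IoU reaches the threshold. A later prediction whose
#' only sufficient overlap is with an already-matched lesion becomes a false
#' positive of kind `double_annotation` (repeated annotation of a true
#' finding counts as FP: a lesion detected three times is 1 TP and 2 FP).
#' Predictions overlapping nothing sufficiently are FPs of kind `unmatched`;
#' lesions left unmatched are false negatives.
#'
#' @param preds prediction data frame (boxes + `score`).
#' @param gts ground-truth data frame (boxes; optional `id`, `category`).
#' @param iou_threshold minimum IoU for a match (default 0.1).
#' @param score_threshold predictions below this score are discarded first.
#' @return an object of class `match_set` with `tps` (prediction boxes plus
#'   `gt_id`, `gt_category`, `iou`), `fps` (prediction boxes plus
#'   `fp_kind`), `fns` (ground-truth rows), and the thresholds used.
#'   Invariant: `nrow(tps) + nrow(fns)` equals the number of lesions.
#' @export
match_predictions <- function(preds, gts, iou_threshold = 0.1,
                              score_threshold = 0) {
  stop_if_not(iou_threshold >= 0 && score_threshold >= 0,
              "thresholds must be non-negative")
  if (is.null(gts$id)) gts$id <- seq_len(nrow(gts))
  if (is.null(gts$category)) gts$category <- NA_character_
  if (nrow(preds) > 0) validate_boxes(preds)
  if (nrow(gts) > 0) validate_boxes(gts)
  preds <- preds[preds$score >= score_threshold, , drop = FALSE]
  preds <- preds[order(preds$score, decreasing = TRUE), , drop = FALSE]

  tps <- cbind(empty_boxes(score = TRUE),
               data.frame(gt_id = integer(), gt_category = character(),
                          iou = numeric()))
  fps <- cbind(empty_boxes(score = TRUE), data.frame(fp_kind = character()))
  matched <- rep(FALSE, nrow(gts))
  iou <- iou_matrix(preds, gts)
  for (i in seq_len(nrow(preds))) {
    row <- preds[i, c(box_cols, "score"), drop = FALSE]
    cand <- if (nrow(gts)) which(iou[i, ] >= iou_threshold) else integer(0)
    open <- cand[!matched[cand]]
    if (length(open) > 0) {
      j <- open[which.max(iou[i, open])]
      matched[j] <- TRUE
      tps <- rbind(tps, cbind(row, data.frame(gt_id = gts$id[j],
                                              gt_category = gts$category[j],
                                              iou = iou[i, j])))
    } else if (length(cand) > 0) {
      fps <- rbind(fps, cbind(row, data.frame(fp_kind = "double_annotation")))
    } else {
      fps <- rbind(fps, cbind(row, data.frame(fp_kind = "unmatched")))
    }
  }
  fns <- gts[!matched, , drop = FALSE]
  structure(list(score_threshold = score_threshold,
                 iou_threshold = iou_threshold,
                 tps = tps, fps = fps, fns = fns,
                 n_gt = nrow(gts)),
            class = "match_set")
}

as_match_sets <- function(x) {
  if (inherits(x, "match_set")) list(x) else x
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Two-sided exact interval for a binomial proportion from Beta quantiles:
#' lower bound `qbeta(alpha/2, k, n-k+1)` (0 when k = 0), upper bound
#' `qbeta(1-alpha/2, k+1, n-k)` (1 when k = n).
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials, `n >= 1`.
#' @param alpha two-sided significance level (default 0.05).
#' @return an object of class `binomial_ci`: `k`, `n`, `rate`, `lower`,
#'   `upper`.
#' @export
clopper_pearson <- function(k, n, alpha = 0.05) {
  stop_if_not(n >= 1, "n must be at least 1")
  stop_if_not(k >= 0 && k <= n, "k must lie in [0, n]")
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  structure(list(k = k, n = n, rate = k / n, lower = lower, upper = upper,
                 alpha = alpha),
            class = "binomial_ci")
}

#' @export
print.binomial_ci <- function(x, ...) {
  cat(sprintf("%.1f%% (95%% CI: %.1f-%.1f%%, n = %d/%d)\n",
              round_half_up(100 * x$rate, 1), round_half_up(100 * x$lower, 1),
              round_half_up(100 * x$upper, 1), x$k, x$n))
  invisible(x)
}

#' Detection sensitivity per lesion category
#'
#' Detection rate (sensitivity) at the fixed score threshold the matching
#' was run at: matched lesions of the category divided by all lesions of
#' the category, with an exact binomial CI.
#'
#' @param match_sets a `match_set` or list of them (one per case).
#' @param category_filter character vector of ground-truth categories to
#'   include (`NULL` = all lesions). Subcategories may be selected directly
#'   (e.g. `"T1"`) or collapsed (`"T"` matches every T subcategory).
#' @param alpha CI level.
#' @return list with `rate`, `percent` (one decimal, half-up), `k`, `n` and
#'   `ci` (a [clopper_pearson()] interval).
#' @export
sensitivity_by_category <- function(match_sets, category_filter = NULL,
                                    alpha = 0.05) {
  sets <- as_match_sets(match_sets)
  in_filter <- function(cat) {
    if (is.null(category_filter)) return(rep(TRUE, length(cat)))
    cat %in% category_filter |
      (("T" %in% category_filter) & grepl("^T", cat))
  }
  k <- sum(vapply(sets, function(s) sum(in_filter(s$tps$gt_category)),
                  numeric(1)))
  miss <- sum(vapply(sets, function(s) sum(in_filter(s$fns$category)),
                     numeric(1)))
  n <- k + miss
  stop_if_not(n > 0, "no lesions of the requested category; rate undefined")
  list(rate = k / n, percent = round_half_up(100 * k / n, 1),
       k = k, n = n, ci = clopper_pearson(k, n, alpha))
}

#' False positives per case
#'
#' @param match_sets a `match_set` or list of them.
#' @param n_cases number of cases (scans), >= 1.
#' @param exclude_double drop FPs of kind `double_annotation` (repeated
#'   annotations of true lesions) before dividing.
#' @return FP per case (numeric).
#' @export
fp_per_case <- function(match_sets, n_cases, exclude_double = FALSE) {
  stop_if_not(n_cases >= 1, "n_cases must be at least 1")
  sets <- as_match_sets(match_sets)
  counts <- vapply(sets, function(s) {
    if (exclude_double) sum(s$fps$fp_kind != "double_annotation")
    else nrow(s$fps)
  }, numeric(1))
  sum(counts) / n_cases
}

#' FROC analysis
#'
#' Free-response ROC: the score threshold sweeps over all observed
#' prediction scores; at each threshold the matching is recomputed and the
#' cohort true-positive rate (optionally restricted to one lesion category)
#' is plotted against false positives per case. The FROC score is the mean
#' TPR at the stated FP/c points (default 0.125, 0.25, 0.5, 1, 2, 4, 8),
#' reading the (FP/c, TPR) staircase at each point and carrying the TPR of
#' the largest achieved FP/c out to larger points.
#'
#' @param preds_per_case list of prediction data frames, one per case.
#' @param gts_per_case list of ground-truth data frames, one per case; at
#'   least one lesion in total.
#' @param fpc_points FP-per-case evaluation points.
#' @param iou_threshold match threshold (default 0.1).
#' @param category optional category restriction for the TPR (FPs always
#'   count globally).
#' @return an object of class `froc_result`: `thresholds` (descending),
#'   `tpr`, `fpc`, `fpc_points`, `tpr_at_points`, `froc_score`.
#' @export
froc <- function(preds_per_case, gts_per_case,
                 fpc_points = c(0.125, 0.25, 0.5, 1, 2, 4, 8),
                 iou_threshold = 0.1, category = NULL) {
  stop_if_not(length(preds_per_case) == length(gts_per_case),
              "need one prediction set per case")
  n_cases <- length(gts_per_case)
  in_cat <- function(cat) {
    if (is.null(category)) rep(TRUE, length(cat))
    else cat %in% category | (("T" %in% category) & grepl("^T", cat))
  }
  n_lesions <- sum(vapply(gts_per_case, function(g) {
    cat <- g$category %||% rep(NA_character_, nrow(g))
    sum(in_cat(cat))
  }, numeric(1)))
  stop_if_not(n_lesions > 0, "no ground-truth lesions; FROC undefined")

  scores <- sort(unique(unlist(lapply(preds_per_case, function(p) p$score))),
                 decreasing = TRUE)
  if (length(scores) == 0) {
    return(structure(list(thresholds = numeric(), tpr = numeric(),
                          fpc = numeric(), fpc_points = fpc_points,
                          tpr_at_points = rep(0, length(fpc_points)),
                          froc_score = 0, n_cases = n_cases,
                          n_lesions = n_lesions),
                     class = "froc_result"))
  }
  tpr <- fpc <- numeric(length(scores))
  for (i in seq_along(scores)) {
    sets <- mapply(function(p, g)
      match_predictions(p, g, iou_threshold, score_threshold = scores[i]),
      preds_per_case, gts_per_case, SIMPLIFY = FALSE)
    tp <- sum(vapply(sets, function(s) sum(in_cat(s$tps$gt_category)),
                     numeric(1)))
    tpr[i] <- tp / n_lesions
    fpc[i] <- fp_per_case(sets, n_cases)
  }
  tpr_at <- vapply(fpc_points, function(f) {
    ok <- fpc <= f
    if (!any(ok)) 0 else max(tpr[ok])
  }, numeric(1))
  structure(list(thresholds = scores, tpr = tpr, fpc = fpc,
                 fpc_points = fpc_points, tpr_at_points = tpr_at,
                 froc_score = mean(tpr_at), n_cases = n_cases,
                 n_lesions = n_lesions),
            class = "froc_result")
}

#' @export
print.froc_result <- function(x, ...) {
  cat(sprintf("<froc_result> %d cases, %d lesions, froc score %.3f\n",
              x$n_cases, x$n_lesions, x$froc_score))
  cat("  TPR at FP/c points:\n")
  print(stats::setNames(round(x$tpr_at_points, 3), x$fpc_points))
  invisible(x)
}

#' Operating score threshold from the FROC grid
#'
#' The smallest evaluated threshold whose FP/c does not exceed `max_fpc`
#' (the threshold at which the FP rate per case drops below the acceptable
#' level). If no threshold qualifies, the highest grid threshold is
#' returned with a warning.
#'
#' @param froc_result a [froc()] result with a non-empty threshold grid.
#' @param max_fpc acceptable FP-per-case level (default 2.0).
#' @return score threshold (numeric).
#' @export
operating_threshold <- function(froc_result, max_fpc = 2.0) {
  thr <- froc_result$thresholds
  stop_if_not(length(thr) > 0, "empty threshold grid")
  ok <- froc_result$fpc <= max_fpc
  if (!any(ok)) {
    warning(sprintf("no threshold reaches FP/c <= %.2f; using the highest grid threshold", max_fpc))
    return(thr[1])
  }
  min(thr[ok])
}

FP_CAUSES <- c("double_annotation", "bone", "mediastinal", "pulmonary",
               "abdominal", "foreign_body", "other")

#' Attribute causes of false-positive findings
#'
#' FPs of kind `double_annotation` are counted as such unconditionally; any
#' other FP is categorized by its box's majority anatomical region: bone ->
#' bone, mediastinum -> mediastinal, lung -> pulmonary, abdomen ->
#' abdominal, other -> other. On phantoms, planted hotspot tags refine the
#' per-FP detail (`tag` column) when an FP overlaps a recorded hotspot.
#'
#' @param fps FP data frame from a `match_set` (boxes + `fp_kind`), or a
#'   list of `match_set`s whose FPs are pooled.
#' @param regions a [build_region_map()] result (or a list of them, one per
#'   case, when `fps` is a list of match sets).
#' @param hotspot_truth optional hotspot data frame (tag + box), or list of
#'   them per case.
#' @return an object of class `fp_cause_table`: `table` (cause, n, percent
#'   with half-up one-decimal rounding) and `detail` (one row per FP).
#' @export
attribute_fp_causes <- function(fps, regions, hotspot_truth = NULL) {
  if (!is.data.frame(fps)) {
    sets <- as_match_sets(fps)
    regions_list <- if (inherits(regions, "region_map"))
      rep(list(regions), length(sets)) else regions
    hot_list <- if (is.null(hotspot_truth) || is.data.frame(hotspot_truth))
      rep(list(hotspot_truth), length(sets)) else hotspot_truth
    details <- mapply(function(s, r, h)
      attribute_fp_causes(s$fps, r, h)$detail,
      sets, regions_list, hot_list, SIMPLIFY = FALSE)
    detail <- do.call(rbind, details)
    return(fp_cause_summary(detail))
  }
  detail <- NULL
  for (i in seq_len(nrow(fps))) {
    row <- fps[i, , drop = FALSE]
    if (row$fp_kind == "double_annotation") {
      cause <- "double_annotation"
      maj <- NA_integer_
    } else {
      att <- attribute_lesion(row[, box_cols], regions)
      maj <- att$majority_region
      cause <- c("pulmonary", "mediastinal", "bone", "abdominal", "other")[maj]
    }
    tag <- NA_character_
    if (!is.null(hotspot_truth) && nrow(hotspot_truth) > 0) {
      ious <- iou_matrix(row[, box_cols], hotspot_truth[, box_cols])[1, ]
      if (max(ious) > 0) tag <- hotspot_truth$tag[which.max(ious)]
    }
    detail <- rbind(detail, cbind(row,
                                  data.frame(cause = cause,
                                             majority_region = maj,
                                             tag = tag)))
  }
  fp_cause_summary(detail)
}

fp_cause_summary <- function(detail) {
  if (is.null(detail)) {
    detail <- cbind(empty_boxes(score = TRUE),
                    data.frame(fp_kind = character(), cause = character(),
                               majority_region = integer(),
                               tag = character()))
  }
  n <- as.vector(table(factor(detail$cause, levels = FP_CAUSES)))
  tab <- data.frame(cause = FP_CAUSES, n = n,
                    percent = if (nrow(detail) > 0)
                      round_half_up(100 * n / nrow(detail), 1)
                    else rep(0, length(FP_CAUSES)))
  structure(list(table = tab, detail = detail, total = nrow(detail)),
            class = "fp_cause_table")
}

#' @export
print.fp_cause_table <- function(x, ...) {
  cat(sprintf("<fp_cause_table> %d false positives\n", x$total))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Breakdown of missed lesions by category
#'
#' Counts and one-decimal percentage shares of false negatives per collapsed
#' category (T, N, M), with T subcategory counts alongside.
#'
#' @param fns FN data frame(s) from `match_set`(s) (with a `category`
#'   column) or a character vector of missed-lesion labels.
#' @return data frame with `category`, `n`, `percent` (empty when there are
#'   no FNs), with T subcategory counts as attribute `t_subcategories`.
#' @export
fn_breakdown <- function(fns) {
  labels <- if (is.character(fns)) {
    fns
  } else {
    sets <- if (is.data.frame(fns)) list(list(fns = fns)) else as_match_sets(fns)
    unlist(lapply(sets, function(s) s$fns$category))
  }
  if (length(labels) == 0) {
    out <- data.frame(category = character(), n = integer(),
                      percent = numeric())
    attr(out, "t_subcategories") <- table(factor(character(),
                                                 levels = paste0("T", 1:4)))
    return(out)
  }
  collapsed <- ifelse(grepl("^T", labels), "T", labels)
  n <- as.vector(table(factor(collapsed, levels = c("T", "N", "M"))))
  out <- data.frame(category = c("T", "N", "M"), n = n,
                    percent = round_half_up(100 * n / length(labels), 1))
  attr(out, "t_subcategories") <-
    table(factor(labels[grepl("^T", labels)], levels = paste0("T", 1:4)))
  out
}

#' Percentage reduction between two counts
#'
#' `100 * (n_before - n_after) / n_before`, rounded half-up to one decimal
#' (e.g. the drop in FP count when raising the classifier threshold).
#'
#' @param n_before count before (>= 1).
#' @param n_after count after.
#' @return percentage (one decimal).
#' @export
percent_reduction <- function(n_before, n_after) {
  stop_if_not(n_before >= 1, "n_before must be at least 1")
  round_half_up(100 * (n_before - n_after) / n_before, 1)
}
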