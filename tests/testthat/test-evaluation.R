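test_that("3D IoU matches hand-computed overlaps", {
  a <- boxes(0, 0, 0, 10, 10, 10)
  expect_equal(iou_3d(a, a), 1.0)
  expect_equal(iou_3d(a, boxes(20, 20, 20, 30, 30, 30)), 0.0)
  expect_equal(iou_3d(a, boxes(5, 5, 5, 15, 15, 15)), 125 / 1875)
  expect_error(iou_3d(c(z0 = 0, y0 = 0, x0 = 0, z1 = 0, y1 = 5, x1 = 5), a),
               "degenerate")
})

test_that("greedy matching implements the double-annotation rule", {
  lesion <- boxes(10, 10, 10, 20, 20, 20)
  lesion$category <- "T1"
  # three overlapping predictions on one lesion: 1 TP + 2 FP (double annotation)
  preds <- rbind(boxes(10, 10, 10, 20, 20, 20, score = 0.9),
                 boxes(11, 11, 11, 21, 21, 21, score = 0.8),
                 boxes(9, 9, 9, 19, 19, 19, score = 0.7))
  ms <- match_predictions(preds, lesion, iou_threshold = 0.1)
  expect_equal(nrow(ms$tps), 1)
  expect_equal(nrow(ms$fps), 2)
  expect_true(all(ms$fps$fp_kind == "double_annotation"))
  expect_equal(nrow(ms$fns), 0)

  # overlap below the 0.1 threshold: unmatched FP plus FN
  low <- boxes(10, 10, 19, 20, 20, 29, score = 0.9)   # IoU = 1/19 < 0.1
  stopifnot(iou_3d(low[, 1:6], lesion[, 1:6]) < 0.1)
  ms2 <- match_predictions(low, lesion, iou_threshold = 0.1)
  expect_equal(nrow(ms2$tps), 0)
  expect_equal(ms2$fps$fp_kind, "unmatched")
  expect_equal(nrow(ms2$fns), 1)

  # no predictions at all: everything is missed
  gts5 <- do.call(rbind, lapply(0:4, function(i)
    boxes(i * 10, 0, 0, i * 10 + 5, 5, 5)))
  ms3 <- match_predictions(boxes(integer(0), integer(0), integer(0),
                                 integer(0), integer(0), integer(0),
                                 score = numeric(0))[0, ], gts5)
  expect_equal(nrow(ms3$tps), 0)
  expect_equal(nrow(ms3$fps), 0)
  expect_equal(nrow(ms3$fns), 5)
})

test_that("greedy matching equals optimal assignment when overlaps are unambiguous", {
  # instances where each prediction overlaps at most one lesion: greedy is
  # optimal, so TP counts must agree with exhaustive assignment
  set.seed(7)
  for (rep in 1:20) {
    n_gt <- sample(1:4, 1)
    gts <- do.call(rbind, lapply(seq_len(n_gt) - 1, function(i)
      boxes(i * 30, 0, 0, i * 30 + 10, 10, 10)))
    preds <- NULL
    for (i in seq_len(n_gt) - 1) {
      for (k in seq_len(sample(0:2, 1))) {
        sh <- sample(0:8, 1)
        preds <- rbind(preds, boxes(i * 30 + sh, 0, 0, i * 30 + 10 + sh, 10, 10,
                                    score = stats::runif(1)))
      }
    }
    if (is.null(preds)) next
    ms <- match_predictions(preds, gts, iou_threshold = 0.1)
    # exhaustive: a lesion is detectable iff some prediction reaches 0.1 IoU
    detectable <- vapply(seq_len(n_gt), function(j)
      any(vapply(seq_len(nrow(preds)), function(i)
        iou_3d(preds[i, 1:6], gts[j, 1:6]) >= 0.1, logical(1))), logical(1))
    expect_equal(nrow(ms$tps), sum(detectable))
  }
})

test_that("exact binomial intervals match their closed forms and binom.test", {
  ci <- clopper_pearson(3, 3)
  expect_equal(ci$lower, 0.025^(1 / 3))
  expect_equal(ci$upper, 1)
  expect_equal(clopper_pearson(0, 10)$lower, 0)
  ci2 <- clopper_pearson(127, 143)
  expect_equal(round(ci2$lower, 3), 0.825)
  expect_equal(round(ci2$upper, 3), 0.935)
  # independent cross-check against stats::binom.test
  for (kn in list(c(0, 5), c(2, 17), c(50, 50), c(31, 88))) {
    bt <- stats::binom.test(kn[1], kn[2])$conf.int
    cp <- clopper_pearson(kn[1], kn[2])
    expect_equal(cp$lower, bt[1], tolerance = 1e-10)
    expect_equal(cp$upper, bt[2], tolerance = 1e-10)
  }
  expect_error(clopper_pearson(1, 0), "at least 1")
  expect_error(clopper_pearson(5, 3), "\\[0, n\\]")
})

test_that("sensitivity, FP/c and breakdown arithmetic follow the match sets", {
  sets <- list(counts_match_set(tp_by_cat = c("T1", "N"),
                                fn_by_cat = c("M"),
                                n_fp_double = 1, n_fp_unmatched = 2),
               counts_match_set(tp_by_cat = c("M"),
                                fn_by_cat = c("T2", "N"),
                                n_fp_unmatched = 1))
  # exactly half of each category matched -> 50% everywhere
  for (cat in c("T", "N", "M")) {
    expect_equal(sensitivity_by_category(sets, cat)$percent, 50.0)
  }
  expect_equal(sensitivity_by_category(sets)$rate, 3 / 6)
  expect_equal(fp_per_case(sets, 2), 2.0)
  expect_equal(fp_per_case(sets, 2, exclude_double = TRUE), 1.5)
  expect_error(sensitivity_by_category(sets, "T4"), "undefined")
  expect_error(fp_per_case(sets, 0), "at least 1")

  fb <- fn_breakdown(c("T1", "N", "M", "M"))
  expect_equal(fb$n, c(1, 1, 2))
  expect_equal(fb$percent, c(25, 25, 50))
  expect_equal(nrow(fn_breakdown(character(0))), 0)
})

test_that("FROC handles the perfect and the silent detector", {
  gt <- boxes(10, 10, 10, 20, 20, 20); gt$category <- "T1"
  perfect <- froc(list(boxes(10, 10, 10, 20, 20, 20, score = 0.9)), list(gt))
  expect_equal(perfect$tpr_at_points, rep(1, 7))
  expect_equal(perfect$froc_score, 1.0)

  silent <- froc(list(empty <- boxes(numeric(0), numeric(0), numeric(0),
                                     numeric(0), numeric(0), numeric(0),
                                     score = numeric(0))), list(gt))
  expect_equal(silent$froc_score, 0.0)
  expect_error(froc(list(empty), list(gt[0, ])), "no ground-truth")
})

test_that("the operating threshold policy picks the FP/c knee", {
  fr <- structure(list(thresholds = c(0.5, 0.3, 0.1),
                       fpc = c(0.8, 2.0, 16.6)), class = "froc_result")
  expect_equal(operating_threshold(fr, max_fpc = 2.0), 0.3)
  fr2 <- structure(list(thresholds = c(0.5, 0.3, 0.1),
                        fpc = c(0.1, 0.5, 1.2)), class = "froc_result")
  expect_equal(operating_threshold(fr2, max_fpc = 2.0), 0.1)
  fr3 <- structure(list(thresholds = c(0.5, 0.3),
                        fpc = c(4, 9)), class = "froc_result")
  expect_warning(thr <- operating_threshold(fr3, max_fpc = 2.0), "no threshold")
  expect_equal(thr, 0.5)
  expect_error(operating_threshold(structure(list(thresholds = numeric()),
                                             class = "froc_result")), "empty")
})

test_that("FP causes map double annotations and majority regions", {
  labels <- array(3L, dim = c(10, 10, 10))   # all bone
  rmap <- structure(list(labels = labels, params = list()),
                    class = "region_map")
  fps <- rbind(cbind(boxes(0, 0, 0, 4, 4, 4, score = 0.9),
                     data.frame(fp_kind = "double_annotation")),
               cbind(boxes(5, 5, 5, 9, 9, 9, score = 0.8),
                     data.frame(fp_kind = "unmatched")))
  tab <- attribute_fp_causes(fps, rmap)
  expect_equal(tab$table$n[tab$table$cause == "double_annotation"], 1)
  expect_equal(tab$table$n[tab$table$cause == "bone"], 1)
  expect_equal(tab$total, 2)
  expect_equal(sum(tab$table$n), 2)
})

test_that("percent arithmetic uses half-up one-decimal rounding", {
  expect_equal(percent_reduction(1227, 150), 87.8)
  expect_equal(percent_reduction(100, 100), 0.0)
  expect_equal(percent_reduction(100, 0), 100.0)
  expect_error(percent_reduction(0, 5), "at least 1")
  expect_equal(round_half_up(94.35, 1), 94.4)   # half rounds up, not to even
})
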