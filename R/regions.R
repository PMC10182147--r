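REGION_LEVELS <- c(lung = 1L, mediastinum = 2L, bone = 3L, abdomen = 4L,
                   other = 5L)
# tie-break / painting precedence: lung > bone > mediastinum > abdomen > other
REGION_PRECEDENCE <- c(1L, 3L, 2L, 4L, 5L)

#' Build the five-region anatomical label map
#'
#' Rule-based partition of the scan volume into (1) lung, (2) mediastinum,
#' (3) bone, (4) abdomen and (5) other:
#' * lung: the supplied lung mask;
#' * bone: voxels strictly above the HU threshold, hole-filled (so marrow
#'   interiors count as bone), restricted to the body contour;
#' * mediastinum: per axial slice within the lungs' z-range, voxels with x
#'   between the two lungs' medial borders and y within the lungs'
#'   anterior-posterior envelope, minus lung and bone;
#' * abdomen: in-body voxels on slices caudal to the lung z-extent, minus
#'   bone;
#' * other: everything else (including outside-body air).
#'
#' Overlaps resolve by precedence lung > bone > mediastinum > abdomen >
#' other. With a single merged lung component the mediastinum falls back to
#' the mask's internal concavity (per-row gaps), flagged as degraded mode
#' with a warning.
#'
#' @param ct a `ct_volume` in HU.
#' @param lung_mask logical lung mask from [segment_lungs()].
#' @param bone_hu_threshold HU above which (strictly) a voxel is bone
#'   (default 120).
#' @return an object of class `region_map`: `labels` (integer array 1..5)
#'   and `params` (provenance).
#' @export
build_region_map <- function(ct, lung_mask, bone_hu_threshold = 120) {
  v <- ct$values
  shape <- dim(v)
  stop_if_not(identical(dim(lung_mask), shape), "lung mask shape mismatch")
  stop_if_not(any(lung_mask), "lung mask has no components")
  body <- body_mask_from_ct(ct)
  bone <- fill_holes(v > bone_hu_threshold & body)

  lab <- label_components(lung_mask)
  sizes <- tabulate(lab, nbins = max(lab))
  main <- order(sizes, decreasing = TRUE)[seq_len(min(2, length(sizes)))]
  degraded <- length(main) < 2

  zs <- which(apply(lung_mask, 1, any))
  z_range <- range(zs)
  med <- array(FALSE, dim = shape)

  if (!degraded) {
    co <- arrayInd(which(lab %in% main), shape)
    comp <- lab[lab %in% main]
    cx <- tapply(co[, 3], comp, mean)
    left_id <- main[which.min(cx[as.character(main)])]
    right_id <- setdiff(main, left_id)
    gl_xL <- max(co[comp == left_id, 3])
    gl_xR <- min(co[comp == right_id, 3])
    gl_y <- range(co[, 2])
    for (z in zs) {
      sl <- lab[z, , ]
      li <- which(sl == left_id, arr.ind = TRUE)
      ri <- which(sl == right_id, arr.ind = TRUE)
      any_l <- nrow(li) > 0; any_r <- nrow(ri) > 0
      xL <- if (any_l) max(li[, 2]) else gl_xL
      xR <- if (any_r) min(ri[, 2]) else gl_xR
      yr <- if (any_l || any_r) range(rbind(li, ri)[, 1]) else gl_y
      if (xR > xL + 1) {
        med[z, yr[1]:yr[2], (xL + 1):(xR - 1)] <- TRUE
      }
    }
  } else {
    warning("single merged lung component; mediastinum derived from the mask's internal concavity (degraded mode)")
    for (z in zs) {
      sl <- lung_mask[z, , ]
      for (y in which(apply(sl, 1, any))) {
        xr <- range(which(sl[y, ]))
        if (diff(xr) > 1) {
          gap <- setdiff((xr[1] + 1):(xr[2] - 1), which(sl[y, ]))
          med[z, y, gap] <- TRUE
        }
      }
    }
  }
  med <- med & body

  labels <- array(REGION_LEVELS[["other"]], dim = shape)
  caudal <- seq_len(shape[1]) > z_range[2]
  labels[array(caudal, dim = shape) & body] <- REGION_LEVELS[["abdomen"]]
  labels[med] <- REGION_LEVELS[["mediastinum"]]
  labels[bone] <- REGION_LEVELS[["bone"]]
  labels[lung_mask] <- REGION_LEVELS[["lung"]]

  structure(list(labels = labels,
                 params = list(bone_hu_threshold = bone_hu_threshold,
                               precedence = REGION_PRECEDENCE,
                               degraded = degraded,
                               lung_z_range = z_range - 1L)),
            class = "region_map")
}

#' Attribute a lesion to T, N, M or "N or M"
#'
#' The lesion's voxels (its mask, or the box interior when no mask is
#' available) vote by region label; the majority region determines the
#' class: lung (1) -> T, mediastinum (2) -> N, bone (3) -> M, abdomen or
#' other (4, 5) -> "N or M". Ties break by precedence lung > bone >
#' mediastinum > abdomen > other.
#'
#' @param lesion a logical 3D mask, or a one-row box data frame.
#' @param regions a [build_region_map()] result.
#' @return list with `assigned_class`, `majority_region`,
#'   `majority_fraction`.
#' @export
attribute_lesion <- function(lesion, regions) {
  labels <- regions$labels
  if (is.array(lesion) && is.logical(lesion)) {
    stop_if_not(any(lesion), "empty lesion geometry")
    vox <- labels[lesion]
  } else {
    b <- as_box(lesion)
    validate_boxes(b, extent = dim(labels))
    vox <- labels[(b$z0 + 1):b$z1, (b$y0 + 1):b$y1, (b$x0 + 1):b$x1]
  }
  counts <- tabulate(vox, nbins = 5)
  best <- which(counts == max(counts))
  maj <- REGION_PRECEDENCE[which(REGION_PRECEDENCE %in% best)[1]]
  cls <- switch(maj, "T", "N", "M", "N_or_M", "N_or_M")
  list(assigned_class = cls, majority_region = maj,
       majority_fraction = counts[maj] / length(vox))
}

#' @rdname attribute_lesion
#' @param boxes_df a box data frame (one lesion per row).
#' @return `attribute_lesions`: data frame with one row per box.
#' @export
attribute_lesions <- function(boxes_df, regions) {
  rows <- lapply(seq_len(nrow(boxes_df)), function(i)
    as.data.frame(attribute_lesion(boxes_df[i, , drop = FALSE], regions)))
  if (length(rows) == 0) {
    return(data.frame(assigned_class = character(), majority_region = integer(),
                      majority_fraction = numeric()))
  }
  do.call(rbind, rows)
}

#' TNM attribution accuracy
#'
#' Compares assigned classes against ground-truth labels. Ground-truth
#' subcategories collapse (T1-T4 -> T); an "N or M" attribution counts as
#' correct when the ground truth is N or M.
#'
#' @param attributions character vector of assigned classes in
#'   `{T, N, M, N_or_M}` (aligned with `ground_truth`).
#' @param ground_truth character vector of true labels in
#'   `{T1, T2, T3, T4, T, N, M}`.
#' @return list with `accuracy` (fraction), `percent` (one-decimal,
#'   half-up), `n_correct`, `n_total` and the `confusion` table (rows:
#'   ground truth, columns: assigned).
#' @export
tnm_attribution_accuracy <- function(attributions, ground_truth) {
  stop_if_not(length(attributions) == length(ground_truth) &&
                length(attributions) > 0,
              "need equal-length, non-empty attribution and ground-truth lists")
  gt <- ifelse(grepl("^T", ground_truth), "T", ground_truth)
  correct <- attributions == gt | (attributions == "N_or_M" & gt %in% c("N", "M"))
  confusion <- table(factor(gt, levels = c("T", "N", "M")),
                     factor(attributions,
                            levels = c("T", "N", "M", "N_or_M")),
                     dnn = c("truth", "assigned"))
  list(accuracy = mean(correct),
       percent = round_half_up(100 * mean(correct), 1),
       n_correct = sum(correct),
       n_total = length(correct),
       confusion = confusion)
}
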