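#' Tile a volume into overlapping patches
#'
#' Chooses patch origins so that the union of patches covers every voxel;
#' the final patch per axis is aligned to the volume end. When the volume is
#' smaller than the patch on some axis, a single zero-padded patch is used
#' on that axis (noted with a message) and predictions are later clipped
#' back to the true extent.
#'
#' @param shape volume shape (nz, ny, nx).
#' @param patch_size patch shape per axis; default mirrors a 32-slice
#'   192 x 192 in-plane detection patch.
#' @param stride step between patch origins per axis; positive,
#'   `<= patch_size`.
#' @return an object of class `patch_grid`: `shape`, `patch_size`, `stride`,
#'   `padded_shape`, and `offsets` (matrix, one 0-based origin per row).
#' @export
tile_volume <- function(shape, patch_size = c(32, 192, 192),
                        stride = patch_size) {
  stop_if_not(all(stride > 0), "stride must be positive")
  stop_if_not(all(stride <= patch_size), "stride must not exceed patch_size")
  padded <- pmax(shape, patch_size)
  if (any(patch_size > shape)) {
    message(sprintf("volume %s smaller than patch %s; zero-padding to %s",
                    paste(shape, collapse = "x"),
                    paste(patch_size, collapse = "x"),
                    paste(padded, collapse = "x")))
  }
  per_axis <- lapply(1:3, function(a) {
    last <- padded[a] - patch_size[a]
    off <- seq(0, last, by = stride[a])
    unique(c(off, last))
  })
  offsets <- as.matrix(expand.grid(z = per_axis[[1]], y = per_axis[[2]],
                                   x = per_axis[[3]]))
  structure(list(shape = shape, patch_size = patch_size, stride = stride,
                 padded_shape = padded, offsets = offsets),
            class = "patch_grid")
}

#' Reference lesion detector for one patch
#'
#' Desk-scale stand-in for a learned detector, behind the same interface:
#' PET voxels whose robust z-score against the patch median/MAD exceeds
#' `suv_zscore_min` are grouped into connected components; components with a
#' voxel count in `[min_voxels, max_voxels]` become predictions with their
#' tight bounding box. The score is the component's mean z-score squashed
#' monotonically into \[0, 1\] (`z / (z + 10)`). A robust scale of zero
#' (all-constant patch) yields no predictions; when the MAD alone is zero
#' but the patch is not constant, the mean absolute deviation about the
#' median is used as a fallback scale.
#'
#' @param ct_patch CT patch (unused by the reference detector; part of the
#'   pluggable detector interface).
#' @param pet_patch 3D array of SUV values.
#' @param params list: `suv_zscore_min` (default 3), `min_voxels` (3),
#'   `max_voxels` (Inf).
#' @return box data frame with a `score` column (possibly empty).
#' @export
reference_detect_patch <- function(ct_patch, pet_patch,
                                   params = list()) {
  p <- c(params, list(suv_zscore_min = 3, min_voxels = 3, max_voxels = Inf))
  p <- p[!duplicated(names(p))]
  med <- stats::median(pet_patch)
  dev <- abs(pet_patch - med)
  s <- 1.4826 * stats::median(dev)
  if (s == 0) s <- 1.2533 * mean(dev)
  if (s == 0) return(empty_boxes(score = TRUE))
  z <- (pet_patch - med) / s
  lab <- label_components(z > p$suv_zscore_min)
  if (max(lab) == 0) return(empty_boxes(score = TRUE))
  comps <- component_table(lab)
  comps <- comps[comps$n_voxels >= p$min_voxels &
                   comps$n_voxels <= p$max_voxels, , drop = FALSE]
  if (nrow(comps) == 0) return(empty_boxes(score = TRUE))
  mz <- vapply(comps$label, function(l) mean(z[lab == l]), numeric(1))
  out <- comps[, box_cols]
  out$score <- mz / (mz + 10)
  rownames(out) <- NULL
  out[order(out$score, decreasing = TRUE), , drop = FALSE]
}

#' Consolidate per-patch predictions
#'
#' Merges duplicate detections arising from overlapping patches:
#' single-linkage clustering of boxes with pairwise IoU at or above
#' `merge_iou`; each cluster emits one prediction whose score is the cluster
#' maximum and whose box is the score-weighted average of the member
#' corners (rounded), clipped to the volume. Consolidation never increases
#' the prediction count and never lowers a cluster's best score.
#'
#' @param per_patch box data frame with scores, in global volume
#'   coordinates.
#' @param grid the [tile_volume()] grid (used to clip merged boxes); may be
#'   `NULL` to skip clipping.
#' @param merge_iou IoU at or above which two boxes are linked (default 0.5).
#' @return consolidated box data frame, sorted by descending score.
#' @export
consolidate_predictions <- function(per_patch, grid = NULL, merge_iou = 0.5) {
  if (nrow(per_patch) <= 1) return(per_patch)
  validate_boxes(per_patch)
  n <- nrow(per_patch)
  adj <- iou_matrix(per_patch, per_patch) >= merge_iou
  # single-linkage clusters = connected components of the IoU graph
  cluster <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (cluster[i] > 0) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (cluster[j] > 0) next
      cluster[j] <- cur
      queue <- c(queue, which(adj[j, ] & cluster == 0))
    }
  }
  merged <- lapply(seq_len(cur), function(k) {
    m <- per_patch[cluster == k, , drop = FALSE]
    w <- m$score / sum(m$score)
    b <- vapply(box_cols, function(col) round(sum(w * m[[col]])), numeric(1))
    out <- as.data.frame(as.list(b))
    out$score <- max(m$score)
    out
  })
  out <- do.call(rbind, merged)
  if (!is.null(grid)) out <- clip_boxes(out, grid$shape)
  validate_boxes(out)
  out[order(out$score, decreasing = TRUE), , drop = FALSE]
}

#' Patch-wise lesion detection over a full volume
#'
#' Applies a patch detector to every patch of the tiling, maps the resulting
#' boxes into global coordinates, and consolidates duplicates from
#' overlapping patches. Deterministic for fixed input.
#'
#' @param ct,pet congruent `ct_volume` and `pet_volume` (e.g. the cropped
#'   pair).
#' @param patch_size,stride tiling parameters, see [tile_volume()].
#' @param params detector parameters, see [reference_detect_patch()].
#' @param merge_iou consolidation link threshold.
#' @param detector patch detector function with the signature of
#'   [reference_detect_patch()].
#' @param border_suppression drop per-patch boxes touching a patch face that
#'   is interior to the volume (default TRUE). A lesion cut by a patch
#'   boundary produces a sliver box there; with overlapping patches
#'   (stride < patch size) every object smaller than `patch_size - stride`
#'   is fully contained in some other patch, so suppressing cut boxes
#'   removes duplicates that IoU clustering cannot merge.
#' @return consolidated prediction data frame in volume coordinates.
#' @export
detect_lesions <- function(ct, pet, patch_size = c(32, 96, 96),
                           stride = patch_size, params = list(),
                           merge_iou = 0.5,
                           detector = reference_detect_patch,
                           border_suppression = TRUE) {
  check_congruent(ct, pet)
  shape <- dim(ct$values)
  grid <- tile_volume(shape, patch_size, stride)
  pad <- function(v) {
    if (all(grid$padded_shape == shape)) return(v)
    out <- array(0, dim = grid$padded_shape)
    out[seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3])] <- v
    out
  }
  ctp <- pad(ct$values); petp <- pad(pet$values)
  all_preds <- empty_boxes(score = TRUE)
  for (i in seq_len(nrow(grid$offsets))) {
    o <- grid$offsets[i, ]
    iz <- (o[1] + 1):(o[1] + patch_size[1])
    iy <- (o[2] + 1):(o[2] + patch_size[2])
    ix <- (o[3] + 1):(o[3] + patch_size[3])
    preds <- detector(ctp[iz, iy, ix, drop = FALSE],
                      petp[iz, iy, ix, drop = FALSE], params)
    if (nrow(preds) == 0) next
    preds$z0 <- preds$z0 + o[1]; preds$z1 <- preds$z1 + o[1]
    preds$y0 <- preds$y0 + o[2]; preds$y1 <- preds$y1 + o[2]
    preds$x0 <- preds$x0 + o[3]; preds$x1 <- preds$x1 + o[3]
    if (border_suppression) {
      lo <- o; hi <- o + patch_size
      cut <- (preds$z0 == lo[1] & lo[1] > 0) | (preds$z1 == hi[1] & hi[1] < shape[1]) |
        (preds$y0 == lo[2] & lo[2] > 0) | (preds$y1 == hi[2] & hi[2] < shape[2]) |
        (preds$x0 == lo[3] & lo[3] > 0) | (preds$x1 == hi[3] & hi[3] < shape[3])
      preds <- preds[!cut, , drop = FALSE]
      if (nrow(preds) == 0) next
    }
    all_preds <- rbind(all_preds, preds)
  }
  all_preds <- clip_boxes(all_preds, shape)
  consolidate_predictions(all_preds, grid = list(shape = shape),
                          merge_iou = merge_iou)
}
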