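#' 3D bounding boxes
#'
#' Boxes are stored as data frames with integer columns `z0, y0, x0, z1, y1,
#' x1`: 0-based voxel indices, half-open on every axis (`[min, max)`), in
#' (z, y, x) axis order. A prediction additionally carries a `score` column
#' in \[0, 1\].
#'
#' @param z0,y0,x0,z1,y1,x1 box corners (0-based, half-open).
#' @param score optional confidence scores in \[0, 1\].
#' @return a data frame of boxes.
#' @export
boxes <- function(z0, y0, x0, z1, y1, x1, score = NULL) {
  df <- data.frame(z0 = z0, y0 = y0, x0 = x0, z1 = z1, y1 = y1, x1 = x1)
  if (!is.null(score)) df$score <- score
  validate_boxes(df)
  df
}

box_cols <- c("z0", "y0", "x0", "z1", "y1", "x1")

empty_boxes <- function(score = FALSE) {
  df <- data.frame(z0 = integer(), y0 = integer(), x0 = integer(),
                   z1 = integer(), y1 = integer(), x1 = integer())
  if (score) df$score <- numeric()
  df
}

validate_boxes <- function(df, extent = NULL) {
  stop_if_not(all(box_cols %in% names(df)),
              "boxes need columns %s", paste(box_cols, collapse = ", "))
  if (nrow(df) == 0) return(invisible(df))
  ok <- df$z1 > df$z0 & df$y1 > df$y0 & df$x1 > df$x0
  stop_if_not(all(ok), "degenerate box (max <= min) at row(s) %s",
              paste(which(!ok), collapse = ", "))
  if (!is.null(extent)) {
    inx <- df$z0 >= 0 & df$y0 >= 0 & df$x0 >= 0 &
      df$z1 <= extent[1] & df$y1 <= extent[2] & df$x1 <= extent[3]
    stop_if_not(all(inx), "box outside volume extent at row(s) %s",
                paste(which(!inx), collapse = ", "))
  }
  if ("score" %in% names(df)) {
    stop_if_not(all(df$score >= 0 & df$score <= 1),
                "scores must lie in [0, 1]")
  }
  invisible(df)
}

#' Box volume in voxels
#' @param df a box data frame.
#' @return integer vector of voxel counts.
#' @export
box_volume <- function(df) {
  (df$z1 - df$z0) * (df$y1 - df$y0) * (df$x1 - df$x0)
}

#' Clip boxes to a volume extent
#' @param df a box data frame.
#' @param extent volume shape (nz, ny, nx); boxes are clipped to
#'   `[0, extent)` and rows that become empty are dropped.
#' @return clipped box data frame.
#' @export
clip_boxes <- function(df, extent) {
  if (nrow(df) == 0) return(df)
  df$z0 <- pmax(df$z0, 0L); df$y0 <- pmax(df$y0, 0L); df$x0 <- pmax(df$x0, 0L)
  df$z1 <- pmin(df$z1, extent[1]); df$y1 <- pmin(df$y1, extent[2])
  df$x1 <- pmin(df$x1, extent[3])
  keep <- df$z1 > df$z0 & df$y1 > df$y0 & df$x1 > df$x0
  df[keep, , drop = FALSE]
}

#' Intersection-over-union of two 3D boxes
#'
#' Overlap of two half-open voxel boxes as intersection volume divided by
#' union volume; 0 for disjoint boxes. This is the matching criterion
#' between predicted and ground-truth lesions.
#'
#' @param a,b boxes: named vectors or one-row data frames with
#'   `z0, y0, x0, z1, y1, x1`.
#' @return IoU in \[0, 1\].
#' @export
iou_3d <- function(a, b) {
  a <- as_box(a); b <- as_box(b)
  iou_matrix(a, b)[1, 1]
}

as_box <- function(b) {
  if (is.data.frame(b)) {
    stop_if_not(nrow(b) == 1, "expected a single box")
    validate_boxes(b)
    return(b)
  }
  stop_if_not(is.numeric(b) && length(b) >= 6, "box must have 6 coordinates")
  if (is.null(names(b))) names(b) <- box_cols
  df <- as.data.frame(as.list(b[box_cols]))
  validate_boxes(df)
  df
}

# Pairwise IoU between two box data frames: rows of A x rows of B.
iou_matrix <- function(A, B) {
  validate_boxes(A); validate_boxes(B)
  nA <- nrow(A); nB <- nrow(B)
  if (nA == 0 || nB == 0) return(matrix(0, nA, nB))
  iz <- pmax(0, outer(A$z1, B$z1, pmin) - outer(A$z0, B$z0, pmax))
  iy <- pmax(0, outer(A$y1, B$y1, pmin) - outer(A$y0, B$y0, pmax))
  ix <- pmax(0, outer(A$x1, B$x1, pmin) - outer(A$x0, B$x0, pmax))
  inter <- iz * iy * ix
  uni <- outer(box_volume(A), box_volume(B), "+") - inter
  inter / uni
}

# Tight bounding box of a logical mask (0-based, half-open); NULL when empty.
box_from_mask <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0) return(NULL)
  co <- arrayInd(idx, dim(mask))
  boxes(z0 = min(co[, 1]) - 1L, y0 = min(co[, 2]) - 1L, x0 = min(co[, 3]) - 1L,
        z1 = max(co[, 1]), y1 = max(co[, 2]), x1 = max(co[, 3]))
}

# Logical mask of a single box within a volume of the given shape.
mask_from_box <- function(box, shape) {
  m <- array(FALSE, dim = shape)
  m[(box$z0 + 1):box$z1, (box$y0 + 1):box$y1, (box$x0 + 1):box$x1] <- TRUE
  m
}
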