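#' 3D connected components
#'
#' Labels connected components of a logical 3D mask (compiled breadth-first
#' search). Components are numbered 1..k in scan order; background is 0.
#'
#' @param mask logical 3D array.
#' @param connectivity 6 (faces, default) or 26 (faces, edges, corners).
#' @return integer array of the same shape with component labels.
#' @export
label_components <- function(mask, connectivity = 6) {
  stop_if_not(is.array(mask) && length(dim(mask)) == 3,
              "mask must be a 3D array")
  .label_components_cpp(as.logical(mask), as.integer(dim(mask)),
                        as.integer(connectivity))
}

#' Fill holes in a 3D binary mask
#'
#' A hole is a connected background component that does not touch any face of
#' the volume; such components are flooded and added to the mask (e.g. the
#' marrow cavity enclosed by cortical bone).
#'
#' @param mask logical 3D array.
#' @param connectivity connectivity used for the background flood (default 6).
#' @return logical array with enclosed cavities filled.
#' @export
fill_holes <- function(mask, connectivity = 6) {
  bg <- label_components(!mask, connectivity = connectivity)
  d <- dim(mask)
  boundary <- unique(c(bg[c(1, d[1]), , ], bg[, c(1, d[2]), ], bg[, , c(1, d[3])]))
  boundary <- boundary[boundary > 0]
  mask | (bg > 0 & !(bg %in% boundary))
}

# Per-component voxel counts and tight bounding boxes for a label array.
# Returns a data frame: label, n_voxels, z0..x1 (0-based half-open).
component_table <- function(labels) {
  idx <- which(labels > 0)
  if (length(idx) == 0) {
    return(cbind(data.frame(label = integer(), n_voxels = integer()),
                 empty_boxes()))
  }
  lab <- labels[idx]
  co <- arrayInd(idx, dim(labels))
  agg <- function(v, f) as.vector(tapply(v, lab, f))
  labs <- sort(unique(lab))
  data.frame(label = labs,
             n_voxels = as.vector(table(factor(lab, levels = labs))),
             z0 = agg(co[, 1], min) - 1L, y0 = agg(co[, 2], min) - 1L,
             x0 = agg(co[, 3], min) - 1L,
             z1 = agg(co[, 1], max), y1 = agg(co[, 2], max),
             x1 = agg(co[, 3], max))
}

# Components of `labels` that touch the volume boundary on the given axes
# (1 = z, 2 = y, 3 = x).
boundary_labels <- function(labels, axes = 1:3) {
  d <- dim(labels)
  out <- integer(0)
  if (1 %in% axes) out <- c(out, labels[c(1, d[1]), , ])
  if (2 %in% axes) out <- c(out, labels[, c(1, d[2]), ])
  if (3 %in% axes) out <- c(out, labels[, , c(1, d[3])])
  setdiff(unique(out), 0L)
}
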