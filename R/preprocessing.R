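#' Normalization parameters
#'
#' Clip window and z-score flag for CT intensity normalization. The default
#' window is \[-1200, 600\] HU so that air lies inside the window; both
#' bounds are configurable.
#'
#' @param clip_low,clip_high clip window in HU, `clip_low < clip_high`.
#' @param zscore apply per-volume z-scoring after rescaling to \[0, 1\].
#' @return an object of class `normalization_params`.
#' @export
normalization_params <- function(clip_low = -1200, clip_high = 600,
                                 zscore = TRUE) {
  stop_if_not(clip_low < clip_high, "clip_low must be below clip_high")
  structure(list(clip_low = clip_low, clip_high = clip_high, zscore = zscore),
            class = "normalization_params")
}

#' Clip and normalize a CT volume
#'
#' Values are clipped to the window, affinely rescaled to \[0, 1\], and then
#' z-scored over the whole volume (mean 0, SD 1). The mapping is monotone
#' non-decreasing in the input HU. A volume with zero variance after
#' rescaling yields all zeros with a warning rather than an error.
#'
#' @param ct a `ct_volume` (values in HU).
#' @param params a [normalization_params()].
#' @return unitless 3D array of the same shape.
#' @export
clip_and_normalize <- function(ct, params = normalization_params()) {
  stop_if_not(inherits(params, "normalization_params"),
              "params must be normalization_params")
  v <- if (inherits(ct, "pc_volume")) ct$values else ct
  v <- pmin(pmax(v, params$clip_low), params$clip_high)
  v <- (v - params$clip_low) / (params$clip_high - params$clip_low)
  if (isTRUE(params$zscore)) {
    s <- stats::sd(v)
    if (s == 0) {
      warning("zero variance after rescaling; z-score step outputs all zeros")
      v[] <- 0
    } else {
      v <- (v - mean(v)) / s
    }
  }
  v
}

# body contour from CT: non-air voxels, largest connected component, holes
# (lungs, bowel gas) filled
body_mask_from_ct <- function(ct, threshold_hu = -500) {
  v <- if (inherits(ct, "pc_volume")) ct$values else ct
  lab <- label_components(v > threshold_hu)
  if (max(lab) == 0) return(array(FALSE, dim = dim(v)))
  sizes <- tabulate(lab[lab > 0])
  fill_holes(lab == which.max(sizes))
}

#' Threshold-based lung segmentation
#'
#' Binary lung mask from intensity thresholding and connected-component
#' analysis: voxels below the air threshold inside the body contour, with
#' components touching the volume boundary in x/y discarded (outside-body
#' air), components below the size cutoff dropped, and the two largest
#' retained (a merged lung pair may be a single component). Interior holes
#' are filled so that soft-tissue lesions inside the lung stay part of the
#' lung region.
#'
#' @param ct a `ct_volume` in HU (not normalized).
#' @param air_threshold_hu threshold below which a voxel counts as air
#'   (default -400 HU).
#' @param min_component_voxels minimum component size retained.
#' @return logical 3D lung mask.
#' @export
segment_lungs <- function(ct, air_threshold_hu = -400,
                          min_component_voxels = 500) {
  v <- ct$values
  body <- body_mask_from_ct(ct)
  air <- v < air_threshold_hu & body
  lab <- label_components(air)
  if (max(lab) > 0) {
    drop <- boundary_labels(lab, axes = 2:3)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  sizes <- if (max(lab) > 0) tabulate(lab, nbins = max(lab)) else integer(0)
  keep <- which(sizes >= min_component_voxels)
  if (length(keep) == 0) {
    stop("lung segmentation produced an empty mask (no air component inside the body)",
         call. = FALSE)
  }
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  keep <- keep[seq_len(min(2, length(keep)))]
  fill_holes(array(lab %in% keep, dim = dim(v)))
}

#' Crop a CT/PET pair to the lung z-range
#'
#' Restricts both volumes to the axial slices spanned by the lung mask, plus
#' an optional margin, and records the z offset needed to map boxes in
#' cropped coordinates back to the original volume.
#'
#' @param ct,pet congruent `ct_volume` and `pet_volume`.
#' @param lung_mask logical mask from [segment_lungs()]; must be non-empty.
#' @param margin_slices extra slices kept on each side (default 0).
#' @return list with cropped `ct`, `pet`, `z_offset` (0-based index of the
#'   first kept slice) and `n_slices`.
#' @export
crop_to_lung_slices <- function(ct, pet, lung_mask, margin_slices = 0) {
  check_congruent(ct, pet)
  zs <- which(apply(lung_mask, 1, any))
  stop_if_not(length(zs) > 0, "lung mask is empty; cannot crop")
  z0 <- max(1L, min(zs) - margin_slices)
  z1 <- min(dim(ct$values)[1], max(zs) + margin_slices)
  sel <- z0:z1
  crop <- function(vol, ctor) {
    ctor(vol$values[sel, , , drop = FALSE], vol$spacing_mm,
         vol$origin_mm + c((z0 - 1) * vol$spacing_mm[1], 0, 0))
  }
  list(ct = crop(ct, ct_volume), pet = crop(pet, pet_volume),
       z_offset = z0 - 1L, n_slices = length(sel))
}

#' Shift boxes along z
#'
#' Maps boxes between cropped and original coordinates: predictions found in
#' a cropped volume are restored to original-volume coordinates by adding
#' the `z_offset` recorded by [crop_to_lung_slices()].
#'
#' @param df box data frame.
#' @param z_offset slices to add to `z0`/`z1` (negative to go the other way).
#' @return shifted box data frame.
#' @export
shift_boxes_z <- function(df, z_offset) {
  if (nrow(df) == 0) return(df)
  df$z0 <- df$z0 + z_offset
  df$z1 <- df$z1 + z_offset
  validate_boxes(df)
  df
}
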