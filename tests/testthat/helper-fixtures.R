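# Shared fixtures, all generated in code. Phantoms are cached per
# configuration key so several test files can reuse the same volumes.

.phantom_cache <- new.env(parent = emptyenv())

hotspots_off <- c(heart = FALSE, marrow = FALSE, kidneys = FALSE,
                  liver = FALSE)
hotspots_on <- c(heart = TRUE, marrow = TRUE, kidneys = TRUE, liver = TRUE)

noiseless_config <- function(seed = 7, hotspots = hotspots_off, ...) {
  phantom_config(ct_noise_sd = 0, pet_noise_scale = 0,
                 physiological_hotspots = hotspots, seed = seed, ...)
}

cached_phantom <- function(key, config) {
  if (!exists(key, envir = .phantom_cache)) {
    assign(key, generate_phantom(config), envir = .phantom_cache)
  }
  get(key, envir = .phantom_cache)
}

# default noiseless phantom without hotspots, used across modules
fixture_phantom <- function() {
  cached_phantom("noiseless7", noiseless_config(seed = 7))
}

fixture_phantom_hot <- function() {
  cached_phantom("hot7", noiseless_config(seed = 7, hotspots = hotspots_on))
}

# random valid boxes inside [0, extent) with scores
random_boxes <- function(n, extent = c(40, 40, 40), max_size = 12) {
  z0 <- sample.int(extent[1] - 2, n, replace = TRUE) - 1L
  y0 <- sample.int(extent[2] - 2, n, replace = TRUE) - 1L
  x0 <- sample.int(extent[3] - 2, n, replace = TRUE) - 1L
  dz <- sample.int(max_size, n, replace = TRUE)
  dy <- sample.int(max_size, n, replace = TRUE)
  dx <- sample.int(max_size, n, replace = TRUE)
  boxes(z0, y0, x0,
        pmin(z0 + dz, extent[1]), pmin(y0 + dy, extent[2]),
        pmin(x0 + dx, extent[3]),
        score = round(stats::runif(n), 3))
}

# a match_set with prescribed counts, for report-arithmetic checks
counts_match_set <- function(tp_by_cat = character(0),
                             fn_by_cat = character(0),
                             n_fp_double = 0, n_fp_unmatched = 0) {
  structure(list(
    score_threshold = 0.3, iou_threshold = 0.1,
    tps = data.frame(gt_category = tp_by_cat),
    fns = data.frame(category = fn_by_cat),
    fps = data.frame(fp_kind = c(rep("double_annotation", n_fp_double),
                                 rep("unmatched", n_fp_unmatched))),
    n_gt = length(tp_by_cat) + length(fn_by_cat)),
    class = "match_set")
}

# voxel-enumeration IoU oracle on small integer boxes
iou_voxel_oracle <- function(a, b, extent) {
  ma <- array(FALSE, dim = extent); mb <- array(FALSE, dim = extent)
  ma[(a$z0 + 1):a$z1, (a$y0 + 1):a$y1, (a$x0 + 1):a$x1] <- TRUE
  mb[(b$z0 + 1):b$z1, (b$y0 + 1):b$y1, (b$x0 + 1):b$x1] <- TRUE
  sum(ma & mb) / sum(ma | mb)
}

truth_gts <- function(ph) {
  cbind(ph$truth$lesions[, c("z0", "y0", "x0", "z1", "y1", "x1")],
        data.frame(category = ph$truth$lesions$category,
                   id = seq_len(nrow(ph$truth$lesions))))
}
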