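#' Phantom configuration
#'
#' Parameters of the synthetic torso phantom: a stylized chest/upper-abdomen
#' CT/PET pair with two air-density lungs inside a soft-tissue body, a
#' mediastinal band with a heart, a capped vertebral column (cortical shell
#' over a marrow cavity) plus rib shells, an abdominal compartment with liver
#' and kidneys, and planted T/N/M lesions with known ground truth.
#'
#' Lesion volumes are drawn log-normally, matched to reported clinical means
#' and standard deviations per category (T: 39.9 (100.7) cm^3, N: 4.8 (12.4)
#' cm^3, M: 6.2 (15.0) cm^3) and truncated to diameter ranges the stylized
#' anatomy can host.
#'
#' @param grid_shape voxels per axis (z, y, x); all >= 32.
#' @param spacing_mm per-axis voxel size in mm (z, y, x).
#' @param n_lesions named counts for categories T, N, M.
#' @param t_diameter_range_cm,n_diameter_range_cm,m_diameter_range_cm
#'   truncation ranges for sampled lesion diameters.
#' @param volume_stats per-category mean/sd (cm^3) of the log-normal lesion
#'   volume distribution.
#' @param lesion_suv_range uptake range of planted lesions (SUV); must exceed
#'   `background_suv`.
#' @param background_suv soft-tissue background uptake.
#' @param lung_suv lung parenchyma uptake.
#' @param physiological_hotspots named logical flags: heart, marrow, kidneys,
#'   liver.
#' @param hotspot_suv named uptake levels for enabled hotspots.
#' @param ct_noise_sd additive Gaussian CT noise (HU).
#' @param pet_noise_scale PET noise: additive Gaussian with sd
#'   `scale * sqrt(intensity)` (Poisson surrogate).
#' @param seed RNG seed; a fixed seed yields byte-identical phantoms.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64, 96, 96),
                           spacing_mm = c(3, 2.5, 2.5),
                           n_lesions = c(T = 1, N = 3, M = 1),
                           t_diameter_range_cm = c(1.0, 4.5),
                           n_diameter_range_cm = c(0.8, 3.0),
                           m_diameter_range_cm = c(0.8, 2.4),
                           volume_stats = list(T = c(mean = 39.9, sd = 100.7),
                                               N = c(mean = 4.8, sd = 12.4),
                                               M = c(mean = 6.2, sd = 15.0)),
                           lesion_suv_range = c(4, 9),
                           background_suv = 1.0,
                           lung_suv = 0.4,
                           physiological_hotspots = c(heart = TRUE,
                                                      marrow = TRUE,
                                                      kidneys = TRUE,
                                                      liver = TRUE),
                           hotspot_suv = c(heart = 5.0, marrow = 3.0,
                                           kidneys = 4.0, liver = 2.5),
                           ct_noise_sd = 10,
                           pet_noise_scale = 0.05,
                           seed = 42L) {
  stop_if_not(length(grid_shape) == 3 && all(grid_shape >= 32),
              "grid_shape must be 3 values, all >= 32")
  stop_if_not(all(spacing_mm > 0), "spacing_mm must be positive")
  stop_if_not(min(lesion_suv_range) > background_suv,
              "lesion SUV must exceed background SUV")
  stop_if_not(all(c("T", "N", "M") %in% names(n_lesions)),
              "n_lesions needs named counts for T, N, M")
  stop_if_not(ct_noise_sd >= 0 && pet_noise_scale >= 0,
              "noise parameters must be non-negative")
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 n_lesions = n_lesions,
                 t_diameter_range_cm = t_diameter_range_cm,
                 n_diameter_range_cm = n_diameter_range_cm,
                 m_diameter_range_cm = m_diameter_range_cm,
                 volume_stats = volume_stats,
                 lesion_suv_range = lesion_suv_range,
                 background_suv = background_suv,
                 lung_suv = lung_suv,
                 physiological_hotspots = physiological_hotspots,
                 hotspot_suv = hotspot_suv,
                 ct_noise_sd = ct_noise_sd,
                 pet_noise_scale = pet_noise_scale,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' T category from tumor diameter
#'
#' Size-based simplified T staging: tumors up to 3 cm are T1, above 3 and up
#' to 5 cm T2, above 5 and up to 7 cm T3, above 7 cm T4 (features such as
#' invasiveness are not modelled).
#'
#' @param diameter_cm tumor diameter(s) in cm, > 0.
#' @return character vector in `{"T1","T2","T3","T4"}`.
#' @export
t_category_from_diameter <- function(diameter_cm) {
  stop_if_not(all(diameter_cm > 0), "diameter must be positive")
  as.character(cut(diameter_cm, breaks = c(0, 3, 5, 7, Inf),
                   labels = c("T1", "T2", "T3", "T4"), right = TRUE))
}

# Analytic geometry of the stylized torso, in mm, derived from the field of
# view. Everything downstream (truth labels, CT/PET painting, lesion
# placement) reads from this one description.
phantom_geometry <- function(config) {
  fov <- config$grid_shape * config$spacing_mm  # (z, y, x) mm
  g <- list(fov = fov)
  g$body_center <- c(0.5 * fov[2], 0.5 * fov[3])          # (y, x)
  g$body_semi <- c(0.40 * fov[2], 0.47 * fov[3])
  g$lung_center_z <- 0.36 * fov[1]
  g$lung_semi <- c(0.23 * fov[1], 0.23 * fov[2], 0.15 * fov[3])
  g$lung_center_y <- 0.49 * fov[2]
  g$lung_center_x <- c(0.5 * fov[3] - 0.25 * fov[3],
                       0.5 * fov[3] + 0.25 * fov[3])
  g$lung_z_range <- g$lung_center_z + c(-1, 1) * g$lung_semi[1]
  # medial gap between the lungs, used for the mediastinal band
  g$gap_x <- c(g$lung_center_x[1] + g$lung_semi[3],
               g$lung_center_x[2] - g$lung_semi[3])
  g$lung_env_y <- g$lung_center_y + c(-1, 1) * g$lung_semi[2]
  # vertebral column: cortical tube with end caps, marrow cavity inside
  g$vert_axis <- c(0.79 * fov[2], 0.5 * fov[3])           # (y, x)
  g$vert_outer_r <- 0.083 * fov[3]
  g$vert_marrow_r <- g$vert_outer_r - 5
  g$vert_z <- c(0.03, 0.97) * fov[1]
  g$vert_cap <- 6
  # rib surrogates: thin elliptical shells near the body surface
  g$rib_z <- c(0.20, 0.33, 0.46) * fov[1]
  g$rib_thickness <- 6
  g$rib_frac <- c(0.90, 0.97)
  g$heart_center <- c(0.48 * fov[1], 0.40 * fov[2], 0.5 * fov[3])
  g$heart_semi <- c(20, 26, 19)
  g$liver_center <- c(0.70 * fov[1], 0.46 * fov[2], 0.28 * fov[3])
  g$liver_semi <- c(16, 42, 38)
  g$kidney_center_z <- 0.78 * fov[1]
  g$kidney_center_y <- 0.62 * fov[2]
  g$kidney_center_x <- c(0.5 * fov[3] - 0.19 * fov[3],
                         0.5 * fov[3] + 0.19 * fov[3])
  g$kidney_semi <- c(14, 14, 11)
  g$marrow_hotspot_z <- c(0.18, 0.52) * fov[1]
  g$marrow_hotspot_r <- 8
  # clear mediastinal strip for N lesions: between heart (anterior) and
  # vertebra (posterior)
  g$n_strip_y <- c(g$heart_center[2] + g$heart_semi[2] + 2,
                   g$vert_axis[1] - g$vert_outer_r - 2)
  g
}

# voxel-center coordinates per axis, mm
axis_coords <- function(config) {
  lapply(1:3, function(a)
    (seq_len(config$grid_shape[a]) - 0.5) * config$spacing_mm[a])
}

# ellipsoid mask via separable outer sums; center/semi in mm, (z, y, x)
ellipsoid_mask <- function(coords, center, semi) {
  A <- ((coords[[1]] - center[1]) / semi[1])^2
  B <- ((coords[[2]] - center[2]) / semi[2])^2
  C <- ((coords[[3]] - center[3]) / semi[3])^2
  outer(outer(A, B, "+"), C, "+") <= 1
}

# in-plane elliptical radius fraction (same for every slice)
plane_radius2 <- function(coords, center_yx, semi_yx) {
  B <- ((coords[[2]] - center_yx[1]) / semi_yx[1])^2
  C <- ((coords[[3]] - center_yx[2]) / semi_yx[2])^2
  r2 <- outer(B, C, "+")
  aperm(array(r2, dim = c(length(coords[[2]]), length(coords[[3]]),
                          length(coords[[1]]))), c(3, 1, 2))
}

# structural masks shared by truth construction and CT/PET painting
phantom_masks <- function(config) {
  g <- phantom_geometry(config)
  co <- axis_coords(config)
  shape <- config$grid_shape
  zmm <- co[[1]]

  body_r2 <- plane_radius2(co, g$body_center, g$body_semi)
  body <- body_r2 <= 1

  lungL <- ellipsoid_mask(co, c(g$lung_center_z, g$lung_center_y,
                                g$lung_center_x[1]), g$lung_semi)
  lungR <- ellipsoid_mask(co, c(g$lung_center_z, g$lung_center_y,
                                g$lung_center_x[2]), g$lung_semi)
  lung <- lungL | lungR

  vert_r2 <- plane_radius2(co, g$vert_axis, rep(g$vert_outer_r, 2))
  marrow_r2 <- plane_radius2(co, g$vert_axis, rep(g$vert_marrow_r, 2))
  in_z <- zmm >= g$vert_z[1] & zmm <= g$vert_z[2]
  cap_z <- in_z & (zmm <= g$vert_z[1] + g$vert_cap |
                     zmm >= g$vert_z[2] - g$vert_cap)
  zsel <- array(in_z, dim = shape)
  zcap <- array(cap_z, dim = shape)
  vert_solid <- vert_r2 <= 1 & zsel
  marrow <- marrow_r2 <= 1 & zsel & !zcap
  cortex <- vert_solid & !marrow

  rib <- array(FALSE, dim = shape)
  for (zr in g$rib_z) {
    band <- array(abs(zmm - zr) <= g$rib_thickness / 2, dim = shape)
    rib <- rib | (band & body_r2 >= g$rib_frac[1]^2 &
                    body_r2 <= g$rib_frac[2]^2)
  }
  rib <- rib & !lung

  heart <- ellipsoid_mask(co, g$heart_center, g$heart_semi)
  liver <- ellipsoid_mask(co, g$liver_center, g$liver_semi) & body
  kidneys <- ellipsoid_mask(co, c(g$kidney_center_z, g$kidney_center_y,
                                  g$kidney_center_x[1]), g$kidney_semi) |
    ellipsoid_mask(co, c(g$kidney_center_z, g$kidney_center_y,
                         g$kidney_center_x[2]), g$kidney_semi)

  list(geometry = g, coords = co, body = body, lung = lung,
       lungL = lungL, lungR = lungR,
       bone_solid = vert_solid | rib, cortex = cortex | rib, marrow = marrow,
       heart = heart, liver = liver, kidneys = kidneys)
}

# ground-truth five-region partition (1 lung, 2 mediastinum, 3 bone,
# 4 abdomen, 5 other incl. outside-body air)
phantom_region_truth <- function(masks, config) {
  g <- masks$geometry
  co <- masks$coords
  shape <- config$grid_shape
  labels <- array(5L, dim = shape)
  in_gap_x <- co[[3]] > g$gap_x[1] & co[[3]] < g$gap_x[2]
  in_env_y <- co[[2]] >= g$lung_env_y[1] & co[[2]] <= g$lung_env_y[2]
  in_lung_z <- co[[1]] >= g$lung_z_range[1] & co[[1]] <= g$lung_z_range[2]
  med <- outer(outer(in_lung_z, in_env_y, "&"), in_gap_x, "&") & masks$body
  caudal <- co[[1]] > g$lung_z_range[2]
  abd <- array(caudal, dim = shape) & masks$body
  labels[abd] <- 4L
  labels[med] <- 2L
  labels[masks$bone_solid] <- 3L
  labels[masks$lung] <- 1L
  labels
}

sample_lesion_diameters <- function(category, n, config) {
  st <- config$volume_stats[[category]]
  rng <- switch(category, T = config$t_diameter_range_cm,
                N = config$n_diameter_range_cm,
                M = config$m_diameter_range_cm)
  sigma2 <- log(1 + (st["sd"] / st["mean"])^2)
  mu <- log(st["mean"]) - sigma2 / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- NA_real_
    for (try in 1:50) {
      vol <- exp(stats::rnorm(1, mu, sqrt(sigma2)))
      d <- (6 * vol / pi)^(1 / 3)
      if (d >= rng[1] && d <= rng[2]) break
    }
    out[i] <- min(max(d, rng[1]), rng[2])
  }
  out
}

# minimum clearance (mm) between an intrapulmonary lesion and the lung
# surface, so threshold-based lung masks keep an enclosing air shell
lesion_margin_mm <- 6

# sample a lesion centre (mm) inside the safe zone of the intended region
sample_lesion_center <- function(category, r_mm, masks, which_lung = 1L) {
  g <- masks$geometry
  if (category == "T") {
    # a sphere of radius r centred anywhere in the ellipsoid scaled by
    # (1 - r/min(semi)) stays wholly inside the lung ellipsoid; the margin
    # keeps an air shell around the lesion so the lung surface is not broken
    shrink <- 1 - (r_mm + lesion_margin_mm) / min(g$lung_semi)
    stop_if_not(shrink > 0, "T lesion too large for the phantom lung")
    semi <- g$lung_semi * shrink
    repeat {
      u <- stats::runif(3, -1, 1)
      if (sum(u^2) <= 1) break
    }
    c(g$lung_center_z, g$lung_center_y, g$lung_center_x[which_lung]) + u * semi
  } else if (category == "N") {
    lo <- c(g$lung_z_range[1] + r_mm, g$n_strip_y[1] + r_mm,
            g$gap_x[1] + r_mm)
    hi <- c(g$lung_z_range[2] - r_mm, g$n_strip_y[2] - r_mm,
            g$gap_x[2] - r_mm)
    stop_if_not(all(hi > lo), "N lesion too large for the mediastinal strip")
    stats::runif(3, lo, hi)
  } else {
    rad <- g$vert_marrow_r - r_mm
    stop_if_not(rad >= 0, "M lesion too large for the marrow cavity")
    repeat {
      u <- stats::runif(2, -1, 1)
      if (sum(u^2) <= 1) break
    }
    # thoracic vertebral metastases: keep within the lung z-extent so the
    # lung-based crop never discards lesion voxels
    zlo <- max(g$vert_z[1] + g$vert_cap, g$lung_z_range[1]) + r_mm
    zhi <- min(g$vert_z[2] - g$vert_cap, g$lung_z_range[2]) - r_mm
    stop_if_not(zhi > zlo, "M lesion too large for the thoracic spine segment")
    z <- stats::runif(1, zlo, zhi)
    c(z, g$vert_axis[1] + u[1] * rad, g$vert_axis[2] + u[2] * rad)
  }
}

region_name <- function(label) {
  c("lung", "mediastinum", "bone", "abdomen", "other")[label]
}

#' Generate a synthetic CT/PET phantom
#'
#' Builds the paired CT (HU) and PET (SUV) volumes of the stylized torso
#' described in [phantom_config()], plants lesions wholly inside their
#' intended anatomical region (T in lung, N in mediastinum, M in bone
#' marrow), adds enabled physiological hotspots, and applies noise last.
#' The same seed yields byte-identical volumes and truth.
#'
#' @param config a [phantom_config()].
#' @param max_place_attempts bounded retries for lesion placement before a
#'   placement error naming the region is raised.
#' @return a list with `ct` (`ct_volume`), `pet` (`pet_volume`) and `truth`,
#'   where `truth` holds `region_truth` (labels 1..5), `lesions` (data frame
#'   with id, category, region, diameter_cm, suv, volume_cm3 and box),
#'   `lesion_labels` (integer array, lesion id per voxel), `hotspots`
#'   (data frame with tag, suv and box), `body_mask` and `lung_mask`.
#' @export
generate_phantom <- function(config, max_place_attempts = 500) {
  stop_if_not(inherits(config, "phantom_config"), "config must be a phantom_config")
  set.seed(config$seed)
  shape <- config$grid_shape
  masks <- phantom_masks(config)
  region_truth <- phantom_region_truth(masks, config)
  vox_cm3 <- prod(config$spacing_mm) / 1000
  co <- masks$coords

  # --- lesion placement -----------------------------------------------------
  plan <- data.frame(category = rep(c("T", "N", "M"),
                                    times = config$n_lesions[c("T", "N", "M")]),
                     stringsAsFactors = FALSE)
  placed <- list()    # center (mm) + radius of everything already occupied
  avoid <- list(list(center = masks$geometry$heart_center,
                     r = max(masks$geometry$heart_semi)))
  for (zc in masks$geometry$marrow_hotspot_z) {
    avoid <- c(avoid, list(list(
      center = c(zc, masks$geometry$vert_axis), r = masks$geometry$marrow_hotspot_r)))
  }
  sep_margin <- 2 * max(config$spacing_mm)

  lesion_labels <- array(0L, dim = shape)
  lesions <- NULL
  if (nrow(plan) > 0) {
    diam <- unlist(lapply(c("T", "N", "M"), function(cat) {
      n <- sum(plan$category == cat)
      if (n > 0) sample_lesion_diameters(cat, n, config) else numeric(0)
    }))
    plan$diameter_cm <- diam   # plan rows are in T..N..M order by construction
    for (i in seq_len(nrow(plan))) {
      cat <- plan$category[i]
      r_mm <- plan$diameter_cm[i] * 10 / 2
      intended <- switch(cat, T = 1L, N = 2L, M = 3L)
      ok <- FALSE
      for (attempt in seq_len(max_place_attempts)) {
        wl <- if (cat == "T") sample(1:2, 1) else 1L
        center <- sample_lesion_center(cat, r_mm, masks, which_lung = wl)
        clear <- all(vapply(c(placed, avoid), function(p)
          sqrt(sum((p$center - center)^2)) >= p$r + r_mm + sep_margin,
          logical(1)))
        if (!clear) next
        sph <- ellipsoid_mask(co, center, rep(r_mm, 3))
        if (!any(sph)) next
        # for lung lesions require the margin-dilated sphere to stay inside
        # the lung too, preserving the surrounding air shell
        check <- if (cat == "T")
          ellipsoid_mask(co, center, rep(r_mm + lesion_margin_mm, 3)) else sph
        if (all(region_truth[check] == intended) && !any(lesion_labels[sph] > 0)) {
          lesion_labels[sph] <- i
          placed <- c(placed, list(list(center = center, r = r_mm)))
          bb <- box_from_mask(sph)
          lesions <- rbind(lesions, cbind(
            data.frame(id = i,
                       category = if (cat == "T")
                         t_category_from_diameter(plan$diameter_cm[i]) else cat,
                       region = intended,
                       diameter_cm = plan$diameter_cm[i],
                       volume_cm3 = sum(sph) * vox_cm3,
                       suv = stats::runif(1, config$lesion_suv_range[1],
                                          config$lesion_suv_range[2]),
                       hu = stats::runif(1, 30, 60)),
            bb))
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop(sprintf(
          "could not place %s lesion (d = %.1f cm) inside region '%s' after %d attempts",
          cat, plan$diameter_cm[i], region_name(intended), max_place_attempts),
          call. = FALSE)
      }
    }
  }
  if (is.null(lesions)) {
    lesions <- cbind(data.frame(id = integer(), category = character(),
                                region = integer(), diameter_cm = numeric(),
                                volume_cm3 = numeric(), suv = numeric(),
                                hu = numeric()), empty_boxes())
  }

  # --- CT -------------------------------------------------------------------
  ct <- array(-1000, dim = shape)
  ct[masks$body] <- 40
  ct[masks$lung] <- -800
  ct[masks$marrow] <- 40
  ct[masks$cortex] <- 400
  for (i in seq_len(nrow(lesions))) {
    ct[lesion_labels == lesions$id[i]] <- lesions$hu[i]
  }

  # --- PET (noiseless; hotspots and noise added below) ----------------------
  pet <- array(0, dim = shape)
  pet[masks$body] <- config$background_suv
  pet[masks$lung] <- config$lung_suv
  for (i in seq_len(nrow(lesions))) {
    pet[lesion_labels == lesions$id[i]] <- lesions$suv[i]
  }

  truth <- structure(list(region_truth = region_truth,
                          lesions = lesions,
                          lesion_labels = lesion_labels,
                          hotspots = cbind(data.frame(tag = character(),
                                                      suv = numeric()),
                                           empty_boxes()),
                          body_mask = masks$body,
                          lung_mask = masks$lung,
                          config = config),
                     class = "phantom_truth")

  pet_vol <- pet_volume(pet, config$spacing_mm)
  withhot <- add_physiological_uptake(pet_vol, truth, config)
  pet_vol <- withhot$pet
  truth <- withhot$truth

  # --- noise last, clamped to physical ranges -------------------------------
  if (config$ct_noise_sd > 0) {
    ct <- ct + stats::rnorm(length(ct), 0, config$ct_noise_sd)
    ct <- pmin(pmax(ct, -1024), 3071)
    dim(ct) <- shape
  }
  if (config$pet_noise_scale > 0) {
    p <- pet_vol$values
    p <- p + stats::rnorm(length(p), 0, config$pet_noise_scale) * sqrt(pmax(p, 0))
    p <- pmax(p, 0)
    dim(p) <- shape
    pet_vol <- pet_volume(p, config$spacing_mm)
  }

  list(ct = ct_volume(ct, config$spacing_mm), pet = pet_vol, truth = truth)
}

#' Add physiological uptake hotspots
#'
#' Paints the enabled physiological hotspots into the PET volume: myocardium
#' (mediastinum), vertebral bone marrow (inside the hole-filled bone), kidneys
#' and liver (abdomen). Each blob is recorded in the truth as a non-lesion
#' hotspot with its anatomical tag. With all flags off the volume is returned
#' unchanged. The operation is deterministic (no randomness).
#'
#' @param pet a `pet_volume`.
#' @param truth the `phantom_truth` of the same phantom.
#' @param config the `phantom_config` (hotspot flags and uptake levels).
#' @return list with updated `pet` and `truth`.
#' @export
add_physiological_uptake <- function(pet, truth, config) {
  flags <- config$physiological_hotspots
  masks <- phantom_masks(config)
  p <- pet$values
  hs <- truth$hotspots

  paint <- function(mask, tag, suv) {
    mask <- mask & !(truth$lesion_labels > 0)
    if (!any(mask)) return(invisible(NULL))
    p[mask] <<- pmax(p[mask], suv)
    hs <<- rbind(hs, cbind(data.frame(tag = tag, suv = suv),
                           box_from_mask(mask)))
    invisible(NULL)
  }

  if (isTRUE(flags[["heart"]])) {
    paint(masks$heart, "heart", config$hotspot_suv[["heart"]])
  }
  if (isTRUE(flags[["marrow"]])) {
    co <- masks$coords
    for (zc in masks$geometry$marrow_hotspot_z) {
      blob <- ellipsoid_mask(co, c(zc, masks$geometry$vert_axis),
                             rep(masks$geometry$marrow_hotspot_r, 3)) &
        masks$marrow
      paint(blob, "marrow", config$hotspot_suv[["marrow"]])
    }
  }
  if (isTRUE(flags[["kidneys"]])) {
    paint(masks$kidneys, "kidney", config$hotspot_suv[["kidneys"]])
  }
  if (isTRUE(flags[["liver"]])) {
    paint(masks$liver, "liver", config$hotspot_suv[["liver"]])
  }

  truth$hotspots <- hs
  list(pet = pet_volume(p, pet$spacing_mm, pet$origin_mm), truth = truth)
}

#' Write a phantom to disk
#'
#' CT and PET as NIfTI (`.nii.gz`) with voxel spacing in the header, the
#' region truth as a NIfTI label map, and the lesion/hotspot truth as JSON.
#'
#' @param phantom result of [generate_phantom()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_nifti(phantom$ct, file.path(dir, "ct.nii.gz"))
  write_nifti(phantom$pet, file.path(dir, "pet.nii.gz"))
  write_nifti(phantom$truth$region_truth, file.path(dir, "regions_truth.nii.gz"),
              spacing_mm = phantom$ct$spacing_mm, datatype = "int32")
  truth <- list(lesions = phantom$truth$lesions,
                hotspots = phantom$truth$hotspots)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(dir)
}
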