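test_that("T category follows the size rules, boundaries included correctly", {
  expect_equal(t_category_from_diameter(c(0.5, 3.0, 3.01, 5.0, 5.1, 7.0, 7.01, 12)),
               c("T1", "T1", "T2", "T2", "T3", "T3", "T4", "T4"))
  expect_error(t_category_from_diameter(0), "positive")
  expect_error(t_category_from_diameter(-2), "positive")
})

test_that("phantom generation is deterministic for a fixed seed", {
  cfg <- noiseless_config(seed = 123, hotspots = hotspots_on)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$ct$values, b$ct$values)
  expect_identical(a$pet$values, b$pet$values)
  expect_identical(a$truth$lesions, b$truth$lesions)
  expect_identical(a$truth$region_truth, b$truth$region_truth)
  # noise paths are seeded too
  cfgn <- phantom_config(seed = 123)
  expect_identical(generate_phantom(cfgn)$pet$values,
                   generate_phantom(cfgn)$pet$values)
})

test_that("region truth partitions the volume and lesions respect it", {
  ph <- fixture_phantom()
  labels <- ph$truth$region_truth
  expect_true(all(labels %in% 1:5))
  expect_equal(sum(tabulate(labels, 5)), length(labels))
  # every lesion lies inside the body and inside its intended region
  les <- ph$truth$lesions
  for (i in seq_len(nrow(les))) {
    vox <- ph$truth$lesion_labels == les$id[i]
    expect_true(all(ph$truth$body_mask[vox]))
    expect_true(all(labels[vox] == les$region[i]))
  }
  # T categories consistent with sampled diameters
  tles <- les[grepl("^T", les$category), ]
  expect_equal(tles$category, t_category_from_diameter(tles$diameter_cm))
})

test_that("with noise off and hotspots off, supra-background PET equals the lesions", {
  cfg <- noiseless_config(seed = 31, n_lesions = c(T = 1, N = 0, M = 0))
  ph <- generate_phantom(cfg)
  hot <- ph$pet$values > cfg$background_suv
  expect_identical(hot, ph$truth$lesion_labels > 0)
  expect_equal(max(label_components(hot)), 1)  # exactly one connected lesion

  ph5 <- fixture_phantom()
  expect_identical(ph5$pet$values > ph5$truth$config$background_suv,
                   ph5$truth$lesion_labels > 0)
})

test_that("a fixed 4 cm T lesion at 2 mm isotropic spacing has the analytic sphere volume", {
  cfg <- noiseless_config(seed = 5,
                          grid_shape = c(96, 120, 120),
                          spacing_mm = c(2, 2, 2),
                          n_lesions = c(T = 1, N = 0, M = 0),
                          t_diameter_range_cm = c(4, 4))
  ph <- generate_phantom(cfg)
  v_true <- 4 / 3 * pi * 2^3   # (4/3) pi r^3, r = 2 cm
  expect_equal(ph$truth$lesions$diameter_cm, 4)
  expect_lt(abs(ph$truth$lesions$volume_cm3 - v_true) / v_true, 0.10)
})

test_that("physiological hotspots are identity when off and land in their regions", {
  ph <- fixture_phantom()
  out <- add_physiological_uptake(ph$pet, ph$truth, ph$truth$config)
  expect_identical(out$pet$values, ph$pet$values)
  expect_equal(nrow(out$truth$hotspots), 0)

  hot <- fixture_phantom_hot()
  hs <- hot$truth$hotspots
  expect_setequal(unique(hs$tag), c("heart", "marrow", "kidney", "liver"))
  # heart: majority of its supra-background voxels are mediastinum
  heart_mask <- hot$pet$values == hot$truth$config$hotspot_suv[["heart"]]
  labs <- hot$truth$region_truth[heart_mask]
  expect_gt(mean(labs == 2), 0.5)
  # marrow blobs lie inside hole-filled bone structures
  marrow_mask <- hot$pet$values == hot$truth$config$hotspot_suv[["marrow"]]
  bone_filled <- fill_holes(hot$ct$values > 300)
  expect_true(all(bone_filled[marrow_mask]))
})

test_that("impossible placements raise an error naming the region", {
  cfg <- noiseless_config(seed = 1, n_lesions = c(T = 0, N = 0, M = 12))
  expect_error(generate_phantom(cfg, max_place_attempts = 25), "bone")
})

test_that("configuration invariants are enforced", {
  expect_error(phantom_config(grid_shape = c(16, 96, 96)), ">= 32")
  expect_error(phantom_config(spacing_mm = c(0, 1, 1)), "positive")
  expect_error(phantom_config(lesion_suv_range = c(0.5, 0.8)),
               "exceed background")
})
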