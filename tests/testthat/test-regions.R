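# small synthetic torso block: -1000 shell, 40 HU body, two "lungs" provided
# as a mask, assorted bone structures painted per test
make_block <- function(side = 24) {
  v <- array(-1000, dim = rep(side, 3))
  v[4:(side - 3), 4:(side - 3), 4:(side - 3)] <- 40
  v
}
block_lungs <- function(side = 24) {
  m <- array(FALSE, dim = rep(side, 3))
  m[8:16, 8:16, 6:9] <- TRUE     # left lung
  m[8:16, 8:16, 15:18] <- TRUE   # right lung
  m
}

test_that("bone labelling is strictly above threshold and hole-filled", {
  v <- make_block()
  v[6, 6, 12] <- 150    # inside body, outside lungs, between them in x
  v[7, 6, 12] <- 120    # exactly at threshold: not bone
  # hollow cortical box (cortex 400), interior 40, fully enclosed
  v[18:22, 14:20, 14:20] <- 400
  v[19:21, 15:19, 15:19] <- 40
  ct <- ct_volume(v, spacing_mm = c(2, 2, 2))
  rm <- build_region_map(ct, block_lungs())
  expect_equal(rm$labels[6, 6, 12], 3L)
  expect_false(rm$labels[7, 6, 12] == 3L)
  expect_true(all(rm$labels[19:21, 15:19, 15:19] == 3L))  # filled interior
  # partition: every voxel labelled exactly once in 1..5
  expect_equal(sum(tabulate(rm$labels, 5)), length(rm$labels))
})

test_that("the mediastinum sits between the lungs and the abdomen below them", {
  ct <- ct_volume(make_block(), spacing_mm = c(2, 2, 2))
  rm <- build_region_map(ct, block_lungs())
  expect_equal(rm$labels[12, 12, 12], 2L)   # between the lungs
  expect_equal(rm$labels[20, 12, 12], 4L)   # in-body, caudal to the lungs
  expect_equal(rm$labels[12, 12, 7], 1L)    # lung voxel
  expect_equal(rm$labels[1, 1, 1], 5L)      # outside-body air
})

test_that("a merged lung mask triggers degraded-mode mediastinum with a warning", {
  m <- array(FALSE, dim = rep(24, 3))
  m[8:16, 8:16, 6:9] <- TRUE
  m[8:16, 8:16, 15:18] <- TRUE
  m[8:16, 8, 10:14] <- TRUE      # bridge merging the two lungs
  ct <- ct_volume(make_block(), spacing_mm = c(2, 2, 2))
  expect_warning(rm <- build_region_map(ct, m), "degraded")
  expect_equal(rm$labels[12, 12, 12], 2L)   # concavity still labelled
})

test_that("lesions are attributed by majority region with precedence tie-breaks", {
  ct <- ct_volume(make_block(), spacing_mm = c(2, 2, 2))
  rm <- build_region_map(ct, block_lungs())
  # fully inside lung -> T
  expect_equal(attribute_lesion(boxes(9, 9, 6, 12, 12, 8), rm)$assigned_class, "T")
  # fully between the lungs -> N
  a <- attribute_lesion(boxes(9, 9, 10, 12, 12, 13), rm)
  expect_equal(a$assigned_class, "N")
  expect_equal(a$majority_fraction, 1)
  # 60% lung / 40% mediastinum -> majority vote T: box spans x 7..11,
  # lung occupies x 7,8,9 (0-based 5-based?) use mask-based lesion
  mask <- array(FALSE, dim = rep(24, 3))
  mask[9:11, 9:11, 7:9] <- TRUE    # 27 voxels in lung (x 6..9 region)
  mask[9:11, 9:11, 10:11] <- TRUE  # 18 voxels mediastinum
  expect_equal(attribute_lesion(mask, rm)$assigned_class, "T")
  # bone majority -> M
  v <- make_block(); v[10:14, 18:20, 10:14] <- 400
  rm2 <- build_region_map(ct_volume(v, spacing_mm = c(2, 2, 2)), block_lungs())
  expect_equal(attribute_lesion(boxes(10, 17, 10, 13, 20, 13), rm2)$assigned_class,
               "M")
  expect_error(attribute_lesion(array(FALSE, dim = rep(24, 3)), rm), "empty")
})

test_that("attribution accuracy collapses subcategories and honours N-or-M", {
  # identity -> 100%
  r <- tnm_attribution_accuracy(c("T", "N", "M"), c("T2", "N", "M"))
  expect_equal(r$accuracy, 1)
  # N_or_M counts as correct for ground-truth N or M, not for T
  r2 <- tnm_attribution_accuracy(c("N_or_M", "N_or_M", "N_or_M"),
                                 c("M", "N", "T1"))
  expect_equal(r2$n_correct, 2)
  # the confusion table carries all assignments
  expect_equal(sum(r2$confusion), 3)
  expect_equal(as.vector(r2$confusion["T", "N_or_M"]), 1)
  expect_error(tnm_attribution_accuracy(character(0), character(0)),
               "non-empty")
})

test_that("on the noiseless phantom, truth-box attribution is perfect", {
  ph <- fixture_phantom()
  mask <- segment_lungs(ph$ct)
  rm <- build_region_map(ph$ct, mask)
  att <- attribute_lesions(ph$truth$lesions[, c("z0", "y0", "x0",
                                                "z1", "y1", "x1")], rm)
  acc <- tnm_attribution_accuracy(att$assigned_class,
                                  ph$truth$lesions$category)
  expect_equal(acc$accuracy, 1)
})
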