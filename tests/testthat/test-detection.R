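test_that("tiling covers the volume with end-aligned patches", {
  g <- tile_volume(c(32, 192, 192), patch_size = c(32, 192, 192),
                   stride = c(32, 192, 192))
  expect_equal(nrow(g$offsets), 1)
  expect_true(all(g$offsets[1, ] == 0))

  g2 <- tile_volume(c(32, 192, 300), patch_size = c(32, 192, 192),
                    stride = c(32, 192, 96))
  covered <- rep(FALSE, 300)
  for (i in seq_len(nrow(g2$offsets))) {
    x0 <- g2$offsets[i, "x"]
    covered[(x0 + 1):(x0 + 192)] <- TRUE
  }
  expect_true(all(covered))

  expect_error(tile_volume(c(32, 32, 32), c(16, 16, 16), c(0, 16, 16)),
               "positive")
})

test_that("the reference detector finds hot spheres and scores by uptake", {
  # uniform background: no signal, no predictions
  flat <- array(1, dim = c(24, 24, 24))
  expect_equal(nrow(reference_detect_patch(NULL, flat)), 0)

  # one hot sphere SUV 8 on background 1
  pet <- array(1, dim = c(24, 24, 24))
  pet <- pet + array(stats::rnorm(length(pet), 0, 0.03), dim = dim(pet))
  sph <- array(FALSE, dim = dim(pet))
  co <- arrayInd(seq_along(sph), dim(sph))
  inside <- rowSums((co - 12)^2) <= 9
  sph[inside] <- TRUE
  pet[sph] <- 8
  preds <- reference_detect_patch(NULL, pet)
  expect_equal(nrow(preds), 1)
  tb <- boxes(min(co[inside, 1]) - 1, min(co[inside, 2]) - 1,
              min(co[inside, 3]) - 1,
              max(co[inside, 1]), max(co[inside, 2]), max(co[inside, 3]))
  expect_gte(iou_3d(preds[1, ], tb), 0.99)

  # two disjoint spheres: two predictions, hotter sphere scores higher
  pet2 <- array(1, dim = c(24, 24, 48))
  pet2[10:14, 10:14, 8:12] <- 4
  pet2[10:14, 10:14, 30:34] <- 9
  p2 <- reference_detect_patch(NULL, pet2)
  expect_equal(nrow(p2), 2)
  hot_first <- p2$x0[1] > p2$x0[2]
  expect_true(hot_first)   # sorted by descending score; SUV 9 sphere first
})

test_that("an all-constant patch (zero robust scale) yields no predictions", {
  expect_equal(nrow(reference_detect_patch(NULL, array(3, dim = c(8, 8, 8)))), 0)
})

test_that("consolidation keeps the max score and merges by single linkage", {
  a <- boxes(0, 0, 0, 10, 10, 10, score = 0.4)
  b <- boxes(0, 0, 0, 10, 10, 10, score = 0.7)
  out <- consolidate_predictions(rbind(a, b))
  expect_equal(nrow(out), 1)
  expect_equal(out$score, 0.7)
  expect_equal(out$z1, 10)

  disjoint <- rbind(boxes(0, 0, 0, 5, 5, 5, score = 0.5),
                    boxes(20, 20, 20, 25, 25, 25, score = 0.6))
  out2 <- consolidate_predictions(disjoint)
  expect_equal(nrow(out2), 2)
})

test_that("single-linkage clustering equals brute-force transitive closure", {
  # chain A~B, B~C, A!~C must merge into one cluster
  A <- boxes(0, 0, 0, 10, 10, 10, score = 0.9)
  B <- boxes(4, 0, 0, 14, 10, 10, score = 0.5)
  C <- boxes(8, 0, 0, 18, 10, 10, score = 0.4)
  stopifnot(iou_3d(A, C) < 0.5, iou_3d(A, B) >= 0.3)
  out <- consolidate_predictions(rbind(A, B, C), merge_iou = 0.3)
  expect_equal(nrow(out), 1)
  expect_equal(out$score, 0.9)

  # random instances vs an independent transitive-closure oracle
  set.seed(42)
  for (rep in 1:20) {
    bx <- random_boxes(sample(3:20, 1))
    n <- nrow(bx)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      adj[i, j] <- iou_3d(bx[i, ], bx[j, ]) >= 0.5
    }
    reach <- adj
    for (k in seq_len(n)) reach <- reach | (reach[, k] %o% reach[k, ] > 0)
    n_clusters <- length(unique(apply(reach, 1, function(r) min(which(r)))))
    out <- consolidate_predictions(bx, merge_iou = 0.5)
    expect_equal(nrow(out), n_clusters)
    expect_equal(max(out$score), max(bx$score))  # never lowers the best score
    expect_lte(nrow(out), n)                     # never increases the count
  }
})

test_that("patch-wise detection is deterministic and clips padded predictions", {
  ph <- fixture_phantom()
  mask <- segment_lungs(ph$ct)
  cr <- crop_to_lung_slices(ph$ct, ph$pet, mask, margin_slices = 12)
  p1 <- detect_lesions(cr$ct, cr$pet, patch_size = c(32, 96, 96),
                       stride = c(16, 96, 96))
  p2 <- detect_lesions(cr$ct, cr$pet, patch_size = c(32, 96, 96),
                       stride = c(16, 96, 96))
  expect_identical(p1, p2)
  expect_equal(nrow(p1), nrow(ph$truth$lesions))

  # volume smaller than the patch: single padded patch, boxes stay in extent
  small_ct <- ct_volume(ph$ct$values[1:20, , ], spacing_mm = ph$ct$spacing_mm)
  small_pet <- pet_volume(ph$pet$values[1:20, , ], spacing_mm = ph$pet$spacing_mm)
  expect_message(
    pd <- detect_lesions(small_ct, small_pet, patch_size = c(32, 96, 96),
                         stride = c(32, 96, 96)),
    "zero-padding")
  if (nrow(pd) > 0) expect_true(all(pd$z1 <= 20))
})
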