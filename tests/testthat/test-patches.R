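test_that("a regular grid yields the expected patch count", {
  cells <- data.frame(x = c(10, 300), y = c(10, 300),
                      cell_type = c("tumour", "normal"), diameter_px = 10)
  tile <- manual_tile(600, 600, cells)
  expect_length(extract_patches(tile, size = 200, stride = 200), 9)
  expect_length(extract_patches(tile, size = 200, stride = 100), 25)
})

test_that("majority rule labels by plurality of cell types", {
  cells <- data.frame(
    x = c(seq(10, 30, 10), seq(50, 90, 10)),
    y = rep(20, 8),
    cell_type = rep(c("tumour", "normal"), c(3, 5)),
    diameter_px = 10)
  tile <- manual_tile(100, 100, cells, patch_size = 100)
  p <- extract_patches(tile, size = 100, stride = 100, rule = "majority")
  expect_equal(p[[1]]$label, "no_cancer")   # 3 tumour vs 5 normal
  # plurality flips when three tumour cells are added (6 vs 5)
  cells2 <- rbind(cells, data.frame(x = c(35, 40, 45), y = 20,
                                    cell_type = "tumour", diameter_px = 10))
  p2 <- extract_patches(manual_tile(100, 100, cells2, 100),
                        size = 100, stride = 100)
  expect_equal(p2[[1]]$label, "cancer")
  # ties are not a plurality of tumour cells
  cells3 <- cells[c(1:3, 4:6), ]
  p3 <- extract_patches(manual_tile(100, 100, cells3, 100),
                        size = 100, stride = 100)
  expect_equal(p3[[1]]$label, "no_cancer")
})

test_that("centre-cell rule labels by the nearest central cell and discards empty centres", {
  # patch centre of a 100 px patch at offset 0 is (49.5, 49.5)
  cells <- data.frame(x = c(49.5, 20, 80), y = c(49.5, 20, 80),
                      cell_type = c("tumour", "normal", "normal"),
                      diameter_px = 10)
  tile <- manual_tile(100, 100, cells, patch_size = 100)
  p <- extract_patches(tile, size = 100, stride = 100, rule = "centre_cell")
  expect_length(p, 1)
  expect_equal(p[[1]]$label, "cancer")
  # no cell within one mean radius of the centre: patch discarded
  far <- data.frame(x = c(10, 90), y = c(10, 90),
                    cell_type = c("tumour", "normal"), diameter_px = 10)
  expect_length(extract_patches(manual_tile(100, 100, far, 100),
                                size = 100, stride = 100, rule = "centre_cell"), 0)
})

test_that("corner marker replaces exactly the top-left block and flags the patch", {
  tile <- small_tile(3)
  p <- extract_patches(tile)[[1]]
  q <- inject_corner_marker(p, side = 5, colour = c(0.2, 0.4, 0.6))
  changed <- which(q$image != p$image, arr.ind = TRUE)
  expect_true(all(changed[, 1] <= 5 & changed[, 2] <= 5))
  expect_equal(q$image[3, 3, ], c(0.2, 0.4, 0.6))
  expect_equal(sum(apply(q$image != p$image, c(1, 2), any)), 25)
  expect_true("corner_marker" %in% q$bias_flags)
  expect_false("corner_marker" %in% p$bias_flags)
  # overwriting with the existing content changes nothing but the flag
  p2 <- p
  p2$image[1:5, 1:5, 1] <- 0.9; p2$image[1:5, 1:5, 2] <- 0.1
  p2$image[1:5, 1:5, 3] <- 0.3
  q2 <- inject_corner_marker(p2, side = 5, colour = c(0.9, 0.1, 0.3))
  expect_identical(q2$image, p2$image)
  expect_true("corner_marker" %in% q2$bias_flags)
  expect_error(inject_corner_marker(p, side = 1000), "exceeds")
})

test_that("region exclusion removes exactly the overlapping patches", {
  h <- 128
  mask <- matrix(FALSE, h, h)
  mask[1:70, 1:70] <- TRUE     # overlaps patches at offsets (0,0), (0,64), (64,0), (64,64)
  cells <- data.frame(x = 100, y = 100, cell_type = "normal", diameter_px = 8)
  tile <- manual_tile(h, h, cells, patch_size = 64,
                      regions = list(list(mask = mask, region_type = "necrosis")))
  patches <- extract_patches(tile, size = 64, stride = 64)
  expect_length(patches, 4)
  # oracle: count overlaps by direct mask intersection
  overlaps <- vapply(patches, function(p) {
    rows <- (p$source$row + 1):(p$source$row + 64)
    cols <- (p$source$col + 1):(p$source$col + 64)
    sum(mask[rows, cols]) > 0
  }, logical(1))
  kept <- exclude_region_patches(patches, tile, "necrosis")
  expect_length(kept, sum(!overlaps))
  expect_length(kept, 0)  # all four patches touch the 70x70 block
  # higher tolerance keeps patches with small overlap
  kept2 <- exclude_region_patches(patches, tile, "necrosis", max_overlap = 0.5)
  fr <- vapply(patches, function(p) {
    rows <- (p$source$row + 1):(p$source$row + 64)
    cols <- (p$source$col + 1):(p$source$col + 64)
    mean(mask[rows, cols])
  }, numeric(1))
  expect_length(kept2, sum(fr <= 0.5))
  # datasets without regions pass through unchanged
  tile0 <- manual_tile(h, h, cells, patch_size = 64)
  expect_length(exclude_region_patches(patches_from <- extract_patches(tile0, 64, 64),
                                       tile0, "necrosis"), 4)
  expect_error(exclude_region_patches(patches, tile, "vessel"), "unknown region type")
})

test_that("augmentation is identity at zero jitter and zero rotation", {
  tile <- small_tile(4)
  p <- extract_patches(tile)[[1]]
  q <- augment_patch(p, tile, jitter_frac = 0, rotations = 0)
  expect_identical(q$image, p$image)
})

test_that("rotation by 180 degrees is an involution", {
  tile <- small_tile(4)
  p <- extract_patches(tile)[[1]]
  q <- augment_patch(p, tile, jitter_frac = 0, rotations = 180)
  expect_false(identical(q$image, p$image))
  q2 <- augment_patch(q, tile, jitter_frac = 0, rotations = 180)
  expect_equal(q2$image, p$image)
})

test_that("seeded augmentation is reproducible and preserves the label", {
  tile <- small_tile(4)
  p <- extract_patches(tile)[[2]]
  set.seed(42); a <- augment_patch(p, tile)
  set.seed(42); b <- augment_patch(p, tile)
  expect_identical(a$image, b$image)
  expect_identical(a$label, p$label)
  expect_identical(dim(a$image), dim(p$image))
})
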