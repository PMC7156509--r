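test_that("non-overlapping stitch forms an exact block mosaic", {
  q <- lapply(1:4, function(i) matrix(i, 2, 2))
  hm <- stitch(q, list(c(0, 0), c(0, 2), c(2, 0), c(2, 2)), c(4, 4))
  expect_equal(hm$values[1:2, 1:2], matrix(1, 2, 2))
  expect_equal(hm$values[1:2, 3:4], matrix(2, 2, 2))
  expect_equal(hm$values[3:4, 1:2], matrix(3, 2, 2))
  expect_equal(hm$values[3:4, 3:4], matrix(4, 2, 2))
  expect_true(all(hm$coverage))
  expect_equal(hm$normalisation, "raw")
})

test_that("overlapping contributions are averaged and gaps flagged", {
  m1 <- matrix(1, 2, 4); m2 <- matrix(3, 2, 4)
  hm <- stitch(list(m1, m2), list(c(0, 0), c(0, 2)), c(2, 8))
  expect_equal(hm$values[, 3:4], matrix(2, 2, 2))   # mean of 1 and 3
  expect_equal(hm$values[, 1:2], matrix(1, 2, 2))
  expect_equal(hm$values[, 5:6], matrix(3, 2, 2))
  expect_false(any(hm$coverage[, 7:8]))
  expect_equal(hm$values[, 7:8], matrix(0, 2, 2))
  expect_error(stitch(list(m1), list(c(0, 6)), c(2, 8)), "fit")
})

test_that("one-tenth overlap of 200 px patches means a 180 px stride", {
  size <- 200
  stride <- size - size / 10
  expect_equal(stride, 180)
  offs <- seq(0, 600 - size, by = stride)
  expect_equal(offs, c(0, 180, 360))
})

test_that("mass is preserved under non-overlapping stitching", {
  set.seed(3)
  maps <- lapply(1:4, function(i) matrix(rnorm(16), 4, 4))
  hm <- stitch(maps, list(c(0, 0), c(0, 4), c(4, 0), c(4, 4)), c(8, 8))
  expect_equal(sum(hm$values), sum(vapply(maps, sum, numeric(1))))
})

test_that("global normalisation uses the set-wide maximum, local the own one", {
  h1 <- stitch(list(matrix(c(-2, 1, 0.5, 0), 2, 2)), list(c(0, 0)), c(2, 2))
  h2 <- stitch(list(matrix(c(1, -0.5, 0, 0), 2, 2)), list(c(0, 0)), c(2, 2))
  g <- normalize_heatmaps(list(h1, h2), "global")
  expect_equal(max(abs(g[[1]]$values)), 1)
  expect_equal(max(abs(g[[2]]$values)), 0.5)
  expect_equal(g[[2]]$global_max_abs, 2)
  l <- normalize_heatmaps(list(h1, h2), "local")
  expect_equal(max(abs(l[[1]]$values)), 1)
  expect_equal(max(abs(l[[2]]$values)), 1)
  # single heatmap: global and local coincide
  s1 <- normalize_heatmaps(h1, "global"); s2 <- normalize_heatmaps(h1, "local")
  expect_equal(s1$values, s2$values)
  # all-zero maps stay untouched but flagged
  hz <- stitch(list(matrix(0, 2, 2)), list(c(0, 0)), c(2, 2))
  gz <- normalize_heatmaps(list(hz), "global")
  expect_true(gz[[1]]$degenerate)
  expect_equal(gz[[1]]$values, matrix(0, 2, 2))
  expect_error(normalize_heatmaps(list(), "global"), "empty")
  expect_error(normalize_heatmaps(g, "global"), "already")
})

test_that("rectification clamps negatives and is idempotent", {
  hm <- stitch(list(matrix(c(-1, 0, 0.5, -2), 2, 2)), list(c(0, 0)), c(2, 2))
  r <- rectify(hm)
  expect_equal(sort(as.vector(r$values)), c(0, 0, 0, 0.5))
  expect_equal(rectify(r)$values, r$values)
  allneg <- rectify(stitch(list(matrix(-1, 2, 2)), list(c(0, 0)), c(2, 2)))
  expect_true(all(allneg$values == 0))
})

test_that("probability maps have grid resolution and probability range", {
  net <- random_small_net(5, zero_bias = FALSE)
  img <- array(runif(72 * 72 * 3), c(72, 72, 3))
  pm <- probability_map(net, img, 24)
  expect_equal(dim(pm), c(3, 3))
  expect_true(all(pm >= 0 & pm <= 1))
  # constant-output network (zero weights everywhere) gives a constant map
  net0 <- net
  for (i in seq_along(net0$layers)) {
    if (!is.null(net0$layers[[i]]$wmat)) net0$layers[[i]]$wmat[] <- 0
    if (!is.null(net0$layers[[i]]$weights)) net0$layers[[i]]$weights[] <- 0
    if (!is.null(net0$layers[[i]]$bias)) net0$layers[[i]]$bias[] <- 0
  }
  pm0 <- probability_map(net0, img, 24)
  expect_true(all(pm0 == 0.5))
  expect_error(probability_map(net, array(0, c(10, 10, 3)), 24), "smaller")
})

test_that("overlay rendering hits the colourbar endpoints", {
  img <- array(0.5, c(2, 2, 3))
  hm <- structure(list(values = matrix(c(1, -1, 0, 0), 2, 2),
                       normalisation = "global"), class = "tile_heatmap")
  out <- render_overlay(hm, img)
  expect_equal(dim(out), dim(img))
  expect_equal(out[1, 1, ], c(1, 0, 0))   # +1: pure red
  expect_equal(out[2, 1, ], c(0, 0, 1))   # -1: pure blue
  grey <- 0.5
  expect_equal(out[1, 2, ], rep(grey, 3), tolerance = 1e-9)  # 0: grey
  hz <- structure(list(values = matrix(0, 2, 2)), class = "tile_heatmap")
  expect_equal(render_overlay(hz, img)[, , 1], matrix(grey, 2, 2), tolerance = 1e-9)
  expect_error(render_overlay(hm, array(0.5, c(3, 3, 3))), "differ")
})

test_that("ROC ranks are invariant to positive rescaling of heatmaps", {
  set.seed(8)
  cells <- data.frame(x = runif(40, 5, 58), y = runif(40, 5, 58),
                      cell_type = sample(c("tumour", "normal"), 40, TRUE),
                      diameter_px = 8)
  raw <- structure(list(values = matrix(runif(64 * 64), 64, 64),
                        rectified = TRUE), class = "tile_heatmap")
  scaled <- raw; scaled$values <- raw$values / max(abs(raw$values))
  r1 <- roc_auc(score_cells(raw, cells, radius = 4))
  r2 <- roc_auc(score_cells(scaled, cells, radius = 4))
  expect_equal(r1$auc, r2$auc, tolerance = 1e-12)
  expect_equal(r1$fpr, r2$fpr)
  expect_equal(r1$tpr, r2$tpr)
})
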