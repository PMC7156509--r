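test_that("disc pixel counts match brute-force lattice enumeration", {
  for (r in 1:10) {
    got <- nrow(disc_offsets(r))
    want <- 0L
    for (dy in -r:r) for (dx in -r:r) if (dy^2 + dx^2 <= r^2) want <- want + 1L
    expect_equal(got, want)
  }
  expect_equal(nrow(disc_offsets(3)), 29)   # the radius-3 closed disc
})

test_that("cell scores are disc means with border clipping", {
  hm <- function(v) structure(list(values = v, rectified = TRUE),
                              class = "tile_heatmap")
  cells <- data.frame(x = c(10, 20), y = c(10, 20),
                      cell_type = c("tumour", "normal"), diameter_px = 6)
  z <- hm(matrix(0, 40, 40))
  expect_equal(score_cells(z, cells, radius = 3)$score, c(0, 0))
  cst <- hm(matrix(0.5, 40, 40))
  expect_equal(score_cells(cst, cells, radius = 3)$score, c(0.5, 0.5))
  # one bright pixel at the annotation, radius 3: mean over the 29-pixel disc
  v <- matrix(0, 40, 40); v[11, 11] <- 1   # cell at 0-based (10, 10)
  expect_equal(score_cells(hm(v), cells[1, ], radius = 3)$score, 1 / 29)
  # a corner cell keeps the clipped mean
  corner <- data.frame(x = 0, y = 0, cell_type = "tumour", diameter_px = 6)
  v2 <- matrix(1, 40, 40)
  expect_equal(score_cells(hm(v2), corner, radius = 3)$score, 1)
  out <- data.frame(x = 45, y = 10, cell_type = "tumour", diameter_px = 6)
  expect_error(score_cells(z, out, radius = 3), "outside")
  # default radius derives from the mean annotated diameter
  expect_equal(score_cells(cst, cells)$score, c(0.5, 0.5))
})

test_that("region scores are per-structure means, signed or rectified", {
  hm <- structure(list(values = matrix(c(1, -1, 0.3, 0.3), 2, 2)),
                  class = "tile_heatmap")
  m_all <- matrix(TRUE, 2, 2)
  m12 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(score_region(hm, m12, "signed"), 0)
  expect_equal(score_region(hm, m12, "rectified"), 0.5)
  expect_equal(score_region(hm, m_all, "signed"), 0.15)
  # disjoint regions score independently, never pooled
  m3 <- matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2)
  expect_equal(score_region(hm, m3, "signed"), 0.3)
  expect_error(score_region(hm, matrix(FALSE, 2, 2)), "empty")
  expect_error(score_region(hm, matrix(TRUE, 3, 3)), "differ")
})

test_that("ROC/AUC behaves at the extremes and rejects one-class input", {
  tab <- data.frame(cell_type = rep(c("tumour", "normal"), c(5, 7)),
                    score = rep(c(1, 0), c(5, 7)))
  r <- roc_auc(tab)
  expect_equal(r$auc, 1)
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(tail(r$fpr, 1), 1); expect_equal(tail(r$tpr, 1), 1)
  const <- data.frame(cell_type = rep(c("tumour", "normal"), c(5, 7)),
                      score = rep(0.4, 12))
  expect_equal(roc_auc(const)$auc, 0.5)
  expect_error(roc_auc(data.frame(cell_type = "tumour", score = 1)),
               "both classes")
})

test_that("trapezoidal AUC equals brute-force pair counting on 1000 sets", {
  set.seed(21)
  for (rep in 1:1000) {
    n <- sample(4:20, 1)
    labels <- c("tumour", "normal",
                sample(c("tumour", "normal"), n - 2, replace = TRUE))
    scores <- round(runif(n), sample(c(1, 2, 8), 1))  # force some ties
    got <- roc_auc(scores, labels)$auc
    pos <- scores[labels == "tumour"]; neg <- scores[labels == "normal"]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(got, mean(pairs), tolerance = 1e-12)
  }
})

test_that("AUC is monotone-curve valid and scale invariant on random input", {
  set.seed(5)
  for (rep in 1:50) {
    n <- sample(6:30, 1)
    labels <- c("tumour", "normal", sample(c("tumour", "normal"), n - 2, TRUE))
    scores <- runif(n)
    r <- roc_auc(scores, labels)
    expect_true(all(diff(r$fpr) >= 0))
    expect_true(all(diff(r$tpr) >= 0))
    expect_gte(r$auc, 0); expect_lte(r$auc, 1)
    r2 <- roc_auc(scores * 7.3, labels)
    expect_equal(r$auc, r2$auc)
    expect_equal(r$fpr, r2$fpr); expect_equal(r$tpr, r2$tpr)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  for (rep in 1:10) {
    n <- 50
    labels <- sample(c("tumour", "normal"), n, TRUE)
    if (length(unique(labels)) < 2) next
    scores <- runif(n)
    got <- roc_auc(scores, labels)$auc
    want <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores, levels = c("normal", "tumour"),
      direction = "<", quiet = TRUE)))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("constant baseline heatmaps give exactly chance AUC", {
  tiles <- list(small_tile(1), small_tile(2))
  z <- baseline_aucs(tiles, "zeros")
  o <- baseline_aucs(tiles, "ones")
  expect_equal(z$mean, 0.5); expect_equal(z$sd, 0)
  expect_equal(o$mean, 0.5); expect_equal(o$sd, 0)
})

test_that("random baseline AUCs concentrate at one half", {
  tiles <- lapply(1:2, function(s)
    generate_tile(generator_spec(tile_size = 256), seed = s,
                  n_tumour = 60, n_normal = 60, n_necrosis = 0))
  b <- baseline_aucs(tiles, "random", runs = 30, seed = 5)
  se <- b$sd / sqrt(length(b$aucs))
  expect_lt(abs(b$mean - 0.5), 3 * max(se, 1e-4))
  expect_lt(b$sd, 0.05)
  # reproducible in the seed
  b2 <- baseline_aucs(tiles, "random", runs = 30, seed = 5)
  expect_identical(b$aucs, b2$aucs)
})

test_that("patch metrics reproduce hand-computed F1 values", {
  perf <- patch_metrics(rep(c("cancer", "no_cancer"), c(5, 5)),
                        rep(c("cancer", "no_cancer"), c(5, 5)))
  expect_equal(perf$weighted_f1, 1)
  expect_equal(perf$accuracy, 1)
  # TP=8, FP=2, FN=2, TN=8 balanced: F1 = 0.8 for both classes
  truth <- rep(c("cancer", "no_cancer"), each = 10)
  pred <- c(rep("cancer", 8), rep("no_cancer", 2),
            rep("cancer", 2), rep("no_cancer", 8))
  perf2 <- patch_metrics(truth, pred)
  expect_equal(unname(perf2$f1), c(0.8, 0.8))
  expect_equal(perf2$weighted_f1, 0.8)
  # all-cancer prediction on a balanced set
  perf3 <- patch_metrics(truth, rep("cancer", 20))
  expect_equal(unname(perf3$f1["cancer"]), 2 / 3)
  expect_equal(unname(perf3$f1["no_cancer"]), 0)
  expect_equal(perf3$weighted_f1, 1 / 3)
  expect_error(patch_metrics(truth, rep("tumor", 20)), "labels")
  expect_error(patch_metrics(character(0), character(0)), "non-empty")
})

test_that("centre profiles report centred-square means of mean |R|", {
  cst <- lapply(1:3, function(i) matrix(0.4, 16, 16))
  prof <- center_profile(cst, c(4, 8, 16))
  expect_equal(prof$mean_abs_relevance, rep(0.4, 3))
  # a single hot centre pixel decays with the square side
  hot <- matrix(0, 16, 16); hot[8, 8] <- 16
  prof2 <- center_profile(list(hot), c(4, 8, 16))
  expect_true(all(diff(prof2$mean_abs_relevance) < 0))
  expect_equal(tail(prof2$mean_abs_relevance, 1), mean(abs(hot)))
  expect_error(center_profile(list(), c(4)), "empty")
  expect_error(center_profile(cst, 99), "exceed")
})

test_that("class-mean heatmaps average pixel-wise", {
  m <- matrix(runif(16), 4, 4)
  expect_equal(class_mean_heatmap(list(m, m, m)), m)
  expect_equal(class_mean_heatmap(list(m, -m)), matrix(0, 4, 4))
  expect_error(class_mean_heatmap(list(m, matrix(0, 2, 2))), "differ")
})

test_that("positive fraction covers the sign spectrum", {
  expect_equal(positive_fraction(matrix(2, 3, 3)), 1)
  expect_equal(positive_fraction(matrix(-1, 3, 3)), 0)
  expect_equal(positive_fraction(matrix(c(1, -1), 4, 4)), 0.5)
  pf0 <- positive_fraction(matrix(0, 2, 2))
  expect_equal(as.numeric(pf0), 0.5)
  expect_true(attr(pf0, "degenerate"))
})

test_that("corner block statistics find the argmax block", {
  v <- matrix(0, 20, 20)
  v[1:5, 1:5] <- 1
  st <- corner_block_stats(v, 5)
  expect_true(st$corner_is_argmax)
  expect_equal(st$corner_mean, 1)
  v2 <- matrix(0, 20, 20); v2[10:14, 10:14] <- 1
  expect_false(corner_block_stats(v2, 5)$corner_is_argmax)
})
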