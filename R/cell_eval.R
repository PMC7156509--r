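# Cell-level quantitative evaluation of heatmaps: circular scoring around
# point annotations, ROC/AUC with constant and random baselines, patch-level
# metrics, centre-mass profiles and class-mean heatmaps.

#' Integer-lattice offsets of a closed disc
#'
#' All `(dy, dx)` integer offsets with `dy^2 + dx^2 <= radius^2` (pixel
#' centres, Euclidean distance, closed disc).
#'
#' @param radius disc radius in px.
#' @return Two-column integer matrix of offsets.
#' @export
disc_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  as.matrix(g[g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE])
}

#' Score annotated cells on a rectified heatmap
#'
#' Each cell receives the mean rectified relevance over the closed disc of
#' `radius` around its point annotation (pixels whose centre lies within the
#' Euclidean radius of the annotation point). Discs clipped by the tile
#' border keep the mean over their remaining pixels; pixels never covered by
#' a patch map are excluded.
#'
#' @param heatmap a rectified `"tile_heatmap"`.
#' @param cells data.frame with 0-based `x`, `y` and `cell_type`.
#' @param radius acceptance radius in px; the default, half the mean
#'   annotated cell diameter, mirrors using half an average cancer-cell
#'   diameter at the data's resolution.
#' @return data.frame `cell_id`, `cell_type`, `score`.
#' @export
score_cells <- function(heatmap, cells, radius = NULL) {
  v <- heatmap$values
  if (min(v) < 0 && !isTRUE(heatmap$rectified))
    stopf("score_cells expects a rectified heatmap")
  h <- nrow(v); w <- ncol(v)
  if (is.null(radius)) {
    if (is.null(cells$diameter_px)) stopf("radius not given and no diameters available")
    radius <- mean(cells$diameter_px) / 2
  }
  if (radius <= 0) stopf("radius must be positive")
  cover <- heatmap$coverage %||% matrix(TRUE, h, w)
  off <- disc_offsets(radius)
  scores <- numeric(nrow(cells))
  for (k in seq_len(nrow(cells))) {
    cy <- cells$y[k]; cx <- cells$x[k]
    if (cy < 0 || cy >= h || cx < 0 || cx >= w)
      stopf("cell %d lies outside the tile", k)
    # pixels with centre within `radius` of the (possibly fractional) point
    rows <- round(cy) + off[, "dy"]; cols <- round(cx) + off[, "dx"]
    keep <- (rows - cy)^2 + (cols - cx)^2 <= radius^2 &
      rows >= 0 & rows < h & cols >= 0 & cols < w
    rows <- rows[keep] + 1L; cols <- cols[keep] + 1L
    ind <- cbind(rows, cols)
    ind <- ind[cover[ind], , drop = FALSE]
    if (!nrow(ind)) stopf("acceptance disc of cell %d covers no scored pixel", k)
    scores[k] <- mean(v[ind])
  }
  data.frame(cell_id = seq_len(nrow(cells)), cell_type = cells$cell_type,
             score = scores, stringsAsFactors = FALSE)
}

#' Mean relevance over one annotated region
#'
#' Regions are treated as single structures: each mask is scored
#' independently, never pooled with other regions.
#'
#' @param heatmap a `"tile_heatmap"`.
#' @param mask logical matrix matching the heatmap shape.
#' @param mode `"signed"` keeps the sign of relevance (used for the
#'   necrosis analysis); `"rectified"` clamps negatives to zero first.
#' @return The mean (signed or rectified) relevance over the mask.
#' @export
score_region <- function(heatmap, mask, mode = c("signed", "rectified")) {
  mode <- match.arg(mode)
  if (!any(mask)) stopf("empty region mask")
  if (!all(dim(mask) == dim(heatmap$values))) stopf("mask and heatmap shapes differ")
  v <- heatmap$values[mask]
  if (mode == "rectified") v <- pmax(v, 0)
  mean(v)
}

#' ROC curve and AUC over cell scores
#'
#' Standard ROC over score thresholds with tied scores grouped, AUC by the
#' trapezoidal rule. Constant score vectors yield the chance diagonal and an
#' AUC of exactly 0.5.
#'
#' @param scores data.frame from [score_cells()] (or a numeric vector).
#' @param labels cell types, required when `scores` is a plain vector.
#' @param positive_type the positive class (default `"tumour"`).
#' @return An object of class `"roc_result"`: `thresholds` (decreasing),
#'   `fpr`, `tpr` (non-decreasing from (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels = NULL, positive_type = "tumour") {
  if (is.data.frame(scores)) {
    labels <- scores$cell_type
    scores <- scores$score
  }
  pos <- labels == positive_type
  if (!any(pos) || all(pos)) stopf("both classes must be present for a ROC curve")
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  tp <- vapply(thr, function(t) sum(scores >= t & pos), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & !pos), numeric(1))
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, thr), fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f over %d thresholds\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}

#' Write a ROC curve as CSV with a JSON summary sidecar
#'
#' @param roc a `"roc_result"`.
#' @param path output CSV (`threshold`, `fpr`, `tpr`); the AUC and point
#'   count are written next to it as `<path>.json`.
#' @export
write_roc_csv <- function(roc, path) {
  utils::write.csv(data.frame(threshold = roc$thresholds, fpr = roc$fpr,
                              tpr = roc$tpr),
                   path, row.names = FALSE)
  jsonlite::write_json(list(auc = roc$auc, n_points = length(roc$fpr)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Baseline AUCs from constant or random heatmaps
#'
#' Scores every annotated cell of every tile against degenerate heatmaps:
#' `zeros` and `ones` give constant scores, hence the chance diagonal and an
#' AUC of exactly 0.5; `random` fills each tile heatmap with i.i.d. uniform
#' [0, 1] values and aggregates the AUC over repeated draws.
#'
#' @param tiles list of `"tissue_tile"` carrying cell annotations.
#' @param mode `"zeros"`, `"ones"` or `"random"`.
#' @param runs number of random draws (ignored for the constant modes).
#' @param radius acceptance radius passed to [score_cells()].
#' @param seed integer seed for the random mode.
#' @return list with `mean`, `sd` and the individual `aucs`.
#' @export
baseline_aucs <- function(tiles, mode = c("zeros", "ones", "random"),
                          runs = 100L, radius = NULL, seed = 0L) {
  mode <- match.arg(mode)
  if (runs < 1) stopf("runs must be >= 1")
  shapes <- lapply(tiles, function(t) dim(t$image)[1:2])
  score_with <- function(make_values) {
    tabs <- lapply(seq_along(tiles), function(i) {
      hm <- structure(list(values = make_values(shapes[[i]]),
                           normalisation = "global", rectified = TRUE),
                      class = "tile_heatmap")
      score_cells(hm, tiles[[i]]$cells, radius)
    })
    do.call(rbind, tabs)
  }
  if (mode %in% c("zeros", "ones")) {
    const <- if (mode == "zeros") 0 else 1
    tab <- score_with(function(sh) matrix(const, sh[1], sh[2]))
    auc <- roc_auc(tab)$auc
    return(list(mean = auc, sd = 0, aucs = auc))
  }
  aucs <- with_local_seed(seed, {
    vapply(seq_len(runs), function(r) {
      tab <- score_with(function(sh) matrix(stats::runif(sh[1] * sh[2]), sh[1], sh[2]))
      roc_auc(tab)$auc
    }, numeric(1))
  })
  list(mean = mean(aucs), sd = stats::sd(aucs), aucs = aucs)
}

#' Patch-level confusion matrix and F1 scores
#'
#' @param truth,predicted character vectors over `"cancer"`/`"no_cancer"`.
#' @return list with `confusion` (rows = truth), per-class `precision`,
#'   `recall`, `f1`, and `weighted_f1` (per-class F1 weighted by support).
#' @export
patch_metrics <- function(truth, predicted) {
  classes <- c("no_cancer", "cancer")
  if (!length(truth) || length(truth) != length(predicted))
    stopf("truth and predicted must be non-empty and of equal length")
  if (!all(c(truth, predicted) %in% classes))
    stopf("labels must be one of: %s", paste(classes, collapse = ", "))
  conf <- table(factor(truth, classes), factor(predicted, classes))
  precision <- recall <- f1 <- stats::setNames(numeric(2), classes)
  for (cl in classes) {
    tp <- conf[cl, cl]
    precision[cl] <- if (sum(conf[, cl]) > 0) tp / sum(conf[, cl]) else 0
    recall[cl] <- if (sum(conf[cl, ]) > 0) tp / sum(conf[cl, ]) else 0
    f1[cl] <- if (precision[cl] + recall[cl] > 0)
      2 * precision[cl] * recall[cl] / (precision[cl] + recall[cl]) else 0
  }
  support <- rowSums(conf)
  list(confusion = conf, precision = precision, recall = recall, f1 = f1,
       accuracy = sum(diag(conf)) / length(truth),
       weighted_f1 = sum(support / sum(support) * f1))
}

#' Centre-mass profile of absolute relevance
#'
#' First averages absolute relevance pixel-wise over all patch heatmaps, then
#' reports the mean of that average inside centred squares of increasing side
#' length. A profile that falls off with side length indicates relevance
#' concentrated at the patch centre; the entry at the full patch side equals
#' the global mean absolute relevance.
#'
#' @param patch_maps list of `"relevance_map"` (or matrices), equal shapes.
#' @param sides integer vector of square side lengths (<= patch side).
#' @return data.frame `side`, `mean_abs_relevance` (class `"center_profile"`).
#' @export
center_profile <- function(patch_maps, sides = NULL) {
  if (!length(patch_maps)) stopf("empty patch list")
  mats <- lapply(patch_maps, function(m) abs(if (is.list(m)) m$values else m))
  s <- nrow(mats[[1]])
  if (is.null(sides)) sides <- unique(pmin(s, round(s * c(0.25, 0.5, 0.75, 1))))
  if (any(sides > s)) stopf("side lengths must not exceed the patch size")
  avg <- Reduce(`+`, mats) / length(mats)
  prof <- vapply(sides, function(side) {
    r0 <- floor((s - side) / 2) + 1L
    mean(avg[r0:(r0 + side - 1L), r0:(r0 + side - 1L)])
  }, numeric(1))
  structure(data.frame(side = sides, mean_abs_relevance = prof),
            class = c("center_profile", "data.frame"))
}

#' Pixel-wise mean heatmap of one class
#'
#' @param maps list of `"relevance_map"`/matrices of equal shape.
#' @return Matrix of pixel-wise means.
#' @export
class_mean_heatmap <- function(maps) {
  if (!length(maps)) stopf("empty heatmap list")
  mats <- lapply(maps, function(m) if (is.list(m)) m$values else m)
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) all(dim(m) == d), logical(1))))
    stopf("heatmap shapes differ")
  Reduce(`+`, mats) / length(mats)
}

#' Fraction of positive relevance mass
#'
#' `sum(max(R, 0)) / sum(|R|)`; 1 for an all-positive map, 0 for all-negative,
#' 0.5 for a sign-symmetric map. Defined as 0.5 (flagged) for an all-zero map.
#'
#' @param heatmap a signed `"tile_heatmap"`/`"relevance_map"` or matrix.
#' @return A number in [0, 1]; attribute `degenerate` is TRUE for a zero map.
#' @export
positive_fraction <- function(heatmap) {
  v <- if (is.list(heatmap)) heatmap$values else heatmap
  tot <- sum(abs(v))
  if (tot == 0) return(structure(0.5, degenerate = TRUE))
  sum(pmax(v, 0)) / tot
}

#' Mean relevance of every square block and the corner argmax
#'
#' Computes the mean relevance of each `side` x `side` block of a patch map
#' (all positions, via summed-area table) and locates the maximum — the
#' signature of a corner-marker shortcut. Because convolutional features
#' respond most strongly to the marker's boundary, the peak block typically
#' straddles the marker's edge rather than coinciding with it exactly;
#' `argmax_overlaps_corner` therefore reports whether the argmax block
#' intersects the corner block (its start lies within `side` px of the
#' corner), while `corner_is_argmax` keeps the strict identity check.
#'
#' @param map a `"relevance_map"` or matrix.
#' @param side block side in px.
#' @return list with `corner_mean`, `max_mean`, `argmax_start` (1-based row,
#'   col), `corner_is_argmax`, `argmax_overlaps_corner` and `overall_mean`.
#' @export
corner_block_stats <- function(map, side = 5L) {
  v <- if (is.list(map)) map$values else map
  h <- nrow(v); w <- ncol(v)
  # summed-area table with a zero border
  sat <- matrix(0, h + 1, w + 1)
  sat[-1, -1] <- apply(apply(v, 2, cumsum), 1, cumsum) |> t()
  rs <- 1:(h - side + 1); cs <- 1:(w - side + 1)
  block_sums <- sat[rs + side, cs + side] - sat[rs, cs + side] -
    sat[rs + side, cs] + sat[rs, cs]
  block_means <- block_sums / side^2
  am <- which(block_means == max(block_means), arr.ind = TRUE)[1, ]
  list(corner_mean = block_means[1, 1],
       max_mean = max(block_means),
       argmax_start = unname(am),
       corner_is_argmax = block_means[1, 1] >= max(block_means) - 1e-12,
       argmax_overlaps_corner = all(am <= side),
       overall_mean = mean(v))
}
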