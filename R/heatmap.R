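# Tile-level heatmap assembly, normalisation and rendering.
#
# Analysis uses non-overlapping tiling with normalisation by the global
# maximum over all heatmaps of a comparison set (this preserves peaks and the
# relative evidence between tiles); locally normalised, one-tenth-overlapping
# stitching is reserved for visualisation.

#' Stitch patch relevance maps into a tile heatmap
#'
#' Pixels covered by several overlapping maps hold the mean of their
#' contributions; uncovered pixels are zero and flagged in the coverage mask
#' (and are excluded from downstream cell scoring).
#'
#' @param patch_maps list of `"relevance_map"` (or plain matrices).
#' @param offsets list or 2-column matrix of 0-based `(row, col)` offsets.
#' @param tile_shape `c(H, W)` of the target tile.
#' @return An object of class `"tile_heatmap"`: `values` (signed H x W),
#'   `coverage` (logical H x W), `offsets`, `normalisation = "raw"`.
#' @export
stitch <- function(patch_maps, offsets, tile_shape) {
  if (!length(patch_maps)) stopf("no patch maps to stitch")
  if (is.matrix(offsets)) offsets <- lapply(seq_len(nrow(offsets)), function(i) offsets[i, ])
  if (length(offsets) != length(patch_maps))
    stopf("need one offset per patch map")
  h <- tile_shape[1]; w <- tile_shape[2]
  acc <- matrix(0, h, w)
  cnt <- matrix(0L, h, w)
  for (i in seq_along(patch_maps)) {
    m <- patch_maps[[i]]
    v <- if (inherits(m, "relevance_map")) m$values else m
    s <- dim(v)
    off <- offsets[[i]]
    if (off[1] < 0 || off[2] < 0 || off[1] + s[1] > h || off[2] + s[2] > w)
      stopf("patch map %d does not fit inside the tile", i)
    rows <- (off[1] + 1):(off[1] + s[1])
    cols <- (off[2] + 1):(off[2] + s[2])
    acc[rows, cols] <- acc[rows, cols] + v
    cnt[rows, cols] <- cnt[rows, cols] + 1L
  }
  covered <- cnt > 0L
  acc[covered] <- acc[covered] / cnt[covered]
  structure(list(values = acc, coverage = covered, offsets = offsets,
                 normalisation = "raw", global_max_abs = NULL),
            class = "tile_heatmap")
}

#' Normalise a set of tile heatmaps to [-1, 1]
#'
#' `global` divides every heatmap by the single maximum absolute value over
#' the whole set, preserving relative evidence between tiles; `local` divides
#' each heatmap by its own maximum. All-zero heatmaps are left unchanged and
#' flagged `degenerate`. Heatmaps can only be normalised once.
#'
#' @param heatmaps list of `"tile_heatmap"` (a single heatmap is accepted).
#' @param mode `"global"` or `"local"`.
#' @return List of normalised heatmaps (or a single one if a single one was
#'   passed).
#' @export
normalize_heatmaps <- function(heatmaps, mode = c("global", "local")) {
  mode <- match.arg(mode)
  single <- inherits(heatmaps, "tile_heatmap")
  if (single) heatmaps <- list(heatmaps)
  if (!length(heatmaps)) stopf("empty heatmap list")
  states <- vapply(heatmaps, `[[`, character(1), "normalisation")
  if (any(states != "raw"))
    stopf("heatmaps are already normalised (state %s)",
          paste(unique(states[states != "raw"]), collapse = ", "))
  gmax <- max(vapply(heatmaps, function(h) max(abs(h$values)), numeric(1)))
  out <- lapply(heatmaps, function(h) {
    m <- if (mode == "global") gmax else max(abs(h$values))
    if (m == 0) {
      h$degenerate <- TRUE
    } else {
      h$values <- h$values / m
    }
    h$normalisation <- mode
    h$global_max_abs <- if (mode == "global") gmax else NULL
    h
  })
  if (single) out[[1]] else out
}

#' Clamp negative relevance to zero
#'
#' Cell-level ROC evaluation considers only positive (class-supporting)
#' relevance; rectification is idempotent.
#'
#' @param heatmap a `"tile_heatmap"` or `"relevance_map"`.
#' @return The heatmap with `values = pmax(values, 0)` and `rectified = TRUE`.
#' @export
rectify <- function(heatmap) {
  heatmap$values <- pmax(heatmap$values, 0)
  heatmap$rectified <- TRUE
  heatmap
}

#' Coarse probability map of a tile
#'
#' Splits the tile into a non-overlapping grid of `patch_size` patches
#' (remainder cropped) and fills cell (i, j) with the cancer-class
#' probability of patch (i, j) — the lowest-resolution explanation baseline.
#'
#' @param network a trained `"layered_network"`.
#' @param tile a `"tissue_tile"` (or H x W x 3 array).
#' @param patch_size grid patch side in px.
#' @return Numeric matrix of cancer probabilities, one value per grid patch.
#' @export
probability_map <- function(network, tile, patch_size = NULL) {
  img <- if (inherits(tile, "tissue_tile")) tile$image else tile
  patch_size <- as.integer(patch_size %||% tile$spec$patch_size)
  h <- dim(img)[1]; w <- dim(img)[2]
  if (h < patch_size || w < patch_size) stopf("tile smaller than one patch")
  nr <- h %/% patch_size; nc <- w %/% patch_size
  patches <- list()
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    patches[[length(patches) + 1L]] <-
      img[((i - 1) * patch_size + 1):(i * patch_size),
          ((j - 1) * patch_size + 1):(j * patch_size), , drop = FALSE]
  }
  probs <- predict_proba(network, patches)[, "cancer"]
  matrix(probs, nr, nc)
}

#' Render a heatmap overlay on the grey-scaled tile
#'
#' Blends a symmetric diverging colour map centred at zero (red = positive,
#' supports the explained class; blue = negative, contradicts it) over the
#' grey-scale luminance of the stain.
#'
#' @param heatmap a normalised `"tile_heatmap"` (values in [-1, 1]).
#' @param image the tile's H x W x 3 RGB array.
#' @return An H x W x 3 RGB array in [0, 1].
#' @export
render_overlay <- function(heatmap, image) {
  v <- heatmap$values
  if (!all(dim(v) == dim(image)[1:2])) stopf("heatmap and image shapes differ")
  grey <- luminance(image)
  a <- abs(v)
  pos <- pmax(v, 0); neg <- pmax(-v, 0)
  out <- array(0, dim(image))
  out[, , 1] <- grey * (1 - a) + pos        # toward pure red at +1
  out[, , 2] <- grey * (1 - a)
  out[, , 3] <- grey * (1 - a) + neg        # toward pure blue at -1
  clamp01(out)
}

#' Compute, stitch and normalise heatmaps for a set of tiles
#'
#' Convenience wrapper for the analysis path: non-overlapping grid, raw
#' stitching, then one global normalisation over all tiles.
#'
#' @param network trained `"layered_network"`.
#' @param tiles list of `"tissue_tile"`.
#' @param patch_size patch side (default: tile spec).
#' @param target_class class to explain.
#' @param params [rule_params()].
#' @param normalise `"global"`, `"local"` or `"none"`.
#' @return List of `"tile_heatmap"`, one per tile.
#' @export
tile_heatmaps <- function(network, tiles, patch_size = NULL,
                          target_class = "cancer", params = rule_params(),
                          normalise = "global") {
  hms <- lapply(tiles, function(tile) {
    ps <- as.integer(patch_size %||% tile$spec$patch_size)
    img <- tile$image
    h <- dim(img)[1]; w <- dim(img)[2]
    offs <- expand.grid(row = seq(0L, h - ps, by = ps),
                        col = seq(0L, w - ps, by = ps))
    maps <- lapply(seq_len(nrow(offs)), function(k) {
      patch <- img[(offs$row[k] + 1):(offs$row[k] + ps),
                   (offs$col[k] + 1):(offs$col[k] + ps), , drop = FALSE]
      explain(network, patch, target_class, params)
    })
    stitch(maps, lapply(seq_len(nrow(offs)), function(k) c(offs$row[k], offs$col[k])),
           c(h, w))
  })
  if (normalise != "none") hms <- normalize_heatmaps(hms, normalise)
  names(hms) <- vapply(tiles, function(t) t$id %||% "", character(1))
  hms
}
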