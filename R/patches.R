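# Patch extraction, labelling rules and controlled corruptions.
#
# Patch footprints are half-open pixel intervals [r, r + S) x [c, c + S) in
# 0-based (row, col) coordinates; "top-left corner" means rows 0..4 x cols
# 0..4 of the patch.

#' Extract labelled patches from a tile
#'
#' Slides a regular grid over the tile and labels each patch either by the
#' plurality cell type inside its footprint (`majority`) or by the cell type
#' nearest to the patch centre (`centre_cell`). The centre-cell rule mirrors
#' datasets whose patch label is defined by the central cell only; patches
#' whose centre neighbourhood (one mean cell radius) contains no cell are
#' discarded rather than given a default label.
#'
#' @param tile a `"tissue_tile"`.
#' @param size patch side length in px (default: the tile spec's patch size).
#' @param stride grid stride in px (default `size`, i.e. non-overlapping).
#' @param rule `"majority"` or `"centre_cell"`.
#' @return A list of `"labelled_patch"` objects: `image` (S x S x 3), `label`
#'   (`"cancer"` or `"no_cancer"`), `source` (tile id and 0-based row/col
#'   offset), `bias_flags` (character vector of applied corruptions).
#' @export
extract_patches <- function(tile, size = NULL, stride = NULL,
                            rule = c("majority", "centre_cell")) {
  rule <- match.arg(rule)
  size <- as.integer(size %||% tile$spec$patch_size)
  stride <- as.integer(stride %||% size)
  h <- dim(tile$image)[1]; w <- dim(tile$image)[2]
  if (size > h || size > w) stopf("patch size %d exceeds tile dimensions", size)
  if (stride < 1) stopf("stride must be >= 1")
  offs_r <- seq(0L, h - size, by = stride)
  offs_c <- seq(0L, w - size, by = stride)
  mean_radius <- if (nrow(tile$cells)) mean(tile$cells$diameter_px) / 2 else size / 8

  patches <- list()
  for (r in offs_r) for (c in offs_c) {
    inside <- tile$cells$y >= r & tile$cells$y < r + size &
      tile$cells$x >= c & tile$cells$x < c + size
    if (rule == "majority") {
      n_t <- sum(inside & tile$cells$cell_type == "tumour")
      n_n <- sum(inside & tile$cells$cell_type == "normal")
      label <- if (n_t > n_n) "cancer" else "no_cancer"
    } else {
      ctr_y <- r + (size - 1) / 2
      ctr_x <- c + (size - 1) / 2
      d2 <- (tile$cells$y - ctr_y)^2 + (tile$cells$x - ctr_x)^2
      ok <- d2 <= mean_radius^2
      if (!any(ok)) next  # no qualifying centre cell: discard
      label <- if (tile$cells$cell_type[which.min(replace(d2, !ok, Inf))] == "tumour")
        "cancer" else "no_cancer"
    }
    patches[[length(patches) + 1L]] <- structure(list(
      image = tile$image[(r + 1):(r + size), (c + 1):(c + size), , drop = FALSE],
      label = label,
      source = list(tile_id = tile$id, row = r, col = c),
      bias_flags = character(0)
    ), class = "labelled_patch")
  }
  patches
}

#' Stamp a single-colour square marker into a patch corner
#'
#' Replaces the `side` x `side` top-left block of the patch by one colour and
#' records the corruption in `bias_flags`. Used to emulate an artefact that is
#' perfectly correlated with one class label.
#'
#' @param patch a `"labelled_patch"`.
#' @param side marker side length in px.
#' @param colour RGB triplet in [0, 1]; defaults to a saturated
#'   erythrocyte-like red-pink within the H&E colour scheme.
#' @return The corrupted patch.
#' @export
inject_corner_marker <- function(patch, side = 5L,
                                 colour = c(0.80, 0.25, 0.35)) {
  s <- dim(patch$image)[1]
  if (side > s) stopf("marker side %d exceeds patch size %d", side, s)
  for (ch in 1:3) patch$image[1:side, 1:side, ch] <- colour[ch]
  patch$bias_flags <- union(patch$bias_flags, "corner_marker")
  patch
}

#' Remove patches overlapping regions of a given type
#'
#' Drops every patch whose footprint overlaps the union of the tile's masks of
#' `region_type` by more than `max_overlap` (a fraction of the patch area; the
#' default 0 removes any patch touching such a region by at least one pixel).
#'
#' @param patches list of `"labelled_patch"`.
#' @param tiles named list of `"tissue_tile"` keyed by tile id, or a single
#'   tile.
#' @param region_type `"necrosis"` or `"artefact"`.
#' @param max_overlap maximal tolerated overlap fraction.
#' @return The filtered patch list.
#' @export
exclude_region_patches <- function(patches, tiles, region_type = "necrosis",
                                   max_overlap = 0) {
  if (!region_type %in% c("necrosis", "artefact"))
    stopf("unknown region type '%s'", region_type)
  if (inherits(tiles, "tissue_tile")) tiles <- stats::setNames(list(tiles), tiles$id)
  keep <- vapply(patches, function(p) {
    tile <- tiles[[p$source$tile_id]]
    if (is.null(tile)) stopf("tile '%s' not resolvable", p$source$tile_id)
    masks <- Filter(function(rg) rg$region_type == region_type, tile$regions)
    if (!length(masks)) return(TRUE)
    s <- dim(p$image)[1]
    rows <- (p$source$row + 1):(p$source$row + s)
    cols <- (p$source$col + 1):(p$source$col + s)
    frac <- 0
    for (rg in masks) frac <- frac + mean(rg$mask[rows, cols])
    frac <- min(frac, 1)
    frac <= max_overlap
  }, logical(1))
  patches[keep]
}

#' Patch overlap fraction with a region type
#'
#' @keywords internal
patch_region_overlap <- function(patch, tile, region_type = "necrosis") {
  masks <- Filter(function(rg) rg$region_type == region_type, tile$regions)
  if (!length(masks)) return(0)
  s <- dim(patch$image)[1]
  rows <- (patch$source$row + 1):(patch$source$row + s)
  cols <- (patch$source$col + 1):(patch$source$col + s)
  min(1, sum(vapply(masks, function(rg) mean(rg$mask[rows, cols]), numeric(1))))
}

#' Randomly translate and rotate a patch
#'
#' Translation is realised as crop jitter: the patch is re-cut from its source
#' tile at an offset displaced by up to `jitter_frac` of the patch side in
#' each direction (clamped to the tile). Rotation is restricted to multiples
#' of 90 degrees, which avoids interpolation artefacts. The label is kept.
#' Draws from the current RNG stream; seed the stream for reproducibility.
#'
#' @param patch a `"labelled_patch"`.
#' @param tile the source `"tissue_tile"`, required when `jitter_frac > 0`.
#' @param jitter_frac maximal translation as a fraction of the patch side.
#' @param rotations set of admissible rotations in degrees.
#' @return The augmented patch.
#' @export
augment_patch <- function(patch, tile = NULL, jitter_frac = 0.25,
                          rotations = c(0, 90, 180, 270)) {
  s <- dim(patch$image)[1]
  jit <- round(jitter_frac * s)
  if (jit > 0) {
    if (is.null(tile)) stopf("translation jitter requires the source tile")
    h <- dim(tile$image)[1]; w <- dim(tile$image)[2]
    dr <- sample(-jit:jit, 1); dc <- sample(-jit:jit, 1)
    r <- min(max(patch$source$row + dr, 0L), h - s)
    c <- min(max(patch$source$col + dc, 0L), w - s)
    patch$image <- tile$image[(r + 1):(r + s), (c + 1):(c + s), , drop = FALSE]
  }
  rot <- if (length(rotations) > 1) sample(rotations, 1) else rotations
  if (rot != 0) patch$image <- rot90(patch$image, rot)
  patch
}
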