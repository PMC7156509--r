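# Synthetic H&E-like tissue generator.
#
# Tiles are RGB rasters in [0, 1] (H x W x 3, row = y, col = x, 0-based
# annotation coordinates, origin top-left) carrying two nucleus populations
# that differ in size, colour and texture (tumour nuclei are larger and
# darker), amorphous pale necrosis-like regions tied to neither class, and an
# eosin-pink background with per-tile stain jitter.

#' Specification of the synthetic tissue generator
#'
#' Bundles every tunable of the synthetic H&E-like tile generator: geometry,
#' per-class nucleus counts and appearance, necrosis-like region frequency and
#' size, the dataset-level tumour fraction used when varying the per-tile cell
#' mix, and the single colour used for the corner-marker corruption.
#'
#' Colours are RGB triplets in [0, 1]. The two nucleus classes must remain
#' separable in at least one statistic (size or mean intensity); the defaults
#' make tumour nuclei both larger and darker, mimicking the hyperchromatic,
#' enlarged nuclei of malignant cells under haematoxylin staining.
#'
#' @param tile_size height/width of square tiles in px.
#' @param patch_size height/width of square patches in px.
#' @param n_tumour,n_normal nucleus count per class drawn on one tile.
#' @param tumour_diameter_mean,tumour_diameter_sd tumour nucleus diameter (px).
#' @param normal_diameter_mean,normal_diameter_sd normal nucleus diameter (px).
#' @param tumour_colour,normal_colour mean nucleus RGB per class.
#' @param nucleus_colour_sd per-nucleus colour jitter (sd, applied per channel).
#' @param tumour_texture_sd,normal_texture_sd per-pixel intra-nucleus noise sd.
#' @param background_colour eosin-like background RGB.
#' @param background_texture_sd per-pixel background noise sd.
#' @param stain_jitter_sd per-tile stain jitter sd added to all palette anchors.
#' @param necrosis_count_range integer range (min, max) of necrosis-like
#'   regions per tile, sampled uniformly.
#' @param necrosis_radius_range radius range (px) of necrosis-like blobs.
#' @param necrosis_colour pale, desaturated RGB of the necrotic ground mass.
#' @param necrosis_texture_sd per-pixel noise inside necrosis.
#' @param necrosis_debris_density karyorrhectic debris fragments per necrosis
#'   pixel: necrotic tissue carries small dark basophilic remnants of
#'   fragmented nuclei, which is exactly what can mislead a nucleus-sensitive
#'   classifier that never saw necrosis during training.
#' @param necrosis_debris_radius_range radius range (px) of debris fragments.
#' @param necrosis_debris_colour dark purple-brown RGB of debris fragments;
#'   debris carries no cell annotation.
#' @param tumour_cell_fraction dataset-level expected fraction of tumour cells;
#'   used by dataset builders that vary the per-tile mix around it.
#' @param marker_colour RGB used by [inject_corner_marker()]; a saturated
#'   erythrocyte-like red-pink within the H&E colour scheme, distinct from
#'   the narrow background/nucleus palette (a colour identical to the
#'   background would carry no signal at all in these synthetic images).
#' @param min_separation_factor minimal centre distance between two nuclei as
#'   a multiple of their mean radius.
#' @return An object of class `"generator_spec"` (a named list).
#' @export
#' @examples
#' spec <- generator_spec(tile_size = 128, n_tumour = 5, n_normal = 10)
#' tile <- generate_tile(spec, seed = 1)
generator_spec <- function(tile_size = 512,
                           patch_size = 64,
                           n_tumour = 108,
                           n_normal = 192,
                           tumour_diameter_mean = 13,
                           tumour_diameter_sd = 1.5,
                           normal_diameter_mean = 9,
                           normal_diameter_sd = 1.0,
                           tumour_colour = c(0.26, 0.12, 0.38),
                           normal_colour = c(0.58, 0.40, 0.68),
                           nucleus_colour_sd = 0.035,
                           tumour_texture_sd = 0.055,
                           normal_texture_sd = 0.03,
                           background_colour = c(0.91, 0.76, 0.84),
                           background_texture_sd = 0.02,
                           stain_jitter_sd = 0.02,
                           necrosis_count_range = c(1L, 3L),
                           necrosis_radius_range = c(25, 60),
                           necrosis_colour = c(0.62, 0.55, 0.50),
                           necrosis_texture_sd = 0.02,
                           necrosis_debris_density = 0.008,
                           necrosis_debris_radius_range = c(1.5, 3),
                           necrosis_debris_colour = c(0.28, 0.15, 0.36),
                           tumour_cell_fraction = 0.36,
                           marker_colour = c(0.80, 0.25, 0.35),
                           min_separation_factor = 1.6) {
  spec <- list(
    tile_size = as.integer(tile_size), patch_size = as.integer(patch_size),
    n_tumour = as.integer(n_tumour), n_normal = as.integer(n_normal),
    tumour_diameter_mean = tumour_diameter_mean,
    tumour_diameter_sd = tumour_diameter_sd,
    normal_diameter_mean = normal_diameter_mean,
    normal_diameter_sd = normal_diameter_sd,
    tumour_colour = tumour_colour, normal_colour = normal_colour,
    nucleus_colour_sd = nucleus_colour_sd,
    tumour_texture_sd = tumour_texture_sd,
    normal_texture_sd = normal_texture_sd,
    background_colour = background_colour,
    background_texture_sd = background_texture_sd,
    stain_jitter_sd = stain_jitter_sd,
    necrosis_count_range = as.integer(necrosis_count_range),
    necrosis_radius_range = necrosis_radius_range,
    necrosis_colour = necrosis_colour,
    necrosis_texture_sd = necrosis_texture_sd,
    necrosis_debris_density = necrosis_debris_density,
    necrosis_debris_radius_range = necrosis_debris_radius_range,
    necrosis_debris_colour = necrosis_debris_colour,
    tumour_cell_fraction = tumour_cell_fraction,
    marker_colour = marker_colour,
    min_separation_factor = min_separation_factor
  )
  class(spec) <- "generator_spec"
  validate_generator_spec(spec)
  spec
}

validate_generator_spec <- function(spec) {
  if (spec$tile_size < spec$patch_size)
    stopf("tile_size (%d) must be >= patch_size (%d)", spec$tile_size, spec$patch_size)
  if (spec$n_tumour < 0 || spec$n_normal < 0)
    stopf("cell counts must be non-negative")
  size_sep <- abs(spec$tumour_diameter_mean - spec$normal_diameter_mean) >
    (spec$tumour_diameter_sd + spec$normal_diameter_sd)
  col_sep <- abs(mean(spec$tumour_colour) - mean(spec$normal_colour)) >
    2 * spec$nucleus_colour_sd
  if (!size_sep && !col_sep)
    stopf("tumour and normal nuclei must be separable in size or mean intensity")
  invisible(spec)
}

# Boolean mask of one amorphous blob: union of discs along a random walk.
draw_blob_mask <- function(h, w, cy, cx, radius) {
  mask <- matrix(FALSE, h, w)
  n_steps <- 7L
  y <- cy; x <- cx
  for (s in seq_len(n_steps)) {
    r <- radius * stats::runif(1, 0.45, 0.8)
    rows <- max(1, floor(y - r)):min(h, ceiling(y + r))
    cols <- max(1, floor(x - r)):min(w, ceiling(x + r))
    if (length(rows) && length(cols)) {
      dy <- rows - y
      dx <- cols - x
      inside <- outer(dy^2, dx^2, "+") <= r^2
      mask[rows, cols] <- mask[rows, cols] | inside
    }
    y <- y + stats::rnorm(1, 0, radius * 0.35)
    x <- x + stats::rnorm(1, 0, radius * 0.35)
    y <- min(max(y, 1), h); x <- min(max(x, 1), w)
  }
  mask
}

# Paint a textured elliptical nucleus onto img (modified in place by value).
paint_nucleus <- function(img, cy, cx, rx, ry, theta, colour, texture_sd) {
  h <- dim(img)[1]; w <- dim(img)[2]
  rmax <- max(rx, ry)
  rows <- max(1, floor(cy - rmax)):min(h, ceiling(cy + rmax))
  cols <- max(1, floor(cx - rmax)):min(w, ceiling(cx + rmax))
  dy <- rows - cy
  dx <- cols - cx
  ct <- cos(theta); st <- sin(theta)
  u <- outer(dy, dx, function(a, b) (b * ct + a * st) / rx)
  v <- outer(dy, dx, function(a, b) (-b * st + a * ct) / ry)
  inside <- u^2 + v^2 <= 1
  n_in <- sum(inside)
  if (n_in == 0) return(img)
  noise <- stats::rnorm(n_in, 0, texture_sd)
  for (ch in 1:3) {
    plane <- img[rows, cols, ch]
    plane[inside] <- colour[ch] + noise
    img[rows, cols, ch] <- plane
  }
  img
}

#' Generate one synthetic tissue tile
#'
#' Deterministic in `(spec, seed)`: the same pair always yields a bit-identical
#' tile. Necrosis-like regions are drawn first; nuclei are then placed by
#' rejection sampling so that no nucleus overlaps a necrotic region or sits
#' closer to another nucleus than the configured separation, and every drawn
#' nucleus contributes exactly one point annotation at its centroid.
#'
#' @param spec a [generator_spec()].
#' @param seed integer seed.
#' @param n_tumour,n_normal optional per-tile overrides of the spec's counts
#'   (used by dataset builders that vary the class mix across tiles).
#' @param n_necrosis optional override of the number of necrosis-like regions.
#' @return An object of class `"tissue_tile"`: a list with `image` (H x W x 3
#'   double in [0, 1]), `cells` (data.frame `x`, `y`, `cell_type`,
#'   `diameter_px`; 0-based pixel coordinates), `regions` (list of masks with
#'   `region_type`), `seed`, `id`, and `spec`.
#' @export
generate_tile <- function(spec, seed, n_tumour = NULL, n_normal = NULL,
                          n_necrosis = NULL) {
  validate_generator_spec(spec)
  n_tum <- as.integer(n_tumour %||% spec$n_tumour)
  n_nor <- as.integer(n_normal %||% spec$n_normal)
  h <- spec$tile_size; w <- spec$tile_size
  with_local_seed(seed, {
    jit <- stats::rnorm(3, 0, spec$stain_jitter_sd)
    bg <- clamp01(spec$background_colour + jit)
    img <- array(0, c(h, w, 3))
    for (ch in 1:3)
      img[, , ch] <- bg[ch] + stats::rnorm(h * w, 0, spec$background_texture_sd)

    # necrosis-like regions
    n_nec <- as.integer(n_necrosis %||%
      sample(spec$necrosis_count_range[1]:spec$necrosis_count_range[2], 1))
    regions <- list()
    nec_mask <- matrix(FALSE, h, w)
    for (i in seq_len(n_nec)) {
      r <- stats::runif(1, spec$necrosis_radius_range[1], spec$necrosis_radius_range[2])
      cy <- stats::runif(1, r, h - r)
      cx <- stats::runif(1, r, w - r)
      mask <- draw_blob_mask(h, w, cy, cx, r)
      if (!any(mask)) next
      ncol_jit <- clamp01(spec$necrosis_colour + jit + stats::rnorm(3, 0, 0.01))
      noise <- stats::rnorm(sum(mask), 0, spec$necrosis_texture_sd)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[mask] <- ncol_jit[ch] + noise
        img[, , ch] <- plane
      }
      # karyorrhectic debris: small dark fragments of disintegrated nuclei,
      # scattered through the necrotic ground mass, never annotated as cells
      n_debris <- stats::rpois(1, sum(mask) * spec$necrosis_debris_density)
      if (n_debris > 0) {
        inside <- which(mask)
        picks <- sample(inside, min(n_debris, length(inside)))
        for (px in picks) {
          fy <- (px - 1) %% h + 1
          fx <- (px - 1) %/% h + 1
          fr <- stats::runif(1, spec$necrosis_debris_radius_range[1],
                             spec$necrosis_debris_radius_range[2])
          fcol <- clamp01(spec$necrosis_debris_colour + jit +
                            stats::rnorm(3, 0, 0.03))
          img <- paint_nucleus(img, fy, fx, fr, fr * stats::runif(1, 0.7, 1),
                               stats::runif(1, 0, pi), fcol, 0.03)
        }
      }
      regions[[length(regions) + 1L]] <- list(mask = mask, region_type = "necrosis")
      nec_mask <- nec_mask | mask
    }

    # nucleus placement by rejection sampling
    n_cells <- n_tum + n_nor
    types <- c(rep("tumour", n_tum), rep("normal", n_nor))
    diam_mean <- ifelse(types == "tumour", spec$tumour_diameter_mean, spec$normal_diameter_mean)
    diam_sd <- ifelse(types == "tumour", spec$tumour_diameter_sd, spec$normal_diameter_sd)
    # shuffle the drawing order so neither class is systematically squeezed out
    ord <- sample.int(n_cells)
    types <- types[ord]; diam_mean <- diam_mean[ord]; diam_sd <- diam_sd[ord]

    ys <- numeric(0); xs <- numeric(0); ds <- numeric(0); ts <- character(0)
    max_attempts <- 300L * max(n_cells, 1L)
    attempts <- 0L
    i <- 1L
    while (i <= n_cells) {
      if (attempts > max_attempts)
        stopf("tile of size %d px cannot accommodate %d cells: configuration error",
              spec$tile_size, n_cells)
      attempts <- attempts + 1L
      d <- max(3, stats::rnorm(1, diam_mean[i], diam_sd[i]))
      r <- d / 2
      cy <- stats::runif(1, r + 1, h - r)
      cx <- stats::runif(1, r + 1, w - r)
      # keep nuclei clear of necrosis: test centre and a ring at the radius
      ring_y <- round(cy + r * sin(seq(0, 2 * pi, length.out = 9)))
      ring_x <- round(cx + r * cos(seq(0, 2 * pi, length.out = 9)))
      ring_y <- pmin(pmax(ring_y, 1), h); ring_x <- pmin(pmax(ring_x, 1), w)
      if (any(nec_mask[cbind(c(round(cy), ring_y), c(round(cx), ring_x))])) next
      if (length(ys)) {
        min_sep <- spec$min_separation_factor * (r + ds / 2) / 2
        if (any((ys - cy)^2 + (xs - cx)^2 < min_sep^2)) next
      }
      ys <- c(ys, cy); xs <- c(xs, cx); ds <- c(ds, d); ts <- c(ts, types[i])
      i <- i + 1L
    }

    for (k in seq_along(ys)) {
      base <- if (ts[k] == "tumour") spec$tumour_colour else spec$normal_colour
      tex <- if (ts[k] == "tumour") spec$tumour_texture_sd else spec$normal_texture_sd
      colour <- clamp01(base + jit + stats::rnorm(3, 0, spec$nucleus_colour_sd))
      rx <- ds[k] / 2 * stats::runif(1, 0.85, 1.15)
      ry <- ds[k] / 2 * stats::runif(1, 0.85, 1.15)
      theta <- stats::runif(1, 0, pi)
      # ys/xs are 1-based raster coordinates here; annotations are 0-based
      img <- paint_nucleus(img, ys[k], xs[k], rx, ry, theta, colour, tex)
    }

    img <- clamp01(img)
    cells <- data.frame(
      x = xs - 1, y = ys - 1,
      cell_type = ts,
      diameter_px = ds,
      stringsAsFactors = FALSE
    )
    structure(list(
      image = img, cells = cells, regions = regions,
      seed = as.integer(seed), id = sprintf("tile_%010d", as.integer(seed)),
      spec = spec
    ), class = "tissue_tile")
  })
}

#' @export
print.tissue_tile <- function(x, ...) {
  cat(sprintf("<tissue_tile %s> %dx%d px, %d cells (%d tumour), %d region(s)\n",
              x$id, dim(x$image)[1], dim(x$image)[2], nrow(x$cells),
              sum(x$cells$cell_type == "tumour"), length(x$regions)))
  invisible(x)
}

# Boolean mask over nucleus interiors of one class (used by tests and the
# separability checks); approximates each nucleus by its mean-radius disc.
nucleus_mask <- function(tile, cell_type = c("tumour", "normal")) {
  cell_type <- match.arg(cell_type)
  h <- dim(tile$image)[1]; w <- dim(tile$image)[2]
  mask <- matrix(FALSE, h, w)
  cells <- tile$cells[tile$cells$cell_type == cell_type, , drop = FALSE]
  for (k in seq_len(nrow(cells))) {
    r <- cells$diameter_px[k] / 2 * 0.7  # interior, avoids boundary mixing
    cy <- cells$y[k] + 1; cx <- cells$x[k] + 1
    rows <- max(1, floor(cy - r)):min(h, ceiling(cy + r))
    cols <- max(1, floor(cx - r)):min(w, ceiling(cx + r))
    inside <- outer((rows - cy)^2, (cols - cx)^2, "+") <= r^2
    mask[rows, cols] <- mask[rows, cols] | inside
  }
  mask
}
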