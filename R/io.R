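# On-disk interchange formats.
#
# Tiles and overlays: 8-bit RGB PNG. Cell annotations: CSV with header
# tile_id,x,y,cell_type,diameter_px (0-based pixel coordinates). Region masks:
# one single-channel label PNG per tile plus a CSV legend. Relevance maps and
# tile heatmaps: 32-bit float single-channel TIFF with a JSON sidecar.
# Dataset manifests: JSON.

#' Write a tile image as 8-bit RGB PNG
#' @param tile a `"tissue_tile"` (or a plain H x W x 3 array in [0, 1]).
#' @param path output file.
#' @export
write_tile_png <- function(tile, path) {
  img <- if (inherits(tile, "tissue_tile")) tile$image else tile
  png::writePNG(clamp01(img), path)
  invisible(path)
}

#' Write per-cell point annotations for a set of tiles as CSV
#' @param tiles list of `"tissue_tile"` (or a single tile).
#' @param path output CSV.
#' @export
write_cell_annotations <- function(tiles, path) {
  if (inherits(tiles, "tissue_tile")) tiles <- list(tiles)
  rows <- do.call(rbind, lapply(tiles, function(t)
    cbind(tile_id = t$id, t$cells)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-cell point annotations from CSV
#' @param path CSV written by [write_cell_annotations()].
#' @export
read_cell_annotations <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write region masks of a tile as a label PNG plus CSV legend
#'
#' Pixel value k / 255 marks membership in the k-th region; 0 is background.
#' Overlapping regions keep the higher label.
#'
#' @param tile a `"tissue_tile"`.
#' @param png_path output label PNG (single channel).
#' @param legend_path output CSV legend `tile_id,label_value,region_type`.
#' @export
write_region_masks <- function(tile, png_path, legend_path) {
  h <- dim(tile$image)[1]; w <- dim(tile$image)[2]
  lab <- matrix(0, h, w)
  legend <- data.frame(tile_id = character(0), label_value = integer(0),
                       region_type = character(0))
  for (k in seq_along(tile$regions)) {
    lab[tile$regions[[k]]$mask] <- k / 255
    legend <- rbind(legend, data.frame(
      tile_id = tile$id, label_value = k,
      region_type = tile$regions[[k]]$region_type))
  }
  png::writePNG(lab, png_path)
  utils::write.csv(legend, legend_path, row.names = FALSE, quote = FALSE)
  invisible(png_path)
}

#' Read region masks from a label PNG plus legend
#' @param png_path label PNG written by [write_region_masks()].
#' @param legend_path its CSV legend.
#' @return list of `list(mask, region_type)`.
#' @export
read_region_masks <- function(png_path, legend_path) {
  lab <- round(png::readPNG(png_path) * 255)
  legend <- utils::read.csv(legend_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(legend)), function(i)
    list(mask = lab == legend$label_value[i],
         region_type = legend$region_type[i]))
}

#' Write a dataset manifest as JSON
#' @param manifest named list (tiles, splits, seeds, applied biases, ...).
#' @param path output JSON file.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a relevance map or tile heatmap as float TIFF with JSON sidecar
#'
#' Signed relevance is stored as a 32-bit float single-channel TIFF after an
#' affine mapping into [0, 1] (TIFF's storable range); the offset and scale
#' are recorded in the JSON sidecar together with the map's metadata, so the
#' round trip restores signed values to float precision.
#'
#' @param map a `"relevance_map"` or `"tile_heatmap"`.
#' @param path output TIFF; the sidecar is written next to it as
#'   `<path>.json`.
#' @export
write_relevance_tiff <- function(map, path) {
  v <- map$values
  lo <- min(v); hi <- max(v)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((v - lo) / scale, path, bits.per.sample = 32L,
                  reduce = FALSE)
  meta <- map[setdiff(names(map), c("values", "channel_values", "coverage"))]
  meta$tiff_offset <- lo
  meta$tiff_scale <- scale
  meta$map_class <- class(map)[1]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a relevance map written by [write_relevance_tiff()]
#' @param path TIFF path (the `<path>.json` sidecar must be present).
#' @export
read_relevance_tiff <- function(path) {
  raw <- tiff::readTIFF(path, as.is = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  values <- raw * meta$tiff_scale + meta$tiff_offset
  cls <- meta$map_class %||% "relevance_map"
  meta <- meta[setdiff(names(meta), c("tiff_offset", "tiff_scale", "map_class"))]
  structure(c(list(values = values), meta), class = cls)
}
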