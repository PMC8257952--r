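# File I/O: masks and images as PNG, partitions as indexed PNG + JSON
# area report, manifests as JSON, tables as CSV.

#' Read a binary mask PNG (0/255 single channel)
#' @param path PNG file.
#' @return Integer 0/1 matrix.
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  matrix(as.integer(a > 0.5), nrow(a), ncol(a))
}

#' Write a leaflet mask as a 0/255 grayscale PNG
#' @param mask `leaflet_mask` or 0/1 matrix.
#' @param path Output PNG path.
#' @export
write_mask_png <- function(mask, path) {
  m <- if (inherits(mask, "leaflet_mask")) mask_matrix(mask) else mask
  png::writePNG(m * 1.0, path)
  invisible(path)
}

#' Read an 8-bit RGB image PNG as a 0..255 array
#' @param path PNG file.
#' @return `h x w x 3` integer array.
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  a <- a[, , 1:3, drop = FALSE]
  array(as.integer(round(a * 255)), dim = dim(a))
}

#' Write an RGB (0..255) array as PNG
#' @param image `h x w x 3` array, values 0..255.
#' @param path Output PNG path.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Write a region partition as indexed PNG plus JSON area report
#'
#' The PNG stores labels 0-3 (background, base, middle, tip) in the low
#' grayscale values; the JSON records per-region pixel areas.
#' @param partition A `region_partition`.
#' @param png_path,json_path Output paths.
#' @export
write_partition <- function(partition, png_path, json_path = NULL) {
  png::writePNG(unclass(partition) / 255, png_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(as.list(region_areas(partition)), json_path,
                         auto_unbox = TRUE)
  }
  invisible(png_path)
}

#' Read a region partition written by [write_partition()]
#' @param png_path Indexed PNG path.
#' @return A `region_partition`.
#' @export
read_partition <- function(png_path) {
  a <- png::readPNG(png_path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  lab <- matrix(as.integer(round(a * 255)), nrow(a), ncol(a))
  areas <- c(base = sum(lab == 1), middle = sum(lab == 2), tip = sum(lab == 3))
  structure(lab, areas = areas, axis = NULL, class = "region_partition")
}

write_manifest_json <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
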