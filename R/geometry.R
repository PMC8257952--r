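# Leaflet geometry: region-of-interest masks, the base->tip axis, and the
# equal-area base/middle/tip partition.
#
# Coordinate convention (documented once, used everywhere): pixels are
# addressed by 0-based (x, y) with x along columns and y along rows; the
# centre of matrix cell [r, c] (1-based R indexing) is (x, y) = (c-1, r-1).
# Row-major order means y varies slowest: index = y * width + x.

REGION_LEVELS <- c("base", "middle", "tip")

new_leaflet_mask <- function(m, micron_per_pixel = NA_real_) {
  storage.mode(m) <- "integer"
  structure(m, micron_per_pixel = micron_per_pixel, class = "leaflet_mask")
}

#' @export
print.leaflet_mask <- function(x, ...) {
  cat("<leaflet_mask> ", nrow(x), "x", ncol(x), " px, area ",
      sum(x), " px\n", sep = "")
  invisible(x)
}

mask_matrix <- function(mask) {
  m <- unclass(mask)
  attr(m, "micron_per_pixel") <- NULL
  m
}

# 0-based pixel-centre coordinates of foreground pixels, row-major order.
mask_coords <- function(mask) {
  idx <- which(t(mask_matrix(mask)) == 1L) - 1L # t() => row-major scan
  w <- ncol(mask)
  cbind(x = idx %% w, y = idx %/% w)
}

#' Load a leaflet region of interest
#'
#' Accepts either a binary mask image (single-channel PNG, 0/255), a logical
#' or 0/1 matrix, or a closed polygon given as an n x 2 matrix (or list of
#' `[x, y]` pairs, or GeoJSON-style JSON file) in pixel coordinates.
#' Polygons are rasterized by the half-open pixel-centre rule: the pixel at
#' `(x, y)` belongs to the ROI iff its centre is inside the polygon, with
#' left/bottom boundaries included and right/top excluded, so the square
#' `(0,0)-(10,0)-(10,10)-(0,10)` covers exactly 100 pixels.
#'
#' After rasterization the mask is cleaned: if several 8-connected
#' components remain, the largest is kept with a warning
#' (`multi_component = "error"` turns this into an error).
#'
#' @param x Mask path / matrix, or polygon (matrix, list, or JSON path).
#' @param shape For polygon input, optional `c(height, width)` of the output
#'   grid; defaults to the polygon bounding box.
#' @param micron_per_pixel Optional physical pixel size, carried as metadata.
#' @param multi_component `"keep_largest"` (default) or `"error"`.
#' @return A `leaflet_mask` (integer 0/1 matrix with attributes).
#' @export
load_roi <- function(x, shape = NULL, micron_per_pixel = NA_real_,
                     multi_component = c("keep_largest", "error")) {
  multi_component <- match.arg(multi_component)
  if (is.character(x)) {
    if (grepl("\\.json$", x, ignore.case = TRUE)) {
      poly <- jsonlite::fromJSON(x)
      x <- matrix(unlist(poly), ncol = 2, byrow = !is.matrix(poly))
      if (is.matrix(poly)) x <- poly
    } else {
      x <- read_mask_png(x)
    }
  }
  if (is.list(x) && !is.data.frame(x)) {
    x <- do.call(rbind, lapply(x, function(p) as.numeric(p)))
  }
  m <- if (is.matrix(x) && ncol(x) == 2 && !all(x %in% c(0, 1))) {
    rasterize_polygon(x, shape = shape)
  } else if (is.logical(x)) {
    matrix(as.integer(x), nrow(x), ncol(x))
  } else {
    stopifnot(is.matrix(x), all(x %in% c(0, 1)))
    matrix(as.integer(x), nrow(x), ncol(x))
  }
  if (sum(m) == 0) stop("empty mask: no foreground pixels")
  m <- clean_mask(m, multi_component)
  if (sum(m) < 9) stop("mask too small: fewer than 9 foreground pixels")
  new_leaflet_mask(m, micron_per_pixel)
}

# Even-odd ray-casting point-in-polygon over pixel centres; half-open by
# the strict `x < x_intersection` test.
rasterize_polygon <- function(poly, shape = NULL) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  if (all(poly[1, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), , drop = FALSE]
  if (is.null(shape)) {
    shape <- c(ceiling(max(poly[, 2])), ceiling(max(poly[, 1])))
  }
  h <- shape[1]; w <- shape[2]
  xs <- rep(0:(w - 1), each = h)
  ys <- rep(0:(h - 1), times = w)
  inside <- rep(FALSE, length(xs))
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > ys) != (yj > ys))
    if (any(crosses)) {
      xint <- xi + (ys - yi) * (xj - xi) / (yj - yi)
      inside[crosses] <- xor(inside[crosses], xs[crosses] < xint[crosses])
    }
    j <- i
  }
  matrix(as.integer(inside), nrow = h, ncol = w)
}

# Keep the largest 8-connected component (EBImage labelling).
clean_mask <- function(m, multi_component = "keep_largest") {
  lab <- EBImage::bwlabel(m)
  ncomp <- max(lab)
  if (ncomp > 1) {
    if (multi_component == "error") {
      stop("mask has ", ncomp, " connected components after cleanup")
    }
    warning("mask has ", ncomp, " components; keeping the largest")
    sizes <- tabulate(lab[lab > 0], nbins = ncomp)
    m <- matrix(as.integer(lab == which.max(sizes)), nrow(m), ncol(m))
  }
  m
}

#' Construct an axis specification manually
#'
#' @param direction Numeric length-2 vector `(dx, dy)`; normalized to unit
#'   length. By convention projections increase from base to tip.
#' @return An `axis_spec` object.
#' @export
axis_spec <- function(direction) {
  stopifnot(is.numeric(direction), length(direction) == 2)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("axis direction must be non-zero")
  structure(list(direction = direction / nrm, base_end = "low"),
            class = "axis_spec")
}

#' Estimate the base-to-tip axis of a leaflet mask
#'
#' The axis direction is the principal eigenvector of the second-moment
#' (covariance) matrix of the foreground pixel coordinates. Which end is the
#' leaflet base (the annulus attachment) is decided by a width heuristic:
#' the base end has the larger mean cross-sectional width, reflecting the
#' anatomy of a leaflet that tapers toward its free edge. `base_hint`
#' overrides the heuristic.
#'
#' @param mask A `leaflet_mask`.
#' @param base_hint Optional `"low"` or `"high"`: which end of the principal
#'   axis (by signed projection) is the base.
#' @return An `axis_spec` whose direction points base -> tip.
#' @export
estimate_axis <- function(mask, base_hint = NULL) {
  stopifnot(inherits(mask, "leaflet_mask"))
  xy <- mask_coords(mask)
  ctr <- colMeans(xy)
  d <- sweep(xy, 2, ctr)
  cov2 <- crossprod(d) / nrow(d)
  ev <- eigen(cov2, symmetric = TRUE)
  lams <- ev$values
  if ((lams[1] - lams[2]) / max(lams[1] + lams[2], .Machine$double.eps) < 1e-6) {
    stop("mask is isotropic (equal principal moments): the axis is ",
         "undefined; supply the axis manually with axis_spec()")
  }
  dir <- ev$vectors[, 1]

  proj <- as.vector(d %*% dir)
  if (!is.null(base_hint)) {
    base_hint <- match.arg(base_hint, c("low", "high"))
    if (base_hint == "high") dir <- -dir
  } else {
    # mean cross-sectional width near each end, from 10 projection bins
    rng <- range(proj)
    bins <- cut(proj, breaks = seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = 11),
                labels = FALSE)
    counts <- tabulate(bins, nbins = 10)
    lo_width <- mean(counts[1:2])
    hi_width <- mean(counts[9:10])
    if (hi_width > lo_width) dir <- -dir
  }
  axis_spec(dir)
}

#' Partition a leaflet mask into three equal-area regions
#'
#' Implements the equal-area "thirds" sectioning: foreground pixels are
#' sorted by their signed projection onto the base->tip axis (ties broken
#' by row-major pixel order), and cut at cumulative areas
#' `ceiling(A/3)` and `ceiling(2A/3)`. The first block is the base, then
#' middle, then tip, so the three areas are fixed by the total area alone
#' and the partition is fully deterministic.
#'
#' @param mask A `leaflet_mask`.
#' @param axis An `axis_spec` from [estimate_axis()] or [axis_spec()].
#' @return A `region_partition`: integer label matrix (0 background,
#'   1 base, 2 middle, 3 tip) with `areas` and `axis` attributes.
#' @export
partition_equal_area <- function(mask, axis) {
  stopifnot(inherits(mask, "leaflet_mask"), inherits(axis, "axis_spec"))
  m <- mask_matrix(mask)
  xy <- mask_coords(mask)
  a <- nrow(xy)
  if (a < 3) stop("mask too small to yield three non-empty regions")
  proj <- as.vector(xy %*% axis$direction)
  ord <- order(proj) # mask_coords is row-major, so ties resolve row-major
  n1 <- ceiling(a / 3)
  n2 <- ceiling(2 * a / 3)
  lab_seq <- integer(a)
  lab_seq[ord[seq_len(n1)]] <- 1L
  lab_seq[ord[(n1 + 1):n2]] <- 2L
  lab_seq[ord[(n2 + 1):a]] <- 3L

  labels <- matrix(0L, nrow(m), ncol(m))
  labels[cbind(xy[, "y"] + 1L, xy[, "x"] + 1L)] <- lab_seq
  areas <- c(base = n1, middle = n2 - n1, tip = a - n2)
  structure(labels, areas = areas, axis = axis, class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  a <- attr(x, "areas")
  cat("<region_partition> base/middle/tip = ",
      paste(a, collapse = "/"), " px\n", sep = "")
  invisible(x)
}

#' Per-region pixel areas of a partition
#' @param partition A `region_partition`.
#' @return Named integer vector (base, middle, tip).
#' @export
region_areas <- function(partition) attr(partition, "areas")
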