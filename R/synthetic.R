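# Synthetic histology and qPCR generators with exact ground truth.
#
# Every generator takes an explicit seed and is bit-reproducible; the
# painter keeps exact per-region bookkeeping so downstream quantification
# can be verified against the manifest rather than against real slides
# (the study's raw sections are not deposited).

#' Parameters of a synthetic leaflet outline
#'
#' The shape model is a tapered super-ellipse: half-width profile
#' `h(u) = h0 * (1 - |u|^2.5)^(1/2.5) * (1 - taper * (u + 1) / 2)` along the
#' normalized axis `u` in `[-1, 1]` (base at -1, tip at +1), optionally
#' perturbed by low-frequency sinusoidal boundary noise. Elongation is the
#' base-to-tip length over the maximum width.
#'
#' @param target_area Foreground area in pixels (> 8).
#' @param elongation Length / max width, >= 1.
#' @param taper Width shrink toward the tip, in `[0, 1)`.
#' @param boundary_roughness Relative amplitude of boundary noise, `[0, 1]`.
#' @param orientation_deg Rotation of the axis in image coordinates.
#' @return A `shape_params` list.
#' @export
shape_params <- function(target_area, elongation = 2.5, taper = 0.45,
                         boundary_roughness = 0, orientation_deg = 0) {
  stopifnot(is.numeric(target_area), target_area > 0,
            elongation >= 1, taper >= 0, taper < 1,
            boundary_roughness >= 0, boundary_roughness <= 1)
  if (target_area < 9) stop("degenerate shape: target_area below 9 px")
  structure(list(target_area = target_area, elongation = elongation,
                 taper = taper, boundary_roughness = boundary_roughness,
                 orientation_deg = orientation_deg),
            class = "shape_params")
}

# Half-width profile on u in [-1, 1], scaled to max 1; includes the seeded
# low-frequency roughness term, floored so the outline cannot pinch off.
half_width_profile <- function(u, shape, rough_coef) {
  p <- 2.5
  base <- (pmax(1 - abs(u)^p, 0))^(1 / p) * (1 - shape$taper * (u + 1) / 2)
  if (shape$boundary_roughness > 0) {
    r <- rowSums(vapply(seq_along(rough_coef$amp), function(k) {
      rough_coef$amp[k] * sin(k * pi * (u + 1) / 2 + rough_coef$phase[k])
    }, numeric(length(u))))
    base <- base * pmax(1 + 0.35 * shape$boundary_roughness * r, 0.25)
  }
  base
}

#' Generate a leaflet-shaped binary mask
#'
#' Rasterizes the tapered super-ellipse of [shape_params()] at the requested
#' orientation, scaling so the realized foreground area is within 5% of
#' `target_area` (typically much closer). The output always has exactly one
#' 8-connected component; identical `(shape, seed)` give bit-identical
#' masks.
#'
#' @param shape A [shape_params()].
#' @param seed Integer seed (drives the boundary-roughness term).
#' @return A `leaflet_mask` with the base at low x (before rotation).
#' @export
generate_leaflet_mask <- function(shape, seed) {
  stopifnot(inherits(shape, "shape_params"))
  rough_coef <- with_seed(seed, list(amp = stats::runif(3, -1, 1),
                                     phase = stats::runif(3, 0, 2 * pi)))
  # unit area of the profile, by fine numeric integration
  ugrid <- seq(-1, 1, length.out = 4001)
  hvals <- half_width_profile(ugrid, shape, rough_coef)
  unit_area <- sum(2 * hvals) * (ugrid[2] - ugrid[1]) # in (L/2 x h0) units

  # L * h0 * unit_area / 2 = target => with h0 = L / (2 e):
  L <- sqrt(shape$target_area * 4 * shape$elongation / (2 * unit_area))
  for (iter in 1:6) {
    h0 <- L / (2 * shape$elongation)
    theta <- shape$orientation_deg * pi / 180
    ct <- cos(theta); st <- sin(theta)
    half_diag <- L / 2 + h0 + 2
    n <- ceiling(2 * half_diag) + 3
    xs0 <- rep(0:(n - 1), each = n)
    ys0 <- rep(0:(n - 1), times = n)
    xs <- xs0 - (n - 1) / 2
    ys <- ys0 - (n - 1) / 2
    # rotate pixel centres into the shape frame
    xr <- ct * xs + st * ys
    yr <- -st * xs + ct * ys
    u <- xr / (L / 2)
    inside <- abs(u) <= 1
    hv <- numeric(length(u))
    hv[inside] <- half_width_profile(u[inside], shape, rough_coef) * h0
    inside <- inside & abs(yr) <= hv
    got <- sum(inside)
    if (abs(got - shape$target_area) / shape$target_area <= 0.02 || iter == 6) break
    L <- L * sqrt(shape$target_area / max(got, 1))
  }
  m <- matrix(0L, nrow = n, ncol = n)
  m[cbind(ys0[inside] + 1L, xs0[inside] + 1L)] <- 1L
  # crop to bounding box plus 1-px border
  rr <- range(which(rowSums(m) > 0)); cc <- range(which(colSums(m) > 0))
  m <- m[max(1, rr[1] - 1):min(n, rr[2] + 1),
         max(1, cc[1] - 1):min(n, cc[2] + 1)]
  m <- clean_mask(m) # single component guaranteed by the width floor
  if (abs(sum(m) - shape$target_area) / shape$target_area > 0.05) {
    stop("realized mask area ", sum(m), " deviates more than 5% from target ",
         shape$target_area)
  }
  new_leaflet_mask(m)
}

#' Define a synthetic stain scene
#'
#' A scene lists stain classes with their target regional distribution
#' (percent of the class's pixels in base/middle/tip, summing to 100), a
#' total pixel budget, and an RGB palette with per-channel Gaussian noise.
#' Unpainted leaflet pixels take the background colour.
#'
#' @param classes List of per-class lists with elements `name`,
#'   `dist` (length-3, base/middle/tip, sums to 100 ± 0.01), `budget`
#'   (total pixels, >= 0), `color` (RGB 0..255), `noise_sd` (per-channel SD,
#'   default 0).
#' @param background RGB of unpainted tissue inside the leaflet.
#' @param background_noise_sd Per-channel SD for the background.
#' @return A `stain_scene`.
#' @export
stain_scene <- function(classes,
                        background = c(235, 210, 215),
                        background_noise_sd = 0) {
  stopifnot(is.list(classes), length(classes) > 0)
  classes <- lapply(classes, function(cl) {
    stopifnot(is_string(cl$name), length(cl$dist) == 3, all(cl$dist >= 0),
              length(cl$color) == 3, all(cl$color >= 0), all(cl$color <= 255),
              is.numeric(cl$budget), cl$budget >= 0)
    if (abs(sum(cl$dist) - 100) > 0.01) {
      stop("class '", cl$name, "': distribution sums to ", sum(cl$dist),
           ", not 100")
    }
    cl$noise_sd <- cl$noise_sd %||% 0
    stopifnot(cl$noise_sd >= 0)
    cl
  })
  structure(list(classes = classes, background = background,
                 background_noise_sd = background_noise_sd),
            class = "stain_scene")
}

#' The Movat/van Gieson-like default palette
#'
#' Palette means chosen to fall squarely inside the corresponding
#' [stain_presets()] intervals: yellow collagen, blue GAGs, near-black
#' elastin.
#' @return Named list of RGB triplets.
#' @export
default_palette <- function() {
  list(collagen = c(218, 165, 32),
       gag = c(70, 130, 180),
       elastin = c(45, 40, 40))
}

noisy_channel <- function(mean_val, sd, n) {
  v <- if (sd > 0) stats::rnorm(n, mean_val, sd) else rep(mean_val, n)
  as.integer(round(clamp(v, 0, 255)))
}

#' Paint a stain scene onto a partitioned leaflet
#'
#' Allocates each class's pixel budget across the three regions by
#' largest-remainder rounding of the target distribution (realized counts
#' match the target to the nearest pixel), places the pixels uniformly at
#' random within each region without overlap between classes, and colours
#' them from the class palette with per-channel Gaussian noise (noise 0
#' gives exactly the palette mean). Pixels outside the mask are white.
#'
#' @param mask A `leaflet_mask`.
#' @param partition A `region_partition` derived from `mask`.
#' @param scene A [stain_scene()].
#' @param seed Integer seed.
#' @return List with `image` (`h x w x 3`, 0..255), `labels` (integer
#'   matrix, 0 = unstained, k = k-th scene class) and `manifest` (realized
#'   per-class regional counts, distributions, seed, areas).
#' @export
paint_stain_image <- function(mask, partition, scene, seed) {
  stopifnot(inherits(mask, "leaflet_mask"),
            inherits(partition, "region_partition"),
            inherits(scene, "stain_scene"),
            all(dim(mask) == dim(partition)))
  labels_part <- unclass(partition)
  h <- nrow(mask); w <- ncol(mask)
  inmask <- mask_matrix(mask) == 1L

  with_seed(seed, {
    class_label <- matrix(0L, h, w)
    avail <- lapply(1:3, function(k) which(labels_part == k))
    manifest_classes <- list()
    for (ci in seq_along(scene$classes)) {
      cl <- scene$classes[[ci]]
      counts <- if (cl$budget > 0) apportion(cl$budget, cl$dist) else
        c(0L, 0L, 0L)
      for (k in 1:3) {
        if (counts[k] > length(avail[[k]])) {
          stop("capacity exceeded: class '", cl$name, "' needs ", counts[k],
               " px in ", REGION_LEVELS[k], " but only ",
               length(avail[[k]]), " remain")
        }
        if (counts[k] > 0) {
          pick <- if (length(avail[[k]]) == 1) avail[[k]] else
            sample(avail[[k]], counts[k])
          class_label[pick] <- ci
          avail[[k]] <- setdiff(avail[[k]], pick)
        }
      }
      manifest_classes[[cl$name]] <- list(
        counts = stats::setNames(as.integer(counts), REGION_LEVELS),
        distribution = if (sum(counts) > 0)
          stats::setNames(100 * counts / sum(counts), REGION_LEVELS) else
          stats::setNames(rep(NA_real_, 3), REGION_LEVELS),
        budget = sum(counts))
    }

    img <- array(255L, dim = c(h, w, 3))
    bg_idx <- which(inmask & class_label == 0L)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[bg_idx] <- noisy_channel(scene$background[ch],
                                     scene$background_noise_sd, length(bg_idx))
      for (ci in seq_along(scene$classes)) {
        cl <- scene$classes[[ci]]
        idx <- which(class_label == ci)
        plane[idx] <- noisy_channel(cl$color[ch], cl$noise_sd, length(idx))
      }
      img[, , ch] <- plane
    }
    list(image = img, labels = class_label,
         manifest = list(classes = manifest_classes, seed = seed,
                         leaflet_area = sum(inmask),
                         region_areas = region_areas(partition)))
  })
}

#' Generate a full synthetic leaflet (mask, partition, image, ground truth)
#'
#' Convenience wrapper: generate the mask, estimate its axis (base at the
#' wide end), partition into equal-area thirds, and paint the scene.
#'
#' @inheritParams paint_stain_image
#' @param shape A [shape_params()].
#' @param base_hint Passed to [estimate_axis()].
#' @param seed Integer seed used for both shape and painting.
#' @return List with `mask`, `axis`, `partition`, `image`, `labels`,
#'   `manifest`.
#' @export
simulate_leaflet <- function(shape, scene, seed, base_hint = NULL) {
  mask <- generate_leaflet_mask(shape, seed)
  axis <- estimate_axis(mask, base_hint = base_hint)
  part <- partition_equal_area(mask, axis)
  painted <- paint_stain_image(mask, part, scene, seed + 1000L)
  c(list(mask = mask, axis = axis, partition = part), painted)
}

#' Design of a synthetic qPCR experiment
#'
#' @param fold_changes Named numeric vector of true relative expressions vs
#'   the control group; the first element is the control and must be 1.
#' @param reference_ct Mean Ct of the reference gene (all groups).
#' @param target_control_ct Mean Ct of the target gene in the control group.
#' @param n_samples Biological samples per group.
#' @param replicates Technical replicates per sample.
#' @param noise_sd Additive Gaussian replicate noise, in Ct units.
#' @param reference_gene,target_gene Gene names used in the emitted table.
#' @return A `ct_design`.
#' @export
ct_design <- function(fold_changes, reference_ct = 18,
                      target_control_ct = 23, n_samples = 3, replicates = 3,
                      noise_sd = 0, reference_gene = "GAPDH",
                      target_gene = "ELN") {
  stopifnot(length(fold_changes) >= 1, !is.null(names(fold_changes)),
            all(fold_changes > 0), replicates >= 1, n_samples >= 1,
            noise_sd >= 0)
  if (abs(fold_changes[1] - 1) > 1e-12) {
    stop("the first (control) group's fold change must be 1")
  }
  structure(list(fold_changes = fold_changes, reference_ct = reference_ct,
                 target_control_ct = target_control_ct,
                 n_samples = n_samples, replicates = replicates,
                 noise_sd = noise_sd, reference_gene = reference_gene,
                 target_gene = target_gene),
            class = "ct_design")
}

#' Generate a Ct table from a design
#'
#' Each group's true target-gene Ct is
#' `target_control_ct - log2(fold change)`, so a zero-noise table is
#' recovered exactly by [delta_delta_ct()]. Replicate noise is additive
#' Gaussian in Ct units, independent across wells.
#'
#' @param design A [ct_design()].
#' @param seed Integer seed.
#' @return A [ct_table()] data.frame.
#' @export
generate_ct_table <- function(design, seed) {
  stopifnot(inherits(design, "ct_design"))
  with_seed(seed, {
    rows <- list()
    for (g in names(design$fold_changes)) {
      tgt_ct <- design$target_control_ct - log2(design$fold_changes[[g]])
      for (s in seq_len(design$n_samples)) {
        sid <- paste0(g, "_s", s)
        genes <- c(design$reference_gene, design$target_gene)
        means <- c(design$reference_ct, tgt_ct)
        for (gi in 1:2) {
          noise <- if (design$noise_sd > 0)
            stats::rnorm(design$replicates, 0, design$noise_sd) else
            rep(0, design$replicates)
          rows[[length(rows) + 1]] <- data.frame(
            sample = sid, group = g, gene = genes[gi],
            replicate = seq_len(design$replicates),
            ct = means[gi] + noise,
            stringsAsFactors = FALSE)
        }
      }
    }
    ct_table(do.call(rbind, rows))
  })
}
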