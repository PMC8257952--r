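# HSI transform and threshold classification.

px_image <- function(colors) {
  # colors: list of RGB triplets -> 1 x n x 3 array
  n <- length(colors)
  img <- array(0, dim = c(1, n, 3))
  for (j in seq_len(n)) img[1, j, ] <- colors[[j]]
  img
}

test_that("achromatic and pure-primary pixels transform as expected", {
  hsi <- rgb_to_hsi(px_image(list(c(255, 255, 255), c(255, 0, 0),
                                  c(0, 0, 0))))
  expect_true(is.na(hsi$h[1, 1]))           # white: hue undefined
  expect_equal(hsi$s[1, 1], 0)
  expect_equal(hsi$i[1, 1], 1)
  expect_equal(hsi$h[1, 2], 0)              # pure red
  expect_equal(hsi$s[1, 2], 1)
  expect_equal(hsi$i[1, 2], 1 / 3, tolerance = 1e-12)
  expect_equal(hsi$s[1, 3], 0)              # black: mean 0 => s = 0
  expect_true(is.na(hsi$h[1, 3]))
})

test_that("the transform matches a scalar transcription of the formulas", {
  cases <- list(c(100, 150, 200), c(218, 165, 32), c(70, 130, 180),
                c(45, 40, 40), c(255, 20, 40), c(10, 200, 90))
  hsi <- rgb_to_hsi(px_image(cases))
  for (j in seq_along(cases)) {
    o <- do.call(oracle_hsi, as.list(cases[[j]]))
    expect_equal(hsi$h[1, j], o$h, tolerance = 1e-9)
    expect_equal(hsi$s[1, j], o$s, tolerance = 1e-12)
    expect_equal(hsi$i[1, j], o$i, tolerance = 1e-12)
  }
})

test_that("hue intervals wrap around zero correctly", {
  # hues ~4.5, ~355.5 and 180 (values confirmed by the formula oracle)
  img <- px_image(list(c(255, 40, 20), c(255, 20, 40), c(0, 255, 255)))
  expect_equal(oracle_hsi(255, 40, 20)$h, 4.48, tolerance = 0.1)
  expect_equal(oracle_hsi(255, 20, 40)$h, 355.52, tolerance = 0.1)
  expect_equal(oracle_hsi(0, 255, 255)$h, 180)
  # replicate the 1 x 3 row into a 3 x 3 image so the mask is valid (>= 9 px)
  img3 <- array(0, dim = c(3, 3, 3))
  for (r in 1:3) img3[r, , ] <- img[1, , ]
  m3 <- load_roi(matrix(1L, 3, 3))
  spec <- list(stain_class_spec("wrap", hue = c(350, 10), sat = c(0.2, 1),
                                int = c(0, 1)))
  hit <- classify_stain(img3, m3, spec)$wrap
  expect_true(all(hit[, 1]))   # H ~ 4.5 accepted
  expect_true(all(hit[, 2]))   # H ~ 355.5 accepted
  expect_false(any(hit[, 3]))  # H = 180 rejected
})

test_that("a uniform yellow leaflet is entirely collagen", {
  img <- array(0, dim = c(6, 6, 3))
  img[, , 1] <- 255; img[, , 2] <- 255; img[, , 3] <- 0
  mask <- load_roi(matrix(1L, 6, 6))
  hit <- classify_stain(img, mask, stain_presets("pentachrome"))
  expect_identical(hit$collagen, unclass(mask)[, ] == 1L)
  expect_equal(sum(hit$gag) + sum(hit$elastin), 0)
})

test_that("low-saturation background is never classified by a sat gate", {
  img <- array(0, dim = c(4, 4, 3))
  img[, , 1] <- 235; img[, , 2] <- 210; img[, , 3] <- 215
  mask <- load_roi(matrix(1L, 4, 4))
  spec <- list(stain_class_spec("any", hue = c(0, 360), sat = c(0.2, 1),
                                int = c(0, 1)))
  expect_equal(sum(classify_stain(img, mask, spec)$any), 0)
})

test_that("zero-noise synthetic pixels classify exactly per the manifest", {
  shape <- shape_params(4000, elongation = 2.2, taper = 0.4,
                        boundary_roughness = 0.3)
  mask <- generate_leaflet_mask(shape, seed = 4)
  ax <- estimate_axis(mask, base_hint = "low")
  part <- partition_equal_area(mask, ax)
  pal <- default_palette()
  scene <- stain_scene(list(
    list(name = "collagen", dist = c(76.9, 21.8, 1.3), budget = 800,
         color = pal$collagen, noise_sd = 0),
    list(name = "gag", dist = c(38.9, 19.3, 41.8), budget = 600,
         color = pal$gag, noise_sd = 0),
    list(name = "elastin", dist = c(26.4, 20.7, 52.9), budget = 500,
         color = pal$elastin, noise_sd = 0)))
  painted <- paint_stain_image(mask, part, scene, seed = 12)
  hit <- classify_stain(painted$image, mask, "pentachrome")
  for (cl in c("collagen", "gag", "elastin")) {
    expect_equal(sum(hit[[cl]]), painted$manifest$classes[[cl]]$budget)
  }
  # per-region counts agree with the generator's bookkeeping exactly
  fr <- regional_fractions(hit, part)
  for (cl in names(painted$manifest$classes)) {
    expect_equal(fr$count[fr$class == cl],
                 unname(painted$manifest$classes[[cl]]$counts))
  }
})

test_that("class counts are invariant under joint translation", {
  mask0 <- generate_leaflet_mask(shape_params(900), seed = 2)
  ax <- estimate_axis(mask0, base_hint = "low")
  part <- partition_equal_area(mask0, ax)
  painted <- paint_stain_image(mask0, part, single_class_scene(budget = 150),
                               seed = 1)
  c0 <- attr(classify_stain(painted$image, mask0, "pentachrome"), "counts")

  h <- nrow(mask0); w <- ncol(mask0)
  img_t <- array(255L, dim = c(h + 7, w + 5, 3))
  img_t[8:(h + 7), 6:(w + 5), ] <- painted$image
  m_t <- matrix(0L, h + 7, w + 5)
  m_t[8:(h + 7), 6:(w + 5)] <- unclass(mask0)[, ]
  c1 <- attr(classify_stain(img_t, load_roi(m_t), "pentachrome"), "counts")
  expect_equal(c1, c0)
})

test_that("exclusive assignment never exceeds the mask area", {
  mask <- generate_leaflet_mask(shape_params(1200), seed = 6)
  part <- partition_equal_area(mask, estimate_axis(mask, base_hint = "low"))
  painted <- paint_stain_image(mask, part, single_class_scene(budget = 700),
                               seed = 3)
  overlapping <- list(
    stain_class_spec("dark1", int = c(0, 0.3)),
    stain_class_spec("dark2", int = c(0, 0.5)),
    stain_class_spec("everything"))
  hit <- classify_stain(painted$image, mask, overlapping)
  expect_lte(sum(attr(hit, "counts")), sum(mask))
  expect_equal(sum(hit$dark1 & hit$dark2), 0) # first match wins
  non_excl <- classify_stain(painted$image, mask, overlapping,
                             exclusive = FALSE)
  expect_gt(sum(non_excl$dark2 & non_excl$dark1), 0)
})

test_that("threshold configs round-trip through YAML and JSON", {
  cfg <- list(collagen = list(hue = c(30, 75), sat = c(0.25, 1),
                              int = c(0.25, 0.9)),
              elastin = list(int = c(0, 0.22)))
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  specs <- read_stain_config(yml)
  expect_equal(length(specs), 2)
  expect_equal(specs[[1]]$name, "collagen")
  expect_equal(specs[[1]]$hue, c(30, 75))
  expect_equal(specs[[2]]$hue, c(0, 360)) # defaulted
  expect_error(stain_class_spec("bad", sat = c(0.9, 0.1)))
  expect_error(stain_class_spec("bad", hue = c(-10, 30)))
})
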