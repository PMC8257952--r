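# Synthetic leaflet, stain-scene and Ct-table generators.

test_that("generated masks hit the target area within 5%", {
  m <- generate_leaflet_mask(shape_params(900, elongation = 3,
                                          boundary_roughness = 0), seed = 1)
  expect_gte(sum(m), 855)
  expect_lte(sum(m), 945)
  for (area in c(300, 2000, 10000)) {
    m <- generate_leaflet_mask(shape_params(area, boundary_roughness = 0.5),
                               seed = area)
    expect_lt(abs(sum(m) - area) / area, 0.05)
  }
})

test_that("identical shape and seed give bit-identical masks", {
  sp <- shape_params(1200, elongation = 2.4, taper = 0.3,
                     boundary_roughness = 0.6, orientation_deg = 17)
  m1 <- generate_leaflet_mask(sp, seed = 33)
  m2 <- generate_leaflet_mask(sp, seed = 33)
  expect_identical(m1, m2)
  m3 <- generate_leaflet_mask(sp, seed = 34)
  expect_false(identical(m1, m3))
})

test_that("masks are a single 8-connected component (flood-fill oracle)", {
  m <- generate_leaflet_mask(shape_params(10000, elongation = 2,
                                          boundary_roughness = 0.3), seed = 7)
  expect_equal(oracle_component_count(unclass(m)[, ]), 1)
  for (s in 1:5) {
    m <- generate_leaflet_mask(shape_params(600, elongation = 3, taper = 0.6,
                                            boundary_roughness = 1), seed = s)
    expect_equal(oracle_component_count(unclass(m)[, ]), 1)
  }
})

test_that("degenerate shape parameters are rejected", {
  expect_error(shape_params(5), "degenerate")
  expect_error(shape_params(900, elongation = 0.5))
  expect_error(shape_params(900, taper = 1.2))
})

test_that("a (100, 0, 0) distribution paints only the base region", {
  mask <- generate_leaflet_mask(shape_params(1500), seed = 2)
  part <- partition_equal_area(mask, estimate_axis(mask, base_hint = "low"))
  painted <- paint_stain_image(mask, part,
                               single_class_scene(dist = c(100, 0, 0),
                                                  budget = 300), seed = 4)
  lab_part <- unclass(part)
  expect_true(all(lab_part[painted$labels == 1] == 1))
  expect_equal(sum(painted$labels == 1), 300)
})

test_that("zero noise paints exactly the palette colors", {
  mask <- generate_leaflet_mask(shape_params(1000), seed = 3)
  part <- partition_equal_area(mask, estimate_axis(mask, base_hint = "low"))
  painted <- paint_stain_image(mask, part,
                               single_class_scene(color = c(45, 40, 40),
                                                  budget = 200),
                               seed = 5)
  idx <- which(painted$labels == 1)
  for (ch in 1:3) {
    plane <- painted$image[, , ch]
    expect_true(all(plane[idx] == c(45, 40, 40)[ch]))
  }
})

test_that("the reported scenario realizes exact pixel counts", {
  mask <- generate_leaflet_mask(shape_params(4000), seed = 9)
  part <- partition_equal_area(mask, estimate_axis(mask, base_hint = "low"))
  painted <- paint_stain_image(
    mask, part, single_class_scene(dist = c(26.4, 20.7, 52.9), budget = 1000),
    seed = 1)
  expect_equal(unname(painted$manifest$classes$elastin$counts),
               c(264, 207, 529))
})

test_that("budgets beyond region capacity raise a capacity error", {
  mask <- generate_leaflet_mask(shape_params(300), seed = 11)
  part <- partition_equal_area(mask, estimate_axis(mask, base_hint = "low"))
  scene <- single_class_scene(dist = c(100, 0, 0), budget = 5000)
  expect_error(paint_stain_image(mask, part, scene, seed = 1),
               "capacity exceeded")
})

test_that("the manifest equals a brute-force recount of the label image", {
  mask <- generate_leaflet_mask(shape_params(2000, boundary_roughness = 0.3),
                                seed = 13)
  part <- partition_equal_area(mask, estimate_axis(mask, base_hint = "low"))
  pal <- default_palette()
  scene <- stain_scene(list(
    list(name = "collagen", dist = c(50, 30, 20), budget = 500,
         color = pal$collagen, noise_sd = 4),
    list(name = "elastin", dist = c(5, 15, 80), budget = 300,
         color = pal$elastin, noise_sd = 4)))
  painted <- paint_stain_image(mask, part, scene, seed = 20)
  masks <- list(collagen = painted$labels == 1, elastin = painted$labels == 2)
  recount <- oracle_recount(masks, unclass(part))
  for (cl in names(recount)) {
    expect_equal(unname(painted$manifest$classes[[cl]]$counts),
                 unname(as.integer(recount[[cl]])))
  }
})

test_that("painting is deterministic and respects stain scene validation", {
  mask <- generate_leaflet_mask(shape_params(800), seed = 15)
  part <- partition_equal_area(mask, estimate_axis(mask, base_hint = "low"))
  scene <- single_class_scene(budget = 200)
  p1 <- paint_stain_image(mask, part, scene, seed = 6)
  p2 <- paint_stain_image(mask, part, scene, seed = 6)
  expect_identical(p1$image, p2$image)
  expect_identical(p1$manifest, p2$manifest)
  expect_error(stain_scene(list(list(name = "x", dist = c(50, 30, 10),
                                     budget = 10, color = c(0, 0, 0)))),
               "sums to")
})

test_that("flat designs give equal dCt across groups at zero noise", {
  des <- ct_design(c(A = 1, B = 1, C = 1), noise_sd = 0)
  tab <- generate_ct_table(des, seed = 1)
  fc <- delta_delta_ct(tab, "GAPDH", "ELN", "A")
  expect_true(all(abs(fc$delta_ct_mean - fc$delta_ct_mean[1]) < 1e-12))
  expect_equal(fc$fold_change, c(1, 1, 1))
})

test_that("Ct tables are reproducible under a fixed seed", {
  des <- ct_design(c(WT = 1, MU = 0.58), noise_sd = 0.2)
  expect_identical(generate_ct_table(des, seed = 42),
                   generate_ct_table(des, seed = 42))
  expect_false(identical(generate_ct_table(des, seed = 42),
                         generate_ct_table(des, seed = 43)))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_leaflet_mask(shape_params(500,
                                               boundary_roughness = 0.5),
                                  seed = 1))
  invisible(generate_ct_table(ct_design(c(A = 1), noise_sd = 0.3), seed = 2))
  expect_identical(.Random.seed, before)
})
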