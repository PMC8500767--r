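test_that("bbox_to_point averages the four coordinates", {
  expect_equal(bbox_to_point(c(0, 0, 10, 10)), c(5, 5))
  expect_equal(bbox_to_point(c(2, 4, 6, 8)), c(4, 6))
  expect_equal(bbox_to_point(c(3, 3, 3, 3)), c(3, 3))
  expect_error(bbox_to_point(c(5, 0, 3, 10)), "inverted")
})

test_that("lesion-free spec yields a negative slide with empty masks", {
  spec <- slide_spec(base_height = 256, base_width = 256, n_levels = 3,
                     pixel_size_um = 1, nuclei_density = 300)
  sl <- generate_slide(spec, seed = 2)
  expect_equal(sl$true_label, "negative")
  expect_true(all(vapply(sl$pyramid$masks, function(m) !any(m), logical(1))))
  expect_gt(nrow(sl$nuclei_points), 0)
})

test_that("same seed gives bit-identical slides", {
  spec <- fixture_slide_spec(diameter_um = 90, cell_count = 15,
                             base = 256, n_levels = 3)
  a <- generate_slide(spec, seed = 7)
  b <- generate_slide(spec, seed = 7)
  expect_identical(a$pyramid$levels, b$pyramid$levels)
  expect_identical(a$nuclei_points, b$nuclei_points)
  c <- generate_slide(spec, seed = 8)
  expect_false(identical(a$pyramid$levels, c$pyramid$levels))
})

test_that("macro-scale lesion is labelled by the staging cut-offs", {
  spec <- slide_spec(base_height = 4096, base_width = 4096, n_levels = 6,
                     pixel_size_um = 1, nuclei_density = 200,
                     lesions = list(lesion_spec(c(2048, 2048), 3000)))
  sl <- generate_slide(spec, seed = 1)
  expect_equal(sl$true_label, "macro")
  # independent check: Feret extent of the planted level-0 mask
  ext <- region_extent_mm(sl$pyramid$masks[[3]], 1, level = 2)
  expect_gt(ext, 2.0)
  expect_lt(abs(ext - 3.0), 0.3)
})

test_that("mask pyramid obeys the any-positive downsampling rule", {
  sl <- generate_slide(fixture_slide_spec(diameter_um = 60, base = 256,
                                          n_levels = 3))
  m0 <- sl$pyramid$masks[[1]]
  m1 <- sl$pyramid$masks[[2]]
  i1 <- seq(1, 256, 2)
  expect_identical(m1, m0[i1, i1] | m0[i1 + 1, i1] | m0[i1, i1 + 1] |
                        m0[i1 + 1, i1 + 1])
})

test_that("nuclei points are bbox centers and lie in bounds", {
  sl <- generate_slide(fixture_slide_spec(diameter_um = 100, cell_count = 25,
                                          base = 256, n_levels = 3))
  bb <- sl$nuclei_bboxes
  expect_equal((bb[, 1] + bb[, 3]) / 2, sl$nuclei_points[, 1])
  expect_equal((bb[, 2] + bb[, 4]) / 2, sl$nuclei_points[, 2])
  expect_true(all(sl$nuclei_points >= 0 & sl$nuclei_points < 256))
  expect_equal(sum(sl$nuclei_in_lesion), 25)
})

test_that("planted circular lesion area matches pi r^2 within 15%", {
  for (d in c(60, 120)) {
    sl <- generate_slide(fixture_slide_spec(diameter_um = d, cell_count = 5,
                                            base = 512, n_levels = 4))
    area <- sum(sl$pyramid$masks[[1]]) * (1 / 1000)^2
    expect_lt(abs(area - pi * (d / 2000)^2) / (pi * (d / 2000)^2), 0.15)
  }
})

test_that("out-of-canvas and out-of-tissue lesions are rejected", {
  bad <- slide_spec(base_height = 256, base_width = 256, n_levels = 3,
                    pixel_size_um = 1,
                    lesions = list(lesion_spec(c(2, 2), 100)))
  expect_error(generate_slide(bad, seed = 1), "canvas|tissue")
})

test_that("spec invariants are enforced", {
  expect_error(slide_spec(base_height = 100, n_levels = 6), "divisible")
  expect_error(slide_spec(n_levels = 1), "n_levels")
  expect_error(slide_spec(pixel_size_um = 2), "pixel_size")
  expect_error(lesion_spec(c(0, 0), -5))
})

test_that("class-typical specs generate their own class labels", {
  for (cl in c("negative", "itc", "micro")) {
    sl <- generate_slide(slide_spec_for_class(cl, seed = 4))
    expect_equal(sl$true_label, cl, label = cl)
  }
})
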