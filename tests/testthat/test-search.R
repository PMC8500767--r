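test_that("location code encode/decode are inverse for all short codes", {
  ps <- 32L
  codes <- unlist(lapply(0:4, function(len) {
    if (len == 0) return("")
    apply(expand.grid(rep(list(0:3), len)), 1, paste, collapse = "")
  }))
  expect_length(codes, 341)
  for (code in codes) {
    lci <- location_code(c(0L, 0L), code, start_level = 4L)
    dec <- lci_to_coords(lci, ps)
    back <- lci_from_coords(dec$level, dec$origin, 4L, ps)
    expect_identical(back$code, code)
    expect_identical(back$root, c(0L, 0L))
  }
})

test_that("lci children tile the parent footprint disjointly", {
  lci <- location_code(c(1L, 2L), "0", 3L)
  kids <- lci_children(lci)
  expect_length(kids, 4)
  ps <- 16
  par <- lci_to_coords(lci, ps)
  kid_origins <- t(vapply(kids, function(k) lci_to_coords(k, ps)$origin,
                          numeric(2)))
  # children live one level finer, inside the doubled parent window
  expect_true(all(kid_origins >= rep(2 * par$origin, each = 4)))
  expect_true(all(kid_origins + ps <= rep(2 * par$origin + 2 * ps, each = 4)))
  expect_equal(nrow(unique(kid_origins)), 4)

  # child "01" decodes inside parent "0" mapped one level down
  p0 <- lci_to_coords(location_code(c(0L, 0L), "0", 3L), ps)$origin
  c01 <- lci_to_coords(location_code(c(0L, 0L), "01", 3L), ps)$origin
  expect_true(all(c01 >= 2 * p0 & c01 + ps <= 2 * p0 + 2 * ps))

  at0 <- location_code(c(0L, 0L), "333", 3L)
  expect_error(lci_children(at0), "level 0")
  expect_equal(lci_to_coords(location_code(c(0L, 0L), "3", 3L), 32)$origin,
               c(32L, 32L))
  expect_error(location_code(c(0, 0), "04x", 3), "malformed")
})

test_that("oracle search equals exhaustive scan and respects the work bound", {
  set.seed(11)
  for (trial in 1:3) {
    d <- round(runif(1, 60, 140))
    spec <- slide_spec(base_height = 512, base_width = 512, n_levels = 4,
                       pixel_size_um = 1,
                       lesions = list(lesion_spec(c(256, 256) +
                                                    round(runif(2, -40, 40)), d)),
                       nuclei_density = 200, background_seed = trial)
    sl <- generate_slide(spec)
    oracle <- make_oracle_classifier(sl$pyramid)
    sr <- search_pyramid(sl$pyramid, oracle, t = 0.5, start_level = 3,
                         stop_level = 0, patch_size = 32, tissue_only = FALSE)
    bf <- scan_level(sl$pyramid, oracle, level = 0, t = 0.5, patch_size = 32)
    got <- sr$rois$level_0[order(sr$rois$level_0$row, sr$rois$level_0$col),
                           c("row", "col")]
    want <- bf[order(bf$row, bf$col), c("row", "col")]
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))

    n_tiles_start <- prod(dim(sl$pyramid$levels[[4]])[1:2] %/% 32)
    n_above_stop <- sum(vapply(2:4, function(i)
      if (is.null(sr$rois[[i]])) 0L else nrow(sr$rois[[i]]), integer(1)))
    expect_lte(sr$evaluations, n_tiles_start + 4 * n_above_stop)
  }
})

test_that("all-negative oracle prunes everything at the start level", {
  sl <- generate_slide(slide_spec(base_height = 256, base_width = 256,
                                  n_levels = 3, pixel_size_um = 1,
                                  nuclei_density = 300), seed = 3)
  sr <- search_pyramid(sl$pyramid, make_oracle_classifier(sl$pyramid),
                       t = 0.5, start_level = 2, stop_level = 0,
                       patch_size = 32, tissue_only = FALSE)
  expect_true(all(vapply(sr$rois, is.null, logical(1))))
  expect_equal(sr$evaluations, (256 / 4 / 32)^2)
})

test_that("t = 0 makes every searched patch an RoI", {
  sl <- generate_slide(slide_spec(base_height = 128, base_width = 128,
                                  n_levels = 3, pixel_size_um = 1,
                                  nuclei_density = 300), seed = 4)
  sr <- search_pyramid(sl$pyramid, make_oracle_classifier(sl$pyramid),
                       t = 0, start_level = 2, stop_level = 0,
                       patch_size = 32, tissue_only = FALSE)
  expect_equal(nrow(sr$rois$level_2), 1)    # 32x32 level fits one patch
  expect_equal(nrow(sr$rois$level_1), 4)
  expect_equal(nrow(sr$rois$level_0), 16)
  expect_equal(sr$evaluations, 21)
})

test_that("missing level model is an explicit error", {
  sl <- generate_slide(slide_spec(base_height = 128, base_width = 128,
                                  n_levels = 3, pixel_size_um = 1), seed = 5)
  models <- list(NULL, make_oracle_classifier(sl$pyramid), NULL)
  expect_error(search_pyramid(sl$pyramid, models, start_level = 2,
                              stop_level = 0, patch_size = 32),
               "no classifier model for level")
})

test_that("connected_roi_area uses 4-connectivity and converts units", {
  rois <- data.frame(level = 2, row = c(0, 32, 64, 0), col = c(0, 32, 64, 64),
                     size = 32, lci = "", confidence = 1)
  p <- build_pyramid(fixture_rgb(512, 512), 3, pixel_size_um = 1)
  out <- connected_roi_area(rois, p)
  # diagonal patches do not connect: (0,0); (32,32); (64,64)+(0,64)? (0,64) is
  # not adjacent to (64,64) either -> 4 components
  expect_equal(nrow(out), 4)
  expect_equal(sort(out$n_patches), c(1, 1, 1, 1))
  # one 32 px patch at level 2 with 1 um level-0 pixels: (32 * 4 um)^2
  expect_equal(out$area_mm2[1], (32 * 4 / 1000)^2)

  single <- data.frame(level = 0, row = 0, col = 0, size = 32,
                       lci = "", confidence = 1)
  expect_equal(connected_roi_area(single, p)$area_mm2, 32^2 * 1e-6)
  expect_equal(nrow(connected_roi_area(NULL, p)), 0)
  # adjacency merges
  adj <- data.frame(level = 0, row = c(0, 32, 0), col = c(0, 0, 32),
                    size = 32, lci = "", confidence = 1)
  expect_equal(nrow(connected_roi_area(adj, p)), 1)
})

test_that("every RoI footprint intersects tissue under the mask oracle", {
  sl <- generate_slide(fixture_slide_spec(diameter_um = 120, base = 512,
                                          n_levels = 4))
  sr <- search_pyramid(sl$pyramid, make_oracle_classifier(sl$pyramid),
                       start_level = 3, stop_level = 0, patch_size = 32)
  r0 <- sr$rois$level_0
  for (i in seq_len(nrow(r0)))
    expect_true(any(sl$tissue_mask[r0$row[i] + 1:32, r0$col[i] + 1:32]))
})
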