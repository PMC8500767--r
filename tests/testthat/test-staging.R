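test_that("region extents convert units and handle degenerate inputs", {
  expect_equal(region_extent_mm(rbind(c(0, 0), c(0, 1000)), 1), 1.0)
  expect_equal(region_extent_mm(rbind(c(5, 5)), 0.5), 0.5 / 1000)
  expect_error(region_extent_mm(matrix(numeric(0), 0, 2), 1), "empty")
  m <- matrix(FALSE, 50, 50); m[10, 10:40] <- TRUE
  expect_equal(region_extent_mm(m, 1), 30 / 1000)
  # level adjustment doubles per level
  expect_equal(region_extent_mm(rbind(c(0, 0), c(0, 100)), 1, level = 2),
               0.4)
})

test_that("planted circular lesion extent is within 10% of its diameter", {
  for (d in c(100, 300)) {
    sl <- generate_slide(fixture_slide_spec(diameter_um = d, base = 512,
                                            n_levels = 4))
    ext <- region_extent_mm(sl$pyramid$masks[[1]], 1)
    expect_lt(abs(ext - d / 1000) / (d / 1000), 0.1)
  }
})

test_that("staging thresholds validate their invariants", {
  expect_error(staging_thresholds(macro_min_mm = 0.1), "macro_min_mm")
  expect_error(staging_thresholds(itc_max_cells = 0), "itc_max_cells")
})

test_that("empty search result stages negative without cell results", {
  p <- build_pyramid(fixture_rgb(256, 256), 4, pixel_size_um = 1)
  empty <- list(rois = lapply(1:4, function(i) NULL))
  lab <- classify_slide(empty, NULL, staging_thresholds(), p)
  expect_equal(lab$label, "negative")
})

test_that("sub-macro candidates without cell results raise an instructive error", {
  p <- build_pyramid(fixture_rgb(512, 512), 4, pixel_size_um = 1)
  rois <- lapply(1:4, function(i) NULL)
  rois[[3]] <- data.frame(level = 2, row = 0, col = 0, size = 32,
                          lci = "", confidence = 1)
  rois[[2]] <- data.frame(level = 1, row = 0, col = 0, size = 32,
                          lci = "", confidence = 1)
  expect_error(classify_slide(list(rois = rois), NULL, staging_thresholds(), p),
               "cell")
})

test_that("oracle detectors reproduce each planted class", {
  cases <- list(
    list(spec = fixture_slide_spec(diameter_um = 140, cell_count = 120,
                                   base = 1024, n_levels = 6),
         want = "itc"),
    list(spec = fixture_slide_spec(diameter_um = 500, base = 1024,
                                   n_levels = 6),
         want = "micro"))
  for (cs in cases) {
    sl <- generate_slide(cs$spec)
    rep <- screen_slide(sl, oracle = TRUE)
    expect_equal(sl$true_label, cs$want)
    expect_equal(rep$label, cs$want)
  }
})

test_that("cell-count evidence alone can promote itc to micro", {
  # a compact region with more than 200 cells is micro even below 0.2 mm:
  # build regions directly
  pts <- cbind(runif(250, 0, 150), runif(250, 0, 150))
  regs <- cluster_points(pts, cutoff_um = 50, pixel_size_um = 1)
  p <- build_pyramid(fixture_rgb(512, 512), 4, pixel_size_um = 1)
  rois <- lapply(1:4, function(i) NULL)
  rois[[1]] <- data.frame(level = 0, row = 0, col = 0, size = 32,
                          lci = "", confidence = 1)
  rois[[3]] <- data.frame(level = 2, row = 0, col = 0, size = 32,
                          lci = "", confidence = 1)
  lab <- classify_slide(list(rois = rois), regs, staging_thresholds(), p)
  expect_equal(lab$label, "micro")
  expect_gt(lab$max_cell_count, 200)
})

test_that("ordinal class is monotone in planted lesion diameter", {
  labels <- character(0)
  diams <- c(40, 150, 300, 600)
  for (d in diams) {
    sl <- generate_slide(fixture_slide_spec(diameter_um = d, base = 1024,
                                            n_levels = 6))
    rep <- screen_slide(sl, oracle = TRUE)
    labels <- c(labels, rep$label)
  }
  ord <- as.integer(factor(labels, levels = SLIDE_LABELS, ordered = TRUE))
  expect_true(all(diff(ord) >= 0))
  expect_equal(labels[1], "itc")
  expect_equal(labels[length(labels)], "micro")
})
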