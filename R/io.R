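#' Write a pyramid to its on-disk directory dialect
#'
#' The dialect is a directory holding `level_<l>.png` for every level, an
#' optional `mask_<l>.png` (0/255) per level, and a `pyramid.yaml` with
#' `n_levels` and `pixel_size_um`.  PNG levels are dependency-light and
#' bit-exact across platforms.
#'
#' @param pyramid a `pyramid` object.
#' @param dir output directory (created if missing).
#' @export
write_pyramid <- function(pyramid, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (l in seq_along(pyramid$levels) - 1L) {
    png::writePNG(clamp01(pyramid$levels[[l + 1]]),
                  file.path(dir, sprintf("level_%d.png", l)))
    if (!is.null(pyramid$masks))
      png::writePNG(pyramid$masks[[l + 1]] * 1,
                    file.path(dir, sprintf("mask_%d.png", l)))
  }
  yaml::write_yaml(list(n_levels = n_levels(pyramid),
                        pixel_size_um = pyramid$pixel_size_um),
                   file.path(dir, "pyramid.yaml"))
  invisible(dir)
}

#' Read a pyramid from a level directory or a pyramidal TIFF
#'
#' Directories must follow the dialect written by [write_pyramid()].
#' Multi-page TIFF files are accepted read-only: pages are sorted from finest
#' to coarsest and validated against the halving rule.
#'
#' @param path directory or `.tif`/`.tiff` file.
#' @param pixel_size_um pixel size at level 0; required for TIFF input,
#'   ignored for directories (taken from `pyramid.yaml`).
#' @return A `pyramid` object.
#' @export
read_pyramid <- function(path, pixel_size_um = NULL) {
  if (dir.exists(path)) {
    meta <- yaml::read_yaml(file.path(path, "pyramid.yaml"))
    levels <- lapply(seq_len(meta$n_levels) - 1L, function(l)
      as_rgb(png::readPNG(file.path(path, sprintf("level_%d.png", l)))))
    p <- new_pyramid(levels, meta$pixel_size_um)
    mask0 <- file.path(path, "mask_0.png")
    if (file.exists(mask0))
      p <- attach_masks(p, png::readPNG(mask0) > 0.5)
    return(p)
  }
  if (!grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop_bad("not a pyramid directory or TIFF file: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  areas <- vapply(pages, function(p) prod(dim(p)[1:2]), numeric(1))
  pages <- lapply(pages[order(areas, decreasing = TRUE)], as_rgb)
  new_pyramid(pages, pixel_size_um %||%
                stop_bad("pixel_size_um is required for TIFF input"))
}

#' Write a synthetic slide (pyramid plus labels) to disk
#'
#' Writes the pyramid dialect plus `lesions.csv` (center, diameter, class),
#' `nuclei.csv` (point and bounding-box coordinates at level 0) and
#' `label.txt` with the slide-level ground truth.
#'
#' @param slide a `synthetic_slide` from [generate_slide()].
#' @param dir output directory.
#' @export
write_slide <- function(slide, dir) {
  write_pyramid(slide$pyramid, dir)
  utils::write.csv(slide$lesions, file.path(dir, "lesions.csv"), row.names = FALSE)
  nuc <- data.frame(row = slide$nuclei_points[, 1], col = slide$nuclei_points[, 2],
                    r0 = slide$nuclei_bboxes[, 1], c0 = slide$nuclei_bboxes[, 2],
                    r1 = slide$nuclei_bboxes[, 3], c1 = slide$nuclei_bboxes[, 4],
                    in_lesion = slide$nuclei_in_lesion)
  utils::write.csv(nuc, file.path(dir, "nuclei.csv"), row.names = FALSE)
  writeLines(as.character(slide$true_label), file.path(dir, "label.txt"))
  invisible(dir)
}

#' Read contour annotations from CSV
#'
#' Expected columns: `polygon_id,row,col` with 0-based vertex coordinates.
#' (Converting vendor XML annotation dialects to this CSV layout is left to
#' external tooling.)
#'
#' @param path CSV file path.
#' @return List of `n x 2` vertex matrices, one per polygon.
#' @export
read_contours_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("polygon_id", "row", "col") %in% names(df)))
  lapply(split(df, df$polygon_id), function(d) as.matrix(d[, c("row", "col")]))
}
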