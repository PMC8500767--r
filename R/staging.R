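#' TNM-style staging thresholds
#'
#' Clinical node-lesion cut-offs: macrometastasis above `macro_min_mm`
#' (2.0 mm Feret extent), micrometastasis between `micro_min_mm` (0.2 mm)
#' and 2.0 mm or above `itc_max_cells` (200 cells), isolated tumor cells
#' below both.  `negative_break_level` is the pyramid level at which the
#' search must still be finding RoIs for a slide to be considered anything
#' but negative, and the level at which connected-RoI extents are measured.
#'
#' @param macro_min_mm,micro_min_mm extent cut-offs in millimetres.
#' @param itc_max_cells maximum cell count of an ITC.
#' @param negative_break_level level for the negative/extent decision.
#' @export
staging_thresholds <- function(macro_min_mm = 2.0, micro_min_mm = 0.2,
                               itc_max_cells = 200, negative_break_level = 2) {
  if (!(macro_min_mm > micro_min_mm && micro_min_mm > 0))
    stop_bad("need macro_min_mm > micro_min_mm > 0")
  if (itc_max_cells <= 0) stop_bad("itc_max_cells must be positive")
  list(macro_min_mm = macro_min_mm, micro_min_mm = micro_min_mm,
       itc_max_cells = itc_max_cells,
       negative_break_level = as.integer(negative_break_level))
}

#' Ordered slide labels
#' @export
SLIDE_LABELS <- c("negative", "itc", "micro", "macro")

#' Maximum Feret extent of a region in millimetres
#'
#' For point input the extent is the maximum pairwise distance (at least one
#' pixel); for mask input the positive pixels are used.  The pixel size is
#' adjusted for the region's pyramid level.
#'
#' @param x `n x 2` matrix of 0-based pixel points or a logical mask.
#' @param pixel_size_um level-0 pixel size in micrometres.
#' @param level 0-based pyramid level of the coordinates.
#' @export
region_extent_mm <- function(x, pixel_size_um, level = 0) {
  pts <- if (is.matrix(x) && !is.logical(x)) x else which(x, arr.ind = TRUE) - 1
  if (nrow(pts) == 0) stop_bad("empty region")
  if (nrow(pts) > 400) {
    hull <- grDevices::chull(pts[, 2], pts[, 1])
    pts <- pts[hull, , drop = FALSE]
  }
  ext <- if (nrow(pts) > 1) max(stats::dist(pts)) else 0
  max(ext, 1) * pixel_size_um * 2^level / 1000
}

# Feret extent (mm) of a connected patch component, using patch corners.
component_extent_mm <- function(rois, comp_id, comp, pyramid) {
  sel <- rois[comp == comp_id, , drop = FALSE]
  corners <- rbind(cbind(sel$row, sel$col),
                   cbind(sel$row + sel$size, sel$col),
                   cbind(sel$row, sel$col + sel$size),
                   cbind(sel$row + sel$size, sel$col + sel$size))
  max(stats::dist(corners)) * pixel_size_at(pyramid, sel$level[1]) / 1000
}

#' Classify a slide into the TNM-style classes
#'
#' Decision cascade: (1) if the search produced no RoI at any level finer
#' than `negative_break_level`, the slide is negative (the search "broke"
#' before reaching it); (2) otherwise any connected-RoI component at that
#' level with Feret extent of at least `macro_min_mm` makes the slide macro;
#' (3) otherwise cell-level evidence decides: a cell region with diameter at
#' least `micro_min_mm` or more than `itc_max_cells` cells makes it micro;
#' (4) any remaining detected cancer cells make it ITC; (5) else negative.
#' The larger class always wins when regions disagree.
#'
#' @param search_result value of [search_pyramid()] (or its `rois` list).
#' @param cell_regions list of `cell_region`s from [cluster_points()], a
#'   zero-argument function returning such a list (evaluated only if the
#'   sub-macro path is reached), or `NULL` when cell detection has not been
#'   run.
#' @param thresholds [staging_thresholds()].
#' @param pyramid the searched `pyramid`.
#' @return list (`slide_label`): `label` plus supporting evidence
#'   (`largest_extent_mm`, `max_cell_count`, `max_region_diameter_mm`).
#' @export
classify_slide <- function(search_result, cell_regions = NULL,
                           thresholds = staging_thresholds(), pyramid) {
  rois <- if (!is.null(search_result$rois)) search_result$rois else search_result
  nbl <- thresholds$negative_break_level
  finer <- seq_len(nbl)  # levels 0 .. nbl-1 -> indices 1..nbl
  any_finer <- any(vapply(finer, function(i)
    !is.null(rois[[i]]) && nrow(rois[[i]]) > 0, logical(1)))
  ev <- list(largest_extent_mm = 0, max_cell_count = 0,
             max_region_diameter_mm = 0)
  mk <- function(label) structure(c(list(label = label), ev),
                                  class = "slide_label")
  if (!any_finer) return(mk("negative"))

  at_nbl <- rois[[nbl + 1]]
  if (!is.null(at_nbl) && nrow(at_nbl) > 0) {
    comp <- roi_components(at_nbl)
    exts <- vapply(unique(comp), function(cid)
      component_extent_mm(at_nbl, cid, comp, pyramid), numeric(1))
    ev$largest_extent_mm <- max(exts)
    mk <- function(label) structure(c(list(label = label), ev),
                                    class = "slide_label")
    if (max(exts) >= thresholds$macro_min_mm) return(mk("macro"))
  }

  if (is.null(cell_regions))
    stop_bad(paste0("sub-macro candidate regions present but no cell-level ",
                    "results supplied; run cell detection (points_to_density",
                    "/nms_peaks/cluster_points) on the candidate regions first"))
  if (is.function(cell_regions)) cell_regions <- cell_regions()
  if (length(cell_regions) > 0) {
    df <- regions_df(cell_regions)
    ev$max_cell_count <- max(df$cell_count)
    ev$max_region_diameter_mm <- max(df$diameter_um) / 1000
    mk <- function(label) structure(c(list(label = label), ev),
                                    class = "slide_label")
    if (any(df$diameter_um / 1000 >= thresholds$micro_min_mm |
            df$cell_count > thresholds$itc_max_cells))
      return(mk("micro"))
    if (sum(df$cell_count) >= 1) return(mk("itc"))
  }
  mk("negative")
}

#' @export
print.slide_label <- function(x, ...) {
  cat(sprintf("<slide_label> %s (extent %.3g mm, max region %.3g mm, max cells %d)\n",
              x$label, x$largest_extent_mm, x$max_region_diameter_mm,
              as.integer(x$max_cell_count)))
  invisible(x)
}
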