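#' Oracle cancer-cell regions for a synthetic slide
#'
#' The ground-truth cell detector: takes the planted nuclei lying inside the
#' lesion masks and clusters them into candidate regions.
#'
#' @param slide a `synthetic_slide`.
#' @param cutoff_um clustering cutoff in micrometres.
#' @export
oracle_cell_regions <- function(slide, cutoff_um = 50) {
  pts <- slide$nuclei_points[slide$nuclei_in_lesion, , drop = FALSE]
  cluster_points(pts, cutoff_um, slide$pyramid$pixel_size_um)
}

#' Detect cells inside sub-macro candidate regions with a trained model
#'
#' For every connected RoI component at the staging level whose extent is
#' below the macro cut-off, the corresponding level-0 window is tiled, the
#' density model is applied per tile, peaks are extracted by NMS and the
#' pooled points are clustered into candidate regions.
#'
#' @param pyramid the searched `pyramid`.
#' @param search_result value of [search_pyramid()].
#' @param cell_model trained density-head `deconvnet`.
#' @param thresholds [staging_thresholds()].
#' @param sigma kernel width the model was trained with (sets the NMS radius).
#' @param tile level-0 tile side (divisible by the pooling factor).
#' @param density_scale target scaling used at training time.
#' @param cutoff_um clustering cutoff in micrometres.
#' @return list of `cell_region` objects (level-0 coordinates).
#' @export
detect_cells_in_regions <- function(pyramid, search_result, cell_model,
                                    thresholds = staging_thresholds(),
                                    sigma = 3, tile = 48, density_scale = 100,
                                    cutoff_um = 50) {
  nbl <- thresholds$negative_break_level
  rois <- search_result$rois[[nbl + 1]]
  if (is.null(rois) || nrow(rois) == 0) return(list())
  comp <- roi_components(rois)
  pts_all <- matrix(numeric(0), 0, 2)
  peak1 <- density_scale / (2 * pi * sigma^2)  # single-kernel peak height
  for (cid in unique(comp)) {
    if (component_extent_mm(rois, cid, comp, pyramid) >= thresholds$macro_min_mm)
      next
    sel <- rois[comp == cid, , drop = FALSE]
    r0 <- map_coords(c(min(sel$row), min(sel$col)), nbl, 0)
    r1 <- map_coords(c(max(sel$row + sel$size), max(sel$col + sel$size)), nbl, 0)
    lvl0 <- pyramid$levels[[1]]
    r1 <- pmin(r1, dim(lvl0)[1:2])
    for (rr in seq(r0[1], r1[1] - 1, by = tile))
      for (cc in seq(r0[2], r1[2] - 1, by = tile)) {
        patch <- crop_level(lvl0, c(rr, cc), c(tile, tile))
        dm <- predict_density(cell_model, patch)
        pk <- nms_peaks(dm, radius = sigma, min_height = 0.1 * peak1)
        if (nrow(pk) > 0)
          pts_all <- rbind(pts_all, sweep(pk, 2, c(rr, cc), "+"))
      }
  }
  cluster_points(pts_all, cutoff_um, pyramid$pixel_size_um)
}

#' Screen one slide end to end
#'
#' Runs the coarse-to-fine search, cell detection on surviving sub-macro
#' candidates, and TNM-style staging.  With `oracle = TRUE` ground-truth
#' detectors (mask classifier, planted lesion nuclei) replace the trained
#' models, which validates the surrounding plumbing independently of
#' training quality.
#'
#' @param slide a `synthetic_slide` (or a `pyramid` when `oracle = FALSE`
#'   and models are supplied).
#' @param oracle use ground-truth detectors.
#' @param tissue_model,cell_model trained models (required when
#'   `oracle = FALSE`).
#' @param thresholds [staging_thresholds()].
#' @param t RoI confidence threshold.
#' @param patch_size search patch side.
#' @param stop_level finest searched level.
#' @return report list: `label`, `evidence`, `rois`, `evaluations`,
#'   `true_label` (when known).
#' @export
screen_slide <- function(slide, oracle = FALSE, tissue_model = NULL,
                         cell_model = NULL, thresholds = staging_thresholds(),
                         t = 0.5, patch_size = 32, stop_level = 1) {
  pyramid <- if (inherits(slide, "pyramid")) slide else slide$pyramid
  start_level <- n_levels(pyramid) - 1
  models <- if (oracle) make_oracle_classifier(pyramid)
            else make_net_classifier(tissue_model %||%
                   stop_bad("tissue_model required when oracle = FALSE"))
  sr <- search_pyramid(pyramid, models, t = t, start_level = start_level,
                       stop_level = stop_level, patch_size = patch_size)
  regions <- if (oracle) {
    if (inherits(slide, "synthetic_slide"))
      function() oracle_cell_regions(slide)
    else function() list()
  } else {
    function() detect_cells_in_regions(
      pyramid, sr, cell_model %||% stop_bad("cell_model required"), thresholds)
  }
  lab <- classify_slide(sr, regions, thresholds, pyramid)
  list(label = lab$label,
       evidence = lab[setdiff(names(lab), "label")],
       rois = sr$rois, evaluations = sr$evaluations,
       true_label = if (inherits(slide, "synthetic_slide")) slide$true_label
                    else NA_character_)
}

#' Write a screening report as YAML
#' @param report value of [screen_slide()].
#' @param path output file.
#' @export
write_report <- function(report, path) {
  roi_counts <- lapply(report$rois, function(r) if (is.null(r)) 0L else nrow(r))
  yaml::write_yaml(list(label = report$label,
                        true_label = report$true_label,
                        evidence = report$evidence,
                        rois_per_level = roi_counts,
                        classifier_evaluations = report$evaluations,
                        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                   path)
  invisible(path)
}
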