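#' Gaussian kernel specification for point-label density maps
#'
#' @param sigma isotropic standard deviation in pixels (used when `Sigma` is
#'   not given).
#' @param Sigma optional 2x2 symmetric positive-definite covariance.
#' @export
gaussian_kernel_spec <- function(sigma = 3, Sigma = NULL) {
  if (is.null(Sigma)) Sigma <- diag(2) * sigma^2
  Sigma <- as.matrix(Sigma)
  if (!isTRUE(all.equal(Sigma, t(Sigma))) || any(eigen(Sigma)$values <= 0))
    stop_bad("Sigma must be symmetric positive definite")
  list(Sigma = Sigma, sigma = sqrt(max(eigen(Sigma)$values)))
}

#' Render point labels as a density map
#'
#' Each point contributes a bivariate normal kernel
#' `P(x) = (2*pi)^(-1) |Sigma|^(-1/2) exp(-(x - mu)' Sigma^{-1} (x - mu) / 2)`
#' truncated at Mahalanobis distance 3 ("3 sigma") and rescaled after
#' truncation to unit mass, so the map integral equals the number of interior
#' points exactly.  The map is evaluated at pixel centers.  A `peak_normalized`
#' mode instead scales each kernel to peak value 1, yielding the 0-1 float
#' maps sometimes used for visualization; counting by integration is then
#' invalid and only peak enumeration counts objects.
#'
#' @param points `k x 2` matrix of 0-based `(row, col)`; may be empty.
#' @param shape `(h, w)` of the map.
#' @param spec [gaussian_kernel_spec()].
#' @param peak_normalized scale kernels to unit peak instead of unit mass.
#' @return `h x w` nonnegative matrix.
#' @export
points_to_density <- function(points, shape, spec = gaussian_kernel_spec(),
                              peak_normalized = FALSE) {
  out <- matrix(0, shape[1], shape[2])
  points <- as.matrix(points)
  if (length(points) == 0) return(out)
  if (any(points[, 1] < 0 | points[, 1] > shape[1] - 1 |
          points[, 2] < 0 | points[, 2] > shape[2] - 1))
    stop_bad("point outside the map bounds")
  Si <- solve(spec$Sigma)
  ext <- ceiling(3 * sqrt(max(diag(spec$Sigma)))) + 1L
  off <- expand.grid(dr = -ext:ext, dc = -ext:ext)
  maha <- Si[1, 1] * off$dr^2 + 2 * Si[1, 2] * off$dr * off$dc + Si[2, 2] * off$dc^2
  keep <- maha <= 9  # 3-sigma truncation
  off <- off[keep, ]
  dens <- exp(-maha[keep] / 2) / (2 * pi * sqrt(det(spec$Sigma)))
  dens <- if (peak_normalized) dens / max(dens) else dens / sum(dens)
  for (i in seq_len(nrow(points))) {
    rr <- round(points[i, 1]) + off$dr + 1
    cc <- round(points[i, 2]) + off$dc + 1
    ok <- rr >= 1 & rr <= shape[1] & cc >= 1 & cc <= shape[2]
    idx <- cbind(rr[ok], cc[ok])
    out[idx] <- out[idx] + dens[ok]
  }
  out
}

#' Non-maximum suppression peak extraction
#'
#' Returns pixels that are maxima of their Euclidean `radius`-neighbourhood,
#' are at least `min_height`, and have at least one strictly smaller
#' neighbour (so constant plateaus yield no peaks).  Tied maxima within one
#' radius of each other are resolved by keeping the lexicographically lowest
#' `(row, col)` and suppressing the others.
#'
#' @param density `h x w` matrix.
#' @param radius suppression radius in pixels (>= 1).
#' @param min_height minimum peak height.
#' @return `m x 2` matrix of 0-based `(row, col)` peaks in lexicographic
#'   order.
#' @export
nms_peaks <- function(density, radius = 3, min_height = 0) {
  stopifnot(radius >= 1)
  h <- nrow(density); w <- ncol(density)
  r <- ceiling(radius)
  off <- expand.grid(dr = -r:r, dc = -r:r)
  off <- off[off$dr^2 + off$dc^2 <= radius^2 & !(off$dr == 0 & off$dc == 0), ]
  cand <- which(density >= min_height, arr.ind = TRUE)
  peaks <- NULL
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    v <- density[p[1], p[2]]
    rr <- p[1] + off$dr; cc <- p[2] + off$dc
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    nb <- density[cbind(rr[ok], cc[ok])]
    if (length(nb) == 0) next
    if (all(v >= nb) && any(v > nb))
      peaks <- rbind(peaks, c(p[1], p[2], v))
  }
  if (is.null(peaks)) return(matrix(numeric(0), 0, 2))
  peaks <- peaks[order(peaks[, 1], peaks[, 2]), , drop = FALSE]
  keep <- rep(TRUE, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (!keep[i]) next
    if (i < nrow(peaks)) for (j in (i + 1):nrow(peaks)) {
      if (keep[j] && peaks[j, 3] == peaks[i, 3] &&
          sum((peaks[j, 1:2] - peaks[i, 1:2])^2) <= radius^2)
        keep[j] <- FALSE
    }
  }
  unname(peaks[keep, 1:2, drop = FALSE]) - 1  # back to 0-based
}

#' Count detected cells
#'
#' The detection count (number of NMS peaks) is the cell count.
#'
#' @param points matrix of detected points.
#' @export
count_cells <- function(points) nrow(as.matrix(points))

#' Cluster detected points into candidate regions
#'
#' Single-linkage clustering: two points belong to the same region iff a
#' chain of pairwise distances of at most `cutoff_um` connects them
#' (equivalently, connected components of the distance graph).  Region
#' diameter is the maximum pairwise member distance in micrometres.
#'
#' @param points `n x 2` matrix of 0-based pixel coordinates.
#' @param cutoff_um linkage cutoff in micrometres.
#' @param pixel_size_um physical pixel size at the points' level.
#' @return list of `cell_region` objects: `points`, `cell_count`,
#'   `diameter_um`.
#' @export
cluster_points <- function(points, cutoff_um = 50, pixel_size_um = 1) {
  stopifnot(cutoff_um > 0)
  points <- as.matrix(points)
  if (nrow(points) == 0) return(list())
  mk <- function(pts) {
    d <- if (nrow(pts) > 1) max(stats::dist(pts * pixel_size_um)) else 0
    structure(list(points = pts, cell_count = nrow(pts), diameter_um = d),
              class = "cell_region")
  }
  if (nrow(points) == 1) return(list(mk(points)))
  hc <- stats::hclust(stats::dist(points * pixel_size_um), method = "single")
  grp <- stats::cutree(hc, h = cutoff_um)
  lapply(sort(unique(grp)), function(g) mk(points[grp == g, , drop = FALSE]))
}

#' Summarize cell regions as a data frame
#' @param regions list of `cell_region` objects.
#' @export
regions_df <- function(regions) {
  data.frame(region_id = seq_along(regions),
             cell_count = vapply(regions, `[[`, numeric(1), "cell_count"),
             diameter_um = vapply(regions, `[[`, numeric(1), "diameter_um"))
}
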