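#' Image pyramid data model
#'
#' A pyramid is an ordered stack of RGB images in which level 0 is the finest
#' resolution and every subsequent level halves both spatial dimensions
#' (rounding up) while doubling the physical pixel size.  Optional per-level
#' binary masks carry ground-truth lesion annotations.
#'
#' All coordinates in this package are 0-based `(row, col)` offsets with
#' half-open pixel intervals; level 0 is the finest level.
#'
#' @param levels list of `h x w x 3` numeric arrays in `[0, 1]`, finest first.
#' @param pixel_size_um physical pixel size in micrometres at level 0.
#' @param masks optional list of logical matrices, one per level.
#' @return An object of class `pyramid`.
#' @export
new_pyramid <- function(levels, pixel_size_um, masks = NULL) {
  stopifnot(is.list(levels), length(levels) >= 1L, pixel_size_um > 0)
  levels <- lapply(levels, as_rgb)
  for (l in seq_along(levels)[-1]) {
    d0 <- dim(levels[[l - 1]])[1:2]
    d1 <- dim(levels[[l]])[1:2]
    if (!all(d1 == ceiling(d0 / 2)))
      stop_bad("level %d dims (%d x %d) are not the halved dims of level %d (%d x %d)",
               l - 1, d1[1], d1[2], l - 2, d0[1], d0[2])
  }
  if (!is.null(masks)) {
    stopifnot(length(masks) == length(levels))
    masks <- lapply(masks, function(m) m > 0)
  }
  structure(list(levels = levels, pixel_size_um = pixel_size_um, masks = masks),
            class = "pyramid")
}

#' @export
print.pyramid <- function(x, ...) {
  cat(sprintf("<pyramid> %d levels, %.3g um/px at level 0\n",
              length(x$levels), x$pixel_size_um))
  for (l in seq_along(x$levels) - 1L) {
    d <- dim(x$levels[[l + 1]])
    cat(sprintf("  level %d: %d x %d (%.3g um/px)%s\n", l, d[1], d[2],
                pixel_size_at(x, l), if (!is.null(x$masks)) " +mask" else ""))
  }
  invisible(x)
}

#' Number of levels in a pyramid
#' @param pyramid a `pyramid` object.
#' @export
n_levels <- function(pyramid) length(pyramid$levels)

#' Physical pixel size at a pyramid level
#'
#' The pixel size doubles at each coarser level.
#'
#' @param pyramid a `pyramid` object.
#' @param level 0-based level index.
#' @return Pixel size in micrometres.
#' @export
pixel_size_at <- function(pyramid, level) pyramid$pixel_size_um * 2^level

# 2x2 mean pooling; odd dims are padded by edge replication first.
downsample_mean <- function(img) {
  img <- as_rgb(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  if (h %% 2 == 1) img <- img[c(seq_len(h), h), , , drop = FALSE]
  if (w %% 2 == 1) img <- img[, c(seq_len(w), w), , drop = FALSE]
  h <- dim(img)[1]; w <- dim(img)[2]
  i1 <- seq(1, h, 2); i2 <- i1 + 1; j1 <- seq(1, w, 2); j2 <- j1 + 1
  (img[i1, j1, , drop = FALSE] + img[i2, j1, , drop = FALSE] +
   img[i1, j2, , drop = FALSE] + img[i2, j2, , drop = FALSE]) / 4
}

# Any-positive 2x downsampling for binary masks.
downsample_any <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  if (h %% 2 == 1) mask <- mask[c(seq_len(h), h), , drop = FALSE]
  if (w %% 2 == 1) mask <- mask[, c(seq_len(w), w), drop = FALSE]
  h <- nrow(mask); w <- ncol(mask)
  i1 <- seq(1, h, 2); i2 <- i1 + 1; j1 <- seq(1, w, 2); j2 <- j1 + 1
  (mask[i1, j1] | mask[i2, j1] | mask[i1, j2] | mask[i2, j2])
}

#' Build an image pyramid by repeated 2x downsampling
#'
#' Level 0 is the input image; each subsequent level is produced by 2x2
#' mean pooling (area averaging), so the mean intensity is conserved up to
#' edge padding.
#'
#' @param base_image `h x w x 3` (or `h x w`) numeric array in `[0, 1]`.
#' @param n_levels number of levels to build (>= 1).
#' @param pixel_size_um physical pixel size at level 0, micrometres.
#' @return A `pyramid` object.
#' @export
build_pyramid <- function(base_image, n_levels, pixel_size_um = 0.25) {
  stopifnot(n_levels >= 1)
  base_image <- as_rgb(base_image)
  if (n_levels - 1 > floor(log2(min(dim(base_image)[1:2]))))
    stop_bad("n_levels = %d exceeds log2 of the smallest image dimension", n_levels)
  levels <- vector("list", n_levels)
  levels[[1]] <- base_image
  for (l in seq_len(n_levels - 1))
    levels[[l + 1]] <- downsample_mean(levels[[l]])
  new_pyramid(levels, pixel_size_um)
}

#' Attach per-level ground-truth masks to a pyramid
#'
#' The level-0 mask is downsampled with the any-positive rule: a coarse pixel
#' is positive when any of its four children is positive.
#'
#' @param pyramid a `pyramid` object.
#' @param base_mask logical matrix matching level 0.
#' @export
attach_masks <- function(pyramid, base_mask) {
  stopifnot(all(dim(base_mask) == dim(pyramid$levels[[1]])[1:2]))
  masks <- vector("list", n_levels(pyramid))
  masks[[1]] <- base_mask > 0
  for (l in seq_len(n_levels(pyramid) - 1))
    masks[[l + 1]] <- downsample_any(masks[[l]])
  pyramid$masks <- masks
  pyramid
}

#' A patch of one pyramid level
#'
#' @param image `h x w x 3` numeric array.
#' @param level 0-based pyramid level the patch was cut from.
#' @param origin 0-based `(row, col)` of the patch's top-left pixel.
#' @param size `(h, w)` of the patch.
#' @param lci optional [location_code()] describing the patch's position in a
#'   quadtree search.
#' @export
new_patch <- function(image, level, origin, size = dim(image)[1:2], lci = NULL) {
  structure(list(image = image, level = level, origin = as.integer(origin),
                 size = as.integer(size), lci = lci), class = "patch")
}

patch_image <- function(x) if (inherits(x, "patch")) x$image else x

# Extract a zero-padded window from a level image; origin is 0-based.
crop_level <- function(level_image, origin, size) {
  h <- dim(level_image)[1]; w <- dim(level_image)[2]
  out <- array(0, c(size[1], size[2], dim(level_image)[3]))
  r <- (origin[1] + 1):min(origin[1] + size[1], h)
  c <- (origin[2] + 1):min(origin[2] + size[2], w)
  if (origin[1] < h && origin[2] < w && origin[1] >= 0 && origin[2] >= 0)
    out[seq_along(r), seq_along(c), ] <- level_image[r, c, , drop = FALSE]
  out
}

#' Tile a pyramid level into patches
#'
#' Patches are laid out on a row-major grid with the given stride.  When the
#' stride does not cover the level exactly, one extra partial patch per axis is
#' appended and zero-padded to `patch_size`.  With `tissue_only = TRUE` only
#' patches containing at least `tissue_fraction` tissue (by
#' [otsu_tissue_mask()]) are kept.
#'
#' @param pyramid a `pyramid` object.
#' @param level 0-based level to tile.
#' @param patch_size patch side length in pixels.
#' @param stride grid stride in pixels (> 0).
#' @param tissue_only keep only tissue-bearing patches.
#' @param tissue_fraction minimum tissue fraction for a patch to be kept.
#' @return List of `patch` objects in row-major order.
#' @export
tile_level <- function(pyramid, level, patch_size, stride = patch_size,
                       tissue_only = FALSE, tissue_fraction = 0.1) {
  if (stride <= 0) stop_bad("stride must be positive")
  img <- pyramid$levels[[level + 1]]
  d <- dim(img)[1:2]
  if (patch_size > min(d)) stop_bad("patch_size %d exceeds level dims", patch_size)
  starts <- function(dd) {
    s <- seq(0L, dd - patch_size, by = stride)
    if (max(s) + patch_size < dd) s <- c(s, max(s) + stride)
    s
  }
  rs <- starts(d[1]); cs <- starts(d[2])
  tis <- if (tissue_only) otsu_tissue_mask(img) else NULL
  out <- list()
  for (r in rs) for (cc in cs) {
    if (tissue_only) {
      rr <- (r + 1):min(r + patch_size, d[1])
      ci <- (cc + 1):min(cc + patch_size, d[2])
      if (mean(tis[rr, ci]) < tissue_fraction) next
    }
    out[[length(out) + 1L]] <-
      new_patch(crop_level(img, c(r, cc), c(patch_size, patch_size)),
                level, c(r, cc), c(patch_size, patch_size))
  }
  out
}

#' Map coordinates between pyramid levels
#'
#' Moving to a finer level multiplies by the level-spacing factor; moving to a
#' coarser level divides with flooring (pixel quantization).
#'
#' @param coords length-2 vector or `n x 2` matrix of 0-based `(row, col)`.
#' @param from_level,to_level 0-based level indices.
#' @export
map_coords <- function(coords, from_level, to_level) {
  m <- if (is.matrix(coords)) coords else matrix(coords, ncol = 2)
  d <- from_level - to_level
  out <- if (d >= 0) m * 2^d else floor(m / 2^(-d))
  if (is.matrix(coords)) out else as.numeric(out)
}
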