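#' Tissue segmentation by Otsu thresholding
#'
#' H&E tissue is chromatic while the slide background is achromatic white, so
#' the threshold is chosen on the HSV saturation channel by maximizing the
#' between-class variance, followed by a morphological closing (disc of
#' radius 2) to seal small holes.
#'
#' @param level_image `h x w x 3` numeric array in `[0, 1]`.
#' @return Logical matrix; `TRUE` marks tissue.
#' @export
otsu_tissue_mask <- function(level_image) {
  img <- as_rgb(level_image)
  if (length(img) == 0) stop_bad("empty image")
  mx <- pmax(img[, , 1], img[, , 2], img[, , 3])
  mn <- pmin(img[, , 1], img[, , 2], img[, , 3])
  sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
  if (diff(range(sat)) < 1e-8) {
    warning("constant image: no tissue found")
    return(matrix(FALSE, nrow(sat), ncol(sat)))
  }
  th <- EBImage::otsu(EBImage::Image(t(sat)), range = range(sat), levels = 256)
  mask <- sat > th
  brush <- EBImage::makeBrush(5, shape = "disc")
  t(EBImage::closing(EBImage::Image(t(mask * 1)), brush)) > 0.5
}

# Point-in-polygon with even-odd rule over all polygons plus boundary
# inclusion; px/py are pixel-center coordinates (vectors), poly an n x 2
# matrix of (row, col) vertices forming an implicitly closed ring.
pip_crossings <- function(py, px, poly) {
  n <- nrow(poly)
  cross <- integer(length(px))
  on_edge <- logical(length(px))
  for (e in seq_len(n)) {
    a <- poly[e, ]; b <- poly[if (e == n) 1L else e + 1L, ]
    y1 <- a[1]; x1 <- a[2]; y2 <- b[1]; x2 <- b[2]
    hit <- (y1 > py) != (y2 > py)
    if (any(hit)) {
      xin <- x1 + (py[hit] - y1) * (x2 - x1) / (y2 - y1)
      cross[hit] <- cross[hit] + (px[hit] < xin)
    }
    # on-segment test
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      on_edge <- on_edge | (abs(px - x1) < 1e-9 & abs(py - y1) < 1e-9)
    } else {
      tt <- ((px - x1) * dx + (py - y1) * dy) / len2
      d2 <- (px - (x1 + tt * dx))^2 + (py - (y1 + tt * dy))^2
      on_edge <- on_edge | (tt >= -1e-9 & tt <= 1 + 1e-9 & d2 < 1e-18)
    }
  }
  list(cross = cross, on_edge = on_edge)
}

#' Rasterize closed contours to a binary mask
#'
#' Pixels whose centers fall inside the contour set under the even-odd rule
#' (or exactly on a contour edge) are set; a polygon nested inside another
#' therefore punches a hole.
#'
#' @param contours list of `n x 2` matrices of 0-based `(row, col)` vertices;
#'   each polygon is an implicitly closed ring with at least 3 vertices.
#' @param shape `(h, w)` of the output mask.
#' @return Logical `h x w` matrix.
#' @export
contour_to_mask <- function(contours, shape) {
  mask <- matrix(FALSE, shape[1], shape[2])
  if (length(contours) == 0) return(mask)
  parity <- matrix(0L, shape[1], shape[2])
  edge <- matrix(FALSE, shape[1], shape[2])
  for (poly in contours) {
    poly <- as.matrix(poly)
    if (nrow(poly) >= 2 && all(poly[1, ] == poly[nrow(poly), ]))
      poly <- poly[-nrow(poly), , drop = FALSE]
    if (nrow(poly) < 3) stop_bad("open polygon: need at least 3 distinct vertices")
    rr <- range(poly[, 1]); cr <- range(poly[, 2])
    ri <- max(0, floor(rr[1])):min(shape[1] - 1, ceiling(rr[2]))
    ci <- max(0, floor(cr[1])):min(shape[2] - 1, ceiling(cr[2]))
    if (length(ri) == 0 || length(ci) == 0) next
    py <- rep(ri, times = length(ci))
    px <- rep(ci, each = length(ri))
    res <- pip_crossings(py, px, poly)
    idx <- cbind(py + 1L, px + 1L)
    parity[idx] <- parity[idx] + res$cross
    edge[idx] <- edge[idx] | res$on_edge
  }
  (parity %% 2L == 1L) | edge
}

#' Histogram-match a patch to a reference patch
#'
#' Per-channel quantile mapping: each pixel's empirical quantile in the patch
#' is replaced by the reference value at the same quantile.  Matching a patch
#' to itself is the identity.
#'
#' @param patch,reference `patch` objects or `h x w x 3` arrays.
#' @return Same type as `patch`.
#' @export
equalize_color <- function(patch, reference) {
  img <- as_rgb(patch_image(patch))
  ref <- as_rgb(patch_image(reference))
  out <- img
  for (ch in 1:3) {
    v <- img[, , ch]
    p <- stats::ecdf(v)(v)
    out[, , ch] <- stats::quantile(ref[, , ch], p, type = 1, names = FALSE)
  }
  if (inherits(patch, "patch")) { patch$image <- out; patch } else out
}

#' Rotate an image by multiples of 90 degrees
#' @param img `h x w x 3` array or matrix.
#' @param k number of counter-clockwise quarter turns (0-3).
#' @export
rotate90 <- function(img, k = 1) {
  k <- k %% 4
  if (k == 0) return(img)
  r1 <- function(x) {  # one CCW quarter turn: transpose then reverse rows
    if (length(dim(x)) == 3L) aperm(x, c(2, 1, 3))[rev(seq_len(dim(x)[2])), , , drop = FALSE]
    else t(x)[rev(seq_len(ncol(x))), , drop = FALSE]
  }
  for (i in seq_len(k)) img <- r1(img)
  img
}

resize_rgb <- function(img, h, w) {
  e <- EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color")
  aperm(EBImage::resize(e, w = w, h = h), c(2, 1, 3))
}

#' Classical patch augmentation
#'
#' Applies a random subset draw of the classical augmentations: right-angle
#' rotation, random cropping (with resize back), random scaling, and colour
#' jittering.  All randomness is governed by `seed`, so the same call is
#' bit-reproducible.
#'
#' @param patch `patch` object or `h x w x 3` array.
#' @param ops character subset of `c("crop", "color_jitter", "scale", "rotate")`.
#' @param seed integer RNG seed.
#' @return Same type as `patch`, same spatial size.
#' @export
augment_patch <- function(patch, ops, seed = 1) {
  known <- c("crop", "color_jitter", "scale", "rotate")
  if (length(ops) == 0) stop_bad("ops must be nonempty")
  bad <- setdiff(ops, known)
  if (length(bad)) stop_bad("unknown augmentation op: %s", paste(bad, collapse = ", "))
  img <- as_rgb(patch_image(patch))
  h <- dim(img)[1]; w <- dim(img)[2]
  img <- with_seed(seed, {
    if ("rotate" %in% ops) img <- rotate90(img, sample(0:3, 1))
    if ("crop" %in% ops) {
      f <- stats::runif(1, 0.8, 1)
      ch <- max(8L, round(f * h)); cw <- max(8L, round(f * w))
      r0 <- sample.int(h - ch + 1L, 1) - 1L
      c0 <- sample.int(w - cw + 1L, 1) - 1L
      img <- resize_rgb(img[r0 + seq_len(ch), c0 + seq_len(cw), , drop = FALSE], h, w)
    }
    if ("scale" %in% ops) {
      s <- stats::runif(1, 0.9, 1.1)
      sh <- max(8L, round(s * h)); sw <- max(8L, round(s * w))
      big <- resize_rgb(img, sh, sw)
      out <- array(0, c(h, w, 3))
      rr <- seq_len(min(h, sh)); cc <- seq_len(min(w, sw))
      out[rr, cc, ] <- big[rr, cc, , drop = FALSE]
      img <- out
    }
    if ("color_jitter" %in% ops) {
      gain <- stats::runif(3, 0.9, 1.1); off <- stats::runif(3, -0.05, 0.05)
      for (ch in 1:3) img[, , ch] <- img[, , ch] * gain[ch] + off[ch]
      img <- clamp01(img)
    }
    img
  })
  if (inherits(patch, "patch")) { patch$image <- img; patch } else img
}
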