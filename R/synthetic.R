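#' Specify a synthetic slide
#'
#' Describes a desk-scale synthetic pyramidal slide: a textured tissue blob on
#' a near-white background, planted lesions of controllable physical diameter,
#' and nuclei rendered as small dark ellipses with point and bounding-box
#' labels.
#'
#' @param base_height,base_width level-0 canvas size in pixels; must be
#'   divisible by `2^(n_levels - 1)`.
#' @param n_levels number of pyramid levels (>= 2).
#' @param pixel_size_um physical pixel size at level 0, in `[0.1, 1]`
#'   micrometres (real scanners sit near 0.25).
#' @param lesions list of [lesion_spec()] objects.
#' @param nuclei_density nuclei per square millimetre inside normal tissue;
#'   lesions are rendered at three times this density.
#' @param background_seed default RNG seed used by [generate_slide()].
#' @export
slide_spec <- function(base_height = 1024, base_width = base_height,
                       n_levels = 6, pixel_size_um = 0.25,
                       lesions = list(), nuclei_density = 500,
                       background_seed = 1) {
  if (n_levels < 2) stop_bad("n_levels must be >= 2")
  f <- 2^(n_levels - 1)
  if (base_height %% f != 0 || base_width %% f != 0)
    stop_bad("base dims must be divisible by 2^(n_levels - 1) = %d", f)
  if (pixel_size_um < 0.1 || pixel_size_um > 1)
    stop_bad("pixel_size_um must lie in [0.1, 1]")
  structure(list(base_height = as.integer(base_height),
                 base_width = as.integer(base_width),
                 n_levels = as.integer(n_levels),
                 pixel_size_um = pixel_size_um,
                 lesions = lesions, nuclei_density = nuclei_density,
                 background_seed = background_seed),
            class = "slide_spec")
}

#' Specify a planted lesion
#'
#' @param center 0-based `(row, col)` of the lesion center at level 0.
#' @param diameter_um physical diameter in micrometres.
#' @param shape_irregularity boundary wobble amplitude in `[0, 1]`; 0 gives a
#'   circular lesion.
#' @param cell_count optional explicit number of tumor cells; used for
#'   ITC-scale lesions, which are defined by cell count rather than area.
#' @export
lesion_spec <- function(center, diameter_um, shape_irregularity = 0,
                        cell_count = NULL) {
  stopifnot(diameter_um > 0, shape_irregularity >= 0, shape_irregularity <= 1)
  structure(list(center = as.numeric(center), diameter_um = diameter_um,
                 shape_irregularity = shape_irregularity,
                 cell_count = cell_count), class = "lesion_spec")
}

#' Center point of a bounding box
#'
#' Converts a bounding-box nucleus label to a point label by averaging the
#' four coordinates.
#'
#' @param bbox `(r0, c0, r1, c1)` with `r0 <= r1`, `c0 <= c1`.
#' @return `(row, col)` center.
#' @export
bbox_to_point <- function(bbox) {
  if (bbox[1] > bbox[3] || bbox[2] > bbox[4])
    stop_bad("inverted bounding box")
  c((bbox[1] + bbox[3]) / 2, (bbox[2] + bbox[4]) / 2)
}

# Smooth scalar noise field in [0, 1]: coarse uniform grid upsampled with
# bilinear interpolation.  Multiple octaves are mixed by the callers.
smooth_noise <- function(h, w, cell) {
  gh <- max(2L, ceiling(h / cell)); gw <- max(2L, ceiling(w / cell))
  g <- matrix(stats::runif(gh * gw), gh, gw)
  if (h %% 2 == 0 && w %% 2 == 0 && h >= 2048) {
    # interpolate at half resolution, then pixel-replicate (texture detail
    # below two pixels is irrelevant at slide scale)
    half <- t(as.matrix(EBImage::resize(EBImage::Image(t(g)),
                                        w = w %/% 2, h = h %/% 2)))
    return(half[rep(seq_len(h %/% 2), each = 2), rep(seq_len(w %/% 2), each = 2)])
  }
  t(as.matrix(EBImage::resize(EBImage::Image(t(g)), w = w, h = h)))
}

# Angular boundary-wobble function for star-shaped regions; returns a
# function theta -> radius multiplier in [1 - amp, 1 + amp].
make_wobble <- function(amplitude, n_harmonics = 4) {
  if (amplitude <= 0) return(function(theta) rep(1, length(theta)))
  k <- 2:(1 + n_harmonics)
  a <- stats::runif(n_harmonics, -1, 1)
  phi <- stats::runif(n_harmonics, 0, 2 * pi)
  norm <- max(abs(colSums(a * sin(outer(k, seq(0, 2 * pi, length.out = 720)) +
                                    phi))), 1e-9)
  function(theta) {
    s <- colSums(a * sin(outer(k, theta) + phi))
    1 + amplitude * s / norm
  }
}

# Rasterize a star-shaped (wobbly) disk into a logical mask window; the
# boundary angle is only evaluated in the annulus the wobble can reach.
rasterize_blob <- function(center, radius_px, wobble, h, w, amplitude = 0.25) {
  pad <- ceiling(radius_px * (1 + amplitude)) + 2
  r0 <- floor(center[1] - pad); r1 <- ceiling(center[1] + pad)
  c0 <- floor(center[2] - pad); c1 <- ceiling(center[2] + pad)
  out_of_canvas <- r0 < 0 || c0 < 0 || r1 > h - 1 || c1 > w - 1
  rs <- max(r0, 0):min(r1, h - 1); cs <- max(c0, 0):min(c1, w - 1)
  dr <- rs - center[1]; dc <- cs - center[2]
  D <- sqrt(outer(dr^2, dc^2, "+"))
  inside <- D <= radius_px * (1 - amplitude)
  band <- which(!inside & D <= radius_px * (1 + amplitude))
  if (length(band)) {
    br <- dr[((band - 1) %% length(dr)) + 1]
    bc <- dc[((band - 1) %/% length(dr)) + 1]
    inside[band] <- D[band] <= radius_px * wobble(atan2(br, bc))
  }
  th <- seq(0, pi, length.out = 360)
  extent_px <- radius_px * max(wobble(th) + wobble(th + pi))
  list(rows = rs, cols = cs, inside = inside,
       out_of_canvas = out_of_canvas && any(inside[row(inside) %in% c(1, nrow(inside)) |
                                                   col(inside) %in% c(1, ncol(inside))]),
       extent_px = extent_px)
}

NUCLEUS_COLOR <- c(0.30, 0.18, 0.45)
TISSUE_COLOR <- c(0.84, 0.62, 0.75)
LESION_TINT <- c(0.78, 0.60, 0.80)

# Draw filled nucleus ellipses onto img (modified in place semantics via
# return); centers is n x 2 0-based.  Semi-axes drawn in [3, 5] px.
draw_nuclei <- function(img, centers) {
  h <- dim(img)[1]; w <- dim(img)[2]
  n <- nrow(centers)
  if (n == 0) return(list(img = img, bboxes = matrix(numeric(0), 0, 4)))
  off <- expand.grid(di = -5:5, dj = -5:5)
  bboxes <- matrix(0, n, 4)
  hw <- h * w
  for (i in seq_len(n)) {
    a <- stats::runif(1, 3, 5); b <- stats::runif(1, 3, 5)
    shade <- stats::runif(1, 0.8, 1.15)
    sel <- (off$di / a)^2 + (off$dj / b)^2 <= 1
    rr <- centers[i, 1] + off$di[sel] + 1  # 1-based
    cc <- centers[i, 2] + off$dj[sel] + 1
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    lin <- rr[ok] + (cc[ok] - 1) * h
    for (ch in 1:3)
      img[lin + (ch - 1) * hw] <- clamp01(NUCLEUS_COLOR[ch] * shade)
    ar <- round(a); br <- round(b)
    bboxes[i, ] <- c(centers[i, 1] - ar, centers[i, 2] - br,
                     centers[i, 1] + ar, centers[i, 2] + br)
  }
  list(img = img, bboxes = bboxes)
}

ord_label <- function(x) factor(x, levels = c("negative", "itc", "micro", "macro"),
                                ordered = TRUE)

# Lesion class from planted physical extent and cell count, using the
# clinical TNM cut-offs (see staging_thresholds()).
lesion_class <- function(extent_mm, cells, th = staging_thresholds()) {
  if (extent_mm > th$macro_min_mm) return("macro")
  if (extent_mm >= th$micro_min_mm || cells > th$itc_max_cells) return("micro")
  if (cells >= 1) return("itc")
  "negative"
}

#' Generate a fully labelled synthetic slide
#'
#' Renders the tissue blob, lesions and nuclei described by `spec` at level 0,
#' builds the image pyramid by 2x mean pooling and the lesion-mask pyramid by
#' any-positive pooling, and derives the slide-level ground-truth label from
#' the planted lesions via the TNM staging cut-offs.  Identical `(spec, seed)`
#' yield bit-identical output.
#'
#' @param spec a [slide_spec()].
#' @param seed RNG seed; defaults to `spec$background_seed`.
#' @return A `synthetic_slide`: list with `pyramid` (masks attached),
#'   `nuclei_points` (n x 2, level-0 0-based), `nuclei_bboxes` (n x 4),
#'   `nuclei_in_lesion` (logical), `lesions` (data frame with per-lesion
#'   extent, cell count and class) and `true_label`.
#' @export
generate_slide <- function(spec, seed = spec$background_seed) {
  stopifnot(inherits(spec, "slide_spec"))
  with_seed(seed, {
    h <- spec$base_height; w <- spec$base_width
    px_mm2 <- (spec$pixel_size_um / 1000)^2

    # tissue blob: wobbly ellipse computed at reduced resolution
    qs <- if (h %% 4 == 0 && w %% 4 == 0) 4L else 2L
    qh <- h %/% qs; qw <- w %/% qs
    wob <- make_wobble(0.06)
    dr <- (seq_len(qh) - 0.5) * qs - h / 2
    dc <- (seq_len(qw) - 0.5) * qs - w / 2
    ry <- 0.42 * h; rx <- 0.42 * w
    R <- sqrt(outer((dr / ry)^2, (dc / rx)^2, "+"))
    TH <- atan2(outer(dr, rep(1, qw)), outer(rep(1, qh), dc))
    qmask <- R <= wob(as.vector(TH)); dim(qmask) <- dim(R)
    tissue <- qmask[rep(seq_len(qh), each = qs), rep(seq_len(qw), each = qs)]

    fine <- matrix(stats::runif(h * w), h, w)
    tex <- 0.6 * smooth_noise(h, w, 16) + 0.4 * smooth_noise(h, w, 64)
    img <- array(0, c(h, w, 3))
    ti <- which(tissue)
    bg <- 0.965 + 0.025 * fine
    tex_t <- (tex[ti] - 0.5) * 0.10 + (fine[ti] - 0.5) * 0.04
    for (ch in 1:3) {
      plane <- bg
      plane[ti] <- TISSUE_COLOR[ch] + tex_t
      img[, , ch] <- plane
    }

    lesion_total <- matrix(FALSE, h, w)
    lesion_members <- list()
    lesion_rows <- list()
    for (li in seq_along(spec$lesions)) {
      ls <- spec$lesions[[li]]
      radius_px <- ls$diameter_um / (2 * spec$pixel_size_um)
      blob <- rasterize_blob(ls$center, radius_px,
                             make_wobble(0.25 * ls$shape_irregularity), h, w,
                             amplitude = max(0.25 * ls$shape_irregularity, 0.02))
      if (blob$out_of_canvas)
        stop_bad("lesion %d (diameter %.0f um at %.0f,%.0f) extends outside the canvas",
                 li, ls$diameter_um, ls$center[1], ls$center[2])
      sub <- tissue[blob$rows + 1, blob$cols + 1]
      if (any(blob$inside & !sub))
        stop_bad("lesion %d does not lie inside the tissue region", li)
      idx <- which(blob$inside)
      rr <- blob$rows[((idx - 1) %% length(blob$rows)) + 1] + 1
      cc <- blob$cols[((idx - 1) %/% length(blob$rows)) + 1] + 1
      lin <- rr + (cc - 1) * h
      for (ch in 1:3)
        img[lin + (ch - 1) * h * w] <- img[lin + (ch - 1) * h * w] * LESION_TINT[ch] +
          (tex[lin] - 0.5) * 0.05
      mask_i <- matrix(FALSE, h, w); mask_i[lin] <- TRUE
      lesion_total[lin] <- TRUE
      lesion_members[[li]] <- lin
      lesion_rows[[li]] <- list(extent_mm = blob$extent_px * spec$pixel_size_um / 1000,
                                area_px = length(lin))
    }

    # nuclei: deterministic counts (rounded density * area) for label stability
    margin <- 6L
    interior <- function(lin) {
      r <- ((lin - 1) %% h) + 1; c <- ((lin - 1) %/% h) + 1
      lin[r > margin & r <= h - margin & c > margin & c <= w - margin]
    }
    centers <- matrix(numeric(0), 0, 2)
    in_lesion <- logical(0)
    lesion_cells <- integer(length(spec$lesions))
    norm_idx <- which(tissue & !lesion_total)
    n_bg <- min(round(length(norm_idx) * px_mm2 * spec$nuclei_density),
                length(norm_idx))
    if (n_bg > 0) {
      pick <- interior(norm_idx[sample.int(length(norm_idx), n_bg)])
      centers <- rbind(centers, cbind(((pick - 1) %% h), ((pick - 1) %/% h)))
      in_lesion <- c(in_lesion, rep(FALSE, length(pick)))
    }
    for (li in seq_along(spec$lesions)) {
      ls <- spec$lesions[[li]]
      n_i <- ls$cell_count %||%
        round(length(lesion_members[[li]]) * px_mm2 * 3 * spec$nuclei_density)
      if (is.null(ls$cell_count) && length(lesion_members[[li]]) > 1e5) {
        # large lesion: sample with headroom, then drop border-adjacent picks
        pick <- interior(lesion_members[[li]][sample.int(
          length(lesion_members[[li]]), min(ceiling(1.2 * n_i),
                                            length(lesion_members[[li]])))])
        pick <- pick[seq_len(min(n_i, length(pick)))]
      } else {
        les_idx <- interior(lesion_members[[li]])
        pick <- les_idx[sample.int(length(les_idx), min(n_i, length(les_idx)))]
      }
      lesion_cells[li] <- length(pick)
      if (length(pick) > 0) {
        centers <- rbind(centers, cbind(((pick - 1) %% h), ((pick - 1) %/% h)))
        in_lesion <- c(in_lesion, rep(TRUE, length(pick)))
      }
    }
    drawn <- draw_nuclei(img, centers)
    img <- drawn$img  # all drawn values already lie in [0, 1]

    pyr <- build_pyramid(img, spec$n_levels, spec$pixel_size_um)
    pyr <- attach_masks(pyr, lesion_total)

    lesions_df <- data.frame(
      center_row = vapply(spec$lesions, function(l) l$center[1], numeric(1)),
      center_col = vapply(spec$lesions, function(l) l$center[2], numeric(1)),
      diameter_um = vapply(spec$lesions, function(l) l$diameter_um, numeric(1)),
      extent_mm = vapply(lesion_rows, function(l) l$extent_mm, numeric(1)),
      area_mm2 = vapply(lesion_rows, function(l) l$area_px, numeric(1)) * px_mm2,
      cell_count = lesion_cells,
      class = vapply(seq_along(spec$lesions), function(i)
        lesion_class(lesion_rows[[i]]$extent_mm, lesion_cells[i]), character(1)))
    true_label <- if (nrow(lesions_df) == 0) "negative" else
      as.character(max(ord_label(c("negative", lesions_df$class))))

    structure(list(pyramid = pyr, tissue_mask = tissue,
                   nuclei_points = centers, nuclei_bboxes = drawn$bboxes,
                   nuclei_in_lesion = in_lesion, lesions = lesions_df,
                   true_label = true_label, spec = spec, seed = seed),
              class = "synthetic_slide")
  })
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cat(sprintf("<synthetic_slide> %d x %d px, %d levels, label = %s, %d nuclei, %d lesion(s)\n",
              x$spec$base_height, x$spec$base_width, x$spec$n_levels,
              x$true_label, nrow(x$nuclei_points), nrow(x$lesions)))
  invisible(x)
}

#' Class-typical slide specification
#'
#' Draws a [slide_spec()] whose planted lesion is typical for the requested
#' staging class: macrometastases 2.3-3.1 mm on a 4.096 mm canvas,
#' micrometastases 0.3-0.7 mm, ITCs defined by an explicit cell count (30-150
#' cells within < 0.2 mm), and negatives with no lesion.  Pixel size is fixed
#' at 1 um so that millimetre-scale lesions fit a desk-scale canvas.
#'
#' @param class one of `"negative"`, `"itc"`, `"micro"`, `"macro"`.
#' @param seed RNG seed used both to draw the lesion parameters and as the
#'   slide's `background_seed`.
#' @export
slide_spec_for_class <- function(class = c("negative", "itc", "micro", "macro"),
                                 seed = 1) {
  class <- match.arg(class)
  with_seed(seed + 90021, {
    base <- if (class == "macro") 4096L else 1024L
    ctr <- c(base / 2, base / 2)
    lesions <- switch(class,
      negative = list(),
      itc = list(lesion_spec(ctr + stats::runif(2, -80, 80),
                             diameter_um = stats::runif(1, 110, 160),
                             shape_irregularity = stats::runif(1, 0, 0.2),
                             cell_count = sample(30:150, 1))),
      micro = list(lesion_spec(ctr + stats::runif(2, -20, 20),
                               diameter_um = stats::runif(1, 300, 700),
                               shape_irregularity = stats::runif(1, 0, 0.2))),
      macro = list(lesion_spec(ctr + stats::runif(2, -100, 100),
                               diameter_um = stats::runif(1, 2300, 3100),
                               shape_irregularity = stats::runif(1, 0, 0.15))))
    slide_spec(base_height = base, base_width = base, n_levels = 6,
               pixel_size_um = 1, lesions = lesions, nuclei_density = 500,
               background_seed = seed)
  })
}

# ---- patch-level training-set generators -------------------------------

render_texture_patch <- function(size, tumor, pixel_size_um, nuclei_density) {
  fine <- matrix(stats::runif(size * size), size, size)
  tex <- 0.6 * smooth_noise(size, size, 8) + 0.4 * smooth_noise(size, size, 24)
  img <- array(0, c(size, size, 3))
  for (ch in 1:3)
    img[, , ch] <- TISSUE_COLOR[ch] + (tex - 0.5) * 0.10 + (fine - 0.5) * 0.04
  dens <- nuclei_density
  if (tumor) {
    for (ch in 1:3) img[, , ch] <- img[, , ch] * LESION_TINT[ch] + (tex - 0.5) * 0.05
    dens <- 3 * nuclei_density
  }
  n <- round(size^2 * (pixel_size_um / 1000)^2 * dens)
  pts <- if (n > 0)
    cbind(stats::runif(n, 6, size - 7), stats::runif(n, 6, size - 7))
  else matrix(numeric(0), 0, 2)
  drawn <- draw_nuclei(img, pts)
  list(image = clamp01(drawn$img), points = pts)
}

#' Generate labelled tumor/normal texture patches
#'
#' Desk-scale training material for the patch classifier head: tumor patches
#' carry the darker lesion tint and a threefold nuclei density.
#'
#' @param n_tumor,n_normal patch counts per class.
#' @param size patch side length in pixels.
#' @param pixel_size_um physical pixel size.
#' @param nuclei_density nuclei per square millimetre in normal tissue.
#' @param seed RNG seed.
#' @return list with `images` (list of arrays) and `labels` (1 = tumor).
#' @export
generate_patch_set <- function(n_tumor = 100, n_normal = 100, size = 64,
                               pixel_size_um = 1, nuclei_density = 500,
                               seed = 1) {
  with_seed(seed, {
    labs <- c(rep(1L, n_tumor), rep(0L, n_normal))
    imgs <- lapply(labs, function(y)
      render_texture_patch(size, y == 1L, pixel_size_um, nuclei_density)$image)
    list(images = imgs, labels = labs)
  })
}

#' Generate nuclei patches with point labels
#'
#' Patches of normal tissue texture with a known number of planted nuclei,
#' used to train and evaluate density-map cell detection and counting.
#'
#' @param n number of patches.
#' @param size patch side in pixels.
#' @param count_range inclusive range of nuclei counts per patch.
#' @param min_sep minimum separation between nuclei centers in pixels.
#' @param seed RNG seed.
#' @return list with `images` and `points` (list of `k x 2` 0-based matrices).
#' @export
generate_cell_patch_set <- function(n = 80, size = 48, count_range = c(3, 12),
                                    min_sep = 7, seed = 1) {
  with_seed(seed, {
    images <- vector("list", n); points <- vector("list", n)
    for (i in seq_len(n)) {
      k <- sample(count_range[1]:count_range[2], 1)
      pts <- matrix(numeric(0), 0, 2)
      guard <- 0
      while (nrow(pts) < k && guard < 500) {
        cand <- stats::runif(2, 6, size - 7)
        if (nrow(pts) == 0 ||
            min(sqrt(colSums((t(pts) - cand)^2))) >= min_sep)
          pts <- rbind(pts, cand)
        guard <- guard + 1
      }
      fine <- matrix(stats::runif(size * size), size, size)
      tex <- 0.6 * smooth_noise(size, size, 8) + 0.4 * smooth_noise(size, size, 24)
      img <- array(0, c(size, size, 3))
      for (ch in 1:3)
        img[, , ch] <- TISSUE_COLOR[ch] + (tex - 0.5) * 0.10 + (fine - 0.5) * 0.04
      drawn <- draw_nuclei(img, pts)
      images[[i]] <- clamp01(drawn$img); points[[i]] <- pts
    }
    list(images = images, points = points)
  })
}

#' Generate patch sequences with planted tumor mass
#'
#' Row-major sequences of textured patches, each with a wobbly tumor blob (or
#' none); ground truth is the binary tumor mask per patch and its mass (pixel
#' sum), the currency of the LSTM-fused counting loss.
#'
#' @param n_seq number of sequences.
#' @param seq_len patches per sequence.
#' @param size patch side in pixels.
#' @param p_empty probability a patch carries no tumor.
#' @param seed RNG seed.
#' @export
generate_mass_sequences <- function(n_seq = 20, seq_len = 4, size = 32,
                                    p_empty = 0.3, seed = 1) {
  with_seed(seed, {
    lapply(seq_len(n_seq), function(s) {
      patches <- vector("list", seq_len); gt_maps <- vector("list", seq_len)
      for (i in seq_len(seq_len)) {
        fine <- matrix(stats::runif(size * size), size, size)
        tex <- 0.6 * smooth_noise(size, size, 8) + 0.4 * smooth_noise(size, size, 24)
        img <- array(0, c(size, size, 3))
        for (ch in 1:3)
          img[, , ch] <- TISSUE_COLOR[ch] + (tex - 0.5) * 0.10 + (fine - 0.5) * 0.04
        mask <- matrix(0, size, size)
        if (stats::runif(1) > p_empty) {
          ctr <- stats::runif(2, 0.3 * size, 0.7 * size)
          rad <- stats::runif(1, 0.15, 0.35) * size
          blob <- rasterize_blob(ctr, rad, make_wobble(0.2), size, size)
          sub <- matrix(FALSE, size, size)
          sub[blob$rows + 1, blob$cols + 1] <- blob$inside
          mask[sub] <- 1
          for (ch in 1:3) {
            pl <- img[, , ch]; pl[sub] <- pl[sub] * LESION_TINT[ch]
            img[, , ch] <- pl
          }
        }
        patches[[i]] <- clamp01(img); gt_maps[[i]] <- mask
      }
      list(patches = patches, gt_maps = gt_maps,
           gt_counts = vapply(gt_maps, sum, numeric(1)))
    })
  })
}
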