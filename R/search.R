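#' Quadtree location codes (LCI)
#'
#' A location code addresses one patch at one level of the pyramid search.
#' The search starts from a grid of root patches at `start_level`; each
#' descent appends one quadrant symbol (`0` = NW, `1` = NE, `2` = SW,
#' `3` = SE), so a code of length `d` addresses a patch at level
#' `start_level - d`.  All patches share the same pixel side length, so the
#' four children of a patch tile its footprint exactly at double resolution.
#'
#' @param root 0-based `(row, col)` grid indices of the root patch at
#'   `start_level`.
#' @param code character string over `{0,1,2,3}`.
#' @param start_level coarsest (starting) level of the search.
#' @export
location_code <- function(root = c(0L, 0L), code = "", start_level = 0L) {
  if (nchar(code) > 0 && grepl("[^0-3]", code))
    stop_bad("malformed location code '%s': symbols must be 0-3", code)
  if (nchar(code) > start_level)
    stop_bad("code longer than start_level allows")
  structure(list(root = as.integer(root), code = code,
                 start_level = as.integer(start_level)),
            class = "location_code")
}

#' @export
format.location_code <- function(x, ...)
  sprintf("L%d@%d,%d:%s", lci_level(x), x$root[1], x$root[2], x$code)

#' @export
print.location_code <- function(x, ...) {
  cat("<lci>", format(x), "\n"); invisible(x)
}

#' Level addressed by a location code
#' @param lci a [location_code()].
#' @export
lci_level <- function(lci) lci$start_level - nchar(lci$code)

#' The four child codes one level finer
#'
#' Children carry quadrant symbols 0-3 and tile the parent footprint exactly.
#'
#' @param lci a [location_code()].
#' @export
lci_children <- function(lci) {
  if (lci_level(lci) <= 0)
    stop_bad("cannot descend below level 0")
  lapply(c("0", "1", "2", "3"), function(q)
    location_code(lci$root, paste0(lci$code, q), lci$start_level))
}

QUAD_OFFSET <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), ncol = 2, byrow = TRUE)

#' Decode a location code to level and pixel origin
#'
#' Each descent doubles the parent origin and adds the quadrant offset times
#' `patch_size`.
#'
#' @param lci a [location_code()].
#' @param patch_size patch side in pixels (identical across levels).
#' @return list(level, origin) with 0-based `(row, col)` origin.
#' @export
lci_to_coords <- function(lci, patch_size) {
  origin <- lci$root * patch_size
  if (nchar(lci$code) > 0) {
    for (s in strsplit(lci$code, "")[[1]]) {
      q <- as.integer(s)
      origin <- 2 * origin + QUAD_OFFSET[q + 1, ] * patch_size
    }
  }
  list(level = lci_level(lci), origin = as.integer(origin))
}

#' Encode level and origin back into a location code
#'
#' Inverse of [lci_to_coords()]: quadrant symbols are recovered from the
#' parity of `origin / patch_size` while ascending to `start_level`.
#'
#' @param level level of the patch.
#' @param origin 0-based `(row, col)` pixel origin; must be a multiple of
#'   `patch_size`.
#' @param start_level coarsest level of the search.
#' @param patch_size patch side in pixels.
#' @export
lci_from_coords <- function(level, origin, start_level, patch_size) {
  if (any(origin %% patch_size != 0))
    stop_bad("origin must be aligned to the patch grid")
  g <- as.integer(origin) %/% patch_size
  code <- character(0)
  for (l in seq_len(start_level - level)) {
    qr <- g %% 2L
    # quadrant symbol: row parity selects S (2/3), col parity selects E (1/3)
    code <- c(as.character(2L * qr[1] + qr[2]), code)
    g <- g %/% 2L
  }
  location_code(g, paste(code, collapse = ""), start_level)
}

#' Coarse-to-fine pyramid search with location codes
#'
#' Evaluates a per-level cancer classifier on every tissue patch of the
#' coarsest searched level; any patch whose confidence reaches the level's
#' threshold becomes a region of interest (RoI) and its four quadrant
#' children are queued at the next finer level, while sub-threshold patches
#' are pruned together with their entire subtree.  The search stops at
#' `stop_level`.
#'
#' @param pyramid a `pyramid` object.
#' @param models a single classifier model or a list with one model per
#'   level index (`models[[level + 1]]`); a model is a list holding a
#'   `classify(patch)` function returning a confidence in `[0, 1]`.
#' @param t RoI threshold; scalar or per-level numeric vector indexed
#'   `t[level + 1]`.
#' @param start_level,stop_level 0-based coarsest/finest searched levels
#'   (`start_level > stop_level >= 0`).
#' @param patch_size patch side in pixels; `start_level` dims must be
#'   divisible by it.
#' @param tissue_only evaluate only tissue-bearing root patches.
#' @param tissue_fraction minimum tissue fraction for a root patch.
#' @return list with `rois` (list of per-level data frames:
#'   `level, lci, row, col, size, confidence`) and `evaluations`
#'   (classifier call count).
#' @export
search_pyramid <- function(pyramid, models, t = 0.5, start_level,
                           stop_level = 1, patch_size = 32,
                           tissue_only = TRUE, tissue_fraction = 0.1) {
  L <- n_levels(pyramid)
  if (!(start_level > stop_level && stop_level >= 0 && start_level < L))
    stop_bad("need start_level > stop_level >= 0 within the pyramid")
  get_model <- function(level) {
    m <- if (!is.null(models$classify)) models else models[[level + 1]]
    if (is.null(m) || is.null(m$classify))
      stop_bad("no classifier model for level %d", level)
    m
  }
  for (l in stop_level:start_level) get_model(l)  # fail fast
  thr <- function(level) if (length(t) == 1) t else t[level + 1]

  d0 <- dim(pyramid$levels[[start_level + 1]])[1:2]
  if (any(d0 %% patch_size != 0))
    stop_bad("start level dims must be divisible by patch_size")
  grid <- d0 %/% patch_size

  tis <- if (tissue_only) otsu_tissue_mask(pyramid$levels[[start_level + 1]]) else NULL
  frontier <- list()
  for (gr in 0:(grid[1] - 1)) for (gc in 0:(grid[2] - 1)) {
    if (tissue_only) {
      rr <- gr * patch_size + seq_len(patch_size)
      cc <- gc * patch_size + seq_len(patch_size)
      if (mean(tis[rr, cc]) < tissue_fraction) next
    }
    frontier[[length(frontier) + 1L]] <-
      location_code(c(gr, gc), "", start_level)
  }

  hits <- vector("list", 4096); nh <- 0L
  evals <- 0L
  qpos <- 1L
  while (qpos <= length(frontier)) {
    lci <- frontier[[qpos]]; qpos <- qpos + 1L
    dec <- lci_to_coords(lci, patch_size)
    level <- dec$level
    img <- pyramid$levels[[level + 1]]
    p <- new_patch(crop_level(img, dec$origin, c(patch_size, patch_size)),
                   level, dec$origin, c(patch_size, patch_size), lci = lci)
    conf <- get_model(level)$classify(p)
    evals <- evals + 1L
    if (conf >= thr(level)) {
      nh <- nh + 1L
      if (nh > length(hits)) hits <- c(hits, vector("list", length(hits)))
      hits[[nh]] <- data.frame(level = level, lci = format(lci),
                               row = dec$origin[1], col = dec$origin[2],
                               size = patch_size, confidence = conf)
      if (level > stop_level)
        for (ch in lci_children(lci)) frontier[[length(frontier) + 1L]] <- ch
    }
  }
  flat <- if (nh > 0) do.call(rbind, hits[seq_len(nh)]) else NULL
  rois <- lapply(seq_len(L) - 1L, function(l)
    if (!is.null(flat) && any(flat$level == l))
      flat[flat$level == l, , drop = FALSE] else NULL)
  names(rois) <- sprintf("level_%d", seq_len(L) - 1)
  list(rois = rois, evaluations = evals, patch_size = patch_size,
       start_level = start_level, stop_level = stop_level)
}

#' Exhaustive single-level scan (brute-force reference)
#'
#' Evaluates the classifier on every aligned patch of one level and returns
#' the positives, for validating the pruned search.
#'
#' @inheritParams search_pyramid
#' @param level the level to scan.
#' @export
scan_level <- function(pyramid, models, level, t = 0.5, patch_size = 32) {
  img <- pyramid$levels[[level + 1]]
  d <- dim(img)[1:2]
  m <- if (!is.null(models$classify)) models else models[[level + 1]]
  out <- NULL
  for (r in seq(0, d[1] - patch_size, by = patch_size))
    for (cc in seq(0, d[2] - patch_size, by = patch_size)) {
      p <- new_patch(crop_level(img, c(r, cc), c(patch_size, patch_size)),
                     level, c(r, cc), c(patch_size, patch_size))
      conf <- m$classify(p)
      if (conf >= t)
        out <- rbind(out, data.frame(level = level, row = r, col = cc,
                                     size = patch_size, confidence = conf))
    }
  out
}

# 4-connected components over the patch grid; rois is one level's data frame.
roi_components <- function(rois) {
  if (is.null(rois) || nrow(rois) == 0) return(integer(0))
  g <- cbind(rois$row %/% rois$size, rois$col %/% rois$size)
  n <- nrow(g)
  comp <- integer(n)
  key <- paste(g[, 1], g[, 2])
  lut <- stats::setNames(seq_len(n), key)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (comp[j] > 0) next
      comp[j] <- cid
      nb <- rbind(g[j, ] + c(1, 0), g[j, ] - c(1, 0),
                  g[j, ] + c(0, 1), g[j, ] - c(0, 1))
      for (k in seq_len(4)) {
        hit <- lut[paste(nb[k, 1], nb[k, 2])]
        if (!is.na(hit) && comp[hit] == 0) queue <- c(queue, hit)
      }
    }
  }
  comp
}

#' Connected RoI areas at one level
#'
#' Groups same-level RoIs into 4-connected components on the patch grid and
#' reports each component's physical area in square millimetres
#' (`patches * (patch_size * pixel_size_at_level)^2`).
#'
#' @param rois data frame of RoIs at a single level (columns
#'   `level,row,col,size`).
#' @param pyramid the searched `pyramid`.
#' @return data frame `component, n_patches, area_mm2`.
#' @export
connected_roi_area <- function(rois, pyramid) {
  if (is.null(rois) || nrow(rois) == 0)
    return(data.frame(component = integer(0), n_patches = integer(0),
                      area_mm2 = numeric(0)))
  if (length(unique(rois$level)) != 1) stop_bad("RoIs span multiple levels")
  comp <- roi_components(rois)
  px_mm <- pixel_size_at(pyramid, rois$level[1]) / 1000
  patch_mm2 <- (rois$size[1] * px_mm)^2
  agg <- table(comp)
  data.frame(component = as.integer(names(agg)),
             n_patches = as.integer(agg),
             area_mm2 = as.integer(agg) * patch_mm2)
}

#' Ground-truth-mask oracle classifier
#'
#' Returns confidence 1 for a patch whose footprint contains any positive
#' ground-truth pixel at its level, 0 otherwise.  Because mask pyramids use
#' any-positive downsampling this oracle is monotone: a positive child
#' implies a positive parent, under which the pruned search provably equals
#' the exhaustive scan.
#'
#' @param pyramid a `pyramid` with `masks` attached.
#' @export
make_oracle_classifier <- function(pyramid) {
  if (is.null(pyramid$masks)) stop_bad("pyramid has no ground-truth masks")
  list(classify = function(patch) {
    m <- pyramid$masks[[patch$level + 1]]
    r <- (patch$origin[1] + 1):min(patch$origin[1] + patch$size[1], nrow(m))
    cc <- (patch$origin[2] + 1):min(patch$origin[2] + patch$size[2], ncol(m))
    as.numeric(any(m[r, cc]))
  })
}

#' Wrap a trained classifier network as a search model
#'
#' @param model a `deconvnet` with the classifier head.
#' @export
make_net_classifier <- function(model) {
  list(classify = function(patch) as.numeric(predict_confidence(model, patch)))
}
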