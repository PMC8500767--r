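# Shared in-code fixtures for the test suite.

# Small textured RGB image with a known bright/dark structure.
fixture_rgb <- function(h = 32, w = 32, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3), c(h, w, 3))
}

# A tiny slide spec with a single lesion placed at the canvas center.
fixture_slide_spec <- function(diameter_um = 120, cell_count = NULL,
                               base = 512, n_levels = 4, pixel_size_um = 1) {
  slide_spec(base_height = base, base_width = base, n_levels = n_levels,
             pixel_size_um = pixel_size_um,
             lesions = list(lesion_spec(c(base / 2, base / 2), diameter_um,
                                        cell_count = cell_count)),
             nuclei_density = 500, background_seed = 1)
}

# Brute-force point-in-polygon oracle (winding-independent, even-odd by
# angle-crossing count), used to validate contour_to_mask.
pip_oracle <- function(py, px, poly) {
  n <- nrow(poly)
  cross <- 0
  on_edge <- FALSE
  for (e in seq_len(n)) {
    a <- poly[e, ]; b <- poly[if (e == n) 1 else e + 1, ]
    # on-segment
    d <- b - a; len2 <- sum(d^2)
    tt <- if (len2 > 0) sum((c(py, px) - a) * d) / len2 else 0
    proj <- a + max(0, min(1, tt)) * d
    if (sum((c(py, px) - proj)^2) < 1e-18) on_edge <- TRUE
    if ((a[1] > py) != (b[1] > py)) {
      xin <- a[2] + (py - a[1]) * (b[2] - a[2]) / (b[1] - a[1])
      if (px < xin) cross <- cross + 1
    }
  }
  (cross %% 2 == 1) || on_edge
}
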