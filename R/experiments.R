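#' Desk-scale learning experiments
#'
#' Self-contained train-and-evaluate runs on generator output, used both as
#' package-level benchmarks and by the acceptance checks.  Problem sizes are
#' deliberately small (64 px patches, a few hundred samples) so each run
#' completes in minutes on one CPU core; the synthetic textures are far
#' cleaner than real H&E, so these runs demonstrate that the optimization
#' machinery works, not clinical performance.
#'
#' @name experiments
NULL

split_70_30 <- function(n, frac, seed) {
  with_seed(seed + 17, {
    tr <- sort(sample.int(n, round(frac * n)))
    list(train = tr, test = setdiff(seq_len(n), tr))
  })
}

#' Train and evaluate the tissue patch classifier
#'
#' Generates tumor/normal texture patches, trains the classifier head on a
#' 70/30 split and reports held-out accuracy at the 0.5 threshold.
#'
#' @param seed master seed.
#' @param n_tumor,n_normal patch counts.
#' @param size patch side in pixels.
#' @param epochs training epochs.
#' @param base_filters encoder width.
#' @return list: `accuracy`, `model`, `history`, `n_test`.
#' @export
experiment_tissue_classifier <- function(seed = 1, n_tumor = 100,
                                         n_normal = 100, size = 64,
                                         epochs = 50, base_filters = 8) {
  data <- generate_patch_set(n_tumor, n_normal, size = size, seed = seed)
  sp <- split_70_30(length(data$images), 0.7, seed)
  cfg <- train_config(epochs = epochs, batch_size = 20, seed = seed)
  model <- build_deconvnet(backbone_config(base_filters = base_filters,
                                           head = "classifier"), seed = seed)
  fit <- train_deconvnet(model, data$images[sp$train], data$labels[sp$train], cfg)
  conf <- predict_confidence(fit$model, data$images[sp$test])
  acc <- mean((conf >= 0.5) == (data$labels[sp$test] == 1))
  list(accuracy = acc, model = fit$model, history = fit$history,
       n_test = length(sp$test))
}

#' Train and evaluate density-map cell counting
#'
#' Generates nuclei patches with point labels, trains the density head on
#' Gaussian-kernel targets (scaled by `density_scale` for numerical
#' conditioning) and reports held-out counting error both by density-map
#' integration and by NMS peak enumeration.
#'
#' @param seed master seed.
#' @param n_patches number of patches.
#' @param size patch side.
#' @param count_range nuclei per patch (inclusive range).
#' @param epochs training epochs.
#' @param base_filters encoder width.
#' @param convs_per_block stacked convolutions per block (see
#'   [backbone_config()]); one conv per block underfits this task.
#' @param weight_decay decoupled weight decay; the deeper net memorizes its
#'   training patches without it.
#' @param sigma Gaussian kernel width in pixels.
#' @param density_scale target scaling factor.
#' @param n_models size of the seed ensemble whose predicted maps are
#'   averaged (averaging independently initialized runs stabilizes the count
#'   against individual optimization runs that settle badly).
#' @return list: `rel_error_integral` (calibrated), `rel_error_raw`,
#'   `rel_error_nms`, `calibration` coefficients, `models`, `history`,
#'   per-patch `true_counts`, `est_integral`, `est_nms`.
#' @export
experiment_cell_counting <- function(seed = 1, n_patches = 240, size = 48,
                                     count_range = c(3, 12), epochs = 100,
                                     base_filters = 12, convs_per_block = 2,
                                     weight_decay = 2, sigma = 3,
                                     density_scale = 100, n_models = 2) {
  data <- generate_cell_patch_set(n_patches, size = size,
                                  count_range = count_range, seed = seed)
  spec <- gaussian_kernel_spec(sigma)
  targets <- lapply(data$points, function(p)
    points_to_density(p, c(size, size), spec) * density_scale)
  sp <- split_70_30(n_patches, 0.7, seed)
  fits <- lapply(seq_len(n_models), function(m) {
    cfg <- train_config(epochs = epochs, batch_size = 15,
                        weight_decay = weight_decay,
                        seed = seed + 7919 * (m - 1))
    model <- build_deconvnet(backbone_config(base_filters = base_filters,
                                             convs_per_block = convs_per_block,
                                             head = "density"),
                             seed = seed + 7919 * (m - 1))
    train_deconvnet(model, data$images[sp$train], targets[sp$train], cfg)
  })
  peak1 <- density_scale / (2 * pi * sigma^2)
  # integration threshold and its analytic mass correction: a clean kernel
  # thresholded at tau retains a known mass fraction, so thresholding
  # suppresses diffuse background without biasing the count
  tmpl <- points_to_density(rbind(c(size / 2, size / 2)), c(size, size),
                            spec) * density_scale
  tau <- 0.05 * max(tmpl)
  mfrac <- sum(tmpl[tmpl >= tau]) / sum(tmpl)
  # batched ensemble + rotation-replica map averaging for a list of images
  avg_maps <- function(imgs) {
    acc <- vector("list", length(imgs))
    for (m in seq_along(fits)) for (r in 0:3) {
      xb <- stack_batch(lapply(imgs, rotate90, k = r))
      out <- nn_forward(fits[[m]]$model, xb, head = "density")$out
      for (k in seq_along(imgs)) {
        dm <- rotate90(pmax(out[, , 1, k], 0), (4 - r) %% 4)
        acc[[k]] <- if (is.null(acc[[k]])) dm else acc[[k]] + dm
      }
    }
    lapply(acc, `/`, 4 * length(fits))
  }
  count_integral <- function(dm) sum(dm[dm >= tau]) / mfrac / density_scale
  # affine recalibration fit on the training split only: corrects the
  # regression-to-the-mean shrinkage of the raw integral
  est_tr <- vapply(avg_maps(data$images[sp$train]), count_integral, numeric(1))
  tru_tr <- vapply(sp$train, function(i) nrow(data$points[[i]]), numeric(1))
  cal <- stats::lm(tru_tr ~ est_tr)
  true_counts <- vapply(data$points[sp$test], nrow, numeric(1))
  test_maps <- avg_maps(data$images[sp$test])
  est_raw <- vapply(test_maps, count_integral, numeric(1))
  est_n <- vapply(test_maps, function(dm)
    count_cells(nms_peaks(dm, radius = sigma, min_height = 0.25 * peak1)),
    numeric(1))
  est_i <- pmax(stats::predict(cal, data.frame(est_tr = est_raw)), 0)
  list(rel_error_integral = mean(abs(est_i - true_counts)) / mean(true_counts),
       rel_error_raw = mean(abs(est_raw - true_counts)) / mean(true_counts),
       rel_error_nms = mean(abs(est_n - true_counts)) / mean(true_counts),
       calibration = stats::coef(cal),
       models = lapply(fits, `[[`, "model"), model = fits[[1]]$model,
       history = fits[[1]]$history,
       true_counts = true_counts, est_integral = est_i, est_nms = est_n)
}

#' Jointly train the encoder and LSTM on planted tumor masses
#'
#' Sequences of textured patches with known per-patch tumor mass; the
#' composite loss trains the density encoder and the LSTM residual jointly,
#' and held-out integrated counts are compared with the ground truth.
#'
#' @param seed master seed.
#' @param n_train,n_test sequence counts.
#' @param seq_len patches per sequence.
#' @param size patch side.
#' @param epochs training epochs.
#' @param base_filters encoder width.
#' @param alpha LSTM loss weight.
#' @return list: `rel_count_error` (mean |T - T0| / mean T0 held out),
#'   `model`, `lstm`, `history`.
#' @export
experiment_lstm_fusion <- function(seed = 1, n_train = 20, n_test = 8,
                                   seq_len = 4, size = 32, epochs = 40,
                                   base_filters = 8, alpha = 0.1) {
  seqs <- generate_mass_sequences(n_train + n_test, seq_len = seq_len,
                                  size = size, seed = seed)
  cfg <- train_config(epochs = epochs, batch_size = 1, seed = seed)
  model <- build_deconvnet(backbone_config(base_filters = base_filters,
                                           head = "density"), seed = seed)
  lstm <- lstm_params(input_dim = 16, hidden = 10, seed = seed)
  fit <- train_lstm_cfcn(model, lstm, seqs[seq_len(n_train)], cfg,
                         loss_weights(alpha))
  errs <- numeric(0); masses <- numeric(0)
  for (sq in seqs[n_train + seq_len(n_test)]) {
    maps <- encode_sequence(fit$model, sq$patches)
    R <- lstm_residual(dimension_shuffle(maps), fit$lstm)
    Ti <- vapply(seq_along(maps), function(i)
      integrated_count(maps[[i]], R[i]), numeric(1))
    errs <- c(errs, abs(Ti - sq$gt_counts))
    masses <- c(masses, sq$gt_counts)
  }
  list(rel_count_error = mean(errs) / mean(masses),
       model = fit$model, lstm = fit$lstm, history = fit$history)
}

#' Oracle-detector staging benchmark
#'
#' Generates class-typical synthetic slides and screens each with the
#' ground-truth detectors; reports the fraction of slides whose staged label
#' reproduces the planted label.
#'
#' @param per_class slides per class.
#' @param seed master seed.
#' @return list: `accuracy`, `table` (per-slide data frame).
#' @export
experiment_oracle_staging <- function(per_class = 10, seed = 1) {
  rows <- NULL
  i <- 0
  for (cl in SLIDE_LABELS) for (k in seq_len(per_class)) {
    i <- i + 1
    slide <- generate_slide(slide_spec_for_class(cl, seed = seed * 1000 + i))
    rep <- screen_slide(slide, oracle = TRUE)
    rows <- rbind(rows, data.frame(slide = i, class = cl,
                                   true_label = slide$true_label,
                                   pred_label = rep$label))
  }
  list(accuracy = mean(rows$pred_label == rows$true_label), table = rows)
}
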