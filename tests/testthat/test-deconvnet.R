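test_that("config invariants are enforced", {
  expect_error(backbone_config(kernel_size = 5), "fixed at 3")
  expect_error(backbone_config(n_down_blocks = 3, n_up_blocks = 2), "equal")
  expect_error(train_config(lr_initial = 1e-5, lr_final = 1e-3), "lr_final")
  expect_error(train_config(split_fraction = 1.2), "split_fraction")
})

test_that("density head preserves spatial dims for any divisible size", {
  model <- build_deconvnet(backbone_config(base_filters = 4), seed = 1)
  for (sz in c(16, 48, 64)) {
    dm <- predict_density(model, array(runif(sz * sz * 3), c(sz, sz, 3)))
    expect_equal(dim(dm), c(sz, sz))
    expect_true(all(dm >= 0))
  }
  expect_error(predict_density(model, array(0, c(50, 50, 3))), "divisible")
})

test_that("classifier head outputs deterministic confidences in [0, 1]", {
  model <- build_deconvnet(backbone_config(base_filters = 4,
                                           head = "classifier"), seed = 2)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  c1 <- predict_confidence(model, x)
  c2 <- predict_confidence(model, x)
  expect_identical(c1, c2)
  expect_true(c1 >= 0 && c1 <= 1)
  cb <- predict_confidence(model, list(x, x, 1 - x))
  expect_length(cb, 3)
  expect_equal(cb[1], cb[2])
})

test_that("backward pass matches finite differences", {
  model <- build_deconvnet(backbone_config(base_filters = 2), seed = 3)
  set.seed(9)
  x <- array(runif(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  tgt <- array(runif(8 * 8 * 2), c(8, 8, 1, 2))
  lossf <- function(m) {
    o <- pyrascreen:::nn_forward(m, x, head = "density")$out
    sum((o - tgt)^2) / 4
  }
  fwd <- pyrascreen:::nn_forward(model, x, keep = TRUE)
  g <- pyrascreen:::nn_backward(model, fwd$cache, (fwd$out - tgt) / 2)
  eps <- 1e-6
  for (li in seq_along(model$layers)) {
    if (is.null(model$layers[[li]]$W)) next
    for (k in sample(length(model$layers[[li]]$W),
                     min(4, length(model$layers[[li]]$W)))) {
      m2 <- model
      m2$layers[[li]]$W[k] <- m2$layers[[li]]$W[k] + eps
      num <- (lossf(m2) - lossf(model)) / eps
      expect_lt(abs(num - g$layers[[li]]$W[k]) / max(abs(num), 1e-4), 2e-3)
    }
  }
})

test_that("training is seeded-reproducible and memorizes a single pair", {
  set.seed(44)
  x <- list(array(runif(16 * 16 * 3), c(16, 16, 3)))
  y <- list(points_to_density(rbind(c(8, 8)), c(16, 16),
                              gaussian_kernel_spec(2)))
  cfg <- train_config(epochs = 200, batch_size = 1, seed = 4)
  m0 <- build_deconvnet(backbone_config(base_filters = 8), seed = 4)
  f1 <- train_deconvnet(m0, x, y, cfg)
  f2 <- train_deconvnet(m0, x, y, cfg)
  expect_identical(tail(f1$history$loss, 1), tail(f2$history$loss, 1))
  mse <- mean((predict_density(f1$model, x[[1]]) - y[[1]])^2)
  expect_lt(mse, 1e-3)
  expect_error(train_deconvnet(m0, list(), list(), cfg), "empty")
})

test_that("learning rate decays in equal steps to lr_final", {
  cfg <- train_config(epochs = 5, lr_initial = 1e-3, lr_final = 1e-5)
  lrs <- pyrascreen:::lr_schedule(cfg)
  expect_equal(lrs[1], 1e-3)
  expect_equal(lrs[5], 1e-5)
  expect_true(all(abs(diff(diff(lrs))) < 1e-12))
})

test_that("constant-zero targets drive the output map toward zero", {
  set.seed(5)
  x <- lapply(1:4, function(i) array(runif(16 * 16 * 3), c(16, 16, 3)))
  y <- lapply(1:4, function(i) matrix(0, 16, 16))
  m <- build_deconvnet(backbone_config(base_filters = 4), seed = 5)
  fit <- train_deconvnet(m, x, y, train_config(epochs = 60, batch_size = 4,
                                               seed = 5))
  expect_lt(mean(predict_density(fit$model, x[[1]])), 0.01)
  expect_lt(tail(fit$history$loss, 1), head(fit$history$loss, 1) / 10)
})

test_that("smoothed training loss is non-increasing", {
  data <- generate_patch_set(12, 12, size = 32, seed = 6)
  m <- build_deconvnet(backbone_config(base_filters = 4, head = "classifier"),
                       seed = 6)
  fit <- train_deconvnet(m, data$images, data$labels,
                         train_config(epochs = 40, batch_size = 8, seed = 6))
  sm <- stats::filter(fit$history$loss, rep(1 / 10, 10), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) <= 0.05 * sm[-length(sm)] + 1e-8))
})

test_that("checkpoints round-trip with their configuration", {
  m <- build_deconvnet(backbone_config(base_filters = 4), seed = 7)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$config, m$config)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(predict_density(m, x), predict_density(m2, x))
})
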