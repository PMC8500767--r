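test_that("loss formulas match direct scalar evaluation", {
  # hand-evaluated cases
  expect_equal(loss_tissue(list(matrix(3)), list(matrix(1))), 2)
  expect_equal(loss_lstm(c(1, -1) + c(5, 5), c(5, 5)), 0.5)
  expect_equal(total_loss(2, 0.5, loss_weights(0.1)), 2.05)
  expect_equal(total_loss(2, 0.5, loss_weights(0)), 2)

  # random small inputs against a brute-force double loop
  set.seed(8)
  for (trial in 1:100) {
    n <- sample(1:5, 1); h <- sample(2:4, 1); w <- sample(2:4, 1)
    pred <- lapply(1:n, function(i) matrix(rnorm(h * w), h, w))
    gt <- lapply(1:n, function(i) matrix(rnorm(h * w), h, w))
    s <- 0
    for (i in 1:n) for (p in 1:(h * w)) s <- s + (pred[[i]][p] - gt[[i]][p])^2
    expect_lt(abs(loss_tissue(pred, gt) - s / (2 * n)), 1e-9)

    T0 <- rnorm(n); Tt <- rnorm(n)
    expect_lt(abs(loss_lstm(Tt, T0) - sum((Tt - T0)^2) / (2 * n)), 1e-9)
    a <- runif(1)
    expect_lt(abs(total_loss(loss_tissue(pred, gt), loss_lstm(Tt, T0),
                             loss_weights(a)) -
                  (s / (2 * n) + a * sum((Tt - T0)^2) / (2 * n))), 1e-9)
  }

  expect_equal(loss_tissue(list(matrix(1:4, 2)), list(matrix(1:4, 2))), 0)
  # duplicating pairs leaves the mean-normalized loss unchanged
  p1 <- list(matrix(rnorm(4), 2)); g1 <- list(matrix(rnorm(4), 2))
  expect_equal(loss_tissue(p1, g1), loss_tissue(c(p1, p1), c(g1, g1)))
  # quadratic scaling
  expect_equal(loss_lstm(3 * c(1, 2), c(0, 0)), 9 * loss_lstm(c(1, 2), c(0, 0)))
  expect_error(loss_tissue(p1, list(matrix(0, 3, 3))), "shape")
  expect_error(loss_lstm(1:3, 1:2), "length")
})

test_that("integrated count is residual plus map mass", {
  expect_equal(integrated_count(matrix(c(5, 7.5)), 0), 12.5)
  expect_equal(integrated_count(matrix(c(4, 6)), -2), 8)
  expect_equal(integrated_count(matrix(0, 3, 3), 1.5), 1.5)
})

test_that("dimension shuffle preserves order and total mass", {
  maps <- lapply(1:5, function(i) matrix(runif(64), 8, 8))
  d <- dimension_shuffle(maps, grid = 4)
  expect_equal(dim(d), c(5, 16))
  expect_equal(rowSums(d), vapply(maps, sum, numeric(1)))
  same <- dimension_shuffle(list(maps[[1]], maps[[1]]), grid = 4)
  expect_identical(same[1, ], same[2, ])
  # permuting the sequence permutes descriptors identically
  perm <- c(3, 1, 5, 2, 4)
  expect_identical(dimension_shuffle(maps[perm], 4), d[perm, ])
})

test_that("zero-initialized LSTM returns zero residuals, deterministic otherwise", {
  z <- lstm_params(input_dim = 16, hidden = 10, init = "zero")
  X <- matrix(runif(4 * 16), 4, 16)
  expect_identical(lstm_residual(X, z), rep(0, 4))
  p <- lstm_params(input_dim = 16, hidden = 10, seed = 11)
  expect_identical(lstm_residual(X, p), lstm_residual(X, p))
})

test_that("LSTM trained on a systematic under-count learns a positive residual", {
  set.seed(12)
  desc <- lapply(1:10, function(i) matrix(runif(4 * 16, 0, 2), 4, 16))
  base <- lapply(desc, rowSums)           # pretend map masses
  T0 <- lapply(base, function(b) b + 5)   # truth is always 5 higher
  p <- lstm_params(16, 10, seed = 12)
  fit <- train_lstm(p, desc, base, T0,
                    train_config(epochs = 150, lr_initial = 1e-2,
                                 lr_final = 1e-3, seed = 12))
  R <- lstm_residual(desc[[1]], fit$params)
  expect_true(all(R > 2))
  expect_lt(tail(fit$history, 1), head(fit$history, 1) / 20)
})

test_that("encoding a sequence equals per-patch prediction", {
  model <- build_deconvnet(backbone_config(base_filters = 4), seed = 13)
  patches <- lapply(1:3, function(i) array(runif(16 * 16 * 3), c(16, 16, 3)))
  maps <- encode_sequence(model, patches)
  expect_length(maps, 3)
  for (i in 1:3)
    expect_equal(maps[[i]], predict_density(model, patches[[i]]))
  expect_error(encode_sequence(model, list(patches[[1]],
                                           array(0, c(8, 8, 3)))), "mixed")
})

test_that("stitching writes disjoint patches and round-trips", {
  ps <- 8
  maps <- lapply(1:4, function(i) matrix(i, ps, ps))
  lcis <- list(location_code(c(0, 0), "0", 1), location_code(c(0, 0), "1", 1),
               location_code(c(0, 0), "2", 1), location_code(c(0, 0), "3", 1))
  out <- stitch_density(maps, lcis, c(16, 16), ps)
  expect_equal(sum(out), sum(vapply(maps, sum, numeric(1))))
  expect_equal(out[1:8, 1:8], maps[[1]])
  expect_equal(out[9:16, 9:16], maps[[4]])
  # re-tiling recovers each patch map
  for (i in 1:4) {
    o <- lci_to_coords(lcis[[i]], ps)$origin
    expect_equal(out[o[1] + 1:ps, o[2] + 1:ps], maps[[i]])
  }
  expect_error(stitch_density(maps[c(1, 1)], lcis[c(1, 1)], c(16, 16), ps),
               "overlapping")
  one <- stitch_density(maps[1], lcis[1], c(8, 8), ps)
  expect_equal(one, maps[[1]], ignore_attr = TRUE)
})

test_that("joint CFCN+LSTM training recovers held-out tumor masses within 20%", {
  res <- experiment_lstm_fusion(seed = 1)
  expect_lte(res$rel_count_error, 0.2)
})

test_that("with alpha = 0 the LSTM receives exactly zero gradient", {
  seqs <- generate_mass_sequences(2, seq_len = 2, size = 16, seed = 14)
  model <- build_deconvnet(backbone_config(base_filters = 2), seed = 14)
  lstm0 <- lstm_params(16, 10, seed = 14)
  fit <- train_lstm_cfcn(model, lstm0, seqs,
                         train_config(epochs = 2, seed = 14),
                         loss_weights(alpha = 0))
  for (nm in c("Wx", "Wh", "b", "v", "b_r"))
    expect_identical(fit$lstm[[nm]], lstm0[[nm]])
})

test_that("joint training reduces the composite loss on tumor-mass sequences", {
  seqs <- generate_mass_sequences(6, seq_len = 3, size = 16, seed = 15)
  model <- build_deconvnet(backbone_config(base_filters = 8), seed = 15)
  lstm <- lstm_params(16, 10, seed = 15)
  fit <- train_lstm_cfcn(model, lstm, seqs,
                         train_config(epochs = 50, seed = 15),
                         loss_weights(0.1))
  expect_lt(tail(fit$history$L, 1), head(fit$history$L, 1) / 5)
})
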