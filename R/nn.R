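#' Backbone network configuration
#'
#' The shared encoder-decoder backbone: `n_down_blocks` blocks of 3x3
#' convolution + ReLU + 2x2 max pooling, mirrored by `n_up_blocks` blocks of
#' 2x nearest-neighbour upsampling + 3x3 convolution + ReLU, and a final 1x1
#' convolution producing a single-channel nonnegative density map at the
#' input resolution.  Filter widths double per down block.  The classifier
#' head replaces the decoder with global average pooling of the bottleneck
#' features, a fully connected layer and a logistic squashing to `[0, 1]`.
#'
#' @param in_channels input channels (3 for RGB).
#' @param base_filters filters in the first block; doubles per block.
#' @param kernel_size convolution kernel side; fixed at 3.
#' @param n_down_blocks,n_up_blocks encoder/decoder depth; must be equal.
#' @param head `"density"` or `"classifier"`.
#' @param upsample `"unpool"` routes each decoder upsampling through the
#'   switches (argmax positions) recorded by the mirrored encoder pooling
#'   layer, which is the mechanism that lets a skip-less decoder recover
#'   sub-window localization; `"nearest"` is plain nearest-neighbour
#'   upsampling.
#' @export
#' @param convs_per_block stacked 3x3 convolutions per encoder/decoder block.
backbone_config <- function(in_channels = 3, base_filters = 16, kernel_size = 3,
                            n_down_blocks = 3, n_up_blocks = n_down_blocks,
                            head = c("density", "classifier"),
                            upsample = c("nearest", "unpool"),
                            convs_per_block = 1) {
  head <- match.arg(head)
  if (kernel_size != 3) stop_bad("kernel_size is fixed at 3")
  if (n_down_blocks != n_up_blocks)
    stop_bad("n_down_blocks must equal n_up_blocks")
  list(in_channels = in_channels, base_filters = base_filters,
       kernel_size = 3L, n_down_blocks = as.integer(n_down_blocks),
       n_up_blocks = as.integer(n_up_blocks), head = head,
       upsample = match.arg(upsample),
       convs_per_block = as.integer(convs_per_block))
}

#' Training configuration
#'
#' Adam with a learning rate decayed from `lr_initial` to `lr_final` by an
#' equal step per epoch; mean-squared-error loss by default (a cross-entropy
#' switch is provided for the classifier head).  The train/test split
#' fraction defaults to 0.70/0.30.
#'
#' @param lr_initial,lr_final initial and final learning rates.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param split_fraction fraction of data used for training in helpers that
#'   split; in `(0, 1)`.
#' @param loss `"mse"` or `"cross_entropy"` (classifier head only).
#' @param weight_decay decoupled weight decay applied to convolution and
#'   dense weights (not biases) at each step; 0 disables.
#' @param seed RNG seed controlling init, shuffling and splits.
#' @export
train_config <- function(lr_initial = 1e-3, lr_final = 1e-5, epochs = 50,
                         batch_size = 16, split_fraction = 0.7,
                         loss = c("mse", "cross_entropy"),
                         weight_decay = 0, seed = 1) {
  if (lr_final > lr_initial) stop_bad("lr_final must be <= lr_initial")
  if (split_fraction <= 0 || split_fraction >= 1)
    stop_bad("split_fraction must be in (0, 1)")
  list(lr_initial = lr_initial, lr_final = lr_final, epochs = as.integer(epochs),
       batch_size = as.integer(batch_size), split_fraction = split_fraction,
       loss = match.arg(loss), weight_decay = weight_decay, seed = seed)
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

#' Build the encoder-decoder density network
#'
#' @param config a [backbone_config()].
#' @param seed RNG seed for weight initialization.
#' @return A `deconvnet` model object.
#' @export
build_deconvnet <- function(config = backbone_config(), seed = 1) {
  nb <- config$n_down_blocks
  cpb <- config$convs_per_block %||% 1L
  f <- config$base_filters * 2^(0:(nb - 1))
  chans_in <- c(config$in_channels, f[-nb])
  layers <- list()
  pool_idx <- integer(nb)
  add_convs <- function(layers, cin, cout) {
    for (k in seq_len(cpb)) {
      layers[[length(layers) + 1L]] <- list(
        type = "conv", relu = TRUE,
        W = he_init(9 * cin, cout, 9 * cin), b = numeric(cout))
      cin <- cout
    }
    layers
  }
  with_seed(seed, {
    for (b in seq_len(nb)) {
      layers <- add_convs(layers, chans_in[b], f[b])
      layers[[length(layers) + 1L]] <- list(type = "pool")
      pool_idx[b] <- length(layers)
    }
    dec_in <- rev(f)
    dec_out <- c(rev(f)[-1], config$base_filters)
    for (b in seq_len(nb)) {
      # unpooling reuses the switches of the mirrored encoder pool layer
      layers[[length(layers) + 1L]] <- list(type = "up",
                                            switch_pool = pool_idx[nb - b + 1L])
      layers <- add_convs(layers, dec_in[b], dec_out[b])
    }
    # linear output; negative responses are clamped at zero at prediction
    # time (training through a terminal ReLU starves the gradient whenever
    # the map is mostly background)
    layers[[length(layers) + 1L]] <- list(
      type = "conv1x1", relu = FALSE,
      W = he_init(config$base_filters, 1, config$base_filters),
      b = numeric(1))
    fc <- list(W = he_init(f[nb], 1, f[nb]), b = 0)
  })
  structure(list(config = config, layers = layers, fc = fc,
                 encoder_end = pool_idx[nb]), class = "deconvnet")
}

#' Attach (activate) the fully connected classifier head
#'
#' Returns a model whose forward pass runs the encoder only, followed by
#' global average pooling, a fully connected layer and a logistic squashing
#' to a patch-level cancer confidence in `[0, 1]`.  Encoder weights are
#' shared with the density model.
#'
#' @param model a `deconvnet`.
#' @export
attach_classifier_head <- function(model) {
  stopifnot(inherits(model, "deconvnet"))
  model$config$head <- "classifier"
  model
}

check_divisible <- function(d, nb) {
  f <- 2^nb
  if (d[1] %% f != 0 || d[2] %% f != 0)
    stop_bad(paste0("input dims (%d x %d) must be divisible by 2^n_down_blocks",
                    " = %d for the pooling/upsampling chain"), d[1], d[2], f)
}

# Stack a list of h x w x c arrays into an (h, w, c, n) batch.
stack_batch <- function(imgs) {
  imgs <- lapply(imgs, function(x) {
    x <- patch_image(x)
    if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 1L))
    x
  })
  d <- dim(imgs[[1]])
  for (x in imgs) if (!all(dim(x) == d)) stop_bad("mixed patch sizes in batch")
  array(unlist(imgs, use.names = FALSE), c(d, length(imgs)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward pass; returns list(out, cache).  For head = "classifier" the
# decoder is skipped and out is an n-vector of confidences.
nn_forward <- function(model, x, head = model$config$head, keep = FALSE) {
  nb <- model$config$n_down_blocks
  check_divisible(dim(x)[1:2], nb)
  cache <- list()
  swargs <- list()   # pooling switches, needed by "unpool" decoders
  n_layers <- if (head == "classifier") model$encoder_end else length(model$layers)
  for (i in seq_len(n_layers)) {
    ly <- model$layers[[i]]
    if (ly$type == "conv") {
      if (keep) cache[[i]] <- list(x = x)
      x <- conv3x3_fwd_cpp(x, ly$W, ly$b, ly$relu)
      if (keep) cache[[i]]$y <- x
    } else if (ly$type == "conv1x1") {
      if (keep) cache[[i]] <- list(x = x)
      x <- conv1x1_fwd(x, ly$W, ly$b, ly$relu)
      if (keep) cache[[i]]$y <- x
    } else if (ly$type == "pool") {
      r <- maxpool2_fwd_cpp(x)
      swargs[[i]] <- list(arg = r$arg, h = dim(x)[1], w = dim(x)[2])
      if (keep) cache[[i]] <- swargs[[i]]
      x <- r$y
    } else if (ly$type == "up") {
      if (keep) cache[[i]] <- list()
      if ((model$config$upsample %||% "nearest") == "unpool") {
        sw <- swargs[[ly$switch_pool]]
        x <- unpool2_fwd_cpp(x, sw$arg, sw$h, sw$w)
      } else {
        x <- upsample2_fwd_cpp(x)
      }
    }
  }
  if (head == "classifier") {
    d <- dim(x)
    z <- apply(x, c(3, 4), mean)               # channels x n
    logit <- as.numeric(t(z) %*% model$fc$W) + model$fc$b
    conf <- sigmoid(logit)
    if (keep) cache$fc <- list(z = z, conf = conf, feat_dim = d)
    return(list(out = conf, cache = cache))
  }
  list(out = x, cache = cache)
}

conv1x1_fwd <- function(x, W, b, relu) {
  d <- dim(x)
  a <- aperm(x, c(1, 2, 4, 3)); dim(a) <- c(d[1] * d[2] * d[4], d[3])
  y <- a %*% W
  y <- sweep(y, 2, b, "+")
  if (relu) y[y < 0] <- 0
  dim(y) <- c(d[1], d[2], d[4], ncol(W))
  aperm(y, c(1, 2, 4, 3))
}

conv1x1_bwd <- function(cache, W, dy, relu) {
  x <- cache$x; y <- cache$y
  d <- dim(x)
  if (relu) dy <- dy * (y > 0)
  dym <- aperm(dy, c(1, 2, 4, 3)); dim(dym) <- c(d[1] * d[2] * d[4], ncol(W))
  a <- aperm(x, c(1, 2, 4, 3)); dim(a) <- c(d[1] * d[2] * d[4], d[3])
  dW <- crossprod(a, dym)
  db <- colSums(dym)
  dx <- dym %*% t(W)
  dim(dx) <- c(d[1], d[2], d[4], d[3])
  list(dW = dW, db = db, dx = aperm(dx, c(1, 2, 4, 3)))
}

# Backward pass; dout matches the head's output.  Returns gradients in the
# same structure as the model parameters.
nn_backward <- function(model, cache, dout, head = model$config$head) {
  grads <- vector("list", length(model$layers))
  gfc <- NULL
  n_layers <- if (head == "classifier") model$encoder_end else length(model$layers)
  if (head == "classifier") {
    fcc <- cache$fc
    dlogit <- dout * fcc$conf * (1 - fcc$conf)       # through sigmoid
    gfc <- list(W = fcc$z %*% matrix(dlogit), b = sum(dlogit))
    d <- fcc$feat_dim
    # gradient of global average pooling: spread evenly over h x w
    per_px <- outer(as.numeric(model$fc$W), dlogit) / (d[1] * d[2])  # c x n
    dx <- array(rep(per_px, each = d[1] * d[2]), d)
  } else {
    dx <- dout
  }
  for (i in rev(seq_len(n_layers))) {
    ly <- model$layers[[i]]
    if (ly$type == "conv") {
      g <- conv3x3_bwd_cpp(cache[[i]]$x, ly$W, dx, cache[[i]]$y, ly$relu, i > 1L)
      grads[[i]] <- list(W = g$dW, b = g$db)
      if (i > 1L) dx <- g$dx else dx <- NULL
    } else if (ly$type == "conv1x1") {
      g <- conv1x1_bwd(cache[[i]], ly$W, dx, ly$relu)
      grads[[i]] <- list(W = g$dW, b = g$db)
      dx <- g$dx
    } else if (ly$type == "pool") {
      dx <- maxpool2_bwd_cpp(dx, cache[[i]]$arg, cache[[i]]$h, cache[[i]]$w)
    } else if (ly$type == "up") {
      dx <- if ((model$config$upsample %||% "nearest") == "unpool")
        unpool2_bwd_cpp(dx, cache[[ly$switch_pool]]$arg)
      else upsample2_bwd_cpp(dx)
    }
  }
  list(layers = grads, fc = gfc)
}

# ---- Adam optimizer ----------------------------------------------------

adam_state <- function(model) {
  zero_like <- function(p) list(m = p * 0, v = p * 0)
  st <- list(layers = lapply(model$layers, function(ly)
    if (!is.null(ly$W)) list(W = zero_like(ly$W), b = zero_like(ly$b)) else NULL),
    fc = list(W = zero_like(model$fc$W), b = zero_like(model$fc$b)), t = 0L)
  st
}

adam_apply <- function(p, g, s, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8, t) {
  s$m <- b1 * s$m + (1 - b1) * g
  s$v <- b2 * s$v + (1 - b2) * g^2
  mh <- s$m / (1 - b1^t); vh <- s$v / (1 - b2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), s = s)
}

adam_step <- function(model, grads, state, lr, weight_decay = 0) {
  state$t <- state$t + 1L
  for (i in seq_along(model$layers)) {
    if (is.null(grads$layers[[i]])) next
    for (nm in c("W", "b")) {
      u <- adam_apply(model$layers[[i]][[nm]], grads$layers[[i]][[nm]],
                      state$layers[[i]][[nm]], lr, t = state$t)
      model$layers[[i]][[nm]] <- u$p
      if (nm == "W" && weight_decay > 0)
        model$layers[[i]][[nm]] <- model$layers[[i]][[nm]] * (1 - lr * weight_decay)
      state$layers[[i]][[nm]] <- u$s
    }
  }
  if (!is.null(grads$fc)) {
    for (nm in c("W", "b")) {
      u <- adam_apply(model$fc[[nm]], grads$fc[[nm]], state$fc[[nm]], lr,
                      t = state$t)
      model$fc[[nm]] <- u$p
      if (nm == "W" && weight_decay > 0)
        model$fc[[nm]] <- model$fc[[nm]] * (1 - lr * weight_decay)
      state$fc[[nm]] <- u$s
    }
  }
  list(model = model, state = state)
}

lr_schedule <- function(cfg) {
  if (cfg$epochs <= 1) return(cfg$lr_initial)
  cfg$lr_initial + (cfg$lr_final - cfg$lr_initial) *
    (seq_len(cfg$epochs) - 1) / (cfg$epochs - 1)
}

# ---- training ----------------------------------------------------------

#' Train the density or classifier head
#'
#' Minimizes the mean-squared-error loss `sum(err^2) / (2N)` with Adam; the
#' learning rate decays from `lr_initial` to `lr_final` by an equal step per
#' epoch.  All randomness (shuffling) is governed by `cfg$seed`, so repeated
#' runs are bit-identical.
#'
#' @param model a `deconvnet`.
#' @param images list of `h x w x 3` arrays (or `patch` objects).
#' @param targets list of `h x w` density matrices (density head) or a
#'   numeric 0/1 vector (classifier head).
#' @param cfg a [train_config()].
#' @param verbose print per-epoch loss.
#' @return list with the trained `model` and a `history` data frame
#'   (`epoch`, `loss`, `lr`).
#' @export
train_deconvnet <- function(model, images, targets, cfg = train_config(),
                            verbose = FALSE) {
  if (length(images) == 0) stop_bad("empty training dataset")
  head <- model$config$head
  n <- length(images)
  if (head == "density") {
    stopifnot(length(targets) == n)
  } else stopifnot(length(targets) == n)
  x_all <- lapply(images, patch_image)
  lrs <- lr_schedule(cfg)
  state <- adam_state(model)
  history <- data.frame(epoch = integer(0), loss = numeric(0), lr = numeric(0))
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, n)]
        xb <- stack_batch(x_all[idx])
        fwd <- nn_forward(model, xb, keep = TRUE)
        if (head == "density") {
          tb <- stack_batch(lapply(targets[idx], function(m) array(m, c(dim(m), 1))))
          diff <- fwd$out - tb
          loss <- sum(diff^2) / (2 * length(idx))
          dout <- diff / length(idx)
        } else {
          y <- targets[idx]
          if (cfg$loss == "mse") {
            loss <- sum((fwd$out - y)^2) / (2 * length(idx))
            dconf <- (fwd$out - y) / length(idx)
          } else {
            p <- pmin(pmax(fwd$out, 1e-12), 1 - 1e-12)
            loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
            # dL/dconf; the sigmoid factor is re-applied in nn_backward
            dconf <- (p - y) / (length(idx) * pmax(p * (1 - p), 1e-12))
          }
          dout <- dconf
        }
        if (!is.finite(loss))
          stop_bad("NaN/Inf loss at epoch %d (lr %.2g); inspect inputs or lower lr",
                   ep, lrs[ep])
        grads <- nn_backward(model, fwd$cache, dout)
        up <- adam_step(model, grads, state, lrs[ep],
                        cfg$weight_decay %||% 0)
        model <- up$model; state <- up$state
        ep_loss <- ep_loss + loss; nb <- nb + 1
      }
      history <- rbind(history,
                       data.frame(epoch = ep, loss = ep_loss / nb, lr = lrs[ep]))
      if (verbose) message(sprintf("epoch %3d  loss %.6g  lr %.2g",
                                   ep, ep_loss / nb, lrs[ep]))
    }
  })
  list(model = model, history = history)
}

#' Predict a density map for one patch
#'
#' Output is nonnegative (negative responses are clamped at zero by the final
#' ReLU) with the same spatial dimensions as the input; input dims must be
#' divisible by `2^n_down_blocks`.
#'
#' @param model a `deconvnet` (density head).
#' @param patch `patch` object or `h x w x 3` array.
#' @return `h x w` nonnegative matrix.
#' @export
predict_density <- function(model, patch) {
  x <- stack_batch(list(patch))
  out <- nn_forward(model, x, head = "density")$out
  pmax(out[, , 1, 1], 0)
}

#' Predict patch-level cancer confidence
#'
#' @param model a `deconvnet` with the classifier head attached.
#' @param patch `patch` object or array; a list/batch is also accepted.
#' @return Confidence(s) in `[0, 1]`.
#' @export
predict_confidence <- function(model, patch) {
  pts <- if (is.list(patch) && !inherits(patch, "patch")) patch else list(patch)
  x <- stack_batch(pts)
  nn_forward(model, x, head = "classifier")$out
}

#' Save / load a model checkpoint
#'
#' The configuration travels with the weights so a checkpoint is
#' self-describing.
#'
#' @param model a `deconvnet`.
#' @param path file path.
#' @export
save_model <- function(model, path) { saveRDS(model, path); invisible(path) }

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
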