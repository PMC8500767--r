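#' Sequence fusion of patch density maps with an LSTM residual count
#'
#' A patch sequence (row-major over the tiling grid) is encoded per patch by
#' the shared density network, each map is pooled to a fixed-length grid
#' descriptor ("dimension shuffle"), and a small LSTM with a fully connected
#' readout predicts a per-patch residual count `R_i`.  The integrated count is
#' `T_i = R_i + sum_p F_i(p)`; training minimizes
#' `L = L_t + alpha * L_lstm` where `L_t` is the density MSE and `L_lstm` the
#' count MSE (both with the 1/(2N) convention).
#'
#' @name lstm_cfcn
NULL

#' Loss weights
#' @param alpha nonnegative weight of the LSTM count loss.
#' @export
loss_weights <- function(alpha = 0.1) {
  stopifnot(alpha >= 0)
  list(alpha = alpha)
}

#' Encode a patch sequence into density maps
#'
#' Applies the shared density network independently to each patch (the
#' encoder carries no cross-patch coupling, so permuting the sequence
#' permutes the outputs identically).
#'
#' @param model a `deconvnet` (density head).
#' @param patches list of equally sized patches.
#' @return list of nonnegative `h x w` density maps.
#' @export
encode_sequence <- function(model, patches) {
  stopifnot(length(patches) >= 1)
  x <- stack_batch(patches)   # errors on mixed sizes
  out <- nn_forward(model, x, head = "density")$out
  lapply(seq_len(dim(out)[4]), function(i) pmax(out[, , 1, i], 0))
}

#' Dimension shuffle: pool density maps to LSTM descriptors
#'
#' Each map is summed over a `grid x grid` spatial partition, giving a
#' fixed-length descriptor whose entries sum to the map integral; sequence
#' order is preserved.
#'
#' @param maps list of `h x w` matrices.
#' @param grid partition side (descriptor length is `grid^2`).
#' @return `N x grid^2` matrix of descriptors.
#' @export
dimension_shuffle <- function(maps, grid = 4) {
  stopifnot(length(maps) >= 1)
  h <- nrow(maps[[1]]); w <- ncol(maps[[1]])
  ri <- pmin(floor((seq_len(h) - 1) * grid / h), grid - 1)
  ci <- pmin(floor((seq_len(w) - 1) * grid / w), grid - 1)
  cell <- outer(ri, ci, function(a, b) a + grid * b) + 1  # h x w cell ids
  t(vapply(maps, function(m) {
    as.numeric(rowsum(as.numeric(m), as.numeric(cell), reorder = TRUE))
  }, numeric(grid^2)))
}

#' LSTM parameters
#'
#' Gate order in the stacked matrices is input, forget, output, candidate.
#' `init = "zero"` gives an identically zero readout (R = 0 for any input).
#'
#' @param input_dim descriptor length.
#' @param hidden hidden state size (10 cells by default).
#' @param seed RNG seed for random init.
#' @param init `"random"` or `"zero"`.
#' @export
lstm_params <- function(input_dim = 16, hidden = 10, seed = 1,
                        init = c("random", "zero")) {
  init <- match.arg(init)
  H <- hidden; D <- input_dim
  if (init == "zero") {
    p <- list(Wx = matrix(0, 4 * H, D), Wh = matrix(0, 4 * H, H),
              b = numeric(4 * H), v = numeric(H), b_r = 0)
  } else {
    p <- with_seed(seed, list(
      Wx = matrix(stats::rnorm(4 * H * D, sd = 1 / sqrt(D)), 4 * H, D),
      Wh = matrix(stats::rnorm(4 * H * H, sd = 1 / sqrt(H)), 4 * H, H),
      b = c(numeric(H), rep(1, H), numeric(2 * H)),  # forget bias 1
      v = stats::rnorm(H, sd = 0.1), b_r = 0))
  }
  p$hidden <- H; p$input_dim <- D
  structure(p, class = "lstm_params")
}

lstm_fwd <- function(params, X) {
  H <- params$hidden; N <- nrow(X)
  hs <- matrix(0, H, N + 1); cs <- matrix(0, H, N + 1)
  gates <- array(0, c(4 * H, N))
  tc <- matrix(0, H, N)
  R <- numeric(N)
  for (t in seq_len(N)) {
    a <- params$Wx %*% X[t, ] + params$Wh %*% hs[, t] + params$b
    i <- sigmoid(a[1:H]); f <- sigmoid(a[(H + 1):(2 * H)])
    o <- sigmoid(a[(2 * H + 1):(3 * H)]); g <- tanh(a[(3 * H + 1):(4 * H)])
    cs[, t + 1] <- f * cs[, t] + i * g
    tc[, t] <- tanh(cs[, t + 1])
    hs[, t + 1] <- o * tc[, t]
    gates[, t] <- c(i, f, o, g)
    R[t] <- sum(params$v * hs[, t + 1]) + params$b_r
  }
  list(R = R, hs = hs, cs = cs, gates = gates, tc = tc, X = X)
}

lstm_bwd <- function(params, cache, dR) {
  H <- params$hidden; N <- nrow(cache$X)
  g <- list(Wx = params$Wx * 0, Wh = params$Wh * 0, b = params$b * 0,
            v = params$v * 0, b_r = 0)
  dh_next <- numeric(H); dc_next <- numeric(H)
  dX <- cache$X * 0
  for (t in rev(seq_len(N))) {
    i <- cache$gates[1:H, t]; f <- cache$gates[(H + 1):(2 * H), t]
    o <- cache$gates[(2 * H + 1):(3 * H), t]; gg <- cache$gates[(3 * H + 1):(4 * H), t]
    dh <- dR[t] * params$v + dh_next
    g$v <- g$v + dR[t] * cache$hs[, t + 1]
    g$b_r <- g$b_r + dR[t]
    do <- dh * cache$tc[, t]
    dc <- dh * o * (1 - cache$tc[, t]^2) + dc_next
    di <- dc * gg; dgg <- dc * i; df <- dc * cache$cs[, t]
    dc_next <- dc * f
    da <- c(di * i * (1 - i), df * f * (1 - f), do * o * (1 - o),
            dgg * (1 - gg^2))
    g$Wx <- g$Wx + outer(da, cache$X[t, ])
    g$Wh <- g$Wh + outer(da, cache$hs[, t])
    g$b <- g$b + da
    dX[t, ] <- as.numeric(t(params$Wx) %*% da)
    dh_next <- as.numeric(t(params$Wh) %*% da)
  }
  list(grads = g, dX = dX)
}

#' Residual counts from an LSTM over a descriptor sequence
#'
#' @param descriptors `N x D` matrix from [dimension_shuffle()].
#' @param params [lstm_params()].
#' @return Numeric vector of per-patch residual counts (any sign).
#' @export
lstm_residual <- function(descriptors, params) {
  stopifnot(nrow(descriptors) >= 1)
  lstm_fwd(params, descriptors)$R
}

#' Integrated count: density-map mass plus LSTM residual
#'
#' @param F_i `h x w` density map (or its precomputed sum).
#' @param R scalar residual.
#' @export
integrated_count <- function(F_i, R) R + sum(F_i)

#' Density (tissue) loss
#'
#' `L_t = (1/2N) * sum_i sum_p (F_i(p) - F0_i(p))^2`.
#'
#' @param pred,gt lists of equally sized density maps.
#' @export
loss_tissue <- function(pred, gt) {
  if (length(pred) != length(gt)) stop_bad("length mismatch")
  n <- length(pred)
  s <- 0
  for (i in seq_len(n)) {
    if (!all(dim(pred[[i]]) == dim(gt[[i]]))) stop_bad("density map shape mismatch")
    s <- s + sum((pred[[i]] - gt[[i]])^2)
  }
  s / (2 * n)
}

#' Count (LSTM) loss
#'
#' `L_lstm = (1/2N) * sum_i (T_i - T0_i)^2`.
#'
#' @param T,T0 numeric vectors of integrated and ground-truth counts.
#' @export
loss_lstm <- function(T, T0) {
  if (length(T) != length(T0)) stop_bad("length mismatch")
  sum((T - T0)^2) / (2 * length(T))
}

#' Composite loss
#'
#' `L = L_t + alpha * L_lstm`.
#'
#' @param L_t,L_lstm component losses (>= 0).
#' @param weights [loss_weights()].
#' @export
total_loss <- function(L_t, L_lstm, weights = loss_weights()) {
  L_t + weights$alpha * L_lstm
}

#' Stitch patch density maps into a whole-level map
#'
#' Each map is written at the location its location code decodes to;
#' unfilled pixels are zero.  Overlapping codes are an error.
#'
#' @param maps list of `h x w` matrices.
#' @param lcis list of [location_code()]s, one per map.
#' @param level_dims `(h, w)` of the target level.
#' @param patch_size patch side used by the codes.
#' @export
stitch_density <- function(maps, lcis, level_dims, patch_size) {
  stopifnot(length(maps) == length(lcis))
  out <- matrix(0, level_dims[1], level_dims[2])
  filled <- matrix(FALSE, level_dims[1], level_dims[2])
  for (i in seq_along(maps)) {
    o <- lci_to_coords(lcis[[i]], patch_size)$origin
    rr <- (o[1] + 1):(o[1] + nrow(maps[[i]]))
    cc <- (o[2] + 1):(o[2] + ncol(maps[[i]]))
    if (max(rr) > level_dims[1] || max(cc) > level_dims[2])
      stop_bad("patch %d falls outside the level", i)
    if (any(filled[rr, cc])) stop_bad("overlapping location codes at patch %d", i)
    out[rr, cc] <- maps[[i]]
    filled[rr, cc] <- TRUE
  }
  out
}

#' Train the LSTM readout on residual-count targets
#'
#' Fits only the recurrent parameters: minimizes
#' `(1/2N) sum (R_i + base_i - T0_i)^2` per sequence with Adam, holding the
#' encoder fixed.  Used when the density network is trained first and the
#' residual integrator is tuned on its systematic count errors.
#'
#' @param params [lstm_params()].
#' @param desc_seqs list of `N x D` descriptor matrices.
#' @param base_counts list of numeric vectors: per-patch density-map sums.
#' @param T0 list of numeric vectors: ground-truth counts.
#' @param cfg [train_config()].
#' @export
train_lstm <- function(params, desc_seqs, base_counts, T0,
                       cfg = train_config(epochs = 200)) {
  st <- list(Wx = list(m = params$Wx * 0, v = params$Wx * 0),
             Wh = list(m = params$Wh * 0, v = params$Wh * 0),
             b = list(m = params$b * 0, v = params$b * 0),
             v = list(m = params$v * 0, v = params$v * 0),
             b_r = list(m = 0, v = 0))
  lrs <- lr_schedule(cfg)
  t <- 0L
  history <- numeric(cfg$epochs)
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      tot <- 0
      for (s in sample.int(length(desc_seqs))) {
        fw <- lstm_fwd(params, desc_seqs[[s]])
        T_i <- fw$R + base_counts[[s]]
        N <- length(T_i)
        dR <- (T_i - T0[[s]]) / N
        tot <- tot + sum((T_i - T0[[s]])^2) / (2 * N)
        bw <- lstm_bwd(params, fw, dR)
        t <- t + 1L
        for (nm in c("Wx", "Wh", "b", "v", "b_r")) {
          u <- adam_apply(params[[nm]], bw$grads[[nm]], st[[nm]], lrs[ep], t = t)
          params[[nm]] <- u$p; st[[nm]] <- u$s
        }
      }
      history[ep] <- tot / length(desc_seqs)
    }
  })
  list(params = params, history = history)
}

#' Jointly train the encoder and LSTM on the composite loss
#'
#' Backpropagates `L = L_t + alpha * L_lstm` through both the per-patch
#' density encoder and the LSTM (full-sequence backpropagation; desk-scale
#' sequences are short).  With `alpha = 0` the LSTM receives exactly zero
#' gradient.
#'
#' @param model a `deconvnet` (density head).
#' @param lstm [lstm_params()].
#' @param sequences list of sequences: each
#'   `list(patches = , gt_maps = , gt_counts = )`.
#' @param cfg [train_config()].
#' @param weights [loss_weights()].
#' @param grid dimension-shuffle partition side.
#' @return list(model, lstm, history) where history has columns
#'   `epoch, L_t, L_lstm, L`.
#' @export
train_lstm_cfcn <- function(model, lstm, sequences, cfg = train_config(),
                            weights = loss_weights(), grid = 4) {
  stopifnot(length(sequences) >= 1)
  state <- adam_state(model)
  stl <- list(Wx = list(m = lstm$Wx * 0, v = lstm$Wx * 0),
              Wh = list(m = lstm$Wh * 0, v = lstm$Wh * 0),
              b = list(m = lstm$b * 0, v = lstm$b * 0),
              v = list(m = lstm$v * 0, v = lstm$v * 0),
              b_r = list(m = 0, v = 0))
  tl <- 0L
  lrs <- lr_schedule(cfg)
  history <- data.frame(epoch = integer(0), L_t = numeric(0),
                        L_lstm = numeric(0), L = numeric(0))
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      eLt <- 0; eLl <- 0
      for (s in sample.int(length(sequences))) {
        sq <- sequences[[s]]
        N <- length(sq$patches)
        xb <- stack_batch(sq$patches)
        fwd <- nn_forward(model, xb, head = "density", keep = TRUE)
        maps <- lapply(seq_len(N), function(i) fwd$out[, , 1, i])
        desc <- dimension_shuffle(maps, grid)
        lf <- lstm_fwd(lstm, desc)
        Ti <- lf$R + vapply(maps, sum, numeric(1))
        Lt <- loss_tissue(maps, sq$gt_maps)
        Ll <- loss_lstm(Ti, sq$gt_counts)
        eLt <- eLt + Lt; eLl <- eLl + Ll
        if (!is.finite(Lt + Ll)) stop_bad("NaN loss in joint training (epoch %d)", ep)

        # gradients
        dT <- weights$alpha * (Ti - sq$gt_counts) / N        # dL/dT_i
        dF <- array(0, dim(fwd$out))
        h <- nrow(maps[[1]]); w <- ncol(maps[[1]])
        ri <- pmin(floor((seq_len(h) - 1) * grid / h), grid - 1)
        ci <- pmin(floor((seq_len(w) - 1) * grid / w), grid - 1)
        cell <- outer(ri, ci, function(a, b) a + grid * b) + 1
        if (any(dT != 0)) {
          bw <- lstm_bwd(lstm, lf, dT)
          tl <- tl + 1L
          for (nm in c("Wx", "Wh", "b", "v", "b_r")) {
            u <- adam_apply(lstm[[nm]], bw$grads[[nm]], stl[[nm]], lrs[ep], t = tl)
            lstm[[nm]] <- u$p; stl[[nm]] <- u$s
          }
          ddesc <- bw$dX
        } else ddesc <- matrix(0, N, grid^2)
        for (i in seq_len(N)) {
          dmap <- (maps[[i]] - sq$gt_maps[[i]]) / N +        # from L_t
            dT[i] +                                          # through sum_p F
            matrix(ddesc[i, cell], h, w)                     # through descriptor
          dF[, , 1, i] <- dmap
        }
        grads <- nn_backward(model, fwd$cache, dF)
        up <- adam_step(model, grads, state, lrs[ep])
        model <- up$model; state <- up$state
      }
      history <- rbind(history, data.frame(
        epoch = ep, L_t = eLt / length(sequences), L_lstm = eLl / length(sequences),
        L = (eLt + weights$alpha * eLl) / length(sequences)))
    }
  })
  list(model = model, lstm = lstm, history = history)
}
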