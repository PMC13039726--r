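## Layer primitives for the CNN-LSTM engine: each layer is a list with a
## `type`, trainable `params`, and non-trainable `buffers`. Forward passes
## return the output plus a cache consumed by the matching backward pass.
## Shapes: sequence tensors are [N, T, C]; flat tensors are [N, F].

glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -limit, limit), dim = dims)
}

## ---- Conv1D (valid padding) + ReLU -----------------------------------------

layer_conv1d <- function(in_channels, filters, kernel) {
  list(type = "conv1d",
       params = list(W = glorot(kernel * in_channels, filters),
                     b = numeric(filters)),
       kernel = kernel, in_channels = in_channels, filters = filters)
}

conv1d_im2col <- function(X, kernel) {
  d <- dim(X); N <- d[1]; Tn <- d[2]; C <- d[3]
  T_out <- Tn - kernel + 1L
  Xc <- matrix(0, N * T_out, kernel * C)
  for (tau in seq_len(kernel)) {
    blk <- X[, tau:(tau + T_out - 1L), , drop = FALSE]
    dim(blk) <- c(N * T_out, C)
    Xc[, ((tau - 1L) * C + 1L):(tau * C)] <- blk
  }
  list(Xc = Xc, N = N, T_out = T_out, C = C)
}

fwd_conv1d <- function(layer, X, train) {
  ic <- conv1d_im2col(X, layer$kernel)
  pre <- sweep(ic$Xc %*% layer$params$W, 2, layer$params$b, `+`)
  out <- pmax(pre, 0)
  dim(out) <- c(ic$N, ic$T_out, layer$filters)
  list(out = out, cache = list(ic = ic, pre = pre, dimX = dim(X)))
}

bwd_conv1d <- function(layer, cache, dOut) {
  ic <- cache$ic
  dflat <- dOut
  dim(dflat) <- c(ic$N * ic$T_out, layer$filters)
  dflat <- dflat * (cache$pre > 0)
  dW <- crossprod(ic$Xc, dflat)
  db <- colSums(dflat)
  dXc <- dflat %*% t(layer$params$W)
  dX <- array(0, dim = cache$dimX)
  C <- ic$C
  for (tau in seq_len(layer$kernel)) {
    blk <- dXc[, ((tau - 1L) * C + 1L):(tau * C), drop = FALSE]
    dim(blk) <- c(ic$N, ic$T_out, C)
    dX[, tau:(tau + ic$T_out - 1L), ] <-
      dX[, tau:(tau + ic$T_out - 1L), , drop = FALSE] + blk
  }
  list(grads = list(W = dW, b = db), dX = dX)
}

## ---- Batch normalization over the feature axis -----------------------------

layer_batchnorm <- function(features, momentum = 0.99, eps = 1e-3) {
  list(type = "batchnorm",
       params = list(gamma = rep(1, features), beta = numeric(features)),
       buffers = list(running_mean = numeric(features),
                      running_var = rep(1, features)),
       features = features, momentum = momentum, eps = eps)
}

fwd_batchnorm <- function(layer, X, train) {
  d <- dim(X)
  flat <- X
  dim(flat) <- c(prod(d[-length(d)]), d[length(d)])
  if (train) {
    mu <- colMeans(flat)
    v <- colMeans(sweep(flat, 2, mu)^2)
    layer$buffers$running_mean <- layer$momentum * layer$buffers$running_mean +
      (1 - layer$momentum) * mu
    layer$buffers$running_var <- layer$momentum * layer$buffers$running_var +
      (1 - layer$momentum) * v
  } else {
    mu <- layer$buffers$running_mean
    v <- layer$buffers$running_var
  }
  xhat <- sweep(sweep(flat, 2, mu), 2, sqrt(v + layer$eps), `/`)
  out <- sweep(sweep(xhat, 2, layer$params$gamma, `*`), 2,
               layer$params$beta, `+`)
  dim(out) <- d
  list(out = out, cache = list(xhat = xhat, v = v, d = d), layer = layer)
}

bwd_batchnorm <- function(layer, cache, dOut) {
  d <- cache$d
  dflat <- dOut
  dim(dflat) <- c(prod(d[-length(d)]), d[length(d)])
  m <- nrow(dflat)
  dgamma <- colSums(dflat * cache$xhat)
  dbeta <- colSums(dflat)
  dxhat <- sweep(dflat, 2, layer$params$gamma, `*`)
  inv_sd <- 1 / sqrt(cache$v + layer$eps)
  dx <- sweep(
    dxhat * m - matrix(colSums(dxhat), m, ncol(dflat), byrow = TRUE) -
      cache$xhat * matrix(colSums(dxhat * cache$xhat), m, ncol(dflat),
                          byrow = TRUE),
    2, inv_sd / m, `*`)
  dim(dx) <- d
  list(grads = list(gamma = dgamma, beta = dbeta), dX = dx)
}

## ---- Max pooling over time -------------------------------------------------

layer_maxpool <- function(pool_size = 2L) {
  list(type = "maxpool", params = list(), pool_size = as.integer(pool_size))
}

fwd_maxpool <- function(layer, X, train) {
  d <- dim(X); N <- d[1]; Tn <- d[2]; C <- d[3]
  p <- layer$pool_size
  T_out <- Tn %/% p
  if (T_out < 1L) stop("sequence too short for max pooling", call. = FALSE)
  out <- array(-Inf, dim = c(N, T_out, C))
  argmax <- array(0L, dim = c(N, T_out, C))
  for (j in seq_len(p)) {
    cand <- X[, seq.int(j, by = p, length.out = T_out), , drop = FALSE]
    upd <- cand > out
    out[upd] <- cand[upd]
    argmax[upd] <- j
  }
  list(out = out, cache = list(argmax = argmax, d = d, T_out = T_out))
}

bwd_maxpool <- function(layer, cache, dOut) {
  p <- layer$pool_size
  dX <- array(0, dim = cache$d)
  for (j in seq_len(p)) {
    sel <- cache$argmax == j
    blk <- array(0, dim = dim(dOut))
    blk[sel] <- dOut[sel]
    dX[, seq.int(j, by = p, length.out = cache$T_out), ] <- blk
  }
  list(grads = list(), dX = dX)
}

## ---- LSTM ------------------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

layer_lstm <- function(in_features, units, return_sequences = FALSE) {
  b <- numeric(4 * units)
  b[(units + 1):(2 * units)] <- 1   # forget-gate bias init
  list(type = "lstm",
       params = list(Wx = glorot(in_features, 4 * units,
                                 c(in_features, 4 * units)),
                     Wh = glorot(units, 4 * units, c(units, 4 * units)),
                     b = b),
       units = units, in_features = in_features,
       return_sequences = return_sequences)
}

fwd_lstm <- function(layer, X, train) {
  d <- dim(X); N <- d[1]; Tn <- d[2]
  H <- layer$units
  h <- matrix(0, N, H); cc <- matrix(0, N, H)
  steps <- vector("list", Tn)
  seq_out <- if (layer$return_sequences) array(0, dim = c(N, Tn, H)) else NULL
  iu <- 1:H; fu <- (H + 1):(2 * H); gu <- (2 * H + 1):(3 * H)
  ou <- (3 * H + 1):(4 * H)
  for (t in seq_len(Tn)) {
    Xt <- matrix(X[, t, ], N, d[3])
    Z <- Xt %*% layer$params$Wx + h %*% layer$params$Wh
    Z <- sweep(Z, 2, layer$params$b, `+`)
    i_g <- sigmoid(Z[, iu, drop = FALSE])
    f_g <- sigmoid(Z[, fu, drop = FALSE])
    g_g <- tanh(Z[, gu, drop = FALSE])
    o_g <- sigmoid(Z[, ou, drop = FALSE])
    c_new <- f_g * cc + i_g * g_g
    tc <- tanh(c_new)
    h_new <- o_g * tc
    steps[[t]] <- list(Xt = Xt, i = i_g, f = f_g, g = g_g, o = o_g,
                       c_prev = cc, h_prev = h, tc = tc)
    cc <- c_new; h <- h_new
    if (layer$return_sequences) seq_out[, t, ] <- h
  }
  out <- if (layer$return_sequences) seq_out else h
  list(out = out, cache = list(steps = steps, d = d))
}

bwd_lstm <- function(layer, cache, dOut) {
  d <- cache$d; N <- d[1]; Tn <- d[2]; H <- layer$units
  dWx <- array(0, dim = dim(layer$params$Wx))
  dWh <- array(0, dim = dim(layer$params$Wh))
  db <- numeric(4 * H)
  dX <- array(0, dim = d)
  dh_next <- matrix(0, N, H); dc <- matrix(0, N, H)
  iu <- 1:H; fu <- (H + 1):(2 * H); gu <- (2 * H + 1):(3 * H)
  ou <- (3 * H + 1):(4 * H)
  for (t in rev(seq_len(Tn))) {
    st <- cache$steps[[t]]
    dh <- dh_next
    if (layer$return_sequences) {
      dh <- dh + matrix(dOut[, t, ], N, H)
    } else if (t == Tn) {
      dh <- dh + dOut
    }
    do_g <- dh * st$tc
    dc <- dc + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    dg <- dc * st$i
    df <- dc * st$c_prev
    dc <- dc * st$f
    dZ <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do_g * st$o * (1 - st$o))
    dWx <- dWx + crossprod(st$Xt, dZ)
    dWh <- dWh + crossprod(st$h_prev, dZ)
    db <- db + colSums(dZ)
    dX[, t, ] <- dZ %*% t(layer$params$Wx)
    dh_next <- dZ %*% t(layer$params$Wh)
  }
  list(grads = list(Wx = dWx, Wh = dWh, b = db), dX = dX)
}

## ---- Bidirectional LSTM (concatenating merge) ------------------------------

layer_bilstm <- function(in_features, units, return_sequences = FALSE) {
  list(type = "bilstm",
       fwd = layer_lstm(in_features, units, return_sequences),
       bwd = layer_lstm(in_features, units, return_sequences),
       params = list(),  # parameters live in the two sub-layers
       units = units, return_sequences = return_sequences)
}

reverse_time <- function(X) {
  X[, rev(seq_len(dim(X)[2])), , drop = FALSE]
}

fwd_bilstm <- function(layer, X, train) {
  f <- fwd_lstm(layer$fwd, X, train)
  b <- fwd_lstm(layer$bwd, reverse_time(X), train)
  if (layer$return_sequences) {
    H <- layer$units; d <- dim(X)
    out <- array(0, dim = c(d[1], d[2], 2 * H))
    out[, , 1:H] <- f$out
    out[, , (H + 1):(2 * H)] <- reverse_time(b$out)
  } else {
    out <- cbind(f$out, b$out)
  }
  list(out = out, cache = list(f = f$cache, b = b$cache))
}

bwd_bilstm <- function(layer, cache, dOut) {
  H <- layer$units
  if (layer$return_sequences) {
    dF <- dOut[, , 1:H, drop = FALSE]
    dB <- reverse_time(dOut[, , (H + 1):(2 * H), drop = FALSE])
  } else {
    dF <- dOut[, 1:H, drop = FALSE]
    dB <- dOut[, (H + 1):(2 * H), drop = FALSE]
  }
  rf <- bwd_lstm(layer$fwd, cache$f, dF)
  rb <- bwd_lstm(layer$bwd, cache$b, dB)
  list(grads = list(fwd = rf$grads, bwd = rb$grads),
       dX = rf$dX + reverse_time(rb$dX))
}

## ---- Dropout (inverted) ----------------------------------------------------

layer_dropout <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  list(type = "dropout", params = list(), rate = rate)
}

fwd_dropout <- function(layer, X, train) {
  if (!train || layer$rate == 0) {
    return(list(out = X, cache = list(mask = NULL)))
  }
  keep <- 1 - layer$rate
  mask <- array(stats::rbinom(length(X), 1L, keep) / keep, dim = dim(X))
  list(out = X * mask, cache = list(mask = mask))
}

bwd_dropout <- function(layer, cache, dOut) {
  dX <- if (is.null(cache$mask)) dOut else dOut * cache$mask
  list(grads = list(), dX = dX)
}

## ---- Dense -----------------------------------------------------------------

layer_dense <- function(in_features, units, activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  list(type = "dense",
       params = list(W = glorot(in_features, units), b = numeric(units)),
       activation = activation, units = units, in_features = in_features)
}

fwd_dense <- function(layer, X, train) {
  pre <- sweep(X %*% layer$params$W, 2, layer$params$b, `+`)
  out <- if (layer$activation == "relu") pmax(pre, 0) else pre
  list(out = out, cache = list(X = X, pre = pre))
}

bwd_dense <- function(layer, cache, dOut) {
  if (layer$activation == "relu") dOut <- dOut * (cache$pre > 0)
  list(grads = list(W = crossprod(cache$X, dOut), b = colSums(dOut)),
       dX = dOut %*% t(layer$params$W))
}

## ---- Dispatch --------------------------------------------------------------

layer_forward <- function(layer, X, train) {
  switch(layer$type,
         conv1d = fwd_conv1d(layer, X, train),
         batchnorm = fwd_batchnorm(layer, X, train),
         maxpool = fwd_maxpool(layer, X, train),
         lstm = fwd_lstm(layer, X, train),
         bilstm = fwd_bilstm(layer, X, train),
         dropout = fwd_dropout(layer, X, train),
         dense = fwd_dense(layer, X, train),
         stop("unknown layer type ", layer$type))
}

layer_backward <- function(layer, cache, dOut) {
  switch(layer$type,
         conv1d = bwd_conv1d(layer, cache, dOut),
         batchnorm = bwd_batchnorm(layer, cache, dOut),
         maxpool = bwd_maxpool(layer, cache, dOut),
         lstm = bwd_lstm(layer, cache, dOut),
         bilstm = bwd_bilstm(layer, cache, dOut),
         dropout = bwd_dropout(layer, cache, dOut),
         dense = bwd_dense(layer, cache, dOut),
         stop("unknown layer type ", layer$type))
}

## flatten a layer's trainable parameter arrays into a named list keyed by
## "<layer index>/<param>" (bilstm recurses into its halves)
layer_param_list <- function(layer, prefix) {
  if (layer$type == "bilstm") {
    c(layer_param_list(layer$fwd, paste0(prefix, "/fwd")),
      layer_param_list(layer$bwd, paste0(prefix, "/bwd")))
  } else {
    out <- layer$params
    if (length(out) == 0L) return(list())
    names(out) <- paste0(prefix, "/", names(out))
    out
  }
}

layer_set_params <- function(layer, values, prefix) {
  if (layer$type == "bilstm") {
    layer$fwd <- layer_set_params(layer$fwd, values, paste0(prefix, "/fwd"))
    layer$bwd <- layer_set_params(layer$bwd, values, paste0(prefix, "/bwd"))
    return(layer)
  }
  for (p in names(layer$params)) {
    key <- paste0(prefix, "/", p)
    if (key %in% names(values)) layer$params[[p]] <- values[[key]]
  }
  layer
}

layer_grad_list <- function(layer, grads, prefix) {
  if (layer$type == "bilstm") {
    c(layer_grad_list(layer$fwd, grads$fwd, paste0(prefix, "/fwd")),
      layer_grad_list(layer$bwd, grads$bwd, paste0(prefix, "/bwd")))
  } else {
    if (length(grads) == 0L) return(list())
    names(grads) <- paste0(prefix, "/", names(grads))
    grads
  }
}
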