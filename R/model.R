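#' TCN branch configuration
#'
#' Architecture of the temporal convolutional branch: a stack of uniform
#' blocks, each applying channel-wise layer normalization, a causal dilated
#' 1-D convolution, a nonlinearity, (spatial) dropout, and a residual
#' connection (with a 1x1 projection when channel counts differ). The
#' number of blocks equals the number of dilation rates; with kernel size
#' `k` and dilations `d_1..d_n` the receptive field of the last timestep is
#' `1 + (k - 1) * sum(d_i)` samples.
#'
#' @param channels Channels per block.
#' @param kernel_size Convolution kernel size.
#' @param dilations Integer vector of dilation rates, one per block
#'   (typically powers of two).
#' @param dropout Dropout rate in `[0, 1)`, applied channel-wise during
#'   training.
#' @param activation `"relu"`, `"tanh"` or `"identity"`.
#' @param normalization `"layer"` (channel-wise layer normalization per
#'   timestep) or `"none"`.
#' @return A list of class `tcn_config`.
#' @export
tcn_config <- function(channels = 32, kernel_size = 3,
                       dilations = c(1, 2, 4), dropout = 0.2,
                       activation = "relu", normalization = "layer") {
  if (!all(dilations >= 1) || any(dilations != as.integer(dilations)))
    abort("dilations must be positive integers")
  if (dropout < 0 || dropout >= 1) abort("dropout must be in [0, 1)")
  if (!is_count(kernel_size, 1L)) abort("kernel_size must be a positive integer")
  activation <- match.arg(activation, c("relu", "tanh", "identity"))
  normalization <- match.arg(normalization, c("layer", "none"))
  structure(list(channels = as.integer(channels),
                 kernel_size = as.integer(kernel_size),
                 dilations = as.integer(dilations),
                 n_blocks = length(dilations),
                 dropout = dropout, activation = activation,
                 normalization = normalization),
            class = "tcn_config")
}

#' Hybrid / baseline model specification
#'
#' Describes one of the three architectures under study:
#' * `"hybrid"` — the TCN branch over the gait time series, a dense
#'   embedding branch over the static clinical features, concatenation,
#'   then a dense head with dropout and a single-neuron regression output;
#' * `"tcn_only"` — the identical TCN branch and head without the static
#'   concatenation;
#' * `"lstm"` — a recurrent LSTM layer with last-hidden-state readout
#'   feeding the same head.
#'
#' @param kind Model kind, see above.
#' @param tcn A [tcn_config()].
#' @param static_units Integer vector of dense-layer widths of the static
#'   branch (empty for a pass-through).
#' @param head_units Integer vector of hidden-layer widths of the fusion
#'   head (the single output neuron is implicit).
#' @param head_dropout Dropout rate of the head's hidden layers.
#' @param readout Temporal readout of the TCN branch: `"last"` timestep
#'   (the causal summary) or `"mean"` over time.
#' @param lstm_units Hidden state size of the LSTM baseline.
#' @param activation Activation of the static branch and head.
#' @return A list of class `model_spec` (`output_units` is always 1).
#' @export
model_spec <- function(kind = c("hybrid", "tcn_only", "lstm"),
                       tcn = tcn_config(), static_units = 16,
                       head_units = c(32, 16), head_dropout = 0.2,
                       readout = c("last", "mean"), lstm_units = 32,
                       activation = "relu") {
  kind <- match.arg(kind)
  readout <- match.arg(readout)
  if (head_dropout < 0 || head_dropout >= 1)
    abort("head_dropout must be in [0, 1)")
  activation <- match.arg(activation, c("relu", "tanh", "identity"))
  structure(list(kind = kind, tcn = tcn,
                 static_units = as.integer(static_units),
                 head_units = as.integer(head_units),
                 head_dropout = head_dropout, readout = readout,
                 lstm_units = as.integer(lstm_units),
                 activation = activation, output_units = 1L),
            class = "model_spec")
}

activation_fwd <- function(x, name) {
  switch(name, relu = pmax(x, 0), tanh = tanh(x), identity = x)
}

activation_grad <- function(pre, name) {
  switch(name,
         relu = (pre > 0) + 0,
         tanh = 1 - tanh(pre)^2,
         identity = array(1, dim = dim(pre) %||% length(pre)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_series_cube <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(nrow(x), ncol(x), 1L))
  if (length(dim(x)) != 3L) abort("series must be a matrix or 3-d array")
  x
}

#' Causal dilated 1-D convolution
#'
#' One convolutional operation `y = sigma(W * x + b)` where `*` is a
#' dilated causal convolution: with left zero-padding of
#' `(kernel_size - 1) * dilation` samples, `y[, t]` depends only on
#' `x[, t']` with `t' <= t`, and the output length equals the input
#' length.
#'
#' @param x Input series: channels x timesteps matrix, or a
#'   channels x timesteps x batch array.
#' @param W Weight array `(out_channels, in_channels, kernel_size)`.
#' @param b Bias vector of length `out_channels`.
#' @param dilation Dilation rate (>= 1).
#' @param activation Activation name (default identity).
#' @return Output with the same time/batch shape as `x` and
#'   `out_channels` rows.
#' @export
causal_conv_forward <- function(x, W, b, dilation = 1,
                                activation = "identity") {
  xc <- as_series_cube(x)
  if (dim(W)[2] != dim(xc)[1])
    abort("weight expects %d input channels, series has %d",
          dim(W)[2], dim(xc)[1])
  if (dilation < 1) abort("dilation must be >= 1")
  if ((dim(W)[3] - 1) * dilation + 1 > dim(xc)[2])
    abort("effective kernel length %d exceeds series length %d",
          (dim(W)[3] - 1) * dilation + 1, dim(xc)[2])
  y <- conv_causal_fwd_cpp(xc, W, as.numeric(b), as.integer(dilation))
  y <- activation_fwd(y, activation)
  if (is.matrix(x)) matrix(y, dim(y)[1], dim(y)[2]) else y
}

# Expand a (C x B) channel mask over time into a (C x T x B) cube factor.
expand_channel_mask <- function(mask, T) {
  array(mask[, rep(seq_len(ncol(mask)), each = T)],
        dim = c(nrow(mask), T, ncol(mask)))
}

#' Forward pass of one TCN block
#'
#' Composition: layer normalization, causal dilated convolution,
#' activation, channel-wise dropout (active only during training, with
#' inverted scaling so inference needs no rescaling), and residual
#' addition (identity when input and output channel counts match, a 1x1
#' projection otherwise).
#'
#' @param x Input series (matrix or channels x timesteps x batch array).
#' @param config A [tcn_config()].
#' @param block_index Which block's dilation rate to use.
#' @param params List with `W`, `b` and optionally `P` (1x1 projection).
#' @param training Enable dropout?
#' @return Block output, same time/batch shape, `config$channels` rows.
#' @export
tcn_block_forward <- function(x, config, block_index, params,
                              training = FALSE) {
  xc <- as_series_cube(x)
  res <- tcn_block_fwd_cached(xc, config, block_index, params, training)
  if (is.matrix(x)) matrix(res$out, dim(res$out)[1], dim(res$out)[2])
  else res$out
}

activation_code <- function(name) {
  switch(name, identity = 0L, relu = 1L, tanh = 2L)
}

tcn_block_fwd_cached <- function(xc, config, block_index, params,
                                 training = FALSE) {
  d <- dim(xc)
  if (dim(params$W)[2] != d[1])
    abort("TCN block %d: weight expects %d input channels, got %d",
          block_index, dim(params$W)[2], d[1])
  mask <- matrix(numeric(0), 0, 0)
  if (training && config$dropout > 0) {
    keep <- 1 - config$dropout
    mask <- matrix(rbinom(dim(params$W)[1] * d[3], 1, keep),
                   dim(params$W)[1], d[3]) / keep
  }
  res <- tcn_block_fwd_cpp(xc, params$W, as.numeric(params$b),
                           params$P %||% matrix(numeric(0), 0, 0),
                           as.integer(config$dilations[block_index]),
                           activation_code(config$activation),
                           config$normalization == "layer", mask)
  res$x_in <- xc
  res$mask <- mask
  res
}

tcn_block_bwd <- function(dOut, config, block_index, params, cache) {
  bb <- tcn_block_bwd_cpp(dOut, cache$x_in, cache$Xn, cache$sd, cache$pre,
                          params$W,
                          params$P %||% matrix(numeric(0), 0, 0),
                          as.integer(config$dilations[block_index]),
                          activation_code(config$activation),
                          config$normalization == "layer", cache$mask)
  grads <- list(W = bb$dW, b = as.numeric(bb$db))
  if (!is.null(params$P)) grads$P <- bb$dP
  list(dX = bb$dX, grads = grads)
}

dense_fwd <- function(A, W, b) W %*% A + b

#' Forward pass of the static feature branch
#'
#' A sequence of fully connected layers `y = sigma(W x + b)` applied to
#' the standardized static feature vector(s).
#'
#' @param f Static features: a vector or a features x batch matrix.
#' @param layers List of layers, each a list with `W` and `b`.
#' @param activation Activation name.
#' @return Embedding vector (or embedding x batch matrix).
#' @export
static_branch_forward <- function(f, layers, activation = "relu") {
  vec <- is.null(dim(f))
  A <- if (vec) matrix(f, ncol = 1) else f
  if (any(!is.finite(A))) abort("static features contain non-finite values")
  for (ly in layers) {
    if (ncol(ly$W) != nrow(A))
      abort("static layer expects %d inputs, got %d", ncol(ly$W), nrow(A))
    A <- activation_fwd(dense_fwd(A, ly$W, ly$b), activation)
  }
  if (vec) as.numeric(A) else A
}

#' Initialize model parameters
#'
#' He-style normal initialization for convolutional and dense weights
#' (variance `2 / fan_in` under ReLU, `1 / fan_in` otherwise), zero
#' biases; the LSTM uses uniform `(-1/sqrt(H), 1/sqrt(H))` weights with a
#' unit forget-gate bias. Deterministic given `seed`.
#'
#' @param spec A [model_spec()].
#' @param n_channels Number of time-series channels.
#' @param n_static Length of the static feature vector (hybrid only).
#' @param seed Integer seed.
#' @return Named list of parameter arrays.
#' @export
init_model <- function(spec, n_channels, n_static = NULL, seed = 1) {
  gain <- function(fan_in, act) {
    if (act == "relu") sqrt(2 / fan_in) else sqrt(1 / fan_in)
  }
  with_seed(seed, {
    params <- list()
    tc <- spec$tcn
    if (spec$kind %in% c("hybrid", "tcn_only")) {
      cin <- n_channels
      for (i in seq_len(tc$n_blocks)) {
        fan <- cin * tc$kernel_size
        params[[paste0("tcn", i, "_W")]] <-
          array(rnorm(tc$channels * cin * tc$kernel_size,
                      0, gain(fan, tc$activation)),
                dim = c(tc$channels, cin, tc$kernel_size))
        params[[paste0("tcn", i, "_b")]] <- numeric(tc$channels)
        if (cin != tc$channels)
          params[[paste0("tcn", i, "_P")]] <-
            matrix(rnorm(tc$channels * cin, 0, gain(cin, "identity")),
                   tc$channels, cin)
        cin <- tc$channels
      }
      branch_out <- tc$channels
    } else {
      H <- spec$lstm_units
      r <- 1 / sqrt(H)
      params$lstm_Wx <- matrix(runif(4 * H * n_channels, -r, r),
                               4 * H, n_channels)
      params$lstm_Wh <- matrix(runif(4 * H * H, -r, r), 4 * H, H)
      b <- numeric(4 * H)
      b[(H + 1):(2 * H)] <- 1
      params$lstm_b <- b
      branch_out <- H
    }
    head_in <- branch_out
    if (spec$kind == "hybrid") {
      if (is.null(n_static)) abort("hybrid model needs n_static")
      din <- n_static
      for (j in seq_along(spec$static_units)) {
        dout <- spec$static_units[j]
        params[[paste0("static", j, "_W")]] <-
          matrix(rnorm(dout * din, 0, gain(din, spec$activation)), dout, din)
        params[[paste0("static", j, "_b")]] <- numeric(dout)
        din <- dout
      }
      head_in <- branch_out + din
    }
    widths <- c(spec$head_units, 1L)
    din <- head_in
    for (j in seq_along(widths)) {
      act <- if (j == length(widths)) "identity" else spec$activation
      params[[paste0("head", j, "_W")]] <-
        matrix(rnorm(widths[j] * din, 0, gain(din, act)), widths[j], din)
      params[[paste0("head", j, "_b")]] <- numeric(widths[j])
      din <- widths[j]
    }
    params
  })
}

static_layer_params <- function(params, spec) {
  lapply(seq_along(spec$static_units), function(j)
    list(W = params[[paste0("static", j, "_W")]],
         b = params[[paste0("static", j, "_b")]]))
}

# Full batched forward pass with optional cache for backprop.
model_forward <- function(params, spec, X, S = NULL, training = FALSE,
                          keep_cache = FALSE) {
  X <- as_series_cube(X)
  d <- dim(X)
  B <- d[3]
  cache <- list(blocks = list(), head = list(), static = list())

  if (spec$kind %in% c("hybrid", "tcn_only")) {
    tc <- spec$tcn
    a <- X
    for (i in seq_len(tc$n_blocks)) {
      bp <- list(W = params[[paste0("tcn", i, "_W")]],
                 b = params[[paste0("tcn", i, "_b")]],
                 P = params[[paste0("tcn", i, "_P")]])
      res <- tcn_block_fwd_cached(a, tc, i, bp, training)
      if (keep_cache) cache$blocks[[i]] <- res
      a <- res$out
    }
    if (anyNA(a)) abort("NaN in forward pass at TCN branch output")
    branch <- if (spec$readout == "last") a[, d[2], , drop = TRUE]
              else apply(a, c(1, 3), mean)
    branch <- matrix(branch, nrow = tc$channels, ncol = B)
  } else {
    lf <- lstm_fwd_cpp(X, params$lstm_Wx, params$lstm_Wh, params$lstm_b)
    if (keep_cache) cache$lstm <- lf
    branch <- matrix(lf$H[, , d[2]], nrow = spec$lstm_units, ncol = B)
    if (anyNA(branch)) abort("NaN in forward pass at LSTM branch output")
  }

  if (spec$kind == "hybrid") {
    if (is.null(S)) abort("hybrid model needs static features")
    A <- S
    for (j in seq_along(spec$static_units)) {
      W <- params[[paste0("static", j, "_W")]]
      b <- params[[paste0("static", j, "_b")]]
      pre <- dense_fwd(A, W, b)
      if (keep_cache) cache$static[[j]] <- list(input = A, pre = pre)
      A <- activation_fwd(pre, spec$activation)
    }
    if (anyNA(A)) abort("NaN in forward pass at static branch output")
    fused <- rbind(branch, A)
    cache$n_branch <- nrow(branch)
  } else {
    fused <- branch
  }

  widths <- c(spec$head_units, 1L)
  A <- fused
  for (j in seq_along(widths)) {
    W <- params[[paste0("head", j, "_W")]]
    b <- params[[paste0("head", j, "_b")]]
    pre <- dense_fwd(A, W, b)
    last <- j == length(widths)
    act <- activation_fwd(pre, if (last) "identity" else spec$activation)
    mask <- NULL
    if (!last && training && spec$head_dropout > 0) {
      keep <- 1 - spec$head_dropout
      mask <- matrix(rbinom(length(act), 1, keep), nrow(act), ncol(act)) / keep
      act <- act * mask
    }
    if (keep_cache) cache$head[[j]] <- list(input = A, pre = pre, mask = mask)
    A <- act
  }
  yhat <- as.numeric(A)
  if (anyNA(yhat)) abort("NaN in forward pass at output layer")
  list(yhat = yhat, cache = if (keep_cache) cache else NULL)
}

# Gradients of all parameters given d loss / d yhat.
model_backward <- function(params, spec, X, S, cache, dyhat) {
  X <- as_series_cube(X)
  d <- dim(X)
  B <- d[3]
  grads <- list()
  widths <- c(spec$head_units, 1L)
  dA <- matrix(dyhat, nrow = 1)
  for (j in rev(seq_along(widths))) {
    hc <- cache$head[[j]]
    last <- j == length(widths)
    if (!last) {
      if (!is.null(hc$mask)) dA <- dA * hc$mask
      dA <- dA * activation_grad(hc$pre, spec$activation)
    }
    W <- params[[paste0("head", j, "_W")]]
    grads[[paste0("head", j, "_W")]] <- dA %*% t(hc$input)
    grads[[paste0("head", j, "_b")]] <- rowSums(dA)
    dA <- t(W) %*% dA
  }

  if (spec$kind == "hybrid") {
    nb <- cache$n_branch
    dBranch <- dA[seq_len(nb), , drop = FALSE]
    dS <- dA[-seq_len(nb), , drop = FALSE]
    for (j in rev(seq_along(spec$static_units))) {
      sc <- cache$static[[j]]
      dS <- dS * activation_grad(sc$pre, spec$activation)
      W <- params[[paste0("static", j, "_W")]]
      grads[[paste0("static", j, "_W")]] <- dS %*% t(sc$input)
      grads[[paste0("static", j, "_b")]] <- rowSums(dS)
      dS <- t(W) %*% dS
    }
  } else {
    dBranch <- dA
  }

  if (spec$kind %in% c("hybrid", "tcn_only")) {
    tc <- spec$tcn
    dOut <- array(0, dim = c(tc$channels, d[2], B))
    if (spec$readout == "last") {
      dOut[, d[2], ] <- dBranch
    } else {
      dOut <- expand_channel_mask(dBranch, d[2]) / d[2]
    }
    for (i in rev(seq_len(tc$n_blocks))) {
      bp <- list(W = params[[paste0("tcn", i, "_W")]],
                 b = params[[paste0("tcn", i, "_b")]],
                 P = params[[paste0("tcn", i, "_P")]])
      bb <- tcn_block_bwd(dOut, tc, i, bp, cache$blocks[[i]])
      grads[[paste0("tcn", i, "_W")]] <- bb$grads$W
      grads[[paste0("tcn", i, "_b")]] <- bb$grads$b
      if (!is.null(bb$grads$P)) grads[[paste0("tcn", i, "_P")]] <- bb$grads$P
      dOut <- bb$dX
    }
  } else {
    lb <- lstm_bwd_cpp(X, params$lstm_Wx, params$lstm_Wh,
                       cache$lstm$H, cache$lstm$C, cache$lstm$G, dBranch)
    grads$lstm_Wx <- lb$dWx
    grads$lstm_Wh <- lb$dWh
    grads$lstm_b <- as.numeric(lb$db)
  }
  grads
}

#' Forward pass of the hybrid model
#'
#' Runs the TCN branch over the time-series matrix, pools it over time
#' (last-timestep readout by default), concatenates the static embedding,
#' and applies the dense head ending in the single regression neuron.
#' With `training = FALSE` the pass is deterministic (dropout inactive).
#'
#' @param series Channels x timesteps matrix, or channels x timesteps x
#'   batch array.
#' @param statics Static feature vector (or features x batch matrix).
#' @param spec A [model_spec()] of kind `"hybrid"`.
#' @param params Parameters from [init_model()] or [train_model()].
#' @param training Enable dropout?
#' @return Predicted ACL force in BW (numeric, one value per batch item).
#' @export
hybrid_forward <- function(series, statics, spec, params,
                           training = FALSE) {
  stopifnot(spec$kind == "hybrid")
  if (is.null(dim(statics))) statics <- matrix(statics, ncol = 1)
  model_forward(params, spec, series, statics, training = training)$yhat
}

#' Forward pass of a baseline model
#'
#' Series-only baselines sharing the hybrid's head: `"tcn_only"` (the
#' identical TCN branch without the static concatenation) and `"lstm"`
#' (a recurrent layer with last-hidden-state readout).
#'
#' @param series Channels x timesteps matrix or array.
#' @param spec A [model_spec()] of the matching kind.
#' @param params Model parameters.
#' @param kind `"tcn_only"` or `"lstm"`; defaults to `spec$kind`.
#' @param training Enable dropout?
#' @return Predicted ACL force in BW.
#' @export
baseline_forward <- function(series, spec, params, kind = spec$kind,
                             training = FALSE) {
  if (!kind %in% c("tcn_only", "lstm"))
    abort("kind must be 'tcn_only' or 'lstm'")
  stopifnot(spec$kind == kind)
  model_forward(params, spec, series, NULL, training = training)$yhat
}
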