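#' Adam optimizer hyperparameters
#'
#' @param alpha Learning rate (> 0).
#' @param beta1,beta2 Exponential decay rates of the first and second
#'   moment estimates, in `[0, 1)`.
#' @param eps Numerical-stability constant (> 0).
#' @return A list of class `adam_hyper`.
#' @export
adam_hyper <- function(alpha = 0.001, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  if (alpha <= 0) abort("learning rate alpha must be positive")
  if (beta1 < 0 || beta1 >= 1 || beta2 < 0 || beta2 >= 1)
    abort("beta1 and beta2 must be in [0, 1)")
  if (eps <= 0) abort("eps must be positive")
  structure(list(alpha = alpha, beta1 = beta1, beta2 = beta2, eps = eps),
            class = "adam_hyper")
}

#' Initialize Adam optimizer state
#'
#' @param params Parameters: a numeric vector/array or a named list of
#'   arrays.
#' @return A list of class `adam_state` with first/second moment estimates
#'   `m`, `v` (zeroed, same shapes as `params`) and step counter `t = 0`.
#' @export
adam_init <- function(params) {
  zero_like <- function(p) {
    z <- p
    z[] <- 0
    z
  }
  mv <- if (is.list(params)) lapply(params, zero_like) else zero_like(params)
  structure(list(m = mv, v = mv, t = 0L), class = "adam_state")
}

adam_core <- function(theta, g, m, v, t, hyper) {
  m <- hyper$beta1 * m + (1 - hyper$beta1) * g
  v <- hyper$beta2 * v + (1 - hyper$beta2) * g^2
  m_hat <- m / (1 - hyper$beta1^t)
  v_hat <- v / (1 - hyper$beta2^t)
  theta <- theta - hyper$alpha * m_hat / (sqrt(v_hat) + hyper$eps)
  list(theta = theta, m = m, v = v)
}

#' One Adam update step
#'
#' Applies the Adam recurrences elementwise:
#' `m_t = beta1 m_{t-1} + (1 - beta1) g_t`,
#' `v_t = beta2 v_{t-1} + (1 - beta2) g_t^2`,
#' `m_hat = m_t / (1 - beta1^t)`, `v_hat = v_t / (1 - beta2^t)`,
#' `theta_{t+1} = theta_t - alpha m_hat / (sqrt(v_hat) + eps)`.
#' The step counter increments by exactly one per call. `theta` and `g`
#' may be numeric arrays or parallel named lists of arrays (one update
#' over all model parameters).
#'
#' @param theta Current parameters.
#' @param g Gradient of the loss at `theta` (same shape as `theta`).
#' @param state An [adam_init()] state.
#' @param hyper An [adam_hyper()].
#' @return List with updated `theta` and `state`.
#' @export
adam_update <- function(theta, g, state, hyper = adam_hyper()) {
  stopifnot(inherits(state, "adam_state"))
  t <- state$t + 1L
  if (is.list(theta)) {
    for (nm in names(theta)) {
      gi <- g[[nm]]
      if (is.null(gi)) abort("missing gradient for parameter '%s'", nm)
      if (any(!is.finite(gi)))
        abort("non-finite gradient for parameter '%s'", nm)
      up <- adam_core(theta[[nm]], gi, state$m[[nm]], state$v[[nm]], t, hyper)
      theta[[nm]] <- up$theta
      state$m[[nm]] <- up$m
      state$v[[nm]] <- up$v
    }
  } else {
    if (any(!is.finite(g))) abort("non-finite gradient")
    up <- adam_core(theta, g, state$m, state$v, t, hyper)
    theta <- up$theta
    state$m <- up$m
    state$v <- up$v
  }
  state$t <- t
  list(theta = theta, state = state)
}

#' Training configuration
#'
#' The reference protocol trains for 1000 epochs with mini-batches of 32
#' under mean-squared-error loss; smaller budgets are used for grid search
#' and for desk-scale experiments.
#'
#' @param epochs Number of passes over the training set (>= 1).
#' @param batch_size Mini-batch size (>= 1).
#' @param adam An [adam_hyper()].
#' @param shuffle Reshuffle examples every epoch?
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 1000, batch_size = 32,
                         adam = adam_hyper(), shuffle = TRUE) {
  if (!is_count(epochs, 1L)) abort("epochs must be a positive integer")
  if (!is_count(batch_size, 1L)) abort("batch_size must be a positive integer")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 adam = adam, shuffle = shuffle, loss = "mse"),
            class = "train_config")
}

#' Train a model by mini-batch Adam on MSE
#'
#' Minimizes the mean squared error of the single-neuron regression output
#' over the training set, with per-epoch shuffling and dropout draws taken
#' from the seeded RNG stream; given the same seed and inputs the loss
#' history and fitted parameters are reproducible exactly (single-threaded
#' arithmetic).
#'
#' @param series Channels x timesteps x examples array.
#' @param statics Features x examples matrix (ignored by series-only
#'   models; may be `NULL`).
#' @param labels Numeric vector of targets (BW).
#' @param spec A [model_spec()].
#' @param config A [train_config()].
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @return A list of class `fitted_model`: `params`, `loss_history` (one
#'   mean training MSE per epoch), `spec`, `config`.
#' @export
train_model <- function(series, statics, labels, spec, config = train_config(),
                        seed = 1) {
  series <- as_series_cube(series)
  n <- dim(series)[3]
  if (n == 0 || length(labels) == 0) abort("training set is empty")
  if (length(labels) != n)
    abort("labels length %d does not match %d examples", length(labels), n)
  needs_statics <- spec$kind == "hybrid"
  if (needs_statics) {
    if (is.null(statics)) abort("hybrid model needs static features")
    if (ncol(statics) != n)
      abort("statics columns %d do not match %d examples", ncol(statics), n)
  }
  # per-channel standardization of the series, fitted on the training set
  # (raw joint angles are tens of degrees while GRF is ~1 BW; a common
  # scale keeps the branch activations and the initial loss well behaved)
  series_center <- apply(series, 1, mean)
  series_scale <- apply(series, 1, sd)
  series_scale[!is.finite(series_scale) | series_scale == 0] <- 1
  series <- (series - series_center) / series_scale
  params <- init_model(spec, dim(series)[1],
                       if (needs_statics) nrow(statics) else NULL,
                       seed = derive_seed(seed, 1))
  # flat-vector Adam state (same recurrences as adam_update, via adam_core)
  pnames <- names(params)
  plens <- vapply(params, length, integer(1))
  pends <- cumsum(plens)
  pstarts <- pends - plens + 1L
  theta <- unlist(params, use.names = FALSE)
  m <- v <- numeric(length(theta))
  tstep <- 0L
  loss_history <- numeric(config$epochs)
  with_seed(derive_seed(seed, 2), {
    for (ep in seq_len(config$epochs)) {
      ord <- if (config$shuffle) sample.int(n) else seq_len(n)
      starts <- seq(1, n, by = config$batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1, n)]
        Xb <- series[, , idx, drop = FALSE]
        Sb <- if (needs_statics) statics[, idx, drop = FALSE] else NULL
        yb <- labels[idx]
        fw <- model_forward(params, spec, Xb, Sb, training = TRUE,
                            keep_cache = TRUE)
        resid <- fw$yhat - yb
        ep_loss <- ep_loss + sum(resid^2)
        dyhat <- 2 * resid / length(idx)
        grads <- model_backward(params, spec, Xb, Sb, fw$cache, dyhat)
        g <- unlist(grads[pnames], use.names = FALSE)
        if (any(!is.finite(g))) {
          bad <- which(pends >= which(!is.finite(g))[1])[1]
          abort("non-finite gradient for parameter '%s'", pnames[bad])
        }
        tstep <- tstep + 1L
        up <- adam_core(theta, g, m, v, tstep, config$adam)
        theta <- up$theta
        m <- up$m
        v <- up$v
        for (j in seq_along(pnames))
          params[[j]][] <- theta[pstarts[j]:pends[j]]
      }
      loss_history[ep] <- ep_loss / n
    }
  })
  structure(list(params = params, loss_history = loss_history,
                 spec = spec, config = config, seed = seed,
                 series_center = series_center,
                 series_scale = series_scale),
            class = "fitted_model")
}

#' Predict with a fitted model
#'
#' @param object A [train_model()] fit.
#' @param series Channels x timesteps x examples array.
#' @param statics Features x examples matrix (hybrid only).
#' @param ... Unused.
#' @return Numeric vector of predictions (BW); deterministic (dropout
#'   inactive).
#' @export
predict.fitted_model <- function(object, series, statics = NULL, ...) {
  series <- as_series_cube(series)
  series <- (series - object$series_center) / object$series_scale
  model_forward(object$params, object$spec, series,
                if (object$spec$kind == "hybrid") statics else NULL,
                training = FALSE)$yhat
}

#' Default hyperparameter grid
#'
#' The three searched axes: learning rate, dilation scheme of the
#' convolutional blocks, and dropout rate.
#'
#' @return A named list defining the grid.
#' @export
default_grid <- function() {
  list(learning_rate = c(1e-2, 1e-3, 1e-4),
       dilations = list(c(1L, 2L, 4L), c(1L, 2L, 4L, 8L)),
       dropout = c(0.1, 0.2, 0.3))
}

apply_grid_cell <- function(spec, config, cell) {
  if (!is.null(cell$learning_rate)) config$adam$alpha <- cell$learning_rate
  if (!is.null(cell$dilations) && !is.null(spec$tcn)) {
    spec$tcn$dilations <- as.integer(cell$dilations)
    spec$tcn$n_blocks <- length(cell$dilations)
  }
  if (!is.null(cell$dropout)) {
    if (!is.null(spec$tcn)) spec$tcn$dropout <- cell$dropout
    spec$head_dropout <- cell$dropout
  }
  list(spec = spec, config = config)
}

#' Grid search over training hyperparameters
#'
#' Trains one model per grid cell on an inner split of the training data
#' (the validation examples are held out of every cell's training subset)
#' and scores each cell by validation R-squared. Cells whose training
#' fails or diverges receive a score of `-Inf`. Ties are broken by lower
#' dropout, then lower learning rate, then declaration order. Grid-search
#' training uses a reduced epoch budget; the winning cell is meant to be
#' retrained at the full budget.
#'
#' @param grid Named list with any of `learning_rate`, `dilations`
#'   (list of integer vectors), `dropout`. See [default_grid()].
#' @param series,statics,labels Training data as in [train_model()].
#' @param spec Base [model_spec()].
#' @param config Base [train_config()]; `epochs` is overridden by the
#'   `epochs` argument during the search.
#' @param val_fraction Inner hold-out fraction.
#' @param epochs Epochs per grid cell.
#' @param seed Integer seed (split and per-cell training).
#' @return List with `best` (winning cell: values, spec, config),
#'   `table` (one row per cell with its validation score), `train_ids`,
#'   `val_ids`.
#' @export
grid_search <- function(grid, series, statics, labels, spec,
                        config = train_config(), val_fraction = 0.2,
                        epochs = 100, seed = 1) {
  if (!length(grid)) abort("grid is empty")
  series <- as_series_cube(series)
  n <- dim(series)[3]
  n_val <- max(1L, round(val_fraction * n))
  if (n_val >= n) abort("validation fraction leaves no training data")
  val_ids <- with_seed(derive_seed(seed, 1), sort(sample.int(n, n_val)))
  train_ids <- setdiff(seq_len(n), val_ids)

  lr <- grid$learning_rate %||% NA_real_
  dil <- grid$dilations %||% list(NULL)
  dr <- grid$dropout %||% NA_real_
  cells <- expand.grid(learning_rate = lr,
                       dilation_scheme = seq_along(dil),
                       dropout = dr, KEEP.OUT.ATTRS = FALSE)
  cells$order <- seq_len(nrow(cells))

  score <- numeric(nrow(cells))
  diag_msg <- character(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- list(
      learning_rate = if (is.na(cells$learning_rate[i])) NULL
                      else cells$learning_rate[i],
      dilations = dil[[cells$dilation_scheme[i]]],
      dropout = if (is.na(cells$dropout[i])) NULL else cells$dropout[i])
    mod <- apply_grid_cell(spec, config, cell)
    mod$config$epochs <- as.integer(epochs)
    score[i] <- tryCatch({
      fit <- train_model(series[, , train_ids, drop = FALSE],
                         if (is.null(statics)) NULL
                         else statics[, train_ids, drop = FALSE],
                         labels[train_ids], mod$spec, mod$config,
                         seed = derive_seed(seed, 100 + i))
      pred <- predict(fit, series[, , val_ids, drop = FALSE],
                      if (is.null(statics)) NULL
                      else statics[, val_ids, drop = FALSE])
      if (any(!is.finite(pred))) stop("non-finite validation predictions")
      r_squared(labels[val_ids], pred)
    }, error = function(e) {
      diag_msg[i] <<- conditionMessage(e)
      -Inf
    })
  }
  tab <- data.frame(
    learning_rate = cells$learning_rate,
    dilations = vapply(cells$dilation_scheme, function(k)
      paste(dil[[k]] %||% "-", collapse = ","), character(1)),
    dropout = cells$dropout,
    val_r2 = score, note = diag_msg, stringsAsFactors = FALSE)
  if (all(!is.finite(score)))
    abort("all grid cells failed to train:\n%s",
          paste(sprintf("  cell %d: %s", seq_along(diag_msg), diag_msg),
                collapse = "\n"))
  ord <- order(-score,
               if (all(is.na(cells$dropout))) cells$order else cells$dropout,
               if (all(is.na(cells$learning_rate))) cells$order
               else cells$learning_rate,
               cells$order)
  best_i <- ord[1]
  best_cell <- list(
    learning_rate = if (is.na(cells$learning_rate[best_i])) NULL
                    else cells$learning_rate[best_i],
    dilations = dil[[cells$dilation_scheme[best_i]]],
    dropout = if (is.na(cells$dropout[best_i])) NULL
              else cells$dropout[best_i])
  best <- apply_grid_cell(spec, config, best_cell)
  list(best = c(best_cell, list(spec = best$spec, config = best$config),
                val_r2 = score[best_i]),
       table = tab, train_ids = train_ids, val_ids = val_ids)
}
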