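test_that("causal convolution reduces to identity and respects causality", {
  x <- matrix(rnorm(40), 2, 20)
  W <- array(0, c(2, 2, 1))
  W[1, 1, 1] <- 1
  W[2, 2, 1] <- 1
  expect_equal(causal_conv_forward(x, W, c(0, 0), 1), x, tolerance = 1e-12)
  # perturbing the input at t0 leaves all earlier outputs unchanged
  set.seed(4)
  W2 <- array(rnorm(3 * 2 * 3), c(3, 2, 3))
  xp <- x
  t0 <- 12
  xp[, t0] <- xp[, t0] + 5
  y1 <- causal_conv_forward(xp, W2, rep(0, 3), dilation = 2)
  y0b <- causal_conv_forward(x, W2, rep(0, 3), dilation = 2)
  expect_equal(y1[, 1:(t0 - 1)], y0b[, 1:(t0 - 1)], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(y1[, t0:20], y0b[, t0:20])))
  expect_error(causal_conv_forward(x, W2, rep(0, 3), dilation = 30),
               "exceeds")
})

test_that("causal convolution matches a brute-force nested-loop oracle", {
  set.seed(11)
  for (i in 1:25) {
    Cin <- sample(1:3, 1); Cout <- sample(1:3, 1)
    K <- sample(1:3, 1); d <- sample(1:3, 1)
    T <- sample(8:15, 1)
    x <- matrix(rnorm(Cin * T), Cin, T)
    W <- array(rnorm(Cout * Cin * K), c(Cout, Cin, K))
    b <- rnorm(Cout)
    expect_equal(causal_conv_forward(x, W, b, d), conv_oracle(x, W, b, d),
                 tolerance = 1e-9)
  }
})

test_that("TCN blocks compose normalization, convolution, dropout and residual", {
  cfg <- tcn_config(channels = 6, kernel_size = 2, dilations = c(1, 2),
                    dropout = 0)
  params <- init_model(model_spec("tcn_only", tcn = cfg, head_units = 4),
                       n_channels = 6, seed = 3)
  bp <- list(W = params$tcn1_W, b = params$tcn1_b, P = NULL)
  x <- matrix(rnorm(6 * 30), 6, 30)
  # dropout rate 0: training on and off agree
  set.seed(1)
  y_tr <- tcn_block_forward(x, cfg, 1, bp, training = TRUE)
  y_te <- tcn_block_forward(x, cfg, 1, bp, training = FALSE)
  expect_identical(y_tr, y_te)
  # zero input, zero bias, odd activation: output is zero
  cfg_t <- tcn_config(channels = 6, kernel_size = 2, dilations = c(1, 2),
                      dropout = 0, activation = "tanh")
  z <- matrix(0, 6, 30)
  expect_equal(tcn_block_forward(z, cfg_t, 1, bp, training = FALSE),
               z, tolerance = 1e-12)
  expect_error(tcn_block_forward(matrix(0, 3, 30), cfg, 1, bp), "block 1")
})

test_that("stacked dilations 1,2,4 with kernel 2 give an 8-sample receptive field", {
  cfg <- tcn_config(channels = 5, kernel_size = 2, dilations = c(1, 2, 4),
                    dropout = 0, normalization = "none")
  spec <- model_spec("tcn_only", tcn = cfg, head_units = integer(0))
  T <- 30
  params <- init_model(spec, n_channels = 5, seed = 8)
  x <- array(rnorm(5 * T), c(5, T, 1))
  base <- baseline_forward(x, spec, params, "tcn_only")
  probe <- function(t0) {
    xp <- x
    xp[, t0, 1] <- xp[, t0, 1] + 10
    baseline_forward(xp, spec, params, "tcn_only")
  }
  rf <- 1 + (2 - 1) * (1 + 2 + 4)
  expect_equal(probe(T - rf), base, tolerance = 1e-12)   # outside the field
  expect_false(isTRUE(all.equal(probe(T - rf + 1), base)))  # just inside
})

test_that("the static branch is the printed affine map", {
  # identity weights pass the features through
  f <- c(0.5, -1.2)
  layers <- list(list(W = diag(2), b = c(0, 0)))
  expect_equal(static_branch_forward(f, layers, "identity"), f)
  # hand-set 2x2 affine map, identity activation
  W <- matrix(c(1, 2, 3, 4), 2, 2)
  b <- c(0.1, -0.2)
  expect_equal(static_branch_forward(f, list(list(W = W, b = b)), "identity"),
               as.numeric(W %*% f + b), tolerance = 1e-12)
  # zero input, zero bias
  expect_equal(static_branch_forward(c(0, 0), list(list(W = W, b = c(0, 0)))),
               pmax(as.numeric(W %*% c(0, 0)), 0))
  expect_error(static_branch_forward(c(1, 2, 3), list(list(W = W, b = b))),
               "expects 2")
})

test_that("hybrid forward has dead-branch ablation identities", {
  spec <- tiny_spec("hybrid")
  set.seed(2)
  x <- array(rnorm(4 * 25 * 2), c(4, 25, 2))
  s <- matrix(rnorm(11 * 2), 11, 2)
  params <- init_model(spec, 4, 11, seed = 5)
  # zero the static branch: prediction ignores statics
  p0 <- params
  p0$static1_W[] <- 0
  p0$static1_b[] <- 0
  expect_equal(hybrid_forward(x, s, spec, p0),
               hybrid_forward(x, s * 10 + 3, spec, p0), tolerance = 1e-12)
  # zero the TCN branch: prediction ignores the series
  p1 <- params
  for (nm in grep("^tcn", names(p1), value = TRUE)) p1[[nm]][] <- 0
  expect_equal(hybrid_forward(x, s, spec, p1),
               hybrid_forward(x * 10 + 3, s, spec, p1), tolerance = 1e-12)
  # deterministic with training off
  expect_identical(hybrid_forward(x, s, spec, params),
                   hybrid_forward(x, s, spec, params))
  # NaN rejection names the offending stage
  pn <- params
  pn$head1_W[1] <- NaN
  expect_error(hybrid_forward(x, s, spec, pn), "NaN")
})

test_that("tcn_only equals the hybrid with a zeroed static branch and matched head", {
  hs <- model_spec("hybrid",
                   tcn = tcn_config(channels = 8, kernel_size = 2,
                                    dilations = c(1, 2), dropout = 0),
                   static_units = 6, head_units = 10, head_dropout = 0)
  bs <- model_spec("tcn_only", tcn = hs$tcn, head_units = 10,
                   head_dropout = 0)
  ph <- init_model(hs, 4, 11, seed = 9)
  ph$static1_W[] <- 0
  ph$static1_b[] <- 0
  pb <- list(tcn1_W = ph$tcn1_W, tcn1_b = ph$tcn1_b, tcn1_P = ph$tcn1_P,
             tcn2_W = ph$tcn2_W, tcn2_b = ph$tcn2_b,
             head1_W = ph$head1_W[, 1:8, drop = FALSE], head1_b = ph$head1_b,
             head2_W = ph$head2_W, head2_b = ph$head2_b)
  set.seed(3)
  x <- array(rnorm(4 * 20 * 3), c(4, 20, 3))
  s <- matrix(rnorm(11 * 3), 11, 3)
  expect_equal(baseline_forward(x, bs, pb, "tcn_only"),
               hybrid_forward(x, s, hs, ph), tolerance = 1e-12)
})

test_that("LSTM readout is zero for all-zero input and zero biases", {
  spec <- tiny_spec("lstm")
  params <- init_model(spec, 4, seed = 13)
  params$lstm_b[] <- 0
  x0 <- array(0, c(4, 15, 2))
  # hidden state stays zero, so the prediction equals the head at zero
  head_at_zero <- static_branch_forward(rep(0, spec$lstm_units),
                                        list(list(W = params$head1_W,
                                                  b = params$head1_b)))
  out <- static_branch_forward(head_at_zero,
                               list(list(W = params$head2_W,
                                         b = params$head2_b)), "identity")
  expect_equal(baseline_forward(x0, spec, params, "lstm"), rep(out, 2),
               tolerance = 1e-12)
  expect_identical(baseline_forward(x0, spec, params, "lstm"),
                   baseline_forward(x0, spec, params, "lstm"))
})

test_that("backpropagation matches finite-difference gradients", {
  num_grad <- function(fun, params, eps = 1e-6) {
    g <- params
    for (nm in names(params)) {
      gp <- params[[nm]]
      for (i in seq_along(gp)) {
        pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
        gp[i] <- (fun(pp) - fun(pm)) / (2 * eps)
      }
      g[[nm]] <- gp
    }
    g
  }
  set.seed(17)
  cases <- list(list("hybrid", "last"), list("hybrid", "mean"),
                list("tcn_only", "last"), list("lstm", "last"))
  for (case in cases) {
    kind <- case[[1]]
    spec <- model_spec(kind,
                       tcn = tcn_config(channels = 4, kernel_size = 2,
                                        dilations = c(1, 2), dropout = 0,
                                        activation = "tanh"),
                       static_units = 3, head_units = 3, head_dropout = 0,
                       lstm_units = 3, activation = "tanh",
                       readout = case[[2]])
    X <- array(rnorm(2 * 8 * 3), c(2, 8, 3))
    S <- if (kind == "hybrid") matrix(rnorm(4 * 3), 4, 3) else NULL
    y <- rnorm(3)
    params <- init_model(spec, 2, if (kind == "hybrid") 4 else NULL, seed = 7)
    lossfun <- function(p)
      mean((aclgait:::model_forward(p, spec, X, S)$yhat - y)^2)
    fw <- aclgait:::model_forward(params, spec, X, S, training = TRUE,
                                  keep_cache = TRUE)
    gr <- aclgait:::model_backward(params, spec, X, S, fw$cache,
                                   2 * (fw$yhat - y) / 3)
    ng <- num_grad(lossfun, params)
    err <- max(unlist(Map(function(a, b) max(abs(a - b)),
                          gr[names(params)], ng)))
    expect_lt(err, 1e-6)
  }
})
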