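test_that("Adam follows the printed recurrences exactly", {
  h <- adam_hyper()
  st <- adam_init(0)
  # one step from theta = 0 with g = 1: m = 0.1, v = 0.001,
  # bias-corrected moments both 1, step of -alpha
  up <- adam_update(0, 1, st, h)
  expect_equal(up$state$m, 0.1, tolerance = 1e-12)
  expect_equal(up$state$v, 0.001, tolerance = 1e-12)
  expect_identical(up$state$t, 1L)
  expect_lt(abs(up$theta - (-0.001)), 1e-9)
  # zero gradients never move the parameters
  th <- 1.5
  st <- adam_init(th)
  for (i in 1:5) {
    up <- adam_update(th, 0, st, h)
    th <- up$theta
    st <- up$state
  }
  expect_identical(th, 1.5)
  expect_identical(st$t, 5L)
  # odd symmetry: flipping the gradient sign flips the step
  u1 <- adam_update(0.3, 0.7, adam_init(0.3), h)
  u2 <- adam_update(0.3, -0.7, adam_init(0.3), h)
  expect_equal(u1$theta - 0.3, -(u2$theta - 0.3), tolerance = 1e-15)
  expect_error(adam_update(0, NaN, adam_init(0), h), "non-finite")
})

test_that("Adam matches an independent transcription on random trajectories", {
  set.seed(6)
  for (r in 1:5) {
    grads <- rnorm(40)
    theta <- rnorm(1)
    ref <- adam_oracle_trajectory(theta, grads)
    st <- adam_init(theta)
    got <- numeric(40)
    for (t in 1:40) {
      up <- adam_update(theta, grads[t], st, adam_hyper())
      theta <- up$theta
      st <- up$state
      got[t] <- theta
    }
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("Adam updates whole parameter lists elementwise", {
  params <- list(W = matrix(1:4 / 10, 2, 2), b = c(0, 0))
  grads <- list(W = matrix(1, 2, 2), b = c(1, -1))
  up <- adam_update(params, grads, adam_init(params), adam_hyper())
  expect_equal(dim(up$theta$W), c(2L, 2L))
  expect_equal(up$theta$W, params$W - 0.001, tolerance = 1e-6)
  expect_equal(up$theta$b, c(-0.001, 0.001), tolerance = 1e-6)
  expect_error(adam_update(params, list(W = grads$W), adam_init(params)),
               "missing gradient")
})

test_that("training is seeded, shaped and fails loudly on empty input", {
  co <- tiny_cohort()
  sc <- fit_static_scaler(co$profiles)
  S <- build_feature_matrix(co$profiles, sc)[, co$meta$subject_id]
  spec <- tiny_spec("hybrid")
  cfg <- train_config(epochs = 8, batch_size = 8)
  f1 <- train_model(co$series, S, co$labels, spec, cfg, seed = 3)
  f2 <- train_model(co$series, S, co$labels, spec, cfg, seed = 3)
  expect_length(f1$loss_history, 8)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(f1$params, f2$params)
  f3 <- train_model(co$series, S, co$labels, spec, cfg, seed = 4)
  expect_false(identical(f1$loss_history, f3$loss_history))
  expect_error(train_model(co$series[, , 0, drop = FALSE], S[, 0],
                           numeric(0), spec, cfg), "empty")
})

test_that("training loss trends down on the synthetic cohort", {
  co <- tiny_cohort()
  sc <- fit_static_scaler(co$profiles)
  S <- build_feature_matrix(co$profiles, sc)[, co$meta$subject_id]
  fit <- train_model(co$series, S, co$labels, tiny_spec("hybrid"),
                     train_config(epochs = 40, batch_size = 8), seed = 5)
  n <- length(fit$loss_history)
  first <- fit$loss_history[1:(n / 10)]
  last <- fit$loss_history[(n - n / 10 + 1):n]
  expect_lt(median(last), median(first))
})

test_that("the default hybrid architecture can memorize 32 examples", {
  # capacity sanity: full-batch Adam drives training MSE below 1e-3 well
  # within 2000 steps (dropout off, since this probes capacity)
  set.seed(5)
  X <- array(rnorm(4 * 101 * 32), c(4, 101, 32))
  S <- matrix(rnorm(11 * 32), 11, 32)
  y <- runif(32)
  spec <- model_spec("hybrid", tcn = tcn_config(dropout = 0),
                     head_dropout = 0)
  fit <- train_model(X, S, y, spec,
                     train_config(epochs = 800, batch_size = 32), seed = 2)
  expect_lt(mean((predict(fit, X, S) - y)^2), 1e-3)
})

test_that("grid search scores cells on a leak-free inner split", {
  co <- tiny_cohort()
  sc <- fit_static_scaler(co$profiles)
  S <- build_feature_matrix(co$profiles, sc)[, co$meta$subject_id]
  spec <- tiny_spec("hybrid")
  cfg <- train_config(batch_size = 8)
  # singleton grid returns that combination
  g1 <- grid_search(list(learning_rate = 0.005), co$series, S, co$labels,
                    spec, cfg, epochs = 3, seed = 2)
  expect_equal(g1$best$learning_rate, 0.005)
  expect_identical(nrow(g1$table), 1L)
  # leakage guard: validation ids never appear in the training subset
  expect_length(intersect(g1$train_ids, g1$val_ids), 0)
  expect_setequal(union(g1$train_ids, g1$val_ids), seq_along(co$labels))
  # full grid: one row per cell, degenerate learning rate never wins
  g2 <- grid_search(list(learning_rate = c(1e3, 1e-3),
                         dropout = c(0.1, 0.2)),
                    co$series, S, co$labels, spec, cfg, epochs = 3, seed = 2)
  expect_identical(nrow(g2$table), 4L)
  expect_false(isTRUE(all.equal(g2$best$learning_rate, 1e3)))
  expect_error(grid_search(list(), co$series, S, co$labels, spec, cfg),
               "empty")
})
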