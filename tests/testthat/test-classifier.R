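test_that("SELU closed-form values and network parameter count", {
  expect_identical(selu(0), 0)
  expect_equal(selu(1), 1.0507009873554805, tolerance = 1e-12)
  x <- c(0.3, 1.7, 4)
  expect_equal(selu(x), 1.0507009873554805 * x, tolerance = 1e-12)
  expect_equal(selu(-1e9), -1.0507009873554805 * 1.6732632423543772,
               tolerance = 1e-6)                     # negative saturation limit
  model <- build_snn(snn_spec(n_layers = 8, width = 50), n_inputs = 4)
  expect_equal(snn_parameter_count(model), 18151)
})

test_that("down-sampling balances the reference pool sizes exactly", {
  feats <- data.frame(delta_eps = rnorm(810, 68), tau_ps = rnorm(810, 9),
                      alpha = rnorm(810, 0.985, 0.003),
                      sigma_dc = rnorm(810, 0.9, 0.02))
  labels <- rep(c(TRUE, FALSE), c(168, 642))
  bal <- balance_downsample(feats, labels, seed = 1)
  expect_equal(sum(bal$labels), 168)
  expect_equal(sum(!bal$labels), 168)
  expect_identical(balance_downsample(feats, labels, seed = 1)$index, bal$index)
  expect_false(identical(balance_downsample(feats, labels, seed = 2)$index,
                         bal$index))
  # already balanced input passes through
  bal2 <- balance_downsample(feats[1:20, ], rep(c(TRUE, FALSE), 10), seed = 1)
  expect_equal(bal2$index, 1:20)
  expect_error(balance_downsample(feats, rep(TRUE, 810)), "both classes")
})

test_that("feature scaling is a fixed invertible map", {
  feats <- data.frame(delta_eps = 70, tau_ps = 0, alpha = 0.985, sigma_dc = 0.9)
  x <- scale_features(feats)
  expect_equal(x[1, "delta_eps"], 1.0, ignore_attr = TRUE)
  expect_equal(x[1, "tau_ps"], 0, ignore_attr = TRUE)   # zero in, zero out
  scales <- c(delta_eps = 70, tau_ps = 10, alpha = 1, sigma_dc = 1)
  back <- sweep(x, 2, scales, `*`)
  expect_equal(unname(back[1, ]), unname(as.matrix(feats)[1, ]),
               tolerance = 1e-12)
  expect_error(scale_features(feats, scales = c(delta_eps = -1, tau_ps = 10,
                                                alpha = 1, sigma_dc = 1)),
               "positive")
  # the network reference frame standardises typical cohorts
  pool <- latent_pool(150, seed = 40)
  ref <- snn_reference_frame()
  z <- scale_features(pool$features, ref$scale, ref$center)
  expect_true(all(abs(colMeans(z)) < 1.5))
  expect_true(all(apply(z, 2, sd) > 0.3 & apply(z, 2, sd) < 3))
})

test_that("holdout split is an exact stratified partition", {
  pool <- latent_pool(168, seed = 50)
  sp <- holdout_split(pool$features, pool$labels, test_per_class = 15, seed = 1)
  expect_equal(length(sp$test$labels), 30)
  expect_equal(sum(sp$test$labels), 15)
  expect_equal(length(sp$train$labels), 306)
  expect_setequal(c(sp$train$index, sp$test$index), seq_len(336))
  expect_length(intersect(sp$train$index, sp$test$index), 0)
  sp2 <- holdout_split(pool$features, pool$labels, test_per_class = 15, seed = 2)
  expect_false(identical(sp$test$index, sp2$test$index))
  sp0 <- holdout_split(pool$features, pool$labels, test_per_class = 0, seed = 1)
  expect_equal(length(sp0$test$labels), 0)
  expect_equal(length(sp0$train$labels), 336)
  expect_error(holdout_split(pool$features[1:20, ], pool$labels[1:20],
                             test_per_class = 15), "fewer")
})

test_that("self-normalization holds through all eight layers at init", {
  model <- build_snn(seed = 7)
  set.seed(99)
  x <- matrix(rnorm(1000 * 4), 1000, 4)
  fw <- lactowave:::snn_forward(model, x, training = FALSE)
  for (l in 1:8) {
    expect_gt(mean(fw$pre[[l]]), -0.3)
    expect_lt(mean(fw$pre[[l]]), 0.3)
    v <- mean(apply(fw$pre[[l]], 2, var))
    expect_gt(v, 0.5)
    expect_lt(v, 1.5)
  }
})

test_that("training is reproducible and learns a separable problem", {
  set.seed(2)
  n <- 80
  x <- rbind(matrix(rnorm(4 * n, -0.6), ncol = 4),
             matrix(rnorm(4 * n, 0.6), ncol = 4))
  y <- rep(c(0, 1), each = n)
  m <- build_snn(seed = 3)
  tr1 <- train_snn(m, x, y, epochs = 20, seed = 5)
  tr2 <- train_snn(m, x, y, epochs = 20, seed = 5)
  expect_identical(tr1$model$weights, tr2$model$weights)
  expect_identical(tr1$curves, tr2$curves)
  expect_lte(tr1$curves$train_loss[20], tr1$curves$train_loss[1])
  expect_gt(tail(tr1$curves$train_accuracy, 1), 0.75)
})

test_that("alpha dropout is train-only: inference is deterministic", {
  pool <- latent_pool(60, seed = 60)
  ref <- snn_reference_frame()
  x <- scale_features(pool$features, ref$scale, ref$center)
  m <- build_snn(seed = 4)
  tr <- train_snn(m, x, pool$labels, epochs = 5, seed = 6)
  e1 <- evaluate_snn(tr$model, x, pool$labels)
  e2 <- evaluate_snn(tr$model, x, pool$labels)
  expect_identical(e1, e2)
  expect_error(evaluate_snn(tr$model, x[0, , drop = FALSE], logical(0)),
               "empty")
  # trivial evaluators: perfect and constant predictors
  expect_equal(mean((c(0.9, 0.1, 0.8) > 0.5) == c(TRUE, FALSE, TRUE)), 1)
})

test_that("label shuffling drives validation accuracy to chance", {
  accs <- vapply(1:10, function(s) {
    pool <- latent_pool(60, seed = 70 + s)
    labs <- with_seed_shuffle(pool$labels, seed = s)
    classify_pregnancy(pool$features, labs, seed = s,
                       test_per_class = 10)$test_accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.65)
})

test_that("the full classifier pipeline separates the synthetic states", {
  accs <- vapply(1:10, function(s) {
    pool <- latent_pool(168, seed = 200 + s)
    classify_pregnancy(pool$features, pool$labels, seed = s,
                       test_per_class = 15)$test_accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.6)
})
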