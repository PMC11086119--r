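# Self-normalizing neural network (SNN) pregnancy classifier.
# Pure matrix implementation: SELU activations, alpha dropout, ADAM, binary
# cross-entropy.  The network is small (4 -> 8 x 50 -> 1) and the data sets
# are a few hundred rows, so dense base-R linear algebra is the right tool.

# SELU constants (fixed by the self-normalizing fixed-point derivation).
SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

#' Scaled exponential linear unit
#'
#' `selu(x) = lambda * x` for `x > 0` and
#' `lambda * alpha * (exp(x) - 1)` otherwise, with the fixed
#' self-normalizing constants.
#'
#' @param x numeric vector/matrix.
#' @return transformed values.
#' @examples
#' selu(0); selu(1)  # 0, ~1.0507
#' @export
selu <- function(x) SELU_LAMBDA * ifelse(x > 0, x, SELU_ALPHA * (exp(x) - 1))

selu_grad <- function(x) SELU_LAMBDA * ifelse(x > 0, 1, SELU_ALPHA * exp(x))

# Alpha dropout: dropped units saturate to the SELU negative limit
# alpha' = -lambda * alpha, then an affine correction restores zero mean /
# unit variance.  Returns the transformed matrix and the backprop scale.
alpha_dropout <- function(x, p) {
  if (p <= 0) return(list(x = x, grad = 1))
  q <- 1 - p
  ap <- -SELU_LAMBDA * SELU_ALPHA
  keep <- matrix(stats::runif(length(x)) < q, nrow(x), ncol(x))
  x[!keep] <- ap
  a <- 1 / sqrt(q * (1 + p * ap^2))
  b <- -a * p * ap
  list(x = a * x + b, grad = a * keep)
}

#' Network architecture specification
#'
#' @param n_layers number of hidden SELU layers.
#' @param width neurons per hidden layer.
#' @param dropout_p alpha-dropout probability per hidden layer.
#' @return list of class `snn_spec`.
#' @export
snn_spec <- function(n_layers = 8L, width = 50L, dropout_p = 0.01) {
  stopifnot(n_layers >= 1, width >= 1, dropout_p >= 0, dropout_p < 1)
  structure(list(n_layers = as.integer(n_layers), width = as.integer(width),
                 dropout_p = dropout_p), class = "snn_spec")
}

#' Build a self-normalizing network
#'
#' Feed-forward binary classifier: `n_inputs` features, `n_layers` dense
#' SELU layers of `width` neurons with alpha dropout, then a single
#' sigmoid output.  Weights are drawn `N(0, 1/fan_in)` (the
#' self-normalizing-compatible initialisation); biases start at zero.
#'
#' @param spec an [snn_spec()].
#' @param n_inputs number of input features (the four model parameters).
#' @param seed integer seed for the weight draw.
#' @return list of class `snn_model` with `weights`, `biases`, `spec`.
#' @export
build_snn <- function(spec = snn_spec(), n_inputs = 4L, seed = 1L) {
  dims <- c(n_inputs, rep(spec$width, spec$n_layers), 1L)
  with_seed(seed, {
    weights <- lapply(seq_len(length(dims) - 1), function(l) {
      fan_in <- dims[l]
      matrix(stats::rnorm(fan_in * dims[l + 1], 0, sqrt(1 / fan_in)),
             fan_in, dims[l + 1])
    })
  })
  biases <- lapply(seq_len(length(dims) - 1), function(l) rep(0, dims[l + 1]))
  structure(list(weights = weights, biases = biases, spec = spec,
                 n_inputs = as.integer(n_inputs)),
            class = "snn_model")
}

#' Number of trainable parameters
#'
#' @param model an `snn_model`.
#' @return total count of weights and biases.
#' @export
snn_parameter_count <- function(model) {
  sum(vapply(model$weights, length, numeric(1))) +
    sum(vapply(model$biases, length, numeric(1)))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass.  training = TRUE applies alpha dropout to hidden
# activations and caches everything needed for backprop.
snn_forward <- function(model, x, training = FALSE) {
  n_hidden <- model$spec$n_layers
  pre <- post <- dgrad <- vector("list", n_hidden)
  h <- x
  for (l in seq_len(n_hidden)) {
    z <- sweep(h %*% model$weights[[l]], 2, model$biases[[l]], `+`)
    a <- selu(z)
    if (training && model$spec$dropout_p > 0) {
      dr <- alpha_dropout(a, model$spec$dropout_p)
      a <- dr$x
      dgrad[[l]] <- dr$grad
    } else {
      dgrad[[l]] <- 1
    }
    pre[[l]] <- z
    post[[l]] <- a
    h <- a
  }
  lout <- n_hidden + 1
  z_out <- as.numeric(h %*% model$weights[[lout]] + model$biases[[lout]])
  list(prob = sigmoid(z_out), pre = pre, post = post, dgrad = dgrad, input = x)
}

bce_loss <- function(prob, y, eps = 1e-12) {
  prob <- pmin(pmax(prob, eps), 1 - eps)
  -mean(y * log(prob) + (1 - y) * log(1 - prob))
}

#' Down-sample the majority class
#'
#' Randomly subsamples the majority class without replacement to the
#' minority class size, so the classifier sees balanced labels.
#'
#' @param features data.frame or matrix of features.
#' @param labels logical or two-level vector; `TRUE`/`"PREGNANT"` is the
#'   positive class.
#' @param seed integer seed.
#' @return list: `features`, `labels` (logical), `index` (rows kept from
#'   the input).
#' @export
balance_downsample <- function(features, labels, seed = 1L) {
  y <- as_binary_labels(labels)
  if (!any(y) || all(y))
    stop("balance_downsample: both classes must be present", call. = FALSE)
  idx_pos <- which(y)
  idx_neg <- which(!y)
  n_min <- min(length(idx_pos), length(idx_neg))
  with_seed(seed, {
    if (length(idx_pos) > n_min)
      idx_pos <- sort(idx_pos[sample.int(length(idx_pos), n_min)])
    if (length(idx_neg) > n_min)
      idx_neg <- sort(idx_neg[sample.int(length(idx_neg), n_min)])
  })
  keep <- sort(c(idx_pos, idx_neg))
  list(features = features[keep, , drop = FALSE], labels = y[keep],
       index = keep)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  u <- toupper(as.character(labels))
  if (all(u %in% c("PREGNANT", "NONPREGNANT"))) return(u == "PREGNANT")
  if (all(u %in% c("TRUE", "FALSE"))) return(u == "TRUE")
  if (all(u %in% c("0", "1"))) return(u == "1")
  stop("labels must be logical, 0/1 or PREGNANT/NONPREGNANT", call. = FALSE)
}

#' Scale features to order one
#'
#' Fixed affine map `(x - center) / scale` with constants chosen once from
#' the physics of each parameter -- never from data statistics, so nothing
#' leaks between training and test splits.  The default is plain division
#' by a reference magnitude (`center = 0`).  For network input the
#' recommended constants in [snn_reference_frame()] subtract the
#' literature baseline and divide by the typical biological dispersion,
#' because the self-normalizing propagation assumes inputs near zero mean
#' and unit variance; division alone leaves milk parameters with order-1
#' means but order-0.01 spread.
#'
#' @param features data.frame or matrix with the four parameter columns.
#' @param scales named positive reference scales.
#' @param center named reference centers (defaults to zero).
#' @return matrix of scaled features.
#' @export
scale_features <- function(features,
                           scales = c(delta_eps = 70, tau_ps = 10,
                                      alpha = 1, sigma_dc = 1),
                           center = 0 * scales) {
  if (any(!is.finite(scales)) || any(scales <= 0))
    stop("scale_features: reference scales must be positive", call. = FALSE)
  x <- as.matrix(features[, names(scales), drop = FALSE])
  sweep(sweep(x, 2, center[names(scales)], `-`), 2, scales, `/`)
}

#' Reference frame for network inputs
#'
#' Fixed centers (literature milk baselines at 25 degC) and scales
#' (typical biological dispersion of each parameter) used to standardise
#' classifier inputs without touching data statistics.
#'
#' @return list with `center` and `scale` named vectors.
#' @export
snn_reference_frame <- function() {
  list(center = c(delta_eps = 68, tau_ps = 9, alpha = 0.985, sigma_dc = 0.9),
       scale = c(delta_eps = 0.5, tau_ps = 1, alpha = 0.003, sigma_dc = 0.015))
}

#' Stratified random holdout split
#'
#' Draws exactly `test_per_class` samples per class into the test set at
#' random; the remainder trains.
#'
#' @param features matrix/data.frame of features.
#' @param labels binary labels (see [balance_downsample()]).
#' @param test_per_class test-set size per class.
#' @param seed integer seed.
#' @return list with `train` and `test`, each holding `features`,
#'   `labels`, `index`.
#' @export
holdout_split <- function(features, labels, test_per_class = 15L, seed = 1L) {
  y <- as_binary_labels(labels)
  if (test_per_class < 0) stop("test_per_class must be >= 0", call. = FALSE)
  if (min(sum(y), sum(!y)) < test_per_class)
    stop("holdout_split: a class has fewer samples than test_per_class",
         call. = FALSE)
  pos <- which(y)
  neg <- which(!y)
  test_idx <- with_seed(seed, {
    c(if (test_per_class > 0) pos[sample.int(length(pos), test_per_class)],
      if (test_per_class > 0) neg[sample.int(length(neg), test_per_class)])
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(y), test_idx)
  list(train = list(features = features[train_idx, , drop = FALSE],
                    labels = y[train_idx], index = train_idx),
       test = list(features = features[test_idx, , drop = FALSE],
                   labels = y[test_idx], index = test_idx))
}

#' Train the SNN classifier
#'
#' ADAM optimisation of the binary cross-entropy over mini-batches, with
#' per-epoch loss and accuracy recorded on the training set and on a
#' validation set.  Fully deterministic given the seed (batch shuffling
#' and dropout masks included).
#'
#' @param model an `snn_model` from [build_snn()].
#' @param x_train,y_train scaled feature matrix and binary labels.
#' @param x_val,y_val validation set evaluated once per epoch (defaults to
#'   the training set when absent).
#' @param epochs training epochs.
#' @param learning_rate ADAM step size.
#' @param batch_size mini-batch size (capped at the training-set size).
#' @param beta1,beta2,epsilon ADAM moment decays and stability constant.
#' @param seed integer seed for shuffling and dropout.
#' @return list: `model` (trained), `curves` (data.frame of per-epoch
#'   `train_loss`, `train_accuracy`, `val_loss`, `val_accuracy`).
#' @export
train_snn <- function(model, x_train, y_train, x_val = NULL, y_val = NULL,
                      epochs = 20L, learning_rate = 1e-3, batch_size = 32L,
                      beta1 = 0.9, beta2 = 0.999, epsilon = 1e-5,
                      seed = 1L) {
  x_train <- as.matrix(x_train)
  y_train <- as.numeric(as_binary_labels(y_train))
  if (is.null(x_val)) {
    x_val <- x_train
    y_val <- y_train
  } else {
    x_val <- as.matrix(x_val)
    y_val <- as.numeric(as_binary_labels(y_val))
  }
  n <- nrow(x_train)
  batch_size <- min(as.integer(batch_size), n)
  n_mat <- length(model$weights)
  m_w <- v_w <- lapply(model$weights, function(w) w * 0)
  m_b <- v_b <- lapply(model$biases, function(b) b * 0)
  t_step <- 0
  curves <- data.frame(epoch = seq_len(epochs), train_loss = NA_real_,
                       train_accuracy = NA_real_, val_loss = NA_real_,
                       val_accuracy = NA_real_)

  with_seed(derive_seed(seed, "snn-train"), {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      for (start in seq(1, n, by = batch_size)) {
        idx <- perm[start:min(start + batch_size - 1, n)]
        xb <- x_train[idx, , drop = FALSE]
        yb <- y_train[idx]
        fw <- snn_forward(model, xb, training = TRUE)
        if (any(!is.finite(fw$prob)))
          stop("train_snn: divergence (non-finite output); lower the learning rate",
               call. = FALSE)

        # backprop; d(BCE)/d(z_out) = (p - y)/m
        m_batch <- length(yb)
        delta <- matrix((fw$prob - yb) / m_batch, ncol = 1)
        g_w <- vector("list", n_mat)
        g_b <- vector("list", n_mat)
        h_last <- fw$post[[model$spec$n_layers]]
        g_w[[n_mat]] <- t(h_last) %*% delta
        g_b[[n_mat]] <- colSums(delta)
        back <- delta %*% t(model$weights[[n_mat]])
        for (l in rev(seq_len(model$spec$n_layers))) {
          back <- back * fw$dgrad[[l]] * selu_grad(fw$pre[[l]])
          h_prev <- if (l == 1) fw$input else fw$post[[l - 1]]
          g_w[[l]] <- t(h_prev) %*% back
          g_b[[l]] <- colSums(back)
          if (l > 1) back <- back %*% t(model$weights[[l]])
        }

        t_step <- t_step + 1
        corr1 <- 1 - beta1^t_step
        corr2 <- 1 - beta2^t_step
        for (l in seq_len(n_mat)) {
          m_w[[l]] <- beta1 * m_w[[l]] + (1 - beta1) * g_w[[l]]
          v_w[[l]] <- beta2 * v_w[[l]] + (1 - beta2) * g_w[[l]]^2
          model$weights[[l]] <- model$weights[[l]] - learning_rate *
            (m_w[[l]] / corr1) / (sqrt(v_w[[l]] / corr2) + epsilon)
          m_b[[l]] <- beta1 * m_b[[l]] + (1 - beta1) * g_b[[l]]
          v_b[[l]] <- beta2 * v_b[[l]] + (1 - beta2) * g_b[[l]]^2
          model$biases[[l]] <- model$biases[[l]] - learning_rate *
            (m_b[[l]] / corr1) / (sqrt(v_b[[l]] / corr2) + epsilon)
        }
      }
      tr <- evaluate_snn(model, x_train, y_train)
      va <- evaluate_snn(model, x_val, y_val)
      curves$train_loss[ep] <- tr$loss
      curves$train_accuracy[ep] <- tr$accuracy
      curves$val_loss[ep] <- va$loss
      curves$val_accuracy[ep] <- va$accuracy
    }
  })
  list(model = model, curves = curves)
}

#' Evaluate the classifier
#'
#' Inference pass (dropout off): fraction of correct labels at the 0.5
#' threshold and mean binary cross-entropy.
#'
#' @param model a trained `snn_model`.
#' @param x feature matrix.
#' @param y binary labels.
#' @return list: `accuracy`, `loss`, `prob` (per-sample probabilities).
#' @export
evaluate_snn <- function(model, x, y) {
  y <- as.numeric(as_binary_labels(y))
  if (length(y) == 0) stop("evaluate_snn: empty evaluation set", call. = FALSE)
  prob <- snn_forward(model, as.matrix(x), training = FALSE)$prob
  list(accuracy = mean((prob > 0.5) == (y == 1)), loss = bce_loss(prob, y),
       prob = prob)
}

#' End-to-end classifier pipeline on a feature table
#'
#' Balance the classes by down-sampling, scale features by fixed reference
#' scales, draw the stratified holdout, build the SNN and train it; the
#' held-out test set doubles as the per-epoch validation set.
#'
#' @param features data.frame with `delta_eps`, `tau_ps`, `alpha`,
#'   `sigma_dc` columns.
#' @param labels binary labels (see [balance_downsample()]).
#' @param seed root seed; balancing, splitting, initialisation and
#'   training draw named child seeds from it.
#' @param test_per_class held-out samples per class.
#' @param epochs,learning_rate,batch_size training hyperparameters.
#' @param spec an [snn_spec()].
#' @param reference fixed feature centering/scaling constants
#'   (see [snn_reference_frame()]).
#' @return list: `model`, `curves`, `test_accuracy`, `test_loss`,
#'   `n_train`, `n_test`, `split`.
#' @export
classify_pregnancy <- function(features, labels, seed = 1L,
                               test_per_class = 15L, epochs = 20L,
                               learning_rate = 1e-3, batch_size = 32L,
                               spec = snn_spec(),
                               reference = snn_reference_frame()) {
  bal <- balance_downsample(features, labels,
                            seed = derive_seed(seed, "balance"))
  x <- scale_features(bal$features, reference$scale, reference$center)
  split <- holdout_split(x, bal$labels, test_per_class = test_per_class,
                         seed = derive_seed(seed, "split"))
  model <- build_snn(spec, n_inputs = ncol(x),
                     seed = derive_seed(seed, "init"))
  trained <- train_snn(model, split$train$features, split$train$labels,
                       x_val = split$test$features, y_val = split$test$labels,
                       epochs = epochs, learning_rate = learning_rate,
                       batch_size = batch_size, seed = derive_seed(seed, "sgd"))
  ev <- evaluate_snn(trained$model, split$test$features, split$test$labels)
  list(model = trained$model, curves = trained$curves,
       test_accuracy = ev$accuracy, test_loss = ev$loss,
       n_train = length(split$train$labels), n_test = length(split$test$labels),
       split = split)
}
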