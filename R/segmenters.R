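#' Training configuration for the perceptron segmenter
#'
#' @param a Learning rate of the gradient update `W <- W - a * dE/dW`
#'   (default 0.01).
#' @param epochs Training epochs (default 50).
#' @param batch_size Mini-batch size (default 256).
#' @param seed Integer seed controlling weight initialization and shuffling.
#' @param patience Early-stopping patience on validation loss in epochs
#'   (default 8).
#' @param hidden Hidden-layer width `m` (default 20, one hidden layer).
#' @return A `train_config` object.
#' @export
train_config <- function(a = 0.01, epochs = 50L, batch_size = 256L,
                         seed = 0L, patience = 8L, hidden = 20L) {
  if (a <= 0) stop("learning rate must be positive", call. = FALSE)
  if (epochs < 1L) stop("at least one epoch is required", call. = FALSE)
  structure(list(a = a, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 patience = as.integer(patience), hidden = as.integer(hidden)),
            class = "train_config")
}

# ---- MLP internals ---------------------------------------------------------

mlp_init <- function(n_inputs, hidden, seed) {
  withr::with_seed(seed, {
    r1 <- sqrt(6 / (n_inputs + hidden))
    r2 <- sqrt(6 / (hidden + 1))
    list(W_ji = matrix(stats::runif(hidden * n_inputs, -r1, r1),
                       nrow = hidden, ncol = n_inputs),
         W_jb = rep(0, hidden),
         W_kj = stats::runif(hidden, -r2, r2),
         W_kb = 0)
  })
}

#' Forward pass of the perceptron
#'
#' Evaluates `P = a0[ sum_j W_kj * ah( sum_i W_ji X_i + W_jb ) + W_kb ]` with
#' ReLU hidden activation `ah` and logistic output activation `a0`, for a
#' batch of pixels.
#'
#' @param weights List with `W_ji` (`m x d`), `W_jb` (`m`), `W_kj` (`m`),
#'   `W_kb` (scalar) — as stored in an `mlp_model`.
#' @param X Numeric matrix `B x d` of input features.
#' @return List with `p` (output probabilities), `H` (hidden activations),
#'   `Z1` (hidden pre-activations).
#' @export
mlp_forward <- function(weights, X) {
  Z1 <- X %*% t(weights$W_ji) +
    matrix(weights$W_jb, nrow(X), length(weights$W_jb), byrow = TRUE)
  H <- pmax(Z1, 0)
  z2 <- as.vector(H %*% weights$W_kj) + weights$W_kb
  list(p = stats::plogis(z2), H = H, Z1 = Z1)
}

#' One backpropagation gradient step
#'
#' Applies the update `W <- W - a * dError/dW` for mean binary cross-entropy
#' over the batch, with ReLU hidden and logistic output units.
#'
#' @inheritParams mlp_forward
#' @param y 0/1 targets, length `nrow(X)`.
#' @param a Learning rate.
#' @return Updated weights list; the batch loss is attached as attribute
#'   `loss`.
#' @export
mlp_gradient_step <- function(weights, X, y, a) {
  B <- nrow(X)
  fw <- mlp_forward(weights, X)
  p <- fw$p
  eps <- 1e-12
  loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  d2 <- (p - y) / B                        # dLoss/dz2, averaged
  g_Wkj <- as.vector(t(fw$H) %*% d2)
  g_Wkb <- sum(d2)
  dH <- outer(d2, weights$W_kj)            # B x m
  dZ1 <- dH * (fw$Z1 > 0)
  g_Wji <- t(dZ1) %*% X
  g_Wjb <- colSums(dZ1)
  out <- list(W_ji = weights$W_ji - a * g_Wji,
              W_jb = weights$W_jb - a * g_Wjb,
              W_kj = weights$W_kj - a * g_Wkj,
              W_kb = weights$W_kb - a * g_Wkb)
  attr(out, "loss") <- loss
  out
}

mlp_loss <- function(weights, X, y) {
  p <- mlp_forward(weights, X)$p
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

#' Train the perceptron pixel classifier
#'
#' Single-hidden-layer perceptron (ReLU hidden units, logistic output
#' thresholded at 0.5) trained by mini-batch stochastic gradient descent on
#' binary cross-entropy. Validation loss is evaluated each epoch; the weights
#' with the best validation loss are returned, and training stops early when
#' the validation loss has not improved for `config$patience` epochs. A fixed
#' seed yields identical weights.
#'
#' @param train,val [pixel_dataset()] parts sharing the same channels, each
#'   containing both classes (train must).
#' @param config A [train_config()].
#' @return List with `model` (an `mlp_model`) and `report`
#'   (a [classification_metrics()] report on the validation part).
#' @export
train_mlp <- function(train, val, config = train_config()) {
  stopifnot(inherits(train, "pixel_dataset"), inherits(val, "pixel_dataset"))
  if (!identical(train$channel_names, val$channel_names))
    stop("train and validation channels differ", call. = FALSE)
  if (length(unique(train$labels)) < 2L)
    stop("training data must contain both classes", call. = FALSE)

  X <- train$features; y <- train$labels
  Xv <- val$features; yv <- val$labels
  n <- nrow(X)
  weights <- mlp_init(ncol(X), config$hidden, config$seed)

  best <- list(loss = Inf, weights = weights, epoch = 0L)
  stale <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_accuracy = numeric(0))

  withr::with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        weights <- mlp_gradient_step(weights, X[idx, , drop = FALSE], y[idx],
                                     config$a)
        loss <- attr(weights, "loss")
        if (!is.finite(loss))
          stop(sprintf(
            "training diverged (non-finite loss); reduce the learning rate a = %g",
            config$a), call. = FALSE)
        ep_loss <- ep_loss + loss * length(idx)
      }
      vl <- mlp_loss(weights, Xv, yv)
      va <- mean(as.integer(mlp_forward(weights, Xv)$p >= 0.5) == yv)
      history[nrow(history) + 1L, ] <- list(epoch, ep_loss / n, vl, va)
      if (vl < best$loss) {
        best <- list(loss = vl, weights = weights, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= config$patience) break
      }
    }
  })

  model <- structure(list(kind = "mlp",
                          n_inputs = ncol(X),
                          hidden = config$hidden,
                          weights = best$weights,
                          channel_names = train$channel_names,
                          config = config,
                          best_epoch = best$epoch,
                          history = history),
                     class = c("mlp_model", "segmenter_model"))
  pred <- predict_pixels(model, Xv)
  list(model = model, report = classification_metrics(pred, yv))
}

#' Predict 0/1 pixel labels from a trained segmenter
#'
#' @param model An `mlp_model`, `rf_model` or `svm_model`.
#' @param X Numeric matrix whose columns match the model's channels.
#' @return Integer vector of 0/1 labels.
#' @export
predict_pixels <- function(model, X) UseMethod("predict_pixels")

#' @export
predict_pixels.mlp_model <- function(model, X) {
  as.integer(mlp_forward(model$weights, X)$p >= 0.5)
}

#' @export
predict_pixels.rf_model <- function(model, X) {
  pr <- stats::predict(model$fit, data = as.data.frame(X),
                       num.threads = 1L)$predictions
  as.integer(pr[, "1"] >= 0.5)
}

#' @export
predict_pixels.svm_model <- function(model, X) {
  as.integer(as.character(stats::predict(model$fit, as.data.frame(X))))
}

#' Cross-validated grid search over hidden-layer widths
#'
#' 10-fold cross-validated accuracy on the training part for each candidate
#' neuron count; returns the argmax, preferring the smallest count on ties.
#'
#' @param train A [pixel_dataset()].
#' @param candidates Neuron counts to try (default `c(12, 20, 35, 60, 100)`).
#' @param k Number of folds (default 10).
#' @param config Base [train_config()] reused for each fit (its `hidden`
#'   field is overridden per candidate).
#' @return List with `chosen` (the selected count) and `cv_accuracy` (named
#'   mean accuracy per candidate).
#' @export
grid_search_neurons <- function(train, candidates = c(12L, 20L, 35L, 60L, 100L),
                                k = 10L, config = train_config(epochs = 10L)) {
  stopifnot(inherits(train, "pixel_dataset"))
  if (length(candidates) == 0L) stop("no candidates", call. = FALSE)
  n1 <- sum(train$labels == 1L); n0 <- sum(train$labels == 0L)
  if (k > min(n1, n0))
    stop("more folds than rows per class", call. = FALSE)
  folds <- withr::with_seed(config$seed, {
    f <- integer(train$n_rows)
    for (lab in c(0L, 1L)) {
      idx <- sample(which(train$labels == lab))
      f[idx] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
  acc <- vapply(candidates, function(m) {
    cfg <- config; cfg$hidden <- as.integer(m)
    fold_acc <- vapply(seq_len(k), function(fold) {
      tr_idx <- which(folds != fold); te_idx <- which(folds == fold)
      tr <- pixel_dataset(train$features[tr_idx, , drop = FALSE],
                          train$labels[tr_idx])
      te <- pixel_dataset(train$features[te_idx, , drop = FALSE],
                          train$labels[te_idx])
      fit <- train_mlp(tr, te, cfg)
      fit$report$accuracy
    }, numeric(1))
    mean(fold_acc)
  }, numeric(1))
  names(acc) <- as.character(candidates)
  best <- candidates[acc >= max(acc) - 1e-12]
  list(chosen = min(best), cv_accuracy = acc)
}

#' Train the random-forest pixel classifier
#'
#' Random forest with the packaged defaults (200 trees, maximum depth 20,
#' minimum leaf size 4); the final label is the averaged per-tree class
#' probability thresholded at 0.5.
#'
#' @inheritParams train_mlp
#' @param seed Integer seed.
#' @param n_estimator,max_depth,min_samples_leaf Forest hyperparameters.
#' @return List with `model` (an `rf_model`) and `report` on the validation
#'   part.
#' @export
train_rf <- function(train, val, seed = 0L, n_estimator = 200L,
                     max_depth = 20L, min_samples_leaf = 4L) {
  stopifnot(inherits(train, "pixel_dataset"), inherits(val, "pixel_dataset"))
  if (!identical(train$channel_names, val$channel_names))
    stop("train and validation channels differ", call. = FALSE)
  if (length(unique(train$labels)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  df <- as.data.frame(train$features)
  fit <- ranger::ranger(x = df, y = factor(train$labels, levels = c(0, 1)),
                        num.trees = n_estimator, max.depth = max_depth,
                        min.node.size = min_samples_leaf,
                        probability = TRUE, seed = seed, num.threads = 1L)
  model <- structure(list(kind = "rf", fit = fit,
                          n_estimator = as.integer(n_estimator),
                          max_depth = as.integer(max_depth),
                          min_samples_leaf = as.integer(min_samples_leaf),
                          channel_names = train$channel_names, seed = seed),
                     class = c("rf_model", "segmenter_model"))
  pred <- predict_pixels(model, val$features)
  list(model = model, report = classification_metrics(pred, val$labels))
}

#' Train the support-vector-machine pixel classifier
#'
#' RBF-kernel SVM with the packaged defaults `C = 0.001`, `gamma = 1` (both
#' overridable). Training is capped at `max_rows` rows by a seeded stratified
#' subsample, which is logged loudly when it triggers.
#'
#' @inheritParams train_rf
#' @param C,gamma SVM hyperparameters.
#' @param max_rows Training-row cap (default 100000).
#' @return List with `model` (an `svm_model`) and `report` on the validation
#'   part.
#' @export
train_svm <- function(train, val, seed = 0L, C = 0.001, gamma = 1,
                      max_rows = 100000L) {
  stopifnot(inherits(train, "pixel_dataset"), inherits(val, "pixel_dataset"))
  if (!identical(train$channel_names, val$channel_names))
    stop("train and validation channels differ", call. = FALSE)
  if (length(unique(train$labels)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  X <- train$features; y <- train$labels
  if (nrow(X) > max_rows) {
    cs_log("WARNING: SVM training subsampled from %d to %d rows (stratified)",
           nrow(X), max_rows)
    keep <- withr::with_seed(seed, {
      idx <- unlist(lapply(c(0L, 1L), function(lab) {
        pool <- which(y == lab)
        sample(pool, round(max_rows * length(pool) / length(y)))
      }))
      sort(idx)
    })
    X <- X[keep, , drop = FALSE]; y <- y[keep]
  }
  fit <- withr::with_seed(seed,
    e1071::svm(x = as.data.frame(X), y = factor(y, levels = c(0, 1)),
               kernel = "radial", cost = C, gamma = gamma, scale = FALSE))
  model <- structure(list(kind = "svm", fit = fit, C = C, gamma = gamma,
                          channel_names = train$channel_names, seed = seed),
                     class = c("svm_model", "segmenter_model"))
  pred <- predict_pixels(model, val$features)
  list(model = model, report = classification_metrics(pred, val$labels))
}

#' Repeated training over a set of seeds
#'
#' Re-splits and re-trains per seed (3:1:1 stratified by default, matching
#' the repeated-seed protocol with seeds 0-99) and aggregates the held-out
#' test metrics.
#'
#' @param trainer Function `(train, val, seed) -> list(model, report)`; e.g.
#'   a wrapper around [train_mlp()], [train_rf()] or [train_svm()].
#' @param dataset A [pixel_dataset()] to be split each round.
#' @param seeds Integer seeds (default `0:99`).
#' @param ratios Split ratios (default 3:1:1).
#' @return List with `mean` and `sd` (population) of accuracy, F-score and
#'   recall over seeds, plus the per-seed data frame `runs`.
#' @export
repeat_train <- function(trainer, dataset, seeds = 0:99,
                         ratios = c(3, 1, 1) / 5) {
  if (length(seeds) == 0L) stop("seeds must be nonempty", call. = FALSE)
  runs <- lapply(seeds, function(s) {
    parts <- split_dataset(dataset, split_spec(ratios, seed = s))
    fit <- trainer(parts$train, parts$validation, s)
    pred <- predict_pixels(fit$model, parts$test$features)
    rep <- classification_metrics(pred, parts$test$labels)
    c(seed = s, accuracy = rep$accuracy, F_score = rep$F_score,
      recall = rep$recall)
  })
  runs <- as.data.frame(do.call(rbind, runs))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  metrics <- c("accuracy", "F_score", "recall")
  list(mean = vapply(runs[metrics], mean, numeric(1)),
       sd = vapply(runs[metrics], pop_sd, numeric(1)),
       runs = runs)
}

#' Segment a full image with a trained pixel classifier
#'
#' Builds the 24-channel feature stack, restricts it to the channels the
#' model was trained on, classifies every pixel, and returns a `{0, 255}`
#' mask with the image's dimensions.
#'
#' @param model A trained segmenter model.
#' @param image An [rgb_image()].
#' @param channels Channel names (or a `selected_channels` object) to feed
#'   the model; defaults to the model's own training channels and must match
#'   them.
#' @return A [binary_mask()].
#' @export
segment_image <- function(model, image, channels = NULL) {
  stopifnot(inherits(model, "segmenter_model"))
  assert_rgb_image(image)
  if (is.null(channels)) channels <- model$channel_names
  if (inherits(channels, "selected_channels")) channels <- channels$names
  if (!identical(channels, model$channel_names))
    stop("channel mismatch: model was trained on a different channel set",
         call. = FALSE)
  stack <- to_feature_stack(image)
  X <- stack_to_matrix(stack)[, channels, drop = FALSE]
  pred <- predict_pixels(model, X)
  m <- matrix(as.integer(pred) * 255L, nrow = dim(image)[1],
              ncol = dim(image)[2])
  binary_mask(m)
}

#' Persist / restore a trained segmenter
#'
#' Models are stored as a single RDS file wrapped in a version header.
#'
#' @param model A `segmenter_model`.
#' @param path Output file.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "segmenter_model") ||
              inherits(model, "gbrt_model"))
  saveRDS(list(format = "canopyseg-model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model()` returns the stored model.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "canopyseg-model"))
    stop("not a canopyseg model file", call. = FALSE)
  obj$model
}
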