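test_that("pearson correlation matches closed forms", {
  x <- 1:10
  expect_equal(pearson_cor(x, 2 * x + 1), 1)
  expect_equal(pearson_cor(x, -x), -1)
  expect_equal(pearson_cor(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_cor(1:2, 1:2), "length >= 3")
})

test_that("correlation tables sort by |r| with registry-order ties", {
  withr::with_seed(1, {
    n <- 40
    spad <- stats::runif(n, 20, 60)
    df <- data.frame(spad = spad)
    for (ix in cvi_registry()) df[[ix]] <- stats::rnorm(n)
    df$DGCI <- spad + stats::rnorm(n, 0, 1)       # strongest by construction
    df$GBRG <- rep(-1, n)                         # degenerate, constant
  })
  expect_warning(tab <- correlation_table(df), "GBRG")
  expect_equal(tab$index[1], "DGCI")
  expect_true(is.na(tab$r[tab$index == "GBRG"]))
  expect_equal(nrow(tab), 11L)

  top <- top_indices(tab, 5)
  expect_length(top, 5L)
  expect_equal(top[1], "DGCI")
  expect_false("GBRG" %in% top)

  # exact ties resolved by registry order, reproducibly
  tie <- data.frame(spad = c(1, 2, 3, 4), ExG = c(1, 2, 3, 4),
                    Green = c(1, 2, 3, 4))
  t2 <- correlation_table(tie, indices = c("ExG", "Green"))
  expect_identical(t2$index, c("Green", "ExG"))   # Green precedes ExG in registry

  expect_error(top_indices(t2, 5), "need 5")
})

# independent oracle: stagewise boosting with exhaustive exact-value splits
exact_boost_oracle <- function(X, y, n_trees, depth, lr, min_leaf) {
  fit_tree <- function(r) {
    grow <- function(idx, d) {
      if (d >= depth || length(idx) < 2 * min_leaf)
        return(list(leaf = TRUE, value = mean(r[idx])))
      best <- list(gain = 1e-12)
      n <- length(idx); S <- sum(r[idx])
      for (j in seq_len(ncol(X))) {
        xs <- sort(unique(X[idx, j]))
        if (length(xs) < 2) next
        for (cut in (xs[-1] + xs[-length(xs)]) / 2) {
          L <- idx[X[idx, j] <= cut]
          if (length(L) < min_leaf || n - length(L) < min_leaf) next
          SL <- sum(r[L])
          gain <- SL^2 / length(L) + (S - SL)^2 / (n - length(L)) - S^2 / n
          if (gain > best$gain) best <- list(gain = gain, j = j, cut = cut)
        }
      }
      if (is.null(best$j)) return(list(leaf = TRUE, value = mean(r[idx])))
      sel <- X[idx, best$j] <= best$cut
      list(leaf = FALSE, j = best$j, cut = best$cut,
           left = grow(idx[sel], d + 1), right = grow(idx[!sel], d + 1))
    }
    grow(seq_len(nrow(X)), 0)
  }
  pred_node <- function(node, i) {
    if (node$leaf) return(node$value)
    if (X[i, node$j] <= node$cut) pred_node(node$left, i)
    else pred_node(node$right, i)
  }
  pred <- rep(mean(y), nrow(X))
  for (t in seq_len(n_trees)) {
    tree <- fit_tree(y - pred)
    pred <- pred + lr * vapply(seq_len(nrow(X)), function(i)
      pred_node(tree, i), numeric(1))
  }
  pred
}

test_that("histogram boosting reproduces exact-split boosting on small data", {
  withr::with_seed(4, {
    X <- cbind(f1 = stats::runif(20), f2 = stats::runif(20))
    y <- 3 * X[, 1] - 2 * X[, 2]^2 + stats::rnorm(20, 0, 0.05)
  })
  df <- data.frame(X, spad = y)
  cfg <- gbrt_config(n_estimators = 25L, learning_rate = 0.3, max_depth = 2L,
                     subsample = 1, max_bins = 256L, min_samples_leaf = 2L)
  model <- fit_gbrt(df, c("f1", "f2"), cfg)
  oracle <- exact_boost_oracle(X, y, n_trees = 25L, depth = 2L, lr = 0.3,
                               min_leaf = 2L)
  expect_equal(predict(model, df), oracle, tolerance = 1e-8)
})

test_that("boosting converges on noiseless linear data and never increases train loss", {
  withr::with_seed(2, x <- stats::runif(40, 0, 10))
  df <- data.frame(g = x, spad = 5 + 3 * x)
  model <- fit_gbrt(df, "g", gbrt_config(n_estimators = 300L, max_depth = 2L,
                                         learning_rate = 0.1,
                                         min_samples_leaf = 2L))
  target_range <- diff(range(df$spad))
  expect_lt(sqrt(mean((predict(model, df) - df$spad)^2)), 0.01 * target_range)
  expect_true(all(diff(model$train_rmse) <= 1e-9))
})

test_that("degenerate configurations collapse to the mean model", {
  df <- data.frame(g = 1:20, spad = rep(7, 20))
  expect_warning(model <- fit_gbrt(df, "g"), "constant target")
  expect_equal(predict(model, df), rep(7, 20))

  # depth 0: every tree is a root leaf on zero-mean residuals
  df2 <- data.frame(g = 1:20, spad = (1:20)^1.5)
  m0 <- fit_gbrt(df2, "g", gbrt_config(n_estimators = 10L, max_depth = 0L,
                                       learning_rate = 1))
  expect_equal(predict(m0, df2), rep(mean(df2$spad), 20))

  expect_error(fit_gbrt(df[1:5, ], "g"), "at least 10")
})

test_that("validation-set tuning picks a grid member and returns its fit", {
  withr::with_seed(6, {
    n <- 60
    g <- stats::runif(n)
    df <- data.frame(g = g, spad = 30 + 20 * g + stats::rnorm(n, 0, 1))
  })
  tuned <- tune_gbrt(df[1:40, ], df[41:60, ], "g",
                     grid = expand.grid(n_estimators = c(20L, 50L),
                                        max_depth = c(1L, 2L),
                                        learning_rate = 0.1, subsample = 1.0))
  expect_s3_class(tuned$model, "gbrt_model")
  expect_equal(nrow(tuned$grid), 4L)
  expect_equal(tuned$val_rmse, min(tuned$grid$val_rmse))
})

test_that("regression evaluation matches hand arithmetic", {
  # simple predictable model: predict spad exactly / with fixed errors
  model_exact <- structure(list(features = "g", shift = 0),
                           class = "shift_model")
  model_off <- structure(list(features = "g", shift = c(2, -2)),
                         class = "shift_model")
  assign("predict.shift_model",
         function(object, newdata, ...) newdata$spad +
           rep_len(object$shift, nrow(newdata)),
         envir = globalenv())
  on.exit(rm("predict.shift_model", envir = globalenv()))

  df <- data.frame(g = 1:8, spad = c(10, 12, 15, 13, 17, 20, 22, 19))
  r <- evaluate_regression(model_exact, df, n_features = 1)
  expect_equal(r$RMSE, 0)
  expect_equal(r$MAE, 0)
  expect_equal(r$R2_adj, 1)

  r2 <- evaluate_regression(model_off, df[1:4, ], n_features = 1)
  expect_equal(r2$RMSE, 2)
  expect_equal(r2$MAE, 2)

  # constant predictor at the observed mean: R2 = 0, adjusted <= 0
  const <- structure(list(features = "g", value = mean(df$spad)),
                     class = "const_model")
  assign("predict.const_model",
         function(object, newdata, ...) rep(object$value, nrow(newdata)),
         envir = globalenv())
  on.exit(rm("predict.const_model", envir = globalenv()), add = TRUE)
  r3 <- evaluate_regression(const, df, n_features = 1)
  expect_equal(r3$R2, 0)
  expect_lte(r3$R2_adj, 0)

  expect_error(evaluate_regression(model_exact, df[1:2, ], n_features = 1),
               "n > p \\+ 1")
})
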