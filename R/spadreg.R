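#' Pearson correlation between two numeric vectors
#'
#' @param x,y Equal-length numeric vectors (length at least 3) with nonzero
#'   variance.
#' @return The product-moment correlation coefficient.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("pearson_cor needs equal-length vectors of length >= 3", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  stats::cor(x, y)
}

#' Correlate color vegetation indices with SPAD values
#'
#' One Pearson coefficient per index column, sorted by `|r|` descending.
#' Indices with zero variance across the cohort (e.g. GBRG, which is
#' constant by construction) or with undefined values are reported as `NA`
#' with a warning and sort last.
#'
#' @param samples Data frame with one row per image: a `spad` column plus one
#'   column per index.
#' @param indices Index columns to use (default [cvi_registry()]).
#' @return A `correlation_table`: data frame with `index`, `r`, `abs_r`.
#' @export
correlation_table <- function(samples, indices = cvi_registry()) {
  stopifnot(is.data.frame(samples), "spad" %in% names(samples))
  missing <- setdiff(indices, names(samples))
  if (length(missing) > 0)
    stop(sprintf("missing index column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  r <- vapply(indices, function(ix) {
    v <- samples[[ix]]
    if (anyNA(v) || stats::var(v) == 0) return(NA_real_)
    pearson_cor(v, samples$spad)
  }, numeric(1))
  if (anyNA(r))
    warning(sprintf("correlation undefined for: %s",
                    paste(indices[is.na(r)], collapse = ", ")), call. = FALSE)
  df <- data.frame(index = indices, r = unname(r), abs_r = abs(unname(r)),
                   stringsAsFactors = FALSE)
  # sort by |r| descending, registry order on ties, NA last
  ord <- order(-ifelse(is.na(df$abs_r), -Inf, df$abs_r),
               match(df$index, cvi_registry()))
  df <- df[ord, ]
  rownames(df) <- NULL
  structure(df, class = c("correlation_table", "data.frame"))
}

#' Top-k indices by absolute correlation
#'
#' @param table A [correlation_table()].
#' @param k Number of indices to keep (default 5); ties broken by registry
#'   order.
#' @return Character vector of `k` index names.
#' @export
top_indices <- function(table, k = 5L) {
  stopifnot(inherits(table, "correlation_table"))
  defined <- table[!is.na(table$r), , drop = FALSE]
  if (nrow(defined) < k)
    stop(sprintf("only %d defined indices, need %d", nrow(defined), k),
         call. = FALSE)
  defined$index[seq_len(k)]
}

#' Configuration of the gradient-boosted-trees regressor
#'
#' @param n_estimators Number of boosting stages (default 200).
#' @param learning_rate Shrinkage applied to each stage (default 0.1).
#' @param max_depth Tree depth; 0 gives the constant mean model (default 3).
#' @param subsample Row fraction per stage (default 1.0).
#' @param max_bins Histogram bins per feature for split finding (default 256).
#' @param min_samples_leaf Minimum rows per leaf (default 5).
#' @param seed Integer seed (used when `subsample < 1`).
#' @return A `gbrt_config` object.
#' @export
gbrt_config <- function(n_estimators = 200L, learning_rate = 0.1,
                        max_depth = 3L, subsample = 1.0, max_bins = 256L,
                        min_samples_leaf = 5L, seed = 0L) {
  stopifnot(n_estimators >= 0, learning_rate > 0, max_depth >= 0,
            subsample > 0, subsample <= 1, max_bins >= 2)
  structure(list(n_estimators = as.integer(n_estimators),
                 learning_rate = learning_rate,
                 max_depth = as.integer(max_depth), subsample = subsample,
                 max_bins = as.integer(max_bins),
                 min_samples_leaf = as.integer(min_samples_leaf),
                 seed = as.integer(seed)),
            class = "gbrt_config")
}

# Candidate cut points of a feature: midpoints between distinct values when
# few, interior quantiles otherwise (histogram binning).
gbrt_cuts <- function(x, max_bins) {
  v <- sort(unique(x))
  if (length(v) <= 1L) return(numeric(0))
  if (length(v) <= max_bins) {
    (v[-1] + v[-length(v)]) / 2
  } else {
    qs <- stats::quantile(x, probs = seq(0, 1, length.out = max_bins + 1),
                          names = FALSE, type = 7)
    sort(unique(qs[-c(1, length(qs))]))
  }
}

# Fit one regression tree on binned features by greedy variance-reduction
# splits over the histogram bins. Returns a list of node records.
gbrt_tree <- function(binmat, cuts, r, idx, max_depth, min_leaf) {
  nodes <- list()
  new_node <- function(rec) {
    nodes[[length(nodes) + 1L]] <<- rec
    length(nodes)
  }
  grow <- function(idx, depth) {
    n <- length(idx)
    node_sum <- sum(r[idx])
    if (depth >= max_depth || n < 2L * min_leaf) {
      return(new_node(list(leaf = TRUE, value = node_sum / n)))
    }
    best <- list(gain = 1e-12, feature = NA_integer_, cut = NA_integer_)
    for (j in seq_len(ncol(binmat))) {
      ncuts <- length(cuts[[j]])
      if (ncuts == 0L) next
      b <- binmat[idx, j]
      cnt <- tabulate(b, nbins = ncuts + 1L)
      sm <- numeric(ncuts + 1L)
      agg <- rowsum(r[idx], group = b)
      sm[as.integer(rownames(agg))] <- agg[, 1]
      cnt_l <- cumsum(cnt)[seq_len(ncuts)]
      sum_l <- cumsum(sm)[seq_len(ncuts)]
      cnt_r <- n - cnt_l
      sum_r <- node_sum - sum_l
      ok <- cnt_l >= min_leaf & cnt_r >= min_leaf
      if (!any(ok)) next
      gain <- rep(-Inf, ncuts)
      gain[ok] <- sum_l[ok]^2 / cnt_l[ok] + sum_r[ok]^2 / cnt_r[ok] -
        node_sum^2 / n
      c_best <- which.max(gain)
      if (gain[c_best] > best$gain) {
        best <- list(gain = gain[c_best], feature = j, cut = c_best)
      }
    }
    if (is.na(best$feature)) {
      return(new_node(list(leaf = TRUE, value = node_sum / n)))
    }
    left_sel <- binmat[idx, best$feature] <= best$cut
    left_id <- grow(idx[left_sel], depth + 1L)
    right_id <- grow(idx[!left_sel], depth + 1L)
    new_node(list(leaf = FALSE, feature = best$feature, cut = best$cut,
                  threshold = cuts[[best$feature]][best$cut],
                  left = left_id, right = right_id))
  }
  root <- grow(idx, 0L)
  list(nodes = nodes, root = root)
}

gbrt_tree_predict <- function(tree, binmat) {
  out <- numeric(nrow(binmat))
  descend <- function(id, idx) {
    node <- tree$nodes[[id]]
    if (isTRUE(node$leaf)) {
      out[idx] <<- node$value
      return(invisible(NULL))
    }
    sel <- binmat[idx, node$feature] <= node$cut
    if (any(sel)) descend(node$left, idx[sel])
    if (any(!sel)) descend(node$right, idx[!sel])
  }
  descend(tree$root, seq_len(nrow(binmat)))
  out
}

#' Fit the gradient-boosted-trees SPAD regressor
#'
#' Stagewise least-squares boosting: the model starts at the target mean,
#' each regression tree is fitted to the residuals of the running ensemble,
#' and the ensemble is updated with `learning_rate` times the new tree's
#' prediction. Splits are found over histogram-binned feature values. With a
#' constant target the model degenerates (with a warning) to the constant.
#'
#' @param train Data frame with the feature columns and a `spad` column; at
#'   least 10 rows.
#' @param features Character vector of feature (index) names.
#' @param config A [gbrt_config()].
#' @return A `gbrt_model` with `f0`, `trees`, `cuts`, `features`, `config`
#'   and the per-stage `train_rmse` history. Predict with
#'   [predict.gbrt_model()].
#' @export
fit_gbrt <- function(train, features, config = gbrt_config()) {
  stopifnot(is.data.frame(train), "spad" %in% names(train))
  if (nrow(train) < 10L)
    stop("at least 10 training samples are required", call. = FALSE)
  X <- as.matrix(train[, features, drop = FALSE])
  y <- train$spad
  n <- nrow(X)
  f0 <- mean(y)
  if (stats::var(y) == 0) {
    warning("constant target: returning the constant mean model",
            call. = FALSE)
    return(structure(list(f0 = f0, trees = list(), cuts = NULL,
                          features = features, config = config,
                          train_rmse = 0),
                     class = "gbrt_model"))
  }
  cuts <- lapply(seq_len(ncol(X)), function(j) gbrt_cuts(X[, j], config$max_bins))
  binmat <- vapply(seq_len(ncol(X)), function(j) {
    findInterval(X[, j], cuts[[j]], left.open = FALSE) + 1L
  }, integer(n))
  if (!is.matrix(binmat)) binmat <- matrix(binmat, nrow = n)

  pred <- rep(f0, n)
  trees <- vector("list", config$n_estimators)
  rmse_hist <- numeric(config$n_estimators)
  withr::with_seed(config$seed, {
    for (t in seq_len(config$n_estimators)) {
      resid <- y - pred
      idx <- if (config$subsample < 1) {
        sort(sample.int(n, max(2L * config$min_samples_leaf,
                               round(config$subsample * n))))
      } else seq_len(n)
      tree <- gbrt_tree(binmat, cuts, resid, idx, config$max_depth,
                        config$min_samples_leaf)
      trees[[t]] <- tree
      pred <- pred + config$learning_rate * gbrt_tree_predict(tree, binmat)
      rmse_hist[t] <- sqrt(mean((y - pred)^2))
    }
  })
  structure(list(f0 = f0, trees = trees, cuts = cuts, features = features,
                 config = config, train_rmse = rmse_hist),
            class = "gbrt_model")
}

#' Predict SPAD values from a fitted GBRT model
#'
#' @param object A `gbrt_model`.
#' @param newdata Data frame containing the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.gbrt_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  n <- nrow(X)
  if (length(object$trees) == 0L) return(rep(object$f0, n))
  binmat <- vapply(seq_along(object$cuts), function(j) {
    findInterval(X[, j], object$cuts[[j]], left.open = FALSE) + 1L
  }, integer(n))
  if (!is.matrix(binmat)) binmat <- matrix(binmat, nrow = n)
  pred <- rep(object$f0, n)
  for (tree in object$trees) {
    pred <- pred + object$config$learning_rate * gbrt_tree_predict(tree, binmat)
  }
  pred
}

#' Tune GBRT hyperparameters on a validation set
#'
#' Fits one model per grid row on the training frame, scores RMSE on the
#' validation frame, and returns the best (first minimum in grid order).
#'
#' @param train,val Data frames with feature columns and `spad`.
#' @param features Feature names.
#' @param grid Data frame of hyperparameter combinations; defaults to
#'   `n_estimators {100, 300} x max_depth {2, 3, 4} x learning_rate
#'   {0.05, 0.1} x subsample {0.8, 1.0}`.
#' @param seed Seed passed to each fit.
#' @return List with `model`, `config`, `val_rmse` and the scored `grid`.
#' @export
tune_gbrt <- function(train, val, features,
                      grid = expand.grid(n_estimators = c(100L, 300L),
                                         max_depth = c(2L, 3L, 4L),
                                         learning_rate = c(0.05, 0.1),
                                         subsample = c(0.8, 1.0)),
                      seed = 0L) {
  scores <- numeric(nrow(grid))
  models <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- gbrt_config(n_estimators = grid$n_estimators[i],
                       max_depth = grid$max_depth[i],
                       learning_rate = grid$learning_rate[i],
                       subsample = grid$subsample[i], seed = seed)
    models[[i]] <- fit_gbrt(train, features, cfg)
    pred <- predict(models[[i]], val)
    scores[i] <- sqrt(mean((val$spad - pred)^2))
  }
  best <- which.min(scores)
  grid$val_rmse <- scores
  list(model = models[[best]], config = models[[best]]$config,
       val_rmse = scores[best], grid = grid)
}

#' Evaluate a SPAD regression model
#'
#' Root-mean-square error, mean absolute error, and the adjusted
#' determination coefficient
#' `R2_adj = 1 - (1 - R2) (n - 1) / (n - p - 1)` with `p` predictors.
#'
#' @param model A model with a `predict` method over `data`.
#' @param data Data frame with the feature columns and observed `spad`.
#' @param n_features Number of predictors `p` (default: the model's feature
#'   count).
#' @return A `regression_report` list: `R2`, `R2_adj`, `RMSE`, `MAE`, `n`,
#'   `p`.
#' @export
evaluate_regression <- function(model, data, n_features = NULL) {
  stopifnot(is.data.frame(data), "spad" %in% names(data), nrow(data) > 0)
  p <- n_features %||% length(model$features)
  n <- nrow(data)
  if (n <= p + 1)
    stop("adjusted R^2 undefined: need n > p + 1 samples", call. = FALSE)
  pred <- predict(model, data)
  err <- data$spad - pred
  ss_res <- sum(err^2)
  ss_tot <- sum((data$spad - mean(data$spad))^2)
  r2 <- 1 - ss_res / ss_tot
  structure(list(R2 = r2,
                 R2_adj = 1 - (1 - r2) * (n - 1) / (n - p - 1),
                 RMSE = sqrt(mean(err^2)), MAE = mean(abs(err)),
                 n = n, p = p),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("<regression_report n=%d p=%d R2=%.3f R2_adj=%.3f RMSE=%.3f MAE=%.3f>\n",
              x$n, x$p, x$R2, x$R2_adj, x$RMSE, x$MAE))
  invisible(x)
}
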