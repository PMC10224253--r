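#' The packaged default selected channels
#'
#' The twelve channels that a decision-tree recursive-feature-elimination run
#' on the annotated patch data retains at the 0.04 importance threshold:
#' R and G (RGB), H and S (HSV), L and a (Lab), v (Luv), Y (YCbCr),
#' U (YUV), and h, l, s (HLS).
#'
#' @return A `selected_channels` object with `origin = "default"`.
#' @export
default_selected_channels <- function() {
  structure(list(names = c("rgb.R", "rgb.G", "hsv.H", "hsv.S", "lab.L",
                           "lab.a", "luv.v", "ycbcr.Y", "yuv.U", "hls.h",
                           "hls.l", "hls.s"),
                 origin = "default", threshold_used = 0.04),
            class = "selected_channels")
}

#' @export
print.selected_channels <- function(x, ...) {
  cat(sprintf("<selected_channels (%s, threshold %.3g): %s>\n", x$origin,
              x$threshold_used, paste(x$names, collapse = ", ")))
  invisible(x)
}

# Impurity-decrease importances of a single bounded-depth decision tree.
# Primary splits only (maxsurrogate = 0), normalized to sum to 1.
tree_importance <- function(features, labels, max_depth = 12L) {
  df <- as.data.frame(features)
  safe <- make.names(colnames(features))
  names(df) <- safe
  df$.label <- factor(labels)
  fit <- rpart::rpart(.label ~ ., data = df, method = "class",
                      control = rpart::rpart.control(
                        maxdepth = max_depth, cp = 0, xval = 0,
                        maxsurrogate = 0, maxcompete = 0,
                        minsplit = 4, minbucket = 2))
  imp <- rep(0, ncol(features))
  names(imp) <- safe
  vi <- fit$variable.importance
  if (!is.null(vi)) imp[names(vi)] <- vi
  if (sum(imp) > 0) imp <- imp / sum(imp)
  names(imp) <- colnames(features)
  imp
}

#' Rank channels by decision-tree recursive feature elimination (DT-RFE)
#'
#' Fits a bounded-depth decision tree, records its impurity-decrease (Gini)
#' channel importances, removes the `step` least-important channels, and
#' repeats until one channel remains. Reported importance scores come from
#' the initial full-feature fit; the elimination order (rank 1 = eliminated
#' first, highest rank = survivor) is recorded separately.
#'
#' The seed randomizes the column order presented to the tree, which breaks
#' ties among duplicated or equally informative channels reproducibly.
#'
#' @param dataset A [pixel_dataset()] with at least 2 channels and both
#'   classes present.
#' @param step Channels removed per iteration (default 1).
#' @param seed Integer seed.
#' @param max_depth Depth bound of each tree (default 12).
#' @return A `feature_ranking`: data frame `entries` with columns `channel`,
#'   `importance` (from the full fit), `elimination_rank`.
#' @export
rank_dtrfe <- function(dataset, step = 1L, seed = 0L, max_depth = 12L) {
  stopifnot(inherits(dataset, "pixel_dataset"))
  if (length(dataset$channel_names) < 2L)
    stop("DT-RFE needs at least 2 channels", call. = FALSE)
  if (length(unique(dataset$labels)) < 2L)
    stop("degenerate labels: both classes must be present", call. = FALSE)

  col_order <- withr::with_seed(seed, sample(dataset$channel_names))
  feats <- dataset$features[, col_order, drop = FALSE]

  full_importance <- tree_importance(feats, dataset$labels, max_depth)

  remaining <- colnames(feats)
  elim_rank <- integer(0)
  rank_counter <- 0L
  while (length(remaining) > 1L) {
    imp <- tree_importance(feats[, remaining, drop = FALSE], dataset$labels,
                           max_depth)
    n_drop <- min(step, length(remaining) - 1L)
    drop <- names(sort(imp))[seq_len(n_drop)]   # lowest importance first
    for (d in drop) {
      rank_counter <- rank_counter + 1L
      elim_rank[d] <- rank_counter
    }
    remaining <- setdiff(remaining, drop)
  }
  elim_rank[remaining] <- rank_counter + 1L

  entries <- data.frame(channel = names(full_importance),
                        importance = unname(full_importance),
                        elimination_rank = unname(elim_rank[names(full_importance)]),
                        stringsAsFactors = FALSE)
  entries <- entries[order(-entries$importance, -entries$elimination_rank), ]
  rownames(entries) <- NULL
  structure(list(entries = entries, seed = as.integer(seed)),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat("<feature_ranking>\n")
  print(x$entries, digits = 3)
  invisible(x)
}

#' Select channels above an importance threshold
#'
#' Channels whose importance strictly exceeds `threshold`, ordered by
#' descending importance. When `k` is given, exactly the top-`k` channels are
#' returned regardless of the threshold.
#'
#' @param ranking A [rank_dtrfe()] result.
#' @param threshold Importance cutoff (default 0.04).
#' @param k Optional count overriding the threshold.
#' @return A `selected_channels` object with `origin = "computed"`.
#' @export
select_channels <- function(ranking, threshold = 0.04, k = NULL) {
  stopifnot(inherits(ranking, "feature_ranking"))
  e <- ranking$entries
  if (nrow(e) == 0L) stop("empty ranking", call. = FALSE)
  if (!is.null(k)) {
    if (k < 1L || k > nrow(e)) stop("k out of range", call. = FALSE)
    names <- e$channel[seq_len(k)]
  } else {
    keep <- e$importance > threshold
    if (!any(keep))
      stop(paste0("no channel exceeds importance threshold ", threshold,
                  "; consider selecting a fixed top-k instead"), call. = FALSE)
    names <- e$channel[keep]
  }
  structure(list(names = names, origin = "computed",
                 threshold_used = if (is.null(k)) threshold else NA_real_),
            class = "selected_channels")
}
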