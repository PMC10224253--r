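#' Construct a binary segmentation mask
#'
#' @param m Integer matrix with values in `{0, 255}` (255 = plant foreground).
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(m) {
  if (!is.matrix(m)) stop("binary_mask requires a matrix", call. = FALSE)
  if (!all(m %in% c(0L, 255L)))
    stop("binary_mask values must be 0 or 255", call. = FALSE)
  storage.mode(m) <- "integer"
  structure(m, class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d x %d, %d foreground px>\n",
              nrow(x), ncol(x), sum(x == 255L)))
  invisible(x)
}

#' Segmentation quality factors Qseg, Sr and Es
#'
#' Pixel-by-pixel comparison of a segmentation `S` against a reference mask
#' `R` using logical intersection, union and complement over foreground
#' pixels:
#' \deqn{Qseg = |S \cap R| / |S \cup R|, \quad Sr = |S \cap R| / |R|, \quad
#'       Es = |S \cap !R| / |R|.}
#' Qseg (the foreground intersection-over-union) and Sr lie in `[0, 1]`;
#' Es is a false-positive rate relative to the reference foreground and may
#' exceed 1. A perfect segmentation scores (1, 1, 0).
#'
#' @param S,R [binary_mask()] objects of identical dimensions; `R` must have
#'   at least one foreground pixel.
#' @return A `quality_scores` list: `Qseg`, `Sr`, `Es`, `h`, `w`.
#' @export
segmentation_quality <- function(S, R) {
  stopifnot(inherits(S, "binary_mask"), inherits(R, "binary_mask"))
  if (!all(dim(S) == dim(R)))
    stop("segmentation and reference masks must share dimensions", call. = FALSE)
  s <- S == 255L; r <- R == 255L
  n_ref <- sum(r)
  if (n_ref == 0L)
    stop("reference mask has no foreground pixels; Sr and Es are undefined",
         call. = FALSE)
  inter <- sum(s & r)
  union <- sum(s | r)
  structure(list(Qseg = inter / union,
                 Sr = inter / n_ref,
                 Es = sum(s & !r) / n_ref,
                 h = nrow(S), w = ncol(S)),
            class = "quality_scores")
}

#' @export
print.quality_scores <- function(x, ...) {
  cat(sprintf("<quality_scores %dx%d: Qseg %.3f  Sr %.3f  Es %.3f>\n",
              x$h, x$w, x$Qseg, x$Sr, x$Es))
  invisible(x)
}

#' Binary classification metrics (accuracy, precision, recall, F-score)
#'
#' Counts TP/TN/FP/FN for binary labels (1 = foreground) and derives
#' `accuracy = (TP + TN) / n`, `recall = TP / (TP + FN)`,
#' `precision = TP / (TP + FP)` and `F = 2PR / (P + R)`. When precision and
#' recall are both zero (or undefined) the F-score is reported as 0 with
#' `degenerate_f = TRUE`.
#'
#' @param predicted,truth Equal-length vectors of 0/1 labels.
#' @return A `classification_report` list with the counts and derived metrics.
#' @export
classification_metrics <- function(predicted, truth) {
  if (length(predicted) == 0L || length(predicted) != length(truth))
    stop("predicted and true labels must be nonempty and equal length",
         call. = FALSE)
  if (!all(predicted %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("labels must be binary (0/1)", call. = FALSE)
  tp <- sum(predicted == 1 & truth == 1)
  tn <- sum(predicted == 0 & truth == 0)
  fp <- sum(predicted == 1 & truth == 0)
  fn <- sum(predicted == 0 & truth == 1)
  n <- tp + tn + fp + fn
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  degenerate <- (precision + recall) == 0
  f <- if (degenerate) 0 else 2 * precision * recall / (precision + recall)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 accuracy = (tp + tn) / n,
                 precision = precision, recall = recall,
                 F_score = f, degenerate_f = degenerate, n = n),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report n=%d acc=%.4f P=%.4f R=%.4f F=%.4f>\n",
              x$n, x$accuracy, x$precision, x$recall, x$F_score))
  invisible(x)
}

#' Aggregate quality scores across images
#'
#' Arithmetic mean and population standard deviation (divide by N) of Qseg,
#' Sr and Es over a list of [segmentation_quality()] results.
#'
#' @param scores Nonempty list of `quality_scores`.
#' @return List with named numeric vectors `mean` and `sd`.
#' @export
aggregate_quality <- function(scores) {
  if (length(scores) == 0L) stop("no quality scores to aggregate", call. = FALSE)
  stopifnot(all(vapply(scores, inherits, logical(1), "quality_scores")))
  m <- vapply(scores, function(s) c(Qseg = s$Qseg, Sr = s$Sr, Es = s$Es),
              numeric(3))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  list(mean = rowMeans(m), sd = apply(m, 1, pop_sd), n = length(scores))
}
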