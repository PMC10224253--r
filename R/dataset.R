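#' Construct an annotated image patch
#'
#' @param crop An [rgb_image()].
#' @param label `"foreground"` or `"background"`.
#' @param source `"glasshouse"` or `"field"`.
#' @param patch_id Unique identifier string.
#' @return A `patch` object.
#' @export
patch <- function(crop, label, source = "glasshouse", patch_id = NULL) {
  assert_rgb_image(crop)
  label <- match.arg(label, c("foreground", "background"))
  source <- match.arg(source, c("glasshouse", "field"))
  structure(list(crop = crop, label = label, source = source,
                 patch_id = patch_id %||% paste0(label, "-", source)),
            class = "patch")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standardize a patch to 20 x 20 pixels
#'
#' Bilinear resize of the crop; label and metadata are preserved. A crop that
#' is already 20 x 20 is returned unchanged.
#'
#' @param p A [patch()].
#' @param size Target side length in pixels (default 20).
#' @return A `patch` whose crop is `size x size`.
#' @export
standardize_patch <- function(p, size = 20L) {
  stopifnot(inherits(p, "patch"))
  d <- dim(p$crop)
  if (d[1] == size && d[2] == size) return(p)
  # EBImage uses x (width) as the first array dimension
  arr <- aperm(array(as.numeric(p$crop) / 255, dim = d), c(2, 1, 3))
  img <- EBImage::Image(arr, colormode = "Color")
  res <- EBImage::resize(img, w = size, h = size, filter = "bilinear")
  out <- aperm(EBImage::imageData(res), c(2, 1, 3))
  p$crop <- rgb_image(pmin(pmax(out * 255, 0), 255))
  p
}

#' Construct a per-pixel labeled feature dataset
#'
#' @param features Numeric matrix `n x C` with channel names as column names.
#' @param labels Integer vector of 0/1 labels (1 = foreground).
#' @param row_ids Optional integer identifiers (default `1:n`).
#' @return A `pixel_dataset` object.
#' @export
pixel_dataset <- function(features, labels, row_ids = NULL) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  structure(list(features = features,
                 labels = as.integer(labels),
                 channel_names = colnames(features),
                 row_ids = as.integer(row_ids %||% seq_len(nrow(features))),
                 n_rows = nrow(features)),
            class = "pixel_dataset")
}

#' @export
print.pixel_dataset <- function(x, ...) {
  cat(sprintf("<pixel_dataset %d rows x %d channels (%d foreground)>\n",
              x$n_rows, length(x$channel_names), sum(x$labels)))
  invisible(x)
}

#' Assemble standardized patches into a pixel dataset
#'
#' Converts every 20 x 20 patch to its 24-channel feature stack and emits one
#' labeled row per pixel, so the dataset holds `400 x 24` scalar features per
#' patch. The total scalar-feature counts (foreground, background, total) are
#' returned in the `assembly` attribute and logged.
#'
#' @param patches List of standardized [patch()] objects (all the same size).
#' @param verbose Log the assembly counts (default `TRUE`).
#' @return A [pixel_dataset()] with an `assembly` attribute listing
#'   `n_patches`, `scalar_features_fg`, `scalar_features_bg`,
#'   `scalar_features_total`.
#' @export
assemble_patches <- function(patches, verbose = TRUE) {
  if (length(patches) == 0L) stop("no patches to assemble", call. = FALSE)
  stopifnot(all(vapply(patches, inherits, logical(1), "patch")))
  sizes <- t(vapply(patches, function(p) dim(p$crop)[1:2], integer(2)))
  if (length(unique(sizes[, 1])) != 1L || length(unique(sizes[, 2])) != 1L)
    stop("mixed patch sizes; standardize patches first", call. = FALSE)
  px_per_patch <- sizes[1, 1] * sizes[1, 2]

  n <- length(patches) * px_per_patch
  rgbmat <- matrix(0, nrow = n, ncol = 3L)
  labels <- integer(n)
  for (i in seq_along(patches)) {
    cr <- patches[[i]]$crop
    rows <- ((i - 1) * px_per_patch + 1):(i * px_per_patch)
    rgbmat[rows, ] <- cbind(as.vector(cr[, , 1]), as.vector(cr[, , 2]),
                            as.vector(cr[, , 3]))
    labels[rows] <- if (patches[[i]]$label == "foreground") 1L else 0L
  }
  feats <- pixels_to_features(rgbmat)
  ds <- pixel_dataset(feats, labels)
  n_ch <- ncol(feats)
  assembly <- list(n_patches = length(patches),
                   pixels_per_patch = px_per_patch,
                   scalar_features_fg = sum(labels == 1L) * n_ch,
                   scalar_features_bg = sum(labels == 0L) * n_ch,
                   scalar_features_total = n * n_ch)
  attr(ds, "assembly") <- assembly
  if (verbose)
    cs_log("assembled %d patches: %s fg + %s bg = %s scalar features",
           assembly$n_patches,
           format(assembly$scalar_features_fg, big.mark = ","),
           format(assembly$scalar_features_bg, big.mark = ","),
           format(assembly$scalar_features_total, big.mark = ","))
  ds
}

#' Split specification
#'
#' @param ratios Positive fractions summing to 1 (within 1e-9), e.g.
#'   `c(3, 1, 1) / 5` for the train:validation:test split or
#'   `c(0.70, 0.15, 0.15)` for the regression cohorts.
#' @param seed Integer seed for the shuffle.
#' @param stratified Stratify by class label (default `TRUE`).
#' @return A `split_spec` object.
#' @export
split_spec <- function(ratios = c(3, 1, 1) / 5, seed = 0L, stratified = TRUE) {
  if (any(ratios <= 0)) stop("all split ratios must be positive", call. = FALSE)
  if (abs(sum(ratios) - 1) > 1e-9)
    stop("split ratios must sum to 1", call. = FALSE)
  structure(list(ratios = ratios, seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "split_spec")
}

# Largest-remainder apportionment of n rows into parts proportional to ratios
largest_remainder <- function(n, ratios) {
  exact <- n * ratios
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    order_by_frac <- order(exact - base, decreasing = TRUE)
    base[order_by_frac[seq_len(rem)]] <- base[order_by_frac[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Split a pixel dataset into train / validation / test parts
#'
#' Seeded shuffle followed by a largest-remainder partition so part sizes
#' always sum to the input size; optionally stratified by label, which keeps
#' class proportions within one row per part. The same seed always reproduces
#' the identical split.
#'
#' @param dataset A [pixel_dataset()].
#' @param spec A [split_spec()].
#' @return List of [pixel_dataset()] parts, named `train`, `validation`,
#'   `test` when three ratios are given.
#' @export
split_dataset <- function(dataset, spec) {
  stopifnot(inherits(dataset, "pixel_dataset"), inherits(spec, "split_spec"))
  k <- length(spec$ratios)
  if (dataset$n_rows < k)
    stop("dataset has fewer rows than split parts", call. = FALSE)
  assign_part <- function(idx) {
    sizes <- largest_remainder(length(idx), spec$ratios)
    rep(seq_len(k), times = sizes)
  }
  parts_of <- withr::with_seed(spec$seed, {
    part <- integer(dataset$n_rows)
    if (spec$stratified) {
      for (lab in c(0L, 1L)) {
        idx <- which(dataset$labels == lab)
        if (length(idx) == 0L) next
        idx <- sample(idx)
        part[idx] <- assign_part(idx)
      }
    } else {
      idx <- sample.int(dataset$n_rows)
      part[idx] <- assign_part(idx)
    }
    part
  })
  nm <- if (k == 3L) c("train", "validation", "test") else paste0("part", 1:k)
  out <- lapply(seq_len(k), function(p) {
    sel <- which(parts_of == p)
    pixel_dataset(dataset$features[sel, , drop = FALSE],
                  dataset$labels[sel],
                  row_ids = dataset$row_ids[sel])
  })
  names(out) <- nm
  out
}

#' Restrict a dataset to a channel subset
#'
#' @param dataset A [pixel_dataset()].
#' @param channels Character vector of channel names (subset of the dataset's
#'   channels) or a `selected_channels` object.
#' @return A [pixel_dataset()] whose columns are exactly `channels`, in the
#'   requested order; labels untouched.
#' @export
restrict_channels <- function(dataset, channels) {
  stopifnot(inherits(dataset, "pixel_dataset"))
  if (inherits(channels, "selected_channels")) channels <- channels$names
  missing <- setdiff(channels, dataset$channel_names)
  if (length(missing) > 0)
    stop(sprintf("unknown channel(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  pixel_dataset(dataset$features[, channels, drop = FALSE], dataset$labels,
                row_ids = dataset$row_ids)
}

#' Read patches from labeled directories
#'
#' Expects PNG crops under `fg/` and `bg/` subdirectories of `dir`.
#'
#' @param dir Directory containing `fg/` and `bg/`.
#' @param source Scene provenance label for the patches.
#' @return List of standardized [patch()] objects.
#' @export
read_patch_dir <- function(dir, source = "glasshouse") {
  out <- list()
  subdirs <- c(foreground = "fg", background = "bg")
  for (lab in names(subdirs)) {
    sub <- file.path(dir, subdirs[[lab]])
    files <- list.files(sub, pattern = "\\.(png|jpg|jpeg)$",
                        ignore.case = TRUE, full.names = TRUE)
    for (f in files) {
      p <- patch(read_image(f), label = lab, source = source,
                 patch_id = basename(f))
      out[[length(out) + 1L]] <- standardize_patch(p)
    }
  }
  out
}

#' Write / read a pixel dataset as CSV
#'
#' The CSV carries a `# canopyseg pixel_dataset schema v1` comment line, then
#' a header of channel names plus `label`.
#'
#' @param dataset A [pixel_dataset()].
#' @param path Output CSV path.
#' @export
write_dataset_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "pixel_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# canopyseg pixel_dataset schema v1", con)
  df <- as.data.frame(dataset$features)
  df$label <- dataset$labels
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @return `read_dataset_csv()` returns a [pixel_dataset()].
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  labels <- as.integer(df$label)
  feats <- as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
  pixel_dataset(feats, labels)
}
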