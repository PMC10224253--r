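#' Registry of color vegetation indices
#'
#' The eleven region-level color vegetation indices (CVIs) computed by
#' [cvi_from_region()], in the fixed registry order used for tie-breaking.
#'
#' @return Character vector of index names.
#' @export
cvi_registry <- function() {
  c("Green", "Blue", "ExG", "ExR", "CIVE", "ERI", "DGCI", "GR", "COM1",
    "GBRG", "EGI")
}

#' Per-pixel vegetation index image
#'
#' Evaluates an index on raw 8-bit channel values at every pixel. Only the two
#' indices used for threshold segmentation are available per pixel:
#' `ExG = 2G - R - B` and `ExGR = ExG - (1.4 R - G)`.
#'
#' @param image An [rgb_image()].
#' @param name `"ExG"` or `"ExGR"`.
#' @return An `index_image`: list with `values` (numeric matrix `h x w`) and
#'   `index_name`.
#' @export
index_image <- function(image, name) {
  assert_rgb_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  R <- matrix(image[, , 1], h, w); G <- matrix(image[, , 2], h, w)
  B <- matrix(image[, , 3], h, w)
  vals <- switch(name,
    ExG  = 2 * G - R - B,
    ExGR = (2 * G - R - B) - (1.4 * R - G),
    stop(sprintf("unknown index '%s'; per-pixel indices are ExG, ExGR", name),
         call. = FALSE))
  structure(list(values = vals, index_name = name,
                 height = nrow(vals), width = ncol(vals)),
            class = "index_image")
}

#' Otsu threshold of a numeric vector or index image
#'
#' Values are linearly rescaled into 256 bins; the returned bin threshold
#' maximizes the between-class variance, exhaustively over all candidate
#' splits (smallest maximizer on ties).
#'
#' @param values Numeric vector (finite, at least two distinct values).
#' @return List with `bin` (the split bin, 0-254), `value` (threshold on the
#'   original scale: pixels strictly above it are foreground), `lo`, `hi`.
#' @export
otsu_threshold <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values)))
    stop("otsu_threshold requires finite values", call. = FALSE)
  lo <- min(values); hi <- max(values)
  if (lo == hi)
    stop("degenerate histogram: index image is constant", call. = FALSE)
  bins <- pmin(255L, as.integer(floor((values - lo) / (hi - lo) * 256)))
  counts <- tabulate(bins + 1L, nbins = 256L)
  n <- length(values)
  level <- 0:255
  w0 <- cumsum(counts)                     # class sizes for split after bin t
  sum0 <- cumsum(counts * level)
  total <- sum0[256]
  w0 <- w0[1:255]; sum0 <- sum0[1:255]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- sum0 / w0
  mu1 <- (total - sum0) / w1
  bcv <- w0 * w1 * (mu0 - mu1)^2
  bcv[!valid] <- -Inf
  t_star <- which.max(bcv) - 1L            # first maximizer -> smallest bin
  list(bin = t_star,
       value = lo + (t_star + 1) * (hi - lo) / 256,
       lo = lo, hi = hi)
}

#' Segment an index image by Otsu thresholding
#'
#' @param index An `index_image` (see [index_image()]).
#' @return A [binary_mask()]: pixels above the Otsu threshold are foreground
#'   (255).
#' @export
otsu_mask <- function(index) {
  stopifnot(inherits(index, "index_image"))
  th <- otsu_threshold(index$values)
  bins <- pmin(255L, as.integer(floor((index$values - th$lo) /
                                        (th$hi - th$lo) * 256)))
  m <- matrix(0L, nrow = index$height, ncol = index$width)
  m[bins > th$bin] <- 255L
  binary_mask(m)
}

#' Region-level color vegetation indices
#'
#' Computes the mean 8-bit R, G, B over the mask's foreground pixels, the HSV
#' coordinates of that mean color (H in degrees, S and brightness Bv as
#' fractions), and the eleven registry CVIs from those means:
#' `Green = G`, `Blue = B`, `ExG = 2G - R - B`, `ExR = 1.4R - G`,
#' `CIVE = 0.441R - 0.811G + 0.385B + 18.78`, `ERI = (R - G)(R - B)`,
#' `DGCI = [(H - 60)/60 + (1 - S) + (1 - Bv)]/3`, `GR = G - R`,
#' `COM1 = ExG + CIVE + ExGR`, `GBRG = (G - R)/(R - G)`,
#' `EGI = (G - R)/(G - B)`.
#'
#' As printed, GBRG is identically -1 wherever R differs from G; it is kept in
#' that form and flagged undefined at R = G, as is EGI at G = B.
#'
#' @param image An [rgb_image()].
#' @param mask A [binary_mask()] with at least one foreground pixel.
#' @param dgci_literal If `TRUE`, evaluate DGCI with the literal printed
#'   parenthesization `(H - 60) / (60 + (1 - S) + (1 - Bv)) / 3` instead of
#'   the canonical mean of three rescaled components.
#' @param chromatic If `TRUE`, replace the mean R, G, B by chromatic
#'   coordinates `r = R/(R+G+B)` etc. before evaluating the RGB-based indices
#'   (off by default; the raw-channel form is canonical here).
#' @param per_pixel If `TRUE`, RGB-based indices are computed per foreground
#'   pixel and averaged, instead of being evaluated at the mean color
#'   (sensitivity mode).
#' @return A `cvi_record`: list with `mean_R`, `mean_G`, `mean_B`, `mean_H`,
#'   `mean_S`, `mean_Bv`, `values` (named numeric, `NA` where undefined) and
#'   `defined` (named logical).
#' @export
cvi_from_region <- function(image, mask, dgci_literal = FALSE,
                            chromatic = FALSE, per_pixel = FALSE) {
  assert_rgb_image(image)
  stopifnot(inherits(mask, "binary_mask"))
  if (!all(dim(mask) == dim(image)[1:2]))
    stop("mask dimensions must match the image", call. = FALSE)
  fg <- mask == 255L
  if (!any(fg)) stop("empty region: mask has no foreground pixels", call. = FALSE)

  Rv <- image[, , 1][fg]; Gv <- image[, , 2][fg]; Bv8 <- image[, , 3][fg]
  mean_R <- mean(Rv); mean_G <- mean(Gv); mean_B <- mean(Bv8)
  hsv <- grDevices::rgb2hsv(mean_R, mean_G, mean_B, maxColorValue = 255)
  H <- unname(hsv[1, 1]) * 360; S <- unname(hsv[2, 1]); Bv <- unname(hsv[3, 1])

  rgb_indices <- function(R, G, B) {
    ExG <- 2 * G - R - B
    ExR <- 1.4 * R - G
    CIVE <- 0.441 * R - 0.811 * G + 0.385 * B + 18.78
    ExGR <- ExG - ExR
    list(Green = G, Blue = B, ExG = ExG, ExR = ExR, CIVE = CIVE,
         ERI = (R - G) * (R - B),
         GR = G - R,
         COM1 = ExG + CIVE + ExGR,
         GBRG = ifelse(R == G, NA_real_, (G - R) / (R - G)),
         EGI = ifelse(G == B, NA_real_, (G - R) / (G - B)))
  }

  if (per_pixel) {
    px <- rgb_indices(Rv, Gv, Bv8)
    idx <- lapply(px, function(v) mean(v, na.rm = TRUE))
    idx <- lapply(idx, function(v) if (is.nan(v)) NA_real_ else v)
  } else if (chromatic) {
    tot <- mean_R + mean_G + mean_B
    if (tot == 0) {
      idx <- rgb_indices(0, 0, 0)
    } else {
      idx <- rgb_indices(mean_R / tot, mean_G / tot, mean_B / tot)
    }
  } else {
    idx <- rgb_indices(mean_R, mean_G, mean_B)
  }

  dgci <- if (dgci_literal) {
    (H - 60) / (60 + (1 - S) + (1 - Bv)) / 3
  } else {
    ((H - 60) / 60 + (1 - S) + (1 - Bv)) / 3
  }

  values <- c(Green = idx$Green, Blue = idx$Blue, ExG = idx$ExG, ExR = idx$ExR,
              CIVE = idx$CIVE, ERI = idx$ERI, DGCI = dgci, GR = idx$GR,
              COM1 = idx$COM1, GBRG = idx$GBRG, EGI = idx$EGI)
  values <- values[cvi_registry()]
  structure(list(mean_R = mean_R, mean_G = mean_G, mean_B = mean_B,
                 mean_H = H, mean_S = S, mean_Bv = Bv,
                 values = values, defined = !is.na(values)),
            class = "cvi_record")
}

#' @export
print.cvi_record <- function(x, ...) {
  cat(sprintf("<cvi_record mean RGB (%.1f, %.1f, %.1f)>\n",
              x$mean_R, x$mean_G, x$mean_B))
  print(round(x$values, 4))
  invisible(x)
}
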