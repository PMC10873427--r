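# Pearson colocalization of two-channel confocal images.

#' Construct a single-channel image
#'
#' @param pixels Numeric matrix of intensities (finite, >= 0).
#' @param pixel_size Pixel size in micrometres per pixel.
#' @param channel_label One of `"receptor_yfp"`, `"receptor_mtq2"`,
#'   `"er_marker"`, `"pm_marker"`, `"nuclei"`.
#' @return Object of class `channel_image`.
#' @export
channel_image <- function(pixels, pixel_size = 1,
                          channel_label = c("receptor_yfp", "receptor_mtq2",
                                            "er_marker", "pm_marker", "nuclei")) {
  channel_label <- match.arg(channel_label)
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (any(!is.finite(pixels))) stop("pixel intensities must be finite")
  if (any(pixels < 0)) stop("pixel intensities must be >= 0")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 channel_label = channel_label),
            class = "channel_image")
}

#' Pearson correlation between two channels
#'
#' Sample Pearson correlation over all pixel pairs of the two channels,
#' optionally restricted to a binary mask. Whole-frame correlation without
#' thresholding: intensities are treated as continuous and no background
#' subtraction is applied.
#'
#' @param a,b [channel_image()] objects (or plain matrices) of identical
#'   dimensions.
#' @param mask Optional logical matrix of the same dimensions with at least
#'   two `TRUE` pixels.
#' @return Object of class `coloc_result`: `r`, `n_pixels`, `pair`.
#' @export
pearson_r <- function(a, b, mask = NULL) {
  pa <- if (inherits(a, "channel_image")) a$pixels else a
  pb <- if (inherits(b, "channel_image")) b$pixels else b
  la <- if (inherits(a, "channel_image")) a$channel_label else "a"
  lb <- if (inherits(b, "channel_image")) b$channel_label else "b"
  if (!identical(dim(pa), dim(pb))) stop("channel dimensions differ")
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(pa))) stop("mask dimensions differ from image")
    mask <- as.logical(mask)
    if (sum(mask) < 2) stop("mask must select at least 2 pixels")
    va <- pa[mask]; vb <- pb[mask]
  } else {
    va <- as.vector(pa); vb <- as.vector(pb)
  }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("zero variance: a channel is constant over the analysed region")
  }
  structure(list(r = stats::cor(va, vb),
                 n_pixels = length(va),
                 pair = c(la, lb)),
            class = "coloc_result")
}

#' Summarize replicate colocalization measurements
#'
#' Mean and sample standard deviation (n - 1 denominator) of Pearson r over
#' replicate images of the same channel pair.
#'
#' @param results List of `coloc_result` objects with identical pair labels.
#' @return List: `mean_r`, `sd_r`, `n`, `pair`, `sd_flagged` (`TRUE` when a
#'   single replicate forced SD to 0).
#' @export
summarize_replicates <- function(results) {
  stopifnot(length(results) >= 1)
  pairs <- vapply(results, function(x) paste(x$pair, collapse = "|"), character(1))
  if (length(unique(pairs)) != 1) stop("mixed pair labels in replicate set")
  r <- vapply(results, `[[`, numeric(1), "r")
  n <- length(r)
  list(mean_r = mean(r),
       sd_r = if (n == 1) 0 else stats::sd(r),
       n = n,
       pair = results[[1]]$pair,
       sd_flagged = n == 1)
}
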