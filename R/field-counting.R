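# Particle counting in stained retinal field images: threshold, label
# connected components, filter by area. Mirrors an ImageJ threshold +
# "Analyze Particles" workflow with a deterministic automatic threshold.

#' Construct a stained retinal field image
#'
#' Fields are nominally 317 x 317 um acquired 700-1100 um from the optic
#' nerve. The declared field size must agree with pixel grid x pixel size to
#' within one pixel.
#'
#' @param pixels Numeric intensity matrix.
#' @param pixel_size um per pixel.
#' @param stain One of `"TUNEL"`, `"PROTEOSTAT"`, `"DAPI"`.
#' @param region `"superior"` or `"inferior"`.
#' @param field_size Declared field edge lengths in um (length-2, defaults to
#'   grid x pixel_size).
#' @param eccentricity_window Acquisition window in um from the optic nerve.
#' @return Object of class `field_image`.
#' @export
field_image <- function(pixels, pixel_size,
                        stain = c("TUNEL", "PROTEOSTAT", "DAPI"),
                        region = c("superior", "inferior"),
                        field_size = NULL,
                        eccentricity_window = c(700, 1100)) {
  stain <- match.arg(stain); region <- match.arg(region)
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  implied <- dim(pixels) * pixel_size
  if (is.null(field_size)) field_size <- implied
  if (any(abs(field_size - implied) > pixel_size)) {
    stop("field_size inconsistent with pixel grid x pixel_size (> 1 pixel off)")
  }
  structure(list(pixels = pixels, pixel_size = pixel_size, stain = stain,
                 region = region, field_size = field_size,
                 eccentricity_window = eccentricity_window),
            class = "field_image")
}

#' Threshold a field image
#'
#' A pixel is foreground iff its intensity >= threshold. `"auto"` picks the
#' threshold by Otsu's between-class-variance maximization over a 256-bin
#' histogram, a deterministic stand-in for interactive threshold adjustment;
#' a numeric threshold overrides it.
#'
#' @param image A [field_image()] or intensity matrix.
#' @param threshold Numeric intensity within the image range, or `"auto"`.
#' @return Logical matrix with the chosen threshold attached as attribute
#'   `threshold`.
#' @export
binarize <- function(image, threshold = "auto") {
  px <- if (inherits(image, "field_image")) image$pixels else image
  if (length(px) == 0) stop("empty image")
  rng <- range(px)
  if (identical(threshold, "auto")) {
    if (rng[1] == rng[2]) {
      thr <- rng[1] + 1  # constant image: nothing above threshold
    } else {
      norm <- (px - rng[1]) / (rng[2] - rng[1])
      t01 <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1), levels = 256)
      thr <- rng[1] + t01 * (rng[2] - rng[1])
    }
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1)
    if (threshold < rng[1] || threshold > rng[2]) {
      stop("numeric threshold outside image intensity range")
    }
    thr <- threshold
  }
  structure(px >= thr, dim = dim(px), threshold = thr)
}

# label connected foreground components; EBImage::bwlabel is 4-connected, so
# 8-connectivity additionally merges labels that touch diagonally
.label_components <- function(binary, connectivity = 8) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(binary * 1)))
  lab <- matrix(as.integer(lab), nrow(binary), ncol(binary))
  if (connectivity == 4 || max(lab) <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  edges <- NULL
  for (sh in list(c(1, 1), c(1, -1))) {
    a <- lab[seq_len(nr - 1), , drop = FALSE]
    b <- lab[seq_len(nr - 1) + 1, , drop = FALSE]
    if (sh[2] == 1) {
      a <- a[, seq_len(nc - 1), drop = FALSE]
      b <- b[, seq_len(nc - 1) + 1, drop = FALSE]
    } else {
      a <- a[, seq_len(nc - 1) + 1, drop = FALSE]
      b <- b[, seq_len(nc - 1), drop = FALSE]
    }
    keep <- a > 0 & b > 0 & a != b
    if (any(keep)) edges <- rbind(edges, cbind(a[keep], b[keep]))
  }
  if (is.null(edges)) return(lab)
  el <- unique(edges)
  g <- igraph::graph_from_edgelist(matrix(as.character(el), ncol = 2),
                                   directed = FALSE)
  missing_labels <- setdiff(as.character(seq_len(max(lab))),
                            igraph::V(g)$name)
  g <- igraph::add_vertices(g, length(missing_labels), name = missing_labels)
  comp <- igraph::components(g)$membership
  remap <- integer(max(lab))
  remap[as.integer(names(comp))] <- comp
  lab[lab > 0] <- remap[lab[lab > 0]]
  lab
}

#' Count particles in a thresholded field
#'
#' Connected components of the foreground, filtered by physical area.
#'
#' @param binary Logical matrix (output of [binarize()]).
#' @param min_area Minimum particle area in um^2 (default 10, excluding
#'   single-pixel noise at typical confocal sampling).
#' @param connectivity 8 (default) or 4.
#' @param pixel_size um per pixel, for the um^2 to pixel conversion.
#' @return Object of class `field_count_result`: `count`, `threshold_used`,
#'   `min_area_used`, `connectivity`, `areas_um2` (per retained particle).
#' @export
count_particles <- function(binary, min_area = 10, connectivity = 8,
                            pixel_size = 1) {
  stopifnot(is.logical(binary) || all(binary %in% c(0, 1)),
            connectivity %in% c(4, 8))
  thr <- attr(binary, "threshold")
  binary <- matrix(as.logical(binary), nrow(binary), ncol(binary))
  if (!any(binary)) {
    return(structure(list(count = 0L, threshold_used = thr,
                          min_area_used = min_area,
                          connectivity = connectivity,
                          areas_um2 = numeric(0)),
                     class = "field_count_result"))
  }
  lab <- .label_components(binary, connectivity)
  areas_px <- tabulate(lab[lab > 0])
  areas_um2 <- areas_px * pixel_size^2
  keep <- areas_um2 >= min_area
  structure(list(count = sum(keep),
                 threshold_used = thr,
                 min_area_used = min_area,
                 connectivity = connectivity,
                 areas_um2 = areas_um2[keep]),
            class = "field_count_result")
}

#' Group summary of per-field particle counts
#'
#' @param counts Data frame with columns `stain`, `region`, `age`,
#'   `genotype`, `count` (one row per field).
#' @return Tibble ordered by (stain, region, age, genotype) with `mean_count`,
#'   `sd_count` (NA with `sd_flagged = TRUE` for single-member groups), `n`.
#' @export
counts_summary <- function(counts) {
  counts <- as.data.frame(counts)
  stopifnot(all(c("stain", "region", "age", "genotype", "count") %in% names(counts)))
  counts |>
    dplyr::group_by(.data$stain, .data$region, .data$age, .data$genotype) |>
    dplyr::summarise(mean_count = mean(.data$count),
                     sd_count = ifelse(dplyr::n() > 1, stats::sd(.data$count), NA_real_),
                     n = dplyr::n(),
                     sd_flagged = dplyr::n() == 1,
                     .groups = "drop") |>
    dplyr::arrange(.data$stain, .data$region, .data$age, .data$genotype)
}

#' Read a single-channel image from TIFF or PNG
#'
#' @param path File path ending in .tif/.tiff/.png.
#' @return Numeric intensity matrix (first channel if multi-channel).
#' @export
read_channel_matrix <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.numeric(img), nrow(img), ncol(img))
}

#' Write an intensity matrix as PNG (scaled to [0, 1])
#'
#' @param pixels Numeric matrix.
#' @param path Output path (.png).
#' @export
write_channel_png <- function(pixels, path) {
  rng <- range(pixels)
  norm <- if (rng[1] == rng[2]) pixels * 0 else (pixels - rng[1]) / (rng[2] - rng[1])
  png::writePNG(norm, path)
  invisible(path)
}
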