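# Quantification of saline permeation between substrate and encapsulation
# from grayscale microscope images: thresholding (Otsu or fixed),
# percent permeated area within a region of interest, maximum permeation
# distance from the electrode-opening boundary (exact Euclidean distance
# transform), and a conservative electrical-shorting risk flag.

#' Grayscale microscopy image with physical pixel size
#'
#' @param pixels numeric matrix of intensities (arbitrary units), at
#'   least 16 x 16.
#' @param pixel_size_um physical size of one pixel, um.
#' @return object of class `microscopy_image`.
#' @export
microscopy_image <- function(pixels, pixel_size_um) {
  if (!is.matrix(pixels) || nrow(pixels) < 16 || ncol(pixels) < 16) {
    stop("image must be a matrix of at least 16 x 16 pixels", call. = FALSE)
  }
  if (!all(is.finite(pixels))) stop("non-finite pixel values", call. = FALSE)
  check_positive(pixel_size_um, "pixel_size_um")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um),
            class = "microscopy_image")
}

#' Read a microscope image from PNG or TIFF
#'
#' RGB images are converted to grayscale with the standard luminance
#' weights 0.299 R + 0.587 G + 0.114 B; an alpha channel is ignored.
#' Pixel size comes from `pixel_size_um` or from a JSON sidecar with key
#' `pixel_size_um` (and optionally `roi` / `boundary`, retrievable with
#' [read_image_meta()]).
#'
#' @param path image path ending in `.png`, `.tif` or `.tiff`.
#' @param pixel_size_um pixel size, um; required unless `meta` is given.
#' @param meta optional path to the JSON sidecar.
#' @return a [microscopy_image()].
#' @export
read_microscopy_image <- function(path, pixel_size_um = NULL, meta = NULL) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(arr)) == 3) {
    if (dim(arr)[3] >= 3) {
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  if (is.null(pixel_size_um)) {
    if (is.null(meta)) stop("pixel_size_um or meta sidecar required",
                            call. = FALSE)
    pixel_size_um <- read_image_meta(meta)$pixel_size_um
  }
  microscopy_image(arr, pixel_size_um)
}

#' Read an image metadata sidecar
#'
#' JSON with `pixel_size_um`, and optionally `roi` (rectangle
#' `[row0, col0, row1, col1]`, 0-based inclusive) and `boundary` (n x 2
#' array of 0-based `[row, col]` pixel coordinates). Coordinates are
#' converted to the package's 1-based matrix convention.
#'
#' @param path JSON file path.
#' @return list with `pixel_size_um`, and when present `roi` (1-based
#'   rectangle vector) and `boundary` (1-based n x 2 matrix).
#' @export
read_image_meta <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$pixel_size_um)) stop("meta JSON lacks pixel_size_um",
                                     call. = FALSE)
  out <- list(pixel_size_um = j$pixel_size_um)
  if (!is.null(j$roi)) out$roi <- as.numeric(j$roi) + 1
  if (!is.null(j$boundary)) {
    b <- matrix(as.numeric(unlist(j$boundary)), ncol = 2, byrow = is.list(j$boundary))
    out$boundary <- b + 1
  }
  out
}

# Otsu's criterion over a fixed-level histogram of an image already
# scaled to [0, 1]: the threshold (a bin centre) maximising the
# between-class variance of the two disjoint classes; ties resolved as
# the midpoint of the first and last maximising bins.
otsu_threshold01 <- function(scaled, levels = 256) {
  breaks <- seq(0, 1, length.out = levels + 1)
  mids <- (breaks[-1] + breaks[-(levels + 1)]) / 2
  bins <- pmin(pmax(ceiling(scaled * levels), 1L), levels)
  counts <- tabulate(bins, nbins = levels)
  w1 <- cumsum(counts)
  m1 <- cumsum(counts * mids)
  w2 <- w1[levels] - w1
  m2 <- m1[levels] - m1
  ok <- w1 > 0 & w2 > 0
  v <- rep(-Inf, levels)
  v[ok] <- (w1 * w2)[ok] * ((m2 / w2 - m1 / w1)[ok])^2
  maxi <- which(v == max(v))
  (mids[maxi[1]] + mids[maxi[length(maxi)]]) / 2
}

#' Threshold an image into a permeation mask
#'
#' Flags pixels as permeated by intensity. `"otsu"` rescales the image to
#' its own intensity range and picks the threshold maximising the
#' between-class variance over a 256-level histogram (Otsu's criterion);
#' `"fixed"` reproduces a manually adjusted threshold on the original
#' intensity scale. Permeated pixels are those strictly above the
#' threshold (`polarity = "bright"`) or strictly below it (`"dark"`).
#'
#' @param image a [microscopy_image()] or numeric matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold intensity threshold for `method = "fixed"`.
#' @param polarity whether permeation appears bright or dark.
#' @return logical matrix of the same shape, with the threshold used in
#'   attribute `"threshold"`. A constant image yields an empty mask with
#'   a warning (no contrast to threshold).
#' @export
binarize <- function(image, method = c("otsu", "fixed"), threshold = NULL,
                     polarity = c("bright", "dark")) {
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  px <- if (inherits(image, "microscopy_image")) image$pixels else image
  stopifnot(is.matrix(px))
  if (method == "fixed") {
    if (is.null(threshold)) stop("fixed method needs a threshold", call. = FALSE)
    t_use <- threshold
  } else {
    rng <- range(px)
    if (diff(rng) == 0) {
      warning("constant image: no contrast, returning empty mask")
      mask <- matrix(FALSE, nrow(px), ncol(px))
      attr(mask, "threshold") <- NA_real_
      return(mask)
    }
    scaled <- (px - rng[1]) / diff(rng)
    t01 <- otsu_threshold01(scaled)
    t_use <- rng[1] + t01 * diff(rng)
  }
  mask <- if (polarity == "bright") px > t_use else px < t_use
  attr(mask, "threshold") <- t_use
  mask
}

#' Percent permeated area within a region of interest
#'
#' `100 * |mask AND roi| / |roi|`. The ROI defines the denominator (for
#' example a rectangle around one electrode opening) and reported
#' percentages depend directly on its choice, so it should be stated
#' alongside any result.
#'
#' @param mask logical matrix of permeated pixels.
#' @param roi logical matrix of the same shape, or `NULL` for the whole
#'   image.
#' @return percentage in [0, 100].
#' @export
permeation_area_percent <- function(mask, roi = NULL) {
  stopifnot(is.matrix(mask))
  if (is.null(roi)) roi <- matrix(TRUE, nrow(mask), ncol(mask))
  stopifnot(identical(dim(mask), dim(roi)))
  n_roi <- sum(roi)
  if (n_roi == 0) stop("empty ROI", call. = FALSE)
  100 * sum(mask & roi) / n_roi
}

#' Rectangle ROI helper
#'
#' @param shape image dimensions `c(nrow, ncol)`.
#' @param rows,cols inclusive 1-based index ranges of the rectangle.
#' @return logical matrix.
#' @export
rect_roi <- function(shape, rows, cols) {
  roi <- matrix(FALSE, shape[1], shape[2])
  roi[rows, cols] <- TRUE
  roi
}

#' Rasterise a polygon outline into boundary pixel coordinates
#'
#' Walks each polygon edge at sub-pixel steps and rounds to pixel
#' centres, producing the set of boundary pixels used as the distance
#' reference in [max_permeation_distance()]. Vertices are 1-based
#' `(row, col)` pixel centres; the polygon is closed automatically.
#'
#' @param vertices n x 2 matrix of `(row, col)` vertices.
#' @return m x 2 integer matrix of unique boundary pixels.
#' @export
polygon_boundary <- function(vertices) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 2, nrow(vertices) >= 2)
  v <- rbind(vertices, vertices[1, , drop = FALSE])
  pts <- do.call(rbind, lapply(seq_len(nrow(v) - 1), function(i) {
    a <- v[i, ]; b <- v[i + 1, ]
    n <- max(2, ceiling(2 * max(abs(b - a))) + 1)
    cbind(seq(a[1], b[1], length.out = n), seq(a[2], b[2], length.out = n))
  }))
  unique(round(pts))
}

#' Maximum permeation distance from a reference boundary
#'
#' For every permeated pixel, the minimum Euclidean distance to the
#' boundary pixel set (the perimeter of the electrode opening) is
#' computed with an exact Euclidean distance transform
#' ([EBImage::distmap()]); the maximum over the mask, scaled by the
#' pixel size, is returned. An empty mask gives 0.
#'
#' @param mask logical matrix of permeated pixels.
#' @param boundary n x 2 matrix of 1-based `(row, col)` boundary pixels.
#' @param pixel_size_um physical pixel size, um.
#' @return maximum distance, um.
#' @export
max_permeation_distance <- function(mask, boundary, pixel_size_um = 1) {
  stopifnot(is.matrix(mask))
  if (is.null(boundary) || nrow(boundary) == 0) {
    stop("boundary must be a non-empty set of pixel coordinates", call. = FALSE)
  }
  check_positive(pixel_size_um, "pixel_size_um")
  if (!any(mask)) return(0)
  seed <- matrix(1, nrow(mask), ncol(mask))
  seed[cbind(boundary[, 1], boundary[, 2])] <- 0
  d <- EBImage::distmap(seed, metric = "euclidean")
  max(d[mask]) * pixel_size_um
}

#' Electrical-shorting risk from permeation extent
#'
#' Permeation can grow from both neighbouring electrode sites, so the
#' conservative rule flags risk when the maximum permeation distance
#' reaches half the inter-electrode spacing.
#'
#' @param max_distance_um maximum permeation distance, um.
#' @param electrode_spacing_um centre-to-centre electrode spacing, um.
#' @return logical risk flag.
#' @export
shorting_risk <- function(max_distance_um, electrode_spacing_um = 400) {
  stopifnot(max_distance_um >= 0, electrode_spacing_um > 0)
  max_distance_um >= electrode_spacing_um / 2
}

#' Full permeation analysis of one image
#'
#' Threshold, measure percent area within the ROI, maximum distance from
#' the electrode-opening boundary, and shorting risk.
#'
#' @param image a [microscopy_image()].
#' @param boundary n x 2 matrix of boundary pixels (1-based `(row, col)`).
#' @param roi logical ROI matrix, or `NULL` for the whole image.
#' @param method,threshold,polarity passed to [binarize()].
#' @param electrode_spacing_um spacing for [shorting_risk()].
#' @return object of class `permeation_result`: `mask`, `area_percent`,
#'   `max_distance_um`, `risk`, `threshold`.
#' @export
analyze_permeation <- function(image, boundary, roi = NULL,
                               method = c("otsu", "fixed"), threshold = NULL,
                               polarity = c("bright", "dark"),
                               electrode_spacing_um = 400) {
  stopifnot(inherits(image, "microscopy_image"))
  mask <- binarize(image, match.arg(method), threshold, match.arg(polarity))
  area <- permeation_area_percent(mask, roi)
  dist <- max_permeation_distance(mask, boundary, image$pixel_size_um)
  structure(list(mask = mask, area_percent = area, max_distance_um = dist,
                 risk = shorting_risk(dist, electrode_spacing_um),
                 threshold = attr(mask, "threshold")),
            class = "permeation_result")
}

#' @export
print.permeation_result <- function(x, ...) {
  cat(sprintf("Permeation: %.2f%% of ROI, max distance %.2f um, %s\n",
              x$area_percent, x$max_distance_um,
              if (x$risk) "SHORTING RISK" else "no shorting risk"))
  invisible(x)
}
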