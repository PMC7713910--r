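# Batch images are H x W x 3 numeric arrays on [0, 255] (8-bit scale),
# row-major, 0-based pixel coordinates with origin at top-left; bounding
# boxes are half-open intervals [x0, x1) x [y0, y1) in pixels.

#' Construct a batch image
#'
#' @param pixels H x W x 3 array, channel values on \[0, 255\].
#' @param resolution pixels per mm (> 0).
#' @param view "dorsal" or "ventral".
#' @param image_id identifier used for provenance.
#' @return A `batch_image` object.
#' @export
batch_image <- function(pixels, resolution, view = c("dorsal", "ventral"),
                        image_id = "img") {
  view <- match.arg(view)
  stopifnot(is.array(pixels), length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  if (!is.numeric(resolution) || length(resolution) != 1 || resolution <= 0)
    stop("resolution (pixels per mm) must be a positive number")
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255)
    stop("channel values must lie in [0, 255]")
  structure(list(pixels = pixels, resolution = resolution, view = view,
                 image_id = image_id),
            class = "batch_image")
}

#' Read a batch image from PNG or TIFF
#'
#' 8-bit RGB input; values are rescaled to \[0, 255\]. Grayscale images are
#' replicated across channels; an alpha channel is dropped.
#'
#' @param path image file (.png, .tif, .tiff).
#' @param resolution pixels per mm.
#' @param view "dorsal" or "ventral".
#' @param image_id defaults to the file name.
#' @return A `batch_image`.
#' @export
read_batch_image <- function(path, resolution, view = c("dorsal", "ventral"),
                             image_id = basename(path)) {
  view <- match.arg(view)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the tiff package is required to read TIFF images")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext))
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3, drop = FALSE]
  batch_image(px * 255, resolution, view, image_id)
}

#' Write a batch image as PNG
#' @param image a `batch_image`.
#' @param path output .png path.
#' @export
write_batch_image <- function(image, path) {
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' Threshold a batch image to a specimen mask
#'
#' Converts a colour image of dark specimens on a light background to a
#' binary foreground mask. Two modes: `"otsu"` applies a global Otsu
#' threshold to the luminance channel with dark-object polarity; `"manual"`
#' keeps pixels whose channels all fall inside the supplied per-channel
#' bands, mirroring interactive colour thresholding.
#'
#' @param image a `batch_image`.
#' @param method "otsu" (default) or "manual".
#' @param bands for manual mode: a 2 x 3 matrix of per-channel \[low, high\]
#'   bounds on the 0-255 scale (columns R, G, B).
#' @return Logical H x W matrix, `TRUE` = specimen.
#' @export
binarize <- function(image, method = c("otsu", "manual"), bands = NULL) {
  stopifnot(inherits(image, "batch_image"))
  method <- match.arg(method)
  px <- image$pixels
  if (method == "otsu") {
    lum <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
    thr <- EBImage::otsu(EBImage::Image(t(lum) / 255), range = c(0, 1)) * 255
    mask <- lum < thr
  } else {
    if (is.null(bands) || !is.matrix(bands) || !all(dim(bands) == c(2, 3)))
      stop("manual mode needs a 2 x 3 matrix of per-channel [low, high] bands")
    mask <- px[, , 1] >= bands[1, 1] & px[, , 1] <= bands[2, 1] &
            px[, , 2] >= bands[1, 2] & px[, , 2] <= bands[2, 2] &
            px[, , 3] >= bands[1, 3] & px[, , 3] <= bands[2, 3]
  }
  frac <- mean(mask)
  if (frac == 0) stop("empty foreground: threshold selected no pixels")
  if (frac > 0.5)
    warning(sprintf(
      "threshold selects %.0f%% of pixels as foreground; polarity may be inverted",
      100 * frac))
  mask
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that
# touch diagonally are merged with a union-find pass (ImageJ Analyze
# Particles uses 8-connectivity).
.label8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask) * 1)))
  lab <- t(lab)
  n <- max(lab)
  if (n <= 1) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  H <- nrow(lab); W <- ncol(lab)
  # diagonal neighbour pairs: (r, c) vs (r+1, c+1) and (r+1, c-1)
  a1 <- lab[-H, -W]; b1 <- lab[-1, -1]
  a2 <- lab[-H, -1]; b2 <- lab[-1, -W]
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs) > 0) {
    pairs <- unique(pairs)
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    roots <- vapply(seq_len(n), find, integer(1))
    dense <- match(roots, sort(unique(roots)))
    lab[lab > 0] <- dense[lab[lab > 0]]
  }
  lab
}

#' Find specimen regions in a binary mask
#'
#' Labels 8-connected foreground components, discards components smaller
#' than `min_area_px` (debris, noise), and returns the survivors sorted
#' top-to-bottom then left-to-right by bounding-box origin.
#'
#' @param mask logical H x W matrix from [binarize()].
#' @param min_area_px minimum component size in pixels.
#' @return List of `region_mask` objects, each with `label_id`, `coords`
#'   (n x 2 matrix of 0-based (row, col) pixel coordinates), and `bbox`
#'   (half-open `c(x0, x1, y0, y1)` in pixels).
#' @export
find_regions <- function(mask, min_area_px = 50) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) return(list())
  lab <- .label8(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area_px)
  if (length(keep) == 0) return(list())
  idx <- which(lab > 0, arr.ind = TRUE)
  vals <- lab[lab > 0]
  regions <- lapply(keep, function(k) {
    pix <- idx[vals == k, , drop = FALSE]
    coords <- cbind(row = pix[, 1] - 1L, col = pix[, 2] - 1L)
    bbox <- c(x0 = min(coords[, 2]), x1 = max(coords[, 2]) + 1L,
              y0 = min(coords[, 1]), y1 = max(coords[, 1]) + 1L)
    structure(list(label_id = k, coords = coords, bbox = bbox,
                   n_pixels = nrow(coords)),
              class = "region_mask")
  })
  ord <- order(vapply(regions, function(r) r$bbox["y0"], numeric(1)),
               vapply(regions, function(r) r$bbox["x0"], numeric(1)))
  regions <- regions[ord]
  for (i in seq_along(regions)) regions[[i]]$label_id <- i
  regions
}

#' Export a labeled region map for audit
#'
#' Writes a PNG in which each region's pixels carry a distinct gray level
#' (label / n_regions), background black.
#'
#' @param regions list of `region_mask` objects.
#' @param dim image dimensions `c(H, W)`.
#' @param path output .png path.
#' @export
write_region_map <- function(regions, dim, path) {
  lab <- matrix(0, dim[1], dim[2])
  n <- length(regions)
  for (r in regions) lab[r$coords + 1L] <- r$label_id / max(n, 1)
  png::writePNG(lab, path)
  invisible(path)
}
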