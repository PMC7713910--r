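# The canonical 68-feature manifest: 34 descriptors per view (13 size/shape
# + 21 colour), dorsal first, then ventral.

SHAPE_FEATURES <- c("area", "perimeter", "width", "height", "feret",
                    "min_feret", "major", "minor", "angle", "circularity",
                    "aspect_ratio", "roundness", "solidity")
COLOR_FEATURES <- as.vector(outer(
  c("mean", "sd", "integrated_density", "skewness", "kurtosis", "min", "max"),
  c("R", "G", "B"), paste, sep = "_"))

#' The canonical feature manifest
#'
#' Returns the ordered names of the 68 per-specimen features: 13 size/shape
#' and 21 colour descriptors for each of the dorsal and ventral views.
#'
#' @param views view prefixes, in order.
#' @return Character vector of 68 feature names.
#' @export
feature_manifest <- function(views = c("dorsal", "ventral")) {
  unlist(lapply(views, function(v)
    paste0(v, "_", c(SHAPE_FEATURES, COLOR_FEATURES))))
}

.centroids <- function(regions) {
  t(vapply(regions, function(r)
    c(x = mean(r$coords[, 2]) + 0.5, y = mean(r$coords[, 1]) + 0.5),
    numeric(2)))
}

#' Pair dorsal and ventral regions into specimen feature vectors
#'
#' Specimens are flipped left-right between the dorsal and ventral
#' photographs of a trapping event, so ventral centroids are mirrored
#' horizontally and both region lists are put in reading order
#' (top-to-bottom, then left-to-right); the order-preserving assignment
#' then pairs them one-to-one. Region counts must match: unmatched regions
#' are reported in the error, never silently dropped.
#'
#' @param dorsal_regions list of `region_mask` from the dorsal image.
#' @param ventral_regions list of `region_mask` from the ventral image.
#' @param dorsal_image,ventral_image the source `batch_image`s.
#' @param event_id identifier prefixed to specimen ids.
#' @return data.frame with `specimen_id`, 68 feature columns in manifest
#'   order, and provenance columns (image ids, region label ids).
#' @export
pair_views <- function(dorsal_regions, ventral_regions,
                       dorsal_image, ventral_image, event_id = "event") {
  nd <- length(dorsal_regions); nv <- length(ventral_regions)
  if (nd != nv) {
    extra <- if (nd > nv) {
      sprintf("unmatched dorsal region(s): %s",
              paste(vapply(dorsal_regions[(nv + 1):nd],
                           function(r) r$label_id, numeric(1)), collapse = ", "))
    } else {
      sprintf("unmatched ventral region(s): %s",
              paste(vapply(ventral_regions[(nd + 1):nv],
                           function(r) r$label_id, numeric(1)), collapse = ", "))
    }
    stop(sprintf("cannot pair views: %d dorsal vs %d ventral regions; %s",
                 nd, nv, extra))
  }
  if (nd == 0) stop("no regions to pair")

  W <- dim(ventral_image$pixels)[2]
  cd <- .centroids(dorsal_regions)
  cv <- .centroids(ventral_regions)
  cv[, "x"] <- W - cv[, "x"]  # mirror the ventral layout horizontally

  # reading order with a row-band tolerance of half the median region height
  band <- stats::median(vapply(dorsal_regions, function(r)
    r$bbox[["y1"]] - r$bbox[["y0"]], numeric(1))) / 2
  reading_order <- function(cc) order(round(cc[, "y"] / max(band, 1)), cc[, "x"])
  od <- reading_order(cd)
  ov <- reading_order(cv)

  rows <- lapply(seq_len(nd), function(i) {
    rd <- dorsal_regions[[od[i]]]
    rv <- ventral_regions[[ov[i]]]
    md <- measure_region(rd, dorsal_image)
    mv <- measure_region(rv, ventral_image)
    feats <- c(stats::setNames(md, paste0("dorsal_", names(md))),
               stats::setNames(mv, paste0("ventral_", names(mv))))
    stopifnot(identical(names(feats), feature_manifest()))
    data.frame(specimen_id = sprintf("%s_%02d", event_id, i),
               as.list(feats),
               dorsal_image = dorsal_image$image_id,
               ventral_image = ventral_image$image_id,
               dorsal_label = rd$label_id,
               ventral_label = rv$label_id,
               pair_distance_px = sqrt(sum((cd[od[i], ] - cv[ov[i], ])^2)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Extract specimen feature vectors from a dorsal/ventral image pair
#'
#' Runs the full imaging pipeline on one trapping event: threshold both
#' views, find regions, measure shape and colour, and pair dorsal with
#' ventral regions into 68-feature specimen vectors.
#'
#' @param dorsal_image,ventral_image `batch_image`s of the same event.
#' @param min_area_px minimum region size in pixels (debris filter).
#' @param method thresholding method passed to [binarize()].
#' @param bands manual threshold bands passed to [binarize()].
#' @param event_id identifier for the trapping event.
#' @return data.frame of specimen feature vectors (see [pair_views()]).
#' @export
extract_event_features <- function(dorsal_image, ventral_image,
                                   min_area_px = 50, method = "otsu",
                                   bands = NULL, event_id = "event") {
  md <- binarize(dorsal_image, method = method, bands = bands)
  mv <- binarize(ventral_image, method = method, bands = bands)
  rd <- find_regions(md, min_area_px = min_area_px)
  rv <- find_regions(mv, min_area_px = min_area_px)
  pair_views(rd, rv, dorsal_image, ventral_image, event_id = event_id)
}
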