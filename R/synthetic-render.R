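# Renders synthetic batch photographs: elliptical specimen blobs on a
# near-white textured background, laid out on a grid, with exact analytic
# ground truth (area, axes, mean colour) so the imaging pipeline can be
# validated end to end. The ventral image mirrors the dorsal layout
# horizontally, as when a tray of specimens is flipped over.

#' Sample specimen render specs
#'
#' Draws per-specimen ellipse geometry and dorsal/ventral colours for
#' [render_batch_image()]. Sizes are in pixels; dark, slightly elongate
#' bodies on the 8-bit colour scale.
#'
#' @param n number of specimens.
#' @param seed integer seed.
#' @param a_range semi-major axis range in px.
#' @param aspect_range ratio of semi-major to semi-minor axis.
#' @return data.frame of render specs, one row per specimen.
#' @export
sample_specimen_specs <- function(n, seed = 1, a_range = c(18, 32),
                                  aspect_range = c(1.6, 3)) {
  set.seed(seed)
  a <- stats::runif(n, a_range[1], a_range[2])
  b <- a / stats::runif(n, aspect_range[1], aspect_range[2])
  base <- stats::runif(n, 20, 90)
  data.frame(
    a_px = a, b_px = b,
    angle = stats::runif(n, 0, 180),
    R_d = base + stats::runif(n, 0, 30),
    G_d = base * stats::runif(n, 0.5, 0.9),
    B_d = base * stats::runif(n, 0.3, 0.7),
    R_v = base + stats::runif(n, 20, 50),
    G_v = base * stats::runif(n, 0.6, 1.0),
    B_v = base * stats::runif(n, 0.4, 0.8))
}

.draw_ellipses <- function(H, W, centers, specs, colors, background,
                           noise_sd) {
  px <- array(0, c(H, W, 3))
  for (ch in 1:3)
    px[, , ch] <- background[ch] + stats::rnorm(H * W, 0, noise_sd)
  xx <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
  yy <- matrix(rep(seq_len(H) - 0.5, W), H, W)
  for (i in seq_len(nrow(specs))) {
    th <- specs$angle[i] * pi / 180
    dx <- xx - centers[i, 1]; dy <- yy - centers[i, 2]
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    inside <- (u / specs$a_px[i])^2 + (v / specs$b_px[i])^2 <= 1
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[inside] <- colors[i, ch] + stats::rnorm(sum(inside), 0, noise_sd)
      px[, , ch] <- plane
    }
  }
  array(pmin(pmax(px, 0), 255), c(H, W, 3))
}

#' Render a dorsal/ventral synthetic batch image pair
#'
#' Lays the specimens out on a grid, renders both views, and returns the
#' exact analytic ground truth per specimen. The ventral view mirrors the
#' layout horizontally and uses the ventral colours.
#'
#' @param specs data.frame from [sample_specimen_specs()].
#' @param resolution pixels per mm for the returned `batch_image`s.
#' @param spacing_px clearance between grid cells in px.
#' @param cell_px grid cell size in px; defaults to the largest specimen
#'   extent plus `spacing_px`. A cell too small for a specimen is an
#'   overlap error.
#' @param background background RGB (near-white).
#' @param noise_sd pixel noise sd (8-bit units).
#' @param seed seed for the pixel noise.
#' @param event_id identifier for the trapping event.
#' @return List with `dorsal`, `ventral` (`batch_image`s) and `truth`
#'   (data.frame: grid order, analytic area/axes in mm, base colours).
#' @export
render_batch_image <- function(specs, resolution = 12, spacing_px = 14,
                               cell_px = NULL,
                               background = c(246, 244, 241), noise_sd = 2,
                               seed = 1, event_id = "event") {
  n <- nrow(specs)
  stopifnot(n >= 1)
  set.seed(seed + 7L)
  cell <- if (is.null(cell_px)) ceiling(2 * max(specs$a_px) + spacing_px)
          else as.integer(cell_px)
  if (any(2 * specs$a_px > cell))
    stop("specimen overlap: ellipse larger than its grid cell")
  ncol_g <- ceiling(sqrt(n))
  nrow_g <- ceiling(n / ncol_g)
  W <- ncol_g * cell + spacing_px
  H <- nrow_g * cell + spacing_px
  gi <- seq_len(n) - 1L
  cx <- (gi %% ncol_g) * cell + cell / 2 + spacing_px / 2
  cy <- (gi %/% ncol_g) * cell + cell / 2 + spacing_px / 2
  centers_d <- cbind(cx, cy)
  centers_v <- cbind(W - cx, cy)

  pxd <- .draw_ellipses(H, W, centers_d, specs,
                        as.matrix(specs[, c("R_d", "G_d", "B_d")]),
                        background, noise_sd)
  pxv <- .draw_ellipses(H, W, centers_v, specs,
                        as.matrix(specs[, c("R_v", "G_v", "B_v")]),
                        background, noise_sd)
  truth <- data.frame(
    index = seq_len(n),
    cx_px = cx, cy_px = cy,
    area_mm2 = pi * specs$a_px * specs$b_px / resolution^2,
    major_mm = 2 * specs$a_px / resolution,
    minor_mm = 2 * specs$b_px / resolution,
    angle = specs$angle,
    specs[, c("R_d", "G_d", "B_d", "R_v", "G_v", "B_v")])
  list(
    dorsal = batch_image(pxd, resolution, "dorsal",
                         paste0(event_id, "_dorsal")),
    ventral = batch_image(pxv, resolution, "ventral",
                          paste0(event_id, "_ventral")),
    truth = truth)
}
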