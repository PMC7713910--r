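# Shared fixtures, all built in code.

# rasterize shapes into logical masks
raster_disk <- function(H, W, cx, cy, r) {
  xx <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
  yy <- matrix(rep(seq_len(H) - 0.5, W), H, W)
  (xx - cx)^2 + (yy - cy)^2 <= r^2
}

raster_ellipse <- function(H, W, cx, cy, a, b, theta_deg = 0) {
  xx <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
  yy <- matrix(rep(seq_len(H) - 0.5, W), H, W)
  th <- theta_deg * pi / 180
  u <- (xx - cx) * cos(th) + (yy - cy) * sin(th)
  v <- -(xx - cx) * sin(th) + (yy - cy) * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

raster_rect <- function(H, W, x0, x1, y0, y1) {
  m <- matrix(FALSE, H, W)
  m[y0:y1, x0:x1] <- TRUE
  m
}

# uniform-colour batch image from a mask
image_from_mask <- function(mask, fg = c(60, 40, 30), bg = c(245, 245, 245),
                            resolution = 12, view = "dorsal", id = "img") {
  px <- array(0, c(dim(mask), 3))
  for (ch in 1:3) px[, , ch] <- ifelse(mask, fg[ch], bg[ch])
  batch_image(px, resolution, view, id)
}

# taxonomy of the study's worked examples
examples_taxonomy <- function() {
  load_taxonomy(system.file("extdata", "carabid_examples_taxonomy.csv",
                            package = "pitfallID"))
}

# a prediction matrix with given probabilities and uniform class frequency
pm <- function(probs, classes, freq = NULL) {
  colnames(probs) <- classes
  if (is.null(freq)) freq <- rep(1 / length(classes), length(classes))
  structure(probs, class_freq = stats::setNames(freq, classes),
            class = c("prediction_matrix", "matrix", "array"))
}

# small 2-class gaussian problem, well separated
separable_toy <- function(n = 60, sep = 6, seed = 42, p = 2) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * p), n, p),
             matrix(rnorm(n * p, sep), n, p))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = rep(c("A", "B"), each = n))
}
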