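test_that("binarize separates dark specimens and flags degenerate cases", {
  mask <- raster_disk(80, 120, 30, 40, 12) | raster_disk(80, 120, 70, 40, 12) |
    raster_disk(80, 120, 100, 30, 10)
  img <- image_from_mask(mask)
  out <- binarize(img)
  expect_equal(length(find_regions(out, 20)), 3)

  white <- image_from_mask(matrix(FALSE, 20, 20))
  expect_error(binarize(white, method = "manual",
                        bands = matrix(c(0, 10, 0, 10, 0, 10), 2, 3)),
               "empty foreground")
  # full-range bands select everything: polarity warning
  expect_warning(binarize(img, method = "manual",
                          bands = matrix(c(0, 255), 2, 3)),
                 "polarity")
})

test_that("find_regions is 8-connected, size-filtered, and ordered", {
  # 3 blobs of ~500 px and 2 specks
  m <- raster_rect(120, 200, 10, 32, 10, 32) |
    raster_rect(120, 200, 60, 82, 10, 32) |
    raster_rect(120, 200, 10, 32, 60, 82)
  m[100, 100] <- TRUE
  m[110, 150:151] <- TRUE
  regs <- find_regions(m, min_area_px = 50)
  expect_length(regs, 3)
  # reading order: two top blobs left to right, then the lower one
  origins <- t(vapply(regs, function(r) r$bbox[c("x0", "y0")], numeric(2)))
  expect_equal(origins[, 2], c(9, 9, 59))
  expect_equal(origins[1:2, 1], c(9, 59))

  # diagonal touch merges under 8-connectivity
  d <- matrix(FALSE, 8, 8); d[2, 2] <- TRUE; d[3, 3] <- TRUE
  expect_length(find_regions(d, 1), 1)

  expect_length(find_regions(matrix(FALSE, 5, 5), 1), 0)
})

test_that("shape descriptors match analytic values for known shapes", {
  res <- 12
  disk <- raster_disk(140, 150, 75, 70, 50)
  s <- measure_shape(find_regions(disk, 50)[[1]], res)
  expect_equal(s[["area"]], pi * (50 / res)^2, tolerance = 0.02)
  expect_equal(s[["circularity"]], 1, tolerance = 0.05)
  expect_equal(s[["feret"]], 100 / res, tolerance = 0.02)
  expect_equal(s[["aspect_ratio"]], 1, tolerance = 0.03)

  rect <- raster_rect(100, 120, 20, 69, 30, 59)
  sr <- measure_shape(find_regions(rect, 10)[[1]], res)
  expect_equal(sr[["solidity"]], 1, tolerance = 1e-6)
  expect_equal(sr[["width"]], 50 / res)
  expect_equal(sr[["height"]], 30 / res)
  expect_equal(sr[["min_feret"]], 30 / res, tolerance = 0.01)

  ell <- raster_ellipse(160, 180, 90, 80, 60, 20)
  se <- measure_shape(find_regions(ell, 50)[[1]], res)
  expect_equal(se[["aspect_ratio"]], 3, tolerance = 0.05)
  expect_equal(se[["feret"]], se[["major"]], tolerance = 0.02)
  expect_equal(se[["roundness"]], 1 / 3, tolerance = 0.05)

  # degenerate geometry
  line <- matrix(FALSE, 10, 10); line[5, 2:8] <- TRUE
  reg <- find_regions(line, 1)[[1]]
  expect_error(measure_shape(reg, res), "degenerate")
})

test_that("shape invariants: scale equivariance and rotation robustness", {
  base <- raster_ellipse(150, 150, 75, 75, 45, 25)
  big <- raster_ellipse(300, 300, 150, 150, 90, 50)
  s1 <- measure_shape(find_regions(base, 50)[[1]], 12)
  s2 <- measure_shape(find_regions(big, 50)[[1]], 24)
  for (f in c("area", "perimeter", "feret", "major", "minor"))
    expect_equal(s2[[f]], s1[[f]], tolerance = 0.03)

  rot <- raster_ellipse(150, 150, 75, 75, 45, 25, theta_deg = 30)
  s3 <- measure_shape(find_regions(rot, 50)[[1]], 12)
  for (f in c("area", "feret", "circularity", "solidity"))
    expect_equal(s3[[f]], s1[[f]], tolerance = 0.05)
  expect_equal(s3[["angle"]], 180 - 30, tolerance = 0.05 * 180)
})

test_that("colour moments equal brute-force pixel computations", {
  # uniform region
  mask <- raster_disk(40, 40, 20, 20, 10)
  img <- image_from_mask(mask, fg = c(120, 80, 40))
  reg <- find_regions(mask, 10)[[1]]
  cs <- measure_color(reg, img)
  expect_equal(cs[["mean_R"]], 120)
  expect_equal(cs[["sd_G"]], 0)
  expect_equal(cs[["skewness_B"]], 0)
  expect_equal(cs[["kurtosis_R"]], 0)
  expect_equal(cs[["min_B"]], cs[["max_B"]])
  expect_equal(cs[["integrated_density_R"]], reg$n_pixels * 120)

  # two-pixel closed form: mean 127.5, population sd 127.5
  m2 <- matrix(FALSE, 4, 4); m2[2, 2:3] <- TRUE
  px <- array(200, c(4, 4, 3)); px[2, 2, 1] <- 0; px[2, 3, 1] <- 255
  img2 <- batch_image(px, 1)
  reg2 <- find_regions(m2, 1)[[1]]
  cs2 <- measure_color(reg2, img2)
  expect_equal(cs2[["mean_R"]], 127.5)
  expect_equal(cs2[["sd_R"]], 127.5)

  # random pixels vs a brute-force loop oracle
  set.seed(9)
  mask3 <- raster_ellipse(50, 60, 30, 25, 18, 9, 20)
  px3 <- array(sample(0:255, 50 * 60 * 3, TRUE), c(50, 60, 3))
  img3 <- batch_image(px3, 1)
  reg3 <- find_regions(mask3, 10)[[1]]
  cs3 <- measure_color(reg3, img3)
  for (ch in 1:3) {
    v <- apply(reg3$coords, 1, function(rc) px3[rc[1] + 1, rc[2] + 1, ch])
    nm <- c("R", "G", "B")[ch]
    m <- mean(v); m2c <- mean((v - m)^2)
    expect_equal(cs3[[paste0("mean_", nm)]], m)
    expect_equal(cs3[[paste0("sd_", nm)]], sqrt(m2c))
    expect_equal(cs3[[paste0("skewness_", nm)]], mean((v - m)^3) / m2c^1.5)
    expect_equal(cs3[[paste0("kurtosis_", nm)]], mean((v - m)^4) / m2c^2 - 3)
    expect_equal(cs3[[paste0("min_", nm)]], min(v))
    expect_equal(cs3[[paste0("max_", nm)]], max(v))
  }
})

test_that("pair_views matches mirrored layouts and reports mismatches", {
  specs <- sample_specimen_specs(6, seed = 4)
  batch <- render_batch_image(specs, seed = 4)
  fv <- extract_event_features(batch$dorsal, batch$ventral, min_area_px = 60)
  expect_equal(nrow(fv), 6)
  expect_equal(ncol(fv[, feature_manifest()]), 68)
  expect_false(anyNA(fv))
  # the order-preserving mirrored pairing recovers the grid ground truth:
  # dorsal means match the dorsal base colours, ventral the ventral ones
  expect_equal(fv$dorsal_mean_R, batch$truth$R_d, tolerance = 0.05)
  expect_equal(fv$ventral_mean_R, batch$truth$R_v, tolerance = 0.05)
  expect_equal(fv$dorsal_area, batch$truth$area_mm2, tolerance = 0.03)

  # single region per image pairs trivially
  one_d <- image_from_mask(raster_disk(60, 60, 30, 30, 12))
  one_v <- image_from_mask(raster_disk(60, 60, 25, 30, 12),
                           view = "ventral")
  rd <- find_regions(binarize(one_d), 20)
  rv <- find_regions(binarize(one_v), 20)
  expect_equal(nrow(pair_views(rd, rv, one_d, one_v)), 1)

  # 3 dorsal vs 2 ventral is an error naming the unmatched region
  m3 <- raster_disk(60, 140, 25, 30, 10) | raster_disk(60, 140, 65, 30, 10) |
    raster_disk(60, 140, 105, 30, 10)
  m2v <- raster_disk(60, 140, 25, 30, 10) | raster_disk(60, 140, 65, 30, 10)
  i3 <- image_from_mask(m3)
  i2 <- image_from_mask(m2v, view = "ventral")
  expect_error(pair_views(find_regions(binarize(i3), 20),
                          find_regions(binarize(i2), 20), i3, i2),
               "unmatched dorsal")
})
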