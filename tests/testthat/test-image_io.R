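test_that("read_channel max-projects multi-page stacks and preserves intensities", {
  td <- withr::local_tempdir()
  p1 <- file.path(td, "stack.tif")
  pages <- list(matrix(0, 6, 5), matrix(0, 6, 5), matrix(0, 6, 5))
  pages[[2]][3, 4] <- 7
  tiff::writeTIFF(lapply(pages, function(m) m / 255), p1, bits.per.sample = 8L)
  img <- read_channel(p1, pixel_size_um = 0.5)
  expect_equal(dim(img$pixels), c(6, 5))
  expect_equal(img$pixels[3, 4], 7)
  expect_equal(sum(img$pixels), 7)

  p2 <- file.path(td, "single.tif")
  m <- matrix(sample(0:255, 30, replace = TRUE), 6, 5)
  tiff::writeTIFF(m / 255, p2, bits.per.sample = 8L)
  expect_equal(read_channel(p2, 1)$pixels, m)

  p3 <- file.path(td, "consts.tif")
  tiff::writeTIFF(list(matrix(1 / 255, 4, 4), matrix(2 / 255, 4, 4), matrix(3 / 255, 4, 4)),
                  p3, bits.per.sample = 8L)
  expect_true(all(read_channel(p3, 1)$pixels == 3))
})

test_that("read_channel and calibrated_image reject invalid inputs distinctly", {
  expect_error(read_channel("no/such/file.tif", 1), "cannot read")
  td <- withr::local_tempdir()
  p <- file.path(td, "ok.tif")
  tiff::writeTIFF(matrix(0.5, 4, 4), p)
  expect_error(read_channel(p, -1), "positive")
  expect_error(read_channel(file.path(td, "x.bmp"), 1), "cannot read|format")
  expect_error(calibrated_image(matrix(numeric(0), 0, 0), 1), "non-empty")
  expect_error(calibrated_image(matrix(-1, 2, 2), 1), "non-negative")
  expect_error(calibrated_image(matrix(1, 2, 2), 0), "positive")
})

test_that("max projection is idempotent", {
  td <- withr::local_tempdir()
  p <- file.path(td, "s.tif")
  set.seed(11)
  pages <- replicate(4, matrix(sample(0:255, 64, TRUE), 8, 8) / 255, simplify = FALSE)
  tiff::writeTIFF(pages, p, bits.per.sample = 8L)
  once <- read_channel(p, 1)$pixels
  p2 <- file.path(td, "s2.tif")
  tiff::writeTIFF(once / 255, p2, bits.per.sample = 8L)
  expect_equal(read_channel(p2, 1)$pixels, once)
})

test_that("channel_set enforces matching geometry across channels", {
  a <- calibrated_image(matrix(1, 5, 5), 1, role = "glia_marker")
  b <- calibrated_image(matrix(1, 5, 5), 1, role = "nucleus")
  expect_s3_class(channel_set(a, b), "channel_set")
  bad_dim <- calibrated_image(matrix(1, 4, 5), 1, role = "nucleus")
  expect_error(channel_set(a, bad_dim), "dimensions")
  bad_ps <- calibrated_image(matrix(1, 5, 5), 2, role = "nucleus")
  expect_error(channel_set(a, bad_ps), "pixel size")
})

test_that("rasterize_roi uses pixel-centre semantics", {
  # square covering pixel centres (2,2)-(5,5) in 0-based coordinates
  roi <- roi_polygon(rbind(c(3, 3), c(3, 6), c(6, 6), c(6, 3)))
  mask <- rasterize_roi(roi, c(10, 10))
  expect_equal(sum(mask), 16)
  expect_true(all(mask[3:6, 3:6]))

  whole <- roi_polygon(rbind(c(0, 0), c(0, 11), c(11, 11), c(11, 0)))
  expect_true(all(rasterize_roi(whole, c(10, 10))))

  expect_error(roi_polygon(rbind(c(1, 1), c(2, 2), c(3, 3))), "zero area")
  expect_error(roi_polygon(rbind(c(1, 1), c(5, 5))), "at least 3")
  expect_error(roi_polygon(rbind(c(0, 0), c(4, 4), c(4, 0), c(0, 5))), "self-intersecting")
})

test_that("rasterized area of convex polygons converges to the polygon area", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(5:9, 1)
    ang <- sort(stats::runif(n, 0, 2 * pi))
    rad <- stats::runif(1, 12, 20)
    ctr <- c(30, 30)
    v <- cbind(ctr[1] + rad * sin(ang), ctr[2] + rad * cos(ang))
    roi <- roi_polygon(v)
    mask <- rasterize_roi(roi, c(60, 60))
    r <- v[, 1]; c <- v[, 2]
    area <- abs(sum(r * c[c(2:n, 1)] - r[c(2:n, 1)] * c)) / 2
    perim <- sum(sqrt(rowSums((v - v[c(2:n, 1), ])^2)))
    expect_lt(abs(sum(mask) - area), perim + 1)
  }
})

test_that("ROI JSON round-trips through the 0-based interchange format", {
  td <- withr::local_tempdir()
  rois <- list(roi_polygon(rbind(c(3, 3), c(3, 8), c(9, 8), c(9, 3))))
  p <- file.path(td, "roi.json")
  write_roi_json(rois, p)
  back <- read_roi_json(p)
  expect_equal(back[[1]]$vertices, rois[[1]]$vertices)
})

test_that("write_results emits the four sections and round-trips exactly", {
  td <- withr::local_tempdir()
  res <- analyze_channels(small_noisy_scene()$channels, list(thresholds = c(0.1, 0.75)))
  singles <- res$records[!res$records$is_cluster, ]
  clusters <- res$records[res$records$is_cluster, ]
  files <- write_results(singles, clusters, res$histograms, td)
  expect_true(all(file.exists(files)))
  comb <- utils::read.csv(files["combined"])
  expect_equal(nrow(comb), nrow(singles) + nrow(clusters))
  # round trip: numeric columns to full written precision
  sc <- utils::read.csv(files["single_cells"])
  expect_equal(sc$object_id, singles$object_id)
  expect_equal(sc$n_endpoints, singles$n_endpoints)
  expect_equal(sc$morphology_ratio, signif(singles$morphology_ratio, 15))
  hist_df <- utils::read.csv(files["histograms"])
  expect_setequal(unique(hist_df$stratum), c("single_cells", "clusters", "all"))

  # writers are deterministic: identical inputs give byte-identical files
  td2 <- withr::local_tempdir()
  files2 <- write_results(singles, clusters, res$histograms, td2)
  for (k in names(files))
    expect_identical(readBin(files[k], "raw", file.size(files[k])),
                     readBin(files2[k], "raw", file.size(files2[k])))

  # empty analysis still produces all four sections with headers
  td3 <- withr::local_tempdir()
  empty <- res$records[0, ]
  f3 <- write_results(empty, empty, NULL, td3)
  expect_true(all(file.exists(f3)))
  expect_equal(nrow(utils::read.csv(f3["combined"])), 0)
})

test_that("write_overlay colour-codes activation classes", {
  td <- withr::local_tempdir()
  scene <- closure_scene()
  res <- closure_result()
  classes <- rep(c("activated", "intermediate", "non_activated"),
                 length.out = length(res$components))
  p <- file.path(td, "ov.png")
  write_overlay(scene$channels, res$components, classes, p)
  rgb <- png::readPNG(p)
  pure_red <- rgb[, , 1] == 1 & rgb[, , 2] == 0 & rgb[, , 3] == 0
  pure_green <- rgb[, , 2] == 1 & rgb[, , 1] == 0 & rgb[, , 3] == 0
  pure_blue <- rgb[, , 3] == 1 & rgb[, , 1] == 0 & rgb[, , 2] == 0
  expect_gt(sum(pure_red), 0)
  expect_gt(sum(pure_green), 0)
  expect_gt(sum(pure_blue), 0)

  # zero components: overlay is the grayscale source in all three channels
  p0 <- file.path(td, "ov0.png")
  write_overlay(scene$channels, list(), character(0), p0)
  rgb0 <- png::readPNG(p0)
  expect_equal(rgb0[, , 1], rgb0[, , 2])
  expect_equal(rgb0[, , 2], rgb0[, , 3])

  expect_error(write_overlay(scene$channels, res$components, classes[-1], p),
               "same length")
})

test_that("downscale_preview performs mean-based resampling", {
  img <- calibrated_image(matrix(5, 100, 100), 2)
  prev <- downscale_preview(img, 0.1)
  expect_equal(dim(prev$pixels), c(10, 10))
  expect_true(all(prev$pixels == 5))
  expect_equal(prev$pixel_size_um, 20)

  # 4x4 checkerboard of 0/2 at factor 0.5: every 2x2 block means to 1
  cb <- calibrated_image(outer(1:4, 1:4, function(i, j) ((i + j) %% 2) * 2), 1)
  expect_true(all(downscale_preview(cb, 0.5)$pixels == 1))

  expect_error(downscale_preview(img, 0), "factor")
  expect_error(downscale_preview(img, 1), "factor")
})
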