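test_that("process_length counts weighted skeleton links", {
  line <- matrix(FALSE, 5, 15); line[3, 3:13] <- TRUE     # 11 px
  expect_equal(unname(process_length(line, 1)), 10)
  expect_equal(unname(process_length(line, 0.5)), 5)
  expect_equal(unname(process_length(matrix(FALSE, 5, 5), 1)), 0)

  # L-shaped path: 5 orthogonal then 5 diagonal links
  lpath <- matrix(FALSE, 12, 12)
  for (i in 0:5) lpath[3, 2 + i] <- TRUE
  for (i in 1:5) lpath[3 + i, 7 + i] <- TRUE
  expect_equal(unname(process_length(lpath, 1)), 5 + 5 * sqrt(2))
})

test_that("endpoint and branch point counts follow the 8-neighbour rules", {
  line <- matrix(FALSE, 7, 9); line[4, 3:7] <- TRUE
  expect_equal(count_endpoints(line), 2)
  expect_equal(count_branchpoints(line), 0)

  plus <- matrix(FALSE, 11, 11)
  plus[6, 4:8] <- TRUE; plus[4:8, 6] <- TRUE
  expect_equal(count_endpoints(plus), 4)
  expect_equal(count_branchpoints(plus), 1)

  single <- matrix(FALSE, 3, 3); single[2, 2] <- TRUE
  expect_equal(count_endpoints(single), 1)
  expect_equal(count_branchpoints(matrix(FALSE, 4, 4)), 0)
})

test_that("percent_fill is the object-to-bounding-box ratio", {
  rect <- matrix(FALSE, 20, 20); rect[4:13, 6:15] <- TRUE
  expect_equal(unname(percent_fill(rect)), 1)

  n <- 12
  diagm <- matrix(FALSE, 20, 20); for (i in 1:n) diagm[3 + i, 3 + i] <- TRUE
  expect_equal(unname(percent_fill(diagm)), 1 / n)

  disk <- disc_mask(121, 121, 61, 61, 50)
  expect_lt(abs(unname(percent_fill(disk)) - pi / 4), 0.02)

  expect_error(percent_fill(matrix(FALSE, 3, 3)), "empty")
})

test_that("span_ratio matches the moment-equivalent ellipse", {
  disk <- disc_mask(61, 61, 31, 31, 20)
  expect_lt(abs(span_ratio(disk) - 1), 0.02)

  rect <- matrix(FALSE, 50, 20); rect[5:44, 5:14] <- TRUE
  expect_lt(abs(span_ratio(rect) - 4), 0.05)

  sq <- matrix(FALSE, 20, 20); sq[4:15, 4:15] <- TRUE
  expect_lt(abs(span_ratio(sq) - 1), 0.02)

  expect_error(span_ratio(matrix(c(TRUE, rep(FALSE, 8)), 3, 3)), "at least 2")

  line <- matrix(FALSE, 3, 12); line[2, 2:11] <- TRUE
  capped <- span_ratio(line)
  expect_equal(as.numeric(capped), 100)
  expect_true(attr(capped, "degenerate"))
})

test_that("perimeter is a weighted contour length, linear in pixel size", {
  sq <- matrix(FALSE, 14, 14); sq[3:12, 3:12] <- TRUE
  p <- unname(perimeter(sq, 1))
  expect_lt(abs(p - 36), 4)

  row10 <- matrix(FALSE, 5, 14); row10[3, 3:12] <- TRUE
  expect_equal(unname(perimeter(row10, 1)), oracle_perimeter(row10, 1))

  expect_equal(unname(perimeter(sq, 2)), 2 * p)
  expect_error(perimeter(matrix(FALSE, 3, 3), 1), "empty")
})

test_that("marker_sum_intensity sums raw values inside the mask", {
  mask <- matrix(FALSE, 10, 10); mask[2:4, 2:4] <- TRUE; mask[9, 9] <- TRUE
  marker <- calibrated_image(matrix(3, 10, 10), 1, role = "activation_marker")
  expect_equal(marker_sum_intensity(mask, marker), 30)
  expect_equal(marker_sum_intensity(matrix(FALSE, 10, 10), marker), 0)

  set.seed(3)
  g16 <- matrix(sample(0:65535, 100, TRUE), 10, 10)
  m <- matrix(stats::runif(100) < 0.4, 10, 10)
  mk <- calibrated_image(g16, 1, role = "activation_marker")
  expect_equal(marker_sum_intensity(m, mk), oracle_marker_sum(m, g16))

  small <- calibrated_image(matrix(1, 5, 5), 1, role = "activation_marker")
  expect_error(marker_sum_intensity(mask, small), "dimensions")
})

test_that("measure assembles the eleven parameters coherently", {
  ps <- 0.5
  # amoeboid: soma = mask, no processes
  disk <- disc_mask(40, 40, 20, 20, 10)
  amoe <- make_component(disk, disk)
  rec <- measure(amoe, pixel_size_um = ps)
  expect_equal(rec$process_length_um, 0)
  expect_equal(rec$morphology_ratio, 0)
  expect_equal(rec$n_endpoints, 0)
  expect_equal(rec$cell_area_um2, sum(disk) * ps^2)
  expect_true(is.na(rec$cd68_sum_intensity))
  expect_false(rec$degenerate)

  # degenerate: zero soma
  deg <- make_component(disk, matrix(FALSE, 40, 40))
  rec2 <- measure(deg, pixel_size_um = ps)
  expect_true(rec2$degenerate)
  expect_true(is.na(rec2$morphology_ratio))

  # ratio arithmetic on real records
  res <- closure_result()
  ok <- !res$records$degenerate
  expect_equal(res$records$morphology_ratio[ok] * res$records$soma_area_um2[ok],
               res$records$process_length_um[ok])
})

test_that("morphometry matches brute-force oracles on random masks", {
  set.seed(99)
  for (rep in 1:60) {
    m <- random_mask(sample(15:40, 1), sample(15:40, 1), n_blobs = sample(1:3, 1),
                     salt = 0.01)
    if (!any(m)) next
    expect_equal(count_endpoints(m), oracle_endpoints(m))
    expect_equal(count_branchpoints(m), oracle_branchpoints(m))
    expect_equal(unname(process_length(m, 1)), oracle_process_length(m, 1))
    marker <- matrix(sample(0:255, length(m), TRUE), nrow(m))
    expect_equal(marker_sum_intensity(m, calibrated_image(marker, 1, role = "activation_marker")),
                 oracle_marker_sum(m, marker))
    comp <- largest_component(m)
    if (sum(comp) >= 2) {
      expect_equal(unname(percent_fill(comp)), oracle_percent_fill(comp))
      o_span <- oracle_span_ratio(comp)
      if (is.finite(o_span)) expect_equal(as.numeric(span_ratio(comp)), o_span, tolerance = 1e-8)
      expect_equal(unname(perimeter(comp, 1)), oracle_perimeter(comp, 1), tolerance = 1e-8)
    }
  }
})

test_that("a rigid 90-degree rotation leaves the parameters unchanged", {
  res <- closure_result()
  comp <- res$components[[which.max(vapply(res$components, function(x) sum(x$mask), numeric(1)))]]
  rot <- function(m) t(m)[, nrow(m):1, drop = FALSE]
  comp_r <- make_component(rot(comp$mask), rot(comp$soma_mask))
  a <- measure(comp, pixel_size_um = 0.334)
  b <- measure(comp_r, pixel_size_um = 0.334)
  expect_equal(b$cell_area_um2, a$cell_area_um2)
  expect_equal(b$soma_area_um2, a$soma_area_um2)
  expect_equal(b$n_endpoints, a$n_endpoints)
  expect_equal(b$n_branchpoints, a$n_branchpoints)
  expect_equal(b$percent_fill, a$percent_fill)
  expect_lt(abs(b$perimeter_um - a$perimeter_um) / a$perimeter_um, 0.02)
  expect_lt(abs(b$span_ratio - a$span_ratio) / a$span_ratio, 0.02)
  expect_lt(abs(b$process_length_um - a$process_length_um) /
            max(a$process_length_um, 1), 0.02)
})
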