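fake_components <- function(n) {
  lapply(seq_len(n), function(i) {
    m <- matrix(FALSE, 30, 30); m[10:20, 10:20] <- TRUE
    structure(list(id = i, bbox = c(r0 = 10L, r1 = 20L, c0 = 10L, c1 = 20L),
                   mask = m[10:20, 10:20], soma_mask = m[10:20, 10:20],
                   skeleton = NULL, nucleus_count = 1L, is_cluster = FALSE,
                   nucleus_centroids = matrix(c(15, 15), 1, 2)),
              class = "glia_component")
  })
}

test_that("sample_cells is seeded, uniform and exhausts gracefully", {
  comps <- fake_components(10)
  s1 <- sample_cells(comps, 50, seed = 3)
  expect_equal(sort(s1$ids), 1:10)          # n > available: everything returned

  s2 <- sample_cells(comps, 5, seed = 3)
  s3 <- sample_cells(comps, 5, seed = 3)
  expect_identical(s2$ids, s3$ids)          # determinism
  expect_equal(anyDuplicated(s2$ids), 0)

  expect_error(sample_cells(comps, 0, seed = 1), ">= 1")
  expect_warning(s0 <- sample_cells(list(), 5, seed = 1), "no detected")
  expect_length(s0$ids, 0)
})

test_that("sampling is uniform over cells", {
  comps <- fake_components(10)
  hits <- integer(10)
  for (k in 1:2000) {
    s <- sample_cells(comps, 5, seed = k)
    hits[s$ids] <- hits[s$ids] + 1L
  }
  freq <- hits / 2000
  se <- sqrt(0.5 * 0.5 / 2000)
  expect_true(all(abs(freq - 0.5) < 3 * se + 0.02))
})

test_that("export_crops writes one colour-coded crop per sampled cell", {
  td <- withr::local_tempdir()
  scene <- closure_scene()
  res <- closure_result()
  classes <- rep("activated", length(res$components))
  sample <- sample_cells(res$components, 5, seed = 11, classes = classes)
  paths <- export_crops(sample, scene$channels, res$components, td)
  expect_length(paths, 5)
  expect_true(all(file.exists(paths)))
  # tinted pixels in an activated crop are red only
  rgb <- png::readPNG(paths[1])
  tinted <- rgb[, , 1] != rgb[, , 2] | rgb[, , 2] != rgb[, , 3]
  expect_gt(sum(tinted), 0)
  expect_true(all(rgb[, , 1][tinted] == 1 & rgb[, , 2][tinted] == 0 &
                  rgb[, , 3][tinted] == 0))
})

test_that("crops at the image border are clipped, not errors", {
  px <- matrix(10, 40, 40); px[1:8, 1:8] <- 200
  ch <- channel_set(calibrated_image(px, 1, role = "glia_marker"))
  comp <- structure(list(id = 1L, bbox = c(r0 = 1L, r1 = 8L, c0 = 1L, c1 = 8L),
                         mask = matrix(TRUE, 8, 8), soma_mask = matrix(TRUE, 8, 8),
                         skeleton = NULL, nucleus_count = 1L, is_cluster = FALSE,
                         nucleus_centroids = matrix(c(4, 4), 1, 2)),
                    class = "glia_component")
  s <- sample_cells(list(comp), 1, seed = 1, classes = "intermediate", pad_px = 10)
  td <- withr::local_tempdir()
  paths <- export_crops(s, ch, list(comp), td)
  expect_true(file.exists(paths[1]))
  expect_equal(dim(png::readPNG(paths[1]))[1:2], c(18, 18))  # clipped at border
})

test_that("score_agreement rounds replicate scores half-up and tallies mismatches", {
  # (2, 3, 3) averages 2.67 and rounds to 3
  man <- data.frame(cell_id = 1, rep1 = 2, rep2 = 3, rep3 = 3)
  rec <- data.frame(object_id = 1, morphology_ratio = 0.5,
                    activation_class = "intermediate")
  rep_round <- score_agreement(man, rec)
  expect_equal(rep_round$n_score_mismatch, 0)   # score 3 maps to intermediate

  # a perfect 20-cell set: zero mismatches, strongly negative rho (replicate
  # scores are tied within levels, so |rho| < 1 even at perfect agreement)
  set.seed(4)
  ratio <- sort(stats::runif(20, 0.01, 2), decreasing = TRUE)
  score <- rep(1:4, each = 5)                    # high score = low ratio
  cls <- c("4" = "activated", "3" = "intermediate", "2" = "intermediate",
           "1" = "non_activated")[as.character(score)]
  man2 <- data.frame(cell_id = 1:20, rep1 = score, rep2 = score, rep3 = score)
  rec2 <- data.frame(object_id = 1:20, morphology_ratio = ratio,
                     activation_class = unname(cls))
  rep2 <- score_agreement(man2, rec2)
  expect_equal(rep2$n_evaluated, 20)
  expect_equal(rep2$n_true_positive, 20)
  expect_equal(rep2$n_score_mismatch, 0)
  expect_lt(rep2$spearman_rho, -0.9)

  # four untied cells give exactly rho = -1 under a strictly monotone mapping
  man_u <- data.frame(cell_id = 1:4, rep1 = 1:4, rep2 = 1:4, rep3 = 1:4)
  rec_u <- data.frame(object_id = 1:4, morphology_ratio = c(2, 1.2, 0.5, 0.05),
                      activation_class = c("non_activated", "intermediate",
                                           "intermediate", "activated"))
  expect_equal(score_agreement(man_u, rec_u)$spearman_rho, -1)

  # plant exactly two class mismatches (against the classes the scores map to)
  rec3 <- rec2
  rec3$activation_class[c(2, 17)] <- c("activated", "non_activated")
  expect_equal(score_agreement(man2, rec3)$n_score_mismatch, 2)

  # a manual score of 0 marks a false-positive detection
  man4 <- man2; man4$rep1[5] <- 0; man4$rep2[5] <- 0; man4$rep3[5] <- 0
  rep4 <- score_agreement(man4, rec2)
  expect_equal(rep4$n_false_positive, 1)
  expect_equal(rep4$n_true_positive, 19)
  expect_equal(rep4$n_true_positive + rep4$n_false_positive, rep4$n_evaluated)

  # manual rows without a detection are missed detections; extra automated
  # records are excluded with a warning
  man5 <- rbind(man2, data.frame(cell_id = 99, rep1 = 1, rep2 = 1, rep3 = 1))
  expect_equal(score_agreement(man5, rec2)$n_false_negative_detection, 1)
  expect_warning(score_agreement(man2[1:10, ], rec2), "without manual scores")
})

test_that("score_agreement is invariant under cell id relabelling", {
  set.seed(9)
  score <- sample(1:4, 15, TRUE)
  ratio <- stats::runif(15, 0.01, 2)
  cls <- sample(c("activated", "intermediate", "non_activated"), 15, TRUE)
  man <- data.frame(cell_id = 1:15, rep1 = score, rep2 = score, rep3 = score)
  rec <- data.frame(object_id = 1:15, morphology_ratio = ratio, activation_class = cls)
  perm <- sample(1000:2000, 15)
  man2 <- man; man2$cell_id <- perm
  rec2 <- rec; rec2$object_id <- perm
  a <- score_agreement(man, rec)
  b <- score_agreement(man2, rec2)
  expect_equal(a$n_score_mismatch, b$n_score_mismatch)
  expect_equal(a$spearman_rho, b$spearman_rho)
})
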