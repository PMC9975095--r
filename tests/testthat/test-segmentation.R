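test_that("chromogen inversion turns dark stain into high signal and is an involution", {
  px <- matrix(255, 20, 20)
  px[8:12, 8:12] <- 0
  img <- calibrated_image(px, 1, modality = "chromogen", role = "transmitted")
  inv <- chromogen_to_signal(img)
  expect_equal(inv$pixels[10, 10], 255)
  expect_equal(inv$pixels[1, 1], 0)
  back <- chromogen_to_signal(inv)
  expect_equal(unname(back$pixels), px, ignore_attr = TRUE)

  set.seed(5)
  rnd <- matrix(sample(0:255, 400, TRUE), 20, 20)
  out <- chromogen_to_signal(calibrated_image(rnd, 1, "chromogen", "transmitted"),
                             white_level = 255)
  expect_equal(unname(out$pixels), 255 - rnd, ignore_attr = TRUE)

  fl <- calibrated_image(px, 1, modality = "fluorescence")
  expect_error(chromogen_to_signal(fl), "fluorescence")
})

test_that("hysteresis binarisation keeps only strong-seeded structures", {
  img <- matrix(0, 40, 60)
  img[10:20, 5:15] <- 200        # strong blob
  img[14:16, 16:35] <- 80        # weak corridor attached to it
  img[28:34, 40:50] <- 80        # isolated weak-only blob
  ci <- calibrated_image(img, 1)
  mask <- binarize_glia(ci, weak = 60, strong = 150, closing_radius_um = 0,
                        use_edges = FALSE)
  expect_true(all(mask[10:20, 5:15]))
  expect_true(all(mask[14:16, 16:35]))
  expect_false(any(mask[28:34, 40:50]))

  expect_error(binarize_glia(ci, weak = 100, strong = 50), "out of order")
  blank <- calibrated_image(matrix(0, 10, 10), 1)
  expect_equal(sum(binarize_glia(blank)), 0)
})

test_that("strong = weak reduces to single-threshold binarisation", {
  set.seed(7)
  img <- matrix(sample(0:255, 1600, TRUE), 40, 40)
  ci <- calibrated_image(img, 1)
  a <- binarize_glia(ci, weak = 90, strong = 90, closing_radius_um = 1, use_edges = FALSE)
  # single-threshold reference: threshold then close, keep all components
  ref_raw <- img >= 90
  ref <- gliamorph:::mask_close(ref_raw, 1)
  # every closed component touching a >=90 pixel is kept, which is all of them
  expect_equal(a, ref)
})

test_that("hysteresis sandwich holds on random scenes", {
  set.seed(31)
  for (rep in 1:25) {
    img <- matrix(0, 50, 50)
    for (b in 1:4) {
      r0 <- sample(5:45, 1); c0 <- sample(5:45, 1)
      lvl <- sample(c(60, 120, 220), 1)
      rad <- stats::runif(1, 2, 6)
      for (r in max(1, r0 - 8):min(50, r0 + 8)) for (c in max(1, c0 - 8):min(50, c0 + 8))
        if ((r - r0)^2 + (c - c0)^2 <= rad^2) img[r, c] <- pmax(img[r, c], lvl)
    }
    ci <- calibrated_image(img, 1)
    weak <- 50; strong <- 180
    out <- binarize_glia(ci, weak = weak, strong = strong,
                         closing_radius_um = 1, use_edges = FALSE)
    closed_weak <- gliamorph:::mask_close(img >= weak, 1)
    expect_true(all(closed_weak[out]))                      # out within closed weak mask
    lbl <- gliamorph:::label_components(out)
    if (max(lbl) > 0) {
      for (k in seq_len(max(lbl)))                          # every component has a seed
        expect_true(any(img[lbl == k] >= strong))
    }
  }
})

test_that("clean_mask fills small holes and removes small structures", {
  m <- matrix(FALSE, 30, 30)
  m[5:24, 5:24] <- TRUE
  m[10, 10] <- FALSE; m[10, 11] <- FALSE          # 2-px hole
  m[28, 28] <- TRUE; m[28, 29] <- TRUE            # 2-px speck
  out <- clean_mask(m, min_area_um2 = 5, max_hole_um2 = 10, pixel_size_um = 1)
  expect_true(out[10, 10] && out[10, 11])
  expect_false(out[28, 28] || out[28, 29])
  expect_error(clean_mask(m, -1, 10, 1), "non-negative")
})

test_that("clean_mask equals the remove-then-fill oracle on random fields", {
  set.seed(13)
  for (rep in 1:10) {
    m <- random_mask(40, 40, n_blobs = 4, salt = 0.05)
    out <- clean_mask(m, min_area_um2 = 6, max_hole_um2 = 4, pixel_size_um = 1)
    ref <- gliamorph:::fill_small_holes(
      gliamorph:::remove_small_components(m, 6), 4)
    expect_equal(out, ref)
    # never increases the component count
    expect_lte(gliamorph:::.n_components(out), gliamorph:::.n_components(m))
  }
})

test_that("separate_bridges deletes single-pixel articulations between large parts", {
  m <- matrix(FALSE, 20, 20)
  m[3:7, 3:7] <- TRUE
  m[9:13, 9:13] <- TRUE
  m[8, 8] <- TRUE                                  # diagonal one-pixel bridge
  expect_equal(gliamorph:::.n_components(m), 1)
  out <- separate_bridges(m, min_part_area_um2 = 10, pixel_size_um = 1)
  expect_false(out[8, 8])
  expect_equal(gliamorph:::.n_components(out), 2)

  disk <- disc_mask(21, 21, 11, 11, 7)
  expect_equal(separate_bridges(disk, 10, 1), disk)

  # a short line is untouched: any cut leaves a part below the minimum
  line <- matrix(FALSE, 5, 20); line[3, 3:17] <- TRUE
  expect_equal(separate_bridges(line, 10, 1), line)
})

test_that("separate_bridges leaves no qualifying articulation and is idempotent", {
  set.seed(17)
  for (rep in 1:5) {
    m <- random_mask(30, 30, n_blobs = 4, salt = 0)
    out <- separate_bridges(m, 10, 1)
    expect_equal(separate_bridges(out, 10, 1), out)
    # exhaustive check: removing any remaining pixel never splits its
    # component into >= 2 parts of >= 10 px each
    idx <- which(out, arr.ind = TRUE)
    before <- gliamorph:::.n_components(out)
    for (i in seq_len(nrow(idx))) {
      tmp <- out
      tmp[idx[i, 1], idx[i, 2]] <- FALSE
      after <- gliamorph:::.n_components(tmp)
      if (after > before) {
        # the parts around the removed pixel cannot all be >= 10 px
        lbl <- gliamorph:::label_components(tmp)
        sizes <- tabulate(lbl)
        nb <- integer(0)
        for (dr in -1:1) for (dc in -1:1) {
          rr <- idx[i, 1] + dr; cc <- idx[i, 2] + dc
          if (rr >= 1 && cc >= 1 && rr <= nrow(lbl) && cc <= ncol(lbl) &&
              lbl[rr, cc] > 0L) nb <- c(nb, lbl[rr, cc])
        }
        expect_lt(min(sizes[unique(nb)]), 10)
      }
    }
  }
})

test_that("extract_somata keeps only the thick cell parts", {
  ps <- 0.334
  line <- matrix(FALSE, 30, 60); line[15, 5:55] <- TRUE
  expect_equal(sum(extract_somata(line, pixel_size_um = ps)), 0)

  disk <- disc_mask(60, 90, 30, 30, 10)
  withproc <- disk; withproc[30, 41:85] <- TRUE
  soma <- extract_somata(withproc, pixel_size_um = ps)
  opened <- gliamorph:::mask_open(withproc, 2.5 / ps)
  expect_lt(abs(sum(soma) - sum(opened)) / sum(opened), 0.2)
  expect_false(any(soma[, 60:90]))                  # the process is gone
  expect_true(all(withproc[soma]))                  # soma within the mask

  empty <- matrix(FALSE, 10, 10)
  expect_equal(sum(extract_somata(empty, pixel_size_um = ps)), 0)
})

test_that("soma of any structure thinner than the opening element is empty", {
  ps <- 1
  for (w in 1:2) {
    bar <- matrix(FALSE, 20, 40)
    bar[10:(9 + w), 5:35] <- TRUE
    soma <- extract_somata(bar, thinning_iters = 3, opening_radius_um = 3,
                           dilation_radius_um = 1, pixel_size_um = ps)
    expect_equal(sum(soma), 0)
  }
})

test_that("detect_nuclei finds, fills and splits nuclei", {
  ps <- 1
  img <- matrix(0, 50, 50)
  for (r in 1:50) for (c in 1:50)
    img[r, c] <- 200 * exp(-((r - 25)^2 + (c - 30)^2) / 18)
  nm <- detect_nuclei(calibrated_image(img, ps, role = "nucleus"))
  expect_equal(nrow(nm$centroids), 1)
  expect_lt(max(abs(nm$centroids[1, ] - c(25, 30))), 1.01)

  # two equal discs overlapping by ~20% of a radius split into 2
  two <- matrix(0, 50, 70)
  two[disc_mask(50, 70, 25, 25, 9)] <- 200
  two[disc_mask(50, 70, 25, 41, 9)] <- 200
  nm2 <- detect_nuclei(calibrated_image(two, ps, role = "nucleus"))
  expect_equal(nrow(nm2$centroids), 2)

  blank <- detect_nuclei(calibrated_image(matrix(0, 20, 20), ps, role = "nucleus"))
  expect_equal(nrow(blank$centroids), 0)
})

test_that("nucleus centroids lie inside their own labelled region", {
  scene <- small_noisy_scene()
  nm <- detect_nuclei(scene$channels$nucleus)
  for (i in seq_len(nrow(nm$centroids))) {
    r <- round(nm$centroids[i, 1]); c <- round(nm$centroids[i, 2])
    expect_equal(nm$labels[r, c], i)
  }
})

test_that("assign_components sorts by nucleus overlap and discards orphans", {
  glia <- matrix(FALSE, 40, 80)
  glia[disc_mask(40, 80, 20, 12, 8)] <- TRUE          # single cell
  glia[disc_mask(40, 80, 20, 40, 10)] <- TRUE         # cluster of 3
  glia[10:12, 60:75] <- TRUE                          # orphan process fragment
  soma <- glia
  labels <- matrix(0L, 40, 80)
  cents <- rbind(c(20, 12), c(17, 37), c(20, 43), c(24, 40))
  for (i in seq_len(nrow(cents))) labels[cents[i, 1], cents[i, 2]] <- i
  nuclei <- structure(list(labels = labels, centroids = cents), class = "nucleus_map")
  comps <- assign_components(glia, soma, nuclei, mode = "fluorescence")
  expect_length(comps, 2)
  counts <- sort(vapply(comps, `[[`, integer(1), "nucleus_count"))
  expect_equal(counts, c(1L, 3L))
  expect_equal(vapply(comps, `[[`, logical(1), "is_cluster"), counts >= 2)

  expect_error(assign_components(glia, soma, NULL, mode = "fluorescence"),
               "nucleus")
})

test_that("segmentation is fully deterministic", {
  scene <- small_noisy_scene()
  a <- measure_scene(scene$channels, list())
  b <- measure_scene(scene$channels, list())
  expect_identical(a$masks$glia, b$masks$glia)
  expect_identical(a$records, b$records)
})
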