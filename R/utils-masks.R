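# Internal binary-mask utilities. Masks are plain logical matrices (rows x cols,
# 1-based indices); connectivity is 8-neighbour for foreground throughout, and
# 4-neighbour for background (hole semantics).

#' @importFrom EBImage bwlabel imageData makeBrush erode dilate opening closing
#'   fillHull distmap watershed otsu filter2 gblur Image ocontour
NULL

.as_mask <- function(x) {
  if (is.logical(x)) {
    m <- x
  } else {
    m <- x > 0
  }
  storage.mode(m) <- "logical"
  m
}

# Shift a matrix so that out[i, j] = m[i + dr, j + dc]; out-of-range -> fill.
.shift_mat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs - dr, cs - dc] <- m[rs, cs]
  out
}

# Number of 8-neighbours that are foreground, for every pixel.
.neighbour_count <- function(mask) {
  n <- matrix(0L, nrow(mask), ncol(mask))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    n <- n + .shift_mat(mask, dr, dc)
  }
  n
}

# 8-connected labelling. EBImage::bwlabel is 4-connected, so labels that touch
# diagonally are merged with a union-find pass.
label_components <- function(mask) {
  mask <- .as_mask(mask)
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lbl <- EBImage::imageData(EBImage::bwlabel(mask * 1))
  storage.mode(lbl) <- "integer"
  k <- max(lbl)
  if (k > 1L) {
    pairs <- NULL
    for (off in list(c(1L, 1L), c(1L, -1L))) {
      nb <- .shift_mat(lbl, off[1], off[2], fill = 0L)
      sel <- lbl > 0L & nb > 0L & lbl != nb
      if (any(sel)) pairs <- rbind(pairs, unique(cbind(lbl[sel], nb[sel])))
    }
    if (!is.null(pairs)) {
      parent <- seq_len(k)
      find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
      for (r in seq_len(nrow(pairs))) {
        a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      root <- vapply(seq_len(k), find, integer(1))
      remap <- match(root, sort(unique(root)))
      lbl[lbl > 0L] <- remap[lbl[lbl > 0L]]
    }
  }
  lbl
}

.n_components <- function(mask) max(label_components(mask))

# Disc structuring element of the given radius in pixels (radius < 0.5 px is a
# no-op element).
.disc_brush <- function(radius_px) {
  size <- 2L * as.integer(round(radius_px)) + 1L
  if (size < 3L) return(NULL)
  EBImage::makeBrush(size, shape = "disc")
}

.morph <- function(mask, radius_px, op) {
  mask <- .as_mask(mask)
  br <- .disc_brush(radius_px)
  if (is.null(br)) return(mask)
  out <- EBImage::imageData(op(mask * 1, br))
  out > 0.5
}

mask_erode  <- function(mask, radius_px) .morph(mask, radius_px, EBImage::erode)
mask_dilate <- function(mask, radius_px) .morph(mask, radius_px, EBImage::dilate)
mask_open   <- function(mask, radius_px) .morph(mask, radius_px, EBImage::opening)
mask_close  <- function(mask, radius_px) .morph(mask, radius_px, EBImage::closing)

# Dilate by one pixel in all 8 directions (3x3 square element).
mask_dilate3x3 <- function(mask) {
  out <- .as_mask(mask)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out | .shift_mat(mask, dr, dc)
  }
  out
}

# Fill background holes (4-connected background components not touching the
# border) whose pixel area is <= max_hole_px.
fill_small_holes <- function(mask, max_hole_px) {
  mask <- .as_mask(mask)
  bg <- !mask
  if (!any(bg)) return(mask)
  lbl <- EBImage::imageData(EBImage::bwlabel(bg * 1))  # 4-connected: correct for holes
  storage.mode(lbl) <- "integer"
  border <- unique(c(lbl[1, ], lbl[nrow(lbl), ], lbl[, 1], lbl[, ncol(lbl)]))
  border <- border[border > 0L]
  if (max(lbl) == 0L) return(mask)
  areas <- tabulate(lbl, nbins = max(lbl))
  fill <- setdiff(which(areas <= max_hole_px), border)
  if (length(fill)) mask[lbl %in% fill] <- TRUE
  mask
}

# Remove 8-connected components with pixel area < min_area_px.
remove_small_components <- function(mask, min_area_px) {
  mask <- .as_mask(mask)
  lbl <- label_components(mask)
  if (max(lbl) == 0L) return(mask)
  areas <- tabulate(lbl, nbins = max(lbl))
  drop <- which(areas < min_area_px)
  if (length(drop)) mask[lbl %in% drop] <- FALSE
  mask
}

# Otsu threshold on raw intensity values (EBImage::otsu works on [0, 1]).
otsu_threshold <- function(pixels, levels = 256L) {
  m <- max(pixels)
  if (!is.finite(m) || m <= 0) return(0)
  EBImage::otsu(EBImage::Image(pixels / m), range = c(0, 1), levels = levels) * m
}

# Per-label centroids of an integer label matrix; returns a k x 2 matrix of
# (row, col). Centroids are snapped to the nearest labelled pixel when the
# arithmetic mean falls outside the region (non-convex shapes).
.label_centroids <- function(lbl) {
  k <- max(lbl)
  if (k == 0L) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  idx <- which(lbl > 0L)
  rr <- (idx - 1L) %% nrow(lbl) + 1L
  cc <- (idx - 1L) %/% nrow(lbl) + 1L
  g <- lbl[idx]
  cen <- cbind(row = tapply(rr, g, mean), col = tapply(cc, g, mean))
  for (i in seq_len(k)) {
    r0 <- as.integer(round(cen[i, 1])); c0 <- as.integer(round(cen[i, 2]))
    if (r0 < 1 || c0 < 1 || r0 > nrow(lbl) || c0 > ncol(lbl) || lbl[r0, c0] != i) {
      sel <- g == i
      d2 <- (rr[sel] - cen[i, 1])^2 + (cc[sel] - cen[i, 2])^2
      j <- which.min(d2)
      cen[i, ] <- c(rr[sel][j], cc[sel][j])
    }
  }
  dimnames(cen) <- list(NULL, c("row", "col"))
  cen
}

# Bounding box (r0, r1, c0, c1) of TRUE pixels.
.mask_bbox <- function(mask) {
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  c(r0 = rr[1], r1 = rr[2], c0 = cc[1], c1 = cc[2])
}

# Evaluate .Random.seed-preserving code under a fixed seed.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
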