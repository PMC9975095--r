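# Segmentation: from a channel set to nucleus-assigned glia components.
#
# The binarisation is a hysteresis (strong/weak) double threshold combined
# with Sobel edge detection and morphological closing: weak-threshold and
# edge pixels form candidate structures, but only 8-connected structures that
# contain at least one strong-threshold pixel are accepted as glia. Threshold
# selection is automatic (Otsu for the weak level; the strong level is placed
# a configurable fraction of the way from the weak level to the image
# maximum), with absolute overrides for batch-calibrated pipelines.

#' Convert a chromogen (DAB) image to a signal image
#'
#' Chromogenic detection produces dark stain on a bright transmitted-light
#' background -- the opposite polarity to fluorescence. This inverts the
#' intensities (`white_level - value`) so that stain becomes high-valued and
#' every downstream threshold works identically in both modalities. The white
#' level used is remembered on the result, so applying the inversion twice is
#' an exact involution.
#'
#' @param image a [calibrated_image] with `modality = "chromogen"`. A
#'   fluorescence image is rejected rather than silently inverted, because the
#'   corruption would only surface later as nonsense thresholds.
#' @param white_level background (paper-white) intensity; default is the
#'   remembered level from a previous inversion, or the image maximum.
#' @return a [calibrated_image] with stain high-valued (modality tag kept).
#' @export
chromogen_to_signal <- function(image, white_level = NULL) {
  stopifnot(inherits(image, "calibrated_image"))
  if (image$modality != "chromogen")
    stop("chromogen_to_signal() expects a chromogen image; got fluorescence")
  if (is.null(white_level)) {
    white_level <- attr(image$pixels, "chromogen_white_level")
    if (is.null(white_level)) white_level <- max(image$pixels)
  }
  inv <- pmax(white_level - image$pixels, 0)
  attr(inv, "chromogen_white_level") <- white_level
  out <- calibrated_image(inv, image$pixel_size_um, modality = "chromogen", role = image$role)
  attr(out$pixels, "chromogen_white_level") <- white_level
  out
}

.sobel_magnitude <- function(px) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- EBImage::imageData(EBImage::filter2(EBImage::Image(px), kx))
  gy <- EBImage::imageData(EBImage::filter2(EBImage::Image(px), t(kx)))
  sqrt(gx^2 + gy^2)
}

#' Binarise the glia-marker channel by hysteresis thresholding
#'
#' Candidate pixels are the union of the weak-threshold mask and a Sobel edge
#' mask (edges recover faint thin processes that fall below the intensity
#' threshold). The union is morphologically closed, then only 8-connected
#' components containing at least one strong-threshold pixel are retained.
#'
#' @param image a [calibrated_image] (glia-marker signal; invert chromogen
#'   images with [chromogen_to_signal()] first).
#' @param weak,strong absolute intensity thresholds; by default `weak` is the
#'   Otsu threshold of the channel and `strong = weak + strong_scale *
#'   (max - weak)`. `strong >= weak` is required.
#' @param strong_scale fraction in `[0, 1]` placing the strong threshold
#'   between the weak level and the image maximum (default 0.5).
#' @param closing_radius_um radius of the disc used for morphological closing,
#'   in micrometres (default 0.5: closing repairs sub-resolution staining
#'   gaps along thin processes; a much larger radius starts fusing distinct
#'   parallel processes a micrometre or two apart).
#' @param use_edges union Sobel edges (thresholded at their own Otsu level)
#'   into the weak mask before closing.
#' @return logical mask of valid glia structures.
#' @export
binarize_glia <- function(image, weak = NULL, strong = NULL, strong_scale = 0.5,
                          closing_radius_um = 0.5, use_edges = TRUE) {
  stopifnot(inherits(image, "calibrated_image"))
  px <- image$pixels
  if (max(px) <= 0) return(matrix(FALSE, nrow(px), ncol(px)))
  if (is.null(weak)) weak <- otsu_threshold(px)
  if (is.null(strong)) {
    if (!is.numeric(strong_scale) || strong_scale < 0 || strong_scale > 1)
      stop("`strong_scale` must be in [0, 1]")
    strong <- weak + strong_scale * (max(px) - weak)
  }
  if (strong < weak) stop("thresholds out of order: strong < weak")
  cand <- px >= weak
  if (use_edges) {
    g <- .sobel_magnitude(px)
    if (max(g) > 0) {
      et <- otsu_threshold(g)
      # edge pixels are admitted only above an intensity floor (half the weak
      # threshold): the gradient is strong on both sides of a boundary, and
      # without the floor every object would gain a one-pixel background halo
      if (et > 0) cand <- cand | (g >= et & px >= weak / 2)
    }
  }
  closed <- mask_close(cand, closing_radius_um / image$pixel_size_um)
  strong_mask <- px >= strong
  if (!any(strong_mask)) return(matrix(FALSE, nrow(px), ncol(px)))
  lbl <- label_components(closed)
  keep <- unique(lbl[strong_mask & lbl > 0L])
  out <- matrix(FALSE, nrow(px), ncol(px))
  if (length(keep)) out[lbl %in% keep] <- TRUE
  out
}

#' Correct a raw binary mask
#'
#' Deletes structures smaller than `min_area_um2`, then fills morphological
#' gaps (background holes) no larger than `max_hole_um2`. Areas are given in
#' square micrometres and converted to pixel counts via the pixel size.
#'
#' @param mask logical matrix.
#' @param min_area_um2 minimum structure area; smaller 8-connected components
#'   are removed (default 10 um^2).
#' @param max_hole_um2 maximum hole area to fill (default 10 um^2).
#' @param pixel_size_um pixel size in micrometres.
#' @return cleaned logical mask.
#' @export
clean_mask <- function(mask, min_area_um2 = 10, max_hole_um2 = 10, pixel_size_um) {
  if (min_area_um2 < 0 || max_hole_um2 < 0) stop("area parameters must be non-negative")
  stopifnot(pixel_size_um > 0)
  a <- pixel_size_um^2
  m <- remove_small_components(mask, min_area_um2 / a)
  fill_small_holes(m, max_hole_um2 / a)
}

# Local 8-neighbour groups of a pixel (used to seed part discovery).
.neighbour_groups <- function(mask, r, c) {
  nbs <- .skel_neighbours(mask, r, c)
  if (is.null(nbs) || nrow(nbs) < 2) return(list())
  groups <- list()
  assigned <- rep(0L, nrow(nbs))
  for (i in seq_len(nrow(nbs))) {
    if (assigned[i] > 0L) next
    g <- length(groups) + 1L
    queue <- i; assigned[i] <- g
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      for (j in seq_len(nrow(nbs))) {
        if (assigned[j] == 0L &&
            max(abs(nbs[a, ] - nbs[j, ])) <= 1L) {
          assigned[j] <- g; queue <- c(queue, j)
        }
      }
    }
    groups[[g]] <- nbs[assigned == g, , drop = FALSE]
  }
  groups
}

# Bounded BFS from `seed` pixels within mask, with pixel (vr, vc) removed.
# Stops once `cap` pixels have been visited; returns list(size, capped, hit)
# where hit marks which other seed groups were absorbed.
.bounded_part <- function(mask, vr, vc, seed, other_seeds, cap) {
  nr <- nrow(mask); nc <- ncol(mask)
  key <- function(m) (m[, 2] - 1L) * nr + m[, 1]
  visited <- new.env(hash = TRUE, size = 2L * cap)
  queue <- seed
  for (k in key(seed)) assign(as.character(k), TRUE, envir = visited)
  count <- nrow(seed)
  hit <- rep(FALSE, length(other_seeds))
  other_keys <- lapply(other_seeds, key)
  while (nrow(queue) > 0 && count < cap) {
    cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- cur[1] + dr; cc <- cur[2] + dc
      if (rr < 1 || cc < 1 || rr > nr || cc > nc) next
      if (rr == vr && cc == vc) next
      if (!mask[rr, cc]) next
      k <- (cc - 1L) * nr + rr
      ks <- as.character(k)
      if (exists(ks, envir = visited, inherits = FALSE)) next
      assign(ks, TRUE, envir = visited)
      for (g in seq_along(other_keys)) if (k %in% other_keys[[g]]) hit[g] <- TRUE
      queue <- rbind(queue, c(rr, cc))
      count <- count + 1L
      if (count >= cap) break
    }
  }
  list(size = count, capped = count >= cap, hit = hit)
}

# Exact articulation pixels of the mask's 8-connected pixel graph, via igraph.
.articulation_pixels <- function(mask) {
  idx <- which(mask)
  if (length(idx) < 3) return(matrix(integer(0), 0, 2))
  nr <- nrow(mask)
  map <- integer(length(mask))
  map[idx] <- seq_along(idx)
  edges <- NULL
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    nb <- .shift_mat(mask, off[1], off[2])
    sel <- which(mask & nb)
    if (!length(sel)) next
    nb_idx <- sel + off[1] + off[2] * nr
    edges <- c(edges, rbind(map[sel], map[nb_idx]))
  }
  if (is.null(edges)) return(matrix(integer(0), 0, 2))
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  ap <- as.integer(igraph::articulation_points(g))
  if (!length(ap)) return(matrix(integer(0), 0, 2))
  pix <- idx[ap]
  cbind((pix - 1L) %% nr + 1L, (pix - 1L) %/% nr + 1L)
}

#' Separate objects connected by a single pixel
#'
#' Deletes every set pixel whose removal splits its 8-connected component into
#' two or more parts, each at least `min_part_area_um2` in area, and repeats
#' until no such single-pixel articulation remains. The area guard keeps thin
#' cell processes intact: cutting a one-pixel-wide process would create a part
#' below the minimum, so process pixels are never removed.
#'
#' @param mask cleaned logical mask.
#' @param min_part_area_um2 minimum area of each resulting part (default
#'   10 um^2, the small-structure minimum).
#' @param pixel_size_um pixel size in micrometres.
#' @return logical mask with single-pixel bridges removed.
#' @export
separate_bridges <- function(mask, min_part_area_um2 = 10, pixel_size_um) {
  stopifnot(pixel_size_um > 0)
  mask <- .as_mask(mask)
  min_px <- max(1L, as.integer(ceiling(min_part_area_um2 / pixel_size_um^2)))
  repeat {
    cand <- .articulation_pixels(mask)
    if (nrow(cand) == 0) break
    del <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      r <- cand[i, 1]; c <- cand[i, 2]
      groups <- .neighbour_groups(mask, r, c)
      if (length(groups) < 2) next
      sizes <- numeric(0)
      remaining <- seq_along(groups)
      while (length(remaining)) {
        gi <- remaining[1]
        others <- setdiff(remaining, gi)
        res <- .bounded_part(mask, r, c, groups[[gi]], groups[others], cap = min_px)
        absorbed <- others[res$hit]
        remaining <- setdiff(remaining, c(gi, absorbed))
        sizes <- c(sizes, if (res$capped) Inf else res$size)
      }
      if (length(sizes) >= 2 && all(sizes >= min_px)) del[i] <- TRUE
    }
    if (!any(del)) break
    mask[cand[del, , drop = FALSE]] <- FALSE
  }
  mask
}

#' Extract cell somata from a glia mask
#'
#' Partial morphological thinning (which peels `thinning_iters` pixels off the
#' boundary) followed by opening removes everything thinner than the opening
#' element -- the cell processes -- leaving only the thick central parts, the
#' somata. The survivors are then dilated back toward the original soma
#' extent; the dilation radius is chosen to compensate the thinning erosion
#' (iterations x pixel size), and the result is intersected with the input
#' mask so the soma can never grow beyond the cell.
#'
#' @param mask glia mask from the clean/separate stages.
#' @param thinning_iters partial thinning depth in iterations (default 3; full
#'   thinning would erase the somata).
#' @param opening_radius_um disc radius of the opening (default 1.7 um); must
#'   stay below the smallest expected soma radius minus the thinning depth
#'   (erosion), yet above the half-width of the thickest cell process.
#' @param dilation_radius_um disc radius of the final dilation (default
#'   1.5 um: slightly more than the thinning erosion `thinning_iters *
#'   pixel_size`, so the recovered soma reaches back to the cell boundary;
#'   the intersection with the mask stops it from overshooting, and a larger
#'   value prevents one-pixel mask rims around the soma from surviving into
#'   the process region, where they would skeletonise into spurious rings).
#' @param pixel_size_um pixel size in micrometres.
#' @return logical soma mask (subset of `mask`).
#' @export
extract_somata <- function(mask, thinning_iters = 3, opening_radius_um = 1.7,
                           dilation_radius_um = 1.5, pixel_size_um) {
  stopifnot(pixel_size_um > 0)
  mask <- .as_mask(mask)
  if (!any(mask)) return(mask)
  t <- thin_mask(mask, max_iters = thinning_iters)
  o <- mask_open(t, opening_radius_um / pixel_size_um)
  d <- mask_dilate(o, dilation_radius_um / pixel_size_um)
  d & mask
}

#' Detect nuclei and build the nucleus position matrix
#'
#' Otsu threshold, hole filling, small-object removal, then splitting of
#' touching nuclei by distance-transform watershed. Centroids of the resulting
#' labels form the nucleus position matrix used to sort glia structures into
#' single cells and clusters.
#'
#' @param nucleus_image fluorescence nucleus channel ([calibrated_image]).
#' @param min_nucleus_area_um2 minimum nucleus area (default 5 um^2).
#' @param watershed_tolerance minimum depth (in distance-map units, pixels) a
#'   catchment basin must have to count as a separate nucleus.
#' @param min_separation_um minimum seed separation for the watershed
#'   (default 1 um).
#' @return an object of class `nucleus_map`: `labels` (integer matrix, 0 =
#'   background) and `centroids` (k x 2 matrix of (row, col)).
#' @export
detect_nuclei <- function(nucleus_image, min_nucleus_area_um2 = 5,
                          watershed_tolerance = 1, min_separation_um = 1) {
  stopifnot(inherits(nucleus_image, "calibrated_image"))
  ps <- nucleus_image$pixel_size_um
  px <- nucleus_image$pixels
  empty <- function() structure(
    list(labels = matrix(0L, nrow(px), ncol(px)),
         centroids = matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col")))),
    class = "nucleus_map")
  if (max(px) <= 0) return(empty())
  th <- otsu_threshold(px)
  mask <- px >= th
  mask <- fill_small_holes(mask, max_hole_px = Inf)
  mask <- remove_small_components(mask, min_nucleus_area_um2 / ps^2)
  if (!any(mask)) return(empty())
  dm <- EBImage::distmap(mask * 1)
  ext <- max(1L, as.integer(round(min_separation_um / ps)))
  lbl <- EBImage::imageData(EBImage::watershed(dm, tolerance = watershed_tolerance, ext = ext))
  storage.mode(lbl) <- "integer"
  structure(list(labels = lbl, centroids = .label_centroids(lbl)), class = "nucleus_map")
}

#' @export
print.nucleus_map <- function(x, ...) {
  cat(sprintf("<nucleus_map> %d nuclei in a %d x %d field\n",
              nrow(x$centroids), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

.new_component <- function(id, bbox, mask, soma, nucleus_count, nucleus_centroids) {
  structure(
    list(id = id, bbox = bbox, mask = mask, soma_mask = soma & mask,
         skeleton = NULL, nucleus_count = as.integer(nucleus_count),
         is_cluster = nucleus_count >= 2L,
         nucleus_centroids = nucleus_centroids),
    class = "glia_component"
  )
}

#' @export
print.glia_component <- function(x, ...) {
  cat(sprintf("<glia_component #%d> %d px, soma %d px, %d nucleus(i), %s\n",
              x$id, sum(x$mask), sum(x$soma_mask), x$nucleus_count,
              if (x$is_cluster) "cluster" else "single cell"))
  invisible(x)
}

#' Sort glia structures into nucleus-assigned components
#'
#' Overlaps every 8-connected glia structure with the nucleus position matrix
#' and annotates it with the number of nucleus centroids falling on it.
#' Structures covering no centroid are discarded -- they are cell-process
#' fragments from cells whose body lies in another focal layer -- and the
#' survivors are sorted into single cells (one nucleus) or clusters (two or
#' more). In chromogen mode no nucleus channel exists, so the centroids of the
#' soma regions act as nucleus surrogates.
#'
#' @param glia_mask cleaned, bridge-separated glia mask.
#' @param soma_mask soma mask from [extract_somata()].
#' @param nuclei a `nucleus_map` (required in fluorescence mode; ignored in
#'   chromogen mode).
#' @param mode `"fluorescence"` or `"chromogen"`.
#' @return list of `glia_component` objects with bounding-box-local masks.
#' @export
assign_components <- function(glia_mask, soma_mask, nuclei = NULL,
                              mode = c("fluorescence", "chromogen")) {
  mode <- match.arg(mode)
  glia_mask <- .as_mask(glia_mask)
  if (!identical(dim(glia_mask), dim(soma_mask)))
    stop("glia and soma masks must share dimensions")
  if (mode == "fluorescence") {
    if (is.null(nuclei) || !inherits(nuclei, "nucleus_map"))
      stop("fluorescence mode requires the nucleus channel (a nucleus_map)")
    centroids <- nuclei$centroids
  } else {
    soma_lbl <- label_components(soma_mask)
    centroids <- .label_centroids(soma_lbl)
  }
  lbl <- label_components(glia_mask)
  k <- max(lbl)
  if (k == 0L || nrow(centroids) == 0) return(list())
  hits <- integer(nrow(centroids))
  for (i in seq_len(nrow(centroids))) {
    r <- as.integer(round(centroids[i, 1])); c <- as.integer(round(centroids[i, 2]))
    lab <- 0L
    if (r >= 1 && c >= 1 && r <= nrow(lbl) && c <= ncol(lbl)) lab <- lbl[r, c]
    if (lab == 0L) {
      # a centroid can round off a thin structure by one pixel; look around
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (lab == 0L && rr >= 1 && cc >= 1 && rr <= nrow(lbl) && cc <= ncol(lbl) &&
            lbl[rr, cc] > 0L) lab <- lbl[rr, cc]
      }
    }
    hits[i] <- lab
  }
  counts <- tabulate(hits[hits > 0L], nbins = k)
  keep <- which(counts >= 1L)
  out <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    lab <- keep[j]
    sel <- lbl == lab
    bb <- .mask_bbox(sel)
    local <- sel[bb["r0"]:bb["r1"], bb["c0"]:bb["c1"], drop = FALSE]
    soma_local <- soma_mask[bb["r0"]:bb["r1"], bb["c0"]:bb["c1"], drop = FALSE] & local
    cen <- centroids[hits == lab, , drop = FALSE]
    out[[j]] <- .new_component(j, bb, local, soma_local, counts[lab], cen)
  }
  out
}
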