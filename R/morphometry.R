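# Per-object morphometry: the eleven parameters measured for every glia
# structure. Physical quantities are reported both in pixels and micrometres;
# the morphology ratio (process length / soma area, um/um^2) is the continuous
# activation scale -- the smaller the ratio, the more activated the cell.

#' Skeletonise the cell processes of a component
#'
#' The process skeleton is the topological thinning of the cell mask minus the
#' soma mask, pruned of spurs shorter than `min_spur_px`. An amoeboid cell
#' (soma = mask) yields an empty skeleton. The skeleton is stored on the
#' returned component.
#'
#' @param component a `glia_component` with `mask` and `soma_mask`.
#' @param min_spur_px prune spurs shorter than this many pixels (default 4:
#'   topological thinning of a curved tube leaves staircase side-spurs of up
#'   to ~3 px that would otherwise count as false branch points and
#'   endpoints; real side branches are longer).
#' @return the component, with `$skeleton` populated.
#' @export
skeletonize_processes <- function(component, min_spur_px = 4L) {
  stopifnot(inherits(component, "glia_component"))
  region <- component$mask & !component$soma_mask
  skel <- thin_mask(region)
  # a sharp bend of a thick process can thin into a pixel-scale loop (two
  # spurious junctions); filling sub-tube-sized holes and re-thinning
  # restores a simple arc, while real enclosures are far larger
  skel <- thin_mask(fill_small_holes(skel, max_hole_px = 12))
  skel <- .remove_staircase_pixels(skel)
  skel <- prune_spurs(skel, min_px = min_spur_px)
  if (any(skel)) {
    # drop skeleton fragments that lie entirely against the soma: these are
    # rim residues of the soma extraction (the mask boundary the recovered
    # soma just missed), not cell processes
    zone <- .soma_zone(component$soma_mask)
    lbl <- label_components(skel)
    if (max(lbl) > 0) {
      inside <- tapply(zone[skel], lbl[skel], all)
      drop <- as.integer(names(inside))[inside]
      if (length(drop)) skel[lbl %in% drop] <- FALSE
    }
  }
  component$skeleton <- skel
  component
}

# Chebyshev-4 neighbourhood of the soma: the zone where skeleton structure is
# attributable to the soma boundary (retracted roots, rim residues) rather
# than to cell processes.
.soma_zone <- function(soma) {
  mask_dilate3x3(mask_dilate3x3(mask_dilate3x3(mask_dilate3x3(soma))))
}

# Link counts between 8-adjacent skeleton pixels. A diagonal link is skipped
# when the two pixels share a common orthogonal skeleton neighbour (the path
# already runs through it); counting it too would overstate the length of
# every staircase corner.
.skeleton_links <- function(skel) {
  s <- .as_mask(skel)
  e <- .shift_mat(s, 0L, 1L)   # east neighbour
  so <- .shift_mat(s, 1L, 0L)  # south neighbour
  n_orth <- sum(s & e) + sum(s & so)
  se <- .shift_mat(s, 1L, 1L)
  sw <- .shift_mat(s, 1L, -1L)
  w <- .shift_mat(s, 0L, -1L)
  # diagonal to SE: common orthogonal neighbours are E and S
  d_se <- s & se & !(e | so)
  # diagonal to SW: common orthogonal neighbours are W and S
  d_sw <- s & sw & !(w | so)
  c(orth = n_orth, diag = sum(d_se) + sum(d_sw))
}

#' Total process length of a skeleton
#'
#' Sums link lengths between adjacent skeleton pixels: orthogonal links count
#' one pixel, diagonal links `sqrt(2)` pixels (raw pixel counting would
#' understate diagonal runs by up to 29%). The result is scaled by the pixel
#' size.
#'
#' @param skeleton one-pixel-wide logical skeleton.
#' @param pixel_size_um pixel size in micrometres.
#' @return length in micrometres (0 for an empty skeleton).
#' @export
process_length <- function(skeleton, pixel_size_um) {
  stopifnot(pixel_size_um > 0)
  lk <- .skeleton_links(skeleton)
  (lk["orth"] + sqrt(2) * lk["diag"]) * pixel_size_um
}

#' Count skeleton endpoints
#'
#' A skeleton pixel with at most one skeleton 8-neighbour is an endpoint; an
#' isolated pixel counts as one endpoint.
#'
#' @param skeleton logical skeleton mask.
#' @return integer count.
#' @export
count_endpoints <- function(skeleton) {
  sum(.endpoint_pixels(.as_mask(skeleton)))
}

#' Count skeleton branch points
#'
#' Candidate pixels have three or more skeleton 8-neighbours; 8-adjacent
#' candidates are merged into a single junction before counting, so a thick
#' crossing is one branch point, not several.
#'
#' @param skeleton logical skeleton mask.
#' @return integer count of junctions.
#' @export
count_branchpoints <- function(skeleton) {
  skel <- .as_mask(skeleton)
  cand <- skel & .neighbour_count(skel) >= 3L
  if (!any(cand)) return(0L)
  max(label_components(cand))
}

# Root bridging: thinning retracts the blunt (soma-side) end of a process
# skeleton a few pixels away from the soma boundary, so the bare skeleton
# length systematically understates the process length. For every skeleton
# endpoint lying in the soma-adjacent zone (a root end), the straight-line
# gap to the nearest soma pixel (minus the one-pixel adjacency) is added
# back.
.root_bridge_um <- function(skel, soma, pixel_size_um) {
  if (!any(skel) || !any(soma)) return(0)
  roots <- which(.endpoint_pixels(skel) & .soma_zone(soma), arr.ind = TRUE)
  if (nrow(roots) == 0) return(0)
  total <- 0
  nr <- nrow(soma); nc <- ncol(soma)
  for (i in seq_len(nrow(roots))) {
    r <- roots[i, 1]; c <- roots[i, 2]
    win_r <- max(1, r - 8):min(nr, r + 8)
    win_c <- max(1, c - 8):min(nc, c + 8)
    sp <- which(soma[win_r, win_c, drop = FALSE], arr.ind = TRUE)
    if (nrow(sp) == 0) next
    d <- sqrt((win_r[sp[, 1]] - r)^2 + (win_c[sp[, 2]] - c)^2)
    total <- total + min(max(0, min(d) - 1), 7)
  }
  total * pixel_size_um
}

# Branch points with junction candidates inside an exclusion zone discarded
# before junction merging (used by measure() to ignore root-area junctions).
.count_branchpoints_excl <- function(skel, zone) {
  skel <- .as_mask(skel)
  cand <- skel & .neighbour_count(skel) >= 3L & !zone
  if (!any(cand)) return(0L)
  max(label_components(cand))
}

#' Percent fill of a cell mask
#'
#' Ratio of the object pixel count to the pixel count of its axis-aligned
#' bounding box; a compact (amoeboid) cell approaches 1, a sprawling ramified
#' cell is small.
#'
#' @param mask single-component logical mask (non-empty).
#' @return fraction in (0, 1].
#' @export
percent_fill <- function(mask) {
  mask <- .as_mask(mask)
  if (!any(mask)) stop("percent_fill is undefined for an empty mask")
  bb <- .mask_bbox(mask)
  sum(mask) / ((bb["r1"] - bb["r0"] + 1) * (bb["c1"] - bb["c0"] + 1))
}

#' Span ratio of a cell mask
#'
#' Ratio of the major to the minor axis of the ellipse with the same second
#' central moments as the object (>= 1). Degenerate (collinear) masks, whose
#' minor axis vanishes, return `degenerate_cap` with attribute
#' `degenerate = TRUE`.
#'
#' @param mask single-component logical mask with at least 2 pixels.
#' @param degenerate_cap value reported for collinear masks (default 100).
#' @return span ratio >= 1.
#' @export
span_ratio <- function(mask, degenerate_cap = 100) {
  mask <- .as_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 2) stop("span_ratio requires at least 2 pixels")
  cv <- stats::cov(idx) * (nrow(idx) - 1) / nrow(idx)  # population moments
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= .Machine$double.eps * max(1, ev[1]))
    return(structure(degenerate_cap, degenerate = TRUE))
  max(1, sqrt(ev[1] / ev[2]))
}

#' Perimeter of a cell mask
#'
#' Length of the boundary contour by weighted step counting along the traced
#' outline: orthogonal steps count one pixel, diagonal steps `sqrt(2)`, scaled
#' by the pixel size. Linear in the pixel size by construction.
#'
#' @param mask single-component logical mask (non-empty).
#' @param pixel_size_um pixel size in micrometres.
#' @return perimeter in micrometres.
#' @export
perimeter <- function(mask, pixel_size_um) {
  stopifnot(pixel_size_um > 0)
  mask <- .as_mask(mask)
  if (!any(mask)) stop("perimeter is undefined for an empty mask")
  if (sum(mask) == 1) return(0)
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  total <- 0
  for (ct in oc) {
    if (nrow(ct) < 2) next
    steps <- rbind(diff(ct), ct[1, ] - ct[nrow(ct), ])  # closed contour
    d <- pmax(abs(steps[, 1]), abs(steps[, 2]))
    diagonal <- abs(steps[, 1]) == 1 & abs(steps[, 2]) == 1
    total <- total + sum(ifelse(diagonal, sqrt(2), d))
  }
  total * pixel_size_um
}

#' Sum intensity of a marker channel within a mask
#'
#' Exact sum of the raw marker intensities over the mask pixels; no
#' normalisation or rescaling is applied.
#'
#' @param mask logical mask.
#' @param marker a [calibrated_image] sharing the mask's dimensions.
#' @return numeric sum (0 for an empty mask).
#' @export
marker_sum_intensity <- function(mask, marker) {
  stopifnot(inherits(marker, "calibrated_image"))
  mask <- .as_mask(mask)
  if (!identical(dim(mask), dim(marker$pixels)))
    stop("mask and marker channel must share dimensions")
  sum(marker$pixels[mask])
}

#' Measure the eleven morphometric parameters of a component
#'
#' Assembles one record with: percent fill, soma (cell-body) area, process
#' length, morphology ratio (process length / soma area), number of cells
#' (nuclei), cell area, activation-marker (CD68) sum intensity when an
#' activation channel is present, endpoint count, branch-point count, span
#' ratio and perimeter. A component whose soma area is zero is flagged
#' degenerate and its morphology ratio is reported as missing.
#'
#' Endpoints counted here are process *tips*: skeleton endpoints that touch
#' the soma are process roots, not tips, and are excluded.
#'
#' @param component a `glia_component` (its skeleton is computed on the fly if
#'   absent).
#' @param channels optional [channel_set]; when it carries an
#'   `activation_marker`, the CD68 sum intensity is measured inside the cell
#'   mask.
#' @param pixel_size_um pixel size in micrometres.
#' @param min_spur_px spur-pruning minimum passed to
#'   [skeletonize_processes()].
#' @return a one-row data frame (see `vignette("gliamorph-methods")` for the
#'   column dictionary).
#' @export
measure <- function(component, channels = NULL, pixel_size_um, min_spur_px = 4L) {
  stopifnot(inherits(component, "glia_component"), pixel_size_um > 0)
  if (is.null(component$skeleton))
    component <- skeletonize_processes(component, min_spur_px = min_spur_px)
  mask <- component$mask
  soma <- component$soma_mask
  skel <- component$skeleton
  ps <- pixel_size_um
  cell_px <- sum(mask)
  soma_px <- sum(soma)
  len_um <- unname(process_length(skel, ps)) + .root_bridge_um(skel, soma, ps)
  # process tips: skeleton endpoints clear of the soma (thinning can retract
  # a blunt process root end a few pixels away from the soma boundary, so the
  # root-exclusion zone is four pixels wide); junctions in the same zone are
  # root artifacts, not process branch points
  zone <- .soma_zone(soma)
  ep <- .endpoint_pixels(skel) & !zone
  soma_um2 <- soma_px * ps^2
  degenerate <- soma_px == 0
  sr <- if (cell_px >= 2) span_ratio(mask) else NA_real_
  cd68 <- NA_real_
  if (!is.null(channels) && !is.null(channels$activation_marker)) {
    bb <- component$bbox
    marker_local <- channels$activation_marker$pixels[bb["r0"]:bb["r1"],
                                                      bb["c0"]:bb["c1"], drop = FALSE]
    cd68 <- sum(marker_local[mask])
  }
  data.frame(
    object_id = component$id,
    is_cluster = component$is_cluster,
    n_cells = component$nucleus_count,
    percent_fill = unname(percent_fill(mask)),
    soma_area_um2 = soma_um2,
    process_length_um = len_um,
    morphology_ratio = if (degenerate) NA_real_ else len_um / soma_um2,
    cell_area_um2 = cell_px * ps^2,
    cd68_sum_intensity = cd68,
    n_endpoints = sum(ep),
    n_branchpoints = .count_branchpoints_excl(skel, zone),
    span_ratio = as.numeric(sr),
    perimeter_um = unname(perimeter(mask, ps)),
    cell_area_px = cell_px,
    soma_area_px = soma_px,
    process_length_px = len_um / ps,
    perimeter_px = unname(perimeter(mask, 1)),
    degenerate = degenerate,
    activation_class = NA_character_,
    stringsAsFactors = FALSE
  )
}
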