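# Reading calibrated channel images and ROI polygons; writing result tables,
# overlays, previews and crops.
#
# In-memory convention: images and masks are R matrices addressed with 1-based
# (row, col) indices, the idiomatic choice for R. File formats that carry
# coordinates (the ROI JSON) use 0-based (row, col) pixel-centre coordinates;
# the conversion happens at the I/O boundary and nowhere else.

#' Construct a calibrated image
#'
#' A calibrated image couples a 2D intensity grid with its physical pixel size
#' and two tags: the acquisition modality and the biological role of the
#' channel. Intensities are kept exactly as read -- no rescaling is ever
#' applied, because the activation-marker (CD68) sum intensity parameter is
#' defined on raw values.
#'
#' @param pixels numeric matrix of finite, non-negative intensities.
#' @param pixel_size_um physical pixel size in micrometres per pixel (> 0).
#' @param modality `"fluorescence"` (bright signal on dark background) or
#'   `"chromogen"` (dark DAB stain on a bright transmitted-light background).
#' @param role one of `"glia_marker"`, `"nucleus"`, `"activation_marker"`,
#'   `"transmitted"`.
#' @return an object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, pixel_size_um,
                             modality = c("fluorescence", "chromogen"),
                             role = c("glia_marker", "nucleus", "activation_marker", "transmitted")) {
  modality <- match.arg(modality)
  role <- match.arg(role)
  if (!is.matrix(pixels) || length(pixels) == 0)
    stop("`pixels` must be a non-empty matrix")
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop("intensities must be finite and non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 || !is.finite(pixel_size_um) ||
      pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         modality = modality, role = role),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %d x %d px @ %.4g um/px, %s/%s, range [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um, x$modality, x$role,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.calibrated_image <- function(x) dim(x$pixels)

#' Bundle the channels of one imaging field
#'
#' @param glia_marker required `calibrated_image` (IBA-1 or equivalent).
#' @param nucleus optional nucleus channel (DAPI); required for single-cell vs.
#'   cluster sorting in fluorescence mode.
#' @param activation_marker optional activation-marker channel (CD68).
#' @return an object of class `channel_set`.
#' @export
channel_set <- function(glia_marker, nucleus = NULL, activation_marker = NULL) {
  stopifnot(inherits(glia_marker, "calibrated_image"))
  for (ch in list(nucleus, activation_marker)) {
    if (is.null(ch)) next
    stopifnot(inherits(ch, "calibrated_image"))
    if (!identical(dim(ch$pixels), dim(glia_marker$pixels)))
      stop("all channels must share identical dimensions")
    if (!isTRUE(all.equal(ch$pixel_size_um, glia_marker$pixel_size_um)))
      stop("all channels must share the same pixel size")
  }
  structure(list(glia_marker = glia_marker, nucleus = nucleus,
                 activation_marker = activation_marker),
            class = "channel_set")
}

.read_page_gray <- function(page) {
  if (is.matrix(page)) return(page)
  if (length(dim(page)) == 3) {
    # colour plane stack: accept only if all planes agree (i.e. stored grey)
    pl <- lapply(seq_len(dim(page)[3]), function(i) page[, , i])
    if (dim(page)[3] >= 3) {
      if (max(abs(pl[[1]] - pl[[2]])) > 0 || max(abs(pl[[1]] - pl[[3]])) > 0)
        stop("expected a grayscale image, got distinct colour channels")
    }
    return(pl[[1]])
  }
  stop("unsupported image page layout")
}

#' Read one channel image from disk
#'
#' Reads a single- or multi-page grayscale TIFF (or a PNG) and returns a
#' [calibrated_image]. Multi-page stacks are collapsed by per-pixel maximum
#' (maximum intensity projection) -- the same reduction applied to confocal
#' z-stacks at acquisition time. Raw integer intensities are preserved
#' (`as.is` for TIFF; PNG values are mapped back to their integer bit range).
#'
#' @param path file path to a readable TIFF or PNG.
#' @param pixel_size_um pixel size in micrometres per pixel (> 0); this is a
#'   required user input because acquisition metadata are not trusted.
#' @inheritParams calibrated_image
#' @return a [calibrated_image].
#' @export
read_channel <- function(path, pixel_size_um,
                         modality = c("fluorescence", "chromogen"),
                         role = c("glia_marker", "nucleus", "activation_marker", "transmitted")) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path))
    stop(sprintf("cannot read image file '%s'", path))
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    depth <- if (!is.null(info) && !is.null(info$bit.depth)) info$bit.depth else 8L
    pages <- list(img * (2^depth - 1))
  } else {
    stop(sprintf("unsupported image format '.%s' (expected TIFF or PNG)", ext))
  }
  pages <- lapply(pages, .read_page_gray)
  if (length(pages[[1]]) == 0 || any(dim(pages[[1]]) == 0))
    stop("zero-sized image")
  proj <- Reduce(pmax, pages)
  calibrated_image(proj, pixel_size_um, modality = match.arg(modality), role = match.arg(role))
}

#' Construct a polygon region of interest
#'
#' Vertices are (row, col) pixel-centre coordinates. The polygon must be
#' simple (non-self-intersecting) and have non-zero area.
#'
#' @param vertices numeric n x 2 matrix of (row, col) vertices, n >= 3.
#' @return an object of class `roi_polygon`.
#' @export
roi_polygon <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2 || nrow(vertices) < 3)
    stop("a polygon needs at least 3 (row, col) vertices")
  r <- vertices[, 1]; c <- vertices[, 2]
  area2 <- sum(r * c[c(2:length(c), 1)] - r[c(2:length(r), 1)] * c)
  if (abs(area2) < sqrt(.Machine$double.eps))
    stop("degenerate polygon: zero area")
  if (.polygon_self_intersects(vertices))
    stop("polygon is self-intersecting")
  structure(list(vertices = vertices), class = "roi_polygon")
}

# O(n^2) proper-crossing test between non-adjacent edges.
.polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), ])
  cross <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  for (i in seq_len(n - 2)) {
    for (j in (i + 1):n) {
      if (j == i || abs(i - j) == 1 || (i == 1 && j == n)) next
      p1 <- seg[i, 1:2]; p2 <- seg[i, 3:4]; p3 <- seg[j, 1:2]; p4 <- seg[j, 3:4]
      d1 <- cross(p3, p4, p1); d2 <- cross(p3, p4, p2)
      d3 <- cross(p1, p2, p3); d4 <- cross(p1, p2, p4)
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Read ROI polygons from the JSON interchange format
#'
#' The on-disk format is `{"polygons": [{"vertices": [[row, col], ...]}, ...]}`
#' with 0-based pixel-centre coordinates; coordinates are converted to 1-based
#' on read.
#'
#' @param path path to a ROI JSON file.
#' @return a list of [roi_polygon] objects.
#' @export
read_roi_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyMatrix = TRUE, simplifyDataFrame = FALSE)
  if (is.null(doc$polygons)) stop("ROI JSON must contain a 'polygons' array")
  lapply(doc$polygons, function(p) roi_polygon(as.matrix(p$vertices) + 1))
}

#' Write ROI polygons to the JSON interchange format
#' @param rois list of [roi_polygon] objects.
#' @param path output path.
#' @export
write_roi_json <- function(rois, path) {
  polys <- lapply(rois, function(p) list(vertices = unname(p$vertices) - 1))
  jsonlite::write_json(list(polygons = polys), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rasterise a polygon ROI to a binary mask
#'
#' A pixel is set iff its centre lies inside the polygon; centres exactly on an
#' edge count as inside.
#'
#' @param roi a [roi_polygon].
#' @param shape integer vector `c(rows, cols)` of the target image.
#' @return logical matrix of dimension `shape`.
#' @export
rasterize_roi <- function(roi, shape) {
  stopifnot(inherits(roi, "roi_polygon"), length(shape) == 2)
  mask <- matrix(FALSE, shape[1], shape[2])
  v <- roi$vertices
  rs <- max(1L, floor(min(v[, 1]))):min(shape[1], ceiling(max(v[, 1])))
  cs <- max(1L, floor(min(v[, 2]))):min(shape[2], ceiling(max(v[, 2])))
  if (length(rs) == 0 || length(cs) == 0) return(mask)
  grid <- expand.grid(row = rs, col = cs)
  inside <- pracma::inpolygon(grid$row, grid$col, v[, 1], v[, 2], boundary = TRUE)
  mask[cbind(grid$row, grid$col)] <- inside
  mask
}

# Fixed, documented column order of the result tables.
.record_columns <- c(
  "object_id", "is_cluster", "n_cells", "percent_fill", "soma_area_um2",
  "process_length_um", "morphology_ratio", "cell_area_um2", "cd68_sum_intensity",
  "n_endpoints", "n_branchpoints", "span_ratio", "perimeter_um",
  "cell_area_px", "soma_area_px", "process_length_px", "perimeter_px",
  "degenerate", "activation_class"
)

.empty_records <- function() {
  df <- as.data.frame(setNames(rep(list(logical(0)), length(.record_columns)), .record_columns))
  df$object_id <- integer(0); df$n_cells <- integer(0)
  df
}

.order_record_columns <- function(df) {
  if (nrow(df) == 0 && ncol(df) == 0) return(.empty_records())
  for (col in setdiff(.record_columns, names(df))) df[[col]] <- NA
  df[, .record_columns, drop = FALSE]
}

#' Write the morphometry result tables
#'
#' Emits four deterministic CSV files into `path` (a directory), mirroring the
#' four spreadsheet tabs of the original workflow: `single_cells.csv`,
#' `clusters.csv`, `combined.csv` (single cells and clusters concatenated) and
#' `histograms.csv`. Column order is fixed; re-reading the files reproduces
#' integer columns bit-exactly and real columns to full printed precision
#' (values are written with 15 significant digits).
#'
#' @param single_records,cluster_records data frames of morphometry records.
#' @param histograms result of [build_histograms()] (may be `NULL`).
#' @param path output directory (created if missing).
#' @return invisibly, the named vector of written file paths.
#' @export
write_results <- function(single_records, cluster_records, histograms, path) {
  if (file.exists(path) && !dir.exists(path)) stop("`path` must be a directory")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop(sprintf("cannot create output directory '%s'", path))
  single_records <- .order_record_columns(single_records)
  cluster_records <- .order_record_columns(cluster_records)
  combined <- rbind(single_records, cluster_records)
  hist_df <- .histograms_as_df(histograms)
  files <- c(
    single_cells = file.path(path, "single_cells.csv"),
    clusters     = file.path(path, "clusters.csv"),
    combined     = file.path(path, "combined.csv"),
    histograms   = file.path(path, "histograms.csv")
  )
  .write_csv(single_records, files["single_cells"])
  .write_csv(cluster_records, files["clusters"])
  .write_csv(combined, files["combined"])
  .write_csv(hist_df, files["histograms"])
  invisible(files)
}

.write_csv <- function(df, file) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 15))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE, eol = "\n", na = "")
}

.histograms_as_df <- function(histograms) {
  if (is.null(histograms))
    return(data.frame(stratum = character(0), bin_left = numeric(0),
                      bin_right = numeric(0), count = integer(0)))
  do.call(rbind, lapply(histograms, function(h) {
    k <- length(h$counts)
    data.frame(stratum = h$stratum, bin_left = h$bin_edges[seq_len(k)],
               bin_right = h$bin_edges[seq_len(k) + 1], count = h$counts)
  }))
}

.class_rgb <- c(activated = "red", intermediate = "green", non_activated = "blue")

.class_channel_values <- function(cls) {
  # returns list(r, g, b) unit intensities for a class label
  switch(cls,
         activated = c(1, 0, 0),
         intermediate = c(0, 1, 0),
         non_activated = c(0, 0, 1),
         stop(sprintf("unknown activation class '%s'", cls)))
}

#' Write a colour-coded overlay image
#'
#' Renders the glia channel as grayscale and paints, for every component, its
#' soma outline and process skeleton in the colour of its activation class:
#' activated cells in red, intermediate in green, non-activated in blue.
#'
#' @param channels a [channel_set].
#' @param components list of `glia_component` objects.
#' @param classes character vector of activation classes, parallel to
#'   `components`.
#' @param path output PNG path.
#' @return invisibly, `path`.
#' @export
write_overlay <- function(channels, components, classes, path) {
  stopifnot(inherits(channels, "channel_set"))
  if (length(components) != length(classes))
    stop("`components` and `classes` must have the same length")
  px <- channels$glia_marker$pixels
  base <- px / max(px, 1)
  rgb <- array(rep(base, 3), dim = c(nrow(base), ncol(base), 3))
  for (i in seq_along(components)) {
    rgb <- .paint_component(rgb, components[[i]], as.character(classes[[i]]))
  }
  png::writePNG(rgb, path)
  invisible(path)
}

.paint_component <- function(rgb, comp, cls) {
  col <- .class_channel_values(cls)
  bb <- comp$bbox
  paint <- comp$soma_mask & !mask_erode(comp$soma_mask, 1)  # soma outline
  if (!is.null(comp$skeleton)) paint <- paint | comp$skeleton
  idx <- which(paint, arr.ind = TRUE)
  if (nrow(idx) == 0) return(rgb)
  gr <- idx[, 1] + bb["r0"] - 1L
  gc <- idx[, 2] + bb["c0"] - 1L
  for (ch in 1:3) rgb[cbind(gr, gc, ch)] <- col[ch]
  rgb
}

#' Downscale an image for preview
#'
#' Mean-based resampling: each output pixel is the mean of the source pixels
#' that map onto it, so a constant image stays constant and intensities are
#' preserved in expectation. The physical pixel size grows by `1/factor`.
#'
#' @param image a [calibrated_image].
#' @param factor scale factor in (0, 1); the original workflow used 0.1
#'   ("10% sized" previews).
#' @return a [calibrated_image] preview.
#' @export
downscale_preview <- function(image, factor = 0.1) {
  stopifnot(inherits(image, "calibrated_image"))
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0 || factor >= 1)
    stop("`factor` must be a single number in (0, 1)")
  px <- image$pixels
  ri <- floor((seq_len(nrow(px)) - 1) * factor)
  ci <- floor((seq_len(ncol(px)) - 1) * factor)
  sums <- rowsum(px, group = ri, reorder = TRUE)
  sums <- t(rowsum(t(sums), group = ci, reorder = TRUE))
  counts <- outer(as.vector(table(ri)), as.vector(table(ci)))
  calibrated_image(sums / counts, image$pixel_size_um / factor,
                   modality = image$modality, role = image$role)
}

#' Write a calibrated image to TIFF
#'
#' Intensities are written as 16-bit (values are scaled by 1/65535 for the
#' writer and round-trip exactly for integer inputs in 0..65535).
#' @param image a [calibrated_image].
#' @param path output path.
#' @export
write_channel_tiff <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  px <- pmin(pmax(image$pixels, 0), 65535)
  tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
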