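# Validation mode: seeded random sampling of detected single cells, export of
# colour-coded per-cell crops, and agreement scoring against manual labels.

#' Randomly sample detected cells for manual review
#'
#' Uniform sampling without replacement from the detected single cells, under
#' a named, seedable generator: the same seed always returns the same sample.
#' When fewer cells are available than requested, all of them are returned.
#'
#' @param components list of `glia_component` objects (clusters are excluded
#'   from sampling).
#' @param n requested sample size (>= 1).
#' @param seed integer RNG seed (required for reproducibility of the draw).
#' @param classes optional character vector of activation classes parallel to
#'   `components`; carried into the sample for colour-coded export.
#' @param pad_px crop padding recorded in the sample geometry (default 10).
#' @return object of class `cell_sample` with `ids`, `bboxes` (padded,
#'   unclipped crop geometry), `classes`, `seed`, `n_requested`.
#' @export
sample_cells <- function(components, n, seed, classes = NULL, pad_px = 10L) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) stop("`n` must be >= 1")
  if (missing(seed) || !is.numeric(seed)) stop("`seed` is required")
  singles <- Filter(function(cp) !cp$is_cluster, components)
  if (!is.null(classes)) {
    if (length(classes) != length(components))
      stop("`classes` must be parallel to `components`")
    cls_singles <- as.character(classes)[!vapply(components, `[[`, logical(1), "is_cluster")]
  } else cls_singles <- rep(NA_character_, length(singles))
  if (length(singles) == 0) {
    warning("no detected single cells to sample from")
    idx <- integer(0)
  } else {
    idx <- .with_seed(seed, sort(sample.int(length(singles), min(n, length(singles)))))
  }
  ids <- vapply(singles, `[[`, integer(1), "id")[idx]
  bboxes <- lapply(singles[idx], function(cp) {
    bb <- cp$bbox
    c(r0 = bb[["r0"]] - pad_px, r1 = bb[["r1"]] + pad_px,
      c0 = bb[["c0"]] - pad_px, c1 = bb[["c1"]] + pad_px)
  })
  structure(list(ids = ids, bboxes = bboxes, classes = cls_singles[idx],
                 seed = seed, n_requested = as.integer(n), pad_px = as.integer(pad_px)),
            class = "cell_sample")
}

#' @export
print.cell_sample <- function(x, ...) {
  cat(sprintf("<cell_sample> %d of %d requested cells (seed %d)\n",
              length(x$ids), x$n_requested, x$seed))
  invisible(x)
}

#' Export colour-coded single-cell crops
#'
#' Writes one PNG per sampled cell: the glia channel cropped to the padded
#' cell bounding box (clipped at the image border), with soma outline and
#' process skeleton tinted by activation class (activated red, intermediate
#' green, non-activated blue). Filenames encode the cell id and class.
#'
#' @param sample a `cell_sample`.
#' @param channels a [channel_set].
#' @param components the component list the sample was drawn from.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the vector of written file paths.
#' @export
export_crops <- function(sample, channels, components, out_dir) {
  stopifnot(inherits(sample, "cell_sample"), inherits(channels, "channel_set"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create output directory '%s'", out_dir))
  px <- channels$glia_marker$pixels
  comp_ids <- vapply(components, `[[`, integer(1), "id")
  paths <- character(length(sample$ids))
  for (i in seq_along(sample$ids)) {
    cp <- components[[match(sample$ids[i], comp_ids)]]
    cls <- sample$classes[i]
    bb <- sample$bboxes[[i]]
    r0 <- max(1L, bb[["r0"]]); r1 <- min(nrow(px), bb[["r1"]])
    c0 <- max(1L, bb[["c0"]]); c1 <- min(ncol(px), bb[["c1"]])
    crop <- px[r0:r1, c0:c1, drop = FALSE]
    base <- crop / max(crop, 1)
    rgb <- array(rep(base, 3), dim = c(nrow(base), ncol(base), 3))
    paint <- (cp$soma_mask & !mask_erode(cp$soma_mask, 1))
    if (!is.null(cp$skeleton)) paint <- paint | cp$skeleton
    idx <- which(paint, arr.ind = TRUE)
    if (nrow(idx) && !is.na(cls)) {
      col <- .class_channel_values(cls)
      gr <- idx[, 1] + cp$bbox[["r0"]] - 1L - r0 + 1L
      gc <- idx[, 2] + cp$bbox[["c0"]] - 1L - c0 + 1L
      ok <- gr >= 1 & gr <= nrow(base) & gc >= 1 & gc <= ncol(base)
      for (ch in 1:3) rgb[cbind(gr[ok], gc[ok], ch)] <- col[ch]
    }
    fname <- sprintf("cell_%04d_%s.png", cp$id, if (is.na(cls)) "unclassified" else cls)
    paths[i] <- file.path(out_dir, fname)
    png::writePNG(rgb, paths[i])
  }
  invisible(paths)
}

#' Score agreement between manual and automated classification
#'
#' Manual scores come as three replicate readings per cell on the 4-point
#' morphology scale (1 = ramified ... 4 = fully amoeboid); the replicate
#' average is rounded half-up to a whole score, then mapped to the automated
#' 3-class scheme (4 = activated, 2-3 = intermediate, 1 = non-activated). A
#' manual score of 0 marks a detection the reviewer could not identify as a
#' cell (a false-positive detection). Manual rows with no matching automated
#' record count as missed detections; automated records with no manual row are
#' excluded with a warning.
#'
#' @param manual_scores data frame with columns `cell_id`, `rep1`, `rep2`,
#'   `rep3`.
#' @param records classified morphometry records (`object_id`,
#'   `morphology_ratio`, `activation_class`).
#' @return object of class `agreement_report`: counts `n_evaluated`,
#'   `n_true_positive`, `n_false_positive`, `n_false_negative_detection`,
#'   `n_score_mismatch`, and `spearman_rho` between the rounded manual score
#'   and the automated morphology ratio.
#' @export
score_agreement <- function(manual_scores, records) {
  need <- c("cell_id", "rep1", "rep2", "rep3")
  if (!all(need %in% names(manual_scores)))
    stop("manual_scores must have columns cell_id, rep1, rep2, rep3")
  avg <- rowMeans(manual_scores[, c("rep1", "rep2", "rep3")])
  rounded <- floor(avg + 0.5)  # round half up
  manual <- data.frame(cell_id = manual_scores$cell_id, manual_score = rounded)
  unmatched_auto <- setdiff(records$object_id, manual$cell_id)
  if (length(unmatched_auto))
    warning(sprintf("%d automated record(s) without manual scores excluded: %s",
                    length(unmatched_auto), paste(utils::head(unmatched_auto, 10), collapse = ", ")))
  missed <- setdiff(manual$cell_id, records$object_id)
  joined <- merge(manual, records, by.x = "cell_id", by.y = "object_id")
  fp <- joined$manual_score < 1
  tp <- !fp
  manual_class <- .manual_score_to_class(joined$manual_score)
  mismatch <- tp & manual_class != joined$activation_class
  rho <- if (sum(tp) >= 3 && stats::sd(joined$manual_score[tp]) > 0 &&
             stats::sd(joined$morphology_ratio[tp]) > 0)
    spearman_correlation(joined$manual_score[tp], joined$morphology_ratio[tp])$rho
  else NA_real_
  structure(list(
    n_evaluated = nrow(joined),
    n_true_positive = sum(tp),
    n_false_positive = sum(fp),
    n_false_negative_detection = length(missed),
    n_score_mismatch = sum(mismatch),
    missed_ids = missed,
    unmatched_automated_ids = unmatched_auto,
    spearman_rho = rho
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<agreement_report> %d detections evaluated: %d true positive, %d false positive;\n",
    "  %d missed detections, %d score mismatches; Spearman rho (score vs ratio) = %s\n"),
    x$n_evaluated, x$n_true_positive, x$n_false_positive,
    x$n_false_negative_detection, x$n_score_mismatch,
    ifelse(is.na(x$spearman_rho), "NA", sprintf("%.3f", x$spearman_rho))))
  invisible(x)
}

#' Write an agreement report as CSV
#' @param report an `agreement_report`.
#' @param path output CSV path.
#' @export
write_agreement_csv <- function(report, path) {
  df <- data.frame(
    n_evaluated = report$n_evaluated,
    n_true_positive = report$n_true_positive,
    n_false_positive = report$n_false_positive,
    n_false_negative_detection = report$n_false_negative_detection,
    n_score_mismatch = report$n_score_mismatch,
    spearman_rho = report$spearman_rho
  )
  .write_csv(df, path)
  invisible(path)
}
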