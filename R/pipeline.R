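# Run configuration and the end-to-end analysis / validation pipelines.

#' Default run configuration
#'
#' Every tunable parameter of the pipeline with its effective default. A run
#' records the full effective configuration in its provenance log.
#'
#' @return named list of parameters.
#' @export
default_config <- function() {
  list(
    mode = "analyze",                  # analyze | validate
    modality = "fluorescence",         # fluorescence | chromogen
    pixel_size_um = 0.334,
    # binarisation
    weak_threshold = NULL,             # NULL = Otsu
    strong_threshold = NULL,           # NULL = weak + strong_scale * (max - weak)
    strong_scale = 0.5,
    closing_radius_um = 0.5,
    use_edges = TRUE,
    # mask correction
    min_structure_um2 = 10,
    max_hole_um2 = 10,
    # soma extraction
    thinning_iters = 3,
    soma_opening_um = 1.7,
    soma_dilation_um = 1.5,
    # nuclei
    min_nucleus_area_um2 = 5,
    watershed_tolerance = 1,
    nucleus_min_separation_um = 1,
    # morphometry
    min_spur_px = 4,
    # classification
    thresholds = NULL,                 # c(t_low, t_high); NULL = reference calibration
    histogram_edges = NULL,            # NULL = 12 equal bins over the observed range
    max_cluster_cells = 15,
    # validation mode
    sample_n = 30,
    seed = NULL,
    crop_pad_px = 10,
    out_dir = "gliamorph_out"
  )
}

.merge_config <- function(config) {
  utils::modifyList(default_config(), config %||% list())
}

#' Calibrate default activation thresholds on a synthetic reference scene
#'
#' The activation cutoffs on the morphology-ratio scale are a calibration
#' choice (they are study-specific dotted lines, not universal constants).
#' This bundles a reproducible default: a balanced synthetic reference scene
#' (equal numbers of ramified, intermediate and amoeboid cells) is generated,
#' analysed with the standard pipeline, and the terciles of the measured
#' single-cell morphology-ratio distribution become `(t_low, t_high)`. With a
#' balanced reference, the terciles fall in the gaps between the phenotype
#' ratio distributions.
#'
#' @param seed seed of the reference scene (default 20230208).
#' @param n_per_phenotype reference cells per phenotype (default 25).
#' @param config pipeline parameters (classification entries ignored).
#' @param phenotypes phenotype specifications for the reference.
#' @return numeric `c(t_low, t_high)`.
#' @export
calibrate_activation_thresholds <- function(seed = 20230208, n_per_phenotype = 25,
                                            config = list(),
                                            phenotypes = default_phenotypes()) {
  config <- .merge_config(config)
  scene <- generate_scene(
    n_per_phenotype = stats::setNames(rep(n_per_phenotype, 3),
                                      c("ramified", "intermediate", "amoeboid")),
    pixel_size_um = config$pixel_size_um, seed = seed, phenotypes = phenotypes)
  res <- measure_scene(scene$channels, config)
  ratios <- res$records$morphology_ratio[!res$records$is_cluster]
  ratios <- ratios[!is.na(ratios)]
  q <- unname(stats::quantile(ratios, c(1 / 3, 2 / 3), type = 7))
  # amoeboid cells give a point mass at ratio 0, which can pin a tercile onto
  # the tie; placing the cutoff halfway to the next distinct observed ratio
  # keeps the boundary inside the gap between phenotype distributions
  vapply(q, function(qi) {
    above <- ratios[ratios > qi]
    if (length(above)) (qi + min(above)) / 2 else qi
  }, numeric(1))
}

#' Segment and measure a channel set
#'
#' The measurement core shared by the analysis and validation modes:
#' (chromogen inversion ->) hysteresis binarisation -> mask correction ->
#' single-pixel bridge separation -> soma extraction -> nucleus detection ->
#' nucleus-overlap component assignment -> per-component skeletonisation and
#' morphometry. Classification is *not* applied here.
#'
#' @param channels a [channel_set] (for chromogen mode, the `glia_marker`
#'   slot holds the transmitted-light image with `modality = "chromogen"`).
#' @param config configuration list (see [default_config()]).
#' @param roi optional [roi_polygon] (or list of them) restricting the
#'   analysis.
#' @return list with `components`, `records`, per-stage `counts` and the
#'   intermediate `masks`.
#' @export
measure_scene <- function(channels, config = list(), roi = NULL) {
  stopifnot(inherits(channels, "channel_set"))
  config <- .merge_config(config)
  ps <- channels$glia_marker$pixel_size_um
  glia_img <- channels$glia_marker
  mode <- if (glia_img$modality == "chromogen") "chromogen" else "fluorescence"
  if (mode == "chromogen") glia_img <- chromogen_to_signal(glia_img)
  raw <- binarize_glia(glia_img, weak = config$weak_threshold,
                       strong = config$strong_threshold,
                       strong_scale = config$strong_scale,
                       closing_radius_um = config$closing_radius_um,
                       use_edges = config$use_edges)
  if (!is.null(roi)) {
    if (inherits(roi, "roi_polygon")) roi <- list(roi)
    roi_mask <- Reduce(`|`, lapply(roi, rasterize_roi, shape = dim(raw)))
    raw <- raw & roi_mask
  }
  cleaned <- clean_mask(raw, config$min_structure_um2, config$max_hole_um2, ps)
  separated <- separate_bridges(cleaned, config$min_structure_um2, ps)
  soma <- extract_somata(separated, config$thinning_iters, config$soma_opening_um,
                         config$soma_dilation_um, ps)
  nuclei <- NULL
  if (mode == "fluorescence") {
    if (is.null(channels$nucleus))
      stop("fluorescence mode requires the nucleus channel")
    nuclei <- detect_nuclei(channels$nucleus, config$min_nucleus_area_um2,
                            config$watershed_tolerance, config$nucleus_min_separation_um)
  }
  components <- assign_components(separated, soma, nuclei, mode = mode)
  components <- lapply(components, skeletonize_processes, min_spur_px = config$min_spur_px)
  records <- if (length(components))
    do.call(rbind, lapply(components, measure, channels = channels,
                          pixel_size_um = ps, min_spur_px = config$min_spur_px))
  else .empty_records()
  counts <- list(
    raw_components = .n_components(raw),
    cleaned_components = .n_components(cleaned),
    separated_components = .n_components(separated),
    nuclei = if (is.null(nuclei)) NA_integer_ else nrow(nuclei$centroids),
    components = length(components),
    single_cells = sum(!records$is_cluster),
    clusters = sum(records$is_cluster)
  )
  list(components = components, records = records, counts = counts,
       masks = list(glia = separated, soma = soma,
                    nuclei = if (is.null(nuclei)) NULL else nuclei$labels))
}

.resolve_thresholds <- function(config) {
  if (is.null(config$thresholds)) {
    message("no activation thresholds supplied; using the synthetic reference calibration")
    calibrate_activation_thresholds(config = config)
  } else .check_thresholds(config$thresholds)
}

.histogram_edges <- function(records, config) {
  if (!is.null(config$histogram_edges)) return(config$histogram_edges)
  r <- records$morphology_ratio
  hi <- max(c(r, 0), na.rm = TRUE)
  if (hi <= 0) hi <- 1
  seq(0, hi * (1 + 1e-9), length.out = 13)
}

#' Analyse a channel set end to end
#'
#' Runs [measure_scene()], classifies every object on the activation
#' continuum, applies the cluster-size filter, and builds the
#' morphology-ratio histograms for single cells, clusters and all cells.
#'
#' @inheritParams measure_scene
#' @return list with `components`, `records` (classified, cluster-filtered),
#'   `records_unfiltered`, `classes`, `histograms`, `thresholds`, `counts`.
#' @export
analyze_channels <- function(channels, config = list(), roi = NULL) {
  config <- .merge_config(config)
  res <- measure_scene(channels, config, roi)
  thresholds <- .resolve_thresholds(config)
  records <- classify_records(res$records, thresholds)
  filtered <- filter_clusters(records, config$max_cluster_cells)
  histograms <- build_histograms(filtered, .histogram_edges(filtered, config))
  res$counts$removed_oversized_clusters <- attr(filtered, "n_removed")
  list(components = res$components, records = filtered,
       records_unfiltered = records,
       classes = records$activation_class, histograms = histograms,
       thresholds = thresholds, counts = res$counts, masks = res$masks)
}

.run_log <- function(config, counts, extra = list()) {
  c(list(
    package = "gliamorph",
    version = as.character(utils::packageVersion("gliamorph")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = NA,  # deliberately constant: run logs must be byte-reproducible
    config = config[order(names(config))],
    stage_counts = counts
  ), extra)
}

#' Run the full analysis mode against files on disk
#'
#' Reads the configured channels, analyses them, and writes: the four result
#' CSVs, the colour-coded overlay PNG, 10%-scale channel previews, and a
#' machine-readable provenance log (`run_log.json`) with the effective
#' configuration and per-stage object counts.
#'
#' @param config configuration list; must contain `glia_path` (and
#'   `nucleus_path` for fluorescence mode; optionally `cd68_path`,
#'   `roi_path`), plus any overrides of [default_config()].
#' @return invisibly, the output directory.
#' @export
run_analyze <- function(config) {
  config <- .merge_config(config)
  if (is.null(config$glia_path)) stop("config$glia_path is required")
  channels <- .read_channels(config)
  roi <- if (!is.null(config$roi_path)) read_roi_json(config$roi_path) else NULL
  res <- analyze_channels(channels, config, roi)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_results(res$records[!res$records$is_cluster, , drop = FALSE],
                res$records[res$records$is_cluster, , drop = FALSE],
                res$histograms, out)
  write_overlay(channels, res$components, res$records_unfiltered$activation_class,
                file.path(out, "overlay.png"))
  prev <- downscale_preview(channels$glia_marker, 0.1)
  write_channel_tiff(prev, file.path(out, "glia_preview.tif"))
  config$thresholds <- res$thresholds
  jsonlite::write_json(.run_log(config, res$counts), file.path(out, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  if (res$counts$components == 0) warning("no cells detected in the image")
  invisible(out)
}

#' Run the validation mode against files on disk
#'
#' Same preprocessing as the analysis mode, followed by seeded random
#' sampling of single cells, export of colour-coded per-cell crops and a
#' sample manifest; when a manual-score CSV (`cell_id, rep1, rep2, rep3`) is
#' supplied, an agreement report is computed and written.
#'
#' @param config configuration list; requires `glia_path`, `sample_n` and
#'   `seed`; optional `manual_scores_path`.
#' @return invisibly, the output directory.
#' @export
run_validate <- function(config) {
  config <- .merge_config(config)
  if (is.null(config$seed)) stop("validation mode requires config$seed")
  if (is.null(config$glia_path)) stop("config$glia_path is required")
  channels <- .read_channels(config)
  roi <- if (!is.null(config$roi_path)) read_roi_json(config$roi_path) else NULL
  res <- analyze_channels(channels, config, roi)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  sample <- sample_cells(res$components, config$sample_n, config$seed,
                         classes = res$records_unfiltered$activation_class,
                         pad_px = config$crop_pad_px)
  crop_dir <- file.path(out, "crops")
  paths <- export_crops(sample, channels, res$components, crop_dir)
  manifest <- data.frame(cell_id = sample$ids, activation_class = sample$classes,
                         file = basename(paths))
  .write_csv(manifest, file.path(out, "sample_manifest.csv"))
  extra <- list(sample_seed = config$seed, sample_n = length(sample$ids))
  if (!is.null(config$manual_scores_path)) {
    manual <- utils::read.csv(config$manual_scores_path)
    singles <- res$records_unfiltered[!res$records_unfiltered$is_cluster, , drop = FALSE]
    report <- score_agreement(manual, singles[singles$object_id %in% sample$ids, , drop = FALSE])
    write_agreement_csv(report, file.path(out, "agreement.csv"))
    extra$agreement <- unclass(report)[c("n_evaluated", "n_true_positive",
                                         "n_false_positive", "n_false_negative_detection",
                                         "n_score_mismatch", "spearman_rho")]
  }
  config$thresholds <- res$thresholds
  jsonlite::write_json(.run_log(config, res$counts, extra), file.path(out, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(out)
}

.read_channels <- function(config) {
  modality <- config$modality
  ps <- config$pixel_size_um
  if (modality == "chromogen") {
    glia <- read_channel(config$glia_path, ps, "chromogen", "transmitted")
    return(channel_set(glia_marker = glia))
  }
  glia <- read_channel(config$glia_path, ps, "fluorescence", "glia_marker")
  nucleus <- if (!is.null(config$nucleus_path))
    read_channel(config$nucleus_path, ps, "fluorescence", "nucleus") else NULL
  cd68 <- if (!is.null(config$cd68_path))
    read_channel(config$cd68_path, ps, "fluorescence", "activation_marker") else NULL
  if (is.null(nucleus))
    stop("fluorescence mode requires the nucleus channel (config$nucleus_path)")
  channel_set(glia_marker = glia, nucleus = nucleus, activation_marker = cd68)
}
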