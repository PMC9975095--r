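# Activation classification along the morphology-ratio continuum, cluster
# filtering, ratio histograms, and the descriptive statistics reported with
# them (log-shift transforms, geometric mean ratios, Spearman correlations).

.activation_levels <- c("activated", "intermediate", "non_activated")

.check_thresholds <- function(thresholds) {
  if (!is.numeric(thresholds) || length(thresholds) != 2 ||
      any(!is.finite(thresholds)) || thresholds[1] >= thresholds[2])
    stop("`thresholds` must be c(t_low, t_high) with t_low < t_high")
  thresholds
}

#' Classify morphology ratios into activation classes
#'
#' Three-way split of the continuous activation scale: `activated` when the
#' ratio is below `t_low`, `intermediate` when `t_low <= ratio <= t_high`
#' (both boundaries inclusive), `non_activated` above `t_high`. Degenerate
#' records (zero soma area, missing ratio) classify as `activated` -- a cell
#' reduced to processes-free debris is at the terminal end of the scale.
#'
#' @param ratio numeric vector of morphology ratios (`NA` = degenerate).
#' @param thresholds `c(t_low, t_high)` in morphology-ratio units
#'   (um of process length per um^2 of soma). The scale's cutoffs are a
#'   calibration choice; see [calibrate_activation_thresholds()] for the
#'   bundled reference calibration.
#' @return factor with levels activated, intermediate, non_activated.
#' @export
classify <- function(ratio, thresholds) {
  .check_thresholds(thresholds)
  out <- ifelse(is.na(ratio) | ratio < thresholds[1], "activated",
                ifelse(ratio <= thresholds[2], "intermediate", "non_activated"))
  factor(out, levels = .activation_levels)
}

#' Classify a table of morphometry records
#'
#' @param records data frame with a `morphology_ratio` column.
#' @inheritParams classify
#' @return `records` with `activation_class` filled in.
#' @export
classify_records <- function(records, thresholds) {
  records$activation_class <- as.character(classify(records$morphology_ratio, thresholds))
  records
}

#' Drop oversized cell clusters
#'
#' Retains records whose estimated cell count is at most `max_cells`; single
#' cells are always retained. Oversized clusters are extreme outliers that
#' otherwise dominate log-scale summaries. The number of removed records is
#' attached as attribute `n_removed`.
#'
#' @param records data frame carrying `n_cells` and `is_cluster`.
#' @param max_cells largest cluster size kept (default 15).
#' @return filtered records (idempotent).
#' @export
filter_clusters <- function(records, max_cells = 15L) {
  if (!is.numeric(max_cells) || length(max_cells) != 1 || max_cells < 1)
    stop("`max_cells` must be a single integer >= 1")
  keep <- !records$is_cluster | records$n_cells <= max_cells
  out <- records[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

.one_histogram <- function(x, bin_edges, stratum) {
  k <- length(bin_edges) - 1L
  if (length(x)) {
    x <- pmin(pmax(x, bin_edges[1]), bin_edges[length(bin_edges)])
    bins <- findInterval(x, bin_edges, rightmost.closed = TRUE)
    counts <- tabulate(bins, nbins = k)
  } else counts <- integer(k)
  structure(list(stratum = stratum, bin_edges = bin_edges, counts = counts),
            class = "ratio_histogram")
}

#' Morphology-ratio histograms by stratum
#'
#' Groups records into histograms for single cells, cell clusters, and all
#' cells. Interior bins are half-open `[e_i, e_{i+1})` (a ratio exactly on an
#' interior edge goes to the right bin); the last bin is right-inclusive.
#' Ratios outside the edge range are clamped into the first/last bin so that
#' counts always sum to the number of records; degenerate records (missing
#' ratio) count in the first bin.
#'
#' @param records data frame with `morphology_ratio` and `is_cluster`.
#' @param bin_edges strictly increasing numeric vector of edges.
#' @return list of three `ratio_histogram` objects named `single_cells`,
#'   `clusters`, `all`.
#' @export
build_histograms <- function(records, bin_edges) {
  if (!is.numeric(bin_edges) || length(bin_edges) < 2 || any(diff(bin_edges) <= 0))
    stop("`bin_edges` must be strictly increasing")
  ratio <- records$morphology_ratio
  ratio[is.na(ratio)] <- bin_edges[1]
  list(
    single_cells = .one_histogram(ratio[!records$is_cluster], bin_edges, "single_cells"),
    clusters     = .one_histogram(ratio[records$is_cluster], bin_edges, "clusters"),
    all          = .one_histogram(ratio, bin_edges, "all")
  )
}

#' Shifted natural-log transform
#'
#' `log(value + shift)`. Count-like outcomes that contain zeros (the number of
#' process endpoints) are shifted by 0.5 before the log; other log-transformed
#' outcomes use shift 0.
#'
#' @param values numeric vector.
#' @param shift added before taking the log (default 0).
#' @return transformed vector.
#' @export
log_shift_transform <- function(values, shift = 0) {
  bad <- which(values + shift <= 0)
  if (length(bad))
    stop(sprintf("log_shift_transform: non-positive argument at index %d", bad[1]))
  log(values + shift)
}

#' Geometric mean ratio between two groups
#'
#' `exp(mean(log(a)) - mean(log(b)))`: the fold change of group A relative to
#' group B on the original scale. A ratio of 1.5 corresponds to a 50%
#' increase, 0.5 to a 50% decrease.
#'
#' @param group_a,group_b positive numeric vectors.
#' @return the GMR (a single positive number).
#' @export
geometric_mean_ratio <- function(group_a, group_b) {
  if (any(group_a <= 0) || any(group_b <= 0))
    stop("geometric_mean_ratio requires strictly positive values")
  exp(mean(log(group_a)) - mean(log(group_b)))
}

#' Spearman rank correlation with a Fisher-z confidence interval
#'
#' Rank correlation with average ranks for ties. The confidence interval uses
#' the Fisher z-transform with the Fieller-Hartley-Pearson variance
#' `1.06 / (n - 3)` appropriate for Spearman's rho.
#'
#' @param x,y equal-length paired numeric vectors, `n >= 3`.
#' @param conf_level confidence level (default 0.95).
#' @return list with `rho`, `conf_low`, `conf_high`, `n`. A constant input
#'   vector makes rho undefined; it is reported as `NA` with a warning.
#' @export
spearman_correlation <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("spearman_correlation requires n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined, reported as NA")
    return(list(rho = NA_real_, conf_low = NA_real_, conf_high = NA_real_, n = n))
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (n > 3 && abs(rho) < 1) {
    z <- atanh(rho)
    se <- sqrt(1.06 / (n - 3))
    q <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- tanh(c(z - q * se, z + q * se))
  } else ci <- c(NA_real_, NA_real_)
  list(rho = rho, conf_low = ci[1], conf_high = ci[2], n = n)
}

# Mapping between the 4-point manual morphology score and the 3-class
# automated scheme, used for agreement scoring only: score 4 (fully amoeboid)
# is activated, scores 2-3 intermediate, score 1 (ramified) non-activated.
.manual_score_to_class <- function(score) {
  ifelse(score >= 4, "activated", ifelse(score >= 2, "intermediate",
                                         ifelse(score >= 1, "non_activated", NA_character_)))
}
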