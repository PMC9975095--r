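# Optical-fractionator arithmetic, used to benchmark automated 2D counts
# against stereology-style volumetric estimates.

#' Optical-fractionator sampling fractions
#'
#' `ssf = 1/section_period` (every k-th section), `asf = (frame/grid)^2` (the
#' counting frame over the sampling grid, both given as side lengths), and
#' `hsf = dissector_height/section_thickness`.
#'
#' @param section_period positive integer: every `section_period`-th section
#'   is sampled.
#' @param grid_side_um,frame_side_um side lengths of the sampling grid and the
#'   counting frame (frame <= grid).
#' @param dissector_height_um,section_thickness_um optical dissector height
#'   and mounted section thickness (height <= thickness).
#' @return named list `ssf`, `asf`, `hsf`, all in (0, 1].
#' @export
sampling_fractions <- function(section_period, grid_side_um, frame_side_um,
                               dissector_height_um, section_thickness_um) {
  if (!is.numeric(section_period) || section_period < 1 ||
      section_period != round(section_period))
    stop("`section_period` must be a positive integer")
  if (grid_side_um <= 0 || frame_side_um <= 0 || dissector_height_um <= 0 ||
      section_thickness_um <= 0)
    stop("all lengths must be positive")
  if (frame_side_um > grid_side_um) stop("counting frame must not exceed the grid")
  if (dissector_height_um > section_thickness_um)
    stop("dissector height must not exceed section thickness")
  list(ssf = 1 / section_period,
       asf = (frame_side_um / grid_side_um)^2,
       hsf = dissector_height_um / section_thickness_um)
}

#' Fractionator parameter bundle
#' @param ssf,asf,hsf sampling fractions in (0, 1].
#' @param q_counted total cells counted in the dissectors (sum of Q-, >= 0).
#' @return object of class `fractionator_params`.
#' @export
fractionator_params <- function(ssf, asf, hsf, q_counted) {
  for (f in c(ssf = ssf, asf = asf, hsf = hsf))
    if (!is.numeric(f) || f <= 0 || f > 1) stop("sampling fractions must be in (0, 1]")
  if (q_counted < 0 || q_counted != round(q_counted)) stop("`q_counted` must be an integer >= 0")
  structure(list(ssf = ssf, asf = asf, hsf = hsf, q_counted = as.integer(q_counted)),
            class = "fractionator_params")
}

#' Optical-fractionator total-count estimate
#'
#' `N = q_counted / (ssf * asf * hsf)`: the counted cells scaled up by the
#' inverse of the overall sampling fraction.
#'
#' @param params a [fractionator_params] bundle.
#' @return estimated total cell count.
#' @export
fractionator_estimate <- function(params) {
  stopifnot(inherits(params, "fractionator_params"))
  params$q_counted / (params$ssf * params$asf * params$hsf)
}
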