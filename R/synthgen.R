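# Synthetic microglia scenes with exact ground truth.
#
# Cells are built generatively: a rasterised soma disc plus persistent random
# walks for the processes, with per-step branching. Every truth quantity
# (soma area, total process length, endpoint and branch-point counts) is
# computed from the constructed geometry -- the drawn pixel paths -- never
# from the rendered image. Walks obey exclusion constraints (new path pixels
# keep a Euclidean distance >= 8 from other branches, and >= 3 px from the
# soma once they have left it) so that a tip of the drawn geometry is still a tip
# after the rendered tube is re-skeletonised. A walker that runs out of
# admissible moves is committed early if it has drawn at least 12 pixels (its
# last pixel is then a valid, soma-clear tip); below that it is erased and
# excluded from the truth.

#' Phenotype specification for the synthetic generator
#'
#' Ranges are sampled uniformly per cell. The bundled defaults emulate the
#' ramified-to-amoeboid activation continuum: ramified cells have small somata
#' and many long thin branching processes and low activation marker; amoeboid
#' cells have large somata, at most one stubby process and a high activation
#' marker; intermediate cells sit between. Process lengths below ~5 um are
#' avoided by the defaults because at 0.334 um/px the +-2 px discretisation of
#' skeleton ends would dominate shorter processes.
#'
#' @param label one of `"ramified"`, `"intermediate"`, `"amoeboid"`.
#' @param soma_radius_um range (min, max) of soma radius in micrometres.
#' @param n_processes integer range of primary processes.
#' @param process_length_um range of per-process target length.
#' @param branch_prob_per_step probability of spawning a side branch at each
#'   walk step (one step is about one pixel).
#' @param process_width_um rendered process diameter.
#' @param cd68_level activation-marker intensity rendered over the soma.
#' @return object of class `phenotype_spec`.
#' @export
phenotype_spec <- function(label, soma_radius_um, n_processes, process_length_um,
                           branch_prob_per_step, process_width_um, cd68_level) {
  stopifnot(length(soma_radius_um) == 2, length(n_processes) == 2,
            length(process_length_um) == 2,
            branch_prob_per_step >= 0, branch_prob_per_step < 1)
  structure(list(label = label, soma_radius_um = soma_radius_um,
                 n_processes = n_processes, process_length_um = process_length_um,
                 branch_prob_per_step = branch_prob_per_step,
                 process_width_um = process_width_um, cd68_level = cd68_level),
            class = "phenotype_spec")
}

#' Default phenotype specifications
#'
#' @return named list of [phenotype_spec] for the ramified, intermediate and
#'   amoeboid phenotypes.
#' @export
default_phenotypes <- function() {
  list(
    ramified = phenotype_spec("ramified",
      soma_radius_um = c(3.2, 4.5), n_processes = c(4L, 6L),
      process_length_um = c(15, 30), branch_prob_per_step = 0.03,
      process_width_um = 1.0, cd68_level = 8),
    intermediate = phenotype_spec("intermediate",
      soma_radius_um = c(4.2, 6.0), n_processes = c(2L, 4L),
      process_length_um = c(8, 15), branch_prob_per_step = 0.01,
      process_width_um = 1.0, cd68_level = 40),
    amoeboid = phenotype_spec("amoeboid",
      soma_radius_um = c(5.5, 8.0), n_processes = c(0L, 1L),
      process_length_um = c(5, 8), branch_prob_per_step = 0,
      process_width_um = 1.0, cd68_level = 120)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The 8 step directions, their angles and lengths.
.dirs <- cbind(dr = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
               dc = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L))
.dir_angles <- atan2(.dirs[, 1], .dirs[, 2])
.dir_len <- sqrt(rowSums(.dirs^2))

.ang_dist <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

.pix_key <- function(r, c) r * 1e5 + c

# Exclusion radius between different branches, in pixels (Euclidean,
# centreline to centreline). Paths are rendered as 3-px-wide tubes and the
# binarisation closes with a 1-px disc, which can bridge tube-surface gaps up
# to ~4 px (more where a rounded tube cap faces another tube); a centreline
# distance of 8 keeps surfaces > 5 px apart in every direction, so distinct
# branches can never fuse and drawn tips stay tips.
.walk_excl_px <- 8

# 17x17 window of offsets within the exclusion radius
.walk_excl_win <- local({
  d <- expand.grid(dr = -8:8, dc = -8:8)
  d[sqrt(d$dr^2 + d$dc^2) < .walk_excl_px, ]
})

# Can the walker place a pixel at (r, c)? occ: 0 empty, 1 soma, 2 process.
# Foreign process pixels inside the exclusion radius are forbidden unless
# exempt: the walker's immediate tail (`recent`, last 6 pixels) and its
# branch-origin corridor (`allow_set`) are fully exempt; slightly older own
# pixels (`near`, 7-12 steps back) may be approached -- a mildly curving walk
# sweeps them through the exclusion radius -- but not closer than 6 px, which
# keeps the closed, rendered tube from bridging onto itself. The soma exclusion uses a
# Chebyshev <= 6 window (the recovered soma can reach a pixel past the disc,
# and its measurement zone three more) and is suspended while the walker is
# still leaving the soma.
.step_ok <- function(occ, r, c, recent, near, allow_soma, allow_set) {
  n <- nrow(occ)
  if (r < 9 || c < 9 || r > n - 8 || c > n - 8) return(FALSE)
  if (occ[r, c] != 0L) return(FALSE)
  if (!allow_soma && any(occ[(r - 6):(r + 6), (c - 6):(c + 6)] == 1L)) return(FALSE)
  hr <- r + .walk_excl_win$dr
  hc <- c + .walk_excl_win$dc
  hit <- which(occ[cbind(hr, hc)] == 2L)
  for (i in hit) {
    key <- .pix_key(hr[i], hc[i])
    if (key %in% recent || key %in% allow_set) next
    if (key %in% near &&
        (hr[i] - r)^2 + (hc[i] - c)^2 >= 36) next
    return(FALSE)
  }
  TRUE
}

# Minimum committed walker length in pixels. Anything shorter is erased from
# the canvas and from the truth: a stub this short would sit inside the
# soma-root exclusion zone of the measurement and its tip would be
# ambiguous. The soma-proximity grace (allow_soma) ends well before this, so
# every committed walker's tip pixel has passed the soma-distance check.
.walk_commit_min <- 12L

# Run one walker; side branches are run inline at the branch point, so the
# parent and child avoid each other from then on (with a mutual exemption in
# the immediate neighbourhood of the branch origin).
# Returns list(occ, committed, pixels, length_px, n_tips, n_branch).
.run_walker <- function(occ, start, heading, budget_px, branch_prob,
                        primary, allow_set, depth = 0L, centre = NULL) {
  pixels <- NULL
  lens <- numeric(0)     # per-pixel link weights, for trimming
  r <- start[1]; c <- start[2]
  step <- 0L
  last_branch <- 0L
  branch_at <- NULL      # c(pixel index, origin r, origin c) of last committed branch
  length_px <- 0
  own <- numeric(0)      # all own pixel keys, in walk order
  n_tips <- 0L
  n_branch <- 0L
  child_pixels <- NULL
  if (primary) {
    # draw the root pixel itself (already admissibility-checked by the caller);
    # its link to the soma is not part of the process skeleton, weight 0
    occ[r, c] <- 2L
    pixels <- matrix(c(r, c), 1, 2)
    lens <- 0
    own <- .pix_key(r, c)
    step <- 1L
  }
  while (length_px < budget_px) {
    heading <- heading + stats::rnorm(1, 0, 0.15)
    if (!is.null(centre) && step < 12L) {
      # young primary processes grow radially away from the soma; without the
      # outward pull a jittering walker can skim the boundary, where the
      # recovered soma would swallow its first pixels
      radial <- atan2(r - centre[1], c - centre[2])
      heading <- atan2(0.75 * sin(heading) + 0.25 * sin(radial),
                       0.75 * cos(heading) + 0.25 * cos(radial))
    }
    ord <- order(.ang_dist(.dir_angles, heading))[1:3]
    placed <- FALSE
    no <- length(own)
    recent <- own[max(1, no - 5):max(1, no)]
    near <- if (no > 6) own[max(1, no - 11):(no - 6)] else numeric(0)
    for (k in ord) {
      nr <- r + .dirs[k, 1]; nc <- c + .dirs[k, 2]
      if (.step_ok(occ, nr, nc, recent, near,
                   allow_soma = step < 8L, allow_set = allow_set)) {
        occ[nr, nc] <- 2L
        pixels <- rbind(pixels, c(nr, nc))
        lens <- c(lens, .dir_len[k])
        length_px <- length_px + .dir_len[k]
        own <- c(own, .pix_key(nr, nc))
        heading <- 0.35 * .dir_angles[k] + 0.65 * heading
        r <- nr; c <- nc
        step <- step + 1L
        placed <- TRUE
        break
      }
    }
    if (!placed) break
    if (branch_prob > 0 && depth < 3L && step - last_branch >= 10L &&
        step >= .walk_commit_min &&
        budget_px - length_px >= .walk_commit_min + 2 &&
        stats::runif(1) < branch_prob) {
      side <- if (stats::runif(1) < 0.5) -1 else 1
      child_budget <- (budget_px - length_px) * stats::runif(1, 0.5, 0.8)
      soma_near <- any(occ[max(1, r - 10):min(nrow(occ), r + 10),
                           max(1, c - 10):min(ncol(occ), c + 10)] == 1L)
      if (child_budget >= .walk_commit_min && !soma_near) {
        # the child may use the parent's corridor around the branch origin
        # while it diverges (and nothing else: inheriting older exemptions
        # would let it die inside a previous branch's corridor); the wide
        # branch angle gets it clear of the exclusion radius in time
        near <- pixels[abs(pixels[, 1] - r) <= 8 & abs(pixels[, 2] - c) <= 8, , drop = FALSE]
        res <- .run_walker(occ, c(r, c),
                           heading + side * stats::runif(1, 0.8, 1.3),
                           child_budget, branch_prob, primary = FALSE,
                           allow_set = .pix_key(near[, 1], near[, 2]),
                           depth = depth + 1L)
        occ <- res$occ
        if (res$committed) {
          n_branch <- n_branch + 1L + res$n_branch
          n_tips <- n_tips + res$n_tips
          length_px <- length_px + res$length_px
          child_pixels <- rbind(child_pixels, res$pixels)
          # let the parent continue past its child's first pixels
          cn <- res$pixels[abs(res$pixels[, 1] - r) <= 8 &
                           abs(res$pixels[, 2] - c) <= 8, , drop = FALSE]
          allow_set <- c(allow_set, .pix_key(cn[, 1], cn[, 2]))
          last_branch <- step
          branch_at <- c(nrow(pixels), r, c)
        }
      }
    }
  }
  if (!primary && !is.null(pixels)) {
    # a side branch that never escaped its origin corridor -- or whose tip
    # stopped next to an exempted parent pixel -- would have its tip fused
    # into the parent tube; erase such branches entirely
    ar <- allow_set %/% 1e5
    ac <- allow_set %% 1e5
    if (max(abs(r - start[1]), abs(c - start[2])) < 13 ||
        (length(allow_set) && min((ar - r)^2 + (ac - c)^2) < 64)) {
      occ[pixels] <- 0L
      return(list(occ = occ, committed = FALSE, pixels = NULL,
                  length_px = 0, n_tips = 0L, n_branch = 0L))
    }
  }
  own_tip <- 1L
  if (!is.null(branch_at) &&
      max(abs(r - branch_at[2]), abs(c - branch_at[3])) <= 12) {
    # the walker ended too close to its last branch point: the stub past the
    # junction would be swallowed by the junction blob and spur pruning, so
    # trim it back to the origin -- the branch point dissolves into a plain
    # continuation of the path
    idx <- branch_at[1]
    if (nrow(pixels) > idx) {
      drop <- (idx + 1L):nrow(pixels)
      occ[pixels[drop, , drop = FALSE]] <- 0L
      length_px <- length_px - sum(lens[drop])
      pixels <- pixels[seq_len(idx), , drop = FALSE]
    }
    own_tip <- 0L
    n_branch <- n_branch - 1L
  }
  committed <- !is.null(pixels) && nrow(pixels) >= .walk_commit_min
  if (!committed) {
    # erase the stub; committed children are impossible here because
    # branching requires step >= .walk_commit_min
    if (!is.null(pixels)) occ[pixels] <- 0L
    return(list(occ = occ, committed = FALSE, pixels = NULL,
                length_px = 0, n_tips = 0L, n_branch = 0L))
  }
  list(occ = occ, committed = TRUE, pixels = rbind(pixels, child_pixels),
       length_px = length_px, n_tips = n_tips + own_tip, n_branch = n_branch)
}

#' Generate one synthetic cell
#'
#' Draws phenotype parameters from the spec ranges (using the current RNG
#' stream) and constructs the cell geometry: a rasterised soma disc and
#' branching random-walk process paths. The returned truth fields are exact
#' properties of that geometry: the soma area is the disc's pixel count times
#' the pixel area, the process length is the sum of drawn step lengths
#' (orthogonal 1 px, diagonal sqrt(2) px; a side branch's link to its parent
#' counts, a primary process's root link to the soma does not), endpoints are
#' the committed walker tips, branch points the committed branch events.
#'
#' @param spec a [phenotype_spec].
#' @param pixel_size_um pixel size of the target scene (default 0.334 um, a
#'   typical 20x high-content objective).
#' @return list with `soma` and `process` (k x 2 matrices of pixel coords
#'   relative to the soma centre), `width_px`, `extent` (half-width of the
#'   local canvas) and `truth`.
#' @export
generate_cell <- function(spec, pixel_size_um = 0.334) {
  stopifnot(inherits(spec, "phenotype_spec"))
  ps <- pixel_size_um
  r_um <- stats::runif(1, spec$soma_radius_um[1], spec$soma_radius_um[2])
  r_px <- r_um / ps
  n_proc <- if (spec$n_processes[2] > spec$n_processes[1])
    sample(spec$n_processes[1]:spec$n_processes[2], 1) else spec$n_processes[1]
  # a walk can reach at most its length budget beyond its root
  half <- as.integer(ceiling(r_px + spec$process_length_um[2] / ps + 7))
  n <- 2L * half + 1L
  ctr <- half + 1L
  occ <- matrix(0L, n, n)
  dr2 <- outer(((1:n) - ctr)^2, rep(1, n))
  soma_sel <- dr2 + t(dr2) <= r_px^2
  occ[soma_sel] <- 1L
  total_len_px <- 0
  n_tips <- 0L
  n_branch <- 0L
  n_committed_proc <- 0L
  proc_pixels <- NULL
  base_angle <- stats::runif(1, 0, 2 * pi)
  for (i in seq_len(n_proc)) {
    ang <- base_angle + (i - 1) * 2 * pi / max(1, n_proc) + stats::rnorm(1, 0, 0.12)
    budget <- stats::runif(1, spec$process_length_um[1], spec$process_length_um[2]) / ps
    # root pixel: first lattice point just outside the disc along the ray
    d <- r_px + 1
    repeat {
      sr <- ctr + as.integer(round(d * sin(ang)))
      sc <- ctr + as.integer(round(d * cos(ang)))
      if (!soma_sel[sr, sc]) break
      d <- d + 0.5
    }
    if (!.step_ok(occ, sr, sc, recent = numeric(0), near = numeric(0),
                  allow_soma = TRUE, allow_set = numeric(0))) next
    res <- .run_walker(occ, c(sr, sc), ang, budget, spec$branch_prob_per_step,
                       primary = TRUE, allow_set = numeric(0), centre = c(ctr, ctr))
    occ <- res$occ
    if (res$committed) {
      n_committed_proc <- n_committed_proc + 1L
      total_len_px <- total_len_px + res$length_px
      n_tips <- n_tips + res$n_tips
      n_branch <- n_branch + res$n_branch
      proc_pixels <- rbind(proc_pixels, res$pixels)
    }
  }
  soma_idx <- which(soma_sel, arr.ind = TRUE)
  list(
    soma = cbind(soma_idx[, 1] - ctr, soma_idx[, 2] - ctr),
    process = if (is.null(proc_pixels)) matrix(integer(0), 0, 2)
              else cbind(proc_pixels[, 1] - ctr, proc_pixels[, 2] - ctr),
    width_px = max(1L, as.integer(round(spec$process_width_um / ps))),
    extent = half,
    truth = list(
      phenotype = spec$label,
      soma_radius_um = r_um,
      soma_area_um2 = sum(soma_sel) * ps^2,
      process_length_um = total_len_px * ps,
      n_processes = n_committed_proc,
      n_endpoints = n_tips,
      n_branchpoints = n_branch,
      cd68_level = spec$cd68_level
    )
  )
}

.paint_disc <- function(mask, r0, c0, radius_px) {
  rad <- ceiling(radius_px)
  rs <- max(1, r0 - rad):min(nrow(mask), r0 + rad)
  cs <- max(1, c0 - rad):min(ncol(mask), c0 + rad)
  sub <- outer((rs - r0)^2, (cs - c0)^2, `+`) <= radius_px^2
  mask[rs, cs] <- mask[rs, cs] | sub
  mask
}

#' Generate a synthetic scene with ground truth
#'
#' Places cells (and optional forced-contact clusters) on a jittered grid with
#' a minimum separation, renders the three fluorescence channels (glia
#' marker, nuclei, activation marker) with optional Gaussian blur and additive
#' noise, and returns the channel set together with the exact per-cell ground
#' truth. With `blur_sigma_um = 0` and `noise_sd = 0` the rendered glia
#' channel is exactly `signal_level` on the geometric cell mask and 0
#' elsewhere.
#'
#' @param n_per_phenotype named integer vector, e.g.
#'   `c(ramified = 10, intermediate = 5, amoeboid = 5)`; names must match
#'   entries of `phenotypes`.
#' @param cluster_spec optional list of cluster descriptors, each a list with
#'   `n_cells` and `phenotype`: the member somata are chained with overlapping
#'   discs so the rendered masks form one connected structure while their
#'   nuclei stay separate.
#' @param image_size optional `c(rows, cols)`; computed from the content when
#'   `NULL`. If given and the cells cannot be placed at the required
#'   separation, the call is rejected.
#' @param pixel_size_um pixel size (default 0.334).
#' @param noise list with `blur_sigma_um` (Gaussian point-spread blur),
#'   `noise_sd` (additive Gaussian noise), `background` (constant offset);
#'   defaults 0.4 / 4 / 6.
#' @param seed integer seed; the full scene (geometry and noise) is a pure
#'   function of it.
#' @param phenotypes named list of [phenotype_spec].
#' @param signal_level rendered glia-marker intensity (default 180);
#'   nucleus discs render at 200.
#' @param nucleus_radius_um rendered nucleus disc radius (default 2.2).
#' @return object of class `glia_scene`: `channels` (a [channel_set]),
#'   `truth` (data frame, one row per cell), `seed`, `noise`,
#'   `pixel_size_um`.
#' @export
generate_scene <- function(n_per_phenotype = c(ramified = 8, intermediate = 6, amoeboid = 6),
                           cluster_spec = NULL, image_size = NULL,
                           pixel_size_um = 0.334,
                           noise = list(blur_sigma_um = 0.4, noise_sd = 4, background = 6),
                           seed = 1L, phenotypes = default_phenotypes(),
                           signal_level = 180, nucleus_radius_um = 2.2) {
  noise <- utils::modifyList(list(blur_sigma_um = 0.4, noise_sd = 4, background = 6), noise)
  stopifnot(all(names(n_per_phenotype) %in% names(phenotypes)))
  ps <- pixel_size_um
  .with_seed(seed, {
    units <- list()
    for (ph in names(n_per_phenotype)) {
      for (i in seq_len(n_per_phenotype[[ph]]))
        units[[length(units) + 1]] <- list(kind = "cell", phenotype = ph)
    }
    if (!is.null(cluster_spec)) {
      for (cl in cluster_spec)
        units[[length(units) + 1]] <- list(kind = "cluster",
                                           n_cells = cl$n_cells, phenotype = cl$phenotype)
    }
    if (!length(units)) stop("empty scene requested")
    units <- units[sample.int(length(units))]
    geoms <- lapply(units, function(u) {
      if (u$kind == "cell") {
        g <- generate_cell(phenotypes[[u$phenotype]], ps)
        list(cells = list(g), offsets = list(c(0, 0)), extent = g$extent)
      } else {
        cells <- replicate(u$n_cells, generate_cell(phenotypes[[u$phenotype]], ps),
                           simplify = FALSE)
        # chain the somata along a gently curving line with overlapping discs
        offs <- vector("list", u$n_cells)
        offs[[1]] <- c(0, 0)
        ang <- stats::runif(1, 0, 2 * pi)
        if (u$n_cells > 1) {
          for (j in 2:u$n_cells) {
            gap <- (cells[[j - 1]]$truth$soma_radius_um + cells[[j]]$truth$soma_radius_um) * 0.85 / ps
            ang <- ang + stats::rnorm(1, 0, 0.35)
            offs[[j]] <- offs[[j - 1]] + c(gap * sin(ang), gap * cos(ang))
          }
        }
        offs <- lapply(offs, round)
        ext <- max(vapply(seq_along(cells), function(j)
          max(abs(offs[[j]])) + cells[[j]]$extent, numeric(1)))
        list(cells = cells, offsets = offs, extent = ext)
      }
    })
    pitch <- 2L * max(vapply(geoms, `[[`, numeric(1), "extent")) + 9L
    ncols <- ceiling(sqrt(length(geoms)))
    nrows <- ceiling(length(geoms) / ncols)
    need <- c(nrows, ncols) * pitch + 2L
    if (is.null(image_size)) {
      image_size <- need
    } else if (any(image_size < need)) {
      stop(sprintf("requested density impossible: %d unit(s) need at least %d x %d px",
                   length(geoms), need[1], need[2]))
    }
    glia <- matrix(FALSE, image_size[1], image_size[2])
    nuc <- matrix(FALSE, image_size[1], image_size[2])
    cd68 <- matrix(0, image_size[1], image_size[2])
    truth <- list()
    cell_id <- 0L
    for (ui in seq_along(geoms)) {
      gi <- (ui - 1L) %/% ncols
      gj <- (ui - 1L) %% ncols
      ext <- geoms[[ui]]$extent
      slack <- max(0L, pitch - 2L * ext - 10L)  # stay inside the grid slot
      jit <- if (slack > 0) sample(0:slack, 2, replace = TRUE) else c(0L, 0L)
      base_r <- gi * pitch + ext + 5L + jit[1]
      base_c <- gj * pitch + ext + 5L + jit[2]
      cluster_id <- if (length(geoms[[ui]]$cells) > 1) ui else NA_integer_
      for (j in seq_along(geoms[[ui]]$cells)) {
        cellg <- geoms[[ui]]$cells[[j]]
        off <- geoms[[ui]]$offsets[[j]]
        r0 <- base_r + off[1]; c0 <- base_c + off[2]
        cell_id <- cell_id + 1L
        soma_px <- cbind(cellg$soma[, 1] + r0, cellg$soma[, 2] + c0)
        glia[soma_px] <- TRUE
        if (nrow(cellg$process)) {
          pp <- cbind(cellg$process[, 1] + r0, cellg$process[, 2] + c0)
          # dilate the drawn path to the rendered tube width in a local window
          mar <- cellg$width_px + 1L
          rr <- range(pp[, 1]); cc <- range(pp[, 2])
          lr <- max(1L, rr[1] - mar):min(image_size[1], rr[2] + mar)
          lc <- max(1L, cc[1] - mar):min(image_size[2], cc[2] + mar)
          tube <- matrix(FALSE, length(lr), length(lc))
          tube[cbind(pp[, 1] - lr[1] + 1L, pp[, 2] - lc[1] + 1L)] <- TRUE
          if (cellg$width_px >= 2) tube <- mask_dilate(tube, (cellg$width_px - 1) / 2)
          glia[lr, lc] <- glia[lr, lc] | tube
        }
        nuc <- .paint_disc(nuc, r0, c0, nucleus_radius_um / ps)
        cd68[soma_px] <- cd68[soma_px] + cellg$truth$cd68_level
        tr <- cellg$truth
        truth[[cell_id]] <- data.frame(
          cell_id = cell_id, phenotype = tr$phenotype,
          soma_center_row = r0, soma_center_col = c0,
          soma_radius_um = tr$soma_radius_um, soma_area_um2 = tr$soma_area_um2,
          process_length_um = tr$process_length_um,
          n_processes = tr$n_processes, n_endpoints = tr$n_endpoints,
          n_branchpoints = tr$n_branchpoints,
          nucleus_row = r0, nucleus_col = c0,
          cd68_total = tr$cd68_level * nrow(cellg$soma),
          cluster_id = cluster_id, stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, truth)
    render <- function(base, level) {
      img <- if (is.logical(base)) base * level else base
      if (noise$blur_sigma_um > 0)
        img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                                 sigma = noise$blur_sigma_um / ps))
      if (noise$background > 0) img <- img + noise$background
      if (noise$noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise$noise_sd)
      matrix(pmax(img, 0), nrow(img), ncol(img))
    }
    channels <- channel_set(
      glia_marker = calibrated_image(render(glia, signal_level), ps,
                                     "fluorescence", "glia_marker"),
      nucleus = calibrated_image(render(nuc, 200), ps, "fluorescence", "nucleus"),
      activation_marker = calibrated_image(render(cd68, NA), ps,
                                           "fluorescence", "activation_marker")
    )
    structure(list(channels = channels, truth = truth, geometry_mask = glia,
                   seed = seed, noise = noise, pixel_size_um = ps),
              class = "glia_scene")
  })
}

#' @export
print.glia_scene <- function(x, ...) {
  cat(sprintf("<glia_scene> %d cells (%s) in %d x %d px @ %.3f um/px, seed %d\n",
              nrow(x$truth),
              paste(sprintf("%s: %d", names(table(x$truth$phenotype)),
                            as.integer(table(x$truth$phenotype))), collapse = ", "),
              nrow(x$channels$glia_marker$pixels), ncol(x$channels$glia_marker$pixels),
              x$pixel_size_um, x$seed))
  invisible(x)
}

#' Render a scene as a chromogen (DAB-style) image
#'
#' Bright transmitted-light background minus the glia signal: dark stain on a
#' light field, with optional extra noise. No nucleus channel exists in this
#' modality; the analysis pipeline substitutes soma centroids for nuclei.
#' Inverting the rendering with [chromogen_to_signal()] recovers the
#' fluorescent glia channel up to the added noise.
#'
#' @param scene a `glia_scene`.
#' @param white_level background intensity (default 255).
#' @param noise_sd extra additive noise (default 0: the glia channel's own
#'   rendering noise is already embedded).
#' @param seed seed for the extra noise draw (only used when `noise_sd > 0`).
#' @return a [calibrated_image] with `modality = "chromogen"`.
#' @export
render_chromogen <- function(scene, white_level = 255, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(scene, "glia_scene"))
  px <- pmax(white_level - scene$channels$glia_marker$pixels, 0)
  if (noise_sd > 0)
    px <- pmax(px + .with_seed(seed, stats::rnorm(length(px), 0, noise_sd)), 0)
  px <- matrix(px, nrow(scene$channels$glia_marker$pixels))
  calibrated_image(px, scene$pixel_size_um, modality = "chromogen", role = "transmitted")
}
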