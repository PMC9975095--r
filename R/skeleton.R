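# Morphological thinning (Zhang-Suen) and skeleton editing.
#
# Thinning is authored here because none of the image packages available to
# this toolchain expose a binary skeletonization, and partial thinning is a
# load-bearing step of the soma-extraction procedure (a full thinning erases
# the soma, so the depth must be controllable).

# Neighbour stack in the Zhang-Suen ordering: p2 = N, p3 = NE, p4 = E, p5 = SE,
# p6 = S, p7 = SW, p8 = W, p9 = NW.
.zs_offsets <- list(
  p2 = c(-1L, 0L), p3 = c(-1L, 1L), p4 = c(0L, 1L), p5 = c(1L, 1L),
  p6 = c(1L, 0L), p7 = c(1L, -1L), p8 = c(0L, -1L), p9 = c(-1L, -1L)
)

#' Topological thinning of a binary mask (Zhang-Suen)
#'
#' Iteratively deletes boundary pixels while preserving connectivity. With
#' `max_iters = Inf` the result is a one-pixel-wide skeleton; a finite number
#' of iterations performs *partial* thinning (each iteration peels roughly one
#' pixel off convex boundaries), which is how cell somata are isolated before
#' morphological opening.
#'
#' One-pixel-wide 8-connected arcs are invariant under this operator, so
#' re-thinning a skeleton returns it unchanged.
#'
#' @param mask logical matrix (any non-logical input is binarised at > 0).
#' @param max_iters maximum number of full iterations (two sub-iterations
#'   each); `Inf` thins to convergence.
#' @return logical matrix of the same dimensions.
#' @export
thin_mask <- function(mask, max_iters = Inf) {
  m <- .as_mask(mask)
  if (!any(m)) return(m)
  iter <- 0
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p <- lapply(.zs_offsets, function(o) .shift_mat(m, o[1], o[2]))
      b <- Reduce(`+`, p)
      seqp <- p[c("p2", "p3", "p4", "p5", "p6", "p7", "p8", "p9", "p2")]
      a <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) a <- a + (!seqp[[i]] & seqp[[i + 1]])
      if (sub == 1) {
        extra <- !(p$p2 & p$p4 & p$p6) & !(p$p4 & p$p6 & p$p8)
      } else {
        extra <- !(p$p2 & p$p4 & p$p8) & !(p$p2 & p$p6 & p$p8)
      }
      del <- m & b >= 2L & b <= 6L & a == 1L & extra
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    iter <- iter + 1
    if (!changed || iter >= max_iters) break
  }
  m
}

# Pixels with <= 1 skeleton 8-neighbours (isolated pixels count).
.endpoint_pixels <- function(skel) {
  skel & .neighbour_count(skel) <= 1L
}

# Skeleton neighbours of pixel (r, c) as a 2-column matrix.
.skel_neighbours <- function(skel, r, c) {
  out <- NULL
  nr <- nrow(skel); nc <- ncol(skel)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- r + dr; cc <- c + dc
    if (rr >= 1 && cc >= 1 && rr <= nr && cc <= nc && skel[rr, cc]) out <- rbind(out, c(rr, cc))
  }
  out
}

# Remove redundant staircase corner pixels: a pixel with exactly two skeleton
# neighbours that are themselves 8-adjacent lies on a corner whose path can
# run through the diagonal; Zhang-Suen keeps such pixels, and each one makes
# the adjacent corner pixel look like a false 3-neighbour junction.
.remove_staircase_pixels <- function(skel) {
  repeat {
    b <- .neighbour_count(skel)
    cand <- which(skel & b == 2L, arr.ind = TRUE)
    removed <- FALSE
    for (i in seq_len(nrow(cand))) {
      r <- cand[i, 1]; c <- cand[i, 2]
      if (!skel[r, c]) next
      nbs <- .skel_neighbours(skel, r, c)
      if (is.null(nbs) || nrow(nbs) != 2) next
      if (max(abs(nbs[1, ] - nbs[2, ])) <= 1L) {
        skel[r, c] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  skel
}

#' Prune short spurs from a skeleton
#'
#' Walks inward from every endpoint; if a junction pixel (>= 3 neighbours) is
#' reached after fewer than `min_px` pixels, the traversed spur is deleted.
#' Free arcs (no junction on the way) are never pruned, so an isolated short
#' skeleton survives intact.
#'
#' @param skel logical skeleton matrix.
#' @param min_px minimum spur length in pixels; spurs shorter than this are
#'   removed. `0` disables pruning.
#' @return pruned logical matrix.
#' @export
prune_spurs <- function(skel, min_px = 2L) {
  skel <- .as_mask(skel)
  if (min_px <= 0 || !any(skel)) return(skel)
  repeat {
    ncount <- .neighbour_count(skel)
    eps <- which(skel & ncount <= 1L, arr.ind = TRUE)
    removed <- FALSE
    for (i in seq_len(nrow(eps))) {
      r <- eps[i, 1]; c <- eps[i, 2]
      if (!skel[r, c]) next
      path <- matrix(c(r, c), 1, 2)
      prev <- c(NA_integer_, NA_integer_)
      repeat {
        if (nrow(path) >= min_px) { path <- NULL; break }  # long enough: keep
        cur <- path[nrow(path), ]
        nbs <- .skel_neighbours(skel, cur[1], cur[2])
        if (!is.null(nbs) && !is.na(prev[1]))
          nbs <- nbs[!(nbs[, 1] == prev[1] & nbs[, 2] == prev[2]), , drop = FALSE]
        if (is.null(nbs) || nrow(nbs) == 0) { path <- NULL; break }  # free arc
        if (nrow(nbs) > 1) break  # reached a junction neighbourhood
        nxt <- nbs[1, ]
        if (ncount[nxt[1], nxt[2]] >= 3L) break  # next pixel is a junction
        prev <- cur
        path <- rbind(path, nxt)
      }
      if (!is.null(path) && nrow(path) < min_px) {
        skel[path] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  skel
}
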