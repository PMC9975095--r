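# Brute-force oracles, written independently of the package internals:
# everything here is plain nested loops over pixels.

oracle_neighbours <- function(mask, r, c) {
  n <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- r + dr; cc <- c + dc
    if (rr >= 1 && cc >= 1 && rr <= nrow(mask) && cc <= ncol(mask) && mask[rr, cc])
      n <- n + 1L
  }
  n
}

oracle_endpoints <- function(mask) {
  n <- 0L
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask)))
    if (mask[r, c] && oracle_neighbours(mask, r, c) <= 1L) n <- n + 1L
  n
}

oracle_branchpoints <- function(mask) {
  cand <- matrix(FALSE, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask)))
    if (mask[r, c] && oracle_neighbours(mask, r, c) >= 3L) cand[r, c] <- TRUE
  # merge 8-adjacent candidates by breadth-first flood
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  groups <- 0L
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (!cand[r, c] || seen[r, c]) next
    groups <- groups + 1L
    queue <- list(c(r, c)); seen[r, c] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr >= 1 && cc >= 1 && rr <= nrow(mask) && cc <= ncol(mask) &&
            cand[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  groups
}

oracle_percent_fill <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  sum(mask) / ((max(idx[, 1]) - min(idx[, 1]) + 1) * (max(idx[, 2]) - min(idx[, 2]) + 1))
}

oracle_span_ratio <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  mr <- mean(idx[, 1]); mc <- mean(idx[, 2])
  srr <- mean((idx[, 1] - mr)^2); scc <- mean((idx[, 2] - mc)^2)
  src <- mean((idx[, 1] - mr) * (idx[, 2] - mc))
  tr <- srr + scc
  disc <- sqrt(max(0, (srr - scc)^2 + 4 * src^2))
  l1 <- (tr + disc) / 2; l2 <- (tr - disc) / 2
  if (l2 <= 1e-12 * max(1, l1)) return(Inf)
  max(1, sqrt(l1 / l2))
}

# Moore-neighbour boundary tracing, independent of EBImage::ocontour. The
# trace (current pixel, backtrack direction) is deterministic, so it must
# eventually cycle; the perimeter is the step length of that cycle.
oracle_perimeter <- function(mask, pixel_size_um = 1) {
  if (sum(mask) == 1) return(0)
  nr <- nrow(mask); nc <- ncol(mask)
  inside <- function(r, c) r >= 1 && c >= 1 && r <= nr && c <= nc && mask[r, c]
  # clockwise Moore neighbourhood starting west
  moves <- list(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  start <- which(mask, arr.ind = TRUE)
  start <- start[order(start[, 2], start[, 1]), , drop = FALSE][1, ]
  cur <- start
  bdir <- 1L  # the west neighbour of the start pixel is background
  states <- character(0)
  steps <- numeric(0)
  repeat {
    state <- paste(cur[1], cur[2], bdir)
    seen_at <- match(state, states)
    if (!is.na(seen_at)) {
      return(sum(steps[seen_at:length(steps)]) * pixel_size_um)
    }
    states <- c(states, state)
    found <- FALSE
    for (k in 1:8) {
      d <- ((bdir - 1L + k) %% 8L) + 1L   # scan clockwise after the backtrack
      nxt <- c(cur[1] + moves[[d]][1], cur[2] + moves[[d]][2])
      if (inside(nxt[1], nxt[2])) {
        steps <- c(steps, if (all(abs(nxt - cur) == 1)) sqrt(2) else 1)
        cur <- nxt
        bdir <- ((d - 1L + 4L) %% 8L) + 1L  # points back where we came from
        found <- TRUE
        break
      }
    }
    if (!found) return(0)  # isolated pixel
    if (length(steps) > 8 * sum(mask) + 16) stop("tracing failed to cycle")
  }
}

oracle_marker_sum <- function(mask, marker) {
  s <- 0
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask)))
    if (mask[r, c]) s <- s + marker[r, c]
  s
}

# Link-enumeration length oracle with the shared-orthogonal-neighbour rule for
# diagonal links.
oracle_process_length <- function(skel, pixel_size_um = 1) {
  idx <- which(skel, arr.ind = TRUE)
  total <- 0
  n <- nrow(idx)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    dr <- idx[j, 1] - idx[i, 1]; dc <- idx[j, 2] - idx[i, 2]
    if (max(abs(dr), abs(dc)) != 1) next
    if (abs(dr) == 1 && abs(dc) == 1) {
      a <- c(idx[i, 1], idx[j, 2]); b <- c(idx[j, 1], idx[i, 2])
      common <- skel[a[1], a[2]] || skel[b[1], b[2]]
      if (!common) total <- total + sqrt(2)
    } else {
      total <- total + 1
    }
  }
  total * pixel_size_um
}

# A random blob mask: union of a few discs plus salt, at most nr x nc.
random_mask <- function(nr = 30, nc = 30, n_blobs = 3, salt = 0.02) {
  m <- matrix(FALSE, nr, nc)
  for (b in seq_len(n_blobs)) {
    r0 <- sample(3:(nr - 2), 1); c0 <- sample(3:(nc - 2), 1)
    rad <- stats::runif(1, 1.5, min(nr, nc) / 4)
    for (r in seq_len(nr)) for (c in seq_len(nc))
      if ((r - r0)^2 + (c - c0)^2 <= rad^2) m[r, c] <- TRUE
  }
  m | matrix(stats::runif(nr * nc) < salt, nr, nc)
}

# Largest 8-connected component of a mask (single-component oracles need
# one), by plain BFS labelling.
largest_component <- function(mask) {
  seen <- matrix(0L, nrow(mask), ncol(mask))
  best <- NULL; best_n <- 0L; g <- 0L
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (!mask[r, c] || seen[r, c] > 0L) next
    g <- g + 1L
    comp <- list(c(r, c)); seen[r, c] <- g; queue <- list(c(r, c))
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr >= 1 && cc >= 1 && rr <= nrow(mask) && cc <= ncol(mask) &&
            mask[rr, cc] && seen[rr, cc] == 0L) {
          seen[rr, cc] <- g
          comp[[length(comp) + 1]] <- c(rr, cc)
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
    if (length(comp) > best_n) { best_n <- length(comp); best <- comp }
  }
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (p in best) out[p[1], p[2]] <- TRUE
  out
}
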