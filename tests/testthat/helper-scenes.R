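# Shared synthetic scenes, generated once per test run.

.scene_cache <- new.env(parent = emptyenv())

cached_scene <- function(key, expr) {
  if (!exists(key, envir = .scene_cache)) assign(key, force(expr), envir = .scene_cache)
  get(key, envir = .scene_cache)
}

noise_free <- list(blur_sigma_um = 0, noise_sd = 0, background = 0)

# The reference noise-free closure scene: 20 non-overlapping cells.
closure_scene <- function() {
  cached_scene("closure", generate_scene(
    c(ramified = 7, intermediate = 7, amoeboid = 6),
    noise = noise_free, seed = 42))
}

closure_result <- function() {
  cached_scene("closure_res", measure_scene(closure_scene()$channels, list()))
}

# Match measured components to ground-truth rows by nucleus position.
match_truth <- function(res, truth) {
  vapply(seq_along(res$components), function(i) {
    cen <- res$components[[i]]$nucleus_centroids[1, ]
    which.min((truth$nucleus_row - cen[1])^2 + (truth$nucleus_col - cen[2])^2)
  }, integer(1))
}

# A small fluorescent scene with default (noisy) rendering, for pipeline tests.
small_noisy_scene <- function() {
  cached_scene("small_noisy", generate_scene(
    c(ramified = 3, intermediate = 3, amoeboid = 3), seed = 8))
}

# Build a glia_component by hand from global masks (single 8-connected object).
make_component <- function(mask, soma, id = 1L, nucleus_count = 1L) {
  comp <- structure(
    list(id = id, bbox = c(r0 = 1L, r1 = nrow(mask), c0 = 1L, c1 = ncol(mask)),
         mask = mask, soma_mask = soma & mask, skeleton = NULL,
         nucleus_count = as.integer(nucleus_count),
         is_cluster = nucleus_count >= 2,
         nucleus_centroids = matrix(colMeans(which(soma, arr.ind = TRUE)), 1, 2)),
    class = "glia_component")
  comp
}

disc_mask <- function(nr, nc, r0, c0, rad) {
  m <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc))
    if ((r - r0)^2 + (c - c0)^2 <= rad^2) m[r, c] <- TRUE
  m
}
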