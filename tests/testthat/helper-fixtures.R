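# shared fixtures, built in code and memoised across test files

.fixture_cache <- new.env(parent = emptyenv())

# default-condition phantom with surface mesh, cell table and layer annotation
phantom_fixture <- function(jitter = 0, seed = 0, spec = NULL) {
  key <- if (is.null(spec)) sprintf("ph_%g_%d", jitter, seed) else
    paste0("ph_", digest_spec(spec))
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  if (is.null(spec)) spec <- phantom_spec(jitter = jitter, seed = seed)
  ph <- generate_phantom(spec)
  mesh <- extract_surface_mesh(ph$volume, sigma = 2, cut_base = TRUE)
  cells <- compute_cell_table(ph$volume, mesh)
  layers <- detect_layers(cells)
  res <- list(spec = spec, volume = ph$volume, truth = ph$truth,
              mesh = mesh, cells = cells, layers = layers)
  .fixture_cache[[key]] <- res
  res
}

digest_spec <- function(spec) paste(unlist(spec[c("dome_radius", "n_shells", "seed", "jitter")]),
                                    collapse = "_")

# a pocket-sized phantom for exhaustive voxel-level checks
small_phantom_spec <- function(seed = 0, jitter = 0.1, ...) {
  phantom_spec(dome_radius = 16, n_shells = 3, shell_thickness = 4,
               jitter = jitter, seed = seed, ...)
}

# two touching 2x2x2 blocks along the x axis inside a padded volume
two_block_volume <- function(voxel_size = c(1, 1, 1)) {
  arr <- array(0L, dim = c(4, 4, 6))  # (z, y, x)
  arr[2:3, 2:3, 2:3] <- 1L
  arr[2:3, 2:3, 4:5] <- 2L
  labeled_volume(arr, voxel_size = voxel_size)
}

# hand-built cell table under a flat surface mesh at z = 0 (tissue below)
flat_cells <- function(centroids, volume = 10) {
  stopifnot(ncol(centroids) == 3)
  surf <- cbind(centroids[, 1], centroids[, 2], 0)
  tv <- centroids - surf
  tibble::tibble(
    label = seq_len(nrow(centroids)),
    x = centroids[, 1], y = centroids[, 2], z = centroids[, 3],
    volume = rep_len(volume, nrow(centroids)),
    surf_x = surf[, 1], surf_y = surf[, 2], surf_z = surf[, 3],
    t_x = tv[, 1], t_y = tv[, 2], t_z = tv[, 3],
    t_norm = sqrt(rowSums(tv^2))
  )
}

# a large flat square mesh at z = 0 (two triangles)
flat_mesh <- function(half = 100) {
  v <- rbind(c(-half, -half, 0), c(half, -half, 0),
             c(half, half, 0), c(-half, half, 0))
  surface_mesh(v, rbind(c(1, 2, 3), c(1, 3, 4)))
}

# independent point-to-triangle projection (plane projection + edge clamping)
closest_on_triangle_r <- function(p, a, b, c) {
  seg <- function(p, s, e) {
    d <- e - s
    t <- sum((p - s) * d) / sum(d * d)
    s + min(max(t, 0), 1) * d
  }
  n <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
         (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
         (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
  q <- p - n * sum((p - a) * n) / sum(n * n)
  # barycentric coordinates of q
  v0 <- b - a; v1 <- c - a; v2 <- q - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  if (v >= 0 && w >= 0 && v + w <= 1) return(q)
  cand <- list(seg(p, a, b), seg(p, b, c), seg(p, c, a))
  d2 <- vapply(cand, function(x) sum((p - x)^2), 0)
  cand[[which.min(d2)]]
}

# exhaustive nearest point over all mesh triangles, via the R projection
brute_nearest_on_mesh <- function(p, mesh) {
  best <- NULL; bd <- Inf
  for (t in seq_len(nrow(mesh$triangles))) {
    tri <- mesh$triangles[t, ]
    q <- closest_on_triangle_r(p, mesh$vertices[tri[1], ],
                               mesh$vertices[tri[2], ], mesh$vertices[tri[3], ])
    d <- sum((p - q)^2)
    if (d < bd) { bd <- d; best <- q }
  }
  list(point = best, distance = sqrt(bd))
}
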