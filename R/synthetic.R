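#' Specification of a synthetic dome phantom
#'
#' Parameterises a dome-shaped synthetic meristem: a solid hemisphere of
#' radius `dome_radius` resting on the z = 0 plane, partitioned into cells
#' by Voronoi regions of seed points arranged on concentric shells beneath
#' the surface. Optional Gaussian bumps emulate emerging primordia. The
#' construction records the ground-truth shell (layer) of every cell, so
#' the annotation algorithms can be validated without microscopy data.
#'
#' The defaults (40 µm dome, three 5 µm shells, ~5 µm cells, jitter 0.1)
#' approximate the scale of an angiosperm floral meristem.
#'
#' @param dome_radius dome radius, micrometres.
#' @param n_shells number of annotated concentric shells (>= 1); the core
#'   beneath them is filled with additional deep cells.
#' @param shell_thickness radial thickness of each shell, micrometres.
#' @param cells_per_shell integer vector (recycled) forcing seed counts per
#'   shell, or `NULL` for area-proportional counts.
#' @param layer_volume_profile `"uniform"`, `"increasing"` (deeper cells
#'   larger) or `"decreasing"` (deeper cells smaller).
#' @param primordia `NULL` or a data frame with columns `dir_x`, `dir_y`,
#'   `dir_z` (outward bump direction), `bump_radius` (lateral extent, µm)
#'   and `bump_height` (µm).
#' @param jitter seed-point displacement as a fraction of the local seed
#'   spacing, in `[0, 0.5)`.
#' @param voxel_size voxel edge lengths `(x, y, z)`, micrometres.
#' @param seed integer RNG seed; the phantom is deterministic given the
#'   spec.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(dome_radius = 40, n_shells = 3, shell_thickness = 5,
                         cells_per_shell = NULL,
                         layer_volume_profile = c("uniform", "increasing", "decreasing"),
                         primordia = NULL, jitter = 0.1,
                         voxel_size = c(1, 1, 1), seed = 0L) {
  layer_volume_profile <- match.arg(layer_volume_profile)
  if (n_shells < 1) stop("n_shells must be >= 1", call. = FALSE)
  if (jitter < 0 || jitter >= 0.5) stop("jitter must be in [0, 0.5)", call. = FALSE)
  if (dome_radius <= 0 || shell_thickness <= 0) {
    stop("dome_radius and shell_thickness must be > 0", call. = FALSE)
  }
  if (!is.null(primordia)) {
    primordia <- tibble::as_tibble(primordia)
    need <- c("dir_x", "dir_y", "dir_z", "bump_radius", "bump_height")
    if (!all(need %in% names(primordia))) {
      stop("primordia needs columns ", paste(need, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(
    dome_radius = dome_radius, n_shells = as.integer(n_shells),
    shell_thickness = shell_thickness, cells_per_shell = cells_per_shell,
    layer_volume_profile = layer_volume_profile, primordia = primordia,
    jitter = jitter, voxel_size = voxel_size, seed = as.integer(seed)
  ), class = "phantom_spec")
}

# near-uniform directions on the upper hemisphere (Fibonacci lattice)
fibonacci_hemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  uz <- i / n
  r <- sqrt(pmax(1 - uz^2, 0))
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (seq_len(n) - 1)
  cbind(x = r * cos(phi), y = r * sin(phi), z = uz)
}

# radial surface distance R_surf(u) for unit directions u (rows)
surface_radius <- function(u, spec) {
  r <- rep(spec$dome_radius, nrow(u))
  if (!is.null(spec$primordia) && nrow(spec$primordia) > 0) {
    for (k in seq_len(nrow(spec$primordia))) {
      p <- spec$primordia[k, ]
      d <- c(p$dir_x, p$dir_y, p$dir_z)
      d <- d / sqrt(sum(d^2))
      cosang <- pmin(pmax(u %*% d, -1), 1)
      ang <- acos(as.vector(cosang))
      sig <- p$bump_radius / spec$dome_radius  # angular width (radians)
      r <- r + p$bump_height * exp(-ang^2 / (2 * sig^2))
    }
  }
  r
}

#' Generate a synthetic dome phantom with ground truth
#'
#' Seed points are placed on concentric shells beneath the (optionally
#' bumped) dome surface at depths `(s - 1/2) * shell_thickness`, the core
#' is filled with a deeper seed lattice, seeds are jittered by
#' `jitter * local spacing`, and every foreground voxel is assigned to its
#' nearest seed (Voronoi labelling). Deterministic for a fixed spec.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` (a [labeled_volume()]) and `truth`
#'   (list with `cells` tibble: `label`, `true_shell`, `true_layer`,
#'   `primordium`; `apex_cell`; `primordia` tibble of `k`, `peak_cell`,
#'   `saddle_cell`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  R0 <- spec$dome_radius
  h <- spec$shell_thickness
  ns <- spec$n_shells
  growth <- switch(spec$layer_volume_profile,
                   uniform = 1, increasing = 1.25, decreasing = 0.8)

  hmax <- if (!is.null(spec$primordia) && nrow(spec$primordia) > 0) {
    max(spec$primordia$bump_height)
  } else 0

  # --- seed points -----------------------------------------------------------
  seeds <- NULL
  seed_shell <- integer(0)
  seed_dir <- NULL
  seed_spacing <- numeric(0)
  for (s in seq_len(ns)) {
    depth <- (s - 0.5) * h
    rho_nom <- R0 - depth
    if (rho_nom <= 0.3 * h) next
    spacing <- h * growth^(s - 1)
    n_s <- if (!is.null(spec$cells_per_shell)) {
      rep_len(spec$cells_per_shell, ns)[s]
    } else {
      max(8L, round(2 * pi * rho_nom^2 / spacing^2))
    }
    u <- fibonacci_hemisphere(n_s)
    rho <- surface_radius(u, spec) - depth
    pts <- u * rho
    seeds <- rbind(seeds, pts)
    seed_shell <- c(seed_shell, rep(s, n_s))
    seed_dir <- rbind(seed_dir, u)
    seed_spacing <- c(seed_spacing, rep(spacing, n_s))
  }
  # core lattice below the annotated shells
  core_r <- R0 - ns * h
  if (core_r > 0.5 * h) {
    spacing <- h * growth^ns
    g <- seq(-core_r, core_r, by = spacing)
    gz <- seq(0.4 * spacing, core_r, by = spacing)
    if (length(gz) > 0) {
      lat <- as.matrix(expand.grid(x = g, y = g, z = gz))
      keep <- sqrt(rowSums(lat^2)) <= core_r - 0.2 * spacing
      lat <- lat[keep, , drop = FALSE]
      if (nrow(lat) > 0) {
        rho <- sqrt(rowSums(lat^2))
        u <- lat / rho
        depth <- surface_radius(u, spec) - rho
        seeds <- rbind(seeds, lat)
        seed_shell <- c(seed_shell, pmin(floor(depth / h) + 1L, 99L))
        seed_dir <- rbind(seed_dir, u)
        seed_spacing <- c(seed_spacing, rep(spacing, nrow(lat)))
      }
    }
  }
  if (is.null(seeds) || nrow(seeds) == 0) {
    stop("degenerate phantom spec: no seed points fit the dome", call. = FALSE)
  }

  if (spec$jitter > 0) {
    nsd <- nrow(seeds)
    dir <- matrix(stats::rnorm(3 * nsd), ncol = 3)
    dir <- dir / sqrt(rowSums(dir^2))
    mag <- spec$jitter * seed_spacing * stats::runif(nsd)^(1 / 3)
    seeds <- seeds + dir * mag
    # keep jittered seeds inside the tissue
    seeds[, 3] <- pmax(seeds[, 3], 0.2)
    rho <- sqrt(rowSums(seeds^2))
    u <- seeds / rho
    rs <- surface_radius(u, spec)
    over <- rho > rs - 0.3
    if (any(over)) seeds[over, ] <- u[over, , drop = FALSE] * (rs[over] - 0.3)
  }

  # --- voxel grid ------------------------------------------------------------
  vs <- setNames(as.numeric(spec$voxel_size), c("x", "y", "z"))
  margin <- 2
  ext <- R0 + hmax + margin
  nx <- floor(2 * ext / vs["x"]) + 1L
  ny <- floor(2 * ext / vs["y"]) + 1L
  nz <- floor((ext + vs["z"]) / vs["z"]) + 1L
  cx <- (nx - 1) / 2 * vs["x"]
  cy <- (ny - 1) / 2 * vs["y"]
  centre <- c(cx, cy, 0)

  xs <- (seq_len(nx) - 1) * vs["x"] - cx
  ys <- (seq_len(ny) - 1) * vs["y"] - cy
  zs <- (seq_len(nz) - 1) * vs["z"]

  # (z, y, x) array order
  relx <- rep(xs, each = nz * ny)
  rely <- rep(rep(ys, each = nz), times = nx)
  relz <- rep(zs, times = ny * nx)
  rho <- sqrt(relx^2 + rely^2 + relz^2)
  u <- cbind(relx, rely, relz) / pmax(rho, 1e-12)
  fg <- rho <= surface_radius(u, spec) & rho > 0

  labels <- array(0L, dim = c(nz, ny, nx))
  fg_idx <- which(fg)
  vox_phys <- cbind(relx[fg_idx], rely[fg_idx], relz[fg_idx])
  assign_idx <- cpp_nearest_seed(vox_phys, seeds)
  labels[fg_idx] <- assign_idx

  present <- sort(unique(assign_idx))
  vol <- labeled_volume(labels, voxel_size = vs)

  # --- ground truth ----------------------------------------------------------
  truth_cells <- tibble::tibble(
    label = present,
    true_shell = seed_shell[present],
    true_layer = paste0("L", pmin(seed_shell[present], 3L))
  )
  prim_of <- rep(NA_integer_, length(present))
  if (!is.null(spec$primordia) && nrow(spec$primordia) > 0) {
    for (k in seq_len(nrow(spec$primordia))) {
      p <- spec$primordia[k, ]
      d <- c(p$dir_x, p$dir_y, p$dir_z)
      d <- d / sqrt(sum(d^2))
      ang <- acos(pmin(pmax(seed_dir[present, , drop = FALSE] %*% d, -1), 1))
      prim_of[ang < p$bump_radius / R0] <- k
    }
  }
  truth_cells$primordium <- prim_of

  shell1 <- present[seed_shell[present] == 1L]
  apex_cell <- shell1[which.max(seed_dir[shell1, 3])]

  prim_truth <- NULL
  if (!is.null(spec$primordia) && nrow(spec$primordia) > 0) {
    prim_truth <- purrr::map_dfr(seq_len(nrow(spec$primordia)), function(k) {
      p <- spec$primordia[k, ]
      d <- c(p$dir_x, p$dir_y, p$dir_z)
      d <- d / sqrt(sum(d^2))
      ang <- acos(pmin(pmax(seed_dir[shell1, , drop = FALSE] %*% d, -1), 1))
      peak <- shell1[which.min(ang)]
      # saddle direction: between bump and apex, at twice the bump's angular width
      apex_dir <- c(0, 0, 1)
      sad_dir <- d * 0.5 + apex_dir * 0.5
      sad_dir <- sad_dir / sqrt(sum(sad_dir^2))
      ang_s <- acos(pmin(pmax(seed_dir[shell1, , drop = FALSE] %*% sad_dir, -1), 1))
      saddle <- shell1[which.min(ang_s)]
      tibble::tibble(k = k, peak_cell = peak, saddle_cell = saddle)
    })
  }

  list(volume = vol,
       truth = list(cells = truth_cells, apex_cell = apex_cell,
                    primordia = prim_truth, centre = centre,
                    seeds = sweep(seeds, 2, centre, "+")))
}
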