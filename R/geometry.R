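#' Per-cell geometry: centroids, volumes and surface vectors
#'
#' For each cell the centroid is the mean physical position of its voxel
#' centres and the volume is voxel count times voxel volume. For each
#' centroid the nearest point on the surface mesh is found by exact
#' point-to-triangle projection (not nearest vertex), giving the surface
#' vector `t = centroid - surface_point` that the cone-based layer
#' detection is built on.
#'
#' @param vol a [labeled_volume()].
#' @param mesh a [surface_mesh()] of the tissue's outer surface.
#' @return A tibble with one row per cell: `label`, centroid `x`, `y`, `z`
#'   (micrometres), `volume` (cubic micrometres), nearest surface point
#'   `surf_x/y/z`, surface vector `t_x/y/z` and its norm `t_norm`.
#' @export
compute_cell_table <- function(vol, mesh) {
  stopifnot(inherits(vol, "labeled_volume"), inherits(mesh, "surface_mesh"))
  labs <- cell_labels(vol)
  if (length(labs) == 0) stop("volume contains no cells", call. = FALSE)
  if (nrow(mesh$triangles) == 0) stop("surface mesh is empty", call. = FALSE)

  idx <- which(vol$labels != vol$background_label, arr.ind = TRUE)  # (z,y,x) 1-based
  lab <- vol$labels[idx]
  vs <- vol$voxel_size
  phys <- cbind(x = (idx[, 3] - 1) * vs["x"],
                y = (idx[, 2] - 1) * vs["y"],
                z = (idx[, 1] - 1) * vs["z"])

  sums <- rowsum(phys, lab)
  counts <- as.vector(rowsum(rep(1, length(lab)), lab))
  cent <- sums / counts
  labels_out <- as.integer(rownames(sums))
  vol_um3 <- counts * prod(vs)

  nn <- cpp_nearest_on_mesh(cent, mesh$vertices, mesh$triangles)
  tvec <- cent - nn$point

  tibble::tibble(
    label = labels_out,
    x = cent[, 1], y = cent[, 2], z = cent[, 3],
    volume = vol_um3,
    surf_x = nn$point[, 1], surf_y = nn$point[, 2], surf_z = nn$point[, 3],
    t_x = tvec[, 1], t_y = tvec[, 2], t_z = tvec[, 3],
    t_norm = nn$distance
  ) %>% dplyr::arrange(.data$label)
}

#' Nearest point on a surface mesh
#'
#' Exact closest point on any mesh triangle for each query point, via
#' per-triangle projection with bounding-sphere culling.
#'
#' @param points numeric length-3 point or `n x 3` matrix.
#' @param mesh a [surface_mesh()].
#' @return A list with `point` (`n x 3` matrix of nearest surface points)
#'   and `distance` (numeric vector).
#' @export
nearest_mesh_point <- function(points, mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (!is.matrix(points)) points <- matrix(points, ncol = 3)
  cpp_nearest_on_mesh(points, mesh$vertices, mesh$triangles)
}

#' Cone membership test
#'
#' Tests whether query points lie inside the unbounded cone with vertex
#' `apex`, axis `axis_to_surface` (for a cell, the direction from its
#' centroid toward its nearest surface point, i.e. `-t`) and semi-cone
#' angle `theta`. A point is inside iff the angle between `query - apex`
#' and the axis is strictly less than `theta`.
#'
#' The `"literal"` convention instead applies the inequality
#' `cos(angle to t) < cos(theta)` with `t = -axis_to_surface`, which
#' selects the complement of the cone around the inward direction; it is
#' provided for comparison only.
#'
#' @param apex numeric length-3, cone vertex.
#' @param axis_to_surface numeric length-3, non-zero axis direction.
#' @param theta semi-cone angle in degrees, in (0, 90).
#' @param query numeric length-3 point or an `n x 3` matrix of points.
#' @param convention `"described"` (default) or `"literal"`.
#' @return Logical vector, one element per query point.
#' @export
cone_contains <- function(apex, axis_to_surface, theta, query,
                          convention = c("described", "literal")) {
  convention <- match.arg(convention)
  if (!is.matrix(query)) query <- matrix(query, ncol = 3)
  axis_norm <- sqrt(sum(axis_to_surface^2))
  if (axis_norm == 0) {
    stop("degenerate geometry: zero-length cone axis (centroid on surface)",
         call. = FALSE)
  }
  if (theta <= 0 || theta >= 90) stop("theta must be in (0, 90) degrees", call. = FALSE)
  d <- sweep(query, 2, apex)
  dn <- sqrt(rowSums(d^2))
  cosang <- as.vector(d %*% axis_to_surface) / (dn * axis_norm)
  ct <- cos(theta * pi / 180)
  if (convention == "described") {
    ok <- cosang > ct
  } else {
    ok <- -cosang < ct   # printed inequality with t = -axis_to_surface
  }
  ok[dn == 0] <- FALSE   # the apex itself is never a member
  ok
}
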