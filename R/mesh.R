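#' Triangle surface mesh
#'
#' @param vertices numeric matrix `n x 3` of vertex positions `(x, y, z)`
#'   in micrometres.
#' @param triangles integer matrix `m x 3` of 1-based vertex indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  if (ncol(vertices) != 3) stop("`vertices` must be n x 3", call. = FALSE)
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1 || max(triangles) > nrow(vertices))) {
    stop("triangle indices out of range", call. = FALSE)
  }
  colnames(vertices) <- c("x", "y", "z")
  structure(list(vertices = vertices, triangles = triangles),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices
  t <- mesh$triangles
  a <- v[t[, 1], , drop = FALSE]
  ab <- v[t[, 2], , drop = FALSE] - a
  ac <- v[t[, 3], , drop = FALSE] - a
  cx <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  0.5 * sqrt(rowSums(cx^2))
}

#' Total surface area of a mesh
#'
#' @param mesh a [surface_mesh()].
#' @return Area in square micrometres.
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh))

#' Enclosed volume of a closed mesh
#'
#' Signed-tetrahedron (divergence theorem) volume; the absolute value is
#' returned so orientation does not matter.
#'
#' @param mesh a closed [surface_mesh()].
#' @return Volume in cubic micrometres.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  t <- mesh$triangles
  a <- v[t[, 1], , drop = FALSE]
  b <- v[t[, 2], , drop = FALSE]
  c_ <- v[t[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  abs(sum(rowSums(a * cr)) / 6)
}

# drop zero-area triangles, then keep the connected component with the
# largest total area
clean_mesh <- function(mesh, area_eps = 1e-12) {
  areas <- triangle_areas(mesh)
  keep <- areas > area_eps
  tri <- mesh$triangles[keep, , drop = FALSE]
  areas <- areas[keep]
  if (nrow(tri) == 0) return(surface_mesh(mesh$vertices[0, , drop = FALSE], tri))

  edges <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  comp <- igraph::components(g)$membership
  tri_comp <- comp[tri[, 1]]
  comp_area <- tapply(areas, tri_comp, sum)
  main <- as.integer(names(comp_area)[which.max(comp_area)])
  tri <- tri[tri_comp == main, , drop = FALSE]

  used <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  surface_mesh(mesh$vertices[used, , drop = FALSE],
               matrix(remap[tri], ncol = 3))
}

# separable Gaussian smoothing of a 3D array; sigma in voxels per axis,
# truncated at 3 sigma, kernel rows renormalised at the boundary
gauss_smooth_3d <- function(arr, sigma_vox) {
  smooth_axis <- function(a, axis, s) {
    if (s <= 0) return(a)
    n <- dim(a)[axis]
    half <- max(1L, ceiling(3 * s))
    idx <- seq_len(n)
    K <- outer(idx, idx, function(i, j) {
      d <- abs(i - j)
      ifelse(d <= half, exp(-(d^2) / (2 * s^2)), 0)
    })
    K <- K / rowSums(K)
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    ap <- aperm(a, perm)
    d <- dim(ap)
    m <- K %*% matrix(ap, nrow = d[1])
    ap <- array(m, dim = d)
    aperm(ap, order(perm))
  }
  for (ax in 1:3) arr <- smooth_axis(arr, ax, sigma_vox[ax])
  arr
}

#' Extract the tissue surface mesh from a labeled volume
#'
#' The foreground (all non-background labels) is binarised, smoothed with a
#' Gaussian of physical width `sigma`, and triangulated with a marching
#' tetrahedra isosurface at `iso`. Only the largest connected component is
#' kept and degenerate triangles are removed. With `cut_base = TRUE`,
#' triangles lying on the volume's lower z boundary face (the mounting
#' plane of a dome-shaped sample) are discarded so that the mesh describes
#' the biological outer surface only.
#'
#' @param vol a [labeled_volume()].
#' @param sigma Gaussian smoothing width in micrometres (default 2).
#' @param iso iso-level in the smoothed 0/1 mask (default 0.5).
#' @param cut_base drop the flat base cap at the lower z face (default
#'   `FALSE`).
#' @return A [surface_mesh()] with vertices in micrometres.
#' @export
extract_surface_mesh <- function(vol, sigma = 2, iso = 0.5, cut_base = FALSE) {
  stopifnot(inherits(vol, "labeled_volume"))
  mask <- (vol$labels != vol$background_label) * 1.0
  if (!any(mask > 0)) stop("volume has no foreground voxels", call. = FALSE)
  d <- dim(mask)
  # pad with one background layer so the isosurface closes at array borders
  padded <- array(0, dim = d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask

  vs <- vol$voxel_size  # (x, y, z); array axes are (z, y, x)
  sigma_vox <- c(sigma / vs["z"], sigma / vs["y"], sigma / vs["x"])
  padded <- gauss_smooth_3d(padded, sigma_vox)

  raw <- cpp_marching_tetrahedra(padded, iso)
  if (nrow(raw$triangles) == 0) {
    stop("no isosurface found at the requested iso-level", call. = FALSE)
  }
  # fractional array indices (z,y,x; 0-based in padded grid) -> physical (x,y,z)
  vz <- raw$vertices
  phys <- cbind(x = (vz[, 3] - 1) * vs["x"],
                y = (vz[, 2] - 1) * vs["y"],
                z = (vz[, 1] - 1) * vs["z"])
  mesh <- clean_mesh(surface_mesh(phys, raw$triangles))
  if (cut_base) {
    zmax <- apply(matrix(mesh$vertices[t(mesh$triangles), "z"], nrow = 3), 2, max)
    keep <- zmax >= 0.5 * vs["z"]
    tri <- mesh$triangles[keep, , drop = FALSE]
    used <- sort(unique(as.vector(tri)))
    remap <- integer(nrow(mesh$vertices))
    remap[used] <- seq_along(used)
    mesh <- surface_mesh(mesh$vertices[used, , drop = FALSE],
                         matrix(remap[tri], ncol = 3))
  }
  mesh
}

#' Read a PLY triangle mesh
#'
#' Supports ASCII and binary little-endian PLY with float/double vertex
#' properties x, y, z and triangular faces.
#'
#' @param path PLY file path.
#' @return A [surface_mesh()].
#' @export
read_mesh_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("unexpected end of PLY header", call. = FALSE)
    header <- c(header, line)
    if (trimws(line) == "end_header") break
  }
  if (header[1] != "ply") stop("not a PLY file: ", path, call. = FALSE)
  fmt_line <- grep("^format ", header, value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]

  elems <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "element") {
      cur <- tok[2]
      elems[[cur]] <- list(count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      elems[[cur]]$props <- c(elems[[cur]]$props, list(tok[-1]))
    }
  }
  if (is.null(elems$vertex) || is.null(elems$face)) {
    stop("PLY must contain vertex and face elements", call. = FALSE)
  }
  nv <- elems$vertex$count
  nf <- elems$face$count

  type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1,
                 short = 2, ushort = 2, int16 = 2, uint16 = 2,
                 int = 4, uint = 4, int32 = 4, uint32 = 4,
                 float = 4, float32 = 4, double = 8, float64 = 8)

  if (fmt == "ascii") {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))]
    vlines <- txt[seq_len(nv)]
    flines <- txt[nv + seq_len(nf)]
    vprops <- vapply(elems$vertex$props, function(p) p[length(p)], "")
    vm <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), as.numeric))
    colnames(vm) <- vprops
    verts <- vm[, c("x", "y", "z"), drop = FALSE]
    tris <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"), function(tok) {
      n <- as.integer(tok[1])
      if (n != 3) stop("only triangular faces are supported", call. = FALSE)
      as.integer(tok[2:4]) + 1L
    }))
  } else if (fmt == "binary_little_endian") {
    vprops <- elems$vertex$props
    pnames <- vapply(vprops, function(p) p[length(p)], "")
    ptypes <- vapply(vprops, function(p) p[1], "")
    verts <- matrix(NA_real_, nv, 3)
    xi <- match(c("x", "y", "z"), pnames)
    for (i in seq_len(nv)) {
      row <- numeric(length(pnames))
      for (j in seq_along(pnames)) {
        sz <- type_size[[ptypes[j]]]
        what <- if (ptypes[j] %in% c("float", "float32", "double", "float64")) "numeric" else "integer"
        row[j] <- readBin(con, what, n = 1, size = sz, endian = "little",
                          signed = !(ptypes[j] %in% c("uchar", "uint8", "ushort", "uint16")))
      }
      verts[i, ] <- row[xi]
    }
    fp <- elems$face$props[[1]]  # list <count type> <index type> name
    cnt_sz <- type_size[[fp[2]]]
    idx_sz <- type_size[[fp[3]]]
    tris <- matrix(NA_integer_, nf, 3)
    for (i in seq_len(nf)) {
      n <- readBin(con, "integer", n = 1, size = cnt_sz, endian = "little",
                   signed = cnt_sz > 1)
      idx <- readBin(con, "integer", n = n, size = idx_sz, endian = "little")
      if (n != 3) stop("only triangular faces are supported", call. = FALSE)
      tris[i, ] <- idx + 1L
    }
  } else {
    stop("unsupported PLY format: ", fmt, call. = FALSE)
  }
  colnames(verts) <- c("x", "y", "z")
  surface_mesh(verts, tris)
}

#' Write a mesh as ASCII PLY
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mesh_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply",
    "format ascii 1.0",
    sprintf("element vertex %d", nrow(mesh$vertices)),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nrow(mesh$triangles)),
    "property list uchar int vertex_indices",
    "end_header"
  ), con)
  utils::write.table(format(mesh$vertices, trim = TRUE, digits = 9),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$triangles - 1L),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
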