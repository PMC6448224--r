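#' Labeled 3D cell volume
#'
#' The container for watershed-style 3D segmentations: an integer array of
#' cell labels (0 = background) plus the physical voxel size. The array is
#' stored in `(z, y, x)` index order (TIFF page = z); all physical
#' coordinates reported by the package are `(x, y, z)` in micrometres, with
#' 0-based voxel centres at `index * voxel_size`.
#'
#' @param labels 3D integer array, dimension `(nz, ny, nx)`; values >= 0,
#'   0 is background.
#' @param voxel_size numeric length-3, physical voxel edge lengths in
#'   micrometres, in `(x, y, z)` order; all strictly positive.
#' @param background_label integer, the background value (default 0).
#'
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(labels, voxel_size = c(1, 1, 1), background_label = 0L) {
  if (length(dim(labels)) != 3) {
    stop("`labels` must be a 3-dimensional array", call. = FALSE)
  }
  if (any(labels != round(labels))) {
    stop("`labels` must contain integer values", call. = FALSE)
  }
  if (any(labels < 0)) {
    stop("label values must be >= 0", call. = FALSE)
  }
  if (length(voxel_size) != 3 || any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("`voxel_size` must be three strictly positive lengths (µm)", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  structure(
    list(
      labels = labels,
      voxel_size = setNames(as.numeric(voxel_size), c("x", "y", "z")),
      background_label = as.integer(background_label)
    ),
    class = "labeled_volume"
  )
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf(
    "<labeled_volume> %d x %d x %d voxels (z,y,x), voxel size %.3g x %.3g x %.3g um, %d cells\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    length(cell_labels(x))
  ))
  invisible(x)
}

#' Cell labels present in a volume
#'
#' @param vol a [labeled_volume()].
#' @return Sorted integer vector of non-background labels.
#' @export
cell_labels <- function(vol) {
  stopifnot(inherits(vol, "labeled_volume"))
  u <- sort(unique(as.vector(vol$labels)))
  u[u != vol$background_label]
}

#' Read a labeled volume from a multi-page TIFF
#'
#' Pages are stacked as the z axis; each page is a `(y, x)` matrix of
#' integer cell labels. Non-integer pixel types are rejected.
#'
#' @param path path to a multi-page TIFF of integer type (uint8/16/32).
#' @param voxel_size physical voxel size `(x, y, z)` in micrometres.
#' @param background values to treat as background; if more than one is
#'   given they are merged into 0 before constructing the volume.
#' @return A [labeled_volume()].
#' @export
read_labeled_volume <- function(path, voxel_size = c(1, 1, 1), background = 0L) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0) {
    stop("empty TIFF stack: ", path, call. = FALSE)
  }
  # the raw (as.is) and normalised reads must agree for an unsigned-integer
  # sample format; a float TIFF reinterprets to inconsistent (often negative)
  # values
  norm <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(norm)) norm <- list(norm)
  info <- tiff::readTIFF(path, payload = FALSE, all = TRUE)
  bits <- if (is.data.frame(info)) info$bits.per.sample else info[[1]]$bits.per.sample
  maxv <- 2^bits - 1
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    if (length(dim(p)) != 2) {
      stop("each TIFF page must be a single-channel 2D image", call. = FALSE)
    }
    if (any(p < 0) || any(p != round(p)) ||
        max(abs(p - round(norm[[k]] * maxv[min(k, length(maxv))]))) > 1) {
      stop("TIFF pixel type must be integer (labels), not floating point", call. = FALSE)
    }
  }
  nz <- length(pages)
  ny <- nrow(pages[[1]])
  nx <- ncol(pages[[1]])
  arr <- array(0L, dim = c(nz, ny, nx))
  for (z in seq_len(nz)) {
    if (!all(dim(pages[[z]]) == c(ny, nx))) {
      stop("TIFF pages have inconsistent dimensions", call. = FALSE)
    }
    arr[z, , ] <- as.integer(pages[[z]])
  }
  background <- as.integer(background)
  if (length(background) > 1 || background[1] != 0L) {
    arr[arr %in% background] <- 0L
  }
  labeled_volume(arr, voxel_size = voxel_size, background_label = 0L)
}

#' Write a labeled volume to a multi-page TIFF
#'
#' Labels are stored as 16-bit unsigned integers (page = z slice).
#'
#' @param vol a [labeled_volume()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labeled_volume <- function(vol, path) {
  stopifnot(inherits(vol, "labeled_volume"))
  if (max(vol$labels) > 65535L) {
    stop("labels exceed 16-bit range; cannot write as uint16 TIFF", call. = FALSE)
  }
  nz <- dim(vol$labels)[1]
  pages <- lapply(seq_len(nz), function(z) vol$labels[z, , , drop = TRUE] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

zone_levels <- function() {
  c("L1", "L2", "L3", "OC",
    "L1_above_OC", "L2_above_OC", "L3_above_OC",
    "primordium_L1", "primordium_L2", "primordium_L3",
    "boundary", "unassigned")
}

#' Write the per-cell annotation table to CSV
#'
#' One row per annotated cell, sorted by label, with the zone, the
#' primordium index (NA outside primordia/boundaries), centroid coordinates
#' and volume, and anisotropy when supplied.
#'
#' @param annotation tibble with columns `label`, `zone` and optionally
#'   `primordium_index` (as produced by [detect_layers()], [mark_meristem()],
#'   [mark_primordia()]).
#' @param cells the cell geometry table from [compute_cell_table()].
#' @param path output CSV path.
#' @param anisotropy optional tibble from [cell_anisotropy()] joined in by
#'   label.
#' @return `path`, invisibly.
#' @export
write_annotation_csv <- function(annotation, cells, path, anisotropy = NULL) {
  stopifnot(is.data.frame(annotation), is.data.frame(cells))
  if (!"primordium_index" %in% names(annotation)) {
    annotation$primordium_index <- NA_integer_
  }
  missing <- setdiff(annotation$label, cells$label)
  if (length(missing) > 0) {
    stop("annotated labels absent from the cell table: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  out <- annotation %>%
    dplyr::select("label", "zone", "primordium_index") %>%
    dplyr::left_join(
      dplyr::select(cells,
                    "label", centroid_x = "x", centroid_y = "y", centroid_z = "z",
                    "volume"),
      by = "label"
    )
  if (!is.null(anisotropy)) {
    out <- dplyr::left_join(out, dplyr::select(anisotropy, "label", "anisotropy"),
                            by = "label")
  }
  out <- dplyr::arrange(out, .data$label)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an annotation CSV written by [write_annotation_csv()]
#'
#' @param path CSV path.
#' @return A tibble with one row per cell.
#' @export
read_annotation_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' Write a cell network to GraphML
#'
#' Nodes carry the `zone` attribute from the annotation (cells without an
#' annotation are written as `"unassigned"`); edges carry `interface_area`
#' in square micrometres.
#'
#' @param net a `cell_network` from [build_cell_network()].
#' @param annotation annotation tibble (may be `NULL`).
#' @param path output GraphML path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, annotation = NULL, path) {
  g <- as_igraph(net, annotation = annotation)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Convert a cell network to an igraph graph
#'
#' @param net a `cell_network`.
#' @param annotation optional annotation tibble; adds a `zone` vertex
#'   attribute (missing cells become `"unassigned"`).
#' @return An undirected [igraph::graph] with `interface_area` edge weights.
#' @export
as_igraph <- function(net, annotation = NULL) {
  stopifnot(inherits(net, "cell_network"))
  verts <- data.frame(name = as.character(net$nodes$label),
                      label_id = net$nodes$label)
  if (!is.null(annotation)) {
    zmap <- setNames(as.character(annotation$zone), as.character(annotation$label))
    verts$zone <- unname(zmap[verts$name])
    verts$zone[is.na(verts$zone)] <- "unassigned"
  } else {
    verts$zone <- "unassigned"
  }
  edges <- data.frame(from = as.character(net$edges$from),
                      to = as.character(net$edges$to),
                      interface_area = net$edges$interface_area)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}
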