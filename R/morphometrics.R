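#' PCA shape anisotropy of each cell
#'
#' The shape of a cell is abstracted into three principal vectors: the
#' square roots of the eigenvalues of the (population) covariance of the
#' cell's voxel-centre physical coordinates. Each magnitude is divided by
#' the sum of the three magnitudes and the maximum of the normalised values
#' is the anisotropy, so a perfectly isotropic cell scores 1/3 and a
#' rod-like cell approaches 1.
#'
#' Single-voxel cells have zero magnitudes; their anisotropy is undefined
#' and reported as `NA` with a warning.
#'
#' @param vol a [labeled_volume()].
#' @param labels optional subset of cell labels (default: all cells).
#' @return A tibble `label`, `m1`, `m2`, `m3` (principal magnitudes,
#'   micrometres, descending), `anisotropy` in `[1/3, 1]`.
#' @export
cell_anisotropy <- function(vol, labels = NULL) {
  stopifnot(inherits(vol, "labeled_volume"))
  all_labs <- cell_labels(vol)
  labels <- if (is.null(labels)) all_labs else intersect(labels, all_labs)

  idx <- which(vol$labels != vol$background_label, arr.ind = TRUE)
  lab <- vol$labels[idx]
  vs <- vol$voxel_size
  phys <- cbind((idx[, 3] - 1) * vs["x"],
                (idx[, 2] - 1) * vs["y"],
                (idx[, 1] - 1) * vs["z"])
  groups <- split(seq_along(lab), lab)

  res <- purrr::map(as.character(labels), function(lb) {
    rows <- groups[[lb]]
    P <- phys[rows, , drop = FALSE]
    n <- nrow(P)
    C <- sweep(P, 2, colMeans(P))
    S <- crossprod(C) / n  # population covariance
    ev <- sort(pmax(eigen(S, symmetric = TRUE, only.values = TRUE)$values, 0),
               decreasing = TRUE)
    m <- sqrt(ev)
    tibble::tibble(label = as.integer(lb), m1 = m[1], m2 = m[2], m3 = m[3],
                   anisotropy = if (sum(m) > 0) m[1] / sum(m) else NA_real_)
  })
  out <- dplyr::bind_rows(res)
  if (any(is.na(out$anisotropy))) {
    warning(sum(is.na(out$anisotropy)),
            " degenerate cell(s) with zero extent: anisotropy undefined")
  }
  out
}

#' Cell adjacency network with shared interface areas
#'
#' Two cells are adjacent iff they share at least one voxel face
#' (6-connectivity); the edge weight is the accumulated physical area of
#' all shared faces. Corner and edge contacts carry zero area and create no
#' edge. Each node also records its background-facing (exposed) face area,
#' so that for every cell: sum of edge areas + exposed area = the cell's
#' total voxel-face surface area.
#'
#' @param vol a [labeled_volume()].
#' @return An object of class `cell_network`: a list with `nodes` (tibble
#'   `label`, `exposed_area`) and `edges` (tibble `from`, `to`,
#'   `interface_area` in square micrometres, `from < to`).
#' @export
build_cell_network <- function(vol) {
  stopifnot(inherits(vol, "labeled_volume"))
  A <- vol$labels
  labs <- cell_labels(vol)
  if (length(labs) == 0) stop("volume contains no cells", call. = FALSE)
  d <- dim(A)
  vs <- vol$voxel_size
  # face area orthogonal to each array axis: axis 1=z -> x*y, 2=y -> x*z, 3=x -> y*z
  face_area <- c(vs["x"] * vs["y"], vs["x"] * vs["z"], vs["y"] * vs["z"])

  key_base <- max(labs) + 1
  edge_keys <- numeric(0)
  edge_areas <- numeric(0)
  exp_labs <- integer(0)
  exp_areas <- numeric(0)

  for (ax in 1:3) {
    n_ax <- d[ax]
    take <- function(range) {
      switch(ax,
             A[range, , , drop = FALSE],
             A[, range, , drop = FALSE],
             A[, , range, drop = FALSE])
    }
    a1 <- take(seq_len(n_ax - 1))
    a2 <- take(1 + seq_len(n_ax - 1))
    diffsel <- which(a1 != a2)
    p1 <- a1[diffsel]; p2 <- a2[diffsel]
    both <- p1 > 0 & p2 > 0
    if (any(both)) {
      lo <- pmin(p1[both], p2[both]); hi <- pmax(p1[both], p2[both])
      edge_keys <- c(edge_keys, lo * key_base + hi)
      edge_areas <- c(edge_areas, rep(face_area[ax], sum(both)))
    }
    one <- xor(p1 > 0, p2 > 0)
    if (any(one)) {
      exp_labs <- c(exp_labs, pmax(p1[one], p2[one]))
      exp_areas <- c(exp_areas, rep(face_area[ax], sum(one)))
    }
    # array-border faces are exposed
    b1 <- take(1); b2 <- take(n_ax)
    border <- c(b1[b1 > 0], b2[b2 > 0])
    if (length(border) > 0) {
      exp_labs <- c(exp_labs, border)
      exp_areas <- c(exp_areas, rep(face_area[ax], length(border)))
    }
  }

  if (length(edge_keys) > 0) {
    agg <- rowsum(edge_areas, edge_keys)
    keys <- as.numeric(rownames(agg))
    edges <- tibble::tibble(
      from = as.integer(keys %/% key_base),
      to = as.integer(keys %% key_base),
      interface_area = as.vector(agg)
    ) %>% dplyr::arrange(.data$from, .data$to)
  } else {
    edges <- tibble::tibble(from = integer(), to = integer(),
                            interface_area = numeric())
  }

  exposed <- setNames(rep(0, length(labs)), labs)
  if (length(exp_labs) > 0) {
    eagg <- rowsum(exp_areas, exp_labs)
    exposed[rownames(eagg)] <- as.vector(eagg)
  }
  nodes <- tibble::tibble(label = labs, exposed_area = unname(exposed[as.character(labs)]))
  structure(list(nodes = nodes, edges = edges), class = "cell_network")
}

#' @export
print.cell_network <- function(x, ...) {
  cat(sprintf("<cell_network> %d cells, %d contacts, total interface %.4g um^2\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$interface_area)))
  invisible(x)
}

#' Per-zone and per-zone-pair morphometric summaries
#'
#' Summarises cell counts, volumes and anisotropy per annotation zone, and
#' shared-interface areas per zone pair (within-layer and between-layer
#' contacts reported separately).
#'
#' @param cells cell table.
#' @param annotation annotation tibble with `label`, `zone`.
#' @param net optional `cell_network` for the interface summary.
#' @param anisotropy optional tibble from [cell_anisotropy()].
#' @return A list of class `zone_summary` with tibbles `zones` and
#'   `interfaces` (`NULL` when `net` is not given).
#' @export
zone_summaries <- function(cells, annotation, net = NULL, anisotropy = NULL) {
  df <- dplyr::left_join(annotation, dplyr::select(cells, "label", "volume"),
                         by = "label")
  if (!is.null(anisotropy)) {
    df <- dplyr::left_join(df, dplyr::select(anisotropy, "label", "anisotropy"),
                           by = "label")
  } else {
    df$anisotropy <- NA_real_
  }
  zones <- df %>%
    dplyr::group_by(.data$zone) %>%
    dplyr::summarise(
      n_cells = dplyr::n(),
      volume_mean = mean(.data$volume),
      volume_median = median(.data$volume),
      volume_sd = sd(.data$volume),
      anisotropy_mean = if (all(is.na(.data$anisotropy))) NA_real_
                        else mean(.data$anisotropy, na.rm = TRUE),
      anisotropy_sd = if (all(is.na(.data$anisotropy))) NA_real_
                      else sd(.data$anisotropy, na.rm = TRUE),
      .groups = "drop"
    )

  interfaces <- NULL
  if (!is.null(net)) {
    zmap <- setNames(annotation$zone, annotation$label)
    e <- net$edges
    z1 <- zmap[as.character(e$from)]
    z2 <- zmap[as.character(e$to)]
    z1[is.na(z1)] <- "unassigned"
    z2[is.na(z2)] <- "unassigned"
    pair <- ifelse(z1 <= z2, paste(z1, z2, sep = "|"), paste(z2, z1, sep = "|"))
    interfaces <- tibble::tibble(pair = pair, interface_area = e$interface_area) %>%
      dplyr::group_by(.data$pair) %>%
      dplyr::summarise(
        n_interfaces = dplyr::n(),
        area_mean = mean(.data$interface_area),
        area_sd = sd(.data$interface_area),
        area_total = sum(.data$interface_area),
        .groups = "drop"
      )
  }
  structure(list(zones = zones, interfaces = interfaces), class = "zone_summary")
}

#' Write zone summaries to CSV
#'
#' Writes the per-zone table to `path` and, when present, the zone-pair
#' interface table next to it with suffix `_interfaces.csv`.
#'
#' @param summary a `zone_summary` from [zone_summaries()].
#' @param path output CSV path for the zone table.
#' @return `path`, invisibly.
#' @export
write_zone_summary_csv <- function(summary, path) {
  stopifnot(inherits(summary, "zone_summary"))
  write.csv(summary$zones, path, row.names = FALSE)
  if (!is.null(summary$interfaces)) {
    ipath <- sub("\\.csv$", "_interfaces.csv", path)
    if (identical(ipath, path)) ipath <- paste0(path, "_interfaces.csv")
    write.csv(summary$interfaces, ipath, row.names = FALSE)
  }
  invisible(path)
}
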