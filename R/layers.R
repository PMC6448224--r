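#' Detect cell layers L1-L3 by iterative cone peeling
#'
#' Each cell anchors an unbounded cone at its centroid, aimed at its nearest
#' point on the surface mesh, with semi-cone angle `theta`. L1 cells are the
#' cells whose cones contain no other active centroid; they are removed and
#' the test repeated to find L2; every remaining cell is L3 (deeper strata
#' share the L3 identity). Surface vectors are computed once against the
#' original mesh and are not recomputed between rounds.
#'
#' Cells smaller than `min_cell_volume` are excluded from the analysis
#' entirely (zone `"unassigned"`, and they do not occlude other cells'
#' cones). A cell whose centroid lies exactly on the mesh has no cone axis;
#' it is assigned L1 with a warning, as it sits at the surface.
#'
#' @param cells cell table from [compute_cell_table()].
#' @param theta semi-cone angle in degrees (default 60).
#' @param min_cell_volume minimum cell volume in cubic micrometres
#'   (default 0, keep everything).
#' @param convention cone convention passed to [cone_contains()].
#' @return A tibble `label`, `layer` (`L1`/`L2`/`L3`/`NA`), `zone`
#'   (`layer` or `"unassigned"`), `primordium_index` (`NA`).
#' @export
detect_layers <- function(cells, theta = 60, min_cell_volume = 0,
                          convention = c("described", "literal")) {
  convention <- match.arg(convention)
  stopifnot(is.data.frame(cells), nrow(cells) > 0)
  if (theta <= 0 || theta >= 90) stop("theta must be in (0, 90) degrees", call. = FALSE)
  if (min_cell_volume < 0) stop("min_cell_volume must be >= 0", call. = FALSE)

  active <- cells$volume >= min_cell_volume
  if (!any(active)) stop("no cells remain above the minimum cell volume", call. = FALSE)

  on_surface <- active & cells$t_norm == 0
  if (any(on_surface)) {
    warning(sum(on_surface), " cell(s) have centroids on the surface mesh; assigned L1")
  }

  X <- as.matrix(cells[, c("x", "y", "z")])
  Tv <- as.matrix(cells[, c("t_x", "t_y", "t_z")])
  ct <- cos(theta * pi / 180)
  n <- nrow(cells)

  layer <- rep(NA_character_, n)

  # TRUE if any active centroid other than i lies inside cell i's cone
  occluded <- function(i, active_idx) {
    js <- setdiff(active_idx, i)
    if (length(js) == 0) return(FALSE)
    axis <- -Tv[i, ]
    an <- sqrt(sum(axis^2))
    d <- X[js, , drop = FALSE] - matrix(X[i, ], length(js), 3, byrow = TRUE)
    dn <- sqrt(rowSums(d^2))
    cosang <- as.vector(d %*% axis) / (dn * an)
    cosang[dn == 0] <- -Inf
    if (convention == "described") any(cosang > ct) else any(-cosang < ct)
  }

  remaining <- which(active)
  for (round in 1:2) {
    lay <- paste0("L", round)
    hits <- vapply(remaining, function(i) {
      if (on_surface[i]) return(round == 1)  # surface-degenerate cells are L1
      !occluded(i, remaining)
    }, logical(1))
    layer[remaining[hits]] <- lay
    remaining <- remaining[!hits]
    if (length(remaining) == 0) break
  }
  layer[remaining] <- "L3"

  tibble::tibble(
    label = cells$label,
    layer = layer,
    zone = ifelse(is.na(layer), "unassigned", layer),
    primordium_index = NA_integer_
  )
}

#' Mark the organizing centre (stem-cell niche) and the column above it
#'
#' The user names the apex cell at the top of the dome. From the apex
#' cell's nearest surface point `a`, the inward unit normal `n` (the
#' direction of its surface vector) defines the niche centre
#' `c = a + depth * n`. The organizing centre is the set of L3 cells whose
#' centroids lie within `radius` of `c`. Cells in the axial cylinder of
#' radius `radius` between the surface and the niche depth keep their layer
#' stratum but are renamed `L1_above_OC`/`L2_above_OC`/`L3_above_OC`, so
#' the niche and the column above it are not absorbed into the plain layer
#' labels.
#'
#' @param cells cell table from [compute_cell_table()].
#' @param layers annotation tibble from [detect_layers()].
#' @param apex_cell label of the user-selected cell at the top of the dome;
#'   must be an L1 cell.
#' @param depth depth of the organizing centre beneath the surface,
#'   micrometres (> 0).
#' @param radius niche radius in micrometres (> 0).
#' @return The annotation tibble with `zone` updated; `layer` is unchanged.
#' @export
mark_meristem <- function(cells, layers, apex_cell, depth, radius) {
  stopifnot(is.data.frame(cells), is.data.frame(layers))
  if (depth <= 0 || radius <= 0) stop("depth and radius must be > 0", call. = FALSE)
  ai <- match(apex_cell, cells$label)
  if (is.na(ai)) stop("apex cell ", apex_cell, " not found", call. = FALSE)
  alayer <- layers$layer[match(apex_cell, layers$label)]
  if (is.na(alayer) || alayer != "L1") {
    stop("apex cell must be an L1 cell (got ", alayer %||% "unassigned", ")",
         call. = FALSE)
  }

  a <- c(cells$surf_x[ai], cells$surf_y[ai], cells$surf_z[ai])
  tv <- c(cells$t_x[ai], cells$t_y[ai], cells$t_z[ai])
  tn <- sqrt(sum(tv^2))
  if (tn == 0) stop("apex cell centroid lies on the surface; cannot orient the niche axis",
                    call. = FALSE)
  n <- tv / tn  # inward unit normal (centroid is inside the tissue)
  centre <- a + depth * n

  X <- as.matrix(cells[, c("x", "y", "z")])
  rel <- sweep(X, 2, centre)
  dist_centre <- sqrt(rowSums(rel^2))

  rel_a <- sweep(X, 2, a)
  axial <- as.vector(rel_a %*% n)
  lateral <- sqrt(pmax(rowSums(rel_a^2) - axial^2, 0))

  ann <- layers
  ord <- match(cells$label, ann$label)
  lay <- ann$layer[ord]

  oc <- !is.na(lay) & lay == "L3" & dist_centre <= radius
  if (!any(oc)) warning("organizing centre is empty: depth/radius miss the tissue")

  above <- !oc & !is.na(lay) & lateral <= radius & axial >= 0 & axial < depth

  zone <- ann$zone[ord]
  zone[oc] <- "OC"
  zone[above] <- paste0(lay[above], "_above_OC")
  ann$zone[ord] <- zone
  ann
}

#' Suggest an apex cell (advisory)
#'
#' Returns the L1 cell with the highest centroid z, a convenience stand-in
#' for the interactive apex click. Always review the suggestion.
#'
#' @param cells cell table.
#' @param layers annotation from [detect_layers()].
#' @return A cell label.
#' @export
suggest_apex <- function(cells, layers) {
  l1 <- layers$label[!is.na(layers$layer) & layers$layer == "L1"]
  sub <- cells[cells$label %in% l1, ]
  sub$label[which.max(sub$z)]
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a
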