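#' Delineate one primordium by a weighted Voronoi partition
#'
#' Three user-selected cells give the SAM peak, the primordium peak and the
#' boundary saddle. Writing `x_SAM`, `x_p`, `x_b` for their centroids, the
#' reference ratio is `r` `= d_p / d_SAM` with `d_p = ||x_p - x_b||` and
#' `d_SAM = ||x_SAM - x_b||`. For every cell `i` the ratio
#' `rho_i = ||x_i - x_p|| / ||x_i - x_SAM||` assigns
#' \itemize{
#'   \item Primordium: `rho_i < r - delta`
#'   \item Boundary:   `rho_i` between `(r - delta)` and `(r + delta)`
#'     inclusive, and additionally
#'     `||x_i - x_b|| <= absolute_distance` (the boundary ring's depth cap)
#'   \item SAM: everything else.
#' }
#' Ratio-band cells beyond the absolute-distance cap fall back to the
#' `delta = 0` rule (`rho_i < r` goes to the primordium, otherwise the SAM).
#' The primordium-peak cell itself is always in P (`rho = 0` limit) and the
#' SAM-peak cell always in S (`rho = +Inf` limit).
#'
#' @param cells cell table from [compute_cell_table()] (or any data frame
#'   with `label`, `x`, `y`, `z`).
#' @param sam_peak_cell,primordium_peak_cell,saddle_cell labels of the
#'   three distinct selection cells.
#' @param delta ratio half-width (>= 0) controlling how large the boundary
#'   band is; dimensionless.
#' @param absolute_distance maximum distance from the saddle centroid for
#'   boundary membership, micrometres (> 0).
#' @return A tibble `label`, `region` with region in `P`, `B`, `S`.
#' @export
mark_primordium <- function(cells, sam_peak_cell, primordium_peak_cell,
                            saddle_cell, delta = 0, absolute_distance = Inf) {
  stopifnot(is.data.frame(cells))
  sel <- c(sam_peak_cell, primordium_peak_cell, saddle_cell)
  if (length(unique(sel)) != 3) {
    stop("SAM peak, primordium peak and saddle cells must be three distinct cells",
         call. = FALSE)
  }
  idx <- match(sel, cells$label)
  if (any(is.na(idx))) {
    stop("selection cell(s) not found: ", paste(sel[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  if (delta < 0) stop("delta must be >= 0", call. = FALSE)
  if (absolute_distance <= 0) stop("absolute_distance must be > 0", call. = FALSE)

  X <- as.matrix(cells[, c("x", "y", "z")])
  x_sam <- X[idx[1], ]
  x_p <- X[idx[2], ]
  x_b <- X[idx[3], ]

  d_sam <- sqrt(sum((x_sam - x_b)^2))
  d_p <- sqrt(sum((x_p - x_b)^2))
  if (d_sam == 0 || d_p == 0) {
    stop("selection centroids coincide; cannot form the Voronoi ratio", call. = FALSE)
  }
  r <- d_p / d_sam

  dp_i <- sqrt(rowSums(sweep(X, 2, x_p)^2))
  dsam_i <- sqrt(rowSums(sweep(X, 2, x_sam)^2))
  db_i <- sqrt(rowSums(sweep(X, 2, x_b)^2))

  rho <- dp_i / dsam_i
  rho[dsam_i == 0] <- Inf  # the SAM peak cell: always SAM
  rho[dp_i == 0] <- 0      # the primordium peak cell: always primordium

  in_band <- rho >= r - delta & rho <= r + delta
  region <- ifelse(rho < r - delta, "P",
                   ifelse(in_band & db_i <= absolute_distance, "B",
                          ifelse(in_band & rho < r, "P", "S")))

  tibble::tibble(label = cells$label, region = region)
}

#' Sequentially mark several primordia on an annotated meristem
#'
#' Runs [mark_primordium()] once per selection, in order. Cells captured as
#' primordium or boundary by an earlier selection are frozen against later
#' reassignment (first selection wins). Primordium cells keep their layer
#' stratum: zone becomes `primordium_L1`/`primordium_L2`/`primordium_L3`
#' with `primordium_index = k`; boundary cells get zone `boundary` with the
#' same index. With `same_label = TRUE` every selection shares index 1.
#'
#' @param cells cell table.
#' @param selections a data frame with one row per primordium and columns
#'   `sam_peak_cell`, `primordium_peak_cell`, `saddle_cell` and optionally
#'   `delta`, `absolute_distance` (defaults 0 and `Inf`).
#' @param annotation base annotation from [detect_layers()] (optionally
#'   after [mark_meristem()]).
#' @param same_label collapse all primordia onto one index (default
#'   `FALSE`).
#' @return The annotation tibble with primordium/boundary zones applied.
#' @export
mark_primordia <- function(cells, selections, annotation, same_label = FALSE) {
  stopifnot(is.data.frame(selections), nrow(selections) > 0,
            is.data.frame(annotation))
  if (!"delta" %in% names(selections)) selections$delta <- 0
  if (!"absolute_distance" %in% names(selections)) selections$absolute_distance <- Inf

  ann <- annotation
  frozen <- rep(FALSE, nrow(ann))
  for (k in seq_len(nrow(selections))) {
    s <- selections[k, ]
    sel_labels <- c(s$sam_peak_cell, s$primordium_peak_cell, s$saddle_cell)
    prior <- ann$label[frozen & !is.na(ann$primordium_index) &
                         startsWith(ann$zone, "primordium")]
    if (any(sel_labels %in% prior)) {
      stop("selection cell for primordium ", k,
           " already lies inside a previously marked primordium", call. = FALSE)
    }
    part <- mark_primordium(cells, s$sam_peak_cell, s$primordium_peak_cell,
                            s$saddle_cell, delta = s$delta,
                            absolute_distance = s$absolute_distance)
    reg <- part$region[match(ann$label, part$label)]
    idx_k <- if (same_label) 1L else as.integer(k)

    take_p <- !frozen & !is.na(reg) & reg == "P" & ann$zone != "unassigned"
    take_b <- !frozen & !is.na(reg) & reg == "B" & ann$zone != "unassigned"
    ann$zone[take_p] <- paste0("primordium_", ann$layer[take_p])
    ann$primordium_index[take_p] <- idx_k
    ann$zone[take_b] <- "boundary"
    ann$primordium_index[take_b] <- idx_k
    frozen <- frozen | take_p | take_b
  }
  ann
}
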