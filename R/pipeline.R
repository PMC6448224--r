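#' Annotate a segmented meristem end to end
#'
#' Chains the workflow: surface mesh (extracted unless supplied), per-cell
#' geometry, cone-peeling layer detection, optional organizing-centre
#' marking and optional primordium delineation. Returns a `sam_atlas`
#' object carrying the cell table, the annotation and the parameters used.
#'
#' @param vol a [labeled_volume()].
#' @param mesh optional [surface_mesh()]; extracted from `vol` when `NULL`.
#' @param theta semi-cone angle in degrees (default 60).
#' @param min_cell_volume minimum cell volume, cubic micrometres.
#' @param apex_cell optional apex cell label; with `oc_depth` and
#'   `oc_radius`, triggers organizing-centre marking.
#' @param oc_depth,oc_radius organizing-centre depth and radius,
#'   micrometres.
#' @param primordia optional selections data frame for [mark_primordia()].
#' @param same_label collapse primordium indices (default `FALSE`).
#' @param sigma,iso,cut_base surface extraction parameters, see
#'   [extract_surface_mesh()].
#' @param convention cone convention, see [cone_contains()].
#' @return An object of class `sam_atlas`.
#' @export
annotate_meristem <- function(vol, mesh = NULL, theta = 60, min_cell_volume = 0,
                              apex_cell = NULL, oc_depth = NULL, oc_radius = NULL,
                              primordia = NULL, same_label = FALSE,
                              sigma = 2, iso = 0.5, cut_base = FALSE,
                              convention = "described") {
  stopifnot(inherits(vol, "labeled_volume"))
  if (is.null(mesh)) {
    mesh <- extract_surface_mesh(vol, sigma = sigma, iso = iso, cut_base = cut_base)
  }
  cells <- compute_cell_table(vol, mesh)
  annotation <- detect_layers(cells, theta = theta,
                              min_cell_volume = min_cell_volume,
                              convention = convention)
  if (!is.null(apex_cell)) {
    if (is.null(oc_depth) || is.null(oc_radius)) {
      stop("apex_cell given without oc_depth/oc_radius", call. = FALSE)
    }
    annotation <- mark_meristem(cells, annotation, apex_cell,
                                depth = oc_depth, radius = oc_radius)
  }
  if (!is.null(primordia)) {
    annotation <- mark_primordia(cells, primordia, annotation,
                                 same_label = same_label)
  }
  structure(list(
    cells = cells, annotation = annotation, mesh = mesh,
    params = list(theta = theta, min_cell_volume = min_cell_volume,
                  apex_cell = apex_cell, oc_depth = oc_depth,
                  oc_radius = oc_radius, sigma = sigma, iso = iso,
                  cut_base = cut_base, convention = convention,
                  same_label = same_label)
  ), class = "sam_atlas")
}

#' @export
print.sam_atlas <- function(x, ...) {
  counts <- table(x$annotation$zone)
  cat(sprintf("<sam_atlas> %d cells, theta = %g deg\n", nrow(x$cells),
              x$params$theta))
  for (z in names(counts)) cat(sprintf("  %-16s %d\n", z, counts[[z]]))
  invisible(x)
}

#' Tidy a sam_atlas into one row per cell
#'
#' @param x a `sam_atlas`.
#' @param ... unused.
#' @return A tibble joining per-cell geometry and annotation.
#' @export
tidy.sam_atlas <- function(x, ...) {
  dplyr::left_join(x$cells, x$annotation, by = "label")
}

#' One-row summary of a sam_atlas
#'
#' @param x a `sam_atlas`.
#' @param ... unused.
#' @return A one-row tibble of cell and zone counts and parameters.
#' @export
glance.sam_atlas <- function(x, ...) {
  ann <- x$annotation
  tibble::tibble(
    n_cells = nrow(x$cells),
    n_L1 = sum(ann$layer == "L1", na.rm = TRUE),
    n_L2 = sum(ann$layer == "L2", na.rm = TRUE),
    n_L3 = sum(ann$layer == "L3", na.rm = TRUE),
    n_OC = sum(ann$zone == "OC"),
    n_primordium = sum(startsWith(ann$zone, "primordium")),
    n_boundary = sum(ann$zone == "boundary"),
    n_unassigned = sum(ann$zone == "unassigned"),
    theta = x$params$theta,
    min_cell_volume = x$params$min_cell_volume
  )
}

# ---------------------------------------------------------------------------
# Config-driven pipeline with run manifest
# ---------------------------------------------------------------------------

#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Values are parsed
#' as numbers or logicals when possible; comma-separated values become
#' vectors.
#'
#' @param path config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    parsed <- suppressWarnings(as.numeric(parts))
    if (!any(is.na(parsed))) {
      out[[key]] <- parsed
    } else if (all(tolower(parts) %in% c("true", "false"))) {
      out[[key]] <- tolower(parts) == "true"
    } else {
      out[[key]] <- if (length(parts) == 1) val else parts
    }
  }
  out
}

#' Run the annotation pipeline from a configuration
#'
#' Executes the requested stages in workflow order (`synth` or input
#' volume, `surface`, `layers`, `niche`, `primordium`, `measure`), writes
#' the annotation CSV, optional GraphML network and summary CSVs into
#' `out_dir`, and emits a JSON run manifest with the full parameter set and
#' input checksums. Stage dependencies are validated up front: `niche`
#' requires `layers`, `primordium` requires `layers`, `measure` requires
#' `layers`.
#'
#' @param config named list (see [read_config()]) or path to a flat
#'   key=value config file. Recognised keys: `input` (TIFF path) or
#'   `synth_seed`/`synth_preset`; `stages` (comma-separated); `voxel_size`;
#'   `mesh` (PLY path); `sigma`, `iso`, `cut_base`; `theta`, `min_volume`;
#'   `apex`, `oc_depth`, `oc_radius`; `sam_peak`, `peak`, `saddle`,
#'   `delta`, `abs_distance`, `same_label`; `out_dir`.
#' @return Invisibly, a list with the `sam_atlas`, output paths and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stages <- config$stages %||% c("layers")
  if (length(stages) == 1 && grepl(",", stages)) {
    stages <- trimws(strsplit(stages, ",")[[1]])
  }
  known <- c("layers", "niche", "primordium", "measure")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (st in c("niche", "primordium", "measure")) {
    if (st %in% stages && !"layers" %in% stages) {
      stop("stage '", st, "' requires stage 'layers' to run first", call. = FALSE)
    }
  }
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  inputs <- character(0)
  truth <- NULL
  if (!is.null(config$input)) {
    vol <- read_labeled_volume(config$input,
                               voxel_size = config$voxel_size %||% c(1, 1, 1))
    inputs <- c(inputs, config$input)
  } else {
    ph <- generate_phantom(phantom_preset(config$synth_preset %||% "arabidopsis-like",
                                          seed = config$synth_seed %||% 0L))
    vol <- ph$volume
    truth <- ph$truth
  }

  mesh <- NULL
  if (!is.null(config$mesh)) {
    mesh <- read_mesh_ply(config$mesh)
    inputs <- c(inputs, config$mesh)
  }

  apex <- config$apex
  if (!is.null(apex) && identical(apex, "auto") && !is.null(truth)) {
    apex <- truth$apex_cell
  }

  if ("niche" %in% stages &&
      (is.null(apex) || is.null(config$oc_depth) || is.null(config$oc_radius))) {
    stop("niche stage requires apex, oc_depth and oc_radius", call. = FALSE)
  }

  primordia <- NULL
  if ("primordium" %in% stages) {
    if (is.null(config$sam_peak) || is.null(config$peak) || is.null(config$saddle)) {
      stop("primordium stage requires sam_peak, peak and saddle labels", call. = FALSE)
    }
    primordia <- tibble::tibble(
      sam_peak_cell = config$sam_peak,
      primordium_peak_cell = config$peak,
      saddle_cell = config$saddle,
      delta = config$delta %||% 0,
      absolute_distance = config$abs_distance %||% Inf
    )
  }

  atlas <- annotate_meristem(
    vol, mesh = mesh,
    theta = config$theta %||% 60,
    min_cell_volume = config$min_volume %||% 0,
    apex_cell = if ("niche" %in% stages) apex else NULL,
    oc_depth = config$oc_depth, oc_radius = config$oc_radius,
    primordia = primordia,
    same_label = isTRUE(config$same_label),
    sigma = config$sigma %||% 2, iso = config$iso %||% 0.5,
    cut_base = isTRUE(config$cut_base)
  )

  counts <- table(atlas$annotation$zone)
  message("cells per zone: ",
          paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))

  paths <- list(annotation = file.path(out_dir, "annotation.csv"))
  aniso <- NULL
  net <- NULL
  if ("measure" %in% stages) {
    aniso <- suppressWarnings(cell_anisotropy(vol))
    net <- build_cell_network(vol)
    paths$network <- file.path(out_dir, "network.graphml")
    paths$summary <- file.path(out_dir, "summary.csv")
    write_network_graphml(net, atlas$annotation, paths$network)
    write_zone_summary_csv(
      zone_summaries(atlas$cells, atlas$annotation, net = net, anisotropy = aniso),
      paths$summary
    )
  }
  write_annotation_csv(atlas$annotation, atlas$cells, paths$annotation,
                       anisotropy = aniso)

  manifest <- list(
    tool = "meristem3d",
    version = as.character(utils::packageVersion("meristem3d")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = stages,
    parameters = config[setdiff(names(config), "stages")],
    input_checksums = as.list(tools::md5sum(inputs)),
    outputs = lapply(paths, normalizePath)
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE,
                       force = TRUE)

  invisible(list(atlas = atlas, paths = paths, manifest = manifest,
                 network = net, truth = truth))
}

#' Phantom presets mirroring the two species-like size gradients
#'
#' `"arabidopsis-like"` makes deeper layers larger (L1 < L2 < L3 cell
#' volumes) with two primordium bumps; `"tomato-like"` makes the epidermis
#' largest (L1 > L2 > L3), no bumps.
#'
#' @param preset preset name.
#' @param seed RNG seed.
#' @return A [phantom_spec()].
#' @export
phantom_preset <- function(preset = c("arabidopsis-like", "tomato-like"), seed = 0L) {
  preset <- match.arg(preset)
  if (preset == "arabidopsis-like") {
    phantom_spec(
      layer_volume_profile = "increasing",
      primordia = tibble::tibble(
        dir_x = c(0.8, -0.75), dir_y = c(0.25, -0.35), dir_z = c(0.54, 0.56),
        bump_radius = c(12, 12), bump_height = c(8, 8)
      ),
      jitter = 0.1, seed = seed
    )
  } else {
    phantom_spec(layer_volume_profile = "decreasing", jitter = 0.1, seed = seed)
  }
}
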