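# Configuration, reporting and file-format plumbing: JSON config with schema
# validation, tidy CSV/JSON report bundle with a hashed run manifest, and
# legacy-ASCII VTK export/import of the unstructured meshes.

default_config_skeleton <- function() {
  list(
    seed = 1L,
    geometry = list(length = 64.18, d_max = 53.46, d_min = 50.72,
                    skin_thickness = 0.3, core_length_fraction = 0.55,
                    core_diameter_fraction = 0.25),
    mesh = list(element_size = 2, quality_floor = 0.05),
    materials = list(),   # per-material field overrides of the library
    solver = list(time_step_safety = 0.9, penalty_reference_thickness = 10,
                  bulk_viscosity_linear = 0.06, n_frames = 400L,
                  contact_friction = 0),
    damage = list(flesh_yield = 0.26, skin_yield = 0.52, core_yield = 1.12),
    grid = list(heights = c(0.25, 0.5, 1), angles = c(0, 45, 90),
                surfaces = c("steel", "pvc", "neoprene")))
}

.check_keys <- function(user, skeleton, path = "") {
  extra <- setdiff(names(user), names(skeleton))
  if (length(extra) > 0)
    stopf("unknown configuration key%s: %s", if (length(extra) > 1) "s" else "",
          paste0(path, extra, collapse = ", "))
  for (k in names(user)) {
    if (is.list(skeleton[[k]]) && !is.null(names(skeleton[[k]])) &&
        k != "materials" && is.list(user[[k]]))
      .check_keys(user[[k]], skeleton[[k]], paste0(path, k, "."))
  }
}

merge_defaults <- function(user, defaults) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(defaults[[k]]))
      defaults[[k]] <- merge_defaults(user[[k]], defaults[[k]])
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Reads a JSON configuration, applies defaults (measured fruit geometry,
#' library materials, solver and damage defaults, the 3x3x3 factorial grid),
#' rejects unknown keys, and validates every invariant by constructing the
#' corresponding objects. An empty file yields the full defaults. Material
#' overrides go under `materials.<name>.<field>`, e.g.
#' `{"materials": {"flesh": {"young_modulus": 2.0}}}`.
#'
#' @param path JSON file path, or `NULL` for pure defaults.
#' @return Object of class `pipeline_config`: validated `geometry`
#'   ([fruit_geometry()]), `materials` (list of [material_params()]),
#'   `solver` ([solver_config()]), `damage` ([damage_thresholds()]), `mesh`,
#'   `grid` and `seed` entries.
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (nzchar(trimws(txt)))
      user <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  }
  skel <- default_config_skeleton()
  .check_keys(user, skel)
  cfg <- merge_defaults(user, skel)

  lib <- material_library()
  known_fields <- c("young_modulus", "tangent_modulus", "yield_stress",
                    "density", "poisson_ratio")
  for (nm in names(cfg$materials)) {
    if (!nm %in% names(lib))
      stopf("materials.%s: unknown material (library has: %s)", nm,
            paste(names(lib), collapse = ", "))
    ov <- cfg$materials[[nm]]
    bad <- setdiff(names(ov), known_fields)
    if (length(bad) > 0)
      stopf("unknown configuration key%s: %s",
            if (length(bad) > 1) "s" else "",
            paste0("materials.", nm, ".", bad, collapse = ", "))
    base <- lib[[nm]]
    for (f in names(ov)) base[[f]] <- ov[[f]]
    # re-validate through the constructor
    lib[[nm]] <- material_params(base$name, base$young_modulus,
                                 base$tangent_modulus, base$yield_stress,
                                 base$density, base$poisson_ratio,
                                 base$metadata)
  }

  structure(list(
    seed = as.integer(cfg$seed),
    geometry = do.call(fruit_geometry, cfg$geometry),
    mesh = cfg$mesh,
    materials = lib,
    solver = do.call(solver_config, cfg$solver),
    damage = do.call(damage_thresholds, cfg$damage),
    grid = cfg$grid), class = "pipeline_config")
}

#' Write the report bundle of a scenario sweep
#'
#' Writes `grid.csv` (one tidy row per scenario cell; failed cells annotated),
#' `models.json` (response-surface coefficients, R^2, p-values per surface)
#' and `manifest.json` (package version, seed, config snapshot, content
#' hashes of every artifact, wall-time metadata) under `path`. The CSV is
#' byte-identical across re-runs with identical inputs.
#'
#' @param grid A `scenario_grid`.
#' @param models Named list of `response_surface_model` (may be `NULL`).
#' @param path Output directory (created if needed).
#' @param config Optional `pipeline_config` to snapshot.
#' @return Invisibly, the manifest list.
#' @export
write_report <- function(grid, models = NULL, path, config = NULL) {
  stopifnot(inherits(grid, "scenario_grid"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cells <- grid$cells
  csv_path <- file.path(path, "grid.csv")
  if (is.null(cells) || nrow(cells) == 0) {
    warning("empty scenario grid: writing header-only CSV")
    cells <- grid$cells[0, ]
  }
  utils::write.csv(cells, csv_path, row.names = FALSE)
  files <- csv_path
  if (!is.null(models)) {
    mj <- lapply(models, function(m) list(
      material = m$material, coefficients = as.list(m$coefficients),
      r_squared = m$r_squared, p_values = as.list(m$p_values),
      source = m$source))
    mpath <- file.path(path, "models.json")
    jsonlite::write_json(mj, mpath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, mpath)
  }
  manifest <- list(
    package = "fruitdrop",
    version = as.character(utils::packageVersion("fruitdrop")),
    seed = grid$seed,
    element_size_mm = grid$element_size,
    n_cells = nrow(grid$cells),
    n_failed = sum(grid$cells$failed),
    config = if (!is.null(config)) unclass(config$mesh) else NULL,
    artifacts = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))),
    written_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Export a mesh as legacy ASCII VTK
#'
#' Unstructured-grid export with the tetrahedra and skin triangles; region
#' labels and any per-element fields go out as CELL_DATA, node sets and
#' per-node fields as POINT_DATA. Readable by ParaView and meshio.
#'
#' @param mesh A `fruit_mesh`.
#' @param path Output `.vtk` file.
#' @param cell_data Named list of per-tetrahedron numeric vectors (skin
#'   triangles receive NA-padding as -1).
#' @param point_data Named list of per-node numeric vectors.
#' @return Invisibly, `path`.
#' @export
write_vtk <- function(mesh, path, cell_data = list(), point_data = list()) {
  stopifnot(inherits(mesh, "fruit_mesh"))
  n <- nrow(mesh$nodes)
  nt <- nrow(mesh$tets)
  ns <- nrow(mesh$skin_tris)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("fruitdrop mesh (mm)")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl("POINTS %d double", n)
  writeLines(apply(format(mesh$nodes, digits = 12, trim = TRUE,
                          scientific = FALSE), 1, paste, collapse = " "), con)
  wl("CELLS %d %d", nt + ns, 5 * nt + 4 * ns)
  writeLines(c(paste(4, mesh$tets[, 1] - 1, mesh$tets[, 2] - 1,
                     mesh$tets[, 3] - 1, mesh$tets[, 4] - 1),
               paste(3, mesh$skin_tris[, 1] - 1, mesh$skin_tris[, 2] - 1,
                     mesh$skin_tris[, 3] - 1)), con)
  wl("CELL_TYPES %d", nt + ns)
  writeLines(c(rep("10", nt), rep("5", ns)), con)
  wl("CELL_DATA %d", nt + ns)
  wl("SCALARS region int 1")
  wl("LOOKUP_TABLE default")
  writeLines(c(ifelse(mesh$region == "core", "2", "1"), rep("0", ns)), con)
  for (nm in names(cell_data)) {
    v <- cell_data[[nm]]
    pad <- if (length(v) == nt) rep(-1, ns) else NULL
    wl("SCALARS %s double 1", nm)
    wl("LOOKUP_TABLE default")
    writeLines(format(c(v, pad), digits = 9, trim = TRUE), con)
  }
  if (length(point_data) > 0 || length(mesh$node_sets$skin_surface) > 0) {
    wl("POINT_DATA %d", n)
    skin_flag <- integer(n)
    skin_flag[mesh$node_sets$skin_surface] <- 1L
    skin_flag[mesh$node_sets$core_interface] <- 2L
    wl("SCALARS node_set int 1")
    wl("LOOKUP_TABLE default")
    writeLines(as.character(skin_flag), con)
    for (nm in names(point_data)) {
      wl("SCALARS %s double 1", nm)
      wl("LOOKUP_TABLE default")
      writeLines(format(point_data[[nm]], digits = 9, trim = TRUE), con)
    }
  }
  invisible(path)
}

#' Import a tetrahedral mesh from legacy ASCII VTK
#'
#' Minimal reader for the format written by [write_vtk()]: reads points,
#' tetrahedral cells (type 10), triangle cells (type 5, used as the skin) and
#' an optional integer `region` cell field.
#'
#' @param path `.vtk` file path.
#' @param skin_thickness Membrane thickness (mm) to attach.
#' @param element_size Nominal element size (mm) recorded on the mesh.
#' @return A `fruit_mesh`.
#' @export
read_vtk <- function(path, skin_thickness = 0.3, element_size = NA_real_) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  np <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  nodes <- matrix(scan(text = lines[(ip + 1):(ip + np)], quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  ncl <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cell_rows <- strsplit(trimws(lines[(ic + 1):(ic + ncl)]), "\\s+")
  it <- grep("^CELL_TYPES", lines)[1]
  types <- as.integer(lines[(it + 1):(it + ncl)])
  tets <- do.call(rbind, lapply(cell_rows[types == 10L], function(r)
    as.integer(r[2:5]) + 1L))
  tris <- do.call(rbind, lapply(cell_rows[types == 5L], function(r)
    as.integer(r[2:4]) + 1L))
  if (is.null(tris)) tris <- matrix(integer(0), ncol = 3)
  region <- rep("flesh", nrow(tets))
  ir <- grep("^SCALARS region", lines)
  if (length(ir) > 0) {
    vals <- as.integer(lines[(ir[1] + 2):(ir[1] + 1 + ncl)])
    region <- ifelse(vals[types == 10L] == 2L, "core", "flesh")
  }
  new_fruit_mesh(nodes, tets, region, tris, skin_thickness, element_size)
}
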