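# Configuration-driven pipeline: geometry -> simulation -> markers -> RVI
# maps, with CSV/VTK/JSON outputs. A thin command-line wrapper around these
# functions ships in inst/cli/rvimap.R.

#' Assemble an experiment configuration
#'
#' Bundles every knob of a full in-silico mapping experiment. All stochastic
#' steps draw their seeds deterministically from the single `seed` here, so a
#' rerun with the same configuration is bit-identical.
#'
#' @param geometry An [infarct_spec()].
#' @param variant Border-zone variant: `"long_apd"`, `"slow_cv"` or
#'   `"homogeneous"`.
#' @param protocol A [pacing_protocol()].
#' @param tissue A [tissue_params()] (the variant is applied on top).
#' @param grids Named list describing recording grids; each entry is a list
#'   with a `kind` (`"high_density"`, `"decapolar"`, `"fan"`,
#'   `"multipolar_random"`) plus that placer's arguments.
#' @param methods,radii RVI interpolation methods and search radii to sweep.
#' @param threshold Vulnerability threshold, ms.
#' @param noise_sd Length-2 numeric `c(at, rt)` marker noise, ms; `c(0, 0)`
#'   disables noise.
#' @param seed Master seed.
#' @param outdir Output directory for the file-emitting commands.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(geometry = infarct_spec(),
                              variant = "long_apd",
                              protocol = pacing_protocol(),
                              tissue = tissue_params(),
                              grids = list(high_density = list(kind = "high_density")),
                              methods = c("nearest_neighbor", "average", "minimum"),
                              radii = c(4, 8, 16),
                              threshold = 50,
                              noise_sd = c(0, 0),
                              seed = 1L,
                              outdir = "rvimap-out") {
  stopifnot(inherits(geometry, "infarct_spec"),
            inherits(protocol, "pacing_protocol"),
            inherits(tissue, "tissue_params"))
  variant <- match.arg(variant, c("long_apd", "slow_cv", "homogeneous"))
  structure(list(geometry = geometry, variant = variant, protocol = protocol,
                 tissue = tissue, grids = grids, methods = methods,
                 radii = radii, threshold = threshold, noise_sd = noise_sd,
                 seed = as.integer(seed), outdir = outdir),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Every key is optional and falls back to the [experiment_config()] default.
#' Nested keys mirror the constructor arguments of [infarct_spec()],
#' [pacing_protocol()], [tissue_params()] and [ionic_params()].
#'
#' @param path YAML file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  geom <- do.call(infarct_spec, y$geometry %||% list())
  prot <- do.call(pacing_protocol, y$protocol %||% list())
  ion <- do.call(ionic_params, y$ionic %||% list())
  tp_args <- y$tissue %||% list()
  tp_args$ionic <- ion
  tis <- do.call(tissue_params, tp_args)
  experiment_config(
    geometry = geom, variant = y$variant %||% "long_apd",
    protocol = prot, tissue = tis,
    grids = y$grids %||% list(high_density = list(kind = "high_density")),
    methods = y$methods %||% c("nearest_neighbor", "average", "minimum"),
    radii = y$radii %||% c(4, 8, 16),
    threshold = y$threshold %||% 50,
    noise_sd = y$noise_sd %||% c(0, 0),
    seed = y$seed %||% 1L,
    outdir = y$outdir %||% "rvimap-out")
}

build_grid_from_config <- function(mesh, g, seed) {
  kind <- g$kind %||% "high_density"
  switch(kind,
    high_density = place_high_density(mesh),
    decapolar = place_decapolar(
      mesh, origin = unlist(g$origin),
      direction = unlist(g$direction %||% c(0, 1)),
      spacing_pattern = unlist(g$spacing_pattern %||% c(2, 8, 2, 8, 2, 8, 2, 8, 2))),
    fan = place_fan(
      mesh, origin = unlist(g$origin),
      arm_angles = unlist(g$arm_angles %||% c(-30, 0, 30)),
      direction = unlist(g$direction %||% c(0, 1)),
      spacing_pattern = unlist(g$spacing_pattern %||% c(2, 8, 2, 8, 2, 8, 2, 8, 2))),
    multipolar_random = place_multipolar_random(
      mesh, n_clusters = g$n_clusters %||% 50,
      cluster_radius = g$cluster_radius %||% 1.5,
      node_fraction = g$node_fraction %||% 0.05,
      seed = g$seed %||% seed),
    abort(sprintf("unknown grid kind '%s'", kind)))
}

config_json <- function(config) {
  jsonlite::toJSON(rapply(unclass(config), unclass, how = "replace"),
                   auto_unbox = TRUE, digits = NA, null = "null",
                   force = TRUE)
}

#' Run the full simulation stage of an experiment
#'
#' Builds the mesh and recording grids, applies the border-zone variant, runs
#' the monodomain simulation, extracts full-field and per-grid marker maps
#' (adding noise when configured) and, when `write = TRUE`, writes mesh,
#' grids, traces and marker CSVs plus a resolved-configuration JSON under
#' `config$outdir`.
#'
#' @param config An [experiment_config()].
#' @param write Write output files (default `TRUE`).
#' @return Invisibly, a list with `mesh`, `grids`, `sim`, `field_markers`
#'   and per-grid `markers`.
#' @export
cmd_simulate <- function(config, write = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  mesh <- build_idealized_infarct_sheet(config$geometry)
  params <- make_bz_variant(config$tissue, config$variant)
  grids <- purrr::imap(config$grids, function(g, nm)
    build_grid_from_config(mesh, g, derive_seed(config$seed, 1L)))
  sim <- run_monodomain(mesh, params, config$protocol,
                        grid = if (length(grids)) grids[[1]] else NULL)
  field <- markers_from_crossings(sim)
  markers <- purrr::imap(grids, function(g, nm) {
    # re-index full-field markers onto the grid's electrodes via host nodes
    out <- purrr::map_dfr(unique(field$beat), function(b) {
      fb <- field[field$beat == b, ]
      pos <- match(g$host_node, fb$electrode)
      tibble(electrode = g$electrode, beat = b,
             at = fb$at[pos], rt = fb$rt[pos])
    })
    out <- new_marker_map(out, sim$at_threshold, sim$rt_threshold,
                          attr(field, "onsets"))
    if (any(config$noise_sd > 0))
      out <- add_marker_noise(out, config$noise_sd[1], config$noise_sd[2],
                              seed = derive_seed(config$seed, 2L))
    out
  })
  if (write) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    od <- config$outdir
    writeLines(config_json(config), file.path(od, "config.json"))
    write_mesh_csv(mesh, file.path(od, "mesh.csv"))
    write_mesh_vtk(mesh, file.path(od, "mesh.vtk"))
    purrr::iwalk(grids, function(g, nm)
      write_grid_csv(g, file.path(od, sprintf("grid_%s.csv", nm))))
    purrr::iwalk(markers, function(m, nm)
      write_marker_csv(m, file.path(od, sprintf("markers_%s.csv", nm))))
    write_marker_csv(field, file.path(od, "markers_field.csv"))
    if (!is.null(sim$traces))
      utils::write.csv(sim$traces, file.path(od, "traces.csv"),
                       row.names = FALSE)
  }
  invisible(list(mesh = mesh, grids = grids, sim = sim,
                 field_markers = field, markers = markers))
}

#' Run the mapping stage of an experiment
#'
#' Sweeps the configured interpolation methods and search radii over a marker
#' map, writes one RVI-map CSV (and VTK for node-indexed maps) per
#' combination plus the summary sweep table.
#'
#' @param markers Single-beat `marker_map` (or pass `beat`).
#' @param grid The `recording_grid` the markers live on.
#' @param config An [experiment_config()].
#' @param mesh The host `labeled_mesh`.
#' @param beat Beat label to map (default `"S2"` when present).
#' @param write Write output files (default `TRUE`).
#' @return Invisibly, a list with `maps` (named list of `rvi_map`s) and
#'   `sweep` (the summary tibble).
#' @export
cmd_map <- function(markers, grid, config, mesh = NULL, beat = NULL,
                    write = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(beat) && "S2" %in% markers$beat) beat <- "S2"
  maps <- list()
  for (m in config$methods)
    for (r in config$radii) {
      cfg <- rvi_config(radius = r, method = m,
                        vulnerability_threshold = config$threshold)
      maps[[sprintf("%s_R%g", m, r)]] <-
        build_rvi_map(markers, grid, cfg, mesh = mesh, beat = beat)
    }
  sweep <- rvi_sweep(markers, grid, config$methods, config$radii,
                     mesh = mesh, beat = beat, threshold = config$threshold)
  if (write) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    od <- config$outdir
    purrr::iwalk(maps, function(mp, nm) {
      write_rvi_csv(mp, file.path(od, sprintf("rvi_%s.csv", nm)))
      if (attr(mp, "semantics") == "node" && !is.null(mesh))
        write_rvi_vtk(mp, mesh, file.path(od, sprintf("rvi_%s.vtk", nm)))
    })
    utils::write.csv(sweep, file.path(od, "sweep.csv"), row.names = FALSE)
    writeLines(config_json(config), file.path(od, "config.json"))
  }
  invisible(list(maps = maps, sweep = sweep))
}

# ---------------------------------------------------------------- writers --

#' Write a labeled mesh as CSV
#' @param mesh A `labeled_mesh`.
#' @param path Output file.
#' @export
write_mesh_csv <- function(mesh, path) {
  utils::write.csv(mesh$nodes, path, row.names = FALSE)
  invisible(path)
}

#' Write a labeled mesh as legacy VTK (structured points, region point data)
#' @inheritParams write_mesh_csv
#' @export
write_mesh_vtk <- function(mesh, path) {
  region_code <- match(mesh$nodes$region, c("MYO", "BZ", "SCAR")) - 1L
  write_vtk_structured(path, mesh, list(region = region_code),
                       title = "labeled infarct sheet")
}

#' Write a recording grid as CSV
#' @param grid A `recording_grid`.
#' @param path Output file.
#' @export
write_grid_csv <- function(grid, path) {
  df <- as.data.frame(grid)
  df$kind <- attr(grid, "kind")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a recording grid from CSV
#' @param path CSV written by [write_grid_csv()].
#' @param mesh Optional `labeled_mesh` to (re)compute host nodes.
#' @return A `recording_grid`.
#' @export
read_grid_csv <- function(path, mesh = NULL) {
  df <- utils::read.csv(path)
  stopifnot(all(c("electrode", "x", "y") %in% names(df)))
  kind <- if ("kind" %in% names(df)) df$kind[1] else "unknown"
  df$kind <- NULL
  new_recording_grid(df, kind = kind, mesh = mesh)
}

#' Write a marker map as CSV (explicit NA for undefined markers)
#' @param map A `marker_map`.
#' @param path Output file.
#' @export
write_marker_csv <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a marker map from CSV
#' @param path CSV with columns `electrode`, `beat`, `at`, `rt`.
#' @param at_threshold,rt_threshold Thresholds recorded in the map metadata.
#' @return A `marker_map`.
#' @export
read_marker_csv <- function(path, at_threshold = -20, rt_threshold = -70) {
  df <- utils::read.csv(path)
  stopifnot(all(c("electrode", "beat", "at", "rt") %in% names(df)))
  new_marker_map(df, at_threshold, rt_threshold)
}

#' Write an RVI map as CSV
#' @param map An `rvi_map`.
#' @param path Output file.
#' @export
write_rvi_csv <- function(map, path) {
  df <- as.data.frame(map)
  df$method <- attr(map, "method")
  df$radius <- attr(map, "radius")
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a node-indexed RVI map as legacy VTK point data
#' @param map A node-indexed `rvi_map`.
#' @param mesh The host `labeled_mesh`.
#' @param path Output file.
#' @export
write_rvi_vtk <- function(map, mesh, path) {
  if (attr(map, "semantics") != "node")
    abort("VTK export needs a node-indexed (nearest-neighbour) map")
  vals <- rep(NA_real_, nrow(mesh$nodes))
  vals[map$site] <- map$rvi
  vals[is.na(vals)] <- 9999  # sentinel for undefined sites
  write_vtk_structured(path, mesh, list(rvi = vals), title = "RVI map")
}

# legacy-VTK ASCII structured-points writer (2D sheet, z = 0)
write_vtk_structured <- function(path, mesh, point_data, title = "rvimap") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", mesh$nx, mesh$ny),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g 1", mesh$resolution, mesh$resolution),
               sprintf("POINT_DATA %d", mesh$nx * mesh$ny)), con)
  for (nm in names(point_data)) {
    v <- point_data[[nm]]
    is_int <- is.integer(v)
    writeLines(c(sprintf("SCALARS %s %s 1", nm, if (is_int) "int" else "float"),
                 "LOOKUP_TABLE default"), con)
    writeLines(paste(format(v, trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Write full-field voltage snapshots as a legacy-VTK series
#' @param sim A `sim_result` run with `snapshot_dt` set.
#' @param dir Output directory; one `vm_<time>.vtk` file per snapshot.
#' @export
write_snapshot_vtk_series <- function(sim, dir) {
  if (is.null(sim$snapshots)) abort("sim_result has no snapshots")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(sim$snapshots$times)) {
    t <- sim$snapshots$times[k]
    write_vtk_structured(
      file.path(dir, sprintf("vm_%07.1f.vtk", t)), sim$mesh,
      list(vm = sim$snapshots$vm[, k]),
      title = sprintf("Vm at t = %.1f ms", t))
  }
  invisible(dir)
}
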