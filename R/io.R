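#' File interchange: elevation CSV, result summaries, VTK fields
#'
#' Elevation maps travel as plain CSV (columns `x_mm`, `y_mm`,
#' `z_anterior_mm`, `z_posterior_mm`, one row per grid node, full double
#' precision), result summaries as JSON, field data as legacy-ASCII VTK.
#'
#' @name cli_io
NULL

#' Write an elevation pair to CSV
#'
#' @param pair an `elevation_pair`.
#' @param path output file.
#' @export
write_elevation_csv <- function(pair, path) {
  df <- elevation_as_cartesian(pair)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = ","), con)
  writeLines(apply(format(df, digits = 17, scientific = TRUE, trim = TRUE), 1,
                   paste, collapse = ","), con)
  invisible(path)
}

#' Read an elevation pair from CSV
#'
#' Expects the header `x_mm,y_mm,z_anterior_mm,z_posterior_mm` and rows
#' laying out a polar grid (as written by [write_elevation_csv()]); the grid
#' structure is reconstructed from the node radii/angles. The apex is
#' recentered so the innermost anterior height defines the origin convention.
#'
#' @param path CSV file.
#' @return an `elevation_pair`.
#' @export
read_elevation_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("x_mm", "y_mm", "z_anterior_mm", "z_posterior_mm")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0) {
    stop(sprintf("elevation CSV is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  bad <- which(!stats::complete.cases(df[need]))
  if (length(bad) > 0) {
    stop(sprintf("elevation CSV has missing/NaN values (first at data row %d)",
                 bad[1]))
  }
  r <- sqrt(df$x_mm^2 + df$y_mm^2)
  th <- atan2(df$y_mm, df$x_mm) %% (2 * pi)
  ru <- sort(unique(round(r, 9)))
  tu <- sort(unique(round(th, 9)))
  nr <- length(ru); na <- length(tu)
  if (nr * na != nrow(df)) {
    stop(sprintf("elevation CSV rows do not form a polar grid (%d x %d != %d rows)",
                 nr, na, nrow(df)))
  }
  ri <- match(round(r, 9), ru); ti <- match(round(th, 9), tu)
  z_ant <- matrix(NA_real_, nr, na); z_post <- matrix(NA_real_, nr, na)
  z_ant[cbind(ri, ti)] <- df$z_anterior_mm
  z_post[cbind(ri, ti)] <- df$z_posterior_mm
  if (any(is.na(z_ant))) stop("elevation CSV has duplicate or missing grid nodes")
  dr <- ru[2] - ru[1]
  grid <- structure(list(type = "polar", diameter = 2 * (max(ru) + dr / 2),
                         nr = nr, na = na, r = ru, theta = tu, dr = dr,
                         dtheta = tu[2] - tu[1]),
                    class = "polar_grid")
  structure(list(z_ant = z_ant, z_post = z_post, grid = grid, spec = NULL,
                 apex_origin = TRUE),
            class = "elevation_pair")
}

#' Write a map matrix (curvature/elevation/pachymetry) as CSV
#'
#' @param values nr x na matrix on a polar grid.
#' @param grid the `polar_grid`.
#' @param path output file.
#' @param value_name column name for the values.
#' @export
write_map_csv <- function(values, grid, path, value_name = "value") {
  xy <- grid_xy(grid)
  df <- data.frame(x_mm = as.vector(xy$x), y_mm = as.vector(xy$y),
                   v = as.vector(values))
  colnames(df)[3] <- value_name
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a deformed state as legacy-ASCII VTK
#'
#' Writes the hexahedral mesh with displacement vectors as point data and
#' von Mises stress (kPa), maximum principal Green strain and J as cell data
#' (Gauss values averaged per element).
#'
#' @param state a `deformed_state`.
#' @param path output `.vtk` file.
#' @param deformed write deformed (default) or reference coordinates.
#' @export
write_vtk <- function(state, path, deformed = TRUE) {
  mesh <- state$mesh
  nd <- if (deformed) state$nodes_def else mesh$nodes
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("corneafem deformed state")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl(sprintf("POINTS %d double", nrow(nd)))
  writeLines(apply(format(nd, digits = 10, trim = TRUE), 1, paste,
                   collapse = " "), con)
  ne <- nrow(mesh$hex)
  wl(sprintf("CELLS %d %d", ne, ne * 9))
  writeLines(apply(cbind(8L, mesh$hex - 1L), 1, paste, collapse = " "), con)
  wl(sprintf("CELL_TYPES %d", ne))
  writeLines(as.character(rep(12L, ne)), con)
  wl(sprintf("POINT_DATA %d", nrow(nd)))
  wl("VECTORS displacement double")
  U <- matrix(state$u, ncol = 3, byrow = TRUE)
  writeLines(apply(format(U, digits = 10, trim = TRUE), 1, paste,
                   collapse = " "), con)
  agg <- function(x) as.numeric(tapply(x * state$gp$weight, state$gp$elem, sum) /
                                  tapply(state$gp$weight, state$gp$elem, sum))
  wl(sprintf("CELL_DATA %d", ne))
  wl("SCALARS von_mises_kPa double 1"); wl("LOOKUP_TABLE default")
  writeLines(format(1000 * agg(state$gp$von_mises), digits = 8), con)
  wl("SCALARS green_strain_max double 1"); wl("LOOKUP_TABLE default")
  writeLines(format(agg(state$gp$strain_max), digits = 8), con)
  wl("SCALARS J double 1"); wl("LOOKUP_TABLE default")
  writeLines(format(agg(state$gp$J), digits = 8), con)
  invisible(path)
}

result_summary <- function(result) {
  ix <- function(b) list(
    central_D = b$central_D, paracentral_D = b$paracentral_D,
    cylinder_D = b$astigmatism$cylinder, axis_deg = b$astigmatism$axis_deg,
    pachymetry_central_um = b$pachymetry_central_um,
    bfs_radius_mm = b$bfs$radius_mm,
    wavefront_um = b$wavefront[c("spherical", "astigmatic", "coma",
                                 "trefoil", "tetrafoil", "rms_hoa")])
  list(preop = ix(result$preop), predicted = ix(result$predicted),
       changes = result$changes,
       regions = lapply(result$regions, function(rg) {
         lapply(rg, function(x) x[c("mean_stress_kPa", "sd_stress_kPa",
                                    "mean_strain", "sd_strain")])
       }),
       prestress = result$prestress, traction = result$traction,
       provenance = result$provenance)
}

#' Write a simulation result to a directory
#'
#' Writes `summary.json` (all indices, changes and region statistics),
#' curvature-map CSVs, VTK fields for both states, and a `manifest.json`
#' sufficient to reproduce the run (config snapshot, hashes, versions).
#'
#' @param result a `simulation_result`.
#' @param outdir output directory (created if needed).
#' @param config the [simulation_config()] of the run.
#' @return the manifest, invisibly.
#' @export
write_result <- function(result, outdir, config = NULL) {
  stopifnot(inherits(result, "simulation_result"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  summ <- result_summary(result)
  jsonlite::write_json(summ, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cm <- result$preop$curvature_map
  write_map_csv(cm$values, cm$grid, file.path(outdir, "curvature_preop.csv"),
                "curvature_D")
  cm2 <- result$predicted$curvature_map
  write_map_csv(cm2$values, cm2$grid,
                file.path(outdir, "curvature_predicted.csv"), "curvature_D")
  write_vtk(result$states$pre, file.path(outdir, "state_preop.vtk"))
  write_vtk(result$states$post, file.path(outdir, "state_predicted.vtk"))
  manifest <- list(
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    package_version = as.character(utils::packageVersion("corneafem")),
    config = if (is.null(config)) NULL else config_snapshot(config),
    config_hash = result$provenance$config_hash,
    seed = result$provenance$seed,
    files = c("summary.json", "curvature_preop.csv",
              "curvature_predicted.csv", "state_preop.vtk",
              "state_predicted.vtk"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

config_snapshot <- function(config) {
  sn <- unclass(config)
  sn$params <- unclass(sn$params)
  sn$fd <- unclass(sn$fd)
  sn$footprint <- unclass(sn$footprint)
  sn
}

#' Read a simulation configuration from YAML
#'
#' Top-level keys mirror the [simulation_config()] arguments; nested
#' `material`, `fiber_distribution` and `footprint` blocks mirror
#' [material_params()], [fiber_distribution()] and [pterygium_footprint()].
#' Unknown keys are an error.
#'
#' @param path YAML file.
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(block, fun) {
    if (is.null(block)) return(fun())
    bad <- setdiff(names(block), names(formals(fun)))
    if (length(bad) > 0) {
      stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
    }
    do.call(fun, block)
  }
  params <- take(y$material, material_params)
  fd <- take(y$fiber_distribution, fiber_distribution)
  fp <- take(y$footprint, pterygium_footprint)
  rest <- y[setdiff(names(y), c("material", "fiber_distribution", "footprint"))]
  bad <- setdiff(names(rest), names(formals(simulation_config)))
  if (length(bad) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  do.call(simulation_config,
          c(list(params = params, fd = fd, footprint = fp), rest))
}
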