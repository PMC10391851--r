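# Export to legacy ASCII VTK (viewable in ParaView and friends), CSV
# dumps of monitored points, and YAML run configuration.

#' Write a voxel model as VTK structured points
#'
#' Legacy ASCII VTK `STRUCTURED_POINTS` with the integer role label as
#' cell data (0 = air, otherwise the index into [ROLE_NAMES]).
#'
#' @param model A `voxel_model`.
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk_image <- function(model, path) {
  stopifnot(inherits(model, "voxel_model"))
  h <- model$voxel_size
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "cervifem labeled voxel model", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d",
                       model$nx + 1L, model$ny + 1L, model$nz + 1L),
               sprintf("ORIGIN %g %g %g", model$origin[1], model$origin[2],
                       model$origin[3]),
               sprintf("SPACING %g %g %g", h, h, h),
               sprintf("CELL_DATA %d", length(model$labels)),
               "SCALARS role_label int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(as.vector(model$labels)), con)
  invisible(path)
}

#' Write a hex mesh (optionally with solution fields) as VTK
#'
#' Legacy ASCII VTK `UNSTRUCTURED_GRID`; when `fields`/`solution` are
#' given, nodal displacements are attached as point data and Von Mises
#' stress as cell data.
#'
#' @param mesh A `hex_mesh`.
#' @param path Output `.vtk` path.
#' @param solution Optional `fsu_solution`.
#' @param fields Optional `fsu_fields`.
#' @return `path`, invisibly.
#' @export
write_vtk_mesh <- function(mesh, path, solution = NULL, fields = NULL) {
  stopifnot(inherits(mesh, "hex_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "cervifem hex mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", mesh$n_nodes)), con)
  utils::write.table(mesh$nodes, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", mesh$n_elem, 9L * mesh$n_elem), con)
  utils::write.table(cbind(8L, mesh$elem - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", mesh$n_elem), con)
  writeLines(paste(rep(12L, mesh$n_elem)), con)   # VTK_HEXAHEDRON
  cell_started <- FALSE
  writeLines(sprintf("CELL_DATA %d", mesh$n_elem), con)
  writeLines(c("SCALARS role int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(match(mesh$label, ROLE_NAMES)), con)
  if (!is.null(fields)) {
    writeLines(c("SCALARS von_mises double 1", "LOOKUP_TABLE default"), con)
    writeLines(paste(fields$von_mises), con)
  }
  if (!is.null(solution)) {
    writeLines(c(sprintf("POINT_DATA %d", mesh$n_nodes),
                 "VECTORS displacement double"), con)
    utils::write.table(solution$U, con, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write monitored points of a case to CSV
#'
#' Both channels (top-k stress and top-k displacement points) stacked
#' with a `channel` column.
#'
#' @param case An `fsu_case`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_points_csv <- function(case, path) {
  stopifnot(inherits(case, "fsu_case"))
  df <- rbind(cbind(channel = "stress", case$points$stress),
              cbind(channel = "displacement", case$points$displacement))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration from YAML or JSON
#'
#' Recognised keys: `surgery`, `bone_quality`, `load`, `voxel_size`,
#' `k_points`, plus nested `segment` (fields of [segment_spec()]) and
#' `plan` (fields of [surgical_plan()]) overrides.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file (JSON is a YAML
#'   subset).
#' @return List with elements ready for [run_case()] / [run_grid()]:
#'   `surgery`, `bone_quality`, `load`, `spec`, `plan`, `k_points`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  seg_args <- cfg$segment
  if (!is.null(cfg$voxel_size)) seg_args$voxel_size <- cfg$voxel_size
  spec <- do.call(segment_spec, if (is.null(seg_args)) list() else seg_args)
  plan <- NULL
  if (!is.null(cfg$plan) || !is.null(cfg$surgery)) {
    plan_args <- if (is.null(cfg$plan)) list() else cfg$plan
    if (!is.null(cfg$surgery)) plan_args$surgery <- toupper(gsub("-", "_", cfg$surgery))
    plan <- do.call(surgical_plan, plan_args)
  }
  list(surgery = if (is.null(cfg$surgery)) NULL else
         toupper(gsub("-", "_", cfg$surgery)),
       bone_quality = if (is.null(cfg$bone_quality)) "NBM" else
         toupper(cfg$bone_quality),
       load = if (is.null(cfg$load)) 100 else cfg$load,
       spec = spec, plan = plan,
       k_points = if (is.null(cfg$k_points)) 16L else cfg$k_points)
}
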