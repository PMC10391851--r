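# Full factorial experiment: {ACDF, MOD_ACDF, ACCF} x {NBM, OPA, OPS} x
# {100, 150, 200 N}, monitored-point extraction, and grid summaries.

#' Select monitored points of maximum variation
#'
#' Deterministically selects, among the monitored-surface elements, the
#' `k` elements with largest Von Mises stress and, separately, the `k`
#' with largest displacement magnitude. Ties are broken by lexicographic
#' (z, y, x) centroid order (ascending element index). Point coordinates
#' are recorded for reproducibility. The figure-point layout of any
#' particular clinical model is not claimed to be recovered; the scheme
#' is algorithmic so that results are reproducible.
#'
#' @param fields An `fsu_fields` object from [recover_stress()].
#' @param mesh The `hex_mesh` the fields belong to.
#' @param k Number of points per channel (default 16).
#' @param elements Candidate element set; default the mesh's
#'   `monitored_surface_elements`.
#' @return List with two data frames, `stress` and `displacement`, each
#'   with `point_id`, centroid coordinates (mm), `von_mises` (MPa) and
#'   `displacement_um`.
#' @export
select_monitored_points <- function(fields, mesh, k = 16L, elements = NULL) {
  stopifnot(inherits(fields, "fsu_fields"), inherits(mesh, "hex_mesh"))
  if (is.null(elements)) elements <- mesh$sets$monitored_surface_elements
  if (length(elements) < k)
    stop(sprintf(
      "only %d monitored surface elements but k = %d; use a finer voxel_size",
      length(elements), k))
  mk <- function(ord) {
    el <- elements[ord][seq_len(k)]
    data.frame(point_id = seq_len(k), element = el,
               x = mesh$centroids[el, 1], y = mesh$centroids[el, 2],
               z = mesh$centroids[el, 3],
               von_mises = fields$von_mises[el],
               displacement_um = 1000 * fields$disp_mag[el])
  }
  list(stress = mk(order(-fields$von_mises[elements], elements)),
       displacement = mk(order(-fields$disp_mag[elements], elements)))
}

#' Run one simulation case
#'
#' Full pipeline for one cell of the factorial: build geometry, apply
#' the construct, mesh, assemble with quality-degraded materials, fix
#' the lower surface of the monitored vertebra (C5 for ACDF/Mod ACDF,
#' C6 for ACCF) in all directions, apply the axial preload to the upper
#' surface of C4, solve, recover stresses, and extract the monitored
#' points. Deterministic given its configuration.
#'
#' @param surgery `"ACDF"`, `"ACCF"` or `"MOD_ACDF"`.
#' @param bone_quality `"NBM"`, `"OPA"` or `"OPS"`.
#' @param load Axial preload, N (100, 150 or 200 in the default design;
#'   any positive value is accepted).
#' @param spec A [segment_spec()].
#' @param plan A [surgical_plan()] (default: the plan for `surgery`).
#' @param k_points Monitored points per channel.
#' @param keep_fields Keep full field arrays in the result (larger object).
#' @return Object of class `fsu_case` with the monitored point tables,
#'   per-cell summary statistics, and solver diagnostics.
#' @examples
#' \donttest{
#' cs <- run_case("ACDF", "NBM", 100)
#' summary(cs)
#' }
#' @export
run_case <- function(surgery = c("ACDF", "ACCF", "MOD_ACDF"),
                     bone_quality = c("NBM", "OPA", "OPS"),
                     load = 100, spec = segment_spec(), plan = NULL,
                     k_points = 16L, keep_fields = FALSE) {
  surgery <- match.arg(surgery)
  bone_quality <- match.arg(bone_quality)
  model <- build_construct(surgery, spec, plan)
  mesh <- voxel_to_hexmesh(model)
  materials <- degrade_for_bone_quality(base_material_table(), bone_quality)
  sys <- assemble(mesh, materials)
  sys <- fix_nodes(sys, mesh$sets$inferior_fixed_nodes)
  sys <- apply_axial_load(sys, load)
  sol <- solve_system(sys)
  fields <- recover_stress(mesh, sol, materials)
  pts <- select_monitored_points(fields, mesh, k = k_points)
  .finish_case(surgery, bone_quality, load, mesh, sol, fields, pts,
               keep_fields)
}

.finish_case <- function(surgery, bone_quality, load, mesh, sol, fields,
                         pts, keep_fields) {
  sstat <- pts$stress$von_mises
  dstat <- pts$displacement$displacement_um
  peak_s <- pts$stress[1, c("x", "y", "z")]
  peak_d <- pts$displacement[1, c("x", "y", "z")]
  summary_row <- data.frame(
    surgery = surgery, bone_quality = bone_quality, load_N = load,
    stress_mean_MPa = mean(sstat), stress_sd_MPa = stats::sd(sstat),
    disp_mean_um = mean(dstat), disp_sd_um = stats::sd(dstat),
    peak_stress_x = peak_s$x, peak_stress_y = peak_s$y, peak_stress_z = peak_s$z,
    peak_disp_x = peak_d$x, peak_disp_y = peak_d$y, peak_disp_z = peak_d$z,
    reaction_balance_rel = sol$reaction_balance_rel,
    residual_rel = sol$residual_rel)
  structure(list(
    surgery = surgery, bone_quality = bone_quality, load = load,
    monitored_vertebra = mesh$monitored_vertebra,
    points = pts, summary = summary_row,
    n_nodes = mesh$n_nodes, n_elem = mesh$n_elem,
    mesh = if (keep_fields) mesh else NULL,
    fields = if (keep_fields) fields else NULL,
    solution = if (keep_fields) sol else NULL),
    class = "fsu_case")
}

#' @export
print.fsu_case <- function(x, ...) {
  cat(sprintf(
    "%s / %s / %g N (monitored: %s superior surface, %d elements, %d nodes)\n",
    x$surgery, x$bone_quality, x$load, x$monitored_vertebra, x$n_elem,
    x$n_nodes))
  cat(sprintf("  Von Mises over 16 stress points: %.3f +/- %.3f MPa\n",
              x$summary$stress_mean_MPa, x$summary$stress_sd_MPa))
  cat(sprintf("  displacement over 16 points:     %.2f +/- %.2f um\n",
              x$summary$disp_mean_um, x$summary$disp_sd_um))
  invisible(x)
}

#' @export
summary.fsu_case <- function(object, ...) {
  out <- object$summary
  class(out) <- c("summary.fsu_case", "data.frame")
  out
}

#' Run the full factorial grid
#'
#' Runs every surgery x bone-quality x load cell. Within one surgery x
#' quality family the stiffness matrix is identical across loads, so its
#' Cholesky factorization is computed once and reused (a
#' correctness-preserving optimization justified by linearity of the
#' static model). Per-cell failures are collected and reported; the grid
#' continues.
#'
#' @param surgeries,qualities,loads Factor levels of the design.
#' @param spec A [segment_spec()] shared by all cells.
#' @param plans Optional named list of [surgical_plan()]s per surgery.
#' @param k_points Monitored points per channel.
#' @return Object of class `fsu_grid`: `summary` data frame (one row per
#'   cell), per-cell monitored point tables in `cases`, and any collected
#'   `errors`.
#' @export
run_grid <- function(surgeries = c("ACDF", "MOD_ACDF", "ACCF"),
                     qualities = c("NBM", "OPA", "OPS"),
                     loads = c(100, 150, 200),
                     spec = segment_spec(), plans = NULL, k_points = 16L) {
  cases <- list(); errors <- list(); rows <- list()
  for (sg in surgeries) {
    plan <- if (!is.null(plans)) plans[[sg]] else NULL
    model <- tryCatch(build_construct(sg, spec, plan), error = identity)
    if (inherits(model, "error")) {
      errors[[sg]] <- conditionMessage(model); next
    }
    mesh <- voxel_to_hexmesh(model)
    for (bq in qualities) {
      materials <- degrade_for_bone_quality(base_material_table(), bq)
      res <- tryCatch({
        sys0 <- assemble(mesh, materials)
        sys0 <- fix_nodes(sys0, mesh$sets$inferior_fixed_nodes)
        fac <- make_factor(sys0)
        lapply(loads, function(ld) {
          sys <- apply_axial_load(sys0, ld)
          sol <- solve_system(sys, factor = fac)
          fields <- recover_stress(mesh, sol, materials)
          pts <- select_monitored_points(fields, mesh, k = k_points)
          .finish_case(sg, bq, ld, mesh, sol, fields, pts, FALSE)
        })
      }, error = identity)
      if (inherits(res, "error")) {
        errors[[paste(sg, bq, sep = ":")]] <- conditionMessage(res)
        next
      }
      for (cs in res) {
        key <- paste(sg, bq, cs$load, sep = ":")
        cases[[key]] <- cs
        rows[[key]] <- cs$summary
      }
    }
  }
  summary_df <- do.call(rbind, rows)
  rownames(summary_df) <- NULL
  structure(list(summary = summary_df, cases = cases, errors = errors,
                 loads = loads, surgeries = surgeries,
                 qualities = qualities, spec = spec),
            class = "fsu_grid")
}

#' @export
print.fsu_grid <- function(x, ...) {
  cat(sprintf("Factorial grid: %d cells (%d failed)\n",
              nrow(x$summary), length(x$errors)))
  df <- x$summary
  df$stress <- sprintf("%.2f +/- %.2f", df$stress_mean_MPa, df$stress_sd_MPa)
  df$displacement_um <- sprintf("%.2f +/- %.2f", df$disp_mean_um, df$disp_sd_um)
  print(df[, c("surgery", "bone_quality", "load_N", "stress", "displacement_um")],
        ...)
  if (length(x$errors)) {
    cat("Failures:\n")
    for (nm in names(x$errors)) cat("  ", nm, ": ", x$errors[[nm]], "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.fsu_grid <- function(object, ...) object$summary

#' Plot grid displacement and stress trends
#'
#' Base-graphics panel: mean monitored displacement (and optionally
#' stress) versus load, one line per surgery, one panel per bone
#' quality.
#'
#' @param x An `fsu_grid`.
#' @param channel `"displacement"` or `"stress"`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.fsu_grid <- function(x, channel = c("displacement", "stress"), ...) {
  channel <- match.arg(channel)
  col <- if (channel == "displacement") "disp_mean_um" else "stress_mean_MPa"
  ylab <- if (channel == "displacement") "mean displacement (um)" else
    "mean Von Mises stress (MPa)"
  qs <- x$qualities
  op <- graphics::par(mfrow = c(1, length(qs)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (bq in qs) {
    sub <- x$summary[x$summary$bone_quality == bq, ]
    m <- sapply(x$surgeries, function(sg) {
      s2 <- sub[sub$surgery == sg, ]
      s2[[col]][match(sort(x$loads), s2$load_N)]
    })
    graphics::matplot(sort(x$loads), m, type = "b", pch = 1:3, lty = 1,
                      xlab = "axial load (N)", ylab = ylab, main = bq, ...)
    graphics::legend("topleft", legend = x$surgeries, pch = 1:3, lty = 1,
                     col = seq_along(x$surgeries), bty = "n", cex = 0.8)
  }
  invisible(x)
}
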