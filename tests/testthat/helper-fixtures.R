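# Shared fixtures: hand-built voxel models, homogeneous bars, a
# scaled-down surgical configuration for fast pipeline tests, and the
# exhaustive permutation oracle for the Kruskal-Wallis test.

# minimal voxel model around an arbitrary label array
make_voxel_model <- function(labels, h = 1, surgery = "INTACT") {
  d <- dim(labels)
  structure(list(labels = labels, voxel_size = h, origin = c(0, 0, 0),
                 spec = NULL, levels = 1, surgery = surgery,
                 nx = d[1], ny = d[2], ny_body = d[2], nz = d[3],
                 vertebrae = list(V = list(name = "V", z1 = 1L, z2 = d[3],
                                           core_z1 = 1L, core_z2 = d[3])),
                 discs = list(), log = "synthetic test fixture"),
            class = "voxel_model")
}

# homogeneous rectangular bar of one role, nx x ny x nz voxels
make_bar_model <- function(nx, ny, nz, h = 1, role = "peek") {
  lab <- array(match(role, ROLE_NAMES), dim = c(nx, ny, nz))
  make_voxel_model(lab, h = h)
}

# material table with a single adjustable role at nu = 0 (closed-form bars)
bar_table <- function(E1 = 3600, E2 = NULL) {
  tab <- base_material_table()
  tab$entries$peek$young_modulus <- E1
  tab$entries$peek$poisson_ratio <- 0
  if (!is.null(E2)) {
    tab$entries$cancellous$young_modulus <- E2
    tab$entries$cancellous$poisson_ratio <- 0
  }
  tab
}

# fix a bar base in z plus minimal lateral restraints (statically
# determinate in the transverse plane, so the uniaxial state is exact)
fix_bar_base <- function(sys, mesh) {
  bot <- mesh$sets$inferior_fixed_nodes
  sys <- fix_dofs(sys, 3 * bot, 0)
  n1 <- bot[1]; n2 <- bot[length(bot)]
  fix_dofs(sys, c(3 * n1 - 2, 3 * n1 - 1, 3 * n2 - 1), 0)
}

# scaled-down two-level configuration for fast end-to-end tests
mini_spec <- function() segment_spec(vertebra_width_ml = 12,
                                     vertebra_depth_ap = 10,
                                     vertebra_height = 8, disc_height = 4)

mini_plan <- function(surgery = "ACDF") {
  surgical_plan(surgery, cage_dims = c(height = 4, ap = 8, ml = 8),
                osteotomy_notch = c(ml = 4, ap = 5),
                plate_length = 12, plate_width = 8,
                screw_diameter = 2, screw_length = 8, screw_offset_ml = 3)
}

# exhaustive permutation oracle for the Kruskal-Wallis p-value: every
# distinct assignment of the pooled values to the group sizes, statistic
# recomputed independently through stats::kruskal.test
kw_permutation_oracle <- function(samples) {
  sizes <- vapply(samples, length, 1L)
  pooled <- unlist(samples, use.names = FALSE)
  N <- length(pooled)
  H_obs <- suppressWarnings(
    stats::kruskal.test(pooled, factor(rep(seq_along(sizes), sizes)))$statistic)
  hits <- 0L; total <- 0L
  recurse <- function(avail, gi, assign) {
    if (gi == length(sizes)) {
      assign[avail] <- gi
      H <- suppressWarnings(stats::kruskal.test(pooled, factor(assign))$statistic)
      total <<- total + 1L
      if (H >= H_obs - 1e-12) hits <<- hits + 1L
      return(invisible())
    }
    for (p in utils::combn(avail, sizes[gi], simplify = FALSE)) {
      a2 <- assign; a2[p] <- gi
      recurse(setdiff(avail, p), gi + 1L, a2)
    }
  }
  recurse(seq_len(N), 1L, integer(N))
  hits / total
}
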