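code <- function(role) match(role, ROLE_NAMES)
bone_codes <- code(c("cortical", "cancellous", "bony_endplate"))

# bone voxels outside the screw tracks (screw insertion replaces bone)
bone_count_outside_screws <- function(model, reference) {
  scr <- reference$labels == code("titanium")
  sum(model$labels[!scr] %in% bone_codes)
}

test_that("intact stack has the configured heights and tissue layout", {
  m2 <- build_intact_segment(segment_spec(), 2)
  expect_equal(m2$nz, 2 * 12 + 5)
  m3 <- build_intact_segment(segment_spec(), 3)
  expect_equal(m3$nz, 3 * 12 + 2 * 5)
  expect_equal(names(m2$vertebrae), c("C5", "C4"))
  expect_equal(names(m3$vertebrae), c("C6", "C5", "C4"))
  # vertebra cross-sections: endplate faces, shell + core between
  expect_true(all(m2$labels[, 1:16, 1] == code("bony_endplate")))
  mid <- m2$labels[, 1:16, 6]
  expect_equal(mid[1, 1], code("cortical"))
  expect_equal(mid[12, 8], code("cancellous"))
  # nucleus occupies about the configured disc area fraction
  vc <- voxel_counts(m2)
  frac <- vc[["nucleus"]] / (vc[["nucleus"]] + vc[["annulus"]])
  nuc_perimeter_layer <- 2 * (16 + 10) * 3    # one voxel ring, 3 mid layers
  expect_lt(abs(frac - 0.40) * (vc[["nucleus"]] + vc[["annulus"]]),
            nuc_perimeter_layer)
  expect_error(build_intact_segment(segment_spec(vertebra_width_ml = 2)),
               "degenerate")
})

test_that("ACDF resects the disc, seats the cage, and spares vertebral bone", {
  intact <- build_intact_segment(segment_spec(), 2)
  m <- apply_acdf(intact)
  disc <- intact$discs[[1]]
  zr <- disc$z1:disc$z2
  expect_false(any(m$labels[, , zr] %in%
                     code(c("annulus", "nucleus", "cartilaginous_endplate"))))
  # cage bounding box 5 x 14 x 16 mm within one voxel
  idx <- which(m$labels == code("peek"), arr.ind = TRUE)
  expect_lte(abs(diff(range(idx[, 1])) + 1 - 16), 1)
  expect_lte(abs(diff(range(idx[, 2])) + 1 - 14), 1)
  expect_lte(abs(diff(range(idx[, 3])) + 1 - 5), 1)
  # 1 mm anterior clearance: no cage voxel in the anterior-most body layer
  expect_false(any(idx[, 2] >= m$ny_body))
  # vertebral bone preserved outside the screw tracks
  expect_equal(bone_count_outside_screws(m, m),
               bone_count_outside_screws(intact, m))
  expect_equal(m$surgery, "ACDF")
})

test_that("Mod ACDF cuts the planned notch and only removes extra bone", {
  intact <- build_intact_segment(segment_spec(), 2)
  acdf <- apply_acdf(intact)
  mod <- apply_mod_acdf(intact)
  # notch bounding box 8 (ML) x 9 (AP) within one voxel, opening posteriorly
  notch <- which(acdf$labels %in% bone_codes & mod$labels == 0L, arr.ind = TRUE)
  expect_gt(nrow(notch), 0)
  expect_lte(abs(diff(range(notch[, 1])) + 1 - 8), 1)
  expect_lte(abs(diff(range(notch[, 2])) + 1 - 9), 1)
  expect_equal(min(notch[, 2]), 1)               # reaches the posterior margin
  c5 <- intact$vertebrae$C5
  expect_true(all(notch[, 3] <= c5$z2 & notch[, 3] > c5$z1))
  expect_equal(max(notch[, 3]), c5$z2)           # reaches the superior surface
  # strictly less C5 bone than plain ACDF; nothing gains bone
  c5z <- c5$z1:c5$z2
  expect_lt(sum(mod$labels[, , c5z] %in% bone_codes),
            sum(acdf$labels[, , c5z] %in% bone_codes))
  expect_false(any(mod$labels %in% bone_codes & !(acdf$labels %in% bone_codes)))
  # degenerate zero-size notch is the identity edit
  mod0 <- apply_mod_acdf(intact,
                         surgical_plan("MOD_ACDF", osteotomy_notch = c(0, 0)))
  expect_identical(mod0$labels, acdf$labels)
  expect_error(
    apply_mod_acdf(intact, surgical_plan("MOD_ACDF",
                                         osteotomy_notch = c(30, 9))),
    "footprint")
})

test_that("ACCF carves the corpectomy corridor and seats the mesh", {
  intact <- build_intact_segment(segment_spec(), 3)
  m <- apply_accf(intact)
  c5 <- intact$vertebrae$C5
  c5z <- c5$z1:c5$z2
  # channel ML width 15 mm within one voxel, full height, full depth
  removed <- which(intact$labels[, , c5z] %in% bone_codes &
                     m$labels[, , c5z] == 0L, arr.ind = TRUE)
  expect_lte(abs(diff(range(removed[, 1])) + 1 - 15), 1)
  # two lateral columns of C5 remain (15 mm < 24 mm body width)
  mid_slab <- m$labels[, 1:16, c5z[5]]
  expect_true(any(mid_slab[1:4, ] %in% bone_codes))
  expect_true(any(mid_slab[21:24, ] %in% bone_codes))
  expect_false(any(mid_slab[12, ] %in% bone_codes))
  # titanium mesh: hollow ring, wall (10-8)/2 = 1 mm within one voxel
  zr_mid <- intact$discs[[1]]$z2 + 3
  ring <- m$labels[, , zr_mid] == code("titanium")
  ring_cols <- which(ring, arr.ind = TRUE)
  ring_cols <- ring_cols[ring_cols[, 2] < 17, , drop = FALSE]
  expect_gt(nrow(ring_cols), 0)
  row_mid <- ring[, round(mean(range(ring_cols[, 2])))]
  runs <- rle(row_mid)
  walls <- runs$lengths[runs$values]
  expect_equal(length(walls), 2)           # hollow: two wall crossings
  expect_true(all(abs(walls - 1) <= 1))
  expect_lte(abs(diff(range(ring_cols[, 1])) + 1 - 10), 1)  # outer diameter
  # mesh spans the defect from C6 superior to C4 inferior endplates
  zmesh <- range(which(apply(m$labels == code("titanium"), 3, any)))
  expect_lte(zmesh[1], intact$discs[[1]]$z1)
  expect_error(
    apply_accf(intact, surgical_plan("ACCF", corpectomy_width = 40)),
    "wider")
  expect_equal(m$surgery, "ACCF")
})

test_that("surgical edits are monotone on bone", {
  i2 <- build_intact_segment(segment_spec(), 2)
  i3 <- build_intact_segment(segment_spec(), 3)
  for (pair in list(list(apply_acdf(i2), i2),
                    list(apply_mod_acdf(i2), i2),
                    list(apply_accf(i3), i3))) {
    edited <- pair[[1]]; ref <- pair[[2]]
    expect_false(any(edited$labels %in% bone_codes &
                       !(ref$labels %in% bone_codes)))
  }
})

test_that("all default constructs are mirror-symmetric about the mid-sagittal plane", {
  for (m in list(build_intact_segment(segment_spec(), 2),
                 build_construct("ACDF"), build_construct("MOD_ACDF"),
                 build_construct("ACCF"))) {
    expect_identical(m$labels, m$labels[m$nx:1, , ],
                     info = m$surgery)
  }
})
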