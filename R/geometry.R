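# Idealized labeled-voxel geometry of the C4-C6 segment and the three
# surgical constructs applied as boolean edits on the label grid.
#
# Coordinate convention: x = medio-lateral (left positive), y =
# antero-posterior (anterior positive; y index 1 is the posterior face),
# z = cranio-caudal (cranial positive; z index 1 is the caudal face).
# Voxel k spans ((k-1)*h, k*h) mm along each axis, centre (k-0.5)*h.

#' Segment geometry specification
#'
#' Dimensions of the idealized subaxial cervical functional spinal unit.
#' Defaults are typical C4-C6 body dimensions; the grid allocates one
#' extra anterior voxel layer for the plate.
#'
#' @param vertebra_width_ml Vertebral body width, medio-lateral, mm.
#' @param vertebra_depth_ap Body depth, antero-posterior, mm.
#' @param vertebra_height Body height including bony endplates, mm.
#' @param disc_height Disc height including cartilaginous endplates, mm.
#' @param cortical_shell_layers Cortical shell thickness, voxel layers.
#' @param bony_endplate_layers Bony endplate thickness, voxel layers.
#' @param cartilaginous_endplate_layers Cartilaginous endplate thickness,
#'   voxel layers.
#' @param nucleus_area_fraction Fraction of the disc cross-section
#'   occupied by the nucleus pulposus.
#' @param voxel_size Voxel edge length, mm.
#' @return Object of class `segment_spec`.
#' @export
segment_spec <- function(vertebra_width_ml = 24, vertebra_depth_ap = 16,
                         vertebra_height = 12, disc_height = 5,
                         cortical_shell_layers = 1L,
                         bony_endplate_layers = 1L,
                         cartilaginous_endplate_layers = 1L,
                         nucleus_area_fraction = 0.40,
                         voxel_size = 1.0) {
  spec <- list(vertebra_width_ml = vertebra_width_ml,
               vertebra_depth_ap = vertebra_depth_ap,
               vertebra_height = vertebra_height,
               disc_height = disc_height,
               cortical_shell_layers = as.integer(cortical_shell_layers),
               bony_endplate_layers = as.integer(bony_endplate_layers),
               cartilaginous_endplate_layers = as.integer(cartilaginous_endplate_layers),
               nucleus_area_fraction = nucleus_area_fraction,
               voxel_size = voxel_size)
  lens <- c(spec$vertebra_width_ml, spec$vertebra_depth_ap,
            spec$vertebra_height, spec$disc_height, spec$voxel_size)
  if (any(lens <= 0)) stop("all lengths must be positive")
  hv_vox <- round(spec$vertebra_height / spec$voxel_size)
  if (2 * (spec$bony_endplate_layers + spec$cortical_shell_layers) >= hv_vox)
    stop("endplate + shell layers must be below half the vertebra height in voxels")
  structure(spec, class = "segment_spec")
}

#' Surgical plan
#'
#' Implant and resection dimensions for one construct. Defaults are the
#' catalogue values: PEEK cage 5 x 14 x 16 mm (height x AP x ML),
#' titanium mesh outer diameter 10 mm / inner 8 mm (length truncated to
#' the actual C4-C6 defect height), corpectomy width 15 mm, osteotomy
#' notch 8 mm (ML) x 9 mm (AP), anterior plates 1 x 20 x 16 mm
#' (two-level) and 1 x 22 x 16 mm (three-level), four 4 x 14 mm screws.
#' Implants keep a 1 mm clearance from the anterior vertebral edge.
#'
#' @param surgery One of `"INTACT"`, `"ACDF"`, `"ACCF"`, `"MOD_ACDF"`.
#' @param cage_dims Cage height, AP depth, ML width, mm.
#' @param mesh_diameter,mesh_inner_diameter Titanium mesh outer/inner
#'   diameter, mm.
#' @param corpectomy_width Width of the resected C5 channel, ML, mm.
#' @param osteotomy_notch Notch ML width and AP depth (from the posterior
#'   margin forward), mm; `c(0, 0)` disables the notch.
#' @param notch_depth Cranio-caudal notch depth from the C5 superior
#'   surface, mm; `NULL` means half the vertebral body height.
#' @param plate_thickness,plate_length,plate_width Anterior plate
#'   dimensions, mm; `plate_length = NULL` picks the catalogue length for
#'   the construct (20 two-level, 22 three-level), extended when needed to
#'   reach the screw anchor vertebrae.
#' @param plate_offset_from_anterior_edge Cage/mesh clearance, mm.
#' @param screw_diameter,screw_length Screw dimensions, mm.
#' @param screw_offset_ml Screw axis offset from the mid-sagittal plane, mm.
#' @return Object of class `surgical_plan`.
#' @export
surgical_plan <- function(surgery = c("INTACT", "ACDF", "ACCF", "MOD_ACDF"),
                          cage_dims = c(height = 5, ap = 14, ml = 16),
                          mesh_diameter = 10, mesh_inner_diameter = 8,
                          corpectomy_width = 15,
                          osteotomy_notch = c(ml = 8, ap = 9),
                          notch_depth = NULL,
                          plate_thickness = 1, plate_length = NULL,
                          plate_width = 16,
                          plate_offset_from_anterior_edge = 1,
                          screw_diameter = 4, screw_length = 14,
                          screw_offset_ml = 4.5) {
  surgery <- match.arg(surgery)
  if (is.null(plate_length))
    plate_length <- if (surgery == "ACCF") 22 else 20
  structure(list(surgery = surgery, cage_dims = cage_dims,
                 mesh_diameter = mesh_diameter,
                 mesh_inner_diameter = mesh_inner_diameter,
                 corpectomy_width = corpectomy_width,
                 osteotomy_notch = osteotomy_notch,
                 notch_depth = notch_depth,
                 plate_thickness = plate_thickness,
                 plate_length = plate_length, plate_width = plate_width,
                 plate_offset_from_anterior_edge = plate_offset_from_anterior_edge,
                 screw_diameter = screw_diameter,
                 screw_length = screw_length,
                 screw_offset_ml = screw_offset_ml),
            class = "surgical_plan")
}

# voxel indices (1..n) whose centres lie within [center - half, center + half] mm;
# symmetric about `center`, so mirror-symmetric features stay symmetric
.span_idx <- function(center, half, n, h) {
  ctr <- (seq_len(n) - 0.5) * h
  which(abs(ctr - center) <= half + 1e-9)
}

.role_code <- function(role) match(role, ROLE_NAMES)

# round a voxel count to the parity of `n` so a centred feature stays
# mirror-symmetric on the grid
.round_parity <- function(w, n) {
  cand <- c(floor(w), ceiling(w), floor(w) - 1, ceiling(w) + 1)
  cand <- cand[cand >= 1 & ((n - cand) %% 2 == 0)]
  cand[which.min(abs(cand - w))]
}

#' Build the intact stacked C4-C6 (or C4-C5) voxel model
#'
#' Stacks `levels` vertebral bodies separated by discs, caudal to cranial
#' (C5-C4 for two levels, C6-C5-C4 for three). Each vertebra is a bony
#' endplate / cortical shell + cancellous core / bony endplate sandwich;
#' each disc is a cartilaginous endplate / annulus ring with central
#' nucleus / cartilaginous endplate sandwich. The nucleus is a centred
#' rectangle with the body's aspect ratio occupying approximately
#' `nucleus_area_fraction` of the cross-section (parity-adjusted to keep
#' mid-sagittal mirror symmetry).
#'
#' @param spec A [segment_spec()].
#' @param levels 2 or 3 vertebral levels.
#' @return Object of class `voxel_model` with the integer label array
#'   (`0` = air, otherwise indices into [ROLE_NAMES]), voxel size, and
#'   per-vertebra/disc bookkeeping.
#' @export
build_intact_segment <- function(spec = segment_spec(), levels = 2) {
  stopifnot(inherits(spec, "segment_spec"), levels %in% c(2, 3))
  h <- spec$voxel_size
  nx <- round(spec$vertebra_width_ml / h)
  ny_body <- round(spec$vertebra_depth_ap / h)
  hv <- round(spec$vertebra_height / h)
  hd <- round(spec$disc_height / h)
  if (min(nx, ny_body, hv) < 3 || hd < 3)
    stop("degenerate dimensions: every tissue must span at least 3 voxels")
  ny <- ny_body + max(1L, round(1 / h))   # anterior allowance for the plate
  nz <- levels * hv + (levels - 1) * hd
  lab <- array(0L, dim = c(nx, ny, nz))

  nbe <- spec$bony_endplate_layers
  nsh <- spec$cortical_shell_layers
  nce <- spec$cartilaginous_endplate_layers
  if (hd - 2 * nce < 1) stop("disc too thin for its cartilaginous endplates")

  body_x <- seq_len(nx); body_y <- seq_len(ny_body)
  shell <- matrix(FALSE, nx, ny_body)
  shell[c(seq_len(nsh), nx - seq_len(nsh) + 1L), ] <- TRUE
  shell[, c(seq_len(nsh), ny_body - seq_len(nsh) + 1L)] <- TRUE

  # nucleus rectangle: body aspect ratio, parity-matched for symmetry
  wx <- .round_parity(nx * sqrt(spec$nucleus_area_fraction), nx)
  wy <- .round_parity(ny_body * sqrt(spec$nucleus_area_fraction), ny_body)
  nuc_x <- .span_idx(nx * h / 2, wx * h / 2, nx, h)
  nuc_y <- .span_idx(ny_body * h / 2, wy * h / 2, ny_body, h)

  vert_names <- if (levels == 2) c("C5", "C4") else c("C6", "C5", "C4")
  vertebrae <- list(); discs <- list()
  z <- 0L
  for (lv in seq_len(levels)) {
    z1 <- z + 1L; z2 <- z + hv
    # bony endplates top and bottom, cortical shell + cancellous core between
    for (k in z1:z2) {
      if (k - z1 < nbe || z2 - k < nbe) {
        lab[body_x, body_y, k] <- .role_code("bony_endplate")
      } else {
        slab <- matrix(.role_code("cancellous"), nx, ny_body)
        slab[shell] <- .role_code("cortical")
        lab[body_x, body_y, k] <- slab
      }
    }
    vertebrae[[vert_names[lv]]] <- list(
      name = vert_names[lv], z1 = z1, z2 = z2,
      core_z1 = z1 + nbe, core_z2 = z2 - nbe)
    z <- z2
    if (lv < levels) {
      d1 <- z + 1L; d2 <- z + hd
      for (k in d1:d2) {
        if (k - d1 < nce || d2 - k < nce) {
          lab[body_x, body_y, k] <- .role_code("cartilaginous_endplate")
        } else {
          lab[body_x, body_y, k] <- .role_code("annulus")
          lab[nuc_x, nuc_y, k] <- .role_code("nucleus")
        }
      }
      discs[[lv]] <- list(z1 = d1, z2 = d2)
      z <- d2
    }
  }

  structure(list(labels = lab, voxel_size = h, origin = c(0, 0, 0),
                 spec = spec, levels = levels, surgery = "INTACT",
                 nx = nx, ny = ny, ny_body = ny_body, nz = nz,
                 vertebrae = vertebrae, discs = discs,
                 log = sprintf("intact %d-level segment %dx%dx%d voxels",
                               levels, nx, ny, nz)),
            class = "voxel_model")
}

# --- internal edit helpers ---------------------------------------------------

.soft_codes <- function()
  .role_code(c("annulus", "nucleus", "cartilaginous_endplate"))

# remove disc tissue (annulus, nucleus, cartilaginous endplates) in the
# given z range, restricted to x indices `xs`
.resect_disc <- function(model, disc, xs = seq_len(model$nx)) {
  zr <- disc$z1:disc$z2
  sub <- model$labels[xs, , zr, drop = FALSE]
  sub[sub %in% .soft_codes()] <- 0L
  model$labels[xs, , zr] <- sub
  model
}

# anterior plate flush on the anterior cortical face, plus two screws per
# anchor vertebra, symmetric about the mid-sagittal plane
.add_plate_and_screws <- function(model, plan, anchors) {
  h <- model$voxel_size
  nx <- model$nx; ny <- model$ny; ny_body <- model$ny_body
  vb <- model$vertebrae[[anchors[1]]]; vt <- model$vertebrae[[anchors[2]]]
  zb <- (vb$z1 - 1 + vb$z2) / 2 * h   # caudal anchor mid-height, mm
  zt <- (vt$z1 - 1 + vt$z2) / 2 * h
  inset <- plan$screw_diameter / 2 + 1
  L <- plan$plate_length
  mid <- (zb + zt) / 2
  screw_lo <- mid - L / 2 + inset
  screw_hi <- mid + L / 2 - inset
  # screws must anchor inside their vertebra's cancellous core; stretch the
  # plate to the anchor mid-heights when the catalogue length cannot reach
  fits <- function(zc, v) {
    r <- plan$screw_diameter / 2
    zc - r >= (v$core_z1 - 1) * h && zc + r <= v$core_z2 * h
  }
  if (!fits(screw_lo, vb) || !fits(screw_hi, vt)) {
    screw_lo <- zb; screw_hi <- zt
    L <- (zt - zb) + 2 * inset
    mid <- (zb + zt) / 2
  }
  plate_z <- .span_idx(mid, L / 2, model$nz, h)
  plate_x <- .span_idx(nx * h / 2, plan$plate_width / 2, nx, h)
  plate_y <- (ny_body + 1):min(ny, ny_body + max(1L, round(plan$plate_thickness / h)))
  model$labels[plate_x, plate_y, plate_z] <- .role_code("titanium")

  # screws: cylinders along y from the outer plate face into cancellous bone
  xc_ctr <- nx * h / 2
  y_out <- max(plate_y) * h
  ys <- which((seq_len(ny) - 0.5) * h >= y_out - plan$screw_length - 1e-9 &
                (seq_len(ny) - 0.5) * h <= y_out + 1e-9)
  r <- plan$screw_diameter / 2
  xs_ctr <- (seq_len(nx) - 0.5) * h
  zs_ctr <- (seq_len(model$nz) - 0.5) * h
  for (sx in c(xc_ctr - plan$screw_offset_ml, xc_ctr + plan$screw_offset_ml)) {
    for (sz in c(screw_lo, screw_hi)) {
      d2 <- outer((xs_ctr - sx)^2, (zs_ctr - sz)^2, `+`)
      hit <- which(d2 <= r^2 + 1e-9, arr.ind = TRUE)
      for (i in seq_len(nrow(hit)))
        model$labels[hit[i, 1], ys, hit[i, 2]] <- .role_code("titanium")
    }
  }
  model$log <- c(model$log,
                 sprintf("plate %s-%s length %.1f mm + 4 screws", anchors[1],
                         anchors[2], L))
  model
}

.acdf_core <- function(model, plan, notch) {
  stopifnot(inherits(model, "voxel_model"), model$levels == 2,
            model$surgery == "INTACT")
  h <- model$voxel_size
  nx <- model$nx; ny_body <- model$ny_body
  disc <- model$discs[[1]]
  model <- .resect_disc(model, disc)
  model$log <- c(model$log, "C4/5 disc and cartilaginous endplates resected")

  if (notch) {
    nd <- plan$osteotomy_notch
    if (all(nd > 0)) {
      c5 <- model$vertebrae[[1]]
      depth <- plan$notch_depth
      if (is.null(depth)) depth <- (c5$z2 - c5$z1 + 1) * h / 2
      zx <- .span_idx(nx * h / 2, nd[[1]] / 2, nx, h)
      zy <- which((seq_len(model$ny) - 0.5) * h <= nd[[2]] + 1e-9)
      ztop <- c5$z2 * h
      zz <- .span_idx(ztop - depth / 2, depth / 2, model$nz, h)
      zz <- zz[zz >= c5$z1 & zz <= c5$z2]
      if (nd[[1]] > nx * h || nd[[2]] > ny_body * h)
        stop("osteotomy notch exceeds the vertebral body footprint")
      zy <- zy[zy <= ny_body]
      model$labels[zx, zy, zz] <- 0L
      model$log <- c(model$log,
                     sprintf("C5 notch %.0f x %.0f x %.1f mm excised",
                             nd[[1]], nd[[2]], depth))
    }
  }

  # PEEK cage in the cleared interspace, 1 mm behind the anterior edge
  cg <- plan$cage_dims
  clear <- plan$plate_offset_from_anterior_edge
  cx <- .span_idx(nx * h / 2, cg[[3]] / 2, nx, h)
  y_ant <- ny_body * h - clear
  cy <- .span_idx(y_ant - cg[[2]] / 2, cg[[2]] / 2, model$ny, h)
  dz_mid <- (disc$z1 - 1 + disc$z2) / 2 * h
  cz <- .span_idx(dz_mid, cg[[1]] / 2, model$nz, h)
  if (any(model$labels[cx, cy, cz] != 0L))
    stop("cage does not fit the created interspace")
  model$labels[cx, cy, cz] <- .role_code("peek")
  model$log <- c(model$log, "PEEK cage placed")

  .add_plate_and_screws(model, plan, c(names(model$vertebrae)[1], "C4"))
}

#' Apply the ACDF construct
#'
#' Resects the C4/5 disc with both adjacent cartilaginous endplates,
#' places the PEEK interbody cage 1 mm behind the anterior vertebral
#' edge, and adds the two-level anterior plate with four screws buried in
#' cancellous bone. No vertebral bone is removed outside the screw tracks.
#'
#' @param model Two-level intact [build_intact_segment()] output.
#' @param plan A [surgical_plan()].
#' @return Edited `voxel_model` with `surgery = "ACDF"`.
#' @export
apply_acdf <- function(model, plan = surgical_plan("ACDF")) {
  model <- .acdf_core(model, plan, notch = FALSE)
  model$surgery <- "ACDF"
  model
}

#' Apply the modified ACDF construct (partial vertebral osteotomy)
#'
#' ACDF plus excision of a rectangular notch from the superior aspect of
#' C5: `osteotomy_notch` mm ML x AP, the AP extent measured forward from
#' the posterior vertebral margin (the notch opens posteriorly, which is
#' the access corridor to a retro-vertebral ossified mass), to
#' `notch_depth` mm below the C5 superior surface (default half the body
#' height). The notch is cut before instrumentation; a zero-size notch
#' reproduces the ACDF edit exactly.
#'
#' @inheritParams apply_acdf
#' @return Edited `voxel_model` with `surgery = "MOD_ACDF"`.
#' @export
apply_mod_acdf <- function(model, plan = surgical_plan("MOD_ACDF")) {
  model <- .acdf_core(model, plan, notch = TRUE)
  model$surgery <- "MOD_ACDF"
  model
}

#' Apply the ACCF construct (corpectomy)
#'
#' Removes a central full-depth, full-height channel of the C5 body
#' (`corpectomy_width` mm ML) and both adjacent discs with their
#' cartilaginous endplates over the same corridor (lateral disc tissue is
#' retained so the residual lateral C5 columns stay load-bearing), then
#' places the hollow titanium mesh cylinder spanning the C4 inferior to
#' C6 superior bony endplates 1 mm behind the anterior edge, and the
#' three-level anterior plate with screws in C4 and C6.
#'
#' @param model Three-level intact [build_intact_segment()] output.
#' @param plan A [surgical_plan()].
#' @return Edited `voxel_model` with `surgery = "ACCF"`.
#' @export
apply_accf <- function(model, plan = surgical_plan("ACCF")) {
  stopifnot(inherits(model, "voxel_model"), model$levels == 3,
            model$surgery == "INTACT")
  h <- model$voxel_size
  nx <- model$nx; ny_body <- model$ny_body
  if (plan$corpectomy_width > model$spec$vertebra_width_ml)
    stop("corpectomy channel wider than the vertebral body")
  chan_x <- .span_idx(nx * h / 2, plan$corpectomy_width / 2, nx, h)
  c5 <- model$vertebrae$C5
  model$labels[chan_x, seq_len(ny_body), c5$z1:c5$z2] <- 0L
  model <- .resect_disc(model, model$discs[[1]], xs = chan_x)
  model <- .resect_disc(model, model$discs[[2]], xs = chan_x)
  model$log <- c(model$log,
                 sprintf("C5 corpectomy channel %.0f mm + disc resection over corridor",
                         plan$corpectomy_width))

  # hollow titanium mesh: open-annulus coverage rasterization so the 1 mm
  # wall stays face-connected at 1 mm voxels
  r_out <- plan$mesh_diameter / 2
  r_in <- plan$mesh_inner_diameter / 2
  axis_x <- nx * h / 2
  axis_y <- ny_body * h - plan$plate_offset_from_anterior_edge - r_out
  zr <- model$discs[[1]]$z1:model$discs[[2]]$z2
  xc <- (seq_len(nx) - 0.5) * h
  yc <- (seq_len(model$ny) - 0.5) * h
  ring <- matrix(FALSE, nx, model$ny)
  for (ix in seq_len(nx)) for (iy in seq_len(model$ny)) {
    dxlo <- abs(xc[ix] - axis_x) - h / 2; dxhi <- abs(xc[ix] - axis_x) + h / 2
    dylo <- abs(yc[iy] - axis_y) - h / 2; dyhi <- abs(yc[iy] - axis_y) + h / 2
    dmin <- sqrt(max(dxlo, 0)^2 + max(dylo, 0)^2)
    dmax <- sqrt(dxhi^2 + dyhi^2)
    ring[ix, iy] <- (dmin < r_out - 1e-9) && (dmax > r_in + 1e-9)
  }
  hit <- which(ring, arr.ind = TRUE)
  for (i in seq_len(nrow(hit))) {
    col <- model$labels[hit[i, 1], hit[i, 2], zr]
    if (any(col != 0L))
      stop("titanium mesh collides with remaining tissue")
    model$labels[hit[i, 1], hit[i, 2], zr] <- .role_code("titanium")
  }
  model$log <- c(model$log, "titanium mesh cylinder placed (length truncated to defect)")

  model <- .add_plate_and_screws(model, plan, c("C6", "C4"))
  model$surgery <- "ACCF"
  model
}

#' Apply a construct by name
#'
#' Convenience dispatcher: builds the intact segment at the right number
#' of levels (three for ACCF, otherwise two) and applies the edit.
#'
#' @param surgery Construct name.
#' @param spec A [segment_spec()].
#' @param plan A [surgical_plan()]; defaults to the plan for `surgery`.
#' @return A `voxel_model`.
#' @export
build_construct <- function(surgery = c("ACDF", "ACCF", "MOD_ACDF", "INTACT"),
                            spec = segment_spec(), plan = NULL) {
  surgery <- match.arg(surgery)
  levels <- if (surgery == "ACCF") 3 else 2
  model <- build_intact_segment(spec, levels)
  if (surgery == "INTACT") return(model)
  if (is.null(plan)) plan <- surgical_plan(surgery)
  switch(surgery,
         ACDF = apply_acdf(model, plan),
         MOD_ACDF = apply_mod_acdf(model, plan),
         ACCF = apply_accf(model, plan))
}

#' Count voxels per role
#'
#' @param model A `voxel_model`.
#' @return Named integer vector over [ROLE_NAMES] plus `air`.
#' @export
voxel_counts <- function(model) {
  n <- c(air = sum(model$labels == 0L),
         vapply(seq_along(ROLE_NAMES),
                function(i) sum(model$labels == i), integer(1)))
  names(n)[-1] <- ROLE_NAMES
  n
}

#' @export
print.voxel_model <- function(x, ...) {
  cat(sprintf("Labeled voxel model: %s, %d x %d x %d voxels @ %.3g mm\n",
              x$surgery, x$nx, x$ny, x$nz, x$voxel_size))
  cnt <- voxel_counts(x)
  print(cnt[cnt > 0])
  invisible(x)
}
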