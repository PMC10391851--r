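# Conversion of a labeled voxel model to an 8-node hexahedral mesh with
# shared-node (tied) interfaces and the named node/element sets the
# boundary conditions need.

#' Convert a labeled voxel model to a hexahedral mesh
#'
#' One trilinear hexahedron per non-air voxel; voxels sharing a face (or
#' edge, or corner) share nodes, i.e. all interfaces are tied. Elements
#' are numbered in lexicographic (z, y, x) traversal order (x fastest),
#' nodes likewise, so the conversion is fully deterministic. Element-local
#' node order is the VTK hexahedron convention: counter-clockwise bottom
#' face viewed from +z, `(0,0,0) (1,0,0) (1,1,0) (0,1,0)`, then the top
#' face in the same order.
#'
#' Named sets:
#' * `inferior_fixed_nodes` — nodes on the global caudal face (the lower
#'   surface of the caudal, monitored vertebra);
#' * `superior_C4_nodes` — nodes on the global cranial face (upper
#'   surface of C4), with area-tributary face weights for load lumping;
#' * `monitored_surface_elements` — for every (x, y) column, the topmost
#'   bone element within the caudal vertebra's height: the superior
#'   surface of C5 (ACDF / Mod ACDF, including the osteotomy floor) or C6
#'   (ACCF).
#'
#' Errors if the non-air region splits into parts that share no node
#' (such a floating part would make the stiffness matrix singular); the
#' error reports the component sizes.
#'
#' @param model A `voxel_model`.
#' @return Object of class `hex_mesh` with fields `nodes` (n x 3 mm),
#'   `elem` (m x 8 node indices), `label` (role name per element),
#'   `centroids` (m x 3 mm), `voxel_size`, `sets`, and provenance info.
#' @export
voxel_to_hexmesh <- function(model) {
  stopifnot(inherits(model, "voxel_model"))
  lab <- model$labels
  nx <- model$nx; ny <- model$ny; nz <- model$nz
  h <- model$voxel_size
  mask <- lab != 0L
  n_e <- sum(mask)
  if (n_e == 0L) stop("model has no non-air voxels")

  vox <- which(mask)                      # x fastest, then y, then z
  vi <- arrayInd(vox, dim(lab))           # n_e x 3 (ix, iy, iz)

  # connectivity through shared nodes = 26-neighbourhood on the voxel grid
  eidx <- array(0L, dim(lab)); eidx[vox] <- seq_len(n_e)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = 0:1))
  offs <- offs[offs[, 3] == 1 | offs[, 2] == 1 |
                 (offs[, 2] == 0 & offs[, 1] == 1), , drop = FALSE]
  edges <- integer(0)
  for (k in seq_len(nrow(offs))) {
    ni <- vi[, 1] + offs[k, 1]; nj <- vi[, 2] + offs[k, 2]
    nk <- vi[, 3] + offs[k, 3]
    ok <- ni >= 1 & ni <= nx & nj >= 1 & nj <= ny & nk >= 1 & nk <= nz
    if (!any(ok)) next
    nb <- eidx[cbind(ni[ok], nj[ok], nk[ok])]
    hit <- nb > 0L
    if (any(hit))
      edges <- c(edges, rbind(which(ok)[hit], nb[hit]))
  }
  g <- igraph::make_graph(edges, n = n_e, directed = FALSE)
  comp <- igraph::components(g)
  if (comp$no > 1L)
    stop(sprintf(
      "non-air region splits into %d node-disjoint components (sizes %s); the system would be singular",
      comp$no, paste(sort(comp$csize, decreasing = TRUE), collapse = ", ")))

  # node grid (nx+1)(ny+1)(nz+1), lexicographic (z, y, x) numbering
  nnx <- nx + 1L; nny <- ny + 1L
  node_lin <- function(ix, iy, iz) ix + nnx * (iy - 1L) + nnx * nny * (iz - 1L)
  corner <- cbind(c(0L, 1L, 1L, 0L, 0L, 1L, 1L, 0L),
                  c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L),
                  c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L))
  conn_lin <- matrix(0L, n_e, 8L)
  for (a in 1:8)
    conn_lin[, a] <- node_lin(vi[, 1] + corner[a, 1],
                              vi[, 2] + corner[a, 2],
                              vi[, 3] + corner[a, 3])
  used <- sort(unique(as.vector(conn_lin)))
  remap <- integer(nnx * nny * (nz + 1L)); remap[used] <- seq_along(used)
  elem <- matrix(remap[conn_lin], n_e, 8L)

  lin0 <- used - 1L
  ixn <- lin0 %% nnx
  iyn <- (lin0 %/% nnx) %% nny
  izn <- lin0 %/% (nnx * nny)
  nodes <- cbind(x = ixn * h, y = iyn * h, z = izn * h)
  nodes <- sweep(nodes, 2, model$origin, `+`)

  centroids <- sweep(cbind((vi[, 1] - 0.5) * h, (vi[, 2] - 0.5) * h,
                           (vi[, 3] - 0.5) * h), 2, model$origin, `+`)
  colnames(centroids) <- c("x", "y", "z")

  inferior <- which(izn == 0L)
  superior <- which(izn == nz)

  # area-tributary lumping: each top-surface element face spreads its
  # quarter weights onto its 4 top nodes
  top_els <- which(vi[, 3] == nz)
  wt <- numeric(length(used))
  for (a in 5:8) {
    tab <- tabulate(elem[top_els, a], nbins = length(used))
    wt <- wt + tab
  }
  sup_weights <- wt[superior]

  cv <- model$vertebrae[[1]]           # caudal = monitored vertebra
  bone <- .role_code(c("cortical", "cancellous", "bony_endplate"))
  sub <- lab[, , cv$z1:cv$z2, drop = FALSE]
  bmask <- array(sub %in% bone, dim(sub))
  mon <- integer(0)
  for (ix in seq_len(nx)) for (iy in seq_len(ny)) {
    zz <- which(bmask[ix, iy, ])
    if (length(zz))
      mon <- c(mon, eidx[ix, iy, cv$z1 - 1L + max(zz)])
  }
  mon <- sort(mon)

  structure(list(
    nodes = nodes, elem = elem,
    label = ROLE_NAMES[lab[vox]], centroids = centroids,
    voxel_size = h, n_nodes = length(used), n_elem = n_e,
    grid_dim = c(nx, ny, nz), voxel_index = vi,
    monitored_vertebra = cv$name, surgery = model$surgery,
    sets = list(inferior_fixed_nodes = inferior,
                superior_C4_nodes = superior,
                superior_face_weights = sup_weights,
                monitored_surface_elements = mon)),
    class = "hex_mesh")
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf(
    "Hex mesh (%s): %d nodes, %d elements @ %.3g mm\n  fixed caudal nodes: %d, loaded cranial nodes: %d, monitored surface elements: %d (%s)\n",
    x$surgery, x$n_nodes, x$n_elem, x$voxel_size,
    length(x$sets$inferior_fixed_nodes), length(x$sets$superior_C4_nodes),
    length(x$sets$monitored_surface_elements), x$monitored_vertebra))
  invisible(x)
}
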