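# Hexahedral finite-element forward model: one trilinear cube element per
# segmented voxel, reciprocity lead fields, and a direct-dipole solve used
# as an internal oracle. Geometry is carried in mm but all electrical
# quantities are SI (meters, siemens, amperes, volts).

# Local node offsets of the 8-node hexahedron, in the fixed ordering
# (0,0,0),(1,0,0),(0,1,0),(1,1,0),(0,0,1),(1,0,1),(0,1,1),(1,1,1).
hex_offsets <- function() {
  as.matrix(expand.grid(i = 0:1, j = 0:1, k = 0:1))
}

# Gradients of the 8 trilinear shape functions at local coords xi in [0,1]^3,
# for a box with edge lengths h (same units as the desired gradient^-1).
hex_shape_grad <- function(xi, h) {
  off <- hex_offsets()
  f <- function(o, x) ifelse(o == 1, x, 1 - x)
  df <- function(o) ifelse(off[, o] == 1, 1, -1)
  g <- matrix(0, 8, 3)
  fx <- f(off[, 1], xi[1]); fy <- f(off[, 2], xi[2]); fz <- f(off[, 3], xi[3])
  g[, 1] <- df(1) * fy * fz / h[1]
  g[, 2] <- fx * df(2) * fz / h[2]
  g[, 3] <- fx * fy * df(3) / h[3]
  g
}

#' Trilinear hexahedral element stiffness matrix
#'
#' The 8 x 8 conductance matrix of a single box element with edge lengths
#' `h_m` (meters) and isotropic conductivity `sigma`, integrated with
#' 2 x 2 x 2 Gauss quadrature (exact for the trilinear gradient products).
#'
#' @param h_m edge lengths (meters), scalar or length 3.
#' @param sigma conductivity (S/m).
#' @return 8 x 8 symmetric matrix (siemens).
#' @export
hex_element_stiffness <- function(h_m = 1, sigma = 1) {
  h_m <- rep(h_m, length.out = 3)
  gp <- 0.5 + c(-1, 1) / (2 * sqrt(3))  # 2-point Gauss on [0,1]
  K <- matrix(0, 8, 8)
  vol <- prod(h_m)
  for (x in gp) for (y in gp) for (z in gp) {
    G <- hex_shape_grad(c(x, y, z), h_m)
    K <- K + (G %*% t(G)) * (vol / 8)
  }
  sigma * K
}

#' Assemble the FEM stiffness matrix from a voxel segmentation
#'
#' Maps every non-air voxel to one hexahedral element with the voxel's
#' tissue conductivity and assembles the global conductance matrix over
#' the nodes touched by conducting voxels. The matrix is sparse,
#' symmetric, positive semi-definite with zero row sums (pure-Neumann
#' conservation); its nullspace (the constant potential) is fixed at
#' solve time.
#'
#' @param seg a [voxel_segmentation()].
#' @param cond a [conductivity_table()] covering every tissue in `seg`.
#' @return An object of class `stiffness_matrix` holding the sparse matrix
#'   `K`, node coordinates in mm (`node_coords_mm`), the conducting voxel
#'   bookkeeping, and a lazily cached factorization.
#' @export
assemble_stiffness <- function(seg, cond) {
  stopifnot(inherits(seg, "voxel_segmentation"))
  dims <- dim(seg$labels)
  lab <- as.integer(seg$labels)
  tissue_of <- setNames(names(seg$label_names), seg$label_names)
  used <- setdiff(sort(unique(lab)), 0L)
  missing_t <- setdiff(tissue_of[as.character(used)], names(cond))
  if (length(missing_t))
    stop("no conductivity for tissue(s): ", paste(missing_t, collapse = ", "))
  vox <- which(lab != 0L)
  if (!length(vox)) stop("segmentation has no conducting voxel")
  sig <- unname(cond[tissue_of[as.character(lab[vox])]])
  # voxel (i,j,k) from linear index
  idx <- arrayInd(vox, dims)
  nxn <- dims + 1L  # node grid
  node_id <- function(i, j, k) i + nxn[1] * ((j - 1L) + nxn[2] * (k - 1L))
  off <- hex_offsets()
  nodemat <- matrix(0L, length(vox), 8)
  for (a in 1:8) {
    nodemat[, a] <- node_id(idx[, 1] + off[a, 1], idx[, 2] + off[a, 2],
                            idx[, 3] + off[a, 3])
  }
  # compact node numbering over touched nodes
  nodes <- sort(unique(as.integer(nodemat)))
  cmp <- match(nodemat, nodes)
  dim(cmp) <- dim(nodemat)
  check_connected(vox, dims)
  h_m <- seg$voxel_size_mm / 1000
  Ke <- hex_element_stiffness(h_m, 1)
  ii <- cmp[, rep(1:8, times = 8)]
  jj <- cmp[, rep(1:8, each = 8)]
  xx <- outer(sig, as.vector(Ke))
  K <- Matrix::sparseMatrix(i = as.integer(ii), j = as.integer(jj),
                            x = as.numeric(xx),
                            dims = c(length(nodes), length(nodes)))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  # node coordinates: node (i,j,k) sits at the corner shared by voxels,
  # i.e. voxel center (i,j,k) minus half a voxel
  nijk <- arrayInd(nodes, nxn)
  coords <- voxel_to_mm(seg$affine, nijk) -
    matrix(seg$voxel_size_mm / 2, length(nodes), 3, byrow = TRUE)
  structure(list(K = K, node_coords_mm = coords, node_grid_id = nodes,
                 voxel_nodes = cmp, voxel_ijk = idx, voxel_sigma = sig,
                 voxel_lab = lab[vox], dims = dims, seg_affine = seg$affine,
                 voxel_size_mm = seg$voxel_size_mm,
                 cache = new.env(parent = emptyenv())),
            class = "stiffness_matrix")
}

#' @export
print.stiffness_matrix <- function(x, ...) {
  cat(sprintf("stiffness_matrix: %d nodes, %d elements, %.3g mm voxels\n",
              nrow(x$K), nrow(x$voxel_ijk), x$voxel_size_mm[1]))
  invisible(x)
}

# Face-adjacency connectivity check of the conducting voxel set.
check_connected <- function(vox, dims) {
  present <- logical(prod(dims))
  present[vox] <- TRUE
  pos <- arrayInd(vox, dims)
  edges <- NULL
  strides <- c(1L, dims[1], dims[1] * dims[2])
  for (d in 1:3) {
    ok <- pos[, d] < dims[d]
    nb <- vox[ok] + strides[d]
    keep <- present[nb]
    if (any(keep)) edges <- rbind(edges, cbind(vox[ok][keep], nb[keep]))
  }
  ids <- sort(unique(c(vox)))
  if (is.null(edges)) {
    if (length(vox) > 1)
      stop("conducting domain is disconnected: ", length(vox),
           " isolated voxels")
    return(invisible(TRUE))
  }
  g <- igraph::graph_from_edgelist(
    cbind(match(edges[, 1], ids), match(edges[, 2], ids)), directed = FALSE)
  g <- igraph::add_vertices(g, length(ids) - igraph::vcount(g))
  comp <- igraph::components(g)
  if (comp$no > 1)
    stop("conducting domain is disconnected; component sizes: ",
         paste(sort(comp$csize, decreasing = TRUE), collapse = ", "))
  invisible(TRUE)
}

# Cached sparse Cholesky of K with the gauge fixed by grounding node 1.
stiffness_factor <- function(stiff) {
  if (is.null(stiff$cache$factor)) {
    Kred <- stiff$K[-1, -1]
    stiff$cache$factor <- Matrix::Cholesky(Kred, LDL = FALSE, perm = TRUE,
                                           super = TRUE)
  }
  stiff$cache$factor
}

# Solve K u = b for one or many right-hand sides (columns). Potentials are
# gauge-fixed to zero mean over the conducting nodes. Residuals are
# verified against `tol`.
stiffness_solve <- function(stiff, b, tol = 1e-8) {
  b <- as.matrix(b)
  f <- stiffness_factor(stiff)
  u <- matrix(0, nrow(stiff$K), ncol(b))
  sol <- Matrix::solve(f, b[-1, , drop = FALSE])
  u[-1, ] <- as.matrix(sol)
  u <- sweep(u, 2, colMeans(u))
  bn <- sqrt(colSums(b^2))
  nz <- bn > 0
  if (any(nz)) {
    res <- sqrt(colSums(as.matrix(stiff$K %*% u[, nz, drop = FALSE] -
                                  b[, nz, drop = FALSE])^2)) / bn[nz]
    if (any(res > tol))
      stop(sprintf("FEM solve residual %.3g exceeds tolerance %.3g",
                   max(res), tol))
  }
  u
}

#' Solve a current-injection (TES-style) forward problem
#'
#' Injects `current_A` amperes at `source_node` and extracts it at
#' `sink_node`, returning the nodal potential field with zero-mean gauge.
#'
#' @param stiff a [assemble_stiffness()] result.
#' @param source_node,sink_node compact node indices (1-based, distinct).
#' @param current_A injected current (A).
#' @param tol relative residual tolerance for the linear solve.
#' @return Numeric vector of nodal potentials (V), zero mean.
#' @export
solve_current_injection <- function(stiff, source_node, sink_node,
                                    current_A = 1, tol = 1e-8) {
  stopifnot(inherits(stiff, "stiffness_matrix"))
  n <- nrow(stiff$K)
  stopifnot(source_node >= 1, source_node <= n,
            sink_node >= 1, sink_node <= n)
  if (source_node == sink_node) stop("source and sink must differ")
  b <- numeric(n)
  b[source_node] <- current_A
  b[sink_node] <- -current_A
  as.numeric(stiffness_solve(stiff, b, tol = tol))
}

#' Electrode montage
#'
#' Electrode names and mm positions; electrodes are snapped to the nearest
#' scalp-labelled FEM node when a lead field is computed.
#'
#' @param names character vector of channel names.
#' @param positions_mm L x 3 electrode coordinates (mm).
#' @param reference index (or name) of the reference electrode used for
#'   the reciprocity solves; output lead fields are average-referenced so
#'   this choice does not affect results.
#' @return An object of class `electrode_montage`.
#' @export
electrode_montage <- function(names, positions_mm, reference = 1L) {
  positions_mm <- as.matrix(positions_mm)
  L <- nrow(positions_mm)
  stopifnot(L >= 2, ncol(positions_mm) == 3, length(names) == L)
  if (is.character(reference)) reference <- match(reference, names)
  stopifnot(!is.na(reference), reference >= 1, reference <= L)
  structure(list(names = as.character(names), positions_mm = positions_mm,
                 reference = as.integer(reference)),
            class = "electrode_montage")
}

#' @export
print.electrode_montage <- function(x, ...) {
  cat(sprintf("electrode_montage: %d electrodes, reference %s\n",
              length(x$names), x$names[x$reference]))
  invisible(x)
}

# Snap each electrode to the nearest node belonging to a voxel with one of
# the given tissue labels.
snap_electrodes <- function(stiff, montage, scalp_labels) {
  sel <- stiff$voxel_lab %in% scalp_labels
  if (!any(sel)) stop("no voxels with scalp label(s) found")
  cand <- sort(unique(as.integer(stiff$voxel_nodes[sel, ])))
  pts <- stiff$node_coords_mm[cand, , drop = FALSE]
  vapply(seq_len(nrow(montage$positions_mm)), function(e) {
    d2 <- rowSums(sweep(pts, 2, montage$positions_mm[e, ])^2)
    cand[which.min(d2)]
  }, integer(1))
}

# Containing conducting voxel (row into stiff$voxel_ijk) for mm positions;
# returns NA where the position falls in air / outside.
containing_voxel <- function(stiff, xyz) {
  inv <- solve(stiff$seg_affine[1:3, 1:3])
  ijk0 <- t(inv %*% (t(as.matrix(xyz)) - stiff$seg_affine[1:3, 4]))
  ijk <- round(ijk0) + 1L
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  match(key(ijk), key(stiff$voxel_ijk))
}

#' Lead field by the reciprocity principle
#'
#' Computes the L x D gain matrix (scalp volts per unit dipole moment in
#' A*m, oriented along each patch normal) using one current-injection
#' solve per non-reference electrode instead of one solve per dipole. The
#' dipole-site electric field of each injection solve is evaluated from
#' the trilinear shape-function gradients of the containing voxel, and the
#' resulting matrix is re-referenced to the average reference.
#'
#' @param seg a [voxel_segmentation()].
#' @param cond a [conductivity_table()].
#' @param montage an [electrode_montage()].
#' @param ss a [source_space()]; dipoles must sit in gray-matter voxels
#'   (positions in other conducting tissue are snapped to the nearest
#'   gray-matter voxel with a warning).
#' @param stiff optional pre-assembled [assemble_stiffness()] result for
#'   `seg`/`cond` (reused across calls, e.g. by the conductivity grid).
#' @param gm_tissues tissue names whose voxels may host dipoles.
#' @param scalp_tissues tissue names whose nodes electrodes snap to.
#' @param current_A injection current used in the reciprocity solves.
#' @param verbose print the number of linear solves performed.
#' @return An object of class `lead_field` with fields `matrix` (L x D,
#'   average-referenced), `electrodes`, `avg_ref = TRUE` and `provenance`.
#' @export
compute_leadfield_reciprocity <- function(seg, cond, montage, ss,
                                          stiff = NULL,
                                          gm_tissues = c("gray_matter", "brain"),
                                          scalp_tissues = "scalp",
                                          current_A = 1,
                                          verbose = FALSE) {
  stopifnot(inherits(montage, "electrode_montage"),
            inherits(ss, "source_space"))
  if (is.null(stiff)) stiff <- assemble_stiffness(seg, cond)
  L <- length(montage$names)
  scalp_labels <- seg$label_names[intersect(scalp_tissues,
                                            names(seg$label_names))]
  if (!length(scalp_labels)) stop("no scalp tissue in segmentation")
  enodes <- snap_electrodes(stiff, montage, scalp_labels)
  gm_labels <- seg$label_names[intersect(gm_tissues, names(seg$label_names))]
  if (!length(gm_labels)) stop("no gray-matter tissue in segmentation")
  vx <- containing_voxel(stiff, ss$positions)
  pos_eval <- ss$positions
  bad <- is.na(vx)
  if (any(bad))
    stop("dipole(s) outside the conducting domain: ",
         paste(which(bad), collapse = ", "))
  not_gm <- !(stiff$voxel_lab[vx] %in% gm_labels)
  if (any(not_gm)) {
    warning(sum(not_gm), " dipole(s) outside gray matter snapped to the ",
            "nearest gray-matter voxel")
    gm_rows <- which(stiff$voxel_lab %in% gm_labels)
    gm_centers <- voxel_to_mm(stiff$seg_affine,
                              stiff$voxel_ijk[gm_rows, , drop = FALSE])
    for (d in which(not_gm)) {
      j <- which.min(rowSums(sweep(gm_centers, 2, ss$positions[d, ])^2))
      vx[d] <- gm_rows[j]
      pos_eval[d, ] <- gm_centers[j, ]
    }
  }
  ref <- montage$reference
  others <- setdiff(seq_len(L), ref)
  n <- nrow(stiff$K)
  B <- matrix(0, n, length(others))
  for (k in seq_along(others)) {
    B[enodes[others[k]], k] <- B[enodes[others[k]], k] + current_A
    B[enodes[ref], k] <- B[enodes[ref], k] - current_A
  }
  U <- stiffness_solve(stiff, B)
  if (verbose)
    message(sprintf("reciprocity: %d linear solves for %d electrodes",
                    length(others), L))
  # E-field at each dipole from trilinear gradients; reciprocity:
  # (V_e - V_ref) per unit moment = n^T grad(u_e) / I
  D <- nrow(ss$positions)
  lf <- matrix(0, L, D)
  h_m <- stiff$voxel_size_mm / 1000
  corner <- voxel_to_mm(stiff$seg_affine, stiff$voxel_ijk) -
    matrix(stiff$voxel_size_mm / 2, nrow(stiff$voxel_ijk), 3, byrow = TRUE)
  for (d in seq_len(D)) {
    v <- vx[d]
    xi <- (pos_eval[d, ] - corner[v, ]) / stiff$voxel_size_mm
    xi <- pmin(pmax(xi, 0), 1)
    G <- hex_shape_grad(xi, h_m)  # 8 x 3, 1/m
    nd <- stiff$voxel_nodes[v, ]
    grads <- t(U[nd, , drop = FALSE]) %*% G  # (L-1) x 3, V/m
    lf[others, d] <- as.numeric(grads %*% ss$normals[d, ]) / current_A
  }
  lf <- sweep(lf, 2, colMeans(lf))  # average reference
  structure(list(matrix = lf, electrodes = montage$names, avg_ref = TRUE,
                 provenance = list(conductivities = cond,
                                   voxel_size_mm = stiff$voxel_size_mm,
                                   n_nodes = n,
                                   seg_hash = rlang::hash(list(stiff$dims,
                                                               stiff$voxel_lab)))),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("lead_field: %d channels x %d dipoles (%saverage-referenced)\n",
              nrow(x$matrix), ncol(x$matrix), if (x$avg_ref) "" else "not "))
  invisible(x)
}

#' Direct FEM dipole forward solution
#'
#' Solves the forward problem for one explicit dipole by spreading the
#' dipole as a shape-function-gradient load over the nodes of its
#' containing voxel, then reads the potentials at the electrode nodes.
#' One linear solve per dipole; the reciprocity route is the production
#' path and this direct route serves as its validation oracle.
#'
#' @param stiff a [assemble_stiffness()] result.
#' @param position_mm dipole position (mm, length 3).
#' @param moment_Am dipole moment vector (A*m, length 3).
#' @param montage an [electrode_montage()].
#' @param scalp_labels integer labels whose nodes electrodes snap to.
#' @return Average-referenced scalp potentials (V), one per electrode.
#' @export
direct_dipole_forward <- function(stiff, position_mm, moment_Am, montage,
                                  scalp_labels) {
  stopifnot(inherits(stiff, "stiffness_matrix"))
  v <- containing_voxel(stiff, matrix(position_mm, 1))
  if (is.na(v)) stop("dipole outside the conducting domain")
  if (all(moment_Am == 0)) return(numeric(length(montage$names)))
  h_m <- stiff$voxel_size_mm / 1000
  corner <- voxel_to_mm(stiff$seg_affine,
                        stiff$voxel_ijk[v, , drop = FALSE]) -
    stiff$voxel_size_mm / 2
  xi <- (position_mm - as.numeric(corner)) / stiff$voxel_size_mm
  xi <- pmin(pmax(xi, 0), 1)
  G <- hex_shape_grad(xi, h_m)
  b <- numeric(nrow(stiff$K))
  b[stiff$voxel_nodes[v, ]] <- G %*% moment_Am
  u <- as.numeric(stiffness_solve(stiff, b))
  enodes <- snap_electrodes(stiff, montage, scalp_labels)
  y <- u[enodes]
  y - mean(y)
}

#' Compare two scalp topographies (RDM and MAG)
#'
#' The relative difference measure `RDM = || a/||a|| - b/||b|| ||` (0 =
#' identical pattern, 2 = opposite) and the magnitude ratio
#' `MAG = ||a|| / ||b||`.
#'
#' @param y_a,y_b numeric vectors of equal length, not all zero.
#' @return List with elements `RDM` and `MAG`.
#' @export
compare_topographies <- function(y_a, y_b) {
  stopifnot(length(y_a) == length(y_b))
  na <- sqrt(sum(y_a^2)); nb <- sqrt(sum(y_b^2))
  if (na == 0 || nb == 0) stop("cannot compare zero topographies")
  list(RDM = sqrt(sum((y_a / na - y_b / nb)^2)), MAG = na / nb)
}
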