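# Head-model data structures: labelled voxel segmentations, tissue
# conductivities, cortical source spaces and patch adjacency.

#' Labelled voxel segmentation
#'
#' A 3-D integer label grid plus the voxel-index to mm (RAS) affine map.
#' Label 0 always means air / background and is excluded from the
#' finite-element mesh.
#'
#' @param labels 3-D integer array of tissue labels (0 = air).
#' @param voxel_size_mm voxel edge lengths (scalar or length-3, mm).
#' @param label_names named integer vector mapping tissue name -> label.
#' @param origin_mm mm coordinate of the center of voxel (1,1,1)
#'   (default centers the grid on the origin).
#' @return An object of class `voxel_segmentation` with fields `labels`,
#'   `voxel_size_mm`, `affine` (4 x 4, 0-based voxel index -> mm) and
#'   `label_names`.
#' @export
voxel_segmentation <- function(labels, voxel_size_mm, label_names,
                               origin_mm = NULL) {
  stopifnot(length(dim(labels)) == 3)
  if (any(labels < 0)) stop("labels must be nonnegative")
  voxel_size_mm <- rep(as.numeric(voxel_size_mm), length.out = 3)
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be positive")
  label_names <- setNames(as.integer(label_names), names(label_names))
  present <- setdiff(sort(unique(as.integer(labels))), 0L)
  if (!all(present %in% label_names))
    stop("labels present in the grid but missing from label_names: ",
         paste(setdiff(present, label_names), collapse = ", "))
  if (is.null(origin_mm))
    origin_mm <- -(dim(labels) - 1) / 2 * voxel_size_mm
  affine <- diag(c(voxel_size_mm, 1))
  affine[1:3, 4] <- origin_mm
  structure(list(labels = labels, voxel_size_mm = voxel_size_mm,
                 affine = affine, label_names = label_names),
            class = "voxel_segmentation")
}

#' @export
print.voxel_segmentation <- function(x, ...) {
  cat(sprintf("voxel_segmentation: %s grid, %.3g x %.3g x %.3g mm voxels\n",
              paste(dim(x$labels), collapse = " x "),
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  tab <- table(factor(x$labels, levels = c(0L, unname(x$label_names)),
                      labels = c("air", names(x$label_names))))
  print(tab)
  invisible(x)
}

# mm coordinates of voxel centers for 1-based array indices (n x 3 matrix).
voxel_to_mm <- function(seg_or_affine, ijk) {
  affine <- if (is.matrix(seg_or_affine)) seg_or_affine else seg_or_affine$affine
  ijk0 <- as.matrix(ijk) - 1  # affine maps 0-based indices
  t(affine[1:3, 1:3] %*% t(ijk0) + affine[1:3, 4])
}

# Nearest 1-based voxel index for mm positions (n x 3 -> n x 3 integer).
mm_to_voxel <- function(seg, xyz) {
  inv <- solve(seg$affine[1:3, 1:3])
  ijk0 <- t(inv %*% (t(as.matrix(xyz)) - seg$affine[1:3, 4]))
  round(ijk0) + 1L
}

#' Tissue conductivity table
#'
#' Literature isotropic conductivities (S/m) per tissue. Defaults: white
#' matter 0.35, skull 0.01, scalp 0.33, CSF 1.79, gray matter 0.25,
#' eyeball 1.55 S/m. "air" is by convention excluded from the mesh.
#'
#' @param ... named scalar overrides or additions, e.g. `skull = 0.012`.
#' @return Named numeric vector of conductivities (S/m).
#' @export
conductivity_table <- function(...) {
  base <- c(white_matter = 0.35, skull = 0.01, scalp = 0.33,
            csf = 1.79, gray_matter = 0.25, eyeball = 1.55)
  over <- c(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("conductivity overrides must be named")
    base[names(over)] <- as.numeric(over)
  }
  if (any(base <= 0)) stop("conductivities must be > 0")
  base
}

#' Cortical source space
#'
#' One dipole per cortical patch: position (mm), unit orientation normal,
#' the originating patch id and a hemisphere flag.
#'
#' @param positions D x 3 dipole positions (mm).
#' @param normals D x 3 unit orientation vectors.
#' @param patch_id length-D patch labels.
#' @param hemisphere length-D hemisphere codes (e.g. "L"/"R").
#' @return An object of class `source_space`.
#' @export
source_space <- function(positions, normals, patch_id = seq_len(nrow(positions)),
                         hemisphere = rep("L", nrow(positions))) {
  positions <- as.matrix(positions)
  normals <- as.matrix(normals)
  D <- nrow(positions)
  stopifnot(D > 0, ncol(positions) == 3, all(dim(normals) == c(D, 3)))
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (any(abs(row_norms(normals) - 1) > 1e-9))
    stop("normals must have unit length")
  structure(list(positions = positions, normals = normals,
                 patch_id = patch_id, hemisphere = hemisphere),
            class = "source_space")
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("source_space: %d dipoles (%s)\n", nrow(x$positions),
              paste(sprintf("%s: %d", names(table(x$hemisphere)),
                            table(x$hemisphere)), collapse = ", ")))
  invisible(x)
}

#' Parcellate a cortical surface into equal-area patches
#'
#' Splits each hemisphere of a triangulated cortical mesh into
#' approximately equal-size patches and assigns one dipole per patch: the
#' dipole sits at the patch's area-weighted centroid snapped to the
#' nearest member vertex, oriented along the normalized mean of the
#' member-vertex normals. Parcellation is seeded region growing on the
#' mesh graph from farthest-point-sampled seeds, followed by
#' area-balancing boundary moves; it is deterministic given `seed`.
#'
#' @param mesh a [tri_mesh()]; must be manifold within each hemisphere.
#' @param patches_per_hemisphere number of patches per hemisphere (>= 1).
#' @param hemisphere optional per-vertex hemisphere codes; by default
#'   vertices are split by the sign of the x coordinate (RAS: left/right).
#' @param seed integer seed for the farthest-point seeding.
#' @param balance_iter maximum passes of area-balancing boundary moves.
#' @return A list with `source_space` (the [source_space()]), `patch` (the
#'   per-vertex patch assignment) and `patch_area` (mm^2 per patch).
#' @export
parcellate_cortex <- function(mesh, patches_per_hemisphere,
                              hemisphere = NULL, seed = 7L,
                              balance_iter = 40L) {
  stopifnot(inherits(mesh, "tri_mesh"), patches_per_hemisphere >= 1)
  check_manifold(mesh)
  nv <- nrow(mesh$vertices)
  if (is.null(hemisphere))
    hemisphere <- ifelse(mesh$vertices[, 1] < 0, "L", "R")
  stopifnot(length(hemisphere) == nv)
  vg <- vertex_geometry(mesh)
  edges <- mesh_edges(mesh)
  patch <- integer(nv)
  next_id <- 0L
  for (h in unique(hemisphere)) {
    vids <- which(hemisphere == h)
    sub_edges <- edges[hemisphere[edges[, 1]] == h &
                       hemisphere[edges[, 2]] == h, , drop = FALSE]
    assign <- parcellate_component(vids, sub_edges, mesh$vertices,
                                   vg$area, patches_per_hemisphere,
                                   seed, balance_iter)
    patch[vids] <- assign + next_id
    next_id <- next_id + patches_per_hemisphere
  }
  # patch areas; merge degenerate (zero-area) patches into a neighbor
  ids <- sort(unique(patch))
  area <- vapply(ids, function(p) sum(vg$area[patch == p]), numeric(1))
  if (any(area == 0)) {
    warning(sum(area == 0), " degenerate zero-area patch(es) merged")
    for (p in ids[area == 0]) {
      members <- which(patch == p)
      nbr <- unique(patch[c(edges[edges[, 1] %in% members, 2],
                            edges[edges[, 2] %in% members, 1])])
      nbr <- setdiff(nbr, p)
      if (length(nbr)) patch[members] <- nbr[1]
    }
    ids <- sort(unique(patch))
    area <- vapply(ids, function(p) sum(vg$area[patch == p]), numeric(1))
  }
  # dipole per patch: area-weighted centroid -> nearest member vertex
  D <- length(ids)
  pos <- matrix(0, D, 3)
  nrm <- matrix(0, D, 3)
  hemi <- character(D)
  for (k in seq_len(D)) {
    members <- which(patch == ids[k])
    w <- vg$area[members]
    if (sum(w) == 0) w <- rep(1, length(members))
    cen <- colSums(mesh$vertices[members, , drop = FALSE] * w) / sum(w)
    d2 <- rowSums(sweep(mesh$vertices[members, , drop = FALSE], 2, cen)^2)
    anchor <- members[which.min(d2)]
    pos[k, ] <- mesh$vertices[anchor, ]
    mn <- colSums(vg$normal[members, , drop = FALSE] * w)
    nrm[k, ] <- mn / sqrt(sum(mn^2))
    hemi[k] <- hemisphere[anchor]
  }
  ss <- source_space(pos, nrm, patch_id = ids, hemisphere = hemi)
  list(source_space = ss, patch = patch, patch_area = setNames(area, ids))
}

# Region-grow `k` patches over one connected vertex set; returns 1..k per
# vertex of `vids`.
parcellate_component <- function(vids, sub_edges, vertices, varea, k,
                                 seed, balance_iter) {
  nv_local <- length(vids)
  if (k > nv_local) stop("more patches requested than vertices available")
  local <- match(sub_edges, vids)
  dim(local) <- dim(sub_edges)
  g <- igraph::graph_from_edgelist(local, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nv_local - igraph::vcount(g)))
  if (igraph::components(g)$no > 1)
    stop("hemisphere surface is not connected")
  # farthest-point seeds in graph-hop distance
  set.seed(seed)
  seeds <- integer(k)
  seeds[1] <- sample.int(nv_local, 1L)
  dmin <- as.numeric(igraph::distances(g, v = seeds[1]))
  if (k > 1) for (i in 2:k) {
    seeds[i] <- which.max(dmin)
    dmin <- pmin(dmin, as.numeric(igraph::distances(g, v = seeds[i])))
  }
  dmat <- igraph::distances(g, v = seeds)  # k x nv hop distances
  assign <- apply(dmat, 2, which.min)
  assign[seeds] <- seq_len(k)
  # area balancing: move boundary vertices from over-full to under-full
  # neighboring patches (keeps patches connected "enough" for equal areas)
  area_of <- function(a) vapply(seq_len(k), function(p)
    sum(varea[vids[a == p]]), numeric(1))
  target <- sum(varea[vids]) / k
  for (it in seq_len(balance_iter)) {
    pa <- area_of(assign)
    if (max(pa) <= 2.5 * min(pa)) break
    moved <- FALSE
    b <- which(assign[local[, 1]] != assign[local[, 2]])
    for (e in b) {
      u <- local[e, 1]; v <- local[e, 2]
      pu <- assign[u]; pv <- assign[v]
      wu <- varea[vids[u]]; wv <- varea[vids[v]]
      if (pa[pu] > target && pa[pv] < target &&
          pa[pu] - pa[pv] > wu && u != seeds[pu]) {
        pa[pu] <- pa[pu] - wu; pa[pv] <- pa[pv] + wu
        assign[u] <- pv; moved <- TRUE
      } else if (pa[pv] > target && pa[pu] < target &&
                 pa[pv] - pa[pu] > wv && v != seeds[pv]) {
        pa[pv] <- pa[pv] - wv; pa[pu] <- pa[pu] + wv
        assign[v] <- pu; moved <- TRUE
      }
    }
    if (!moved) break
  }
  assign
}

#' Patch adjacency from shared mesh edges
#'
#' Two patches are neighbors if and only if they share at least one mesh
#' edge; proximity in Euclidean distance alone (e.g. across the
#' inter-hemispheric gap) does not create adjacency.
#'
#' @param ss a [source_space()] from [parcellate_cortex()].
#' @param mesh the mesh that was parcellated.
#' @param patch the per-vertex patch assignment from [parcellate_cortex()].
#' @return D x D sparse binary symmetric adjacency matrix with zero
#'   diagonal (a `Matrix::sparseMatrix`).
#' @export
build_adjacency <- function(ss, mesh, patch) {
  stopifnot(inherits(ss, "source_space"), length(patch) == nrow(mesh$vertices))
  if (any(patch == 0)) stop("patch assignment must cover all mesh vertices")
  ids <- ss$patch_id
  edges <- mesh_edges(mesh)
  pi_ <- match(patch[edges[, 1]], ids)
  pj_ <- match(patch[edges[, 2]], ids)
  keep <- pi_ != pj_
  D <- length(ids)
  A <- Matrix::sparseMatrix(i = c(pi_[keep], pj_[keep]),
                            j = c(pj_[keep], pi_[keep]),
                            x = 1, dims = c(D, D))
  A@x[] <- 1  # binary
  iso <- which(Matrix::rowSums(A) == 0)
  if (length(iso))
    warning(length(iso), " isolated patch(es) with no neighbors")
  A
}
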