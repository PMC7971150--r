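# Triangle-mesh utilities used by the cortical source-space builder.

#' Create a triangle mesh
#'
#' Light container for a triangulated surface: vertices in mm and 1-based
#' triangle indices. Used as the input to [parcellate_cortex()].
#'
#' @param vertices numeric matrix, V x 3, vertex coordinates (mm).
#' @param faces integer matrix, F x 3, 1-based vertex indices per triangle.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3, nrow(faces) >= 1)
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# Undirected edge list (E x 2, each row sorted) of a mesh.
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

# Each edge of a closed manifold surface belongs to exactly two faces.
check_manifold <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  if (any(tab > 2))
    stop("non-manifold mesh: ", sum(tab > 2), " edges shared by > 2 faces")
  invisible(TRUE)
}

# Per-face areas and (un-normalized) outward normals.
face_geometry <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  list(area = 0.5 * row_norms(cr), normal = cr)
}

# Vertex areas (one third of incident triangle areas) and area-weighted
# vertex normals.
vertex_geometry <- function(mesh) {
  fg <- face_geometry(mesh)
  nv <- nrow(mesh$vertices)
  varea <- numeric(nv)
  vnorm <- matrix(0, nv, 3)
  for (k in 1:3) {
    idx <- mesh$faces[, k]
    varea <- varea + unname(tapply_add(idx, fg$area / 3, nv))
    for (d in 1:3)
      vnorm[, d] <- vnorm[, d] + tapply_add(idx, fg$normal[, d], nv)
  }
  nrm <- row_norms(vnorm)
  ok <- nrm > 0
  vnorm[ok, ] <- vnorm[ok, , drop = FALSE] / nrm[ok]
  list(area = varea, normal = vnorm)
}

# Sum `val` into bins `idx` of length n (fast aggregate).
tapply_add <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, group = idx, reorder = FALSE)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Icosphere test surface
#'
#' Subdivided icosahedron: the standard quasi-uniform triangulated sphere,
#' handy as a stand-in cortical surface for phantoms and tests.
#'
#' @param subdivisions number of 4-to-1 triangle subdivisions (0 = plain
#'   icosahedron, 20 faces; each level multiplies faces by 4).
#' @param radius sphere radius (mm).
#' @return A [tri_mesh()] with outward-oriented faces.
#' @export
icosphere <- function(subdivisions = 2, radius = 1) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / row_norms(v)
  for (s in seq_len(subdivisions)) {
    midkey <- new.env(hash = TRUE)
    nf <- matrix(0L, 0, 3)
    getmid <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- midkey[[key]]
      if (is.null(id)) {
        m <- (v[i, ] + v[j, ]) / 2
        m <- m / sqrt(sum(m^2))
        v <<- rbind(v, m)
        id <- nrow(v)
        midkey[[key]] <- id
      }
      id
    }
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c3 <- f[k, 3]
      ab <- getmid(a, b); bc <- getmid(b, c3); ca <- getmid(c3, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  tri_mesh(v * radius, f)
}
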