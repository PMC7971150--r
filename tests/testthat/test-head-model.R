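# Cortical parcellation, source spaces and patch adjacency.

test_that("segmentation and conductivity containers validate their inputs", {
  lab <- array(0L, c(4, 4, 4)); lab[2:3, 2:3, 2:3] <- 1L
  seg <- voxel_segmentation(lab, 2, c(gray_matter = 1L))
  expect_equal(dim(seg$affine), c(4, 4))
  expect_error(voxel_segmentation(lab - 1L, 2, c(gray_matter = 1L)),
               "nonnegative")
  expect_error(voxel_segmentation(lab, 0, c(gray_matter = 1L)), "positive")
  expect_error(voxel_segmentation(lab, 2, c(skull = 2L)), "missing")
  ct <- conductivity_table()
  expect_equal(unname(ct[c("white_matter", "skull", "scalp", "csf",
                           "gray_matter", "eyeball")]),
               c(0.35, 0.01, 0.33, 1.79, 0.25, 1.55))
  expect_equal(unname(conductivity_table(skull = 0.02)["skull"]), 0.02)
  expect_error(conductivity_table(skull = -1), "> 0")
})

test_that("one patch per hemisphere of a sphere yields two radial dipoles", {
  mesh <- icosphere(2, radius = 50)
  p <- parcellate_cortex(mesh, 1)
  ss <- p$source_space
  expect_equal(nrow(ss$positions), 2)
  radial <- rowSums(ss$normals * ss$positions) / sqrt(rowSums(ss$positions^2))
  expect_true(all(abs(radial - 1) < 1e-9))    # outward radial
  expect_equal(unname(row_norms <- sqrt(rowSums(ss$normals^2))),
               c(1, 1), tolerance = 1e-9)
})

test_that("icosphere parcellation yields near-equal patch areas", {
  mesh <- icosphere(2, radius = 50)  # 320 faces
  p <- parcellate_cortex(mesh, 8)    # 16 patches
  # brute-force per-face area accumulation
  fg <- hexsource:::face_geometry(mesh)
  va <- hexsource:::vertex_geometry(mesh)$area
  area_bf <- vapply(p$source_space$patch_id,
                    function(id) sum(va[p$patch == id]), numeric(1))
  expect_equal(unname(p$patch_area), area_bf, tolerance = 1e-12)
  expect_lt(max(p$patch_area), 3 * median(p$patch_area))
  expect_gt(min(p$patch_area), median(p$patch_area) / 3)
  # total area conserved
  expect_equal(sum(p$patch_area), sum(fg$area), tolerance = 1e-6)
})

test_that("patch adjacency equals a brute-force edge scan", {
  mesh <- icosphere(2, radius = 50)
  p <- parcellate_cortex(mesh, 8)
  A <- suppressWarnings(build_adjacency(p$source_space, mesh, p$patch))
  expect_equal(max(abs(A - Matrix::t(A))), 0)   # symmetric
  expect_equal(max(Matrix::diag(A)), 0)         # zero diagonal
  expect_true(all(A@x %in% c(0, 1)))
  edges <- hexsource:::mesh_edges(mesh)
  ids <- p$source_space$patch_id
  D <- length(ids)
  Abf <- matrix(0, D, D)
  for (e in seq_len(nrow(edges))) {
    i <- match(p$patch[edges[e, 1]], ids)
    j <- match(p$patch[edges[e, 2]], ids)
    if (i != j) { Abf[i, j] <- 1; Abf[j, i] <- 1 }
  }
  expect_equal(as.matrix(A), Abf, ignore_attr = TRUE)
})

test_that("patches touching only across the hemispheric gap are not adjacent", {
  # two hemisphere meshes separated by a 2 mm gap: Euclidean-closest
  # patches across the gap share no mesh edge, hence no adjacency
  m <- icosphere(1, radius = 20)
  keepL <- m$vertices[, 1] < -1e-6
  keepR <- m$vertices[, 1] > 1e-6
  shift <- function(v, dx) sweep(v, 2, c(dx, 0, 0), "+")
  vs <- rbind(shift(m$vertices, -21), shift(m$vertices, 21))
  fs <- rbind(m$faces, m$faces + nrow(m$vertices))
  mesh <- tri_mesh(vs, fs)
  hemi <- rep(c("L", "R"), each = nrow(m$vertices))
  p <- parcellate_cortex(mesh, 4, hemisphere = hemi)
  A <- suppressWarnings(build_adjacency(p$source_space, mesh, p$patch))
  hl <- p$source_space$hemisphere
  cross <- A[hl == "L", hl == "R"]
  expect_equal(sum(cross), 0)
})

test_that("flipping mesh orientation flips every dipole normal", {
  mesh <- icosphere(2, radius = 30)
  flipped <- tri_mesh(mesh$vertices, mesh$faces[, c(1, 3, 2)])
  p1 <- parcellate_cortex(mesh, 8)
  p2 <- parcellate_cortex(flipped, 8)
  expect_equal(p2$source_space$normals, -p1$source_space$normals,
               tolerance = 1e-12)
})

test_that("non-manifold meshes are rejected", {
  mesh <- icosphere(0, 10)
  bad <- tri_mesh(mesh$vertices, rbind(mesh$faces, mesh$faces[1, ]))
  expect_error(parcellate_cortex(bad, 2), "non-manifold")
})
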