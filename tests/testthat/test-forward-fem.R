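# Hexahedral FEM assembly, current-injection solves, reciprocity lead
# fields and the direct-dipole oracle.

test_that("element stiffness matches an independent Simpson-rule integral", {
  h <- c(1.5, 2, 2.5) / 1000
  sigma <- 0.42
  K <- hex_element_stiffness(h, sigma)
  expect_equal(K, t(K))
  expect_lt(max(abs(rowSums(K))), 1e-15)
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-15)
  # Simpson's rule is exact for the (quadratic per axis) integrand
  sw <- c(1, 4, 1) / 6
  pts <- c(0, 0.5, 1)
  Kref <- matrix(0, 8, 8)
  for (a in 1:3) for (b in 1:3) for (c3 in 1:3) {
    G <- hexsource:::hex_shape_grad(c(pts[a], pts[b], pts[c3]), h)
    Kref <- Kref + (G %*% t(G)) * sw[a] * sw[b] * sw[c3] * prod(h)
  }
  expect_equal(K, sigma * Kref, tolerance = 1e-13)
})

test_that("assembled stiffness conserves current and rejects bad domains", {
  ph <- phantom8()
  st <- ph$stiff
  expect_lt(max(abs(Matrix::rowSums(st$K))) / max(abs(st$K@x)), 1e-8)
  expect_equal(max(abs(st$K - Matrix::t(st$K))), 0)
  # two disconnected blocks
  lab <- array(0L, c(5, 3, 3))
  lab[1, , ] <- 1L; lab[5, , ] <- 1L
  seg <- voxel_segmentation(lab, 5, c(gray_matter = 1L))
  expect_error(assemble_stiffness(seg, c(gray_matter = 1)),
               "disconnected.*component sizes")
  # missing conductivity
  seg2 <- voxel_segmentation(array(1L, c(2, 2, 2)), 5, c(skull = 1L))
  expect_error(assemble_stiffness(seg2, c(gray_matter = 1)),
               "no conductivity")
})

test_that("plate injection through a homogeneous cube gives a linear profile", {
  n <- 10
  seg <- voxel_segmentation(array(1L, c(n, n, n)), 10, c(gray_matter = 1L))
  st <- assemble_stiffness(seg, c(gray_matter = 1))
  xs <- st$node_coords_mm[, 1]
  face <- function(v) which(xs == v)
  # area-consistent nodal injection: corner/edge nodes carry less area
  w_of <- function(idx) {
    y <- st$node_coords_mm[idx, 2]; z <- st$node_coords_mm[idx, 3]
    wy <- ifelse(y %in% range(st$node_coords_mm[, 2]), 0.5, 1)
    wz <- ifelse(z %in% range(st$node_coords_mm[, 3]), 0.5, 1)
    wy * wz
  }
  b <- numeric(nrow(st$K))
  src <- face(min(xs)); snk <- face(max(xs))
  b[src] <- w_of(src) / sum(w_of(src))
  b[snk] <- -w_of(snk) / sum(w_of(snk))
  u <- hexsource:::stiffness_solve(st, b)
  fit <- stats::lm(as.numeric(u) ~ xs)
  expect_lt(stats::sd(stats::resid(fit)) / diff(range(u)), 0.01)
})

test_that("current-injection solves are linear and antisymmetric", {
  ph <- phantom8()
  st <- ph$stiff
  u0 <- solve_current_injection(st, 10, 200, current_A = 0)
  expect_equal(u0, numeric(nrow(st$K)))
  u1 <- solve_current_injection(st, 10, 200, 1)
  u2 <- solve_current_injection(st, 200, 10, 1)
  expect_equal(u2, -u1, tolerance = 1e-10)
  u3 <- solve_current_injection(st, 10, 200, 2.5)
  expect_equal(u3, 2.5 * u1, tolerance = 1e-10)
  expect_error(solve_current_injection(st, 5, 5), "differ")
})

test_that("antipodal injection matches the analytic point-current sphere field", {
  cond <- conductivity_table(skull = 0.33, gray_matter = 0.33)
  seg <- make_sphere_segmentation(c(80, 85, 92), 4)
  st <- assemble_stiffness(seg, cond)
  xyz <- st$node_coords_mm
  r <- sqrt(rowSums(xyz^2))
  top <- which.min(rowSums(sweep(xyz, 2, c(0, 0, 92))^2))
  bot <- which.min(rowSums(sweep(xyz, 2, c(0, 0, -92))^2))
  u <- solve_current_injection(st, top, bot, 1)
  # analytic: superposed surface point sources in an insulated sphere,
  # V = I/(4 pi sigma) sum_n (2n+1)/(n R) (r/R)^n P_n(cos gamma)
  set.seed(1)
  sel <- sample(which(r < 70 & r > 20), 400)
  R <- 0.092; sig <- 0.33
  Va <- numeric(length(sel))
  for (sgn in c(1, -1)) {
    cg <- sgn * xyz[sel, 3] / r[sel]
    rr <- r[sel] / 1000
    P <- hexsource:::legendre_p(80, cg)
    v <- numeric(length(sel))
    for (n in 1:80) v <- v + (2 * n + 1) / (n * R) * (rr / R)^n * P[n + 1, ]
    Va <- Va + sgn * v / (4 * pi * sig)
  }
  cmp <- compare_topographies(u[sel] - mean(u[sel]), Va - mean(Va))
  expect_lt(cmp$RDM, 0.05)
})

test_that("reciprocity lead field uses L-1 solves and matches the direct solve", {
  ph <- phantom8()
  expect_message(
    suppressWarnings(compute_leadfield_reciprocity(
      ph$seg, ph$cond, ph$montage, ph$ss, stiff = ph$stiff, verbose = TRUE)),
    "31 linear solves for 32 electrodes")
  # average-referenced columns sum to zero
  expect_lt(max(abs(colSums(ph$lf$matrix))) / max(abs(ph$lf$matrix)), 1e-10)
  scalp_label <- ph$seg$label_names["scalp"]
  for (d in c(3, 20, 77)) {
    yd <- direct_dipole_forward(ph$stiff, ph$ss$positions[d, ],
                                ph$ss$normals[d, ], ph$montage, scalp_label)
    cmp <- compare_topographies(ph$lf$matrix[, d], yd)
    # identical discrete dipole models: agreement far below the 1e-6 bound
    expect_lt(cmp$RDM, 1e-6)
    expect_equal(cmp$MAG, 1, tolerance = 1e-6)
  }
})

test_that("direct dipole forward is linear in the moment", {
  ph <- phantom8()
  scalp_label <- ph$seg$label_names["scalp"]
  pos <- ph$ss$positions[5, ]
  y0 <- direct_dipole_forward(ph$stiff, pos, c(0, 0, 0), ph$montage,
                              scalp_label)
  expect_equal(y0, numeric(32))
  y1 <- direct_dipole_forward(ph$stiff, pos, c(1e-9, 2e-9, 0), ph$montage,
                              scalp_label)
  y2 <- direct_dipole_forward(ph$stiff, pos, 2 * c(1e-9, 2e-9, 0),
                              ph$montage, scalp_label)
  expect_equal(y2, 2 * y1, tolerance = 1e-10)
  expect_error(direct_dipole_forward(ph$stiff, c(200, 0, 0), c(0, 0, 1e-9),
                                     ph$montage, scalp_label), "outside")
})

test_that("dipoles outside gray matter are snapped with a warning", {
  ph <- phantom8()
  bad_ss <- source_space(rbind(c(0, 0, 86), c(0, 0, 40)),
                         rbind(c(0, 0, 1), c(0, 0, 1)))  # first in skull
  expect_warning(
    compute_leadfield_reciprocity(ph$seg, ph$cond, ph$montage, bad_ss,
                                  stiff = ph$stiff),
    "snapped")
})

test_that("topography comparison returns hand-computed RDM and MAG", {
  expect_equal(compare_topographies(c(1, 2, 3), c(1, 2, 3)),
               list(RDM = 0, MAG = 1))
  y <- c(0.3, -0.1, 0.8, -1)
  cmp <- compare_topographies(y, 2 * y)
  expect_equal(cmp$RDM, 0)
  expect_equal(cmp$MAG, 0.5)
  a <- c(1, 2, -1, 0); b <- c(0, 1, 1, -2)
  cmp <- compare_topographies(a, b)
  expect_equal(cmp$RDM, sqrt(5 / 3), tolerance = 1e-12)  # hand arithmetic
  expect_equal(cmp$MAG, 1)
  expect_error(compare_topographies(c(0, 0), c(1, 1)), "zero")
})
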