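# VOI evaluation metrics: CoM, LE, SD, Foc, conductivity grid.

# small segmentation with a VOI carved out around a point
tiny_voi <- function(voxel_mm = 1, center = c(0, 0, 0), radius = 4) {
  n <- 17
  seg <- voxel_segmentation(array(1L, c(n, n, n)), voxel_mm,
                           c(gray_matter = 1L))
  ss <- source_space(matrix(center, 1), matrix(c(0, 0, 1), 1))
  voi <- make_voi(ss, seg, 1, radius)
  list(seg = seg, voi = voi)
}

test_that("center of mass is the |s|-weighted average of selected dipoles", {
  ss <- source_space(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(5, 5, 5)),
                     matrix(rep(c(0, 0, 1), 4), ncol = 3, byrow = TRUE))
  expect_equal(center_of_mass(list(dipoles = 2, intensities = -3), ss),
               c(0, 1, 0))
  expect_equal(center_of_mass(list(dipoles = c(1, 2),
                                   intensities = c(2, -2)), ss),
               c(0.5, 0.5, 0))  # equal |s|: midpoint
  expect_equal(center_of_mass(list(dipoles = 1:3,
                                   intensities = c(1, -2, 3)), ss),
               c(1, 2, 3) / 6)  # hand arithmetic
  # convex-hull property on random selections
  set.seed(31)
  pos <- matrix(rnorm(30), 10, 3)
  ss2 <- source_space(pos, matrix(rep(c(0, 0, 1), 10), ncol = 3, byrow = TRUE))
  for (k in 1:10) {
    sel <- sample(10, 3)
    com <- center_of_mass(list(dipoles = sel, intensities = rnorm(3)), ss2)
    expect_true(all(com >= apply(pos[sel, ], 2, min) - 1e-12))
    expect_true(all(com <= apply(pos[sel, ], 2, max) + 1e-12))
  }
})

test_that("localization error is the distance to the closest VOI voxel", {
  tv <- tiny_voi(voxel_mm = 1, radius = 3)
  # CoM at a VOI voxel center
  expect_equal(localization_error(c(0, 0, 0), tv$voi), 0)
  # CoM inside a 1-mm-voxel VOI: below 1 mm
  expect_lt(localization_error(c(0.4, 0.3, -0.2), tv$voi), 1)
  # 10 mm outside a single-voxel VOI along an axis
  ssp <- source_space(matrix(c(0, 0, 0), 1), matrix(c(0, 0, 1), 1))
  voi1 <- make_voi(ssp, tv$seg, 1, 0.4)  # radius below voxel size
  expect_equal(nrow(voi1$coords_mm), 1)
  expect_equal(localization_error(c(10, 0, 0), voi1), 10)
})

test_that("dispersion and focality equal a brute-force double loop", {
  set.seed(32)
  seg <- make_sphere_segmentation(c(80, 85, 92), 4)
  src <- make_sphere_source_space(60, 80, seed = 5)
  ss <- src$source_space
  voi <- make_voi(ss, seg, 10, 12)
  for (k in 1:5) {
    s <- rnorm(80)
    m <- source_map(s)
    # brute force: per-dipole min distance over VOI voxels, inside -> 0
    dmin <- vapply(1:80, function(i) {
      min(sqrt(rowSums(sweep(voi$coords_mm, 2, ss$positions[i, ])^2)))
    }, numeric(1))
    vx <- hexsource:::mm_to_voxel(seg, ss$positions)
    inside <- vapply(1:80, function(i)
      voi$mask[vx[i, 1], vx[i, 2], vx[i, 3]], logical(1))
    dmin[inside] <- 0
    sd_bf <- sum(dmin^2 * s^2) / sum(s^2)
    foc_bf <- sum(s[dmin <= 5]^2) / sum(s^2)
    expect_equal(spatial_dispersion(m, voi, ss), sd_bf, tolerance = 1e-10)
    expect_equal(focality(m, voi, ss), foc_bf, tolerance = 1e-10)
    expect_equal(spatial_dispersion(m, voi, ss, sqrt = TRUE), sqrt(sd_bf),
                 tolerance = 1e-10)
  }
  expect_error(spatial_dispersion(source_map(numeric(80)), voi, ss), "zero")
})

test_that("maps confined to the (dilated) VOI give SD 0 and Foc 1", {
  seg <- make_sphere_segmentation(c(80, 85, 92), 4)
  src <- make_sphere_source_space(60, 100, seed = 6)
  ss <- src$source_space
  voi <- make_voi(ss, seg, 25, 22)
  d <- hexsource:::dist_to_voi(ss$positions, voi)
  s <- numeric(100)
  s[d == 0] <- rnorm(sum(d == 0))
  expect_gte(sum(d == 0), 2)
  expect_equal(spatial_dispersion(source_map(s), voi, ss), 0)
  expect_equal(focality(source_map(s), voi, ss), 1)
  # all energy far outside: Foc 0
  far <- numeric(100)
  far[which.max(d)] <- 1
  expect_equal(focality(source_map(far), voi, ss), 0)
  # single active dipole at distance d: SD = d^2
  i <- which.max(d)
  expect_equal(spatial_dispersion(source_map(far), voi, ss), d[i]^2,
               tolerance = 1e-10)
  # constructed half/half split of the squared intensity
  io <- which(d == 0)[1]; oo <- which(d > 5)[1]
  half <- numeric(100); half[io] <- 1; half[oo] <- 1
  expect_equal(focality(source_map(half), voi, ss), 0.5)
})

test_that("growing the dilation never lowers Foc; growing the VOI never raises SD", {
  seg <- make_sphere_segmentation(c(80, 85, 92), 4)
  src <- make_sphere_source_space(60, 100, seed = 8)
  ss <- src$source_space
  set.seed(33)
  s <- source_map(rnorm(100))
  voi_small <- make_voi(ss, seg, 40, 8)
  voi_big <- make_voi(ss, seg, 40, 16)
  f <- vapply(c(0, 2, 5, 10, 20), function(dl)
    focality(s, voi_small, ss, dilation_mm = dl), numeric(1))
  expect_true(all(diff(f) >= 0))
  expect_lte(spatial_dispersion(s, voi_big, ss),
             spatial_dispersion(s, voi_small, ss))
})

test_that("the metrics report flags hits by LE thresholds", {
  tv <- tiny_voi(radius = 3)
  ss <- source_space(matrix(c(0, 0, 0), 1), matrix(c(0, 0, 1), 1))
  rep1 <- metrics_report(list(dipoles = 1, intensities = 1),
                         source_map(1), tv$voi, ss)
  expect_equal(rep1$flag, "hit")
  expect_lt(rep1$LE, 1)
  rep2 <- metrics_report(list(dipoles = 1, intensities = 1),
                         source_map(1), NULL, ss)
  expect_true(is.na(rep2$LE))
})
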