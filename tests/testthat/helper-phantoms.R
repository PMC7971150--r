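# Shared fixtures, built in code and memoized for the whole test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# Random average-referenced lead field with unit average column power.
rand_leadfield <- function(L, D, seed = 1, scale = TRUE) {
  set.seed(seed)
  m <- matrix(rnorm(L * D), L, D)
  m <- sweep(m, 2, colMeans(m))
  if (scale) m <- m / sqrt(sum(m^2) / L)
  structure(list(matrix = m, electrodes = sprintf("E%03d", seq_len(L)),
                 avg_ref = TRUE, provenance = list(synthetic = TRUE)),
            class = "lead_field")
}

as_leadfield <- function(m) {
  structure(list(matrix = m, electrodes = sprintf("E%03d", seq_len(nrow(m))),
                 avg_ref = TRUE, provenance = list(synthetic = TRUE)),
            class = "lead_field")
}

# Coarse (8 mm) three-layer sphere phantom with FEM lead field.
phantom8 <- function() memo("phantom8", function() {
  seg <- make_sphere_segmentation(c(80, 85, 92), 8)
  src <- make_sphere_source_space(72, 100, seed = 7)
  montage <- make_sphere_montage(32, 92)
  cond <- conductivity_table()
  stiff <- assemble_stiffness(seg, cond)
  lf <- suppressWarnings(compute_leadfield_reciprocity(
    seg, cond, montage, src$source_space, stiff = stiff))
  list(seg = seg, ss = src$source_space, A = src$adjacency,
       montage = montage, cond = cond, stiff = stiff, lf = lf)
})

# Study-scale (4 mm, 64 electrodes, 500 dipoles) phantom used by the
# forward-validation and end-to-end recovery checks.
phantom4 <- function() memo("phantom4", function() {
  seg <- make_sphere_segmentation(c(80, 85, 92), 4)
  src <- make_sphere_source_space(72, 500, seed = 7)
  montage <- make_sphere_montage(64, 92)
  cond <- conductivity_table()
  stiff <- assemble_stiffness(seg, cond)
  lf <- compute_leadfield_reciprocity(seg, cond, montage,
                                      src$source_space, stiff = stiff)
  list(seg = seg, ss = src$source_space, A = src$adjacency,
       montage = montage, cond = cond, stiff = stiff, lf = lf)
})

sphere3 <- function(cond = conductivity_table()) {
  sphere_model(c(80, 85, 92),
               unname(cond[c("gray_matter", "skull", "scalp")]))
}

# Closed-form surface potential of a dipole in a homogeneous insulated
# sphere (generating-function summation of the Legendre series); test
# oracle, independent of the package's layered series solver.
homogeneous_sphere_closed_form <- function(R_mm, sigma, pos_mm, moment,
                                           electrode_mm) {
  R <- R_mm / 1000
  x0 <- pos_mm / 1000
  b <- sqrt(sum(x0^2))
  zax <- x0 / b
  m_r <- sum(moment * zax)
  pt <- moment - m_r * zax
  m_t <- sqrt(sum(pt^2))
  xax <- if (m_t > 0) pt / m_t else c(zax[2], -zax[1], 0) /
    sqrt(zax[1]^2 + zax[2]^2)
  yax <- c(zax[2] * xax[3] - zax[3] * xax[2],
           zax[3] * xax[1] - zax[1] * xax[3],
           zax[1] * xax[2] - zax[2] * xax[1])
  ed <- electrode_mm / sqrt(rowSums(electrode_mm^2))
  u <- as.numeric(ed %*% zax)
  phi <- atan2(as.numeric(ed %*% yax), as.numeric(ed %*% xax))
  s <- sqrt(pmax(0, 1 - u^2))
  x <- b / R
  g <- sqrt(1 - 2 * x * u + x^2)
  rad <- m_r / (4 * pi * sigma * R^2) *
    (2 * (u - x) / g^3 + (1 / g - 1) / x)
  tang <- m_t * cos(phi) / (4 * pi * sigma * R^2) *
    (2 * s / g^3 + s * (g + 1) / (g * (1 - x * u + g)))
  rad + tang
}
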