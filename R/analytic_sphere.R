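# Analytic dipole potential in a concentric multilayer sphere, by
# truncated Legendre series. Serves as the independent oracle for the
# hexahedral FEM forward solver.

#' Concentric multilayer sphere model
#'
#' @param radii_mm layer outer radii (mm), strictly increasing,
#'   innermost first.
#' @param conductivities layer conductivities (S/m), same length.
#' @return An object of class `sphere_model`.
#' @export
sphere_model <- function(radii_mm, conductivities) {
  stopifnot(length(radii_mm) == length(conductivities),
            length(radii_mm) >= 1)
  if (any(diff(radii_mm) <= 0)) stop("radii must be strictly increasing")
  if (any(conductivities <= 0)) stop("conductivities must be > 0")
  structure(list(radii_mm = as.numeric(radii_mm),
                 conductivities = as.numeric(conductivities)),
            class = "sphere_model")
}

#' @export
print.sphere_model <- function(x, ...) {
  cat("sphere_model:", length(x$radii_mm), "layers\n")
  print(data.frame(radius_mm = x$radii_mm, sigma_S_per_m = x$conductivities))
  invisible(x)
}

# Solve the per-harmonic radial interface system. Layer j potential is
# a_j (r/R_j)^n + b_j (R_{j-1}/r)^(n+1) (no b term in layer 1), plus the
# primary dipole field c * b^(n-1) r^-(n+1) in layer 1. Returns the outer-
# surface value multiplier for a unit primary coefficient c.
sphere_surface_coef <- function(n, R, sig, b) {
  M <- length(R)
  # primary radial factor at radius r, scaled to avoid under/overflow
  pf <- function(r) if (b > 0) (b / r)^n / (b * r) else
    if (n == 1) 1 / r^2 else 0
  if (M == 1) {
    # insulated homogeneous sphere: surface value = c * pf(R) * (2n+1)/n
    return(pf(R[1]) * (2 * n + 1) / n)
  }
  nun <- 2 * M - 1
  A <- matrix(0, nun, nun)
  rhs <- numeric(nun)
  col_a <- function(j) if (j == 1) 1L else 2L * (j - 1L)
  col_b <- function(j) 2L * j - 1L  # j >= 2
  row <- 0L
  for (i in seq_len(M - 1)) {
    r <- R[i]
    fi <- 1                              # (R_i / R_i)^n
    gi <- if (i >= 2) (R[i - 1] / r)^(n + 1) else 0
    fi1 <- (r / R[i + 1])^n
    gi1 <- 1                             # (R_i / R_i)^(n+1)
    # potential continuity
    row <- row + 1L
    A[row, col_a(i)] <- fi
    if (i >= 2) A[row, col_b(i)] <- gi
    A[row, col_a(i + 1)] <- -fi1
    A[row, col_b(i + 1)] <- -gi1
    if (i == 1) rhs[row] <- -pf(r)
    # normal current continuity: sigma * dV/dr
    row <- row + 1L
    A[row, col_a(i)] <- sig[i] * n / r * fi
    if (i >= 2) A[row, col_b(i)] <- -sig[i] * (n + 1) / r * gi
    A[row, col_a(i + 1)] <- -sig[i + 1] * n / r * fi1
    A[row, col_b(i + 1)] <- sig[i + 1] * (n + 1) / r * gi1
    if (i == 1) rhs[row] <- sig[1] * (n + 1) / r * pf(r)
  }
  # insulating outer boundary
  row <- row + 1L
  A[row, col_a(M)] <- n
  A[row, col_b(M)] <- -(n + 1) * (R[M - 1] / R[M])^(n + 1)
  sol <- solve(A, rhs)
  # outer surface value per unit primary coefficient
  sol[col_a(M)] + sol[col_b(M)] * (R[M - 1] / R[M])^(n + 1)
}

#' Analytic dipole potential on a multilayer sphere surface
#'
#' Truncated Legendre-series solution for a current dipole strictly inside
#' the innermost layer of a concentric isotropic multilayer sphere with an
#' insulating exterior. The series is truncated adaptively once the term
#' magnitude falls below `tol` times the accumulated potential.
#'
#' @param sphere a [sphere_model()].
#' @param position_mm dipole position (mm), strictly inside the innermost
#'   layer.
#' @param moment_Am dipole moment (A*m), length 3.
#' @param electrode_positions_mm E x 3 electrode positions (mm); they are
#'   projected radially onto the outer surface.
#' @param tol relative truncation tolerance.
#' @param nmax hard cap on the series order.
#' @return Numeric vector of surface potentials (V), one per electrode.
#' @export
analytic_sphere_potential <- function(sphere, position_mm, moment_Am,
                                      electrode_positions_mm,
                                      tol = 1e-12, nmax = 400L) {
  stopifnot(inherits(sphere, "sphere_model"))
  R <- sphere$radii_mm / 1000
  sig <- sphere$conductivities
  x0 <- as.numeric(position_mm) / 1000
  p <- as.numeric(moment_Am)
  b <- sqrt(sum(x0^2))
  if (b >= R[1]) stop("dipole must lie strictly inside the innermost layer")
  E <- as.matrix(electrode_positions_mm) / 1000
  ed <- E / row_norms(E)  # radial projection to the outer surface
  # local frame: z' along the dipole radius (or the moment if central)
  if (b > 1e-12 * R[length(R)]) zax <- x0 / b else {
    if (all(p == 0)) return(numeric(nrow(E)))
    zax <- p / sqrt(sum(p^2))
  }
  m_r <- sum(p * zax)
  pt <- p - m_r * zax
  m_t <- sqrt(sum(pt^2))
  if (m_t > 1e-300) xax <- pt / m_t else {
    xax <- c(zax[2], -zax[1], 0)
    if (sum(xax^2) < 1e-12) xax <- c(0, zax[3], -zax[2])
    xax <- xax - sum(xax * zax) * zax
    xax <- xax / sqrt(sum(xax^2))
  }
  yax <- c(zax[2] * xax[3] - zax[3] * xax[2],
           zax[3] * xax[1] - zax[1] * xax[3],
           zax[1] * xax[2] - zax[2] * xax[1])
  u <- as.numeric(ed %*% zax)
  u <- pmin(pmax(u, -1), 1)
  cphi <- cos(atan2(as.numeric(ed %*% yax), as.numeric(ed %*% xax)))
  V <- numeric(nrow(E))
  Pm1 <- rep(1, length(u))  # P_0
  Pn <- u                   # P_1
  quiet <- 0L
  for (n in seq_len(nmax)) {
    if (n >= 2) {
      Pnext <- ((2 * n - 1) * u * Pn - (n - 1) * Pm1) / n
      Pm1 <- Pn
      Pn <- Pnext
    }
    s2 <- 1 - u^2
    P1n <- ifelse(s2 > .Machine$double.eps,
                  sqrt(pmax(0, s2)) * n * (Pm1 - u * Pn) / s2, 0)
    coef <- sphere_surface_coef(n, R, sig, b)
    c_rad <- m_r * n / (4 * pi * sig[1])
    c_tan <- m_t / (4 * pi * sig[1])
    term <- coef * (c_rad * Pn + c_tan * P1n * cphi)
    V <- V + term
    scale_now <- max(abs(V), 1e-300)
    if (max(abs(term)) < tol * scale_now) {
      quiet <- quiet + 1L
      if (quiet >= 3L) break
    } else quiet <- 0L
  }
  V
}
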