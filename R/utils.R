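# Internal numerical helpers shared across modules.

#' @importFrom stats rnorm sd median quantile setNames
#' @importFrom utils head tail
NULL

# Row-wise Euclidean norms of a matrix.
row_norms <- function(x) sqrt(rowSums(x^2))

# Normalize rows to unit length; zero rows raise an error.
normalize_rows <- function(x, what = "vector") {
  n <- row_norms(x)
  if (any(n == 0)) stop("cannot normalize zero-length ", what)
  x / n
}

# Quasi-uniform directions on the unit sphere (Fibonacci lattice),
# optionally rotated by a seeded random rotation so different seeds give
# different (but equally uniform) layouts.
fibonacci_sphere <- function(n, seed = NULL) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  pts <- cbind(rho * cos(phi), rho * sin(phi), z)
  if (!is.null(seed)) {
    # seeded random rotation via QR of a Gaussian matrix
    set.seed(seed)
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    pts <- pts %*% q
  }
  pts
}

# Legendre polynomials P_0..P_nmax at u (vector); returns (nmax+1) x length(u).
legendre_p <- function(nmax, u) {
  P <- matrix(0, nmax + 1L, length(u))
  P[1L, ] <- 1
  if (nmax >= 1L) P[2L, ] <- u
  if (nmax >= 2L) {
    for (n in 2:nmax) {
      P[n + 1L, ] <- ((2 * n - 1) * u * P[n, ] - (n - 1) * P[n - 1L, ]) / n
    }
  }
  P
}

# Associated Legendre P_n^1 (without Condon-Shortley phase):
# P_n^1(u) = sqrt(1-u^2) dP_n/du, using (1-u^2) P_n' = n (P_{n-1} - u P_n).
legendre_p1 <- function(nmax, u) {
  P <- legendre_p(nmax, u)
  s <- sqrt(pmax(0, 1 - u^2))
  out <- matrix(0, nmax + 1L, length(u))
  one_minus <- 1 - u^2
  safe <- one_minus > .Machine$double.eps
  for (n in seq_len(nmax)) {
    d <- numeric(length(u))
    d[safe] <- n * (P[n, safe] - u[safe] * P[n + 1L, safe]) / one_minus[safe]
    out[n + 1L, ] <- s * d  # poles: s = 0 so P_n^1 = 0 there
  }
  out
}

# Minimum distance from each row of `x` (n x 3) to any row of `pts` (m x 3),
# blocked to bound memory.
min_dist_to_points <- function(x, pts, block = 2048L) {
  n <- nrow(x)
  out <- numeric(n)
  p2 <- rowSums(pts^2)
  for (i0 in seq(1L, n, by = block)) {
    idx <- i0:min(n, i0 + block - 1L)
    xb <- x[idx, , drop = FALSE]
    d2 <- outer(rowSums(xb^2), p2, "+") - 2 * xb %*% t(pts)
    out[idx] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  out
}

# Farthest-point sampling over a Euclidean point set. Returns `n` indices,
# the first chosen uniformly at random under `seed`, the rest greedily
# maximizing distance to the already-chosen set. Deterministic given seed.
farthest_point_sample <- function(pos, n, seed = 7L) {
  D <- nrow(pos)
  stopifnot(n >= 1, n <= D)
  set.seed(seed)
  first <- sample.int(D, 1L)
  chosen <- integer(n)
  chosen[1L] <- first
  mind <- row_norms(sweep(pos, 2, pos[first, ], "-"))
  if (n > 1L) {
    for (k in 2:n) {
      nxt <- which.max(mind)
      chosen[k] <- nxt
      mind <- pmin(mind, row_norms(sweep(pos, 2, pos[nxt, ], "-")))
    }
  }
  chosen
}

`%||%` <- function(a, b) if (is.null(a)) b else a
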