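# Multiple sparse priors: compact-support patch priors from the cortical
# adjacency graph, restricted-maximum-likelihood (Fisher scoring) weight
# estimation on the variational free energy, and the MAP source estimate.

#' Graph smoothing matrix for prior construction
#'
#' `G = sum_{i=0}^{order} sigma^i / i! A^i` over the patch adjacency
#' matrix: each column is a compact profile centred on one dipole whose
#' support extends at most `order` graph hops.
#'
#' @param A D x D sparse binary patch adjacency (symmetric, zero
#'   diagonal), e.g. from [build_adjacency()].
#' @param sigma neighbor-influence constant (default 0.6).
#' @param order maximum graph-hop order kept in the sum (default 8).
#' @return Object of class `smoothing_matrix` with fields `G` (sparse
#'   D x D), `sigma`, `order`.
#' @export
build_smoothing_matrix <- function(A, sigma = 0.6, order = 8L) {
  if (order < 0) stop("order must be >= 0")
  A <- methods::as(methods::as(A, "generalMatrix"), "CsparseMatrix")
  D <- nrow(A)
  G <- Matrix::Diagonal(D)
  term <- Matrix::Diagonal(D)
  for (i in seq_len(order)) {
    term <- (term %*% A) * (sigma / i)
    G <- G + term
  }
  structure(list(G = methods::as(G, "CsparseMatrix"),
                 sigma = sigma, order = as.integer(order)),
            class = "smoothing_matrix")
}

#' Select evenly distributed prior centers
#'
#' Farthest-point sampling over the dipole positions, run per hemisphere
#' with counts proportional to hemisphere size, so the centers are
#' quasi-uniform in the brain space. Deterministic given `seed`.
#'
#' @param ss a [source_space()].
#' @param n_priors number of centers (default 400, the standard fraction
#'   of a 4800-dipole space).
#' @param seed RNG seed for the first sample of each hemisphere.
#' @return Sorted integer vector of dipole indices.
#' @export
select_prior_centers <- function(ss, n_priors = 400L, seed = 7L) {
  D <- nrow(ss$positions)
  if (n_priors > D) stop("n_priors exceeds the number of dipoles")
  if (n_priors == D) return(seq_len(D))
  hemis <- unique(ss$hemisphere)
  sizes <- vapply(hemis, function(h) sum(ss$hemisphere == h), numeric(1))
  counts <- floor(n_priors * sizes / D)
  # distribute the remainder to the largest hemispheres
  rem <- n_priors - sum(counts)
  if (rem > 0) {
    ord <- order(sizes - counts * D / n_priors, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  centers <- integer(0)
  for (k in seq_along(hemis)) {
    if (counts[k] == 0) next
    idx <- which(ss$hemisphere == hemis[k])
    sel <- farthest_point_sample(ss$positions[idx, , drop = FALSE],
                                 counts[k], seed = seed + k)
    centers <- c(centers, idx[sel])
  }
  sort(centers)
}

#' Sparse prior set
#'
#' Holds the selected centers and the corresponding columns `g_i` of the
#' smoothing matrix; each implicit covariance component is the rank-one
#' `Q_i = g_i g_i'`.
#'
#' @param G a [build_smoothing_matrix()] result or a sparse matrix:
#'   either the full D x D smoothing matrix (columns are picked by
#'   `center_indices`) or an already-extracted D x n_priors matrix of
#'   prior profiles (one column per center).
#' @param center_indices dipole indices of the prior centers.
#' @return Object of class `prior_set` with `centers` and sparse
#'   `columns` (D x n_priors).
#' @export
prior_set <- function(G, center_indices) {
  Gm <- if (inherits(G, "smoothing_matrix")) G$G else G
  center_indices <- as.integer(center_indices)
  if (anyDuplicated(center_indices)) stop("prior centers must be unique")
  stopifnot(all(center_indices >= 1), all(center_indices <= nrow(Gm)))
  cols <- if (ncol(Gm) == nrow(Gm)) Gm[, center_indices, drop = FALSE]
          else Gm
  if (ncol(cols) != length(center_indices))
    stop("need one prior column per center")
  structure(list(centers = center_indices,
                 columns = methods::as(cols, "CsparseMatrix")),
            class = "prior_set")
}

#' @export
print.prior_set <- function(x, ...) {
  cat(sprintf("prior_set: %d rank-one components over %d dipoles\n",
              length(x$centers), nrow(x$columns)))
  invisible(x)
}

# Orthonormal basis of the average-reference subspace (L x (L-1)):
# normalized Helmert contrasts, deterministic.
avg_ref_basis <- function(L) {
  H <- stats::contr.helmert(L)
  sweep(H, 2, sqrt(colSums(H^2)), "/")
}

#' Multiple-sparse-priors inversion
#'
#' Models the sensor covariance as a sensor-noise component plus one
#' rank-one component per prior, `Sigma = exp(l0) I + sum_i exp(l_i) L
#' Q_i L'` (in the confound-projected space), optimizes the
#' log-hyperparameters by Fisher-scoring restricted maximum likelihood on
#' the variational free energy of the sample covariance, and returns the
#' MAP operator `M = Sigma_src L' Sigma^-1` together with the source
#' estimates `E = M Y`.
#'
#' The free energy maximized is
#' `F = -T/2 (n log 2pi + log det Sigma + tr(Sigma^-1 S))
#'  - sum_k (l_k - mu)^2 pi_h / 2`
#' with `S = Y Y'/T` after projection (and optional temporal reduction),
#' and weak shrinkage hyperpriors `mu = -32`, `pi_h = 1/256` on every
#' log-hyperparameter. Step-halving guarantees a non-decreasing free
#' energy trace.
#'
#' @param Y L x T data window (average-referenced channels x samples).
#' @param lf the `lead_field`.
#' @param priors a [prior_set()].
#' @param temporal_modes keep the leading temporal SVD modes carrying
#'   this fraction of variance before covariance estimation (`NULL` to
#'   disable; default 0.99).
#' @param scale_data internally rescale data and lead field to unit
#'   average power before optimization (numerically safer; reported
#'   hyperparameters are mapped back to the unscaled problem).
#' @param max_iter Fisher-scoring iteration cap.
#' @param tol_df absolute free-energy increase below which iteration
#'   stops.
#' @param hyperprior_mean,hyperprior_prec Gaussian shrinkage hyperprior
#'   on the log-hyperparameters.
#' @param lambda_init optional initial log-hyperparameters (noise first).
#' @param lambda_fixed optional logical vector (noise first) marking
#'   hyperparameters to hold at their initial values.
#' @return Object of class `msp_result`: `lambda` (log-hyperparameters,
#'   noise first, on the unscaled problem), `free_energy` trace, `M`
#'   (D x L MAP operator), `E` (D x T), `U` (L x L average-reference
#'   projector), `posterior_var` (conditional source variance, length D),
#'   `converged`, `centers`.
#' @export
msp_invert <- function(Y, lf, priors, temporal_modes = 0.99,
                       scale_data = TRUE, max_iter = 128L, tol_df = 1e-6,
                       hyperprior_mean = -32, hyperprior_prec = 1/256,
                       lambda_init = NULL, lambda_fixed = NULL) {
  stopifnot(inherits(lf, "lead_field"), inherits(priors, "prior_set"))
  Y <- as.matrix(Y)
  if (anyNA(Y)) stop("Y contains NA")
  L <- nrow(lf$matrix)
  D <- ncol(lf$matrix)
  Tn <- ncol(Y)
  stopifnot(nrow(Y) == L, Tn >= 1)
  B <- avg_ref_basis(L)
  n <- L - 1L
  Yt <- crossprod(B, Y)
  Lt <- crossprod(B, lf$matrix)
  sc_y <- 1; sc_l <- 1
  if (scale_data) {
    sc_y <- sqrt(sum(Yt^2) / (n * Tn))
    if (sc_y == 0) sc_y <- 1
    sc_l <- sqrt(sum(Lt^2) / n)
    Yt <- Yt / sc_y
    Lt <- Lt / sc_l
  }
  # temporal reduction: keep leading right-singular modes of the window
  Yr <- Yt
  if (!is.null(temporal_modes) && Tn > 1 && any(Yt != 0)) {
    sv <- svd(Yt)
    keep <- which(cumsum(sv$d^2) / sum(sv$d^2) >= temporal_modes)[1]
    keep <- max(keep, 1L)
    Yr <- sv$u[, seq_len(keep), drop = FALSE] %*%
      diag(sv$d[seq_len(keep)], keep)
  }
  S <- tcrossprod(Yr) / Tn
  Gs <- priors$columns
  Um <- as.matrix(Lt %*% Gs)            # n x n_priors, u_i = L g_i
  K <- ncol(Um) + 1L                    # noise + priors
  hE <- rep(hyperprior_mean, K)
  hP <- rep(hyperprior_prec, K)
  h <- if (is.null(lambda_init)) {
    c(log(max(sum(diag(S)) / n, 1e-12) / 2),
      rep(log(pmax(sum(diag(S)), 1e-12) / (2 * K *
            pmax(colSums(Um^2), 1e-12))), length.out = K - 1L))
  } else rep(lambda_init, length.out = K)
  fixed <- if (is.null(lambda_fixed)) rep(FALSE, K)
           else rep(lambda_fixed, length.out = K)
  sigma_of <- function(h) {
    diag(exp(h[1]), n) + Um %*% (exp(h[-1]) * t(Um))
  }
  free_energy <- function(h) {
    Sg <- sigma_of(h)
    R <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(R)) return(-Inf)
    ld <- 2 * sum(log(diag(R)))
    tr <- sum(diag(chol2inv(R) %*% S))
    -Tn / 2 * (n * log(2 * pi) + ld + tr) -
      sum(hP[!fixed] * (h[!fixed] - hE[!fixed])^2) / 2
  }
  Ftrace <- free_energy(h)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Sg <- sigma_of(h)
    P <- chol2inv(chol(Sg))
    PS <- P %*% S
    PU <- P %*% Um
    SPU <- S %*% PU
    # gradient of F
    g <- numeric(K)
    g[1] <- -Tn / 2 * exp(h[1]) * (sum(diag(P)) - sum(PS * P))
    g[-1] <- -Tn / 2 * exp(h[-1]) *
      (colSums(Um * PU) - colSums(PU * SPU))
    g <- g - hP * (h - hE)
    # Fisher information (expected negative Hessian)
    Imat <- matrix(0, K, K)
    UtPU <- crossprod(Um, PU)
    Imat[-1, -1] <- (Tn / 2) * (UtPU^2) * tcrossprod(exp(h[-1]))
    Imat[1, 1] <- (Tn / 2) * sum(P * P) * exp(2 * h[1])
    cross <- (Tn / 2) * colSums(PU^2) * exp(h[1]) * exp(h[-1])
    Imat[1, -1] <- cross
    Imat[-1, 1] <- cross
    Imat <- Imat + diag(hP, K)
    g[fixed] <- 0
    Imat[fixed, ] <- 0; Imat[, fixed] <- 0
    diag(Imat)[fixed] <- 1
    dh <- tryCatch(solve(Imat + diag(1e-8 * max(diag(Imat)), K), g),
                   error = function(e) g / max(diag(Imat)))
    dh[fixed] <- 0
    dh <- pmin(pmax(dh, -8), 8)  # trust region on log-hyperparameters
    f0 <- Ftrace[length(Ftrace)]
    step <- 1
    repeat {
      f1 <- free_energy(h + step * dh)
      if (f1 >= f0 || step < 1 / 256) break
      step <- step / 2
    }
    if (f1 < f0) { converged <- TRUE; break }  # no uphill step left
    h <- h + step * dh
    Ftrace <- c(Ftrace, f1)
    if (f1 - f0 < tol_df) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MSP ReML did not converge within ", max_iter, " iterations")
  # MAP operator and source estimates (scaled space, then mapped back)
  Sg <- sigma_of(h)
  P <- chol2inv(chol(Sg))
  W <- t(exp(h[-1]) * as.matrix(crossprod(Um, P)))  # n x n_priors weights
  Ms <- as.matrix(Gs %*% t(W))                      # D x n
  M <- Ms %*% t(B) / sc_l                           # D x L, unscaled
  E <- M %*% Y
  # conditional (posterior) source variance, unscaled
  diag_prior <- as.numeric(Matrix::rowSums(
    Gs %*% Matrix::Diagonal(x = exp(h[-1])) * Gs))
  post_var_s <- diag_prior - rowSums((Ms %*% Sg) * Ms)
  post_var <- post_var_s * (sc_y / sc_l)^2
  lambda <- h
  lambda[1] <- h[1] + 2 * log(sc_y)
  lambda[-1] <- h[-1] + 2 * (log(sc_y) - log(sc_l))
  names(lambda) <- c("noise", paste0("prior_", priors$centers))
  structure(list(lambda = lambda, free_energy = Ftrace, M = M, E = E,
                 U = diag(L) - matrix(1 / L, L, L),
                 posterior_var = pmax(post_var, 0),
                 converged = converged, centers = priors$centers,
                 n_temporal_modes = ncol(Yr)),
            class = "msp_result")
}

#' @export
print.msp_result <- function(x, ...) {
  lamp <- sort(x$lambda[-1], decreasing = TRUE)
  cat(sprintf(paste0("msp_result: %d priors, F = %.4g after %d iterations",
                     " (%sconverged)\n  top priors: %s\n"),
              length(x$lambda) - 1, tail(x$free_energy, 1),
              length(x$free_energy), if (x$converged) "" else "not ",
              paste(names(head(lamp, 3)), collapse = ", ")))
  invisible(x)
}

#' Source-map snapshot from an MSP result
#'
#' Column `t` of the source estimate matrix `E` as a signed
#' [source_map()] (polarity relative to the patch normals).
#'
#' @param result an [msp_invert()] result.
#' @param t time index (1-based, within the inverted window).
#' @return A [source_map()].
#' @export
msp_snapshot <- function(result, t) {
  stopifnot(inherits(result, "msp_result"))
  if (t < 1 || t > ncol(result$E)) stop("time index out of range")
  source_map(result$E[, t], solver = "msp", time_index = as.integer(t))
}
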