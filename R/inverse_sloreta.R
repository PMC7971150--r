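# Standardized low-resolution electromagnetic tomography over a
# hyperparameter grid.

#' Default sLORETA hyperparameter grid
#'
#' Nine values from 1e-4 to 1e4, one order of magnitude apart.
#'
#' @return Increasing numeric vector of length 9.
#' @export
default_alpha_grid <- function() 10^seq(-4, 4)

#' Source map container
#'
#' Signed per-dipole intensities at one time point. The sign is the
#' polarity with respect to the patch normal: positive values are sources
#' (current flowing outward from the cortex), negative values sinks.
#'
#' @param values length-D numeric vector.
#' @param solver solver tag (e.g. `"sloreta"`, `"msp"`).
#' @param alpha hyperparameter that produced the map (`NA` for MSP).
#' @param time_index analysis time-point index.
#' @return Object of class `source_map`.
#' @export
source_map <- function(values, solver = "unknown", alpha = NA_real_,
                       time_index = 1L) {
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("source map values must be finite")
  structure(list(values = values, solver = solver, alpha = alpha,
                 time_index = time_index), class = "source_map")
}

#' @export
print.source_map <- function(x, ...) {
  cat(sprintf("source_map [%s%s]: %d dipoles, |s| max %.3g at #%d\n",
              x$solver,
              if (is.na(x$alpha)) "" else sprintf(", alpha=%g", x$alpha),
              length(x$values), max(abs(x$values)), which.max(abs(x$values))))
  invisible(x)
}

#' sLORETA source map for one scalp snapshot
#'
#' Minimum-norm current estimate standardized by its model variance:
#' for each dipole r, `s(r) = l(r)' C^-1 y / sqrt(l(r)' C^-1 l(r))` with
#' `C = L L' + alpha I`. The square-rooted denominator is the standard
#' sLORETA form and guarantees zero localization error for noiseless
#' single-dipole data as alpha tends to 0; `standardization = "linear"`
#' uses the un-rooted denominator instead.
#'
#' @param y average-referenced scalp snapshot (length L).
#' @param lf a `lead_field` (rows consistent with `y`).
#' @param alpha positive regularization hyperparameter.
#' @param standardization `"sqrt"` (default) or `"linear"`.
#' @return A [source_map()].
#' @export
sloreta_map <- function(y, lf, alpha, standardization = c("sqrt", "linear")) {
  standardization <- match.arg(standardization)
  stopifnot(inherits(lf, "lead_field"))
  L <- lf$matrix
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(L))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0)
    stop("alpha must be a positive scalar")
  C <- tcrossprod(L) + diag(alpha, nrow(L))
  R <- chol(C)
  CiL <- backsolve(R, forwardsolve(t(R), L))   # C^-1 L
  num <- as.numeric(crossprod(CiL, y))         # l(r)' C^-1 y
  den <- colSums(L * CiL)                      # l(r)' C^-1 l(r)
  den <- pmax(den, .Machine$double.xmin)
  s <- if (standardization == "sqrt") num / sqrt(den) else num / den
  source_map(s, solver = "sloreta", alpha = alpha)
}

#' sLORETA hyperparameter sweep
#'
#' One source map per hyperparameter, in grid order (default: the
#' nine-decade grid of [default_alpha_grid()]).
#'
#' @inheritParams sloreta_map
#' @param grid strictly increasing positive hyperparameter values.
#' @return List of [source_map()]s.
#' @export
sloreta_sweep <- function(y, lf, grid = default_alpha_grid(),
                          standardization = c("sqrt", "linear")) {
  standardization <- match.arg(standardization)
  if (!length(grid)) stop("hyperparameter grid is empty")
  if (any(grid <= 0) || is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing and positive")
  lapply(grid, function(a) sloreta_map(y, lf, a, standardization))
}
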