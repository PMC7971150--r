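# Best-hyperparameter-and-polarity selection: enumerate candidate dipole
# pairs by polarity, synthesize their scalp EEG, and keep the candidate
# whose topography best matches the measurement (lowest NRDM).

#' Candidate dipole selections of a source map
#'
#' Three candidates per map, by polarity: `"max"` keeps the two most
#' positive dipoles, `"min"` the two most negative, `"both"` the single
#' most positive plus the single most negative. Positive intensity means
#' outward current flow relative to the patch normal. Ties are broken by
#' the lower dipole index.
#'
#' @param map a [source_map()].
#' @return List of three `candidate_solution` stubs (fields `mode`,
#'   `dipoles`, `intensities`, `solver`, `alpha`).
#' @export
extract_candidates <- function(map) {
  s <- map_values(map)
  if (all(s == 0)) stop("no candidate sources: source map is all zero")
  ord_pos <- order(-s, seq_along(s))
  ord_neg <- order(s, seq_along(s))
  mk <- function(mode, idx) {
    structure(list(mode = mode, dipoles = idx, intensities = s[idx],
                   solver = map$solver, alpha = map$alpha,
                   topography = NULL, nrdm = NA_real_),
              class = "candidate_solution")
  }
  list(mk("max", ord_pos[1:2]),
       mk("min", ord_neg[1:2]),
       mk("both", c(ord_pos[1], ord_neg[1])))
}

#' @export
print.candidate_solution <- function(x, ...) {
  cat(sprintf("candidate [%s%s, %s]: dipoles %s, intensities %s%s\n",
              x$solver, if (is.na(x$alpha)) "" else sprintf(" a=%g", x$alpha),
              x$mode, paste(x$dipoles, collapse = ","),
              paste(signif(x$intensities, 3), collapse = ","),
              if (is.na(x$nrdm)) "" else sprintf(", NRDM %.4f", x$nrdm)))
  invisible(x)
}

#' Synthetic scalp EEG of a candidate
#'
#' Places artificial generators at the candidate's dipoles and simulates
#' the scalp potential: the signed combination of the corresponding
#' lead-field columns, average-referenced. By default the relative
#' magnitudes come from the solver's signed intensities; with
#' `unit_dipoles = TRUE` only the signs are kept (unit generators).
#'
#' @param candidate a `candidate_solution`.
#' @param lf the `lead_field`.
#' @param unit_dipoles use sign-only unit moments instead of the solver
#'   intensities.
#' @return Length-L average-referenced topography.
#' @export
candidate_eeg <- function(candidate, lf, unit_dipoles = FALSE) {
  stopifnot(inherits(lf, "lead_field"))
  if (!length(candidate$dipoles)) return(numeric(nrow(lf$matrix)))
  stopifnot(all(candidate$dipoles >= 1),
            all(candidate$dipoles <= ncol(lf$matrix)))
  w <- if (unit_dipoles) sign(candidate$intensities) else candidate$intensities
  y <- as.numeric(lf$matrix[, candidate$dipoles, drop = FALSE] %*% w)
  y - mean(y)
}

#' Normalized relative difference measure
#'
#' `NRDM = || y_true/||y_true|| - y_sim/||y_sim|| ||` (Euclidean norms):
#' 0 for identical patterns up to positive scaling, 2 for opposite
#' polarity.
#'
#' @param y_true,y_sim nonzero numeric vectors of equal length.
#' @return Scalar in `[0, 2]`.
#' @export
nrdm <- function(y_true, y_sim) {
  stopifnot(length(y_true) == length(y_sim))
  nt <- sqrt(sum(y_true^2)); ns <- sqrt(sum(y_sim^2))
  if (nt == 0 || ns == 0) stop("NRDM undefined for zero-norm input")
  sqrt(sum((y_true / nt - y_sim / ns)^2))
}

#' Choose the best candidate across maps and polarities
#'
#' Scores every (map x polarity) candidate by the NRDM between the
#' measured snapshot and the candidate's synthetic topography and returns
#' the minimizer. Requires no ground truth. Deterministic tie-break:
#' lower hyperparameter first, then mode order max < min < both, then
#' lower dipole index.
#'
#' @param y_true measured average-referenced snapshot (length L).
#' @param maps list of [source_map()]s (e.g. a [sloreta_sweep()] result,
#'   or a single MSP snapshot).
#' @param lf the `lead_field`.
#' @param unit_dipoles see [candidate_eeg()].
#' @return The winning `candidate_solution` with fields `topography` and
#'   `nrdm` filled; all scored candidates are attached as attribute
#'   `"candidates"`.
#' @export
select_best <- function(y_true, maps, lf, unit_dipoles = FALSE) {
  if (inherits(maps, "source_map")) maps <- list(maps)
  if (!length(maps)) stop("need at least one source map")
  mode_rank <- c(max = 1, min = 2, both = 3)
  cands <- list()
  for (m in maps) {
    for (cand in extract_candidates(m)) {
      cand$topography <- candidate_eeg(cand, lf, unit_dipoles)
      # a candidate with zero intensities explains nothing: worst score
      cand$nrdm <- if (all(cand$topography == 0)) Inf
                   else nrdm(y_true, cand$topography)
      cands[[length(cands) + 1L]] <- cand
    }
  }
  score <- vapply(cands, `[[`, numeric(1), "nrdm")
  alpha <- vapply(cands, function(cc) {
    if (is.na(cc$alpha)) Inf else cc$alpha
  }, numeric(1))
  mrank <- mode_rank[vapply(cands, `[[`, character(1), "mode")]
  d1 <- vapply(cands, function(cc) cc$dipoles[1], numeric(1))
  best <- order(score, alpha, mrank, d1)[1]
  out <- cands[[best]]
  attr(out, "candidates") <- cands
  out
}
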