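# Evaluation against a volume of interest: center of mass, localization
# error, spatial dispersion, focality, and the conductivity-perturbation
# grid.

#' Volume-of-interest mask
#'
#' Binary voxel mask of the target (e.g. resected) region, with the
#' voxel-to-mm affine of its segmentation space.
#'
#' @param mask 3-D logical array.
#' @param affine 4 x 4 voxel-index (0-based) to mm map.
#' @return Object of class `voi_mask` with the mm coordinates of the VOI
#'   voxel centers precomputed.
#' @export
voi_mask <- function(mask, affine) {
  stopifnot(length(dim(mask)) == 3, is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stop("VOI mask is empty")
  ijk <- arrayInd(which(mask), dim(mask))
  xyz <- voxel_to_mm(affine, ijk)
  if (!all(is.finite(xyz))) stop("VOI coordinates must be finite")
  structure(list(mask = mask, affine = affine, coords_mm = xyz),
            class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("voi_mask: %d voxels\n", nrow(x$coords_mm)))
  invisible(x)
}

#' Intensity-weighted center of mass of selected dipoles
#'
#' `CoM = sum(|s_i| x_i) / sum(|s_i|)` over the dipoles selected in the
#' candidate (absolute intensities as weights).
#'
#' @param candidate a `candidate_solution` from [extract_candidates()] /
#'   [select_best()], or a list with fields `dipoles` and `intensities`.
#' @param ss the [source_space()].
#' @return Length-3 mm coordinate.
#' @export
center_of_mass <- function(candidate, ss) {
  d <- candidate$dipoles
  s <- abs(candidate$intensities)
  stopifnot(length(d) >= 1, length(s) == length(d))
  if (sum(s) == 0) stop("selected dipoles have zero intensity")
  colSums(ss$positions[d, , drop = FALSE] * s) / sum(s)
}

# Distance (mm) from each row of x to the nearest VOI voxel center; zero
# for points whose containing voxel belongs to the mask.
dist_to_voi <- function(x, voi) {
  x <- matrix(x, ncol = 3)
  d <- min_dist_to_points(x, voi$coords_mm)
  inv <- solve(voi$affine[1:3, 1:3])
  ijk <- round(t(inv %*% (t(x) - voi$affine[1:3, 4]))) + 1L
  dims <- dim(voi$mask)
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= dims[1] &
        ijk[, 2] >= 1 & ijk[, 2] <= dims[2] &
        ijk[, 3] >= 1 & ijk[, 3] <= dims[3]
  lin <- rep(NA_integer_, nrow(x))
  lin[ok] <- ijk[ok, 1] + dims[1] * ((ijk[ok, 2] - 1L) +
                                     dims[2] * (ijk[ok, 3] - 1L))
  inside <- ok & !is.na(lin) & voi$mask[ifelse(is.na(lin), 1L, lin)]
  d[inside] <- 0
  d
}

#' Localization error
#'
#' Euclidean distance (mm) from the center of mass to the closest VOI
#' voxel center; below 1 mm (at 1-mm voxels) the CoM lies inside the VOI.
#'
#' @param com length-3 mm coordinate (see [center_of_mass()]).
#' @param voi a [voi_mask()].
#' @return Distance in mm (0 when the CoM falls inside the VOI mask).
#' @export
localization_error <- function(com, voi) {
  stopifnot(inherits(voi, "voi_mask"))
  min(row_norms(sweep(voi$coords_mm, 2, com, "-")))
}

#' Spatial dispersion of a source map around the VOI
#'
#' `SD = sum_i min_j(D_ij^2) s_i^2 / sum_i s_i^2` over all dipoles, where
#' `D_ij` is the distance (mm) from dipole i to the nearest VOI voxel
#' (zero for dipoles inside the VOI). Units mm^2 as printed; set
#' `sqrt = TRUE` for the square-rooted variant (mm) used by part of the
#' literature.
#'
#' @param map a `source_map` (or numeric vector of dipole intensities).
#' @param voi a [voi_mask()].
#' @param ss the [source_space()].
#' @param sqrt return `sqrt(SD)` instead.
#' @return Scalar dispersion.
#' @export
spatial_dispersion <- function(map, voi, ss, sqrt = FALSE) {
  s <- map_values(map)
  if (all(s == 0)) stop("source map is all zero")
  d <- dist_to_voi(ss$positions, voi)
  out <- sum(d^2 * s^2) / sum(s^2)
  if (sqrt) base::sqrt(out) else out
}

#' Focality of a source map with respect to the dilated VOI
#'
#' Fraction of the squared intensity carried by dipoles within
#' `dilation_mm` of the VOI: `Foc = sum_{i in VOI+5mm} s_i^2 / sum_i
#' s_i^2`, in `[0, 1]`.
#'
#' @inheritParams spatial_dispersion
#' @param dilation_mm dilation radius (mm), default 5.
#' @return Scalar in `[0, 1]`.
#' @export
focality <- function(map, voi, ss, dilation_mm = 5) {
  s <- map_values(map)
  if (all(s == 0)) stop("source map is all zero")
  d <- dist_to_voi(ss$positions, voi)
  sum(s[d <= dilation_mm]^2) / sum(s^2)
}

map_values <- function(map) {
  if (inherits(map, "source_map")) map$values else as.numeric(map)
}

#' Metrics report for one solution
#'
#' Bundles CoM, LE, SD and Foc with the hit flags used for reading
#' results: hit (LE < 5 mm), close no-hit (5-15 mm), large no-hit
#' (> 15 mm).
#'
#' @param candidate the selected `candidate_solution`.
#' @param map the full `source_map` the candidate came from.
#' @param voi a [voi_mask()] or `NULL` (metrics reported as `NA`).
#' @param ss the [source_space()].
#' @return A list of class `metrics_report`.
#' @export
metrics_report <- function(candidate, map, voi, ss) {
  if (is.null(voi)) {
    return(structure(list(CoM = center_of_mass(candidate, ss),
                          LE = NA_real_, SD = NA_real_, Foc = NA_real_,
                          flag = NA_character_), class = "metrics_report"))
  }
  com <- center_of_mass(candidate, ss)
  le <- localization_error(com, voi)
  structure(list(
    CoM = com, LE = le,
    SD = spatial_dispersion(map, voi, ss),
    Foc = focality(map, voi, ss),
    flag = if (le < 5) "hit" else if (le <= 15) "close-no-hit" else "large-no-hit"),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("CoM (%.1f, %.1f, %.1f) mm | LE %.2f mm [%s] | SD %.1f mm^2 | Foc %.3f\n",
              x$CoM[1], x$CoM[2], x$CoM[3], x$LE, x$flag, x$SD, x$Foc))
  invisible(x)
}

#' Conductivity-robustness grid
#'
#' Recomputes the full forward + inverse + selection + localization-error
#' chain for every combination of scalp and skull conductivity deviations
#' (by default -15%, 0, +15%): nine lead fields (the nominal plus eight
#' perturbed) and a 3 x 3 LE matrix whose rows index the scalp deviation
#' and columns the skull deviation, nominal at the center.
#'
#' @param seg a [voxel_segmentation()].
#' @param cond nominal [conductivity_table()].
#' @param montage an [electrode_montage()].
#' @param ss a [source_space()].
#' @param y measured scalp snapshot (average-referenced, length L).
#' @param voi a [voi_mask()].
#' @param deviations relative deviations applied to scalp and skull.
#' @param solver `"sloreta"` or `"msp"`.
#' @param adjacency patch adjacency (required for MSP).
#' @param alphas sLORETA hyperparameter grid.
#' @param msp_args extra arguments passed to [msp_invert()]-based runs.
#' @param verbose print progress.
#' @return 3 x 3 numeric LE matrix (mm) with deviation dimnames.
#' @export
conductivity_grid <- function(seg, cond, montage, ss, y, voi,
                              deviations = c(-0.15, 0, 0.15),
                              solver = c("sloreta", "msp"),
                              adjacency = NULL, alphas = default_alpha_grid(),
                              msp_args = list(), verbose = FALSE) {
  solver <- match.arg(solver)
  stopifnot(all(c("scalp", "skull") %in% names(cond)))
  ndev <- length(deviations)
  LE <- matrix(NA_real_, ndev, ndev,
               dimnames = list(scalp = sprintf("%+.0f%%", 100 * deviations),
                               skull = sprintf("%+.0f%%", 100 * deviations)))
  for (i in seq_len(ndev)) for (j in seq_len(ndev)) {
    cij <- cond
    cij["scalp"] <- cond["scalp"] * (1 + deviations[i])
    cij["skull"] <- cond["skull"] * (1 + deviations[j])
    if (verbose)
      message(sprintf("conductivity grid: scalp %+g%%, skull %+g%%",
                      100 * deviations[i], 100 * deviations[j]))
    lf <- compute_leadfield_reciprocity(seg, cij, montage, ss)
    best <- if (solver == "sloreta") {
      maps <- sloreta_sweep(y, lf, alphas)
      select_best(y, maps, lf)
    } else {
      G <- build_smoothing_matrix(adjacency)
      centers <- select_prior_centers(ss, n_priors = min(100L, nrow(ss$positions)))
      priors <- prior_set(G, centers)
      res <- do.call(msp_invert,
                     c(list(Y = matrix(y, ncol = 1), lf = lf, priors = priors),
                       msp_args))
      select_best(y, list(msp_snapshot(res, 1L)), lf)
    }
    LE[i, j] <- localization_error(center_of_mass(best, ss), voi)
  }
  LE
}
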