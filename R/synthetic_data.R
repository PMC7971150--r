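# Sphere-phantom generator: everything the clinical study supplied
# (segmentation, source space, spike EEG, resection VOI) at desk scale.

#' Multilayer sphere segmentation phantom
#'
#' Concentric labelled shells on a regular voxel grid: gray matter inside
#' `radii_mm[1]`, then skull and scalp shells; everything outside the
#' outer radius is air. Voxels are classified by their center distance.
#'
#' @param radii_mm outer radii (mm) of the brain, skull and scalp layers,
#'   strictly increasing. Defaults to 80 / 85 / 92 mm.
#' @param voxel_mm voxel edge length (mm), > 0.
#' @return A [voxel_segmentation()] with tissues `gray_matter`, `skull`,
#'   `scalp`.
#' @export
make_sphere_segmentation <- function(radii_mm = c(80, 85, 92), voxel_mm = 4) {
  if (voxel_mm <= 0) stop("voxel size must be > 0")
  stopifnot(length(radii_mm) == 3, all(diff(radii_mm) > 0))
  n <- 2L * ceiling(radii_mm[3] / voxel_mm) + 1L
  ax <- (seq_len(n) - (n + 1) / 2) * voxel_mm
  d2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  r <- sqrt(d2)
  lab <- array(0L, dim = c(n, n, n))
  lab[r <= radii_mm[3]] <- 3L
  lab[r <= radii_mm[2]] <- 2L
  lab[r <= radii_mm[1]] <- 1L
  voxel_segmentation(lab, voxel_mm,
                     c(gray_matter = 1L, skull = 2L, scalp = 3L))
}

#' Quasi-uniform spherical source space
#'
#' Dipoles on a sphere of radius `radius_mm` with radial (outward)
#' normals, split into left/right hemispheres at x = 0; patch adjacency
#' is derived from the Delaunay triangulation of the points (the convex
#' hull of the sphere samples).
#'
#' @param radius_mm source-shell radius (mm); keep a margin below the
#'   innermost tissue radius so dipoles sit inside gray matter.
#' @param n_dipoles number of dipoles.
#' @param seed seed for the (rotated) quasi-uniform layout.
#' @return List with `source_space` and sparse `adjacency`.
#' @export
make_sphere_source_space <- function(radius_mm = 72, n_dipoles = 500,
                                     seed = 7L) {
  dirs <- fibonacci_sphere(n_dipoles, seed = seed)
  pos <- dirs * radius_mm
  ss <- source_space(pos, dirs,
                     patch_id = seq_len(n_dipoles),
                     hemisphere = ifelse(pos[, 1] < 0, "L", "R"))
  faces <- convex_hull_sphere(dirs)
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(n_dipoles, n_dipoles))
  A@x[] <- 1
  Matrix::diag(A) <- 0
  A <- Matrix::drop0(A)
  list(source_space = ss, adjacency = A)
}

# Incremental convex hull of points on the unit sphere (all extreme, in
# general position). Returns triangle index matrix with outward faces.
convex_hull_sphere <- function(pts) {
  n <- nrow(pts)
  stopifnot(n >= 4)
  # seed tetrahedron: far-apart points
  i1 <- 1L
  i2 <- which.max(rowSums(sweep(pts, 2, pts[i1, ])^2))
  i3 <- which.max(pmin(rowSums(sweep(pts, 2, pts[i1, ])^2),
                       rowSums(sweep(pts, 2, pts[i2, ])^2)))
  nrm <- crossp(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  h <- abs(as.numeric(pts %*% nrm) - sum(nrm * pts[i1, ]))
  i4 <- which.max(h)
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  faces <- t(apply(faces, 1, orient_face, pts = pts))
  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in rest) {
    x <- pts[p, ]
    fn <- face_normals(faces, pts)
    vis <- (fn$n %*% x) - fn$d > 1e-12
    vis <- as.logical(vis)
    if (!any(vis)) next  # inside current hull (should not happen on a sphere)
    # horizon: edges shared between one visible and one hidden face
    vf <- faces[vis, , drop = FALSE]
    he <- rbind(vf[, c(1, 2)], vf[, c(2, 3)], vf[, c(3, 1)])
    key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
    horizon <- he[key %in% names(which(table(key) == 1)), , drop = FALSE]
    newf <- cbind(horizon, p)
    newf <- t(apply(newf, 1, orient_face, pts = pts))
    faces <- rbind(faces[!vis, , drop = FALSE], newf)
  }
  faces
}

crossp <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# Flip a face so its normal points away from the origin (sphere center).
orient_face <- function(f, pts) {
  nrm <- crossp(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
  if (sum(nrm * pts[f[1], ]) < 0) f[c(1, 3, 2)] else f
}

face_normals <- function(faces, pts) {
  a <- pts[faces[, 1], , drop = FALSE]
  b <- pts[faces[, 2], , drop = FALSE]
  c3 <- pts[faces[, 3], , drop = FALSE]
  u <- b - a
  v <- c3 - a
  nrm <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
  list(n = nrm, d = rowSums(nrm * a))
}

#' Quasi-uniform scalp electrode montage for a sphere phantom
#'
#' Electrodes on the upper part (or all) of the outer sphere surface.
#'
#' @param n_electrodes number of channels.
#' @param radius_mm scalp radius (mm).
#' @param seed layout seed (rotates the quasi-uniform lattice).
#' @param full_sphere if `FALSE`, keep the montage on the upper
#'   hemisphere plus a band (z > -0.3 r), like a real EEG net.
#' @return An [electrode_montage()].
#' @export
make_sphere_montage <- function(n_electrodes = 64, radius_mm = 92,
                                seed = NULL, full_sphere = TRUE) {
  if (full_sphere) {
    dirs <- fibonacci_sphere(n_electrodes, seed = seed)
  } else {
    dirs <- fibonacci_sphere(3 * n_electrodes, seed = seed)
    dirs <- dirs[dirs[, 3] > -0.3, , drop = FALSE]
    dirs <- dirs[seq_len(n_electrodes), , drop = FALSE]
  }
  electrode_montage(sprintf("E%03d", seq_len(n_electrodes)),
                    dirs * radius_mm, reference = 1L)
}

#' Spike waveform template
#'
#' Asymmetric interictal-spike-like template: raised-cosine rising phase
#' (default 70 ms) peaking at amplitude 1 at t = 0, followed by an
#' exponential decay.
#'
#' @param t_ms time axis (ms) relative to the spike peak.
#' @param rise_ms rise duration (ms).
#' @param decay_ms exponential decay time constant (ms).
#' @return Numeric vector of template values in `[0, 1]`.
#' @export
spike_template <- function(t_ms, rise_ms = 70, decay_ms = 40) {
  w <- numeric(length(t_ms))
  rising <- t_ms >= -rise_ms & t_ms <= 0
  w[rising] <- 0.5 * (1 + cos(pi * t_ms[rising] / rise_ms))
  after <- t_ms > 0
  w[after] <- exp(-t_ms[after] / decay_ms)
  w
}

#' Simulate averaged-spike EEG from known generators
#'
#' Scalp EEG `Y = L s(t) + noise` for one or more active patches with a
#' spike-like time course, plus spatially white sensor noise scaled to a
#' requested SNR at the spike peak (amplitude ratio, dB, in the
#' average-reference space). The ground truth is returned for recovery
#' tests.
#'
#' @param lf a [compute_leadfield_reciprocity()] lead field (or any
#'   `lead_field`).
#' @param patches active dipole indices.
#' @param moments_nAm dipole moments (nA*m), recycled over `patches`;
#'   signed (negative = inward current).
#' @param snr_db signal-to-noise ratio at the spike peak (dB); `Inf`
#'   disables noise.
#' @param T_samples number of samples; the spike peak sits at sample
#'   `peak_index`.
#' @param fs sampling rate (Hz).
#' @param peak_index sample index of the spike peak (default: centre).
#' @param seed RNG seed for the noise.
#' @param rise_ms,decay_ms template shape, see [spike_template()].
#' @return An [eeg_recording()] with attached `ground_truth` field
#'   (patches, moments, waveform, seed).
#' @export
simulate_spike <- function(lf, patches, moments_nAm = 20, snr_db = Inf,
                           T_samples = 501L, fs = 500, peak_index = NULL,
                           seed = 7L, rise_ms = 70, decay_ms = 40) {
  stopifnot(inherits(lf, "lead_field"))
  L <- nrow(lf$matrix)
  moments_nAm <- rep(moments_nAm, length.out = length(patches))
  if (is.null(peak_index)) peak_index <- (T_samples + 1L) %/% 2L
  t_ms <- (seq_len(T_samples) - peak_index) / fs * 1000
  w <- spike_template(t_ms, rise_ms, decay_ms)
  # lead field is V per A*m; moments in nA*m; report EEG in microvolts
  S <- outer(moments_nAm * 1e-9, w)                 # sources x time, A*m
  Y <- (lf$matrix[, patches, drop = FALSE] %*% S) * 1e6  # uV
  Y <- as.matrix(Y)
  if (is.finite(snr_db)) {
    set.seed(seed)
    peak_rms <- sqrt(mean(Y[, peak_index]^2))
    noise_sd <- peak_rms * 10^(-snr_db / 20)
    N <- matrix(rnorm(L * T_samples, sd = noise_sd), L, T_samples)
    # project onto the average-reference subspace, compensating the
    # variance the projection removes so the per-entry sd stays noise_sd
    N <- sweep(N, 2, colMeans(N)) * sqrt(L / (L - 1))
    Y <- Y + N
  }
  rec <- eeg_recording(Y, fs = fs, channel_names = lf$electrodes,
                       spike_peak = peak_index)
  rec$ground_truth <- list(patches = patches, moments_nAm = moments_nAm,
                           waveform = w, seed = seed, snr_db = snr_db)
  rec
}

#' Spherical VOI around a source patch
#'
#' Marks all brain-labelled voxels within `radius_mm` of a chosen dipole:
#' the phantom counterpart of a hand-marked resection mask.
#'
#' @param ss a [source_space()].
#' @param seg a [voxel_segmentation()].
#' @param center_patch dipole index at the VOI center.
#' @param radius_mm VOI radius (mm).
#' @param brain_tissues tissue names considered brain.
#' @return A [voi_mask()].
#' @export
make_voi <- function(ss, seg, center_patch, radius_mm = 10,
                     brain_tissues = c("gray_matter", "white_matter", "brain")) {
  stopifnot(inherits(ss, "source_space"), inherits(seg, "voxel_segmentation"))
  labs <- seg$label_names[intersect(brain_tissues, names(seg$label_names))]
  if (!length(labs)) stop("no brain tissue in segmentation")
  center <- ss$positions[center_patch, ]
  dims <- dim(seg$labels)
  vox <- which(seg$labels %in% labs)
  ijk <- arrayInd(vox, dims)
  xyz <- voxel_to_mm(seg$affine, ijk)
  inside <- rowSums(sweep(xyz, 2, center)^2) <= radius_mm^2
  if (!any(inside)) {
    # radius below voxel size: keep the single containing voxel
    inside <- seq_along(vox) == which.min(rowSums(sweep(xyz, 2, center)^2))
  }
  mask <- array(FALSE, dims)
  mask[vox[inside]] <- TRUE
  voi_mask(mask, seg$affine)
}
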