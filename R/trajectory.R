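#' Molecular trajectory container
#'
#' A light container for time-stamped frames of labelled 3D coordinates:
#' `times_ps` (strictly increasing), a `n_frames x n_atoms x 3` coordinate
#' array in nanometres, and per-atom labels enabling selections such as
#' `"ca"` or `"backbone"`.
#'
#' @param times_ps Frame timestamps, picoseconds, strictly increasing.
#' @param coords Numeric array `n_frames x n_atoms x 3`, nm.
#' @param atom_labels Character vector of atom names (e.g. `"CA"`, `"N"`).
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(times_ps, coords, atom_labels = NULL) {
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    abort("`coords` must be an n_frames x n_atoms x 3 array.")
  n_frames <- dim(coords)[1]
  n_atoms <- dim(coords)[2]
  if (length(times_ps) != n_frames)
    abort("`times_ps` must have one entry per frame.")
  if (n_frames > 1 && any(diff(times_ps) <= 0))
    abort("`times_ps` must be strictly increasing.")
  atom_labels <- atom_labels %||% rep("CA", n_atoms)
  if (length(atom_labels) != n_atoms)
    abort("`atom_labels` must have one entry per atom.")
  structure(
    list(times_ps = as.numeric(times_ps), coords = coords,
         atom_labels = as.character(atom_labels)),
    class = "md_trajectory"
  )
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d frames x %d atoms, %.4g-%.4g ps\n",
              dim(x$coords)[1], dim(x$coords)[2],
              min(x$times_ps), max(x$times_ps)))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]

# n_atoms x 3 matrix for one frame, robust to length-1 selections
frame_coords <- function(traj, f, idx) {
  matrix(traj$coords[f, idx, ], length(idx), 3)
}

# resolve a selection (keyword, indices or logical) to atom indices
select_atoms <- function(traj, selection = "all") {
  labels <- traj$atom_labels
  idx <- if (is.character(selection) && length(selection) == 1L &&
             selection %in% c("all", "ca", "backbone")) {
    switch(selection,
           all = seq_along(labels),
           ca = which(toupper(labels) == "CA"),
           backbone = which(toupper(labels) %in% c("N", "CA", "C", "O")))
  } else if (is.logical(selection)) {
    which(selection)
  } else if (is.numeric(selection)) {
    as.integer(selection)
  } else if (is.character(selection)) {
    which(toupper(labels) %in% toupper(selection))
  } else {
    abort("Unsupported selection.")
  }
  if (length(idx) == 0L) abort("Selection matches no atoms.")
  if (any(idx < 1L) || any(idx > length(labels)))
    abort("Selection indices out of range.")
  idx
}

#' Tidy a trajectory into a long coordinate table
#'
#' @param x An `md_trajectory`.
#' @param ... Unused.
#' @return A tibble with `frame`, `time_ps`, `atom`, `label`, `x`, `y`, `z`.
#' @method tidy md_trajectory
#' @export
tidy.md_trajectory <- function(x, ...) {
  nf <- n_frames(x)
  na <- dim(x$coords)[2]
  xs <- as.vector(t(matrix(x$coords[, , 1], nf, na)))
  ys <- as.vector(t(matrix(x$coords[, , 2], nf, na)))
  zs <- as.vector(t(matrix(x$coords[, , 3], nf, na)))
  tibble(
    frame = rep(seq_len(nf), each = na),
    time_ps = rep(x$times_ps, each = na),
    atom = rep(seq_len(na), nf),
    label = rep(x$atom_labels, nf),
    x = xs, y = ys, z = zs
  )
}

#' Mean square displacement over all time origins
#'
#' `MSD(k) = < |r_i(t + k) - r_i(t)|^2 >` averaged over the selected atoms
#' and over every time origin with that lag (sliding window), for lags up
#' to `max_lag_frac` of the trajectory length. Assumes uniform frame
#' spacing for the lag-time axis.
#'
#' @param traj An [md_trajectory()].
#' @param selection Atom selection (see Details of [daura_cluster()]).
#' @param max_lag_frac Largest lag as a fraction of the trajectory length.
#' @return A tibble with `lag_ps`, `msd_nm2` and `n_origins`.
#' @export
msd <- function(traj, selection = "all", max_lag_frac = 0.25) {
  stopifnot(inherits(traj, "md_trajectory"))
  idx <- select_atoms(traj, selection)
  nf <- n_frames(traj)
  if (nf < 2) abort("MSD needs at least two frames.")
  co <- traj$coords[, idx, , drop = FALSE]
  dt <- if (nf > 1) mean(diff(traj$times_ps)) else 1
  max_lag <- max(1L, floor((nf - 1) * max_lag_frac))
  out <- vapply(seq_len(max_lag), function(k) {
    d <- co[seq(k + 1, nf), , , drop = FALSE] - co[seq_len(nf - k), , , drop = FALSE]
    # mean over origins and atoms of the summed squared xyz displacement
    sum(d^2) / ((nf - k) * length(idx))
  }, numeric(1))
  tibble(lag_ps = seq_len(max_lag) * dt, msd_nm2 = out,
         n_origins = nf - seq_len(max_lag))
}

#' Diffusion coefficient from the Einstein relation
#'
#' Ordinary least-squares straight line through the MSD curve over a lag
#' window; for free 3D diffusion `MSD = 6 D t`, so `D = slope / 6`,
#' converted from nm^2/ps to um^2/s.
#'
#' @param msd_curve Output of [msd()] (columns `lag_ps`, `msd_nm2`).
#' @param fit_window Two fractions of the maximum lag delimiting the fit
#'   window; default `c(0.1, 0.9)`. At least 5 points must fall inside.
#' @return A one-row tibble: `D_um2_s`, `D_se_um2_s`, `slope_nm2_ps`,
#'   `intercept_nm2`, `n_points`.
#' @export
einstein_diffusion <- function(msd_curve, fit_window = c(0.1, 0.9)) {
  if (!is.data.frame(msd_curve) ||
      !all(c("lag_ps", "msd_nm2") %in% names(msd_curve)))
    abort("`msd_curve` needs columns `lag_ps` and `msd_nm2`.")
  if (length(fit_window) != 2L || fit_window[1] >= fit_window[2])
    abort("`fit_window` must be an increasing pair of fractions.")
  tmax <- max(msd_curve$lag_ps)
  keep <- msd_curve$lag_ps >= fit_window[1] * tmax &
          msd_curve$lag_ps <= fit_window[2] * tmax
  if (sum(keep) < 5) abort("Fewer than 5 MSD points in the fit window.")
  fit <- lm(msd_nm2 ~ lag_ps, data = msd_curve[keep, ])
  slope <- unname(coef(fit)[2])          # nm^2/ps
  # summary.lm warns on numerically perfect fits; the SE (0) is still valid
  se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  tibble(D_um2_s = slope / 6 * 1e6, D_se_um2_s = se / 6 * 1e6,
         slope_nm2_ps = slope, intercept_nm2 = unname(coef(fit)[1]),
         n_points = sum(keep))
}

# optimal rotation (Kabsch, via SVD) such that moving %*% R best matches
# target; both matrices must already be centred
kabsch_rotation <- function(moving, target) {
  s <- svd(crossprod(moving, target))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Root-mean-square deviation between two frames
#'
#' RMSD of matched atoms, optionally after removing the optimal rigid-body
#' translation and rotation (least-squares Kabsch superposition). The
#' result is symmetric in its arguments.
#'
#' @param frame_a,frame_b Numeric `n_atoms x 3` coordinate matrices, nm.
#' @param superpose Apply the optimal superposition first (default `TRUE`).
#' @return RMSD in nm.
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' kabsch_rmsd(a, a + 1)           # 0: translation removed
#' kabsch_rmsd(a, a + 1, superpose = FALSE)
#' @export
kabsch_rmsd <- function(frame_a, frame_b, superpose = TRUE) {
  frame_a <- as.matrix(frame_a)
  frame_b <- as.matrix(frame_b)
  if (!all(dim(frame_a) == dim(frame_b)) || ncol(frame_a) != 3L)
    abort("Frames must be matched n_atoms x 3 matrices.")
  if (superpose) {
    a <- sweep(frame_a, 2, colMeans(frame_a))
    b <- sweep(frame_b, 2, colMeans(frame_b))
    a <- a %*% kabsch_rotation(a, b)
  } else {
    a <- frame_a
    b <- frame_b
  }
  sqrt(mean(rowSums((a - b)^2)))
}

#' Per-frame RMSD against a reference frame
#'
#' The classic stability diagnostic: superposed RMSD of every frame against
#' a reference (by default the starting structure).
#'
#' @param traj An [md_trajectory()].
#' @param selection Atom selection; `"backbone"` mirrors common practice.
#' @param ref_frame Index of the reference frame.
#' @param superpose Superpose before measuring (default `TRUE`).
#' @return A tibble with `frame`, `time_ps`, `rmsd_nm`.
#' @export
rmsd_trajectory <- function(traj, selection = "all", ref_frame = 1L,
                            superpose = TRUE) {
  stopifnot(inherits(traj, "md_trajectory"))
  idx <- select_atoms(traj, selection)
  ref <- frame_coords(traj, ref_frame, idx)
  vals <- vapply(seq_len(n_frames(traj)), function(f)
    kabsch_rmsd(frame_coords(traj, f, idx), ref, superpose = superpose),
    numeric(1))
  tibble(frame = seq_len(n_frames(traj)), time_ps = traj$times_ps,
         rmsd_nm = vals)
}

#' Radius of gyration
#'
#' Root-mean-square distance of the selected atoms from their centroid
#' (geometric by default; optionally mass-weighted with user masses).
#' Given a trajectory it returns one value per frame; given a single
#' `n_atoms x 3` matrix it returns a scalar.
#'
#' @param x An [md_trajectory()] or a coordinate matrix (nm).
#' @param selection Atom selection (trajectory input only).
#' @param masses Optional per-atom masses for mass weighting.
#' @return A tibble (`frame`, `time_ps`, `rg_nm`) or a scalar, nm.
#' @export
radius_of_gyration <- function(x, selection = "all", masses = NULL) {
  rg_frame <- function(m) {
    w <- masses %||% rep(1, nrow(m))
    w <- w / sum(w)
    ctr <- colSums(m * w)
    sqrt(sum(w * rowSums(sweep(m, 2, ctr)^2)))
  }
  if (inherits(x, "md_trajectory")) {
    idx <- select_atoms(x, selection)
    if (!is.null(masses) && length(masses) == dim(x$coords)[2])
      masses <- masses[idx]
    vals <- vapply(seq_len(n_frames(x)), function(f)
      rg_frame(frame_coords(x, f, idx)), numeric(1))
    return(tibble(frame = seq_len(n_frames(x)), time_ps = x$times_ps,
                  rg_nm = vals))
  }
  m <- as.matrix(x)
  if (ncol(m) != 3L || nrow(m) < 1L)
    abort("Coordinate input must be an n_atoms x 3 matrix.")
  rg_frame(m)
}

#' Pairwise superposed RMSD matrix
#'
#' @param traj An [md_trajectory()].
#' @param selection Atom selection.
#' @param superpose Superpose each pair (default `TRUE`).
#' @return Symmetric `n_frames x n_frames` matrix of RMSDs, nm.
#' @export
rmsd_matrix <- function(traj, selection = "all", superpose = TRUE) {
  stopifnot(inherits(traj, "md_trajectory"))
  idx <- select_atoms(traj, selection)
  nf <- n_frames(traj)
  frames <- lapply(seq_len(nf), function(f) frame_coords(traj, f, idx))
  m <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) {
    for (j in seq(i + 1, nf)) {
      m[i, j] <- m[j, i] <- kabsch_rmsd(frames[[i]], frames[[j]],
                                        superpose = superpose)
    }
  }
  m
}

#' Greedy RMSD-neighbour clustering of conformations (Daura)
#'
#' Iteratively extracts clusters from the pairwise superposed RMSD matrix:
#' the frame with the most neighbours within the cutoff becomes a cluster
#' centre, it and its neighbours are removed, and the count is repeated on
#' the remainder until no frames are left. Equal neighbour counts are
#' broken toward the lowest frame index.
#'
#' @param traj An [md_trajectory()].
#' @param cutoff_nm Neighbour cutoff, nm (MD practice commonly uses 0.25).
#' @param selection Atom selection; keywords `"all"`, `"ca"`, `"backbone"`,
#'   label vectors, indices or logical masks.
#' @param superpose Superpose frame pairs before measuring RMSD.
#' @return An object of class `cluster_result`: `assignments` (frame ->
#'   cluster id, 1 = largest-first extraction order), `centers`
#'   (representative frame per cluster) and `sizes`.
#' @export
daura_cluster <- function(traj, cutoff_nm = 0.25, selection = "all",
                          superpose = TRUE) {
  if (cutoff_nm < 0) abort("`cutoff_nm` must be non-negative.")
  dm <- rmsd_matrix(traj, selection, superpose = superpose)
  daura_from_dist(dm, cutoff_nm)
}

#' @rdname daura_cluster
#' @param dist_matrix Symmetric matrix of pairwise distances (any metric).
#' @param cutoff Neighbour cutoff in the units of `dist_matrix`.
#' @export
daura_from_dist <- function(dist_matrix, cutoff) {
  dm <- as.matrix(dist_matrix)
  nf <- nrow(dm)
  if (nf == 0L || ncol(dm) != nf) abort("Distance matrix must be square.")
  assignments <- integer(nf)
  centers <- integer(0)
  sizes <- integer(0)
  remaining <- seq_len(nf)
  cl <- 0L
  while (length(remaining) > 0L) {
    cl <- cl + 1L
    sub <- dm[remaining, remaining, drop = FALSE]
    counts <- rowSums(sub <= cutoff)  # includes self
    center_pos <- which.max(counts)   # ties -> lowest index
    members <- remaining[sub[center_pos, ] <= cutoff]
    assignments[members] <- cl
    centers <- c(centers, remaining[center_pos])
    sizes <- c(sizes, length(members))
    remaining <- setdiff(remaining, members)
  }
  structure(list(assignments = assignments, centers = centers, sizes = sizes),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d clusters over %d frames; sizes: %s\n",
              length(x$sizes), length(x$assignments),
              paste(utils::head(x$sizes, 8), collapse = ", ")))
  invisible(x)
}

#' Tidy clustering output
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return A tibble with one row per cluster: `cluster`, `center`, `size`.
#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) {
  tibble(cluster = seq_along(x$sizes), center = x$centers, size = x$sizes)
}

#' Principal component analysis of C-alpha coordinates
#'
#' Essential-dynamics PCA: frames are least-squares superposed onto their
#' mean structure (two refinement passes), the covariance matrix of the
#' flattened 3N C-alpha coordinates is eigendecomposed, and every frame is
#' projected on the orthonormal modes. Eigenvalues are positional
#' variances (nm^2), sorted descending; projections have zero mean per
#' mode.
#'
#' @param traj An [md_trajectory()].
#' @param selection Atom selection; default `"ca"`.
#' @return An object of class `pca_result`: `eigenvalues`, `eigenvectors`
#'   (3N x k, orthonormal columns), `projections` (frames x k), the
#'   flattened `mean_coords` and the superposed coordinate matrix
#'   `aligned` (frames x 3N).
#' @export
pca_ca <- function(traj, selection = "ca") {
  stopifnot(inherits(traj, "md_trajectory"))
  nf <- n_frames(traj)
  if (nf < 3) abort("PCA needs at least three frames.")
  idx <- select_atoms(traj, selection)

  frames <- lapply(seq_len(nf), function(f) {
    m <- frame_coords(traj, f, idx)
    sweep(m, 2, colMeans(m))
  })
  ref <- frames[[1]]
  aligned <- frames
  for (pass in 1:2) {
    aligned <- lapply(frames, function(m) m %*% kabsch_rotation(m, ref))
    ref <- Reduce(`+`, aligned) / nf
  }
  X <- t(vapply(aligned, function(m) as.vector(t(m)), numeric(length(ref))))
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  k <- length(pc$sdev)
  structure(
    list(eigenvalues = pc$sdev^2,
         eigenvectors = pc$rotation[, seq_len(k), drop = FALSE],
         projections = pc$x[, seq_len(k), drop = FALSE],
         mean_coords = pc$center,
         aligned = X),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  cat(sprintf("<pca_result> %d modes; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              length(x$eigenvalues),
              100 * x$eigenvalues[1] / tot,
              if (length(x$eigenvalues) > 1) 100 * x$eigenvalues[2] / tot else 0))
  invisible(x)
}

#' Tidy PCA eigenvalues
#'
#' @param x A `pca_result`.
#' @param ... Unused.
#' @return A tibble with `mode`, `eigenvalue_nm2`, `var_explained`.
#' @method tidy pca_result
#' @export
tidy.pca_result <- function(x, ...) {
  tibble(mode = seq_along(x$eigenvalues), eigenvalue_nm2 = x$eigenvalues,
         var_explained = x$eigenvalues / sum(x$eigenvalues))
}

#' Two-dimensional free-energy landscape from PCA projections
#'
#' Bins two projection coordinates into an `n_bins x n_bins` histogram and
#' converts occupation probabilities to relative free energies
#' `dG = -ln(P / P_max)` in units of kT. The most populated bin is exactly
#' 0; bins never visited are reported as `NA` (unvisited), distinct from
#' merely high-energy bins.
#'
#' @param p1,p2 Equal-length projection coordinates (e.g. PC1/PC2 scores).
#' @param n_bins Bins per axis, >= 4.
#' @return A tibble of class `fel_grid` with bin indices, bin mid-points,
#'   `count`, `prob` and `delta_g_kT`; bin edges are kept in the
#'   `"edges1"`/`"edges2"` attributes.
#' @export
free_energy_landscape <- function(p1, p2, n_bins = 32) {
  if (length(p1) != length(p2))
    abort("`p1` and `p2` must have the same length.")
  if (n_bins < 4) abort("`n_bins` must be at least 4.")
  if (diff(range(p1)) == 0 && diff(range(p2)) == 0)
    abort("Degenerate histogram: all points identical.")
  pad <- function(r) if (diff(r) == 0) r + c(-0.5, 0.5) else r
  e1 <- seq(pad(range(p1))[1], pad(range(p1))[2], length.out = n_bins + 1)
  e2 <- seq(pad(range(p2))[1], pad(range(p2))[2], length.out = n_bins + 1)
  i1 <- pmin(findInterval(p1, e1, rightmost.closed = TRUE), n_bins)
  i2 <- pmin(findInterval(p2, e2, rightmost.closed = TRUE), n_bins)
  counts <- matrix(0L, n_bins, n_bins)
  for (k in seq_along(i1)) counts[i1[k], i2[k]] <- counts[i1[k], i2[k]] + 1L
  prob <- counts / length(p1)
  dg <- -log(prob / max(prob))
  dg[counts == 0L] <- NA_real_
  mid <- function(e) (head(e, -1) + tail(e, -1)) / 2
  out <- tibble(
    bin1 = rep(seq_len(n_bins), n_bins),
    bin2 = rep(seq_len(n_bins), each = n_bins),
    pc1_mid = rep(mid(e1), n_bins),
    pc2_mid = rep(mid(e2), each = n_bins),
    count = as.integer(counts[cbind(rep(seq_len(n_bins), n_bins),
                                    rep(seq_len(n_bins), each = n_bins))]),
    prob = prob[cbind(rep(seq_len(n_bins), n_bins),
                      rep(seq_len(n_bins), each = n_bins))],
    delta_g_kT = dg[cbind(rep(seq_len(n_bins), n_bins),
                          rep(seq_len(n_bins), each = n_bins))]
  )
  attr(out, "edges1") <- e1
  attr(out, "edges2") <- e2
  class(out) <- c("fel_grid", class(out))
  out
}
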