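# Rigid-body superposition and rotation machinery.
#
# All RMSD/RMSF here are mass-unweighted over the stated selection only
# (Calpha-based in practice). Angles are degrees at the API surface,
# radians internally.

#' Rigid transform (proper rotation + translation)
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1
#' @param translation length-3 numeric vector, Angstrom
#' @return object of class `rigid_transform`
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3L, 3L)),
            length(translation) == 3L)
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper (det = +1); got det = ", det(rotation))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation matrix is not orthonormal")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  aa <- rotation_angle_axis(x)
  cat(sprintf("rigid transform: %.3f deg about (%.3f, %.3f, %.3f), shift %.3f A\n",
              aa$angle, aa$axis[1], aa$axis[2], aa$axis[3],
              sqrt(sum(x$translation^2))))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#' @param t a [rigid_transform()]
#' @param coords `N x 3` matrix
#' @return transformed `N x 3` matrix
#' @export
apply_transform <- function(t, coords) {
  stopifnot(inherits(t, "rigid_transform"))
  sweep(coords %*% t(t$rotation), 2, t$translation, `+`)
}

#' Invert a rigid transform
#' @param t a [rigid_transform()]
#' @return the inverse transform
#' @export
invert_transform <- function(t) {
  rigid_transform(t(t$rotation), -as.numeric(t(t$rotation) %*% t$translation))
}

#' Rotation matrix from angle and axis (Rodrigues)
#' @param angle_deg rotation angle, degrees
#' @param axis length-3 axis vector (normalised internally)
#' @return 3x3 rotation matrix
#' @export
rotation_matrix <- function(angle_deg, axis) {
  th <- angle_deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

check_pointset <- function(p, what) {
  if (!is.matrix(p) || ncol(p) != 3L) stop(what, " must be an N x 3 matrix")
  if (nrow(p) < 3L) stop("superposition needs at least 3 points, got ", nrow(p))
  s <- svd(sweep(p, 2, colMeans(p)))$d
  if (s[2] < 1e-8 * max(s[1], 1e-12))
    stop("degenerate point set (", what, " is collinear)")
  invisible(TRUE)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' paired point sets; reflections arising from the SVD are corrected by a
#' sign flip on the smallest singular direction, so the returned rotation
#' always has determinant +1 even for mirror-image inputs.
#'
#' @param mobile `N x 3` points to be moved
#' @param target `N x 3` points to fit onto (row-matched to `mobile`)
#' @return list with `transform` (a [rigid_transform()] taking mobile onto
#'   target) and `rmsd` (Angstrom, after the transform)
#' @export
kabsch_superpose <- function(mobile, target) {
  if (!is.matrix(mobile)) mobile <- as.matrix(mobile)
  if (!is.matrix(target)) target <- as.matrix(target)
  if (nrow(mobile) != nrow(target))
    stop(sprintf("point-set size mismatch: %d vs %d", nrow(mobile), nrow(target)))
  check_pointset(mobile, "mobile")
  check_pointset(target, "target")
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  H <- crossprod(P, Q)                      # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- rigid_transform(R, ct - as.numeric(R %*% cm))
  moved <- apply_transform(tr, mobile)
  rmsd <- sqrt(mean(rowSums((moved - target)^2)))
  list(transform = tr, rmsd = rmsd)
}

#' RMSD between two matched coordinate sets
#' @param a,b `N x 3` matrices, row-matched
#' @return Angstrom
#' @export
coord_rmsd <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}

#' Rotation angle and axis of a rigid transform
#'
#' Angle is `acos((trace(R) - 1) / 2)` in `[0, 180]` degrees. The axis sign
#' convention makes the first component of magnitude > 1e-8 positive; the
#' zero-rotation axis is the conventional `(1, 0, 0)`.
#'
#' @param t a [rigid_transform()] or bare 3x3 rotation matrix
#' @return list with `angle` (degrees) and `axis` (unit 3-vector)
#' @export
rotation_angle_axis <- function(t) {
  R <- if (inherits(t, "rigid_transform")) t$rotation else t
  ctheta <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
  angle <- acos(ctheta)
  if (angle < 1e-9) return(list(angle = 0, axis = c(1, 0, 0)))
  if (angle < pi - 1e-6) {
    ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
      (2 * sin(angle))
  } else {
    # near 180 deg the skew part vanishes; use the +1 eigenvector
    ev <- eigen(R)
    k <- which.min(abs(ev$values - 1))
    ax <- Re(ev$vectors[, k])
  }
  ax <- ax / sqrt(sum(ax^2))
  nz <- which(abs(ax) > 1e-8)[1]
  if (!is.na(nz) && ax[nz] < 0) ax <- -ax
  list(angle = angle * 180 / pi, axis = ax)
}

#' Iteratively aligned average structure
#'
#' Frames are least-squares aligned on `fit_sel` to a running reference
#' (first pass: frame 1; second pass: the first-pass mean) and the
#' per-atom coordinate mean is returned. Two passes suffice for the
#' near-rigid cores this is used on.
#'
#' @param traj a [trajectory()]
#' @param fit_sel a [selection()] or index vector naming the fit atoms
#' @param iterations number of align/mean passes (default 2)
#' @return `N x 3` matrix of mean coordinates
#' @export
average_structure <- function(traj, fit_sel, iterations = 2L) {
  idx <- select_atoms(traj$topology, fit_sel)
  if (!length(idx)) stop("empty fit selection")
  ref <- frame_coords(traj, 1L)
  for (it in seq_len(iterations)) {
    al <- align_trajectory(traj, idx, ref)
    ref <- apply(al$coords, c(2, 3), mean)
  }
  ref
}

#' Rigidly align every frame onto a reference
#'
#' Each frame is superposed on `fit_sel` to the reference and the whole
#' frame transformed with the resulting rigid transform, so intra-frame
#' geometry is untouched.
#'
#' @param traj a [trajectory()]
#' @param fit_sel a [selection()] or index vector
#' @param reference full `N x 3` coordinate matrix (or `N_sel x 3` covering
#'   exactly the fit atoms); default: frame 1
#' @return the aligned [trajectory()]
#' @export
align_trajectory <- function(traj, fit_sel, reference = NULL) {
  idx <- select_atoms(traj$topology, fit_sel)
  if (!length(idx)) stop("empty fit selection")
  if (is.null(reference)) reference <- frame_coords(traj, 1L)
  ref_sel <- if (nrow(reference) == n_atoms(traj$topology))
    reference[idx, , drop = FALSE] else reference
  if (nrow(ref_sel) != length(idx))
    stop("reference does not cover the fit selection")
  out <- traj$coords
  for (f in seq_len(n_frames(traj))) {
    fr <- frame_coords(traj, f)
    tr <- kabsch_superpose(fr[idx, , drop = FALSE], ref_sel)$transform
    out[f, , ] <- apply_transform(tr, fr)
  }
  trajectory(traj$topology, out, traj$frame_times)
}
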