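# Rigid-body characterisation of TCR movement atop the pMHC: per-frame
# rocking angle/axis after alignment on the MHC frame, displacement
# decomposition relative to the antigen-binding cleft, and docking-angle
# differences between complexes.

#' Antigen-binding cleft axis
#'
#' Defined as the principal axis of the peptide Calpha coordinates,
#' oriented from the peptide N-terminus toward the C-terminus (positive
#' dot product with the res1 -> resN vector), which makes the orientation
#' deterministic.
#'
#' @param structure a single-frame [trajectory()]
#' @param peptide_sel selection resolving to the peptide Calpha atoms
#'   (>= 3 atoms), in residue order
#' @return unit 3-vector
#' @export
cleft_axis <- function(structure, peptide_sel) {
  idx <- select_atoms(structure$topology, peptide_sel)
  if (length(idx) < 3) stop("cleft axis needs at least 3 peptide atoms")
  x <- frame_coords(structure, 1L)[idx, , drop = FALSE]
  xc <- sweep(x, 2, colMeans(x))
  ax <- svd(xc)$v[, 1]
  term <- x[nrow(x), ] - x[1, ]
  if (sum(ax * term) < 0) ax <- -ax
  ax / sqrt(sum(ax^2))
}

#' Normal of the MHC platform plane
#'
#' The third principal axis of the MHC-core Calpha coordinates: the
#' direction of least extent, i.e. the normal of the beta-sheet/helix
#' platform. Used to confine displacement decomposition to the plane the
#' TCR scans over.
#'
#' @param structure single-frame [trajectory()]
#' @param mhc_sel MHC-core Calpha selection
#' @return unit 3-vector
#' @export
mhc_plane_normal <- function(structure, mhc_sel) {
  idx <- select_atoms(structure$topology, mhc_sel)
  if (length(idx) < 3) stop("plane normal needs at least 3 atoms")
  x <- frame_coords(structure, 1L)[idx, , drop = FALSE]
  xc <- sweep(x, 2, colMeans(x))
  v <- svd(xc)$v[, 3]
  v / sqrt(sum(v^2))
}

#' Per-frame rigid-body motion of the TCR relative to the MHC frame
#'
#' Every frame is first aligned to the reference on the MHC fit selection
#' (so global tumbling of the whole complex cancels exactly); the
#' remaining rigid transform between the frame's TCR atoms and the
#' reference TCR atoms gives the per-frame rocking angle and axis, and the
#' TCR centroid displacement is recorded in that MHC frame.
#'
#' @param traj a [trajectory()]
#' @param mhc_fit_sel MHC-core selection used for alignment (disjoint from
#'   `tcr_sel`)
#' @param tcr_sel TCR selection (conventionally Calpha of the variable
#'   domains, where the binding-orientation signal lives)
#' @param reference reference frame index (default 1) or a full `N x 3`
#'   coordinate matrix
#' @return data.frame of class `motion_series`: `frame`, `angle_deg`,
#'   `axis_x/y/z`, `disp_x/y/z` (Angstrom)
#' @export
tcr_motion_series <- function(traj, mhc_fit_sel, tcr_sel, reference = 1L) {
  top <- traj$topology
  im <- select_atoms(top, mhc_fit_sel)
  it <- select_atoms(top, tcr_sel)
  if (!length(im) || !length(it)) stop("empty MHC or TCR selection")
  if (length(intersect(im, it))) stop("MHC and TCR selections overlap")
  ref <- if (is.matrix(reference)) reference else frame_coords(traj, reference)
  al <- align_trajectory(traj, im, ref)
  ref_tcr <- ref[it, , drop = FALSE]
  ref_cent <- colMeans(ref_tcr)
  nf <- n_frames(al)
  out <- data.frame(frame = seq_len(nf), angle_deg = NA_real_,
                    axis_x = NA_real_, axis_y = NA_real_, axis_z = NA_real_,
                    disp_x = NA_real_, disp_y = NA_real_, disp_z = NA_real_)
  for (f in seq_len(nf)) {
    tcr <- frame_coords(al, f)[it, , drop = FALSE]
    fit <- kabsch_superpose(ref_tcr, tcr)   # reference -> frame orientation
    aa <- rotation_angle_axis(fit$transform)
    out$angle_deg[f] <- aa$angle
    out[f, c("axis_x", "axis_y", "axis_z")] <- aa$axis
    out[f, c("disp_x", "disp_y", "disp_z")] <- colMeans(tcr) - ref_cent
  }
  class(out) <- c("motion_series", "data.frame")
  out
}

#' Maximum-excursion frame of a motion series
#' @param series a [tcr_motion_series()] result
#' @return frame index with the largest rocking angle
#' @export
max_excursion_frame <- function(series) {
  series$frame[which.max(series$angle_deg)]
}

#' Decompose TCR displacement relative to the binding cleft
#'
#' Per-frame TCR centroid displacements are (optionally) projected into
#' the MHC platform plane, then split into components parallel and
#' perpendicular to the cleft axis. The parallel fraction is
#' `sum|d_par| / (sum|d_par| + sum|d_perp|)`; fractions >= 0.6 label the
#' motion `parallel`, <= 0.4 `orthogonal`, in between `mixed`. A series
#' with no displacement at all is labelled `static`.
#'
#' @param series a [tcr_motion_series()] result
#' @param cleft unit cleft-axis vector (see [cleft_axis()])
#' @param plane_normal optional unit normal of the MHC plane (see
#'   [mhc_plane_normal()]); when given, displacements are projected into
#'   that plane before decomposition
#' @param thresholds parallel/orthogonal label cutoffs (default 0.6 / 0.4)
#' @return list: `parallel_fraction`, `label`, `d_par`, `d_perp`
#'   (per-frame absolute components, Angstrom)
#' @export
motion_direction <- function(series, cleft, plane_normal = NULL,
                             thresholds = c(orthogonal = 0.4, parallel = 0.6)) {
  d <- as.matrix(series[, c("disp_x", "disp_y", "disp_z")])
  cleft <- cleft / sqrt(sum(cleft^2))
  if (!is.null(plane_normal)) {
    pn <- plane_normal / sqrt(sum(plane_normal^2))
    d <- d - outer(as.numeric(d %*% pn), pn)
    cleft <- cleft - sum(cleft * pn) * pn
    cl_norm <- sqrt(sum(cleft^2))
    if (cl_norm < 1e-9) stop("cleft axis is normal to the MHC plane")
    cleft <- cleft / cl_norm
  }
  par_comp <- as.numeric(d %*% cleft)
  perp_vec <- d - outer(par_comp, cleft)
  d_par <- abs(par_comp)
  d_perp <- sqrt(rowSums(perp_vec^2))
  tot <- sum(d_par) + sum(d_perp)
  if (tot < 1e-12)
    return(list(parallel_fraction = NA_real_, label = "static",
                d_par = d_par, d_perp = d_perp))
  frac <- sum(d_par) / tot
  label <- if (frac >= thresholds[["parallel"]]) "parallel"
    else if (frac <= thresholds[["orthogonal"]]) "orthogonal"
    else "mixed"
  list(parallel_fraction = frac, label = label, d_par = d_par, d_perp = d_perp)
}

#' Docking-angle difference between two complexes
#'
#' Superposes complex B onto complex A by their MHC-core Calpha atoms,
#' then measures the residual rigid rotation between the two TCR atom
#' sets. Symmetric in its arguments to numerical precision. The value
#' depends on the TCR atom set chosen (variable domains by convention);
#' the convention used is whatever the selections express.
#'
#' @param a,b single-frame [trajectory()] structures
#' @param mhc_sel_a,tcr_sel_a selections into `a`
#' @param mhc_sel_b,tcr_sel_b selections into `b` (defaults: same as `a`'s)
#' @return rotation angle in degrees
#' @export
docking_angle_difference <- function(a, b, mhc_sel_a, tcr_sel_a,
                                     mhc_sel_b = mhc_sel_a,
                                     tcr_sel_b = tcr_sel_a) {
  ma <- frame_coords(a, 1L)[select_atoms(a$topology, mhc_sel_a), , drop = FALSE]
  ta <- frame_coords(a, 1L)[select_atoms(a$topology, tcr_sel_a), , drop = FALSE]
  mb <- frame_coords(b, 1L)[select_atoms(b$topology, mhc_sel_b), , drop = FALSE]
  tb <- frame_coords(b, 1L)[select_atoms(b$topology, tcr_sel_b), , drop = FALSE]
  tr <- kabsch_superpose(mb, ma)$transform
  tb_al <- apply_transform(tr, tb)
  fit <- kabsch_superpose(ta, tb_al)
  rotation_angle_axis(fit$transform)$angle
}

#' Write a motion series as CSV with displacement decomposition
#'
#' @param series a [tcr_motion_series()] result
#' @param path output file
#' @param cleft cleft axis for the decomposition columns
#' @param plane_normal optional plane normal (see [motion_direction()])
#' @return `path`, invisibly
#' @export
write_motion_csv <- function(series, path, cleft, plane_normal = NULL) {
  dir <- motion_direction(series, cleft, plane_normal)
  df <- data.frame(frame = series$frame,
                   angle_deg = sprintf("%.4f", series$angle_deg),
                   axis_x = sprintf("%.6f", series$axis_x),
                   axis_y = sprintf("%.6f", series$axis_y),
                   axis_z = sprintf("%.6f", series$axis_z),
                   disp_par_A = sprintf("%.4f", dir$d_par),
                   disp_perp_A = sprintf("%.4f", dir$d_perp))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# tcrdyn motion series: label=%s parallel_fraction=%s",
                     dir$label,
                     if (is.na(dir$parallel_fraction)) "NA"
                     else sprintf("%.4f", dir$parallel_fraction)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
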