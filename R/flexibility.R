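# Per-residue flexibility: RMSF about the average structure, crystallographic
# B-factor summaries, and between-structure RMSD comparisons.

#' Per-residue RMSF profile
#'
#' Frames are aligned on `fit_sel` to the iteratively computed average
#' structure (see [average_structure()]); for each reported atom i the
#' fluctuation is `sqrt(mean_f |x_i(f) - mean(x_i)|^2)`. The conventional
#' setup fits on the stable MHC core (residues 1-180 Calpha) and reports
#' Calpha of both the MHC core and the peptide. Set `align = FALSE` to
#' measure raw fluctuations in the lab frame (used with synthetic data
#' whose ground truth is defined without alignment).
#'
#' @param traj a [trajectory()]
#' @param report_sel a [selection()] resolving to exactly one atom per
#'   residue (Calpha by default usage)
#' @param fit_sel selection used for alignment; default: the report
#'   selection itself
#' @param align align frames to the average structure first (default TRUE)
#' @return data.frame of class `rmsf_profile` with columns `chain_id`,
#'   `res_seq`, `res_name`, `rmsf` (Angstrom), in topology order;
#'   attributes `n_frames` and `fit` record provenance
#' @export
rmsf <- function(traj, report_sel, fit_sel = report_sel, align = TRUE) {
  top <- traj$topology
  idx <- select_atoms(top, report_sel)
  if (!length(idx)) stop("empty report selection")
  uid <- residue_uid(top)[idx]
  dup <- unique(uid[duplicated(uid)])
  if (length(dup))
    stop("report selection has more than one atom in residue(s): ",
         paste(dup, collapse = ", "))
  if (align) {
    avg <- average_structure(traj, fit_sel)
    traj <- align_trajectory(traj, fit_sel, avg)
  }
  xs <- traj$coords[, idx, , drop = FALSE]
  mean_xyz <- apply(xs, c(2, 3), mean)
  dev2 <- sweep(xs, c(2, 3), mean_xyz)^2
  vals <- sqrt(apply(dev2, 2, mean) * 3)   # mean over frames AND xyz, times 3
  a <- top$atoms[idx, ]
  out <- data.frame(chain_id = a$chain_id, res_seq = a$res_seq,
                    res_name = a$res_name, rmsf = vals,
                    row.names = NULL)
  attr(out, "n_frames") <- n_frames(traj)
  attr(out, "fit") <- if (align) selection_desc(fit_sel) else "none (lab frame)"
  class(out) <- c("rmsf_profile", "data.frame")
  out
}

selection_desc <- function(sel) {
  if (inherits(sel, "selection")) selection_label(sel)
  else sprintf("%d explicit atom indices", length(sel))
}

#' Write an RMSF profile as CSV
#'
#' One row per residue, deterministic topology order; provenance (frame
#' count, fit selection) goes into `#`-prefixed header lines.
#'
#' @param profile an [rmsf()] result
#' @param path output file
#' @param b_equivalent also emit the harmonic-oscillator B-factor
#'   equivalent `8 pi^2 / 3 * rmsf^2` as an annotation column (default
#'   FALSE; this is a convenience conversion, not a crystallographic claim)
#' @return `path`, invisibly
#' @export
write_rmsf_csv <- function(profile, path, b_equivalent = FALSE) {
  stopifnot(inherits(profile, "rmsf_profile"))
  hdr <- c(sprintf("# tcrdyn rmsf profile"),
           sprintf("# n_frames: %s", attr(profile, "n_frames")),
           sprintf("# fit: %s", attr(profile, "fit")))
  df <- data.frame(chain = profile$chain_id, res_seq = profile$res_seq,
                   res_name = profile$res_name,
                   rmsf_A = sprintf("%.4f", profile$rmsf))
  if (b_equivalent)
    df$b_equiv_A2 <- sprintf("%.2f", 8 * pi^2 / 3 * profile$rmsf^2)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mean crystallographic B-factor over a selection
#'
#' Unweighted arithmetic mean of the isotropic temperature factors of the
#' selected atoms. By default hydrogens are excluded (deposited structures
#' rarely refine them); pass `heavy_only = FALSE` to average every
#' selected atom.
#'
#' @param x a [trajectory()] (single-frame structure) or [topology()]
#' @param sel a [selection()] or index vector
#' @param heavy_only drop hydrogens first (default TRUE)
#' @return mean B-factor, Angstrom^2
#' @export
mean_bfactor <- function(x, sel, heavy_only = TRUE) {
  top <- if (inherits(x, "trajectory")) x$topology else x
  idx <- select_atoms(top, sel)
  if (heavy_only) idx <- idx[top$atoms$element[idx] != "H"]
  if (!length(idx)) stop("empty selection for mean_bfactor")
  mean(top$atoms$b_factor[idx])
}

#' RMSD between two structures over matched selections
#'
#' The two selections must resolve to equal-length atom lists; atoms are
#' matched by selection order (no sequence alignment). With
#' `superpose = TRUE` (default) the RMSD is measured after optimal rigid
#' superposition of the compared selections themselves; with `FALSE` the
#' raw deviation in the shared frame is returned.
#'
#' @param a,b single-frame [trajectory()] objects (or `N x 3` matrices)
#' @param sel_a,sel_b selections into `a` and `b` (ignored for matrices)
#' @param superpose superpose before measuring (default TRUE)
#' @return RMSD in Angstrom
#' @export
pairwise_rmsd <- function(a, b, sel_a = NULL, sel_b = NULL, superpose = TRUE) {
  pa <- if (inherits(a, "trajectory")) {
    idx <- if (is.null(sel_a)) seq_len(n_atoms(a$topology))
           else select_atoms(a$topology, sel_a)
    frame_coords(a, 1L)[idx, , drop = FALSE]
  } else as.matrix(a)
  pb <- if (inherits(b, "trajectory")) {
    idx <- if (is.null(sel_b)) seq_len(n_atoms(b$topology))
           else select_atoms(b$topology, sel_b)
    frame_coords(b, 1L)[idx, , drop = FALSE]
  } else as.matrix(b)
  if (nrow(pa) != nrow(pb))
    stop(sprintf("selection length mismatch: %d vs %d atoms", nrow(pa), nrow(pb)))
  if (superpose) kabsch_superpose(pa, pb)$rmsd else coord_rmsd(pa, pb)
}
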