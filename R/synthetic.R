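# Synthetic trajectories with known ground truth. Three generators emulate
# the statistical structure of the analyses' inputs: (a) per-residue
# isotropic Gaussian positional fluctuation (RMSF oracle), (b) scripted
# hydrogen-bond formation schedules (persistence oracle), (c) rigid-body
# rocking of a TCR subunit about a pivot (motion oracle). Noise is i.i.d.
# across residues and frames - the analyses under test are frame-wise
# statistics, so temporal correlation is irrelevant to their correctness.
# Every generator is a pure function of its arguments including `seed`;
# the caller's RNG state is left untouched.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

ca_atom_row <- function(i, chain, res_name = "GLY") {
  data.frame(serial = i, name = "CA", element = "C", res_name = res_name,
             res_seq = i, chain_id = chain, icode = "", occupancy = 1,
             b_factor = 0)
}

#' Fluctuating-chain generator (RMSF ground truth)
#'
#' One Calpha per residue on a gently zig-zagged extended chain (3.8
#' Angstrom spacing); frame f adds i.i.d. Gaussian noise with the
#' residue's sigma to each coordinate. Without alignment the expected
#' RMSF of residue i is exactly `sqrt(3) * sigma_i`.
#'
#' @param n_residues chain length (default 20)
#' @param sigma per-coordinate fluctuation standard deviation, Angstrom;
#'   scalar or per-residue vector (default 0.5)
#' @param n_frames frame count (default 100)
#' @param seed RNG seed; fixes the output bit-for-bit
#' @param chain_id chain label
#' @return a [trajectory()]; attribute `sigma` carries the ground truth
#' @export
gen_fluctuating_chain <- function(n_residues = 20L, sigma = 0.5,
                                  n_frames = 100L, seed = 1L,
                                  chain_id = "A") {
  stopifnot(n_residues >= 1, n_frames >= 1, all(sigma >= 0))
  sig <- rep_len(sigma, n_residues)
  i <- seq_len(n_residues)
  base <- cbind(3.8 * i, 1.2 * (i %% 2L), 0.4 * sin(i / 2))
  atoms <- do.call(rbind, lapply(i, ca_atom_row, chain = chain_id))
  top <- topology(atoms)
  coords <- with_seed(seed, {
    out <- array(0, c(n_frames, n_residues, 3L))
    for (f in seq_len(n_frames))
      out[f, , ] <- base + matrix(stats::rnorm(3L * n_residues, sd = sig),
                                  n_residues, 3L)
    out
  })
  tr <- trajectory(top, coords)
  attr(tr, "sigma") <- sig
  tr
}

# geometry of one scripted donor/acceptor pair, relative to the donor N:
#  H sits 1.0 A along +x; the "on" acceptor position makes the N-H-A angle
#  exactly 175 deg with |N-A| = 2.9 A; "off" parks the acceptor at 5.0 A.
# Non-participating atoms are kept >= 6 A from every scripted site so the
# schedule is the exact oracle for bond detection.
.hb_on_offset <- local({
  # law of cosines at the hydrogen: 2.9^2 = 1 + x^2 - 2 x cos(175 deg)
  x <- cos(175 * pi / 180) + sqrt(cos(175 * pi / 180)^2 - (1 - 2.9^2))
  c(1, 0, 0) + x * c(cos(5 * pi / 180), sin(5 * pi / 180), 0)
})
.hb_off_offset <- c(5, 0, 0)

#' Scripted hydrogen-bond system generator (persistence ground truth)
#'
#' Builds one donor residue (chain `D`: backbone N with an explicit H) and
#' one acceptor residue (chain `E`: backbone O, no hydrogens) per
#' schedule, spatially separated pairs 25 Angstrom apart. In "on" frames
#' the acceptor sits 2.9 Angstrom from the donor nitrogen with a
#' donor-H-acceptor angle of 175 degrees (inside the default criteria);
#' in "off" frames it is parked 5.0 Angstrom away (outside). Optional
#' Gaussian jitter with `sigma <= 0.1` Angstrom leaves all margins intact
#' (distance margin 0.6 A, angle margin 25 deg), so detected persistence
#' still equals the schedule.
#'
#' @param schedules list of logical vectors, one per donor/acceptor pair;
#'   all the same length F (the frame count)
#' @param sigma per-coordinate Gaussian jitter, Angstrom (default 0)
#' @param seed RNG seed (only used when `sigma > 0`)
#' @return a [trajectory()] with hydrogens attached
#'   (`topology$h_attach` populated); attribute `schedules` carries the
#'   ground truth
#' @export
gen_hbond_system <- function(schedules, sigma = 0, seed = 1L) {
  stopifnot(is.list(schedules), length(schedules) >= 1)
  nf <- length(schedules[[1]])
  ok <- vapply(schedules, function(s) is.logical(s) && length(s) == nf, TRUE)
  if (!all(ok)) stop("schedules must be logical vectors of one common length")
  np <- length(schedules)
  # donor residue atoms: N (donor), H, CA, O; acceptor residue: O (acceptor),
  # CA, N (bare, so it can never donate)
  d_atoms <- list(); a_atoms <- list()
  for (p in seq_len(np)) {
    y <- 25 * (p - 1L)
    d_atoms[[p]] <- data.frame(
      serial = 0L, name = c("N", "H", "CA", "O"),
      element = c("N", "H", "C", "O"), res_name = "GLY", res_seq = p,
      chain_id = "D", icode = "", occupancy = 1, b_factor = 0,
      x = c(0, 1, 0, -2) , y = y + c(0, 0, 2, 6), z = c(0, 0, 0, 0))
    a_atoms[[p]] <- data.frame(
      serial = 0L, name = c("O", "CA", "N"),
      element = c("O", "C", "N"), res_name = "GLY", res_seq = p,
      chain_id = "E", icode = "", occupancy = 1, b_factor = 0,
      x = c(NA, 3, 3), y = y + c(NA, 1.5, -1.5), z = c(NA, 6, 6))
    # acceptor x/y placeholders are filled per frame from the schedule
  }
  at <- do.call(rbind, c(d_atoms, a_atoms))
  at$serial <- seq_len(nrow(at))
  top <- topology(at[, c("serial", "name", "element", "res_name", "res_seq",
                         "chain_id", "icode", "occupancy", "b_factor")])
  base <- as.matrix(at[, c("x", "y", "z")])
  acc_row <- function(p) 4L * np + 3L * (p - 1L) + 1L
  coords <- array(0, c(nf, nrow(at), 3L))
  for (f in seq_len(nf)) {
    fr <- base
    for (p in seq_len(np)) {
      origin <- c(0, 25 * (p - 1L), 0)   # donor N of pair p
      off <- if (schedules[[p]][f]) .hb_on_offset else .hb_off_offset
      fr[acc_row(p), ] <- origin + off
    }
    coords[f, , ] <- fr
  }
  if (sigma > 0) {
    if (sigma > 0.1)
      warning("sigma > 0.1 A erodes the schedule's geometric margins")
    coords <- coords + with_seed(seed, {
      array(stats::rnorm(length(coords), sd = sigma), dim(coords))
    })
  }
  tr <- trajectory(top, coords)
  tr <- with_h_attachment(tr)
  attr(tr, "schedules") <- schedules
  tr
}

#' Rocking-complex generator (rigid-motion ground truth)
#'
#' A static MHC chain (`A`, a curved Calpha trace), a static 13-residue
#' peptide chain (`C`) laid out along the x axis (so x is the cleft
#' axis), and a TCR chain (`T`) rigidly rotated about `pivot` by
#' `amplitude * sin(2 pi (f-1) / period)` degrees at frame f. With the
#' default `period = n_frames = 100` the maximum excursion (exactly
#' `amplitude`) occurs at frame 26.
#'
#' @param amplitude_deg rocking amplitude, degrees (default 12)
#' @param axis rotation axis (default z, i.e. normal to the cleft)
#' @param period frames per rocking cycle (default 100)
#' @param n_frames frame count (default 100)
#' @param pivot rotation pivot point; default: the peptide centroid (the
#'   TCR pivots atop the bulged peptide)
#' @param n_mhc,n_tcr residue counts of the MHC and TCR chains
#' @param sigma optional Gaussian jitter on every atom, Angstrom
#' @param seed RNG seed (used when `sigma > 0`)
#' @return a [trajectory()]; attributes `axis`, `amplitude_deg`, `pivot`
#'   carry the ground truth
#' @export
gen_rocking_complex <- function(amplitude_deg = 12, axis = c(0, 0, 1),
                                period = 100L, n_frames = 100L, pivot = NULL,
                                n_mhc = 60L, n_tcr = 40L, sigma = 0,
                                seed = 1L) {
  stopifnot(amplitude_deg >= 0, period >= 1, n_frames >= 1)
  axis <- axis / sqrt(sum(axis^2))
  i <- seq_len(n_mhc)
  mhc <- cbind(2.5 * i, 8 * sin(i / 3), 8 * cos(i / 3))
  j <- seq_len(13L)
  pep <- cbind(10 + 3.3 * j, 18 + 0.8 * (j %% 2L), 6 + 0.3 * j)
  k <- seq_len(n_tcr)
  tcr <- cbind(12 + 2.5 * k, 18 + 7 * sin(k / 2.5), 30 + 6 * cos(k / 2.5))
  if (is.null(pivot)) pivot <- colMeans(pep)
  atoms <- rbind(
    do.call(rbind, lapply(i, ca_atom_row, chain = "A")),
    do.call(rbind, lapply(j, ca_atom_row, chain = "C")),
    do.call(rbind, lapply(k, ca_atom_row, chain = "T"))
  )
  atoms$serial <- seq_len(nrow(atoms))
  top <- topology(atoms)
  base <- rbind(mhc, pep, tcr)
  tcr_rows <- (n_mhc + 13L) + k
  coords <- array(0, c(n_frames, nrow(base), 3L))
  for (f in seq_len(n_frames)) {
    fr <- base
    theta <- amplitude_deg * sin(2 * pi * (f - 1L) / period)
    if (abs(theta) > 0) {
      R <- rotation_matrix(theta, axis)
      fr[tcr_rows, ] <- sweep(sweep(fr[tcr_rows, , drop = FALSE], 2, pivot) %*% t(R),
                              2, pivot, `+`)
    }
    coords[f, , ] <- fr
  }
  if (sigma > 0)
    coords <- coords + with_seed(seed, {
      array(stats::rnorm(length(coords), sd = sigma), dim(coords))
    })
  tr <- trajectory(top, coords)
  attr(tr, "axis") <- axis
  attr(tr, "amplitude_deg") <- amplitude_deg
  attr(tr, "pivot") <- pivot
  tr
}
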