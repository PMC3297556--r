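# Independent oracles and fixture builders shared across tests. Everything
# here is deliberately written from first principles (quaternions, plain
# double loops) so it cannot share a bug with the implementation it checks.

# rotation matrix via unit quaternion, NOT Rodrigues like the package
quat_rotation <- function(angle_deg, axis) {
  th <- angle_deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  w <- cos(th / 2); q <- sin(th / 2) * u
  x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

random_rotation <- function() {
  ax <- stats::rnorm(3)
  quat_rotation(stats::runif(1, 0, 180), ax)
}

rigid_move <- function(coords, R, t) sweep(coords %*% t(R), 2, t, `+`)

# tiny hand-written PDB: one GLY residue, three atoms, fixed coordinates
three_atom_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   GLY A   1       1.000   2.000   3.000  1.00 10.00           N",
    "ATOM      2  CA  GLY A   1       2.500   2.000   3.000  1.00 12.00           C",
    "ATOM      3  C   GLY A   1       3.500   3.000   3.000  1.00 14.00           C",
    "END"), path)
  path
}

# random two-chain system with backbone-style residues for H-bond scans;
# every residue carries N (+H at 1.0 A), CA, O
random_hbond_topology <- function(n_res_a, n_res_b, box = 12) {
  build <- function(n, chain) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      p <- stats::runif(3, 0, box)
      hdir <- stats::rnorm(3); hdir <- hdir / sqrt(sum(hdir^2))
      data.frame(
        serial = 0L, name = c("N", "H", "CA", "O"),
        element = c("N", "H", "C", "O"), res_name = "GLY", res_seq = i,
        chain_id = chain, icode = "", occupancy = 1, b_factor = 0,
        x = p[1] + c(0, hdir[1], 1.6, -1.4),
        y = p[2] + c(0, hdir[2], 0.6, 0.9),
        z = p[3] + c(0, hdir[3], 0.2, 0.8))
    }))
  }
  at <- rbind(build(n_res_a, "A"), build(n_res_b, "B"))
  at$serial <- seq_len(nrow(at))
  list(atoms = at[, c("serial", "name", "element", "res_name", "res_seq",
                      "chain_id", "icode", "occupancy", "b_factor")],
       base = as.matrix(at[, c("x", "y", "z")]))
}

random_hbond_trajectory <- function(n_res_a = 8, n_res_b = 8, n_frames = 10,
                                    jitter = 0.4) {
  sys <- random_hbond_topology(n_res_a, n_res_b)
  n <- nrow(sys$base)
  coords <- array(0, c(n_frames, n, 3))
  for (f in seq_len(n_frames))
    coords[f, , ] <- sys$base + matrix(stats::rnorm(3 * n, sd = jitter), n, 3)
  # jittered hydrogens occasionally drift past the covalent cutoff; the
  # attachment warning is expected noise here, and the brute-force oracle
  # applies the identical rule
  suppressWarnings(tcrdyn::with_h_attachment(
    tcrdyn::trajectory(tcrdyn::topology(sys$atoms), coords)))
}

# exhaustive per-frame hydrogen-bond oracle: plain loops over every
# donor/acceptor pair in both directions; donors are N/O/S heavy atoms
# owning a hydrogen within 1.2 A (recomputed here by brute force), and
# acceptors are backbone O atoms (all the helper systems provide)
brute_hbond_sets <- function(traj, chains_a, chains_b, d_max = 3.5,
                             theta_min = 150) {
  top <- traj$topology
  a <- top$atoms
  nfr <- tcrdyn::n_frames(traj)
  # H attachment is topological: brute-force it once from frame 1
  x1 <- tcrdyn::frame_coords(traj, 1)
  hmap <- rep(NA_integer_, nrow(a))
  for (h in which(a$element == "H")) {
    best <- NA_integer_; bestd <- Inf
    for (j in which(a$element != "H")) {
      dd <- sqrt(sum((x1[h, ] - x1[j, ])^2))
      if (dd < bestd) { bestd <- dd; best <- j }
    }
    if (bestd <= 1.2) hmap[h] <- best
  }
  res <- list()
  for (f in seq_len(nfr)) {
    x <- tcrdyn::frame_coords(traj, f)
    found <- character(0)
    for (d in seq_len(nrow(a))) {
      if (!a$element[d] %in% c("N", "O", "S")) next
      hs <- which(hmap == d)
      if (!length(hs)) next
      for (acc in which(a$name %in% c("O", "OXT"))) {
        ok_dir <- (a$chain_id[d] %in% chains_a && a$chain_id[acc] %in% chains_b) ||
          (a$chain_id[d] %in% chains_b && a$chain_id[acc] %in% chains_a)
        if (!ok_dir) next
        dist <- sqrt(sum((x[d, ] - x[acc, ])^2))
        if (dist > d_max + 1e-9) next
        for (h in hs) {
          u <- x[d, ] - x[h, ]; v <- x[acc, ] - x[h, ]
          ang <- acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
          if (ang >= theta_min - 1e-9) {
            found <- c(found, paste(d, acc, sep = "-"))
            break
          }
        }
      }
    }
    res[[f]] <- sort(unique(found))
  }
  res
}

# package hbond_series reshaped into the oracle's per-frame key sets
series_frame_sets <- function(series, traj) {
  top <- traj$topology
  a <- top$atoms
  idx_of <- function(ref) which(a$chain_id == ref$chain_id &
                                  a$res_seq == ref$res_seq &
                                  a$name == ref$name)
  nfr <- attr(series, "n_frames")
  out <- rep(list(character(0)), nfr)
  for (s in series) {
    key <- paste(idx_of(s$donor), idx_of(s$acceptor), sep = "-")
    for (f in which(s$formed)) out[[f]] <- c(out[[f]], key)
  }
  lapply(out, function(v) sort(unique(v)))
}

# minimal series stub for salt-bridge tests
series_stub <- function(d_res, d_name, a_res, a_name) {
  list(donor = list(chain_id = "A", res_seq = 1L, res_name = d_res, name = d_name),
       acceptor = list(chain_id = "B", res_seq = 2L, res_name = a_res, name = a_name),
       formed = TRUE, label = "stub")
}
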