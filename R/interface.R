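# Geometric hydrogen-bond and heavy-atom contact detection between two
# molecular groups (e.g. the pMHC side and the TCR side of an interface).
#
# A bond is formed when the donor-heavy to acceptor distance is at most
# d_max AND the donor-H-acceptor angle at the central hydrogen is at least
# theta_min, both boundaries inclusive. The distance cutoff is read as
# donor-heavy <-> acceptor (not hydrogen <-> acceptor). Trajectories are
# assumed pre-imaged (molecules whole): there is NO periodic-boundary
# minimum-image handling anywhere in this module.

#' Hydrogen-bond formation criteria
#'
#' Defaults follow the standard geometric criterion: donor/acceptor
#' heavy-atom cutoff 3.5 Angstrom and a donor-H-acceptor angle within 30
#' degrees of linear (i.e. >= 150 degrees at the central hydrogen).
#'
#' @param d_max donor-heavy to acceptor distance cutoff, Angstrom
#' @param theta_min minimum donor-H-acceptor angle, degrees
#' @return object of class `hbond_criteria`
#' @export
hbond_criteria <- function(d_max = 3.5, theta_min = 150) {
  stopifnot(d_max > 0, theta_min > 0, theta_min <= 180)
  structure(list(d_max = d_max, theta_min = theta_min),
            class = "hbond_criteria")
}

# residue-type chemistry tables (three-letter codes, PDB atom names)
.sidechain_donors <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  TRP = "NE1", ASN = "ND2", GLN = "NE2", SER = "OG", THR = "OG1",
  TYR = "OH", CYS = "SG"
)
.sidechain_acceptors <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD"
)

# chemically equivalent atom pairs merged in footprint bookkeeping
.equiv_atoms <- list(
  ARG = list(c("NH1", "NH2")),
  ASP = list(c("OD1", "OD2")),
  GLU = list(c("OE1", "OE2"))
)

merged_atom_name <- function(res_name, atom_name) {
  groups <- .equiv_atoms[[res_name]]
  if (!is.null(groups)) {
    for (g in groups) if (atom_name %in% g)
      return(paste0(substr(g[1], 1, nchar(g[1]) - 1L), "1/2"))
  }
  atom_name
}

#' Assign hydrogen-bond donors and acceptors
#'
#' Donor heavy atoms are N/O/S atoms carrying at least one attached
#' hydrogen (from the topology's `h_attach` map); the proline backbone
#' nitrogen is never a donor. Acceptors come from a residue-type table:
#' backbone O/OXT for every residue, plus side-chain lone-pair sites
#' (Asp Od1/2, Glu Oe1/2, Asn Od1, Gln Oe1, Ser Og, Thr Og1, Tyr Oh,
#' His Nd1/Ne2, Met Sd). Histidine is treated as unprotonated on both ring
#' nitrogens: each is an acceptor, and a donor only when it actually
#' carries a hydrogen.
#'
#' For hydrogen-free topologies (crystal structures) `potential = TRUE`
#' returns the donors that COULD carry a hydrogen by the same residue-type
#' chemistry; this backs the distance-only mode used to decide crystal
#' presence.
#'
#' @param top a [topology()]
#' @param potential table-based donors irrespective of explicit hydrogens
#' @return list with `donors` (data.frame `atom` index + list-column
#'   `hydrogens`) and `acceptors` (integer atom indices)
#' @export
assign_donors_acceptors <- function(top, potential = !any(!is.na(top$h_attach))) {
  a <- top$atoms
  nos <- a$element %in% c("N", "O", "S")
  if (potential) {
    is_backbone_n <- a$name == "N" & a$res_name != "PRO"
    sc <- mapply(function(rn, nm) nm %in% .sidechain_donors[[rn]],
                 a$res_name, a$name, USE.NAMES = FALSE)
    d_idx <- which(nos & (is_backbone_n | sc))
    hyd <- rep(list(integer(0)), length(d_idx))
  } else {
    mapped_h <- which(!is.na(top$h_attach))
    heavy <- top$h_attach[mapped_h]
    keep <- nos[heavy] & !(a$name[heavy] == "N" & a$res_name[heavy] == "PRO")
    heavy <- heavy[keep]; mapped_h <- mapped_h[keep]
    d_idx <- sort(unique(heavy))
    hyd <- lapply(d_idx, function(i) mapped_h[heavy == i])
  }
  is_backbone_o <- a$name %in% c("O", "OXT")
  sc_acc <- mapply(function(rn, nm) nm %in% .sidechain_acceptors[[rn]],
                   a$res_name, a$name, USE.NAMES = FALSE)
  acc <- which(nos & (is_backbone_o | sc_acc))
  donors <- data.frame(atom = d_idx)
  donors$hydrogens <- hyd
  list(donors = donors, acceptors = acc)
}

vec_angle_deg <- function(u, v) {
  c1 <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, c1))) * 180 / pi
}

#' Hydrogen bonds in one frame
#'
#' A (donor, hydrogen, acceptor) triple is formed iff the donor-heavy to
#' acceptor distance is `<= d_max` and the angle at the hydrogen between
#' donor-heavy and acceptor is `>= theta_min`, for at least one attached
#' hydrogen. Boundary values are inclusive. With `distance_only = TRUE`
#' the angle test is waived (hydrogen-free crystal mode) and the hydrogen
#' column is `NA`.
#'
#' @param frame `N x 3` coordinate matrix
#' @param donors,acceptors as returned by [assign_donors_acceptors()]
#'   (donors may be restricted to one group, acceptors to the other)
#' @param criteria an [hbond_criteria()]
#' @param distance_only waive the angle criterion
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor`
#'   (atom indices; zero rows when nothing is formed)
#' @export
hbonds_in_frame <- function(frame, donors, acceptors, criteria = hbond_criteria(),
                            distance_only = FALSE) {
  eps <- 1e-9
  out_d <- integer(0); out_h <- integer(0); out_a <- integer(0)
  if (!nrow(donors) || !length(acceptors))
    return(data.frame(donor = out_d, hydrogen = out_h, acceptor = out_a))
  D <- frame[donors$atom, , drop = FALSE]
  A <- frame[acceptors, , drop = FALSE]
  d2 <- outer(rowSums(D^2), rep(1, nrow(A))) +
    outer(rep(1, nrow(D)), rowSums(A^2)) - 2 * D %*% t(A)
  cand <- which(d2 <= (criteria$d_max + eps)^2, arr.ind = TRUE)
  for (k in seq_len(nrow(cand))) {
    di <- cand[k, 1]; ai <- cand[k, 2]
    d_atom <- donors$atom[di]; a_atom <- acceptors[ai]
    if (d_atom == a_atom) next
    if (distance_only) {
      out_d <- c(out_d, d_atom); out_h <- c(out_h, NA_integer_)
      out_a <- c(out_a, a_atom)
      next
    }
    hs <- donors$hydrogens[[di]]
    for (h in hs) {
      ang <- vec_angle_deg(frame[d_atom, ] - frame[h, ],
                           frame[a_atom, ] - frame[h, ])
      if (ang >= criteria$theta_min - eps) {
        out_d <- c(out_d, d_atom); out_h <- c(out_h, h); out_a <- c(out_a, a_atom)
        break
      }
    }
  }
  data.frame(donor = out_d, hydrogen = out_h, acceptor = out_a)
}

atom_ref <- function(top, idx, merged = FALSE) {
  a <- top$atoms[idx, ]
  nm <- if (merged) merged_atom_name(a$res_name, a$name) else a$name
  list(chain_id = a$chain_id, res_seq = a$res_seq, res_name = a$res_name,
       name = nm)
}

atom_ref_label <- function(ref) {
  sprintf("%s:%s%d:%s", ref$chain_id, ref$res_name, ref$res_seq, ref$name)
}

#' Per-bond formed/broken series over a trajectory
#'
#' Scans every frame for inter-group hydrogen bonds in both directions
#' (group A donating to group B and vice versa) and returns one series per
#' donor/acceptor pair that is formed in at least one frame. With
#' `merge_equivalent = TRUE` (default) chemically equivalent atoms
#' (Arg NH1/NH2, Asp OD1/OD2, Glu OE1/OE2) are merged into a single series
#' by per-frame logical OR and reported with a `1/2` suffix, matching the
#' usual interface bookkeeping.
#'
#' Requires a populated hydrogen attachment map unless
#' `distance_only = TRUE`, which waives the angle criterion (the fallback
#' for hydrogen-free crystal references; the mode is recorded on the
#' result).
#'
#' @param traj a [trajectory()]
#' @param group_a,group_b disjoint [selection()]s (or index vectors)
#' @param criteria an [hbond_criteria()]
#' @param merge_equivalent merge equivalent-atom series (default TRUE)
#' @param distance_only crystal fallback mode (default: TRUE iff the
#'   topology has no mapped hydrogens)
#' @return list of class `hbond_series_list`; each element has `donor`,
#'   `acceptor` (atom refs), `formed` (logical, length F), `label`
#' @export
hbond_series <- function(traj, group_a, group_b, criteria = hbond_criteria(),
                         merge_equivalent = TRUE,
                         distance_only = all(is.na(traj$topology$h_attach))) {
  top <- traj$topology
  ia <- select_atoms(top, group_a)
  ib <- select_atoms(top, group_b)
  if (length(intersect(ia, ib)))
    stop("groups overlap: hydrogen-bond groups must be disjoint")
  da <- assign_donors_acceptors(top, potential = distance_only)
  sub_da <- function(group_idx, other_idx) {
    keep_d <- da$donors$atom %in% group_idx
    list(donors = da$donors[keep_d, , drop = FALSE],
         acceptors = intersect(da$acceptors, other_idx))
  }
  ab <- sub_da(ia, ib)
  ba <- sub_da(ib, ia)
  nf <- n_frames(traj)
  series <- list()
  for (f in seq_len(nf)) {
    fr <- frame_coords(traj, f)
    hits <- rbind(
      hbonds_in_frame(fr, ab$donors, ab$acceptors, criteria, distance_only),
      hbonds_in_frame(fr, ba$donors, ba$acceptors, criteria, distance_only)
    )
    for (k in seq_len(nrow(hits))) {
      dref <- atom_ref(top, hits$donor[k], merged = merge_equivalent)
      aref <- atom_ref(top, hits$acceptor[k], merged = merge_equivalent)
      key <- paste(atom_ref_label(dref), atom_ref_label(aref), sep = " -> ")
      if (is.null(series[[key]]))
        series[[key]] <- list(donor = dref, acceptor = aref,
                              formed = logical(nf), label = key)
      series[[key]]$formed[f] <- TRUE
    }
  }
  out <- if (length(series)) unname(series[order(names(series))]) else list()
  attr(out, "n_frames") <- nf
  attr(out, "criteria") <- criteria
  attr(out, "mode") <- if (distance_only) "distance_only" else "distance_and_angle"
  class(out) <- "hbond_series_list"
  out
}

#' @export
print.hbond_series_list <- function(x, ...) {
  cat(sprintf("%d hydrogen-bond series over %d frames (%s mode)\n",
              length(x), attr(x, "n_frames"), attr(x, "mode")))
  for (s in x)
    cat(sprintf("  %-40s %5.1f%%\n", s$label, 100 * mean(s$formed)))
  invisible(x)
}

#' Residue-residue heavy-atom contacts in one frame
#'
#' A residue pair is in contact iff any inter-group heavy-atom pair is
#' within `cutoff` (default 4.0 Angstrom, a conventional van der Waals
#' contact distance).
#'
#' @param frame `N x 3` coordinates
#' @param top a [topology()]
#' @param group_a,group_b selections or index vectors
#' @param cutoff Angstrom
#' @return data.frame `res_a`, `res_b` (residue uids), `min_dist`
#' @export
contacts_in_frame <- function(frame, top, group_a, group_b, cutoff = 4.0) {
  stopifnot(cutoff > 0)
  ia <- select_atoms(top, group_a)
  ib <- select_atoms(top, group_b)
  ia <- ia[top$atoms$element[ia] != "H"]
  ib <- ib[top$atoms$element[ib] != "H"]
  if (!length(ia) || !length(ib))
    return(data.frame(res_a = character(0), res_b = character(0),
                      min_dist = numeric(0)))
  A <- frame[ia, , drop = FALSE]; B <- frame[ib, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  uid <- residue_uid(top)
  key <- paste(uid[ia][row(d2)], uid[ib][col(d2)], sep = "|")
  mind <- tapply(sqrt(as.vector(d2)), key, min)
  hit <- mind <= cutoff
  parts <- strsplit(names(mind)[hit], "|", fixed = TRUE)
  data.frame(res_a = vapply(parts, `[`, "", 1),
             res_b = vapply(parts, `[`, "", 2),
             min_dist = as.numeric(mind[hit]), row.names = NULL)
}

#' Residue-contact series over a trajectory
#'
#' @param traj a [trajectory()]
#' @param group_a,group_b selections
#' @param cutoff heavy-atom distance cutoff, Angstrom (default 4.0)
#' @return data.frame `res_a`, `res_b`, `n_frames_formed`, `persistence_pct`
#' @export
contact_series <- function(traj, group_a, group_b, cutoff = 4.0) {
  nf <- n_frames(traj)
  counts <- list()
  for (f in seq_len(nf)) {
    cf <- contacts_in_frame(frame_coords(traj, f), traj$topology,
                            group_a, group_b, cutoff)
    for (k in seq_len(nrow(cf))) {
      key <- paste(cf$res_a[k], cf$res_b[k], sep = "|")
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  if (!length(counts))
    return(data.frame(res_a = character(0), res_b = character(0),
                      n_frames_formed = integer(0), persistence_pct = numeric(0)))
  keys <- sort(names(counts))
  parts <- strsplit(keys, "|", fixed = TRUE)
  n <- vapply(keys, function(k) counts[[k]], integer(1))
  data.frame(res_a = vapply(parts, `[`, "", 1),
             res_b = vapply(parts, `[`, "", 2),
             n_frames_formed = as.integer(n),
             persistence_pct = 100 * n / nf, row.names = NULL)
}

#' Is a hydrogen-bond series a salt bridge?
#'
#' TRUE iff one side is a basic side-chain nitrogen (Arg NE/NH1/NH2/NH1-2,
#' Lys NZ) and the other an acidic carboxylate oxygen (Asp OD1/OD2/OD1-2,
#' Glu OE1/OE2/OE1-2), in either donor/acceptor orientation.
#'
#' @param series one element of an [hbond_series()] result
#' @return logical
#' @export
salt_bridge_flag <- function(series) {
  basic <- function(r) (r$res_name == "ARG" && r$name %in% c("NE", "NH1", "NH2", "NH1/2")) ||
    (r$res_name == "LYS" && r$name == "NZ")
  acidic <- function(r) (r$res_name == "ASP" && r$name %in% c("OD1", "OD2", "OD1/2")) ||
    (r$res_name == "GLU" && r$name %in% c("OE1", "OE2", "OE1/2"))
  (basic(series$donor) && acidic(series$acceptor)) ||
    (basic(series$acceptor) && acidic(series$donor))
}

#' Export hydrogen-bond series as a per-bond CSV table
#'
#' @param series an [hbond_series()] result
#' @param path output CSV (or `NULL` to just return the data.frame)
#' @return data.frame with columns donor_chain, donor_res, donor_atom,
#'   acceptor_chain, acceptor_res, acceptor_atom, n_frames_formed,
#'   persistence_pct, salt_bridge
#' @export
hbond_table <- function(series, path = NULL) {
  stopifnot(inherits(series, "hbond_series_list"))
  nf <- attr(series, "n_frames")
  df <- do.call(rbind, lapply(series, function(s) {
    data.frame(
      donor_chain = s$donor$chain_id,
      donor_res = sprintf("%s%d", s$donor$res_name, s$donor$res_seq),
      donor_atom = s$donor$name,
      acceptor_chain = s$acceptor$chain_id,
      acceptor_res = sprintf("%s%d", s$acceptor$res_name, s$acceptor$res_seq),
      acceptor_atom = s$acceptor$name,
      n_frames_formed = sum(s$formed),
      persistence_pct = round(100 * mean(s$formed)),
      salt_bridge = salt_bridge_flag(s)
    )
  }))
  if (is.null(df))
    df <- data.frame(donor_chain = character(0), donor_res = character(0),
                     donor_atom = character(0), acceptor_chain = character(0),
                     acceptor_res = character(0), acceptor_atom = character(0),
                     n_frames_formed = integer(0), persistence_pct = numeric(0),
                     salt_bridge = logical(0))
  if (!is.null(path)) {
    con <- file(path, "wt")
    on.exit(close(con))
    crit <- attr(series, "criteria")
    writeLines(sprintf("# tcrdyn hbonds: n_frames=%d d_max=%g theta_min=%g mode=%s",
                       nf, crit$d_max, crit$theta_min, attr(series, "mode")), con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  }
  df
}
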