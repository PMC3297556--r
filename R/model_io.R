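# Structure / trajectory model and PDB I/O.
#
# The topology is a plain data.frame of atom records plus an optional
# hydrogen -> heavy-atom attachment vector; a trajectory binds an
# F x N x 3 coordinate array (Angstrom) to a topology. PDB reading and
# writing follow wwPDB v3.3 fixed columns (ATOM/HETATM/MODEL/ENDMDL/TER).

# ---- topology ----------------------------------------------------------

#' Create a topology from an atom table
#'
#' A topology is the static description of a molecular system: one row per
#' atom with PDB-style naming, author residue numbering, chain identifiers,
#' occupancies and isotropic B-factors, plus an optional map from each
#' hydrogen to the heavy atom it is covalently attached to (needed by the
#' hydrogen-bond angle criterion).
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `res_name`, `res_seq`, `chain_id`, `icode`, `occupancy`, `b_factor`.
#'   Missing `icode` defaults to `""`, missing `occupancy` to 1, missing
#'   `b_factor` to 0, missing `element` is derived from `name`.
#' @param h_attach integer vector, length = number of atoms: for a hydrogen
#'   atom the row index of its heavy partner, `NA` otherwise. Default all
#'   `NA` (crystal structures typically carry no hydrogens).
#' @return object of class `topology`
#' @seealso [read_structure()], [infer_h_attachment()], [select_atoms()]
#' @export
topology <- function(atoms, h_attach = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  n <- nrow(atoms)
  if (is.null(atoms$icode)) atoms$icode <- ""
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$b_factor)) atoms$b_factor <- 0
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (is.null(atoms$element) || anyNA(atoms$element) || any(atoms$element == "")) {
    der <- derive_element(atoms$name, atoms$res_name)
    if (is.null(atoms$element)) atoms$element <- der
    fix <- is.na(atoms$element) | atoms$element == ""
    atoms$element[fix] <- der[fix]
  }
  need <- c("serial", "name", "element", "res_name", "res_seq", "chain_id",
            "icode", "occupancy", "b_factor")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(atoms$b_factor < 0)) stop("negative B-factor in atom table")
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1))
    stop("occupancy outside [0, 1]")
  atoms$res_seq <- as.integer(atoms$res_seq)
  if (is.null(h_attach)) h_attach <- rep(NA_integer_, n)
  stopifnot(length(h_attach) == n)
  mapped <- which(!is.na(h_attach))
  if (length(mapped)) {
    if (any(atoms$element[mapped] != "H"))
      stop("h_attach maps a non-hydrogen atom")
    if (any(atoms$element[h_attach[mapped]] == "H"))
      stop("h_attach maps a hydrogen onto another hydrogen")
  }
  structure(list(atoms = atoms[, need], h_attach = as.integer(h_attach)),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("topology: %d atoms, %d residues, chains %s\n",
              nrow(a), length(unique(residue_uid(x))),
              paste(unique(a$chain_id), collapse = "")))
  invisible(x)
}

n_atoms <- function(top) nrow(top$atoms)

#' Residue identifiers for every atom
#'
#' @param top a [topology()]
#' @return character vector, one `chain:res_seq:icode` key per atom
#' @export
residue_uid <- function(top) {
  a <- top$atoms
  paste(a$chain_id, a$res_seq, a$icode, sep = ":")
}

# element from PDB atom name when the element column is blank; PDB naming
# rules: digits may precede H names ("1HB"), first letter otherwise
derive_element <- function(name, res_name) {
  nm <- toupper(trimws(name))
  stripped <- sub("^[0-9]+", "", nm)
  el <- substr(stripped, 1, 1)
  el[substr(stripped, 1, 1) %in% c("H", "D")] <- "H"
  ions <- c("NA", "CL", "MG", "ZN", "FE", "MN", "BR", "CA")
  ion <- nm %in% ions & !(res_name %in% names(.aa3)) & nm == res_name
  el[ion] <- paste0(substr(nm[ion], 1, 1), tolower(substr(nm[ion], 2, 2)))
  el
}

.aa3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V")

.water_names <- c("HOH", "WAT", "TIP3", "TIP", "SOL", "H2O", "DOD")
.ion_names <- c("NA", "CL", "K", "MG", "ZN", "CA", "MN", "FE", "CU", "BR", "IOD")

# ---- trajectory --------------------------------------------------------

#' Bind a coordinate array to a topology
#'
#' @param top a [topology()]
#' @param coords numeric array `F x N x 3` (frames x atoms x xyz, Angstrom);
#'   an `N x 3` matrix is promoted to a single frame
#' @param frame_times optional numeric vector of frame times (ns)
#' @return object of class `trajectory`
#' @export
trajectory <- function(top, coords, frame_times = NULL) {
  stopifnot(inherits(top, "topology"))
  if (is.matrix(coords)) coords <- array(coords, c(1L, dim(coords)))
  d <- dim(coords)
  if (length(d) != 3L || d[3] != 3L)
    stop("coords must be an F x N x 3 array")
  if (d[2] != n_atoms(top))
    stop(sprintf("coords have %d atoms but topology has %d", d[2], n_atoms(top)))
  if (d[1] < 1L) stop("trajectory needs at least one frame")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (!is.null(frame_times)) stopifnot(length(frame_times) == d[1])
  structure(list(topology = top, coords = coords, frame_times = frame_times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("trajectory: %d frame(s) x %d atoms\n", d[1], d[2]))
  print(x$topology)
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()]
#' @return integer frame count
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame as an N x 3 matrix
#' @param traj a [trajectory()]
#' @param i frame index (1-based)
#' @return numeric `N x 3` matrix
#' @export
frame_coords <- function(traj, i = 1L) {
  f <- n_frames(traj)
  if (i < 1L || i > f) stop(sprintf("frame index %d out of range 1..%d", i, f))
  matrix(traj$coords[i, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

# ---- PDB parsing -------------------------------------------------------

pdb_field <- function(lines, from, to) substr(lines, from, to)

parse_atom_lines <- function(lines, lineno) {
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(trimws(pdb_field(lines, from, to))))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("malformed ATOM record at line %d: bad %s field",
                   lineno[bad[1]], what), call. = FALSE)
    v
  }
  occ <- suppressWarnings(as.numeric(trimws(pdb_field(lines, 55, 60))))
  occ[is.na(occ)] <- 1
  bf <- suppressWarnings(as.numeric(trimws(pdb_field(lines, 61, 66))))
  bf[is.na(bf)] <- 0
  data.frame(
    record = trimws(pdb_field(lines, 1, 6)),
    serial = as.integer(num(7, 11, "serial")),
    name = trimws(pdb_field(lines, 13, 16)),
    altloc = pdb_field(lines, 17, 17),
    res_name = trimws(pdb_field(lines, 18, 20)),
    chain_id = pdb_field(lines, 22, 22),
    res_seq = as.integer(num(23, 26, "resSeq")),
    icode = trimws(pdb_field(lines, 27, 27)),
    x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
    occupancy = occ, b_factor = bf,
    element = trimws(pdb_field(lines, 77, 78)),
    stringsAsFactors = FALSE
  )
}

# split raw PDB lines into models; a file without MODEL cards is one model
split_models <- function(lines) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (!length(model_starts)) {
    return(list(list(idx = which(is_atom))))
  }
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) < length(model_starts))
    model_ends <- c(model_ends, length(lines))
  lapply(seq_along(model_starts), function(m) {
    rng <- seq(model_starts[m], model_ends[m])
    list(idx = rng[is_atom[rng]])
  })
}

# altloc policy: highest occupancy wins; ties go to the lexicographically
# first altloc (blank, then 'A'), matching single-conformer MD conventions
resolve_altloc <- function(at) {
  if (all(at$altloc == " " | at$altloc == "")) return(at)
  key <- paste(at$chain_id, at$res_seq, at$icode, at$name, sep = ":")
  ord <- order(key, -at$occupancy, at$altloc)
  keep <- !duplicated(key[ord])
  at[sort(seq_len(nrow(at))[ord][keep]), , drop = FALSE]
}

drop_solvent <- function(at) {
  solv <- at$res_name %in% .water_names |
    (at$record == "HETATM" & at$res_name %in% .ion_names)
  at[!solv, , drop = FALSE]
}

#' Read a PDB structure as a single-frame trajectory
#'
#' Parses fixed-width ATOM/HETATM records. Alternate locations are reduced
#' to the highest-occupancy conformer (ties broken toward altloc `A`).
#' Waters and monoatomic HETATM ions are dropped by default: the analyses
#' in this package concern direct protein-protein interactions, so solvent
#' never enters a selection unless explicitly requested.
#'
#' @param path PDB file
#' @param model_index which MODEL to read (default 1, the first)
#' @param protein_only drop waters/ions (default `TRUE`); with `TRUE` an
#'   input containing no non-solvent atoms is an error
#' @return a single-frame [trajectory()]
#' @export
read_structure <- function(path, model_index = 1L, protein_only = TRUE) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path, warn = FALSE)
  models <- split_models(lines)
  if (model_index < 1L || model_index > length(models))
    stop(sprintf("model_index %d out of range: file has %d model(s)",
                 model_index, length(models)))
  idx <- models[[model_index]]$idx
  if (!length(idx)) stop("no ATOM/HETATM records in selected model")
  at <- parse_atom_lines(lines[idx], idx)
  at <- resolve_altloc(at)
  if (protein_only) {
    at <- drop_solvent(at)
    if (!nrow(at)) stop("no protein atoms after removing waters/ions")
  }
  xyz <- as.matrix(at[, c("x", "y", "z")])
  top <- topology(at[, c("serial", "name", "element", "res_name", "res_seq",
                         "chain_id", "icode", "occupancy", "b_factor")])
  trajectory(top, xyz)
}

#' Read a multi-frame trajectory from PDB files
#'
#' The topology comes from `structure_path`; coordinates come from every
#' MODEL of `frames_path` (or of `structure_path` itself when `frames_path`
#' is missing). Every frame must carry exactly the structure's atom count,
#' in the same order.
#'
#' @param structure_path PDB file defining the topology
#' @param frames_path optional multi-MODEL PDB with the frames
#' @param protein_only passed to the structure parse (see [read_structure()])
#' @return an F-frame [trajectory()], frame order preserved
#' @export
read_trajectory <- function(structure_path, frames_path = NULL,
                            protein_only = TRUE) {
  ref <- read_structure(structure_path, 1L, protein_only = protein_only)
  n <- n_atoms(ref$topology)
  fpath <- if (is.null(frames_path)) structure_path else frames_path
  lines <- readLines(fpath, warn = FALSE)
  models <- split_models(lines)
  coords <- array(NA_real_, c(length(models), n, 3L))
  for (k in seq_along(models)) {
    idx <- models[[k]]$idx
    at <- parse_atom_lines(lines[idx], idx)
    at <- resolve_altloc(at)
    if (protein_only) at <- drop_solvent(at)
    if (nrow(at) != n)
      stop(sprintf("frame %d has %d atoms; structure has %d", k, nrow(at), n))
    coords[k, , ] <- as.matrix(at[, c("x", "y", "z")])
  }
  trajectory(ref$topology, coords)
}

# ---- PDB writing -------------------------------------------------------

format_atom_name <- function(name, element) {
  # one-letter elements start in column 14 unless the name is 4 chars wide
  ifelse(nchar(name) >= 4L, substr(name, 1, 4),
         ifelse(nchar(element) == 1L,
                formatC(paste0(" ", name), width = -4L),
                formatC(name, width = -4L)))
}

#' Write a trajectory as a (multi-MODEL) PDB file
#'
#' Coordinates are written at the format's `%8.3f` precision, so a
#' write/read round trip reproduces them within 5e-4 Angstrom.
#'
#' @param traj a [trajectory()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_pdb <- function(traj, path) {
  top <- traj$topology
  a <- top$atoms
  nf <- n_frames(traj)
  # TER after each chain keeps viewers from bonding across chains
  chain_last <- c(a$chain_id[-1] != a$chain_id[-nrow(a)], TRUE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    if (nf > 1L) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(traj, f)
    rec <- sprintf(
      "ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$serial %% 100000L, format_atom_name(a$name, a$element), " ",
      substr(a$res_name, 1, 3), a$chain_id, a$res_seq %% 10000L,
      substr(paste0(a$icode, " "), 1, 1),
      xyz[, 1], xyz[, 2], xyz[, 3], a$occupancy, a$b_factor,
      formatC(a$element, width = 2)
    )
    out <- character(0)
    prev <- 1L
    for (i in which(chain_last)) {
      out <- c(out, rec[prev:i], "TER")
      prev <- i + 1L
    }
    writeLines(out, con)
    if (nf > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- selections --------------------------------------------------------

#' Atom selection expression
#'
#' A selection is a conjunction of optional predicates: chain membership,
#' author residue-number set, atom-name set and element set. Against a
#' topology it resolves to a deterministic, topology-ordered index list;
#' an empty result is a legal value, not an error.
#'
#' @param chain character vector of chain IDs, or `NULL` for any
#' @param res integer vector of author residue numbers (e.g. `1:180`), or
#'   `NULL` for any
#' @param name atom-name set (e.g. `"CA"`), or `NULL`
#' @param element element set (e.g. `c("N","O","S")`), or `NULL`
#' @return object of class `selection`
#' @export
selection <- function(chain = NULL, res = NULL, name = NULL, element = NULL) {
  if (!is.null(res)) res <- as.integer(res)
  structure(list(chain = chain, res = res, name = name, element = element),
            class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat("selection:", selection_label(x), "\n")
  invisible(x)
}

selection_label <- function(sel) {
  p <- character(0)
  if (!is.null(sel$chain)) p <- c(p, paste0("chain ", paste(sel$chain, collapse = "")))
  if (!is.null(sel$res)) p <- c(p, sprintf("res %d-%d", min(sel$res), max(sel$res)))
  if (!is.null(sel$name)) p <- c(p, paste0("name ", paste(sel$name, collapse = ",")))
  if (!is.null(sel$element)) p <- c(p, paste0("element ", paste(sel$element, collapse = ",")))
  if (!length(p)) "all atoms" else paste(p, collapse = ", ")
}

#' Resolve a selection against a topology
#'
#' Pure function of `(top, sel)`: repeated calls return the identical,
#' topology-ordered, de-duplicated index vector. A chain ID absent from
#' the topology yields an empty result with a warning, never an error.
#'
#' @param top a [topology()]
#' @param sel a [selection()], or an integer vector passed through as-is
#' @return integer vector of atom indices (possibly empty)
#' @export
select_atoms <- function(top, sel) {
  if (is.numeric(sel)) return(as.integer(sel))
  stopifnot(inherits(sel, "selection"))
  a <- top$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$chain)) {
    unknown <- setdiff(sel$chain, unique(a$chain_id))
    if (length(unknown))
      warning("chain(s) not in topology: ", paste(unknown, collapse = ", "))
    keep <- keep & a$chain_id %in% sel$chain
  }
  if (!is.null(sel$res)) keep <- keep & a$res_seq %in% sel$res
  if (!is.null(sel$name)) keep <- keep & a$name %in% sel$name
  if (!is.null(sel$element)) keep <- keep & a$element %in% sel$element
  which(keep)
}

#' Union of selections resolved against one topology
#'
#' @param top a [topology()]
#' @param ... selections (or index vectors)
#' @return de-duplicated, topology-ordered index vector
#' @export
select_union <- function(top, ...) {
  idx <- unlist(lapply(list(...), function(s) select_atoms(top, s)))
  sort(unique(idx))
}

# ---- hydrogen attachment ----------------------------------------------

#' Map each hydrogen to its covalently bonded heavy atom
#'
#' Every hydrogen is assigned to the nearest heavy atom, provided that
#' atom lies within the covalent cutoff; hydrogens with no heavy atom in
#' range stay unmapped (with a warning). Partial maps are legal: the
#' hydrogen-bond scan simply skips unmapped hydrogens.
#'
#' @param top a [topology()]
#' @param frame `N x 3` coordinate matrix used to measure distances
#' @param cutoff covalent distance cutoff in Angstrom (default 1.2)
#' @return integer vector as in [topology()]'s `h_attach`
#' @export
infer_h_attachment <- function(top, frame, cutoff = 1.2) {
  stopifnot(is.matrix(frame), nrow(frame) == n_atoms(top))
  el <- top$atoms$element
  hy <- which(el == "H")
  heavy <- which(el != "H")
  out <- rep(NA_integer_, n_atoms(top))
  if (!length(hy) || !length(heavy)) return(out)
  unmapped <- 0L
  for (h in hy) {
    d2 <- (frame[heavy, 1] - frame[h, 1])^2 +
      (frame[heavy, 2] - frame[h, 2])^2 +
      (frame[heavy, 3] - frame[h, 3])^2
    j <- which.min(d2)
    if (d2[j] <= cutoff^2) out[h] <- heavy[j] else unmapped <- unmapped + 1L
  }
  if (unmapped > 0L)
    warning(sprintf("%d hydrogen(s) have no heavy atom within %.2f A",
                    unmapped, cutoff))
  out
}

#' Populate a trajectory's hydrogen attachment map from its first frame
#' @param traj a [trajectory()]
#' @param cutoff covalent cutoff, Angstrom
#' @return the trajectory with `topology$h_attach` filled in
#' @export
with_h_attachment <- function(traj, cutoff = 1.2) {
  traj$topology$h_attach <- infer_h_attachment(traj$topology,
                                               frame_coords(traj, 1L), cutoff)
  traj
}

# ---- chain-role defaults ----------------------------------------------

#' Default chain-role maps for the reference crystal structures
#'
#' Roles are `mhc_heavy`, `b2m`, `peptide` and, for the ternary complex,
#' `tcr_alpha`/`tcr_beta`. For the unliganded pMHC structures (1ZHK,
#' 1ZHL) the conventional A/B/C layout is assumed. For the ternary
#' complex (2AK4) the two crystallographically distinct complexes occupy
#' chains K-P (complex A) and A-E (complex B); the per-chain role
#' assignment within those ranges follows deposition convention and is
#' NOT verified against the deposited file - always override after
#' inspecting your copy of the structure.
#'
#' @param accession one of `"1ZHK"`, `"1ZHL"`, `"2AK4"`
#' @return named list of role -> chain ID (for 2AK4, a list with elements
#'   `complex_a` and `complex_b`)
#' @export
default_chain_roles <- function(accession) {
  acc <- toupper(accession)
  if (acc %in% c("1ZHK", "1ZHL"))
    return(list(mhc_heavy = "A", b2m = "B", peptide = "C"))
  if (acc == "2AK4")
    return(list(
      complex_a = list(mhc_heavy = "K", b2m = "L", peptide = "M",
                       tcr_alpha = "N", tcr_beta = "O"),
      complex_b = list(mhc_heavy = "A", b2m = "B", peptide = "C",
                       tcr_alpha = "D", tcr_beta = "E")
    ))
  stop("no default chain roles for accession ", accession)
}
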