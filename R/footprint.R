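# Dynamic interface footprint: persistence bookkeeping per hydrogen bond,
# classification against the crystal structure, and cross-complex
# conservation comparison.
#
# Novel interactions (not seen in the crystal) are split at 50% persistence
# into short-lived (< 50%) and long-lived (> 50%); exactly 50% is classified
# long-lived (the published convention leaves the boundary unassigned, and
# inclusive-upper keeps classification monotone in persistence).

#' Persistence of a hydrogen-bond series
#'
#' @param series one element of an [hbond_series()] result, or a logical
#'   vector of per-frame formed flags
#' @return percent of frames formed, in `[0, 100]` (full precision; reports
#'   round to integer percent)
#' @export
persistence <- function(series) {
  formed <- if (is.logical(series)) series else series$formed
  if (!length(formed)) stop("persistence of an empty series")
  100 * mean(formed)
}

#' Classify an interface interaction against the crystal structure
#'
#' @param in_crystal was the bond present in the crystal structure?
#' @param persistences numeric vector of per-complex persistence percents;
#'   `NA` marks "not observed in that simulation". At least one complex
#'   column must be supplied.
#' @param threshold novel short/long-lived split, percent (default 50;
#'   exactly `threshold` classifies long-lived)
#' @return one of `"crystal_and_md"`, `"novel_long_lived"`,
#'   `"novel_short_lived"`, `"crystal_only"`
#' @export
classify <- function(in_crystal, persistences, threshold = 50) {
  if (!length(persistences)) stop("no complex persistence columns supplied")
  seen <- any(!is.na(persistences) & persistences > 0)
  if (in_crystal) {
    if (seen) "crystal_and_md" else "crystal_only"
  } else {
    if (!seen) stop("record neither in crystal nor observed in simulation")
    if (max(persistences, na.rm = TRUE) >= threshold) "novel_long_lived"
    else "novel_short_lived"
  }
}

# assign an MHC-side record to the Table-1-style group; the alpha1 domain
# spans roughly residues 1-90 of the heavy chain, alpha2 91-180
mhc_group <- function(chain_id, res_seq, roles,
                      alpha1_range = 1:90, alpha2_range = 91:180) {
  if (!is.null(roles$peptide) && chain_id %in% roles$peptide) return("peptide")
  if (res_seq %in% alpha1_range) return("alpha1")
  if (res_seq %in% alpha2_range) return("alpha2")
  "other"
}

#' Build a dynamic-footprint table
#'
#' Takes one [hbond_series()] list per simulated complex plus (optionally)
#' the bond set detected in the crystal reference, and produces one record
#' per unique (pMHC-side, TCR-side) interaction after equivalent-atom
#' merging: crystal-presence flag, per-complex persistence (NA = not
#' observed, printed as an empty cell), and a class label. Records are
#' grouped alpha1-helix / alpha2-helix / peptide and ordered by MHC residue
#' number within each group.
#'
#' @param complex_series named list, complex label -> [hbond_series()] list
#'   (the pMHC side must be group A, i.e. the series donor OR acceptor on
#'   the pMHC side is identified via `roles`)
#' @param crystal_bonds character vector of crystal bond keys (labels as
#'   produced by the series, e.g. from a distance-only [hbond_series()] on
#'   the crystal: use [series_keys()]), or `NULL` for none
#' @param roles chain-role map; `roles$peptide` and `roles$mhc_heavy` name
#'   the pMHC-side chains, everything else is TCR-side
#' @param threshold classification split, percent
#' @return data.frame of class `footprint_table`: columns `group`, `mhc`,
#'   `tcr`, `in_crystal`, one `persistence_<label>` column per complex,
#'   `class`
#' @export
build_footprint <- function(complex_series, crystal_bonds = NULL, roles,
                            threshold = 50) {
  stopifnot(is.list(complex_series), length(complex_series) >= 1,
            !is.null(names(complex_series)))
  pmhc_chains <- unlist(roles[c("mhc_heavy", "peptide")], use.names = FALSE)
  orient <- function(s) {
    # put the pMHC side first regardless of donor/acceptor direction
    if (s$donor$chain_id %in% pmhc_chains) list(mhc = s$donor, tcr = s$acceptor)
    else if (s$acceptor$chain_id %in% pmhc_chains) list(mhc = s$acceptor, tcr = s$donor)
    else stop("series ", s$label, " touches no pMHC-side chain")
  }
  side_label <- function(ref) sprintf("%s%d %s", ref$res_name, ref$res_seq, ref$name)
  recs <- new.env(parent = emptyenv())
  note <- function(key, field, value, mhc_ref = NULL, tcr_ref = NULL) {
    r <- if (!is.null(recs[[key]])) recs[[key]] else
      list(mhc = mhc_ref, tcr = tcr_ref, in_crystal = FALSE,
           persistence = stats::setNames(rep(NA_real_, length(complex_series)),
                                         names(complex_series)))
    if (field == "crystal") r$in_crystal <- TRUE else r$persistence[[field]] <- value
    recs[[key]] <- r
  }
  for (lab in names(complex_series)) {
    for (s in complex_series[[lab]]) {
      o <- orient(s)
      key <- paste(atom_ref_label(o$mhc), atom_ref_label(o$tcr), sep = " -- ")
      if (!is.null(recs[[key]]) && !is.na(recs[[key]]$persistence[[lab]]))
        stop("duplicate footprint key after merging: ", key,
             " (equivalent-atom merging misconfigured?)")
      note(key, lab, persistence(s), o$mhc, o$tcr)
    }
  }
  for (cb in crystal_bonds) {
    if (is.null(recs[[cb]])) {
      # never seen in simulation: a crystal-only record
      refs <- parse_bond_key(cb)
      note(cb, "crystal", TRUE, refs$mhc, refs$tcr)
    } else note(cb, "crystal", TRUE)
  }
  keys <- ls(recs)
  if (!length(keys)) stop("no interactions to tabulate")
  rows <- lapply(keys, function(k) {
    r <- recs[[k]]
    grp <- mhc_group(r$mhc$chain_id, r$mhc$res_seq, roles)
    out <- data.frame(group = grp, mhc = side_label(r$mhc),
                      tcr = side_label(r$tcr), in_crystal = r$in_crystal)
    for (lab in names(complex_series))
      out[[paste0("persistence_", lab)]] <- r$persistence[[lab]]
    out$class <- classify(r$in_crystal, r$persistence, threshold)
    out$.res <- r$mhc$res_seq
    out
  })
  df <- do.call(rbind, rows)
  grp_order <- c(alpha1 = 1L, alpha2 = 2L, peptide = 3L, other = 4L)
  df <- df[order(grp_order[df$group], df$.res, df$mhc, df$tcr), ]
  df$.res <- NULL
  rownames(df) <- NULL
  attr(df, "threshold") <- threshold
  class(df) <- c("footprint_table", "data.frame")
  df
}

parse_bond_key <- function(key) {
  sides <- strsplit(key, " -- ", fixed = TRUE)[[1]]
  parse_side <- function(s) {
    p <- strsplit(s, ":", fixed = TRUE)[[1]]
    m <- regmatches(p[2], regexec("^([A-Za-z]{3})([0-9]+)$", p[2]))[[1]]
    list(chain_id = p[1], res_name = m[2], res_seq = as.integer(m[3]),
         name = p[3])
  }
  list(mhc = parse_side(sides[1]), tcr = parse_side(sides[2]))
}

#' Bond keys of a hydrogen-bond series list
#'
#' Orientation-normalised keys (pMHC side first) suitable as the
#' `crystal_bonds` argument of [build_footprint()].
#'
#' @param series an [hbond_series()] result
#' @param roles chain-role map as in [build_footprint()]
#' @return character vector of keys
#' @export
series_keys <- function(series, roles) {
  pmhc_chains <- unlist(roles[c("mhc_heavy", "peptide")], use.names = FALSE)
  vapply(series, function(s) {
    if (s$donor$chain_id %in% pmhc_chains)
      paste(atom_ref_label(s$donor), atom_ref_label(s$acceptor), sep = " -- ")
    else
      paste(atom_ref_label(s$acceptor), atom_ref_label(s$donor), sep = " -- ")
  }, "")
}

# ---- serialisation -----------------------------------------------------

persistence_columns <- function(tbl) {
  grep("^persistence_", names(tbl), value = TRUE)
}

#' Write a footprint table as CSV
#'
#' Persistence is printed as integer percent; an unobserved interaction is
#' an empty cell. The layout (and the `Yes`/`No` crystal column) mirrors
#' the packaged reference fixture, so a fixture read back through
#' [read_footprint_csv()] re-exports byte-identically.
#'
#' @param tbl a `footprint_table`
#' @param path output CSV
#' @param class_column include the computed class column (default FALSE:
#'   the reference table carries no class column; classes are recomputed
#'   on read)
#' @return `path`, invisibly
#' @export
write_footprint_csv <- function(tbl, path, class_column = FALSE) {
  pc <- persistence_columns(tbl)
  hdr <- c("group", "mhc", "tcr", "in_crystal", pc, if (class_column) "class")
  fmt_p <- function(v) ifelse(is.na(v), "", sprintf("%d", as.integer(round(v))))
  cols <- c(list(tbl$group, tbl$mhc, tbl$tcr,
                 ifelse(tbl$in_crystal, "Yes", "No")),
            lapply(pc, function(p) fmt_p(tbl[[p]])),
            if (class_column) list(tbl$class))
  lines <- do.call(paste, c(cols, sep = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(hdr, collapse = ","), lines), con, useBytes = TRUE)
  invisible(path)
}

#' Read a footprint CSV (including the packaged reference fixture)
#'
#' @param path CSV as written by [write_footprint_csv()]
#' @param threshold classification split used to recompute the class column
#' @return a `footprint_table`
#' @export
read_footprint_csv <- function(path, threshold = 50) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  cells <- strsplit(lines, ",", fixed = TRUE)
  hdr <- cells[[1]]
  need <- c("group", "mhc", "tcr", "in_crystal")
  if (!all(need %in% hdr)) stop("not a footprint CSV: missing ",
                                paste(setdiff(need, hdr), collapse = ", "))
  pc <- grep("^persistence_", hdr, value = TRUE)
  body <- cells[-1]
  get <- function(row, col) {
    i <- match(col, hdr)
    if (i > length(row)) "" else row[i]
  }
  df <- do.call(rbind, lapply(body, function(r) {
    out <- data.frame(group = get(r, "group"), mhc = get(r, "mhc"),
                      tcr = get(r, "tcr"),
                      in_crystal = identical(get(r, "in_crystal"), "Yes"))
    for (p in pc) {
      v <- get(r, p)
      out[[p]] <- if (nzchar(v)) as.numeric(v) else NA_real_
    }
    out
  }))
  df$class <- vapply(seq_len(nrow(df)), function(i)
    classify(df$in_crystal[i], as.numeric(df[i, pc]), threshold), "")
  attr(df, "threshold") <- threshold
  class(df) <- c("footprint_table", "data.frame")
  df
}

#' Path of the packaged reference footprint fixture
#'
#' A verbatim transcription of the published bond-persistence table for
#' the two simulated TCR-pMHC complexes (31 interactions; `(-)` cells of
#' the original are empty cells here). Known internal inconsistencies of
#' the source table are documented in `table1_notes.md` alongside the
#' fixture and are deliberately NOT corrected.
#'
#' @return file path within the installed package
#' @export
table1_fixture_path <- function() {
  system.file("extdata", "table1_footprint.csv", package = "tcrdyn",
              mustWork = TRUE)
}

#' Footprint table as JSON
#' @param tbl a `footprint_table`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_footprint_json <- function(tbl, path) {
  jsonlite::write_json(as.data.frame(tbl), path, auto_unbox = TRUE,
                       na = "null", digits = NA, pretty = TRUE)
  invisible(path)
}

# ---- conservation ------------------------------------------------------

#' Residue-level footprint conservation between two complexes
#'
#' For every pMHC residue appearing in the footprint, reports whether it is
#' contacted in both complexes, only in the first, or only in the second,
#' with the per-complex class of its strongest interaction. Inconsistencies
#' with any externally stated exception list are for the caller to
#' reconcile; nothing is resolved silently.
#'
#' @param a a `footprint_table` (if `b` is `NULL`, `a` must carry at least
#'   two persistence columns and the first two are compared)
#' @param b optional second `footprint_table` with a single persistence
#'   column each
#' @return data.frame `residue`, `group`, `in_a`, `in_b`, `status`
#'   (`conserved` / `a_only` / `b_only` / `crystal_only`)
#' @export
compare_footprints <- function(a, b = NULL) {
  if (is.null(b)) {
    pc <- persistence_columns(a)
    if (length(pc) < 2)
      stop("single-table comparison needs two persistence columns")
    tab <- a; col_a <- pc[1]; col_b <- pc[2]
  } else {
    pa <- persistence_columns(a); pb <- persistence_columns(b)
    stopifnot(length(pa) == 1, length(pb) == 1)
    tab <- merge(a[, c("group", "mhc", "tcr", "in_crystal", pa)],
                 b[, c("mhc", "tcr", pb)], by = c("mhc", "tcr"), all = TRUE)
    col_a <- pa; col_b <- pb
  }
  res <- sub("^([A-Za-z]{3}[0-9]+).*$", "\\1", tab$mhc)
  split_idx <- split(seq_len(nrow(tab)), res)
  rows <- lapply(names(split_idx), function(rr) {
    i <- split_idx[[rr]]
    in_a <- any(!is.na(tab[[col_a]][i]) & tab[[col_a]][i] > 0)
    in_b <- any(!is.na(tab[[col_b]][i]) & tab[[col_b]][i] > 0)
    status <- if (in_a && in_b) "conserved"
      else if (in_a) "a_only"
      else if (in_b) "b_only"
      else "crystal_only"
    data.frame(residue = rr, group = tab$group[i[1]], in_a = in_a,
               in_b = in_b, status = status)
  })
  out <- do.call(rbind, rows)
  ord <- order(match(out$group, c("alpha1", "alpha2", "peptide", "other")),
               as.integer(sub("^[A-Za-z]{3}", "", out$residue)))
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}
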