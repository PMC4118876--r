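#' Read a (multi-model) PDB file as a trajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; a file without `MODEL`
#' records yields a single-frame trajectory. `ATOM` and `HETATM` coordinate
#' records are parsed; `HETATM` records for standard residues are kept while
#' waters and monatomic ions are dropped by default, because the analysis
#' concerns protein geometry only. When several alternate-location conformers
#' are present the highest-occupancy one is kept (ties broken by altloc
#' letter order) so downstream geometry is single-conformer and
#' deterministic. Files using insertion codes are rejected: all residue
#' numbering here is plain integer (mature-protein numbering for the hPDI
#' defaults).
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier to keep. Default `NULL` keeps the first
#'   protein chain encountered (crystal structures may contain several
#'   copies of the molecule).
#' @param keep_waters Keep water/ion records instead of dropping them.
#' @return A trajectory tibble (see [new_trajectory()]), one frame per model.
#' @export
read_pdb_ensemble <- function(path, chain = NULL, keep_waters = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  prescan_pdb(path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) abort(sprintf("failed to parse PDB '%s': %s",
                                      path, conditionMessage(e)),
                              class = "interdom_parse_error"))
  at <- as_tibble(pdb$atom)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  keep <- rep(TRUE, nrow(at))
  if (!keep_waters) {
    solvent <- c("HOH", "WAT", "TIP", "TIP3", "SOL", "SPC")
    ions <- c("NA", "CL", "K", "MG", "ZN", "MN", "FE", "SOD", "CLA", "POT",
              "CAL", "CES")
    keep <- keep & !(at$resid %in% c(solvent, ions))
  }
  if (is.null(chain)) {
    chains <- unique(at$chain[keep])
    chain <- chains[1]
  }
  keep <- keep & at$chain %in% chain
  if (!any(keep)) abort(sprintf("no atoms left after chain selection '%s'",
                                chain), class = "interdom_selection_error")
  # altloc: highest occupancy wins, ties by altloc letter order
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$elety, at$resno, at$chain, sep = "|")
  ord <- order(key, -occ, alt)
  dup <- duplicated(key[ord])
  drop_idx <- ord[dup]
  keep[drop_idx] <- FALSE
  idx <- which(keep)
  at <- at[idx, ]
  cols <- bio3d::atom2xyz(idx)
  frames <- lapply(seq_len(nrow(xyz)), function(i) {
    m <- matrix(xyz[i, cols], ncol = 3, byrow = TRUE)
    new_frame(tibble(
      serial = as.integer(at$eleno),
      atom_name = at$elety,
      residue_name = at$resid,
      residue_number = as.integer(at$resno),
      chain_id = at$chain,
      x = m[, 1], y = m[, 2], z = m[, 3],
      element = ifelse(is.na(at$elesy) | at$elesy == "",
                       substr(gsub("[0-9']", "", at$elety), 1, 1), at$elesy),
      occupancy = ifelse(is.na(at$o), 1, at$o)))
  })
  new_trajectory(frames)
}

# text pre-scan producing the diagnostics bio3d does not report:
# malformed coordinate fields (with line number), insertion codes, and
# per-model roster consistency (first mismatching atom).
prescan_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_coord <- rec %in% c("ATOM  ", "HETATM")
  for (i in which(is_coord)) {
    ln <- lines[i]
    for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(ln, fld[1], fld[2])))
      if (is.na(v)) {
        abort(sprintf("malformed coordinate field on line %d of '%s'",
                      i, path), class = "interdom_parse_error")
      }
    }
    if (grepl("[A-Za-z]", substr(ln, 27, 27))) {
      abort(sprintf(
        "insertion code '%s' on line %d: renumber to plain integers first",
        substr(ln, 27, 27), i), class = "interdom_parse_error")
    }
  }
  model_id <- cumsum(rec == "MODEL ")
  if (max(model_id) > 1) {
    keys <- paste(substr(lines, 13, 16), substr(lines, 23, 26),
                  substr(lines, 22, 22))
    rosters <- split(keys[is_coord], model_id[is_coord])
    ref <- rosters[[1]]
    for (m in seq_along(rosters)[-1]) {
      k <- rosters[[m]]
      if (length(k) != length(ref) || any(k != ref)) {
        j <- which(c(k, "") != c(ref, ""))[1]
        abort(sprintf(
          "atom roster differs between models 1 and %d at atom %d ('%s' vs '%s')",
          m, j, trimws(k[j]), trimws(ref[j])),
          class = "interdom_roster_error")
      }
    }
  }
  invisible(TRUE)
}

#' Read a CHARMM/NAMD DCD trajectory with a PDB topology
#'
#' The topology PDB supplies the atom roster (names, residues, chains); the
#' DCD supplies per-frame coordinates in file order. Little- and big-endian
#' files are autodetected.
#'
#' @param topology_path PDB file whose atom count matches the DCD.
#' @param dcd_path Binary DCD file.
#' @return A trajectory tibble.
#' @export
read_dcd_trajectory <- function(topology_path, dcd_path) {
  top <- read_pdb_ensemble(topology_path)
  top0 <- get_frame(top, 0)
  hdr <- dcd_header_info(dcd_path)
  if (hdr$natom != nrow(top0)) {
    abort(sprintf(
      "topology mismatch: topology has %d atoms but DCD has %d",
      nrow(top0), hdr$natom), class = "interdom_topology_error")
  }
  if (hdr$nframes_present == 0) {
    abort(sprintf("DCD '%s' contains no frames", dcd_path),
          class = "interdom_format_error")
  }
  if (hdr$truncated) {
    abort(sprintf(
      "truncated DCD '%s': header declares %d frames but data ends after frame %d",
      dcd_path, hdr$nframes_declared, hdr$nframes_present),
      class = "interdom_format_error")
  }
  xyz <- tryCatch(
    bio3d::read.dcd(dcd_path, verbose = FALSE),
    error = function(e) abort(sprintf("failed to read DCD '%s': %s",
                                      dcd_path, conditionMessage(e)),
                              class = "interdom_format_error"))
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  frames <- lapply(seq_len(nrow(xyz)), function(i) {
    m <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    fr <- top0
    fr$x <- m[, 1]; fr$y <- m[, 2]; fr$z <- m[, 3]
    fr
  })
  new_trajectory(frames)
}

# integrity check on the DCD container: endianness, atom count, how many
# complete frames the file actually holds
dcd_header_info <- function(path) {
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  m <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (!identical(m, 84L)) {
    endian <- "big"
    seek(con, 0)
    m <- readBin(con, "integer", 1, size = 4, endian = endian)
    if (!identical(m, 84L)) {
      abort(sprintf("'%s' is not a DCD file (bad header marker)", path),
            class = "interdom_format_error")
    }
  }
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "CORD")) {
    abort(sprintf("'%s' is not a coordinate DCD (magic '%s')", path, magic),
          class = "interdom_format_error")
  }
  icntrl <- readBin(con, "integer", 20, size = 4, endian = endian)
  readBin(con, "integer", 1, size = 4, endian = endian)
  tlen <- readBin(con, "integer", 1, size = 4, endian = endian)
  seek(con, tlen + 4, origin = "current")
  readBin(con, "integer", 1, size = 4, endian = endian)
  natom <- readBin(con, "integer", 1, size = 4, endian = endian)
  readBin(con, "integer", 1, size = 4, endian = endian)
  header_bytes <- seek(con, NA)
  cell <- icntrl[11] == 1L
  frame_bytes <- 3 * (8 + 4 * natom) + if (cell) 56 else 0
  nframes_present <- (size - header_bytes) %/% frame_bytes
  list(natom = natom,
       nframes_declared = icntrl[1],
       nframes_present = as.integer(nframes_present),
       truncated = icntrl[1] > nframes_present,
       endian = endian)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Coordinates are written at standard PDB precision (0.001 Angstrom), so a
#' write/read round trip preserves coordinates to 1e-3 and the roster
#' exactly.
#'
#' @param traj A trajectory tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pdb_ensemble <- function(traj, path) {
  frames <- traj_split(traj)
  f0 <- frames[[1]]
  xyz <- do.call(rbind, lapply(frames, function(fr) as.vector(t(coords_matrix(fr)))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = f0$residue_number,
                   resid = f0$residue_name,
                   eleno = f0$serial,
                   elety = f0$atom_name,
                   chain = f0$chain_id,
                   o = f0$occupancy,
                   elesy = f0$element)
  invisible(path)
}

#' Write a trajectory as a CHARMM-format DCD file
#'
#' Single-precision binary trajectory with classic 4-byte Fortran record
#' markers, readable by the usual MD tool chain. Intended for generating
#' test fixtures for [read_dcd_trajectory()].
#'
#' @param traj A trajectory tibble.
#' @param path Output file.
#' @param n_frames_declared Frame count to put in the header; defaults to the
#'   real number of frames (set lower-level values only to build deliberately
#'   inconsistent fixtures).
#' @return `path`, invisibly.
#' @export
write_dcd <- function(traj, path, n_frames_declared = NULL) {
  frames <- traj_split(traj)
  natom <- nrow(frames[[1]])
  nf <- n_frames_declared %||% length(frames)
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
    writer()
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- as.integer(nf); icntrl[2] <- 1L; icntrl[3] <- 1L
  icntrl[4] <- as.integer(nf); icntrl[20] <- 24L
  rec(function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    writeBin(icntrl, con, size = 4, endian = "little")
  }, 84)
  title <- sprintf("%-80s", "interdom synthetic trajectory")
  rec(function() {
    writeBin(1L, con, size = 4, endian = "little")
    writeChar(title, con, nchars = 80, eos = NULL)
  }, 84)
  rec(function() writeBin(as.integer(natom), con, size = 4, endian = "little"), 4)
  for (fr in frames) {
    m <- coords_matrix(fr)
    for (d in 1:3) {
      rec(function() writeBin(as.numeric(m[, d]), con, size = 4,
                              endian = "little"), 4 * natom)
    }
  }
  invisible(path)
}

#' Write per-frame values as a TSV time series
#'
#' One row per frame with a header row; the first column is the 0-based
#' frame index. Values round-trip losslessly well beyond 6 significant
#' digits.
#'
#' @param table A data frame, or a named list of equal-length columns. A
#'   `frame` column, if present, is used as the index column.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(table, path) {
  if (!is.data.frame(table)) {
    lens <- lengths(table)
    if (length(lens) > 0 && length(unique(lens)) != 1) {
      abort(sprintf("ragged columns: lengths %s",
                    paste(lens, collapse = ", ")),
            class = "interdom_shape_error")
    }
    table <- as_tibble(as.list(table))
  }
  table <- as_tibble(table)
  if (!"frame" %in% names(table)) {
    table <- bind_cols(tibble(frame = seq_len(nrow(table)) - 1L), table)
  } else {
    table <- table[, c("frame", setdiff(names(table), "frame"))]
  }
  readr::write_tsv(table, path)
  invisible(path)
}

#' Read a TSV time series written by [write_timeseries()]
#' @param path TSV file.
#' @return A tibble with a `frame` column.
#' @export
read_timeseries <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
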