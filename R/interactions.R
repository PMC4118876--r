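#' Catalogue of charged side-chain atoms
#'
#' The side-chain terminal atoms used for salt-bridge distances:
#' Arg NE/NH1/NH2 and Lys NZ (positive); Asp OD1/OD2 and Glu OE1/OE2
#' (negative). Histidine and chain termini are excluded by default because
#' Arg/Lys vs Asp/Glu pairs are the unit of interest; pass an extended
#' catalogue to the detection functions to widen it. Distances are measured
#' symmetrically between the charged-atom sets, so hydrogen positions are
#' never required.
#'
#' @return A tibble with columns `residue_name`, `atom_name`, `polarity`
#'   (`"pos"`/`"neg"`).
#' @export
charged_atom_catalog <- function() {
  tibble(
    residue_name = c("ARG", "ARG", "ARG", "LYS", "ASP", "ASP", "GLU", "GLU"),
    atom_name = c("NE", "NH1", "NH2", "NZ", "OD1", "OD2", "OE1", "OE2"),
    polarity = c("pos", "pos", "pos", "pos", "neg", "neg", "neg", "neg"))
}

#' Closest distance between two residues' listed atoms
#'
#' Minimum pairwise Euclidean distance between the two atom sets; symmetric
#' in its arguments. With the defaults the atom sets are the charged
#' side-chain atoms from [charged_atom_catalog()].
#'
#' @param frame A frame tibble.
#' @param res_a,res_b Residue numbers.
#' @param atoms_a,atoms_b Atom-name sets; default `NULL` takes the
#'   catalogued charged atoms for the residue's type.
#' @param catalog Charged-atom catalogue used for the defaults.
#' @return Minimum distance in Angstrom.
#' @export
residue_min_distance <- function(frame, res_a, res_b, atoms_a = NULL,
                                 atoms_b = NULL,
                                 catalog = charged_atom_catalog()) {
  fr <- as_frame(frame)
  ma <- residue_atom_coords(fr, res_a, atoms_a, catalog)
  mb <- residue_atom_coords(fr, res_b, atoms_b, catalog)
  min_cross_distance(ma, mb)
}

residue_atom_coords <- function(fr, resno, atom_names, catalog) {
  rows <- fr[fr$residue_number == resno, , drop = FALSE]
  if (nrow(rows) == 0) {
    abort(sprintf("residue %d not present in frame", resno),
          class = "interdom_missing_atom_error")
  }
  if (is.null(atom_names)) {
    atom_names <- catalog$atom_name[catalog$residue_name == rows$residue_name[1]]
  }
  rows <- rows[rows$atom_name %in% atom_names, , drop = FALSE]
  if (nrow(rows) == 0) {
    abort(sprintf("residue %d (%s) has none of the required atoms (%s)",
                  resno, fr$residue_name[fr$residue_number == resno][1],
                  paste(atom_names, collapse = ",")),
          class = "interdom_missing_atom_error")
  }
  coords_matrix(rows)
}

min_cross_distance <- function(ma, mb) {
  d2 <- outer(rowSums(ma^2), rowSums(mb^2), `+`) - 2 * tcrossprod(ma, mb)
  sqrt(max(0, min(d2)))
}

#' Detect salt bridges in one frame
#'
#' Scans all (positive, negative) charged residue pairs and reports those
#' whose closest charged-atom distance is under the threshold. The default
#' criterion is the strict inequality `distance < 3` Angstrom; set
#' `inclusive = TRUE` for `<=`. With `inter_domain_only = TRUE` (default)
#' the two residues must belong to different segmentation units; named
#' linker residues count as their own unit, so a bridge between a domain and
#' an x-linker residue is reportable. Charged residues whose catalogued
#' side-chain atoms are all absent are skipped with a warning.
#'
#' @param frame A frame tibble.
#' @param seg Segmentation tibble (required when `inter_domain_only`).
#' @param threshold Distance cutoff in Angstrom (default 3.0).
#' @param inter_domain_only Keep only pairs spanning two different units.
#' @param inclusive Use `<=` instead of the default strict `<`.
#' @param catalog Charged-atom catalogue.
#' @return A tibble with one row per bridged pair: `res_pos`, `name_pos`,
#'   `unit_pos`, `res_neg`, `name_neg`, `unit_neg`, `min_distance`,
#'   `bridged`.
#' @export
detect_salt_bridges <- function(frame, seg = NULL, threshold = 3.0,
                                inter_domain_only = TRUE, inclusive = FALSE,
                                catalog = charged_atom_catalog()) {
  fr <- as_frame(frame)
  if (inter_domain_only && is.null(seg)) {
    abort("inter_domain_only = TRUE requires a segmentation",
          class = "interdom_config_error")
  }
  cat_res <- unique(catalog$residue_name)
  # one entry per charged residue with its present charged atoms
  res_tab <- distinct(fr[fr$residue_name %in% cat_res,
                         c("residue_number", "residue_name")])
  if (nrow(res_tab) == 0) return(empty_bridge_table())
  res_tab$polarity <- catalog$polarity[match(res_tab$residue_name,
                                             catalog$residue_name)]
  coords <- vector("list", nrow(res_tab))
  have <- logical(nrow(res_tab))
  for (i in seq_len(nrow(res_tab))) {
    atoms <- catalog$atom_name[catalog$residue_name == res_tab$residue_name[i]]
    rows <- fr[fr$residue_number == res_tab$residue_number[i] &
                 fr$atom_name %in% atoms, , drop = FALSE]
    if (nrow(rows) == 0) {
      warn(sprintf("charged residue %s%d has no side-chain atoms; skipped",
                   res_tab$residue_name[i], res_tab$residue_number[i]))
    } else {
      coords[[i]] <- coords_matrix(rows)
      have[i] <- TRUE
    }
  }
  res_tab <- res_tab[have, ]
  coords <- coords[have]
  if (!is.null(seg)) {
    res_tab$unit <- unit_of(res_tab$residue_number, seg)
  } else {
    res_tab$unit <- NA_character_
  }
  ip <- which(res_tab$polarity == "pos")
  im <- which(res_tab$polarity == "neg")
  out <- list()
  for (i in ip) for (j in im) {
    if (inter_domain_only) {
      if (is.na(res_tab$unit[i]) || is.na(res_tab$unit[j]) ||
          res_tab$unit[i] == res_tab$unit[j]) next
    }
    d <- min_cross_distance(coords[[i]], coords[[j]])
    hit <- if (inclusive) d <= threshold else d < threshold
    if (hit) {
      out[[length(out) + 1]] <- tibble(
        res_pos = res_tab$residue_number[i],
        name_pos = res_tab$residue_name[i],
        unit_pos = res_tab$unit[i],
        res_neg = res_tab$residue_number[j],
        name_neg = res_tab$residue_name[j],
        unit_neg = res_tab$unit[j],
        min_distance = d, bridged = TRUE)
    }
  }
  if (length(out) == 0) return(empty_bridge_table())
  arrange(bind_rows(out), .data$res_pos, .data$res_neg)
}

empty_bridge_table <- function() {
  tibble(res_pos = integer(), name_pos = character(), unit_pos = character(),
         res_neg = integer(), name_neg = character(), unit_neg = character(),
         min_distance = numeric(), bridged = logical())
}

#' Trace residue-pair closest distances across a trajectory
#'
#' One closest-distance time course per requested pair, with the bridge
#' criterion applied per frame. Occupancy (fraction of frames bridged) is
#' summarised by [bridge_occupancy()].
#'
#' @param traj A trajectory tibble.
#' @param pairs A data frame with columns `res_pos`, `res_neg` (residue
#'   numbers).
#' @param threshold Bridge cutoff in Angstrom (default 3.0, strict `<`).
#' @param inclusive Use `<=` instead of `<`.
#' @param catalog Charged-atom catalogue.
#' @return A tibble with columns `res_pos`, `res_neg`, `frame`,
#'   `min_distance`, `bridged`.
#' @export
salt_bridge_series <- function(traj, pairs, threshold = 3.0,
                               inclusive = FALSE,
                               catalog = charged_atom_catalog()) {
  pairs <- as_tibble(pairs)
  frames <- traj_split(traj)
  out <- lapply(seq_len(nrow(pairs)), function(k) {
    d <- vapply(frames, function(fr) {
      residue_min_distance(fr, pairs$res_pos[k], pairs$res_neg[k],
                           catalog = catalog)
    }, numeric(1))
    tibble(res_pos = as.integer(pairs$res_pos[k]),
           res_neg = as.integer(pairs$res_neg[k]),
           frame = as.integer(names(frames)),
           min_distance = unname(d),
           bridged = if (inclusive) d <= threshold else d < threshold)
  })
  bind_rows(out)
}

#' Per-pair bridge occupancy
#'
#' @param series Output of [salt_bridge_series()].
#' @return A tibble `res_pos`, `res_neg`, `n_frames`, `occupancy` with
#'   occupancy = bridged frames / total frames, in \[0, 1\].
#' @export
bridge_occupancy <- function(series) {
  series |>
    group_by(.data$res_pos, .data$res_neg) |>
    summarise(n_frames = n(), occupancy = mean(.data$bridged),
              .groups = "drop")
}

ring_atoms <- list(
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"))

cation_atoms <- c(ARG = "CZ", LYS = "NZ")

#' Detect cation-pi contacts in one frame
#'
#' A cation (Arg guanidinium carbon CZ, or Lys NZ) and an aromatic ring
#' (Trp six-membered ring, or the Tyr/Phe ring) are in contact when the
#' cation-to-ring-centroid distance is at most `d_max` and the angle between
#' the ring normal and the centroid-to-cation vector is at most `theta_max`
#' (the cation must sit over the ring face, not in its plane). The 6.0
#' Angstrom / 45 degree defaults are this package's stated criterion; both
#' are tunable.
#'
#' @param frame A frame tibble.
#' @param d_max Maximum centroid distance in Angstrom (default 6.0).
#' @param theta_max Maximum off-normal angle in degrees (default 45).
#' @param cation_residues,ring_residues Residue types to scan.
#' @return A tibble `res_cation`, `name_cation`, `res_ring`, `name_ring`,
#'   `distance`, `angle` of the contacts found.
#' @export
detect_cation_pi <- function(frame, d_max = 6.0, theta_max = 45,
                             cation_residues = c("ARG", "LYS"),
                             ring_residues = c("TRP", "TYR", "PHE")) {
  fr <- as_frame(frame)
  cats <- distinct(fr[fr$residue_name %in% cation_residues,
                      c("residue_number", "residue_name")])
  rings <- distinct(fr[fr$residue_name %in% ring_residues,
                       c("residue_number", "residue_name")])
  out <- list()
  for (i in seq_len(nrow(cats))) {
    catom <- fr[fr$residue_number == cats$residue_number[i] &
                  fr$atom_name == cation_atoms[[cats$residue_name[i]]], ,
                drop = FALSE]
    if (nrow(catom) == 0) next
    cpos <- c(catom$x[1], catom$y[1], catom$z[1])
    for (j in seq_len(nrow(rings))) {
      need <- ring_atoms[[rings$residue_name[j]]]
      ratoms <- fr[fr$residue_number == rings$residue_number[j] &
                     fr$atom_name %in% need, , drop = FALSE]
      if (nrow(ratoms) < length(need)) {
        abort(sprintf("incomplete aromatic ring for %s%d (found %d of %d atoms)",
                      rings$residue_name[j], rings$residue_number[j],
                      nrow(ratoms), length(need)),
              class = "interdom_missing_atom_error")
      }
      m <- coords_matrix(ratoms)
      centroid <- colMeans(m)
      normal <- svd(sweep(m, 2, centroid))$v[, 3]
      v <- cpos - centroid
      d <- sqrt(sum(v^2))
      if (d < 1e-9 || d > d_max) next
      ct <- abs(sum(v * normal)) / d   # normal sign is arbitrary
      ang <- acos(max(-1, min(1, ct))) * 180 / pi
      if (ang <= theta_max) {
        out[[length(out) + 1]] <- tibble(
          res_cation = cats$residue_number[i],
          name_cation = cats$residue_name[i],
          res_ring = rings$residue_number[j],
          name_ring = rings$residue_name[j],
          distance = d, angle = ang)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(res_cation = integer(), name_cation = character(),
                  res_ring = integer(), name_ring = character(),
                  distance = numeric(), angle = numeric()))
  }
  bind_rows(out)
}

#' Curated hPDI inter-domain bridge pairs
#'
#' The residue pairs whose salt bridges stabilise the compact hPDI
#' conformations: domain a vs b (Arg106/Lys114/Arg120/Arg132 against
#' Glu177/Asp180/Asp181), domain a vs b' (Arg97 against Glu242, Asp297,
#' Glu321-323), b' vs a' (Lys326-Glu431) and b' vs the x-linker
#' (Lys308-Glu359). Shipped as a plain-text table in `extdata`.
#'
#' @return A tibble with columns `res_pos`, `name_pos`, `res_neg`,
#'   `name_neg`, `interface`.
#' @export
hpdi_bridge_pairs <- function() {
  path <- system.file("extdata", "hpdi_bridge_pairs.tsv",
                      package = "interdom", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
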