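#' Geometric centre of an atom selection
#'
#' The unweighted arithmetic mean of the selected coordinates. Domain
#' positions are summarised by the geometric centre of the rigid-core
#' alpha-carbons, which is robust to missing side-chain atoms.
#'
#' @param atoms A frame tibble (typically from [select_atoms()]).
#' @return Length-3 numeric vector (x, y, z) in Angstrom.
#' @export
geometric_center <- function(atoms) {
  fr <- as_frame(atoms)
  if (nrow(fr) == 0) {
    abort("cannot take the centre of an empty atom set",
          class = "interdom_selection_error")
  }
  c(x = mean(fr$x), y = mean(fr$y), z = mean(fr$z))
}

domain_center <- function(frame, seg, dom, atom_names = "CA") {
  geometric_center(domain_core_atoms(frame, seg, dom, atom_names))
}

#' Distance between two domain centres
#'
#' @param frame A frame tibble.
#' @param seg A segmentation tibble.
#' @param dom_a,dom_b Domain names; the result is symmetric in the two.
#' @param atom_names Atom-name filter defining the centres (default
#'   alpha-carbons).
#' @return Euclidean centre-centre distance in Angstrom.
#' @export
center_distance <- function(frame, seg, dom_a, dom_b, atom_names = "CA") {
  fr <- as_frame(frame)
  ca <- domain_center(fr, seg, dom_a, atom_names)
  cb <- domain_center(fr, seg, dom_b, atom_names)
  sqrt(sum((ca - cb)^2))
}

#' Angle subtended at a domain centre
#'
#' The angle at the centre of `dom_mid` between the vectors to the centres
#' of `dom_1` and `dom_3`, in degrees within \[0, 180\]. The middle listed
#' domain is the vertex.
#'
#' @inheritParams center_distance
#' @param dom_1,dom_mid,dom_3 Three distinct domain names; `dom_mid` is the
#'   vertex.
#' @return Angle in degrees.
#' @export
inter_domain_angle <- function(frame, seg, dom_1, dom_mid, dom_3,
                               atom_names = "CA") {
  fr <- as_frame(frame)
  p1 <- domain_center(fr, seg, dom_1, atom_names)
  p2 <- domain_center(fr, seg, dom_mid, atom_names)
  p3 <- domain_center(fr, seg, dom_3, atom_names)
  angle_deg(p1, p2, p3)
}

angle_deg <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12) {
    abort("coincident centres: angle undefined",
          class = "interdom_geometry_error")
  }
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
}

#' Signed dihedral of four domain centres
#'
#' The torsion of the four domain centres taken in sequence order, IUPAC
#' sign convention, range (-180, 180\] degrees. With the hPDI defaults this
#' is the a--b--b'--a' dihedral; values near 0 or +-180 mean the four
#' centres are nearly coplanar.
#'
#' @inheritParams center_distance
#' @param domains Four domain names in order; default = the segmentation's
#'   first four domains in sequence order.
#' @return Signed torsion in degrees.
#' @export
four_domain_dihedral <- function(frame, seg, domains = NULL,
                                 atom_names = "CA") {
  fr <- as_frame(frame)
  domains <- domains %||% head(seg_domains(seg), 4)
  if (length(domains) != 4) {
    abort("dihedral needs exactly four domains", class = "interdom_key_error")
  }
  ps <- lapply(domains, function(d) domain_center(fr, seg, d, atom_names))
  torsion_deg(ps[[1]], ps[[2]], ps[[3]], ps[[4]])
}

torsion_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) {
    abort("three consecutive centres are collinear: dihedral undefined",
          class = "interdom_geometry_error")
  }
  ang <- atan2(sqrt(sum(b2^2)) * sum(b1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` (det = +1 enforced via the smallest
#' singular value, so mirror images are never returned) and translation `t`
#' minimising the RMSD of `R p + t` against the reference points.
#'
#' @param mobile,reference n x 3 coordinate matrices (or frame tibbles) of
#'   paired points; at least 3 non-collinear pairs.
#' @return A list with `rotation` (3x3), `translation` (length 3) and
#'   `rmsd` (Angstrom, after the fit).
#' @export
kabsch_superpose <- function(mobile, reference) {
  P <- if (is.data.frame(mobile)) coords_matrix(as_frame(mobile)) else
    as.matrix(mobile)
  Q <- if (is.data.frame(reference)) coords_matrix(as_frame(reference)) else
    as.matrix(reference)
  if (!all(dim(P) == dim(Q))) {
    abort("mobile and reference must have the same number of points",
          class = "interdom_shape_error")
  }
  if (nrow(P) < 3) {
    abort("superposition needs at least 3 point pairs",
          class = "interdom_geometry_error")
  }
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv_ref <- svd(Qc)$d
  if (sv_ref[2] < 1e-8 * max(sv_ref[1], 1)) {
    abort("reference points are collinear: rotation is not unique",
          class = "interdom_geometry_error")
  }
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  rmsd <- sqrt(max(0, mean(rowSums((Pc %*% t(R) - Qc)^2))))
  list(rotation = R, translation = as.numeric(cq - R %*% cp), rmsd = rmsd)
}

rmsd_raw <- function(P, Q) sqrt(mean(rowSums((P - Q)^2)))

# residue-number selection helper shared by the series functions
sel_coords <- function(frame, residues, atom_names) {
  fr <- frame
  keep <- fr$atom_name %in% atom_names
  if (!is.null(residues)) keep <- keep & fr$residue_number %in% residues
  if (!any(keep)) {
    abort("empty selection in RMSD computation",
          class = "interdom_selection_error")
  }
  coords_matrix(fr[keep, , drop = FALSE])
}

#' Superposition-based RMSD time series
#'
#' For each frame, superpose the `align` selection onto the reference frame
#' (Kabsch, proper rotation), then report the RMSD of the `measure`
#' selection under that transform. With `measure = align` this is the
#' classic per-domain rigid-core RMSD series; with `align` = whole molecule
#' it measures global drift; aligning on one domain while measuring another
#' isolates inter-domain displacement.
#'
#' @param traj A trajectory tibble.
#' @param align Integer vector of residue numbers to fit on (`NULL` = all).
#' @param measure Residue numbers to report RMSD over (default: same as
#'   `align`).
#' @param reference Reference frame tibble, or 0-based frame index into
#'   `traj` (default: first frame).
#' @param atom_names Atom-name filter (default alpha-carbons).
#' @return A tibble with columns `frame` and `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, align = NULL, measure = align,
                        reference = NULL, atom_names = "CA") {
  frames <- traj_split(traj)
  ref <- if (is.data.frame(reference)) as_frame(reference) else
    frames[[ (reference %||% 0) + 1 ]]
  ref_a <- sel_coords(ref, align, atom_names)
  ref_m <- sel_coords(ref, measure, atom_names)
  vals <- vapply(frames, function(fr) {
    fit <- kabsch_superpose(sel_coords(fr, align, atom_names), ref_a)
    M <- sel_coords(fr, measure, atom_names)
    Mt <- sweep(M %*% t(fit$rotation), 2, fit$translation, `+`)
    rmsd_raw(Mt, ref_m)
  }, numeric(1))
  tibble(frame = as.integer(names(frames)), rmsd = unname(vals))
}

#' Relative rotation of one domain between two structures
#'
#' Superposes structure B onto structure A using the rigid-core
#' alpha-carbons of `align_dom`, then takes the best-fit rotation carrying
#' `measure_dom` of A onto `measure_dom` of (aligned) B and returns its
#' axis-angle magnitude in degrees. This is how a "domain b' rotates ~20
#' degrees with respect to b" type of statement is quantified between two
#' conformations.
#'
#' @param struct_a,struct_b Frame tibbles of the same molecule.
#' @param seg Segmentation tibble.
#' @param align_dom Domain held fixed by the superposition.
#' @param measure_dom Domain whose residual rotation is measured.
#' @param atom_names Atom-name filter (default alpha-carbons).
#' @return Rotation angle in degrees, within \[0, 180\]. Symmetric in A and
#'   B.
#' @export
rotation_angle_between <- function(struct_a, struct_b, seg, align_dom,
                                   measure_dom, atom_names = "CA") {
  fa <- as_frame(struct_a); fb <- as_frame(struct_b)
  rng_al <- seg_range(seg, align_dom)
  rng_me <- seg_range(seg, measure_dom)
  al_a <- coords_matrix(select_atoms(fa, rng_al, atom_names))
  al_b <- coords_matrix(select_atoms(fb, rng_al, atom_names))
  me_a <- coords_matrix(select_atoms(fa, rng_me, atom_names))
  me_b <- coords_matrix(select_atoms(fb, rng_me, atom_names))
  fit <- kabsch_superpose(al_b, al_a)
  me_b_al <- sweep(me_b %*% t(fit$rotation), 2, fit$translation, `+`)
  res <- kabsch_superpose(me_a, me_b_al)
  ang <- (sum(diag(res$rotation)) - 1) / 2
  acos(max(-1, min(1, ang))) * 180 / pi
}

#' All inter-domain centre metrics of a trajectory
#'
#' Per frame: every pairwise domain-centre distance, the angle at each
#' interior domain of consecutive triples, and (for a four-domain
#' segmentation) the signed dihedral of the four centres. Column names
#' replace the prime in domain names by `p` (so `b'` appears as `bp`).
#'
#' @param traj A trajectory tibble.
#' @param seg Segmentation tibble.
#' @param atom_names Atom-name filter defining centres (default
#'   alpha-carbons).
#' @return A tibble with one row per frame: `frame`, `dist_*`, `angle_*`
#'   and `dihedral_*` columns (Angstrom / degrees).
#' @export
domain_metrics <- function(traj, seg, atom_names = "CA") {
  doms <- seg_domains(seg)
  frames <- traj_split(traj)
  safe <- function(x) gsub("'", "p", x)
  rows <- lapply(frames, function(fr) {
    cen <- lapply(doms, function(d) domain_center(fr, seg, d, atom_names))
    names(cen) <- doms
    out <- list()
    if (length(doms) >= 2) {
      for (i in seq_len(length(doms) - 1)) for (j in (i + 1):length(doms)) {
        out[[paste0("dist_", safe(doms[i]), "_", safe(doms[j]))]] <-
          sqrt(sum((cen[[i]] - cen[[j]])^2))
      }
    }
    if (length(doms) >= 3) {
      for (i in seq_len(length(doms) - 2)) {
        out[[paste0("angle_", safe(doms[i]), "_", safe(doms[i + 1]), "_",
                    safe(doms[i + 2]))]] <-
          angle_deg(cen[[i]], cen[[i + 1]], cen[[i + 2]])
      }
    }
    if (length(doms) == 4) {
      out[[paste0("dihedral_", paste(safe(doms), collapse = "_"))]] <-
        torsion_deg(cen[[1]], cen[[2]], cen[[3]], cen[[4]])
    }
    as_tibble(out)
  })
  bind_cols(tibble(frame = as.integer(names(frames))), bind_rows(rows))
}
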