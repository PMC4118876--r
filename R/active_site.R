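#' Nearest active-site sulfur distance
#'
#' The minimum SG-SG distance between the reactive cysteines of different
#' active sites (site-internal pairs are excluded). With the hPDI defaults
#' this is the nearest distance between the sulfurs of Cys53/Cys56 in
#' domain a and Cys397/Cys400 in domain a' -- the quantity that gauges
#' whether the two CGHC motifs come close enough for direct thiol-disulfide
#' chemistry.
#'
#' @param frame A frame tibble containing SG atoms for the listed cysteines.
#' @param sites Active-site table (see [hpdi_active_sites()]).
#' @return Minimum cross-site SG-SG distance in Angstrom.
#' @export
min_sulfur_distance <- function(frame, sites = hpdi_active_sites()) {
  fr <- as_frame(frame)
  sg <- lapply(seq_len(nrow(sites)), function(i) {
    res <- c(sites$cys_n[i], sites$cys_c[i])
    m <- lapply(res, function(r) {
      rows <- fr[fr$residue_number == r & fr$atom_name == "SG", , drop = FALSE]
      if (nrow(rows) == 0) {
        abort(sprintf("missing SG atom for cysteine %d", r),
              class = "interdom_missing_atom_error")
      }
      coords_matrix(rows)[1, , drop = FALSE]
    })
    do.call(rbind, m)
  })
  best <- Inf
  for (i in seq_along(sg)) for (j in seq_along(sg)) {
    if (j <= i) next
    best <- min(best, min_cross_distance(sg[[i]], sg[[j]]))
  }
  if (!is.finite(best)) {
    abort("need at least two active sites", class = "interdom_config_error")
  }
  best
}

#' Active-site sulfur distance time course
#'
#' @param traj A trajectory tibble.
#' @param sites Active-site table.
#' @return A tibble with columns `frame`, `sulfur_distance` (Angstrom).
#' @export
sulfur_distance_series <- function(traj, sites = hpdi_active_sites()) {
  frames <- traj_split(traj)
  vals <- vapply(frames, min_sulfur_distance, numeric(1), sites = sites)
  tibble(frame = as.integer(names(frames)), sulfur_distance = unname(vals))
}

#' Compactness summary of a trajectory
#'
#' Summarises every inter-domain centre metric (all pairwise distances, the
#' consecutive-triple angles, the four-domain dihedral) plus the
#' active-site sulfur distance with its initial, final, minimum, maximum
#' and mean value, and flags each metric as `compacted` when the final
#' value is below the initial one. The flag is directional only -- no hard
#' compactness cutoff is imposed.
#'
#' @param traj A trajectory tibble.
#' @param seg Segmentation tibble.
#' @param sites Active-site table (`NULL` to skip the sulfur metric).
#' @param atom_names Atom-name filter defining domain centres.
#' @return A `compactness_report` object; `tidy()` returns the per-metric
#'   summary tibble, `glance()` a one-row overview.
#' @export
compactness_report <- function(traj, seg = hpdi_segmentation(),
                               sites = hpdi_active_sites(),
                               atom_names = "CA") {
  if (n_frames(traj) < 1) {
    abort("empty trajectory", class = "interdom_shape_error")
  }
  met <- domain_metrics(traj, seg, atom_names)
  if (!is.null(sites)) {
    sd <- sulfur_distance_series(traj, sites)
    met <- left_join(met, sd, by = "frame")
  }
  structure(list(summary = summarise_metrics(met), series = met,
                 n_frames = n_frames(traj),
                 conventions = report_conventions(atom_names)),
            class = "compactness_report")
}

# per-metric summary of a wide per-frame metric table (pure summary: the
# report is always recomputable from the emitted series)
summarise_metrics <- function(met) {
  met <- arrange(met, .data$frame)
  long <- tidyr::pivot_longer(met, -"frame", names_to = "metric",
                              values_to = "value")
  long |>
    group_by(.data$metric) |>
    summarise(initial = first(.data$value), final = last(.data$value),
              minimum = min(.data$value), maximum = max(.data$value),
              mean = mean(.data$value), .groups = "drop") |>
    mutate(compacted = .data$final < .data$initial)
}

report_conventions <- function(atom_names = "CA", threshold = 3.0,
                               inclusive = FALSE) {
  list(center_atoms = atom_names,
       angle_vertex = "middle listed domain",
       dihedral = "IUPAC signed torsion, range (-180, 180] degrees",
       distance_unit = "Angstrom", angle_unit = "degree",
       frame_indexing = "0-based",
       bridge_threshold_angstrom = threshold,
       bridge_threshold_strict = !inclusive)
}

#' @export
print.compactness_report <- function(x, ...) {
  cat(sprintf("Compactness report over %d frames\n", x$n_frames))
  print(x$summary, n = Inf)
  invisible(x)
}

#' @rdname compactness_report
#' @param x A `compactness_report`.
#' @param ... Unused.
#' @export
tidy.compactness_report <- function(x, ...) x$summary

#' @rdname compactness_report
#' @export
glance.compactness_report <- function(x, ...) {
  tibble(n_frames = x$n_frames,
         n_metrics = nrow(x$summary),
         n_compacted = sum(x$summary$compacted),
         min_sulfur_distance = if ("sulfur_distance" %in% x$summary$metric)
           x$summary$minimum[x$summary$metric == "sulfur_distance"]
         else NA_real_)
}
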