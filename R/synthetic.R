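#' Specification of a synthetic four-domain toy molecule
#'
#' The toy molecule emulates the geometric structure the analysis assumes:
#' four rigid pseudo-domains labelled a, b, b', a' whose alpha-carbon
#' pseudo-residues are numbered inside the hPDI rigid-core ranges, optional
#' charged side-chain atoms at the residue positions of the curated hPDI
#' bridge pairs, optional active-site cysteine SG atoms at 53/56/397/400,
#' an x-linker Glu359 attached to the b' body, and a Trp396 aromatic ring.
#' Domains are random rigid point clouds, not folded structures: the
#' analysis layer depends only on geometry, never on chemistry.
#'
#' @param atoms_per_domain Alpha-carbon count per domain (>= 4 so
#'   superposition is non-degenerate; default 30).
#' @param domain_radius Radius of each pseudo-domain point cloud in
#'   Angstrom (default 8).
#' @param include_charged Place charged side-chain atoms (one terminal atom
#'   per charged residue).
#' @param include_active_sites Place CYS residues 53/56/397/400 with SG
#'   atoms.
#' @param seed Integer seed; the build is bit-reproducible given the seed.
#' @return A `toy_spec` list.
#' @export
toy_spec <- function(atoms_per_domain = 30, domain_radius = 8,
                     include_charged = TRUE, include_active_sites = TRUE,
                     seed = 1L) {
  if (atoms_per_domain < 4) {
    abort("atoms_per_domain must be at least 4",
          class = "interdom_generation_error")
  }
  structure(list(atoms_per_domain = as.integer(atoms_per_domain),
                 domain_radius = domain_radius,
                 include_charged = include_charged,
                 include_active_sites = include_active_sites,
                 seed = as.integer(seed)),
            class = "toy_spec")
}

# charged pseudo-residues (one terminal charged atom each), hPDI numbering
toy_charged_table <- function() {
  tibble(
    residue_number = c(97L, 106L, 114L, 120L, 132L,
                       177L, 180L, 181L,
                       242L, 297L, 300L, 308L, 321L, 322L, 323L, 326L,
                       431L, 359L),
    residue_name = c("ARG", "ARG", "LYS", "ARG", "ARG",
                     "GLU", "ASP", "ASP",
                     "GLU", "ASP", "ARG", "LYS", "GLU", "GLU", "GLU", "LYS",
                     "GLU", "GLU"),
    body = c(rep("a", 5), rep("b", 3), rep("b'", 8), "a'", "b'"))
}

charged_atom_of <- c(ARG = "NH1", LYS = "NZ", ASP = "OD1", GLU = "OE1")
element_of_atom <- function(a) substr(gsub("[0-9']", "", a), 1, 1)

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

random_rotation <- function() {
  # uniform random rotation from a normalised quaternion
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Build a synthetic articulated four-domain molecule
#'
#' @param spec A [toy_spec()].
#' @return A `toy_model` list with elements `frame` (the reference
#'   conformation, a frame tibble), `segmentation`, `active_sites`, plus
#'   the internal rigid-body tables the trajectory generator uses.
#' @export
build_toy_tetradomain <- function(spec = toy_spec()) {
  seg <- hpdi_segmentation()
  sites <- hpdi_active_sites()
  doms <- seg_domains(seg)
  charged <- if (spec$include_charged) toy_charged_table() else
    toy_charged_table()[0, ]
  with_seed(spec$seed, {
    atoms <- list()
    for (d in doms) {
      rng <- seg_range(seg, d)
      specials <- integer()
      special_names <- character()
      if (spec$include_active_sites) {
        for (i in seq_len(nrow(sites))) {
          if (sites$domain[i] == d) {
            specials <- c(specials, sites$cys_n[i], sites$cys_c[i])
            special_names <- c(special_names, "CYS", "CYS")
          }
        }
      }
      chd <- charged[charged$body == d & charged$residue_number >= rng[1] &
                       charged$residue_number <= rng[2], ]
      specials <- c(specials, chd$residue_number)
      special_names <- c(special_names, chd$residue_name)
      if (spec$include_charged && d == "a'") {
        specials <- c(specials, 396L)
        special_names <- c(special_names, "TRP")
      }
      o <- order(specials)
      specials <- specials[o]; special_names <- special_names[o]
      n_fill <- max(0L, spec$atoms_per_domain - length(specials))
      avail <- setdiff(seq(rng[1], rng[2]), specials)
      fillers <- if (n_fill > 0)
        avail[unique(as.integer(round(seq(1, length(avail),
                                          length.out = n_fill))))]
      else integer()
      res <- tibble(residue_number = c(specials, fillers),
                    residue_name = c(special_names, rep("GLY", length(fillers))))
      res <- arrange(res, .data$residue_number)
      nr <- nrow(res)
      # CA cloud in a ball; recentre so the CA mean is exactly the origin
      m <- matrix(rnorm(nr * 3), ncol = 3)
      m <- m / sqrt(rowSums(m^2)) * spec$domain_radius * runif(nr)^(1 / 3)
      m <- sweep(m, 2, colMeans(m))
      dom_atoms <- tibble(residue_number = res$residue_number,
                          residue_name = res$residue_name,
                          atom_name = "CA", body = d,
                          lx = m[, 1], ly = m[, 2], lz = m[, 3],
                          flexible = FALSE)
      # side-chain atoms hang off their CA (flexible: never part of a core)
      side <- list()
      for (i in seq_len(nr)) {
        rn <- res$residue_name[i]
        add <- character()
        if (rn %in% names(charged_atom_of)) add <- charged_atom_of[[rn]]
        if (rn == "ARG" && res$residue_number[i] == 300L) add <- c(add, "CZ")
        if (rn == "CYS") add <- "SG"
        if (rn == "TRP") add <- ring_atoms$TRP
        for (an in add) {
          off <- rnorm(3)
          off <- off / sqrt(sum(off^2)) * runif(1, 1.5, 3)
          side[[length(side) + 1]] <- tibble(
            residue_number = res$residue_number[i], residue_name = rn,
            atom_name = an, body = d,
            lx = m[i, 1] + off[1], ly = m[i, 2] + off[2],
            lz = m[i, 3] + off[3], flexible = TRUE)
        }
      }
      # the Trp ring must be planar: rebuild it as a hexagon if present
      atoms[[d]] <- bind_rows(dom_atoms, bind_rows(side))
      if (spec$include_charged && d == "a'") {
        atoms[[d]] <- planarise_ring(atoms[[d]], 396L)
      }
    }
    # x-linker residue rides on the b' body, outside its cloud
    if (spec$include_charged) {
      lx <- c(spec$domain_radius * 1.4, 0, 0)
      atoms[["b'"]] <- bind_rows(atoms[["b'"]], tibble(
        residue_number = 359L, residue_name = "GLU",
        atom_name = c("CA", "OE1"), body = "b'",
        lx = lx[1] + c(0, 1.8), ly = c(0, 0.6), lz = c(0, 0),
        flexible = c(TRUE, TRUE)))
    }
    roster <- bind_rows(atoms)
    rotations <- setNames(lapply(doms, function(d) random_rotation()), doms)
    model <- structure(list(spec = spec, segmentation = seg,
                            active_sites = sites, roster = roster,
                            rotations = rotations), class = "toy_model")
    pose <- solve_pose(theta_deg = 110, d_abp = 45, d_aap = 55,
                       phi_deg = 60, R = 30, v = 25)
    model$frame <- assemble_frame(model, pose$centers)
    model
  })
}

planarise_ring <- function(tab, resno) {
  idx <- which(tab$residue_number == resno & tab$atom_name %in% ring_atoms$TRP)
  ca <- which(tab$residue_number == resno & tab$atom_name == "CA")
  centre <- c(tab$lx[ca], tab$ly[ca], tab$lz[ca]) + c(2.5, 0, 0)
  e1 <- rnorm(3); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- rnorm(3); e2 <- e2 - sum(e2 * e1) * e1; e2 <- e2 / sqrt(sum(e2^2))
  th <- seq(0, by = pi / 3, length.out = 6)
  pts <- t(vapply(th, function(a)
    centre + 1.4 * (cos(a) * e1 + sin(a) * e2), numeric(3)))
  tab$lx[idx] <- pts[, 1]; tab$ly[idx] <- pts[, 2]; tab$lz[idx] <- pts[, 3]
  tab
}

# place the four rigid bodies for one frame: coordinates Q_d l + C_d
assemble_frame <- function(model, centers) {
  tab <- model$roster
  m <- matrix(NA_real_, nrow(tab), 3)
  for (d in names(centers)) {
    i <- which(tab$body == d)
    loc <- cbind(tab$lx[i], tab$ly[i], tab$lz[i])
    m[i, ] <- sweep(loc %*% t(model$rotations[[d]]), 2, centers[[d]], `+`)
  }
  new_frame(tibble(
    serial = seq_len(nrow(tab)),
    atom_name = tab$atom_name,
    residue_name = tab$residue_name,
    residue_number = tab$residue_number,
    chain_id = "A",
    x = m[, 1], y = m[, 2], z = m[, 3],
    element = element_of_atom(tab$atom_name),
    occupancy = 1))
}

# exact rigid-pose solution for the prescribed frame metrics:
#   b at the origin, b' at (R, 0, 0);
#   a from the a-b-b' angle and the a-b' distance (law of cosines fixes
#   the a-b distance); a' in the dihedral half-plane at perpendicular
#   offset v, its axial position fixed by the a-a' distance.
solve_pose <- function(theta_deg, d_abp, d_aap, phi_deg, R, v) {
  th <- theta_deg * pi / 180
  ph <- phi_deg * pi / 180
  if (theta_deg <= 0.1 || theta_deg >= 179.9) {
    return(list(ok = FALSE, why = "a-b-b' angle too close to degenerate"))
  }
  disc_r <- d_abp^2 - (R * sin(th))^2
  if (disc_r <= 1e-9) {
    return(list(ok = FALSE,
                why = sprintf("a-b' distance %.3f below reach R*sin(theta) = %.3f",
                              d_abp, R * sin(th))))
  }
  r <- R * cos(th) + sqrt(disc_r)
  if (r <= 1e-6) {
    return(list(ok = FALSE, why = "a-b distance solution collapsed to zero"))
  }
  ca <- c(r * cos(th), r * sin(th), 0)
  perp2 <- (v * cos(ph) - ca[2])^2 + (v * sin(ph))^2
  disc_u <- d_aap^2 - perp2
  if (disc_u <= 1e-9) {
    return(list(ok = FALSE,
                why = sprintf("a-a' distance %.3f shorter than the off-axis offset %.3f",
                              d_aap, sqrt(perp2))))
  }
  cap <- c(ca[1] + sqrt(disc_u), v * cos(ph), v * sin(ph))
  list(ok = TRUE, dist_a_b = r,
       centers = list(a = ca, b = c(0, 0, 0), "b'" = c(R, 0, 0), "a'" = cap))
}

#' Specification of a hinge-motion schedule
#'
#' Per-frame targets are piecewise-linear keyframe schedules for the
#' a--b' and a--a' centre distances, the a-b-b' angle, the four-domain
#' dihedral and the active-site sulfur distance, plus scheduled contact
#' events (a residue pair held at a target closest distance over a frame
#' window). A schedule may be a single value (constant), a length-2 vector
#' (linear start to end) or a `data.frame(frame, value)` of keyframes.
#' Each frame is realised by rigid-body placement of whole domains; a
#' feasibility check confirms a pose sequence exists before any atoms are
#' generated. The defaults reproduce the compaction observed for hPDI:
#' a--b' relaxing from 45 to 32 Angstrom, a--a' from 55 to 35 Angstrom, the
#' a-b-b' angle dropping 40 degrees, the centres approaching coplanarity,
#' the active-site sulfurs approaching from 40 to 5.4 Angstrom, and the
#' Lys326-Glu431 / Lys308-Glu359 bridges forming in the second half.
#'
#' @param n_frames Number of frames (default 201).
#' @param dist_a_bp,dist_a_ap Centre-distance schedules in Angstrom.
#' @param angle_a_b_bp Angle schedule in degrees (vertex at b).
#' @param dihedral Signed four-domain dihedral schedule in degrees.
#' @param sulfur Active-site sulfur distance schedule in Angstrom, or
#'   `NULL` to leave the SG atoms riding on their domains.
#' @param contacts Data frame `res_pos`, `res_neg`, `from`, `to`,
#'   `distance`: the pair's closest charged-atom distance is held at
#'   `distance` for frames `from..to` (0-based, inclusive). `NULL` or
#'   zero rows for none.
#' @param internal_noise_sd Gaussian jitter (Angstrom) added to
#'   non-core, non-scheduled atoms only; rigid cores stay exact.
#' @param dist_b_bp Fixed b--b' centre distance in Angstrom.
#' @param aprime_offset Fixed perpendicular offset of the a' centre from
#'   the b--b' axis in Angstrom.
#' @return A `motion_spec` list.
#' @export
motion_spec <- function(n_frames = 201,
                        dist_a_bp = c(45, 32),
                        dist_a_ap = c(55, 35),
                        angle_a_b_bp = c(110, 70),
                        dihedral = c(60, 5),
                        sulfur = c(40, 5.4),
                        contacts = default_contacts(n_frames),
                        internal_noise_sd = 0,
                        dist_b_bp = 30,
                        aprime_offset = 25) {
  if (n_frames < 1) abort("n_frames must be positive",
                          class = "interdom_generation_error")
  structure(list(n_frames = as.integer(n_frames),
                 dist_a_bp = dist_a_bp, dist_a_ap = dist_a_ap,
                 angle_a_b_bp = angle_a_b_bp, dihedral = dihedral,
                 sulfur = sulfur, contacts = contacts,
                 internal_noise_sd = internal_noise_sd,
                 dist_b_bp = dist_b_bp, aprime_offset = aprime_offset),
            class = "motion_spec")
}

default_contacts <- function(n_frames) {
  half <- as.integer(floor(n_frames / 2))
  if (n_frames < 2) return(NULL)
  tibble(res_pos = c(326L, 308L), res_neg = c(431L, 359L),
         from = c(half, as.integer(min(n_frames - 1, half + 20))),
         to = c(n_frames - 1L, n_frames - 1L),
         distance = c(2.8, 2.8))
}

resolve_schedule <- function(x, n) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) {
    return(approx(x$frame, x$value, xout = seq_len(n) - 1, rule = 2)$y)
  }
  if (length(x) == 1) return(rep(as.numeric(x), n))
  if (length(x) == 2) {
    if (n == 1) return(as.numeric(x[1]))
    return(seq(x[1], x[2], length.out = n))
  }
  if (length(x) == n) return(as.numeric(x))
  abort("schedule must be length 1, 2, n_frames, or a keyframe data frame",
        class = "interdom_generation_error")
}

#' Generate an articulated hinge trajectory with exact ground truth
#'
#' Every frame is produced by rigid-body transforms of whole domains
#' (plus optional jitter on non-core atoms), so the prescribed centre
#' distances, angle, and dihedral are realised exactly; scheduled sulfur
#' and contact atom pairs are laid out along a fixed axis around a
#' grid-snapped midpoint so that PDB coordinate rounding (0.001 Angstrom)
#' perturbs their pair distance by at most 0.001 Angstrom. The returned
#' ground truth records, per frame, the true centre positions, all six
#' centre distances, both angles, the dihedral, the sulfur distance, and
#' each scheduled pair's distance and bridge state.
#'
#' @param model A `toy_model` from [build_toy_tetradomain()].
#' @param motion A [motion_spec()].
#' @param seed Seed for jitter and any under-constrained choices; defaults
#'   to the model's seed + 1.
#' @return A list with `trajectory` (trajectory tibble) and `truth` (a
#'   `hinge_truth` list with elements `metrics`, `centers`, `contacts`,
#'   `occupancy`).
#' @export
generate_hinge_trajectory <- function(model, motion = motion_spec(),
                                      seed = NULL) {
  stopifnot(inherits(model, "toy_model"), inherits(motion, "motion_spec"))
  n <- motion$n_frames
  th <- resolve_schedule(motion$angle_a_b_bp, n)
  d1 <- resolve_schedule(motion$dist_a_bp, n)
  d2 <- resolve_schedule(motion$dist_a_ap, n)
  ph <- resolve_schedule(motion$dihedral, n)
  su <- resolve_schedule(motion$sulfur, n)
  contacts <- motion$contacts
  if (!is.null(contacts) && nrow(contacts) > 0) {
    validate_contacts(contacts, model, n)
  } else {
    contacts <- NULL
  }
  if (!is.null(su) && !model$spec$include_active_sites) {
    abort("sulfur schedule requires include_active_sites = TRUE",
          class = "interdom_generation_error")
  }
  # feasibility pass before any atom is generated
  poses <- vector("list", n)
  for (t in seq_len(n)) {
    p <- solve_pose(th[t], d1[t], d2[t], ph[t], motion$dist_b_bp,
                    motion$aprime_offset)
    if (!p$ok) {
      abort(sprintf("infeasible motion at frame %d: %s", t - 1, p$why),
            class = "interdom_generation_error")
    }
    poses[[t]] <- p
  }
  seed <- seed %||% (model$spec$seed + 1L)
  tab <- model$roster
  sites <- model$active_sites
  with_seed(seed, {
    frames <- vector("list", n)
    truth_rows <- vector("list", n)
    centre_rows <- vector("list", n)
    contact_rows <- vector("list", n)
    for (t in seq_len(n)) {
      pose <- poses[[t]]
      fr <- assemble_frame(model, pose$centers)
      overridden <- rep(FALSE, nrow(fr))
      # scheduled active-site approach: the four SG atoms on a fixed axis
      if (!is.null(su)) {
        mid <- round((pose$centers[["a"]] + pose$centers[["a'"]]) / 2, 3)
        lay <- list(`53` = -su[t] / 2 - 3, `56` = -su[t] / 2,
                    `397` = su[t] / 2, `400` = su[t] / 2 + 3)
        # nearest cross-site pair is 56-397 at exactly su[t]
        for (rn in names(lay)) {
          i <- which(fr$residue_number == as.integer(rn) &
                       fr$atom_name == "SG")
          fr$x[i] <- mid[1] + lay[[rn]]
          fr$y[i] <- mid[2]; fr$z[i] <- mid[3]
          overridden[i] <- TRUE
        }
      }
      # scheduled contacts: pair atoms on a fixed axis about the midpoint
      # of the two residues' home CA positions
      if (!is.null(contacts)) {
        for (k in seq_len(nrow(contacts))) {
          if (t - 1 < contacts$from[k] || t - 1 > contacts$to[k]) next
          ia <- charged_atom_index(fr, contacts$res_pos[k])
          ib <- charged_atom_index(fr, contacts$res_neg[k])
          ca_a <- which(fr$residue_number == contacts$res_pos[k] &
                          fr$atom_name == "CA")
          ca_b <- which(fr$residue_number == contacts$res_neg[k] &
                          fr$atom_name == "CA")
          anchor <- if (length(ca_a) && length(ca_b)) {
            (c(fr$x[ca_a], fr$y[ca_a], fr$z[ca_a]) +
               c(fr$x[ca_b], fr$y[ca_b], fr$z[ca_b])) / 2
          } else {
            (c(fr$x[ia], fr$y[ia], fr$z[ia]) +
               c(fr$x[ib], fr$y[ib], fr$z[ib])) / 2
          }
          mid <- round(anchor, 3)
          half <- contacts$distance[k] / 2
          fr$x[ia] <- mid[1] - half; fr$y[ia] <- mid[2]; fr$z[ia] <- mid[3]
          fr$x[ib] <- mid[1] + half; fr$y[ib] <- mid[2]; fr$z[ib] <- mid[3]
          overridden[c(ia, ib)] <- TRUE
        }
      }
      if (motion$internal_noise_sd > 0) {
        j <- which(tab$flexible & !overridden)
        fr$x[j] <- fr$x[j] + rnorm(length(j), sd = motion$internal_noise_sd)
        fr$y[j] <- fr$y[j] + rnorm(length(j), sd = motion$internal_noise_sd)
        fr$z[j] <- fr$z[j] + rnorm(length(j), sd = motion$internal_noise_sd)
      }
      frames[[t]] <- fr
      # ground truth for this frame
      cen <- pose$centers
      dd <- function(p, q) sqrt(sum((cen[[p]] - cen[[q]])^2))
      sulfur_true <- if (!is.null(su)) su[t] else
        if (model$spec$include_active_sites)
          min_sulfur_distance(fr, sites) else NA_real_
      truth_rows[[t]] <- tibble(
        frame = t - 1L,
        dist_a_b = pose$dist_a_b, dist_a_bp = d1[t], dist_a_ap = d2[t],
        dist_b_bp = motion$dist_b_bp, dist_b_ap = dd("b", "a'"),
        dist_bp_ap = dd("b'", "a'"),
        angle_a_b_bp = th[t],
        angle_b_bp_ap = angle_deg(cen[["b"]], cen[["b'"]], cen[["a'"]]),
        dihedral_a_b_bp_ap = ph[t],
        sulfur_distance = sulfur_true)
      centre_rows[[t]] <- tibble(
        frame = t - 1L, domain = names(cen),
        cx = vapply(cen, `[`, numeric(1), 1),
        cy = vapply(cen, `[`, numeric(1), 2),
        cz = vapply(cen, `[`, numeric(1), 3))
      if (!is.null(contacts)) {
        rows <- lapply(seq_len(nrow(contacts)), function(k) {
          inwin <- (t - 1) >= contacts$from[k] & (t - 1) <= contacts$to[k]
          d <- if (inwin) contacts$distance[k] else
            residue_min_distance(fr, contacts$res_pos[k], contacts$res_neg[k])
          tibble(res_pos = contacts$res_pos[k], res_neg = contacts$res_neg[k],
                 frame = t - 1L, distance = d, bridged = d < 3.0)
        })
        contact_rows[[t]] <- bind_rows(rows)
      }
    }
    truth <- structure(list(
      metrics = bind_rows(truth_rows),
      centers = bind_rows(centre_rows),
      contacts = if (!is.null(contacts)) bind_rows(contact_rows) else NULL,
      occupancy = if (!is.null(contacts)) {
        bind_rows(contact_rows) |>
          group_by(.data$res_pos, .data$res_neg) |>
          summarise(occupancy = mean(.data$bridged), .groups = "drop")
      } else NULL), class = "hinge_truth")
    list(trajectory = new_trajectory(frames), truth = truth, model = model)
  })
}

charged_atom_index <- function(fr, resno) {
  rows <- which(fr$residue_number == resno &
                  fr$atom_name %in% unname(charged_atom_of))
  if (length(rows) == 0) {
    abort(sprintf("scheduled contact residue %d has no charged atom", resno),
          class = "interdom_generation_error")
  }
  rows[1]
}

validate_contacts <- function(contacts, model, n) {
  for (k in seq_len(nrow(contacts))) {
    if (contacts$from[k] < 0 || contacts$to[k] > n - 1 ||
        contacts$from[k] > contacts$to[k]) {
      abort(sprintf("contact window %d..%d invalid for %d frames (keyframe %d)",
                    contacts$from[k], contacts$to[k], n, k),
            class = "interdom_generation_error")
    }
    for (r in c(contacts$res_pos[k], contacts$res_neg[k])) {
      if (!r %in% model$roster$residue_number) {
        abort(sprintf("contact residue %d absent from the toy model", r),
              class = "interdom_generation_error")
      }
    }
  }
  res_use <- c(contacts$res_pos, contacts$res_neg)
  for (r in unique(res_use)) {
    wins <- contacts[contacts$res_pos == r | contacts$res_neg == r, ]
    if (nrow(wins) > 1) {
      o <- order(wins$from)
      if (any(wins$from[o][-1] <= wins$to[o][-nrow(wins)])) {
        abort(sprintf("overlapping contact windows share residue %d", r),
              class = "interdom_generation_error")
      }
    }
  }
  invisible(TRUE)
}
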