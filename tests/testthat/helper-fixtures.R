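# shared fixtures and independent oracles for the test suite

make_frame <- function(atom_name, residue_number, x, y, z,
                       residue_name = "GLY", chain_id = "A") {
  new_frame(tibble::tibble(
    atom_name = atom_name,
    residue_number = as.integer(residue_number),
    residue_name = rep_len(residue_name, length(atom_name)),
    chain_id = rep_len(chain_id, length(atom_name)),
    x = x, y = y, z = z))
}

# one fixed-width PDB coordinate line
pdb_line <- function(serial, name, resn, chain, resno, x, y, z,
                     record = "ATOM  ", occ = 1, b = 0) {
  nm <- if (nchar(name) < 4) paste0(" ", name) else name
  sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          record, serial, nm, resn, chain, resno, x, y, z, occ, b)
}

write_pdb_text <- function(path, models) {
  # models: list of character vectors of coordinate lines
  out <- character()
  if (length(models) == 1) {
    out <- c(models[[1]], "END")
  } else {
    for (i in seq_along(models)) {
      out <- c(out, sprintf("MODEL     %4d", i), models[[i]], "ENDMDL")
    }
    out <- c(out, "END")
  }
  writeLines(out, path)
  path
}

# Rodrigues rotation about a unit axis, independent of package code
rot_axis <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

random_rotation_matrix <- function() rot_axis(stats::rnorm(3), stats::runif(1, 0, 360))

# independent superposition oracle: Horn's quaternion method (largest
# eigenvector of the 4x4 key matrix), always a proper rotation
quaternion_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  S <- crossprod(Pc, Qc)
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    nrow = 4, byrow = TRUE)
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1-2*(y^2+z^2), 2*(x*y-w*z), 2*(x*z+w*y),
                2*(x*y+w*z), 1-2*(x^2+z^2), 2*(y*z-w*x),
                2*(x*z-w*y), 2*(y*z+w*x), 1-2*(x^2+y^2)),
              nrow = 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  list(rotation = R, rmsd = rmsd)
}

# exhaustive O(n^2) atom-pair salt-bridge oracle with its own unit mapping
bf_salt_bridges <- function(frame, seg, threshold = 3.0) {
  cat_tab <- data.frame(
    residue_name = c("ARG","ARG","ARG","LYS","ASP","ASP","GLU","GLU"),
    atom_name = c("NE","NH1","NH2","NZ","OD1","OD2","OE1","OE2"),
    polarity = c("pos","pos","pos","pos","neg","neg","neg","neg"))
  fr <- as.data.frame(frame)
  fr$pol <- NA_character_
  for (i in seq_len(nrow(cat_tab))) {
    hit <- fr$residue_name == cat_tab$residue_name[i] &
      fr$atom_name == cat_tab$atom_name[i]
    fr$pol[hit] <- cat_tab$polarity[i]
  }
  unit <- function(r) {
    for (i in seq_len(nrow(seg))) {
      if (seg$type[i] == "linker" && r >= seg$first[i] && r <= seg$last[i])
        return(seg$name[i])
    }
    for (i in seq_len(nrow(seg))) {
      if (seg$type[i] == "domain" && r >= seg$first[i] && r <= seg$last[i])
        return(seg$name[i])
    }
    NA_character_
  }
  pos <- which(fr$pol == "pos"); neg <- which(fr$pol == "neg")
  best <- list()
  for (i in pos) for (j in neg) {
    d <- sqrt((fr$x[i]-fr$x[j])^2 + (fr$y[i]-fr$y[j])^2 + (fr$z[i]-fr$z[j])^2)
    ui <- unit(fr$residue_number[i]); uj <- unit(fr$residue_number[j])
    if (is.na(ui) || is.na(uj) || ui == uj) next
    key <- paste(fr$residue_number[i], fr$residue_number[j])
    if (is.null(best[[key]]) || d < best[[key]]$d) {
      best[[key]] <- list(rp = fr$residue_number[i],
                          rn = fr$residue_number[j], d = d)
    }
  }
  hits <- Filter(function(b) b$d < threshold, best)
  if (length(hits) == 0) {
    return(data.frame(res_pos = integer(), res_neg = integer(),
                      min_distance = numeric()))
  }
  out <- do.call(rbind, lapply(hits, function(b)
    data.frame(res_pos = b$rp, res_neg = b$rn, min_distance = b$d)))
  out <- out[order(out$res_pos, out$res_neg), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# random charged toy structure for the oracle-equivalence checks
random_charged_frame <- function(n_residues = 30, box = 18) {
  names_pool <- c("ARG", "LYS", "ASP", "GLU", "GLY", "ALA")
  cat_atoms <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                    ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  rows <- list()
  for (r in seq_len(n_residues)) {
    rn <- sample(names_pool, 1)
    ca <- stats::runif(3, 0, box)
    rows[[length(rows) + 1]] <- tibble::tibble(
      atom_name = "CA", residue_name = rn, residue_number = r,
      x = ca[1], y = ca[2], z = ca[3])
    for (an in cat_atoms[[rn]]) {
      p <- ca + stats::rnorm(3, sd = 1.5)
      rows[[length(rows) + 1]] <- tibble::tibble(
        atom_name = an, residue_name = rn, residue_number = r,
        x = p[1], y = p[2], z = p[3])
    }
  }
  new_frame(dplyr::bind_rows(rows))
}

two_domain_seg <- function(n_residues = 30) {
  half <- floor(n_residues / 2)
  segmentation(c("d1", "d2"), c(1, half + 1), c(half, n_residues))
}

# rejection-sample a feasible random motion schedule (seeded by caller)
random_motion_spec <- function(model, max_tries = 50) {
  pos_pool <- c(114L, 106L, 120L, 132L, 97L, 308L, 326L)
  neg_pool <- c(177L, 180L, 181L, 242L, 297L, 321L, 322L, 323L, 431L, 359L)
  for (try in seq_len(max_tries)) {
    n <- sample(8:20, 1)
    k <- sample(1:2, 1)
    from <- sample(0:(n - 2), k)
    contacts <- tibble::tibble(
      res_pos = sample(pos_pool, k), res_neg = sample(neg_pool, k),
      from = from,
      to = vapply(from, function(f) sample(f:(n - 1), 1), integer(1)),
      distance = stats::runif(k, 2.5, 2.9))
    ms <- motion_spec(
      n_frames = n,
      dist_a_bp = stats::runif(2, 34, 48),
      dist_a_ap = stats::runif(2, 40, 62),
      angle_a_b_bp = stats::runif(2, 75, 115),
      dihedral = stats::runif(2, 10, 80),
      sulfur = stats::runif(2, 5, 45),
      contacts = contacts)
    ok <- tryCatch({
      generate_hinge_trajectory(model, ms)
      TRUE
    }, interdom_generation_error = function(e) FALSE)
    if (ok) return(ms)
  }
  stop("could not sample a feasible motion spec")
}

default_toy_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_toy_tetradomain(toy_spec(seed = 42))
    cache
  }
})
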