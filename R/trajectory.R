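#' Atom-table frames and trajectories
#'
#' `interdom` represents one conformation (a *frame*) as a tibble with one row
#' per atom and the columns `serial`, `atom_name`, `residue_name`,
#' `residue_number`, `chain_id`, `x`, `y`, `z`, `element`, `occupancy`.
#' A *trajectory* is the same table with an extra leading `frame` column
#' (0-based frame index); all frames share one atom roster in one fixed order.
#' Coordinates are in Angstrom throughout, angles in degrees.
#'
#' @param atoms A data frame with at least `atom_name`, `residue_number` and
#'   `x`, `y`, `z` columns. Missing metadata columns are filled with defaults.
#' @return `new_frame()` returns a frame tibble; `new_trajectory()` a
#'   trajectory tibble of class `interdom_traj`.
#' @name trajectory
NULL

frame_cols <- c("serial", "atom_name", "residue_name", "residue_number",
                "chain_id", "x", "y", "z", "element", "occupancy")

#' @rdname trajectory
#' @export
new_frame <- function(atoms) {
  atoms <- as_tibble(atoms)
  n <- nrow(atoms)
  if (!"serial" %in% names(atoms)) atoms$serial <- seq_len(n)
  if (!"residue_name" %in% names(atoms)) atoms$residue_name <- "GLY"
  if (!"chain_id" %in% names(atoms)) atoms$chain_id <- "A"
  if (!"element" %in% names(atoms)) {
    atoms$element <- substr(gsub("[0-9']", "", atoms$atom_name), 1, 1)
  }
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1
  atoms$serial <- as.integer(atoms$serial)
  atoms$residue_number <- as.integer(atoms$residue_number)
  for (cc in c("x", "y", "z")) atoms[[cc]] <- as.numeric(atoms[[cc]])
  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad)) {
    abort(sprintf("non-finite coordinates for atom serial %d",
                  atoms$serial[which(bad)[1]]))
  }
  atoms[, frame_cols]
}

#' @rdname trajectory
#' @param frames A list of frame tibbles sharing one atom roster, or a single
#'   trajectory-shaped tibble already carrying a `frame` column.
#' @param frame_interval Optional time between frames in ns (metadata only;
#'   never used in any computation).
#' @export
new_trajectory <- function(frames, frame_interval = NA_real_) {
  if (is.data.frame(frames)) {
    tr <- as_tibble(frames)
    if (!"frame" %in% names(tr)) tr$frame <- 0L
  } else {
    frames <- lapply(frames, new_frame)
    check_roster(frames)
    tr <- bind_rows(frames, .id = ".id")
    tr$frame <- as.integer(tr$.id) - 1L
    tr$.id <- NULL
  }
  tr$frame <- as.integer(tr$frame)
  tr <- tr[, c("frame", frame_cols)]
  structure(tr, frame_interval = frame_interval,
            class = c("interdom_traj", class(tibble())))
}

roster_key <- function(fr) {
  paste(fr$atom_name, fr$residue_number, fr$chain_id, sep = "|")
}

check_roster <- function(frames) {
  ref <- roster_key(frames[[1]])
  for (i in seq_along(frames)[-1]) {
    k <- roster_key(frames[[i]])
    if (length(k) != length(ref)) {
      abort(sprintf(
        "inconsistent atom roster: frame %d has %d atoms, frame 1 has %d",
        i, length(k), length(ref)), class = "interdom_roster_error")
    }
    if (any(k != ref)) {
      j <- which(k != ref)[1]
      abort(sprintf(
        "inconsistent atom roster: frame %d atom %d is '%s', expected '%s'",
        i, j, k[j], ref[j]), class = "interdom_roster_error")
    }
  }
  invisible(TRUE)
}

#' Number of frames in a trajectory
#' @param traj A trajectory tibble.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) {
  if (!"frame" %in% names(traj)) return(1L)
  length(unique(traj$frame))
}

#' Extract one frame from a trajectory
#' @param traj A trajectory tibble.
#' @param index 0-based frame index.
#' @return A frame tibble (no `frame` column).
#' @export
get_frame <- function(traj, index) {
  if (!"frame" %in% names(traj)) return(as_tibble(traj))
  fr <- traj[traj$frame == index, , drop = FALSE]
  if (nrow(fr) == 0) abort(sprintf("no frame with index %d", index))
  fr$frame <- NULL
  as_tibble(fr)[, frame_cols]
}

#' Split a trajectory into a list of frames
#' @param traj A trajectory tibble.
#' @return Named list of frame tibbles in frame order (names = frame index).
#' @export
traj_split <- function(traj) {
  if (!"frame" %in% names(traj)) return(list(`0` = as_tibble(traj)))
  idx <- traj$frame
  traj$frame <- NULL
  tr <- as_tibble(traj)[, frame_cols]
  split(tr, idx)[as.character(sort(unique(idx)))]
}

# coerce either a frame or a 1-frame trajectory to a frame tibble
as_frame <- function(x) {
  if (!is.data.frame(x)) abort("expected a frame (data frame of atoms)")
  if ("frame" %in% names(x)) {
    if (length(unique(x$frame)) > 1)
      abort("expected a single frame, got a multi-frame trajectory")
    x$frame <- NULL
  }
  as_tibble(x)
}

coords_matrix <- function(frame) {
  cbind(x = frame$x, y = frame$y, z = frame$z)
}

#' Apply a rigid transform to a frame or trajectory
#'
#' @param x A frame or trajectory tibble.
#' @param rotation 3x3 proper rotation matrix.
#' @param translation Length-3 numeric vector in Angstrom.
#' @return The transformed object with coordinates `R p + t`.
#' @export
transform_coords <- function(x, rotation = diag(3), translation = c(0, 0, 0)) {
  m <- cbind(x$x, x$y, x$z) %*% t(rotation)
  x$x <- m[, 1] + translation[1]
  x$y <- m[, 2] + translation[2]
  x$z <- m[, 3] + translation[3]
  x
}
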