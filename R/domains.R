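#' Domain segmentations
#'
#' A segmentation maps named structural units to inclusive residue ranges.
#' Units of type `"domain"` are the rigid cores used for geometric centres
#' and superposition; units of type `"linker"` are named single residues
#' (such as Glu359 of the hPDI x-linker) that count as their own unit in
#' inter-domain contact analysis.
#'
#' @param name Character vector of unit names.
#' @param first,last Integer vectors of inclusive residue bounds.
#' @param type `"domain"` or `"linker"` per unit.
#' @return A validated segmentation tibble with columns `name`, `first`,
#'   `last`, `type`.
#' @export
segmentation <- function(name, first, last, type = "domain") {
  seg <- tibble(name = as.character(name), first = as.integer(first),
                last = as.integer(last),
                type = rep_len(as.character(type), length(name)))
  validate_segmentation(seg)
}

#' @rdname segmentation
#' @param seg A segmentation tibble to validate.
#' @export
validate_segmentation <- function(seg) {
  seg <- as_tibble(seg)
  if (!"type" %in% names(seg)) seg$type <- "domain"
  stopifnot(all(c("name", "first", "last") %in% names(seg)))
  if (anyDuplicated(seg$name)) {
    abort("duplicate unit names in segmentation", class = "interdom_config_error")
  }
  if (any(seg$last < seg$first)) {
    bad <- seg$name[which(seg$last < seg$first)[1]]
    abort(sprintf("empty residue range for unit '%s'", bad),
          class = "interdom_config_error")
  }
  dom <- seg[seg$type == "domain", ]
  if (nrow(dom) > 1) {
    o <- order(dom$first)
    if (any(dom$first[o][-1] <= dom$last[o][-nrow(dom)])) {
      abort("domain ranges overlap", class = "interdom_config_error")
    }
    if (!identical(o, seq_len(nrow(dom)))) {
      abort("domain ranges must be listed in sequence order",
            class = "interdom_config_error")
    }
  }
  seg
}

#' Rigid-core segmentation of mature human PDI
#'
#' The four thioredoxin-like domains with the rigid-core residue ranges used
#' for domain centres and superposition, in mature-hPDI numbering:
#' a 22-133, b 138-233, b' 238-349, a' 370-471; plus Glu359 of the x-linker
#' between b' and a' registered as a named linker residue.
#'
#' @return A segmentation tibble (see [segmentation()]).
#' @export
hpdi_segmentation <- function() {
  segmentation(name = c("a", "b", "b'", "a'", "x"),
               first = c(22L, 138L, 238L, 370L, 359L),
               last = c(133L, 233L, 349L, 471L, 359L),
               type = c("domain", "domain", "domain", "domain", "linker"))
}

#' Active-site cysteine pairs of human PDI
#'
#' The two CGHC redox motifs: Cys53/Cys56 in domain a and Cys397/Cys400 in
#' domain a' (mature-hPDI numbering). `cys_c - cys_n = 3` for a CGHC motif.
#'
#' @return A tibble with columns `domain`, `cys_n`, `cys_c`.
#' @export
hpdi_active_sites <- function() {
  tibble(domain = c("a", "a'"), cys_n = c(53L, 397L), cys_c = c(56L, 400L))
}

seg_domains <- function(seg) seg$name[seg$type == "domain"]

seg_range <- function(seg, dom) {
  i <- match(dom, seg$name)
  if (is.na(i)) {
    abort(sprintf("unknown unit '%s' (have: %s)", dom,
                  paste(seg$name, collapse = ", ")),
          class = "interdom_key_error")
  }
  c(seg$first[i], seg$last[i])
}

# map residue numbers to the segmentation unit they fall in (NA if none);
# linker residues take precedence over any containing domain range
unit_of <- function(resno, seg) {
  out <- rep(NA_character_, length(resno))
  for (i in which(seg$type == "domain")) {
    out[resno >= seg$first[i] & resno <= seg$last[i]] <- seg$name[i]
  }
  for (i in which(seg$type == "linker")) {
    out[resno >= seg$first[i] & resno <= seg$last[i]] <- seg$name[i]
  }
  out
}

#' Select atoms by residue range and atom name
#'
#' @param frame A frame tibble.
#' @param range Inclusive `c(first, last)` residue-number range, or `NULL`
#'   for all residues.
#' @param atom_names Character vector of PDB atom names to keep; the default
#'   `"CA"` selects alpha-carbons, the convention used for domain centres
#'   and superposition. `NULL` keeps all atoms.
#' @param require_atoms Error when the selection is empty (callers that need
#'   geometry require a non-empty set).
#' @return A frame tibble subset (atom order preserved).
#' @export
select_atoms <- function(frame, range = NULL, atom_names = "CA",
                         require_atoms = TRUE) {
  fr <- as_frame(frame)
  keep <- rep(TRUE, nrow(fr))
  if (!is.null(range)) {
    keep <- keep & fr$residue_number >= range[1] & fr$residue_number <= range[2]
  }
  if (!is.null(atom_names)) keep <- keep & fr$atom_name %in% atom_names
  out <- fr[keep, , drop = FALSE]
  if (require_atoms && nrow(out) == 0) {
    abort(sprintf("empty atom selection (range %s, atoms %s)",
                  if (is.null(range)) "all" else paste(range, collapse = "-"),
                  if (is.null(atom_names)) "all" else
                    paste(atom_names, collapse = ",")),
          class = "interdom_selection_error")
  }
  out
}

# core selection for one named domain
domain_core_atoms <- function(frame, seg, dom, atom_names = "CA") {
  select_atoms(frame, seg_range(seg, dom), atom_names = atom_names)
}
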