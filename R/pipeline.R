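#' Configure a full inter-domain analysis run
#'
#' The defaults reproduce the package's hPDI conventions exactly: rigid-core
#' segmentation and CGHC active sites, 3.0 Angstrom strict salt-bridge
#' cutoff, alpha-carbon domain centres, automatic bridge-pair discovery.
#'
#' @param input Path to a (multi-model) PDB ensemble, or `NULL` when
#'   `topology`/`dcd` or `trajectory` is given.
#' @param topology,dcd Paths to a topology PDB plus binary DCD trajectory.
#' @param trajectory An in-memory trajectory tibble (takes precedence).
#' @param out_dir Output directory (created if missing).
#' @param seg Segmentation tibble; default [hpdi_segmentation()].
#' @param sites Active-site table or `NULL` to skip sulfur metrics.
#' @param threshold Salt-bridge cutoff in Angstrom (strict `<` unless
#'   `inclusive`).
#' @param inclusive Use `<=` for the bridge criterion.
#' @param pairs Bridge pairs to trace: a data frame with `res_pos`,
#'   `res_neg`, a TSV path, or `NULL` for auto-scan (trace every pair
#'   bridged in any frame).
#' @param center_atoms Atom-name filter defining domain centres (`"CA"` or
#'   a vector of names for heavy-atom mode).
#' @param seed Seed recorded in the manifest (analysis itself is
#'   deterministic).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(input = NULL, topology = NULL, dcd = NULL,
                            trajectory = NULL, out_dir = "interdom_out",
                            seg = hpdi_segmentation(),
                            sites = hpdi_active_sites(),
                            threshold = 3.0, inclusive = FALSE,
                            pairs = NULL, center_atoms = "CA", seed = 1L) {
  seg <- validate_segmentation(seg)
  if (is.character(pairs)) {
    pairs <- readr::read_tsv(pairs, show_col_types = FALSE, progress = FALSE)
  }
  if (!is.null(pairs) && !all(c("res_pos", "res_neg") %in% names(pairs))) {
    abort("pairs needs columns res_pos and res_neg",
          class = "interdom_config_error")
  }
  structure(list(input = input, topology = topology, dcd = dcd,
                 trajectory = trajectory, out_dir = out_dir, seg = seg,
                 sites = sites, threshold = threshold, inclusive = inclusive,
                 pairs = pairs, center_atoms = center_atoms,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from a flat key=value file
#'
#' Recognised keys: `input`, `topology`, `dcd`, `out_dir`, `threshold`,
#' `center_atoms` (comma-separated), `pairs` (TSV path or `auto`), `seed`,
#' `segmentation` (e.g. `a:22-133,b:138-233,b':238-349,a':370-471`),
#' `sulfur` (`on`/`off`). Unknown keys raise an error naming the key.
#'
#' @param path Config file path.
#' @return An `analysis_config` list.
#' @export
read_analysis_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="),
                        character(1)))
  known <- c("input", "topology", "dcd", "out_dir", "threshold",
             "center_atoms", "pairs", "seed", "segmentation", "sulfur")
  bad <- setdiff(keys, known)
  if (length(bad) > 0) {
    abort(sprintf("unknown config key '%s'", bad[1]),
          class = "interdom_config_error")
  }
  get <- function(k, default = NULL) if (k %in% keys) vals[match(k, keys)]
    else default
  seg <- hpdi_segmentation()
  if (!is.null(get("segmentation"))) {
    parts <- strsplit(strsplit(get("segmentation"), ",")[[1]], ":")
    nm <- vapply(parts, `[`, character(1), 1)
    rng <- strsplit(vapply(parts, `[`, character(1), 2), "-")
    seg <- segmentation(trimws(nm),
                        as.integer(vapply(rng, `[`, character(1), 1)),
                        as.integer(vapply(rng, `[`, character(1), 2)))
  }
  pairs <- get("pairs")
  if (!is.null(pairs) && identical(pairs, "auto")) pairs <- NULL
  analysis_config(
    input = get("input"), topology = get("topology"), dcd = get("dcd"),
    out_dir = get("out_dir", "interdom_out"), seg = seg,
    sites = if (identical(get("sulfur", "on"), "off")) NULL
      else hpdi_active_sites(),
    threshold = as.numeric(get("threshold", "3.0")),
    pairs = pairs,
    center_atoms = strsplit(get("center_atoms", "CA"), ",")[[1]],
    seed = as.integer(get("seed", "1")))
}

#' Run the full inter-domain analysis
#'
#' Reads the configured trajectory and emits, in `out_dir`:
#' `domain_rmsd.tsv` (per-domain rigid-core RMSD series),
#' `endpoint_rmsd.tsv` (whole-molecule RMSD against the first and last
#' frames), `centers_metrics.tsv` (all centre distances, angles and the
#' dihedral), `salt_bridges.tsv` and `occupancy.json` (per-pair closest
#' distance time courses and bridge occupancies), `sulfur_distance.tsv`
#' (active-site sulfur proximity), `compactness_report.json`, and
#' `manifest.json` recording the configuration, package version and
#' geometric conventions. Frame indices are 0-based throughout. Any stage
#' failure removes the partial outputs of this run and re-raises the error
#' with the stage name.
#'
#' @param config An [analysis_config()].
#' @return The output directory path, invisibly.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(name, writer) {
    path <- file.path(out, name)
    writer(path)
    written <<- c(written, path)
    path
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      unlink(written)
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            class = "interdom_stage_error", parent = e)
    })
  }
  traj <- stage("read_input", {
    if (!is.null(config$trajectory)) config$trajectory
    else if (!is.null(config$topology) && !is.null(config$dcd))
      read_dcd_trajectory(config$topology, config$dcd)
    else if (!is.null(config$input)) read_pdb_ensemble(config$input)
    else abort("no input configured", class = "interdom_config_error")
  })
  seg <- config$seg
  doms <- seg_domains(seg)
  safe <- function(x) gsub("'", "p", x)

  stage("domain_rmsd", {
    cols <- lapply(doms, function(d) {
      rng <- seg_range(seg, d)
      rmsd_series(traj, align = seq(rng[1], rng[2]),
                  atom_names = config$center_atoms)$rmsd
    })
    tab <- as_tibble(setNames(cols, paste0("rmsd_", safe(doms))))
    tab$frame <- sort(unique(traj$frame))
    emit("domain_rmsd.tsv", function(p) write_timeseries(tab, p))
  })

  stage("endpoint_rmsd", {
    nf <- n_frames(traj)
    r0 <- rmsd_series(traj, align = NULL, atom_names = config$center_atoms,
                      reference = 0)
    rl <- rmsd_series(traj, align = NULL, atom_names = config$center_atoms,
                      reference = nf - 1)
    tab <- tibble(frame = r0$frame, rmsd_vs_initial = r0$rmsd,
                  rmsd_vs_final = rl$rmsd)
    emit("endpoint_rmsd.tsv", function(p) write_timeseries(tab, p))
  })

  metrics <- stage("center_metrics", {
    met <- domain_metrics(traj, seg, atom_names = config$center_atoms)
    emit("centers_metrics.tsv", function(p) write_timeseries(met, p))
    met
  })

  stage("salt_bridges", {
    pairs <- config$pairs
    if (is.null(pairs)) {
      found <- lapply(traj_split(traj), function(fr) {
        detect_salt_bridges(fr, seg, threshold = config$threshold,
                            inclusive = config$inclusive)
      })
      pairs <- distinct(bind_rows(found)[, c("res_pos", "res_neg")])
    }
    pairs <- as_tibble(pairs)
    if (nrow(pairs) > 0) {
      series <- salt_bridge_series(traj, pairs, threshold = config$threshold,
                                   inclusive = config$inclusive)
      occ <- bridge_occupancy(series)
    } else {
      series <- tibble(res_pos = integer(), res_neg = integer(),
                       frame = integer(), min_distance = numeric(),
                       bridged = logical())
      occ <- tibble(res_pos = integer(), res_neg = integer(),
                    n_frames = integer(), occupancy = numeric())
    }
    emit("salt_bridges.tsv", function(p) readr::write_tsv(series, p))
    emit("occupancy.json", function(p)
      jsonlite::write_json(occ, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE))
  })

  sulfur <- stage("sulfur_distance", {
    if (is.null(config$sites)) NULL else {
      ss <- sulfur_distance_series(traj, config$sites)
      emit("sulfur_distance.tsv", function(p) write_timeseries(ss, p))
      ss
    }
  })

  stage("compactness_report", {
    met <- metrics
    if (!is.null(sulfur)) met <- left_join(met, sulfur, by = "frame")
    summary <- summarise_metrics(met)
    rep <- list(n_frames = n_frames(traj), summary = summary,
                conventions = report_conventions(config$center_atoms,
                                                 config$threshold,
                                                 config$inclusive))
    emit("compactness_report.json", function(p)
      jsonlite::write_json(rep, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE))
  })

  stage("manifest", {
    manifest <- list(
      package = "interdom",
      version = as.character(utils::packageVersion("interdom")),
      config = list(input = config$input, topology = config$topology,
                    dcd = config$dcd,
                    in_memory_trajectory = !is.null(config$trajectory),
                    threshold_angstrom = config$threshold,
                    threshold_strict = !config$inclusive,
                    center_atoms = config$center_atoms,
                    pairs_mode = if (is.null(config$pairs)) "auto-scan"
                      else "explicit",
                    seed = config$seed),
      segmentation = config$seg,
      conventions = report_conventions(config$center_atoms, config$threshold,
                                       config$inclusive),
      outputs = basename(written))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  invisible(out)
}

#' Recompute the compactness summary from emitted TSV series
#'
#' Reads `centers_metrics.tsv` (and `sulfur_distance.tsv` when present)
#' from an analysis output directory and recomputes the per-metric summary.
#' Because the report is a pure summary of the emitted series, the result
#' equals the pipeline's own `compactness_report.json` summary.
#'
#' @param dir An output directory produced by [run_full_analysis()].
#' @return The per-metric summary tibble.
#' @export
recompute_report <- function(dir) {
  met <- read_timeseries(file.path(dir, "centers_metrics.tsv"))
  sp <- file.path(dir, "sulfur_distance.tsv")
  if (file.exists(sp)) {
    met <- left_join(met, read_timeseries(sp), by = "frame")
  }
  summarise_metrics(met)
}
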