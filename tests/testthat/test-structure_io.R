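test_that("a single ATOM line parses into one frame with exact fields", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_text(f, list(pdb_line(1, "CA", "ALA", "A", 22, 1, 2, 3)))
  tr <- read_pdb_ensemble(f)
  expect_equal(n_frames(tr), 1L)
  fr <- get_frame(tr, 0)
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$atom_name, "CA")
  expect_equal(fr$residue_name, "ALA")
  expect_equal(fr$residue_number, 22L)
  expect_equal(c(fr$x, fr$y, fr$z), c(1, 2, 3))
})

test_that("multi-model files give one frame per MODEL with a shared roster", {
  lines <- c(pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
             pdb_line(2, "CA", "GLY", "A", 2, 3, 0, 0))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_text(f, list(lines, lines))
  tr <- read_pdb_ensemble(f)
  expect_equal(n_frames(tr), 2L)
  expect_equal(nrow(get_frame(tr, 0)), nrow(get_frame(tr, 1)))
  expect_equal(get_frame(tr, 0), get_frame(tr, 1))
})

test_that("generator output survives a PDB write/read round trip to 1e-3", {
  model <- default_toy_model()
  sim <- generate_hinge_trajectory(model, motion_spec(n_frames = 3))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_ensemble(sim$trajectory, f)
  back <- read_pdb_ensemble(f)
  expect_equal(n_frames(back), 3L)
  expect_equal(back$atom_name, sim$trajectory$atom_name)
  expect_equal(back$residue_number, sim$trajectory$residue_number)
  for (cc in c("x", "y", "z")) {
    expect_lt(max(abs(back[[cc]] - sim$trajectory[[cc]])), 1e-3 + 1e-12)
  }
})

test_that("malformed coordinate lines are rejected with the line number", {
  f <- withr::local_tempfile(fileext = ".pdb")
  good <- pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0)
  bad <- sub("   0.000", "  badnum", pdb_line(2, "CA", "GLY", "A", 2, 0, 0, 0),
             fixed = TRUE)
  writeLines(c(good, bad, "END"), f)
  err <- expect_error(read_pdb_ensemble(f), class = "interdom_parse_error")
  expect_match(conditionMessage(err), "line 2")
})

test_that("an inconsistent roster across models names the first mismatch", {
  m1 <- c(pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
          pdb_line(2, "CA", "GLY", "A", 2, 3, 0, 0))
  m2 <- c(pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
          pdb_line(2, "CB", "GLY", "A", 2, 3, 0, 0))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_text(f, list(m1, m2))
  err <- expect_error(read_pdb_ensemble(f), class = "interdom_roster_error")
  expect_match(conditionMessage(err), "atom 2")
})

test_that("insertion codes are rejected", {
  f <- withr::local_tempfile(fileext = ".pdb")
  ln <- pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0)
  substr(ln, 27, 27) <- "A"
  writeLines(c(ln, "END"), f)
  expect_error(read_pdb_ensemble(f), class = "interdom_parse_error")
})

test_that("altloc conformers collapse to the highest-occupancy one", {
  f <- withr::local_tempfile(fileext = ".pdb")
  l1 <- pdb_line(1, "CA", "ALA", "A", 5, 1, 0, 0, occ = 0.4)
  l2 <- pdb_line(2, "CA", "ALA", "A", 5, 2, 0, 0, occ = 0.6)
  substr(l1, 17, 17) <- "A"
  substr(l2, 17, 17) <- "B"
  writeLines(c(l1, l2, "END"), f)
  fr <- get_frame(read_pdb_ensemble(f), 0)
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$x, 2)
})

test_that("waters and ions are dropped unless kept explicitly", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
               pdb_line(2, "O", "HOH", "A", 90, 5, 5, 5, record = "HETATM"),
               "END"), f)
  expect_equal(nrow(get_frame(read_pdb_ensemble(f), 0)), 1L)
  expect_equal(nrow(get_frame(read_pdb_ensemble(f, keep_waters = TRUE), 0)), 2L)
})

test_that("DCD round trips preserve frames, order and roster", {
  model <- default_toy_model()
  sim <- generate_hinge_trajectory(model, motion_spec(n_frames = 100))
  top <- withr::local_tempfile(fileext = ".pdb")
  dcd <- withr::local_tempfile(fileext = ".dcd")
  write_pdb_ensemble(new_trajectory(list(get_frame(sim$trajectory, 0))), top)
  write_dcd(sim$trajectory, dcd)
  back <- read_dcd_trajectory(top, dcd)
  expect_equal(n_frames(back), 100L)
  expect_equal(back$atom_name, sim$trajectory$atom_name)
  # float32 storage: ~1e-5 absolute at these coordinate magnitudes
  expect_lt(max(abs(back$x - sim$trajectory$x)), 1e-4)
  expect_lt(max(abs(back$z - sim$trajectory$z)), 1e-4)
})

test_that("a 1-frame DCD equals its topology PDB frame", {
  fr <- make_frame(c("CA", "CA", "CA", "CA"), 1:4,
                   c(0, 3, 0, 1), c(0, 0, 4, 1), c(0, 0, 0, 2))
  top <- withr::local_tempfile(fileext = ".pdb")
  dcd <- withr::local_tempfile(fileext = ".dcd")
  tr <- new_trajectory(list(fr))
  write_pdb_ensemble(tr, top)
  write_dcd(tr, dcd)
  back <- read_dcd_trajectory(top, dcd)
  expect_equal(n_frames(back), 1L)
  b0 <- get_frame(back, 0)
  expect_lt(max(abs(coords_matrix(b0) - coords_matrix(fr))), 1e-5)
})

test_that("empty, truncated and mismatched DCDs fail informatively", {
  fr <- make_frame(rep("CA", 4), 1:4, rnorm(4), rnorm(4), rnorm(4))
  tr <- new_trajectory(list(fr, fr, fr))
  top <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_ensemble(new_trajectory(list(fr)), top)

  f0 <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(new_trajectory(list(fr)), f0)

  empty <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(new_trajectory(list(fr)), empty, n_frames_declared = 0)
  con <- file(empty, "r+b")
  seek(con, 196, rw = "write")  # keep the three header records only
  truncate(con)
  close(con)
  err0 <- expect_error(read_dcd_trajectory(top, empty),
                       class = "interdom_format_error")
  expect_match(conditionMessage(err0), "no frames")

  truncated <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(tr, truncated)
  sz <- file.info(truncated)$size
  con <- file(truncated, "r+b")
  seek(con, sz - 30, rw = "write")
  truncate(con)
  close(con)
  err <- expect_error(read_dcd_trajectory(top, truncated),
                      class = "interdom_format_error")
  expect_match(conditionMessage(err), "frame 2")

  top8 <- withr::local_tempfile(fileext = ".pdb")
  fr8 <- make_frame(rep("CA", 8), 1:8, rnorm(8), rnorm(8), rnorm(8))
  write_pdb_ensemble(new_trajectory(list(fr8)), top8)
  expect_error(read_dcd_trajectory(top8, f0),
               class = "interdom_topology_error")
})

test_that("time-series TSVs count rows and round-trip values", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_timeseries(list(dist_a_b = c(5, 5)), f)
  expect_length(readLines(f), 3L)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_timeseries(list(), f2)
  expect_length(readLines(f2), 1L)

  withr::with_seed(7, {
    tab <- tibble::tibble(a = rnorm(1000) * 100, b = runif(1000, -1, 1))
  })
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_timeseries(tab, f3)
  back <- read_timeseries(f3)
  expect_equal(back$frame, 0:999)
  expect_equal(back$a, tab$a, tolerance = 1e-7)
  expect_equal(back$b, tab$b, tolerance = 1e-7)

  expect_error(write_timeseries(list(a = 1:3, b = 1:2), f3),
               class = "interdom_shape_error")
})
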