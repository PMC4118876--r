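charged_pair_frame <- function(d_nz_oe1 = 2.5) {
  # LYS 10 and GLU 20 with one close atom pair and farther decoys
  new_frame(tibble::tibble(
    atom_name = c("CA", "NZ", "CA", "OE1", "OE2"),
    residue_name = c("LYS", "LYS", "GLU", "GLU", "GLU"),
    residue_number = c(10L, 10L, 20L, 20L, 20L),
    x = c(-2, 0, 10, d_nz_oe1, 8),
    y = c(0, 0, 0, 0, 0), z = c(0, 0, 0, 0, 0)))
}

test_that("residue closest distance takes the minimum pair and is symmetric", {
  fr <- charged_pair_frame(2.5)
  expect_equal(residue_min_distance(fr, 10, 20), 2.5)
  expect_equal(residue_min_distance(fr, 20, 10), 2.5)
  withr::with_seed(23, {
    big <- random_charged_frame(12, box = 10)
  })
  charged <- big[big$atom_name != "CA", ]
  ids <- unique(charged$residue_number)
  expect_gte(length(ids), 4L)
  for (pair in list(ids[1:2], ids[2:3], ids[3:4])) {
    ra <- pair[1]
    rb <- pair[2]
    A <- charged[charged$residue_number == ra, ]
    B <- charged[charged$residue_number == rb, ]
    brute <- Inf
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
      brute <- min(brute, sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 +
                                 (A$z[i] - B$z[j])^2))
    }
    expect_lt(abs(residue_min_distance(big, ra, rb) - brute), 1e-12)
  }
  expect_error(residue_min_distance(fr, 10, 99),
               class = "interdom_missing_atom_error")
})

test_that("the bridge criterion is strict at the 3.0 A boundary", {
  seg <- segmentation(c("d1", "d2"), c(1, 15), c(14, 30))
  below <- charged_pair_frame(2.9)
  hits <- detect_salt_bridges(below, seg)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$res_pos, 10L)
  expect_equal(hits$res_neg, 20L)
  expect_true(hits$bridged)
  expect_equal(hits$min_distance, 2.9)

  at_threshold <- charged_pair_frame(3.0)
  expect_equal(nrow(detect_salt_bridges(at_threshold, seg)), 0L)
  expect_equal(nrow(detect_salt_bridges(at_threshold, seg, inclusive = TRUE)),
               1L)
})

test_that("intra-unit pairs are excluded unless asked for", {
  seg <- segmentation("d1", 1, 30)
  fr <- charged_pair_frame(2.5)
  expect_equal(nrow(detect_salt_bridges(fr, seg)), 0L)
  expect_equal(nrow(detect_salt_bridges(fr, seg, inter_domain_only = FALSE)),
               1L)
})

test_that("a linker residue counts as its own unit", {
  seg <- hpdi_segmentation()
  fr <- new_frame(tibble::tibble(
    atom_name = c("CA", "NZ", "CA", "OE1"),
    residue_name = c("LYS", "LYS", "GLU", "GLU"),
    residue_number = c(308L, 308L, 359L, 359L),
    x = c(0, 1, 5, 3.5), y = 0, z = 0))
  hits <- detect_salt_bridges(fr, seg)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$unit_pos, "b'")
  expect_equal(hits$unit_neg, "x")
})

test_that("detection equals the exhaustive atom-pair oracle on random toys", {
  withr::with_seed(29, {
    for (rep in 1:20) {
      n <- sample(10:50, 1)
      fr <- random_charged_frame(n, box = runif(1, 10, 22))
      seg <- two_domain_seg(n)
      got <- detect_salt_bridges(fr, seg)
      want <- bf_salt_bridges(fr, seg)
      expect_equal(nrow(got), nrow(want))
      if (nrow(want) > 0) {
        expect_equal(got$res_pos, want$res_pos)
        expect_equal(got$res_neg, want$res_neg)
        expect_lt(max(abs(got$min_distance - want$min_distance)), 1e-12)
      }
    }
  })
})

test_that("bridge detection is invariant under rigid transforms", {
  withr::with_seed(31, {
    fr <- random_charged_frame(24, box = 14)
    R <- random_rotation_matrix(); t <- rnorm(3, sd = 40)
  })
  seg <- two_domain_seg(24)
  a <- detect_salt_bridges(fr, seg)
  b <- detect_salt_bridges(transform_coords(fr, R, t), seg)
  expect_equal(a$res_pos, b$res_pos)
  expect_equal(a$res_neg, b$res_neg)
  if (nrow(a) > 0) expect_lt(max(abs(a$min_distance - b$min_distance)), 1e-9)
})

test_that("bridge series occupancy follows the schedule and is monotone", {
  fr28 <- charged_pair_frame(2.8)
  static <- new_trajectory(lapply(1:4, function(i) fr28))
  ser <- salt_bridge_series(static, tibble::tibble(res_pos = 10, res_neg = 20))
  expect_equal(bridge_occupancy(ser)$occupancy, 1)

  model <- default_toy_model()
  sim <- generate_hinge_trajectory(model, motion_spec(
    n_frames = 200,
    contacts = tibble::tibble(res_pos = 326L, res_neg = 431L,
                              from = 50L, to = 99L, distance = 2.8)))
  ser2 <- salt_bridge_series(sim$trajectory,
                             tibble::tibble(res_pos = 326, res_neg = 431))
  expect_equal(bridge_occupancy(ser2)$occupancy, 0.25)
  # occupancy can only grow with a looser threshold
  for (pair_thresholds in list(c(3.0, 3.5), c(2.0, 3.0))) {
    o1 <- mean(ser2$min_distance < pair_thresholds[1])
    o2 <- mean(ser2$min_distance < pair_thresholds[2])
    expect_gte(o2, o1)
  }
})

test_that("re-measuring a reported bridge reproduces its stored distance", {
  withr::with_seed(37, fr <- random_charged_frame(40, box = 16))
  seg <- two_domain_seg(40)
  hits <- detect_salt_bridges(fr, seg)
  for (i in seq_len(nrow(hits))) {
    expect_lt(abs(residue_min_distance(fr, hits$res_pos[i], hits$res_neg[i]) -
                    hits$min_distance[i]), 1e-12)
  }
})

test_that("cation-pi detection applies both distance and angle criteria", {
  hexagon <- function(center = c(0, 0, 0)) {
    th <- seq(0, by = pi / 3, length.out = 6)
    tibble::tibble(
      atom_name = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
      residue_name = "TRP", residue_number = 396L,
      x = center[1] + 1.4 * cos(th), y = center[2] + 1.4 * sin(th),
      z = center[3])
  }
  arg_at <- function(p) tibble::tibble(
    atom_name = "CZ", residue_name = "ARG", residue_number = 300L,
    x = p[1], y = p[2], z = p[3])

  on_axis <- new_frame(dplyr::bind_rows(hexagon(), arg_at(c(0, 0, 4.5))))
  hit <- detect_cation_pi(on_axis)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$distance, 4.5, tolerance = 1e-9)
  expect_equal(hit$angle, 0, tolerance = 1e-6)

  far <- new_frame(dplyr::bind_rows(hexagon(), arg_at(c(0, 0, 8))))
  expect_equal(nrow(detect_cation_pi(far)), 0L)

  in_plane <- new_frame(dplyr::bind_rows(hexagon(), arg_at(c(4.5, 0, 0))))
  expect_equal(nrow(detect_cation_pi(in_plane)), 0L)

  broken <- new_frame(dplyr::bind_rows(hexagon()[-1, ], arg_at(c(0, 0, 4.5))))
  expect_error(detect_cation_pi(broken), class = "interdom_missing_atom_error")
})
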