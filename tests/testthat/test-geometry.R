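test_that("geometric centres equal the coordinate-wise mean", {
  one <- make_frame("CA", 1, 1, 2, 3)
  expect_equal(unname(geometric_center(one)), c(1, 2, 3))
  two <- make_frame(c("CA", "CA"), 1:2, c(0, 2), c(0, 0), c(0, 0))
  expect_equal(unname(geometric_center(two)), c(1, 0, 0))
  withr::with_seed(3, {
    m <- matrix(rnorm(150), ncol = 3)
  })
  fr <- make_frame(rep("CA", 50), 1:50, m[, 1], m[, 2], m[, 3])
  # brute-force mean oracle
  expect_lt(max(abs(geometric_center(fr) -
                      apply(m, 2, function(v) sum(v) / length(v)))), 1e-12)
  expect_error(geometric_center(fr[0, ]), class = "interdom_selection_error")
})

test_that("centre distances are Euclidean, symmetric and rigid-invariant", {
  seg <- segmentation(c("d1", "d2"), c(1, 2), c(1, 2))
  fr <- make_frame(c("CA", "CA"), 1:2, c(0, 3), c(0, 4), c(0, 0))
  expect_equal(center_distance(fr, seg, "d1", "d2"), 5)
  expect_equal(center_distance(fr, seg, "d2", "d1"), 5)
  withr::with_seed(11, {
    R <- random_rotation_matrix(); t <- rnorm(3, sd = 20)
  })
  fr2 <- transform_coords(fr, R, t)
  expect_lt(abs(center_distance(fr2, seg, "d1", "d2") - 5), 1e-9)
  expect_error(center_distance(fr, seg, "d1", "zz"),
               class = "interdom_key_error")
})

test_that("inter-domain angles use the middle domain as vertex", {
  seg <- segmentation(c("d1", "d2", "d3"), 1:3, 1:3)
  fr <- make_frame(rep("CA", 3), 1:3, c(1, 0, 0), c(0, 0, 1), c(0, 0, 0))
  expect_equal(inter_domain_angle(fr, seg, "d1", "d2", "d3"), 90)
  col <- make_frame(rep("CA", 3), 1:3, c(-1, 0, 2), c(0, 0, 0), c(0, 0, 0))
  expect_equal(inter_domain_angle(col, seg, "d1", "d2", "d3"), 180)
  same <- make_frame(rep("CA", 3), 1:3, c(0, 0, 1), c(0, 0, 0), c(0, 0, 0))
  expect_error(inter_domain_angle(same, seg, "d1", "d2", "d3"),
               class = "interdom_geometry_error")
})

test_that("the four-centre dihedral follows the IUPAC sign convention", {
  seg <- segmentation(c("d1", "d2", "d3", "d4"), 1:4, 1:4)
  canon <- make_frame(rep("CA", 4), 1:4,
                      c(0, 1, 1, 1), c(0, 0, 1, 1), c(0, 0, 0, 1))
  expect_equal(four_domain_dihedral(canon, seg), 90)
  planar <- make_frame(rep("CA", 4), 1:4,
                       c(0, 1, 1, 0), c(0, 0, 1, 1), c(0, 0, 0, 0))
  expect_equal(four_domain_dihedral(planar, seg), 0)
  # mirror reflection flips the sign, preserves the magnitude
  mirrored <- canon
  mirrored$x <- -mirrored$x
  expect_equal(four_domain_dihedral(mirrored, seg), -90)
  collinear <- make_frame(rep("CA", 4), 1:4,
                          c(0, 1, 2, 2), c(0, 0, 0, 1), c(0, 0, 0, 0))
  expect_error(four_domain_dihedral(collinear, seg),
               class = "interdom_geometry_error")
})

test_that("Kabsch superposition recovers exact transforms and minimises RMSD", {
  withr::with_seed(5, {
    P <- matrix(rnorm(60, sd = 10), ncol = 3)
    R <- rot_axis(c(0, 0, 1), 30)
    t <- c(4, -2, 7)
    Q <- sweep(P %*% t(R), 2, t, `+`)
  })
  self <- kabsch_superpose(P, P)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)

  fit <- kabsch_superpose(P, Q)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(fit$rotation, R, tolerance = 1e-9)
  expect_equal(fit$translation, t, tolerance = 1e-8)

  # noisy pair: fitted RMSD is a minimum and matches the quaternion oracle
  withr::with_seed(6, {
    Qn <- Q + matrix(rnorm(60, sd = 0.5), ncol = 3)
    fitn <- kabsch_superpose(P, Qn)
    expect_lte(fitn$rmsd, rmsd_raw(P, Qn))
    expect_lt(abs(fitn$rmsd - quaternion_superpose(P, Qn)$rmsd), 1e-9)
    for (i in 1:20) {
      pert <- fitn$rotation %*% rot_axis(rnorm(3), runif(1, 0.1, 10))
      Pp <- sweep(P %*% t(pert), 2, fitn$translation, `+`)
      expect_gte(rmsd_raw(Pp, Qn) + 1e-12, fitn$rmsd)
    }
  })

  expect_error(kabsch_superpose(P[1:2, ], Q[1:2, ]),
               class = "interdom_geometry_error")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_superpose(line, line),
               class = "interdom_geometry_error")
})

test_that("mirror-image inputs still yield a proper rotation", {
  withr::with_seed(8, P <- matrix(rnorm(45, sd = 5), ncol = 3))
  Q <- P
  Q[, 1] <- -Q[, 1]
  fit <- kabsch_superpose(P, Q)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_gt(fit$rmsd, 0)
})

test_that("RMSD series vanish for identity and pure rigid motion", {
  model <- default_toy_model()
  sim <- generate_hinge_trajectory(model, motion_spec(
    n_frames = 5, dist_a_bp = 45, dist_a_ap = 55, angle_a_b_bp = 110,
    dihedral = 60, sulfur = 20, contacts = NULL))
  static <- sim$trajectory
  rs <- rmsd_series(static, align = NULL)
  expect_lt(max(rs$rmsd), 1e-9)

  withr::with_seed(13, {
    frames <- lapply(0:4, function(i) {
      transform_coords(get_frame(static, 0), random_rotation_matrix(),
                       rnorm(3, sd = 30))
    })
  })
  moving <- new_trajectory(frames)
  rs2 <- rmsd_series(moving, align = NULL)
  expect_lt(max(rs2$rmsd), 1e-6)
})

test_that("aligning on one domain isolates the other domain's displacement", {
  model <- default_toy_model()
  sim <- generate_hinge_trajectory(model, motion_spec(n_frames = 15))
  seg <- model$segmentation
  rs <- rmsd_series(sim$trajectory,
                    align = seq(138, 233),   # domain b core
                    measure = seq(22, 133))  # domain a core
  cen <- sim$truth$centers
  a0 <- unlist(cen[cen$frame == 0 & cen$domain == "a", c("cx", "cy", "cz")])
  expected <- vapply(0:14, function(t) {
    at <- unlist(cen[cen$frame == t & cen$domain == "a", c("cx", "cy", "cz")])
    sqrt(sum((at - a0)^2))
  }, numeric(1))
  expect_lt(max(abs(rs$rmsd - expected)), 1e-6)
  expect_equal(rs$rmsd[1], 0, tolerance = 1e-9)
})

test_that("relative domain rotation is recovered and symmetric", {
  model <- default_toy_model()
  seg <- model$segmentation
  fa <- model$frame
  expect_equal(rotation_angle_between(fa, fa, seg, "b", "b'"), 0,
               tolerance = 1e-9)
  withr::with_seed(17, {
    axis <- rnorm(3)
    Rb <- rot_axis(axis, 20)
    glob_R <- random_rotation_matrix()
    glob_t <- rnorm(3, sd = 15)
  })
  fb <- fa
  bp <- fb$residue_number >= 238 & fb$residue_number <= 349
  centre <- geometric_center(select_atoms(fa, c(238, 349)))
  m <- coords_matrix(fb[bp, ])
  m <- sweep(sweep(m, 2, centre) %*% t(Rb), 2, centre, `+`)
  fb$x[bp] <- m[, 1]; fb$y[bp] <- m[, 2]; fb$z[bp] <- m[, 3]
  fb <- transform_coords(fb, glob_R, glob_t)
  expect_equal(rotation_angle_between(fa, fb, seg, "b", "b'"), 20,
               tolerance = 1e-6)
  expect_lt(abs(rotation_angle_between(fa, fb, seg, "b", "b'") -
                  rotation_angle_between(fb, fa, seg, "b", "b'")), 1e-9)
})

test_that("all centre metrics are invariant under global rigid transforms", {
  model <- default_toy_model()
  sim <- generate_hinge_trajectory(model, motion_spec(n_frames = 2))
  fr <- get_frame(sim$trajectory, 1)
  seg <- model$segmentation
  withr::with_seed(19, {
    R <- random_rotation_matrix(); t <- rnorm(3, sd = 50)
  })
  fr2 <- transform_coords(fr, R, t)
  expect_lt(abs(center_distance(fr, seg, "a", "b'") -
                  center_distance(fr2, seg, "a", "b'")), 1e-9)
  expect_lt(abs(inter_domain_angle(fr, seg, "a", "b", "b'") -
                  inter_domain_angle(fr2, seg, "a", "b", "b'")), 1e-9)
  expect_lt(abs(four_domain_dihedral(fr, seg) -
                  four_domain_dihedral(fr2, seg)), 1e-9)
  expect_lt(abs(min_sulfur_distance(fr) - min_sulfur_distance(fr2)), 1e-9)
})
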