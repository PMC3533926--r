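test_that("canonical conformations give canonical dihedrals", {
  h <- build_ideal_helix(20)
  d <- backbone_dihedrals(h)
  expect_true(all(abs(d$psi[3:17] - (-47)) < 3))
  expect_true(all(abs(d$phi[3:17] - (-57.8)) < 3))
  expect_true(is.na(d$phi[1L]) && is.na(d$psi[20L]))

  ext <- build_extended_chain(12)
  de <- backbone_dihedrals(ext)
  expect_true(all(abs(de$psi[2:11]) > 120))
})

test_that("dihedrals match the bio3d torsion reference on random conformers", {
  set.seed(51)
  for (rep in 1:50) {
    n <- 6L
    bb <- tecdyn:::build_backbone(n, phi = runif(n, -180, 180),
                                  psi = runif(n, -180, 180))
    at <- tecdyn:::backbone_atom_table(bb, "A")
    s <- tec_structure(at)
    d <- backbone_dihedrals(s)
    xyz <- coords(s)
    for (i in 2:(n - 1L)) {
      Nn <- atom_index(s, sprintf("A:%d:N", i))
      CAn <- atom_index(s, sprintf("A:%d:CA", i))
      Cn <- atom_index(s, sprintf("A:%d:C", i))
      Nn1 <- atom_index(s, sprintf("A:%d:N", i + 1L))
      Cp <- atom_index(s, sprintf("A:%d:C", i - 1L))
      ref_phi <- bio3d::torsion.xyz(as.numeric(t(xyz[c(Cp, Nn, CAn, Cn), ])),
                                    atm.inc = 4)
      ref_psi <- bio3d::torsion.xyz(as.numeric(t(xyz[c(Nn, CAn, Cn, Nn1), ])),
                                    atm.inc = 4)
      expect_equal(d$phi[i], unname(ref_phi), tolerance = 1e-6)
      expect_equal(d$psi[i], unname(ref_psi), tolerance = 1e-6)
    }
  }
})

test_that("missing backbone atoms yield NA with a warning, not an abort", {
  h <- build_ideal_helix(8)
  h$atoms <- h$atoms[!(h$atoms$resid == 4 & h$atoms$name == "CA"), ]
  expect_warning(d <- backbone_dihedrals(h), "missing backbone")
  expect_true(is.na(d$phi[d$resid == 4]))
  expect_false(anyNA(d$psi[d$resid %in% c(6, 7)]))
})

test_that("delta psi is zero for static runs and wraps across 180", {
  fx <- small_toy(1)
  st <- static_traj(fx$structure, 5L)
  ds <- delta_psi_series(st, "A", 19)
  expect_equal(ds$value, rep(0, 5))

  # psi_ref = 170, psi_t = -170 must read +20, not -340
  n <- 6L
  bb <- tecdyn:::build_backbone(n, phi = -120, psi = 170)
  s <- tec_structure(tecdyn:::backbone_atom_table(bb, "A"))
  xyz <- coords(s)
  ca <- atom_index(s, "A:3:CA"); cc <- atom_index(s, "A:3:C")
  move <- which(s$atoms$resid > 3 | (s$atoms$resid == 3 & s$atoms$name == "O"))
  x2 <- xyz
  x2[move, ] <- tecdyn:::rotate_points(x2[move, , drop = FALSE], xyz[ca, ],
                                       xyz[cc, ] - xyz[ca, ], 20)
  tr <- tec_trajectory(s, list(xyz, x2))
  psi2 <- backbone_dihedrals(s, xyz = x2)$psi[3L]
  expect_equal(psi2, -170, tolerance = 1e-6)
  ds2 <- delta_psi_series(tr, "A", 3)
  expect_equal(ds2$value[2L], 20, tolerance = 1e-6)

  # wrap consistency: reversing the reference negates the series
  tr_rev <- tec_trajectory(s, list(x2, xyz))
  ds3 <- delta_psi_series(tr_rev, "A", 3)
  expect_equal(ds3$value[2L], -ds2$value[2L], tolerance = 1e-6)
  expect_true(all(ds2$value > -180 & ds2$value <= 180))
})

test_that("a scripted hinge opening plateaus at the planted angle", {
  p <- small_toy_params(seed = 6, n_frames = 60,
                        psi_schedule = list(c(19, 21, 35)),
                        noise_sigma = 0, translocation_drift = 0)
  s <- build_toy_tec(p)
  tr <- simulate_trajectory(s, p)
  ds <- delta_psi_series(tr, "A", 19)
  expect_equal(ds$value[1:20], rep(0, 20), tolerance = 1e-8)
  expect_true(all(abs(ds$value[21:60] - 35) < 1e-6))

  # with thermal noise the plateau is recovered as a baseline-subtracted
  # step within 3 degrees
  p2 <- small_toy_params(seed = 6, n_frames = 400,
                         psi_schedule = list(c(19, 201, 35)),
                         noise_sigma = 0.2, translocation_drift = 0)
  s2 <- build_toy_tec(p2)
  tr2 <- simulate_trajectory(s2, p2)
  ds2 <- delta_psi_series(tr2, "A", 19)
  step <- mean(ds2$value[201:400]) - mean(ds2$value[1:200])
  expect_equal(step, 35, tolerance = 3 / 35)
})

test_that("hinge definitions validate their flanks", {
  expect_error(hinge_definition("H1", "A", c(19, 19), c(16, 18), c(21, 34)),
               "at least 4")
  expect_error(hinge_definition("H1", "A", c(19, 19), c(5, 25), c(21, 34)),
               "disjoint")
})

test_that("bend angle: straight helix small, planted kink recovered, rigid-motion invariant", {
  hd <- hinge_definition("toy", "A", c(19, 19), c(5, 17), c(21, 34))
  p <- small_toy_params(seed = 7, n_frames = 30, noise_sigma = 0,
                        translocation_drift = 0,
                        bend_schedule = list(c(16, 30)))
  s <- build_toy_tec(p)
  tr <- simulate_trajectory(s, p)
  expect_lt(helix_bend_angle(s, hd), 5)
  bs <- bend_angle_series(tr, hd)
  expect_true(all(bs$value[1:15] < 5))
  expect_true(all(abs(bs$value[16:30] - 30) < 4))

  # invariance under a global rigid motion
  xyz <- tr$frames[[20L]]
  R <- tecdyn:::rotation_matrix(c(1, 2, 0.5), 73)
  moved <- sweep(xyz %*% t(R), 2L, c(5, -3, 8), "+")
  expect_equal(helix_bend_angle(s, hd, xyz = moved),
               helix_bend_angle(s, hd, xyz = xyz), tolerance = 1e-8)

  # noisy recovery stays inside the 4-degree band
  p2 <- small_toy_params(seed = 8, n_frames = 60, noise_sigma = 0.2,
                         translocation_drift = 0,
                         bend_schedule = list(c(31, 30)))
  s2 <- build_toy_tec(p2)
  tr2 <- simulate_trajectory(s2, p2)
  bs2 <- bend_angle_series(tr2, hd)
  expect_equal(mean(bs2$value[31:60]), 30, tolerance = 4 / 30)
})
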