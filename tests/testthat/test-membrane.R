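test_that("leaflet assignment splits phosphates about the midplane", {
  fr <- flat_bilayer_frame(n_side = 3, separation = 24)
  fr <- assign_leaflets(fr)
  po4 <- fr$beads[fr$beads$bead == "PO4", ]
  expect_setequal(unique(po4$leaflet), c("upper", "lower"))
  expect_equal(sum(po4$leaflet == "upper"), sum(po4$leaflet == "lower"))
  expect_true(all(po4$z[po4$leaflet == "upper"] >
                    po4$z[po4$leaflet == "lower"]))
})

test_that("a monolayer is rejected as not a bilayer", {
  fr <- flat_bilayer_frame(n_side = 3, separation = 24)
  mono <- cg_frame(fr$beads[fr$beads$z > 50, ], fr$box)
  expect_error(assign_leaflets(mono), class = "foldkit_input_error")
})

test_that("thickness of flat leaflets equals their separation", {
  fr <- flat_bilayer_frame(n_side = 4, separation = 23)
  expect_equal(membrane_thickness(fr), 23)
})

test_that("thickness is invariant to z-translation and z-reflection", {
  fr <- flat_bilayer_frame(n_side = 4, separation = 23)
  t0 <- membrane_thickness(fr)
  shifted <- fr
  shifted$beads$z <- shifted$beads$z + 7.3
  expect_equal(membrane_thickness(shifted), t0)
  reflected <- fr
  reflected$beads$z <- fr$box[3] - reflected$beads$z
  expect_equal(membrane_thickness(reflected), t0)
})

test_that("an underpopulated leaflet yields a missing thickness", {
  fr <- assign_leaflets(flat_bilayer_frame(n_side = 4, separation = 23))
  po4 <- fr$beads[fr$beads$bead == "PO4", ]
  upper_only <- po4$resid[po4$leaflet == "upper"]
  expect_true(is.na(membrane_thickness(fr, upper_only)))
})

test_that("order parameter limits match the closed form", {
  up <- bond_direction_frame(matrix(c(0, 0, 4.7), 1))
  expect_equal(order_parameters(up)$order_parameter, 1)
  flat <- bond_direction_frame(matrix(c(4.7, 0, 0), 1))
  expect_equal(order_parameters(flat)$order_parameter, -0.5)
  magic <- 54.7356103 * pi / 180
  mg <- bond_direction_frame(
    matrix(4.7 * c(sin(magic), 0, cos(magic)), 1))
  expect_true(all(abs(order_parameters(mg)$order_parameter) < 1e-6))
})

test_that("isotropic bonds average to S = 0", {
  set.seed(7)
  n <- 20000
  cth <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  dirs <- 4.7 * cbind(sqrt(1 - cth^2) * cos(phi),
                      sqrt(1 - cth^2) * sin(phi), cth)
  fr <- bond_direction_frame(dirs, box = c(2000, 2000, 200))
  s <- order_parameters(fr)$order_parameter
  mc_tol <- 3 * sqrt(1 / 5) / sqrt(n)
  expect_true(all(abs(s) < mc_tol))
})

test_that("cone-angle chains give S = P2(cos theta) exactly per bond", {
  set.seed(3)
  for (theta_c in c(10, 35, 60, 80)) {
    traj <- generate_bilayer_trajectory(
      chain_beads = 3, n_lipids_per_leaflet = 49, lattice_spacing = 9,
      protein_radius = 8, thinning_depth = 0,
      cone_angle_bulk = theta_c, cone_angle_seam = theta_c,
      positional_jitter = 0.3, n_frames = 1, n_replicas = 1, seed = 17)
    s <- order_parameters(traj$frame[[1]])
    expected <- 0.5 * (3 * cos(theta_c * pi / 180)^2 - 1)
    expect_equal(s$order_parameter, rep(expected, nrow(s)),
                 tolerance = 1e-10)
    expect_true(all(s$order_parameter >= -0.5 & s$order_parameter <= 1))
  }
})

test_that("annular selection boundaries are inclusive, bulk strict", {
  beads <- dplyr::bind_rows(
    tibble::tibble(kind = "lipid", resid = 1,
                   resname = "PC2",
                   bead = c("PO4", "GL1", "GL2", "C1A", "C1B"),
                   x = c(22, 22, 24, 22, 24), y = 10,
                   z = c(50, 47, 47, 43, 43)),
    tibble::tibble(kind = "protein", resid = 10L, resname = "BARL",
                   bead = "BB1", x = 10, y = 10, z = 50)
  )
  fr <- cg_frame(beads, c(60, 60, 100))
  # PO4 exactly 12 away from the anchor bead: included
  expect_equal(as.integer(select_lipids(fr, "near_residue",
                                        anchor_residue = 10, cutoff = 12)),
               1L)
  # exactly at the bulk cutoff: excluded (> is strict)
  expect_length(select_lipids(fr, "bulk", cutoff = 12), 0)
  expect_equal(as.integer(select_lipids(fr, "bulk", cutoff = 11.99)), 1L)
})

test_that("without protein every lipid is bulk", {
  fr <- flat_bilayer_frame(n_side = 3, separation = 23)
  sel <- select_lipids(fr, "bulk")
  expect_length(sel, 18)
})

test_that("unknown anchor residues are rejected", {
  fr <- flat_bilayer_frame(n_side = 3, separation = 23, protein = TRUE)
  expect_error(select_lipids(fr, "near_residue", anchor_residue = 123456),
               class = "foldkit_input_error")
})

test_that("selection agrees with the brute-force oracle on random frames", {
  for (s in 1:20) {
    fr <- random_frame(n_lipids = 30, n_protein_beads = 6, seed = s)
    n_lip <- 30
    for (anchor in c(n_lip + 1L, n_lip + 2L)) {
      fast <- as.integer(select_lipids(fr, "near_residue",
                                       anchor_residue = anchor,
                                       cutoff = 15))
      slow <- brute_force_select(fr, "near_residue", anchor, 15)
      expect_identical(fast, slow)
    }
    fast_bulk <- as.integer(select_lipids(fr, "bulk", cutoff = 20))
    slow_bulk <- brute_force_select(fr, "bulk", cutoff = 20)
    expect_identical(fast_bulk, slow_bulk)
  }
})

test_that("whole-lipid reference widens the annular selection", {
  fr <- random_frame(n_lipids = 40, n_protein_beads = 6, seed = 5)
  po4_sel <- select_lipids(fr, "near_residue", anchor_residue = 41L,
                           cutoff = 10)
  any_sel <- select_lipids(fr, "near_residue", anchor_residue = 41L,
                           cutoff = 10, lipid_reference = "any_bead")
  expect_true(all(as.integer(po4_sel) %in% as.integer(any_sel)))
})

test_that("profiles aggregate replicas with burn-in and sample SD", {
  # frames whose thickness encodes the frame index: burn-in arithmetic
  # is then directly observable in the replica mean
  frames <- lapply(1:30, function(i) {
    flat_bilayer_frame(n_side = 3, separation = 20 + i, box_z = 120)
  })
  traj <- as_trajectory(frames, times_us = (1:30) / 10)
  prof <- profile_trajectories(traj, anchors = c(),
                               burn_in_fraction = 1 / 6)
  th <- prof$summary[prof$summary$metric == "thickness", ]
  expect_equal(th$mean, mean(20 + 6:30))
  expect_equal(th$sd, 0)           # single replica
  expect_equal(th$n_replicas, 1L)
})

test_that("replicas with different chain topologies are rejected", {
  f2 <- flat_bilayer_frame(n_side = 3, separation = 23, chain_beads = 2)
  f3 <- flat_bilayer_frame(n_side = 3, separation = 23, chain_beads = 3)
  traj <- dplyr::bind_rows(as_trajectory(list(f2), replica = "a"),
                           as_trajectory(list(f3), replica = "b"))
  expect_error(profile_trajectories(traj, anchors = c(),
                                    burn_in_fraction = 0),
               class = "foldkit_input_error")
})
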