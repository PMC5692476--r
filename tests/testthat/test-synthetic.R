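test_that("transient generation is seed-reproducible", {
  a <- generate_transients(seed = 5, noise_fraction = 0.02)
  b <- generate_transients(seed = 5, noise_fraction = 0.02)
  expect_identical(a, b)
  c <- generate_transients(seed = 6, noise_fraction = 0.02)
  expect_false(identical(a$signal, c$signal))
})

test_that("noiseless generated transients round-trip through the fitter", {
  tr <- generate_transients(rates = 0.0149, noise_fraction = 0,
                            n_replicates = 2, seed = 1)
  fit <- fit_exponential_global(tr, 1)
  expect_equal(unname(fit$rates[["k1"]]), 0.0149, tolerance = 1e-6)
})

test_that("generated two-phase transients are classified as such", {
  tr <- generate_transients(model = "double_exp", rates = c(0.0346, 0.004),
                            amplitudes = c(-3, -3), offset = 7,
                            noise_fraction = 0.005, duration = 1500,
                            n_replicates = 1, seed = 2)
  sel <- select_exponential_model(tr)
  expect_equal(sel$n_exponentials, 2L)
})

test_that("the lag-sigmoid model produces a lag then a rise", {
  tr <- generate_transients(model = "lag_sigmoid", rates = 0.02,
                            amplitudes = 5, offset = 1, midpoint = 300,
                            noise_fraction = 0, n_replicates = 1)
  early <- tr$signal[tr$time_s <= 50]
  late <- tr$signal[tr$time_s >= 550]
  expect_lt(max(early) - min(early), 0.2)   # flat lag phase
  expect_gt(min(late), 5.5)                 # risen to near the plateau
  t50 <- extract_t50(tr)
  expect_equal(t50$t50, 300, tolerance = 1)
})

test_that("transient spec validation rejects malformed requests", {
  expect_error(generate_transients(rates = -1),
               class = "foldkit_input_error")
  expect_error(generate_transients(duration = 5, sample_interval = 1),
               class = "foldkit_input_error")
  expect_error(generate_transients(model = "double_exp", rates = 0.01),
               class = "foldkit_input_error")
})

test_that("bilayer trajectories are seed-reproducible", {
  a <- generate_bilayer_trajectory(n_frames = 2, n_replicas = 1, seed = 4)
  b <- generate_bilayer_trajectory(n_frames = 2, n_replicas = 1, seed = 4)
  expect_identical(a$frame[[1]]$beads, b$frame[[1]]$beads)
})

test_that("a homogeneous bilayer shows no seam/opposite/bulk contrast", {
  traj <- generate_bilayer_trajectory(
    thinning_depth = 0, cone_angle_seam = 20, cone_angle_bulk = 20,
    n_frames = 4, n_replicas = 2, seed = 9)
  gt <- attr(traj, "ground_truth")
  prof <- profile_trajectories(
    traj, anchors = c(seam = gt$seam_residue,
                      opposite = gt$opposite_residue),
    burn_in_fraction = 0.25)
  th <- prof$summary[prof$summary$metric == "thickness", ]
  expect_lt(max(th$mean) - min(th$mean), 0.5)
  op <- prof$summary[prof$summary$metric == "order_parameter", ]
  expect_lt(max(op$mean) - min(op$mean), 1e-6)
})

test_that("vertical chains give S = 1 on every bond", {
  traj <- generate_bilayer_trajectory(
    cone_angle_bulk = 0, cone_angle_seam = 0, thinning_depth = 0,
    n_frames = 1, n_replicas = 1, seed = 2)
  s <- order_parameters(traj$frame[[1]])
  expect_equal(s$order_parameter, rep(1, nrow(s)))
})

test_that("imposed seam thinning and disorder are recovered end to end", {
  for (cb in c(2L, 3L, 4L)) {
    traj <- generate_bilayer_trajectory(chain_beads = cb,
                                        n_frames = 4, n_replicas = 2,
                                        seed = 20 + cb)
    gt <- attr(traj, "ground_truth")
    prof <- profile_trajectories(
      traj, anchors = c(seam = gt$seam_residue,
                        opposite = gt$opposite_residue),
      burn_in_fraction = 0.25)
    s <- prof$summary
    n_bonds <- length(unique(s$bond[!is.na(s$bond)]))
    expect_equal(n_bonds, min(cb, 4))
    seam_th <- s$mean[s$selection == "seam" & s$metric == "thickness"]
    bulk_th <- s$mean[s$selection == "bulk" & s$metric == "thickness"]
    opp_th <- s$mean[s$selection == "opposite" & s$metric == "thickness"]
    expect_equal(seam_th, gt$seam_thickness, tolerance = 0.02)
    expect_equal(bulk_th, gt$bulk_thickness, tolerance = 0.02)
    expect_equal(opp_th, gt$bulk_thickness, tolerance = 0.02)
    seam_s <- s$mean[s$selection == "seam" & s$metric == "order_parameter"]
    bulk_s <- s$mean[s$selection == "bulk" & s$metric == "order_parameter"]
    expect_equal(seam_s, rep(gt$s_seam, n_bonds), tolerance = 1e-6)
    expect_equal(bulk_s, rep(gt$s_bulk, n_bonds), tolerance = 1e-4)
    expect_true(all(seam_s < bulk_s))
  }
})

test_that("oversized proteins are rejected", {
  expect_error(generate_bilayer_trajectory(protein_radius = 60,
                                           n_lipids_per_leaflet = 49,
                                           lattice_spacing = 8),
               class = "foldkit_input_error")
})
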