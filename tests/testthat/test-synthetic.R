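test_that("default membrane has 128 lipids, 64 per leaflet, with a percentage report", {
  mem <- build_membrane_topology(seed = 1)
  expect_equal(nrow(mem$topology), 128)
  expect_length(leaflet_atoms(mem$topology, "upper"), 64)
  expect_length(leaflet_atoms(mem$topology, "lower"), 64)
  expect_equal(unname(mem$percentages$upper["PC"]), 62.5)
  # class counts as requested
  expect_equal(sum(mem$topology$residue_name == "SSM"), 7)
  expect_equal(sum(mem$topology$residue_name == "DSPS"), 8)
  # SM only upper, PS only lower
  expect_true(all(mem$topology$leaflet[mem$topology$residue_name ==
                                         "SSM"] == "upper"))
  expect_true(all(mem$topology$leaflet[mem$topology$residue_name ==
                                         "DSPS"] == "lower"))
  # beads sit on the construction planes
  expect_true(all(mem$frame$positions[leaflet_atoms(mem$topology,
                                                    "upper"), 3] == 7.5))
})

test_that("lattice capacity and parameter validation are enforced", {
  expect_error(build_membrane_topology(
    membrane_composition(upper = c(PC = 500), lower = c(PC = 500)),
    box = c(6.4, 6.4, 10)), "capacity")
  expect_error(synthetic_params(D_bulk = 0), "D_bulk")
  expect_error(synthetic_params(core_halfwidth = 3, z_surface = 2.5),
               "core_halfwidth")
  expect_error(synthetic_params(dt = 0), "dt")
  # rms step larger than the well width is unstable
  p <- synthetic_params(dt = 1e6, well_depth = 3)
  sys <- drug_only_system(p)
  expect_error(simulate_adsorption(p, sys$topology, sys$frame),
               "unstable")
})

test_that("the generator is deterministic in its seed", {
  p <- synthetic_params(n_steps = 500, write_stride = 10, seed = 21)
  sys <- drug_only_system(p)
  t1 <- simulate_adsorption(p, sys$topology, sys$frame)
  t2 <- simulate_adsorption(p, sys$topology, sys$frame)
  expect_identical(t1$coords, t2$coords)
  p2 <- p
  p2$seed <- 22L
  t3 <- simulate_adsorption(p2, sys$topology, sys$frame)
  expect_false(identical(t1$coords, t3$coords))
  # the caller's RNG stream is not consumed
  set.seed(77)
  before <- rnorm(1)
  set.seed(77)
  invisible(simulate_adsorption(p, sys$topology, sys$frame))
  expect_identical(rnorm(1), before)
})

test_that("hydrogen-bond fixture guarantees its constructed bond count", {
  for (spec in list(c(5, 3, 2), c(0, 10, 10), c(3, 0, 0))) {
    fx <- make_hbond_fixture(spec[1], spec[2], spec[3], seed = 8)
    hb <- hbond_count(one_frame_traj(fx), fx$donor_group,
                      fx$acceptor_group)
    expect_equal(hb$value, spec[1])
  }
})

test_that("fixture bond detection is invariant under rotation about z", {
  fx <- make_hbond_fixture(4, 2, 3, seed = 12)
  th <- 37 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  ctr <- fx$frame$box / 2
  rot <- sweep(sweep(fx$frame$positions, 2, ctr) %*% R, 2, -ctr)
  fr2 <- frame(0, fx$frame$box, rot)
  tr2 <- trajectory(fx$topology, list(fr2))
  hb <- hbond_count(tr2, fx$donor_group, fx$acceptor_group)
  expect_equal(hb$value, 4)
})

test_that("residence fixture hits its prescribed within-cutoff fraction", {
  for (f in c(0, 1)) {
    tr <- make_residence_fixture(f, 50)
    r <- residence_time(tr, drug_atoms(tr$topology),
                        leaflet_atoms(tr$topology, "lower"))
    expect_equal(r$value, 100 * f)
  }
  expect_error(make_residence_fixture(1.2, 10), "fraction_within")
})

test_that("long-run z histogram is Boltzmann-distributed over the well (chi-square)", {
  p <- synthetic_params(well_depth = 2, dt = 50, n_steps = 100000,
                        write_stride = 50, seed = 14)
  sys <- drug_only_system(p)
  tr <- simulate_adsorption(p, sys$topology, sys$frame)
  z <- tr$coords[1, 3, ] - p$box[3] / 2
  # subsample to roughly decorrelate (every 12th stored frame = 30 ns)
  z <- z[seq(1, length(z), by = 12)]
  inwell <- z >= p$z_surface - p$well_width & z <= p$z_surface
  p_well <- equilibrium_well_occupancy(p)
  gof <- suppressWarnings(stats::chisq.test(
    c(sum(inwell), sum(!inwell)), p = c(p_well, 1 - p_well)))
  expect_gt(gof$p.value, 0.01)
})
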