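test_that("a fixed point mass reproduces the single-bin closed form", {
  tr <- zpath_trajectory(rep(1.05, 4), box = c(5, 5, 10))
  prof <- density_profile(tr, list(drug = drug_atoms(tr$topology)),
                          bin_width = 0.2)
  m <- tr$topology$mass[drug_atoms(tr$topology)]
  expected <- m * 1.66053906660 / (5 * 5 * 0.2)
  hit <- which(prof$values[, "drug"] > 0)
  expect_length(hit, 1)
  expect_equal(unname(prof$values[hit, "drug"]), expected,
               tolerance = 1e-12)
  # empty group gives an all-zero column
  prof2 <- density_profile(tr, list(drug = drug_atoms(tr$topology),
                                    none = integer()), bin_width = 0.2)
  expect_equal(unname(prof2$values[, "none"]),
               rep(0, nrow(prof2$values)))
})

test_that("density profiles conserve the group mass", {
  p <- synthetic_params(n_steps = 2000, write_stride = 20, seed = 6)
  mem <- build_membrane_topology(box = p$box, seed = 6)
  sys <- add_drug_bead(mem$topology, mem$frame)
  tr <- simulate_adsorption(p, sys$topology, sys$frame)
  top <- tr$topology
  groups <- list(membrane = lipid_atoms(top), drug = drug_atoms(top))
  prof <- density_profile(tr, groups, bin_width = 0.15)
  area <- p$box[1] * p$box[2]
  for (g in names(groups)) {
    recovered <- sum(prof$values[, g]) * area * prof$bin_width /
      1.66053906660
    expect_equal(recovered, sum(top$mass[groups[[g]]]),
                 tolerance = 1e-9)
  }
})

test_that("Boltzmann inversion maps occupancy ratios to kT differences", {
  h <- list(z = c(0.05, 0.15), counts = c(1000, 1000))
  F <- free_energy_profile(h)
  expect_equal(F$F_kT, c(0, 0))

  h2 <- list(z = c(0.05, 0.15), counts = c(round(1000 * exp(1)), 1000))
  F2 <- free_energy_profile(h2)
  expect_equal(F2$F_kT[2] - F2$F_kT[1], 1, tolerance = 1e-3)

  h3 <- list(z = c(0.05, 0.15, 0.25), counts = c(100, 0, 50))
  F3 <- free_energy_profile(h3)
  expect_true(is.na(F3$F_kT[2]))
  expect_false(any(is.infinite(F3$F_kT), na.rm = TRUE))
  expect_error(free_energy_profile(list(z = 1, counts = 0)), "all-zero")
})

test_that("mid-plane location splits sides and flags an absent side", {
  tr <- zpath_trajectory(rep(2, 8))
  mp <- midplane_location(tr, drug_atoms(tr$topology))
  expect_equal(mp$upper_side$value, 2)
  expect_true(is.na(mp$lower_side$value))
  expect_equal(mp$lower_side$note, "absent")

  tr2 <- zpath_trajectory(rep(c(1.5, -1.5), 10))
  mp2 <- midplane_location(tr2, drug_atoms(tr2$topology))
  expect_equal(mp2$upper_side$value, 1.5)
  expect_equal(mp2$lower_side$value, 1.5)
})

test_that("block standard deviation matches the sample sd of block values", {
  expect_equal(as.numeric(block_std(rep(7, 40))), 0)
  # series designed so the 4 block means are 10, 20, 30, 40
  x <- rep(c(10, 20, 30, 40), each = 5)
  expect_equal(as.numeric(block_std(x, 4)), 12.909944, tolerance = 1e-6)
  expect_equal(attr(block_std(x, 4), "block_values"), c(10, 20, 30, 40))
  # permutation invariance across block values
  expect_equal(as.numeric(block_std(rep(c(40, 10, 30, 20), each = 5), 4)),
               as.numeric(block_std(x, 4)))
  expect_error(block_std(1:10, 1), "n_blocks")
  expect_error(block_std(1:3, 4), "non-empty")
})

test_that("dipole moments convert point charges to Debye", {
  atoms <- data.frame(charge = c(0.5, -0.5), mass = c(1, 1))
  # zero separation cancels exactly
  expect_equal(dipole_moment(atoms, rbind(c(0, 0, 0), c(0, 0, 0)))$debye, 0)
  # +0.5 e at 0.1 nm above -0.5 e: mu = 0.05 e nm = 2.40160 D
  d <- dipole_moment(atoms, rbind(c(0, 0, 0.1), c(0, 0, 0)))
  expect_equal(d$debye, 0.05 * 48.0321, tolerance = 1e-10)
  # translation invariance for net-neutral sets
  d2 <- dipole_moment(atoms, rbind(c(3, -2, 1.1), c(3, -2, 1)))
  expect_equal(d2$debye, d$debye, tolerance = 1e-9)
  # charged species: reported about the centre of mass, with a warning
  atoms3 <- data.frame(charge = c(1, 0.5), mass = c(2, 1))
  expect_warning(d3 <- dipole_moment(atoms3,
                                     rbind(c(0, 0, 0), c(0, 0, 0.3))),
                 "net charge")
  expect_gt(d3$debye, 0)
})
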