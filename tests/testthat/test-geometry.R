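test_that("minimum-image distance handles identity, wrapping and errors", {
  expect_equal(min_image_distance(c(1, 2, 3), c(1, 2, 3), c(5, 5, 5)), 0)
  expect_equal(min_image_distance(c(0, 0, 0), c(0.9, 0, 0), c(1, 1, 1)),
               0.1)
  expect_error(min_image_distance(c(0, 0, 0), c(1, 1, 1), c(5, 0, 5)),
               "positive")
  # symmetry
  p <- c(0.2, 3.1, 4.9)
  q <- c(4.8, 0.3, 0.1)
  box <- c(5, 5, 5)
  expect_equal(min_image_distance(p, q, box),
               min_image_distance(q, p, box))
})

test_that("minimum-image distance equals the 27-image enumeration oracle", {
  set.seed(101)
  ok <- TRUE
  for (rep in 1:500) {
    box <- runif(3, 1, 10)
    p <- runif(3, 0, box)
    q <- runif(3, 0, box)
    if (abs(min_image_distance(p, q, box) -
              brute_force_min_image(p, q, box)) > 1e-12) ok <- FALSE
  }
  expect_true(ok)
  # points far outside the cell are wrapped consistently: the distance is
  # invariant under shifting either point by whole box vectors
  expect_equal(min_image_distance(c(0.2, 0.3, 0.4) + 7 * c(5, 5, 5),
                                  c(4.1, 0.1, 2.2), c(5, 5, 5)),
               min_image_distance(c(0.2, 0.3, 0.4), c(4.1, 0.1, 2.2),
                                  c(5, 5, 5)), tolerance = 1e-9)
})

test_that("min_distance_to_selection matches hand-computed pair tables", {
  atoms <- topology(do.call(rbind, lapply(1:5, atom_row)))
  pos <- rbind(c(1, 1, 1), c(2, 2, 2), c(4.5, 1, 1),    # group a
               c(1, 1, 1.7), c(0.2, 1, 1))              # group b
  fr <- frame(0, c(5, 5, 5), pos)
  # coincident atoms give zero
  fr0 <- frame(0, c(5, 5, 5), rbind(pos[1:4, ], c(1, 1, 1)))
  expect_equal(min_distance_to_selection(fr0, 1:3, 4:5), 0)
  # manual table: all 6 cross pairs, min is a3-b2 across the x boundary
  d <- as.vector(outer(1:3, 4:5, Vectorize(function(i, j)
    brute_force_min_image(pos[i, ], pos[j, ], c(5, 5, 5)))))
  expect_equal(min_distance_to_selection(fr, 1:3, 4:5), min(d))
  expect_equal(min(d), 0.7)
  # invariant under rigid translation modulo the box
  shift <- c(1.3, -0.7, 2.2)
  fr2 <- frame(0, c(5, 5, 5), sweep(pos, 2, -shift) %% 5)
  expect_equal(min_distance_to_selection(fr2, 1:3, 4:5),
               min_distance_to_selection(fr, 1:3, 4:5), tolerance = 1e-12)
  expect_error(min_distance_to_selection(fr, integer(), 4:5), "group_a")
  expect_error(min_distance_to_selection(fr, 1:3, integer()), "group_b")
})

test_that("mid-plane is the mass-weighted lipid z mean", {
  atoms <- topology(rbind(
    atom_row(1, "HEAD", "P", 100, residue_name = "DSPC",
             leaflet = "upper"),
    atom_row(2, "HEAD", "P", 100, residue_name = "DSPC",
             leaflet = "lower")))
  fr <- frame(0, c(5, 5, 5), rbind(c(1, 1, 1), c(1, 1, 3)))
  expect_equal(assign_midplane(fr, atoms), 2)
  expect_error(assign_midplane(fr, atoms, integer()), "empty")

  # adding mass-balanced pairs mirrored about z0 leaves z0 unchanged
  atoms2 <- topology(rbind(as.data.frame(atoms),
                           atom_row(3, "HEAD", "P", 250,
                                    residue_name = "DSPE",
                                    leaflet = "upper"),
                           atom_row(4, "HEAD", "P", 250,
                                    residue_name = "DSPE",
                                    leaflet = "lower")))
  fr2 <- frame(0, c(5, 5, 5),
               rbind(c(1, 1, 1), c(1, 1, 3), c(2, 2, 2 + 0.8),
                     c(2, 2, 2 - 0.8)))
  expect_equal(assign_midplane(fr2, atoms2), 2)
})

test_that("a symmetric synthetic bilayer centres the mid-plane on the construction plane", {
  comp <- membrane_composition(upper = c(PC = 20, PE = 12),
                               lower = c(PC = 20, PE = 12))
  mem <- build_membrane_topology(comp, box = c(6.4, 6.4, 10),
                                 z_surface = 2.5, seed = 5)
  expect_equal(assign_midplane(mem$frame, mem$topology), 5,
               tolerance = 1e-10)
})
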