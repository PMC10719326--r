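# Shared fixture builders and independent oracles.

# minimal valid atom row; override fields as needed
atom_row <- function(atom_id, name = "C1", element = "C", mass = 12,
                     charge = 0, residue_name = "DRUG",
                     residue_id = atom_id, leaflet = "none",
                     hbond_role = "none", bonded_donor_id = NA_integer_) {
  data.frame(atom_id = atom_id, name = name, element = element, mass = mass,
             charge = charge, residue_name = residue_name,
             residue_id = residue_id, leaflet = leaflet,
             hbond_role = hbond_role, bonded_donor_id = bonded_donor_id,
             stringsAsFactors = FALSE)
}

empty_topology <- function() {
  topology(atom_row(1)[0, ])
}

# a drug bead alone in a box, positioned z_start above the box-centre plane
drug_only_system <- function(p, z_start = 3.8, with_hbond_sites = FALSE) {
  add_drug_bead(empty_topology(), frame(0, p$box, matrix(0, 0, 3)),
                position = c(p$box[1] / 2, p$box[2] / 2,
                             p$box[3] / 2 + z_start),
                with_hbond_sites = with_hbond_sites)
}

# independent oracle: minimum distance over all 27 periodic images
brute_force_min_image <- function(p, q, box) {
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- p - (q + c(i, j, k) * box)
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# independent oracle: plain triple loop over (donor, hydrogen, acceptor)
# with its own distance/angle arithmetic (donor-centred angle convention)
brute_force_hbonds <- function(top, fr, group_a, group_b, r_max = 0.35,
                               angle_max = 30) {
  count_dir <- function(ga, gb) {
    n <- 0L
    for (h in ga) {
      if (top$hbond_role[h] != "polar_hydrogen") next
      don <- which(top$atom_id == top$bonded_donor_id[h])
      if (!length(don) || !(don %in% ga)) next
      for (a in gb) {
        if (!(top$hbond_role[a] %in% c("acceptor", "donor_and_acceptor")))
          next
        if (a == don) next
        da <- fr$positions[a, ] - fr$positions[don, ]
        da <- da - fr$box * round(da / fr$box)
        r <- sqrt(sum(da^2))
        if (r > r_max) next
        dh <- fr$positions[h, ] - fr$positions[don, ]
        dh <- dh - fr$box * round(dh / fr$box)
        cosang <- sum(da * dh) / (sqrt(sum(da^2)) * sqrt(sum(dh^2)))
        ang <- acos(max(-1, min(1, cosang))) * 180 / pi
        if (ang <= angle_max) n <- n + 1L
      }
    }
    n
  }
  count_dir(group_a, group_b) + count_dir(group_b, group_a)
}

# hand-placed donor/hydrogen/acceptor triad at a given distance and
# donor-centred angle (degrees), acceptor along +x
triad_system <- function(r, angle, box = c(5, 5, 5)) {
  atoms <- rbind(
    atom_row(1, "OD", "O", 15.999, -0.6, "DRUG", 1,
             hbond_role = "donor"),
    atom_row(2, "HD", "H", 1.008, 0.4, "DRUG", 1,
             hbond_role = "polar_hydrogen", bonded_donor_id = 1L),
    atom_row(3, "OA", "O", 15.999, -0.5, "DSPC", 2, leaflet = "upper",
             hbond_role = "acceptor"))
  a <- angle * pi / 180
  pos <- rbind(c(2, 2, 2),
               c(2, 2, 2) + 0.1 * c(cos(a), sin(a), 0),
               c(2 + r, 2, 2))
  list(topology = topology(atoms), frame = frame(0, box, pos))
}

one_frame_traj <- function(sys) trajectory(sys$topology, list(sys$frame))

# trajectory with a fixed drug z-path above/below two static leaflet beads
zpath_trajectory <- function(z_path, box = c(5, 5, 10), dt = 100) {
  atoms <- topology(rbind(
    atom_row(1, "HEAD", "P", 790.15, 0, "DSPC", 1, leaflet = "upper",
             hbond_role = "acceptor"),
    atom_row(2, "HEAD", "P", 790.15, 0, "DSPC", 2, leaflet = "lower",
             hbond_role = "acceptor"),
    atom_row(3)))
  z0 <- box[3] / 2
  nf <- length(z_path)
  coords <- array(NA_real_, c(3, 3, nf))
  for (k in seq_len(nf)) {
    coords[1, , k] <- c(2.5, 2.5, z0 + 2.5)
    coords[2, , k] <- c(2.5, 2.5, z0 - 2.5)
    coords[3, , k] <- c(2.5, 2.5, z0 + z_path[k])
  }
  trajectory(atoms, times = (seq_len(nf) - 1) * dt,
             boxes = matrix(box, nf, 3, byrow = TRUE), coords = coords)
}
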