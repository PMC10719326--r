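#' Ground-truth parameters for the synthetic adsorption generator
#'
#' The generator moves a drug bead by overdamped Brownian dynamics in a
#' square-well adsorption potential anchored at the two leaflet planes.
#' All parameters are ground truth against which the estimators are
#' validated: \code{D_bulk} is the true diffusivity, \code{well_depth} the
#' true adsorption free energy, and the geometry fixes the closed-form
#' equilibrium occupancy of the well.
#'
#' @param D_bulk true diffusivity, nm^2/ps.
#' @param well_depth adsorption well depth in kT (>= 0).
#' @param well_width width of the well band in nm; the well spans
#'   \code{[z_surface - well_width, z_surface]} above the mid-plane and its
#'   mirror image below.
#' @param z_surface leaflet plane offset from the mid-plane, nm.
#' @param core_halfwidth half-width of the excluded hydrophobic core slab
#'   \code{|z| < core_halfwidth}; reflective.  Must be < \code{z_surface}.
#'   Zero disables the core (bulk-water geometry).
#' @param box box lengths, nm.
#' @param dt time step, ps.
#' @param n_steps number of integration steps.
#' @param write_stride store every \code{write_stride}-th step.
#' @param temperature K (metadata; energies are expressed directly in kT).
#' @param seed RNG seed.
#' @return object of class \code{"synthetic_params"}.
#' @export
synthetic_params <- function(D_bulk = 4e-4, well_depth = 3, well_width = 0.5,
                             z_surface = 2.5, core_halfwidth = 1.5,
                             box = c(6.4, 6.4, 10), dt = 50,
                             n_steps = 20000, write_stride = 10,
                             temperature = 310, seed = 1) {
  if (D_bulk <= 0) stop("D_bulk must be > 0")
  if (well_width <= 0) stop("well_width must be > 0")
  if (well_depth < 0) stop("well_depth must be >= 0")
  if (core_halfwidth < 0 || core_halfwidth >= z_surface)
    stop("core_halfwidth must satisfy 0 <= core_halfwidth < z_surface")
  if (dt <= 0) stop("dt must be > 0")
  if (length(box) != 3 || any(box <= 0)) stop("box must be 3 positive lengths")
  if (z_surface >= box[3] / 2)
    stop("z_surface must lie inside the box (z_surface < box_z / 2)")
  structure(list(D_bulk = D_bulk, well_depth = well_depth,
                 well_width = well_width, z_surface = z_surface,
                 core_halfwidth = core_halfwidth, box = as.numeric(box),
                 dt = dt, n_steps = as.integer(n_steps),
                 write_stride = as.integer(write_stride),
                 temperature = temperature, seed = as.integer(seed)),
            class = "synthetic_params")
}

#' Closed-form equilibrium well occupancy of the square-well generator
#'
#' Two-state Boltzmann prediction for the fraction of time the drug spends
#' inside the adsorption well band on its side of the (impenetrable) core:
#' \code{p = w e^depth / (w e^depth + L_free)} with \code{L_free} the
#' accessible width outside the well on that side.
#'
#' @param params a [synthetic_params()].
#' @return probability in [0, 1].
#' @export
equilibrium_well_occupancy <- function(params) {
  w <- params$well_width
  zmax <- params$box[3] / 2
  lo <- params$core_halfwidth
  L_free <- (zmax - lo) - w
  b <- w * exp(params$well_depth)
  b / (b + L_free)
}

# lipid head-bead properties per residue class
.lipid_beads <- data.frame(
  residue_name = c("DSPC", "DSPE", "DSPS", "SSM"),
  mass = c(790.15, 748.07, 792.09, 731.09),
  charge = c(0, 0, -1, 0),
  stringsAsFactors = FALSE)
.class_to_residue <- c(PC = "DSPC", PE = "DSPE", PS = "DSPS", SM = "SSM")

#' Build a coarse asymmetric membrane topology
#'
#' Places one head bead per lipid on a jittered square lattice at
#' \code{z0 +/- z_surface} (z0 the box centre), assigns head-group
#' identities by a seeded shuffle within each leaflet, and labels each bead
#' with its residue class and leaflet.  Head beads are flagged as
#' hydrogen-bond acceptors (the phosphate/carbonyl oxygens they stand for).
#'
#' @param composition a [membrane_composition()].
#' @param box box lengths, nm.
#' @param z_surface leaflet plane offset from the box-centre mid-plane, nm.
#' @param seed RNG seed for lattice jitter and identity shuffle.
#' @return list with \code{topology}, \code{frame} and \code{percentages}
#'   (the derived per-leaflet head-group percentage report).
#' @export
build_membrane_topology <- function(composition = membrane_composition(),
                                    box = c(6.4, 6.4, 10), z_surface = 2.5,
                                    seed = 1) {
  stopifnot(inherits(composition, "membrane_composition"))
  if (z_surface >= box[3] / 2) stop("z_surface must fit inside the box")
  z0 <- box[3] / 2
  with_seed(seed, {
    build_leaflet <- function(counts, side) {
      n <- sum(counts)
      n_side <- ceiling(sqrt(n))
      sx <- box[1] / n_side
      sy <- box[2] / n_side
      if (min(sx, sy) < 0.6)
        stop(sprintf(
          "lipid count %d exceeds lattice capacity for a %.1f x %.1f nm box",
          n, box[1], box[2]))
      g <- expand.grid(i = seq_len(n_side) - 0.5, j = seq_len(n_side) - 0.5)
      g <- g[seq_len(n), ]
      res <- sample(rep(.class_to_residue[names(counts)], counts))
      data.frame(
        x = g$i * sx + runif(n, -0.15, 0.15) * sx,
        y = g$j * sy + runif(n, -0.15, 0.15) * sy,
        z = z0 + if (side == "upper") z_surface else -z_surface,
        residue_name = res, leaflet = side, stringsAsFactors = FALSE)
    }
    up <- build_leaflet(composition$upper, "upper")
    lo <- build_leaflet(composition$lower, "lower")
    beads <- rbind(up, lo)
    k <- match(beads$residue_name, .lipid_beads$residue_name)
    atoms <- data.frame(
      atom_id = seq_len(nrow(beads)), name = "HEAD", element = "P",
      mass = .lipid_beads$mass[k], charge = .lipid_beads$charge[k],
      residue_name = beads$residue_name, residue_id = seq_len(nrow(beads)),
      leaflet = beads$leaflet, hbond_role = "acceptor",
      bonded_donor_id = NA_integer_, stringsAsFactors = FALSE)
    list(topology = topology(atoms),
         frame = frame(0, box, cbind(beads$x, beads$y, beads$z)),
         percentages = composition_percentages(composition))
  })
}

#' Append a drug molecule to a system
#'
#' Adds a single-bead drug (residue \code{DRUG}) for the dynamics, optionally
#' decorated with rigidly co-moving satellite sites (a donor oxygen with its
#' polar hydrogen, and an acceptor oxygen) so that hydrogen-bond and dipole
#' analyses have multi-atom input.
#'
#' @param top a [topology()].
#' @param fr the matching [frame()].
#' @param position drug centre position (nm); default: box centre in x/y,
#'   three quarters of the box height in z (above the upper leaflet).
#' @param with_hbond_sites add the donor/H/acceptor satellites?
#' @param net_charge total charge of the drug (e); placed on the centre bead
#'   after the satellite partial charges.
#' @param mass total drug mass (amu); default is anthracycline-like.
#' @return list with updated \code{topology} and \code{frame}.
#' @export
add_drug_bead <- function(top, fr, position = NULL, with_hbond_sites = TRUE,
                          net_charge = 0, mass = 543.5) {
  if (is.null(position))
    position <- c(fr$box[1] / 2, fr$box[2] / 2, 0.75 * fr$box[3])
  id0 <- if (nrow(top)) max(top$atom_id) else 0L
  rid <- if (nrow(top)) max(top$residue_id) + 1L else 1L
  sites <- data.frame(name = "C1", element = "C", dx = 0, dy = 0, dz = 0,
                      mass = NA_real_, charge = NA_real_,
                      hbond_role = "none", stringsAsFactors = FALSE)
  if (with_hbond_sites) {
    sat <- data.frame(
      name = c("OD", "HD", "OA"), element = c("O", "H", "O"),
      dx = c(0.15, 0.25, -0.15), dy = 0, dz = 0,
      mass = c(15.999, 1.008, 15.999), charge = c(-0.65, 0.42, -0.57),
      hbond_role = c("donor", "polar_hydrogen", "acceptor"),
      stringsAsFactors = FALSE)
    sites <- rbind(sites, sat)
  }
  sites$mass[1] <- mass - sum(sites$mass[-1], 0)
  sites$charge[1] <- net_charge - sum(sites$charge[-1], 0)
  atoms <- data.frame(
    atom_id = id0 + seq_len(nrow(sites)), name = sites$name,
    element = sites$element, mass = sites$mass, charge = sites$charge,
    residue_name = "DRUG", residue_id = rid, leaflet = "none",
    hbond_role = sites$hbond_role,
    bonded_donor_id = ifelse(sites$hbond_role == "polar_hydrogen",
                             id0 + match("donor", sites$hbond_role),
                             NA_integer_),
    stringsAsFactors = FALSE)
  pos <- sweep(as.matrix(sites[, c("dx", "dy", "dz")]), 2, -position)
  list(topology = topology(rbind(as.data.frame(top), atoms)),
       frame = frame(fr$time, fr$box, rbind(fr$positions, pos)))
}

# reflect values into [lo, hi] by folding (exact for any excursion size)
reflect_into <- function(x, lo, hi) {
  L <- hi - lo
  y <- (x - lo) %% (2 * L)
  y <- ifelse(y > L, 2 * L - y, y)
  lo + y
}

# square-well potential in kT, z relative to the mid-plane
well_energy <- function(z, params) {
  az <- abs(z)
  ifelse(az >= params$z_surface - params$well_width & az <= params$z_surface,
         -params$well_depth, 0)
}

#' Simulate reversible drug adsorption by Brownian dynamics
#'
#' Overdamped-Langevin dynamics of the drug centre: per step, a Gaussian
#' displacement of variance \code{2 D_bulk dt} per axis, with the square-well
#' adsorption energy applied through a Metropolis acceptance factor
#' \code{min(1, exp(-dU/kT))} — for a piecewise-constant well the
#' deterministic drift term is zero almost everywhere, and the acceptance
#' factor is what carries the Boltzmann weight, so long runs sample
#' \code{exp(-U(z)/kT)} exactly.  z-boundaries are reflective at the core
#' slab and at the box faces (preserving the above/below-membrane
#' distinction); x and y are free and periodically wrapped.  Lipid beads are
#' static; drug satellites co-move rigidly with the centre.  The stored z is
#' never wrapped.
#'
#' @param params a [synthetic_params()].
#' @param top system [topology()] containing one \code{DRUG} residue.
#' @param fr starting [frame()].
#' @return a [trajectory()] of \code{n_steps / write_stride + 1} frames.
#' @export
simulate_adsorption <- function(params, top, fr) {
  stopifnot(inherits(params, "synthetic_params"))
  drug <- drug_atoms(top)
  if (!length(drug)) stop("topology contains no DRUG residue")
  if (!isTRUE(all.equal(as.numeric(fr$box), params$box)))
    stop("frame box disagrees with params$box")
  step_rms <- sqrt(2 * params$D_bulk * params$dt)
  if (params$well_depth > 0 && step_rms > params$well_width)
    stop(sprintf(
      "unstable time step: rms displacement %.3f nm per step exceeds well_width %.3f nm",
      step_rms, params$well_width))

  centre <- drug[1]
  offsets <- sweep(fr$positions[drug, , drop = FALSE], 2,
                   fr$positions[centre, ])
  z0 <- params$box[3] / 2
  zmax <- params$box[3] / 2   # relative to mid-plane
  core <- params$core_halfwidth
  zrel0 <- fr$positions[centre, 3] - z0
  if (core > 0 && abs(zrel0) < core)
    stop("drug starts inside the excluded core slab")
  # with a reflective core the drug is confined to its starting side
  dom <- if (core > 0) {
    if (zrel0 >= 0) c(core, zmax) else c(-zmax, -core)
  } else c(-zmax, zmax)

  ns <- params$n_steps
  stride <- params$write_stride
  rec_steps <- seq(0, ns, by = stride)
  with_seed(params$seed, {
    if (params$well_depth == 0) {
      # flat potential: every move is accepted; reflections commute with
      # folding, so the whole path can be generated vectorized
      steps <- matrix(rnorm(3 * ns, 0, step_rms), ns, 3)
      xy <- sweep(apply(steps[, 1:2, drop = FALSE], 2, cumsum), 2,
                  -fr$positions[centre, 1:2])
      z <- reflect_into(zrel0 + cumsum(steps[, 3]), dom[1], dom[2])
      path <- cbind(rbind(fr$positions[centre, 1:2, drop = FALSE],
                          xy)[rec_steps + 1, , drop = FALSE],
                    c(zrel0, z)[rec_steps + 1])
    } else {
      noise <- matrix(rnorm(3 * ns, 0, step_rms), ns, 3)
      acc <- runif(ns)
      pos <- c(fr$positions[centre, 1:2], zrel0)
      u <- well_energy(pos[3], params)
      nrec <- length(rec_steps)
      path <- matrix(NA_real_, nrec, 3)
      path[1, ] <- pos
      k <- 2L
      for (s in seq_len(ns)) {
        prop <- pos + noise[s, ]
        prop[3] <- reflect_into(prop[3], dom[1], dom[2])
        u_new <- well_energy(prop[3], params)
        if (u_new <= u || acc[s] < exp(u - u_new)) {
          pos <- prop
          u <- u_new
        }
        if (k <= nrec && s == rec_steps[k]) {
          path[k, ] <- pos
          k <- k + 1L
        }
      }
    }
    path[, 1] <- path[, 1] %% params$box[1]
    path[, 2] <- path[, 2] %% params$box[2]
    path[, 3] <- path[, 3] + z0

    nfr <- length(rec_steps)
    coords <- array(fr$positions, c(nrow(top), 3, nfr))
    for (j in seq_along(drug)) {
      for (ax in 1:3) {
        v <- path[, ax] + offsets[j, ax]
        if (ax < 3) v <- v %% params$box[ax]
        coords[drug[j], ax, ] <- v
      }
    }
    trajectory(top, times = rec_steps * params$dt,
               boxes = matrix(params$box, nfr, 3, byrow = TRUE),
               coords = coords)
  })
}

#' Simulate a drug alone in bulk water
#'
#' Reference free-diffusion run used for \code{D_bulk} estimation and for
#' the membrane/bulk diffusivity ratio: the same integrator with the well
#' depth and core slab switched off.
#'
#' @param params a [synthetic_params()]; \code{well_depth} and
#'   \code{core_halfwidth} are overridden to zero.
#' @param with_hbond_sites decorate the drug with satellite sites?
#' @return a [trajectory()] containing only the drug.
#' @export
simulate_bulk <- function(params, with_hbond_sites = FALSE) {
  p <- params
  p$well_depth <- 0
  p$core_halfwidth <- 0
  empty <- topology(data.frame(
    atom_id = integer(), name = character(), element = character(),
    mass = numeric(), charge = numeric(), residue_name = character(),
    residue_id = integer(), leaflet = character(), hbond_role = character(),
    bonded_donor_id = integer(), stringsAsFactors = FALSE))
  sys <- add_drug_bead(empty, frame(0, p$box, matrix(0, 0, 3)),
                       position = p$box / 2,
                       with_hbond_sites = with_hbond_sites)
  simulate_adsorption(p, sys$topology, sys$frame)
}

#' Donor/hydrogen/acceptor fixture with a known bond count
#'
#' Places isolated donor-hydrogen-acceptor triads on a coarse grid (2 nm
#' spacing, so triads cannot cross-bond): \code{n_bonded} triads satisfying
#' the geometric criterion (distance drawn in [0.28, 0.34] nm, angle in
#' [0, 25] degrees), \code{n_near_miss_distance} triads at exactly 0.36 nm
#' with angle 0, and \code{n_near_miss_angle} triads at 0.30 nm with angle
#' 35 degrees; placement and orientation are otherwise random.  Donors (with
#' their polar hydrogens) belong to residue \code{DRUG}; acceptors to
#' residue \code{DSPC}.
#'
#' @param n_bonded,n_near_miss_distance,n_near_miss_angle triad counts.
#' @param seed RNG seed.
#' @return list with \code{topology}, \code{frame}, and the index vectors
#'   \code{donor_group} (donors + hydrogens) and \code{acceptor_group}.
#' @export
make_hbond_fixture <- function(n_bonded, n_near_miss_distance = 0,
                               n_near_miss_angle = 0, seed = 1) {
  if (any(c(n_bonded, n_near_miss_distance, n_near_miss_angle) < 0))
    stop("triad counts must be non-negative")
  n <- n_bonded + n_near_miss_distance + n_near_miss_angle
  if (n == 0) n_grid <- 1 else n_grid <- n
  side <- ceiling(sqrt(max(n_grid, 1)))
  spacing <- 2
  box <- c(side * spacing + 6, side * spacing + 6, 8)
  with_seed(seed, {
    rows <- list()
    pos <- list()
    rand_unit <- function() {
      v <- rnorm(3)
      v / sqrt(sum(v * v))
    }
    # unit vector at `ang` degrees from u, random azimuth
    tilted <- function(u, ang) {
      a <- ang * pi / 180
      p <- rnorm(3)
      p <- p - sum(p * u) * u
      p <- p / sqrt(sum(p * p))
      cos(a) * u + sin(a) * p
    }
    kinds <- c(rep("bond", n_bonded), rep("miss_r", n_near_miss_distance),
               rep("miss_a", n_near_miss_angle))
    cx <- (box[1] - (side - 1) * spacing) / 2
    for (t in seq_len(n)) {
      gi <- (t - 1) %% side
      gj <- (t - 1) %/% side
      origin <- c(cx + gi * spacing, cx + gj * spacing, box[3] / 2)
      r <- switch(kinds[t], bond = runif(1, 0.28, 0.34), miss_r = 0.36,
                  miss_a = 0.30)
      ang <- switch(kinds[t], bond = runif(1, 0, 25), miss_r = 0,
                    miss_a = 35)
      u <- rand_unit()
      do <- origin
      a <- origin + r * u
      h <- origin + 0.10 * tilted(u, ang)
      id <- (t - 1) * 3
      rows[[t]] <- data.frame(
        atom_id = id + 1:3, name = c("OD", "HD", "OA"),
        element = c("O", "H", "O"), mass = c(15.999, 1.008, 15.999),
        charge = c(-0.6, 0.4, -0.5),
        residue_name = c("DRUG", "DRUG", "DSPC"),
        residue_id = c(2 * t - 1, 2 * t - 1, 2 * t),
        leaflet = "none",
        hbond_role = c("donor", "polar_hydrogen", "acceptor"),
        bonded_donor_id = c(NA_integer_, id + 1L, NA_integer_),
        stringsAsFactors = FALSE)
      pos[[t]] <- rbind(do, h, a)
    }
    if (n == 0) {
      atoms <- topology(data.frame(
        atom_id = 1L, name = "C1", element = "C", mass = 12, charge = 0,
        residue_name = "DRUG", residue_id = 1L, leaflet = "none",
        hbond_role = "none", bonded_donor_id = NA_integer_))
      return(list(topology = atoms,
                  frame = frame(0, box, matrix(box / 2, 1, 3)),
                  donor_group = integer(), acceptor_group = integer()))
    }
    atoms <- do.call(rbind, rows)
    # lipid acceptors sit in a leaflet in real systems; here they are free
    # sites, so mark the DSPC beads as upper-leaflet surface atoms
    atoms$leaflet[atoms$residue_name == "DSPC"] <- "upper"
    top <- topology(atoms)
    list(topology = top, frame = frame(0, box, do.call(rbind, pos)),
         donor_group = which(top$residue_name == "DRUG"),
         acceptor_group = which(top$residue_name == "DSPC"))
  })
}

#' Residence-time fixture with a prescribed within-cutoff fraction
#'
#' Builds a drug + two-leaflet-bead system in which the drug sits 0.25 nm
#' from the lower-leaflet bead in \code{round(fraction_within * n_frames)}
#' frames and 1.5 nm away otherwise, so the residence time near the lower
#' leaflet is exactly \code{100 * round(fraction_within * n_frames) /
#' n_frames} percent.
#'
#' @param fraction_within target fraction in [0, 1].
#' @param n_frames number of frames.
#' @param dt frame interval, ps.
#' @return a [trajectory()].
#' @export
make_residence_fixture <- function(fraction_within, n_frames, dt = 1000) {
  if (fraction_within < 0 || fraction_within > 1)
    stop("fraction_within must be in [0, 1]")
  box <- c(5, 5, 10)
  atoms <- topology(data.frame(
    atom_id = 1:3, name = c("HEAD", "HEAD", "C1"),
    element = c("P", "P", "C"), mass = c(790.15, 790.15, 543.5),
    charge = 0, residue_name = c("DSPC", "DSPC", "DRUG"),
    residue_id = 1:3, leaflet = c("upper", "lower", "none"),
    hbond_role = c("acceptor", "acceptor", "none"),
    bonded_donor_id = NA_integer_, stringsAsFactors = FALSE))
  upper <- c(2.5, 2.5, 5 + 2.5)
  lower <- c(2.5, 2.5, 5 - 2.5)
  n_in <- round(fraction_within * n_frames)
  near <- lower - c(0, 0, 0.25)
  far <- lower - c(0, 0, 1.5)
  coords <- array(NA_real_, c(3, 3, n_frames))
  for (k in seq_len(n_frames)) {
    coords[1, , k] <- upper
    coords[2, , k] <- lower
    coords[3, , k] <- if (k <= n_in) near else far
  }
  trajectory(atoms, times = (seq_len(n_frames) - 1) * dt,
             boxes = matrix(box, n_frames, 3, byrow = TRUE), coords = coords)
}
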