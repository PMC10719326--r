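#' Build and validate an atom-level topology
#'
#' A topology is the static description of the simulated system: one row per
#' atom with element, mass, partial charge, residue assignment, leaflet label
#' and hydrogen-bond role.  It is the annotation layer every metric consumes
#' alongside the coordinates.
#'
#' @param atoms data frame with columns \code{atom_id}, \code{name},
#'   \code{element}, \code{mass} (amu), \code{charge} (e),
#'   \code{residue_name}, \code{residue_id}, \code{leaflet} (one of
#'   \code{"upper"}, \code{"lower"}, \code{"none"}), \code{hbond_role} (one
#'   of \code{"donor"}, \code{"acceptor"}, \code{"donor_and_acceptor"},
#'   \code{"polar_hydrogen"}, \code{"none"}) and \code{bonded_donor_id}
#'   (atom_id of the covalently attached donor heavy atom; \code{NA} except
#'   for polar hydrogens).
#' @return the validated data frame with class \code{"topology"}.
#' @details Enforced invariants: unique integer \code{atom_id}; all masses
#'   positive; every polar hydrogen points at an atom whose role includes
#'   donor; non-lipid residues (drug, water, ions) carry leaflet
#'   \code{"none"}; leaflet labels partition lipid atoms (each lipid atom is
#'   upper or lower, never both).
#' @export
topology <- function(atoms) {
  req <- c("atom_id", "name", "element", "mass", "charge", "residue_name",
           "residue_id", "leaflet", "hbond_role", "bonded_donor_id")
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop("topology is missing columns: ", paste(miss, collapse = ", "))
  atoms <- atoms[, req]
  atoms$atom_id <- as.integer(atoms$atom_id)
  atoms$residue_id <- as.integer(atoms$residue_id)
  atoms$mass <- as.numeric(atoms$mass)
  atoms$charge <- as.numeric(atoms$charge)
  atoms$bonded_donor_id <- as.integer(atoms$bonded_donor_id)
  for (ch in c("name", "element", "residue_name", "leaflet", "hbond_role"))
    atoms[[ch]] <- as.character(atoms[[ch]])

  if (anyNA(atoms$atom_id) || anyDuplicated(atoms$atom_id))
    stop("atom_id must be unique non-missing integers")
  if (anyNA(atoms$mass) || any(atoms$mass <= 0))
    stop("all atom masses must be > 0")
  if (!all(atoms$leaflet %in% .leaflet_levels))
    stop("leaflet must be one of: ", paste(.leaflet_levels, collapse = ", "))
  if (!all(atoms$hbond_role %in% .hbond_roles))
    stop("hbond_role must be one of: ", paste(.hbond_roles, collapse = ", "))

  ph <- atoms$hbond_role == "polar_hydrogen"
  if (any(ph)) {
    don <- atoms$bonded_donor_id[ph]
    if (anyNA(don))
      stop("every polar_hydrogen needs a bonded_donor_id")
    idx <- match(don, atoms$atom_id)
    if (anyNA(idx) ||
        !all(atoms$hbond_role[idx] %in% c("donor", "donor_and_acceptor")))
      stop("bonded_donor_id of a polar hydrogen must reference a donor atom")
  }
  nl <- atoms$residue_name %in% .nonlipid_residues
  if (any(nl & atoms$leaflet != "none"))
    stop("non-lipid atoms (drug/water/ions) must have leaflet \"none\"")

  class(atoms) <- c("topology", "data.frame")
  atoms
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d residues (%s)\n",
              nrow(x), length(unique(x$residue_id)),
              paste(sort(unique(x$residue_name)), collapse = ", ")))
  invisible(x)
}

#' Atom selections by annotation
#'
#' Convenience selectors returning integer row indices into a topology.
#'
#' @param top a [topology()].
#' @param side \code{"upper"} or \code{"lower"}.
#' @param residue residue class label of the drug (default \code{"DRUG"}).
#' @return integer vector of atom indices (row positions).
#' @export
leaflet_atoms <- function(top, side = c("upper", "lower")) {
  side <- match.arg(side)
  which(top$leaflet == side)
}

#' @rdname leaflet_atoms
#' @export
lipid_atoms <- function(top) which(top$leaflet != "none")

#' @rdname leaflet_atoms
#' @export
drug_atoms <- function(top, residue = "DRUG") {
  which(top$residue_name == residue)
}

#' Per-leaflet head-group composition of an asymmetric bilayer
#'
#' Book-keeping container for the number of lipids of each head-group class
#' in each leaflet of an asymmetric membrane model.  The default is the
#' myocardial model composition: upper leaflet 40 PC + 17 PE + 7 SM, lower
#' leaflet 35 PC + 21 PE + 8 PS.
#'
#' @param upper,lower named non-negative integer vectors of head-group
#'   counts; allowed names are \code{PC}, \code{PE}, \code{PS}, \code{SM}.
#' @return object of class \code{"membrane_composition"}.
#' @export
membrane_composition <- function(upper = c(PC = 40, PE = 17, SM = 7),
                                 lower = c(PC = 35, PE = 21, PS = 8)) {
  chk <- function(x, lab) {
    if (is.null(names(x)) || !all(names(x) %in% c("PC", "PE", "PS", "SM")))
      stop(lab, " counts must be named with PC/PE/PS/SM")
    if (any(x < 0) || any(x != round(x)))
      stop(lab, " counts must be non-negative integers")
    if (sum(x) == 0)
      stop(lab, " leaflet has zero lipids")
    x
  }
  obj <- list(upper = chk(upper, "upper"), lower = chk(lower, "lower"))
  class(obj) <- "membrane_composition"
  obj
}

#' Head-group percentages per leaflet
#'
#' @param comp a [membrane_composition()].
#' @return list with elements \code{upper} and \code{lower}, each a named
#'   numeric vector of exact percentages (summing to 100), plus
#'   \code{n_upper}, \code{n_lower} and \code{n_total} lipid counts.
#' @export
composition_percentages <- function(comp) {
  stopifnot(inherits(comp, "membrane_composition"))
  pct <- function(x) 100 * x / sum(x)
  list(upper = pct(comp$upper), lower = pct(comp$lower),
       n_upper = sum(comp$upper), n_lower = sum(comp$lower),
       n_total = sum(comp$upper) + sum(comp$lower))
}

#' @export
print.membrane_composition <- function(x, ...) {
  p <- composition_percentages(x)
  cat(sprintf("membrane composition: %d lipids (%d upper / %d lower)\n",
              p$n_total, p$n_upper, p$n_lower))
  for (side in c("upper", "lower")) {
    v <- x[[side]]
    cat(sprintf("  %s: %s\n", side,
                paste(sprintf("%s %.1f%% (%d)", names(v), p[[side]], v),
                      collapse = ", ")))
  }
  invisible(x)
}
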