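#' Geometric hydrogen-bond criterion
#'
#' A hydrogen bond exists when a donor (connected to a polar hydrogen) and
#' an acceptor (oxygen or nitrogen) lie at a donor-acceptor distance of at
#' most \code{r_max}, while the hydrogen-donor-acceptor angle is at most
#' \code{angle_max}.  Both boundaries are inclusive.
#'
#' @param r_max donor-acceptor distance cutoff, nm.
#' @param angle_max angle cutoff, degrees (0 < angle_max < 90).
#' @return object of class \code{"hbond_criterion"}.
#' @export
hbond_criterion <- function(r_max = 0.35, angle_max = 30) {
  if (r_max <= 0) stop("r_max must be > 0")
  if (angle_max <= 0 || angle_max >= 90)
    stop("angle_max must be in (0, 90) degrees")
  structure(list(r_max = r_max, angle_max = angle_max),
            class = "hbond_criterion")
}

# candidate (donor, hydrogen, acceptor) triples with the donor/H in `ga`
# and the acceptor in `gb`
hbond_triples <- function(top, ga, gb) {
  don <- ga[top$hbond_role[ga] %in% c("donor", "donor_and_acceptor")]
  hyd <- ga[top$hbond_role[ga] == "polar_hydrogen"]
  hyd <- hyd[match(top$bonded_donor_id[hyd], top$atom_id) %in% don]
  acc <- gb[top$hbond_role[gb] %in% c("acceptor", "donor_and_acceptor")]
  if (!length(hyd) || !length(acc))
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer()))
  dh <- data.frame(donor = match(top$bonded_donor_id[hyd], top$atom_id),
                   hydrogen = hyd)
  out <- merge(dh, data.frame(acceptor = acc))
  out[out$donor != out$acceptor, c("donor", "hydrogen", "acceptor")]
}

# count bonds among candidate triples in one frame
count_hbonds_frame <- function(pos, box, triples, criterion, angle_at) {
  if (!nrow(triples)) return(list(n = 0L, which = integer()))
  dvec <- mic_displacements(pos[triples$acceptor, , drop = FALSE] -
                              pos[triples$donor, , drop = FALSE], box)
  r <- sqrt(rowSums(dvec * dvec))
  ok <- r <= criterion$r_max
  if (!any(ok)) return(list(n = 0L, which = integer()))
  hvec <- mic_displacements(pos[triples$hydrogen, , drop = FALSE] -
                              pos[triples$donor, , drop = FALSE], box)
  if (angle_at == "donor") {
    # angle at the donor between donor->hydrogen and donor->acceptor
    v1 <- hvec
    v2 <- dvec
  } else {
    # deviation from linearity of donor-H...acceptor
    v1 <- -hvec
    v2 <- mic_displacements(pos[triples$acceptor, , drop = FALSE] -
                              pos[triples$hydrogen, , drop = FALSE], box)
  }
  dot <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1 * v1)) * sqrt(rowSums(v2 * v2)))
  ang <- acos(pmin(1, pmax(-1, dot))) * 180 / pi
  if (angle_at == "hydrogen") ang <- 180 - ang
  hit <- which(ok & ang <= criterion$angle_max)
  list(n = length(hit), which = hit)
}

#' Average drug-membrane hydrogen-bond count
#'
#' Counts, per frame, the (donor, hydrogen, acceptor) triples satisfying the
#' geometric criterion, with the donor in one group and the acceptor in the
#' other (both directions are scanned), and returns the time average with a
#' block-averaged uncertainty and a per-residue-class attribution table for
#' the \code{group_b} side (which phospholipid class contributes most).
#'
#' The angle is measured at the donor, between the donor-to-hydrogen and
#' donor-to-acceptor vectors (\code{angle_at = "donor"}, the default);
#' \code{angle_at = "hydrogen"} instead uses the deviation from linearity of
#' the donor-H-acceptor arrangement.
#'
#' @param traj a [trajectory()].
#' @param group_a,group_b atom index groups carrying \code{hbond_role}
#'   annotations (typically drug and membrane).
#' @param criterion an [hbond_criterion()].
#' @param window analyzed time range (ps); \code{NULL} for all frames.
#' @param n_blocks blocks for the uncertainty estimate.
#' @param angle_at \code{"donor"} or \code{"hydrogen"}.
#' @param selection label stored in the result.
#' @return a \code{"hbond_result"} (a [metric_result()] in bonds/frame with
#'   a \code{by_residue} attribution data frame).
#' @export
hbond_count <- function(traj, group_a, group_b,
                        criterion = hbond_criterion(), window = NULL,
                        n_blocks = 4, angle_at = c("donor", "hydrogen"),
                        selection = "") {
  angle_at <- match.arg(angle_at)
  stopifnot(inherits(criterion, "hbond_criterion"))
  top <- traj$topology
  idx <- window_frames(traj, window)
  t_ab <- hbond_triples(top, group_a, group_b)
  t_ba <- hbond_triples(top, group_b, group_a)
  if (!nrow(t_ab) && !nrow(t_ba))
    warning("no resolvable donor/acceptor pairs between the groups; ",
            "hydrogen-bond count is zero")
  # the group_b atom engaged in each candidate bond, for attribution
  partner <- c(t_ab$acceptor, t_ba$donor)
  triples <- rbind(t_ab, t_ba)
  counts <- integer(length(idx))
  partner_tally <- numeric(nrow(triples))
  for (k in seq_along(idx)) {
    fr <- count_hbonds_frame(traj$coords[, , idx[k]], traj$boxes[idx[k], ],
                             triples, criterion, angle_at)
    counts[k] <- fr$n
    partner_tally[fr$which] <- partner_tally[fr$which] + 1
  }
  by_res <- if (nrow(triples)) {
    agg <- tapply(partner_tally / length(idx), top$residue_name[partner],
                  sum)
    data.frame(residue_name = names(agg),
               bonds_per_frame = as.numeric(agg),
               row.names = NULL, stringsAsFactors = FALSE)
  } else data.frame(residue_name = character(), bonds_per_frame = numeric())
  by_res <- by_res[order(-by_res$bonds_per_frame), , drop = FALSE]
  out <- metric_result(
    value = mean(counts),
    block_std = block_std_or_na(counts, n_blocks),
    n_blocks = if (length(counts) >= n_blocks) n_blocks else NA_integer_,
    selection = selection, window = range(traj$times[idx]),
    units = "bonds/frame", n_frames = length(idx))
  out$by_residue <- by_res
  class(out) <- c("hbond_result", class(out))
  out
}
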