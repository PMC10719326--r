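#' Category band with explicit boundary inclusivity
#'
#' @param lo,hi band bounds (use \code{-Inf}/\code{Inf} for open ends).
#' @param lo_incl,hi_incl is each boundary inclusive?
#' @return object of class \code{"band"}.
#' @export
make_band <- function(lo, hi, lo_incl = TRUE, hi_incl = TRUE) {
  if (lo >= hi) stop("band bounds must satisfy lo < hi")
  structure(list(lo = lo, hi = hi, lo_incl = lo_incl, hi_incl = hi_incl),
            class = "band")
}

in_band <- function(x, band) {
  if (is.na(x)) return(NA)
  above <- if (band$lo_incl) x >= band$lo else x > band$lo
  below <- if (band$hi_incl) x <= band$hi else x < band$hi
  above && below
}

bands_overlap <- function(a, b) {
  lo <- max(a$lo, b$lo)
  hi <- min(a$hi, b$hi)
  if (lo < hi) return(TRUE)
  if (lo > hi) return(FALSE)
  # touching boundaries conflict only if inclusive on both sides
  inc_a <- (a$lo == lo && a$lo_incl) || (a$hi == lo && a$hi_incl)
  inc_b <- (b$lo == lo && b$lo_incl) || (b$hi == lo && b$hi_incl)
  inc_a && inc_b
}

#' Four-criterion anchorage rubric
#'
#' Category thresholds for the anchorage-based potential ranking.  The
#' defaults encode: residence time first category above 20 percent (strict)
#' and second category in [12, 20]; hydrogen bonds first above 0.1
#' bonds/frame (strict) and second in [0.05, 0.1]; mid-plane distance first
#' below 2.6 nm (strict) and second in [2.6, 4.16]; diffusivity ratio first
#' below 25 percent (strict) and second in [25, 35].  Values outside both
#' bands are "neither".  All boundary inclusivities are configurable via
#' [make_band()] since prose thresholds are ambiguous at exact boundaries.
#'
#' @param residence_first,residence_second,hbonds_first,hbonds_second,midplane_first,midplane_second,diffusion_first,diffusion_second
#'   [make_band()] objects.
#' @return object of class \code{"rubric_config"}.
#' @export
rubric_config <- function(
    residence_first = make_band(20, Inf, lo_incl = FALSE),
    residence_second = make_band(12, 20),
    hbonds_first = make_band(0.1, Inf, lo_incl = FALSE),
    hbonds_second = make_band(0.05, 0.1),
    midplane_first = make_band(-Inf, 2.6, hi_incl = FALSE),
    midplane_second = make_band(2.6, 4.16),
    diffusion_first = make_band(-Inf, 25, hi_incl = FALSE),
    diffusion_second = make_band(25, 35)) {
  cfg <- list(
    residence = list(first = residence_first, second = residence_second),
    hbonds = list(first = hbonds_first, second = hbonds_second),
    midplane = list(first = midplane_first, second = midplane_second),
    diffusion_ratio = list(first = diffusion_first,
                           second = diffusion_second))
  for (cr in names(cfg))
    if (bands_overlap(cfg[[cr]]$first, cfg[[cr]]$second))
      stop("first and second bands overlap for criterion: ", cr)
  structure(cfg, class = "rubric_config")
}

#' Per-drug metric bundle for the rubric
#'
#' @param residence named vector \code{c(upper = , lower = )}, percent.
#' @param hbonds named vector \code{c(upper = , lower = )}, bonds/frame.
#' @param midplane named vector \code{c(upper = , lower = )}, nm (mean
#'   distance from the mid-plane on each side).
#' @param diffusion_ratio membrane/bulk diffusivity ratio, percent.
#' @return object of class \code{"metric_bundle"}.
#' @export
metric_bundle <- function(residence = c(upper = NA_real_, lower = NA_real_),
                          hbonds = c(upper = NA_real_, lower = NA_real_),
                          midplane = c(upper = NA_real_, lower = NA_real_),
                          diffusion_ratio = NA_real_) {
  per_leaflet <- function(x, lab) {
    if (is.null(names(x))) names(x) <- c("upper", "lower")[seq_along(x)]
    if (!all(c("upper", "lower") %in% names(x)))
      stop(lab, " needs named upper/lower entries")
    x[c("upper", "lower")]
  }
  structure(list(residence = per_leaflet(residence, "residence"),
                 hbonds = per_leaflet(hbonds, "hbonds"),
                 midplane = per_leaflet(midplane, "midplane"),
                 diffusion_ratio = unname(diffusion_ratio)),
            class = "metric_bundle")
}

.category_order <- c(none = 0, second = 1, first = 2)
.criterion_order <- c("residence", "hbonds", "midplane", "diffusion_ratio")

band_category <- function(x, bands) {
  if (is.na(x)) return(NA_character_)
  if (isTRUE(in_band(x, bands$first))) return("first")
  if (isTRUE(in_band(x, bands$second))) return("second")
  "none"
}

#' Assign rubric categories to per-drug metric bundles
#'
#' For each leaflet-resolved criterion (residence, hydrogen bonds,
#' mid-plane) each leaflet is evaluated against the bands; the drug's
#' overall category for the criterion is the best leaflet's category, and
#' the layer tag records which leaflet(s) achieve it (\code{U}, \code{L},
#' \code{B} for both, \code{-} for none).  The diffusivity-ratio criterion
#' is membrane-wide and carries no layer tag.  A missing metric marks the
#' criterion \code{unavailable} with a warning and is excluded from
#' category counts.
#'
#' @param bundles a named list of [metric_bundle()]s (or a single bundle).
#' @param config a [rubric_config()].
#' @return data frame of class \code{"category_table"}: one row per drug x
#'   criterion with \code{category} and \code{layer}.
#' @export
categorize <- function(bundles, config = rubric_config()) {
  stopifnot(inherits(config, "rubric_config"))
  if (inherits(bundles, "metric_bundle")) bundles <- list(drug = bundles)
  if (is.null(names(bundles))) stop("bundles must be a named list")
  rows <- list()
  for (drug in names(bundles)) {
    b <- bundles[[drug]]
    stopifnot(inherits(b, "metric_bundle"))
    for (cr in .criterion_order) {
      if (cr == "diffusion_ratio") {
        cat_ <- band_category(b$diffusion_ratio, config[[cr]])
        if (is.na(cat_)) {
          warning("drug ", drug, ": diffusion_ratio unavailable")
          cat_ <- "unavailable"
        }
        rows[[length(rows) + 1]] <- data.frame(
          drug = drug, criterion = cr, category = cat_, layer = "-",
          stringsAsFactors = FALSE)
        next
      }
      v <- b[[cr]]
      cats <- c(upper = band_category(v[["upper"]], config[[cr]]),
                lower = band_category(v[["lower"]], config[[cr]]))
      if (all(is.na(cats))) {
        warning("drug ", drug, ": ", cr, " unavailable")
        rows[[length(rows) + 1]] <- data.frame(
          drug = drug, criterion = cr, category = "unavailable",
          layer = "-", stringsAsFactors = FALSE)
        next
      }
      lv <- .category_order[cats[!is.na(cats)]]
      best <- names(.category_order)[max(lv) + 1]
      achieved <- names(cats)[!is.na(cats) & cats == best]
      layer <- if (best == "none") "-"
      else if (length(achieved) == 2) "B"
      else if (achieved == "upper") "U" else "L"
      rows[[length(rows) + 1]] <- data.frame(
        drug = drug, criterion = cr, category = best, layer = layer,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("category_table", "data.frame")
  out
}

#' Render a category table with the conventional symbols
#'
#' First category is shown as \code{*}, second as \code{x}, neither as an
#' empty cell; leaflet-resolved criteria are prefixed with their layer tag.
#'
#' @param x a [categorize()] result.
#' @param ... unused.
#' @return character matrix (drugs x criteria), invisibly printed.
#' @export
format.category_table <- function(x, ...) {
  sym <- c(first = "*", second = "x", none = "", unavailable = "?")
  drugs <- unique(x$drug)
  out <- matrix("", length(drugs), length(.criterion_order),
                dimnames = list(drugs, .criterion_order))
  for (i in seq_len(nrow(x))) {
    s <- sym[[x$category[i]]]
    if (nzchar(s) && x$layer[i] %in% c("U", "L", "B"))
      s <- paste0(x$layer[i], s)
    out[x$drug[i], x$criterion[i]] <- s
  }
  out
}

#' @export
print.category_table <- function(x, ...) {
  print(format(x))
  invisible(x)
}

#' Rank drugs from a category table
#'
#' Drugs are ordered by: number of first-category criteria (descending),
#' then number of second-category criteria (descending), then layer breadth
#' on the residence criterion (both layers beat a single layer), then a
#' criterion-priority comparison (marks on residence outrank marks on
#' hydrogen bonds, then mid-plane, then diffusivity) — an artifact
#' convention for deterministic output, not a scientific claim — and
#' finally alphabetically with an explicit tie annotation.
#'
#' @param table a [categorize()] result covering the compared drugs.
#' @return data frame with \code{rank}, \code{drug}, \code{n_first},
#'   \code{n_second}, \code{tie_group} and \code{tied}.
#' @export
rank_drugs <- function(table) {
  stopifnot(inherits(table, "category_table"))
  drugs <- unique(table$drug)
  key <- lapply(drugs, function(d) {
    rows <- table[table$drug == d, ]
    prio <- match(rows$criterion, .criterion_order)
    firsts <- sort(prio[rows$category == "first"])
    seconds <- sort(prio[rows$category == "second"])
    res <- rows[rows$criterion == "residence", ]
    breadth <- if (nrow(res) && res$category %in% c("first", "second"))
      switch(res$layer, B = 2L, U = 1L, L = 1L, 0L) else 0L
    list(n_first = length(firsts), n_second = length(seconds),
         breadth = breadth,
         prio_key = paste(c(firsts, 9L, seconds), collapse = ""))
  })
  names(key) <- drugs
  kdf <- data.frame(
    drug = drugs,
    n_first = vapply(key, `[[`, 0L, "n_first"),
    n_second = vapply(key, `[[`, 0L, "n_second"),
    breadth = vapply(key, `[[`, 0L, "breadth"),
    prio_key = vapply(key, `[[`, "", "prio_key"),
    stringsAsFactors = FALSE)
  ord <- order(-kdf$n_first, -kdf$n_second, -kdf$breadth, kdf$prio_key,
               kdf$drug)
  kdf <- kdf[ord, ]
  sig <- paste(kdf$n_first, kdf$n_second, kdf$breadth, kdf$prio_key)
  tie_group <- cumsum(!duplicated(sig))
  rank <- match(tie_group, tie_group) # first position of each group
  data.frame(rank = rank, drug = kdf$drug, n_first = kdf$n_first,
             n_second = kdf$n_second, tie_group = tie_group,
             tied = duplicated(sig) | duplicated(sig, fromLast = TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank correlation between a drug ordering and dipole moments
#'
#' Spearman rank correlation (average ranks under ties) between the
#' anchorage ranking and per-drug dipole moments, used to test whether the
#' dipole moment could serve as a cheap proxy for the ranking.
#'
#' @param ranks named numeric vector of rank positions (smaller = higher
#'   anchorage potential), e.g. \code{setNames(r$rank, r$drug)} from
#'   [rank_drugs()].
#' @param dipoles named numeric vector of dipole moments (Debye) for the
#'   charge-neutral species.
#' @return Spearman correlation coefficient.
#' @export
rank_correlation <- function(ranks, dipoles) {
  common <- intersect(names(ranks), names(dipoles))
  r <- ranks[common]
  d <- dipoles[common]
  keep <- !is.na(r) & !is.na(d)
  if (sum(keep) < 3)
    stop("rank correlation needs at least 3 drugs with both values")
  suppressWarnings(cor(r[keep], d[keep], method = "spearman"))
}
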