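#' Read a GRO structure file
#'
#' Parses the fixed-column GRO dialect (title line, atom count, atom
#' records, box line).  Positions are returned in nm; velocity columns, if
#' present, are ignored.  Only orthorhombic boxes are supported: a
#' triclinic box line (nine fields with non-zero off-diagonal entries)
#' raises an unsupported-format error.
#'
#' @param path file path.
#' @return list with \code{atoms} (a topology skeleton data frame with
#'   \code{atom_id}, \code{name}, \code{residue_name}, \code{residue_id})
#'   and \code{frame} (a [frame()] with time 0).
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3)
    stop("GRO file truncated: fewer than 3 lines")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n < 1)
    stop("GRO parse error at line 2: malformed atom count")
  if (length(lines) < n + 3)
    stop(sprintf(
      "GRO file truncated: %d atom records declared but file ends at line %d",
      n, length(lines)))
  rec <- lines[3:(n + 2)]
  bad <- which(nchar(rec) < 44)
  if (length(bad))
    stop("GRO parse error at line ", bad[1] + 2, ": atom record too short")
  num <- function(s, from, to, what) {
    v <- suppressWarnings(as.numeric(substr(s, from, to)))
    if (anyNA(v))
      stop("GRO parse error at line ", which(is.na(v))[1] + 2,
           ": malformed ", what)
    v
  }
  atoms <- data.frame(
    atom_id      = seq_len(n),
    name         = trimws(substr(rec, 11, 15)),
    residue_name = trimws(substr(rec, 6, 10)),
    residue_id   = as.integer(num(rec, 1, 5, "residue number")),
    stringsAsFactors = FALSE)
  pos <- cbind(num(rec, 21, 28, "x coordinate"),
               num(rec, 29, 36, "y coordinate"),
               num(rec, 37, 44, "z coordinate"))
  bx <- suppressWarnings(as.numeric(strsplit(trimws(lines[n + 3]),
                                             "[ \t]+")[[1]]))
  if (length(bx) < 3 || anyNA(bx))
    stop("GRO parse error at line ", n + 3, ": malformed box line")
  if (length(bx) > 3 && any(bx[4:length(bx)] != 0))
    stop("triclinic boxes are unsupported (line ", n + 3, ")")
  if (any(bx[1:3] <= 0))
    stop("GRO parse error at line ", n + 3, ": non-positive box length")
  list(atoms = atoms, frame = frame(0, bx[1:3], pos))
}

#' Write a GRO structure file
#'
#' @param top a [topology()] or topology skeleton data frame.
#' @param fr a [frame()].
#' @param path output file path.
#' @param title title line content.
#' @return \code{path}, invisibly.
#' @export
write_gro <- function(top, fr, path, title = "memanchor system") {
  n <- nrow(top)
  if (nrow(fr$positions) != n)
    stop("frame and topology disagree on atom count")
  rec <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                 top$residue_id %% 100000L,
                 substr(top$residue_name, 1, 5),
                 substr(top$name, 1, 5),
                 top$atom_id %% 100000L,
                 fr$positions[, 1], fr$positions[, 2], fr$positions[, 3])
  writeLines(c(title, sprintf("%5d", n), rec,
               sprintf("%10.5f%10.5f%10.5f", fr$box[1], fr$box[2],
                       fr$box[3])), path)
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' The dialect is, per frame: an atom-count line, a comment line carrying
#' \code{time=<ps> box=<Lx>,<Ly>,<Lz>} (nm), then one \code{element x y z}
#' record per atom.  Frames must appear in strictly increasing time order
#' and the atom count must match the topology; truncated files are
#' rejected rather than partially read.
#'
#' @param path file path.
#' @param top the [topology()] the coordinates belong to.
#' @return a [trajectory()].
#' @export
read_xyz_trajectory <- function(path, top) {
  lines <- readLines(path)
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (!length(lines)) stop("empty trajectory file")
  n <- nrow(top)
  n0 <- suppressWarnings(as.integer(trimws(lines[1])))
  if (!is.na(n0) && n0 != n)
    stop(sprintf("frame 1 declares %d atoms but topology has %d", n0, n))
  block <- n + 2L
  if (length(lines) %% block != 0)
    stop(sprintf(
      "trajectory file truncated: %d lines is not a multiple of %d (%d atoms + 2)",
      length(lines), block, n))
  nf <- length(lines) %/% block
  starts <- (0:(nf - 1)) * block
  counts <- suppressWarnings(as.integer(trimws(lines[starts + 1])))
  if (anyNA(counts) || any(counts != n))
    stop(sprintf("frame %d declares %s atoms but topology has %d",
                 which(is.na(counts) | counts != n)[1],
                 counts[which(is.na(counts) | counts != n)[1]], n))
  comments <- lines[starts + 2]
  gettag <- function(tag) {
    m <- regmatches(comments, regexpr(paste0(tag, "=[^ \t]+"), comments))
    if (length(m) != nf)
      stop("frame comment line missing required '", tag, "=' field")
    sub(paste0(tag, "="), "", m)
  }
  times <- suppressWarnings(as.numeric(gettag("time")))
  if (anyNA(times)) stop("malformed time= field in frame comment")
  boxes <- do.call(rbind, lapply(strsplit(gettag("box"), ","), as.numeric))
  if (ncol(boxes) != 3 || anyNA(boxes) || any(boxes <= 0))
    stop("malformed box= field: need three positive lengths")
  atom_lines <- lines[-c(starts + 1, starts + 2)]
  parts <- strsplit(trimws(atom_lines), "[ \t]+")
  if (any(lengths(parts) < 4))
    stop("malformed atom record in trajectory (need: element x y z)")
  xyz <- vapply(parts, function(p) as.numeric(p[2:4]), numeric(3))
  if (anyNA(xyz)) stop("non-numeric coordinate in trajectory")
  coords <- array(NA_real_, c(n, 3, nf))
  for (k in seq_len(nf))
    coords[, , k] <- t(xyz[, ((k - 1) * n + 1):(k * n)])
  trajectory(top, times = times, boxes = boxes, coords = coords)
}

#' Write an extended-XYZ trajectory
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @param digits decimal places for coordinates (writer precision).
#' @return \code{path}, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path, digits = 6) {
  n <- dim(traj$coords)[1]
  el <- traj$topology$element
  fmt <- paste0("%s %.", digits, "f %.", digits, "f %.", digits, "f")
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames(traj))) {
    writeLines(c(
      sprintf("%d", n),
      sprintf("time=%.6f box=%.6f,%.6f,%.6f", traj$times[k],
              traj$boxes[k, 1], traj$boxes[k, 2], traj$boxes[k, 3]),
      sprintf(fmt, el, traj$coords[, 1, k], traj$coords[, 2, k],
              traj$coords[, 3, k])), con)
  }
  invisible(path)
}

#' Read and write the topology sidecar CSV
#'
#' The sidecar carries the annotations a bare GRO file lacks: element, mass,
#' charge, leaflet label and hydrogen-bond role per atom.  Header columns:
#' \code{atom_id,name,element,mass,charge,residue_name,residue_id,leaflet,hbond_role,bonded_donor_id}.
#'
#' @param path CSV file path.
#' @return [read_topology_csv()] returns a validated [topology()].
#' @export
read_topology_csv <- function(path) {
  topology(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_topology_csv
#' @param top a [topology()].
#' @export
write_topology_csv <- function(top, path) {
  write.csv(as.data.frame(top), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a structure file together with its sidecar annotations
#'
#' Cross-checks the GRO atom records against the sidecar topology (atom
#' count, atom names, residue names) and returns the validated system.
#'
#' @param gro_path GRO structure file.
#' @param csv_path topology sidecar CSV.
#' @return list with \code{topology} and \code{frame}.
#' @export
read_system <- function(gro_path, csv_path) {
  g <- read_gro(gro_path)
  top <- read_topology_csv(csv_path)
  if (nrow(top) != nrow(g$atoms))
    stop(sprintf("sidecar has %d atoms but GRO file has %d",
                 nrow(top), nrow(g$atoms)))
  if (!all(top$name == g$atoms$name) ||
      !all(top$residue_name == g$atoms$residue_name))
    stop("sidecar atom/residue names disagree with the GRO file")
  list(topology = top, frame = g$frame)
}
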