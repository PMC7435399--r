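# Core containers and periodic-boundary geometry.
#
# Internal unit conventions, applied by every reader on ingest:
#   length pm, time ps, mass amu, energy kJ/mol, charge e.
# Boxes are orthorhombic; triclinic cells are rejected.

PM_PER_ANGSTROM <- 100

#' Trajectory container
#'
#' Holds the Cartesian coordinates of every atom in every frame together
#' with the periodic box. Coordinates are stored in picometres as an
#' `n_atoms x 3 x n_frames` array; the box is a per-frame matrix of
#' orthorhombic edge lengths.
#'
#' @param coords numeric array `n_atoms x 3 x n_frames`, pm.
#' @param box numeric matrix `n_frames x 3` of edge lengths (pm), or a
#'   length-3 vector applied to every frame.
#' @param timestep frame spacing in ps.
#' @param wrapped logical; `TRUE` if coordinates are folded into the box.
#' @return An object of class `"Trajectory"`.
#' @export
trajectory <- function(coords, box, timestep = 1, wrapped = TRUE) {
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    stop("coords must be an n_atoms x 3 x n_frames array")
  n_frames <- dim(coords)[3]
  if (is.null(dim(box))) box <- matrix(box, n_frames, 3, byrow = TRUE)
  if (nrow(box) != n_frames || ncol(box) != 3)
    stop("box must be n_frames x 3")
  if (any(!is.finite(coords))) stop("coords must be finite")
  if (any(box <= 0)) stop("all box edges must be positive")
  if (timestep <= 0) stop("timestep must be positive")
  structure(list(coords = coords, box = box, timestep = timestep,
                 wrapped = wrapped),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d atoms, %d frames, dt = %g ps, %s\n",
              n_atoms(x), n_frames(x), x$timestep,
              if (x$wrapped) "wrapped" else "unwrapped"))
  invisible(x)
}

#' @rdname trajectory
#' @param traj a `Trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname trajectory
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' Minimum-image displacement
#'
#' Displacement from `a` to `b` under the minimum image convention in an
#' orthorhombic box. Each component of the result lies in `(-L/2, L/2]`.
#'
#' @param a,b positions (length-3 vectors or n x 3 matrices), pm.
#' @param box length-3 vector of box edge lengths, pm.
#' @return displacement vector(s), same shape as the inputs.
#' @export
minimum_image <- function(a, b, box) {
  if (any(box <= 0)) stop("box edges must be positive")
  d <- b - a
  if (is.matrix(d)) {
    sweep_box <- matrix(box, nrow(d), 3, byrow = TRUE)
    d - sweep_box * ceiling(d / sweep_box - 0.5)
  } else {
    d - box * ceiling(d / box - 0.5)
  }
}

#' Fold coordinates into the primary box
#'
#' Maps every coordinate into `[0, L)` per dimension.
#'
#' @param traj a `Trajectory`.
#' @return a wrapped `Trajectory`.
#' @export
fold_trajectory <- function(traj) {
  # a trajectory produced by unwrap_trajectory() carries its original
  # wrapped coordinates; restoring them makes the round trip bit-identical
  # (pure floating-point re-folding would lose low mantissa bits once the
  # accumulated image offset L*K dwarfs a coordinate)
  if (!traj$wrapped && !is.null(traj$source_wrapped))
    return(trajectory(traj$source_wrapped, traj$box, traj$timestep,
                      wrapped = TRUE))
  co <- traj$coords
  for (f in seq_len(n_frames(traj))) {
    L <- matrix(traj$box[f, ], n_atoms(traj), 3, byrow = TRUE)
    co[, , f] <- co[, , f] - L * floor(co[, , f] / L)
  }
  trajectory(co, traj$box, traj$timestep, wrapped = TRUE)
}

#' Unwrap a periodic trajectory
#'
#' Removes box-crossing jumps so coordinates become continuous in time
#' (required before mean-squared-displacement analysis). Assumes every atom
#' moves less than half a box edge between consecutive frames; larger jumps
#' are ambiguous and raise an error naming the atom and frame.
#'
#' @param traj a wrapped `Trajectory`.
#' @return an unwrapped `Trajectory` whose first frame equals the input's.
#' @export
unwrap_trajectory <- function(traj) {
  if (!traj$wrapped) stop("trajectory is already unwrapped")
  co <- traj$coords
  out <- co
  na <- n_atoms(traj)
  # integer box-crossing counts per atom/dimension: the unwrapped position
  # is wrapped - K * L exactly, so re-folding reproduces the input bitwise
  K <- matrix(0, na, 3)
  for (f in seq_len(n_frames(traj))[-1]) {
    L <- matrix(traj$box[f, ], na, 3, byrow = TRUE)
    d <- co[, , f, drop = TRUE] - co[, , f - 1, drop = TRUE]
    k <- ceiling(d / L - 0.5)
    disp <- d - L * k
    bad <- which(abs(disp) >= L / 2 * (1 - 1e-9), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf(
        "unwrap ambiguous: atom %d moved >= half box edge between frames %d and %d",
        bad[1, 1], f - 1L, f))
    K <- K + k
    out[, , f] <- co[, , f, drop = TRUE] - L * K
  }
  res <- trajectory(out, traj$box, traj$timestep, wrapped = FALSE)
  res$source_wrapped <- co
  res
}

#' Mass-weighted centre of mass of an atom set
#'
#' For wrapped input the molecule is first made whole by minimum-image
#' reconstruction against its first atom; the returned position is folded
#' into `[0, L)`. For unwrapped input this reduces to the arithmetic
#' mass-weighted mean.
#'
#' @param frame n_atoms x 3 coordinate matrix for one frame, pm.
#' @param idx atom indices of the molecule.
#' @param masses per-atom masses for the full frame, amu.
#' @param box length-3 box edges, pm.
#' @param wrapped whether `frame` holds wrapped coordinates.
#' @return length-3 position, pm.
#' @export
center_of_mass <- function(frame, idx, masses, box, wrapped = TRUE) {
  if (length(idx) == 0) stop("empty molecule")
  m <- masses[idx]
  if (sum(m) <= 0) stop("zero total mass")
  xyz <- frame[idx, , drop = FALSE]
  if (wrapped) {
    ref <- xyz[1, ]
    xyz <- matrix(ref, nrow(xyz), 3, byrow = TRUE) +
      minimum_image(matrix(ref, nrow(xyz), 3, byrow = TRUE), xyz, box)
  }
  com <- colSums(xyz * m) / sum(m)
  if (wrapped) com <- com - box * floor(com / box)
  com
}

# ---- readers ---------------------------------------------------------------

#' Read a trajectory file
#'
#' Supports multi-frame XYZ (coordinates in Angstrom) and LAMMPS text dumps
#' (`ITEM: TIMESTEP / NUMBER OF ATOMS / BOX BOUNDS / ATOMS id type x y z`,
#' wrapped `x y z` or unwrapped `xu yu zu` columns). All lengths are
#' converted to pm on ingest. XYZ files carry no box, so it is supplied via
#' `box` (pm) or an extended-XYZ `Lattice="..."` comment (Angstrom,
#' diagonal); LAMMPS dumps carry their own bounds.
#'
#' @param path file path.
#' @param format `"xyz"` or `"lammps-dump"`.
#' @param timestep frame spacing, ps.
#' @param box optional length-3 box edges in pm (XYZ only).
#' @param wrapped whether coordinates are folded (XYZ only; dumps are
#'   detected from the column names).
#' @return a `Trajectory`.
#' @export
read_trajectory <- function(path, format = c("xyz", "lammps-dump"),
                            timestep = 1, box = NULL, wrapped = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  if (format == "xyz") read_xyz_lines(lines, timestep, box, wrapped, path)
  else read_dump_lines(lines, timestep, path)
}

byte_offset <- function(lines, line_no) {
  if (line_no <= 1) return(0L)
  sum(nchar(lines[seq_len(line_no - 1)], type = "bytes") + 1L)
}

read_xyz_lines <- function(lines, timestep, box, wrapped, path) {
  frames <- list()
  boxes <- list()
  i <- 1L
  n_ref <- NA_integer_
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat))
      stop(sprintf("malformed XYZ atom-count line %d (byte offset %d) in %s",
                   i, byte_offset(lines, i), path))
    if (i + 1L + nat > length(lines))
      stop(sprintf("truncated final frame in %s: expected %d atoms after byte offset %d",
                   path, nat, byte_offset(lines, i + 1L)))
    comment <- lines[i + 1L]
    fbox <- box
    lat <- regmatches(comment, regexpr('Lattice="[^"]*"', comment))
    if (length(lat) == 1 && is.null(box)) {
      v <- as.numeric(strsplit(gsub('Lattice="|"', "", lat), "\\s+")[[1]])
      if (length(v) != 9 || any(v[c(2, 3, 4, 6, 7, 8)] != 0))
        stop("only orthorhombic (diagonal) Lattice cells are supported")
      fbox <- v[c(1, 5, 9)] * PM_PER_ANGSTROM
    }
    if (is.null(fbox))
      stop(sprintf("missing box: supply `box` (pm) or a Lattice comment for %s", path))
    block <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(block), "\\s+")
    nf <- lengths(toks)
    if (any(nf < 4))
      stop(sprintf("malformed XYZ atom line %d in %s",
                   i + 1L + which(nf < 4)[1], path))
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (any(!is.finite(xyz)))
      stop(sprintf("non-numeric coordinate in frame %d of %s",
                   length(frames) + 1L, path))
    f_no <- length(frames) + 1L
    if (is.na(n_ref)) n_ref <- nat
    else if (nat != n_ref)
      stop(sprintf("atom-count mismatch at frame %d of %s: %d after %d",
                   f_no, path, nat, n_ref))
    frames[[f_no]] <- xyz * PM_PER_ANGSTROM
    boxes[[f_no]] <- fbox
    i <- i + 2L + nat
  }
  if (length(frames) == 0) stop(sprintf("no frames in %s", path))
  co <- array(0, c(n_ref, 3, length(frames)))
  for (f in seq_along(frames)) co[, , f] <- frames[[f]]
  trajectory(co, do.call(rbind, boxes), timestep, wrapped = wrapped)
}

read_dump_lines <- function(lines, timestep, path) {
  frames <- list(); boxes <- list()
  i <- 1L; n_ref <- NA_integer_; wrapped <- TRUE
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    if (!startsWith(lines[i], "ITEM: TIMESTEP"))
      stop(sprintf("expected ITEM: TIMESTEP at line %d (byte offset %d) of %s",
                   i, byte_offset(lines, i), path))
    if (i + 3L > length(lines))
      stop(sprintf("truncated dump header at byte offset %d in %s",
                   byte_offset(lines, i), path))
    if (!startsWith(lines[i + 2L], "ITEM: NUMBER OF ATOMS"))
      stop(sprintf("missing NUMBER OF ATOMS at line %d of %s", i + 2L, path))
    nat <- as.integer(trimws(lines[i + 3L]))
    bhdr <- lines[i + 4L]
    if (!startsWith(bhdr, "ITEM: BOX BOUNDS"))
      stop(sprintf("missing box: no BOX BOUNDS item at line %d of %s", i + 4L, path))
    if (grepl("xy|xz|yz", bhdr))
      stop("triclinic BOX BOUNDS are not supported (orthorhombic only)")
    bl <- t(vapply(lines[(i + 5L):(i + 7L)],
                   function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]][1:2]),
                   numeric(2), USE.NAMES = FALSE))
    fbox <- unname((bl[, 2] - bl[, 1]) * PM_PER_ANGSTROM)
    ahdr <- lines[i + 8L]
    if (!startsWith(ahdr, "ITEM: ATOMS"))
      stop(sprintf("missing ATOMS item at line %d of %s", i + 8L, path))
    cols <- strsplit(sub("ITEM: ATOMS\\s*", "", ahdr), "\\s+")[[1]]
    xyz_cols <- if (all(c("x", "y", "z") %in% cols)) {
      wrapped <- TRUE; match(c("x", "y", "z"), cols)
    } else if (all(c("xu", "yu", "zu") %in% cols)) {
      wrapped <- FALSE; match(c("xu", "yu", "zu"), cols)
    } else stop(sprintf("dump %s has no x y z / xu yu zu columns", path))
    id_col <- match("id", cols)
    if (i + 8L + nat > length(lines))
      stop(sprintf("truncated final frame in %s: expected %d atoms after byte offset %d",
                   path, nat, byte_offset(lines, i + 9L)))
    block <- lines[(i + 9L):(i + 8L + nat)]
    toks <- strsplit(trimws(block), "\\s+")
    dat <- t(vapply(toks, function(tk) as.numeric(tk), numeric(length(cols))))
    xyz <- dat[, xyz_cols, drop = FALSE]
    if (!is.na(id_col)) xyz <- xyz[order(dat[, id_col]), , drop = FALSE]
    f_no <- length(frames) + 1L
    if (is.na(n_ref)) n_ref <- nat
    else if (nat != n_ref)
      stop(sprintf("atom-count mismatch at frame %d of %s: %d after %d",
                   f_no, path, nat, n_ref))
    frames[[f_no]] <- xyz * PM_PER_ANGSTROM
    boxes[[f_no]] <- fbox
    i <- i + 9L + nat
  }
  if (length(frames) == 0) stop(sprintf("no frames in %s", path))
  co <- array(0, c(n_ref, 3, length(frames)))
  for (f in seq_along(frames)) co[, , f] <- frames[[f]]
  trajectory(co, do.call(rbind, boxes), timestep, wrapped = wrapped)
}

# ---- writers (fixture export) ----------------------------------------------

#' Write a trajectory as multi-frame XYZ (Angstrom) or LAMMPS dump
#'
#' Fixture writers so synthetic bundles round-trip through the readers.
#'
#' @param traj a `Trajectory`.
#' @param path output file.
#' @param elements per-atom element symbols (XYZ; default "X").
#' @export
write_xyz <- function(traj, path, elements = NULL) {
  if (is.null(elements)) elements <- rep("X", n_atoms(traj))
  con <- file(path, "w"); on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    L <- traj$box[f, ] / PM_PER_ANGSTROM
    writeLines(as.character(n_atoms(traj)), con)
    writeLines(sprintf('Lattice="%g 0 0 0 %g 0 0 0 %g"', L[1], L[2], L[3]), con)
    xyz <- traj$coords[, , f, drop = TRUE] / PM_PER_ANGSTROM
    if (is.null(dim(xyz))) xyz <- matrix(xyz, 1, 3)
    writeLines(sprintf("%s %.8f %.8f %.8f", elements, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
write_lammps_dump <- function(traj, path) {
  con <- file(path, "w"); on.exit(close(con))
  tag <- if (traj$wrapped) c("x", "y", "z") else c("xu", "yu", "zu")
  for (f in seq_len(n_frames(traj))) {
    L <- traj$box[f, ] / PM_PER_ANGSTROM
    writeLines(c("ITEM: TIMESTEP", as.character(f - 1L),
                 "ITEM: NUMBER OF ATOMS", as.character(n_atoms(traj)),
                 "ITEM: BOX BOUNDS pp pp pp",
                 sprintf("0 %.8f", L)), con)
    writeLines(sprintf("ITEM: ATOMS id type %s", paste(tag, collapse = " ")), con)
    xyz <- traj$coords[, , f, drop = TRUE] / PM_PER_ANGSTROM
    if (is.null(dim(xyz))) xyz <- matrix(xyz, 1, 3)
    writeLines(sprintf("%d 1 %.8f %.8f %.8f", seq_len(n_atoms(traj)),
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}
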