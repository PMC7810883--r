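#' Construct a trajectory
#'
#' Internal units are nm and ns throughout the package (the units in which
#' the contact criteria — 1 nm cutoff, 20 ns dwell — are stated).
#'
#' @param topology a [topology].
#' @param coords_nm numeric array `n_frames x n_atoms x 3`, nm.
#' @param times_ns strictly increasing frame times, ns.
#' @param box_nm optional `n_frames x 3` orthorhombic box edges, nm.
#' @param aligned logical flag set by [align_trajectory()].
#' @param spacing_tol relative tolerance on constant frame spacing; a
#'   warning is emitted when exceeded.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(topology, coords_nm, times_ns, box_nm = NULL,
                       aligned = FALSE, spacing_tol = 1e-6) {
  stopifnot(inherits(topology, "topology"))
  if (length(dim(coords_nm)) != 3L || dim(coords_nm)[3] != 3L) {
    stop("trajectory: coords_nm must be n_frames x n_atoms x 3")
  }
  nf <- dim(coords_nm)[1]
  if (dim(coords_nm)[2] != n_atoms(topology)) {
    stop(sprintf("trajectory: coords have %d atoms, topology has %d",
                 dim(coords_nm)[2], n_atoms(topology)))
  }
  if (!all(is.finite(coords_nm))) stop("trajectory: non-finite coordinates")
  times_ns <- as.numeric(times_ns)
  if (length(times_ns) != nf) stop("trajectory: times/frames length mismatch")
  if (nf > 1L) {
    dt <- diff(times_ns)
    if (any(dt <= 0)) stop("trajectory: times must be strictly increasing")
    if (diff(range(dt)) > spacing_tol * max(abs(dt))) {
      warning("trajectory: frame spacing is not constant within tolerance")
    }
  }
  if (!is.null(box_nm)) {
    box_nm <- matrix(as.numeric(box_nm), nrow = nf, ncol = 3L)
    if (any(box_nm <= 0)) stop("trajectory: box edges must be positive")
  }
  structure(list(topology = topology, coords = coords_nm, times_ns = times_ns,
                 box_nm = box_nm, aligned = isTRUE(aligned)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, t = %.4g..%.4g ns%s%s\n",
              n_frames(x), dim(x$coords)[2], x$times_ns[1],
              x$times_ns[n_frames(x)],
              if (x$aligned) ", aligned" else "",
              if (!is.null(x$box_nm)) ", periodic box" else ""))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory].
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Frame time step in ns
#' @param traj a [trajectory].
#' @export
frame_dt_ns <- function(traj) {
  if (n_frames(traj) < 2L) return(NA_real_)
  stats::median(diff(traj$times_ns))
}

#' Subset trajectory frames
#' @param traj a [trajectory].
#' @param frames integer frame indices (1-based).
#' @export
subset_frames <- function(traj, frames) {
  trajectory(traj$topology, traj$coords[frames, , , drop = FALSE],
             traj$times_ns[frames],
             box_nm = if (!is.null(traj$box_nm)) traj$box_nm[frames, , drop = FALSE],
             aligned = traj$aligned)
}

#' Drop an initial equilibration window
#'
#' By default the first 10% of frames are discarded before computing
#' summary statistics; the discard is explicit and logged by the pipeline.
#'
#' @param traj a [trajectory].
#' @param frac fraction of initial frames to discard, in `[0, 1)`.
#' @export
discard_equilibration <- function(traj, frac = 0.1) {
  stopifnot(frac >= 0, frac < 1)
  nf <- n_frames(traj)
  drop <- floor(nf * frac)
  if (drop == 0L) return(traj)
  subset_frames(traj, (drop + 1L):nf)
}

# ---------------------------------------------------------------------------
# readers / writers: plain-text CSV (long format), multi-model PDB, and DCD
# (binary; written little-endian by write_trajectory, byte order
# auto-detected on read by bio3d).

traj_format <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(format, c("csv", "pdb", "dcd")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "pdb", "dcd")) ext else
    stop("cannot infer trajectory format from extension: ", path)
}

#' Read a trajectory
#'
#' Formats: long CSV (`frame,time_ns,atom_index,x,y,z`, nm/ns), multi-model
#' PDB (Angstrom, converted to nm), or CHARMM/NAMD DCD (Angstrom, converted;
#' times reconstructed from `dt_ns` since DCD carries no physical clock the
#' reader trusts).
#'
#' @param path file path.
#' @param topology the matching [topology].
#' @param format `"csv"`, `"pdb"` or `"dcd"`; inferred from the extension
#'   when `NULL`.
#' @param dt_ns frame spacing for DCD input (default 1 ns).
#' @param units coordinate units of CSV input: `"nm"` (default) or
#'   `"angstrom"` (scaled by 0.1 on read, with a message).
#' @return A [trajectory].
#' @export
read_trajectory <- function(path, topology, format = NULL, dt_ns = 1,
                            units = c("nm", "angstrom")) {
  units <- match.arg(units)
  fmt <- traj_format(path, format)
  if (!file.exists(path)) stop("read_trajectory: no such file: ", path)
  na <- n_atoms(topology)
  if (fmt == "csv") {
    d <- utils::read.csv(path)
    need <- c("frame", "time_ns", "atom_index", "x", "y", "z")
    if (!all(need %in% names(d))) {
      stop("read_trajectory: CSV must have columns ", paste(need, collapse = ","))
    }
    d <- d[order(d$frame, d$atom_index), ]
    frames <- unique(d$frame)
    nf <- length(frames)
    if (nrow(d) != nf * na) {
      bad <- which(tabulate(factor(d$frame, levels = frames)) != na)[1]
      stop(sprintf("read_trajectory: frame %s has wrong atom count (topology has %d)",
                   frames[bad], na))
    }
    co <- array(NA_real_, c(nf, na, 3L))
    co[, , 1] <- matrix(d$x, nf, na, byrow = TRUE)
    co[, , 2] <- matrix(d$y, nf, na, byrow = TRUE)
    co[, , 3] <- matrix(d$z, nf, na, byrow = TRUE)
    if (units == "angstrom") {
      message("read_trajectory: converting Angstrom -> nm (x 0.1)")
      co <- co * 0.1
    }
    times <- d$time_ns[!duplicated(d$frame)]
    return(trajectory(topology, co, times))
  }
  if (fmt == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
    if (ncol(xyz) != 3L * na) {
      stop(sprintf("read_trajectory: PDB model has %d atoms, topology has %d",
                   ncol(xyz) / 3L, na))
    }
    nf <- nrow(xyz)
    co <- array(NA_real_, c(nf, na, 3L))
    for (k in 1:3) co[, , k] <- xyz[, seq(k, 3L * na, by = 3L), drop = FALSE] * 0.1
    return(trajectory(topology, co, seq(0, by = dt_ns, length.out = nf)))
  }
  # dcd via bio3d (independent reader; byte order auto-detected)
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  if (ncol(xyz) != 3L * na) {
    stop(sprintf("read_trajectory: DCD frame has %d atoms, topology has %d",
                 ncol(xyz) / 3L, na))
  }
  nf <- nrow(xyz)
  co <- array(NA_real_, c(nf, na, 3L))
  for (k in 1:3) co[, , k] <- xyz[, seq(k, 3L * na, by = 3L), drop = FALSE] * 0.1
  trajectory(topology, co, seq(0, by = dt_ns, length.out = nf))
}

#' Write a trajectory
#'
#' CSV and multi-model PDB are plain text; DCD is the binary interchange
#' format (CHARMM layout, little-endian, coordinates in Angstrom).
#'
#' @param traj a [trajectory].
#' @param path output file.
#' @param format see [read_trajectory()].
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = NULL) {
  fmt <- traj_format(path, format)
  nf <- n_frames(traj)
  na <- dim(traj$coords)[2]
  if (fmt == "csv") {
    d <- data.frame(
      frame = rep(seq_len(nf) - 1L, each = na),
      time_ns = rep(traj$times_ns, each = na),
      atom_index = rep(traj$topology$atoms$atom_index, nf),
      x = as.numeric(t(traj$coords[, , 1])),
      y = as.numeric(t(traj$coords[, , 2])),
      z = as.numeric(t(traj$coords[, , 3]))
    )
    utils::write.csv(d, path, row.names = FALSE)
    return(invisible(path))
  }
  if (fmt == "pdb") {
    xyz <- matrix(NA_real_, nf, 3L * na)
    for (k in 1:3) xyz[, seq(k, 3L * na, by = 3L)] <- traj$coords[, , k] * 10
    a <- traj$topology$atoms
    bio3d::write.pdb(file = path, xyz = xyz,
                     type = ifelse(a$residue_name %in% c("NA", "SEP"), "HETATM", "ATOM"),
                     resno = a$residue_number, resid = a$residue_name,
                     eleno = a$atom_index + 1L, elety = a$atom_name,
                     chain = a$chain_id, elesy = a$element)
    return(invisible(path))
  }
  write_dcd(traj, path)
}

# CHARMM-layout DCD writer (little-endian; Fortran record markers).
write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  end <- "little"
  rec <- function(write_payload, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4L, endian = end)
    write_payload()
    writeBin(as.integer(nbytes), con, size = 4L, endian = end)
  }
  nf <- n_frames(traj)
  na <- dim(traj$coords)[2]
  dt <- frame_dt_ns(traj)
  if (is.na(dt)) dt <- 1
  # header: CORD + 9 ints, 8-byte DELTA (X-PLOR layout, version slot 0),
  # 9 trailing ints
  rec(function() {
    writeChar("CORD", con, nchars = 4L, eos = NULL)
    icntrl <- integer(9)
    icntrl[1] <- nf       # NSET
    icntrl[2] <- 1L       # ISTART
    icntrl[3] <- 1L       # NSAVC
    icntrl[4] <- nf       # NSTEP
    writeBin(icntrl, con, size = 4L, endian = end)
    writeBin(dt, con, size = 8L, endian = end)  # DELTA (our convention: ns)
    writeBin(integer(9), con, size = 4L, endian = end)
  }, 84L)
  title <- sprintf("pdzdyn trajectory, %d frames, dt = %g ns", nf, dt)
  title <- formatC(substr(title, 1, 80), width = 80, flag = "-")
  rec(function() {
    writeBin(1L, con, size = 4L, endian = end)
    writeChar(title, con, nchars = 80L, eos = NULL)
  }, 4L + 80L)
  rec(function() writeBin(as.integer(na), con, size = 4L, endian = end), 4L)
  for (f in seq_len(nf)) {
    for (k in 1:3) {
      rec(function() {
        writeBin(as.numeric(traj$coords[f, , k]) * 10, con, size = 4L, endian = end)
      }, 4L * na)
    }
  }
  invisible(path)
}
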