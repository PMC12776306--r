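#' Read a coordinate trajectory
#'
#' Two on-disk formats are supported, chosen by extension:
#'
#' * **portable fixture format** (`.tsv`): a plain-text table with columns
#'   `frame`, `atom_id`, `x`, `y`, `z` (frame and atom ids 0-based,
#'   coordinates in Angstrom, full double precision) plus a JSON sidecar
#'   `<path>.json` holding `box`, `frame_interval_ns`, `n_atoms` and
#'   `n_frames`. Round-trips exactly.
#' * **DCD** (`.dcd`): CHARMM/NAMD binary trajectories (little- or
#'   big-endian, optional crystal block; orthorhombic cells only).
#'   Coordinates are single precision on disk.
#'
#' @param path Trajectory file.
#' @param topology The matching [topology()]; the file's atom count must
#'   agree.
#' @param frame_interval_ns Time between frames (ns). Required for DCD;
#'   optional for the portable format when the sidecar records it.
#' @return A `trajectory`.
#' @export
read_trajectory <- function(path, topology, frame_interval_ns = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "dcd") {
    if (is.null(frame_interval_ns)) {
      stop("read_trajectory(): frame_interval_ns is required for DCD files ",
           "(the format does not record wall-clock frame times)",
           call. = FALSE)
    }
    read_dcd(path, topology, frame_interval_ns)
  } else {
    read_portable_trajectory(path, topology, frame_interval_ns)
  }
}

#' Write a trajectory
#'
#' @param traj A `trajectory`.
#' @param path Output path; `.dcd` writes binary DCD, anything else writes
#'   the portable fixture format (TSV + JSON sidecar).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  if (tolower(tools::file_ext(path)) == "dcd") write_dcd(traj, path)
  else write_portable_trajectory(traj, path)
}

portable_sidecar <- function(path) paste0(path, ".json")

write_portable_trajectory <- function(traj, path) {
  nf <- n_frames(traj); na <- n_atoms(traj)
  tbl <- data.frame(
    frame = rep(seq_len(nf) - 1L, each = na),
    atom_id = rep(traj$topology$atom_id, times = nf),
    x = as.vector(t(traj$coords[, , 1])),
    y = as.vector(t(traj$coords[, , 2])),
    z = as.vector(t(traj$coords[, , 3]))
  )
  # %.17g keeps doubles exact across the round trip
  lines <- sprintf("%d\t%d\t%.17g\t%.17g\t%.17g",
                   tbl$frame, tbl$atom_id, tbl$x, tbl$y, tbl$z)
  writeLines(c("frame\tatom_id\tx\ty\tz", lines), path)
  meta <- list(
    format = "pufabind-portable-trajectory", version = 1L,
    n_atoms = na, n_frames = nf,
    frame_interval_ns = traj$frame_interval_ns,
    box = if (is.null(traj$box)) NULL else as.numeric(traj$box)
  )
  jsonlite::write_json(meta, portable_sidecar(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_portable_trajectory <- function(path, topology, frame_interval_ns) {
  meta <- list()
  if (file.exists(portable_sidecar(path))) {
    meta <- jsonlite::read_json(portable_sidecar(path), simplifyVector = TRUE)
  }
  if (is.null(frame_interval_ns)) frame_interval_ns <- meta$frame_interval_ns
  if (is.null(frame_interval_ns)) {
    stop("read_trajectory(): frame_interval_ns not given and not in sidecar",
         call. = FALSE)
  }
  tbl <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "numeric")
  need <- c("frame", "atom_id", "x", "y", "z")
  if (!all(need %in% names(tbl))) {
    stop("read_trajectory(): portable file must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  na <- nrow(topology)
  frames <- sort(unique(tbl$frame))
  nf <- length(frames)
  if (nrow(tbl) != na * nf) {
    stop("read_trajectory(): atom count mismatch: file has ",
         nrow(tbl) / nf, " atoms/frame, topology has ", na, call. = FALSE)
  }
  tbl <- tbl[order(tbl$frame, tbl$atom_id), ]
  coords <- array(0, dim = c(nf, na, 3))
  coords[, , 1] <- matrix(tbl$x, nrow = nf, ncol = na, byrow = TRUE)
  coords[, , 2] <- matrix(tbl$y, nrow = nf, ncol = na, byrow = TRUE)
  coords[, , 3] <- matrix(tbl$z, nrow = nf, ncol = na, byrow = TRUE)
  box <- if (!is.null(meta$box) && length(meta$box) == 3) as.numeric(meta$box)
  trajectory(topology, coords, frame_interval_ns, box = box)
}

# ---- DCD (CHARMM/NAMD binary, Fortran unformatted records) ----

dcd_marker <- function(con, endian, expect = NULL, what = "record marker") {
  m <- readBin(con, "integer", n = 1, size = 4, endian = endian)
  if (length(m) == 0) stop("read_trajectory(): truncated DCD (", what, ")",
                           call. = FALSE)
  if (!is.null(expect) && m != expect) {
    stop("read_trajectory(): bad DCD ", what, " (", m, " != ", expect, ")",
         call. = FALSE)
  }
  m
}

read_dcd <- function(path, topology, frame_interval_ns) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  endian <- if (identical(first, 84L)) "little" else "big"
  if (endian == "big") {
    seek(con, 0)
    dcd_marker(con, endian, 84, "header size")
  }
  magic <- rawToChar(readBin(con, "raw", n = 4))
  if (magic != "CORD") {
    stop("read_trajectory(): not a DCD file (magic '", magic, "')",
         call. = FALSE)
  }
  icntrl <- readBin(con, "integer", n = 20, size = 4, endian = endian)
  dcd_marker(con, endian, 84, "header size")
  has_cell <- icntrl[11] == 1
  n_title_block <- dcd_marker(con, endian, what = "title size")
  ntitle <- readBin(con, "integer", n = 1, size = 4, endian = endian)
  readBin(con, "raw", n = 80 * ntitle)
  dcd_marker(con, endian, n_title_block, "title size")
  dcd_marker(con, endian, 4, "natoms size")
  natoms <- readBin(con, "integer", n = 1, size = 4, endian = endian)
  dcd_marker(con, endian, 4, "natoms size")
  if (natoms != nrow(topology)) {
    stop("read_trajectory(): DCD has ", natoms, " atoms, topology has ",
         nrow(topology), call. = FALSE)
  }
  frames <- list()
  boxes <- list()
  repeat {
    m <- readBin(con, "integer", n = 1, size = 4, endian = endian)
    if (length(m) == 0) break
    if (has_cell) {
      if (m != 48) stop("read_trajectory(): bad DCD cell block at frame ",
                        length(frames) + 1, call. = FALSE)
      cell <- readBin(con, "double", n = 6, size = 8, endian = endian)
      dcd_marker(con, endian, 48, "cell size")
      # CHARMM order: A, gamma, B, beta, alpha, C; angles in degrees or as
      # cosines. Orthorhombic only: angle entries must be 90 or 0 (cos 90).
      ang <- cell[c(2, 4, 5)]
      ortho <- all(abs(ang - 90) < 1e-4) || all(abs(ang) < 1e-6)
      if (!ortho) {
        stop("read_trajectory(): triclinic DCD cells are not supported",
             call. = FALSE)
      }
      boxes[[length(boxes) + 1]] <- cell[c(1, 3, 6)]
      m <- readBin(con, "integer", n = 1, size = 4, endian = endian)
      if (length(m) == 0) break
    }
    if (m != 4 * natoms) {
      stop("read_trajectory(): truncated DCD at frame ", length(frames) + 1,
           call. = FALSE)
    }
    xyz <- matrix(0, natoms, 3)
    for (k in 1:3) {
      if (k > 1) dcd_marker(con, endian, 4 * natoms, "coordinate size")
      v <- readBin(con, "double", n = natoms, size = 4, endian = endian)
      if (length(v) < natoms) {
        stop("read_trajectory(): truncated DCD at frame ",
             length(frames) + 1, call. = FALSE)
      }
      xyz[, k] <- v
      dcd_marker(con, endian, 4 * natoms, "coordinate size")
    }
    frames[[length(frames) + 1]] <- xyz
  }
  if (length(frames) == 0) stop("read_trajectory(): DCD has no frames",
                                call. = FALSE)
  nf <- length(frames)
  coords <- array(0, dim = c(nf, natoms, 3))
  for (f in seq_len(nf)) coords[f, , ] <- frames[[f]]
  box <- if (has_cell && length(boxes) == nf) boxes[[1]]
  if (!is.null(box) && any(box <= 0)) box <- NULL
  trajectory(topology, coords, frame_interval_ns, box = box)
}

write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- n_frames(traj); na <- n_atoms(traj)
  has_cell <- !is.null(traj$box)
  wr_int <- function(x) writeBin(as.integer(x), con, size = 4,
                                 endian = "little")
  icntrl <- integer(20)
  icntrl[1] <- nf       # frames in file
  icntrl[2] <- 1        # first step
  icntrl[3] <- 1        # steps between frames
  icntrl[4] <- nf
  icntrl[11] <- as.integer(has_cell)
  icntrl[20] <- 24      # CHARMM version stamp
  wr_int(84); writeBin(charToRaw("CORD"), con); wr_int(icntrl); wr_int(84)
  title <- sprintf("%-80s", "pufabind trajectory")
  wr_int(80 + 4); wr_int(1); writeBin(charToRaw(title), con); wr_int(80 + 4)
  wr_int(4); wr_int(na); wr_int(4)
  for (f in seq_len(nf)) {
    if (has_cell) {
      cell <- c(traj$box[1], 90, traj$box[2], 90, 90, traj$box[3])
      wr_int(48)
      writeBin(as.double(cell), con, size = 8, endian = "little")
      wr_int(48)
    }
    for (k in 1:3) {
      wr_int(4 * na)
      writeBin(as.double(traj$coords[f, , k]), con, size = 4,
               endian = "little")
      wr_int(4 * na)
    }
  }
  invisible(path)
}
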