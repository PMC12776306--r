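#' Read a PDB structure
#'
#' Parses ATOM/HETATM records of the first model into a [topology()] and a
#' coordinate matrix. Element is taken from columns 77-78 when present,
#' otherwise inferred from the atom name. A CRYST1 record with a 90/90/90
#' cell is read as an orthorhombic box; any other angles are rejected
#' (triclinic boxes are unsupported throughout).
#'
#' @param path Path to a PDB file.
#' @return A `structure3d` (topology + coordinates + optional box).
#' @export
read_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  end_model <- which(rec == "ENDMDL")
  if (length(end_model) > 0) lines <- lines[seq_len(end_model[1] - 1)]
  rec <- substr(lines, 1, 6)
  atom_idx <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(atom_idx) == 0) {
    stop("read_structure(): no ATOM/HETATM records in ", path, call. = FALSE)
  }
  al <- lines[atom_idx]
  short <- which(nchar(al) < 54)
  if (length(short) > 0) {
    stop("read_structure(): malformed ATOM record at line ",
         atom_idx[short[1]], " (needs at least 54 columns)", call. = FALSE)
  }
  x <- suppressWarnings(as.numeric(substr(al, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(al, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(al, 47, 54)))
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0) {
    stop("read_structure(): unparseable coordinates at line ", atom_idx[bad[1]],
         call. = FALSE)
  }
  resno <- suppressWarnings(as.integer(substr(al, 23, 26)))
  if (anyNA(resno)) {
    stop("read_structure(): unparseable residue number at line ",
         atom_idx[which(is.na(resno))[1]], call. = FALSE)
  }
  element <- trimws(substr(al, 77, 78))
  atoms <- tibble::tibble(
    atom_name = trimws(substr(al, 13, 16)),
    residue_number = resno,
    residue_name = trimws(substr(al, 18, 21)),
    chain_id = trimws(substr(al, 22, 22)),
    element = element
  )
  atoms$chain_id[atoms$chain_id == ""] <- "A"
  box <- NULL
  cryst <- lines[rec == "CRYST1"]
  if (length(cryst) > 0) {
    f <- suppressWarnings(as.numeric(c(
      substr(cryst[1], 7, 15), substr(cryst[1], 16, 24),
      substr(cryst[1], 25, 33), substr(cryst[1], 34, 40),
      substr(cryst[1], 41, 47), substr(cryst[1], 48, 54)
    )))
    if (!anyNA(f) && all(f[1:3] > 1)) {
      if (any(abs(f[4:6] - 90) > 1e-3)) {
        stop("read_structure(): triclinic cells are not supported",
             call. = FALSE)
      }
      box <- f[1:3]
    }
  }
  structure3d(topology(atoms), cbind(x, y, z), box = box)
}

#' Write a PDB snapshot
#'
#' @param x A `structure3d`, or a `trajectory` (then `frame` selects the
#'   snapshot).
#' @param path Output path.
#' @param frame 0-based frame index when `x` is a trajectory.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, frame = 0) {
  if (inherits(x, "trajectory")) {
    x <- structure3d(x$topology, frame_coords(x, frame), box = x$box)
  }
  stopifnot(inherits(x, "structure3d"))
  top <- x$topology
  out <- character(0)
  if (!is.null(x$box)) {
    out <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   x$box[1], x$box[2], x$box[3], 90, 90, 90)
  }
  name4 <- ifelse(nchar(top$atom_name) < 4,
                  sprintf(" %-3s", top$atom_name),
                  substr(top$atom_name, 1, 4))
  rectype <- ifelse(top$molecule_kind == "protein", "ATOM  ", "HETATM")
  lines <- sprintf(
    "%s%5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rectype,
    pmin(top$atom_id + 1L, 99999L),
    name4,
    substr(top$residue_name, 1, 4),
    substr(top$chain_id, 1, 1),
    top$residue_number %% 10000L,
    x$coords[, 1], x$coords[, 2], x$coords[, 3],
    1, 0, formatC(top$element, width = 2)
  )
  writeLines(c(out, lines, "END"), path)
  invisible(path)
}
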