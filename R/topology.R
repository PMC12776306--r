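#' Build a topology from an atom table
#'
#' A topology is the static description of the system: one row per atom with
#' its identity and residue membership. Atom ids are 0-based and contiguous;
#' residue numbers are 1-based as in PDB files. A residue is keyed by
#' `(chain_id, residue_number)`.
#'
#' @param atoms A data frame with columns `atom_name`, `residue_number`,
#'   `residue_name`, `chain_id`, and optionally `element` (inferred from the
#'   atom name when missing) and `molecule_kind` (`"protein"`, `"lipid"` or
#'   `"other"`; inferred from the residue name when missing).
#' @return A `topology` object: a tibble of atoms (with 0-based `atom_id`)
#'   carrying class `topology`.
#' @examples
#' top <- topology(data.frame(
#'   atom_name = c("N", "CA", "C"), residue_number = 1,
#'   residue_name = "GLY", chain_id = "A"
#' ))
#' n_atoms(top)
#' @export
topology <- function(atoms) {
  atoms <- tibble::as_tibble(atoms)
  required <- c("atom_name", "residue_number", "residue_name", "chain_id")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    stop("topology(): missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(atoms) == 0) stop("topology(): no atoms", call. = FALSE)
  if (!"element" %in% names(atoms)) {
    atoms$element <- infer_element(atoms$atom_name)
  } else {
    blank <- is.na(atoms$element) | atoms$element == ""
    atoms$element[blank] <- infer_element(atoms$atom_name[blank])
  }
  if (!"molecule_kind" %in% names(atoms)) {
    atoms$molecule_kind <- infer_molecule_kind(atoms$residue_name)
  }
  bad <- !atoms$molecule_kind %in% c("protein", "lipid", "other")
  if (any(bad)) {
    stop("topology(): molecule_kind must be protein/lipid/other, got: ",
         paste(unique(atoms$molecule_kind[bad]), collapse = ", "),
         call. = FALSE)
  }
  atoms$atom_id <- seq_len(nrow(atoms)) - 1L
  atoms$residue_number <- as.integer(atoms$residue_number)
  atoms <- dplyr::relocate(atoms, "atom_id")
  class(atoms) <- c("topology", class(atoms))
  atoms
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology> %d atoms, %d residues\n", nrow(x),
              nrow(unique(x[, c("chain_id", "residue_number")]))))
  NextMethod()
}

#' Number of atoms in a topology or trajectory
#' @param x A `topology`, `structure3d` or `trajectory`.
#' @return Integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "topology")) return(nrow(x))
  if (inherits(x, "structure3d")) return(nrow(x$topology))
  if (inherits(x, "trajectory")) return(nrow(x$topology))
  stop("n_atoms(): unsupported class", call. = FALSE)
}

# Element from the PDB atom-name convention: strip digits/primes, first letter,
# with a two-letter carve-out for common ions. Adequate for protein/lipid atoms.
infer_element <- function(atom_name) {
  nm <- toupper(gsub("[0-9' ]", "", atom_name))
  two <- c("CL", "BR", "NA", "MG", "ZN", "CA", "FE", "MN")
  # atom names like "CA" are alpha carbons, not calcium: only treat a name as a
  # two-letter element when it matches exactly and is not a standard protein name
  el <- substr(nm, 1, 1)
  ion <- nm %in% setdiff(two, c("CA", "NA"))
  el[ion] <- nm[ion]
  el
}

lipid_resnames <- c("DHA", "POPC", "POPE", "POPS", "CHL1", "OLA", "PLM",
                    "DPPC", "DOPC", "LPC")
aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "HSD",
         "HSE", "HSP", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR",
         "TRP", "TYR", "VAL")

infer_molecule_kind <- function(residue_name) {
  rn <- toupper(residue_name)
  dplyr::case_when(
    rn %in% aa3 ~ "protein",
    rn %in% lipid_resnames ~ "lipid",
    TRUE ~ "other"
  )
}

#' Construct a structure (topology plus one coordinate set)
#'
#' @param topology A [topology()] object.
#' @param coords Numeric matrix, `n_atoms x 3`, in Angstrom.
#' @param box Optional numeric length-3 vector of orthorhombic box edge
#'   lengths (Angstrom), or `NULL` for a non-periodic system.
#' @return A `structure3d` object.
#' @export
structure3d <- function(topology, coords, box = NULL) {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  storage.mode(coords) <- "double"
  if (nrow(coords) != nrow(topology) || ncol(coords) != 3) {
    stop("structure3d(): coords must be n_atoms x 3", call. = FALSE)
  }
  check_box(box)
  structure(list(topology = topology, coords = coords, box = box),
            class = "structure3d")
}

check_box <- function(box) {
  if (is.null(box)) return(invisible(NULL))
  if (length(box) != 3 || !is.numeric(box) || any(!is.finite(box)) ||
      any(box <= 0)) {
    stop("box must be 3 strictly positive orthorhombic edge lengths; ",
         "triclinic boxes are not supported", call. = FALSE)
  }
  invisible(NULL)
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("<structure3d> %d atoms%s\n", nrow(x$topology),
              if (is.null(x$box)) "" else
                sprintf(", box %.1f x %.1f x %.1f A", x$box[1], x$box[2], x$box[3])))
  invisible(x)
}

#' Construct a trajectory
#'
#' A trajectory couples one topology with an ordered stack of coordinate
#' frames. Coordinates are stored as an `n_frames x n_atoms x 3` array in
#' Angstrom; times are in nanoseconds. Frame indices are 0-based wherever the
#' package reports them (event tables, ground truth), so `t = frame *
#' frame_interval_ns`.
#'
#' @param topology A [topology()].
#' @param coords Numeric array `n_frames x n_atoms x 3` (Angstrom).
#' @param frame_interval_ns Positive time between successive frames (ns).
#' @param box Optional length-3 box edge lengths (Angstrom), or `NULL`.
#' @param time_ns Optional per-frame times; defaults to
#'   `(0:(n_frames-1)) * frame_interval_ns`.
#' @return A `trajectory` object.
#' @export
trajectory <- function(topology, coords, frame_interval_ns, box = NULL,
                       time_ns = NULL) {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    stop("trajectory(): coords must be n_frames x n_atoms x 3", call. = FALSE)
  }
  if (dim(coords)[2] != nrow(topology)) {
    stop("trajectory(): coordinate atom count (", dim(coords)[2],
         ") does not match topology (", nrow(topology), ")", call. = FALSE)
  }
  if (!is.numeric(frame_interval_ns) || frame_interval_ns <= 0) {
    stop("trajectory(): frame_interval_ns must be positive", call. = FALSE)
  }
  check_box(box)
  n_frames <- dim(coords)[1]
  if (is.null(time_ns)) time_ns <- (seq_len(n_frames) - 1) * frame_interval_ns
  if (length(time_ns) != n_frames || any(diff(time_ns) <= 0) && n_frames > 1) {
    stop("trajectory(): frame times must be strictly increasing", call. = FALSE)
  }
  storage.mode(coords) <- "double"
  structure(
    list(topology = topology, coords = coords, box = box,
         frame_interval_ns = frame_interval_ns, time_ns = time_ns),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, dt = %g ns%s\n",
              n_frames(x), n_atoms(x), x$frame_interval_ns,
              if (is.null(x$box)) "" else
                sprintf(", box %.1f x %.1f x %.1f A",
                        x$box[1], x$box[2], x$box[3])))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  dim(traj$coords)[1]
}

#' Extract one frame's coordinates
#' @param traj A `trajectory`.
#' @param frame 0-based frame index.
#' @return `n_atoms x 3` coordinate matrix (Angstrom).
#' @export
frame_coords <- function(traj, frame) {
  stopifnot(inherits(traj, "trajectory"))
  if (frame < 0 || frame >= n_frames(traj)) {
    stop("frame_coords(): frame ", frame, " out of range [0, ",
         n_frames(traj) - 1, "]", call. = FALSE)
  }
  m <- traj$coords[frame + 1L, , , drop = FALSE]
  dim(m) <- dim(m)[2:3]
  m
}
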