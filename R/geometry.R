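#' Minimum-image distance under orthorhombic periodic boundaries
#'
#' Distance between two points, computed to the nearest periodic image when a
#' box is given: each displacement component is wrapped into `(-L/2, L/2]`
#' before the Euclidean norm. Without a box this is the plain Euclidean
#' distance.
#'
#' @param p,q Numeric length-3 coordinates (Angstrom).
#' @param box Length-3 positive box edge lengths (Angstrom), or `NULL`.
#' @return Distance in Angstrom.
#' @examples
#' min_image_distance(c(1, 1, 1), c(9, 1, 1), box = c(10, 10, 10)) # 2
#' @export
min_image_distance <- function(p, q, box = NULL) {
  if (any(!is.finite(p)) || any(!is.finite(q))) {
    stop("min_image_distance(): non-finite coordinates", call. = FALSE)
  }
  check_box(box)
  d <- p - q
  if (!is.null(box)) d <- d - box * round(d / box)
  sqrt(sum(d * d))
}

# Vectorised minimum-image displacement wrap of a displacement matrix (n x 3).
wrap_disp <- function(d, box) {
  if (is.null(box)) return(d)
  d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
}

# Squared min-image distances between every row of a (n x 3) and b (m x 3):
# returns n x m matrix. Used by the brute-force pair scans.
pair_dist2 <- function(a, b, box) {
  n <- nrow(a); m <- nrow(b)
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  dz <- outer(a[, 3], b[, 3], "-")
  if (!is.null(box)) {
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
    dz <- dz - box[3] * round(dz / box[3])
  }
  dx * dx + dy * dy + dz * dz
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the rotation + translation that minimises the RMSD of `fit_ids`
#' atoms between a mobile and a reference coordinate set, and applies it to
#' all mobile atoms. Reflections are excluded (proper rotation only).
#'
#' @param mobile `n_atoms x 3` coordinates to transform (Angstrom).
#' @param reference `n_atoms x 3` reference coordinates.
#' @param fit_ids 0-based atom ids used for the fit (e.g. from
#'   [select_atoms()]); all atoms move.
#' @return The transformed copy of `mobile`, with attribute `"rmsd"` giving
#'   the post-fit RMSD over the fit atoms.
#' @export
superpose <- function(mobile, reference, fit_ids) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (length(fit_ids) < 3) {
    stop("superpose(): need at least 3 fit atoms", call. = FALSE)
  }
  i <- as.integer(fit_ids) + 1L
  a <- mobile[i, , drop = FALSE]
  b <- reference[i, , drop = FALSE]
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  s <- svd(crossprod(a0, b0))
  # guard against degenerate (collinear) fit sets: rank < 2 leaves the
  # rotation about the shared axis undetermined
  if (s$d[2] < 1e-10 * max(s$d[1], 1)) {
    stop("superpose(): degenerate fit (collinear or coincident fit atoms)",
         call. = FALSE)
  }
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  out <- sweep(sweep(mobile, 2, ca) %*% t(rot), 2, cb, "+")
  fitted <- out[i, , drop = FALSE]
  attr(out, "rmsd") <- sqrt(mean(rowSums((fitted - b)^2)))
  out
}

#' Superpose every frame of a trajectory onto a reference frame
#'
#' Removes global rotation/translation so that occupancy grids are built in a
#' protein-fixed reference frame. Periodic boxes are dropped from the result:
#' after an arbitrary rigid-body rotation the orthorhombic lattice is no
#' longer axis-aligned, so downstream analyses treat aligned trajectories as
#' non-periodic.
#'
#' @param traj A `trajectory`.
#' @param fit_group Atom ids (0-based) or an `atom_group` used for the fit.
#' @param ref_frame 0-based index of the reference frame (default 0).
#' @return A new aligned `trajectory` (box = NULL).
#' @export
align_trajectory <- function(traj, fit_group, ref_frame = 0) {
  ids <- group_ids(fit_group)
  ref <- frame_coords(traj, ref_frame)
  out <- traj$coords
  for (f in seq_len(n_frames(traj))) {
    out[f, , ] <- superpose(traj$coords[f, , ], ref, ids)
  }
  trajectory(traj$topology, out, traj$frame_interval_ns, box = NULL,
             time_ns = traj$time_ns)
}

group_ids <- function(x) {
  if (inherits(x, "atom_group")) return(x$atom_id)
  as.integer(x)
}
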