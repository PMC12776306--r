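#' Grid specification for occupancy maps
#'
#' @param origin Length-3 corner of voxel (0,0,0), Angstrom.
#' @param spacing_A Voxel edge length (default 1, the analysis resolution).
#' @param dims Length-3 positive integer voxel counts.
#' @return A `grid_spec`.
#' @export
grid_spec <- function(origin, spacing_A = 1, dims) {
  origin <- as.numeric(origin)
  dims <- as.integer(dims)
  if (length(origin) != 3 || any(!is.finite(origin))) {
    stop("grid_spec(): origin must be a finite 3-vector", call. = FALSE)
  }
  if (!is.numeric(spacing_A) || spacing_A <= 0) {
    stop("grid_spec(): spacing_A must be positive", call. = FALSE)
  }
  if (length(dims) != 3 || any(dims < 1)) {
    stop("grid_spec(): dims must be 3 positive integers", call. = FALSE)
  }
  structure(list(origin = origin, spacing_A = spacing_A, dims = dims),
            class = "grid_spec")
}

#' Time-averaged fractional occupancy grid
#'
#' Bins a selection of atoms (typically lipid carboxylate carbons) onto a
#' regular voxel lattice, frame by frame. Occupancy is *binary per frame per
#' voxel*: a voxel is occupied in a frame when at least one selected atom
#' falls in it, regardless of how many, and its value is the fraction of
#' frames in which it was occupied. A value of 0.3 therefore means the
#' headgroup was present at that position for at least 30% of the
#' trajectory. Voxel membership uses half-open intervals
#' `[edge, edge + spacing)`.
#'
#' @param traj A `trajectory`.
#' @param selection An `atom_group` (or 0-based ids) of the atoms to bin.
#' @param spec A [grid_spec()], or `NULL` to span the selection's bounding
#'   box over all frames plus `margin_A` on each side at `spacing_A`
#'   resolution.
#' @param align_group Optional `atom_group`: when given, every frame is
#'   first superposed onto frame 0 on these atoms (protein-fixed reference
#'   frame). Default `NULL` (no alignment).
#' @param spacing_A Grid resolution for the auto grid (default 1).
#' @param margin_A Margin for the auto grid (default 5).
#' @return An `occupancy_grid`: `spec`, 3D `values` array in `[0,1]`,
#'   `n_frames`, `selection_label`, and `n_out_of_grid` (atom-frame
#'   placements falling outside the grid, counted as unoccupied with a
#'   warning).
#' @export
build_occupancy <- function(traj, selection, spec = NULL, align_group = NULL,
                            spacing_A = 1, margin_A = 5) {
  stopifnot(inherits(traj, "trajectory"))
  ids <- group_ids(selection)
  if (length(ids) == 0) stop("build_occupancy(): empty selection",
                             call. = FALSE)
  label <- if (inherits(selection, "atom_group")) selection$label else "selection"
  if (!is.null(align_group)) traj <- align_trajectory(traj, align_group)
  nf <- n_frames(traj)
  sel <- traj$coords[, ids + 1L, , drop = FALSE]
  if (is.null(spec)) {
    lo <- apply(sel, 3, min) - margin_A
    hi <- apply(sel, 3, max) + margin_A
    dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing_A)))
    spec <- grid_spec(lo, spacing_A, dims)
  }
  stopifnot(inherits(spec, "grid_spec"))
  d <- spec$dims
  counts <- array(0L, dim = d)
  n_out <- 0L
  for (f in seq_len(nf)) {
    xyz <- sel[f, , , drop = FALSE]
    dim(xyz) <- dim(sel)[2:3]
    v <- floor(sweep(xyz, 2, spec$origin) / spec$spacing_A)
    inside <- v[, 1] >= 0 & v[, 1] < d[1] & v[, 2] >= 0 & v[, 2] < d[2] &
      v[, 3] >= 0 & v[, 3] < d[3]
    n_out <- n_out + sum(!inside)
    if (!any(inside)) next
    lin <- unique(1 + v[inside, 1] + d[1] * (v[inside, 2] + d[2] * v[inside, 3]))
    counts[lin] <- counts[lin] + 1L   # binary per frame: unique voxels only
  }
  if (n_out > 0) {
    warning("build_occupancy(): ", n_out, " atom placement(s) fell outside ",
            "the grid and count as unoccupied", call. = FALSE)
  }
  structure(
    list(spec = spec, values = counts / nf, n_frames = nf,
         selection_label = label, n_out_of_grid = n_out),
    class = "occupancy_grid"
  )
}

#' @export
print.occupancy_grid <- function(x, ...) {
  d <- x$spec$dims
  cat(sprintf(
    "<occupancy_grid> %d x %d x %d voxels @ %g A, %d frames, max %.3f\n",
    d[1], d[2], d[3], x$spec$spacing_A, x$n_frames, max(x$values)))
  invisible(x)
}

#' Voxels at or above an iso-threshold
#'
#' The display convention for occupancy maps: an iso-value of 0.3 keeps the
#' regions where the selection was present for at least 30% of frames.
#'
#' @param grid An `occupancy_grid`.
#' @param iso Threshold in `[0,1]` (default 0.3); voxels with
#'   `value >= iso` are kept.
#' @return Tibble of kept voxels: 0-based indices `ix`, `iy`, `iz`, voxel
#'   center coordinates `x`, `y`, `z` (Angstrom) and `occupancy`.
#' @export
threshold_voxels <- function(grid, iso = 0.3) {
  stopifnot(inherits(grid, "occupancy_grid"))
  if (iso < 0 || iso > 1) stop("threshold_voxels(): iso must be in [0,1]",
                               call. = FALSE)
  idx <- which(grid$values >= iso, arr.ind = TRUE)
  sp <- grid$spec
  tibble::tibble(
    ix = idx[, 1] - 1L, iy = idx[, 2] - 1L, iz = idx[, 3] - 1L,
    x = sp$origin[1] + (idx[, 1] - 0.5) * sp$spacing_A,
    y = sp$origin[2] + (idx[, 2] - 0.5) * sp$spacing_A,
    z = sp$origin[3] + (idx[, 3] - 0.5) * sp$spacing_A,
    occupancy = grid$values[idx]
  )
}

#' Extract a 2D slice of an occupancy grid
#'
#' Picks the grid layer nearest to a requested z level (the cross-section
#' style of the 2D occupancy panels).
#'
#' @param grid An `occupancy_grid`.
#' @param z_level_A z coordinate (Angstrom); must lie within the grid
#'   extent. The layer index is `round((z - origin_z) / spacing)`.
#' @return A `slice_map`: the 2D `values` matrix (x by y), `z_level_A`
#'   requested, `layer` used (0-based) and the parent `spec`.
#' @export
slice_map <- function(grid, z_level_A) {
  stopifnot(inherits(grid, "occupancy_grid"))
  sp <- grid$spec
  zmax <- sp$origin[3] + sp$dims[3] * sp$spacing_A
  if (z_level_A < sp$origin[3] || z_level_A > zmax) {
    stop("slice_map(): z = ", z_level_A, " outside grid extent [",
         sp$origin[3], ", ", zmax, "]", call. = FALSE)
  }
  layer <- as.integer(round((z_level_A - sp$origin[3]) / sp$spacing_A))
  layer <- max(0L, min(sp$dims[3] - 1L, layer))
  structure(
    list(values = matrix(grid$values[, , layer + 1L], sp$dims[1], sp$dims[2]),
         z_level_A = z_level_A, layer = layer, spec = sp),
    class = "slice_map"
  )
}

#' @export
print.slice_map <- function(x, ...) {
  cat(sprintf("<slice_map> layer %d (z = %g A), %d x %d, max %.3f\n",
              x$layer, x$z_level_A, nrow(x$values), ncol(x$values),
              max(x$values)))
  invisible(x)
}

#' Write / read an occupancy grid as OpenDX
#'
#' Plain-text regular-grid OpenDX, the volumetric exchange format understood
#' by VMD/PyMOL. The fastest-varying index on disk is z (the usual DX
#' convention).
#'
#' @param grid An `occupancy_grid`.
#' @param path Output `.dx` path.
#' @return `write_dx()`: `path` invisibly. `read_dx()`: an
#'   `occupancy_grid` (with `n_frames = NA` unless recorded in the header
#'   comment).
#' @export
write_dx <- function(grid, path) {
  stopifnot(inherits(grid, "occupancy_grid"))
  sp <- grid$spec
  d <- sp$dims
  n <- prod(d)
  # DX wants z fastest: permute from R's x-fastest layout
  vals <- aperm(grid$values, c(3, 2, 1))
  flat <- as.vector(vals)  # now x slowest, z fastest when read in triples
  pad <- c(flat, rep(NA_real_, (3 - n %% 3) %% 3))
  m <- matrix(pad, ncol = 3, byrow = TRUE)
  rows <- apply(m, 1, function(r)
    paste(sprintf("%.10g", r[!is.na(r)]), collapse = " "))
  header <- c(
    sprintf("# pufabind occupancy map: %s, n_frames=%d",
            grid$selection_label, grid$n_frames),
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.10g %.10g %.10g", sp$origin[1], sp$origin[2],
            sp$origin[3]),
    sprintf("delta %.10g 0 0", sp$spacing_A),
    sprintf("delta 0 %.10g 0", sp$spacing_A),
    sprintf("delta 0 0 %.10g", sp$spacing_A),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", n)
  )
  footer <- c("attribute \"dep\" string \"positions\"",
              "object \"density\" class field")
  writeLines(c(header, rows, footer), path)
  invisible(path)
}

#' @rdname write_dx
#' @param path Path to a `.dx` file.
#' @export
read_dx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  g1 <- grep("gridpositions counts", lines, value = TRUE)
  if (length(g1) == 0) stop("read_dx(): no gridpositions object in ", path,
                            call. = FALSE)
  dims <- as.integer(strsplit(trimws(sub(".*counts", "", g1[1])),
                              "\\s+")[[1]])
  og <- grep("^origin", lines, value = TRUE)
  if (length(og) == 0) stop("read_dx(): no origin record", call. = FALSE)
  origin <- as.numeric(strsplit(trimws(sub("^origin", "", og[1])),
                                "\\s+")[[1]])
  dl <- grep("^delta", lines, value = TRUE)
  if (length(dl) != 3) stop("read_dx(): expected 3 delta records",
                            call. = FALSE)
  dm <- t(vapply(dl, function(l)
    as.numeric(strsplit(trimws(sub("^delta", "", l)), "\\s+")[[1]]),
    numeric(3)))
  if (any(abs(dm[upper.tri(dm) | lower.tri(dm)]) > 1e-9) ||
      length(unique(round(diag(dm), 9))) != 1) {
    stop("read_dx(): only cubic axis-aligned voxels are supported",
         call. = FALSE)
  }
  spacing <- unname(dm[1, 1])
  data_at <- grep("data follows", lines)
  if (length(data_at) == 0) stop("read_dx(): no data section", call. = FALSE)
  n <- prod(dims)
  body <- lines[(data_at[1] + 1):length(lines)]
  body <- body[!grepl("attribute|object|component|class", body)]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(body), "\\s+"))))
  vals <- vals[!is.na(vals)]
  if (length(vals) < n) stop("read_dx(): expected ", n, " values, found ",
                             length(vals), call. = FALSE)
  arr <- array(vals[seq_len(n)], dim = rev(dims))   # z fastest on disk
  arr <- aperm(arr, c(3, 2, 1))
  nfr <- sub(".*n_frames=([0-9]+).*", "\\1",
             grep("n_frames=", readLines(path, n = 5), value = TRUE)[1])
  structure(
    list(spec = grid_spec(origin, spacing, dims), values = arr,
         n_frames = if (!is.na(nfr) && grepl("^[0-9]+$", nfr))
           as.integer(nfr) else NA_integer_,
         selection_label = "read_dx", n_out_of_grid = NA_integer_),
    class = "occupancy_grid"
  )
}
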