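#' Per-residue, per-frame contact numbers
#'
#' The contact number of a residue in a frame is the count of (lipid atom,
#' residue atom) pairs whose minimum-image distance is at or below the
#' cutoff (4 Angstrom between heavy atoms by convention). Counts aggregate
#' over all lipid copies in `lipid_group`. Hydrogens in either group are
#' removed with a warning before counting.
#'
#' Two equivalent engines are provided: `method = "cell"` (default) bins
#' atoms into a cutoff-sized cell list and only scans neighbouring cells;
#' `method = "brute"` scans all pairs. They give identical counts; the cell
#' list is simply faster on large systems.
#'
#' @param traj A `trajectory`.
#' @param lipid_group `atom_group` of lipid contact atoms (e.g. the DHA
#'   carboxylate group; see [carboxylate_preset()]).
#' @param residue_groups Named list of per-residue `atom_group`s (heavy
#'   atoms).
#' @param cutoff_A Contact cutoff, Angstrom (default 4, boundary inclusive).
#' @param method `"cell"` or `"brute"`.
#' @return Tibble: `residue`, `frame` (0-based), `n_contacts`, with
#'   attributes `cutoff_A` and `lipid_selection_label`.
#' @export
contact_numbers <- function(traj, lipid_group, residue_groups, cutoff_A = 4,
                            method = c("cell", "brute")) {
  stopifnot(inherits(traj, "trajectory"))
  method <- match.arg(method)
  if (cutoff_A <= 0) stop("contact_numbers(): cutoff_A must be positive",
                          call. = FALSE)
  residue_groups <- name_groups(residue_groups, "residue")
  lab <- if (inherits(lipid_group, "atom_group")) lipid_group$label else "lipid"
  lids <- drop_hydrogens(traj$topology, group_ids(lipid_group), "lipid group")
  rgs <- lapply(residue_groups, function(g)
    drop_hydrogens(traj$topology, group_ids(g), "residue group"))
  if (length(lids) == 0) stop("contact_numbers(): empty lipid group",
                              call. = FALSE)
  nf <- n_frames(traj)
  box <- traj$box
  counts <- matrix(0L, nrow = nf, ncol = length(rgs))
  for (f in seq_len(nf)) {
    xyz <- frame_coords_raw(traj, f)
    lp <- xyz[lids + 1L, , drop = FALSE]
    for (ri in seq_along(rgs)) {
      rp <- xyz[rgs[[ri]] + 1L, , drop = FALSE]
      if (nrow(rp) == 0) next
      counts[f, ri] <- if (method == "brute") {
        count_pairs_brute(lp, rp, cutoff_A, box)
      } else {
        count_pairs_cell(lp, rp, cutoff_A, box)
      }
    }
  }
  out <- dplyr::bind_rows(lapply(seq_along(rgs), function(ri) {
    tibble::tibble(residue = names(rgs)[ri], frame = seq_len(nf) - 1L,
                   n_contacts = counts[, ri])
  }))
  attr(out, "cutoff_A") <- cutoff_A
  attr(out, "lipid_selection_label") <- lab
  out
}

frame_coords_raw <- function(traj, f1) {
  m <- traj$coords[f1, , , drop = FALSE]
  dim(m) <- dim(m)[2:3]
  m
}

drop_hydrogens <- function(topology, ids, what) {
  el <- topology$element[ids + 1L]
  h <- toupper(el) == "H"
  if (any(h)) {
    warning("contact_numbers(): dropped ", sum(h), " hydrogen(s) from ",
            what, call. = FALSE)
  }
  ids[!h]
}

count_pairs_brute <- function(a, b, cutoff, box) {
  sum(pair_dist2(a, b, box) <= cutoff^2)
}

# Cell-list pair counting. Coordinates are wrapped into [0, L) when periodic;
# cells have edge >= cutoff so only the 27 neighbouring cells need scanning.
# Falls back to the brute scan when the box supports < 3 cells along an axis
# (the neighbour enumeration would wrap onto itself) or the system is small.
count_pairs_cell <- function(a, b, cutoff, box) {
  if (nrow(a) * nrow(b) <= 2500) return(count_pairs_brute(a, b, cutoff, box))
  if (is.null(box)) {
    lo <- pmin(apply(a, 2, min), apply(b, 2, min))
    hi <- pmax(apply(a, 2, max), apply(b, 2, max))
    span <- pmax(hi - lo, cutoff)
    nc <- pmax(1L, floor(span / cutoff))
    cell_of <- function(m) {
      v <- floor(sweep(sweep(m, 2, lo), 2, span / nc, "/"))
      pmin(pmax(v, 0), matrix(nc - 1L, nrow(v), 3, byrow = TRUE))
    }
    periodic <- FALSE
  } else {
    nc <- pmax(1L, floor(box / cutoff))
    if (any(nc < 3)) return(count_pairs_brute(a, b, cutoff, box))
    a <- sweep(a, 2, box, "%%"); b <- sweep(b, 2, box, "%%")
    cell_of <- function(m) {
      v <- floor(sweep(m, 2, box / nc, "/"))
      pmin(v, matrix(nc - 1L, nrow(v), 3, byrow = TRUE))
    }
    periodic <- TRUE
  }
  ca <- cell_of(a); cb <- cell_of(b)
  key <- function(v) 1 + v[, 1] + nc[1] * (v[, 2] + nc[2] * v[, 3])
  bk <- key(cb)
  b_by_cell <- split(seq_len(nrow(b)), bk)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  total <- 0L
  ak <- key(ca)
  for (cell in unique(ak)) {
    ai <- which(ak == cell)
    v0 <- c((cell - 1) %% nc[1],
            ((cell - 1) %/% nc[1]) %% nc[2],
            (cell - 1) %/% (nc[1] * nc[2]))
    neigh <- sweep(off, 2, v0, "+")
    if (periodic) {
      neigh <- sweep(neigh, 2, nc, "%%")
    } else {
      ok <- neigh[, 1] >= 0 & neigh[, 1] < nc[1] &
        neigh[, 2] >= 0 & neigh[, 2] < nc[2] &
        neigh[, 3] >= 0 & neigh[, 3] < nc[3]
      neigh <- neigh[ok, , drop = FALSE]
    }
    nk <- unique(1 + neigh[, 1] + nc[1] * (neigh[, 2] + nc[2] * neigh[, 3]))
    bi <- unlist(b_by_cell[as.character(nk)], use.names = FALSE)
    if (length(bi) == 0) next
    total <- total + count_pairs_brute(a[ai, , drop = FALSE],
                                       b[bi, , drop = FALSE], cutoff,
                                       if (periodic) box else NULL)
  }
  total
}

#' Trajectory-averaged contact summary
#'
#' @param contacts Tibble from [contact_numbers()].
#' @return Tibble per residue: `average_contact_number` (mean over all
#'   frames, zeros included), `max_count`, `fraction_frames_nonzero`,
#'   sorted by average descending.
#' @export
average_contacts <- function(contacts) {
  contacts |>
    dplyr::group_by(.data$residue) |>
    dplyr::summarise(
      average_contact_number = mean(.data$n_contacts),
      max_count = max(.data$n_contacts),
      fraction_frames_nonzero = mean(.data$n_contacts > 0),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$average_contact_number))
}

#' Export the contact heatmap matrix
#'
#' Writes a residues-by-frames TSV with residues ordered by decreasing
#' average contact number and the average as the right-most column (the
#' layout of a contact heatmap with its per-residue mean margin), and
#' optionally renders a PNG heatmap.
#'
#' @param contacts Tibble from [contact_numbers()].
#' @param path Output TSV path.
#' @param png_path Optional PNG path rendered with ggplot2.
#' @return `path`, invisibly.
#' @export
export_contact_heatmap <- function(contacts, path, png_path = NULL) {
  avg <- average_contacts(contacts)
  wide <- contacts |>
    tidyr::pivot_wider(names_from = "frame", values_from = "n_contacts",
                       names_prefix = "frame_") |>
    dplyr::left_join(avg[, c("residue", "average_contact_number")],
                     by = "residue") |>
    dplyr::arrange(match(.data$residue, avg$residue))
  readr::write_tsv(wide, path)
  if (!is.null(png_path)) {
    p <- autoplot.contact_series(contacts)
    try(ggplot2::ggsave(png_path, p, width = 8, height = 0.5 +
                          0.35 * nrow(avg), dpi = 120, limitsize = FALSE),
        silent = TRUE)
  }
  invisible(path)
}

#' Lipid headgroup atom presets
#'
#' The two readings of "the DHA headgroup" used in contact and occupancy
#' analyses: the carboxylate carbon alone (`"carbon"`), or the full
#' carboxylate group of one carbon plus two oxygens (`"group"`, the
#' default). Atom names follow the package's fatty-acid convention
#' (`C1`, `O1`, `O2`); pass `atom_names` to override for other topologies.
#'
#' @param topology A [topology()].
#' @param which `"group"` (C1 + O1 + O2) or `"carbon"` (C1 only).
#' @param resname Lipid residue name (default `"DHA"`).
#' @param atom_names Optional explicit atom-name override.
#' @return An `atom_group`.
#' @export
carboxylate_preset <- function(topology, which = c("group", "carbon"),
                               resname = "DHA", atom_names = NULL) {
  which <- match.arg(which)
  if (is.null(atom_names)) {
    atom_names <- if (which == "carbon") "C1" else c("C1", "O1", "O2")
  }
  expr <- sprintf("resname %s and name %s", resname,
                  paste(atom_names, collapse = " "))
  select_atoms(topology, expr, label = sprintf("carboxylate %s", which))
}

#' Per-lipid headgroup groups
#'
#' Splits a headgroup selection into one `atom_group` per lipid molecule
#' (per residue of the lipid residue name), named `DHA<residue_number>`.
#' These are the `lipid_groups` that [compute_distance_series()] expects.
#'
#' @param topology A [topology()].
#' @inheritParams carboxylate_preset
#' @return Named list of `atom_group`s.
#' @export
per_lipid_groups <- function(topology, which = c("group", "carbon"),
                             resname = "DHA", atom_names = NULL) {
  g <- carboxylate_preset(topology, which, resname, atom_names)
  sub <- topology[topology$atom_id %in% g$atom_id, ]
  keys <- unique(sub[, c("chain_id", "residue_number")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    ids <- sub$atom_id[sub$chain_id == keys$chain_id[i] &
                         sub$residue_number == keys$residue_number[i]]
    atom_group(topology, ids,
               label = paste0(resname, keys$residue_number[i]))
  })
  names(out) <- vapply(out, function(x) x$label, character(1))
  out
}

#' Per-residue sidechain groups for a residue list
#'
#' Builds the named residue `atom_group`s (sidechain heavy atoms by
#' default) that the distance and contact analyses consume, pooling chains
#' under one label per residue number when `pool_chains` (the trimer's three
#' symmetric copies map to one label) or keeping `<chain>:<label>` keys
#' otherwise.
#'
#' @param topology A [topology()].
#' @param residue_numbers Integer residue numbers to analyse.
#' @param part `"sidechain"` (default) or `"heavy"` (all heavy atoms).
#' @param pool_chains Pool symmetric subunits under one residue label
#'   (default TRUE).
#' @return Named list of `atom_group`s labelled `<RESNAME><number>` (e.g.
#'   `ARG63`), or `<chain>:<RESNAME><number>` when not pooling.
#' @export
per_residue_groups <- function(topology, residue_numbers,
                               part = c("sidechain", "heavy"),
                               pool_chains = TRUE) {
  part <- match.arg(part)
  partexpr <- if (part == "sidechain") "sidechain" else "heavy"
  out <- list()
  for (rn in residue_numbers) {
    sub <- topology[topology$residue_number == rn &
                      topology$molecule_kind == "protein", ]
    if (nrow(sub) == 0) {
      warning("per_residue_groups(): no protein atoms for residue ", rn,
              call. = FALSE)
      next
    }
    label0 <- paste0(toupper(sub$residue_name[1]), rn)
    chains <- if (pool_chains) list(unique(sub$chain_id)) else
      as.list(unique(sub$chain_id))
    for (ch in chains) {
      expr <- sprintf("resid %d and chain %s and %s", rn,
                      paste(ch, collapse = " "), partexpr)
      label <- if (pool_chains) label0 else
        paste0(paste(ch, collapse = ""), ":", label0)
      g <- withCallingHandlers(
        select_atoms(topology, expr, label = label),
        warning = function(w) invokeRestart("muffleWarning")
      )
      if (length(g$atom_id) == 0) {
        warning("per_residue_groups(): residue ", label,
                " has an empty ", part, " selection; skipped", call. = FALSE)
        next
      }
      out[[label]] <- g
    }
  }
  out
}
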