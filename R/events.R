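#' Per-frame minimum lipid-residue distances
#'
#' For every (lipid, residue) pair, computes the per-frame minimum
#' minimum-image distance between any atom of the lipid group and any atom of
#' the residue group. This is the distance-versus-time series that binding
#' events are called on: a lipid is "at" a residue when its headgroup comes
#' within the cutoff of any sidechain heavy atom.
#'
#' Residue groups with no atoms (e.g. a glycine sidechain) are skipped with a
#' warning.
#'
#' @param traj A `trajectory`.
#' @param lipid_groups Named list of `atom_group`s, one per lipid molecule
#'   (typically the carboxylate carbon of each DHA copy). Names become
#'   `lipid_id`.
#' @param residue_groups Named list of `atom_group`s, one per residue
#'   (typically sidechain heavy atoms). Names become `residue`.
#' @return A tibble with columns `lipid_id`, `residue`, `frame` (0-based),
#'   `time_ns`, `distance_A`, plus the frame interval as attribute
#'   `"frame_interval_ns"`.
#' @export
compute_distance_series <- function(traj, lipid_groups, residue_groups) {
  stopifnot(inherits(traj, "trajectory"))
  lipid_groups <- name_groups(lipid_groups, "lipid")
  residue_groups <- name_groups(residue_groups, "residue")
  empty_res <- vapply(residue_groups, function(g) length(group_ids(g)) == 0,
                      logical(1))
  if (any(empty_res)) {
    warning("compute_distance_series(): skipping residue group(s) with no ",
            "atoms: ", paste(names(residue_groups)[empty_res], collapse = ", "),
            call. = FALSE)
    residue_groups <- residue_groups[!empty_res]
  }
  empty_lip <- vapply(lipid_groups, function(g) length(group_ids(g)) == 0,
                      logical(1))
  if (any(empty_lip)) {
    stop("compute_distance_series(): empty lipid group(s): ",
         paste(names(lipid_groups)[empty_lip], collapse = ", "), call. = FALSE)
  }
  nf <- n_frames(traj)
  box <- traj$box
  out <- vector("list", length(lipid_groups) * length(residue_groups))
  k <- 1L
  for (li in seq_along(lipid_groups)) {
    lids <- group_ids(lipid_groups[[li]]) + 1L
    for (ri in seq_along(residue_groups)) {
      rids <- group_ids(residue_groups[[ri]]) + 1L
      dmin <- rep(Inf, nf)
      for (a in lids) {
        pa <- traj$coords[, a, , drop = FALSE]
        dim(pa) <- c(nf, 3)
        for (b in rids) {
          pb <- traj$coords[, b, , drop = FALSE]
          dim(pb) <- c(nf, 3)
          d <- wrap_disp(pa - pb, box)
          dmin <- pmin(dmin, sqrt(rowSums(d * d)))
        }
      }
      out[[k]] <- tibble::tibble(
        lipid_id = names(lipid_groups)[li],
        residue = names(residue_groups)[ri],
        frame = seq_len(nf) - 1L,
        time_ns = traj$time_ns,
        distance_A = dmin
      )
      k <- k + 1L
    }
  }
  res <- dplyr::bind_rows(out[seq_len(k - 1L)])
  attr(res, "frame_interval_ns") <- traj$frame_interval_ns
  res
}

name_groups <- function(groups, prefix) {
  if (inherits(groups, "atom_group")) groups <- list(groups)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    lb <- vapply(groups, function(g)
      if (inherits(g, "atom_group")) g$label else "", character(1))
    nm <- ifelse(lb == "" | duplicated(lb), paste0(prefix, seq_along(groups)), lb)
    names(groups) <- nm
  }
  groups
}

#' Binding intervals from a boolean bound mask
#'
#' The core event-calling rule. Maximal runs of bound frames are found; runs
#' separated by a gap of *strictly fewer than* `merge_gap_frames` unbound
#' frames are merged into a single event whose span includes the gap frames
#' (the "fewer than 10 consecutive frames" rule: a gap of exactly
#' `merge_gap_frames` splits). Events shorter than `min_event_frames` are
#' dropped after merging. Events touching the first or last frame are flagged
#' censored (their true duration is unknown).
#'
#' @param bound Logical vector, one element per frame.
#' @param merge_gap_frames Non-negative integer; gaps of
#'   `< merge_gap_frames` unbound frames are absorbed (default 10).
#' @param min_event_frames Minimum event length in frames after merging
#'   (default 1).
#' @return Tibble with 0-based inclusive `start_frame`, `end_frame`,
#'   `n_frames`, `censored_start`, `censored_end`.
#' @examples
#' binding_intervals(c(TRUE, TRUE, FALSE, TRUE, TRUE), merge_gap_frames = 10)
#' @export
binding_intervals <- function(bound, merge_gap_frames = 10L,
                              min_event_frames = 1L) {
  bound <- as.logical(bound)
  if (anyNA(bound)) stop("binding_intervals(): NA in bound mask",
                         call. = FALSE)
  if (merge_gap_frames < 0 || min_event_frames < 0) {
    stop("binding_intervals(): negative frame thresholds", call. = FALSE)
  }
  n <- length(bound)
  empty <- tibble::tibble(
    start_frame = integer(0), end_frame = integer(0), n_frames = integer(0),
    censored_start = logical(0), censored_end = logical(0)
  )
  if (n == 0 || !any(bound)) return(empty)
  r <- rle(bound)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bs <- starts[r$values] - 1L   # 0-based run starts
  be <- ends[r$values] - 1L
  # merge runs whose separating gap is strictly shorter than merge_gap_frames
  if (length(bs) > 1 && merge_gap_frames > 0) {
    gaps <- bs[-1] - be[-length(be)] - 1L
    keep_break <- gaps >= merge_gap_frames
    grp <- cumsum(c(TRUE, keep_break))
    bs <- as.integer(tapply(bs, grp, min))
    be <- as.integer(tapply(be, grp, max))
  }
  len <- be - bs + 1L
  keep <- len >= min_event_frames
  tibble::tibble(
    start_frame = bs[keep], end_frame = be[keep], n_frames = len[keep],
    censored_start = bs[keep] == 0L, censored_end = be[keep] == n - 1L
  )
}

#' Detect binding events in distance series
#'
#' Applies the bound criterion `distance_A <= cutoff_A` (boundary inclusive,
#' reading "within 5 A" as closed) per (lipid, residue) pair and calls
#' [binding_intervals()] on each mask. Gap merging is per pair: simultaneous
#' events by different lipid copies at the same residue remain separate
#' events.
#'
#' @param distances Tibble from [compute_distance_series()] (columns
#'   `lipid_id`, `residue`, `frame`, `distance_A`), or any data frame with
#'   those columns.
#' @param cutoff_A Bound cutoff in Angstrom (default 5).
#' @param merge_gap_frames Gap-merge threshold in frames (default 10; gaps
#'   strictly shorter merge).
#' @param min_event_frames Drop merged events shorter than this (default 1).
#' @param frame_interval_ns Frame interval used to convert spans to
#'   durations; defaults to the `"frame_interval_ns"` attribute of
#'   `distances`.
#' @return Tibble of events: `lipid_id`, `residue`, `start_frame`,
#'   `end_frame` (0-based inclusive), `n_frames`, `duration_ns`
#'   (`n_frames * frame_interval_ns`; a 1-frame event lasts one interval),
#'   `censored_start`, `censored_end`.
#' @export
detect_events <- function(distances, cutoff_A = 5, merge_gap_frames = 10L,
                          min_event_frames = 1L, frame_interval_ns = NULL) {
  if (is.null(frame_interval_ns)) {
    frame_interval_ns <- attr(distances, "frame_interval_ns")
  }
  if (is.null(frame_interval_ns)) {
    stop("detect_events(): frame_interval_ns not given and not carried by ",
         "the distance table", call. = FALSE)
  }
  if (cutoff_A <= 0) stop("detect_events(): cutoff_A must be positive",
                          call. = FALSE)
  distances |>
    dplyr::group_by(.data$lipid_id, .data$residue) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::reframe(binding_intervals(.data$distance_A <= cutoff_A,
                                     merge_gap_frames, min_event_frames)) |>
    dplyr::mutate(duration_ns = .data$n_frames * frame_interval_ns,
                  .after = "n_frames") |>
    dplyr::relocate("lipid_id", "residue")
}

#' Residence-lifetime statistics per residue
#'
#' Aggregates events into the per-residue summary: total number of events
#' (N), mean event duration and longest individual event, pooling all lipid
#' copies (and, by default, all symmetric subunits sharing a residue label).
#' Residues with no events report `NA` mean/longest (rendered as `--` by
#' [write_residence_tsv()]).
#'
#' @param events Event tibble from [detect_events()].
#' @param residues Optional character vector of residue labels that must
#'   appear in the output even with zero events.
#' @param state_label Optional label (e.g. `"Open"`, `"Resting"`) recorded in
#'   a `state` column.
#' @param include_censored Include boundary-truncated events (default TRUE,
#'   flagged in the event table so callers can exclude them).
#' @return Tibble: `residue`, (`state`,) `n_events`, `mean_duration_ns`,
#'   `longest_duration_ns`.
#' @export
residence_stats <- function(events, residues = NULL, state_label = NULL,
                            include_censored = TRUE) {
  if (!include_censored) {
    events <- dplyr::filter(events, !.data$censored_start,
                            !.data$censored_end)
  }
  stats <- events |>
    dplyr::group_by(.data$residue) |>
    dplyr::summarise(
      n_events = dplyr::n(),
      mean_duration_ns = mean(.data$duration_ns),
      longest_duration_ns = max(.data$duration_ns),
      .groups = "drop"
    )
  if (!is.null(residues)) {
    stats <- dplyr::left_join(tibble::tibble(residue = residues), stats,
                              by = "residue")
    stats$n_events[is.na(stats$n_events)] <- 0L
  }
  if (!is.null(state_label)) {
    stats <- dplyr::mutate(stats, state = state_label, .after = "residue")
  }
  stats
}

#' Write events and residence statistics as TSV
#'
#' `write_residence_tsv()` uses the lifetime-table column order
#' (`Residue`, optional `State`, `Total events`, `Mean Duration (ns)`,
#' `Longest event (ns)`) and prints `--` for residues without events.
#'
#' @param events Event tibble from [detect_events()].
#' @param stats Stats tibble from [residence_stats()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  readr::write_tsv(events, path)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
write_residence_tsv <- function(stats, path) {
  fmt_num <- function(x) ifelse(is.na(x), "--", format_compact(x))
  out <- tibble::tibble(
    Residue = stats$residue,
    `Total events` = ifelse(stats$n_events == 0, "--",
                            as.character(stats$n_events)),
    `Mean Duration (ns)` = fmt_num(stats$mean_duration_ns),
    `Longest event (ns)` = fmt_num(stats$longest_duration_ns)
  )
  if ("state" %in% names(stats)) {
    out <- tibble::add_column(out, State = stats$state, .after = "Residue")
  }
  readr::write_tsv(out, path)
  invisible(path)
}

format_compact <- function(x) {
  formatC(x, format = "fg", digits = 6, flag = "#") |>
    sub("\\.?0+$", "", x = _) |>
    trimws()
}

#' Read back an exported event TSV
#' @param path File written by [write_events_tsv()].
#' @return Event tibble.
#' @export
read_events_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
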