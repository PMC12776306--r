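#' Specification of the two-state binding kinetics simulator
#'
#' The generator emulates, at toy scale, a membrane system in which lipid
#' headgroup particles alternate between a diffusive unbound state and a
#' site-bound state: the statistical structure (geometric dwell times,
#' spatial proximity within a cutoff, optional sub-threshold "flickers")
#' that the residence-time analysis assumes, and nothing more. Defaults
#' state the reference conditions once: a ~100 Angstrom cubic box (the scale
#' of the membrane simulation boxes), three binding sites (a homotrimer's
#' symmetric copies), dt = 1 ns, `p_off = 0.01`/frame so the analytic mean
#' dwell is `dt / p_off = 100 ns` (the scale of the reported resting-state
#' mean lifetimes), and a 10:1 background:headgroup composition label.
#'
#' @param n_lipids Number of tracked headgroup particles (default 10, i.e.
#'   the minority lipid of a 10:1 mixture at toy scale).
#' @param n_frames Frames to simulate (default 5000).
#' @param frame_interval_ns Frame interval, ns (default 1).
#' @param box Length-3 box, Angstrom (default `c(100, 100, 100)`).
#' @param sites Data frame with columns `x`, `y`, `z` (anchor positions),
#'   optional `residue_number`; default: three sites labelled 63 on chains
#'   A/B/C spread across the box.
#' @param capture_radius_A Radius around an anchor within which an unbound
#'   particle may bind (default 5; must be >= the downstream cutoff).
#' @param p_on Binding probability per frame while inside the capture radius
#'   of a free site (default 0.5).
#' @param p_off Unbinding probability per bound frame (default 0.01).
#' @param bound_jitter_A Placement noise around the anchor while bound
#'   (default 2; must be < `cutoff_A`).
#' @param cutoff_A The downstream bound cutoff the geometry must respect
#'   (default 5).
#' @param flicker_prob Probability per bound frame of starting a brief
#'   sub-threshold excursion (default 0 = disabled).
#' @param max_flicker_frames Flicker lengths are uniform on
#'   `1..max_flicker_frames` (default 3; keep `< merge_gap_frames`
#'   downstream).
#' @param unbound_step_A Per-frame random-walk step scale while unbound
#'   (default 2; toy-scale mixing, not physical lipid diffusion).
#' @param min_unbound_frames Refractory period after a true unbind during
#'   which the particle cannot rebind (default 10). Keeps genuine
#'   inter-event gaps at or above the downstream merge gap, so that gap
#'   merging can never fuse two distinct true events -- true unbound
#'   excursions shorter than the merge threshold would be flickers by
#'   definition.
#' @param planar Restrict unbound diffusion to the membrane headgroup plane
#'   (the z level of the site anchors), the geometry in which lipid
#'   headgroups actually approach TM-facing sidechains (default TRUE).
#'   FALSE gives a full 3D walk.
#' @param start_bound Start lipid `i` bound to site `i` (for `i` up to the
#'   number of sites) at frame 0 (default FALSE).
#' @param seed Integer seed; the same spec + seed reproduce the trajectory
#'   and ground truth exactly.
#' @return A `kinetic_spec` list.
#' @export
kinetic_spec <- function(n_lipids = 10, n_frames = 5000,
                         frame_interval_ns = 1, box = c(100, 100, 100),
                         sites = NULL, capture_radius_A = 5, p_on = 0.5,
                         p_off = 0.01, bound_jitter_A = 2, cutoff_A = 5,
                         flicker_prob = 0, max_flicker_frames = 3,
                         unbound_step_A = 2, min_unbound_frames = 10L,
                         planar = TRUE,
                         start_bound = FALSE, seed = 1L) {
  if (is.null(sites)) {
    sites <- tibble::tibble(
      x = c(30, 70, 50), y = c(30, 30, 75), z = c(50, 50, 50),
      residue_number = 63L, chain_id = c("A", "B", "C")
    )
  }
  sites <- tibble::as_tibble(sites)
  if (is.null(sites$residue_number)) sites$residue_number <- 63L
  if (is.null(sites$chain_id)) sites$chain_id <- LETTERS[seq_len(nrow(sites))]
  spec <- list(
    n_lipids = as.integer(n_lipids), n_frames = as.integer(n_frames),
    frame_interval_ns = frame_interval_ns, box = as.numeric(box),
    sites = sites, capture_radius_A = capture_radius_A, p_on = p_on,
    p_off = p_off, bound_jitter_A = bound_jitter_A, cutoff_A = cutoff_A,
    flicker_prob = flicker_prob,
    max_flicker_frames = as.integer(max_flicker_frames),
    unbound_step_A = unbound_step_A,
    min_unbound_frames = as.integer(min_unbound_frames),
    planar = isTRUE(planar),
    start_bound = isTRUE(start_bound),
    seed = as.integer(seed)
  )
  class(spec) <- "kinetic_spec"
  validate_kinetic_spec(spec)
  spec
}

validate_kinetic_spec <- function(spec) {
  with(spec, {
    if (n_frames < 2) stop("kinetic_spec: n_frames must be >= 2",
                           call. = FALSE)
    if (n_lipids < 1) stop("kinetic_spec: need at least one lipid",
                           call. = FALSE)
    for (p in c(p_on, p_off, flicker_prob)) {
      if (p < 0 || p > 1) stop("kinetic_spec: probabilities must be in [0,1]",
                               call. = FALSE)
    }
    check_box(box)
    if (bound_jitter_A >= cutoff_A) {
      stop("kinetic_spec: bound_jitter_A must be strictly below cutoff_A ",
           "so bound frames always satisfy the bound criterion",
           call. = FALSE)
    }
    if (capture_radius_A < cutoff_A) {
      stop("kinetic_spec: capture_radius_A must be >= cutoff_A",
           call. = FALSE)
    }
    if (max_flicker_frames < 1) {
      stop("kinetic_spec: max_flicker_frames must be >= 1", call. = FALSE)
    }
    if (min_unbound_frames < 0) {
      stop("kinetic_spec: min_unbound_frames must be >= 0", call. = FALSE)
    }
  })
  invisible(spec)
}

#' Simulate a binding trajectory with known ground truth
#'
#' Frame-discrete two-state kinetics per lipid particle:
#'
#' * **unbound**: an isotropic Gaussian random-walk step of scale
#'   `unbound_step_A` with periodic wrapping. A proposed position inside a
#'   free site's capture radius binds with probability `p_on`; otherwise
#'   (and near occupied sites) the particle is reflected just outside the
#'   capture radius, so unbound particles are never within the cutoff of
#'   any site.
#' * **bound**: the particle sits at the site anchor plus isotropic jitter
#'   of at most `bound_jitter_A` (guaranteed inside the cutoff) and unbinds
#'   with probability `p_off` per frame, giving geometric dwell times with
#'   analytic mean `frame_interval_ns / p_off`.
#' * **flickers** (optional): while bound, with probability `flicker_prob`
#'   the particle is displaced just beyond the cutoff for a uniform
#'   `1..max_flicker_frames` frames *without* ending the true event; the
#'   event always resumes with at least one in-cutoff frame afterwards, so
#'   gap merging with any `merge_gap_frames > max_flicker_frames` restores
#'   the flicker-free truth exactly.
#'
#' Sites bind at most one lipid at a time. The emitted topology contains one
#' arginine-like pseudo-residue per site whose single atom (`CZ`) is a
#' sidechain atom at the anchor, and one single-atom lipid residue (`DHA`,
#' atom `C1`) per particle, so the standard selections work unchanged.
#'
#' @param spec A [kinetic_spec()].
#' @return List with `trajectory` (a `trajectory`) and `truth` (tibble of
#'   true events: `lipid_id`, `residue`, `site`, 0-based `start_frame` /
#'   `end_frame`, `n_frames`, `duration_ns`, `censored_start`,
#'   `censored_end`; spans are the flicker-free bound intervals).
#' @export
simulate_binding_trajectory <- function(spec) {
  stopifnot(inherits(spec, "kinetic_spec"))
  validate_kinetic_spec(spec)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  ns <- nrow(spec$sites)
  nl <- spec$n_lipids
  nf <- spec$n_frames
  anchors <- as.matrix(spec$sites[, c("x", "y", "z")])
  site_label <- paste0("ARG", spec$sites$residue_number)
  box <- spec$box

  # state per lipid: 0 = unbound, otherwise site index; flicker_left frames
  bound_site <- integer(nl)
  flicker_left <- integer(nl)
  site_occupied <- logical(ns)
  plane_z <- mean(anchors[, 3])
  pos <- matrix(stats::runif(nl * 3), nl, 3) %*% diag(box)
  if (spec$planar) pos[, 3] <- plane_z
  # keep initial placements clear of all capture spheres
  for (i in seq_len(nl)) {
    pos[i, ] <- push_outside(pos[i, ], anchors, box,
                             spec$capture_radius_A + 1)
  }
  event_start <- integer(nl)
  refract <- integer(nl)
  events <- list()
  if (spec$start_bound) {
    for (i in seq_len(min(nl, ns))) {
      bound_site[i] <- i
      site_occupied[i] <- TRUE
      event_start[i] <- 0L
      # frame 0 is a forced bound frame; unbind decisions start at frame 1
      flicker_left[i] <- -1L
      pos[i, ] <- bound_position(anchors[i, ], spec$bound_jitter_A, box)
    }
  }
  coords <- array(0, dim = c(nf, nl + ns, 3))

  for (f in seq_len(nf)) {
    for (i in seq_len(nl)) {
      if (bound_site[i] == 0L) {
        # unbound: diffuse, then try to bind
        prop <- pos[i, ] + stats::rnorm(3, sd = spec$unbound_step_A)
        if (spec$planar) prop[3] <- plane_z
        prop <- prop %% box
        d2 <- rowSums(wrap_disp(sweep(anchors, 2, prop, "-"), box)^2)
        near <- which(d2 <= spec$capture_radius_A^2)
        bound_now <- FALSE
        if (refract[i] > 0L) {
          refract[i] <- refract[i] - 1L
          near <- integer(0)
        }
        if (length(near) > 0) {
          s <- near[which.min(d2[near])]
          if (!site_occupied[s] && stats::runif(1) <= spec$p_on) {
            bound_site[i] <- s
            site_occupied[s] <- TRUE
            event_start[i] <- f - 1L
            pos[i, ] <- bound_position(anchors[s, ], spec$bound_jitter_A, box)
            bound_now <- TRUE
          }
        }
        if (!bound_now) {
          pos[i, ] <- push_outside(prop, anchors, box,
                                   spec$capture_radius_A + 1e-6)
        }
      } else {
        s <- bound_site[i]
        if (flicker_left[i] > 0L) {
          # mid-flicker: hold just beyond the cutoff; dwell clock suspended
          pos[i, ] <- flicker_position(anchors[s, ], spec, box)
          flicker_left[i] <- flicker_left[i] - 1L
          if (flicker_left[i] == 0L) flicker_left[i] <- -1L
        } else if (flicker_left[i] == -1L) {
          # forced in-cutoff frame after a flicker: the event always resumes
          flicker_left[i] <- 0L
          pos[i, ] <- bound_position(anchors[s, ], spec$bound_jitter_A, box)
        } else if (stats::runif(1) <= spec$p_off) {
          # unbind: this frame is already outside
          events[[length(events) + 1]] <- list(
            lipid = i, site = s, start = event_start[i], end = f - 2L
          )
          site_occupied[s] <- FALSE
          bound_site[i] <- 0L
          refract[i] <- spec$min_unbound_frames
          newp <- pos[i, ] + stats::rnorm(3, sd = spec$unbound_step_A)
          if (spec$planar) newp[3] <- plane_z
          pos[i, ] <- push_outside(newp %% box, anchors, box,
                                   spec$capture_radius_A + 1e-6)
        } else if (spec$flicker_prob > 0 &&
                   stats::runif(1) <= spec$flicker_prob &&
                   (len <- sample.int(spec$max_flicker_frames, 1)) + f <= nf) {
          # out-of-cutoff frames f .. f+len-1 (1-based), then a bound frame
          pos[i, ] <- flicker_position(anchors[s, ], spec, box)
          flicker_left[i] <- if (len == 1L) -1L else len - 1L
        } else {
          pos[i, ] <- bound_position(anchors[s, ], spec$bound_jitter_A, box)
        }
      }
      coords[f, i, ] <- pos[i, ]
    }
    coords[f, nl + seq_len(ns), ] <- anchors
  }
  # close censored events
  for (i in seq_len(nl)) {
    if (bound_site[i] != 0L) {
      events[[length(events) + 1]] <- list(
        lipid = i, site = bound_site[i], start = event_start[i], end = nf - 1L
      )
    }
  }

  lipid_ids <- paste0("DHA", seq_len(nl))
  truth <- if (length(events) == 0) {
    tibble::tibble(lipid_id = character(0), residue = character(0),
                   chain_id = character(0),
                   site = integer(0), start_frame = integer(0),
                   end_frame = integer(0), n_frames = integer(0),
                   duration_ns = numeric(0), censored_start = logical(0),
                   censored_end = logical(0))
  } else {
    ev <- dplyr::bind_rows(lapply(events, tibble::as_tibble))
    tibble::tibble(
      lipid_id = lipid_ids[ev$lipid],
      residue = site_label[ev$site],
      chain_id = spec$sites$chain_id[ev$site],
      site = ev$site,
      start_frame = as.integer(ev$start),
      end_frame = as.integer(ev$end),
      n_frames = as.integer(ev$end - ev$start + 1L),
      duration_ns = (ev$end - ev$start + 1) * spec$frame_interval_ns,
      censored_start = ev$start == 0L,
      censored_end = ev$end == nf - 1L
    ) |>
      dplyr::arrange(.data$lipid_id, .data$residue, .data$start_frame)
  }

  atoms <- tibble::tibble(
    atom_name = c(rep("C1", nl), rep("CZ", ns)),
    residue_number = c(seq_len(nl), spec$sites$residue_number),
    residue_name = c(rep("DHA", nl), rep("ARG", ns)),
    chain_id = c(rep("L", nl), spec$sites$chain_id),
    element = c(rep("C", nl + ns)),
    molecule_kind = c(rep("lipid", nl), rep("protein", ns))
  )
  traj <- trajectory(topology(atoms), coords, spec$frame_interval_ns,
                     box = box)
  list(trajectory = traj, truth = truth, spec = spec,
       analytic_mean_dwell_ns = spec$frame_interval_ns / max(spec$p_off,
                                                             .Machine$double.eps))
}

bound_position <- function(anchor, jitter, box) {
  # isotropic point in a sphere of radius `jitter` around the anchor
  repeat {
    v <- stats::runif(3, -1, 1)
    if (sum(v * v) <= 1) break
  }
  (anchor + v * jitter) %% box
}

flicker_position <- function(anchor, spec, box) {
  # just beyond the cutoff, still inside the capture sphere when possible
  r <- spec$cutoff_A +
    0.5 * max(spec$capture_radius_A - spec$cutoff_A, 0.5)
  u <- stats::rnorm(3)
  u <- u / sqrt(sum(u * u))
  (anchor + u * r) %% box
}

push_outside <- function(p, anchors, box, radius) {
  d <- wrap_disp(matrix(p, 1, 3)[rep(1, nrow(anchors)), , drop = FALSE] -
                   anchors, box)
  d2 <- rowSums(d * d)
  k <- which.min(d2)
  if (d2[k] >= radius^2) return(p)
  dir <- d[k, ]
  nd <- sqrt(d2[k])
  if (nd < 1e-9) {
    dir <- stats::rnorm(3); nd <- sqrt(sum(dir^2))
  }
  (anchors[k, ] + dir / nd * radius * 1.001) %% box
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Specification of the synthetic sweep generator
#'
#' Defaults are the reference protocol: pH 5.5 test pulses sampled at
#' 10 kHz, monoexponential desensitization with tau = 0.390 s (the scale of
#' wild-type decay), fast activation (tau 10 ms), a Hill-type peak-amplitude
#' law with midpoint 6.6 and steepness 4.5 (sign negative so responses grow
#' with acidity, as the verbatim curve requires), and 2% Gaussian noise.
#' The long agonist-free holding period of the real protocol is truncated
#' to the recorded 0.5-s baseline window.
#'
#' @param true_pH05 Generating midpoint (default 6.6).
#' @param true_n Generating signed Hill exponent (default -4.5).
#' @param tau_act_s Activation time constant, s (default 0.010).
#' @param tau_des_s Desensitization time constant, s (default 0.390).
#' @param sampling_hz Sampling rate (default 10000).
#' @param noise_sd Gaussian noise SD as a fraction of the saturating peak
#'   (default 0.02).
#' @param baseline_s Recorded pre-pulse baseline, s (default 0.5).
#' @param pulse_s Pulse duration, s (default 2).
#' @param peak_pA Saturating peak magnitude, pA (default 1000; currents are
#'   inward, i.e. negative).
#' @param pH_list Activation pH series (default the 8 points 7.0 to 5.5).
#' @param n_sweeps Sweeps per pH (default 2, averaged downstream).
#' @param seed Integer seed.
#' @return An `ephys_spec` list.
#' @export
ephys_spec <- function(true_pH05 = 6.6, true_n = -4.5, tau_act_s = 0.010,
                       tau_des_s = 0.390, sampling_hz = 10000,
                       noise_sd = 0.02, baseline_s = 0.5, pulse_s = 2,
                       peak_pA = 1000,
                       pH_list = seq(7.0, 5.5, length.out = 8),
                       n_sweeps = 2, seed = 1L) {
  if (tau_des_s <= 0 || tau_act_s < 0) {
    stop("ephys_spec: time constants must be positive", call. = FALSE)
  }
  if (noise_sd < 0) stop("ephys_spec: noise_sd must be >= 0", call. = FALSE)
  structure(list(
    true_pH05 = true_pH05, true_n = true_n, tau_act_s = tau_act_s,
    tau_des_s = tau_des_s, sampling_hz = sampling_hz, noise_sd = noise_sd,
    baseline_s = baseline_s, pulse_s = pulse_s, peak_pA = peak_pA,
    pH_list = pH_list, n_sweeps = as.integer(n_sweeps),
    seed = as.integer(seed)
  ), class = "ephys_spec")
}

#' Simulate one proton-gated current sweep
#'
#' `I(t) = -A(pH) * (1 - exp(-(t - t0)/tau_act)) * exp(-(t - t0)/tau_des)`
#' for `t >= t0` (inward, hence negative), plus seeded Gaussian noise
#' everywhere; the pre-pulse baseline is noise only. The peak-amplitude law
#' `A(pH) = peak_pA * hill_curve(pH, true_pH05, true_n)` makes the
#' generated dose-response follow the Hill curve by construction. With
#' `tau_act_s = 0` the decay is exactly monoexponential from the pulse
#' onset.
#'
#' @param spec An [ephys_spec()].
#' @param pH Activation pH of this sweep.
#' @param sweep_id Identifier stored on the trace.
#' @param seed Optional per-sweep seed override (defaults to `spec$seed`).
#' @return A `sweep_trace` with attribute `pH`.
#' @export
simulate_current <- function(spec, pH, sweep_id = "sweep1", seed = NULL) {
  stopifnot(inherits(spec, "ephys_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(if (is.null(seed)) spec$seed else seed)
  dt <- 1 / spec$sampling_hz
  t <- seq(0, spec$baseline_s + spec$pulse_s, by = dt)
  t0 <- spec$baseline_s
  amp <- spec$peak_pA * hill_curve(pH, spec$true_pH05, spec$true_n)
  tt <- pmax(t - t0, 0)
  act <- if (spec$tau_act_s > 0) 1 - exp(-tt / spec$tau_act_s) else 1
  ideal <- -amp * act * exp(-tt / spec$tau_des_s)
  ideal[t < t0] <- 0
  noise <- stats::rnorm(length(t), sd = spec$noise_sd * spec$peak_pA)
  tr <- sweep_trace(t, ideal + noise,
                    baseline_window = c(0, t0 * 0.9),
                    pulse_onset_s = t0, sweep_id = sweep_id,
                    condition = sprintf("pH %.2f", pH))
  attr(tr, "pH") <- pH
  tr
}

#' Simulate a full pH-activation experiment
#'
#' Runs `n_sweeps` sweeps at every pH of the protocol, measures peak
#' magnitudes with [decay_time()], averages the sweeps per pH, and returns
#' the peak table ready for [normalize_dose_response()].
#'
#' @param spec An [ephys_spec()].
#' @return Tibble: `pH`, `peak` (mean baseline-subtracted peak magnitude
#'   over the sweeps).
#' @export
simulate_dose_response <- function(spec) {
  stopifnot(inherits(spec, "ephys_spec"))
  rows <- lapply(seq_along(spec$pH_list), function(i) {
    pk <- vapply(seq_len(spec$n_sweeps), function(s) {
      tr <- simulate_current(spec, spec$pH_list[i],
                             sweep_id = sprintf("pH%.2f_s%d",
                                                spec$pH_list[i], s),
                             seed = spec$seed + 1000L * i + s)
      measure_peak(tr)
    }, numeric(1))
    tibble::tibble(pH = spec$pH_list[i], peak = mean(pk))
  })
  dplyr::bind_rows(rows)
}

#' Write the deterministic fixture suite
#'
#' Emits the small, fully synthetic inputs the test-suite and pipeline
#' examples consume: a toy structure (PDB), a binding trajectory in the
#' portable format with its ground-truth event table, sweep CSVs with
#' annotation sidecars, and a manifest JSON recording every file with the
#' seed it was generated from and its SHA-256 checksum. Regenerating with
#' the same seed reproduces every file byte for byte.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Master seed (default 1).
#' @param n_frames Trajectory length (default 600, kept small so the suite
#'   stays fast).
#' @return Invisibly, the manifest as a list.
#' @export
write_fixture_suite <- function(outdir, seed = 1L, n_frames = 600) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  kspec <- kinetic_spec(n_lipids = 6, n_frames = n_frames, seed = seed,
                        flicker_prob = 0.02)
  sim <- simulate_binding_trajectory(kspec)
  pdb <- file.path(outdir, "system.pdb")
  write_structure(structure3d(sim$trajectory$topology,
                              frame_coords(sim$trajectory, 0),
                              box = sim$trajectory$box), pdb)
  trj <- file.path(outdir, "trajectory.tsv")
  write_trajectory(sim$trajectory, trj)
  truth <- file.path(outdir, "ground_truth_events.tsv")
  readr::write_tsv(sim$truth, truth)

  espec <- ephys_spec(seed = seed)
  sweeps <- character(0)
  for (i in seq_along(espec$pH_list)) {
    tr <- simulate_current(espec, espec$pH_list[i],
                           sweep_id = sprintf("sweep_pH%.2f",
                                              espec$pH_list[i]),
                           seed = seed + 7000L + i)
    p <- file.path(outdir, sprintf("sweep_pH%1$.2f.csv", espec$pH_list[i]))
    readr::write_csv(
      tibble::tibble(time_s = tr$time_s,
                     current_pA = round(tr$current, 6)), p)
    jsonlite::write_json(
      list(baseline_window = attr(tr, "baseline_window"),
           pulse_onset_s = attr(tr, "pulse_onset_s"),
           sweep_id = attr(tr, "sweep_id"), pH = attr(tr, "pH")),
      paste0(p, ".json"), auto_unbox = TRUE, digits = NA)
    sweeps <- c(sweeps, p, paste0(p, ".json"))
  }

  files <- c(pdb, trj, portable_sidecar(trj), truth, sweeps)
  manifest <- list(
    generator = "pufabind::write_fixture_suite", version = 1L,
    seed = as.integer(seed), n_frames = as.integer(n_frames),
    files = lapply(files, function(f) list(
      file = basename(f),
      md5 = file_digest(f)
    ))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# base-R file checksum (tools::md5sum; content integrity, not security)
file_digest <- function(path) {
  unname(tools::md5sum(path))
}
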