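test_that("gap merging follows the 'fewer than N frames' rule exactly", {
  # gap of 1 < 10: one event spanning the gap
  ev <- binding_intervals(c(T, T, F, T, T), merge_gap_frames = 10)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_frame, 0)
  expect_equal(ev$end_frame, 4)
  expect_equal(ev$n_frames, 5)
  # gap of exactly 10 splits; 9 merges
  m10 <- c(rep(TRUE, 3), rep(FALSE, 10), rep(TRUE, 3))
  m9 <- c(rep(TRUE, 3), rep(FALSE, 9), rep(TRUE, 3))
  expect_equal(nrow(binding_intervals(m10, 10)), 2)
  expect_equal(nrow(binding_intervals(m9, 10)), 1)
  # all-unbound: zero events
  expect_equal(nrow(binding_intervals(rep(FALSE, 20), 10)), 0)
  # merge_gap 0 never merges
  expect_equal(nrow(binding_intervals(c(T, F, T), 0)), 2)
})

test_that("detected events match the run-length + merge oracle on random masks", {
  set.seed(101)
  for (i in 1:300) {
    n <- sample(10:2000, 1)
    mask <- runif(n) < runif(1, 0.05, 0.9)
    gap <- sample(0:15, 1)
    got <- binding_intervals(mask, gap)
    want <- oracle_events(mask, gap)
    expect_equal(as.data.frame(got[, c("start_frame", "end_frame")]),
                 want, ignore_attr = TRUE)
  }
})

test_that("merging is monotone and idempotent", {
  set.seed(33)
  mask <- runif(500) < 0.4
  prev_n <- Inf
  prev_cov <- -1
  for (gap in c(0, 1, 2, 5, 10, 20)) {
    ev <- binding_intervals(mask, gap)
    covered <- sum(ev$n_frames)
    expect_lte(nrow(ev), prev_n)
    expect_gte(covered, prev_cov)
    prev_n <- nrow(ev)
    prev_cov <- covered
    # idempotence: re-merging the merged mask changes nothing
    remask <- rep(FALSE, length(mask))
    for (k in seq_len(nrow(ev))) {
      remask[(ev$start_frame[k] + 1):(ev$end_frame[k] + 1)] <- TRUE
    }
    again <- binding_intervals(remask, gap)
    expect_identical(again[, c("start_frame", "end_frame")],
                     ev[, c("start_frame", "end_frame")])
  }
})

test_that("bound-frame set is monotone in the cutoff", {
  set.seed(8)
  d <- mask_to_distances(rep(TRUE, 50))
  d$distance_A <- runif(50, 0, 10)
  prev <- rep(FALSE, 50)
  for (cutoff in c(1, 3, 5, 7, 10)) {
    bound <- d$distance_A <= cutoff
    expect_true(all(prev <= bound))  # non-decreasing set
    prev <- bound
  }
})

test_that("distance series equal a brute-force all-pairs scan", {
  top <- toy_arginine_topology()
  set.seed(14)
  nf <- 50
  frames <- lapply(1:nf, function(f) matrix(runif(nrow(top) * 3, 0, 30),
                                            ncol = 3))
  traj <- toy_trajectory(top, frames, dt = 1, box = c(30, 30, 30))
  lip <- list(L1 = select_atoms(top, "resname DHA and name C1"))
  res <- list(R63 = select_atoms(top, "resid 63 and sidechain"))
  ds <- compute_distance_series(traj, lip, res)
  expect_equal(nrow(ds), nf)
  lid <- lip$L1$atom_id + 1
  rid <- res$R63$atom_id + 1
  for (f in c(1, 17, 50)) {
    want <- Inf
    for (b in rid) {
      want <- min(want, oracle_min_image(frames[[f]][lid, ],
                                         frames[[f]][b, ], c(30, 30, 30)))
    }
    expect_equal(ds$distance_A[ds$frame == f - 1], want, tolerance = 1e-12)
  }
})

test_that("per-frame distance takes the minimum over lipid and residue atoms", {
  top <- topology(data.frame(
    atom_name = c("C1", "CB", "CG"),
    residue_number = c(1L, 63L, 63L),
    residue_name = c("DHA", "ARG", "ARG"),
    chain_id = c("L", "A", "A")
  ))
  co <- rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0))
  traj <- toy_trajectory(top, replicate(10, co, simplify = FALSE))
  ds <- compute_distance_series(
    traj, list(L = atom_group(top, 0)),
    list(R63 = atom_group(top, 1:2))
  )
  expect_equal(unique(ds$distance_A), 3)   # min of 3 and 6, constant
  expect_equal(nrow(ds), 10)
})

test_that("empty residue groups are skipped with a warning", {
  top <- topology(data.frame(
    atom_name = c("C1", "N", "CA", "C", "O"),
    residue_number = c(1L, 70L, 70L, 70L, 70L),
    residue_name = c("DHA", "GLY", "GLY", "GLY", "GLY"),
    chain_id = c("L", "A", "A", "A", "A")
  ))
  traj <- toy_trajectory(top, list(matrix(0, 5, 3)))
  gly <- suppressWarnings(select_atoms(top, "resid 70 and sidechain"))
  expect_warning(
    ds <- compute_distance_series(traj, list(L = atom_group(top, 0)),
                                  list(G70 = gly)),
    "no atoms"
  )
  expect_equal(nrow(ds), 0)
})

test_that("residence statistics summarise events as the lifetime table does", {
  ev <- tibble::tibble(
    lipid_id = "L1", residue = "R63",
    start_frame = c(0L, 20L, 60L), end_frame = c(9L, 39L, 89L),
    n_frames = c(10L, 20L, 30L),
    duration_ns = c(10, 20, 30),
    censored_start = c(TRUE, FALSE, FALSE),
    censored_end = FALSE
  )
  st <- residence_stats(ev)
  expect_equal(st$n_events, 3)
  expect_equal(st$mean_duration_ns, 20)
  expect_equal(st$longest_duration_ns, 30)
  # censored exclusion drops the first event
  st2 <- residence_stats(ev, include_censored = FALSE)
  expect_equal(st2$n_events, 2)
  expect_equal(st2$mean_duration_ns, 25)
  # a residue with no events reports N = 0 and NA durations
  st3 <- residence_stats(ev, residues = c("R63", "R65"))
  expect_equal(st3$n_events[st3$residue == "R65"], 0)
  expect_true(is.na(st3$mean_duration_ns[st3$residue == "R65"]))
})

test_that("residence stats on geometric dwells recover the analytic mean", {
  set.seed(42)
  p_off <- 0.01
  dur <- rgeom(2000, p_off) + 1   # geometric dwell, support >= 1 frame
  ev <- tibble::tibble(
    lipid_id = "L1", residue = "R63",
    start_frame = 0L, end_frame = 0L, n_frames = as.integer(dur),
    duration_ns = dur * 1.0, censored_start = FALSE, censored_end = FALSE
  )
  st <- residence_stats(ev)
  expect_equal(st$mean_duration_ns, 100, tolerance = 0.1)
})

test_that("event tables export with the lifetime-table column order", {
  ev <- tibble::tibble(
    lipid_id = c("L1", "L1", "L2"), residue = c("R63", "R65", "R63"),
    start_frame = c(0L, 5L, 8L), end_frame = c(2L, 6L, 9L),
    n_frames = c(3L, 2L, 2L), duration_ns = c(3, 2, 2),
    censored_start = c(TRUE, FALSE, FALSE), censored_end = FALSE
  )
  dir <- withr::local_tempdir()
  evp <- file.path(dir, "events.tsv")
  write_events_tsv(ev, evp)
  back <- read_events_tsv(evp)
  expect_equal(as.data.frame(back), as.data.frame(ev))
  st <- residence_stats(ev, residues = c("R63", "R65", "R68"),
                        state_label = "Open")
  stp <- file.path(dir, "residence_stats.tsv")
  write_residence_tsv(st, stp)
  lines <- readLines(stp)
  expect_equal(strsplit(lines[1], "\t")[[1]],
               c("Residue", "State", "Total events", "Mean Duration (ns)",
                 "Longest event (ns)"))
  # the zero-event residue prints "--" in all three metric columns
  r68 <- strsplit(grep("^R68", lines, value = TRUE), "\t")[[1]]
  expect_equal(r68[3:5], c("--", "--", "--"))
})

test_that("detect_events carries lipid and residue identity through groups", {
  sim <- simulate_binding_trajectory(
    kinetic_spec(n_lipids = 3, n_frames = 400, seed = 9))
  lip <- per_lipid_groups(sim$trajectory$topology, which = "carbon")
  res <- per_residue_groups(sim$trajectory$topology, 63, pool_chains = FALSE)
  ds <- compute_distance_series(sim$trajectory, lip, res)
  ev <- detect_events(ds, merge_gap_frames = 0)
  expect_true(all(ev$lipid_id %in% names(lip)))
  expect_true(all(ev$residue %in% names(res)))
  expect_equal(ev$duration_ns, ev$n_frames * 1.0)
})
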