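# Independent oracles, coded without reference to the package internals.

# Run-length + gap-merge oracle for event detection: walk the mask once,
# recording runs, then merge by explicit scanning of inter-run gaps.
oracle_events <- function(bound, merge_gap, min_frames = 1) {
  n <- length(bound)
  runs <- list()
  i <- 1
  while (i <= n) {
    if (bound[i]) {
      j <- i
      while (j < n && bound[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(runs) == 0) {
    return(data.frame(start_frame = integer(0), end_frame = integer(0)))
  }
  merged <- list(runs[[1]])
  if (length(runs) > 1) {
    for (k in 2:length(runs)) {
      last <- merged[[length(merged)]]
      gap <- runs[[k]][1] - last[2] - 1
      if (gap < merge_gap) {
        merged[[length(merged)]] <- c(last[1], runs[[k]][2])
      } else {
        merged[[length(merged) + 1]] <- runs[[k]]
      }
    }
  }
  out <- do.call(rbind, merged)
  keep <- (out[, 2] - out[, 1] + 1) >= min_frames
  data.frame(start_frame = as.integer(out[keep, 1] - 1),
             end_frame = as.integer(out[keep, 2] - 1))
}

# Brute-force min-image pair-count oracle (plain double loop).
oracle_pair_count <- function(a, b, cutoff, box = NULL) {
  count <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- a[i, ] - b[j, ]
      if (!is.null(box)) d <- d - box * round(d / box)
      if (sqrt(sum(d^2)) <= cutoff) count <- count + 1L
    }
  }
  count
}

# Brute-force 27-image minimum distance (oracle for the min-image formula).
oracle_min_image <- function(p, q, box) {
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    img <- q + c(ix, iy, iz) * box
    best <- min(best, sqrt(sum((p - img)^2)))
  }
  best
}

# Discrete KS distance between completed dwell lengths (frames) and the
# geometric distribution on {1, 2, ...} with parameter p.
ks_geometric <- function(dwell_frames, p) {
  ks <- 0
  for (k in sort(unique(dwell_frames))) {
    ecdf_k <- mean(dwell_frames <= k)
    cdf_k <- 1 - (1 - p)^k
    ks <- max(ks, abs(ecdf_k - cdf_k))
  }
  ks
}

# Small constructed arginine-like topology used across tests.
toy_arginine_topology <- function() {
  topology(data.frame(
    atom_name = c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ",
                  "NH1", "NH2", "HA", "C1", "O1", "O2", "C2"),
    element = c("N", "C", "C", "O", "C", "C", "C", "N", "C", "N", "N",
                "H", "C", "O", "O", "C"),
    residue_number = c(rep(63L, 12), rep(1L, 4)),
    residue_name = c(rep("ARG", 12), rep("DHA", 4)),
    chain_id = c(rep("A", 12), rep("L", 4)),
    molecule_kind = c(rep("protein", 12), rep("lipid", 4))
  ))
}

# Static toy trajectory: given per-frame coordinate list for a topology.
toy_trajectory <- function(top, frames, dt = 1, box = NULL) {
  arr <- array(0, dim = c(length(frames), nrow(top), 3))
  for (f in seq_along(frames)) arr[f, , ] <- frames[[f]]
  trajectory(top, arr, frame_interval_ns = dt, box = box)
}

# Distance tibble from a plain bound mask (distance 0 when bound, 10 when not)
mask_to_distances <- function(mask, dt = 1) {
  d <- tibble::tibble(
    lipid_id = "L1", residue = "R1",
    frame = seq_along(mask) - 1L,
    time_ns = (seq_along(mask) - 1) * dt,
    distance_A = ifelse(mask, 0, 10)
  )
  attr(d, "frame_interval_ns") <- dt
  d
}
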