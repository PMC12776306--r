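# one-atom "lipid" topology used by the grid tests
point_topology <- function() {
  topology(data.frame(atom_name = "C1", residue_number = 1L,
                      residue_name = "DHA", chain_id = "L"))
}

test_that("a particle fixed in one voxel gives exactly its occupancy fraction", {
  top <- point_topology()
  # in voxel (2,2,2) of a 5x5x5 grid at origin 0, spacing 1, for 40/100 frames;
  # elsewhere (voxel (0,0,0)) for the other 60
  frames <- c(lapply(1:40, function(f) matrix(c(2.5, 2.5, 2.5), 1)),
              lapply(1:60, function(f) matrix(c(0.5, 0.5, 0.5), 1)))
  traj <- toy_trajectory(top, frames)
  spec <- grid_spec(c(0, 0, 0), 1, c(5, 5, 5))
  g <- build_occupancy(traj, atom_group(top, 0), spec = spec)
  expect_identical(g$values[3, 3, 3], 0.4)
  expect_identical(g$values[1, 1, 1], 0.6)
  expect_equal(sum(g$values > 0), 2)
  # occupancy mass for a single always-in-grid atom is exactly n_frames
  expect_equal(sum(g$values) * g$n_frames, 100 * 1)
  expect_true(all(g$values >= 0 & g$values <= 1))
})

test_that("per-frame occupancy is binary regardless of atom count", {
  top <- topology(data.frame(atom_name = c("C1", "C1"),
                             residue_number = c(1L, 2L),
                             residue_name = "DHA", chain_id = "L"))
  # both atoms in the same voxel every frame
  frames <- lapply(1:10, function(f) rbind(c(1.2, 1.2, 1.2),
                                           c(1.7, 1.7, 1.7)))
  traj <- toy_trajectory(top, frames)
  spec <- grid_spec(c(0, 0, 0), 1, c(3, 3, 3))
  g2 <- build_occupancy(traj, atom_group(top, 0:1), spec = spec)
  expect_identical(g2$values[2, 2, 2], 1)
  # same value as a single-atom run
  g1 <- build_occupancy(traj, atom_group(top, 0), spec = spec)
  expect_identical(g2$values[2, 2, 2], g1$values[2, 2, 2])
})

test_that("iso-thresholding keeps voxels at or above the level", {
  top <- point_topology()
  frames <- c(lapply(1:40, function(f) matrix(c(2.5, 2.5, 2.5), 1)),
              lapply(1:25, function(f) matrix(c(0.5, 0.5, 0.5), 1)),
              lapply(1:35, function(f) matrix(c(4.5, 4.5, 4.5), 1)))
  traj <- toy_trajectory(top, frames)
  g <- build_occupancy(traj, atom_group(top, 0),
                       spec = grid_spec(c(0, 0, 0), 1, c(5, 5, 5)))
  vox <- threshold_voxels(g, iso = 0.3)
  expect_true(any(vox$ix == 2 & vox$iy == 2 & vox$iz == 2))   # 0.40 kept
  expect_false(any(vox$ix == 0 & vox$iy == 0 & vox$iz == 0))  # 0.25 dropped
  expect_true(any(vox$ix == 4 & vox$occupancy == 0.35))
  # iso 0 keeps the whole grid; nesting property
  expect_equal(nrow(threshold_voxels(g, 0)), 125)
  hi <- threshold_voxels(g, 0.39)
  lo <- threshold_voxels(g, 0.2)
  expect_true(all(paste(hi$ix, hi$iy, hi$iz) %in% paste(lo$ix, lo$iy, lo$iz)))
})

test_that("translation equivariance: shifting frames and origin together", {
  top <- point_topology()
  set.seed(3)
  pts <- lapply(1:30, function(f) matrix(runif(3, 1, 9), 1))
  traj <- toy_trajectory(top, pts)
  shift <- c(11.3, -4.2, 7.7)
  traj2 <- toy_trajectory(top, lapply(pts, function(p) p +
                                        matrix(shift, 1, 3)))
  s1 <- grid_spec(c(0, 0, 0), 1, c(10, 10, 10))
  s2 <- grid_spec(shift, 1, c(10, 10, 10))
  g1 <- build_occupancy(traj, atom_group(top, 0), spec = s1)
  g2 <- build_occupancy(traj2, atom_group(top, 0), spec = s2)
  expect_identical(g1$values, g2$values)
})

test_that("alignment removes rigid global rotation before binning", {
  # 5 protein atoms rotating rigidly + 1 lipid atom co-rotating: after
  # alignment on the protein, the lipid sits still in the protein frame
  top <- topology(data.frame(
    atom_name = c("CA", "CA", "CA", "CA", "CA", "C1"),
    residue_number = c(1:5, 100L),
    residue_name = c(rep("ALA", 5), "DHA"),
    chain_id = c(rep("A", 5), "L")
  ))
  base <- rbind(c(5, 5, 5), c(8, 5, 5), c(5, 9, 5), c(5, 5, 8), c(7, 7, 7),
                c(10, 5, 5))
  rot_z <- function(th) matrix(c(cos(th), sin(th), 0,
                                 -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  frames <- lapply(seq(0, 2, length.out = 20), function(th) base %*% rot_z(th))
  traj <- toy_trajectory(top, frames)
  ca <- select_atoms(top, "name CA")
  g <- build_occupancy(traj, atom_group(top, 5),
                       spec = NULL, align_group = ca, margin_A = 2)
  # all frames collapse onto one voxel
  expect_equal(max(g$values), 1)
  expect_equal(sum(g$values > 0), 1)
})

test_that("atoms outside an explicit grid are tallied, not binned", {
  top <- point_topology()
  frames <- c(lapply(1:5, function(f) matrix(c(1.5, 1.5, 1.5), 1)),
              lapply(1:5, function(f) matrix(c(99, 99, 99), 1)))
  traj <- toy_trajectory(top, frames)
  expect_warning(
    g <- build_occupancy(traj, atom_group(top, 0),
                         spec = grid_spec(c(0, 0, 0), 1, c(3, 3, 3))),
    "outside the grid")
  expect_equal(g$n_out_of_grid, 5)
  expect_equal(g$values[2, 2, 2], 0.5)
})

test_that("slice extraction picks the nearest layer", {
  top <- point_topology()
  frames <- lapply(1:10, function(f) matrix(c(2.5, 2.5, 2.5), 1))
  traj <- toy_trajectory(top, frames)
  g <- build_occupancy(traj, atom_group(top, 0),
                       spec = grid_spec(c(0, 0, 0), 1, c(5, 5, 5)))
  expect_equal(slice_map(g, 0)$layer, 0)
  expect_equal(slice_map(g, 0.4)$layer, 0)    # rounds down
  expect_equal(slice_map(g, 0.6)$layer, 1)    # rounds up
  sl <- slice_map(g, 2.5)                     # the particle's own z layer
  expect_equal(sl$layer, 2)                   # round(2.5) == 2 (banker's)
  sl3 <- slice_map(g, 2.2)                    # inside the particle's voxel
  expect_equal(sl3$layer, 2)
  expect_equal(sl3$values[3, 3], 1)
  expect_error(slice_map(g, 40), "outside")
})

test_that("OpenDX files round-trip origin, spacing and values", {
  top <- point_topology()
  set.seed(12)
  frames <- lapply(1:50, function(f) matrix(runif(3, 0, 4), 1))
  traj <- toy_trajectory(top, frames)
  g <- suppressWarnings(
    build_occupancy(traj, atom_group(top, 0),
                    spec = grid_spec(c(-1.5, 2, 0), 1, c(2, 3, 4))))
  path <- withr::local_tempfile(fileext = ".dx")
  write_dx(g, path)
  r <- read_dx(path)
  expect_equal(r$spec$origin, g$spec$origin)
  expect_equal(r$spec$spacing_A, g$spec$spacing_A)
  expect_equal(r$spec$dims, g$spec$dims)
  expect_equal(r$values, g$values, tolerance = 1e-9)
  expect_equal(r$n_frames, 50)
})

test_that("a hand-written 8-voxel DX fixture parses to the expected array", {
  path <- withr::local_tempfile(fileext = ".dx")
  writeLines(c(
    "object 1 class gridpositions counts 2 2 2",
    "origin 1 2 3",
    "delta 0.5 0 0",
    "delta 0 0.5 0",
    "delta 0 0 0.5",
    "object 2 class gridconnections counts 2 2 2",
    "object 3 class array type double rank 0 items 8 data follows",
    "0.1 0.2 0.3",
    "0.4 0.5 0.6",
    "0.7 0.8",
    "object \"density\" class field"
  ), path)
  r <- read_dx(path)
  # z varies fastest on disk: value(ix,iy,iz) = flat[iz + 2*iy + 4*ix]
  expect_equal(r$spec$origin, c(1, 2, 3))
  expect_equal(r$spec$spacing_A, 0.5)
  expect_equal(r$values[1, 1, 1], 0.1)
  expect_equal(r$values[1, 1, 2], 0.2)
  expect_equal(r$values[1, 2, 1], 0.3)
  expect_equal(r$values[2, 1, 1], 0.5)
  expect_equal(r$values[2, 2, 2], 0.8)
})

test_that("grid auto-spec covers every selected atom position", {
  sim <- simulate_binding_trajectory(
    kinetic_spec(n_lipids = 3, n_frames = 200, seed = 4))
  g <- build_occupancy(sim$trajectory,
                       carboxylate_preset(sim$trajectory$topology, "carbon"))
  expect_equal(g$n_out_of_grid, 0)
  expect_true(all(g$values >= 0 & g$values <= 1))
})
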