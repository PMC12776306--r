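test_that("a toy PDB reads back with the identities it was written with", {
  top <- toy_arginine_topology()
  coords <- matrix(rnorm(nrow(top) * 3, sd = 5), ncol = 3) + 20
  s <- structure3d(top, coords, box = c(50, 50, 50))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, path)
  r <- read_structure(path)
  expect_equal(nrow(r$topology), nrow(top))
  expect_equal(r$topology$atom_name, top$atom_name)
  expect_equal(r$topology$residue_number, top$residue_number)
  expect_equal(r$topology$chain_id, top$chain_id)
  expect_equal(r$topology$molecule_kind, top$molecule_kind)
  expect_equal(r$box, c(50, 50, 50))
  # PDB stores 3 decimals
  expect_equal(r$coords, unname(coords), tolerance = 1e-3)
})

test_that("read_structure rejects malformed and empty files", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), path)
  expect_error(read_structure(path), "no ATOM")
  writeLines(c("ATOM      1  CA  ALA A   1      bad"), path)
  expect_error(read_structure(path), "malformed|54")
})

test_that("a three-atom fixture parses with inferred elements and kinds", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000",
    "ATOM      2  CA  GLY A   1       1.458   0.000   0.000",
    "ATOM      3  C   GLY A   1       2.009   1.420   0.000",
    "END"), path)
  s <- read_structure(path)
  expect_equal(nrow(s$topology), 3)
  expect_equal(s$topology$element, c("N", "C", "C"))
  expect_equal(s$topology$molecule_kind, rep("protein", 3))
  expect_equal(s$coords[2, 1], 1.458)
})

test_that("portable trajectory format round-trips coordinates exactly", {
  top <- toy_arginine_topology()
  set.seed(7)
  arr <- array(rnorm(5 * nrow(top) * 3, sd = 10), dim = c(5, nrow(top), 3))
  traj <- trajectory(top, arr, frame_interval_ns = 0.5, box = c(80, 80, 80))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(traj, path)
  r <- read_trajectory(path, top)     # dt from the sidecar
  expect_identical(r$coords, traj$coords)
  expect_equal(r$frame_interval_ns, 0.5)
  expect_equal(r$box, c(80, 80, 80))
  expect_equal(r$time_ns, (0:4) * 0.5)
})

test_that("read_trajectory errors on atom-count mismatch", {
  top <- toy_arginine_topology()
  arr <- array(0, dim = c(2, nrow(top), 3))
  traj <- trajectory(top, arr, 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(traj, path)
  small <- topology(data.frame(atom_name = "CA", residue_number = 1,
                               residue_name = "ALA", chain_id = "A"))
  expect_error(read_trajectory(path, small), "mismatch")
})

test_that("DCD round-trips through our writer and reader to float precision", {
  top <- toy_arginine_topology()
  set.seed(11)
  arr <- array(rnorm(4 * nrow(top) * 3, sd = 20), dim = c(4, nrow(top), 3))
  traj <- trajectory(top, arr, 2, box = c(100, 90, 80))
  path <- withr::local_tempfile(fileext = ".dcd")
  write_trajectory(traj, path)
  r <- read_trajectory(path, top, frame_interval_ns = 2)
  expect_equal(n_frames(r), 4)
  expect_equal(r$box, c(100, 90, 80))
  expect_lt(max(abs(r$coords - traj$coords)), 1e-3)
})

test_that("DCD written by MDAnalysis reads back within float tolerance", {
  py <- Sys.which("python")
  skip_if(py == "", "python not on PATH")
  has_mda <- system2(py, c("-c", shQuote("import MDAnalysis")),
                     stdout = FALSE, stderr = FALSE) == 0
  skip_if_not(has_mda, "MDAnalysis not importable")
  dir <- withr::local_tempdir()
  dcd <- file.path(dir, "ref.dcd")
  csv <- file.path(dir, "ref_coords.csv")
  script <- file.path(dir, "write_ref.py")
  writeLines(c(
    "import numpy as np",
    "import MDAnalysis as mda",
    "from MDAnalysis.coordinates.DCD import DCDWriter",
    "rng = np.random.default_rng(3)",
    "n_atoms, n_frames = 16, 3",
    "u = mda.Universe.empty(n_atoms, trajectory=True)",
    "coords = rng.normal(scale=15, size=(n_frames, n_atoms, 3))",
    sprintf("with DCDWriter('%s', n_atoms) as w:", dcd),
    "    for f in range(n_frames):",
    "        u.atoms.positions = coords[f]",
    "        u.dimensions = [100, 100, 100, 90, 90, 90]",
    "        w.write(u.atoms)",
    sprintf("np.savetxt('%s', coords.reshape(-1, 3), delimiter=',')", csv)
  ), script)
  status <- system2(py, script, stdout = FALSE, stderr = FALSE)
  skip_if(status != 0, "reference writer failed")
  top <- topology(data.frame(atom_name = "CA", residue_number = 1:16,
                             residue_name = "ALA", chain_id = "A"))
  r <- read_trajectory(dcd, top, frame_interval_ns = 1)
  ref_arr <- array(0, dim = c(3, 16, 3))
  flat <- as.matrix(utils::read.csv(csv, header = FALSE))
  for (f in 1:3) ref_arr[f, , ] <- flat[(f - 1) * 16 + 1:16, ]
  expect_equal(n_frames(r), 3)
  expect_lt(max(abs(r$coords - ref_arr)), 1e-3)
})

test_that("selection grammar matches hand-enumerated sets", {
  top <- toy_arginine_topology()
  sc <- select_atoms(top, "resid 63 and sidechain")
  expect_equal(top$atom_name[sc$atom_id + 1],
               c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"))
  expect_equal(select_atoms(top, "not protein")$atom_id,
               top$atom_id[top$molecule_kind == "lipid"])
  # compound expression vs. hand-built id set
  byhand <- sort(top$atom_id[(top$residue_name == "DHA" &
                                top$atom_name %in% c("C1", "O1", "O2")) |
                               top$atom_name == "CZ"])
  got <- select_atoms(top, "(resname DHA and name C1 O1 O2) or name CZ")
  expect_equal(got$atom_id, byhand)
  # stable under re-evaluation
  expect_identical(got$atom_id,
                   select_atoms(top, "(resname DHA and name C1 O1 O2) or name CZ")$atom_id)
})

test_that("selection grammar errors and warnings are informative", {
  top <- toy_arginine_topology()
  expect_error(select_atoms(top, "resid 63 and"), "end of expression")
  expect_error(select_atoms(top, "frobnicate"), "unknown keyword")
  expect_error(select_atoms(top, "(resid 63"), "\\)")
  expect_warning(select_atoms(top, "resid 999"), "matched no atoms")
})

test_that("min-image distance agrees with the 27-image oracle", {
  expect_equal(min_image_distance(c(1, 1, 1), c(9, 1, 1), c(10, 10, 10)), 2)
  expect_equal(min_image_distance(c(2, 3, 4), c(2, 3, 4), c(10, 10, 10)), 0)
  expect_equal(min_image_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  set.seed(21)
  box <- c(20, 25, 30)
  for (i in 1:50) {
    p <- runif(3, 0, box)
    q <- runif(3, 0, box)
    expect_equal(min_image_distance(p, q, box), oracle_min_image(p, q, box),
                 tolerance = 1e-12)
  }
  expect_error(min_image_distance(c(Inf, 0, 0), c(0, 0, 0)), "non-finite")
})

test_that("superposition recovers known rigid-body transforms", {
  set.seed(5)
  ref <- matrix(rnorm(30, sd = 4), ncol = 3)
  ids <- 0:9
  # identity
  fit <- superpose(ref, ref, ids)
  expect_lt(attr(fit, "rmsd"), 1e-10)
  # known rotation + translation
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  mob <- ref %*% t(R) + matrix(c(3, -2, 7), 10, 3, byrow = TRUE)
  back <- superpose(mob, ref, ids)
  expect_lt(attr(back, "rmsd"), 1e-8)
  expect_equal(unclass(back), ref, tolerance = 1e-8,
               ignore_attr = TRUE)
  # idempotence
  again <- superpose(back, ref, ids)
  expect_lt(max(abs(again - back)), 1e-9)
  # degenerate: collinear points
  line <- cbind(1:5, 1:5, 1:5)
  expect_error(superpose(line, line, 0:4), "degenerate")
})
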