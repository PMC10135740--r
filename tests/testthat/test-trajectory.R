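test_that("fixture trajectories round-trip through GRO and the CSV table", {
  traj <- generate_ideal_gas(4, 3, box_edge = 2.5, seed = 11)

  gro <- withr::local_tempfile(fileext = ".gro")
  write_gro(traj, gro)
  rt <- load_trajectory(gro)
  expect_equal(n_frames(rt), 3)
  expect_equal(n_atoms(rt), 4)
  expect_lt(max(abs(rt$xyz - traj$xyz)), 1e-3)  # GRO stores 3 decimals
  expect_lt(max(abs(rt$cell - traj$cell)), 1e-5)
  expect_equal(rt$time, traj$time)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_table(traj, csv)
  rt2 <- load_trajectory(csv)
  expect_identical(rt2$xyz, traj$xyz)  # lossless path is bit-exact
  expect_identical(rt2$cell, traj$cell)
  expect_equal(rt2$topology$name, traj$topology$name)
  expect_equal(rt2$topology$resid, traj$topology$resid)
})

test_that("triclinic cells survive the GRO box line", {
  cell <- rbind(c(3, 0, 0), c(1.2, 2.8, 0), c(-0.9, 0.5, 2.6))
  traj <- generate_ideal_gas(3, 2, cell = cell, seed = 3)
  gro <- withr::local_tempfile(fileext = ".gro")
  write_gro(traj, gro)
  rt <- read_gro(gro)
  expect_lt(max(abs(rt$cell[1, , ] - cell)), 1e-5)
})

test_that("stride keeps frames 1, 1+s, 1+2s, ...", {
  traj <- generate_ideal_gas(2, 10, box_edge = 2, seed = 5)
  s <- stride_trajectory(traj, 2)
  expect_equal(n_frames(s), 5)
  expect_identical(s$xyz[3, , ], traj$xyz[5, , ])
  expect_equal(s$time, traj$time[c(1, 3, 5, 7, 9)])
  gro <- withr::local_tempfile(fileext = ".gro")
  write_gro(traj, gro)
  expect_equal(n_frames(load_trajectory(gro, stride = 2)), 5)
})

test_that("GRO files written by MDTraj are read back within format precision", {
  gro <- tempfile(fileext = ".gro")
  py <- sprintf("
import mdtraj as md, numpy as np
top = md.Topology(); ch = top.add_chain()
res = top.add_residue('ALA', ch)
for nm in ['N', 'CA', 'C', 'O']:
    top.add_atom(nm, md.element.get_by_symbol(nm[0]), res)
xyz = np.array([[[0.111, 0.222, 0.333], [0.444, 0.555, 0.666],
                 [0.777, 0.888, 0.999], [1.012, 1.123, 1.234]]])
t = md.Trajectory(xyz, top, unitcell_lengths=np.array([[2.0, 2.5, 3.0]]),
                  unitcell_angles=np.array([[90.0, 90.0, 90.0]]))
t.save_gro('%s')
", gro)
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(py, script)
  status <- system2("python", script, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(gro))
  rt <- read_gro(gro)
  expect_equal(n_atoms(rt), 4)
  expected <- rbind(c(0.111, 0.222, 0.333), c(0.444, 0.555, 0.666),
                    c(0.777, 0.888, 0.999), c(1.012, 1.123, 1.234))
  expect_lt(max(abs(rt$xyz[1, , ] - expected)), 1e-3)
  expect_equal(diag(rt$cell[1, , ]), c(2.0, 2.5, 3.0), tolerance = 1e-4)
  expect_equal(rt$topology$name, c("N", "CA", "C", "O"))
  unlink(gro)
})

test_that("multi-model PDB reads as a trajectory in nm", {
  traj <- peptide_trajectory(n_frames = 1)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  top <- traj$topology
  lines <- c("CRYST1   60.000   60.000   60.000  90.00  90.00  90.00 P 1",
             "MODEL     1",
             sprintf("ATOM  %5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                     seq_len(nrow(top)), top$name, top$resname, top$resid,
                     traj$xyz[1, , 1] * 10, traj$xyz[1, , 2] * 10,
                     traj$xyz[1, , 3] * 10, top$element),
             "ENDMDL", "END")
  writeLines(lines, pdb)
  rt <- read_pdb_trajectory(pdb)
  expect_equal(n_atoms(rt), nrow(top))
  expect_lt(max(abs(rt$xyz[1, , ] - traj$xyz[1, , ])), 1e-3)
})

test_that("trajectory constructor enforces its invariants", {
  xyz <- array(0, c(2, 3, 3))
  top <- fixture_top <- data.frame(name = c("A", "B", "C"), element = "C",
                                   resname = "X", resid = 0:2, chain = "A")
  expect_error(trajectory(xyz, top[1:2, ]), class = "trrdf_topology_error")
  expect_error(trajectory(xyz, top, time = c(1, 1)),
               class = "trrdf_format_error")
  bad_cell <- rbind(c(2, 0, 0), c(0, -1, 0), c(0, 0, 2))
  expect_error(trajectory(xyz, top, cell = bad_cell),
               class = "trrdf_cell_error")
  # cell-free trajectories refuse periodic analyses
  t0 <- trajectory(xyz, top)
  expect_error(frame_cell(t0, 1), class = "trrdf_cell_error")
})

test_that("window partitioning tiles strided frames into disjoint blocks", {
  expect_equal(partition_windows(10, window_scheme(5)),
               list(structure(1:5, partial = FALSE),
                    structure(6:10, partial = FALSE)))
  # trailing frames dropped by default
  b <- partition_windows(10, window_scheme(4))
  expect_equal(lapply(b, as.integer), list(1:4, 5:8))
  bk <- partition_windows(10, window_scheme(4, partial = "keep"))
  expect_equal(as.integer(bk[[3]]), 9:10)
  expect_true(attr(bk[[3]], "partial"))
  # no complete window -> empty with a warning, not an error
  expect_warning(empty <- partition_windows(3, window_scheme(5)))
  expect_length(empty, 0)

  set.seed(42)
  for (i in 1:20) {
    n <- sample(1:50, 1); nw <- sample(1:10, 1); st <- sample(1:3, 1)
    blocks <- suppressWarnings(partition_windows(n, window_scheme(nw,
                                                                  stride = st)))
    flat <- unlist(blocks)
    expect_false(any(duplicated(flat)))
    expect_length(flat, (length(seq(1, n, by = st)) %/% nw) * nw)
    expect_true(all(lengths(blocks) == nw))
    if (length(flat)) expect_true(all(diff(flat) > 0))
  }
})

test_that("selection grammar matches brute-force predicate filtering", {
  traj <- peptide_trajectory()
  top <- traj$topology
  expect_equal(resolve_selection(traj, "name CA"), which(top$name == "CA"))
  expect_equal(resolve_selection(traj, "resid 0 to 1 and element C"),
               which(top$resid <= 1 & top$element == "C"))
  expect_equal(
    resolve_selection(traj, "(name CA or name CB) and not resid 0"),
    which((top$name %in% c("CA", "CB")) & top$resid != 0))
  expect_equal(resolve_selection(traj, "all"), seq_len(nrow(top)))
  expect_equal(resolve_selection(traj, c(5, 2, 2)), c(2L, 5L))

  expect_error(resolve_selection(traj, "name"), class = "trrdf_selection_error")
  expect_error(resolve_selection(traj, "name ZZTOP"),
               class = "trrdf_selection_error")
  expect_error(resolve_selection(traj, "bogus CA"),
               class = "trrdf_selection_error")
  expect_error(resolve_selection(traj, 999), class = "trrdf_selection_error")

  # property: random expressions over random topologies
  set.seed(99)
  for (i in 1:25) {
    top <- random_topology(40)
    nm <- sample(unique(top$name), 1)
    rn <- sample(unique(top$resname), 1)
    lo <- sample(0:5, 1); hi <- lo + sample(0:4, 1)
    expr <- sprintf("(name %s or resname %s) and not resid %d to %d",
                    nm, rn, lo, hi)
    want <- which((top$name == nm | top$resname == rn) &
                    !(top$resid >= lo & top$resid <= hi))
    if (length(want))
      expect_equal(resolve_selection(top, expr), want)
    else
      expect_error(resolve_selection(top, expr),
                   class = "trrdf_selection_error")
  }
})

test_that("0-based index files resolve to 1-based atom indices", {
  f <- withr::local_tempfile(fileext = ".ndx")
  writeLines(c("# ions", "0 2, 5", "7"), f)
  expect_equal(read_index_file(f), c(1L, 3L, 6L, 8L))
})
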