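test_that("the Bjerrum length reproduces its physiological value and scaling", {
  expect_equal(round(bjerrum_length(300, 80), 2), 0.70)
  expect_equal(bjerrum_length(150, 80), 2 * bjerrum_length(300, 80))
  expect_equal(bjerrum_length(300, 40), 2 * bjerrum_length(300, 80))
  expect_error(bjerrum_length(-1, 80), class = "trrdf_domain_error")
  expect_error(bjerrum_length(300, 0), class = "trrdf_domain_error")
})

test_that("ion sites resolve to the designated carbons with CA fallback", {
  traj <- peptide_trajectory()
  sites <- default_ion_sites(traj)
  top <- traj$topology
  expect_equal(sites$groups$res0, which(top$resid == 0 & top$name == "CD"))
  expect_equal(sites$groups$res1, which(top$resid == 1 & top$name == "CA"))
  expect_equal(sites$groups$res2, which(top$resid == 2 & top$name == "CG"))
  expect_true(sites$residues$fallback[sites$residues$resname == "GLY"])
  # every resolved site is carbon by element
  all_idx <- unlist(sites$groups)
  expect_true(all(top$element[all_idx] == "C"))
  # one site list per residue
  expect_equal(length(sites$groups), length(unique(top$resid)))
})

test_that("a non-carbon designated site raises a topology error", {
  top <- peptide_topology()
  top$element[top$resid == 0 & top$name == "CD"] <- "N"
  xyz <- array(stats::runif(nrow(top) * 3, 1, 3), c(1, nrow(top), 3))
  traj <- trajectory(xyz, top, cell = diag(rep(6, 3)))
  expect_error(default_ion_sites(traj), class = "trrdf_topology_error")
})

test_that("a user site table overrides the packaged one", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("LYS\tCE\ttest", f)
  tb <- ion_site_table(f)
  expect_equal(attr(tb, "provenance"), "user")
  sites <- default_ion_sites(peptide_trajectory(), table = tb)
  top <- peptide_topology()
  expect_equal(sites$groups$res0, which(top$resid == 0 & top$name == "CE"))
})

test_that("per-residue mean ion counts follow occupancy semantics", {
  # one site at the centre; one ion permanently at 0.4 nm, one at 0.9 nm
  xyz <- array(NA_real_, c(4, 3, 3))
  for (f in 1:4) {
    xyz[f, 1, ] <- c(2, 2, 2)
    xyz[f, 2, ] <- c(2.4, 2, 2)
    xyz[f, 3, ] <- c(2.9, 2, 2)
  }
  top <- data.frame(name = c("CA", "CL", "CL"), element = c("C", "Cl", "Cl"),
                    resname = c("GLY", "CL", "CL"), resid = 0:2, chain = "A")
  traj <- trajectory(xyz, top, cell = diag(rep(4, 3)))
  groups <- particle_groups(traj, list(res0 = "resid 0"),
                            list(cl = "element Cl"))
  grid <- radial_grid(0, 1.2, 120)
  coord <- running_coordination(
    compute_trrdf(traj, groups, grid, window_scheme(2)))
  p70 <- per_residue_ion_counts(coord, cutoff = 0.70)
  p100 <- per_residue_ion_counts(coord, cutoff = 1.0)
  expect_equal(p70$mean_count, 1.0)
  expect_equal(p100$mean_count, 2.0)
  expect_equal(p70$resid, 0L)
  expect_error(per_residue_ion_counts(coord, cutoff = 0.001),
               class = "trrdf_domain_error")
  expect_error(per_residue_ion_counts(coord, cutoff = 5),
               class = "trrdf_domain_error")
})

test_that("an ion inside the cutoff for a quarter of the frames scores 0.25", {
  traj <- generate_two_particle(c(0.4, rep(0.9, 3)), box_edge = 2)
  groups <- particle_groups(traj, list(res0 = "name REF"),
                            list(cl = "name CL"))
  coord <- running_coordination(
    compute_trrdf(traj, groups, radial_grid(0, 1, 100), window_scheme(4)))
  p <- per_residue_ion_counts(coord, cutoff = 0.70)
  expect_equal(p$mean_count, 0.25)
})

test_that("profile values never decrease with the cutoff", {
  traj <- generate_random_walk_ions(5, 12, box_edge = 4, step_sd = 0.25,
                                    seed = 77)
  groups <- particle_groups(traj, list(res0 = "element C"),
                            list(cl = "element Cl"))
  coord <- running_coordination(
    compute_trrdf(traj, groups, radial_grid(0, 1.8, 90), window_scheme(3)))
  cuts <- c(0.3, 0.5, 0.7, 1.0, 1.4, 1.8)
  vals <- vapply(cuts, function(ct)
    per_residue_ion_counts(coord, ct)$mean_count, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("cluster-weighted profiles recombine into the unconditional one", {
  traj <- generate_random_walk_ions(4, 12, box_edge = 4, step_sd = 0.3,
                                    seed = 31)
  groups <- particle_groups(traj, list(res0 = "element C"),
                            list(cl = "element Cl"))
  tw <- compute_trrdf(traj, groups, radial_grid(0, 1.8, 60), window_scheme(2))
  coord <- running_coordination(tw)
  clusters <- c(1L, 2L, 1L, 2L, 2L, 1L)
  byc <- per_residue_ion_counts(coord, 0.70, clusters = clusters)
  uncond <- per_residue_ion_counts(coord, 0.70)
  recombined <- sum(byc$mean_count * byc$n_windows) / sum(byc$n_windows)
  expect_equal(recombined, uncond$mean_count, tolerance = 1e-10)
  expect_equal(sum(unique(byc[, c("cluster", "n_windows")])$n_windows), 6)
})

test_that("windows inherit the majority cluster label; ties unassigned", {
  traj <- generate_ideal_gas(3, 10, box_edge = 2, seed = 1)
  groups <- particle_groups(traj, list(a = "all"), list(b = "all"))
  tw <- compute_trrdf(traj, groups, radial_grid(0, 0.9, 9), window_scheme(5))
  expect_equal(assign_windows_to_clusters(tw, rep(3L, 10)), c(3L, 3L))
  expect_equal(assign_windows_to_clusters(tw,
                                          c(1, 1, 1, 2, 2, 1, 2, 1, 2, 9)),
               c(1L, NA_integer_))
  expect_error(assign_windows_to_clusters(tw, rep(1L, 4)),
               class = "trrdf_metadata_error")
  # frame mapping: labels stored every other frame
  labs <- rep(c(7L, 8L), each = 3)
  expect_equal(assign_windows_to_clusters(tw, labs,
                                          frame_map = function(f)
                                            (f + 1L) %/% 2L),
               c(7L, 8L))
})

test_that("residue distance maps and 0.5 nm contacts follow the mean rule", {
  mk_two_res <- function(seps) {
    nf <- length(seps)
    xyz <- array(NA_real_, c(nf, 2, 3))
    for (f in seq_len(nf)) {
      xyz[f, 1, ] <- c(2, 2, 2)
      xyz[f, 2, ] <- c(2 + seps[f], 2, 2)
    }
    top <- data.frame(name = c("CA", "CA"), element = c("C", "C"),
                      resname = c("GLY", "GLY"), resid = 0:1, chain = "A")
    trajectory(xyz, top, cell = diag(rep(5, 3)))
  }
  m1 <- residue_distance_map(mk_two_res(rep(0.4, 3)))
  expect_equal(m1$distance[1, 2], 0.4)
  expect_true(m1$contact[1, 2])
  m2 <- residue_distance_map(mk_two_res(rep(0.6, 3)))
  expect_false(m2$contact[1, 2])
  m3 <- residue_distance_map(mk_two_res(c(0.4, 0.8, 0.4, 0.8)))
  expect_equal(m3$distance[1, 2], 0.6)
  expect_false(m3$contact[1, 2])
  expect_equal(m3$distance, t(m3$distance))
  expect_equal(diag(m3$distance), c(0, 0), ignore_attr = TRUE)
})

test_that("min-over-atoms residue distances never exceed representative ones", {
  traj <- peptide_trajectory(n_frames = 2)
  rep_map <- residue_distance_map(traj)
  min_map <- residue_distance_map(traj, mode = "min")
  expect_true(all(min_map$distance <= rep_map$distance + 1e-12))
})
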