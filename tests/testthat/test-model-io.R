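test_that("topology validates its inputs", {
  at <- data.frame(serial = c(1L, 1L), name = c("A", "B"), element = "C",
                   resno = c(1L, 1L), resname = "RES")
  expect_error(topology(at), "serials must be unique")
  at$serial <- 1:2
  at$resno <- c(2L, 1L)
  expect_error(topology(at), "non-decreasing")
  at$resno <- c(1L, 2L)
  expect_error(topology(at, groups = list(bad = 3L)), "outside the topology")
  expect_error(topology(at, groups = list(receptor = 1L, ligand = 1L)),
               "disjoint")
  top <- topology(at, groups = list(receptor = 1L, ligand = 2L))
  expect_s3_class(top, "topology")
  expect_equal(n_atoms(top), 2L)
})

test_that("atom_group and select_atoms resolve names and indices", {
  tc <- gen_toy_complex("stable", n_frames = 12, seed = 1)
  top <- tc$topology
  expect_identical(atom_group(top, "ligand"), top$groups$ligand)
  expect_identical(atom_group(top, c(3L, 5L)), c(3L, 5L))
  expect_error(atom_group(top, "no_such_group"), "unknown atom group")
  expect_error(atom_group(top, 10000L), "outside the topology")
  ser_og <- select_atoms(top, 1, "OG")
  expect_length(ser_og, 1)
  expect_equal(top$atoms$name[ser_og], "OG")
})

test_that("trajectory construction enforces shape and times", {
  top <- ion_topology(2)
  xyz <- matrix(rnorm(5 * 6), 5, 6)
  tr <- trajectory(top, xyz, times = (0:4) * 0.1)
  expect_equal(n_frames(tr), 5)
  expect_equal(dim(get_frame(tr, 3)), c(2L, 3L))
  expect_error(trajectory(top, matrix(0, 2, 9)), "topology mismatch")
  expect_error(trajectory(top, xyz, times = rep(0, 5)),
               "strictly increasing")
})

test_that("PDB round trip preserves coordinates and atom identity", {
  tc <- gen_toy_complex("stable", n_frames = 5, seed = 2)
  co <- unflat_xyz(tc$trajectory$xyz[1, ])
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(tc$topology, co, path)
  back <- read_pdb(path)
  expect_equal(n_atoms(back$topology), n_atoms(tc$topology))
  expect_equal(back$topology$atoms$name, tc$topology$atoms$name)
  expect_equal(back$topology$atoms$resno, tc$topology$atoms$resno)
  expect_equal(unclass(back$frame), co, ignore_attr = TRUE,
               tolerance = 1e-3)  # PDB fixed-point: 3 decimals
})

test_that("malformed PDB records fail with the line number", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      11.104  13.207   2.100  1.00  0.00",
    "ATOM      2  CB  ALA A   1      badxyz  13.207   2.100  1.00  0.00"),
    path)
  expect_error(read_pdb(path), "line 2")
  writeLines("REMARK nothing here", path)
  expect_error(read_pdb(path), "no ATOM/HETATM")
})

test_that("DCD round trip reproduces the trajectory to float precision", {
  top <- ion_topology(3)
  set.seed(4)
  xyz <- matrix(rnorm(4 * 9, sd = 5), 4, 9)
  tr <- trajectory(top, xyz, times = (0:3) * 0.5)
  path <- withr::local_tempfile(fileext = ".dcd")
  write_trajectory(tr, path)
  back <- read_trajectory(path, top, times = tr$times)
  expect_equal(back$xyz, tr$xyz, tolerance = 1e-6)
  expect_error(read_trajectory(path, ion_topology(5)), "topology mismatch")
})

test_that("multi-model PDB trajectory round trip works", {
  tc <- gen_toy_complex("stable", n_frames = 3, seed = 5)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tc$trajectory, path)
  back <- read_trajectory(path, tc$topology, times = tc$trajectory$times)
  expect_equal(n_frames(back), 3)
  expect_equal(back$xyz, tc$trajectory$xyz, tolerance = 1e-3)
})

test_that("ff_params validates entries and globals", {
  tab <- data.frame(resname = "GAL", name = "C1", charge = 0.3,
                    rmin_half = 1.9, epsilon = 0.1, mass = 12.01,
                    gb_radius = NA_real_)
  expect_error(ff_params(tab), "GAL:C1.*gb_radius")
  tab$gb_radius <- 1.7
  expect_error(ff_params(tab, eps_int = 0.5), "eps_int")
  expect_error(ff_params(tab, eps_int = 80, eps_solv = 78.5), "eps_solv")
  p <- ff_params(tab)
  expect_equal(p$atoms$screen, 0.8)  # default descreening scale
})

test_that("parameter file round trip (YAML and JSON)", {
  p <- ion_params(2)
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_ff_params(p, path)
    back <- load_ff_params(path)
    expect_equal(back$atoms$charge, p$atoms$charge)
    expect_equal(back$global$eps_int, p$global$eps_int)
    expect_equal(back$global$coulomb, p$global$coulomb)
  }
})

test_that("match_params reports all missing atoms together", {
  tc <- gen_toy_complex("stable", n_frames = 5, seed = 1)
  p <- tc$params
  ptab <- match_params(tc$topology, p)
  lig <- tc$topology$groups$ligand
  expect_false(anyNA(ptab$charge[lig]))
  # drop two entries -> both named in one error
  p2 <- p
  p2$atoms <- p2$atoms[!(p2$atoms$resname == "FUC" &
                           p2$atoms$name %in% c("C1", "O5")), ]
  expect_error(match_params(tc$topology, p2), "FUC14:C1.*FUC14:O5")
})

test_that("wildcard resname fallback matches any residue", {
  tab <- data.frame(resname = c("*", "ION"), name = c("I1", "I2"),
                    charge = c(0.1, 0.2), rmin_half = 1.7, epsilon = 0.1,
                    mass = 12, gb_radius = 1.7)
  p <- ff_params(tab)
  ptab <- match_params(ion_topology(2), p)
  expect_equal(ptab$charge[1:2], c(0.1, 0.2))
})

test_that("analysis_config defaults and validation", {
  cfg <- analysis_config()
  expect_equal(cfg$n_snapshots, 5000)
  expect_equal(cfg$voxel_cell, 0.5)
  expect_equal(cfg$pose_stride_ns, 0.1)
  expect_equal(cfg$rmsd_cutoff, 1.5)
  expect_error(analysis_config(voxel_cell = 0), "voxel_cell")
  expect_error(analysis_config(n_snapshots = -1), "n_snapshots")
})

test_that("config file round trip keeps unknown fields", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_snapshots = 100, rmsd_cutoff = 2.0,
                        my_extra = "x"), path)
  cfg <- load_config(path)
  expect_equal(cfg$n_snapshots, 100)
  expect_equal(cfg$rmsd_cutoff, 2.0)
  expect_equal(cfg$my_extra, "x")
})
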