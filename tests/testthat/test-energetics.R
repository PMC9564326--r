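test_that("Coulomb pair energy matches the closed form", {
  top <- ion_topology(2)
  p <- ion_params(2, charge = 1)
  ptab <- match_params(top, p)
  co <- rbind(c(0, 0, 0), c(5, 0, 0))
  e <- pair_energy(co, ptab, 1, 2, eps_int = 3.0,
                   coulomb = p$global$coulomb)
  expect_equal(e$E_elec, 332.0636 * 1 / (3 * 5), tolerance = 1e-10)
})

test_that("LJ minimum sits at the combined rmin with depth -eps", {
  top <- ion_topology(2)
  p <- ion_params(2, charge = 0)
  ptab <- match_params(top, p)
  rmin <- 2 * 1.7
  at_min <- pair_energy(rbind(c(0, 0, 0), c(rmin, 0, 0)), ptab, 1, 2)
  expect_equal(at_min$E_vdW, -0.1, tolerance = 1e-10)
  # energy rises on both sides of the minimum
  for (r in c(rmin - 0.2, rmin + 0.4)) {
    e <- pair_energy(rbind(c(0, 0, 0), c(r, 0, 0)), ptab, 1, 2)
    expect_gt(e$E_vdW, -0.1)
  }
})

test_that("near-overlapping atoms raise a singularity error", {
  top <- ion_topology(2)
  ptab <- match_params(top, ion_params(2))
  expect_error(pair_energy(rbind(c(0, 0, 0), c(0.05, 0, 0)), ptab, 1, 2),
               "singularity")
  expect_error(pair_energy(rbind(c(0, 0, 0), c(1, 0, 0)), ptab, 1, 1),
               "overlap")
})

test_that("GB single-ion energy equals the Born closed form", {
  p <- ion_params(1, charge = 1, gb_radius = 2.0)
  ptab <- match_params(ion_topology(1), p)
  g <- p$global
  e <- gb_energy(matrix(0, 1, 3), ptab, 1, g)
  R <- 2.0 - g$gb_offset
  born <- -0.5 * (1 / g$eps_int - 1 / g$eps_solv) * g$coulomb / R
  expect_equal(as.numeric(e), born, tolerance = 1e-6 * abs(born))
  expect_equal(as.numeric(attr(e, "radii")), R, tolerance = 1e-12)
})

test_that("distant GB pair equals Born sum plus the screened cross term", {
  # at 200 A separation mutual descreening is negligible but the
  # pairwise cross term (-(1/ei - 1/eo) k q1 q2 / f) is not
  p <- ion_params(2, charge = 1, gb_radius = 2.0)
  ptab <- match_params(ion_topology(2), p)
  g <- p$global
  co <- rbind(c(0, 0, 0), c(200, 0, 0))
  e_pair <- as.numeric(gb_energy(co, ptab, 1:2, g))
  R <- 2.0 - g$gb_offset
  pref2 <- 1 / g$eps_int - 1 / g$eps_solv
  born2 <- 2 * (-0.5 * pref2 * g$coulomb / R)
  f <- sqrt(200^2 + R^2 * exp(-200^2 / (4 * R^2)))
  cross <- -pref2 * g$coulomb / f
  expect_equal(e_pair, born2 + cross, tolerance = 1e-3 * abs(e_pair))
})

test_that("OBC effective radii grow under descreening and stay finite", {
  p <- ion_params(2, gb_radius = 1.7)
  co <- rbind(c(0, 0, 0), c(3, 0, 0))
  eff <- gb_effective_radii(co, rho = c(1.7, 1.7), screen = c(0.8, 0.8))
  lone <- 1.7 - 0.09
  expect_true(all(eff$radii > lone))        # neighbour buries each atom
  expect_true(all(is.finite(eff$radii)))
  expect_error(gb_effective_radii(co, rho = c(0.05, 1.7),
                                  screen = c(0.8, 0.8)), "offset")
})

test_that("SASA of an isolated atom is the full sphere", {
  a <- sasa(matrix(0, 1, 3), radii = 1.6, probe = 1.4)
  expect_equal(a, 4 * pi * 3^2, tolerance = 1e-6)
})

test_that("SASA decreases on contact and vanishes when buried", {
  two_far <- sasa(rbind(c(0, 0, 0), c(50, 0, 0)), radii = c(1.6, 1.6))
  two_near <- sasa(rbind(c(0, 0, 0), c(2.0, 0, 0)), radii = c(1.6, 1.6))
  expect_equal(sum(two_far), 2 * 4 * pi * 3^2, tolerance = 1e-6)
  expect_lt(sum(two_near), sum(two_far))
  # a tiny atom at the centre of a big one is fully buried
  buried <- sasa(rbind(c(0, 0, 0), c(0.3, 0, 0)), radii = c(3, 0.2))
  expect_equal(buried[2], 0)
})

test_that("mmgbsa interaction assembles components over runs", {
  tcs <- lapply(1:2, function(r)
    gen_toy_complex("stable", n_frames = 30, seed = r, run_id = r))
  trajs <- lapply(tcs, `[[`, "trajectory")
  mm <- mmgbsa_interaction(trajs, tcs[[1]]$params, n_snapshots = 10)
  expect_equal(nrow(mm$per_run), 2)
  expect_equal(unname(mm$mean["total"]),
               unname(sum(mm$mean[c("E_elec", "E_vdW", "dG_GB",
                                    "dG_SASA")])),
               tolerance = 1e-10)
  expect_error(mmgbsa_interaction(trajs, tcs[[1]]$params,
                                  n_snapshots = 100), "available frames")
})

test_that("per-group decomposition sums exactly to the total", {
  tc <- gen_toy_complex("stable", n_frames = 12, seed = 3)
  part <- tc$topology$groups[c("Neu5Ac", "Gal", "GlcNAc", "Fuc", "SO3")]
  mm <- mmgbsa_interaction(tc$trajectory, tc$params, n_snapshots = 4)
  dec <- per_group_decomposition(tc$trajectory, tc$params,
                                 partition = part, n_snapshots = 4)
  expect_equal(attr(dec, "total"), unname(mm$mean["total"]),
               tolerance = 1e-6)
  expect_equal(sum(dec$energy), attr(dec, "total"), tolerance = 1e-10)
  # component-wise conservation too
  for (comp in c("E_elec", "E_vdW", "dG_GB", "dG_SASA"))
    expect_equal(sum(dec[[comp]]), unname(mm$mean[comp]),
                 tolerance = 1e-6)
  # partition must cover the ligand exactly
  expect_error(per_group_decomposition(tc$trajectory, tc$params,
                                       partition = part[-1],
                                       n_snapshots = 2),
               "cover the ligand")
})

test_that("decomposition without solvation matches plain MM cross sums", {
  tc <- gen_toy_complex("stable", n_frames = 6, seed = 5)
  part <- tc$topology$groups[c("Neu5Ac", "Gal", "GlcNAc", "Fuc", "SO3")]
  dec <- per_group_decomposition(tc$trajectory, tc$params,
                                 partition = part, n_snapshots = 2,
                                 include_gb = FALSE, include_sasa = FALSE)
  mm <- mmgbsa_interaction(tc$trajectory, tc$params, n_snapshots = 2,
                           include_gb = FALSE, include_sasa = FALSE)
  expect_equal(sum(dec$energy), unname(mm$mean["total"]),
               tolerance = 1e-10)
  expect_true(all(dec$dG_GB == 0) && all(dec$dG_SASA == 0))
})

test_that("alanine truncation keeps backbone + CB and renames the residue", {
  tc <- gen_toy_complex("stable", n_frames = 4, seed = 1)
  top <- tc$topology
  mut <- mutate_to_alanine(top, tc$trajectory, resnos = 2)
  at <- mut$topology$atoms
  res2 <- at[at$resno == 2, ]
  expect_true(all(res2$resname == "ALA"))
  expect_true(all(res2$name %in% c("N", "CA", "CB", "C", "O")))
  expect_false(any(res2$name %in% c("CG", "CZ")))
  # other residues untouched; frame count preserved
  expect_equal(sum(at$resno == 1), sum(top$atoms$resno == 1))
  expect_equal(n_frames(mut$xyz), 4)
  # coordinates of surviving atoms unchanged
  keep_old <- which(!(top$atoms$resno == 2 &
                        !top$atoms$name %in% c("N", "CA", "CB", "C", "O")))
  cols <- as.numeric(t(outer(keep_old, 1:3,
                             function(i, d) 3 * (i - 1) + d)))
  expect_equal(mut$xyz$xyz, tc$trajectory$xyz[, cols], ignore_attr = TRUE)
  expect_error(mutate_to_alanine(top, tc$trajectory, resnos = 99),
               "no residue")
})

test_that("alanine-scanned complex still scores with the same parameters", {
  tc <- gen_toy_complex("stable", n_frames = 6, seed = 7)
  mut <- mutate_to_alanine(tc$topology, tc$trajectory, resnos = 2)
  mm <- mmgbsa_interaction(mut$xyz, tc$params, n_snapshots = 2)
  expect_true(is.finite(mm$mean["total"]))
  # losing the +1 arginine tip weakens the electrostatic attraction
  mm0 <- mmgbsa_interaction(tc$trajectory, tc$params, n_snapshots = 2)
  expect_gt(mm$mean["E_elec"], mm0$mean["E_elec"])
})

test_that("residue removal restores a hydroxyl on the dangling oxygen", {
  tc <- gen_toy_complex("stable", n_frames = 3, seed = 2)
  top <- tc$topology
  out <- remove_residue(top, tc$trajectory, resno = 14)  # drop the fucose
  at <- out$topology$atoms
  expect_false(any(at$resno == 14))
  # the glycosidic O3 of GlcNAc gained a hydroxyl H right after it
  o3 <- which(at$resno == 13 & at$name == "O3")
  expect_equal(at$element[o3 + 1], "H")
  co <- unflat_xyz(out$xyz$xyz[1, ])
  expect_equal(sqrt(sum((co[o3, ] - co[o3 + 1, ])^2)), 0.96,
               tolerance = 1e-6)
  no_h <- remove_residue(top, tc$trajectory, resno = 14,
                         restore_hydroxyl = FALSE)
  expect_equal(n_atoms(no_h$topology), n_atoms(top) - 3)
})
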