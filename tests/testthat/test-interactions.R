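test_that("hbond criteria validate their ranges", {
  expect_error(hbond_criteria(distance = 0), "> 0")
  expect_error(hbond_criteria(angle = 80), "90, 180")
  crit <- hbond_criteria()
  expect_equal(crit$distance, 3.5)
  expect_equal(crit$angle, 135)
  expect_equal(crit$stable_occupancy, 0.5)
})

# minimal donor-H / acceptor system with controllable geometry
hb_top <- function() {
  at <- data.frame(serial = 1:3, name = c("OD", "HD", "OA"),
                   element = c("O", "H", "O"), resno = c(1L, 1L, 2L),
                   resname = c("DON", "DON", "ACC"))
  topology(at, groups = list(receptor = 1:2, ligand = 3L),
           bonds = cbind(1L, 2L))
}

test_that("detect_hbonds applies distance and angle cutoffs", {
  top <- hb_top()
  co <- function(d, ang_dev = 0) {
    # acceptor at distance d from donor, rotated ang_dev off the O-H line
    rad <- ang_dev * pi / 180
    rbind(c(0, 0, 0), c(1, 0, 0),
          c(d * cos(rad), d * sin(rad), 0))
  }
  hit <- detect_hbonds(co(2.9), top)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$distance, 2.9)
  expect_equal(hit$angle, 180, tolerance = 1e-6)
  expect_equal(nrow(detect_hbonds(co(3.6), top)), 0)   # too far
  expect_equal(nrow(detect_hbonds(co(2.9, 80), top)), 0)  # bad angle
  # distance-only mode ignores the angle and needs no hydrogens
  expect_equal(nrow(detect_hbonds(co(2.9, 80), top,
                                  distance_only = TRUE)), 1)
})

test_that("occupancy pools runs frame-weighted and flags stability", {
  top <- hb_top()
  good <- flat_xyz(rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0)))
  bad <- flat_xyz(rbind(c(0, 0, 0), c(1, 0, 0), c(6, 0, 0)))
  tr1 <- trajectory(top, rbind(good, good, good, bad), times = 0:3,
                    run_id = 1L)                      # 3/4
  tr2 <- trajectory(top, rbind(good, bad), times = 0:1, run_id = 2L)  # 1/2
  occ <- hbond_occupancy(list(tr1, tr2))
  expect_equal(nrow(occ), 1)
  expect_equal(occ$occ_run1, 0.75)
  expect_equal(occ$occ_run2, 0.5)
  expect_equal(occ$occupancy, 4 / 6)  # frame-weighted pooled
  expect_true(occ$stable)
})

test_that("planted hydrogen-bond occupancy is recovered on the toy complex", {
  tc <- gen_toy_complex("stable", n_frames = 300, seed = 4,
                        hbond_fraction = 0.7)
  occ <- hbond_occupancy(tc$trajectory,
                         hbond_criteria(stable_occupancy = 0.5),
                         distance_only = TRUE)
  row <- occ[occ$donor_idx == tc$truth$hbond_donor &
               occ$acceptor_idx == tc$truth$hbond_acceptor, ]
  expect_equal(nrow(row), 1)
  expect_equal(row$occupancy, 0.7, tolerance = 0.05)
  expect_true(row$stable)
})

test_that("water density map finds a planted static water site", {
  # one water oxygen jittering tightly around a known point
  at <- data.frame(serial = 1:2, name = c("O", "O"),
                   element = c("O", "O"), resno = 1:2,
                   resname = c("WAT", "WAT"))
  top <- topology(at, groups = list(all = 1:2))
  expect_true(all(top$atoms$is_water))
  set.seed(6)
  site <- c(2, 3, 4)
  far <- c(8, 8, 8)
  nfr <- 200
  xyz <- t(vapply(seq_len(nfr), function(i)
    flat_xyz(rbind(site + rnorm(3, sd = 0.05),
                   far + runif(3, -2, 2))), numeric(6)))
  tr <- trajectory(top, xyz, times = seq_len(nfr) - 1)
  # radius chosen so the site falls at a voxel centre, not a boundary
  grid <- water_density_map(tr, region = list(center = site, radius = 4.25),
                            cell = 0.5, floor = 0.25)
  expect_gt(nrow(grid$maxima), 0)
  top_site <- as.numeric(grid$maxima[1, c("x", "y", "z")])
  expect_lt(sqrt(sum((top_site - site)^2)), 0.5)
  # OpenDX export is text
  path <- withr::local_tempfile(fileext = ".dx")
  write_dx(grid, path)
  head <- readLines(path, n = 3)
  expect_match(head[1], "gridpositions", all = FALSE)
})

test_that("water bridge fires on planted geometry and stays silent when the ion is displaced", {
  tcs <- lapply(1:2, function(r)
    gen_toy_complex("stable", n_frames = 80, seed = r, run_id = r,
                    bridge = list(ca_water = 2.0, water_so3 = 3.0)))
  trajs <- lapply(tcs, `[[`, "trajectory")
  top <- tcs[[1]]$topology
  wb <- detect_water_bridge(trajs, ion = top$groups$ion,
                            target_atoms = top$groups$SO3,
                            site = tcs[[1]]$truth$bridge_site, cell = 1.0)
  expect_true(wb$present_all_runs)
  expect_equal(mean(wb$per_run$ion_water_mean), 2.0, tolerance = 0.1)
  expect_equal(mean(wb$per_run$water_target_mean), 3.0, tolerance = 0.2)
  # displace the ion far away in every frame -> no bridge
  moved <- lapply(trajs, function(tr) {
    ion <- top$groups$ion
    cols <- (3 * (ion - 1) + 1):(3 * ion)
    tr$xyz[, cols] <- tr$xyz[, cols] + 20
    tr
  })
  wb2 <- detect_water_bridge(moved, ion = top$groups$ion,
                             target_atoms = top$groups$SO3,
                             site = tcs[[1]]$truth$bridge_site, cell = 1.0)
  expect_false(wb2$present_all_runs)
})

test_that("distance-only criteria capture calcium coordination", {
  tc <- gen_toy_complex("stable", n_frames = 50, seed = 2,
                        bridge = list(ca_water = 2.0, water_so3 = 3.0))
  top <- tc$topology
  crit <- hbond_criteria(distance = 3.0)
  occ <- hbond_occupancy(tc$trajectory, crit,
                         groupA = top$groups$ion,
                         groupB = top$groups$bridge_water,
                         distance_only = TRUE)
  expect_equal(nrow(occ), 1)
  expect_gt(occ$occupancy, 0.95)
})
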