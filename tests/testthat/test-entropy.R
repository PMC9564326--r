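# physical constants for closed-form oracles (SI + cal units)
HBAR <- 1.054571817e-34
KB <- 1.380649e-23
AMU <- 1.66053906892e-27
RCAL <- 1.98720425864083

test_that("QH mode entropy at x = 1 matches the oscillator formula", {
  T <- 300
  lambda1 <- HBAR^2 / (KB * T * AMU * 1e-20)  # makes x exactly 1
  s <- qh_entropy_from_cov(lambda1, T = T)
  s_ref <- RCAL * (1 / (exp(1) - 1) - log(1 - exp(-1)))
  expect_equal(as.numeric(s), s_ref, tolerance = 1e-12)
  expect_equal(attr(s, "eigenvalues"), lambda1)
})

test_that("QH entropy from a covariance matrix equals the eigenvalue route", {
  set.seed(1)
  masses <- c(12, 16)
  A <- matrix(rnorm(36), 6)
  cv <- crossprod(A) / 50 + diag(0.05, 6)
  mw <- sqrt(rep(masses, each = 3))
  lam <- eigen(t(cv * mw) * mw, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(as.numeric(qh_entropy_from_cov(cv, masses)),
               as.numeric(qh_entropy_from_cov(lam)), tolerance = 1e-10)
  expect_error(qh_entropy_from_cov(cv), "masses")
})

test_that("QH entropy recovers a harmonic bath within a few percent", {
  masses <- c(12, 16, 14, 1, 12)
  sig <- 0.35
  tr <- gen_harmonic_trajectory(masses, sigmas = sig, n_frames = 20000,
                                seed = 5)
  s_est <- quasiharmonic_entropy(tr, "all", masses = masses, fit = FALSE)
  lam <- rep(masses, each = 3) * sig^2
  s_true <- as.numeric(qh_entropy_from_cov(lam))
  expect_equal(as.numeric(s_est), s_true, tolerance = 0.03)
})

test_that("QH entropy grows with fluctuation amplitude", {
  masses <- c(12, 12, 12, 12)
  narrow <- gen_harmonic_trajectory(masses, sigmas = 0.2,
                                    n_frames = 3000, seed = 1)
  wide <- gen_harmonic_trajectory(masses, sigmas = 0.6,
                                  n_frames = 3000, seed = 1)
  s_n <- quasiharmonic_entropy(narrow, "all", masses = masses, fit = FALSE)
  s_w <- quasiharmonic_entropy(wide, "all", masses = masses, fit = FALSE)
  expect_gt(as.numeric(s_w), as.numeric(s_n))
})

test_that("fitted QH entropy is invariant to a rigid motion of the input", {
  masses <- c(12, 16, 14, 1, 32, 12)
  tr <- gen_harmonic_trajectory(masses, sigmas = 0.3,
                                n_frames = 2000, seed = 7,
                                centers = matrix(rnorm(18, sd = 4), 6, 3))
  set.seed(8)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  shift <- c(10, -5, 2)
  moved <- tr
  moved$xyz <- t(apply(tr$xyz, 1, function(row)
    flat_xyz(sweep(unflat_xyz(row) %*% q, 2, -shift))))
  s0 <- quasiharmonic_entropy(tr, "all", masses = masses)
  s1 <- quasiharmonic_entropy(moved, "all", masses = masses)
  expect_equal(as.numeric(s1), as.numeric(s0), tolerance = 1e-6)
})

test_that("entropy series + extrapolation recover an exact linear law", {
  ser <- data.frame(t_end = 1 / seq(0.5, 0.05, length.out = 8),
                    inv_t = seq(0.5, 0.05, length.out = 8))
  ser$entropy <- 120 - 35 * ser$inv_t
  ex <- suppressWarnings(extrapolate_entropy(ser))  # noiseless: lm warns
  expect_equal(ex$intercept, 120, tolerance = 1e-9)
  expect_equal(ex$slope, -35, tolerance = 1e-9)
  expect_equal(ex$r_squared, 1, tolerance = 1e-12)
  expect_error(extrapolate_entropy(ser[1:2, ]), "at least 3")
})

test_that("entropy_series windows are evenly spaced in inverse time", {
  masses <- c(12, 16, 14)
  tr <- gen_harmonic_trajectory(masses, sigmas = 0.3, n_frames = 2000,
                                seed = 3, dt = 0.01)
  ser <- entropy_series(tr, "all", masses = masses, n_windows = 6)
  expect_s3_class(ser, "entropy_series")
  expect_equal(nrow(ser), 6)
  expect_equal(diff(ser$inv_t), rep(diff(ser$inv_t)[1], 5),
               tolerance = 1e-9)
  expect_false(anyNA(ser$entropy))
  # entropy converges: the widest window sits closest to the intercept
  ex <- extrapolate_entropy(ser)
  expect_lt(abs(ser$entropy[6] - ex$intercept),
            abs(ser$entropy[1] - ex$intercept) + 1e-9)
})

test_that("KK matches the 1D Gaussian closed form: 30 deg -> 10 deg", {
  free <- gen_torsion_ensemble(mean = 40, cov = matrix(30^2), n = 2e5,
                               seed = 1, names = "phi")
  bound <- gen_torsion_ensemble(mean = -120, cov = matrix(10^2), n = 2e5,
                                seed = 2, names = "phi")
  pen <- torsional_entropy_kk(bound, free, T = 300)
  exact <- -300 * (RCAL * log(10 / 30)) / 1000   # 0.655 kcal/mol
  expect_equal(as.numeric(pen), exact, tolerance = 0.05 * exact)
  expect_gt(as.numeric(pen), 0)  # narrowing on binding costs entropy
})

test_that("KK is antisymmetric and vanishes for identical ensembles", {
  x <- gen_torsion_ensemble(mean = c(60, -60), cov = diag(c(144, 400)),
                            n = 5000, seed = 4, names = c("phi", "psi"))
  y <- gen_torsion_ensemble(mean = c(55, -70), cov = diag(c(64, 100)),
                            n = 5000, seed = 5, names = c("phi", "psi"))
  ab <- torsional_entropy_kk(x, y)
  ba <- torsional_entropy_kk(y, x)
  expect_equal(as.numeric(ab), -as.numeric(ba), tolerance = 1e-10)
  expect_equal(as.numeric(torsional_entropy_kk(x, x)), 0, tolerance = 1e-12)
})

test_that("KK handles wrapped torsions near the +/-180 seam", {
  # same width, mean at the seam: dS must still be ~0 vs an unwrapped twin
  seam <- gen_torsion_ensemble(mean = 178, cov = matrix(100), n = 5e4,
                               seed = 6, names = "phi")
  mid <- gen_torsion_ensemble(mean = 0, cov = matrix(100), n = 5e4,
                              seed = 7, names = "phi")
  pen <- torsional_entropy_kk(seam, mid)
  expect_equal(as.numeric(pen), 0, tolerance = 0.02)
})

test_that("KK reorders named columns and rejects mismatched ensembles", {
  x <- gen_torsion_ensemble(mean = c(0, 90), cov = diag(c(100, 225)),
                            n = 4000, seed = 8, names = c("phi", "psi"))
  y <- x[, c("psi", "phi")]
  expect_equal(as.numeric(torsional_entropy_kk(x, y)), 0, tolerance = 1e-10)
  z <- x; colnames(z) <- c("phi", "omega")
  expect_error(torsional_entropy_kk(x, z), "share torsion names")
})

test_that("KK warns on multimodal torsions and errors on degenerate ones", {
  set.seed(9)
  bimodal <- cbind(phi = c(rnorm(2000, -90, 8), rnorm(2000, 90, 8)))
  uni <- cbind(phi = rnorm(4000, 0, 8))
  expect_warning(torsional_entropy_kk(bimodal, uni), "multimodal")
  frozen <- cbind(phi = rep(12.3, 100))
  expect_error(suppressWarnings(torsional_entropy_kk(frozen, uni)),
               "singular covariance")
})

test_that("entropy assembly combines RTV and conformational penalties", {
  est <- assemble_entropy(S_complex = c(400, 402),
                          S_receptor = c(280, 281),
                          S_ligand = c(160, 158),
                          minus_TdS_conf = c(2.0, 2.2), T = 300)
  expect_s3_class(est, "entropy_estimate")
  rtv <- -300 * (c(400, 402) - c(280, 281) - c(160, 158)) / 1000
  expect_equal(est$minus_TdS_rtv, mean(rtv), tolerance = 1e-12)
  expect_equal(est$total, mean(rtv + c(2.0, 2.2)), tolerance = 1e-12)
  expect_equal(est$sd, sd(rtv + c(2.0, 2.2)), tolerance = 1e-12)
  expect_error(assemble_entropy(1:2, 1:3, 1:2, 0), "per-run")
})
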