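#' Harmonic-bath trajectory with known covariance
#'
#' Each coordinate fluctuates as an independent Gaussian about its mean
#' with the requested SD, so the mass-weighted covariance is diagonal
#' with entries `m_i sigma_i^2` -- a closed-form oracle for the
#' quasiharmonic entropy estimator.
#'
#' @param masses per-atom masses (amu).
#' @param sigmas per-coordinate fluctuation SDs (A); length 1, one per
#'   atom, or one per coordinate (3N).
#' @param n_frames number of frames.
#' @param seed RNG seed (generation is reproducible).
#' @param centers optional `N x 3` mean positions (default: atoms
#'   spread 5 A apart along x).
#' @param dt frame spacing (ns).
#' @return a `trajectory`; the topology carries group `"all"`.
#' @export
gen_harmonic_trajectory <- function(masses, sigmas, n_frames = 1000,
                                    seed = 1L, centers = NULL, dt = 0.01) {
  n <- length(masses)
  sig <- if (length(sigmas) == 1) rep(sigmas, 3 * n)
         else if (length(sigmas) == n) rep(sigmas, each = 3)
         else sigmas
  if (length(sig) != 3 * n) stop("sigmas must map to 3N coordinates")
  if (any(sig <= 0)) stop("fluctuation SDs must be > 0")
  if (is.null(centers)) centers <- cbind(5 * (seq_len(n) - 1), 0, 0)
  atoms <- data.frame(serial = seq_len(n), name = paste0("X", seq_len(n)),
                      element = "C", resno = 1L, resname = "BTH",
                      stringsAsFactors = FALSE)
  top <- topology(atoms, groups = list(all = seq_len(n)))
  set.seed(seed)
  mu <- flat_xyz(centers)
  xyz <- matrix(stats::rnorm(n_frames * 3 * n, mean = rep(mu, each = n_frames),
                             sd = rep(sig, each = n_frames)),
                nrow = n_frames)
  tr <- trajectory(top, xyz, times = (seq_len(n_frames) - 1) * dt)
  attr(tr, "truth") <- list(masses = masses, sigmas = sig, centers = centers)
  tr
}

#' Torsion ensemble from a known multivariate Gaussian
#'
#' Samples are drawn from `N(mean, cov)` and wrapped to (-180, 180],
#' giving a ground-truth input for the Karplus-Kushick estimator.
#'
#' @param mean mean torsions (degrees).
#' @param cov covariance matrix (degrees^2); a scalar or vector is
#'   taken as a diagonal.
#' @param n sample count.
#' @param seed RNG seed.
#' @param names torsion names (columns).
#' @return matrix `n x length(mean)` in degrees.
#' @export
gen_torsion_ensemble <- function(mean, cov, n = 1e4, seed = 1L,
                                 names = NULL) {
  p <- length(mean)
  if (!is.matrix(cov)) cov <- diag(rep_len(as.numeric(cov), p), nrow = p)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("covariance must be symmetric positive-definite")
  set.seed(seed)
  x <- MASS::mvrnorm(n, mu = mean, Sigma = cov)
  x <- matrix(x, nrow = n)
  x <- .wrap180(x)
  colnames(x) <- if (is.null(names)) paste0("tor", seq_len(p)) else names
  x
}

#' Synthetic protein-glycan toy complex
#'
#' Generates a small receptor-ligand complex trajectory with planted,
#' recoverable properties: a stable / multi-pose / diffusing ligand, a
#' hydrogen bond with a requested occupancy, a salt bridge between an
#' arginine-like side chain and the ligand sulfate, and (optionally) a
#' Ca2+ -- water -- sulfate-oxygen bridge at stated distances. The
#' matching force-field parameter table (with alanine templates) is
#' attached, so the full analysis pipeline runs on the output
#' unchanged.
#'
#' The ligand mimics a sulfated tetrasaccharide: four sugar residues
#' (SIA, GAL, NAG, FUC) with the galactose carrying an SO3 group; the
#' GAL ring supplies the `"ring_atoms"` group used for pose analysis.
#' Pose switching is block-wise (contiguous dwells) to mimic the
#' autocorrelation of real trajectories.
#'
#' @param mode `"stable"`, `"multi-pose"` or `"diffusing"`.
#' @param n_frames frames to generate.
#' @param noise_sd per-coordinate Gaussian jitter (A).
#' @param seed RNG seed.
#' @param pose_centers list of ligand displacement 3-vectors
#'   (multi-pose mode; default three poses 6 A apart).
#' @param dwell_fractions fraction of frames per pose (multi-pose).
#' @param hbond_fraction fraction of frames in which the planted
#'   receptor-ligand hydrogen bond holds its geometry.
#' @param hbond_distance heavy-atom distance of the planted bond (A).
#' @param bridge NULL, or `list(ca_water =, water_so3 =)` distances (A)
#'   for the planted Ca2+ -- water -- sulfate bridge.
#' @param run_id run label.
#' @param dt frame spacing (ns).
#' @return list of class `"toy_complex"`: `trajectory`, `topology`,
#'   `params`, and `truth` (planted pose labels, hydrogen-bond frames,
#'   bridge site).
#' @export
gen_toy_complex <- function(mode = c("stable", "multi-pose", "diffusing"),
                            n_frames = 1000, noise_sd = 0.2, seed = 1L,
                            pose_centers = NULL, dwell_fractions = NULL,
                            hbond_fraction = 1.0, hbond_distance = 2.8,
                            bridge = NULL, run_id = 1L, dt = 0.1) {
  mode <- match.arg(mode)
  lay <- .toy_layout(bridge)
  base <- lay$coords
  if (min(stats::dist(base)) < 0.5)
    stop("geometry error: overlapping atoms (< 0.5 A) in layout")
  top <- lay$topology
  n <- nrow(base)
  lig <- top$groups$ligand
  move_with_lig <- c(top$groups$ion, top$groups$bridge_water)

  if (mode == "multi-pose") {
    if (is.null(pose_centers))
      pose_centers <- list(c(0, 0, 0), c(6, 0, 0), c(0, 6, 0))
    if (is.null(dwell_fractions))
      dwell_fractions <- c(0.5, 0.3, 0.2)
    if (length(pose_centers) != length(dwell_fractions))
      stop("one dwell fraction per pose center required")
    counts <- diff(round(cumsum(c(0, dwell_fractions)) * n_frames))
    pose_of <- rep(seq_along(pose_centers), counts)
    pose_of <- rep_len(pose_of, n_frames)
  } else pose_of <- rep(1L, n_frames)

  set.seed(seed)
  xyz <- matrix(0, n_frames, 3 * n)
  hb_on <- rep(TRUE, n_frames)
  if (hbond_fraction < 1)
    hb_on <- seq_len(n_frames) %in%
      sample.int(n_frames, round(hbond_fraction * n_frames))
  acceptor <- lay$hb_acceptor
  for (f in seq_len(n_frames)) {
    co <- base
    disp <- c(0, 0, 0)
    if (mode == "multi-pose") disp <- pose_centers[[pose_of[f]]]
    if (mode == "diffusing") disp <- c(15, 8, 5) * (f - 1) / max(1, n_frames - 1)
    mv <- c(lig, move_with_lig)
    co[mv, ] <- sweep(co[mv, , drop = FALSE], 2, disp, "+")
    if (!hb_on[f]) co[acceptor, ] <- co[acceptor, ] + c(0, 0, 2.5)
    co <- co + matrix(stats::rnorm(3 * n, sd = noise_sd), n, 3)
    # ion + bridge water track the sulfate tightly (coordination shell)
    if (length(move_with_lig)) {
      so3_o <- lay$bridge_target
      shift <- co[so3_o, ] - (base[so3_o, ] + disp)
      co[move_with_lig, ] <- sweep(base[move_with_lig, , drop = FALSE],
                                   2, disp + shift, "+") +
        matrix(stats::rnorm(3 * length(move_with_lig), sd = 0.02),
               length(move_with_lig), 3)
    }
    xyz[f, ] <- flat_xyz(co)
  }
  traj <- trajectory(top, xyz, times = (seq_len(n_frames) - 1) * dt,
                     run_id = run_id)
  structure(list(trajectory = traj, topology = top, params = lay$params,
                 reference = frame(base),
                 truth = list(mode = mode, pose_of = pose_of,
                              dwell_fractions = dwell_fractions,
                              hbond_frames = hb_on,
                              hbond_donor = lay$hb_donor,
                              hbond_acceptor = acceptor,
                              bridge_site = lay$bridge_site,
                              bridge = bridge)),
            class = "toy_complex")
}

# Fixed toy geometry. Receptor: SER1 (H-bond donor), ARG2 (+1 tip for
# the salt bridge), ALA3. Ligand: SIA11-GAL12(-SO3)-NAG13-FUC14.
# Optional Ca2+ ion (res 20) and bridging water (res 21).
.toy_layout <- function(bridge = NULL) {
  a <- function(name, element, resno, resname, x, y, z)
    data.frame(name = name, element = element, resno = resno,
               resname = resname, x = x, y = y, z = z,
               stringsAsFactors = FALSE)
  hexagon <- function(cx, cy, cz, r = 1.4) {
    th <- 2 * pi * (0:5) / 6
    cbind(cx + r * cos(th), cy + r * sin(th),
          cz + 0.25 * c(1, -1, 1, -1, 1, -1))
  }
  rows <- list(
    # receptor residue 1: serine-like donor (OG-HG points at the ligand)
    a("N",  "N", 1, "SER", -6.0, 0.0, 0.0),
    a("CA", "C", 1, "SER", -4.6, 0.0, 0.0),
    a("C",  "C", 1, "SER", -3.9, 1.3, 0.0),
    a("O",  "O", 1, "SER", -4.5, 2.4, 0.0),
    a("CB", "C", 1, "SER", -3.9, -1.3, 0.0),
    a("OG", "O", 1, "SER", -2.5, -1.3, 0.0),
    a("HG", "H", 1, "SER", -1.9, -1.3, 0.8),
    # receptor residue 2: arginine-like, long side chain reaching the
    # sulfate with its charged tip CZ
    a("N",  "N", 2, "ARG", -3.6, 9.4, -1.2),
    a("CA", "C", 2, "ARG", -3.0, 8.2, -1.0),
    a("CB", "C", 2, "ARG", -3.3, 6.9, -0.3),
    a("CG", "C", 2, "ARG", -3.2, 5.5, 0.2),
    a("CZ", "C", 2, "ARG", -2.3, 4.3, 0.6),
    a("C",  "C", 2, "ARG", -1.6, 8.6, -1.4),
    a("O",  "O", 2, "ARG", -1.2, 9.7, -1.5),
    # receptor residue 3: alanine on the far side of the ligand; the
    # three C-alpha atoms must span a well-conditioned triangle or the
    # superposition fit is rotationally degenerate under jitter
    a("N",  "N", 3, "ALA", 11.4, 0.4, 0.9),
    a("CA", "C", 3, "ALA", 10.0, 0.0, 0.8),
    a("CB", "C", 3, "ALA", 9.6, -1.2, 1.6),
    a("C",  "C", 3, "ALA", 9.2, 1.2, 1.3),
    a("O",  "O", 3, "ALA", 9.7, 2.3, 1.5))
  # ligand: SIA (3 atoms), GAL ring + O3/O6-SO3, NAG ring, FUC (3)
  gal <- hexagon(1.5, 0, 0)
  nag <- hexagon(5.0, 1.2, -0.4)
  ring_names <- c("O5", "C1", "C2", "C3", "C4", "C5")
  rows <- c(rows, list(
    a("C2", "C", 11, "SIA", 4.6, -2.2, 0.5),
    a("C3", "C", 11, "SIA", 5.6, -3.2, 0.5),
    a("O6", "O", 11, "SIA", 5.2, -1.0, 0.2)))
  for (k in 1:6)
    rows <- c(rows, list(a(ring_names[k], ifelse(k == 1, "O", "C"), 12, "GAL",
                           gal[k, 1], gal[k, 2], gal[k, 3])))
  rows <- c(rows, list(
    a("O3", "O", 12, "GAL", 3.0, -1.5, 0.4),   # link to SIA C2
    # planted H-bond acceptor: collinear with the SER OG-HG vector at a
    # 2.8 A heavy-atom distance, so the geometric criteria hold
    a("O4", "O", 12, "GAL", -0.82, -1.3, 2.24),
    a("O6", "O", 12, "GAL", 1.5, 2.0, 1.2),    # sulfate attachment
    a("S",  "S", 12, "GAL", 1.5, 3.6, 1.4),
    a("O1S", "O", 12, "GAL", 0.2, 4.2, 1.4),
    a("O2S", "O", 12, "GAL", 2.2, 4.0, 2.6)))
  for (k in 1:6)
    rows <- c(rows, list(a(ring_names[k], ifelse(k == 1, "O", "C"), 13, "NAG",
                           nag[k, 1], nag[k, 2], nag[k, 3])))
  rows <- c(rows, list(
    a("O4", "O", 13, "NAG", 3.25, 0.6, -0.2),  # Gal b1-4 glycosidic oxygen
    a("O3", "O", 13, "NAG", 2.8, 0.35, -1.6),  # Fuc a1-3 glycosidic oxygen
    a("C1", "C", 14, "FUC", 2.0, -0.5, -2.6),
    a("O5", "O", 14, "FUC", 1.2, -1.6, -2.9),
    a("C2", "C", 14, "FUC", 3.4, -0.6, -3.2)))
  df <- do.call(rbind, rows)
  has_bridge <- !is.null(bridge)
  if (has_bridge) {
    d1 <- bridge$water_so3; d2 <- bridge$ca_water
    # extend up and away from the sulfate, clear of the Arg tip
    o1s <- c(0.2, 4.2, 1.4)
    u <- c(-0.55, 0.45, 0.70) / sqrt(0.995)
    wat <- o1s + d1 * u
    ca <- wat + d2 * u
    df <- rbind(df,
                a("CA", "CA", 20, "CA", ca[1], ca[2], ca[3]),
                a("O", "O", 21, "WAT", wat[1], wat[2], wat[3]))
  }
  n <- nrow(df)
  atoms <- data.frame(serial = seq_len(n), name = df$name,
                      element = df$element, resno = df$resno,
                      resname = df$resname, stringsAsFactors = FALSE)
  idx_of <- function(resno, name) which(df$resno == resno & df$name == name)
  receptor <- which(df$resno <= 3)
  ligand <- which(df$resno >= 11 & df$resno <= 14)
  groups <- list(
    receptor = receptor, ligand = ligand,
    receptor_ca = which(df$resno <= 3 & df$name == "CA"),
    ring_atoms = unlist(lapply(ring_names, idx_of, resno = 12)),
    Neu5Ac = which(df$resno == 11),
    Gal = setdiff(which(df$resno == 12),
                  c(idx_of(12, "S"), idx_of(12, "O1S"), idx_of(12, "O2S"))),
    GlcNAc = which(df$resno == 13),
    Fuc = which(df$resno == 14),
    SO3 = c(idx_of(12, "S"), idx_of(12, "O1S"), idx_of(12, "O2S")))
  if (has_bridge) {
    groups$ion <- which(df$resno == 20)
    groups$bridge_water <- which(df$resno == 21)
  }
  bonds <- rbind(
    cbind(idx_of(1, "OG"), idx_of(1, "HG")),
    cbind(idx_of(11, "C2"), idx_of(12, "O3")),  # Neu5Ac a2-3 Gal
    cbind(idx_of(12, "O3"), idx_of(12, "C3")),
    cbind(idx_of(12, "C1"), idx_of(13, "O4")),  # Gal b1-4 GlcNAc
    cbind(idx_of(13, "O4"), idx_of(13, "C4")),
    cbind(idx_of(14, "C1"), idx_of(13, "O3")),  # Fuc a1-3 GlcNAc
    cbind(idx_of(13, "O3"), idx_of(13, "C3")),
    cbind(idx_of(12, "O6"), idx_of(12, "S")))
  top <- topology(atoms, groups = groups, bonds = bonds)
  params <- .toy_params()
  list(coords = as.matrix(df[, c("x", "y", "z")]), topology = top,
       params = params,
       hb_donor = idx_of(1, "OG"), hb_acceptor = idx_of(12, "O4"),
       bridge_target = if (has_bridge) idx_of(12, "O1S") else idx_of(12, "O1S"),
       bridge_site = if (has_bridge) {
         o1s <- c(0.2, 4.2, 1.4); u <- c(-0.55, 0.45, 0.70) / sqrt(0.995)
         o1s + bridge$water_so3 * u
       } else NULL)
}

# toy parameter table: neutral scaffold, +1 on ARG CZ, -1 spread on SO3
.toy_params <- function() {
  entry <- function(resname, name, charge, rmin_half = 1.7, eps = 0.1,
                    mass = 12.011, gbr = 1.7) {
    data.frame(resname = resname, name = name, charge = charge,
               rmin_half = rmin_half, epsilon = eps, mass = mass,
               gb_radius = gbr, stringsAsFactors = FALSE)
  }
  tab <- rbind(
    entry("SER", "N", -0.1, 1.824, 0.17, 14.007, 1.55),
    entry("SER", "CA", 0.05), entry("SER", "C", 0.2),
    entry("SER", "O", -0.25, 1.66, 0.21, 15.999, 1.5),
    entry("SER", "CB", 0.05),
    entry("SER", "OG", -0.3, 1.72, 0.21, 15.999, 1.5),
    entry("SER", "HG", 0.35, 0.6, 0.0157, 1.008, 1.2),
    entry("ARG", "N", -0.1, 1.824, 0.17, 14.007, 1.55),
    entry("ARG", "CA", 0.05), entry("ARG", "CB", 0.0),
    entry("ARG", "CG", 0.0), entry("ARG", "CZ", 1.0),
    entry("ARG", "C", 0.2),
    entry("ARG", "O", -0.25, 1.66, 0.21, 15.999, 1.5),
    entry("ALA", "N", -0.1, 1.824, 0.17, 14.007, 1.55),
    entry("ALA", "CA", 0.05), entry("ALA", "CB", 0.0),
    entry("ALA", "C", 0.2),
    entry("ALA", "O", -0.25, 1.66, 0.21, 15.999, 1.5),
    entry("SIA", "C2", 0.1), entry("SIA", "C3", 0.0),
    entry("SIA", "O6", -0.3, 1.72, 0.21, 15.999, 1.5),
    entry("GAL", "O5", -0.2, 1.72, 0.17, 15.999, 1.5),
    entry("GAL", "C1", 0.1), entry("GAL", "C2", 0.05),
    entry("GAL", "C3", 0.05), entry("GAL", "C4", 0.05),
    entry("GAL", "C5", 0.05),
    entry("GAL", "O3", -0.25, 1.72, 0.21, 15.999, 1.5),
    entry("GAL", "O4", -0.3, 1.72, 0.21, 15.999, 1.5),
    entry("GAL", "O6", -0.25, 1.72, 0.21, 15.999, 1.5),
    entry("GAL", "S", 0.2, 2.0, 0.25, 32.06, 1.8),
    entry("GAL", "O1S", -0.6, 1.66, 0.21, 15.999, 1.5),
    entry("GAL", "O2S", -0.6, 1.66, 0.21, 15.999, 1.5),
    entry("NAG", "C1", 0.1), entry("NAG", "O5", -0.2, 1.72, 0.17, 15.999, 1.5),
    entry("NAG", "C2", 0.05), entry("NAG", "C3", 0.05),
    entry("NAG", "C4", 0.05), entry("NAG", "C5", 0.05),
    entry("NAG", "O3", -0.25, 1.72, 0.21, 15.999, 1.5),
    entry("NAG", "O4", -0.25, 1.72, 0.21, 15.999, 1.5),
    entry("FUC", "C1", 0.1), entry("FUC", "O5", -0.2, 1.72, 0.17, 15.999, 1.5),
    entry("FUC", "C2", 0.05),
    entry("CA", "CA", 2.0, 1.7, 0.1, 40.08, 1.7),
    entry("WAT", "O", -0.834, 1.768, 0.152, 15.999, 1.5))
  ff_params(tab, eps_int = 3.0)
}

#' @export
print.toy_complex <- function(x, ...) {
  cat("synthetic toy complex (", x$truth$mode, " mode): ",
      n_frames(x$trajectory), " frames\n", sep = "")
  invisible(x)
}
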