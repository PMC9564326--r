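#' Cross-group molecular-mechanics interaction energy
#'
#' Coulomb energy `k * sum(qi qj / (eps_int rij))` and 12-6
#' Lennard-Jones energy with Lorentz-Berthelot combination
#' (`rmin = rmin_half_i + rmin_half_j`, `eps = sqrt(eps_i eps_j)`),
#' summed over all cross pairs with no cutoff, as is conventional for
#' MM-GBSA rescoring.
#'
#' @param coords `N x 3` frame.
#' @param ptab per-atom parameter table from [match_params()].
#' @param groupA,groupB disjoint atom index vectors.
#' @param eps_int internal dielectric.
#' @param coulomb Coulomb constant, kcal A/(mol e^2).
#' @return list: `E_elec`, `E_vdW` (kcal/mol).
#' @export
pair_energy <- function(coords, ptab, groupA, groupB, eps_int = 3.0,
                        coulomb = .COULOMB_KCAL) {
  if (length(intersect(groupA, groupB))) stop("groups overlap")
  xyz <- as.matrix(coords)
  r <- .dist_between(xyz[groupA, , drop = FALSE], xyz[groupB, , drop = FALSE])
  if (any(r < 0.1))
    stop("overlapping atoms (r < 0.1 A): electrostatic singularity")
  qq <- outer(ptab$charge[groupA], ptab$charge[groupB])
  E_elec <- coulomb * sum(qq / r) / eps_int
  rmin <- outer(ptab$rmin_half[groupA], ptab$rmin_half[groupB], "+")
  epsm <- sqrt(outer(ptab$epsilon[groupA], ptab$epsilon[groupB]))
  sr6 <- (rmin / r)^6
  E_vdW <- sum(epsm * (sr6^2 - 2 * sr6))
  list(E_elec = E_elec, E_vdW = E_vdW)
}

.dist_between <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Pairwise HCT descreening contributions: C[i, j] is the reduction of
# atom i's inverse Born radius caused by atom j (0 on the diagonal).
# rho: offset-corrected intrinsic radii; s: screened radii (screen * rho).
.gb_descreen <- function(xyz, rho, s) {
  n <- nrow(xyz)
  C <- matrix(0, n, n)
  if (n < 2) return(C)
  r <- .dist_between(xyz, xyz)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    rij <- r[i, j]
    if (rho[i] >= rij + s[j]) next  # j fully inside i's sphere
    U <- rij + s[j]
    L <- max(rho[i], abs(rij - s[j]))
    C[i, j] <- 0.5 * (1 / L - 1 / U +
                        0.25 * rij * (1 / U^2 - 1 / L^2) +
                        0.5 / rij * log(L / U) +
                        0.25 * s[j]^2 / rij * (1 / L^2 - 1 / U^2))
  }
  C
}

#' Effective Born radii (GB-OBC, model I)
#'
#' Intrinsic radii reduced by the radius offset are descreened through
#' the pairwise HCT integral and rescaled with the OBC tanh correction
#' `1/R = 1/rho~ - tanh(a P - b P^2 + g P^3) / rho`, with the model-I
#' constants (0.8, 0, 2.909125) by default.
#'
#' @param coords `N x 3` coordinates of the (sub)system.
#' @param rho intrinsic GB radii (A).
#' @param screen per-atom descreening scale factors.
#' @param offset radius offset (A).
#' @param alpha,beta,gamma OBC constants.
#' @return list: `radii` (effective, A), `descreen` (contribution
#'   matrix), `psi` (the OBC Psi values).
#' @export
gb_effective_radii <- function(coords, rho, screen, offset = 0.09,
                               alpha = 0.8, beta = 0, gamma = 2.909125) {
  xyz <- as.matrix(coords)
  if (any(rho <= offset)) stop("GB radius <= offset for some atom")
  rt <- rho - offset
  C <- .gb_descreen(xyz, rt, screen * rt)
  psi <- rt * rowSums(C)
  inv <- 1 / rt - tanh(alpha * psi - beta * psi^2 + gamma * psi^3) / rho
  list(radii = 1 / inv, descreen = C, psi = psi)
}

# matrix of GB pair energy terms; `pref` is the half-prefactor
# 0.5 (1/eps_int - 1/eps_solv). In the canonical double sum
# -pref sum_ij qi qj / f_ij each unordered pair appears twice, so the
# once-counted off-diagonal entries carry 2 pref while the diagonal
# (self/Born) terms carry pref. sum(T) over upper+diag is the polar
# energy.
.gb_pair_terms <- function(xyz, q, R, pref, coulomb) {
  n <- length(q)
  r2 <- .dist_between(xyz, xyz)^2
  RR <- outer(R, R)
  f <- sqrt(r2 + RR * exp(-r2 / (4 * RR)))
  tmat <- -2 * pref * coulomb * outer(q, q) / f
  tmat[lower.tri(tmat)] <- 0
  diag(tmat) <- -pref * coulomb * q^2 / R
  tmat
}

#' Generalized-Born polar solvation energy
#'
#' Canonical smooth pairwise form with
#' `f_GB = sqrt(r^2 + Ri Rj exp(-r^2 / (4 Ri Rj)))` and prefactor
#' `-1/2 (1/eps_int - 1/eps_solv)`, over effective GB-OBC radii
#' computed for the given subsystem alone.
#'
#' @param coords `N x 3` frame (full topology coordinates).
#' @param ptab per-atom parameter table from [match_params()].
#' @param group atom indices of the subsystem.
#' @param global list of global parameters (an `ff_params$global`).
#' @return polar energy (kcal/mol) with attribute `"radii"`.
#' @export
gb_energy <- function(coords, ptab, group, global) {
  xyz <- as.matrix(coords)[group, , drop = FALSE]
  rho <- ptab$gb_radius[group]
  if (anyNA(rho)) stop("missing GB radius in group")
  eff <- gb_effective_radii(xyz, rho, ptab$screen[group],
                            offset = global$gb_offset,
                            alpha = global$gb_alpha, beta = global$gb_beta,
                            gamma = global$gb_gamma)
  pref <- 0.5 * (1 / global$eps_int - 1 / global$eps_solv)
  tmat <- .gb_pair_terms(xyz, ptab$charge[group], eff$radii, pref,
                         global$coulomb)
  structure(sum(tmat), radii = eff$radii)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic quadrature: each atom's solvent-extended sphere is
#' sampled on a Fibonacci lattice and points inside any neighbour's
#' extended sphere are discarded.
#'
#' @param coords `N x 3` frame.
#' @param radii per-atom radii (A).
#' @param probe probe radius (A).
#' @param n_points quadrature points per atom.
#' @return per-atom accessible areas (A^2).
#' @export
sasa <- function(coords, radii, probe = 1.4, n_points = 960) {
  xyz <- as.matrix(coords)
  n <- nrow(xyz)
  if (length(radii) != n) stop("one radius per atom required")
  sphere <- .fibonacci_sphere(n_points)
  ext <- radii + probe
  areas <- numeric(n)
  if (n > 1) dmat <- .dist_between(xyz, xyz)
  for (i in seq_len(n)) {
    pts <- sweep(sphere * ext[i], 2, xyz[i, ], "+")
    nb <- if (n > 1) which(dmat[i, ] < ext[i] + ext & seq_len(n) != i) else integer()
    free <- rep(TRUE, n_points)
    for (j in nb) {
      d2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
      free <- free & d2 > ext[j]^2
      if (!any(free)) break
    }
    areas[i] <- 4 * pi * ext[i]^2 * sum(free) / n_points
  }
  areas
}

.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

# evenly spaced snapshot indices
.even_snapshots <- function(nf, n) {
  if (is.null(n) || n >= nf) return(seq_len(nf))
  unique(round(seq(1, nf, length.out = n)))
}

#' Single-trajectory MM-GBSA interaction energy
#'
#' For snapshots sampled evenly from each run, computes
#' `dG = G(complex) - G(receptor) - G(ligand)` with receptor and ligand
#' coordinates taken from the complex frame, so internal bonded terms
#' cancel and only the cross molecular-mechanics terms plus the
#' solvation changes remain:
#' `dG = E_elec + E_vdW + ddG_GB + ddG_SASA`.
#'
#' @param trajs a `trajectory` or list of runs.
#' @param params an `"ff_params"`.
#' @param receptor,ligand group names or index vectors.
#' @param n_snapshots snapshots per run (NULL = every frame).
#' @param include_gb,include_sasa disable solvation terms (for
#'   closed-form checks).
#' @return object of class `"energy_components"`.
#' @export
mmgbsa_interaction <- function(trajs, params, receptor = "receptor",
                               ligand = "ligand", n_snapshots = NULL,
                               include_gb = TRUE, include_sasa = TRUE) {
  trajs <- as_traj_list(trajs)
  top <- trajs[[1]]$topology
  rec <- atom_group(top, receptor); lig <- atom_group(top, ligand)
  ptab <- match_params(top, params, subset = c(rec, lig))
  g <- params$global
  per_run <- list()
  for (tr in trajs) {
    if (!is.null(n_snapshots) && n_snapshots > n_frames(tr))
      stop("n_snapshots exceeds the ", n_frames(tr), " available frames")
    snaps <- .even_snapshots(n_frames(tr), n_snapshots)
    comp <- matrix(0, length(snaps), 4,
                   dimnames = list(NULL, c("E_elec", "E_vdW", "dG_GB",
                                           "dG_SASA")))
    for (s in seq_along(snaps)) {
      xyz <- unflat_xyz(tr$xyz[snaps[s], ])
      mm <- pair_energy(xyz, ptab, rec, lig, eps_int = g$eps_int,
                        coulomb = g$coulomb)
      comp[s, 1:2] <- c(mm$E_elec, mm$E_vdW)
      if (include_gb) {
        all_idx <- c(rec, lig)
        comp[s, 3] <- gb_energy(xyz, ptab, all_idx, g) -
          gb_energy(xyz, ptab, rec, g) - gb_energy(xyz, ptab, lig, g)
      }
      if (include_sasa) {
        all_idx <- c(rec, lig)
        a_c <- sasa(xyz[all_idx, , drop = FALSE], ptab$rmin_half[all_idx],
                    probe = g$probe_radius)
        a_r <- sasa(xyz[rec, , drop = FALSE], ptab$rmin_half[rec],
                    probe = g$probe_radius)
        a_l <- sasa(xyz[lig, , drop = FALSE], ptab$rmin_half[lig],
                    probe = g$probe_radius)
        comp[s, 4] <- g$surface_tension * (sum(a_c) - sum(a_r) - sum(a_l))
      }
    }
    m <- colMeans(comp)
    per_run[[length(per_run) + 1L]] <-
      data.frame(run = tr$run_id, t(m), total = sum(m),
                 sd_snapshots = stats::sd(rowSums(comp)),
                 n_snapshots = length(snaps))
  }
  per_run <- do.call(rbind, per_run)
  totals <- per_run$total
  structure(list(per_run = per_run,
                 mean = colMeans(per_run[, c("E_elec", "E_vdW", "dG_GB",
                                             "dG_SASA", "total")]),
                 sd = if (nrow(per_run) > 1) stats::sd(totals) else NA_real_),
            class = "energy_components")
}

#' @export
print.energy_components <- function(x, ...) {
  m <- x$mean
  cat(sprintf(
    "MM-GBSA interaction energy over %d run(s):\n", nrow(x$per_run)))
  cat(sprintf("  E_elec %8.2f  E_vdW %8.2f  dG_GB %8.2f  dG_SASA %8.2f\n",
              m["E_elec"], m["E_vdW"], m["dG_GB"], m["dG_SASA"]))
  cat(sprintf("  dG_MM/GBSA = %.2f%s kcal/mol\n", m["total"],
              if (is.na(x$sd)) "" else sprintf(" +/- %.2f", x$sd)))
  invisible(x)
}

#' Per-group MM-GBSA decomposition of the ligand
#'
#' Attributes the interaction energy to named ligand atom groups (e.g.
#' the Neu5Ac / Gal / GlcNAc / Fuc / SO3 moieties). Each group receives
#' its full cross molecular-mechanics interaction with the receptor, a
#' pairwise decomposition of the GB change, and its SASA change; group
#' energies sum to the [mmgbsa_interaction()] total by construction.
#' GB attribution: cross pairs go to the ligand-side group; ligand
#' self-pairs to their own group (split evenly across two groups);
#' receptor self-pair changes are apportioned by each ligand group's
#' share of the receptor descreening change, which is exact because the
#' OBC Psi is linear in per-source contributions. Receptor atoms' SASA
#' changes go to the nearest ligand group.
#'
#' @param trajs a `trajectory` or list of runs.
#' @param params an `"ff_params"`.
#' @param receptor receptor group name or indices.
#' @param partition named list of atom groups that exactly covers the
#'   ligand.
#' @param ligand the ligand group the partition must cover.
#' @param n_snapshots snapshots per run (NULL = every frame).
#' @param include_gb,include_sasa as in [mmgbsa_interaction()].
#' @return data.frame of class `"pergroup_table"` with per-group
#'   energies, cross-run SDs and integer percent contributions;
#'   attribute `"total"` holds the summed mean.
#' @export
per_group_decomposition <- function(trajs, params, receptor = "receptor",
                                    partition, ligand = "ligand",
                                    n_snapshots = NULL, include_gb = TRUE,
                                    include_sasa = TRUE) {
  trajs <- as_traj_list(trajs)
  top <- trajs[[1]]$topology
  rec <- atom_group(top, receptor)
  partition <- lapply(partition, function(p) atom_group(top, p))
  lig <- atom_group(top, ligand)
  if (anyDuplicated(unlist(partition)) ||
      !setequal(unlist(partition), lig))
    stop("partition must cover the ligand exactly with disjoint groups")
  gnames <- names(partition)
  ptab <- match_params(top, params, subset = c(rec, lig))
  g <- params$global
  group_of <- integer(n_atoms(top))          # 0 = receptor/none
  for (k in seq_along(partition)) group_of[partition[[k]]] <- k
  run_mats <- list()
  for (tr in trajs) {
    snaps <- .even_snapshots(n_frames(tr), n_snapshots)
    acc <- matrix(0, length(gnames), 4,
                  dimnames = list(gnames, c("E_elec", "E_vdW", "dG_GB",
                                            "dG_SASA")))
    for (s in snaps) {
      xyz <- unflat_xyz(tr$xyz[s, ])
      acc <- acc + .decompose_snapshot(xyz, ptab, rec, partition, group_of,
                                       g, include_gb, include_sasa)
    }
    run_mats[[length(run_mats) + 1L]] <- acc / length(snaps)
  }
  arr <- simplify2array(run_mats)            # groups x comps x runs
  mean_mat <- apply(arr, c(1, 2), mean)
  energy <- rowSums(mean_mat)
  energy_runs <- apply(arr, c(1, 3), sum)    # groups x runs
  sds <- if (length(run_mats) > 1) apply(energy_runs, 1, stats::sd)
         else rep(NA_real_, length(gnames))
  out <- data.frame(group = gnames, mean_mat, energy = energy, sd = sds,
                    row.names = NULL)
  total <- sum(energy)
  out$percent <- .format_percent(100 * energy / total)
  attr(out, "total") <- total
  class(out) <- c("pergroup_table", "data.frame")
  out
}

# one snapshot of the decomposition; returns groups x 4 matrix
.decompose_snapshot <- function(xyz, ptab, rec, partition, group_of, g,
                                include_gb, include_sasa) {
  gnames <- names(partition)
  ng <- length(gnames)
  acc <- matrix(0, ng, 4, dimnames = list(gnames, NULL))
  lig <- unlist(partition)
  for (k in seq_len(ng)) {
    mm <- pair_energy(xyz, ptab, rec, partition[[k]], eps_int = g$eps_int,
                      coulomb = g$coulomb)
    acc[k, 1] <- mm$E_elec; acc[k, 2] <- mm$E_vdW
  }
  if (include_gb) {
    all_idx <- c(rec, lig)
    pref <- 0.5 * (1 / g$eps_int - 1 / g$eps_solv)
    sub <- function(idx) {
      rho <- ptab$gb_radius[idx]
      eff <- gb_effective_radii(xyz[idx, , drop = FALSE], rho,
                                ptab$screen[idx], offset = g$gb_offset,
                                alpha = g$gb_alpha, beta = g$gb_beta,
                                gamma = g$gb_gamma)
      tm <- .gb_pair_terms(xyz[idx, , drop = FALSE], ptab$charge[idx],
                           eff$radii, pref, g$coulomb)
      list(eff = eff, tmat = tm)
    }
    cx <- sub(all_idx); rx <- sub(rec); lx <- sub(lig)
    nall <- length(all_idx)
    # delta term matrix in complex indexing
    delta <- cx$tmat
    nr <- length(rec); nl <- length(lig)
    delta[seq_len(nr), seq_len(nr)] <-
      delta[seq_len(nr), seq_len(nr)] - rx$tmat
    delta[nr + seq_len(nl), nr + seq_len(nl)] <-
      delta[nr + seq_len(nl), nr + seq_len(nl)] - lx$tmat
    # receptor descreening shares per ligand group (Psi is linear in
    # per-source contributions)
    rt_rec <- (ptab$gb_radius[rec] - g$gb_offset)
    Cc <- cx$eff$descreen
    psi_g <- sapply(seq_along(partition), function(k) {
      cols <- nr + which(group_of[lig] == k)
      rt_rec * rowSums(Cc[seq_len(nr), cols, drop = FALSE])
    })
    psi_g <- matrix(psi_g, nrow = nr)
    denom <- rowSums(psi_g)
    w <- psi_g / ifelse(denom > 0, denom, 1)
    w[denom <= 0, ] <- 1 / ng
    gidx_all <- c(rep(0L, nr), group_of[lig])   # group per complex index
    for (i in seq_len(nall)) for (j in i:nall) {
      d <- delta[i, j]
      if (d == 0) next
      gi <- gidx_all[i]; gj <- gidx_all[j]
      if (gi > 0 && gj > 0) {               # ligand self pair
        acc[gi, 3] <- acc[gi, 3] + d / 2
        acc[gj, 3] <- acc[gj, 3] + d / 2
      } else if (gi == 0 && gj == 0) {      # receptor self pair
        ww <- if (i == j) w[i, ] else (w[i, ] + w[j, ]) / 2
        acc[, 3] <- acc[, 3] + d * ww
      } else {                              # cross pair -> ligand group
        acc[max(gi, gj), 3] <- acc[max(gi, gj), 3] + d
      }
    }
  }
  if (include_sasa) {
    all_idx <- c(rec, lig)
    a_c <- sasa(xyz[all_idx, , drop = FALSE], ptab$rmin_half[all_idx],
                probe = g$probe_radius)
    a_r <- sasa(xyz[rec, , drop = FALSE], ptab$rmin_half[rec],
                probe = g$probe_radius)
    a_l <- sasa(xyz[lig, , drop = FALSE], ptab$rmin_half[lig],
                probe = g$probe_radius)
    nr <- length(rec)
    dA <- a_c - c(a_r, a_l)
    # ligand atoms to their own group
    for (k in seq_along(partition)) {
      cols <- nr + which(group_of[lig] == k)
      acc[k, 4] <- acc[k, 4] + g$surface_tension * sum(dA[cols])
    }
    # receptor atoms to the nearest ligand group
    if (nr) {
      gmin <- vapply(seq_len(nr), function(i) {
        dmin <- vapply(partition, function(p)
          min(sqrt(rowSums(sweep(xyz[p, , drop = FALSE], 2,
                                 xyz[rec[i], ])^2))), numeric(1))
        which.min(dmin)
      }, integer(1))
      for (k in seq_along(partition))
        acc[k, 4] <- acc[k, 4] +
          g$surface_tension * sum(dA[seq_len(nr)][gmin == k])
    }
  }
  acc
}

.format_percent <- function(p) {
  ifelse(abs(p) < 1, "<1%",
         paste0(sign(p) * floor(abs(p) + 0.5), "%"))
}

#' @export
print.pergroup_table <- function(x, ...) {
  cat("per-group MM-GBSA decomposition (kcal/mol):\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-10s %7.2f%s (%s)\n", x$group[i], x$energy[i],
                if (is.na(x$sd[i])) "" else sprintf(" +/- %.2f", x$sd[i]),
                x$percent[i]))
  cat(sprintf("  total      %7.2f\n", attr(x, "total")))
  invisible(x)
}

#' Truncate residues to alanine
#'
#' Removes all side-chain atoms beyond C-beta in the topology and in
#' every frame, renames the residue ALA (so parameter lookup switches
#' to the alanine templates), and leaves backbone and C-beta
#' coordinates untouched. Groups and bonds are remapped.
#'
#' @param top a `topology`.
#' @param xyz a `trajectory`, an `nframes x 3N` matrix, or an `N x 3`
#'   frame.
#' @param resnos residue numbers to truncate (each must have a CB).
#' @return list with elements `topology` and `xyz` (same shape as the
#'   input), or a `trajectory` when one was supplied.
#' @export
mutate_to_alanine <- function(top, xyz, resnos) {
  at <- top$atoms
  drop <- integer()
  for (rn in resnos) {
    res <- which(at$resno == rn)
    if (!length(res)) stop("no residue ", rn, " in topology")
    if (!"CB" %in% at$name[res])
      stop("residue ", rn, " (", at$resname[res[1]],
           ") has no CB: cannot truncate to alanine")
    drop <- c(drop, res[!at$name[res] %in% .ALA_KEEP])
  }
  out <- .drop_atoms(top, xyz, drop)
  out$topology$atoms$resname[out$topology$atoms$resno %in% resnos] <- "ALA"
  out
}

#' Delete a residue (e.g. remove the fucose from a glycan)
#'
#' Removes every atom of the residue from the topology and all frames.
#' When the deleted residue was attached through a glycosidic bond, the
#' dangling oxygen stays on the remaining residue and, by default, a
#' hydroxyl hydrogen is restored on it along the former bond direction
#' (0.96 A), matching the chemistry of the free sugar.
#'
#' @param top a `topology` (bond list needed for hydroxyl restoration).
#' @param xyz a `trajectory`, an `nframes x 3N` matrix, or an `N x 3`
#'   frame.
#' @param resno residue number to delete.
#' @param restore_hydroxyl add the hydroxyl hydrogen on the dangling
#'   oxygen.
#' @return as [mutate_to_alanine()].
#' @export
remove_residue <- function(top, xyz, resno, restore_hydroxyl = TRUE) {
  at <- top$atoms
  res <- which(at$resno == resno)
  if (!length(res)) stop("no residue ", resno, " in topology")
  dangling <- NULL
  if (restore_hydroxyl && !is.null(top$bonds)) {
    b <- top$bonds
    crossing <- b[xor(b[, 1] %in% res, b[, 2] %in% res), , drop = FALSE]
    for (r in seq_len(nrow(crossing))) {
      inn <- crossing[r, crossing[r, ] %in% res]
      outb <- crossing[r, !crossing[r, ] %in% res]
      if (at$element[outb] == "O") { dangling <- c(o = outb, c = inn); break }
    }
  }
  out <- .drop_atoms(top, xyz, res, add_h_on = dangling)
  out
}

# Remove atoms `drop` from topology + coordinates; optionally add a
# hydroxyl H on atom add_h_on["o"], directed at (removed) add_h_on["c"].
.drop_atoms <- function(top, xyz, drop, add_h_on = NULL) {
  was_traj <- inherits(xyz, "trajectory")
  traj <- NULL
  if (was_traj) { traj <- xyz; xyz <- traj$xyz }
  single <- is.matrix(xyz) && ncol(xyz) == 3L
  mat <- if (single) matrix(flat_xyz(xyz), nrow = 1) else as.matrix(xyz)
  keep <- setdiff(seq_len(n_atoms(top)), drop)
  at <- top$atoms[keep, , drop = FALSE]
  cols <- as.numeric(t(outer(keep, 1:3, function(i, d) 3 * (i - 1) + d)))
  mat2 <- mat[, cols, drop = FALSE]
  remap <- integer(n_atoms(top)); remap[keep] <- seq_along(keep)
  groups <- lapply(top$groups, function(gk) {
    v <- remap[setdiff(gk, drop)]; v[v > 0]
  })
  groups <- groups[lengths(groups) > 0]
  bonds <- top$bonds
  if (!is.null(bonds)) {
    ok <- !(bonds[, 1] %in% drop | bonds[, 2] %in% drop)
    bonds <- cbind(remap[bonds[ok, 1]], remap[bonds[ok, 2]])
    if (!nrow(bonds)) bonds <- NULL
  }
  if (!is.null(add_h_on)) {
    o_old <- add_h_on[["o"]]; c_old <- add_h_on[["c"]]
    o_new <- remap[o_old]
    # insert H right after the dangling O
    hname <- paste0("H", top$atoms$name[o_old])
    hrow <- at[o_new, , drop = FALSE]
    hrow$serial <- max(at$serial) + 1L
    hrow$name <- substr(hname, 1, 4)
    hrow$element <- "H"
    pos <- o_new
    at <- rbind(at[seq_len(pos), , drop = FALSE], hrow,
                if (pos < nrow(at)) at[(pos + 1):nrow(at), , drop = FALSE])
    ocols <- 3 * (o_new - 1) + 1:3
    c_cols <- 3 * (c_old - 1) + 1:3
    hxyz <- t(apply(cbind(mat2[, ocols, drop = FALSE],
                          mat[, c_cols, drop = FALSE]), 1, function(v) {
      o <- v[1:3]; cc <- v[4:6]
      u <- cc - o; u <- u / sqrt(sum(u^2))
      o + 0.96 * u
    }))
    if (nrow(mat2) == 1) hxyz <- matrix(hxyz, nrow = 1)
    before <- seq_len(3 * pos)
    after <- if (3 * pos < ncol(mat2)) (3 * pos + 1):ncol(mat2) else integer()
    mat2 <- cbind(mat2[, before, drop = FALSE], hxyz,
                  mat2[, after, drop = FALSE])
    shift <- function(v) ifelse(v > pos, v + 1L, v)
    groups <- lapply(groups, shift)
    if (!is.null(bonds)) bonds <- matrix(shift(bonds), ncol = 2)
    bonds <- rbind(bonds, c(pos, pos + 1L))
  }
  top2 <- topology(at, groups = groups, bonds = bonds)
  if (was_traj)
    return(list(topology = top2,
                xyz = trajectory(top2, mat2, times = traj$times,
                                 run_id = traj$run_id)))
  list(topology = top2,
       xyz = if (single) unflat_xyz(mat2[1, ]) else mat2)
}
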