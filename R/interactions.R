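#' Hydrogen-bond criteria
#'
#' Defaults follow common MD-analysis practice: donor-acceptor
#' heavy-atom distance <= 3.5 A and donor-H...acceptor angle >= 135
#' degrees; a hydrogen bond is called "stable" when its pooled
#' occupancy over all runs reaches `stable_occupancy`.
#'
#' @param distance heavy-atom distance cutoff (A).
#' @param angle D-H...A angle cutoff (degrees), in (90, 180].
#' @param stable_occupancy pooled-occupancy threshold for stability.
#' @export
hbond_criteria <- function(distance = 3.5, angle = 135,
                           stable_occupancy = 0.5) {
  if (distance <= 0) stop("distance cutoff must be > 0")
  if (angle <= 90 || angle > 180) stop("angle cutoff must be in (90, 180]")
  structure(list(distance = distance, angle = angle,
                 stable_occupancy = stable_occupancy),
            class = "hbond_criteria")
}

# donors: N/O/S heavy atoms with a bonded hydrogen (topology bonds);
# acceptors: N/O heavy atoms. Returns list(donors=data.frame(heavy, h),
# acceptors=integer).
.hbond_roles <- function(top) {
  at <- top$atoms
  polar <- which(at$element %in% c("N", "O", "S", "F"))
  acceptors <- which(at$element %in% c("N", "O", "F"))
  donors <- NULL
  if (!is.null(top$bonds)) {
    b <- top$bonds
    ish <- at$element == "H"
    hpair <- rbind(b[ish[b[, 2]] & !ish[b[, 1]], , drop = FALSE],
                   b[ish[b[, 1]] & !ish[b[, 2]], 2:1, drop = FALSE])
    if (nrow(hpair))
      donors <- data.frame(heavy = hpair[, 1], h = hpair[, 2])[
        hpair[, 1] %in% polar, , drop = FALSE]
  }
  if (is.null(donors)) donors <- data.frame(heavy = integer(), h = integer())
  list(donors = donors, acceptors = acceptors)
}

#' Detect hydrogen bonds between two groups in one frame
#'
#' Returns every (donor, acceptor) pair with the donor in one group and
#' the acceptor in the other that satisfies both the distance and the
#' angle criterion. `distance_only = TRUE` drops the angle test, for
#' hydrogen-free topologies and for ion coordination.
#'
#' @param coords `N x 3` frame.
#' @param top the `topology` (bond list required unless
#'   `distance_only`).
#' @param criteria an [hbond_criteria()] object.
#' @param groupA,groupB group names or index vectors (must not overlap).
#' @param distance_only skip the angle test and treat every polar/ion
#'   heavy atom as donor and acceptor.
#' @return data.frame: `donor`, `hydrogen` (NA in distance-only mode),
#'   `acceptor`, `distance` (A), `angle` (degrees).
#' @export
detect_hbonds <- function(coords, top, criteria = hbond_criteria(),
                          groupA = "receptor", groupB = "ligand",
                          distance_only = FALSE) {
  ia <- atom_group(top, groupA); ib <- atom_group(top, groupB)
  if (length(intersect(ia, ib))) stop("groups overlap")
  xyz <- as.matrix(coords)
  out <- list()
  if (distance_only) {
    at <- top$atoms
    heavyA <- ia[at$element[ia] %in% c("N", "O", "F", "S") | at$is_ion[ia]]
    heavyB <- ib[at$element[ib] %in% c("N", "O", "F", "S") | at$is_ion[ib]]
    for (i in heavyA) for (j in heavyB) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d <= criteria$distance)
        out[[length(out) + 1L]] <- data.frame(donor = i, hydrogen = NA_integer_,
                                              acceptor = j, distance = d,
                                              angle = NA_real_)
    }
  } else {
    roles <- .hbond_roles(top)
    pairs <- rbind(
      expand.grid(d = which(roles$donors$heavy %in% ia),
                  a = roles$acceptors[roles$acceptors %in% ib]),
      expand.grid(d = which(roles$donors$heavy %in% ib),
                  a = roles$acceptors[roles$acceptors %in% ia]))
    for (r in seq_len(nrow(pairs))) {
      dn <- roles$donors[pairs$d[r], ]
      acc <- pairs$a[r]
      if (dn$heavy == acc) next
      d <- sqrt(sum((xyz[dn$heavy, ] - xyz[acc, ])^2))
      if (d > criteria$distance) next
      v1 <- xyz[dn$heavy, ] - xyz[dn$h, ]
      v2 <- xyz[acc, ] - xyz[dn$h, ]
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                 sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang >= criteria$angle)
        out[[length(out) + 1L]] <- data.frame(donor = dn$heavy,
                                              hydrogen = dn$h,
                                              acceptor = acc, distance = d,
                                              angle = ang)
    }
  }
  if (!length(out))
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(),
                      angle = numeric()))
  do.call(rbind, out)
}

#' Hydrogen-bond occupancy over trajectory runs
#'
#' Per (donor, acceptor) pair, the fraction of frames satisfying the
#' criteria in each run and pooled over runs (frame-weighted); pairs at
#' or above the stable-occupancy threshold are flagged stable.
#'
#' @param trajs a `trajectory` or list of them.
#' @inheritParams detect_hbonds
#' @return data.frame of class `"occupancy_table"`: donor/acceptor atom
#'   descriptions, `occ_run<k>` columns, `occupancy` (pooled), `stable`.
#' @export
hbond_occupancy <- function(trajs, criteria = hbond_criteria(),
                            groupA = "receptor", groupB = "ligand",
                            distance_only = FALSE) {
  trajs <- as_traj_list(trajs)
  top <- trajs[[1]]$topology
  counts <- list(); nf <- integer(length(trajs))
  for (k in seq_along(trajs)) {
    tr <- trajs[[k]]
    nf[k] <- n_frames(tr)
    tab <- new.env(parent = emptyenv())
    for (i in seq_len(n_frames(tr))) {
      hb <- detect_hbonds(unflat_xyz(tr$xyz[i, ]), top, criteria,
                          groupA, groupB, distance_only)
      if (!nrow(hb)) next
      keys <- unique(paste(hb$donor, hb$acceptor, sep = "-"))
      for (kk in keys) assign(kk, (if (exists(kk, tab)) get(kk, tab) else 0L) + 1L, tab)
    }
    counts[[k]] <- tab
  }
  keys <- unique(unlist(lapply(counts, ls)))
  if (!length(keys))
    return(structure(data.frame(), class = c("occupancy_table", "data.frame")))
  at <- top$atoms
  rows <- lapply(keys, function(kk) {
    idx <- as.integer(strsplit(kk, "-")[[1]])
    per_run <- vapply(seq_along(trajs), function(k)
      (if (exists(kk, counts[[k]])) get(kk, counts[[k]]) else 0L) / nf[k],
      numeric(1))
    pooled <- sum(per_run * nf) / sum(nf)
    row <- data.frame(
      donor = sprintf("%s%d:%s", at$resname[idx[1]], at$resno[idx[1]],
                      at$name[idx[1]]),
      acceptor = sprintf("%s%d:%s", at$resname[idx[2]], at$resno[idx[2]],
                         at$name[idx[2]]),
      donor_idx = idx[1], acceptor_idx = idx[2])
    for (k in seq_along(per_run)) row[[paste0("occ_run", k)]] <- per_run[k]
    row$occupancy <- pooled
    row$stable <- pooled >= criteria$stable_occupancy
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$occupancy), ]
  rownames(out) <- NULL
  structure(out, class = c("occupancy_table", "data.frame"))
}

#' Water-density voxel map
#'
#' Counts water-oxygen occupancy in a grid of cubic voxels (default
#' edge 0.5 A), averaged over all frames of all runs, and ranks local
#' maxima: voxels exceeding all 26 neighbours and a density floor.
#'
#' @param trajs a `trajectory` or list of them.
#' @param region either `list(center =, radius =)` (sphere) or
#'   `list(min =, max =)` (box) in A.
#' @param cell voxel edge (A).
#' @param floor minimum mean occupancy for a reported maximum.
#' @return object of class `"density_grid"`: `origin`, `cell`, `dim`,
#'   `density` (3D array of mean counts per voxel), `n_frames`,
#'   `maxima` (data.frame x, y, z, density, ranked).
#' @export
water_density_map <- function(trajs, region, cell = 0.5, floor = 0.25) {
  if (cell <= 0) stop("cell size must be > 0")
  trajs <- as_traj_list(trajs)
  top <- trajs[[1]]$topology
  wox <- which(top$atoms$is_water & top$atoms$element == "O")
  if (!length(wox)) {
    warning("topology contains no water oxygens; returning empty grid")
    return(structure(list(origin = c(0, 0, 0), cell = cell, dim = c(0, 0, 0),
                          density = array(0, c(0, 0, 0)), n_frames = 0,
                          maxima = data.frame()),
                     class = "density_grid"))
  }
  if (!is.null(region$center)) {
    lo <- region$center - region$radius; hi <- region$center + region$radius
  } else { lo <- region$min; hi <- region$max }
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / cell)))
  counts <- array(0, dims)
  nf_total <- 0L
  for (tr in trajs) for (i in seq_len(n_frames(tr))) {
    nf_total <- nf_total + 1L
    xyz <- unflat_xyz(tr$xyz[i, ])[wox, , drop = FALSE]
    if (!is.null(region$center)) {
      keep <- rowSums(sweep(xyz, 2, region$center)^2) <= region$radius^2
      xyz <- xyz[keep, , drop = FALSE]
    }
    if (!nrow(xyz)) next
    v <- floor(sweep(xyz, 2, lo) / cell) + 1
    ok <- v[, 1] >= 1 & v[, 1] <= dims[1] & v[, 2] >= 1 & v[, 2] <= dims[2] &
      v[, 3] >= 1 & v[, 3] <= dims[3]
    v <- v[ok, , drop = FALSE]
    for (r in seq_len(nrow(v)))
      counts[v[r, 1], v[r, 2], v[r, 3]] <- counts[v[r, 1], v[r, 2], v[r, 3]] + 1
  }
  dens <- counts / nf_total
  maxima <- .grid_maxima(dens, lo, cell, floor)
  structure(list(origin = lo, cell = cell, dim = dims, density = dens,
                 n_frames = nf_total, maxima = maxima),
            class = "density_grid")
}

.grid_maxima <- function(dens, origin, cell, floor) {
  dims <- dim(dens)
  hits <- list()
  cand <- which(dens >= floor, arr.ind = TRUE)
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]; k <- cand[r, 3]
    v <- dens[i, j, k]
    nb <- dens[max(1, i - 1):min(dims[1], i + 1),
               max(1, j - 1):min(dims[2], j + 1),
               max(1, k - 1):min(dims[3], k + 1)]
    if (sum(nb >= v) == 1L)  # strict maximum over the 26-neighbourhood
      hits[[length(hits) + 1L]] <- data.frame(
        x = origin[1] + (i - 0.5) * cell, y = origin[2] + (j - 0.5) * cell,
        z = origin[3] + (k - 0.5) * cell, density = v)
  }
  if (!length(hits)) return(data.frame(x = numeric(), y = numeric(),
                                       z = numeric(), density = numeric()))
  out <- do.call(rbind, hits)
  out[order(-out$density), , drop = FALSE]
}

#' @export
print.density_grid <- function(x, ...) {
  cat("water density grid:", paste(x$dim, collapse = " x "),
      "voxels of", x$cell, "A,", x$n_frames, "frames\n")
  if (nrow(x$maxima))
    cat("  top maximum:", sprintf("(%.2f, %.2f, %.2f) density %.2f\n",
                                  x$maxima$x[1], x$maxima$y[1],
                                  x$maxima$z[1], x$maxima$density[1]))
  invisible(x)
}

#' Write a density grid in OpenDX text format
#' @param grid a `"density_grid"`.
#' @param path output file.
#' @export
write_dx <- function(grid, path) {
  d <- grid$dim
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %g %g %g", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %g 0 0", grid$cell),
    sprintf("delta 0 %g 0", grid$cell),
    sprintf("delta 0 0 %g", grid$cell),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  vals <- as.numeric(aperm(grid$density, c(3, 2, 1)))
  writeLines(apply(matrix(c(vals, rep(NA, (3 - length(vals) %% 3) %% 3)),
                          ncol = 3, byrow = TRUE), 1,
                   function(r) paste(r[!is.na(r)], collapse = " ")), con)
  invisible(path)
}

#' Detect a water-mediated ion bridge
#'
#' Given a high-occupancy water site (e.g. the top maximum of
#' [water_density_map()]), identifies per frame the water oxygen
#' occupying the site (nearest within one cell), and records its
#' distances to the ion and to the nearest target atom (e.g. the
#' sulfate oxygens). A bridge is declared for a run when both mean
#' distances fall inside the given windows.
#'
#' @param trajs a `trajectory` or list of them.
#' @param ion atom index of the ion.
#' @param target_atoms atom indices of the ligand group bridged to.
#' @param site site position (length-3, A).
#' @param windows `list(ion_water = c(lo, hi), water_target = c(lo, hi))`.
#' @param cell site-capture radius (A); a water counts as occupying the
#'   site when within one grid cell of it.
#' @return object of class `"water_bridge_report"`.
#' @export
detect_water_bridge <- function(trajs, ion, target_atoms, site,
                                windows = list(ion_water = c(1.8, 2.4),
                                               water_target = c(2.2, 3.8)),
                                cell = 0.5) {
  trajs <- as_traj_list(trajs)
  top <- trajs[[1]]$topology
  wox <- which(top$atoms$is_water & top$atoms$element == "O")
  runs <- list()
  for (tr in trajs) {
    d_iw <- c(); d_wt <- c(); occupied <- 0L
    for (i in seq_len(n_frames(tr))) {
      xyz <- unflat_xyz(tr$xyz[i, ])
      if (!length(wox)) break
      dsite <- sqrt(rowSums(sweep(xyz[wox, , drop = FALSE], 2, site)^2))
      w <- which.min(dsite)
      if (dsite[w] > cell) next
      occupied <- occupied + 1L
      wpos <- xyz[wox[w], ]
      d_iw <- c(d_iw, sqrt(sum((xyz[ion, ] - wpos)^2)))
      d_wt <- c(d_wt, min(sqrt(rowSums(sweep(xyz[target_atoms, , drop = FALSE],
                                             2, wpos)^2))))
    }
    present <- occupied > 0L &&
      mean(d_iw) >= windows$ion_water[1] && mean(d_iw) <= windows$ion_water[2] &&
      mean(d_wt) >= windows$water_target[1] && mean(d_wt) <= windows$water_target[2]
    runs[[length(runs) + 1L]] <- list(
      run_id = tr$run_id, occupancy = occupied / n_frames(tr),
      ion_water_mean = if (occupied) mean(d_iw) else NA_real_,
      ion_water_sd = if (occupied > 1) stats::sd(d_iw) else NA_real_,
      water_target_mean = if (occupied) mean(d_wt) else NA_real_,
      water_target_sd = if (occupied > 1) stats::sd(d_wt) else NA_real_,
      present = present)
  }
  per_run <- do.call(rbind, lapply(runs, as.data.frame))
  structure(list(site = site, per_run = per_run,
                 present_all_runs = all(per_run$present),
                 windows = windows),
            class = "water_bridge_report")
}

#' @export
print.water_bridge_report <- function(x, ...) {
  cat("water-mediated bridge at site",
      sprintf("(%.2f, %.2f, %.2f):\n", x$site[1], x$site[2], x$site[3]))
  for (r in seq_len(nrow(x$per_run)))
    with(x$per_run[r, ], cat(sprintf(
      "  run %d: ion-O(w) %.2f +/- %.2f A, O(w)-target %.2f +/- %.2f A, %s\n",
      run_id, ion_water_mean, ion_water_sd, water_target_mean,
      water_target_sd, if (present) "bridge" else "no bridge")))
  cat(if (x$present_all_runs) "bridge present in all runs\n"
      else "bridge NOT present in all runs\n")
  invisible(x)
}
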