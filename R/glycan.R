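#' Signed dihedral angle
#'
#' Standard right-handed torsion over four atoms, in degrees in
#' (-180, 180].
#'
#' @param coords `N x 3` frame (or any coordinate matrix).
#' @param quad integer vector of 4 distinct atom indices.
#' @return angle in degrees.
#' @export
torsion_angle <- function(coords, quad) {
  if (length(unique(quad)) != 4L) stop("need 4 distinct atoms")
  p <- as.matrix(coords)[quad, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop("undefined dihedral: three atoms are collinear")
  b2n <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(.cross3(n1, n2) * b2n), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

# Vectorised torsion over all frames of an xyz matrix (nframes x 3N)
.torsion_series <- function(xyz, quad) {
  cols <- function(i) xyz[, (3 * (i - 1) + 1):(3 * i), drop = FALSE]
  p1 <- cols(quad[1]); p2 <- cols(quad[2]); p3 <- cols(quad[3]); p4 <- cols(quad[4])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  crossm <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- crossm(b1, b2); n2 <- crossm(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  ang <- atan2(rowSums(crossm(n1, n2) * b2n), rowSums(n1 * n2)) * 180 / pi
  ang[ang <= -180] <- ang[ang <= -180] + 360
  ang
}

# residue-name -> monosaccharide class
.SUGAR_CLASS <- c(SIA = "Neu5Ac", SLB = "Neu5Ac", NEU = "Neu5Ac",
                  "NEU5AC" = "Neu5Ac", NANA = "Neu5Ac", "0SA" = "Neu5Ac",
                  GAL = "Gal", GLA = "Gal", "0LB" = "Gal", "6LS" = "Gal",
                  NAG = "GlcNAc", NDG = "GlcNAc", "0YB" = "GlcNAc",
                  "GLCNAC" = "GlcNAc",
                  FUC = "Fuc", FUL = "Fuc", "0FA" = "Fuc")
# default anomeric configuration per class for linkage labels
.SUGAR_ANOMER <- c(Neu5Ac = "a", Gal = "b", GlcNAc = "b", Fuc = "a")

sugar_class <- function(resname) {
  cls <- .SUGAR_CLASS[toupper(resname)]
  ifelse(is.na(cls), "unknown", cls)
}

#' Identify glycosidic linkages and their phi/psi atom quadruples
#'
#' Scans the inter-residue bonds of the topology for glycosidic bonds
#' (anomeric carbon of the donor sugar to a hydroxyl oxygen `Ox` of the
#' acceptor) and emits the torsion definitions used throughout the
#' analysis: phi = C2-C1-Ox-Cx and psi = C1-Ox-Cx-Cx-1, switching to
#' phi = C3-C2-Ox-Cx and psi = C2-Ox-Cx-Cx-1 when the donor is a
#' sialic acid (Neu5Ac). Linkages from Neu5Ac to O3 of galactose are
#' flagged excluded from CHI scoring; fucose linkages (alpha-L sugar)
#' carry the mirror flag so they are scored on the mirror image of the
#' beta-D reference curves.
#'
#' @param top a `topology` with a bond list and standard sugar atom
#'   names (C1, C2, ..., O2, O3, ...).
#' @return data.frame of class `"linkage_table"`, one row per linkage,
#'   with list-columns `phi` and `psi` holding the atom quadruples.
#' @export
assign_glycosidic_linkages <- function(top) {
  if (is.null(top$bonds)) stop("topology carries no bond list")
  at <- top$atoms
  out <- list()
  for (b in seq_len(nrow(top$bonds))) {
    i <- top$bonds[b, 1]; j <- top$bonds[b, 2]
    if (at$resno[i] == at$resno[j]) next
    # orient: anomeric carbon (donor) -> oxygen (acceptor)
    for (swap in c(FALSE, TRUE)) {
      ci <- if (swap) j else i; oi <- if (swap) i else j
      dclass <- sugar_class(at$resname[ci])
      if (dclass == "unknown") next
      anomer_c <- if (dclass == "Neu5Ac") "C2" else "C1"
      if (at$name[ci] != anomer_c) next
      mo <- regmatches(at$name[oi], regexec("^O([0-9])$", at$name[oi]))[[1]]
      if (length(mo) != 2L) next
      x <- as.integer(mo[2])
      dres <- at$resno[ci]; ares <- at$resno[oi]
      aclass <- sugar_class(at$resname[which(at$resno == ares)[1]])
      need <- function(res, nm) {
        idx <- select_atoms(top, res, nm)
        if (length(idx) != 1L)
          stop("linkage construction failed: residue ", res,
               " lacks atom ", nm)
        idx
      }
      if (dclass == "Neu5Ac") {
        phi <- c(need(dres, "C3"), need(dres, "C2"), oi, need(ares, paste0("C", x)))
        psi <- c(need(dres, "C2"), oi, need(ares, paste0("C", x)),
                 need(ares, paste0("C", x - 1)))
        dpos <- 2L
      } else {
        phi <- c(need(dres, "C2"), need(dres, "C1"), oi, need(ares, paste0("C", x)))
        psi <- c(need(dres, "C1"), oi, need(ares, paste0("C", x)),
                 need(ares, paste0("C", x - 1)))
        dpos <- 1L
      }
      anomer <- .SUGAR_ANOMER[dclass]
      label <- sprintf("%s%s%d-%d%s", dclass, anomer, dpos, x, aclass)
      out[[length(out) + 1L]] <- data.frame(
        label = label, donor_resno = dres, acceptor_resno = ares,
        donor_class = dclass, acceptor_class = aclass,
        curve_class = sprintf("%s%d-%d", anomer, dpos, x),
        excluded = (dclass == "Neu5Ac" && aclass == "Gal" && x == 3L),
        mirror = (dclass == "Fuc"),
        phi = I(list(phi)), psi = I(list(psi)))
      break
    }
  }
  if (!length(out)) stop("no glycosidic linkages found in topology")
  res <- do.call(rbind, out)
  class(res) <- c("linkage_table", "data.frame")
  res
}

#' Load a CHI strain-curve registry
#'
#' The registry is a directory of CSV grids, one file per linkage class
#' and torsion, named `<class>_<torsion>.csv` (e.g. `b1-4_phi.csv`)
#' with columns `angle` (degrees) and `energy` (kcal/mol). Curves are
#' relative energies: the grid minimum is shifted to zero on load.
#'
#' @param dir registry directory.
#' @return named list of class `"chi_registry"`; element `[[class]]` is
#'   a list with `phi` and `psi` grid data.frames.
#' @export
load_chi_curves <- function(dir) {
  files <- list.files(dir, pattern = "_(phi|psi)\\.csv$", full.names = TRUE)
  if (!length(files)) stop("no CHI curve files (*_phi.csv / *_psi.csv) in ", dir)
  reg <- list()
  for (f in files) {
    base <- sub("\\.csv$", "", basename(f))
    torsion <- sub("^.*_", "", base)
    cls <- sub("_(phi|psi)$", "", base)
    grid <- utils::read.csv(f)
    reg[[cls]][[torsion]] <- .chi_grid(grid)
  }
  structure(reg, class = "chi_registry")
}

#' Build a CHI registry from in-memory grids
#'
#' @param ... named arguments, one per linkage class, each a list with
#'   `phi` and `psi` data.frames (`angle`, `energy`).
#' @export
chi_registry <- function(...) {
  reg <- lapply(list(...), function(cl) lapply(cl, .chi_grid))
  structure(reg, class = "chi_registry")
}

.chi_grid <- function(grid) {
  stopifnot(all(c("angle", "energy") %in% names(grid)))
  grid <- grid[order(grid$angle), ]
  if (min(grid$angle) <= -180 || max(grid$angle) > 180)
    grid$angle <- .wrap180(grid$angle)
  grid <- grid[order(grid$angle), ]
  grid$energy <- grid$energy - min(grid$energy)  # curves are relative
  grid
}

.wrap180 <- function(a) {
  w <- (a + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

# periodic linear interpolation on a (-180, 180] grid
.chi_eval <- function(grid, angle) {
  a <- .wrap180(angle)
  x <- grid$angle; y <- grid$energy
  # close the period: repeat first node at +360
  x <- c(x, x[1] + 360); y <- c(y, y[1])
  a[a < x[1]] <- a[a < x[1]] + 360
  stats::approx(x, y, xout = a, rule = 2)$y
}

#' CHI strain energy of one linkage at given torsions
#'
#' Energy is `curve_phi(phi*) + curve_psi(psi*)`, with
#' `(phi*, psi*) = (-phi, -psi)` for mirror-flagged (alpha-L fucose)
#' linkages -- negating both torsions is the enantiomeric relation
#' between an alpha-L sugar and the beta-D reference curves. Linkages
#' flagged excluded return 0 (attribute `"excluded"` set).
#'
#' @param linkage one row of a `"linkage_table"` (or a list with
#'   `curve_class`, `excluded`, `mirror`).
#' @param phi,psi torsion angles (degrees); vectorised.
#' @param curves a `"chi_registry"`.
#' @return strain energy in kcal/mol.
#' @export
chi_energy <- function(linkage, phi, psi, curves) {
  if (isTRUE(linkage$excluded))
    return(structure(rep(0, length(phi)), excluded = TRUE))
  cl <- as.character(linkage$curve_class)
  if (is.null(curves[[cl]]))
    stop("no CHI curves registered for linkage class '", cl, "'")
  if (isTRUE(linkage$mirror)) { phi <- -phi; psi <- -psi }
  .chi_eval(curves[[cl]]$phi, phi) + .chi_eval(curves[[cl]]$psi, psi)
}

#' Per-frame glycosidic torsions of a trajectory
#'
#' @param traj a `trajectory`.
#' @param linkages a `"linkage_table"`.
#' @return data.frame: `time`, then `<label>.phi` / `<label>.psi`
#'   columns in degrees.
#' @export
glycosidic_torsion_series <- function(traj, linkages) {
  out <- data.frame(time = traj$times)
  for (k in seq_len(nrow(linkages))) {
    lab <- linkages$label[k]
    out[[paste0(lab, ".phi")]] <- .torsion_series(traj$xyz, linkages$phi[[k]])
    out[[paste0(lab, ".psi")]] <- .torsion_series(traj$xyz, linkages$psi[[k]])
  }
  out
}

#' Total CHI strain-energy series
#'
#' Per-frame sum of the CHI energies of all non-excluded linkages.
#'
#' @param traj a `trajectory`.
#' @param linkages a `"linkage_table"`.
#' @param curves a `"chi_registry"`.
#' @return data.frame: `time`, `chi` (kcal/mol).
#' @export
total_chi_series <- function(traj, linkages, curves) {
  if (!nrow(linkages)) stop("empty linkage list")
  total <- rep(0, n_frames(traj))
  for (k in seq_len(nrow(linkages))) {
    lk <- linkages[k, ]
    if (lk$excluded) next
    phi <- .torsion_series(traj$xyz, linkages$phi[[k]])
    psi <- .torsion_series(traj$xyz, linkages$psi[[k]])
    total <- total + chi_energy(lk, phi, psi, curves)
  }
  data.frame(time = traj$times, chi = total)
}

#' Cremer-Pople puckering of a six-membered ring
#'
#' Computes the puckering amplitude Q, polar angle theta and phase
#' phi_ring from the ring atom displacements about the Cremer-Pople
#' mean plane, and labels the chair: `4C1` for theta <= 45 degrees,
#' `1C4` for theta >= 135 degrees, `"other"` in between. Near-planar
#' rings (Q < 0.1 A) are labelled `"other"` with a warning.
#'
#' @param coords `N x 3` frame.
#' @param ring integer vector of 6 atom indices in ring order
#'   O5, C1, C2, C3, C4, C5.
#' @return list of class `"pucker_state"`: `Q` (A), `theta`, `phi_ring`
#'   (degrees), `label`.
#' @export
ring_pucker <- function(coords, ring) {
  if (length(ring) != 6L) stop("need 6 ring atoms in sequence")
  r <- as.matrix(coords)[ring, , drop = FALSE]
  r <- sweep(r, 2, colMeans(r))
  j <- 0:5
  rp <- colSums(r * sin(2 * pi * j / 6))
  rpp <- colSums(r * cos(2 * pi * j / 6))
  n <- .cross3(rp, rpp); n <- n / sqrt(sum(n^2))
  z <- as.numeric(r %*% n)
  q2c <- sqrt(1 / 3) * sum(z * cos(4 * pi * j / 6))
  q2s <- -sqrt(1 / 3) * sum(z * sin(4 * pi * j / 6))
  q3 <- sqrt(1 / 6) * sum((-1)^j * z)
  q2 <- sqrt(q2c^2 + q2s^2)
  Q <- sqrt(q2^2 + q3^2)
  theta <- atan2(q2, q3) * 180 / pi
  phi_ring <- (atan2(q2s, q2c) * 180 / pi) %% 360
  label <- if (Q < 0.1) {
    warning("near-planar ring (Q < 0.1 A); pucker label unreliable")
    "other"
  } else if (theta <= 45) "4C1" else if (theta >= 135) "1C4" else "other"
  structure(list(Q = Q, theta = theta, phi_ring = phi_ring, label = label),
            class = "pucker_state")
}

#' @export
print.pucker_state <- function(x, ...) {
  cat(sprintf("pucker: Q = %.3f A, theta = %.1f, phi = %.1f -> %s\n",
              x$Q, x$theta, x$phi_ring, x$label))
  invisible(x)
}
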