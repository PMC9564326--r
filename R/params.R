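#' Force-field parameter tables
#'
#' The analysis consumes (never derives) force-field parameters: per-atom
#' partial charges, 12-6 Lennard-Jones parameters, masses and intrinsic
#' generalized-Born radii, plus the global settings of the energy model.
#' Parameters arrive through a structured YAML/JSON file with two blocks:
#'
#' ```
#' defaults:
#'   eps_int: 3.0        # internal (solute) dielectric
#'   eps_solv: 78.5      # solvent dielectric
#'   temperature: 300    # K
#' atoms:
#'   - {resname: GAL, name: C1, charge: 0.3, rmin_half: 1.9,
#'      epsilon: 0.1094, mass: 12.01, gb_radius: 1.7}
#' ```
#'
#' @param atoms data.frame with columns `resname`, `name`, `charge` (e),
#'   `rmin_half` (A), `epsilon` (kcal/mol), `mass` (amu), `gb_radius` (A)
#'   and optionally `screen` (GB descreening scale, default 0.8).
#' @param eps_int,eps_solv internal and solvent dielectric constants.
#' @param temperature simulation temperature (K).
#' @param probe_radius solvent probe radius for SASA (A).
#' @param surface_tension SASA surface tension, kcal/(mol A^2).
#' @param sasa_offset constant added to the SASA energy (kcal/mol).
#' @param coulomb Coulomb constant, kcal A/(mol e^2).
#' @param gb_alpha,gb_beta,gb_gamma GB-OBC (model I) tanh-rescaling
#'   constants.
#' @param gb_offset intrinsic-radius offset (A).
#' @param gb_screen default descreening scale where `screen` is absent.
#' @param scale_14_elec,scale_14_vdw intramolecular 1-4 scale factors;
#'   recorded for completeness, unused in cross-group energies (they
#'   cancel in the single-trajectory scheme).
#' @return an object of class `"ff_params"`.
#' @export
ff_params <- function(atoms,
                      eps_int = 3.0, eps_solv = 78.5, temperature = 300,
                      probe_radius = 1.4, surface_tension = 0.0072,
                      sasa_offset = 0, coulomb = .COULOMB_KCAL,
                      gb_alpha = 0.8, gb_beta = 0, gb_gamma = 2.909125,
                      gb_offset = 0.09, gb_screen = 0.8,
                      scale_14_elec = 1 / 1.2, scale_14_vdw = 0.5) {
  stopifnot(is.data.frame(atoms))
  need <- c("resname", "name", "charge", "rmin_half", "epsilon", "mass",
            "gb_radius")
  for (i in seq_len(nrow(atoms))) {
    row <- atoms[i, ]
    bad <- need[vapply(need, function(f)
      is.null(row[[f]]) || is.na(row[[f]]), TRUE)]
    if (length(bad))
      stop("parameter table entry for atom ", row$resname, ":", row$name,
           " is missing field(s): ", paste(bad, collapse = ", "))
  }
  if (!"screen" %in% names(atoms)) atoms$screen <- gb_screen
  atoms$screen[is.na(atoms$screen)] <- gb_screen
  if (any(atoms$mass <= 0)) stop("masses must be > 0")
  if (any(atoms$gb_radius <= 0)) stop("GB radii must be > 0")
  if (eps_int < 1) stop("eps_int must be >= 1")
  if (eps_solv <= eps_int) stop("eps_solv must exceed eps_int")
  structure(list(atoms = atoms,
                 global = list(eps_int = eps_int, eps_solv = eps_solv,
                               temperature = temperature,
                               probe_radius = probe_radius,
                               surface_tension = surface_tension,
                               sasa_offset = sasa_offset,
                               coulomb = coulomb,
                               gb_alpha = gb_alpha, gb_beta = gb_beta,
                               gb_gamma = gb_gamma, gb_offset = gb_offset,
                               gb_screen = gb_screen,
                               scale_14_elec = scale_14_elec,
                               scale_14_vdw = scale_14_vdw)),
            class = "ff_params")
}

#' @export
print.ff_params <- function(x, ...) {
  g <- x$global
  cat("force-field parameters:", nrow(x$atoms), "atom entries\n")
  cat(sprintf("  eps_int = %g, eps_solv = %g, T = %g K\n",
              g$eps_int, g$eps_solv, g$temperature))
  invisible(x)
}

#' Load force-field parameters from YAML or JSON
#'
#' Unspecified global settings take the package defaults (eps_int 3.0,
#' eps_solv 78.5, T 300 K, probe 1.4 A).
#'
#' @param path parameter file (`.yaml`/`.yml` or `.json`).
#' @return an `"ff_params"` object.
#' @export
load_ff_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw$atoms)) stop("parameter file has no 'atoms' block")
  atoms <- raw$atoms
  if (!is.data.frame(atoms))
    atoms <- do.call(rbind, lapply(atoms, function(a)
      as.data.frame(a, stringsAsFactors = FALSE)))
  args <- c(list(atoms = atoms), raw$defaults)
  do.call(ff_params, args)
}

#' Write force-field parameters (YAML or JSON)
#'
#' @param params an `"ff_params"` object.
#' @param path output file; format from extension.
#' @export
write_ff_params <- function(params, path) {
  out <- list(defaults = params$global,
              atoms = params$atoms)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    out$atoms <- lapply(seq_len(nrow(params$atoms)), function(i)
      as.list(params$atoms[i, ]))
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

#' Match per-atom parameters to a topology
#'
#' Looks up each topology atom by (residue name, atom name); a fallback
#' entry with `resname = "*"` matches any residue. All missing atoms are
#' reported together before failure.
#'
#' @param top a `topology`.
#' @param params an `"ff_params"` object.
#' @param subset optional atom indices to match (default: all non-water
#'   atoms).
#' @return data.frame with one row per topology atom (NA rows outside
#'   `subset`): `charge`, `rmin_half`, `epsilon`, `mass`, `gb_radius`,
#'   `screen`.
#' @export
match_params <- function(top, params, subset = NULL) {
  at <- top$atoms
  if (is.null(subset)) subset <- which(!at$is_water)
  tab <- params$atoms
  key <- paste(toupper(tab$resname), toupper(tab$name))
  out <- data.frame(charge = rep(NA_real_, nrow(at)), rmin_half = NA_real_,
                    epsilon = NA_real_, mass = NA_real_,
                    gb_radius = NA_real_, screen = NA_real_)
  want <- paste(toupper(at$resname[subset]), toupper(at$name[subset]))
  hit <- match(want, key)
  fallback <- match(paste("*", toupper(at$name[subset])), key)
  hit[is.na(hit)] <- fallback[is.na(hit)]
  if (anyNA(hit)) {
    miss <- subset[is.na(hit)]
    stop("no force-field parameters for atom(s): ",
         paste(sprintf("%s%d:%s", at$resname[miss], at$resno[miss],
                       at$name[miss]), collapse = ", "))
  }
  cols <- c("charge", "rmin_half", "epsilon", "mass", "gb_radius", "screen")
  out[subset, cols] <- tab[hit, cols]
  out
}

#' Analysis configuration
#'
#' Bundles the tunable knobs of the pipeline with their defaults:
#' 5,000 snapshots for the energy averages and a 0.5-A voxel size
#' (matching the analysis protocol this package implements), a 0.1-ns
#' pose sampling stride, a 1.5-A pose-clustering cutoff, 3.5 A / 135
#' degree hydrogen-bond criteria with a 0.5 stable-occupancy threshold,
#' and an 8-A ligand-escape threshold for the instability gate.
#'
#' @param n_snapshots snapshots sampled evenly per run for the energies.
#' @param pose_stride_ns sampling stride for the pairwise RMSD matrix (ns).
#' @param rmsd_cutoff pose-clustering cutoff (A).
#' @param hbond_distance,hbond_angle hydrogen-bond criteria (A, degrees).
#' @param stable_occupancy pooled occupancy above which a hydrogen bond
#'   is labelled stable.
#' @param ion_distance distance cutoff for distance-only ion coordination (A).
#' @param voxel_cell water-density voxel edge (A).
#' @param density_floor minimum mean occupancy for a density maximum.
#' @param entropy_windows number of cumulative windows for the 1/t
#'   entropy extrapolation.
#' @param escape_threshold ligand RMSD (A) above which a run is flagged
#'   unstable and energies are withheld.
#' @param seed random seed recorded with the run.
#' @return list of class `"analysis_config"`.
#' @export
analysis_config <- function(n_snapshots = 5000, pose_stride_ns = 0.1,
                            rmsd_cutoff = 1.5, hbond_distance = 3.5,
                            hbond_angle = 135, stable_occupancy = 0.5,
                            ion_distance = 3.0, voxel_cell = 0.5,
                            density_floor = 0.25, entropy_windows = 10,
                            escape_threshold = 8, seed = 1L) {
  cfg <- list(n_snapshots = n_snapshots, pose_stride_ns = pose_stride_ns,
              rmsd_cutoff = rmsd_cutoff, hbond_distance = hbond_distance,
              hbond_angle = hbond_angle, stable_occupancy = stable_occupancy,
              ion_distance = ion_distance, voxel_cell = voxel_cell,
              density_floor = density_floor,
              entropy_windows = entropy_windows,
              escape_threshold = escape_threshold, seed = as.integer(seed))
  pos <- c("n_snapshots", "pose_stride_ns", "rmsd_cutoff", "hbond_distance",
           "ion_distance", "voxel_cell", "escape_threshold")
  for (f in pos) if (cfg[[f]] <= 0) stop(f, " must be > 0")
  structure(cfg, class = c("analysis_config", "list"))
}

#' Read an analysis configuration from YAML or JSON
#' @param path config file.
#' @return `"analysis_config"` list (unknown fields are carried along).
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- intersect(names(raw), names(formals(analysis_config)))
  cfg <- do.call(analysis_config, raw[known])
  extra <- setdiff(names(raw), known)
  for (f in extra) cfg[[f]] <- raw[[f]]
  cfg
}
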