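#' Build a topology for a protein-glycan system
#'
#' A topology holds the atom table, named atom-index groups (e.g.
#' `"receptor"`, `"ligand"`, `"ring_atoms"`, `"SO3"`) and, optionally, a
#' bond list. All indices are 1-based row indices into the atom table;
#' file I/O retains the native 1-based PDB serials separately.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resno`, `resname`, and optionally `chain`, `is_water`, `is_ion`.
#'   `resno` is the residue identifier (integer, non-decreasing in file
#'   order), `resname` the residue name.
#' @param groups named list of integer vectors indexing rows of `atoms`.
#' @param bonds two-column integer matrix of bonded atom pairs, or NULL.
#' @param water_resnames,ion_resnames residue-name whitelists used to
#'   flag waters and monoatomic ions when `is_water`/`is_ion` columns
#'   are absent.
#' @return an object of class `"topology"`.
#' @export
topology <- function(atoms, groups = list(), bonds = NULL,
                     water_resnames = .WATER_RESNAMES,
                     ion_resnames = .ION_RESNAMES) {
  stopifnot(is.data.frame(atoms))
  required <- c("serial", "name", "element", "resno", "resname")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(atoms$serial))
    stop("atom serials must be unique within a topology")
  if (is.unsorted(atoms$resno))
    stop("residue numbers must be non-decreasing in file order")
  if (!"chain" %in% names(atoms)) atoms$chain <- NA_character_
  if (!"is_water" %in% names(atoms))
    atoms$is_water <- toupper(atoms$resname) %in% water_resnames
  if (!"is_ion" %in% names(atoms))
    atoms$is_ion <- toupper(atoms$resname) %in% ion_resnames & !atoms$is_water
  n <- nrow(atoms)
  if (length(groups)) {
    if (is.null(names(groups)) || any(!nzchar(names(groups))))
      stop("groups must be a named list")
    for (g in names(groups)) {
      idx <- groups[[g]]
      if (length(idx) && (any(idx < 1L) || any(idx > n)))
        stop("group '", g, "' references atom indices outside the topology")
      groups[[g]] <- as.integer(idx)
    }
    if (all(c("receptor", "ligand") %in% names(groups)) &&
        length(intersect(groups$receptor, groups$ligand)))
      stop("'receptor' and 'ligand' groups must be disjoint")
  }
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    if (any(bonds < 1L) || any(bonds > n))
      stop("bond list references atom indices outside the topology")
  }
  structure(list(atoms = atoms, groups = groups, bonds = bonds),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("topology:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$resno)), "residues\n")
  if (length(x$groups))
    cat("  groups:", paste(sprintf("%s(%d)", names(x$groups),
                                   lengths(x$groups)), collapse = ", "), "\n")
  if (!is.null(x$bonds)) cat("  bonds:", nrow(x$bonds), "\n")
  invisible(x)
}

n_atoms <- function(top) nrow(top$atoms)

#' Look up a named atom group
#'
#' @param top a `topology`.
#' @param selection a group name or an integer index vector (returned
#'   unchanged after range checking).
#' @return integer vector of atom indices.
#' @export
atom_group <- function(top, selection) {
  if (is.character(selection)) {
    if (length(selection) != 1L || !selection %in% names(top$groups))
      stop("unknown atom group '", paste(selection, collapse = ","), "'")
    idx <- top$groups[[selection]]
  } else {
    idx <- as.integer(selection)
    if (any(idx < 1L) || any(idx > n_atoms(top)))
      stop("atom indices outside the topology")
  }
  if (!length(idx)) stop("empty atom selection")
  idx
}

#' Select atoms by residue number and atom name
#'
#' Stable under reordering of the input file: matching is on the
#' (residue number, atom name) pair, not on file position.
#'
#' @param top a `topology`.
#' @param resno residue number(s).
#' @param name atom name(s); NULL selects whole residues.
#' @return integer vector of atom indices (in atom-table order).
#' @export
select_atoms <- function(top, resno, name = NULL) {
  keep <- top$atoms$resno %in% resno
  if (!is.null(name)) keep <- keep & top$atoms$name %in% name
  which(keep)
}

#' Construct a single coordinate frame
#'
#' @param coords numeric matrix, one row per atom, columns x/y/z (Angstrom).
#' @param time time stamp in ns.
#' @param box optional box lengths (3-vector, Angstrom).
#' @return matrix of class `"frame"` with `time`/`box` attributes.
#' @export
frame <- function(coords, time = 0, box = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("frame coordinates must be an N x 3 matrix")
  if (time < 0) stop("frame time must be >= 0")
  structure(coords, time = time, box = box, class = c("frame", "matrix"))
}

#' Assemble a trajectory
#'
#' Frames are stored in the flat `bio3d` layout: an `nframes x 3N`
#' matrix whose rows are `c(x1, y1, z1, x2, ...)`.
#'
#' @param top the shared `topology`.
#' @param xyz numeric matrix `nframes x 3N`.
#' @param times frame times in ns (strictly increasing).
#' @param run_id integer label for the independent simulation the
#'   trajectory came from (analyses pool several runs).
#' @return an object of class `"trajectory"`.
#' @export
trajectory <- function(top, xyz, times = NULL, run_id = 1L) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * n_atoms(top))
    stop("trajectory has ", ncol(xyz) / 3, " atoms per frame but the ",
         "topology has ", n_atoms(top), " (topology mismatch)")
  nf <- nrow(xyz)
  if (is.null(times)) times <- seq_len(nf) - 1
  if (length(times) != nf) stop("one time stamp per frame required")
  if (nf > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(topology = top, xyz = xyz, times = as.numeric(times),
                 run_id = as.integer(run_id)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory: run", x$run_id, "-", n_frames(x), "frames x",
      n_atoms(x$topology), "atoms,",
      sprintf("t = %g..%g ns\n", x$times[1], x$times[n_frames(x)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Extract one frame from a trajectory as an N x 3 matrix
#' @param traj a `trajectory`.
#' @param i frame index.
#' @export
get_frame <- function(traj, i) {
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range")
  frame(matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE), time = traj$times[i])
}

# Coerce a frame (N x 3) to the flat xyz vector and back.
flat_xyz <- function(coords) as.numeric(t(as.matrix(coords)))
unflat_xyz <- function(v) matrix(v, ncol = 3, byrow = TRUE)

# Accept either one trajectory or a list of them; always return a list.
as_traj_list <- function(trajs) {
  if (inherits(trajs, "trajectory")) return(list(trajs))
  if (!length(trajs) || !all(vapply(trajs, inherits, TRUE, "trajectory")))
    stop("expected a trajectory or a non-empty list of trajectories")
  trajs
}
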