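#' Read a PDB file into a topology and a frame
#'
#' Thin wrapper around [bio3d::read.pdb()] that builds the package's
#' `topology` container. Multi-model files yield the first model (the
#' remaining models are available through [read_trajectory()]).
#'
#' @param path PDB file.
#' @param chain optional chain filter (e.g. `"A"`).
#' @param water_resnames,ion_resnames residue-name whitelists for
#'   flagging waters and monoatomic ions.
#' @return list with elements `topology` and `frame`.
#' @export
read_pdb <- function(path, chain = NULL,
                     water_resnames = .WATER_RESNAMES,
                     ion_resnames = .ION_RESNAMES) {
  if (!file.exists(path)) stop("no such file: ", path)
  .validate_pdb_records(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  if (!is.null(chain)) {
    keep <- at$chain %in% chain
    if (!any(keep)) stop("no atoms on chain ", paste(chain, collapse = "/"))
    at <- at[keep, , drop = FALSE]
  }
  if (!nrow(at)) stop("no ATOM/HETATM records in ", path)
  atoms <- data.frame(serial = at$eleno,
                      name = at$elety,
                      element = .element_of(at$elesy, at$elety),
                      resno = at$resno,
                      resname = at$resid,
                      chain = at$chain,
                      stringsAsFactors = FALSE)
  top <- topology(atoms, water_resnames = water_resnames,
                  ion_resnames = ion_resnames)
  coords <- cbind(at$x, at$y, at$z)
  list(topology = top, frame = frame(coords, time = 0))
}

# Line-level sanity check so malformed records fail with the line number,
# which bio3d does not report.
.validate_pdb_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records in ", path)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed PDB record at line ", i, ": record too short")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz))
      stop("malformed PDB record at line ", i, ": bad coordinate field")
  }
  invisible(TRUE)
}

.element_of <- function(elesy, elety) {
  el <- toupper(trimws(elesy))
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    # fall back on the first alphabetic character of the atom name
    guess <- toupper(sub("^[0-9]*([A-Za-z]).*$", "\\1", elety[miss]))
    el[miss] <- guess
  }
  el
}

#' Write a topology + coordinates as PDB
#'
#' @param top a `topology`.
#' @param coords an `N x 3` frame, or an `nframes x 3N` xyz matrix /
#'   `trajectory` for multi-model output.
#' @param path output file.
#' @export
write_pdb <- function(top, coords, path) {
  if (inherits(coords, "trajectory")) coords <- coords$xyz
  xyz <- if (is.matrix(coords) && ncol(coords) == 3L * n_atoms(top))
    coords else matrix(flat_xyz(coords), nrow = 1)
  at <- top$atoms
  bio3d::write.pdb(file = path, xyz = xyz, resno = at$resno,
                   resid = at$resname, eleno = at$serial, elety = at$name,
                   chain = ifelse(is.na(at$chain), "A", at$chain),
                   elesy = at$element)
  invisible(path)
}

#' Read a trajectory (multi-model PDB or DCD)
#'
#' @param path trajectory file; format chosen from the extension
#'   (`.dcd` binary, anything else is treated as multi-model PDB).
#' @param top the matching `topology`.
#' @param times optional frame times (ns); if absent they are assigned
#'   from `stride` (default 1 frame unit).
#' @param stride time step between frames in ns when `times` is absent.
#' @param run_id run label.
#' @return a `trajectory`.
#' @export
read_trajectory <- function(path, top, times = NULL, stride = 1, run_id = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    xyz <- matrix(as.numeric(xyz), nrow = nrow(xyz))
  } else {
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  }
  if (ncol(xyz) != 3L * n_atoms(top))
    stop("trajectory frames have ", ncol(xyz) / 3, " atoms but the topology ",
         "has ", n_atoms(top), " (topology mismatch)")
  if (is.null(times)) times <- (seq_len(nrow(xyz)) - 1) * stride
  trajectory(top, xyz, times = times, run_id = run_id)
}

#' Write a trajectory as DCD or multi-model PDB
#'
#' Intended for round-trips and test fixtures only.
#'
#' @param traj a `trajectory`.
#' @param path output file; `.dcd` selects the binary CHARMM/NAMD DCD
#'   layout, anything else multi-model PDB.
#' @export
write_trajectory <- function(traj, path) {
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    .write_dcd(path, traj$xyz)
  } else {
    write_pdb(traj$topology, traj$xyz, path)
  }
  invisible(path)
}

# Minimal native-endian DCD writer (header + per-frame x/y/z records with
# Fortran record markers). bio3d::read.dcd reads it back.
.write_dcd <- function(path, xyz) {
  nf <- nrow(xyz); natom <- ncol(xyz) / 3L
  con <- file(path, "wb"); on.exit(close(con))
  rec <- function(writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4)
    writer()
    writeBin(as.integer(nbytes), con, size = 4)
  }
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[20] <- 24L
  rec(function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    writeBin(icntrl, con, size = 4)
  }, 84)
  title <- sprintf("%-80s", "glycomd trajectory")
  rec(function() {
    writeBin(1L, con, size = 4)
    writeChar(title, con, nchars = 80, eos = NULL)
  }, 84)
  rec(function() writeBin(as.integer(natom), con, size = 4), 4)
  xi <- seq(1, 3 * natom, by = 3)
  for (f in seq_len(nf)) {
    fr <- xyz[f, ]
    for (d in 0:2)
      local({
        vals <- fr[xi + d]
        rec(function() writeBin(as.numeric(vals), con, size = 4), 4 * natom)
      })
  }
  invisible(path)
}
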