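#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fit of `mobile` onto `reference` using the SVD form of
#' the Kabsch algorithm. The returned rotation is always proper
#' (determinant +1); reflections are never introduced.
#'
#' @param mobile,reference `N x 3` coordinate matrices, same N >= 3.
#' @param weights optional per-atom weights.
#' @return list of class `"superposition"`: `rotation` (3 x 3),
#'   `translation` (length-3), `rmsd` (A). The fitted coordinates are
#'   `mobile %*% t(rotation) + translation` (row-wise).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L)
    stop("mobile and reference must be N x 3 matrices of equal size")
  n <- nrow(mobile)
  if (n < 3L) stop("degenerate geometry: need at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  a <- sweep(mobile, 2, cm); b <- sweep(reference, 2, cr)
  if (.is_collinear(a) || .is_collinear(b))
    stop("degenerate geometry: points are collinear")
  h <- t(a * w) %*% b
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- a %*% t(rot)
  rmsd <- sqrt(sum(w * rowSums((fitted - b)^2)))
  structure(list(rotation = rot, translation = as.numeric(cr - rot %*% cm),
                 rmsd = rmsd),
            class = "superposition")
}

.is_collinear <- function(centered, tol = 1e-10) {
  s <- svd(centered, nu = 0, nv = 0)$d
  s[2] < tol * max(s[1], 1)
}

#' Apply a superposition to coordinates
#' @param coords `N x 3` matrix.
#' @param sup a `"superposition"`.
#' @export
apply_superposition <- function(coords, sup) {
  sweep(as.matrix(coords) %*% t(sup$rotation), 2, sup$translation, "+")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

# plain RMSD between two matched coordinate sets (no fitting)
coord_rmsd <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))

#' Positional RMSD series of a ligand in its binding site
#'
#' Each frame is superposed on the reference using `fit_selection`
#' (typically the receptor C-alpha atoms); the RMSD is then measured
#' over `measure_selection` (typically the ligand ring atoms) *without*
#' refitting, so the series reports where the ligand sits relative to
#' the binding site rather than its internal shape.
#'
#' @param traj a `trajectory`.
#' @param fit_selection,measure_selection group names or index vectors.
#' @param reference reference frame (`N x 3` for the full topology).
#' @return data.frame of class `"rmsd_series"` with columns `time`, `rmsd`.
#' @export
ligand_rmsd_series <- function(traj, fit_selection, measure_selection,
                               reference) {
  top <- traj$topology
  fit_idx <- atom_group(top, fit_selection)
  mea_idx <- atom_group(top, measure_selection)
  ref <- as.matrix(reference)
  if (nrow(ref) != n_atoms(top))
    stop("reference frame does not match the topology")
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    fr <- unflat_xyz(traj$xyz[i, ])
    sup <- kabsch_superpose(fr[fit_idx, , drop = FALSE],
                            ref[fit_idx, , drop = FALSE])
    moved <- apply_superposition(fr, sup)
    coord_rmsd(moved[mea_idx, , drop = FALSE], ref[mea_idx, , drop = FALSE])
  }, numeric(1))
  out <- data.frame(time = traj$times, rmsd = vals)
  attr(out, "run_id") <- traj$run_id
  class(out) <- c("rmsd_series", "data.frame")
  out
}

#' @export
plot.rmsd_series <- function(x, ...) {
  graphics::plot(x$time, x$rmsd, type = "l", xlab = "time (ns)",
                 ylab = "RMSD (A)", ...)
  invisible(x)
}

#' Pairwise (2D) RMSD matrix over sampled frames
#'
#' Samples frames at a fixed time stride from one or more runs, then
#' fills the symmetric matrix of selection RMSDs after pairwise
#' superposition. By default the superposition uses the measured
#' selection itself; note that this measures *internal* shape only --
#' any rigid displacement of the selection is removed by the fit. To
#' cluster ligand *placements* (distinct binding poses), pass a
#' `fit_selection` (typically the receptor C-alpha atoms): sample j is
#' then superposed on sample i over the fit atoms and the RMSD is
#' measured over `selection` without refitting.
#'
#' @param trajs a `trajectory` or list of them (pooled).
#' @param selection group name or atom indices measured.
#' @param stride_ns sampling stride in ns; NULL keeps every frame.
#' @param fit_selection optional group name or indices used for the
#'   pairwise superposition; default: `selection`.
#' @return symmetric matrix with zero diagonal; attribute `"samples"`
#'   is a data.frame (run, frame, time) describing the rows.
#' @export
pairwise_rmsd_matrix <- function(trajs, selection, stride_ns = NULL,
                                 fit_selection = NULL) {
  trajs <- as_traj_list(trajs)
  sel <- atom_group(trajs[[1]]$topology, selection)
  fit <- if (is.null(fit_selection)) sel
         else atom_group(trajs[[1]]$topology, fit_selection)
  samples <- list(); coords <- list(); fits <- list()
  for (tr in trajs) {
    keep <- if (is.null(stride_ns)) seq_len(n_frames(tr)) else {
      tt <- tr$times - tr$times[1]
      idx <- which(abs(tt / stride_ns - round(tt / stride_ns)) < 1e-9)
      if (!length(idx)) idx <- seq(1, n_frames(tr),
                                   by = max(1L, round(stride_ns / mean(diff(tr$times)))))
      idx
    }
    for (i in keep) {
      fr <- unflat_xyz(tr$xyz[i, ])
      coords[[length(coords) + 1L]] <- fr[sel, , drop = FALSE]
      fits[[length(fits) + 1L]] <- fr[fit, , drop = FALSE]
      samples[[length(samples) + 1L]] <-
        data.frame(run = tr$run_id, frame = i, time = tr$times[i])
    }
  }
  m <- length(coords)
  if (m < 2L) stop("insufficient frames: stride yields fewer than 2 samples")
  mat <- matrix(0, m, m)
  same_fit <- is.null(fit_selection)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    sup <- kabsch_superpose(fits[[j]], fits[[i]])
    r <- if (same_fit) sup$rmsd
         else coord_rmsd(apply_superposition(coords[[j]], sup), coords[[i]])
    mat[i, j] <- mat[j, i] <- r
  }
  attr(mat, "samples") <- do.call(rbind, samples)
  mat
}

#' Cluster ligand poses from a pairwise RMSD matrix
#'
#' Average-linkage agglomerative clustering cut at an RMSD height.
#' Poses are numbered by descending population; each pose's medoid is
#' the member minimising its summed RMSD to the rest of the cluster,
#' ties broken by lowest run id, then earliest time.
#'
#' @param mat symmetric RMSD matrix from [pairwise_rmsd_matrix()].
#' @param cutoff clustering cutoff (A); default 1.5.
#' @return object of class `"pose_assignment"`: `assignment` data.frame
#'   (run, frame, time, pose), `populations`, `medoids` data.frame.
#' @export
cluster_poses <- function(mat, cutoff = 1.5) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  m <- nrow(mat)
  samples <- attr(mat, "samples")
  if (is.null(samples))
    samples <- data.frame(run = 1L, frame = seq_len(m), time = seq_len(m) - 1)
  labels <- if (max(mat) == 0) rep(1L, m) else {
    hc <- stats::hclust(stats::as.dist(mat), method = "average")
    stats::cutree(hc, h = cutoff)
  }
  pop <- table(labels)
  # renumber by descending population; ties by first appearance
  ord <- order(-as.integer(pop), vapply(names(pop), function(l)
    min(which(labels == as.integer(l))), numeric(1)))
  relabel <- integer(length(pop)); relabel[as.integer(names(pop)[ord])] <- seq_along(ord)
  pose <- relabel[labels]
  populations <- as.numeric(table(pose)) / m
  medoids <- do.call(rbind, lapply(seq_along(populations), function(k) {
    members <- which(pose == k)
    score <- rowSums(mat[members, members, drop = FALSE])
    best <- members[order(score, samples$run[members],
                          samples$time[members])][1]
    cbind(samples[best, , drop = FALSE], pose = k)
  }))
  structure(list(assignment = cbind(samples, pose = pose),
                 populations = populations, medoids = medoids,
                 cutoff = cutoff),
            class = "pose_assignment")
}

#' @export
print.pose_assignment <- function(x, ...) {
  cat("pose assignment:", length(x$populations), "pose(s), cutoff",
      x$cutoff, "A\n")
  for (k in seq_along(x$populations))
    cat(sprintf("  pose %d: %.1f%% (medoid run %d, t = %g ns)\n", k,
                100 * x$populations[k], x$medoids$run[k], x$medoids$time[k]))
  invisible(x)
}

#' Representative frame of a trajectory collection
#'
#' Superposes every frame's selection onto the running mean structure
#' and returns the frame whose selection is closest (RMSD) to that mean
#' -- the conformation most similar to the average shape over all runs.
#' Ties are broken by lowest run id, then earliest time.
#'
#' @param trajs a `trajectory` or list of them.
#' @param selection group name or atom indices.
#' @param iterations mean-structure refinement passes.
#' @return list: `run_id`, `frame`, `time`, `coords` (full frame of the
#'   winning trajectory), `rmsd_to_mean`, and the per-sample RMSDs.
#' @export
representative_frame <- function(trajs, selection, iterations = 2L) {
  trajs <- as_traj_list(trajs)
  sel <- atom_group(trajs[[1]]$topology, selection)
  sets <- list(); meta <- list()
  for (tr in trajs) for (i in seq_len(n_frames(tr))) {
    sets[[length(sets) + 1L]] <- unflat_xyz(tr$xyz[i, ])[sel, , drop = FALSE]
    meta[[length(meta) + 1L]] <- data.frame(run = tr$run_id, frame = i,
                                            time = tr$times[i])
  }
  meta <- do.call(rbind, meta)
  if (!length(sets)) stop("empty trajectory set")
  if (length(sets) == 1L) {
    tr <- trajs[[1]]
    return(list(run_id = tr$run_id, frame = 1L, time = tr$times[1],
                coords = get_frame(tr, 1L), rmsd_to_mean = 0,
                rmsds = 0))
  }
  mean_coords <- sets[[1]]
  for (it in seq_len(iterations)) {
    fitted <- lapply(sets, function(s)
      apply_superposition(s, kabsch_superpose(s, mean_coords)))
    mean_coords <- Reduce(`+`, fitted) / length(fitted)
  }
  rmsds <- vapply(sets, function(s)
    kabsch_superpose(s, mean_coords)$rmsd, numeric(1))
  ord <- order(rmsds, meta$run, meta$time)
  best <- ord[1]
  tr <- trajs[[match(meta$run[best], vapply(trajs, `[[`, 0L, "run_id"))]]
  list(run_id = meta$run[best], frame = meta$frame[best],
       time = meta$time[best], coords = get_frame(tr, meta$frame[best]),
       rmsd_to_mean = rmsds[best], rmsds = rmsds)
}
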