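#' Quasiharmonic entropy from covariance eigenvalues
#'
#' Mass-weighted Cartesian covariance eigenvalues `lambda` (amu A^2)
#' define quasiharmonic frequencies `omega = sqrt(kB T / lambda)`;
#' each mode contributes the quantum harmonic-oscillator entropy
#' `S/kB = x/(e^x - 1) - ln(1 - e^-x)` with `x = hbar omega / (kB T)`.
#' The classical formula (`S/kB = 1 - ln x`) is available for
#' cross-checks.
#'
#' @param cov 3N x 3N covariance of Cartesian fluctuations (A^2), or a
#'   vector of mass-weighted eigenvalues (amu A^2) when `masses` is
#'   NULL.
#' @param masses per-atom masses (amu); each expands to 3 coordinates.
#' @param T temperature (K).
#' @param drop_modes number of smallest eigenvalues to discard (6 after
#'   a rigid-body superposition removed the external modes).
#' @param quantum use the quantum oscillator formula (default).
#' @return entropy in cal/(mol K), with attribute `"eigenvalues"`.
#' @export
qh_entropy_from_cov <- function(cov, masses = NULL, T = 300,
                                drop_modes = 0, quantum = TRUE) {
  if (is.matrix(cov)) {
    if (is.null(masses)) stop("masses required with a covariance matrix")
    m3 <- rep(masses, each = 3)
    if (length(m3) != ncol(cov)) stop("3 coordinates per atom expected")
    mw <- sqrt(m3)
    lambda <- eigen(t(cov * mw) * mw, symmetric = TRUE,
                    only.values = TRUE)$values
  } else lambda <- sort(as.numeric(cov), decreasing = TRUE)
  lambda <- sort(lambda, decreasing = TRUE)
  if (drop_modes > 0)
    lambda <- lambda[seq_len(max(0L, length(lambda) - drop_modes))]
  lambda <- lambda[lambda > 1e-12]
  if (!length(lambda)) return(structure(0, eigenvalues = numeric()))
  kT_si <- .KB_SI * T
  x <- .HBAR_SI / sqrt(kT_si * lambda * .AMU_SI * 1e-20)
  s_mode <- if (quantum) x / (exp(x) - 1) - log(1 - exp(-x))
            else 1 - log(x)
  structure(.R_CAL * sum(s_mode), eigenvalues = lambda)
}

#' Quasiharmonic entropy of a trajectory selection
#'
#' Frames are superposed on the selection's mean structure (removing
#' the six external modes, which are then dropped from the eigenvalue
#' spectrum), the mass-weighted covariance of the Cartesian
#' fluctuations is diagonalised, and the quantum harmonic-oscillator
#' entropy is summed over modes.
#'
#' @param traj a `trajectory`.
#' @param selection group name or atom indices.
#' @param masses per-atom masses for the selection (amu); taken from
#'   `params` when supplied.
#' @param T temperature (K).
#' @param params optional `"ff_params"` supplying masses.
#' @param fit superpose on the mean structure first (drop 6 external
#'   modes); disable only for synthetic closed-form checks.
#' @param frames optional frame subset (e.g. a time window).
#' @return entropy in cal/(mol K).
#' @export
quasiharmonic_entropy <- function(traj, selection, masses = NULL, T = 300,
                                  params = NULL, fit = TRUE, frames = NULL) {
  top <- traj$topology
  sel <- atom_group(top, selection)
  if (is.null(masses)) {
    if (is.null(params)) stop("supply masses or params")
    masses <- match_params(top, params, subset = sel)$mass[sel]
  }
  if (length(masses) != length(sel))
    stop("one mass per selected atom required")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  if (length(frames) < 10) stop("insufficient sampling: fewer than 10 frames")
  cols <- as.numeric(t(outer(sel, 1:3, function(i, d) 3 * (i - 1) + d)))
  X <- traj$xyz[frames, cols, drop = FALSE]
  if (fit) X <- .fit_to_mean(X)
  qh_entropy_from_cov(stats::cov(X), masses, T = T,
                      drop_modes = if (fit) 6L else 0L)
}

# iteratively superpose each frame (rows of X, flat xyz) on the mean
.fit_to_mean <- function(X, iterations = 2L) {
  ref <- unflat_xyz(X[1, ])
  for (it in seq_len(iterations)) {
    for (i in seq_len(nrow(X))) {
      fr <- unflat_xyz(X[i, ])
      X[i, ] <- flat_xyz(apply_superposition(fr, kabsch_superpose(fr, ref)))
    }
    ref <- unflat_xyz(colMeans(X))
  }
  X
}

#' Quasiharmonic entropy over a 1/t window schedule
#'
#' Computes the QH entropy on cumulative windows whose end points are
#' evenly spaced in inverse time between `T_total / n_windows` and
#' `T_total`, the input for the infinite-sampling extrapolation.
#'
#' @inheritParams quasiharmonic_entropy
#' @param n_windows number of cumulative windows.
#' @return data.frame of class `"entropy_series"`: `t_end` (ns),
#'   `inv_t`, `entropy` (cal/(mol K)).
#' @export
entropy_series <- function(traj, selection, masses = NULL, T = 300,
                           params = NULL, n_windows = 10, fit = TRUE) {
  t0 <- traj$times[1]
  t_total <- traj$times[n_frames(traj)] - t0
  inv <- seq(n_windows / t_total, 1 / t_total, length.out = n_windows)
  out <- data.frame(t_end = 1 / inv, inv_t = inv, entropy = NA_real_)
  for (k in seq_len(n_windows)) {
    frames <- which(traj$times - t0 <= out$t_end[k] + 1e-9)
    out$entropy[k] <- quasiharmonic_entropy(traj, selection, masses, T,
                                            params, fit, frames)
  }
  class(out) <- c("entropy_series", "data.frame")
  out
}

#' Extrapolate a quasiharmonic entropy series to infinite sampling
#'
#' Ordinary least squares of S against 1/t; the intercept is the
#' infinite-simulation-time estimate.
#'
#' @param series an `"entropy_series"` (or any data.frame with columns
#'   `inv_t` and `entropy`).
#' @return list: `intercept` (cal/(mol K)), `slope`, `r_squared`, `fit`.
#' @export
extrapolate_entropy <- function(series) {
  if (nrow(series) < 3) stop("need at least 3 windows for the fit")
  fit <- stats::lm(entropy ~ inv_t, data = series)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       r_squared = summary(fit)$r.squared,
       fit = fit)
}

#' Karplus-Kushick torsional entropy change on binding
#'
#' Each torsion is unwrapped about its circular mean; the entropy of an
#' ensemble is `S = (kB/2) ln[(2 pi e)^n det(Sigma)]` with `Sigma` the
#' covariance of the unwrapped angles in radians. Returns the binding
#' penalty `-T (S_bound - S_free)` in kcal/mol.
#'
#' @param bound,free sample matrices (rows = samples, columns = named
#'   torsions in degrees), e.g. from [gen_torsion_ensemble()] or
#'   [glycosidic_torsion_series()].
#' @param T temperature (K).
#' @return `-T dS_conf` in kcal/mol, with attribute `"dS"` in
#'   cal/(mol K).
#' @export
torsional_entropy_kk <- function(bound, free, T = 300) {
  bound <- as.matrix(bound); free <- as.matrix(free)
  if (!is.null(colnames(bound)) && !is.null(colnames(free))) {
    if (!setequal(colnames(bound), colnames(free)))
      stop("bound and free ensembles must share torsion names")
    free <- free[, colnames(bound), drop = FALSE]
  } else if (ncol(bound) != ncol(free))
    stop("bound and free ensembles must share torsions")
  s_b <- .kk_entropy(bound)
  s_f <- .kk_entropy(free)
  structure(-T * (s_b - s_f) / 1000, dS = s_b - s_f)
}

.kk_entropy <- function(ang) {
  n <- ncol(ang)
  rad <- apply(ang, 2, function(col) {
    mu <- atan2(mean(sin(col * pi / 180)), mean(cos(col * pi / 180)))
    rbar <- sqrt(mean(sin(col * pi / 180))^2 + mean(cos(col * pi / 180))^2)
    if (rbar < 0.7)
      warning("torsion distribution looks broad or multimodal; ",
              "the Karplus-Kushick Gaussian assumption may be poor")
    d <- (col * pi / 180 - mu + pi) %% (2 * pi) - pi
    d
  })
  sig <- stats::cov(rad)
  dt <- det(sig)
  if (!is.finite(dt) || dt <= 0) {
    vars <- diag(sig)
    worst <- colnames(ang)[which.min(vars)]
    stop("degenerate torsion ensemble (singular covariance); ",
         "offending torsion: ", if (is.null(worst)) which.min(vars) else worst)
  }
  0.5 * .R_CAL * (n * log(2 * pi * exp(1)) + log(dt))
}

#' Assemble the entropy block of a binding report
#'
#' Combines per-run quasiharmonic intercepts of complex, receptor and
#' ligand into the rigid-body + vibrational penalty
#' `-T dS_RTV = -T (S_complex - S_receptor - S_ligand)` and adds the
#' torsional (conformational) penalty `-T dS_conf`.
#'
#' @param S_complex,S_receptor,S_ligand per-run QH entropy intercepts,
#'   cal/(mol K).
#' @param minus_TdS_conf the Karplus-Kushick penalty (kcal/mol; scalar
#'   or per-run).
#' @param T temperature (K).
#' @return an [entropy_estimate()].
#' @export
assemble_entropy <- function(S_complex, S_receptor, S_ligand,
                             minus_TdS_conf, T = 300) {
  nr <- length(S_complex)
  if (length(S_receptor) != nr || length(S_ligand) != nr)
    stop("per-run entropies of complex, receptor and ligand required")
  rtv <- -T * (S_complex - S_receptor - S_ligand) / 1000
  entropy_estimate(rtv, minus_TdS_conf, T = T)
}

#' Entropy estimate (-T dS terms in kcal/mol)
#'
#' Holds the rigid-body/vibrational and conformational entropy
#' penalties and their total, `-T dS = -T dS_RTV + (-T dS_conf)`,
#' with cross-run mean and SD when per-run values are supplied.
#'
#' @param minus_TdS_rtv per-run (or mean) `-T dS_RTV`, kcal/mol.
#' @param minus_TdS_conf per-run (or mean) `-T dS_conf`, kcal/mol.
#' @param T temperature (K).
#' @export
entropy_estimate <- function(minus_TdS_rtv, minus_TdS_conf, T = 300) {
  nr <- max(length(minus_TdS_rtv), length(minus_TdS_conf))
  rtv <- rep_len(minus_TdS_rtv, nr)
  conf <- rep_len(minus_TdS_conf, nr)
  tot <- rtv + conf
  structure(list(minus_TdS_rtv = mean(rtv), minus_TdS_conf = mean(conf),
                 total = mean(tot),
                 sd = if (nr > 1) stats::sd(tot) else NA_real_,
                 per_run = data.frame(run = seq_len(nr), rtv = rtv,
                                      conf = conf, total = tot),
                 T = T),
            class = "entropy_estimate")
}

#' @export
print.entropy_estimate <- function(x, ...) {
  cat(sprintf("-TdS_RTV  = %6.2f kcal/mol\n", x$minus_TdS_rtv))
  cat(sprintf("-TdS_conf = %6.2f kcal/mol\n", x$minus_TdS_conf))
  cat(sprintf("-TdS      = %6.2f%s kcal/mol (T = %g K)\n", x$total,
              if (is.na(x$sd)) "" else sprintf(" +/- %.2f", x$sd), x$T))
  invisible(x)
}
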