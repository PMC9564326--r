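#' Run the full analysis pipeline
#'
#' Drives the pose, torsion/strain, hydrogen-bond, energy, entropy and
#' report stages over one or more trajectory runs of a complex, writing
#' one CSV per stage plus a JSON summary into `outdir`. Stage failures
#' are logged, dependent downstream stages are skipped, and the result
#' carries a nonzero `status`. When any run's ligand RMSD exceeds the
#' configured escape threshold, the energy/entropy/report stages are
#' withheld with the flag `"unstable ligand -- energies not reported"`.
#'
#' Reruns with the same input, config and seed produce byte-identical
#' outputs.
#'
#' @param input a `"toy_complex"` from [gen_toy_complex()], a list of
#'   them (one per run), or a list with elements `trajectories` (list
#'   of `trajectory`), `params` (`"ff_params"`), `reference` (frame or
#'   `N x 3` matrix), and optionally `partition` (named list of ligand
#'   group names for the decomposition).
#' @param config an [analysis_config()].
#' @param outdir output directory (created if missing).
#' @param seed RNG seed recorded and set before stochastic stages.
#' @param stages character subset of
#'   `c("poses", "torsions", "hbonds", "energy", "entropy", "report")`.
#' @param chi_curves optional `"chi_registry"` for linkage strain.
#' @param free_torsions optional free-ligand torsion ensemble (matrix,
#'   degrees) for the Karplus-Kushick conformational term; without it
#'   the conformational penalty is reported as 0 with a note.
#' @param label complex label used in the report.
#' @return list of class `"pipeline_result"`: `status` (0 = success),
#'   `stages` (per-stage status/message), `outputs` (file paths),
#'   `unstable` flag, and the in-memory results of each stage.
#' @export
run_pipeline <- function(input, config = analysis_config(), outdir,
                         seed = config$seed,
                         stages = c("poses", "torsions", "hbonds",
                                    "energy", "entropy", "report"),
                         chi_curves = NULL, free_torsions = NULL,
                         label = "complex") {
  inp <- .pipeline_input(input)
  trajs <- inp$trajectories
  params <- inp$params
  top <- trajs[[1]]$topology
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  set.seed(seed)

  res <- list(status = 0L, stages = list(), outputs = character(),
              unstable = FALSE, label = label, seed = seed)
  log <- character()
  note <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    message(msg)
  }
  emit <- function(name, df) {
    path <- file.path(outdir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    res$outputs <<- c(res$outputs, path)
  }
  run_stage <- function(name, enabled, deps_ok, fun) {
    if (!(name %in% stages)) {
      res$stages[[name]] <<- list(status = "disabled", message = "")
      return(NULL)
    }
    if (!enabled || !deps_ok) {
      msg <- if (!enabled) attr(enabled, "why") %||% "withheld"
             else "skipped: upstream stage failed"
      note("stage ", name, ": ", msg)
      res$stages[[name]] <<- list(status = "skipped", message = msg)
      return(NULL)
    }
    out <- tryCatch(fun(), error = function(e) {
      note("stage ", name, " FAILED: ", conditionMessage(e))
      res$stages[[name]] <<- list(status = "failed",
                                  message = conditionMessage(e))
      res$status <<- 1L
      NULL
    })
    if (!is.null(out))
      res$stages[[name]] <<- list(status = "ok", message = "")
    out
  }
  ok <- function(name) {
    s <- res$stages[[name]]
    !is.null(s) && s$status == "ok"
  }

  # ---- poses: RMSD series, instability gate, clustering, medoid -----
  poses <- run_stage("poses", TRUE, TRUE, function() {
    series <- lapply(trajs, function(tr)
      ligand_rmsd_series(tr, "receptor_ca", "ring_atoms", inp$reference))
    long <- do.call(rbind, lapply(seq_along(series), function(k)
      cbind(run = trajs[[k]]$run_id, series[[k]])))
    emit("rmsd_series", long)
    stride <- config$pose_stride_ns
    nsamp <- sum(vapply(trajs, function(tr) {
      tt <- tr$times - tr$times[1]
      sum(abs(tt / stride - round(tt / stride)) < 1e-9)
    }, numeric(1)))
    # keep the matrix tractable: coarsen the stride past 400 samples
    while (nsamp > 400) { stride <- stride * 2; nsamp <- ceiling(nsamp / 2) }
    mat <- pairwise_rmsd_matrix(trajs, "ring_atoms", stride_ns = stride,
                                fit_selection = "receptor")
    cl <- cluster_poses(mat, cutoff = config$rmsd_cutoff)
    emit("poses", cl$assignment)
    emit("pose_populations",
         data.frame(pose = seq_along(cl$populations),
                    population = cl$populations,
                    medoid_run = cl$medoids$run,
                    medoid_time = cl$medoids$time))
    rep_fr <- representative_frame(trajs, "ring_atoms")
    pdb_path <- file.path(outdir, "representative.pdb")
    write_pdb(top, rep_fr$coords, pdb_path)
    res$outputs <<- c(res$outputs, pdb_path)
    list(rmsd = series, clusters = cl, representative = rep_fr)
  })
  if (ok("poses")) {
    mx <- max(vapply(poses$rmsd, function(s) max(s$rmsd), numeric(1)))
    if (mx > config$escape_threshold) {
      res$unstable <- TRUE
      note("unstable ligand -- energies not reported (max ligand RMSD ",
           sprintf("%.1f", mx), " A > ", config$escape_threshold, " A)")
    }
  }
  stable <- structure(!res$unstable,
                      why = "unstable ligand -- energies not reported")

  # ---- torsions / linkage strain -----------------------------------
  torsions <- run_stage("torsions", TRUE, TRUE, function() {
    links <- assign_glycosidic_linkages(top)
    if (!nrow(links)) {
      note("stage torsions: no glycosidic linkages found")
      return(list(linkages = links, series = NULL, chi = NULL))
    }
    ser <- lapply(trajs, glycosidic_torsion_series, linkages = links)
    long <- do.call(rbind, lapply(seq_along(ser), function(k)
      cbind(run = trajs[[k]]$run_id, as.data.frame(ser[[k]]))))
    emit("torsions", long)
    chi <- NULL
    if (!is.null(chi_curves)) {
      chi <- lapply(trajs, total_chi_series, linkages = links,
                    curves = chi_curves)
      emit("chi_energy", do.call(rbind, lapply(seq_along(chi), function(k)
        cbind(run = trajs[[k]]$run_id, chi[[k]]))))
    }
    list(linkages = links, series = ser, chi = chi)
  })

  # ---- hydrogen bonds (and ion coordination when an ion exists) ----
  hbonds <- run_stage("hbonds", TRUE, TRUE, function() {
    crit <- hbond_criteria(config$hbond_distance, config$hbond_angle,
                           config$stable_occupancy)
    occ <- hbond_occupancy(trajs, crit, "receptor", "ligand")
    emit("hbonds", as.data.frame(occ))
    occ
  })

  # ---- energetics (gated on ligand stability) ----------------------
  energy <- run_stage("energy", stable, TRUE, function() {
    nsnap <- min(config$n_snapshots,
                 min(vapply(trajs, n_frames, numeric(1))))
    mm <- mmgbsa_interaction(trajs, params, n_snapshots = nsnap)
    emit("energy", mm$per_run)
    dec <- NULL
    if (!is.null(inp$partition)) {
      dec <- per_group_decomposition(trajs, params,
                                     partition = inp$partition,
                                     n_snapshots = nsnap)
      emit("energy_pergroup", as.data.frame(dec))
    }
    list(mmgbsa = mm, per_group = dec)
  })

  # ---- entropy (gated on ligand stability) -------------------------
  entropy <- run_stage("entropy", stable, TRUE, function() {
    sel <- list(complex = sort(c(atom_group(top, "receptor"),
                                 atom_group(top, "ligand"))),
                receptor = atom_group(top, "receptor"),
                ligand = atom_group(top, "ligand"))
    intercepts <- sapply(names(sel), function(nm) {
      vapply(trajs, function(tr) {
        ser <- entropy_series(tr, sel[[nm]], params = params,
                              T = params$global$temperature,
                              n_windows = config$entropy_windows)
        extrapolate_entropy(ser)$intercept
      }, numeric(1))
    })
    intercepts <- matrix(intercepts, nrow = length(trajs),
                         dimnames = list(NULL, names(sel)))
    conf <- 0
    if (!is.null(free_torsions) && ok("torsions") &&
        !is.null(torsions$series)) {
      bound <- do.call(rbind, lapply(torsions$series, function(s)
        as.matrix(s[, setdiff(names(s), "time"), drop = FALSE])))
      conf <- torsional_entropy_kk(bound, free_torsions,
                                   T = params$global$temperature)
    } else if (is.null(free_torsions)) {
      note("stage entropy: no free-ligand ensemble supplied; ",
           "conformational term reported as 0")
    }
    est <- assemble_entropy(intercepts[, "complex"],
                            intercepts[, "receptor"],
                            intercepts[, "ligand"],
                            minus_TdS_conf = as.numeric(conf),
                            T = params$global$temperature)
    emit("entropy", cbind(est$per_run,
                          S_complex = intercepts[, "complex"],
                          S_receptor = intercepts[, "receptor"],
                          S_ligand = intercepts[, "ligand"]))
    est
  })

  # ---- report ------------------------------------------------------
  report <- run_stage("report", stable, ok("energy") && ok("entropy"),
                      function() {
    rep <- assemble_binding(energy$mmgbsa, entropy, label = label,
                            per_group = energy$per_group)
    emit("report", data.frame(
      label = label,
      dG_mmgbsa = rep$dG_mmgbsa, dG_mmgbsa_sd = rep$dG_mmgbsa_sd,
      minus_TdS = rep$minus_TdS, minus_TdS_sd = rep$minus_TdS_sd,
      dG_binding = rep$dG_binding, dG_binding_sd = rep$dG_binding_sd))
    rep
  })

  # ---- summary -----------------------------------------------------
  cfg_path <- file.path(outdir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  summary <- list(
    label = label, seed = seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    n_runs = length(trajs),
    n_frames = vapply(trajs, n_frames, numeric(1)),
    unstable = res$unstable,
    stages = lapply(res$stages, function(s) s$status),
    log = log)
  if (!is.null(report)) {
    summary$dG_mmgbsa <- report$dG_mmgbsa
    summary$minus_TdS <- report$minus_TdS
    summary$dG_binding <- report$dG_binding
  }
  if (ok("poses"))
    summary$pose_populations <- poses$clusters$populations
  sum_path <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary, sum_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  res$outputs <- c(res$outputs, cfg_path, sum_path)
  res$poses <- poses; res$torsions <- torsions; res$hbonds <- hbonds
  res$energy <- energy; res$entropy <- entropy; res$report <- report
  res$log <- log
  class(res) <- "pipeline_result"
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# normalise pipeline input shapes
.pipeline_input <- function(input) {
  default_partition <- function(top) {
    cand <- c("Neu5Ac", "Gal", "GlcNAc", "Fuc", "SO3")
    have <- intersect(cand, names(top$groups))
    if (length(have)) top$groups[have] else NULL
  }
  if (inherits(input, "toy_complex"))
    input <- list(input)
  if (is.list(input) && length(input) &&
      all(vapply(input, inherits, logical(1), what = "toy_complex"))) {
    trajs <- lapply(input, `[[`, "trajectory")
    return(list(trajectories = trajs, params = input[[1]]$params,
                reference = unclass(as.matrix(input[[1]]$reference)),
                partition = default_partition(trajs[[1]]$topology)))
  }
  if (!is.list(input) || is.null(input$trajectories) ||
      is.null(input$params) || is.null(input$reference))
    stop("input must be a toy complex (or list of them) or a list with ",
         "trajectories, params and reference")
  ref <- unclass(as.matrix(input$reference))
  part <- input$partition
  if (is.null(part))
    part <- default_partition(input$trajectories[[1]]$topology)
  list(trajectories = input$trajectories, params = input$params,
       reference = ref, partition = part)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline for", x$label, "-- status", x$status,
      if (x$unstable) "(unstable ligand -- energies not reported)" else "",
      "\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-8s %s %s\n", nm, x$stages[[nm]]$status,
                x$stages[[nm]]$message))
  invisible(x)
}
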