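#' Assemble a binding free energy
#'
#' `dG_binding = dG_MM/GBSA + (-T dS)`; SDs are propagated in
#' quadrature across runs when both are available.
#'
#' @param dG_mmgbsa mean MM-GBSA interaction energy (kcal/mol), or an
#'   `"energy_components"` object.
#' @param entropy an [entropy_estimate()] (or a bare `-T dS` total in
#'   kcal/mol).
#' @param label complex label carried into the report.
#' @param dG_sd,per_group optional SD of the MM-GBSA mean and a
#'   `"pergroup_table"` for percent annotation.
#' @return list of class `"binding_report"`: `label`, `dG_mmgbsa` (+
#'   `dG_mmgbsa_sd`), `minus_TdS` (+ `minus_TdS_sd`), `dG_binding`,
#'   `dG_binding_sd` (quadrature), `per_group` (with percents, when
#'   supplied).
#' @export
assemble_binding <- function(dG_mmgbsa, entropy, label = "complex",
                             dG_sd = NA_real_, per_group = NULL) {
  if (inherits(dG_mmgbsa, "energy_components")) {
    dG_sd <- dG_mmgbsa$sd
    dG_mmgbsa <- unname(dG_mmgbsa$mean["total"])
  }
  if (inherits(entropy, "entropy_estimate")) {
    tds <- entropy$total
    tds_sd <- entropy$sd
  } else {
    tds <- as.numeric(entropy)
    tds_sd <- NA_real_
  }
  if (!is.finite(dG_mmgbsa) || !is.finite(tds))
    stop("assembly error: non-finite energy or entropy component")
  dG <- dG_mmgbsa + tds
  quad <- if (is.finite(dG_sd) && is.finite(tds_sd))
    sqrt(dG_sd^2 + tds_sd^2) else NA_real_
  pg <- if (!is.null(per_group)) percent_contributions(per_group) else NULL
  structure(list(label = label,
                 dG_mmgbsa = dG_mmgbsa, dG_mmgbsa_sd = dG_sd,
                 minus_TdS = tds, minus_TdS_sd = tds_sd,
                 dG_binding = dG, dG_binding_sd = quad,
                 per_group = pg),
            class = "binding_report")
}

#' @export
print.binding_report <- function(x, ...) {
  pm <- function(m, s) if (is.finite(s)) sprintf("%.1f +/- %.1f", m, s)
                       else sprintf("%.1f", m)
  cat(x$label, "\n", sep = "")
  cat("  dG_MM/GBSA :", pm(x$dG_mmgbsa, x$dG_mmgbsa_sd), "kcal/mol\n")
  cat("  -TdS       :", pm(x$minus_TdS, x$minus_TdS_sd), "kcal/mol\n")
  cat("  dG_binding :", pm(x$dG_binding, x$dG_binding_sd), "kcal/mol\n")
  if (!is.null(x$per_group)) {
    cat("  per-group contributions:\n")
    val <- x$per_group[[intersect(c("energy", "total"),
                                  names(x$per_group))[1]]]
    for (i in seq_len(nrow(x$per_group)))
      cat(sprintf("    %-8s %6.1f kcal/mol (%s)\n", x$per_group$group[i],
                  val[i], x$per_group$percent[i]))
  }
  invisible(x)
}

#' Percent-of-binding annotation for a per-group table
#'
#' `percent = 100 * group_total / overall_total`, rounded
#' half-away-from-zero to integers; magnitudes below 1% are rendered
#' `"<1%"`.
#'
#' @param table a `"pergroup_table"` from [per_group_decomposition()],
#'   or any data.frame with columns `group` and `total`.
#' @param total overall total (kcal/mol); defaults to the table's
#'   `"total"` attribute, else the column sum.
#' @return the table with a character `percent` column appended.
#' @export
percent_contributions <- function(table, total = NULL) {
  out <- as.data.frame(table)
  col <- intersect(c("energy", "total"), names(out))[1]
  if (is.na(col)) stop("table needs an 'energy' (or 'total') column")
  if (is.null(total)) total <- attr(table, "total")
  if (is.null(total)) total <- sum(out[[col]])
  if (!is.finite(total) || total == 0)
    stop("undefined percentage: zero total energy")
  out$percent <- .format_percent(100 * out[[col]] / total)
  attr(out, "total") <- total
  out
}

#' Mean and sample SD over independent runs
#'
#' @param values per-run numbers (>= 1).
#' @return list: `mean`, `sd` (NA for a single value), `n`.
#' @export
mean_over_runs <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("no values supplied")
  list(mean = mean(values),
       sd = if (length(values) >= 2) stats::sd(values) else NA_real_,
       n = length(values))
}

#' Two-sample comparison of binding energies across complexes
#'
#' Pooled-variance two-sample t test by default (Welch available).
#' Accepts either raw per-run vectors or summary statistics
#' (`list(mean =, sd =, n =)`) on each side.
#'
#' @param A,B per-run values, or summary lists with `mean`, `sd`, `n`.
#' @param labels length-2 character labels.
#' @param var_equal pooled-variance test (default); `FALSE` for Welch.
#' @return list of class `"comparison_report"`: `labels`, `mean_A`,
#'   `mean_B`, `ddG` (= mean_A - mean_B), `t`, `df`, `p_value`.
#' @export
compare_complexes <- function(A, B, labels = c("A", "B"),
                              var_equal = TRUE) {
  st <- function(x, side) {
    if (is.list(x)) {
      if (!all(c("mean", "sd", "n") %in% names(x)))
        stop("summary entry mode needs mean, sd and n")
      x
    } else {
      x <- as.numeric(x)
      if (length(x) < 2)
        stop("insufficient replicates on side ", side, " (need n >= 2)")
      list(mean = mean(x), sd = stats::sd(x), n = length(x))
    }
  }
  a <- st(A, labels[1]); b <- st(B, labels[2])
  if (a$n < 2 || b$n < 2) stop("insufficient replicates (need n >= 2)")
  va <- a$sd^2; vb <- b$sd^2
  if (var_equal) {
    sp2 <- ((a$n - 1) * va + (b$n - 1) * vb) / (a$n + b$n - 2)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  } else {
    se <- sqrt(va / a$n + vb / b$n)
    df <- (va / a$n + vb / b$n)^2 /
      ((va / a$n)^2 / (a$n - 1) + (vb / b$n)^2 / (b$n - 1))
  }
  tstat <- if (se == 0) 0 else (a$mean - b$mean) / se
  p <- if (se == 0) 1 else 2 * stats::pt(-abs(tstat), df)
  structure(list(labels = labels, mean_A = a$mean, mean_B = b$mean,
                 ddG = a$mean - b$mean, t = tstat, df = df,
                 p_value = p, var_equal = var_equal),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("%s vs %s: ddG = %.1f kcal/mol\n", x$labels[1], x$labels[2],
              x$ddG))
  cat(sprintf("  %s t = %.4f, df = %.4g, two-tailed P = %.4f\n",
              if (x$var_equal) "pooled" else "Welch",
              x$t, x$df, x$p_value))
  invisible(x)
}

# one-decimal presentation rounding (half away from zero), used for
# report text; machine-readable outputs keep full precision
.round1 <- function(x) sign(x) * floor(abs(x) * 10 + 0.5) / 10
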